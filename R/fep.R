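#' Construct a flat-bottom restraint
#'
#' @param lower,upper Bounds of the zero region in Angstrom.
#' @param forceConstant Harmonic force constant outside the bounds,
#'   kcal/(mol A^2).
#' @return A [RestraintSpec-class].
#' @export
restraintSpec <- function(lower, upper, forceConstant) {
  new("RestraintSpec", lower = lower, upper = upper,
      forceConstant = forceConstant)
}

#' Flat-bottom restraint energy
#'
#' Zero inside `[lower, upper]`, half-harmonic outside; continuous and once
#' differentiable at the bounds.
#'
#' @param distance Distance(s) in Angstrom, >= 0.
#' @param spec A [RestraintSpec-class].
#' @return Energies in kcal/mol.
#' @examples
#' sp <- restraintSpec(2.5, 6.5, 10)
#' flatBottomEnergy(c(2.5, 4, 7.5), sp)   # 0, 0, 5
#' @export
flatBottomEnergy <- function(distance, spec) {
  stopifnot(is(spec, "RestraintSpec"), all(distance >= 0))
  below <- pmin(distance - spec@lower, 0)
  above <- pmax(distance - spec@upper, 0)
  0.5 * spec@forceConstant * (below^2 + above^2)
}

#' Construct a PerturbationSeries
#'
#' @param deltaU Samples of U_target - U_reference in kcal/mol, evaluated on
#'   reference-ensemble frames.
#' @param temperature Temperature in K.
#' @return A [PerturbationSeries-class].
#' @export
perturbationSeries <- function(deltaU, temperature = 300) {
  new("PerturbationSeries", deltaU = as.numeric(deltaU),
      temperature = temperature)
}

#' Free-energy perturbation (exponential averaging)
#'
#' The Zwanzig estimator dF = -kT log < exp(-dU/kT) > over reference-ensemble
#' frames, evaluated with log-sum-exp for overflow safety. The standard error
#' comes from a circular block bootstrap with block length 2 tau_int (in
#' samples); tau_int is estimated from the dU series itself unless a block
#' length is supplied. By Jensen's inequality the estimate always satisfies
#' the Gibbs-Bogoliubov bound dF <= mean(dU).
#'
#' @param series A [PerturbationSeries-class].
#' @param blockLength Bootstrap block length in samples; default NULL
#'   estimates 2 tau_int from the series.
#' @param nBoot Number of bootstrap replicates (default 200).
#' @return List with `deltaF` (kcal/mol), `se`, `n`, and `blockLength`.
#' @export
fepDeltaF <- function(series, blockLength = NULL, nBoot = 200) {
  stopifnot(is(series, "PerturbationSeries"))
  dU <- series@deltaU
  kT <- thermalEnergy(series@temperature)
  n <- length(dU)
  est <- function(x) -kT * (.logSumExp(-x / kT) - log(length(x)))
  dF <- est(dU)
  if (!is.finite(dF)) stop("FEP estimate is not finite")
  se <- NA_real_
  if (n >= 2) {
    if (is.null(blockLength)) {
      blockLength <- 1L
      if (var(dU) > 0 && n >= 10) {
        C <- autocorrelation(dU, maxLag = min(n - 1, 200))
        cross <- which(C <= 0)[1]
        upto <- if (is.na(cross)) length(C) else cross - 1
        tauSamples <- 0.5 + sum(C[2:max(2, upto)])
        blockLength <- max(1L, as.integer(round(2 * tauSamples)))
      }
    }
    blockLength <- min(blockLength, n)
    nBlocks <- ceiling(n / blockLength)
    reps <- vapply(seq_len(nBoot), function(r) {
      starts <- sample.int(n, nBlocks, replace = TRUE)
      idx <- as.vector(outer(0:(blockLength - 1), starts, `+`)) %% n + 1
      est(dU[idx[seq_len(n)]])
    }, numeric(1))
    se <- sd(reps)
  }
  list(deltaF = dF, se = se, n = n, blockLength = blockLength)
}

#' Forward/backward FEP consistency (hysteresis)
#'
#' Removing then re-adding the same restraint satisfies
#' dF_forward = -dF_backward only in the infinite-sampling limit; the
#' hysteresis dF_forward + dF_backward is a practical convergence check.
#'
#' @param forward,backward [PerturbationSeries-class] objects for the two
#'   directions.
#' @param ... Passed to [fepDeltaF()].
#' @return List with `forward`, `backward` (each the [fepDeltaF()] result)
#'   and `hysteresis` (kcal/mol).
#' @export
fepHysteresis <- function(forward, backward, ...) {
  f <- fepDeltaF(forward, ...)
  b <- fepDeltaF(backward, ...)
  list(forward = f, backward = b, hysteresis = f$deltaF + b$deltaF)
}

#' Apply per-window FEP corrections to a profile
#'
#' Restraint-release corrections are computed separately for each umbrella
#' window; the corrected profile is F(xi_i) + dF(xi_i), re-referenced to a
#' zero minimum. Corrections are supplied at window centers and carried onto
#' the profile grid by linear interpolation (clamped at the ends of the
#' sampled range).
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param windowCenters Window centers in degrees.
#' @param corrections dF per window in kcal/mol (same length).
#' @return A corrected [FreeEnergyProfile-class].
#' @export
applyFEPCorrection <- function(profile, windowCenters, corrections) {
  stopifnot(is(profile, "FreeEnergyProfile"),
            length(windowCenters) == length(corrections))
  x <- binCenters(profile)
  corr <- approx(windowCenters, corrections, xout = x, rule = 2)$y
  Fv <- profileValues(profile) + corr
  Fv <- Fv - min(Fv[profile@occupancy > 0], na.rm = TRUE)
  new("FreeEnergyProfile", binCenters = x, values = Fv,
      occupancy = profile@occupancy, period = profile@period,
      temperature = profile@temperature)
}
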