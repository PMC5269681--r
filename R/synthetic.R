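#' Class "SimulationSpec": overdamped Langevin propagation settings
#'
#' @slot dt Timestep in ps.
#' @slot steps Total number of steps.
#' @slot stride Store every `stride`-th position.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(dt = "numeric", steps = "numeric", stride = "integer"),
  prototype(dt = 0.01, steps = 1e6, stride = 10L)
)

setValidity("SimulationSpec", function(object) {
  if (object@dt <= 0) return("dt must be positive")
  if (object@steps < 1) return("steps must be >= 1")
  if (object@stride < 1) return("stride must be >= 1")
  if (object@steps < object@stride) return("steps must be >= stride")
  TRUE
})

#' Construct a SimulationSpec
#'
#' Defaults emulate one 10 ns data-gathering window: 1e6 steps of 0.01 ps,
#' storing every 10th position (1e5 samples at 0.1 ps).
#'
#' @param dt Timestep in ps.
#' @param steps Number of steps.
#' @param stride Storage stride.
#' @return A [SimulationSpec-class].
#' @export
simulationSpec <- function(dt = 0.01, steps = 1e6, stride = 10) {
  new("SimulationSpec", dt = dt, steps = steps, stride = as.integer(stride))
}

# Fourier evaluation helpers for ModelSystem (x in radians)
.fourierEval <- function(x, cosC, sinC, const) {
  v <- rep(const, length(x))
  for (k in seq_along(cosC))
    v <- v + cosC[k] * cos(k * x) + sinC[k] * sin(k * x)
  v
}

#' Model PMF in kcal/mol
#'
#' @param model A [ModelSystem-class].
#' @param xiDeg Positions in degrees.
#' @return F(xi) in kcal/mol (not re-referenced).
#' @export
modelPMF <- function(model, xiDeg) {
  stopifnot(is(model, "ModelSystem"))
  .fourierEval(.deg2rad(xiDeg), model@fourierCos, model@fourierSin,
               model@offset)
}

#' Model diffusivity in rad^2/ps
#'
#' @param model A [ModelSystem-class].
#' @param xiDeg Positions in degrees.
#' @return D(xi) in rad^2/ps.
#' @export
modelDiffusivity <- function(model, xiDeg) {
  stopifnot(is(model, "ModelSystem"))
  exp(.fourierEval(.deg2rad(xiDeg), model@logDCos, model@logDSin,
                   model@logD0))
}

#' Ground-truth profile of a model system
#'
#' Evaluates the model PMF on a uniform periodic grid and packages it as a
#' min-referenced [FreeEnergyProfile-class] (all bins marked occupied), e.g.
#' for quadrature oracles and recovery comparisons.
#'
#' @param model A [ModelSystem-class].
#' @param nBins Number of bins over one period (default 360, 1-degree bins).
#' @param gridOrigin Left edge of the first bin in degrees (default -321).
#' @return A [FreeEnergyProfile-class].
#' @export
modelProfile <- function(model, nBins = 360, gridOrigin = -321) {
  h <- 360 / nBins
  bc <- gridOrigin + (seq_len(nBins) - 0.5) * h
  Fv <- modelPMF(model, bc)
  new("FreeEnergyProfile", binCenters = bc, values = Fv - min(Fv),
      occupancy = rep(1, nBins), period = 360,
      temperature = model@temperature)
}

# Solve the two-harmonic double-well coefficients: conditions F'(intra) = 0,
# F'(extra) = 0, F(extra) - F(intra) = deltaF define a one-parameter family
# (linear in the Fourier coefficients); the remaining degree of freedom is
# pinned by the barrier height on the positive path from intra to extra.
.calibrateDoubleWell <- function(intraMin, extraMin, barrier, deltaF) {
  xi <- .deg2rad(intraMin)
  xe <- .deg2rad(extraMin)
  basis <- function(x) c(cos(x), sin(x), cos(2 * x), sin(2 * x))
  dbasis <- function(x) c(-sin(x), cos(x), -2 * sin(2 * x), 2 * cos(2 * x))
  A <- rbind(dbasis(xi), dbasis(xe), basis(xe) - basis(xi))
  rhs <- c(0, 0, deltaF)
  sv <- svd(A, nu = 3, nv = 4)
  pinv <- sv$v[, 1:3] %*% diag(1 / sv$d) %*% t(sv$u)
  p0 <- as.numeric(pinv %*% rhs)
  nullv <- sv$v[, 4]

  # barrier (relative to the intra minimum) on the positive path
  path <- seq(0, angularPath(intraMin, extraMin, "positive"), length.out = 721)
  xPath <- .deg2rad(intraMin + path)
  evalF <- function(p, x) p[1] * cos(x) + p[2] * sin(x) +
    p[3] * cos(2 * x) + p[4] * sin(2 * x)
  bOf <- function(t) {
    p <- p0 + t * nullv
    max(evalF(p, xPath)) - evalF(p, xi)
  }
  # bracket the requested barrier along the null direction
  ts <- seq(-50, 50, length.out = 2001)
  bs <- vapply(ts, bOf, numeric(1))
  idx <- which(diff(sign(bs - barrier)) != 0)
  if (length(idx) == 0)
    stop("cannot reach the requested barrier with two harmonics")
  # prefer the root for which the intra state is a genuine minimum
  for (i in idx) {
    r <- stats::uniroot(function(t) bOf(t) - barrier,
                        c(ts[i], ts[i + 1]), tol = 1e-12)
    p <- p0 + r$root * nullv
    curv <- function(x) -p[1] * cos(x) - p[2] * sin(x) -
      4 * p[3] * cos(2 * x) - 4 * p[4] * sin(2 * x)
    if (curv(xi) > 0 && curv(xe) > 0) return(p)
  }
  stop("no calibration with minima at the requested positions")
}

#' Construct a synthetic model system
#'
#' Presets:
#' \describe{
#'   \item{flat}{F = 0 everywhere.}
#'   \item{single-well}{F = (barrier/2)(1 - cos(xi - intraMin)): one minimum
#'     at `intraMin`, maximum `barrier` on the opposite side.}
#'   \item{double-well}{Two-harmonic landscape calibrated so that the
#'     intra-helical minimum sits at `intraMin`, the extra-helical minimum at
#'     `extraMin`, F(extra) - F(intra) = `deltaF`, and the saddle on the
#'     positive (major-groove) path lies `barrier` above the intra minimum.
#'     The defaults emulate a protein-bound thymine-dimer flipping landscape:
#'     minima near 30 and -135 degrees, extra-helical state 2 kcal/mol below
#'     the intra-helical one, barrier 3.5 kcal/mol.}
#'   \item{custom}{Pass the Fourier coefficients directly.}
#' }
#'
#' The diffusivity is log-cosine, D(xi) = D0 exp(dLogAmp cos(xi - dPhase)):
#' constant for `dLogAmp = 0`; `dLogAmp = log(10)/2` gives the
#' one-order-of-magnitude max/min fluctuation seen for flipping coordinates.
#'
#' @param preset One of "double-well", "single-well", "flat", "custom".
#' @param barrier Barrier height in kcal/mol (positive path), default 3.5.
#' @param deltaF F(extra) - F(intra) in kcal/mol, default -2.
#' @param intraMin,extraMin Minima positions in degrees (30 / -135).
#' @param D0 Baseline diffusivity in rad^2/ps (default 1e-3).
#' @param dLogAmp Log-amplitude of the diffusivity modulation (default 0).
#' @param dPhase Phase of the diffusivity modulation in degrees.
#' @param temperature Temperature in K (default 300).
#' @param fourierCos,fourierSin,offset Custom PMF coefficients (kcal/mol).
#' @return A [ModelSystem-class].
#' @examples
#' m <- modelSystem("double-well")
#' modelPMF(m, c(30, -135)) - modelPMF(m, 30)   # 0, -2
#' @export
modelSystem <- function(preset = c("double-well", "single-well", "flat",
                                   "custom"),
                        barrier = 3.5, deltaF = -2, intraMin = 30,
                        extraMin = -135, D0 = 1e-3, dLogAmp = 0,
                        dPhase = -60, temperature = 300,
                        fourierCos = numeric(0), fourierSin = numeric(0),
                        offset = 0) {
  preset <- match.arg(preset)
  if (preset == "flat") {
    fc <- numeric(0); fs <- numeric(0); off <- 0
  } else if (preset == "single-well") {
    x0 <- .deg2rad(intraMin)
    fc <- -barrier / 2 * cos(x0)
    fs <- -barrier / 2 * sin(x0)
    off <- barrier / 2
  } else if (preset == "double-well") {
    p <- .calibrateDoubleWell(intraMin, extraMin, barrier, deltaF)
    fc <- c(p[1], p[3]); fs <- c(p[2], p[4]); off <- 0
  } else {
    fc <- fourierCos; fs <- fourierSin; off <- offset
  }
  phr <- .deg2rad(dPhase)
  ldc <- if (dLogAmp != 0) dLogAmp * cos(phr) else numeric(0)
  lds <- if (dLogAmp != 0) dLogAmp * sin(phr) else numeric(0)
  new("ModelSystem", fourierCos = fc, fourierSin = fs, offset = off,
      logDCos = ldc, logDSin = lds, logD0 = log(D0),
      temperature = temperature, preset = preset)
}

.modelArgs <- function(model) {
  list(fc = model@fourierCos, fs = model@fourierSin, f0 = model@offset,
       ldc = model@logDCos, lds = model@logDSin, ld0 = model@logD0,
       beta = 1 / thermalEnergy(model@temperature))
}

#' Simulate one overdamped Langevin trajectory
#'
#' Euler-Maruyama propagation on the model landscape (Ito convention with the
#' spurious-drift term for position-dependent D), optionally under a harmonic
#' umbrella bias. Deterministic given `(seed, stream)`: each window of a
#' campaign uses its own counter-derived stream.
#'
#' @param model A [ModelSystem-class].
#' @param spec A [SimulationSpec-class].
#' @param seed Integer seed.
#' @param x0 Start position in degrees (default: bias center, else 0).
#' @param biasCenter,biasK Optional harmonic bias: center in degrees, force
#'   constant in kcal/(mol rad^2). `biasK = 0` disables the bias.
#' @param stream Substream index (default 1).
#' @return An [AngleSeries-class] in degrees (sampling interval
#'   `dt * stride`).
#' @export
langevinTrajectory <- function(model, spec = simulationSpec(), seed = 1,
                               x0 = NULL, biasCenter = 0, biasK = 0,
                               stream = 1) {
  stopifnot(is(model, "ModelSystem"), is(spec, "SimulationSpec"))
  if (is.null(x0)) x0 <- if (biasK > 0) biasCenter else 0
  a <- .modelArgs(model)
  xs <- .langevin_cpp(a$fc, a$fs, a$f0, a$ldc, a$lds, a$ld0, a$beta,
                      spec@dt, spec@steps, spec@stride, .deg2rad(x0),
                      .deg2rad(biasCenter), biasK, seed, stream)
  angleSeries(.rad2deg(xs), dt = spec@dt * spec@stride,
              label = sprintf("langevin-seed%d-stream%d", seed, stream))
}

#' Run a synthetic umbrella campaign
#'
#' One walker per window, all propagated in lockstep on the model landscape
#' under their harmonic biases. If `exchangeEvery > 0`, neighbouring windows
#' attempt configuration swaps every `exchangeEvery` ps (randomly chosen
#' neighbour parity, Metropolis acceptance on the bias energies), emulating
#' Hamiltonian replica exchange; the realized acceptance rate is recorded in
#' the set's metadata. Exchange leaves each window's stationary distribution
#' unchanged but interrupts its time correlation, so campaigns meant for
#' diffusivity estimation should run with `exchangeEvery = 0`.
#'
#' @param model A [ModelSystem-class].
#' @param windowCenters Window centers in degrees (default -320..38 step 2).
#' @param kU Umbrella force constant in kcal/(mol rad^2) (default 400).
#' @param spec A [SimulationSpec-class] (per window).
#' @param exchangeEvery Exchange attempt interval in ps (0 = no exchange).
#' @param seed Integer seed; per-window substreams are derived internally.
#' @return A [WindowSet-class]; `windowMetadata(ws)$acceptance` holds the realized
#'   exchange acceptance rate (NA without exchange).
#' @export
runUmbrellaCampaign <- function(model, windowCenters = seq(-320, 38, by = 2),
                                kU = 400, spec = simulationSpec(),
                                exchangeEvery = 2, seed = 1) {
  stopifnot(is(model, "ModelSystem"), is(spec, "SimulationSpec"))
  a <- .modelArgs(model)
  exSteps <- if (exchangeEvery > 0) max(1, round(exchangeEvery / spec@dt))
             else 0
  res <- .campaign_cpp(a$fc, a$fs, a$f0, a$ldc, a$lds, a$ld0, a$beta,
                       spec@dt, spec@steps, spec@stride,
                       .deg2rad(windowCenters), kU, exSteps, seed,
                       exSteps > 0)
  dtOut <- spec@dt * spec@stride
  wins <- lapply(seq_along(windowCenters), function(i) {
    umbrellaWindow(windowCenters[i],
                   angleSeries(.rad2deg(res$samples[, i]), dtOut,
                               label = sprintf("window-%03d", i)),
                   forceConstant = kU, temperature = model@temperature)
  })
  windowSet(wins, metadata = list(acceptance = res$acceptance,
                                  exchangeAttempts = res$attempts,
                                  seed = seed))
}

#' Brute-force first-passage oracle
#'
#' Simulates `nWalkers` independent Langevin walkers from `x0` (default the
#' reflecting boundary) with position mirroring at `reflectAt` until first
#' crossing of `absorbAt`, and returns the sample mean and standard error of
#' the first-passage time. The step cap defaults to 200 times the
#' double-integral MFPT predicted from the model itself; walkers hitting the
#' cap are censored, and more than 1% censoring is an error.
#'
#' @param model A [ModelSystem-class].
#' @param reflectAt,absorbAt Boundaries in degrees on the unwrapped branch.
#' @param nWalkers Number of walkers (default 1e4).
#' @param dt Oracle timestep in ps (default 0.5; the oracle can take larger
#'   steps than the campaign because only boundary crossing matters).
#' @param seed Integer seed.
#' @param x0 Start position in degrees (default `reflectAt`).
#' @param maxTime Per-walker time cap in ps (default 200x the predicted
#'   MFPT).
#' @return List with `mean` (ps), `se`, `times` (ps, NA when censored) and
#'   `censored` (count).
#' @export
firstPassageOracle <- function(model, reflectAt, absorbAt, nWalkers = 1e4,
                               dt = 0.5, seed = 1, x0 = reflectAt,
                               maxTime = NULL) {
  stopifnot(is(model, "ModelSystem"))
  a <- .modelArgs(model)
  if (is.null(maxTime)) {
    prof <- modelProfile(model, nBins = 720,
                         gridOrigin = min(reflectAt, absorbAt) - 0.25)
    ctr <- seq(min(reflectAt, absorbAt), max(reflectAt, absorbAt),
               length.out = 181)
    dp <- new("DiffusivityProfile", centers = ctr,
              values = modelDiffusivity(model, ctr))
    maxTime <- 200 * mfptForward(prof, dp, reflectAt, absorbAt)
  }
  times <- .fpt_cpp(a$fc, a$fs, a$f0, a$ldc, a$lds, a$ld0, a$beta, dt,
                    .deg2rad(x0), .deg2rad(reflectAt), .deg2rad(absorbAt),
                    nWalkers, ceiling(maxTime / dt), seed)
  nc <- sum(is.na(times))
  if (nc > 0.01 * nWalkers)
    stop(sprintf("%d of %d walkers censored at the step cap", nc, nWalkers))
  ok <- times[!is.na(times)]
  list(mean = mean(ok), se = sd(ok) / sqrt(length(ok)), times = times,
       censored = nc)
}

#' Synthetic restraint-perturbation series
#'
#' Simulates an auxiliary distance coordinate under the reference (restrained)
#' dynamics U_ref(d) = k_ref/2 (d - d0)^2 + flat-bottom restraint, and
#' evaluates dU = -U_restraint on the stored frames (restraint-removal
#' direction). The analytic reference answer is available from
#' [analyticRestraintDeltaF()].
#'
#' @param restraint A [RestraintSpec-class].
#' @param kRef Reference harmonic force constant in kcal/(mol A^2).
#' @param d0 Reference harmonic center in Angstrom.
#' @param D Diffusivity of the auxiliary coordinate in A^2/ps.
#' @param spec A [SimulationSpec-class].
#' @param temperature Temperature in K.
#' @param seed Integer seed.
#' @return A [PerturbationSeries-class].
#' @export
makePerturbationSeries <- function(restraint, kRef = 5, d0 = 4, D = 0.1,
                                   spec = simulationSpec(dt = 0.01,
                                                         steps = 1e5,
                                                         stride = 10),
                                   temperature = 300, seed = 1) {
  stopifnot(is(restraint, "RestraintSpec"))
  beta <- 1 / thermalEnergy(temperature)
  d <- .aux_langevin_cpp(kRef, d0, restraint@lower, restraint@upper,
                         restraint@forceConstant, D, beta, spec@dt,
                         spec@steps, spec@stride, d0, seed)
  dU <- -flatBottomEnergy(pmax(d, 0), restraint)
  perturbationSeries(dU, temperature)
}

#' Analytic restraint-removal free energy
#'
#' Quadrature reference for [makePerturbationSeries()]: the free-energy
#' change of removing the flat-bottom restraint from the harmonic reference,
#' dF = -kT log(Z_unrestrained / Z_restrained), both partition functions by
#' 1D integration.
#'
#' @param restraint A [RestraintSpec-class].
#' @param kRef,d0 Harmonic reference parameters.
#' @param temperature Temperature in K.
#' @return dF in kcal/mol.
#' @export
analyticRestraintDeltaF <- function(restraint, kRef = 5, d0 = 4,
                                    temperature = 300) {
  stopifnot(is(restraint, "RestraintSpec"))
  kT <- thermalEnergy(temperature)
  harm <- function(d) 0.5 * kRef * (d - d0)^2
  rest <- function(d) {
    0.5 * restraint@forceConstant *
      (pmin(d - restraint@lower, 0)^2 + pmax(d - restraint@upper, 0)^2)
  }
  zRef <- integrate(function(d) exp(-(harm(d) + rest(d)) / kT),
                    -Inf, Inf, rel.tol = 1e-10)$value
  zTar <- integrate(function(d) exp(-harm(d) / kT), -Inf, Inf,
                    rel.tol = 1e-10)$value
  -kT * log(zTar / zRef)
}

#' Write a window set in the text dialect, with a ground-truth sidecar
#'
#' Writes every window via [writeWindowSeries()] plus a `windows.yaml`
#' metadata file (paths, centers, force constants, temperature, period), and
#' optionally a `ground_truth.yaml` sidecar with the generating model's
#' coefficients and seed.
#'
#' @param ws A [WindowSet-class].
#' @param dir Output directory (created if needed).
#' @param model Optional [ModelSystem-class] ground truth.
#' @param seed Optional generating seed, recorded in the sidecar.
#' @return The metadata file path, invisibly.
#' @export
writeWindowSet <- function(ws, dir, model = NULL, seed = NULL) {
  stopifnot(is(ws, "WindowSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wins <- windows(ws)
  meta <- list(period = ws@period, windows = lapply(seq_along(wins),
    function(i) {
      w <- wins[[i]]
      f <- sprintf("window_%03d.dat", i)
      writeWindowSeries(w, file.path(dir, f))
      list(path = f, center = windowCenter(w),
           force_constant = forceConstant(w),
           temperature = temperature(w))
    }))
  metaPath <- file.path(dir, "windows.yaml")
  yaml::write_yaml(meta, metaPath)
  if (!is.null(model)) {
    gt <- list(preset = model@preset, fourier_cos = model@fourierCos,
               fourier_sin = model@fourierSin, offset = model@offset,
               logD_cos = model@logDCos, logD_sin = model@logDSin,
               logD0 = model@logD0, temperature = model@temperature,
               seed = seed)
    yaml::write_yaml(gt, file.path(dir, "ground_truth.yaml"))
  }
  invisible(metaPath)
}

#' Read a window set written by [writeWindowSet()]
#'
#' @param dir Directory containing `windows.yaml` and the series files.
#' @param burnIn Burn-in fraction passed to [loadWindowSeries()].
#' @return A [WindowSet-class].
#' @export
readWindowSet <- function(dir, burnIn = 0) {
  meta <- yaml::read_yaml(file.path(dir, "windows.yaml"))
  wins <- lapply(meta$windows, function(m) {
    loadWindowSeries(file.path(dir, m$path), center = m$center,
                     forceConstant = m$force_constant,
                     temperature = m$temperature, burnIn = burnIn)
  })
  windowSet(wins, period = meta$period)
}
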