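# periodic minimal-image difference in degrees
.periodicDiff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Periodic WHAM: free-energy profile from umbrella windows
#'
#' Self-consistent weighted-histogram analysis on a periodic angular grid.
#' Samples are binned on a uniform grid covering one period (anchored on the
#' branch of the window centers); the window free-energy constants f_i are
#' iterated until max |df_i| < `tol`, using the periodic minimal-image
#' distance inside each harmonic bias. The profile is referenced to its
#' minimum. Bins without samples are marked undefined (NA), never infinite.
#'
#' Correlated samples can be down-weighted by per-window statistical
#' inefficiencies g_i = 2 tau_int / dt + 1 (see
#' [statisticalInefficiency()]); pass them via `inefficiency`.
#'
#' @param ws A [WindowSet-class]; all windows must share one temperature.
#' @param binWidth Bin width in degrees (default 2, one bin per window at the
#'   standard spacing).
#' @param nBins Alternative to `binWidth`: number of bins over one period.
#' @param tol Convergence tolerance on the window constants, kcal/mol
#'   (default 1e-7).
#' @param maxIter Iteration cap (default 1e5); non-convergence is an error
#'   that reports the last residual.
#' @param inefficiency Optional numeric vector g_i (one per window, >= 1).
#' @param gridOrigin Optional left edge of the first bin, degrees. Defaults
#'   to half a bin below the smallest window center.
#' @param biasOffset Optional per-window constant (kcal/mol) added to each
#'   bias; the estimate is gauge-invariant under such shifts.
#' @return A [FreeEnergyProfile-class].
#' @export
wham <- function(ws, binWidth = 2, nBins = NULL, tol = 1e-7, maxIter = 1e5,
                 inefficiency = NULL, gridOrigin = NULL, biasOffset = NULL) {
  stopifnot(is(ws, "WindowSet"))
  wins <- windows(ws)
  temp <- vapply(wins, temperature, numeric(1))
  if (diff(range(temp)) > 1e-8)
    stop("all windows must share one temperature")
  kT <- thermalEnergy(temp[1])
  P <- ws@period
  if (is.null(nBins)) nBins <- round(P / binWidth)
  h <- P / nBins
  ctr <- centers(ws)
  if (is.null(gridOrigin)) gridOrigin <- min(ctr) - h / 2
  binC <- gridOrigin + (seq_len(nBins) - 0.5) * h

  nw <- length(wins)
  g <- if (is.null(inefficiency)) rep(1, nw) else inefficiency
  stopifnot(length(g) == nw, all(g >= 1))

  # per-window histogram counts on the periodic grid
  counts <- matrix(0, nrow = nw, ncol = nBins)
  for (i in seq_len(nw)) {
    v <- (angleValues(wins[[i]]) - gridOrigin) %% P
    idx <- pmin(floor(v / h) + 1L, nBins)
    counts[i, ] <- tabulate(idx, nbins = nBins)
  }
  rawOcc <- colSums(counts)
  countsEff <- counts / g
  nEff <- rowSums(countsEff)

  # bias energies at bin centers, kcal/mol, periodic minimal image in rad
  kU <- vapply(wins, forceConstant, numeric(1))
  dmat <- .deg2rad(outer(ctr, binC, function(a, b) .periodicDiff(b, a, P)))
  U <- 0.5 * kU * dmat^2
  if (!is.null(biasOffset)) {
    stopifnot(length(biasOffset) == nw)
    U <- U + biasOffset
  }
  EmU <- exp(-U / kT)                      # nw x nBins

  f <- numeric(nw)
  occ <- rawOcc > 0
  num <- colSums(countsEff)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(nEff * exp(f / kT) * EmU)
    rho <- ifelse(occ & denom > 0, num / denom, NA_real_)
    z <- EmU[, occ, drop = FALSE] %*% rho[occ]
    fNew <- -kT * log(as.numeric(z))
    fNew <- fNew - fNew[1]
    resid <- max(abs(fNew - f))
    f <- fNew
    if (resid < tol) break
    if (iter >= maxIter)
      stop(sprintf(
        "WHAM did not converge in %d iterations (last residual %.3g kcal/mol)",
        iter, resid))
  }

  Fv <- -kT * log(rho)
  sampled <- range(which(occ))
  inside <- seq(sampled[1], sampled[2])
  if (any(!occ[inside]))
    warning(sum(!occ[inside]),
            " empty bin(s) inside the sampled range marked undefined")
  Fv <- Fv - min(Fv, na.rm = TRUE)
  new("FreeEnergyProfile", binCenters = binC, values = Fv,
      occupancy = rawOcc, period = P, temperature = temp[1])
}

# periodic membership of angle x in interval(s) given as rows (lower, upper),
# interpreted going from lower upward (mod period)
.inRegion <- function(x, region, period = 360) {
  region <- matrix(region, ncol = 2)
  hit <- rep(FALSE, length(x))
  for (r in seq_len(nrow(region))) {
    arc <- (region[r, 2] - region[r, 1]) %% period
    if (arc == 0) arc <- period
    hit <- hit | ((x - region[r, 1]) %% period) <= arc
  }
  hit
}

#' Free-energy difference between two coordinate regions
#'
#' Boltzmann-integrated state free energies: dF = F_B - F_A with
#' F_X = -kT log( sum_{b in X} exp(-F_b/kT) w ), w the bin width. Regions are
#' angular intervals (lower, upper), traversed upward modulo the period, so
#' they may wrap the branch ends.
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param regionA,regionB Numeric length-2 vectors (or 2-column matrices of
#'   intervals) in degrees.
#' @return dF in kcal/mol (sign convention F_B - F_A).
#' @export
stateDeltaF <- function(profile, regionA, regionB) {
  stopifnot(is(profile, "FreeEnergyProfile"))
  kT <- thermalEnergy(profile@temperature)
  x <- binCenters(profile)
  Fv <- profileValues(profile)
  ok <- profile@occupancy > 0 & is.finite(Fv)
  fOf <- function(region) {
    m <- ok & .inRegion(x, region, profile@period)
    if (!any(m)) stop("region contains no occupied bins")
    -kT * .logSumExp(-Fv[m] / kT)
  }
  fOf(regionB) - fOf(regionA)
}

#' Locate minima, maxima and barriers of a profile
#'
#' Local extrema of the (optionally moving-average smoothed) profile with
#' periodic neighbor logic when the full period is occupied; on a partially
#' occupied grid the contiguous occupied range is treated as linear and its
#' endpoints are not extrema.
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param smoothingWindow Odd moving-average width in bins (1 = no
#'   smoothing).
#' @return Data frame with columns `position` (deg), `value` (kcal/mol) and
#'   `kind` ("min"/"max"), ordered by position. Empty for a flat profile.
#' @export
locateExtrema <- function(profile, smoothingWindow = 1) {
  stopifnot(is(profile, "FreeEnergyProfile"))
  x <- binCenters(profile)
  Fv <- profileValues(profile)
  ok <- which(profile@occupancy > 0 & is.finite(Fv))
  if (length(ok) < 3) stop("need at least 3 occupied bins")
  periodic <- length(ok) == length(x)
  v <- Fv[ok]
  if (smoothingWindow > 1) {
    k <- as.integer(smoothingWindow)
    if (k %% 2 == 0) stop("smoothingWindow must be odd")
    half <- (k - 1) / 2
    n <- length(v)
    vs <- numeric(n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      if (periodic) j <- ((j - 1) %% n) + 1 else j <- j[j >= 1 & j <= n]
      vs[i] <- mean(v[j])
    }
    v <- vs
  }
  n <- length(v)
  left <- if (periodic) v[c(n, seq_len(n - 1))] else c(NA, v[-n])
  right <- if (periodic) v[c(seq_len(n - 1) + 1, 1)] else c(v[-1], NA)
  isMin <- !is.na(left) & !is.na(right) & v < left & v <= right
  isMax <- !is.na(left) & !is.na(right) & v > left & v >= right
  out <- data.frame(
    position = x[ok][isMin | isMax],
    value = Fv[ok][isMin | isMax],
    kind = ifelse(isMin[isMin | isMax], "min", "max"),
    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Barrier height between two minima
#'
#' Maximum of the profile on the upward path (mod period) from `from` to
#' `to`, minus the lower of the two endpoint values.
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param from,to Positions of the two minima in degrees.
#' @return List with `height` (kcal/mol, relative to the lower minimum),
#'   `position` (deg) of the barrier top and `top` (kcal/mol, absolute).
#' @export
barrierHeight <- function(profile, from, to) {
  stopifnot(is(profile, "FreeEnergyProfile"))
  x <- binCenters(profile)
  Fv <- profileValues(profile)
  ok <- profile@occupancy > 0 & is.finite(Fv)
  m <- ok & .inRegion(x, c(from, to), profile@period)
  if (!any(m)) stop("no occupied bins on the path")
  i <- which(m)[which.max(Fv[m])]
  ends <- Fv[ok][c(which.min(abs(x[ok] - unwrapToBranch(from, x[ok]))),
                   which.min(abs(x[ok] - unwrapToBranch(to, x[ok]))))]
  list(height = Fv[i] - min(ends), position = x[i], top = Fv[i])
}

#' Pairwise RMSD between segment profiles
#'
#' Convergence diagnostic: for profiles computed on identical grids from data
#' segments, the RMSD over mutually occupied bins after re-referencing every
#' profile to zero mean on that bin set (free-energy profiles are defined up
#' to a constant).
#'
#' @param profiles List of >= 2 [FreeEnergyProfile-class] objects on one
#'   grid.
#' @return Symmetric matrix of RMSDs in kcal/mol.
#' @export
convergenceRMSD <- function(profiles) {
  stopifnot(length(profiles) >= 2,
            all(vapply(profiles, is, logical(1), "FreeEnergyProfile")))
  grids <- lapply(profiles, binCenters)
  for (gd in grids[-1])
    if (length(gd) != length(grids[[1]]) ||
        max(abs(gd - grids[[1]])) > 1e-9)
      stop("profiles must share one grid")
  occ <- Reduce(`&`, lapply(profiles, function(p)
    p@occupancy > 0 & is.finite(profileValues(p))))
  if (!any(occ)) stop("no mutually occupied bins")
  vals <- lapply(profiles, function(p) {
    v <- profileValues(p)[occ]
    v - mean(v)
  })
  np <- length(profiles)
  out <- matrix(0, np, np)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    out[i, j] <- out[j, i] <- sqrt(mean((vals[[i]] - vals[[j]])^2))
  }
  out
}
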