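#' Normalized autocorrelation of a series
#'
#' Biased (1/N) normalized autocovariance of the mean-removed series, as
#' returned by [stats::acf()].
#'
#' @param series Numeric vector (or an [AngleSeries-class]).
#' @param maxLag Maximum lag in samples (1 <= maxLag < length).
#' @return Numeric vector C(0..maxLag), C(0) = 1.
#' @export
autocorrelation <- function(series, maxLag) {
  if (is(series, "AngleSeries")) series <- series@values
  stopifnot(is.numeric(series), maxLag >= 1, length(series) > maxLag)
  if (var(series) == 0) stop("series has zero variance")
  as.numeric(acf(series, lag.max = maxLag, plot = FALSE,
                 demean = TRUE)$acf)
}

#' Block-averaging standard-error curve
#'
#' Standard error of the series mean estimated from non-overlapping block
#' means at increasing block lengths. For a correlated series the curve rises
#' to a plateau at sigma * sqrt(2 tau_int / T); it serves as a consistency
#' diagnostic for the fitted integrated autocorrelation time.
#'
#' @param series Numeric vector.
#' @param dt Sampling interval in ps.
#' @param blockLengths Block lengths in samples (default: powers of 2 up to
#'   n/8).
#' @return Data frame with columns `blockLength` (samples), `blockTime` (ps)
#'   and `se`.
#' @export
blockStandardError <- function(series, dt,
                               blockLengths = 2^(0:floor(log2(length(series) / 8)))) {
  stopifnot(is.numeric(series), length(series) >= 16, dt > 0)
  out <- lapply(blockLengths, function(m) {
    nb <- length(series) %/% m
    if (nb < 2) return(NULL)
    bm <- colMeans(matrix(series[seq_len(nb * m)], nrow = m))
    data.frame(blockLength = m, blockTime = m * dt,
               se = sd(bm) / sqrt(nb))
  })
  do.call(rbind, out)
}

#' Double-exponential fit of the correlation function (Hess procedure)
#'
#' Fits C(t) = A exp(-t/tau1) + (1-A) exp(-t/tau2) by bounded least squares
#' over lags up to the first zero crossing (or the full range if none), using
#' several starting points. The integrated autocorrelation time is
#' tau_int = A tau1 + (1-A) tau2. If every fit fails, the estimate falls back
#' to direct trapezoidal integration of C(t) to the first zero crossing and
#' is flagged (`fitted = FALSE`). When the raw series is supplied, a
#' block-averaging standard-error curve is attached as the plateau
#' diagnostic.
#'
#' @param C Normalized autocorrelation values, C[1] = 1 (lag 0).
#' @param dt Lag spacing in ps.
#' @param series Optional raw series for the block-averaging diagnostic.
#' @param floor Noise floor: lags after C first drops below this value are
#'   excluded from the fit (they carry estimator noise, not decay signal).
#' @param nSamples Length of the series C was estimated from (taken from
#'   `series` when supplied); enables the Bartlett noise estimate used to
#'   test the slow component's significance.
#' @return A [CorrelationEstimate-class].
#' @export
fitCorrelationTime <- function(C, dt, series = NULL, floor = 0.05,
                               nSamples = NULL) {
  if (!is.null(series) && is.null(nSamples)) nSamples <- length(series)
  stopifnot(abs(C[1] - 1) < 1e-8, dt > 0, length(C) >= 3)
  # fit only where signal dominates the acf noise floor: up to the first
  # zero crossing or the first drop below `floor`, whichever is earlier
  cross <- which(C <= max(0, floor))[1]
  upto <- if (is.na(cross)) length(C) else max(3L, cross - 1L)
  lagT <- (seq_len(upto) - 1) * dt
  Cf <- C[seq_len(upto)]
  # direct-integration estimate, also the fallback
  tau0 <- max(dt * (0.5 + sum(Cf[-1])), dt / 10)

  starts <- list(c(A = 0.5, tau1 = tau0 / 3, tau2 = 2 * tau0),
                 c(A = 0.9, tau1 = tau0, tau2 = 5 * tau0),
                 c(A = 0.2, tau1 = tau0 / 10, tau2 = 1.2 * tau0),
                 c(A = 0.99, tau1 = tau0, tau2 = tau0 / 5))
  resFn <- function(p) p[1] * exp(-lagT / p[2]) +
    (1 - p[1]) * exp(-lagT / p[3]) - Cf
  tauMax <- 5 * max(lagT) + dt
  lmFit <- function(par, fn, lower, upper) {
    tryCatch(
      minpack.lm::nls.lm(par = par, fn = fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
  }
  best <- NULL
  for (s in starts) {
    fit <- lmFit(s, resFn, c(0, dt / 100, dt / 100), c(1, tauMax, tauMax))
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, par = setNames(fit$par,
                                               c("A", "tau1", "tau2")))
    }
  }
  # guard against fitting acf noise as a spurious slow component: the acf
  # estimate carries smooth, correlated noise that reliably masquerades as a
  # weak slow decay. Keep the two-scale model only if (a) BIC favours it
  # over one exponential and (b) the slow component's amplitude clears 4x
  # the acf noise scale - the Bartlett standard error when the sample count
  # is known, else the RMS of C(t) beyond twice the fit range, where a true
  # single exponential has decayed and only estimator noise remains.
  single <- lmFit(c(tau = tau0), function(p) exp(-lagT / p[1]) - Cf,
                  dt / 100, tauMax)
  if (!is.null(single) && !is.null(best)) {
    n <- length(Cf)
    rss1 <- max(sum(single$fvec^2), 1e-300)
    rss2 <- max(best$rss, 1e-300)
    bic1 <- n * log(rss1 / n) + 1 * log(n)
    bic2 <- n * log(rss2 / n) + 3 * log(n)
    slowAmp <- with(as.list(best$par),
                    if (tau2 >= tau1) 1 - A else A)
    sigmaC <- 0
    if (!is.null(nSamples))
      sigmaC <- sqrt((1 + 2 * sum(C^2)) / nSamples)
    noiseIdx <- seq.int(min(2L * upto, length(C)), length(C))
    if (length(noiseIdx) >= 10)
      sigmaC <- max(sigmaC, sqrt(mean(C[noiseIdx]^2)))
    sigSlow <- sigmaC == 0 || slowAmp > 4 * sigmaC
    if (bic1 <= bic2 || !sigSlow)
      best <- list(rss = rss1,
                   par = c(A = 1, tau1 = unname(single$par),
                           tau2 = unname(single$par)))
  }
  bse <- if (!is.null(series)) blockStandardError(series, dt)
         else data.frame()
  if (is.null(best)) {
    return(new("CorrelationEstimate", lags = (seq_along(C) - 1) * dt,
               acf = C, amplitude = 1, tau1 = tau0, tau2 = tau0,
               tauInt = tau0, fitted = FALSE, blockSE = bse))
  }
  p <- best$par
  A <- unname(p["A"]); t1 <- unname(p["tau1"]); t2 <- unname(p["tau2"])
  new("CorrelationEstimate", lags = (seq_along(C) - 1) * dt, acf = C,
      amplitude = A, tau1 = t1, tau2 = t2,
      tauInt = A * t1 + (1 - A) * t2, fitted = TRUE, blockSE = bse)
}

#' Statistical inefficiency of a window series
#'
#' g = 2 tau_int / dt + 1: the factor by which correlated samples overcount
#' independent information; used to down-weight window histograms in WHAM.
#'
#' @param window An [UmbrellaWindow-class] (or numeric series).
#' @param dt Sampling interval in ps (taken from the window if omitted).
#' @param maxLag Maximum autocorrelation lag in samples.
#' @return g >= 1.
#' @export
statisticalInefficiency <- function(window, dt = NULL, maxLag = NULL) {
  v <- if (is(window, "UmbrellaWindow")) angleValues(window) else window
  if (is.null(dt)) dt <- samplingInterval(window)
  if (is.null(maxLag)) maxLag <- min(length(v) - 1, 1000L)
  est <- fitCorrelationTime(autocorrelation(v, maxLag), dt,
                            nSamples = length(v))
  max(1, 2 * est@tauInt / dt + 1)
}

#' Local diffusivity of one umbrella window
#'
#' D = var(xi) / tau_int with xi in radians: the stationary variance of the
#' biased window divided by its integrated autocorrelation time. Exact for an
#' Ornstein-Uhlenbeck window and accurate while windows are narrow enough
#' that D is locally constant.
#'
#' @param window An [UmbrellaWindow-class] (burn-in already removed).
#' @param maxLag Maximum autocorrelation lag in samples (default
#'   min(n-1, 1000)).
#' @param diagnostics If TRUE attach the block-averaging curve.
#' @return List with `D` (rad^2/ps), `tauInt` (ps), `variance` (rad^2) and
#'   `estimate` (the [CorrelationEstimate-class]).
#' @export
localDiffusivity <- function(window, maxLag = NULL, diagnostics = FALSE) {
  stopifnot(is(window, "UmbrellaWindow"))
  v <- .deg2rad(angleValues(window))
  dt <- samplingInterval(window)
  if (is.null(maxLag)) maxLag <- min(length(v) - 1, 1000L)
  C <- autocorrelation(v, maxLag)
  est <- fitCorrelationTime(C, dt, series = if (diagnostics) v else NULL,
                            nSamples = length(v))
  vr <- var(v)
  list(D = vr / est@tauInt, tauInt = est@tauInt, variance = vr,
       estimate = est)
}

#' Diffusivity profile over a window set
#'
#' Applies [localDiffusivity()] to every window.
#'
#' @param ws A [WindowSet-class].
#' @param maxLag Passed to [localDiffusivity()].
#' @return A [DiffusivityProfile-class] (log-linear interpolation rule).
#' @export
diffusivityProfile <- function(ws, maxLag = NULL) {
  stopifnot(is(ws, "WindowSet"))
  D <- vapply(windows(ws), function(w) localDiffusivity(w, maxLag)$D,
              numeric(1))
  new("DiffusivityProfile", centers = centers(ws), values = D,
      interpolation = "loglinear")
}

#' Interpolate a diffusivity profile
#'
#' Linear interpolation in log D between window centers (D is positive and
#' can vary over an order of magnitude), clamped to the end values outside
#' the covered range. Positions are matched periodically to the profile's
#' branch.
#'
#' @param dp A [DiffusivityProfile-class].
#' @param xi Positions in degrees.
#' @return D at `xi` in rad^2/ps.
#' @export
interpolateDiffusivity <- function(dp, xi) {
  stopifnot(is(dp, "DiffusivityProfile"))
  if (length(dp@centers) == 1) return(rep(dp@values, length(xi)))
  ref <- mean(range(dp@centers))
  x <- unwrapToBranch(xi, ref)
  exp(approx(dp@centers, log(dp@values), xout = x, rule = 2)$y)
}

# periodic linear interpolation of profile F onto arbitrary positions (deg);
# errors on undefined bins inside the requested range
.profileInterp <- function(profile, xi) {
  bc <- binCenters(profile)
  Fv <- profileValues(profile)
  P <- profile@period
  h <- bc[2] - bc[1]
  # map query points into the grid branch [bc1 - h/2, bc1 - h/2 + P)
  x <- ((xi - (bc[1] - h / 2)) %% P) + bc[1] - h / 2
  n <- length(bc)
  j <- pmax(1L, pmin(n - 1L, findInterval(x, bc)))
  # handle the wrap segment between the last and first bin
  wrapSeg <- x > bc[n] | x < bc[1]
  lo <- ifelse(wrapSeg, n, j)
  hi <- ifelse(wrapSeg, 1L, j + 1L)
  dx <- ifelse(wrapSeg, (x - bc[n]) %% P, x - bc[lo]) / h
  vlo <- Fv[lo]; vhi <- Fv[hi]
  if (any(!is.finite(vlo) | !is.finite(vhi)))
    stop("profile undefined (unoccupied bins) inside the requested range")
  vlo * (1 - dx) + vhi * dx
}

# shared Smoluchowski double integral; a = reflecting, b = absorbing, deg
.mfptIntegral <- function(profile, diffusivity, reflectAt, absorbAt,
                          nGrid = NULL) {
  stopifnot(is(profile, "FreeEnergyProfile"))
  kT <- thermalEnergy(profile@temperature)
  h <- binCenters(profile)[2] - binCenters(profile)[1]
  span <- abs(absorbAt - reflectAt)
  if (span <= 0) stop("boundaries must be distinct")
  if (is.null(nGrid)) nGrid <- max(2L, ceiling(span / h) * 4L + 1L)
  x <- seq(reflectAt, absorbAt, length.out = nGrid)   # may run downhill
  Fx <- .profileInterp(profile, x)
  Dx <- if (is(diffusivity, "DiffusivityProfile"))
    interpolateDiffusivity(diffusivity, x)
  else rep(as.numeric(diffusivity), nGrid)
  if (any(Dx <= 0)) stop("non-positive diffusivity")
  xr <- .deg2rad(x)
  dxr <- abs(xr[2] - xr[1])
  eNeg <- exp(-Fx / kT)
  ePos <- exp(Fx / kT) / Dx
  # cumulative trapezoid of exp(-F/kT) from the reflecting end
  inner <- c(0, cumsum((eNeg[-1] + eNeg[-nGrid]) / 2 * dxr))
  integrand <- ePos * inner
  sum((integrand[-1] + integrand[-nGrid]) / 2 * dxr)   # ps
}

#' Forward mean first passage time (Smoluchowski double integral)
#'
#' tau+ = int_a^b dxi exp(F(xi)/kT)/D(xi) int_a^xi dxi' exp(-F(xi')/kT), with
#' a the reflecting (intra-helical) and b the absorbing (extra-helical)
#' boundary, evaluated by trapezoidal quadrature with the cumulative inner
#' integral. The boundaries are given on an unwrapped branch; the profile is
#' evaluated periodically, so the integration domain may leave the profile's
#' own branch. For flat F and constant D the quadrature reproduces L^2/(2D)
#' exactly.
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param diffusivity A [DiffusivityProfile-class], or a single constant D in
#'   rad^2/ps.
#' @param reflectAt,absorbAt Boundary positions in degrees on an unwrapped
#'   branch.
#' @param nGrid Number of quadrature nodes (default: 4 per profile bin).
#' @return tau+ in ps.
#' @export
mfptForward <- function(profile, diffusivity, reflectAt, absorbAt,
                        nGrid = NULL) {
  .mfptIntegral(profile, diffusivity, reflectAt, absorbAt, nGrid)
}

#' Backward mean first passage time
#'
#' Mirror of [mfptForward()] with the boundary roles exchanged: reflecting at
#' the extra-helical and absorbing at the intra-helical boundary, the inner
#' probability integral running backwards.
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param diffusivity A [DiffusivityProfile-class] or a constant D
#'   (rad^2/ps).
#' @param absorbAt,reflectAt Boundary positions in degrees (note the
#'   exchanged roles relative to [mfptForward()]).
#' @param nGrid Number of quadrature nodes.
#' @return tau- in ps.
#' @export
mfptBackward <- function(profile, diffusivity, absorbAt, reflectAt,
                         nGrid = NULL) {
  .mfptIntegral(profile, diffusivity, reflectAt, absorbAt, nGrid)
}

#' Kinetic vs thermodynamic equilibrium constant
#'
#' K_kin = tau- / tau+ and K_thermo = exp(-dF/kT) with dF the
#' Boltzmann-integrated free-energy difference F(extra) - F(intra) between
#' the two state regions. Under detailed balance the two agree in the deep
#' two-state limit, independently of the diffusivity profile.
#'
#' @param tauForward,tauBackward MFPTs (any common time unit).
#' @param profile A [FreeEnergyProfile-class].
#' @param regionIntra,regionExtra State regions in degrees (length-2
#'   intervals, traversed upward mod period).
#' @return List with `Kkin`, `Kthermo`, `logRatio` = log(Kkin/Kthermo) and
#'   `deltaF` (kcal/mol).
#' @export
equilibriumCheck <- function(tauForward, tauBackward, profile, regionIntra,
                             regionExtra) {
  stopifnot(tauForward > 0, tauBackward > 0)
  dF <- stateDeltaF(profile, regionIntra, regionExtra)
  kT <- thermalEnergy(profile@temperature)
  Kkin <- tauBackward / tauForward
  Kthermo <- exp(-dF / kT)
  list(Kkin = Kkin, Kthermo = Kthermo, logRatio = log(Kkin / Kthermo),
       deltaF = dF)
}

#' MFPTs with one average (constant) diffusion coefficient
#'
#' Recomputes both MFPTs with D replaced by the arithmetic mean of the window
#' diffusivities and reports the ratio to the local-D result. Roughness in
#' D(xi) slows the passage, so the constant-D times are typically shorter.
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param diffusivity A [DiffusivityProfile-class].
#' @param reflectAt,absorbAt Boundaries in degrees (intra / extra).
#' @param nGrid Number of quadrature nodes.
#' @return List with `Dbar` (rad^2/ps), `tauForward`, `tauBackward` (ps,
#'   constant-D), and `ratioForward`, `ratioBackward` (local-D tau divided by
#'   constant-D tau, >= 1 for rough D).
#' @export
constantDiffusivityVariant <- function(profile, diffusivity, reflectAt,
                                       absorbAt, nGrid = NULL) {
  stopifnot(is(diffusivity, "DiffusivityProfile"))
  Dbar <- mean(diffusivities(diffusivity))
  tfL <- mfptForward(profile, diffusivity, reflectAt, absorbAt, nGrid)
  tbL <- mfptBackward(profile, diffusivity, absorbAt = reflectAt,
                      reflectAt = absorbAt, nGrid = nGrid)
  tfC <- mfptForward(profile, Dbar, reflectAt, absorbAt, nGrid)
  tbC <- mfptBackward(profile, Dbar, absorbAt = reflectAt,
                      reflectAt = absorbAt, nGrid = nGrid)
  list(Dbar = Dbar, tauForward = tfC, tauBackward = tbC,
       ratioForward = tfL / tfC, ratioBackward = tbL / tbC)
}

#' Assemble a kinetics report
#'
#' Runs both MFPT integrals and the equilibrium cross-check and packages the
#' results, with times converted from ps to seconds.
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param diffusivity A [DiffusivityProfile-class] or constant D (rad^2/ps).
#' @param reflectAt,absorbAt Boundaries in degrees (intra / extra).
#' @param regionIntra,regionExtra State regions in degrees.
#' @param label System label.
#' @param nGrid Number of quadrature nodes.
#' @return A [KineticsReport-class].
#' @export
kineticsReport <- function(profile, diffusivity, reflectAt, absorbAt,
                           regionIntra, regionExtra, label = "system",
                           nGrid = NULL) {
  tf <- mfptForward(profile, diffusivity, reflectAt, absorbAt, nGrid)
  tb <- mfptBackward(profile, diffusivity, absorbAt = reflectAt,
                     reflectAt = absorbAt, nGrid = nGrid)
  eq <- equilibriumCheck(tf, tb, profile, regionIntra, regionExtra)
  mode <- if (is(diffusivity, "DiffusivityProfile")) "local" else "constant"
  psToS <- 1e-12
  new("KineticsReport", label = label, tauForward = tf * psToS,
      tauBackward = tb * psToS, kForward = 1 / (tf * psToS),
      kBackward = 1 / (tb * psToS), Keq = eq$Kkin, KeqThermo = eq$Kthermo,
      deltaF = eq$deltaF, reflectAt = reflectAt, absorbAt = absorbAt,
      diffusivityMode = mode)
}

#' Write a kinetics report as a flat key-value record
#'
#' @param report A [KineticsReport-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeKineticsReport <- function(report, path) {
  stopifnot(is(report, "KineticsReport"))
  lines <- c(
    sprintf("system %s", report@label),
    sprintf("tau_forward_s %.10g", report@tauForward),
    sprintf("tau_backward_s %.10g", report@tauBackward),
    sprintf("k_forward_per_s %.10g", report@kForward),
    sprintf("k_backward_per_s %.10g", report@kBackward),
    sprintf("K_eq_kinetic %.10g", report@Keq),
    sprintf("K_eq_thermo %.10g", report@KeqThermo),
    sprintf("delta_F_kcal_mol %.10g", report@deltaF),
    sprintf("reflect_at_deg %.10g", report@reflectAt),
    sprintf("absorb_at_deg %.10g", report@absorbAt),
    sprintf("diffusivity_mode %s", report@diffusivityMode))
  writeLines(lines, path)
  invisible(path)
}

#' Read a table of mean first passage times
#'
#' Parses a plain-text MFPT summary table: one row per system with columns
#' system label, tau+ in seconds and tau- in seconds (whitespace-delimited,
#' `#` comments, scientific notation). Returns the times both in seconds and
#' in microseconds.
#'
#' @param path Path to the table.
#' @return Data frame with columns `system`, `tauForward`, `tauBackward`
#'   (seconds), `tauForwardUs`, `tauBackwardUs` (microseconds).
#' @export
readMFPTTable <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("system", "tauForward", "tauBackward"),
                    stringsAsFactors = FALSE)
  if (!is.numeric(tab$tauForward) || !is.numeric(tab$tauBackward))
    stop("MFPT columns must be numeric (seconds)")
  tab$tauForwardUs <- tab$tauForward * 1e6
  tab$tauBackwardUs <- tab$tauBackward * 1e6
  tab
}
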