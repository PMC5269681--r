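#' Construct an AngleSeries
#'
#' @param values Angle samples in degrees (one branch, unwrapped).
#' @param dt Sampling interval in ps.
#' @param label Source label.
#' @return An [AngleSeries-class].
#' @export
angleSeries <- function(values, dt, label = "") {
  new("AngleSeries", dt = dt, values = as.numeric(values), label = label)
}

#' Construct an UmbrellaWindow
#'
#' The series is unwrapped to the branch of the window center. A warning is
#' issued if any sample ends up more than 90 degrees from the center: that is
#' almost always a sign of a mislabeled window or an unconverged run.
#'
#' @param center Window center in degrees.
#' @param series An [AngleSeries-class].
#' @param forceConstant Torsion force constant in kcal/(mol rad^2); the
#'   production default is 400.
#' @param temperature Temperature in K (default 300).
#' @return An [UmbrellaWindow-class].
#' @export
umbrellaWindow <- function(center, series, forceConstant = 400,
                          temperature = 300) {
  vals <- unwrapToBranch(series@values, center)
  if (any(abs(vals - center) > 90))
    warning(sprintf(
      "window at %.1f deg: samples stray more than 90 deg from the center",
      center))
  new("UmbrellaWindow", center = center, forceConstant = forceConstant,
      temperature = temperature,
      series = angleSeries(vals, series@dt, series@label))
}

#' Construct a WindowSet
#'
#' @param windows List of [UmbrellaWindow-class] objects; they are sorted by
#'   center.
#' @param period Coordinate period in degrees (default 360).
#' @param metadata Optional free-form list.
#' @return A [WindowSet-class].
#' @export
windowSet <- function(windows, period = 360, metadata = list()) {
  ctr <- vapply(windows, windowCenter, numeric(1))
  new("WindowSet", windows = windows[order(ctr)], period = period,
      metadata = metadata)
}

#' Load one umbrella-window time series from a text file
#'
#' Reads a two-column whitespace-delimited file (time in ps, angle in
#' degrees). Lines starting with `#` are comments; scientific notation is
#' accepted. The sampling interval is inferred from the first two times and
#' checked to be constant (tolerance 1e-6 ps); angles are unwrapped to the
#' branch of the window center. An optional burn-in fraction discards the
#' start of the series.
#'
#' @param path Path to the series file.
#' @param center Window center in degrees.
#' @param forceConstant Force constant in kcal/(mol rad^2) (default 400).
#' @param temperature Temperature in K (default 300).
#' @param burnIn Fraction of samples to discard from the start (default 0).
#' @return An [UmbrellaWindow-class].
#' @export
loadWindowSeries <- function(path, center, forceConstant = 400,
                             temperature = 300, burnIn = 0) {
  stopifnot(burnIn >= 0, burnIn < 1)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  dat <- lines[keep]
  lineNo <- which(keep)
  if (length(dat) < 2)
    stop("series file '", path, "' has fewer than 2 samples")
  toks <- strsplit(trimws(dat), "\\s+")
  nf <- lengths(toks)
  if (any(nf != 2))
    stop("ragged row in '", path, "' at line ", lineNo[which(nf != 2)[1]],
         ": expected 2 columns, found ", nf[which(nf != 2)[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 2,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("non-numeric value in '", path, "' at line ", lineNo[bad])
  }
  tm <- m[, 1]
  if (any(diff(tm) <= 0))
    stop("non-monotone time column in '", path, "'")
  dt <- tm[2] - tm[1]
  if (any(abs(diff(tm) - dt) > 1e-6))
    stop("non-uniform sampling interval in '", path, "'")
  vals <- m[, 2]
  if (burnIn > 0) vals <- vals[-seq_len(floor(burnIn * length(vals)))]
  if (length(vals) < 2) stop("fewer than 2 samples left after burn-in")
  umbrellaWindow(center, angleSeries(vals, dt, label = basename(path)),
                 forceConstant = forceConstant, temperature = temperature)
}

#' Write one umbrella-window series to a text file
#'
#' Inverse of [loadWindowSeries()]: two whitespace-delimited columns (time in
#' ps from 0, angle in degrees) with a `#` header recording center, force
#' constant and temperature. Values are written with full precision so that a
#' load/write/load cycle round-trips exactly.
#'
#' @param window An [UmbrellaWindow-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeWindowSeries <- function(window, path) {
  stopifnot(is(window, "UmbrellaWindow"))
  v <- angleValues(window)
  dt <- samplingInterval(window)
  tm <- (seq_along(v) - 1) * dt
  hdr <- c(sprintf("# center_deg %.17g", windowCenter(window)),
           sprintf("# force_constant_kcal_mol_rad2 %.17g",
                   forceConstant(window)),
           sprintf("# temperature_K %.17g", temperature(window)),
           "# time_ps angle_deg")
  writeLines(c(hdr, sprintf("%.17g %.17g", tm, v)), path)
  invisible(path)
}

#' Coverage report for a window set
#'
#' Reports window count, spacing, span, whether the set closes the full
#' period (span + spacing >= period), and any gaps larger than twice the
#' typical spacing. Report-only: nothing is modified and no error is raised.
#'
#' @param ws A [WindowSet-class].
#' @return A list with elements `nWindows`, `spacing` (median neighbor
#'   spacing, degrees), `span` (degrees), `periodicClosure` (logical), and
#'   `gaps` (data frame of flagged neighbor pairs).
#' @export
validateCoverage <- function(ws) {
  stopifnot(is(ws, "WindowSet"))
  ctr <- centers(ws)
  n <- length(ctr)
  if (n == 1) {
    return(list(nWindows = 1L, spacing = NA_real_, span = 0,
                periodicClosure = FALSE,
                gaps = data.frame(from = numeric(0), to = numeric(0),
                                  gap = numeric(0))))
  }
  d <- diff(ctr)
  spacing <- median(d)
  span <- max(ctr) - min(ctr)
  # a gap is a neighbour distance of at least twice the tightest spacing
  flag <- d >= 2 * min(d) * (1 - 1e-9) & d > min(d)
  gaps <- data.frame(from = ctr[-n][flag], to = ctr[-1][flag], gap = d[flag])
  list(nWindows = as.integer(n), spacing = spacing, span = span,
       periodicClosure = (span + spacing) >= ws@period, gaps = gaps)
}

#' Split every window's series into contiguous segments
#'
#' Each returned WindowSet holds the i-th equal-length contiguous slice of
#' every window's series (slice length floor(n/nSegments) per window;
#' remainders are dropped from the end). Used for segment-wise convergence
#' analysis of the free-energy profile.
#'
#' @param ws A [WindowSet-class].
#' @param nSegments Number of segments (>= 1).
#' @return List of `nSegments` [WindowSet-class] objects.
#' @export
splitSegments <- function(ws, nSegments) {
  stopifnot(is(ws, "WindowSet"))
  if (!is.numeric(nSegments) || nSegments < 1)
    stop("nSegments must be >= 1")
  nSegments <- as.integer(nSegments)
  lens <- vapply(windows(ws), function(w) length(angleValues(w)), integer(1))
  if (any(lens < nSegments))
    stop("every series must have at least nSegments samples")
  lapply(seq_len(nSegments), function(i) {
    ws2 <- lapply(windows(ws), function(w) {
      v <- angleValues(w)
      m <- length(v) %/% nSegments
      slice <- v[((i - 1) * m + 1):(i * m)]
      umbrellaWindow(windowCenter(w),
                     angleSeries(slice, samplingInterval(w),
                                 windowSeries(w)@label),
                     forceConstant = forceConstant(w),
                     temperature = temperature(w))
    })
    windowSet(ws2, period = ws@period)
  })
}
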