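# stage logging helper: every stage reports its name and key parameters
.logStage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration driving [runAnalysis()]. Recognized keys:
#' \describe{
#'   \item{windows}{Either a directory written by [writeWindowSet()]
#'     (`windows: path/`), or a list of `{path, center}` entries with
#'     optional `force_constant` and `temperature`.}
#'   \item{temperature}{Default temperature in K (300).}
#'   \item{force_constant}{Default umbrella force constant (400).}
#'   \item{burn_in}{Burn-in fraction per window (0).}
#'   \item{bin_width}{WHAM bin width in degrees (2).}
#'   \item{use_inefficiency}{Down-weight histograms by statistical
#'     inefficiency (FALSE).}
#'   \item{n_segments}{Segment count for the convergence RMSD table (0 =
#'     skip).}
#'   \item{smoothing_window}{Extrema smoothing in bins (1).}
#'   \item{intra_near, extra_near}{Hints (degrees) selecting the
#'     intra-/extra-helical minima among the located extrema (30 / -135).}
#'   \item{reflect_at, absorb_at}{Explicit boundary override (degrees).}
#'   \item{region_intra, region_extra}{Explicit state regions (length-2).}
#'   \item{diffusivity_mode}{"local" (default) or "constant".}
#'   \item{fep}{Optional: list of per-window one-column dU series paths
#'     (restraint-removal direction), applied as a profile correction.}
#'   \item{output_dir}{Where [runAnalysis()] writes its files.}
#'   \item{label}{System label for the kinetics report.}
#' }
#'
#' @param path Path to a YAML file.
#' @return A validated config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg A config list (as from [yaml::read_yaml()]).
#' @export
validatePipelineConfig <- function(cfg) {
  defaults <- list(temperature = 300, force_constant = 400, burn_in = 0,
                   bin_width = 2, use_inefficiency = FALSE, n_segments = 0,
                   smoothing_window = 1, intra_near = 30, extra_near = -135,
                   diffusivity_mode = "local", label = "system",
                   output_dir = ".")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$windows)) stop("config must name the umbrella windows")
  if (!cfg$diffusivity_mode %in% c("local", "constant"))
    stop("diffusivity_mode must be 'local' or 'constant'")
  root <- if (is.null(cfg$.dir)) "." else cfg$.dir
  resolve <- function(p) if (file.exists(p)) p else file.path(root, p)
  if (is.character(cfg$windows)) {
    cfg$windows <- resolve(cfg$windows)
    if (!dir.exists(cfg$windows))
      stop("window directory not found: ", cfg$windows)
  } else {
    for (i in seq_along(cfg$windows)) {
      cfg$windows[[i]]$path <- resolve(cfg$windows[[i]]$path)
      if (!file.exists(cfg$windows[[i]]$path))
        stop("window series not found: ", cfg$windows[[i]]$path)
      if (is.null(cfg$windows[[i]]$center))
        stop("every window entry needs a center")
    }
  }
  if (!is.null(cfg$fep)) {
    for (i in seq_along(cfg$fep$series)) {
      cfg$fep$series[[i]] <- resolve(cfg$fep$series[[i]])
      if (!file.exists(cfg$fep$series[[i]]))
        stop("FEP series not found: ", cfg$fep$series[[i]])
    }
  }
  cfg
}

.loadConfigWindows <- function(cfg) {
  if (is.character(cfg$windows))
    return(readWindowSet(cfg$windows, burnIn = cfg$burn_in))
  wins <- lapply(cfg$windows, function(w) {
    loadWindowSeries(
      w$path, center = w$center,
      forceConstant = if (is.null(w$force_constant)) cfg$force_constant
                      else w$force_constant,
      temperature = if (is.null(w$temperature)) cfg$temperature
                    else w$temperature,
      burnIn = cfg$burn_in)
  })
  windowSet(wins)
}

# choose intra/extra minima from located extrema by periodic proximity to
# the hints, and derive boundaries and basin regions
.pickStates <- function(profile, extrema, intraNear, extraNear) {
  mins <- extrema[extrema$kind == "min", , drop = FALSE]
  maxs <- extrema[extrema$kind == "max", , drop = FALSE]
  if (nrow(mins) < 2)
    stop("need at least two minima to define intra/extra states")
  nearest <- function(target) {
    d <- abs(.periodicDiff(mins$position, target))
    mins$position[which.min(d)]
  }
  intra <- nearest(intraNear)
  extra <- nearest(extraNear)
  if (abs(.periodicDiff(intra, extra)) < 1e-9)
    stop("intra and extra hints select the same minimum")
  # basins: delimited by the two flanking maxima when the landscape is
  # two-state; otherwise split at midpoints of the connecting arcs
  if (nrow(maxs) == 2) {
    b <- sort(wrapAngle(maxs$position))
    inBetween <- .inRegion(intra, c(b[1], b[2]))
    regionIntra <- if (inBetween) c(b[1], b[2]) else c(b[2], b[1])
    regionExtra <- if (inBetween) c(b[2], b[1]) else c(b[1], b[2])
  } else {
    up <- angularPath(intra, extra, "positive")
    m1 <- intra + up / 2
    m2 <- extra + (360 - up) / 2
    regionIntra <- c(wrapAngle(m2), wrapAngle(m1))
    regionExtra <- c(wrapAngle(m1), wrapAngle(m2))
  }
  # boundaries on the unwrapped branch: absorb reached from the reflecting
  # intra minimum along the positive (major-groove) direction
  list(intra = intra, extra = extra,
       reflectAt = intra,
       absorbAt = intra + angularPath(intra, extra, "positive"),
       regionIntra = regionIntra, regionExtra = regionExtra)
}

#' Run the full umbrella-to-kinetics analysis
#'
#' Stages: load windows, coverage report, (optional) segment convergence,
#' WHAM profile, (optional) per-window FEP restraint correction, extrema and
#' state assignment, per-window diffusivity, MFPT double integrals with the
#' equilibrium cross-check, and the constant-diffusivity variant. Writes
#' `profile.txt` (bin center, F, occupancy), `diffusivity.txt`,
#' `convergence_rmsd.txt` (if requested), `fep_corrections.txt` (if
#' requested) and `kinetics_report.txt` into the output directory; every
#' output carries a header stating units and bias conventions.
#'
#' @param config A config list ([readPipelineConfig()] /
#'   [validatePipelineConfig()]) or the path to a YAML config.
#' @return Invisibly, a list bundle: `windowSet`, `coverage`, `profile`,
#'   `diffusivity`, `extrema`, `states`, `report` (local or constant mode per
#'   config), `constantVariant`, `equilibrium`, `segmentsRMSD`, `fep`.
#' @export
runAnalysis <- function(config) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else validatePipelineConfig(config)
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  .logStage("load", "reading umbrella windows (burn-in %.2f)", cfg$burn_in)
  ws <- .loadConfigWindows(cfg)
  cov <- validateCoverage(ws)
  .logStage("coverage", "%d windows, spacing %.3g deg, span %.4g deg, closure: %s",
            cov$nWindows, cov$spacing, cov$span, cov$periodicClosure)
  if (nrow(cov$gaps) > 0)
    warning("coverage gaps flagged at: ",
            paste(sprintf("%.1f-%.1f", cov$gaps$from, cov$gaps$to),
                  collapse = ", "))

  ineff <- NULL
  if (isTRUE(cfg$use_inefficiency)) {
    .logStage("wham", "estimating per-window statistical inefficiencies")
    ineff <- vapply(windows(ws), statisticalInefficiency, numeric(1))
  }
  .logStage("wham", "bin width %.3g deg, tol 1e-7 kcal/mol", cfg$bin_width)
  profile <- wham(ws, binWidth = cfg$bin_width, inefficiency = ineff)

  segRMSD <- NULL
  if (cfg$n_segments >= 2) {
    .logStage("convergence", "%d segments", cfg$n_segments)
    segs <- splitSegments(ws, cfg$n_segments)
    segProfiles <- lapply(segs, wham, binWidth = cfg$bin_width,
                          gridOrigin = binCenters(profile)[1] -
                            cfg$bin_width / 2)
    segRMSD <- convergenceRMSD(segProfiles)
    .writeMatrix(segRMSD, file.path(outDir, "convergence_rmsd.txt"),
                 "pairwise segment RMSD, kcal/mol (zero-mean referenced)")
  }

  fepOut <- NULL
  if (!is.null(cfg$fep)) {
    .logStage("fep", "restraint-release correction for %d windows",
              length(cfg$fep$series))
    temp <- if (is.null(cfg$fep$temperature)) cfg$temperature
            else cfg$fep$temperature
    corr <- vapply(cfg$fep$series, function(p) {
      dU <- scan(p, quiet = TRUE, comment.char = "#")
      fepDeltaF(perturbationSeries(dU, temp))$deltaF
    }, numeric(1))
    ctrs <- centers(ws)
    if (length(corr) != length(ctrs))
      stop("one FEP series per window required")
    profile <- applyFEPCorrection(profile, ctrs, corr)
    fepOut <- data.frame(center = ctrs, deltaF = corr)
    .writeTable(fepOut, file.path(outDir, "fep_corrections.txt"),
                "per-window restraint-release dF, kcal/mol")
  }

  ext <- locateExtrema(profile, smoothingWindow = cfg$smoothing_window)
  if (!is.null(cfg$reflect_at) && !is.null(cfg$absorb_at)) {
    states <- list(reflectAt = cfg$reflect_at, absorbAt = cfg$absorb_at,
                   intra = cfg$reflect_at, extra = cfg$absorb_at)
  } else {
    states <- .pickStates(profile, ext, cfg$intra_near, cfg$extra_near)
  }
  if (!is.null(cfg$region_intra)) states$regionIntra <- cfg$region_intra
  if (!is.null(cfg$region_extra)) states$regionExtra <- cfg$region_extra
  .logStage("states", "reflecting %.1f deg, absorbing %.1f deg",
            states$reflectAt, states$absorbAt)

  .logStage("diffusivity", "per-window var/tau_int estimates")
  dp <- diffusivityProfile(ws)
  .writeTable(data.frame(center = centers(dp), D = diffusivities(dp)),
              file.path(outDir, "diffusivity.txt"),
              "local diffusivity, rad^2/ps, from var(xi)/tau_int per window")

  .logStage("kinetics", "Smoluchowski double integrals (%s diffusivity)",
            cfg$diffusivity_mode)
  diffArg <- if (cfg$diffusivity_mode == "local") dp
             else mean(diffusivities(dp))
  report <- kineticsReport(profile, diffArg, states$reflectAt,
                           states$absorbAt, states$regionIntra,
                           states$regionExtra, label = cfg$label)
  cv <- constantDiffusivityVariant(profile, dp, states$reflectAt,
                                   states$absorbAt)
  eq <- equilibriumCheck(report@tauForward, report@tauBackward, profile,
                         states$regionIntra, states$regionExtra)

  .writeProfile(profile, file.path(outDir, "profile.txt"))
  writeKineticsReport(report, file.path(outDir, "kinetics_report.txt"))
  .logStage("done", "tau+ = %.4g s, tau- = %.4g s", report@tauForward,
            report@tauBackward)

  invisible(list(windowSet = ws, coverage = cov, profile = profile,
                 diffusivity = dp, extrema = ext, states = states,
                 report = report, constantVariant = cv, equilibrium = eq,
                 segmentsRMSD = segRMSD, fep = fepOut))
}

.writeProfile <- function(profile, path) {
  hdr <- c("# free-energy profile: bin_center_deg F_kcal_mol occupancy",
           sprintf("# temperature_K %.6g, period_deg %.6g, min-referenced",
                   profile@temperature, profile@period),
           "# bias convention: U_i = k/2 (xi - xi_i)^2, k in kcal/(mol rad^2)")
  body <- sprintf("%.6f %s %d", binCenters(profile),
                  ifelse(is.na(profileValues(profile)), "NA",
                         sprintf("%.8f", profileValues(profile))),
                  as.integer(occupancy(profile)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

.writeTable <- function(df, path, comment) {
  writeLines(c(paste("#", comment),
               paste("#", paste(names(df), collapse = " ")),
               do.call(sprintf,
                       c(list(fmt = paste(rep("%.10g", ncol(df)),
                                          collapse = " ")),
                         unname(df)))),
             path)
  invisible(path)
}

.writeMatrix <- function(m, path, comment) {
  writeLines(c(paste("#", comment),
               apply(m, 1, function(r) paste(sprintf("%.6g", r),
                                             collapse = " "))),
             path)
  invisible(path)
}

#' Read a profile written by [runAnalysis()]
#'
#' @param path Path to `profile.txt`.
#' @param temperature Temperature in K (default: parsed from the header).
#' @return A [FreeEnergyProfile-class].
#' @export
readProfile <- function(path, temperature = NULL) {
  lines <- readLines(path)
  if (is.null(temperature)) {
    m <- regmatches(lines, regexec("temperature_K ([0-9.eE+-]+)", lines))
    hit <- which(lengths(m) == 2)[1]
    temperature <- if (is.na(hit)) 300 else as.numeric(m[[hit]][2])
  }
  tab <- read.table(path, comment.char = "#",
                    col.names = c("center", "F", "occupancy"))
  Fv <- tab$F
  occ <- tab$occupancy
  Fv[occ > 0] <- Fv[occ > 0] - min(Fv[occ > 0])
  new("FreeEnergyProfile", binCenters = tab$center, values = Fv,
      occupancy = occ, period = 360, temperature = temperature)
}

#' Synthetic end-to-end benchmark: campaign, WHAM, diffusivity, MFPT
#'
#' Generates an umbrella campaign on a known model system, runs the full
#' analysis, and scores the recovery: RMS of the WHAM profile against the
#' model PMF (after zero-mean alignment on occupied bins), the mean
#' diffusivity against the model baseline, and the double-integral MFPT
#' against a brute-force Langevin first-passage oracle. The campaign is
#' propagated without replica exchange so that the window time correlations
#' that feed the diffusivity estimator are uninterrupted (exchange is
#' validated separately as leaving the window marginals unchanged).
#'
#' @param model A [ModelSystem-class] (default: the double-well preset with
#'   constant diffusivity).
#' @param windowCenters Window centers in degrees (default -320..38 step 2).
#' @param kU Umbrella force constant (default 400 kcal/(mol rad^2)).
#' @param spec Per-window [SimulationSpec-class] (default 1e6 x 0.01 ps,
#'   stride 10).
#' @param oracleWalkers Number of first-passage walkers (default 1e4).
#' @param oracleDt Oracle timestep in ps (default 0.5).
#' @param seed Integer seed for campaign and oracle.
#' @param maxLag Autocorrelation lag cap in samples for the diffusivity
#'   estimates (default 400).
#' @return List with `model`, `windowSet`, `profile`, `pmfRMS` (kcal/mol),
#'   `diffusivity`, `meanD`, `dRatio` (mean estimated / true baseline),
#'   `tauForward` (ps), `oracle` (list), `mfptRatio` (double integral /
#'   oracle mean), `states`, and `verdicts` (named logical vector).
#' @export
runBenchmark <- function(model = modelSystem("double-well"),
                         windowCenters = seq(-320, 38, by = 2), kU = 400,
                         spec = simulationSpec(), oracleWalkers = 1e4,
                         oracleDt = 0.5, seed = 1, maxLag = 400) {
  .logStage("benchmark", "campaign: %d windows x %g steps, seed %d",
            length(windowCenters), spec@steps, seed)
  ws <- runUmbrellaCampaign(model, windowCenters, kU = kU, spec = spec,
                            exchangeEvery = 0, seed = seed)
  .logStage("benchmark", "WHAM")
  profile <- wham(ws)
  gt <- modelPMF(model, binCenters(profile))
  occ <- occupancy(profile) > 0
  dev <- (profileValues(profile) - gt)[occ]
  dev <- dev - mean(dev)
  pmfRMS <- sqrt(mean(dev^2))

  .logStage("benchmark", "diffusivity (%d windows)", nWindows(ws))
  dp <- diffusivityProfile(ws, maxLag = maxLag)
  meanD <- mean(diffusivities(dp))
  dRatio <- meanD / exp(model@logD0)

  ext <- locateExtrema(profile, smoothingWindow = 3)
  states <- .pickStates(profile, ext, 30, -135)
  .logStage("benchmark", "MFPT integrals, reflecting %.1f, absorbing %.1f",
            states$reflectAt, states$absorbAt)
  tauF <- mfptForward(profile, dp, states$reflectAt, states$absorbAt)

  .logStage("benchmark", "first-passage oracle: %d walkers, dt %.2g ps",
            oracleWalkers, oracleDt)
  oracle <- firstPassageOracle(model, states$reflectAt, states$absorbAt,
                               nWalkers = oracleWalkers, dt = oracleDt,
                               seed = seed + 1)
  mfptRatio <- tauF / oracle$mean
  verdicts <- c(pmf = pmfRMS < 0.3,
                diffusivity = abs(dRatio - 1) < 0.1,
                mfpt = abs(mfptRatio - 1) < 0.15)
  .logStage("benchmark",
            "PMF RMS %.3f kcal/mol | mean D ratio %.3f | MFPT ratio %.3f",
            pmfRMS, dRatio, mfptRatio)
  list(model = model, windowSet = ws, profile = profile, pmfRMS = pmfRMS,
       diffusivity = dp, meanD = meanD, dRatio = dRatio, tauForward = tauF,
       oracle = oracle, mfptRatio = mfptRatio, states = states,
       verdicts = verdicts)
}

#' Plot a free-energy or diffusivity profile
#'
#' @param profile A [FreeEnergyProfile-class] or [DiffusivityProfile-class].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plotProfile <- function(profile, ...) {
  if (is(profile, "FreeEnergyProfile")) {
    graphics::plot(binCenters(profile), profileValues(profile), type = "l",
                   xlab = "reaction coordinate (deg)",
                   ylab = "F (kcal/mol)", ...)
  } else if (is(profile, "DiffusivityProfile")) {
    graphics::plot(centers(profile), diffusivities(profile), type = "b",
                   log = "y", xlab = "reaction coordinate (deg)",
                   ylab = "D (rad^2/ps)", ...)
  } else stop("unsupported profile type")
  invisible(NULL)
}
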