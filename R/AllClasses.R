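#' Class "AngleSeries": a sampled angular time series
#'
#' One umbrella window's reaction-coordinate trace: equally spaced samples of
#' the flipping pseudo-dihedral, stored in degrees on a single branch
#' (unwrapped, i.e. not folded into (-180, 180]).
#'
#' @slot dt Sampling interval in ps.
#' @slot values Angle samples in degrees, unwrapped to one branch.
#' @slot label Free-text source label (e.g. the file the series came from).
#' @exportClass AngleSeries
setClass("AngleSeries",
  representation(dt = "numeric", values = "numeric", label = "character"),
  prototype(label = "")
)

setValidity("AngleSeries", function(object) {
  if (length(object@dt) != 1 || !is.finite(object@dt) || object@dt <= 0)
    return("dt must be a single positive number (ps)")
  if (length(object@values) < 2)
    return("an angle series needs at least 2 samples")
  if (!all(is.finite(object@values)))
    return("all angle values must be finite")
  TRUE
})

#' Class "UmbrellaWindow": one biased sampling window
#'
#' A harmonic umbrella window along the flipping coordinate: its center,
#' torsional force constant, temperature, and the sampled series. The bias is
#' U(xi) = k/2 * (xi - center)^2 with the angular difference taken in radians
#' on the window's branch.
#'
#' @slot center Window center in degrees (on the unwrapped branch).
#' @slot forceConstant Torsion force constant in kcal/(mol rad^2).
#' @slot temperature Temperature in K.
#' @slot series An [AngleSeries-class] with the sampled coordinate.
#' @exportClass UmbrellaWindow
setClass("UmbrellaWindow",
  representation(center = "numeric", forceConstant = "numeric",
                 temperature = "numeric", series = "AngleSeries")
)

setValidity("UmbrellaWindow", function(object) {
  if (length(object@center) != 1 || !is.finite(object@center))
    return("center must be a single finite number (degrees)")
  if (length(object@forceConstant) != 1 || object@forceConstant <= 0)
    return("forceConstant must be positive (kcal/(mol rad^2))")
  if (length(object@temperature) != 1 || object@temperature <= 0)
    return("temperature must be positive (K)")
  TRUE
})

#' Class "WindowSet": an ordered collection of umbrella windows
#'
#' Windows sorted by center on a common unwrapped branch, with the declared
#' period of the reaction coordinate (360 degrees for a dihedral).
#'
#' @slot windows List of [UmbrellaWindow-class] objects, centers strictly
#'   increasing.
#' @slot period Coordinate period in degrees.
#' @slot metadata Free-form list (e.g. realized replica-exchange acceptance).
#' @exportClass WindowSet
setClass("WindowSet",
  representation(windows = "list", period = "numeric", metadata = "list"),
  prototype(period = 360, metadata = list())
)

setValidity("WindowSet", function(object) {
  if (length(object@windows) < 1) return("at least one window required")
  if (!all(vapply(object@windows, is, logical(1), class2 = "UmbrellaWindow")))
    return("all elements must be UmbrellaWindow objects")
  ctr <- vapply(object@windows, function(w) w@center, numeric(1))
  if (any(diff(ctr) <= 0))
    return("window centers must be strictly increasing on the unwrapped branch")
  if (length(object@period) != 1 || object@period <= 0)
    return("period must be a single positive number (degrees)")
  TRUE
})

#' Class "FreeEnergyProfile": F(xi) on a periodic angular grid
#'
#' The potential of mean force on uniform bins covering one period, in
#' kcal/mol, referenced so that the global minimum is zero. Bins with no
#' samples carry NA (undefined), never +Inf, so that downstream integrals are
#' restricted to the occupied range.
#'
#' @slot binCenters Bin centers in degrees, strictly increasing, uniform.
#' @slot values F in kcal/mol (NA where unoccupied); min over occupied bins 0.
#' @slot occupancy Per-bin sample counts used in the estimate.
#' @slot period Coordinate period in degrees.
#' @slot temperature Temperature in K.
#' @exportClass FreeEnergyProfile
setClass("FreeEnergyProfile",
  representation(binCenters = "numeric", values = "numeric",
                 occupancy = "numeric", period = "numeric",
                 temperature = "numeric"),
  prototype(period = 360)
)

setValidity("FreeEnergyProfile", function(object) {
  n <- length(object@binCenters)
  if (n < 2) return("need at least 2 bins")
  if (length(object@values) != n || length(object@occupancy) != n)
    return("binCenters, values and occupancy must have equal length")
  w <- diff(object@binCenters)
  if (any(w <= 0)) return("bin centers must be strictly increasing")
  if (max(w) - min(w) > 1e-6 * mean(w)) return("bins must be uniform")
  occ <- object@values[object@occupancy > 0]
  if (any(!is.finite(occ)))
    return("F must be finite on occupied bins")
  if (length(occ) && abs(min(occ)) > 1e-8)
    return("profile must be referenced to min(F) = 0 on occupied bins")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' Class "DiffusivityProfile": local D(xi) at window centers
#'
#' Position-dependent diffusion coefficients of the reaction coordinate, one
#' per analyzed window, in rad^2/ps. The interpolation tag records how values
#' are carried onto other grids (log-linear between centers, clamped at the
#' ends).
#'
#' @slot centers Window centers in degrees.
#' @slot values D in rad^2/ps, strictly positive.
#' @slot interpolation Interpolation rule tag ("loglinear").
#' @exportClass DiffusivityProfile
setClass("DiffusivityProfile",
  representation(centers = "numeric", values = "numeric",
                 interpolation = "character"),
  prototype(interpolation = "loglinear")
)

setValidity("DiffusivityProfile", function(object) {
  if (length(object@centers) != length(object@values))
    return("centers and values must have equal length")
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    return("all diffusivities must be finite and positive")
  if (any(diff(object@centers) <= 0))
    return("centers must be strictly increasing")
  TRUE
})

#' Class "CorrelationEstimate": Hess-style autocorrelation analysis
#'
#' Normalized autocorrelation of a window series together with a
#' double-exponential fit C(t) = A exp(-t/tau1) + (1-A) exp(-t/tau2) and the
#' integrated autocorrelation time tau_int = A tau1 + (1-A) tau2. A
#' block-averaging standard-error curve may be attached as a consistency
#' diagnostic.
#'
#' @slot lags Lag times in ps (starting at 0).
#' @slot acf Normalized autocorrelation values, acf[1] = 1.
#' @slot amplitude Fitted fast-component amplitude A in [0, 1].
#' @slot tau1,tau2 Fitted decay times in ps.
#' @slot tauInt Integrated autocorrelation time in ps.
#' @slot fitted TRUE if the double-exponential fit succeeded; FALSE when the
#'   estimate fell back to direct integration of C(t).
#' @slot blockSE Data frame (blockLength, se) from block averaging; may be
#'   empty.
#' @exportClass CorrelationEstimate
setClass("CorrelationEstimate",
  representation(lags = "numeric", acf = "numeric", amplitude = "numeric",
                 tau1 = "numeric", tau2 = "numeric", tauInt = "numeric",
                 fitted = "logical", blockSE = "data.frame"),
  prototype(blockSE = data.frame())
)

setValidity("CorrelationEstimate", function(object) {
  if (abs(object@acf[1] - 1) > 1e-8) return("C(0) must be 1")
  if (object@tau1 <= 0 || object@tau2 <= 0) return("tau1, tau2 must be > 0")
  if (object@amplitude < 0 || object@amplitude > 1)
    return("amplitude must lie in [0, 1]")
  ti <- object@amplitude * object@tau1 + (1 - object@amplitude) * object@tau2
  if (abs(ti - object@tauInt) > 1e-6 * max(1, ti))
    return("tauInt must equal A*tau1 + (1-A)*tau2")
  TRUE
})

#' Class "KineticsReport": mean first passage times and rates
#'
#' The end product of the kinetics stage: forward/backward mean first passage
#' times in seconds, the corresponding rates, the kinetic equilibrium constant
#' K = tau-/tau+, its thermodynamic counterpart exp(-dF/kT), the state
#' free-energy difference, the boundary placement and the diffusivity mode
#' used.
#'
#' @slot label System label.
#' @slot tauForward,tauBackward MFPTs in seconds.
#' @slot kForward,kBackward Rates in 1/s.
#' @slot Keq Kinetic equilibrium constant tauBackward/tauForward.
#' @slot KeqThermo exp(-deltaF/kT) from the profile.
#' @slot deltaF State free-energy difference F(extra) - F(intra), kcal/mol.
#' @slot reflectAt,absorbAt Boundary positions in degrees.
#' @slot diffusivityMode "local" or "constant".
#' @exportClass KineticsReport
setClass("KineticsReport",
  representation(label = "character", tauForward = "numeric",
                 tauBackward = "numeric", kForward = "numeric",
                 kBackward = "numeric", Keq = "numeric", KeqThermo = "numeric",
                 deltaF = "numeric", reflectAt = "numeric",
                 absorbAt = "numeric", diffusivityMode = "character"),
  prototype(label = "system", diffusivityMode = "local")
)

setValidity("KineticsReport", function(object) {
  if (object@tauForward <= 0 || object@tauBackward <= 0)
    return("MFPTs must be positive")
  if (object@Keq <= 0) return("Keq must be positive")
  TRUE
})

#' Class "ModelSystem": synthetic ground truth for validation
#'
#' A periodic model free-energy landscape (truncated Fourier series, period
#' 360 degrees, kcal/mol) with a strictly positive diffusivity of log-Fourier
#' form, used to generate umbrella data with known ground truth.
#'
#' F(x)    = offset + sum_k fourierCos[k] cos(kx) + fourierSin[k] sin(kx)
#' log D(x) = logD0  + sum_k logDCos[k]  cos(kx) + logDSin[k]  sin(kx)
#'
#' with x in radians, D in rad^2/ps.
#'
#' @slot fourierCos,fourierSin PMF Fourier coefficients in kcal/mol.
#' @slot offset PMF constant term in kcal/mol.
#' @slot logDCos,logDSin log-diffusivity Fourier coefficients.
#' @slot logD0 log of the baseline diffusivity (D in rad^2/ps).
#' @slot temperature Temperature in K.
#' @slot preset Name of the preset the system was built from ("" if custom).
#' @exportClass ModelSystem
setClass("ModelSystem",
  representation(fourierCos = "numeric", fourierSin = "numeric",
                 offset = "numeric", logDCos = "numeric", logDSin = "numeric",
                 logD0 = "numeric", temperature = "numeric",
                 preset = "character"),
  prototype(offset = 0, logDCos = numeric(0), logDSin = numeric(0),
            temperature = 300, preset = "")
)

setValidity("ModelSystem", function(object) {
  if (length(object@fourierCos) != length(object@fourierSin))
    return("fourierCos and fourierSin must have equal length")
  if (length(object@logDCos) != length(object@logDSin))
    return("logDCos and logDSin must have equal length")
  if (!all(is.finite(c(object@fourierCos, object@fourierSin, object@offset,
                       object@logDCos, object@logDSin, object@logD0))))
    return("all coefficients must be finite")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' Class "MolecularStructure": atoms with coordinates and masses
#'
#' A light container for the atoms of a parsed PDB structure: one row per
#' atom with name, residue number/name, chain, element, mass (amu) and
#' Cartesian coordinates (Angstrom).
#'
#' @slot atoms Data frame with columns name, resno, resname, chain, element,
#'   mass, x, y, z.
#' @exportClass MolecularStructure
setClass("MolecularStructure", representation(atoms = "data.frame"))

setValidity("MolecularStructure", function(object) {
  a <- object@atoms
  need <- c("name", "resno", "resname", "chain", "element", "mass",
            "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("all atom coordinates must be finite")
    if (!all(is.finite(a$mass) & a$mass > 0))
      return("all atom masses must be positive")
  }
  TRUE
})

#' Class "GroupSpec": atom selection for one pseudo-dihedral center
#'
#' Selects the atoms whose (mass-weighted) mean position defines one of the
#' four centers of the flipping pseudo-dihedral: chain / residue-number /
#' atom-name-pattern triples, with optional hydrogen exclusion and a
#' mass-weighting flag.
#'
#' @slot selectors Data frame with columns chain, resno, pattern (regular
#'   expression on the atom name).
#' @slot massWeighted If TRUE (default) use the center of mass, else the
#'   unweighted centroid.
#' @slot heavyOnly If TRUE (default) exclude hydrogen atoms.
#' @exportClass GroupSpec
setClass("GroupSpec",
  representation(selectors = "data.frame", massWeighted = "logical",
                 heavyOnly = "logical"),
  prototype(massWeighted = TRUE, heavyOnly = TRUE)
)

setValidity("GroupSpec", function(object) {
  if (!all(c("chain", "resno", "pattern") %in% names(object@selectors)))
    return("selectors must have columns chain, resno, pattern")
  if (nrow(object@selectors) < 1) return("at least one selector required")
  TRUE
})

#' Class "PseudoDihedralSpec": the four centers of the flipping coordinate
#'
#' Exactly four [GroupSpec-class] entries, ordered center 1 to center 4. A
#' warning is emitted at evaluation time if groups share atoms.
#'
#' @slot groups List of four GroupSpec objects.
#' @exportClass PseudoDihedralSpec
setClass("PseudoDihedralSpec", representation(groups = "list"))

setValidity("PseudoDihedralSpec", function(object) {
  if (length(object@groups) != 4) return("exactly four groups required")
  if (!all(vapply(object@groups, is, logical(1), class2 = "GroupSpec")))
    return("all groups must be GroupSpec objects")
  TRUE
})

#' Class "RestraintSpec": a flat-bottom distance restraint
#'
#' Zero inside [lower, upper], harmonic with the given force constant outside;
#' continuous and once-differentiable at the bounds. Used for the
#' center-of-mass stacking restraint whose removal is corrected by FEP.
#'
#' @slot lower,upper Flat-bottom bounds in Angstrom, lower < upper.
#' @slot forceConstant Force constant in kcal/(mol A^2), >= 0.
#' @exportClass RestraintSpec
setClass("RestraintSpec",
  representation(lower = "numeric", upper = "numeric",
                 forceConstant = "numeric")
)

setValidity("RestraintSpec", function(object) {
  if (object@lower >= object@upper) return("lower must be < upper")
  if (object@forceConstant < 0) return("forceConstant must be >= 0")
  TRUE
})

#' Class "PerturbationSeries": energy differences for FEP
#'
#' Samples of dU = U_target - U_reference (kcal/mol) evaluated on frames of
#' the reference ensemble, plus the temperature, feeding the exponential
#' (Zwanzig) free-energy estimator.
#'
#' @slot deltaU Energy differences in kcal/mol.
#' @slot temperature Temperature in K.
#' @exportClass PerturbationSeries
setClass("PerturbationSeries",
  representation(deltaU = "numeric", temperature = "numeric")
)

setValidity("PerturbationSeries", function(object) {
  if (length(object@deltaU) < 1) return("at least one sample required")
  if (!all(is.finite(object@deltaU))) return("all dU must be finite")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})
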