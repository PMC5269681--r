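#' @name accessors
#' @title Accessors for flipkinetics classes
#'
#' @description Slot accessors: prefer these over direct slot access.
#'
#' @param x An object of the documented class.
#' @return The slot value; see the individual generic.
NULL

#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setGeneric("angleValues", function(x) standardGeneric("angleValues"))
#' @rdname accessors
#' @export
setGeneric("windowCenter", function(x) standardGeneric("windowCenter"))
#' @rdname accessors
#' @export
setGeneric("forceConstant", function(x) standardGeneric("forceConstant"))
#' @rdname accessors
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))
#' @rdname accessors
#' @export
setGeneric("windowSeries", function(x) standardGeneric("windowSeries"))
#' @rdname accessors
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))
#' @rdname accessors
#' @export
setGeneric("period", function(x) standardGeneric("period"))
#' @rdname accessors
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("diffusivities", function(x) standardGeneric("diffusivities"))
#' @rdname accessors
#' @export
setGeneric("tauInt", function(x) standardGeneric("tauInt"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

setMethod("samplingInterval", "AngleSeries", function(x) x@dt)
setMethod("angleValues", "AngleSeries", function(x) x@values)
setMethod("samplingInterval", "UmbrellaWindow",
          function(x) x@series@dt)
setMethod("angleValues", "UmbrellaWindow", function(x) x@series@values)
setMethod("windowCenter", "UmbrellaWindow", function(x) x@center)
setMethod("forceConstant", "UmbrellaWindow", function(x) x@forceConstant)
setMethod("temperature", "UmbrellaWindow", function(x) x@temperature)
setMethod("windowSeries", "UmbrellaWindow", function(x) x@series)
setMethod("windows", "WindowSet", function(x) x@windows)
setMethod("period", "WindowSet", function(x) x@period)
setMethod("period", "FreeEnergyProfile", function(x) x@period)
setMethod("centers", "WindowSet",
          function(x) vapply(x@windows, function(w) w@center, numeric(1)))
setMethod("centers", "DiffusivityProfile", function(x) x@centers)
setMethod("binCenters", "FreeEnergyProfile", function(x) x@binCenters)
setMethod("profileValues", "FreeEnergyProfile", function(x) x@values)
setMethod("occupancy", "FreeEnergyProfile", function(x) x@occupancy)
setMethod("temperature", "FreeEnergyProfile", function(x) x@temperature)
setMethod("temperature", "ModelSystem", function(x) x@temperature)
setMethod("temperature", "PerturbationSeries", function(x) x@temperature)
setMethod("diffusivities", "DiffusivityProfile", function(x) x@values)
setMethod("tauInt", "CorrelationEstimate", function(x) x@tauInt)
setMethod("atoms", "MolecularStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("windowMetadata", function(x) standardGeneric("windowMetadata"))
setMethod("windowMetadata", "WindowSet", function(x) x@metadata)

#' Number of windows in a WindowSet
#'
#' @param x A [WindowSet-class].
#' @return Integer window count.
#' @export
nWindows <- function(x) {
  stopifnot(is(x, "WindowSet"))
  length(x@windows)
}

setMethod("show", "AngleSeries", function(object) {
  cat(sprintf("AngleSeries: %d samples, dt = %g ps, range [%.2f, %.2f] deg%s\n",
              length(object@values), object@dt, min(object@values),
              max(object@values),
              if (nzchar(object@label)) paste0(" (", object@label, ")") else ""))
})

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf(
    "UmbrellaWindow: center %.2f deg, k = %g kcal/(mol rad^2), T = %g K\n",
    object@center, object@forceConstant, object@temperature))
  show(object@series)
})

setMethod("show", "WindowSet", function(object) {
  ctr <- centers(object)
  cat(sprintf(
    "WindowSet: %d windows, centers %.1f..%.1f deg, period %g deg\n",
    length(ctr), min(ctr), max(ctr), object@period))
  if (!is.null(object@metadata$acceptance))
    cat(sprintf("  replica-exchange acceptance: %.3f\n",
                object@metadata$acceptance))
})

setMethod("show", "FreeEnergyProfile", function(object) {
  occ <- sum(object@occupancy > 0)
  vmax <- suppressWarnings(max(object@values, na.rm = TRUE))
  cat(sprintf(
    "FreeEnergyProfile: %d bins (%d occupied), T = %g K, max F = %.3f kcal/mol\n",
    length(object@binCenters), occ, object@temperature, vmax))
})

setMethod("show", "DiffusivityProfile", function(object) {
  cat(sprintf(
    "DiffusivityProfile: %d windows, D in [%.3g, %.3g] rad^2/ps (%s interpolation)\n",
    length(object@centers), min(object@values), max(object@values),
    object@interpolation))
})

setMethod("show", "CorrelationEstimate", function(object) {
  cat(sprintf(
    "CorrelationEstimate: tau_int = %.4g ps (A = %.3f, tau1 = %.4g, tau2 = %.4g)%s\n",
    object@tauInt, object@amplitude, object@tau1, object@tau2,
    if (object@fitted) "" else " [fallback: direct integration]"))
})

setMethod("show", "KineticsReport", function(object) {
  cat(sprintf("KineticsReport [%s] (%s diffusivity)\n", object@label,
              object@diffusivityMode))
  cat(sprintf("  tau+ = %.4g s   tau- = %.4g s\n", object@tauForward,
              object@tauBackward))
  cat(sprintf("  k+   = %.4g /s  k-   = %.4g /s\n", object@kForward,
              object@kBackward))
  cat(sprintf("  K_eq(kinetic) = %.4g   K_eq(thermo) = %.4g   dF = %.3f kcal/mol\n",
              object@Keq, object@KeqThermo, object@deltaF))
  cat(sprintf("  reflecting at %.1f deg, absorbing at %.1f deg\n",
              object@reflectAt, object@absorbAt))
})

setMethod("show", "ModelSystem", function(object) {
  nm <- if (nzchar(object@preset)) object@preset else "custom"
  cat(sprintf(
    "ModelSystem (%s): %d PMF harmonics, D0 = %.3g rad^2/ps, T = %g K\n",
    nm, length(object@fourierCos), exp(object@logD0), object@temperature))
})

setMethod("show", "MolecularStructure", function(object) {
  cat(sprintf("MolecularStructure: %d atoms, %d residues\n",
              nrow(object@atoms),
              nrow(unique(object@atoms[c("chain", "resno")]))))
})
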