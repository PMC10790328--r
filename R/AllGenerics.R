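#' Accessors for memprotMS classes
#'
#' Small accessor generics: `peakMz`/`peakIntensity` for
#' [PeakList-class], `kdValues` for [BindingModel-class] and
#' [BindingFit-class], `uptakeTable`/`peptideTable` for [HDXDataset-class].
#'
#' @param object an object of the documented class.
#' @return the slot content, see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peakMz", function(object) standardGeneric("peakMz"))

#' @rdname accessors
#' @export
setGeneric("peakIntensity", function(object) standardGeneric("peakIntensity"))

#' @rdname accessors
#' @export
setGeneric("kdValues", function(object) standardGeneric("kdValues"))

#' @rdname accessors
#' @export
setGeneric("uptakeTable", function(object) standardGeneric("uptakeTable"))

#' @rdname accessors
#' @export
setGeneric("peptideTable", function(object) standardGeneric("peptideTable"))

#' @rdname accessors
#' @export
setMethod("peakMz", "PeakList", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("peakIntensity", "PeakList", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("kdValues", "BindingModel", function(object) object@kd)

#' @rdname accessors
#' @export
setMethod("kdValues", "BindingFit", function(object) object@kd)

#' @rdname accessors
#' @export
setMethod("uptakeTable", "HDXDataset", function(object) object@uptake)

#' @rdname accessors
#' @export
setMethod("peptideTable", "HDXDataset", function(object) object@peptides)

setMethod("show", "PeakList", function(object) {
  cat("PeakList with", length(object@mz), "peaks")
  if (length(object@mz))
    cat(sprintf(" [%.1f, %.1f] Th", min(object@mz), max(object@mz)))
  lbl <- object@metadata$label
  if (!is.null(lbl)) cat(" |", lbl)
  cat("\n")
})

setMethod("show", "ChargeSeries", function(object) {
  cat(sprintf("ChargeSeries: M = %.2f Da, z = %s, score = %.3g\n",
              object@mass, paste(range(object@charges), collapse = "-"),
              object@score))
})

setMethod("show", "AdductAssignment", function(object) {
  a <- object@assignments
  cat(sprintf("AdductAssignment: M0 = %.2f Da, %d assigned peaks, k <= %d\n",
              object@baseMass, nrow(a), object@maxStoichiometry))
})

setMethod("show", "BindingModel", function(object) {
  cat("Sequential binding model,", length(object@kd), "site(s)\n")
  cat("  K_D (uM):", paste(signif(object@kd, 4), collapse = ", "), "\n")
})

setMethod("show", "BindingFit", function(object) {
  cat("BindingFit:", length(object@kd), "site(s);",
      sprintf("R2 = %.4f; SSE = %.4g\n", object@r2, object@sse))
  for (i in seq_along(object@kd))
    cat(sprintf("  K_D%d = %.4g uM (SD %s)%s\n", i, object@kd[i],
                ifelse(is.na(object@sd[i]), "NA", sprintf("%.3g", object@sd[i])),
                if (object@atBound[i]) " [at bound]" else ""))
})

setMethod("show", "HDXDataset", function(object) {
  cat("HDXDataset:", nrow(object@peptides), "peptides,",
      length(unique(object@uptake$state)), "states,",
      length(object@exposures), "exposures,",
      length(unique(object@uptake$replicate)), "replicates\n")
})

setMethod("show", "TitrationPreset", function(object) {
  cat(sprintf("TitrationPreset '%s': %d site(s), K_D1 = %.3g uM, cv = %.2f\n",
              object@name, length(object@model@kd), object@model@kd[1],
              object@cv))
})
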