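#' @include AllClasses.R
NULL

#' @describeIn ProtomerTable-accessors records as a data.frame
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @describeIn ProtomerTable-accessors symmetry group label
#' @export
setGeneric("symmetryGroup", function(x) standardGeneric("symmetryGroup"))

#' @describeIn ProtomerTable-accessors number of distinct particle ids
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' Accessors for ProtomerTable and CompositionSet
#'
#' \code{records} returns the underlying record data.frame; \code{nParticles}
#' the number of distinct parent particles; \code{symmetryGroup} the point
#' group of the (expanded) table; \code{compositions} the per-particle
#' composition data.frame.
#'
#' @param x a \code{ProtomerTable} or \code{CompositionSet}
#' @name ProtomerTable-accessors
NULL

#' @rdname ProtomerTable-accessors
#' @export
setGeneric("compositions", function(x) standardGeneric("compositions"))

setMethod("records", "ProtomerTable", function(x) x@records)
setMethod("symmetryGroup", "ProtomerTable", function(x) x@symmetryGroup)
setMethod("symmetryGroup", "CompositionSet", function(x) x@symmetryGroup)
setMethod("nParticles", "ProtomerTable",
          function(x) length(unique(x@records$particle_id)))
setMethod("nParticles", "CompositionSet",
          function(x) nrow(x@compositions))
setMethod("compositions", "CompositionSet", function(x) x@compositions)

setMethod("show", "ProtomerTable", function(object) {
  rec <- object@records
  cat("ProtomerTable with", nrow(rec), "records,",
      length(unique(rec$particle_id)), "particles,",
      "symmetry", object@symmetryGroup, "\n")
  if ("state" %in% names(rec) && nrow(rec)) {
    tab <- table(factor(rec$state, levels = .STATE_LEVELS))
    cat("  states:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "ClassStateMap", function(object) {
  cat("ClassStateMap:\n")
  for (st in unique(object@mapping))
    cat(" ", st, "<- classes",
        paste(names(object@mapping)[object@mapping == st], collapse = ", "),
        "\n")
})

setMethod("show", "CompositionSet", function(object) {
  cat("CompositionSet with", nrow(object@compositions),
      "complete particles (symmetry", paste0(object@symmetryGroup, ")"), "\n")
  cat("  duplicates removed:", object@nDuplicatesRemoved,
      "| incomplete particles excluded:",
      length(object@incompleteParticles), "\n")
})

setMethod("show", "CompositionDistribution", function(object) {
  cat("CompositionDistribution over", object@nParticles,
      "particles (k = number of PLN protomers)\n")
  print(object@counts)
})

setMethod("show", "StateFractionEstimate", function(object) {
  cat(sprintf("PLN fraction: %.4f (Wilson 95%% CI %.4f-%.4f, n = %d)\n",
              object@pHat, object@ciLow, object@ciHigh, object@n))
})

setMethod("show", "IndependenceTestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              object@method, object@statistic,
              ifelse(is.na(object@df), "NA", format(object@df)),
              object@p.value))
  if (nzchar(object@pooledBins)) cat("  pooling:", object@pooledBins, "\n")
})

setMethod("show", "IonTrajectory", function(object) {
  cat("IonTrajectory:", ncol(object@z), "ions,", nrow(object@z),
      "frames, dt =", object@dt, "ps\n")
  cat("  species:", paste(names(table(object@species)),
                          table(object@species), sep = "=", collapse = " "),
      "\n")
  cat(sprintf("  box %.1f x %.1f x %.1f A, V = %g mV, T = %g K\n",
              object@box[1], object@box[2], object@box[3],
              object@voltage, object@temperature))
})

setMethod("show", "CrossingCount", function(object) {
  cat(sprintf("CrossingCount [%s] gate (%.2f, %.2f) A: up = %d, down = %d, net = %d\n",
              object@species, object@gate[1], object@gate[2],
              object@nUp, object@nDown, object@nUp - object@nDown))
})

setMethod("show", "CurrentEstimate", function(object) {
  cat(sprintf(
    "I = %.4g nA at %g mV: g = %.4g pS, corrected (/%.2g) = %.4g pS\n",
    object@I, object@V, object@g, object@correctionFactor,
    object@gCorrected))
})

setMethod("show", "ConcentrationProfile", function(object) {
  cat("ConcentrationProfile:", nrow(object@molarity), "z bins, cylinder r =",
      object@radius, "A, species:", paste(object@species, collapse = ", "),
      "\n")
})

setMethod("show", "DensityFluxMap", function(object) {
  cat("DensityFluxMap:", paste(object@dims, collapse = " x "),
      "voxels at", object@spacing, "A spacing\n")
})

setMethod("show", "AtomSet", function(object) {
  cat("AtomSet with", nrow(object@coords), "atoms\n")
  if (nrow(object@coords)) {
    zr <- range(object@coords[, 3])
    cat(sprintf("  z range %.2f to %.2f A, vdW radii %.2f-%.2f A\n",
                zr[1], zr[2], min(object@radius), max(object@radius)))
  }
})

setMethod("show", "PoreProfile", function(object) {
  cat("PoreProfile:", length(object@z), "samples, z",
      sprintf("%.2f to %.2f A", min(object@z), max(object@z)), "\n")
  cat(sprintf("  min radius %.3f A at z = %.2f A (diameter %.3f A)\n",
              min(object@radius), object@z[which.min(object@radius)],
              2 * min(object@radius)))
})
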