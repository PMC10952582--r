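#' Accessors for gabakin S4 objects
#'
#' Small accessor generics: `schemeStates()`, `conductingStates()`,
#' `restingState()`, `transitions()` for [KineticScheme-class];
#' `rateValues()`, `rateUnits()` for [RateSet-class]; `epochs()` for
#' [ConcentrationProtocol-class]; `timePoints()` for trajectories and traces;
#' `traceCurrent()`, `traceMetadata()` for [CurrentTrace-class];
#' `occupancyMatrix()` for [OccupancyTrajectory-class].
#'
#' @param x the object.
#' @return the slot contents (a character vector, numeric vector, matrix or
#'   `data.frame` as appropriate).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("schemeStates", function(x) standardGeneric("schemeStates"))
#' @rdname accessors
#' @export
setGeneric("conductingStates", function(x) standardGeneric("conductingStates"))
#' @rdname accessors
#' @export
setGeneric("restingState", function(x) standardGeneric("restingState"))
#' @rdname accessors
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))
#' @rdname accessors
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))
#' @rdname accessors
#' @export
setGeneric("rateUnits", function(x) standardGeneric("rateUnits"))
#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("traceCurrent", function(x) standardGeneric("traceCurrent"))
#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))
#' @rdname accessors
#' @export
setGeneric("occupancyMatrix", function(x) standardGeneric("occupancyMatrix"))

#' @rdname accessors
#' @export
setMethod("schemeStates", "KineticScheme", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("conductingStates", "KineticScheme", function(x) x@conducting)
#' @rdname accessors
#' @export
setMethod("restingState", "KineticScheme", function(x) x@resting)
#' @rdname accessors
#' @export
setMethod("transitions", "KineticScheme", function(x) x@transitions)
#' @rdname accessors
#' @export
setMethod("rateValues", "RateSet", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("rateUnits", "RateSet", function(x) x@units)
#' @rdname accessors
#' @export
setMethod("epochs", "ConcentrationProtocol", function(x) x@epochs)
#' @rdname accessors
#' @export
setMethod("timePoints", "OccupancyTrajectory", function(x) x@time)
#' @rdname accessors
#' @export
setMethod("timePoints", "CurrentTrace", function(x) x@time)
#' @rdname accessors
#' @export
setMethod("traceCurrent", "CurrentTrace", function(x) x@current)
#' @rdname accessors
#' @export
setMethod("traceMetadata", "CurrentTrace", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("occupancyMatrix", "OccupancyTrajectory", function(x) x@occupancy)

setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("KineticScheme '%s': %d states (%s), resting %s\n",
              object@id, length(object@states),
              paste(object@states, collapse = ", "), object@resting))
  cat(sprintf("  conducting: %s\n", paste(object@conducting, collapse = ", ")))
  cat(sprintf("  %d directed transitions\n", nrow(object@transitions)))
  invisible(NULL)
})

setMethod("show", "RateSet", function(object) {
  cat(sprintf("RateSet (%s): %d rates\n", object@provenance,
              length(object@values)))
  v <- object@values
  u <- if (length(object@units)) object@units[names(v)] else
    rep("", length(v))
  for (i in seq_along(v))
    cat(sprintf("  %-8s %.4g %s\n", names(v)[i], v[i], u[i]))
  invisible(NULL)
})

setMethod("show", "ConcentrationProtocol", function(object) {
  cat("ConcentrationProtocol:\n")
  print(object@epochs, row.names = FALSE)
  if (object@exchangeTau > 0)
    cat(sprintf("  exchange tau: %g s\n", object@exchangeTau))
  invisible(NULL)
})

setMethod("show", "CurrentTrace", function(object) {
  n <- length(object@time)
  cat(sprintf("CurrentTrace: %d samples, %.3g-%.3g s, peak %.4g\n",
              n, object@time[1], object@time[n], max(object@current)))
  md <- object@metadata
  if (!is.null(md$scheme_id))
    cat(sprintf("  scheme: %s\n", md$scheme_id))
  invisible(NULL)
})

setMethod("show", "MeasurementSummary", function(object) {
  cat(sprintf(
    "MeasurementSummary: peak %.4g (t = %.3g s), steady %.4g, desensitisation %.4g%%\n",
    object@peak, object@peakTime, object@steady,
    object@percentDesensitisation))
  if (length(object@flags))
    cat(sprintf("  flags: %s\n", paste(object@flags, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "DecayFit", function(object) {
  if (isTRUE(object@degenerate)) {
    cat("DecayFit: degenerate (trace did not decay)\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "DecayFit: A1 %.4g tau1 %.4g s | A2 %.4g tau2 %.4g s | C %.4g | tauw %.4g s\n",
    object@A1, object@tau1, object@A2, object@tau2, object@plateau, object@tauw))
  invisible(NULL)
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf(
    "HillFit: pIC50 %.3f (IC50 %.3g M), n %.3f, %d points%s\n",
    object@pic50, object@ic50, object@hillSlope, object@nPoints,
    if (object@converged) "" else " [not converged]"))
  invisible(NULL)
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult: y = %.4gx + %.4g, R^2 = %.4f (n = %d)\n",
              object@slope, object@intercept, object@r2, object@n))
  invisible(NULL)
})

setMethod("show", "WaveformFitResult", function(object) {
  cat(sprintf("WaveformFitResult [%s]: objective %.6g after %d evaluations%s\n",
              object@spec@label, object@objective, length(object@iterTrace),
              if (object@converged) "" else " [not converged]"))
  free <- object@spec@free
  if (length(free)) {
    v <- object@rates@values[free]
    for (i in seq_along(v))
      cat(sprintf("  %-8s %.4g\n", names(v)[i], v[i]))
  }
  invisible(NULL)
})
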