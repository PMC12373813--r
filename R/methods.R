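#' Accessors for TrajectorySet
#'
#' @param x a \linkS4class{TrajectorySet}.
#' @param individual optional individual label; when given, \code{positions}
#'   returns that individual's n x 3 matrix, otherwise the full named list.
#' @name TrajectorySet-accessors
#' @aliases roster rateHz sessionId positions nTicks geometry
NULL

#' @rdname TrajectorySet-accessors
#' @export
setMethod("roster", "TrajectorySet", function(x) x@roster)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("rateHz", "TrajectorySet", function(x) x@rateHz)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("sessionId", "TrajectorySet", function(x) x@sessionId)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("nTicks", "TrajectorySet", function(x) length(x@timesS))

#' @rdname TrajectorySet-accessors
#' @export
setMethod("geometry", "TrajectorySet", function(x) x@geometry)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("positions", "TrajectorySet", function(x, individual) {
  if (missing(individual)) return(x@positions)
  if (!individual %in% x@roster)
    stop("unknown individual '", individual, "'", call. = FALSE)
  x@positions[[individual]]
})

setMethod("show", "TrajectorySet", function(object) {
  n <- length(object@timesS)
  miss <- vapply(object@positions,
                 function(p) mean(!stats::complete.cases(p)), numeric(1))
  cat("TrajectorySet '", object@sessionId, "': ",
      length(object@roster), " individuals (",
      paste(object@roster, collapse = ", "), "), ",
      n, " ticks @ ", object@rateHz, " Hz (",
      sprintf("%.1f", n / object@rateHz / 60), " min)\n", sep = "")
  if (n > 0)
    cat("  missing fraction: ",
        paste(sprintf("%s=%.3f", names(miss), miss), collapse = ", "),
        "\n", sep = "")
  invisible(object)
})

#' Accessors for OccupancyMap
#'
#' @param x an \linkS4class{OccupancyMap}.
#' @name OccupancyMap-accessors
#' @aliases occupancyGrid
NULL

#' @rdname OccupancyMap-accessors
#' @export
setMethod("occupancyGrid", "OccupancyMap", function(x) x@grid)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("sessionId", "OccupancyMap", function(x) x@sessionId)

setMethod("show", "OccupancyMap", function(object) {
  cat("OccupancyMap: individual '", object@individualId, "', session '",
      object@sessionId, "', grid ", nrow(object@grid), " x ",
      ncol(object@grid), ", occupied cells ",
      sum(object@grid > 0), "/", length(object@grid), "\n", sep = "")
  invisible(object)
})

#' Accessors for DistanceSeries
#'
#' @param x a \linkS4class{DistanceSeries}.
#' @name DistanceSeries-accessors
#' @aliases distances ticks
NULL

#' @rdname DistanceSeries-accessors
#' @export
setMethod("distances", "DistanceSeries", function(x) x@dCm)

#' @rdname DistanceSeries-accessors
#' @export
setMethod("ticks", "DistanceSeries", function(x) x@ticks)

setMethod("show", "DistanceSeries", function(object) {
  cat("DistanceSeries ", object@pair[1], "-", object@pair[2], ": ",
      length(object@dCm), " ticks", sep = "")
  if (length(object@dCm))
    cat(", median ", sprintf("%.1f", stats::median(object@dCm)), " cm",
        sep = "")
  cat("\n")
  invisible(object)
})

#' Accessor for ChunkSet
#'
#' @param x a \linkS4class{ChunkSet}.
#' @name ChunkSet-accessors
#' @aliases chunkDurations
NULL

#' @rdname ChunkSet-accessors
#' @export
setMethod("chunkDurations", "ChunkSet", function(x) x@durationsS)

setMethod("show", "ChunkSet", function(object) {
  cat("ChunkSet ", object@pair[1], "-", object@pair[2], ": ",
      length(object@durationsS), " chunks below ", object@thresholdCm,
      " cm", sep = "")
  if (length(object@durationsS))
    cat(", longest ", sprintf("%.1f", max(object@durationsS)), " s",
        sep = "")
  cat("\n")
  invisible(object)
})

#' Accessors for DecodingResult
#'
#' @param x a \linkS4class{DecodingResult}.
#' @name DecodingResult-accessors
#' @aliases accuracies meanAccuracy nullAccuracies pValue
NULL

#' @rdname DecodingResult-accessors
#' @export
setMethod("accuracies", "DecodingResult", function(x) x@accuracies)

#' @rdname DecodingResult-accessors
#' @export
setMethod("meanAccuracy", "DecodingResult", function(x) x@meanAccuracy)

#' @rdname DecodingResult-accessors
#' @export
setMethod("nullAccuracies", "DecodingResult", function(x) x@nullAccuracies)

#' @rdname DecodingResult-accessors
#' @export
setMethod("pValue", "DecodingResult", function(x) x@pValue)

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult [", object@protocol, "] ", object@pair[1], " vs ",
      object@pair[2], ": mean accuracy ",
      sprintf("%.3f", object@meanAccuracy), " over ",
      length(object@accuracies), " ",
      if (object@protocol == "within_cv") "folds" else "test sessions",
      sep = "")
  if (length(object@nullAccuracies))
    cat(", null mean ", sprintf("%.3f", mean(object@nullAccuracies)),
        ", p = ", sprintf("%.4g", object@pValue), sep = "")
  cat("\n")
  invisible(object)
})

setMethod("show", "PermutationTestResult", function(object) {
  cat("PermutationTestResult: mean p = ", sprintf("%.4g", object@meanP),
      " over ", object@nRepeats, " repeats (", object@nPerGroup,
      " draws/group)\n", sep = "")
  invisible(object)
})

setMethod("show", "WalkResult", function(object) {
  cat("WalkResult: ", length(object@distance), " samples, pStay = ",
      object@config@pStay, ", close fraction (< ",
      object@config@proximityThresh, ") = ",
      sprintf("%.3f", object@closeFraction), "\n", sep = "")
  invisible(object)
})

#' Close-proximity fraction of a walk simulation
#'
#' @param x a \linkS4class{WalkResult}.
#' @return Fraction of samples with inter-agent distance below the
#'   configured proximity threshold.
#' @export
closeFraction <- function(x) {
  stopifnot(is(x, "WalkResult"))
  x@closeFraction
}
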