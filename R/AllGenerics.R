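#' @rdname TrajectorySet-accessors
#' @export
setGeneric("roster", function(x) standardGeneric("roster"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("positions", function(x, individual) standardGeneric("positions"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("nTicks", function(x) standardGeneric("nTicks"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname OccupancyMap-accessors
#' @export
setGeneric("occupancyGrid", function(x) standardGeneric("occupancyGrid"))

#' @rdname DistanceSeries-accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname DistanceSeries-accessors
#' @export
setGeneric("ticks", function(x) standardGeneric("ticks"))

#' @rdname ChunkSet-accessors
#' @export
setGeneric("chunkDurations", function(x) standardGeneric("chunkDurations"))

#' @rdname DecodingResult-accessors
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' @rdname DecodingResult-accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname DecodingResult-accessors
#' @export
setGeneric("nullAccuracies", function(x) standardGeneric("nullAccuracies"))

#' @rdname DecodingResult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
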