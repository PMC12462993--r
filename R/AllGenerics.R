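## Accessor generics. Slot access outside the package should go through
## these.

#' @rdname accessors
#' @param x a graspflow object.
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("units2", function(x) standardGeneric("units2"))
#' @rdname accessors
#' @export
setGeneric("regionMap", function(x) standardGeneric("regionMap"))
#' @rdname accessors
#' @export
setGeneric("gripForce", function(x) standardGeneric("gripForce"))
#' @rdname accessors
#' @export
setGeneric("stimTrains", function(x) standardGeneric("stimTrains"))
#' @rdname accessors
#' @export
setGeneric("conditionLevels", function(x) standardGeneric("conditionLevels"))
#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))
#' @rdname accessors
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setGeneric("effectTable", function(x) standardGeneric("effectTable"))

#' Accessors for graspflow containers
#'
#' `trials()` returns the trial table; `units2()` the list of
#' [SpikeTrain] objects (named by unit id); `regionMap()` the
#' channel-to-region table; `gripForce()` the [ForceTrace];
#' `stimTrains()` the list of [StimTrain]s; `conditionLevels()` the declared
#' texture/load levels; `spikeTimes()` the spike-time vector of a
#' [SpikeTrain]; `unitIds()` the unit identifiers; `windowStarts()` the
#' window starts of a [WindowGrid] or [EffectSeries]; `effectTable()` the
#' per-window effect table of an [EffectSeries].
#'
#' @param x a graspflow object.
#' @return see Description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("trials", "SessionBundle", function(x) x@trials)
#' @rdname accessors
#' @export
setMethod("units2", "SessionBundle", function(x) {
  setNames(x@units, vapply(x@units, function(u) u@unitId, character(1)))
})
#' @rdname accessors
#' @export
setMethod("regionMap", "SessionBundle", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("gripForce", "SessionBundle", function(x) x@force)
#' @rdname accessors
#' @export
setMethod("stimTrains", "SessionBundle", function(x) x@stimTrains)
#' @rdname accessors
#' @export
setMethod("conditionLevels", "SessionBundle", function(x) x@conditionLevels)
#' @rdname accessors
#' @export
setMethod("sessionId", "SessionBundle", function(x) x@sessionId)
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("unitIds", "SessionBundle", function(x)
  vapply(x@units, function(u) u@unitId, character(1)))
#' @rdname accessors
#' @export
setMethod("windowStarts", "WindowGrid", function(x) x@starts)
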