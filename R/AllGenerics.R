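#' @rdname SpikeTrain-accessors
#' @export
setGeneric("traceId", function(x) standardGeneric("traceId"))

#' @rdname SpikeTrain-accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname SpikeTrain-accessors
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname SpikeTrain-accessors
#' @export
setGeneric("groupRole", function(x) standardGeneric("groupRole"))

#' @rdname SpikeTrain-accessors
#' @export
setGeneric("traceDuration", function(x) standardGeneric("traceDuration"))

#' @rdname SpikeTrain-accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SpikeTrain-accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' Detect bursts in a spike train
#'
#' @param train a [SpikeTrain-class] object.
#' @param params a [BurstParams-class] object (default: 100 ms maximum ISI,
#'   minimum 3 spikes).
#' @return See [detectBursts()].
#' @rdname detectBursts
#' @export
setGeneric("detectBursts",
  function(train, params = burstParams()) standardGeneric("detectBursts"))

#' @rdname detectBursts
#' @export
setGeneric("detectBurstsOracle",
  function(train, params = burstParams()) standardGeneric("detectBurstsOracle"))

#' @rdname summarizeTrace
#' @export
setGeneric("summarizeTrace",
  function(train, bursts) standardGeneric("summarizeTrace"))

#' @rdname bandAccessors
#' @export
setGeneric("bandLower", function(x) standardGeneric("bandLower"))

#' @rdname bandAccessors
#' @export
setGeneric("bandUpper", function(x) standardGeneric("bandUpper"))

#' @rdname bandAccessors
#' @export
setGeneric("bandMean", function(x) standardGeneric("bandMean"))

#' @rdname bandAccessors
#' @export
setGeneric("bandSD", function(x) standardGeneric("bandSD"))

#' @rdname effectAccessors
#' @export
setGeneric("meanDifference", function(x) standardGeneric("meanDifference"))

#' @rdname effectAccessors
#' @export
setGeneric("confint95", function(x) standardGeneric("confint95"))

#' @rdname effectAccessors
#' @export
setGeneric("effectD", function(x) standardGeneric("effectD"))
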