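#' Construct a SpikeTrain
#'
#' User-facing constructor; validates and normalises the spike-time vector.
#' Unsorted times are sorted; exact duplicate times are collapsed to a
#' single spike with a warning (tolerant ingestion, strict output).
#'
#' @param traceId single character identifier.
#' @param spikes numeric vector of spike times in seconds.
#' @param duration recording duration in seconds (default 180, the standard
#'   recording length for these preparations).
#' @param genotype,cellType,groupRole trace metadata; \code{groupRole} must
#'   be one of \code{"wildtype_reference"}, \code{"control"},
#'   \code{"mutant"}, \code{"treated"}.
#' @return a validated [SpikeTrain-class] object.
#' @examples
#' st <- SpikeTrain("t1", c(0.1, 0.2, 0.5), duration = 180,
#'                  genotype = "CS", groupRole = "wildtype_reference")
#' nSpikes(st)
#' @export
SpikeTrain <- function(traceId, spikes = numeric(0), duration = 180,
                       genotype = NA_character_, cellType = NA_character_,
                       groupRole = "control") {
  spikes <- as.numeric(spikes)
  if (anyNA(spikes) || any(!is.finite(spikes)))
    stop("spike times must be finite and non-missing for trace '",
         traceId, "'")
  if (is.unsorted(spikes)) spikes <- sort(spikes)
  if (anyDuplicated(spikes)) {
    ndup <- length(spikes) - length(unique(spikes))
    warning(sprintf(
      "trace '%s': collapsed %d duplicate spike time(s)", traceId, ndup))
    spikes <- unique(spikes)
  }
  new("SpikeTrain", traceId = as.character(traceId), spikes = spikes,
      duration = as.numeric(duration), genotype = as.character(genotype),
      cellType = as.character(cellType), groupRole = as.character(groupRole))
}

#' Accessors for SpikeTrain objects
#'
#' @param x a [SpikeTrain-class] object.
#' @return \code{traceId}, \code{genotype}, \code{cellType},
#'   \code{groupRole}: a single character; \code{traceDuration}: seconds;
#'   \code{spikeTimes}: numeric vector of spike times in seconds;
#'   \code{nSpikes}: integer spike count.
#' @name SpikeTrain-accessors
NULL

#' @rdname SpikeTrain-accessors
setMethod("traceId", "SpikeTrain", function(x) x@traceId)
#' @rdname SpikeTrain-accessors
setMethod("genotype", "SpikeTrain", function(x) x@genotype)
#' @rdname SpikeTrain-accessors
setMethod("cellType", "SpikeTrain", function(x) x@cellType)
#' @rdname SpikeTrain-accessors
setMethod("groupRole", "SpikeTrain", function(x) x@groupRole)
#' @rdname SpikeTrain-accessors
setMethod("traceDuration", "SpikeTrain", function(x) x@duration)
#' @rdname SpikeTrain-accessors
setMethod("spikeTimes", "SpikeTrain", function(x) x@spikes)
#' @rdname SpikeTrain-accessors
setMethod("nSpikes", "SpikeTrain", function(x) length(x@spikes))

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf(
    "SpikeTrain '%s' (%s, %s, %s)\n  %d spikes over %.1f s (%.3f Hz)\n",
    object@traceId,
    ifelse(is.na(object@genotype), "?", object@genotype),
    ifelse(is.na(object@cellType), "?", object@cellType),
    object@groupRole, length(object@spikes), object@duration,
    length(object@spikes) / object@duration))
})

#' Construct burst-detection parameters
#'
#' @param maxISI maximum inter-spike interval within a burst, seconds
#'   (default 0.100 s).
#' @param minSpikes minimum spikes per burst (default 3).
#' @return a [BurstParams-class] object.
#' @examples
#' burstParams()            # the standard 100 ms / 3-spike rule
#' burstParams(maxISI = 0.05)
#' @export
burstParams <- function(maxISI = 0.100, minSpikes = 3L) {
  new("BurstParams", maxISI = as.numeric(maxISI),
      minSpikes = as.integer(minSpikes))
}

setMethod("show", "BurstParams", function(object) {
  cat(sprintf("BurstParams: maxISI = %g s, minSpikes = %d\n",
              object@maxISI, object@minSpikes))
})
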