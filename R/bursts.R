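#' Segment a spike train into bursts
#'
#' Applies the ISI-threshold burst rule: a burst is a maximal run of
#' consecutive spikes whose successive inter-spike intervals are all at most
#' \code{maxISI} seconds (chain rule); the burst ends when no spike follows
#' within \code{maxISI} of the last spike. Runs shorter than
#' \code{minSpikes} are discarded — their spikes still count toward the
#' overall firing rate but toward no burst. The boundary is inclusive: an
#' ISI of exactly \code{maxISI} continues the burst. Burst duration is the
#' time from its first to its last spike, with no padding.
#'
#' The ISI comparison carries a 1 ns tolerance so that spike times recorded
#' at millisecond resolution behave as exact arithmetic would (successive
#' differences of decimal times are not exactly representable in binary
#' floating point).
#'
#' \code{detectBurstsOracle} implements the identical contract by an
#' independent exhaustive forward scan (per-start-index growth with direct
#' pairwise interval checks) instead of the vectorised run-length pass; it
#' exists for cross-validation in tests and must always agree exactly with
#' \code{detectBursts}.
#'
#' @param train a [SpikeTrain-class].
#' @param params a [BurstParams-class].
#' @return a data.frame with one row per burst, ordered by start time:
#'   \code{trace_id}, \code{burst_index} (1-based), \code{start_s},
#'   \code{end_s}, \code{n_spikes}, \code{duration_s}. Zero rows for a
#'   train with no qualifying runs.
#' @examples
#' st <- SpikeTrain("ex", c(0.00, 0.05, 0.10, 0.30, 0.35, 0.40, 0.45))
#' detectBursts(st)   # two bursts: 3 spikes / 0.10 s and 4 spikes / 0.15 s
#' @rdname detectBursts
#' @aliases detectBursts detectBurstsOracle
#' @export detectBursts detectBurstsOracle
setMethod("detectBursts", "SpikeTrain", function(train, params = burstParams()) {
  validObject(train); validObject(params)
  s <- train@spikes
  n <- length(s)
  if (n == 0L) return(.emptyBurstFrame(train@traceId))
  # runs of spikes chained by ISI <= maxISI (inclusive, 1 ns tolerance)
  linked <- diff(s) <= params@maxISI + 1e-9
  # run boundaries over the "linked" indicator: a run of k consecutive TRUEs
  # corresponds to k+1 chained spikes
  r <- rle(c(linked, FALSE))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= params@minSpikes)
  first <- starts[keep]
  last <- ends[keep]          # index of last linked ISI; last spike is +1
  .burstFrame(train@traceId, s, first, last + 1L)
})

#' @rdname detectBursts
setMethod("detectBurstsOracle", "SpikeTrain",
          function(train, params = burstParams()) {
  validObject(train); validObject(params)
  s <- train@spikes
  n <- length(s)
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (s[j + 1L] - s[j]) <= params@maxISI + 1e-9) j <- j + 1L
    if (j - i + 1L >= params@minSpikes) {
      first <- c(first, i); last <- c(last, j)
    }
    i <- j + 1L
  }
  .burstFrame(train@traceId, s, first, last)
})

.emptyBurstFrame <- function(trace_id) {
  data.frame(trace_id = character(0), burst_index = integer(0),
             start_s = numeric(0), end_s = numeric(0),
             n_spikes = integer(0), duration_s = numeric(0),
             stringsAsFactors = FALSE)
}

.burstFrame <- function(trace_id, s, first, last) {
  if (!length(first)) return(.emptyBurstFrame(trace_id))
  data.frame(trace_id = trace_id,
             burst_index = seq_along(first),
             start_s = s[first], end_s = s[last],
             n_spikes = last - first + 1L,
             duration_s = s[last] - s[first],
             stringsAsFactors = FALSE)
}

#' Detect bursts across a list of spike trains
#'
#' Convenience wrapper applying [detectBursts()] to each train and binding
#' the per-trace burst tables.
#'
#' @param trains list of [SpikeTrain-class] objects.
#' @param params a [BurstParams-class].
#' @return one data.frame of bursts (see [detectBursts()]).
#' @export
detectBurstsAll <- function(trains, params = burstParams()) {
  do.call(rbind, c(lapply(trains, detectBursts, params = params),
                   list(.emptyBurstFrame(character(0)))))
}
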