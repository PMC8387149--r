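#' Read spike-time tables into SpikeTrain objects
#'
#' The canonical spike file is long-format delimited text with one spike per
#' row and columns \code{trace_id} and \code{spike_time_s} (or
#' \code{spike_time_ms}; millisecond values are converted to seconds on
#' read). Per-trace metadata lives in a separate trace-metadata table keyed
#' by \code{trace_id} with columns \code{trace_id, genotype, cell_type,
#' group_role, duration_s}. Delimiter is inferred from the file extension
#' (.csv uses comma, anything else tab) unless \code{sep} is given.
#'
#' Ingestion is tolerant where harmless and strict where it matters:
#' unsorted times are sorted, duplicate times within a trace are collapsed
#' with a warning, but missing columns, non-numeric or negative times, and
#' spikes beyond the declared duration are errors.
#'
#' @param path spike file path.
#' @param metaPath optional trace-metadata file path; when absent every
#'   trace gets duration 180 s, role \code{"control"} and \code{NA}
#'   genotype/cell type.
#' @param sep field delimiter; \code{NULL} (default) infers from extension.
#' @return named list of [SpikeTrain-class] objects, one per distinct
#'   \code{trace_id}, in order of first appearance. Traces present only in
#'   the metadata (recorded but silent) come back with zero spikes.
#' @export
readSpikeTrains <- function(path, metaPath = NULL, sep = NULL) {
  tab <- .readDelim(path, sep)
  .requireColumns(tab, "trace_id", path)
  timeCol <- intersect(c("spike_time_s", "spike_time_ms"), names(tab))
  if (!length(timeCol))
    stop("format error in '", path,
         "': missing column 'spike_time_s' (or 'spike_time_ms')")
  timeCol <- timeCol[1L]
  raw <- tab[[timeCol]]
  times <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(times) & !(is.na(raw) | raw == ""))
  if (length(bad))
    stop("parse error in '", path, "' line ", bad[1L] + 1L,
         ": non-numeric spike time '", raw[bad[1L]], "'")
  if (anyNA(times))
    stop("parse error in '", path, "' line ",
         which(is.na(times))[1L] + 1L, ": missing spike time")
  neg <- which(times < 0)
  if (length(neg))
    stop("parse error in '", path, "' line ", neg[1L] + 1L,
         ": negative spike time ", raw[neg[1L]])
  if (timeCol == "spike_time_ms") times <- times / 1000

  meta <- if (!is.null(metaPath)) .readTraceMeta(metaPath, sep) else NULL
  ids <- unique(c(as.character(tab$trace_id),
                  if (!is.null(meta)) meta$trace_id))
  trains <- lapply(ids, function(id) {
    m <- if (!is.null(meta) && id %in% meta$trace_id)
      meta[match(id, meta$trace_id), , drop = FALSE]
    else
      data.frame(genotype = NA_character_, cell_type = NA_character_,
                 group_role = "control", duration_s = 180)
    tt <- times[tab$trace_id == id]
    if (length(tt) && max(tt) > m$duration_s)
      stop("validation error: trace '", id, "' has a spike at ",
           max(tt), " s beyond its declared duration of ",
           m$duration_s, " s")
    SpikeTrain(id, tt, duration = m$duration_s, genotype = m$genotype,
               cellType = m$cell_type, groupRole = m$group_role)
  })
  names(trains) <- ids
  trains
}

.readTraceMeta <- function(path, sep = NULL) {
  meta <- .readDelim(path, sep)
  .requireColumns(meta, c("trace_id", "genotype", "cell_type",
                          "group_role", "duration_s"), path)
  meta$trace_id <- as.character(meta$trace_id)
  meta$group_role <- tolower(as.character(meta$group_role))
  bad <- setdiff(meta$group_role, .GROUP_ROLES)
  if (length(bad))
    stop("unknown group_role '", bad[1L], "' in '", path,
         "'; allowed: ", paste(.GROUP_ROLES, collapse = ", "))
  if (anyDuplicated(meta$trace_id))
    stop("duplicate trace_id in metadata file '", path, "'")
  meta
}

#' Read behavioral measurement tables
#'
#' Expects columns \code{animal_id, genotype, assay, value} and optionally
#' \code{onset_time_s} (seizure onset within the heat assay, used for
#' cumulative-incidence curves; empty/NA means the animal never seized
#' before the cutoff, i.e. censored). Assay labels are case-folded on read;
#' allowed assays are \code{vortex, heat, eshock, locomotion_day,
#' locomotion_night, larval_crawl}. Values are seconds for seizure
#' durations and mm or mm/h for locomotion, and must be non-negative.
#'
#' @param path behavior file path.
#' @param sep field delimiter; \code{NULL} infers from extension.
#' @return data.frame with columns \code{animal_id, genotype, assay, value,
#'   onset_time_s}.
#' @export
readBehavior <- function(path, sep = NULL) {
  tab <- .readDelim(path, sep)
  .requireColumns(tab, c("animal_id", "genotype", "assay", "value"), path)
  tab$animal_id <- as.character(tab$animal_id)
  tab$genotype <- as.character(tab$genotype)
  tab$assay <- tolower(as.character(tab$assay))
  unknown <- setdiff(unique(tab$assay), .ASSAYS)
  if (length(unknown))
    stop("unknown assay label '", unknown[1L], "' in '", path,
         "'; allowed: ", paste(.ASSAYS, collapse = ", "))
  tab$value <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(tab$value))
    stop("parse error in '", path, "' line ",
         which(is.na(tab$value))[1L] + 1L, ": non-numeric value")
  if (any(tab$value < 0))
    stop("validation error in '", path, "' line ",
         which(tab$value < 0)[1L] + 1L, ": negative value")
  if (!"onset_time_s" %in% names(tab)) {
    tab$onset_time_s <- NA_real_
  } else {
    tab$onset_time_s <- suppressWarnings(as.numeric(tab$onset_time_s))
    if (any(tab$onset_time_s < 0, na.rm = TRUE))
      stop("validation error in '", path, "': negative onset_time_s")
  }
  tab[c("animal_id", "genotype", "assay", "value", "onset_time_s")]
}

#' Write and read result tables
#'
#' All result tables are tab-delimited UTF-8 text with a header row and '.'
#' as the decimal separator. Numeric values are written with 15 significant
#' digits so a write/read round trip is the identity well past 12
#' significant digits.
#'
#' @param rows a data.frame of homogeneous rows (zero rows allowed: a
#'   header-only file is written).
#' @param path output (or input) file path.
#' @return \code{writeResultTable} invisibly returns \code{path};
#'   \code{readResultTable} returns a data.frame.
#' @export
writeResultTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    y <- sprintf("%.15g", x)
    y[is.na(x)] <- "NA"
    y
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error writing '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  .readDelim(path, sep = "\t")
}

.readDelim <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = TRUE)
}

.requireColumns <- function(tab, cols, path) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("format error in '", path, "': missing column '", miss[1L], "'")
  invisible(TRUE)
}
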