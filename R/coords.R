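# Per-type rMATS coordinate schemas and coordinate arithmetic.
#
# All coordinates follow the rMATS/BED convention: "*_0base" columns are
# 0-based starts, end columns are exclusive, so every exon is a 0-based
# half-open interval [start, end).

AS_TYPES <- c("SE", "A3SS", "A5SS", "MXE", "RI")

RMATS_SHARED_COLS <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
                       "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
                       "IncFormLen", "SkipFormLen", "PValue", "FDR",
                       "IncLevel1", "IncLevel2", "IncLevelDifference")

RMATS_COORD_COLS <- list(
  SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  MXE  = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart_0base", "2ndExonEnd",
           "upstreamES", "upstreamEE", "downstreamES", "downstreamEE"),
  RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE")
)

check_event_type <- function(event_type) {
  if (length(event_type) != 1L || !event_type %in% AS_TYPES)
    stop_fmt("unknown AS event type '%s' (expected one of %s)",
             paste(event_type, collapse = ","), paste(AS_TYPES, collapse = ", "))
  event_type
}

#' Canonical key for an alternative-splicing event
#'
#' Builds a deterministic text key from the event type, chromosome, strand and
#' the full per-type coordinate tuple, so that the identical exon junction seen
#' in independent rMATS runs receives the identical key. Two events are the
#' same if and only if their keys are equal.
#'
#' @param event_type one of `"SE"`, `"A3SS"`, `"A5SS"`, `"MXE"`, `"RI"`
#'   (recycled if scalar).
#' @param chrom,strand character vectors.
#' @param coords a list of integer vectors, one per event, with the arity of
#'   the event type's coordinate schema (6 for SE/A3SS/A5SS/RI, 8 for MXE).
#' @return character vector of keys, e.g. `"SE|chr1|+|100-200-50-80-250-300"`.
#' @examples
#' event_key("SE", "chr1", "+", list(c(100L, 200L, 50L, 80L, 250L, 300L)))
#' @export
event_key <- function(event_type, chrom, strand, coords) {
  if (!is.list(coords)) coords <- list(coords)
  n <- length(coords)
  event_type <- rep_len(event_type, n)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  vapply(seq_len(n), function(i) {
    et <- check_event_type(event_type[i])
    cc <- coords[[i]]
    want <- length(RMATS_COORD_COLS[[et]])
    if (length(cc) != want)
      stop_fmt("%s event needs %d coordinates, got %d", et, want, length(cc))
    if (any(is.na(cc)) || any(cc < 0))
      stop_fmt("event coordinates must be non-negative and non-missing")
    paste(et, chrom[i], strand[i], paste(cc, collapse = "-"), sep = "|")
  }, "")
}

# target exon per type: the alternatively used exon whose inclusion PSI measures
# SE: cassette exon; A3SS/A5SS: long exon; MXE: 1st exon; RI: retained region
target_exon <- function(events) {
  n <- nrow(events)
  out <- data.frame(start = integer(n), end = integer(n))
  for (i in seq_len(n)) {
    cc <- events$coords[[i]]
    out$start[i] <- cc[1L]
    out$end[i] <- cc[2L]
  }
  out
}

# full event span, upstream exon start to downstream exon end
# (min start .. max end over the coordinate tuple)
event_span <- function(events) {
  n <- nrow(events)
  data.frame(
    start = vapply(events$coords, function(cc) {
      min(cc[seq(1L, length(cc), by = 2L)])
    }, 0L),
    end = vapply(events$coords, function(cc) {
      max(cc[seq(2L, length(cc), by = 2L)])
    }, 0L)
  )
}

# splice-site boundary positions of the target exon(s), used for novelty calls
target_boundaries <- function(events) {
  lapply(seq_len(nrow(events)), function(i) {
    cc <- events$coords[[i]]
    if (events$event_type[i] == "MXE") cc[1:4] else cc[1:2]
  })
}
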