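# Canonical event model: PSI recomputation, coverage and significance
# filtering, cross-dataset joining, interval overlap and novelty annotation.

#' Length-normalised percent-spliced-in (PSI)
#'
#' Recomputes the inclusion level from junction counts and isoform effective
#' lengths: `(ijc/inc_form_len) / (ijc/inc_form_len + sjc/skip_form_len)`.
#' Used to validate `IncLevel` columns, not to replace them. Returns `NA`
#' where `ijc + sjc == 0`.
#'
#' @param ijc,sjc inclusion- and skipping-junction counts (non-negative,
#'   vectorised).
#' @param inc_form_len,skip_form_len positive effective lengths of the
#'   inclusion and skipping forms.
#' @return numeric vector of PSI values in `[0, 1]`, `NA` when uncovered.
#' @examples
#' compute_psi(30, 10, 2, 1)  # 0.6
#' @export
compute_psi <- function(ijc, sjc, inc_form_len, skip_form_len) {
  if (any(ijc < 0, na.rm = TRUE) || any(sjc < 0, na.rm = TRUE))
    stop_fmt("junction counts must be non-negative")
  if (any(inc_form_len <= 0) || any(skip_form_len <= 0))
    stop_fmt("form lengths must be positive")
  inc <- ijc / inc_form_len
  skp <- sjc / skip_form_len
  out <- inc / (inc + skp)
  out[(ijc + sjc) == 0] <- NA_real_
  out
}

#' Bundle per-type rMATS tables into one comparison set
#'
#' Concatenates the per-AS-type tables of one two-group comparison into a
#' single keyed event table, mirroring the practice of combining the splice
#' types into one file before downstream filtering.
#'
#' @param tables a list of event data frames from [read_rmats_table()] (any
#'   subset of the five AS types), or a single such data frame.
#' @param label text label for the comparison (e.g.
#'   `"fibroblast/Ctrl-DMSO_vs_HD-DMSO"`).
#' @param group1_name,group2_name names of sample groups 1 and 2.
#' @return an object of class `comparison_set`: a list with `label`,
#'   `group1_name`, `group2_name` and the combined `events` data frame.
#'   Duplicate keys are an error.
#' @export
comparison_set <- function(tables, label, group1_name = "group1",
                           group2_name = "group2") {
  if (is.data.frame(tables)) tables <- list(tables)
  events <- do.call(rbind, tables)
  rownames(events) <- NULL
  if (anyDuplicated(events$key))
    stop_fmt("duplicate event keys in comparison '%s'", label)
  structure(list(label = label, group1_name = group1_name,
                 group2_name = group2_name, events = events),
            class = "comparison_set")
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf("<comparison_set> %s (%s vs %s): %d events\n",
              x$label, x$group1_name, x$group2_name, nrow(x$events)))
  tab <- table(x$events$event_type)
  if (length(tab)) cat("  ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# per-sample total junction support (ijc + sjc), both groups concatenated
sample_totals <- function(events) {
  lapply(seq_len(nrow(events)), function(i) {
    c(events$ijc1[[i]] + events$sjc1[[i]], events$ijc2[[i]] + events$sjc2[[i]])
  })
}

#' Coverage filter: minimum junction support in every sample
#'
#' Retains exactly the events whose total junction support (`ijc + sjc`) is at
#' least `min_count` in every sample of both groups; an event covered with at
#' least ten counts in each sample passes at the default.
#'
#' @param cs a [comparison_set()].
#' @param min_count minimum per-sample total junction count (default 10,
#'   inclusive).
#' @return the filtered `comparison_set` (possibly with zero events).
#' @export
coverage_filter <- function(cs, min_count = 10) {
  stopifnot(inherits(cs, "comparison_set"))
  keep <- vapply(sample_totals(cs$events), function(tot) all(tot >= min_count), TRUE)
  cs$events <- cs$events[keep, , drop = FALSE]
  rownames(cs$events) <- NULL
  cs
}

#' Significance filter with direction labels
#'
#' Keeps events with `fdr < fdr_max` and `|inc_level_difference| >
#' min_abs_delta` (both strict, matching "below 0.05" and "more than 0.1").
#' Adds a `direction` column using the sign convention that a negative
#' inclusion-level difference reflects inclusion of the exon in the target
#' (group 2) condition: negative difference -> `"included"`, positive ->
#' `"excluded"`.
#'
#' @param cs a coverage-filtered [comparison_set()].
#' @param fdr_max FDR ceiling (strict; default 0.05).
#' @param min_abs_delta minimum absolute inclusion-level difference (strict;
#'   default 0.1).
#' @return the filtered `comparison_set`; events with missing `fdr` or
#'   difference are skipped with a warning.
#' @export
significant_events <- function(cs, fdr_max = 0.05, min_abs_delta = 0.1) {
  stopifnot(inherits(cs, "comparison_set"))
  ev <- cs$events
  miss <- is.na(ev$fdr) | is.na(ev$inc_level_difference)
  if (any(miss))
    warn_fmt("%d event(s) skipped in '%s': missing FDR or inclusion-level difference",
             sum(miss), cs$label)
  keep <- !miss & ev$fdr < fdr_max & abs(ev$inc_level_difference) > min_abs_delta
  ev <- ev[keep, , drop = FALSE]
  ev$direction <- ifelse(ev$inc_level_difference < 0, "included", "excluded")
  rownames(ev) <- NULL
  cs$events <- ev
  cs
}

#' Events significant in two comparisons with matching direction
#'
#' @param a,b significance-called [comparison_set()]s (with `direction`).
#' @param direction `"included"` or `"excluded"` (relative to each
#'   comparison's target condition).
#' @return character vector of shared event keys.
#' @export
shared_events <- function(a, b, direction = c("included", "excluded")) {
  direction <- match.arg(direction)
  ka <- a$events$key[a$events$direction == direction]
  kb <- b$events$key[b$events$direction == direction]
  intersect(ka, kb)
}

#' Overlap events with a set of genomic intervals
#'
#' Tests each event's target-exon interval for >= 1 bp overlap with any query
#' interval (0-based half-open on both sides); used e.g. to compare called
#' events against previously reported drug-induced exon coordinates.
#' Chromosome names are matched after normalising the "chr" prefix, so
#' `"chr1"` and `"1"` agree.
#'
#' @param events event data frame (rows of a `comparison_set`).
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param stranded match strand as well (default `FALSE`); requires a
#'   `strand` column in `intervals`.
#' @return character vector of overlapping event keys.
#' @export
overlap_with_intervals <- function(events, intervals, stranded = FALSE) {
  if (nrow(events) == 0L || nrow(intervals) == 0L) return(character(0))
  te <- target_exon(events)
  ev_gr <- GenomicRanges::GRanges(
    strip_chr(events$chrom),
    IRanges::IRanges(start = te$start + 1L, end = te$end),
    strand = if (stranded) events$strand else "*")
  q_gr <- GenomicRanges::GRanges(
    strip_chr(intervals$chrom),
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = if (stranded) intervals$strand else "*")
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ev_gr, q_gr,
                                                       ignore.strand = !stranded))
  unique(events$key[unique(S4Vectors_queryHits(hits))])
}

# avoid importing S4Vectors wholesale for one accessor
S4Vectors_queryHits <- function(hits) {
  as.data.frame(hits)$queryHits
}

#' Benjamini-Hochberg adjusted P values
#'
#' Validation utility wrapping [stats::p.adjust()] with a domain check; the
#' consumed rMATS tables already carry an FDR column.
#'
#' @param pvalues numeric vector in `[0, 1]` (no missing values).
#' @return BH-adjusted values in the input order.
#' @export
recompute_bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop_fmt("P values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Annotate novel-splice-site events against known exon boundaries
#'
#' Flags an event as `novel_ss` when any boundary of its target exon(s) is
#' absent from the annotation's exon-boundary set (the synthetic annotation
#' supplies this set; real rMATS novelSS bookkeeping is not re-derived).
#'
#' @param cs a [comparison_set()] or event data frame.
#' @param boundaries boundary `data.frame` from
#'   [read_annotation_boundaries()].
#' @return the input with a logical `novel_ss` column filled in.
#' @export
annotate_novel_ss <- function(cs, boundaries) {
  ev <- if (inherits(cs, "comparison_set")) cs$events else cs
  known <- paste(strip_chr(boundaries$chrom), boundaries$pos)
  tb <- target_boundaries(ev)
  ev$novel_ss <- vapply(seq_len(nrow(ev)), function(i) {
    !all(paste(strip_chr(ev$chrom[i]), tb[[i]]) %in% known)
  }, TRUE)
  if (inherits(cs, "comparison_set")) { cs$events <- ev; cs } else ev
}

#' Genomic span of each event from upstream exon start to downstream exon end
#'
#' The interval used for eCLIP peak intersection.
#'
#' @param events event data frame.
#' @return `data.frame` with `key`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @export
event_regions <- function(events) {
  sp <- event_span(events)
  data.frame(key = events$key, chrom = events$chrom, strand = events$strand,
             start = sp$start, end = sp$end, stringsAsFactors = FALSE)
}

#' Export significant events as a tab-separated table
#'
#' @param cs significance-called [comparison_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_significant_events <- function(cs, path) {
  ev <- cs$events
  out <- data.frame(key = ev$key, event_type = ev$event_type,
                    direction = ev$direction %||% NA_character_,
                    fdr = ev$fdr, inc_level_difference = ev$inc_level_difference,
                    novel_ss = ev$novel_ss %||% NA, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
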