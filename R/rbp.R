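# eCLIP-based RNA-binding-protein enrichment at alternative-splicing events:
# peak significance filtering, event-region intersection, hypergeometric
# enrichment against the coverage-passing background, and Fisher comparison of
# rescued vs non-rescued event binding.

#' Filter eCLIP peaks on significance and enrichment
#'
#' A peak is kept when `neg_log10_p >= min_neg_log10_p` and
#' `log2_fold_change >= min_log2fc` (both inclusive).
#'
#' @param peaks peak `data.frame` from [read_peaks()].
#' @param min_neg_log10_p minimum -log10(P) (default 3).
#' @param min_log2fc minimum log2 fold change (default 3).
#' @return the filtered peak `data.frame`.
#' @export
filter_peaks <- function(peaks, min_neg_log10_p = 3, min_log2fc = 3) {
  keep <- peaks$neg_log10_p >= min_neg_log10_p &
    peaks$log2_fold_change >= min_log2fc
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Event regions overlapped by at least one peak
#'
#' An event counts as bound when its region (upstream exon start to downstream
#' exon end, 0-based half-open) overlaps any peak by >= 1 bp, regardless of
#' peak multiplicity. Chromosome naming is normalised ("chr1" == "1");
#' strand is ignored unless `stranded = TRUE`.
#'
#' @param regions `data.frame` from [event_regions()].
#' @param peaks peak `data.frame` (typically already [filter_peaks()]ed).
#' @param stranded require matching strand (default `FALSE`).
#' @return character vector of bound event keys.
#' @export
events_bound <- function(regions, peaks, stranded = FALSE) {
  if (nrow(regions) == 0L || nrow(peaks) == 0L) return(character(0))
  r_gr <- GenomicRanges::GRanges(
    strip_chr(regions$chrom),
    IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = if (stranded) regions$strand else "*")
  p_gr <- GenomicRanges::GRanges(
    strip_chr(peaks$chrom),
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = if (stranded) ifelse(peaks$strand == ".", "*", peaks$strand) else "*")
  hits <- suppressWarnings(GenomicRanges::findOverlaps(r_gr, p_gr,
                                                       ignore.strand = !stranded))
  unique(regions$key[unique(S4Vectors_queryHits(hits))])
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` events from a
#' universe of `N` of which `K` are bound. `k = 0` gives exactly 1.
#'
#' @param k observed bound count in the draw.
#' @param N universe size.
#' @param K bound events in the universe.
#' @param n draw (foreground) size.
#' @return upper-tail probability.
#' @export
hyper_upper_tail <- function(k, N, K, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric RBP enrichment at foreground events
#'
#' For each RBP, with `N` background events of which `K` are bound and a
#' foreground of `n` events of which `k` are bound, reports the fold
#' enrichment `(k/n)/(K/N)` and the upper-tail hypergeometric P value. The
#' background is the coverage-passing event universe; the foreground must be
#' a subset of it. RBPs binding no background event are omitted.
#'
#' @param foreground_keys,background_keys character vectors of event keys,
#'   `foreground_keys` a subset of `background_keys`.
#' @param bound_by_rbp named list: RBP name -> character vector of bound
#'   event keys (from [events_bound()]).
#' @return `data.frame` sorted by ascending P: `rbp_name`, `N`, `K`, `n`,
#'   `k_bound`, `fold_enrichment`, `pvalue`.
#' @export
rbp_enrichment <- function(foreground_keys, background_keys, bound_by_rbp) {
  foreground_keys <- unique(foreground_keys)
  background_keys <- unique(background_keys)
  if (length(background_keys) == 0L) stop_fmt("background is empty")
  if (!all(foreground_keys %in% background_keys))
    stop_fmt("foreground must be a subset of the background universe")
  N <- length(background_keys)
  n <- length(foreground_keys)
  rows <- lapply(names(bound_by_rbp), function(rbp) {
    bound <- intersect(bound_by_rbp[[rbp]], background_keys)
    K <- length(bound)
    if (K == 0L) return(NULL)
    k <- length(intersect(bound, foreground_keys))
    data.frame(rbp_name = rbp, N = N, K = K, n = n, k_bound = k,
               fold_enrichment = (k / n) / (K / N),
               pvalue = hyper_upper_tail(k, N, K, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(rbp_name = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k_bound = integer(0),
                      fold_enrichment = numeric(0), pvalue = numeric(0)))
  out <- out[order(out$pvalue, -out$fold_enrichment, out$rbp_name), ]
  rownames(out) <- NULL
  out
}

#' Compare RBP binding between rescued and non-rescued events
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[bound & rescued, unbound & rescued], [bound & unrescued, unbound &
#' unrescued]]`.
#'
#' @param rescued,unrescued disjoint character vectors of event keys.
#' @param bound character vector of keys bound by the RBP.
#' @return list with the `table`, `odds_ratio` (cross-product, +0.5
#'   continuity fallback on zero cells) and two-sided `pvalue`; an empty
#'   class yields P = 1 with a warning.
#' @export
rescued_vs_unrescued_binding <- function(rescued, unrescued, bound) {
  if (length(intersect(rescued, unrescued)))
    stop_fmt("rescued and unrescued sets must be disjoint")
  a <- length(intersect(rescued, bound))
  b <- length(setdiff(rescued, bound))
  c_ <- length(intersect(unrescued, bound))
  d <- length(setdiff(unrescued, bound))
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("rescued", "unrescued"), c("bound", "unbound")))
  if (length(rescued) == 0L || length(unrescued) == 0L) {
    warn_fmt("one class is empty; reporting P = 1")
    return(list(table = tab, odds_ratio = NA_real_, pvalue = 1))
  }
  orr <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
         else (a * d) / (b * c_)
  list(table = tab, odds_ratio = orr,
       pvalue = stats::fisher.test(tab)$p.value)
}

#' Export RBP enrichment records
#'
#' @param records result of [rbp_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rbp_enrichment <- function(records, path) {
  out <- records
  names(out) <- c("rbp", "N", "K", "n", "k", "fold_enrichment", "pvalue")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
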