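# Splice-site sequence windows and k-mer enrichment (foreground = target
# exon's 3'/5' splice sites; background = upstream exon's 3'SS and downstream
# exon's 5'SS).

#' Configuration for splice-site window extraction
#'
#' Windows span `flank` bases on each side of a splice-site boundary (a
#' `2*flank`-nt window centred on the exon edge); the default 5-base flank
#' gives a 10-nt window that just fits an 8-mer.
#'
#' @param flank bases on each side of the boundary (default 5).
#' @param k_sizes k-mer sizes to analyse (default `c(4, 6, 8)`).
#' @return a named list; `2*flank >= max(k_sizes)` is enforced.
#' @export
motif_window_config <- function(flank = 5L, k_sizes = c(4L, 6L, 8L)) {
  flank <- as.integer(flank); k_sizes <- as.integer(k_sizes)
  if (flank < 1L) stop_fmt("flank must be >= 1")
  if (2L * flank < max(k_sizes))
    stop_fmt("window (2*flank = %d) shorter than largest k-mer (%d)",
             2L * flank, max(k_sizes))
  list(flank = flank, k_sizes = sort(k_sizes))
}

#' Extract splice-site sequence windows for foreground and background sites
#'
#' For each (by default cassette-exon-like) event, the foreground windows sit
#' at the target exon's 3' splice site (exon start boundary in transcript
#' sense) and 5' splice site (exon end boundary); the background windows sit
#' at the upstream exon's own 3' splice site and the downstream exon's own 5'
#' splice site. Each window covers `[boundary - flank, boundary + flank)` in
#' genomic coordinates; minus-strand windows are reverse-complemented so the
#' splice-site grammar always reads in the sense direction.
#'
#' @param events event data frame (rows of a `comparison_set`).
#' @param genome named character vector from [read_fasta()].
#' @param cfg a [motif_window_config()].
#' @param restrict_types event types analysed (default `"SE"`, the cassette
#'   geometry the window definitions describe).
#' @return `data.frame` with `key`, `site` (`three_prime`/`five_prime`),
#'   `role` (`foreground`/`background`), `sequence` (length `2*flank`).
#'   Events whose windows run off a contig end are skipped with a warning;
#'   a missing contig is an error.
#' @export
extract_windows <- function(events, genome, cfg = motif_window_config(),
                            restrict_types = "SE") {
  ev <- events[events$event_type %in% restrict_types, , drop = FALSE]
  flank <- cfg$flank
  rows <- vector("list", nrow(ev))
  n_skipped <- 0L
  for (i in seq_len(nrow(ev))) {
    chrom <- ev$chrom[i]
    if (!chrom %in% names(genome))
      stop_fmt("contig '%s' absent from genome", chrom)
    contig <- genome[[chrom]]
    cc <- ev$coords[[i]]       # SE: exonS, exonE, upS, upE, downS, downE
    plus <- ev$strand[i] == "+"
    # transcript-sense boundaries (rMATS upstream/downstream are strand-aware)
    b <- if (plus) c(three_prime = cc[1], five_prime = cc[2],
                     bg_three_prime = cc[3], bg_five_prime = cc[6])
         else      c(three_prime = cc[2], five_prime = cc[1],
                     bg_three_prime = cc[4], bg_five_prime = cc[5])
    if (any(b - flank < 0) || any(b + flank > nchar(contig))) {
      n_skipped <- n_skipped + 1L
      next
    }
    seqs <- substring(contig, b - flank + 1L, b + flank)
    if (!plus) seqs <- revcomp(seqs)
    rows[[i]] <- data.frame(
      key = ev$key[i],
      site = c("three_prime", "five_prime", "three_prime", "five_prime"),
      role = c("foreground", "foreground", "background", "background"),
      sequence = unname(seqs), stringsAsFactors = FALSE)
  }
  if (n_skipped)
    warn_fmt("%d event(s) skipped: splice-site window off contig end", n_skipped)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(key = character(0), site = character(0),
                      role = character(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  out
}

#' Count overlapping k-mers in a set of windows
#'
#' All overlapping k-substrings are pooled across windows
#' ([Biostrings::oligonucleotideFrequency()]); positions spanning an `N`
#' contribute nothing. The total is the number of counted k-mer positions.
#'
#' @param sequences character vector of window sequences (or a window
#'   `data.frame` from [extract_windows()], in which case its `sequence`
#'   column is used).
#' @param k k-mer size (must not exceed the window length).
#' @return list with `counts` (named integer vector over observed k-mers) and
#'   `total`.
#' @export
count_kmers <- function(sequences, k) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (length(sequences) == 0L) return(list(counts = integer(0), total = 0L))
  if (any(nchar(sequences) < k))
    stop_fmt("k = %d exceeds window length %d", k, min(nchar(sequences)))
  freq <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = k)
  counts <- as.integer(colSums(freq))
  names(counts) <- colnames(freq)
  counts <- counts[counts > 0L]
  list(counts = counts, total = sum(counts))
}

#' K-mer enrichment of foreground vs background splice-site windows
#'
#' For every k-mer observed in either set, forms the 2x2 table
#' `[[fg_count, fg_total - fg_count], [bg_count, bg_total - bg_count]]`,
#' computes the two-sided Fisher exact P value ([stats::fisher.test()]), the
#' cross-product odds ratio (with a +0.5 continuity fallback when any cell is
#' zero) and the relative frequencies. No multiple-testing correction is
#' applied by default (see [recompute_bh_fdr()]).
#'
#' @param fg,bg results of [count_kmers()] for the foreground and background
#'   windows; totals must be positive.
#' @return `data.frame` sorted by ascending P then descending foreground
#'   frequency: `kmer`, `fg_count`, `fg_total`, `bg_count`, `bg_total`,
#'   `relative_frequency_fg`, `relative_frequency_bg`, `odds_ratio`,
#'   `pvalue`.
#' @export
kmer_enrichment <- function(fg, bg) {
  if (fg$total <= 0L || bg$total <= 0L)
    stop_fmt("foreground and background totals must be positive")
  kmers <- sort(union(names(fg$counts), names(bg$counts)))
  a <- unname(ifelse(is.na(fg$counts[kmers]), 0L, fg$counts[kmers]))
  c_ <- unname(ifelse(is.na(bg$counts[kmers]), 0L, bg$counts[kmers]))
  b <- fg$total - a
  d <- bg$total - c_
  pv <- vapply(seq_along(kmers), function(i) {
    stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), nrow = 2,
                              byrow = TRUE))$p.value
  }, 0)
  orr <- ifelse(a == 0 | b == 0 | c_ == 0 | d == 0,
                ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
                (a * d) / (b * c_))
  out <- data.frame(kmer = kmers, fg_count = a, fg_total = fg$total,
                    bg_count = c_, bg_total = bg$total,
                    relative_frequency_fg = a / fg$total,
                    relative_frequency_bg = c_ / bg$total,
                    odds_ratio = orr, pvalue = pv, stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, -out$relative_frequency_fg, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' End-to-end splice-site k-mer enrichment
#'
#' Extracts windows, then tests foreground vs background k-mer counts at each
#' site (3' and 5') for every configured k.
#'
#' @inheritParams extract_windows
#' @return `data.frame` of [kmer_enrichment()] records with extra `k` and
#'   `site` columns.
#' @export
splice_site_kmer_enrichment <- function(events, genome,
                                        cfg = motif_window_config(),
                                        restrict_types = "SE") {
  win <- extract_windows(events, genome, cfg, restrict_types)
  out <- list()
  for (k in cfg$k_sizes) {
    for (site in c("three_prime", "five_prime")) {
      fg <- count_kmers(win$sequence[win$site == site & win$role == "foreground"], k)
      bg <- count_kmers(win$sequence[win$site == site & win$role == "background"], k)
      if (fg$total == 0L || bg$total == 0L) next
      rec <- kmer_enrichment(fg, bg)
      rec$k <- k
      rec$site <- site
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Export k-mer enrichment records
#'
#' @param records result of [splice_site_kmer_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_enrichment <- function(records, path) {
  out <- records[, c("kmer", "k", "site", "relative_frequency_fg",
                     "relative_frequency_bg", "odds_ratio", "pvalue")]
  names(out)[4:5] <- c("fg_freq", "bg_freq")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
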