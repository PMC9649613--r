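# RPKM normalisation, drug-vs-vehicle expression ratios, and the
# transcript-consequence arithmetic for induced novel exons.

#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = counts * 1e9 / (length_bp * total_mapped)`. By default the
#' per-sample depth is the column sum of assigned gene counts.
#'
#' @param counts gene-count `data.frame` from [read_gene_counts()]
#'   (`gene_id`, `length_bp`, one column per sample).
#' @param total_mapped optional named numeric vector of per-sample depths;
#'   defaults to `colSums` over the count columns. Zero depth is an error.
#' @return `data.frame` with `gene_id` and one RPKM column per sample.
#' @examples
#' gc <- data.frame(gene_id = "g1", length_bp = 1000L, s1 = 10L)
#' rpkm(gc, total_mapped = c(s1 = 1e6))  # 10
#' @export
rpkm <- function(counts, total_mapped = NULL) {
  samples <- setdiff(names(counts), c("gene_id", "length_bp"))
  if (is.null(total_mapped))
    total_mapped <- vapply(counts[samples], sum, 0)
  if (any(total_mapped[samples] <= 0))
    stop_fmt("total mapped reads must be positive for every sample")
  out <- data.frame(gene_id = counts$gene_id, stringsAsFactors = FALSE)
  for (s in samples)
    out[[s]] <- counts[[s]] * 1e9 / (counts$length_bp * total_mapped[[s]])
  out
}

#' Drug-vs-vehicle log2 expression ratios per comparison
#'
#' For each named comparison, `log2(mean RPKM of the drug samples / mean RPKM
#' of the vehicle samples)`; the ratio is defined only when both group means
#' are positive (`NA` otherwise).
#'
#' @param rpkm_table result of [rpkm()].
#' @param comparisons named list; each element is a list with character
#'   vectors `drug` and `vehicle` naming sample columns.
#' @return `data.frame` with `gene_id` and one log2-ratio column per
#'   comparison.
#' @export
log2_expression_ratios <- function(rpkm_table, comparisons) {
  out <- data.frame(gene_id = rpkm_table$gene_id, stringsAsFactors = FALSE)
  for (cmp in names(comparisons)) {
    grp <- comparisons[[cmp]]
    mu_d <- rowMeans(rpkm_table[, grp$drug, drop = FALSE])
    mu_v <- rowMeans(rpkm_table[, grp$vehicle, drop = FALSE])
    r <- ifelse(mu_d > 0 & mu_v > 0, log2(mu_d / mu_v), NA_real_)
    out[[cmp]] <- r
  }
  out
}

#' Genes with a consistent expression response across comparisons
#'
#' A gene responds consistently when its log2 ratio has the same strict sign
#' in every listed comparison. Genes with a missing ratio are excluded with a
#' warning.
#'
#' @param ratios result of [log2_expression_ratios()].
#' @param comparisons character vector of ratio columns to require (default:
#'   all).
#' @return list with character vectors `up` and `down`.
#' @export
consistent_direction_genes <- function(ratios, comparisons = NULL) {
  comparisons <- comparisons %||% setdiff(names(ratios), "gene_id")
  mat <- as.matrix(ratios[comparisons])
  miss <- apply(mat, 1, anyNA)
  if (any(miss))
    warn_fmt("%d gene(s) excluded: missing log2 ratio", sum(miss))
  up <- !miss & apply(mat > 0, 1, all)
  down <- !miss & apply(mat < 0, 1, all)
  list(up = ratios$gene_id[up], down = ratios$gene_id[down])
}

#' Transcript consequences of an induced novel exon
#'
#' Pure arithmetic on an exon inserted between two constitutive exons: the
#' included-isoform RT-PCR amplicon equals the excluded amplicon plus the
#' exon length; the exon induces a frameshift iff its length is not a
#' multiple of 3; and, when the exon sequence and the reading-frame offset at
#' its 5' end are supplied, the in-frame stop codons (TAA/TAG/TGA) inside the
#' exon are counted.
#'
#' @param exon_length_nt novel exon length in nucleotides (positive).
#' @param excluded_amplicon_bp amplicon size of the exon-skipping isoform
#'   (positive).
#' @param exon_sequence optional exon nucleotide sequence; its length must
#'   equal `exon_length_nt`.
#' @param upstream_frame_offset optional 0..2: number of bases of the codon
#'   in progress when the transcript enters the exon (0 = exon starts a new
#'   codon).
#' @return list of class `novel_exon_consequence`: `exon_length_nt`,
#'   `excluded_amplicon_bp`, `included_amplicon_bp`, `frameshift`,
#'   `stop_codons_in_frame` (`NA` when no sequence given).
#' @examples
#' novel_exon_consequence(115, 88)  # 203-bp included amplicon, frameshift
#' @export
novel_exon_consequence <- function(exon_length_nt, excluded_amplicon_bp,
                                   exon_sequence = NULL,
                                   upstream_frame_offset = NULL) {
  stopifnot(exon_length_nt > 0, excluded_amplicon_bp > 0)
  n_stops <- NA_integer_
  if (!is.null(exon_sequence)) {
    exon_sequence <- toupper(exon_sequence)
    if (nchar(exon_sequence) != exon_length_nt)
      stop_fmt("exon sequence length (%d) differs from exon_length_nt (%d)",
               nchar(exon_sequence), exon_length_nt)
    off <- upstream_frame_offset %||% 0L
    if (!off %in% 0:2) stop_fmt("upstream_frame_offset must be 0, 1 or 2")
    # first full codon inside the exon starts after completing the one in progress
    first <- ((3L - off) %% 3L) + 1L
    starts <- if (first <= exon_length_nt - 2L)
      seq.int(first, exon_length_nt - 2L, by = 3L) else integer(0)
    codons <- substring(exon_sequence, starts, starts + 2L)
    n_stops <- sum(codons %in% c("TAA", "TAG", "TGA"))
  }
  structure(list(exon_length_nt = as.integer(exon_length_nt),
                 excluded_amplicon_bp = as.integer(excluded_amplicon_bp),
                 included_amplicon_bp = as.integer(excluded_amplicon_bp + exon_length_nt),
                 frameshift = (exon_length_nt %% 3L) != 0L,
                 stop_codons_in_frame = n_stops),
            class = "novel_exon_consequence")
}

#' @export
print.novel_exon_consequence <- function(x, ...) {
  cat(sprintf(
    "<novel_exon_consequence> %d-nt exon: amplicon %d -> %d bp; frameshift: %s; in-frame stops: %s\n",
    x$exon_length_nt, x$excluded_amplicon_bp, x$included_amplicon_bp,
    x$frameshift, x$stop_codons_in_frame))
  invisible(x)
}
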