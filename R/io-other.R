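# Readers/writers for eCLIP peak files (BED6+ dialects), FASTA genomes,
# annotation splice-site boundary lists and gene-count tables.

#' Column schema for a BED-like peak dialect
#'
#' eCLIP narrowPeak dialects differ in which extra columns carry the
#' enrichment and significance values, so the mapping is explicit
#' configuration rather than guesswork.
#'
#' @param log2_fold_change 1-based column index of the log2(fold change)
#'   field (default 7, the BED6+2 convention used here).
#' @param neg_log10_p 1-based column index of the -log10(P value) field
#'   (default 8).
#' @return a named list used by [read_peaks()].
#' @export
peak_schema <- function(log2_fold_change = 7L, neg_log10_p = 8L) {
  stopifnot(log2_fold_change >= 1L, neg_log10_p >= 1L)
  list(log2_fold_change = as.integer(log2_fold_change),
       neg_log10_p = as.integer(neg_log10_p))
}

#' Read an eCLIP peak file
#'
#' Reads a BED-like tab-separated peak file. Coordinates are interpreted
#' 0-based half-open, per BED. The positions of the numeric
#' log2(fold change) and -log10(P) columns come from `schema`.
#'
#' @param path path to the peak file (no header).
#' @param schema a [peak_schema()].
#' @param rbp_name,cell_line optional annotations attached to every peak
#'   (typically from a manifest).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, `log2_fold_change`, `neg_log10_p`, `rbp_name`, `cell_line`.
#' @export
read_peaks <- function(path, schema = peak_schema(), rbp_name = NA_character_,
                       cell_line = NA_character_) {
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) data.frame())
  if (nrow(raw) == 0L || ncol(raw) < 3L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), strand = character(0),
                      log2_fold_change = numeric(0), neg_log10_p = numeric(0),
                      rbp_name = character(0), cell_line = character(0),
                      stringsAsFactors = FALSE))
  }
  if (max(schema$log2_fold_change, schema$neg_log10_p) > ncol(raw))
    stop_fmt("peak schema column index out of range for '%s' (%d columns)",
             path, ncol(raw))
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  if (anyNA(start) || anyNA(end)) stop_fmt("non-integer peak coordinate in %s", path)
  if (any(start < 0)) stop_fmt("negative peak coordinate in %s", path)
  if (any(start >= end)) stop_fmt("peak start >= end in %s", path)
  lfc <- suppressWarnings(as.numeric(raw[[schema$log2_fold_change]]))
  nlp <- suppressWarnings(as.numeric(raw[[schema$neg_log10_p]]))
  if (anyNA(lfc) || anyNA(nlp))
    stop_fmt("non-numeric enrichment/significance field in %s", path)
  data.frame(
    chrom = raw[[1]], start = start, end = end,
    name = if (ncol(raw) >= 4L) raw[[4]] else NA_character_,
    strand = if (ncol(raw) >= 6L) raw[[6]] else ".",
    log2_fold_change = lfc, neg_log10_p = nlp,
    rbp_name = rbp_name, cell_line = cell_line,
    stringsAsFactors = FALSE)
}

#' Write peaks in BED6+2 form
#'
#' @param peaks peak `data.frame` as from [read_peaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    ifelse(is.na(peaks$name), ".", peaks$name), 0L,
                    ifelse(is.na(peaks$strand), ".", peaks$strand),
                    fmt_num(signif(peaks$log2_fold_change, 6)),
                    fmt_num(signif(peaks$neg_log10_p, 6)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA genome into a named character vector
#'
#' Sequences are uppercased; the contig name is the header token before the
#' first whitespace. Duplicate contig names and empty sequences are errors.
#'
#' @param path FASTA path.
#' @return named character vector, one element per contig.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop_fmt("duplicate contig name in %s", path)
  if (any(Biostrings::width(ss) == 0L)) stop_fmt("empty sequence in %s", path)
  out <- toupper(as.character(ss))
  names(out) <- nm
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param genome named character vector (contig -> sequence).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a gene-count table
#'
#' Tab-separated with header: `gene_id`, `length`, then one column per sample.
#'
#' @param path input path.
#' @return `data.frame` with `gene_id`, `length_bp` and one integer column per
#'   sample.
#' @export
read_gene_counts <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "length") %in% names(raw)))
    stop_fmt("gene-count table '%s' must have gene_id and length columns", path)
  if (any(raw$length <= 0)) stop_fmt("non-positive gene length in %s", path)
  samples <- setdiff(names(raw), c("gene_id", "length"))
  counts <- raw[samples]
  if (any(vapply(counts, function(x) any(x < 0 | x != floor(x)), TRUE)))
    stop_fmt("counts must be non-negative integers in %s", path)
  out <- data.frame(gene_id = raw$gene_id, length_bp = as.integer(raw$length),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in samples) out[[s]] <- as.integer(raw[[s]])
  out
}

#' @rdname read_gene_counts
#' @param counts gene-count `data.frame` as from [read_gene_counts()].
#' @export
write_gene_counts <- function(counts, path) {
  out <- counts
  names(out)[names(out) == "length_bp"] <- "length"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an annotation splice-site boundary list
#'
#' The annotation is reduced to the set of known exon-boundary positions
#' (tab-separated `chrom`, `pos`, `side`, `strand`; `pos` on the 0-based
#' half-open exon scale). An event is a novel-splice-site (novelSS) event when
#' any boundary of its target exon is absent from this set.
#'
#' @param path input/output path.
#' @return `data.frame` with columns `chrom`, `pos`, `side`, `strand`.
#' @export
read_annotation_boundaries <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "side", "strand")
  if (!all(need %in% names(raw)))
    stop_fmt("boundary list '%s' must have columns %s", path, paste(need, collapse = ", "))
  raw$pos <- as.integer(raw$pos)
  raw
}

#' @rdname read_annotation_boundaries
#' @param boundaries boundary `data.frame`.
#' @export
write_annotation_boundaries <- function(boundaries, path) {
  utils::write.table(boundaries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an eCLIP peak-file manifest
#'
#' Tab-separated with header `file`, `rbp_name`, `cell_line`; `file` paths are
#' resolved relative to the manifest's directory when not absolute.
#'
#' @param path manifest path.
#' @return `data.frame` with resolved `file`, `rbp_name`, `cell_line`.
#' @export
read_peak_manifest <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("file", "rbp_name", "cell_line")
  if (!all(need %in% names(raw)))
    stop_fmt("peak manifest '%s' must have columns %s", path, paste(need, collapse = ", "))
  rel <- !grepl("^/", raw$file)
  raw$file[rel] <- file.path(dirname(path), raw$file[rel])
  raw
}

#' Load all peaks named by a manifest
#'
#' @param manifest `data.frame` from [read_peak_manifest()].
#' @param schema a [peak_schema()].
#' @return single peak `data.frame` with per-peak `rbp_name` / `cell_line`.
#' @export
read_manifest_peaks <- function(manifest, schema = peak_schema()) {
  do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    read_peaks(manifest$file[i], schema = schema,
               rbp_name = manifest$rbp_name[i],
               cell_line = manifest$cell_line[i])
  }))
}
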