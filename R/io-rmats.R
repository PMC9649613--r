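# Readers/writers for rMATS-dialect junction-count tables (the "JC" flavour).

#' Read an rMATS junction-count table
#'
#' Parses one per-type rMATS output table (tab-separated, JC flavour) into a
#' tidy event data frame. Comma-separated per-replicate fields (`IJC_SAMPLE_1`,
#' `IncLevel1`, ...) become list-columns of numeric vectors; the literal
#' `"NA"` (or an empty field) maps to missing; any other non-numeric token is a
#' parse error. Coordinates are kept exactly as printed: `*_0base` columns are
#' 0-based starts, end columns are exclusive.
#'
#' @param path path to the table.
#' @param event_type one of `"SE"`, `"A3SS"`, `"A5SS"`, `"MXE"`, `"RI"`;
#'   selects the coordinate-column schema.
#' @return a `data.frame` with one row per event: `id`, `gene_id`,
#'   `gene_symbol`, `chrom`, `strand`, `event_type`, list-column `coords`
#'   (per-type coordinate tuple), list-columns `ijc1`, `sjc1`, `ijc2`, `sjc2`,
#'   `inc1`, `inc2`, plus `inc_form_len`, `skip_form_len`, `pvalue`, `fdr`,
#'   `inc_level_difference` and the canonical `key`.
#' @seealso [write_rmats_table()], [event_key()]
#' @export
read_rmats_table <- function(path, event_type) {
  event_type <- check_event_type(event_type)
  coord_cols <- RMATS_COORD_COLS[[event_type]]
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c(RMATS_SHARED_COLS, coord_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_fmt("rMATS %s table '%s' lacks mandatory column(s): %s",
             event_type, path, paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  lines <- seq_len(n) + 1L  # header is line 1

  int_scalar <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop_fmt("column %s: non-integer value '%s' at line %d in %s",
               col, raw[[col]][i], lines[i], path)
    }
    v
  }
  count_list <- function(col) {
    out <- split_commas(raw[[col]], what = col, line = lines)
    lapply(seq_along(out), function(i) {
      v <- out[[i]]
      if (anyNA(v) || any(v != floor(v)) || any(v < 0))
        stop_fmt("column %s: counts must be non-negative integers (line %d in %s)",
                 col, lines[i], path)
      as.integer(v)
    })
  }
  prob_scalar <- function(col) {
    v <- vapply(split_commas(raw[[col]], what = col, line = lines),
                function(x) x[1], 0)
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop_fmt("column %s: value outside [0,1] in %s", col, path)
    v
  }

  coords <- if (n) {
    coord_mat <- vapply(coord_cols, int_scalar, integer(n))
    if (n == 1L) coord_mat <- matrix(coord_mat, nrow = 1L)
    if (any(coord_mat < 0)) stop_fmt("negative coordinate in %s", path)
    starts <- coord_mat[, seq(1L, length(coord_cols), by = 2L), drop = FALSE]
    ends   <- coord_mat[, seq(2L, length(coord_cols), by = 2L), drop = FALSE]
    if (any(starts >= ends)) stop_fmt("exon start >= end in %s", path)
    lapply(seq_len(n), function(i) unname(coord_mat[i, ]))
  } else list()

  ev <- data.frame(
    id = if (n) raw$ID else character(0),
    gene_id = if (n) raw$GeneID else character(0),
    gene_symbol = if (n) raw$geneSymbol else character(0),
    chrom = if (n) raw$chr else character(0),
    strand = if (n) raw$strand else character(0),
    event_type = rep_len(event_type, n),
    stringsAsFactors = FALSE
  )
  ev$coords <- coords
  for (pair in list(c("ijc1", "IJC_SAMPLE_1"), c("sjc1", "SJC_SAMPLE_1"),
                    c("ijc2", "IJC_SAMPLE_2"), c("sjc2", "SJC_SAMPLE_2"))) {
    ev[[pair[1]]] <- if (n) count_list(pair[2]) else list()
  }
  if (n) {
    if (any(lengths(ev$ijc1) != lengths(ev$sjc1)) ||
        any(lengths(ev$ijc2) != lengths(ev$sjc2)))
      stop_fmt("replicate list lengths differ between IJC and SJC in %s", path)
    ev$inc_form_len <- int_scalar("IncFormLen")
    ev$skip_form_len <- int_scalar("SkipFormLen")
    if (any(ev$inc_form_len <= 0) || any(ev$skip_form_len <= 0))
      stop_fmt("IncFormLen/SkipFormLen must be positive in %s", path)
    ev$pvalue <- prob_scalar("PValue")
    ev$fdr <- prob_scalar("FDR")
    ev$inc1 <- split_commas(raw$IncLevel1, what = "IncLevel1", line = lines)
    ev$inc2 <- split_commas(raw$IncLevel2, what = "IncLevel2", line = lines)
    if (any(lengths(ev$inc1) != lengths(ev$ijc1)) ||
        any(lengths(ev$inc2) != lengths(ev$ijc2)))
      stop_fmt("IncLevel replicate count differs from junction counts in %s", path)
    ild <- vapply(split_commas(raw$IncLevelDifference, what = "IncLevelDifference",
                               line = lines), function(x) x[1], 0)
    if (any(!is.na(ild) & abs(ild) > 1))
      stop_fmt("IncLevelDifference outside [-1,1] in %s", path)
    ev$inc_level_difference <- ild
    ev$key <- event_key(ev$event_type, ev$chrom, ev$strand, ev$coords)
  } else {
    ev$inc_form_len <- integer(0); ev$skip_form_len <- integer(0)
    ev$pvalue <- numeric(0); ev$fdr <- numeric(0)
    ev$inc1 <- list(); ev$inc2 <- list()
    ev$inc_level_difference <- numeric(0); ev$key <- character(0)
  }
  ev
}

#' Write an rMATS-dialect junction-count table
#'
#' Inverse of [read_rmats_table()]: emits the per-type tab-separated dialect
#' (shared columns plus the type's coordinate columns) so that reading the file
#' back reproduces the input field-by-field.
#'
#' @param events event data frame as returned by [read_rmats_table()] (all rows
#'   must share one `event_type`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmats_table <- function(events, path) {
  et <- unique(events$event_type)
  if (length(et) != 1L) stop_fmt("write_rmats_table() needs a single event type")
  coord_cols <- RMATS_COORD_COLS[[check_event_type(et)]]
  n <- nrow(events)
  out <- data.frame(ID = events$id, GeneID = events$gene_id,
                    geneSymbol = events$gene_symbol, chr = events$chrom,
                    strand = events$strand, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in seq_along(coord_cols))
    out[[coord_cols[j]]] <- vapply(events$coords, `[`, 0L, j)
  out[["IJC_SAMPLE_1"]] <- commas(events$ijc1)
  out[["SJC_SAMPLE_1"]] <- commas(events$sjc1)
  out[["IJC_SAMPLE_2"]] <- commas(events$ijc2)
  out[["SJC_SAMPLE_2"]] <- commas(events$sjc2)
  out$IncFormLen <- events$inc_form_len
  out$SkipFormLen <- events$skip_form_len
  out$PValue <- fmt_num(signif(events$pvalue, 6))
  out$FDR <- fmt_num(signif(events$fdr, 6))
  out$IncLevel1 <- commas(events$inc1, digits = 3)
  out$IncLevel2 <- commas(events$inc2, digits = 3)
  out$IncLevelDifference <- fmt_num(events$inc_level_difference, digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
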