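# Events x comparisons delta-PSI matrix with masking, and k-means response
# clustering of the events significant in any comparison.

#' Build the events x comparisons delta-PSI matrix
#'
#' Rows are the union of event keys significant in at least one of the
#' supplied comparisons; the cell for comparison j holds that comparison's
#' inclusion-level difference when the event passed the coverage filter there,
#' and is masked (recorded in the `mask` matrix, value `NA`) when the event
#' was not detected with sufficient reads in that comparison.
#'
#' @param covered list of coverage-filtered [comparison_set()]s (typically the
#'   four drug-vs-vehicle comparisons), each with `novel_ss` annotated.
#' @param fdr_max,min_abs_delta significance thresholds passed to
#'   [significant_events()] per comparison.
#' @return an object of class `delta_psi_matrix`: list with numeric `values`
#'   (rows = events, columns = comparisons, `NA` where masked), logical
#'   `mask` (`TRUE` = not detected), and per-event `annotations`
#'   (`event_type`, `novel_ss`). Zero qualifying events is an error.
#' @export
build_delta_psi_matrix <- function(covered, fdr_max = 0.05, min_abs_delta = 0.1) {
  stopifnot(length(covered) >= 1L, all(vapply(covered, inherits, TRUE, "comparison_set")))
  labels <- vapply(covered, `[[`, "", "label")
  sig <- lapply(covered, function(cs)
    suppressWarnings(significant_events(cs, fdr_max, min_abs_delta)))
  keys <- sort(unique(unlist(lapply(sig, function(cs) cs$events$key))))
  if (length(keys) == 0L)
    stop_fmt("no event is significant in any comparison: empty matrix")
  values <- matrix(NA_real_, nrow = length(keys), ncol = length(covered),
                   dimnames = list(keys, labels))
  for (j in seq_along(covered)) {
    ev <- covered[[j]]$events
    hit <- ev$key %in% keys
    values[ev$key[hit], j] <- ev$inc_level_difference[hit]
  }
  mask <- is.na(values)
  if (any(rowSums(!mask) == 0L))
    stop_fmt("internal error: matrix row with no unmasked cell")
  ann <- data.frame(key = keys, event_type = NA_character_, novel_ss = NA,
                    stringsAsFactors = FALSE)
  for (cs in covered) {
    ev <- cs$events
    m <- match(ann$key, ev$key)
    got <- !is.na(m)
    ann$event_type[got] <- ev$event_type[m[got]]
    if (!is.null(ev$novel_ss)) ann$novel_ss[got] <- ev$novel_ss[m[got]]
  }
  structure(list(values = values, mask = mask, annotations = ann,
                 comparison_labels = labels),
            class = "delta_psi_matrix")
}

#' @export
print.delta_psi_matrix <- function(x, ...) {
  cat(sprintf("<delta_psi_matrix> %d events x %d comparisons (%d masked cells)\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' K-means clustering of delta-PSI response profiles
#'
#' Partitions events into `k` response clusters with [stats::kmeans()]
#' (`nstart` restarts, squared-Euclidean distance on the raw delta-PSI scale,
#' all columns sharing the `[-1, 1]` range). Masked cells are imputed with
#' `imputation_value` (default 0 = "no change") before clustering; unmasked
#' cells are never altered. The run is deterministic for a given seed.
#'
#' @param m a [build_delta_psi_matrix()] result.
#' @param k number of clusters (default 10; must be >= 2 and <= rows).
#' @param seed RNG seed for the restarts (default 42).
#' @param n_init number of random restarts (default 10).
#' @param max_iter maximum iterations per run (default 300).
#' @param imputation_value value substituted for masked cells (default 0).
#' @return object of class `cluster_assignment`: list with `labels` (named
#'   integer vector, cluster ids `0 .. k-1`), `k`, `seed`, `imputation_value`
#'   and the k-means `centers`.
#' @export
cluster_events <- function(m, k = 10, seed = 42, n_init = 10, max_iter = 300,
                           imputation_value = 0) {
  stopifnot(inherits(m, "delta_psi_matrix"))
  if (k < 2) stop_fmt("k must be at least 2")
  if (nrow(m$values) < k)
    stop_fmt("only %d events for k = %d clusters; choose a smaller k",
             nrow(m$values), k)
  x <- m$values
  x[m$mask] <- imputation_value
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = n_init, iter.max = max_iter)
  labels <- as.integer(km$cluster) - 1L
  names(labels) <- rownames(x)
  structure(list(labels = labels, k = as.integer(k), seed = as.integer(seed),
                 imputation_value = imputation_value, centers = km$centers),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d (seed %d); sizes: %s\n", x$k, x$seed,
              paste(table(factor(x$labels, levels = 0:(x$k - 1))), collapse = ", ")))
  invisible(x)
}

#' Summarise one response cluster
#'
#' Per-comparison delta-PSI distribution summaries, cluster size, novelSS
#' fraction, and a coherence flag that is `TRUE` when every unmasked cell in
#' the cluster shares one sign — the signature of a drug-responsive cluster
#' with unidirectional splicing change (negative = exon inclusion in the
#' treated condition).
#'
#' @param m the [build_delta_psi_matrix()] result.
#' @param ca the [cluster_events()] assignment.
#' @param cluster_id cluster id in `0 .. k-1`.
#' @param coherent_fraction fraction of unmasked cells required to share the
#'   majority sign (default 1 = strict).
#' @return list with `cluster_id`, `n_events`, `keys`, `novel_ss_fraction`,
#'   `coherent`, `direction` (`"included"`, `"excluded"` or `NA`), and a
#'   `per_comparison` data frame (mean/median delta-PSI, n unmasked).
#' @export
cluster_summary <- function(m, ca, cluster_id, coherent_fraction = 1) {
  stopifnot(inherits(m, "delta_psi_matrix"), inherits(ca, "cluster_assignment"))
  if (!cluster_id %in% 0:(ca$k - 1L)) stop_fmt("unknown cluster id %s", cluster_id)
  keys <- names(ca$labels)[ca$labels == cluster_id]
  if (length(keys) == 0L) stop_fmt("cluster %d is empty", cluster_id)
  vals <- m$values[keys, , drop = FALSE]
  unmasked <- vals[!is.na(vals)]
  sgn <- sign(unmasked)
  frac_neg <- mean(sgn < 0)
  frac_pos <- mean(sgn > 0)
  coherent <- max(frac_neg, frac_pos) >= coherent_fraction
  direction <- if (!coherent) NA_character_
               else if (frac_neg >= frac_pos) "included" else "excluded"
  ann <- m$annotations[match(keys, m$annotations$key), ]
  per_comp <- data.frame(
    comparison = m$comparison_labels,
    mean_delta_psi = apply(vals, 2, mean, na.rm = TRUE),
    median_delta_psi = apply(vals, 2, stats::median, na.rm = TRUE),
    n_unmasked = apply(vals, 2, function(v) sum(!is.na(v))),
    row.names = NULL, stringsAsFactors = FALSE)
  list(cluster_id = as.integer(cluster_id), n_events = length(keys), keys = keys,
       novel_ss_fraction = mean(ann$novel_ss, na.rm = TRUE),
       coherent = coherent, direction = direction, per_comparison = per_comp)
}

#' Export the delta-PSI matrix with cluster labels
#'
#' Tab-separated `key`, one delta-PSI column per comparison (`NA` for masked
#' cells), `cluster`, `novel_ss`; rows ordered heatmap-ready by cluster then
#' mean delta-PSI.
#'
#' @param m a [build_delta_psi_matrix()] result.
#' @param ca a [cluster_events()] assignment.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delta_psi_matrix <- function(m, ca, path) {
  ord <- order(ca$labels[rownames(m$values)],
               rowMeans(m$values, na.rm = TRUE))
  out <- data.frame(key = rownames(m$values)[ord],
                    round(m$values[ord, , drop = FALSE], 4),
                    cluster = unname(ca$labels[rownames(m$values)[ord]]),
                    novel_ss = m$annotations$novel_ss[match(rownames(m$values)[ord],
                                                            m$annotations$key)],
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
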