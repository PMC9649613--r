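# Quantification of drug-induced reversal ("rescue") of disease-associated
# splicing: per-event absolute inclusion-level deviations from control under
# vehicle and under drug, a strict rescue call, and cohort summaries.

#' Per-event rescue records
#'
#' For each significant disease-associated event (control-vehicle vs
#' disease-vehicle), compares the group-mean PSI deviation from control under
#' vehicle (`abs_diff_dmso = |psi_ctrl - psi_hd_dmso|`) with the deviation
#' under drug (`abs_diff_drug = |psi_ctrl - psi_hd_drug|`). An event is
#' rescued when `abs_diff_drug` drops strictly below `rescue_threshold`.
#'
#' Only events detected in all samples of the cell type are used: every
#' sample of the disease comparison and every drug-treated sample must carry
#' strictly more than `min_reads` junction reads (this ">10" detection rule is
#' deliberately distinct from the inclusive ">= 10" global coverage filter).
#' Events failing the rule are excluded and counted in attribute
#' `n_excluded`.
#'
#' @param hd_cs significance-called [comparison_set()] whose group 1 is
#'   control-vehicle and group 2 is disease-vehicle.
#' @param drug_cs [comparison_set()] carrying the disease-drug samples (by
#'   default as its group 2, e.g. the disease vehicle-vs-drug comparison).
#' @param rescue_threshold absolute inclusion-level-difference corridor
#'   (default 0.1, strict).
#' @param min_reads per-sample detection threshold (default 10, strict).
#' @param drug_group which group of `drug_cs` holds the drug-treated samples
#'   (1 or 2; default 2).
#' @return `data.frame` of class `rescue_records`: `key`, `direction_in_hd`
#'   (`"included"`/`"excluded"` in the disease state), `psi_ctrl_dmso`,
#'   `psi_hd_dmso`, `psi_hd_drug`, `abs_diff_dmso`, `abs_diff_drug`,
#'   `rescued`.
#' @export
rescue_records <- function(hd_cs, drug_cs, rescue_threshold = 0.1,
                           min_reads = 10, drug_group = 2L) {
  stopifnot(inherits(hd_cs, "comparison_set"), inherits(drug_cs, "comparison_set"))
  hd <- hd_cs$events
  if (is.null(hd$direction))
    stop_fmt("hd_cs must be significance-called (see significant_events())")
  dr <- drug_cs$events
  m <- match(hd$key, dr$key)
  if (all(is.na(m)) && nrow(hd) > 0L)
    stop_fmt("no disease event is present in the drug comparison set")
  icol <- if (drug_group == 1L) "ijc1" else "ijc2"
  scol <- if (drug_group == 1L) "sjc1" else "sjc2"
  pcol <- if (drug_group == 1L) "inc1" else "inc2"
  n_excluded <- 0L
  rows <- vector("list", nrow(hd))
  for (i in seq_len(nrow(hd))) {
    j <- m[i]
    if (is.na(j)) { n_excluded <- n_excluded + 1L; next }
    tot_hd <- c(hd$ijc1[[i]] + hd$sjc1[[i]], hd$ijc2[[i]] + hd$sjc2[[i]])
    tot_dr <- dr[[icol]][[j]] + dr[[scol]][[j]]
    if (!all(c(tot_hd, tot_dr) > min_reads)) { n_excluded <- n_excluded + 1L; next }
    psi_ctrl <- mean(hd$inc1[[i]])
    psi_hd <- mean(hd$inc2[[i]])
    psi_drug <- mean(dr[[pcol]][[j]])
    if (anyNA(c(psi_ctrl, psi_hd, psi_drug))) { n_excluded <- n_excluded + 1L; next }
    rows[[i]] <- data.frame(
      key = hd$key[i], direction_in_hd = hd$direction[i],
      psi_ctrl_dmso = psi_ctrl, psi_hd_dmso = psi_hd, psi_hd_drug = psi_drug,
      abs_diff_dmso = abs(psi_ctrl - psi_hd),
      abs_diff_drug = abs(psi_ctrl - psi_drug),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(key = character(0), direction_in_hd = character(0),
                      psi_ctrl_dmso = numeric(0), psi_hd_dmso = numeric(0),
                      psi_hd_drug = numeric(0), abs_diff_dmso = numeric(0),
                      abs_diff_drug = numeric(0), stringsAsFactors = FALSE)
  # strict corridor; rounding guards binary representation at exact ties
  out$rescued <- round(out$abs_diff_drug, 9) < round(rescue_threshold, 9)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  attr(out, "rescue_threshold") <- rescue_threshold
  class(out) <- c("rescue_records", "data.frame")
  out
}

#' Summarise rescue of disease-associated splicing
#'
#' Mean absolute deviations under vehicle and drug, the percent reduction
#' `100 * (1 - mean_drug/mean_dmso)`, the rescued fraction, a two-sided
#' Wilcoxon rank-sum test comparing the two deviation samples (normal
#' approximation without continuity correction at n >= 20, exact below), and
#' the pie-chart partition rescued / still-included / still-excluded (the
#' residual direction of unrescued events read from the sign of
#' `psi_ctrl - psi_hd_drug`).
#'
#' @param records a [rescue_records()] result with at least one row.
#' @return list with `n_events`, `mean_abs_diff_dmso`, `mean_abs_diff_drug`,
#'   `percent_reduction`, `rescued_fraction`, `ranksum_statistic`,
#'   `ranksum_p`, and `partition` (named counts).
#' @export
rescue_summary <- function(records) {
  if (nrow(records) == 0L) stop_fmt("no rescue records to summarise")
  x <- records$abs_diff_dmso
  y <- records$abs_diff_drug
  exact <- length(x) < 20 && length(y) < 20
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = FALSE))
  still <- !records$rescued
  resid_dir <- ifelse(records$psi_ctrl_dmso - records$psi_hd_drug > 0,
                      "excluded", "included")
  partition <- c(rescued = sum(records$rescued),
                 still_included = sum(still & resid_dir == "included"),
                 still_excluded = sum(still & resid_dir == "excluded"))
  list(n_events = nrow(records),
       mean_abs_diff_dmso = mean(x),
       mean_abs_diff_drug = mean(y),
       percent_reduction = 100 * (1 - mean(y) / mean(x)),
       rescued_fraction = mean(records$rescued),
       ranksum_statistic = unname(wt$statistic),
       ranksum_p = wt$p.value,
       partition = partition)
}

#' Overlap between drug-responsive and disease-associated events
#'
#' Reports the intersection and Jaccard index of two significance-called key
#' sets; a small overlap supports the reading that the drug does not directly
#' target the disease-associated events.
#'
#' @param hd_keys,drug_keys character vectors of event keys from the same
#'   cell type.
#' @return list with `intersection`, `n_hd`, `n_drug`, `n_shared`,
#'   `jaccard`.
#' @export
drug_targets_disease_events <- function(hd_keys, drug_keys) {
  hd_keys <- unique(hd_keys); drug_keys <- unique(drug_keys)
  shared <- intersect(hd_keys, drug_keys)
  uni <- union(hd_keys, drug_keys)
  list(intersection = shared, n_hd = length(hd_keys),
       n_drug = length(drug_keys), n_shared = length(shared),
       jaccard = if (length(uni)) length(shared) / length(uni) else 0)
}

#' Export rescue records
#'
#' @param records a [rescue_records()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rescue_records <- function(records, path) {
  out <- data.frame(key = records$key, direction = records$direction_in_hd,
                    abs_diff_dmso = round(records$abs_diff_dmso, 4),
                    abs_diff_drug = round(records$abs_diff_drug, 4),
                    rescued = records$rescued, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
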