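# Truth-annotated synthetic four-condition splicing-modulator study.
#
# Emulates the data structure the downstream pipeline consumes: per-sample
# inclusion/skipping junction counts with group PSI structure (rMATS-dialect
# tables for each AS type and comparison), a genome with splice-site motifs
# written at drug-induced novel exons, an annotation exon-boundary set that
# excludes those exons (novelSS), eCLIP peak files with planted RBP binding
# structure, and gene-count tables with planted drug expression effects.
# Every planted quantity is recorded in a truth bundle.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Configuration for the synthetic splicing-modulator study
#'
#' Defaults emulate the study design the pipeline targets: two cell types
#' (fibroblasts with 4 replicates per condition, cortical neurons with 3),
#' four conditions each (Ctrl/HD crossed with DMSO/drug), disease-associated
#' events with |delta PSI| drawn from 0.15-0.6, 55 drug-induced novel-splice
#' -site cassette exons in two coherent response clusters, a planted rescue
#' fraction of 0.5, the drug-associated splice-site 8-mers AGAGTAAG (5'SS)
#' and TTCAGTTT (3'SS), RBP binding models including a rescue-preferential
#' binder, and planted consistent expression responses.
#'
#' @param seed integer RNG seed; the same seed reproduces byte-identical
#'   files.
#' @param cell_types named list: cell type -> list(n_rep =).
#' @param n_background named integer vector of unaffected events per AS type.
#' @param n_hd number of disease-associated (HD vs Ctrl) cassette events.
#' @param hd_delta_range magnitude range of the planted HD delta PSI.
#' @param n_drug_clusters sizes of the drug-induced novelSS event clusters.
#' @param drug_cluster_delta PSI increase under drug for each cluster.
#' @param rescue_fraction fraction of HD events whose drug-treated PSI is
#'   returned to control level.
#' @param depth mean per-sample junction depth (Poisson).
#' @param low_depth depth used for planted not-detected (masked) cells.
#' @param n_masked number of drug-induced events planted as undetected in one
#'   drug comparison each.
#' @param psi_sd per-sample PSI noise (truncated normal sd).
#' @param inc_form_len,skip_form_len effective form lengths used to split
#'   counts so that [compute_psi()] inverts the simulation.
#' @param motif_5ss,motif_3ss splice-site motifs written at drug-induced
#'   events' windows.
#' @param motif_rate probability that a drug-induced event carries the motif
#'   at a given site.
#' @param flank window half-width used when planting motifs (must cover the
#'   motifs).
#' @param rbp_models named list of RBP binding models; each a list with
#'   `rate_bg` and optional `rate_hd`, `rate_rescued`, `rate_unrescued`.
#' @param n_expr_background background genes added to the gene-count table.
#' @param n_expr_up,n_expr_down planted consistently up-/down-regulated genes
#'   (taken from the drug-induced events' genes).
#' @param expr_log2fc magnitude of the planted consistent log2 effects.
#' @param boundary_cases add adversarial filter-boundary rows (exact-threshold
#'   FDR/delta/coverage events and peaks) to the first cell type's disease
#'   comparison; used by the small fixture.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       cell_types = list(fibroblast = list(n_rep = 4L),
                                         neuron = list(n_rep = 3L)),
                       n_background = c(SE = 120L, A3SS = 20L, A5SS = 20L,
                                        MXE = 15L, RI = 20L),
                       n_hd = 150L,
                       hd_delta_range = c(0.15, 0.6),
                       n_drug_clusters = c(30L, 25L),
                       drug_cluster_delta = c(0.65, 0.35),
                       rescue_fraction = 0.5,
                       depth = 100,
                       low_depth = 3,
                       n_masked = 4L,
                       psi_sd = 0.05,
                       inc_form_len = 200L,
                       skip_form_len = 100L,
                       motif_5ss = "AGAGTAAG",
                       motif_3ss = "TTCAGTTT",
                       motif_rate = 0.9,
                       flank = 5L,
                       rbp_models = list(
                         QKI = list(rate_bg = 0.15, rate_rescued = 0.75,
                                    rate_unrescued = 0.2),
                         RBP01 = list(rate_bg = 0.1, rate_hd = 0.5),
                         RBP02 = list(rate_bg = 0.15)),
                       n_expr_background = 40L,
                       n_expr_up = 3L,
                       n_expr_down = 3L,
                       expr_log2fc = 1,
                       boundary_cases = FALSE) {
  if (rescue_fraction < 0 || rescue_fraction > 1)
    stop_fmt("rescue_fraction must lie in [0,1]")
  if (motif_rate < 0 || motif_rate > 1) stop_fmt("motif_rate must lie in [0,1]")
  if (max(nchar(motif_5ss), nchar(motif_3ss)) > 2L * flank)
    stop_fmt("motif longer than the 2*flank window")
  if (length(n_drug_clusters) != length(drug_cluster_delta))
    stop_fmt("n_drug_clusters and drug_cluster_delta lengths differ")
  structure(as.list(environment()), class = "sim_config")
}

# ---- event catalogue ------------------------------------------------------

# three-exon layout inside a 1500-bp block starting at `o`; L = target length
sim_coords <- function(event_type, o, L, strand) {
  up <- c(o, o + 150L)
  down <- c(o + 300L + L + 150L, o + 300L + L + 300L)
  if (strand == "-") { tmp <- up; up <- down; down <- tmp }  # transcript sense
  switch(event_type,
    SE = c(o + 300L, o + 300L + L, up, down),
    A3SS = c(o + 300L, o + 300L + L, o + 330L, o + 300L + L, o, o + 150L),
    A5SS = c(o + 300L, o + 300L + L, o + 330L, o + 300L + L, o, o + 150L),
    MXE = c(o + 300L, o + 300L + L, o + 300L + L + 50L, o + 300L + L + 140L,
            up, down),
    RI = c(o, o + 300L + L + 300L, up, down))
}

sim_catalog <- function(cfg) {
  classes <- c(rep("drug", sum(cfg$n_drug_clusters)),
               rep("hd", cfg$n_hd),
               unlist(lapply(names(cfg$n_background), function(t)
                 rep(paste0("bg_", t), cfg$n_background[[t]]))),
               if (cfg$boundary_cases)
                 c("b_cov_pass", "b_cov_fail", "b_fdr", "b_delta"))
  types <- ifelse(startsWith(classes, "bg_"), sub("^bg_", "", classes), "SE")
  n <- length(classes)
  cluster <- rep(NA_integer_, n)
  cluster[classes == "drug"] <- rep(seq_along(cfg$n_drug_clusters),
                                    cfg$n_drug_clusters)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  L <- ifelse(classes == "drug", 115L,
              sample(c(90L, 120L, 150L), n, replace = TRUE))
  contig <- rep_len(c("chrS1", "chrS2"), n)
  # per-contig block index in catalogue order
  block <- integer(n)
  for (ctg in unique(contig)) block[contig == ctg] <- seq_len(sum(contig == ctg))
  o <- 100L + (block - 1L) * 1500L
  cat_df <- data.frame(
    class = classes, event_type = types, cluster = cluster, strand = strand,
    L = L, contig = contig, origin = o,
    gene_id = sprintf("G%04d", seq_len(n)),
    gene_symbol = sprintf("GENE%04d", seq_len(n)),
    stringsAsFactors = FALSE)
  cat_df$coords <- lapply(seq_len(n), function(i)
    sim_coords(types[i], o[i], L[i], strand[i]))
  cat_df$key <- event_key(cat_df$event_type, cat_df$contig, cat_df$strand,
                          cat_df$coords)
  cat_df$novel_ss <- cat_df$class == "drug"
  cat_df
}

# ---- PSI model ------------------------------------------------------------

# conditions per cell type, in fixed order
SIM_CONDS <- c("Ctrl-DMSO", "Ctrl-Bran", "HD-DMSO", "HD-Bran")

sim_true_psi <- function(cfg, cat_df) {
  n <- nrow(cat_df)
  cts <- names(cfg$cell_types)
  cond_names <- as.vector(outer(SIM_CONDS, cts, function(cd, ct) paste(ct, cd, sep = ":")))
  psi <- matrix(NA_real_, n, length(cond_names), dimnames = list(cat_df$key, cond_names))
  is_drug <- cat_df$class == "drug"
  is_hd <- cat_df$class == "hd"
  psi0 <- numeric(n)
  psi0[is_drug] <- stats::runif(sum(is_drug), 0.02, 0.08)
  psi0[!is_drug] <- stats::runif(sum(!is_drug), 0.2, 0.8)

  hd_sign <- sample(c(-1, 1), n, replace = TRUE)
  hd_delta <- stats::runif(n, cfg$hd_delta_range[1], cfg$hd_delta_range[2])
  # choose a baseline compatible with the drawn effect so no clamping occurs
  pos <- is_hd & hd_sign > 0
  neg <- is_hd & hd_sign < 0
  psi0[pos] <- stats::runif(sum(pos), 0.02, 0.98 - hd_delta[pos])
  psi0[neg] <- stats::runif(sum(neg), 0.02 + hd_delta[neg], 0.98)
  psi_hd <- psi0 + hd_sign * hd_delta

  rescued <- rep(FALSE, n)
  rescued[is_hd] <- stats::runif(sum(is_hd)) < cfg$rescue_fraction
  psi_hd_drug <- ifelse(rescued, clamp(psi0 + stats::runif(n, -0.02, 0.02), 0, 1),
                        psi_hd)
  drug_shift <- ifelse(is_drug, cfg$drug_cluster_delta[cat_df$cluster], 0)

  for (ct in cts) {
    psi[, paste(ct, "Ctrl-DMSO", sep = ":")] <- psi0
    psi[, paste(ct, "Ctrl-Bran", sep = ":")] <- clamp(psi0 + drug_shift, 0, 1)
    psi[, paste(ct, "HD-DMSO", sep = ":")] <- ifelse(is_hd, psi_hd, psi0)
    psi[, paste(ct, "HD-Bran", sep = ":")] <-
      ifelse(is_hd, psi_hd_drug, clamp(psi0 + drug_shift, 0, 1))
  }
  list(psi = psi, rescued_keys = cat_df$key[is_hd & rescued],
       hd_keys = cat_df$key[is_hd], drug_keys = cat_df$key[is_drug])
}

# ---- per-sample counts ----------------------------------------------------

sim_samples <- function(cfg) {
  out <- list()
  for (ct in names(cfg$cell_types)) {
    for (cond in SIM_CONDS) {
      reps <- seq_len(cfg$cell_types[[ct]]$n_rep)
      out[[paste(ct, cond, sep = ":")]] <-
        paste(ct, cond, reps, sep = "_")
    }
  }
  out
}

sim_counts <- function(cfg, cat_df, psi, samples, low_cov) {
  n <- nrow(cat_df)
  all_samples <- unlist(samples, use.names = FALSE)
  ijc <- sjc <- matrix(0L, n, length(all_samples),
                       dimnames = list(cat_df$key, all_samples))
  li <- cfg$inc_form_len; ls <- cfg$skip_form_len
  for (grp in names(samples)) {
    mu <- psi[, grp]
    dep <- rep(cfg$depth, n)
    low <- low_cov$key[low_cov$condition == grp]
    dep[cat_df$key %in% low] <- cfg$low_depth
    for (s in samples[[grp]]) {
      ps <- clamp(stats::rnorm(n, mu, cfg$psi_sd), 0, 1)
      tot <- stats::rpois(n, dep)
      p_inc <- ps * li / (ps * li + (1 - ps) * ls)
      p_inc[is.na(p_inc)] <- 0
      ijc[, s] <- stats::rbinom(n, tot, p_inc)
      sjc[, s] <- tot - ijc[, s]
    }
  }
  list(ijc = ijc, sjc = sjc)
}

# two-sample Welch t-test P on per-sample PSI values; degenerate -> 1
sim_pvalue <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(1)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
}

# ---- table assembly -------------------------------------------------------

sim_comparisons_spec <- function(cfg) {
  specs <- list()
  for (ct in names(cfg$cell_types)) {
    specs[[length(specs) + 1L]] <- list(
      label = paste0(ct, ":Ctrl-DMSO_vs_Ctrl-Bran"), ct = ct,
      cond1 = paste(ct, "Ctrl-DMSO", sep = ":"),
      cond2 = paste(ct, "Ctrl-Bran", sep = ":"), role = "drug")
    specs[[length(specs) + 1L]] <- list(
      label = paste0(ct, ":HD-DMSO_vs_HD-Bran"), ct = ct,
      cond1 = paste(ct, "HD-DMSO", sep = ":"),
      cond2 = paste(ct, "HD-Bran", sep = ":"), role = "drug")
    specs[[length(specs) + 1L]] <- list(
      label = paste0(ct, ":Ctrl-DMSO_vs_HD-DMSO"), ct = ct,
      cond1 = paste(ct, "Ctrl-DMSO", sep = ":"),
      cond2 = paste(ct, "HD-DMSO", sep = ":"), role = "hd")
  }
  specs
}

sim_build_table <- function(cfg, cat_df, counts, samples, spec, type) {
  sel <- which(cat_df$event_type == type)
  s1 <- samples[[spec$cond1]]; s2 <- samples[[spec$cond2]]
  ev <- data.frame(
    id = as.character(seq_along(sel)),
    gene_id = cat_df$gene_id[sel], gene_symbol = cat_df$gene_symbol[sel],
    chrom = cat_df$contig[sel], strand = cat_df$strand[sel],
    event_type = type, stringsAsFactors = FALSE)
  ev$coords <- cat_df$coords[sel]
  ev$ijc1 <- lapply(sel, function(i) unname(counts$ijc[i, s1]))
  ev$sjc1 <- lapply(sel, function(i) unname(counts$sjc[i, s1]))
  ev$ijc2 <- lapply(sel, function(i) unname(counts$ijc[i, s2]))
  ev$sjc2 <- lapply(sel, function(i) unname(counts$sjc[i, s2]))
  ev$inc_form_len <- cfg$inc_form_len
  ev$skip_form_len <- cfg$skip_form_len
  psi_of <- function(icol, scol) lapply(seq_along(sel), function(r)
    round(compute_psi(icol[[r]], scol[[r]], cfg$inc_form_len, cfg$skip_form_len), 3))
  ev$inc1 <- psi_of(ev$ijc1, ev$sjc1)
  ev$inc2 <- psi_of(ev$ijc2, ev$sjc2)
  ev$pvalue <- vapply(seq_along(sel), function(r)
    sim_pvalue(ev$inc1[[r]], ev$inc2[[r]]), 0)
  ev$fdr <- recompute_bh_fdr(ev$pvalue)
  ev$inc_level_difference <- round(
    vapply(seq_along(sel), function(r)
      mean(ev$inc1[[r]], na.rm = TRUE) - mean(ev$inc2[[r]], na.rm = TRUE), 0), 3)
  ev$inc_level_difference[is.nan(ev$inc_level_difference)] <- NA_real_
  ev$key <- cat_df$key[sel]
  ev
}

# force the adversarial boundary rows in one table (SE of the first cell
# type's disease comparison); IncLevels stay honest, the statistic columns
# are pinned at the filter thresholds
sim_force_boundaries <- function(ev, cat_df, cfg) {
  set_counts <- function(ev, r, i1, s1v, i2, s2v) {
    ev$ijc1[[r]] <- i1; ev$sjc1[[r]] <- s1v
    ev$ijc2[[r]] <- i2; ev$sjc2[[r]] <- s2v
    ev$inc1[[r]] <- round(compute_psi(i1, s1v, cfg$inc_form_len, cfg$skip_form_len), 3)
    ev$inc2[[r]] <- round(compute_psi(i2, s2v, cfg$inc_form_len, cfg$skip_form_len), 3)
    ev
  }
  n1 <- length(ev$ijc1[[1]]); n2 <- length(ev$ijc2[[1]])
  r <- match(cat_df$key[cat_df$class == "b_cov_pass"], ev$key)
  ev <- set_counts(ev, r, rep(5L, n1), rep(5L, n1), rep(5L, n2), rep(5L, n2))
  ev$pvalue[r] <- 0.001; ev$fdr[r] <- 0.01; ev$inc_level_difference[r] <- -0.5
  r <- match(cat_df$key[cat_df$class == "b_cov_fail"], ev$key)
  ev <- set_counts(ev, r, c(4L, rep(25L, n1 - 1L)), rep(5L, n1),
                   rep(25L, n2), rep(25L, n2))
  ev$pvalue[r] <- 0.001; ev$fdr[r] <- 0.001; ev$inc_level_difference[r] <- 0.6
  r <- match(cat_df$key[cat_df$class == "b_fdr"], ev$key)
  ev <- set_counts(ev, r, rep(25L, n1), rep(25L, n1), rep(25L, n2), rep(25L, n2))
  ev$pvalue[r] <- 0.05; ev$fdr[r] <- 0.05; ev$inc_level_difference[r] <- 0.5
  r <- match(cat_df$key[cat_df$class == "b_delta"], ev$key)
  ev <- set_counts(ev, r, rep(25L, n1), rep(25L, n1), rep(25L, n2), rep(25L, n2))
  ev$pvalue[r] <- 0.001; ev$fdr[r] <- 0.01; ev$inc_level_difference[r] <- 0.1
  ev
}

# direct-arithmetic truth for which table rows pass the filters (independent
# of the comparison_set code path)
sim_truth_filters <- function(tables, min_count = 10, fdr_max = 0.05,
                              min_abs_delta = 0.1) {
  all_ev <- do.call(rbind, tables)
  tot_ok <- vapply(seq_len(nrow(all_ev)), function(i)
    all(c(all_ev$ijc1[[i]] + all_ev$sjc1[[i]],
          all_ev$ijc2[[i]] + all_ev$sjc2[[i]]) >= min_count), TRUE)
  sig <- tot_ok & !is.na(all_ev$fdr) & !is.na(all_ev$inc_level_difference) &
    all_ev$fdr < fdr_max & abs(all_ev$inc_level_difference) > min_abs_delta
  list(coverage_pass = all_ev$key[tot_ok], significant = all_ev$key[sig])
}

# ---- genome, annotation, motifs -------------------------------------------

sim_genome <- function(cfg, cat_df) {
  genome <- vapply(unique(cat_df$contig), function(ctg) {
    len <- max(cat_df$origin[cat_df$contig == ctg]) + 1500L + 200L
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "", USE.NAMES = TRUE)

  planted <- data.frame(key = character(0), site = character(0),
                        planted = logical(0), stringsAsFactors = FALSE)
  drug_idx <- which(cat_df$class == "drug")
  flank <- cfg$flank
  for (i in drug_idx) {
    cc <- cat_df$coords[[i]]
    plus <- cat_df$strand[i] == "+"
    for (site in c("five_prime", "three_prime")) {
      motif <- if (site == "five_prime") cfg$motif_5ss else cfg$motif_3ss
      b <- if (site == "five_prime") { if (plus) cc[2] else cc[1] }
           else { if (plus) cc[1] else cc[2] }
      hit <- stats::runif(1) < cfg$motif_rate
      if (hit) {
        off <- (2L * flank - nchar(motif)) %/% 2L
        g0 <- if (plus) b - flank + off else b + flank - off - nchar(motif)
        ins <- if (plus) motif else revcomp(motif)
        substr(genome[[cat_df$contig[i]]], g0 + 1L, g0 + nchar(motif)) <- ins
      }
      planted <- rbind(planted, data.frame(key = cat_df$key[i], site = site,
                                           planted = hit, stringsAsFactors = FALSE))
    }
  }
  list(genome = genome, planted = planted)
}

sim_boundaries <- function(cat_df) {
  rows <- list()
  for (i in seq_len(nrow(cat_df))) {
    cc <- cat_df$coords[[i]]
    starts <- cc[seq(1, length(cc), 2)]
    ends <- cc[seq(2, length(cc), 2)]
    if (cat_df$novel_ss[i]) {           # target exon boundaries unannotated
      starts <- starts[-1]; ends <- ends[-1]
    }
    rows[[i]] <- data.frame(
      chrom = cat_df$contig[i],
      pos = c(starts, ends),
      side = c(rep("start", length(starts)), rep("end", length(ends))),
      strand = cat_df$strand[i], stringsAsFactors = FALSE)
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$chrom, out$pos, out$side), ]
}

# ---- eCLIP peaks ----------------------------------------------------------

sim_peaks <- function(cfg, cat_df, truth_sets, dir) {
  peak_dir <- file.path(dir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- event_span(cat_df)
  is_hd <- cat_df$key %in% truth_sets$hd_keys
  is_rescued <- cat_df$key %in% truth_sets$rescued_keys
  manifest <- data.frame(file = character(0), rbp_name = character(0),
                         cell_line = character(0), stringsAsFactors = FALSE)
  bound_by_rbp <- list()
  n_pass <- integer(0)
  first_rbp <- TRUE
  for (rbp in names(cfg$rbp_models)) {
    mdl <- cfg$rbp_models[[rbp]]
    p <- rep(mdl$rate_bg, nrow(cat_df))
    if (!is.null(mdl$rate_hd)) p[is_hd] <- mdl$rate_hd
    if (!is.null(mdl$rate_rescued)) p[is_hd & is_rescued] <- mdl$rate_rescued
    if (!is.null(mdl$rate_unrescued)) p[is_hd & !is_rescued] <- mdl$rate_unrescued
    bound <- stats::runif(nrow(cat_df)) < p
    rows <- list()
    for (i in which(bound)) {
      n_pk <- 1L + stats::rbinom(1, 1, 0.3)
      for (j in seq_len(n_pk)) {
        w <- sample(30:80, 1)
        st <- sample(sp$start[i]:(sp$end[i] - w), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cat_df$contig[i], start = st, end = st + w,
          name = rbp, strand = cat_df$strand[i],
          log2_fold_change = round(stats::runif(1, 3, 8), 3),
          neg_log10_p = round(stats::runif(1, 3, 10), 3),
          rbp_name = rbp, cell_line = "synthCell", stringsAsFactors = FALSE)
      }
    }
    # sub-threshold decoys at random events (must not survive the filter)
    n_decoy <- max(1L, ceiling(0.25 * sum(bound)))
    for (i in sample(seq_len(nrow(cat_df)), n_decoy, replace = TRUE)) {
      w <- sample(30:80, 1)
      st <- sample(sp$start[i]:(sp$end[i] - w), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cat_df$contig[i], start = st, end = st + w,
        name = rbp, strand = cat_df$strand[i],
        log2_fold_change = round(stats::runif(1, 0.5, 2.9), 2),
        neg_log10_p = round(stats::runif(1, 0.5, 2.9), 2),
        rbp_name = rbp, cell_line = "synthCell", stringsAsFactors = FALSE)
    }
    if (cfg$boundary_cases && first_rbp) {
      i <- which(bound)[1]
      if (!is.na(i)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cat_df$contig[i], start = sp$start[i] + 5L,
          end = sp$start[i] + 55L, name = rbp, strand = cat_df$strand[i],
          log2_fold_change = 3, neg_log10_p = 3,
          rbp_name = rbp, cell_line = "synthCell", stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cat_df$contig[i], start = sp$start[i] + 60L,
          end = sp$start[i] + 110L, name = rbp, strand = cat_df$strand[i],
          log2_fold_change = 10, neg_log10_p = 2.99,
          rbp_name = rbp, cell_line = "synthCell", stringsAsFactors = FALSE)
      }
      first_rbp <- FALSE
    }
    pk <- do.call(rbind, rows)
    pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
    f <- file.path(peak_dir, paste0(rbp, ".bed"))
    write_peaks(pk, f)
    manifest <- rbind(manifest, data.frame(
      file = paste0(rbp, ".bed"), rbp_name = rbp,
      cell_line = "synthCell", stringsAsFactors = FALSE))
    bound_by_rbp[[rbp]] <- cat_df$key[bound]
    n_pass[rbp] <- sum(pk$neg_log10_p >= 3 & pk$log2_fold_change >= 3)
  }
  manifest_path <- file.path(dir, "peaks", "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(manifest = manifest_path, bound_by_rbp = bound_by_rbp, n_pass = n_pass)
}

# ---- gene expression ------------------------------------------------------

sim_expression <- function(cfg, cat_df, samples, dir) {
  drug_genes <- cat_df$gene_id[cat_df$class == "drug"]
  bg_pool <- cat_df$gene_id[startsWith(cat_df$class, "bg_")]
  bg_genes <- utils::head(bg_pool, cfg$n_expr_background)
  genes <- c(drug_genes, bg_genes)
  up <- utils::head(drug_genes, cfg$n_expr_up)
  down <- utils::head(setdiff(drug_genes, up), cfg$n_expr_down)
  comparisons <- as.vector(outer(c("Ctrl", "HD"), names(cfg$cell_types),
                                 function(g, ct) paste(ct, g, sep = ":")))
  # planted per-comparison log2 effects: consistent for up/down genes,
  # deliberately sign-mixed for all others so the consistency truth is
  # well-defined under counting noise
  eff <- matrix(0, length(genes), length(comparisons),
                dimnames = list(genes, comparisons))
  eff[up, ] <- cfg$expr_log2fc
  eff[down, ] <- -cfg$expr_log2fc
  others <- setdiff(genes, c(up, down))
  for (g in others) {
    repeat {
      e <- stats::runif(length(comparisons), 0.3, 0.6) *
        sample(c(-1, 1), length(comparisons), replace = TRUE)
      if (length(unique(sign(e))) > 1L) break
    }
    eff[g, ] <- e
  }
  base_rpkm <- exp(stats::rnorm(length(genes), log(20), 0.4))
  len <- rep(2000L, length(genes))
  all_samples <- unlist(samples, use.names = FALSE)
  lib <- round(stats::runif(length(all_samples), 2e7, 4e7))
  names(lib) <- all_samples
  counts <- data.frame(gene_id = genes, length_bp = len, stringsAsFactors = FALSE)
  for (grp in names(samples)) {
    parts <- strsplit(grp, ":")[[1]]
    ct <- parts[1]; cond <- parts[2]
    geno <- sub("-.*$", "", cond)
    is_drug_cond <- grepl("Bran$", cond)
    cmp <- paste(ct, geno, sep = ":")
    fc <- if (is_drug_cond) 2^eff[, cmp] else rep(1, length(genes))
    for (s in samples[[grp]]) {
      mu <- base_rpkm * fc * len * lib[[s]] / 1e9
      counts[[s]] <- stats::rpois(length(genes), mu)
    }
  }
  path <- file.path(dir, "gene_counts.tsv")
  write_gene_counts(counts, path)
  list(path = path, up_genes = up, down_genes = down,
       comparisons = comparisons,
       sample_groups = samples)
}

# ---- main entry points ----------------------------------------------------

#' Generate a complete synthetic splicing-modulator dataset
#'
#' Writes, under `dir`: one rMATS-dialect table per AS type for each of the
#' six comparisons (per cell type: Ctrl DMSO-vs-drug, HD DMSO-vs-drug, and
#' Ctrl-vs-HD under DMSO), a genome FASTA with drug splice-site motifs
#' planted at the drug-induced novelSS exons, the annotation exon-boundary
#' list (excluding those exons), per-RBP eCLIP peak files with a manifest, a
#' gene-count table, and `truth.json`. The same seed yields byte-identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return the truth bundle (invisibly written as `truth.json`): a list with
#'   the event catalogue, true group PSI matrix, planted key sets
#'   (`hd_keys`, `drug_keys`, `rescued_keys`), per-comparison truth
#'   (coverage-passing and significant keys), planted motif/RBP/expression
#'   structure and all file paths.
#' @export
generate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  cat_df <- sim_catalog(cfg)
  truth_psi <- sim_true_psi(cfg, cat_df)
  samples <- sim_samples(cfg)
  specs <- sim_comparisons_spec(cfg)

  # planted not-detected cells: drug-induced events, one drug comparison each
  drug_specs <- Filter(function(s) s$role == "drug", specs)
  low_cov <- data.frame(key = character(0), condition = character(0),
                        label = character(0), stringsAsFactors = FALSE)
  drug_keys <- truth_psi$drug_keys
  n_mask <- min(cfg$n_masked, length(drug_keys))
  if (n_mask > 0) {
    pick <- sample(drug_keys, n_mask)
    for (i in seq_len(n_mask)) {
      sp <- drug_specs[[((i - 1L) %% length(drug_specs)) + 1L]]
      low_cov <- rbind(low_cov, data.frame(key = pick[i], condition = sp$cond2,
                                           label = sp$label,
                                           stringsAsFactors = FALSE))
    }
  }

  counts <- sim_counts(cfg, cat_df, truth_psi$psi, samples, low_cov)

  comp_dirs <- character(0)
  comp_truth <- list()
  for (sp in specs) {
    safe <- gsub("[:]", "__", sp$label)
    cdir <- file.path(dir, "comparisons", safe)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    tables <- list()
    for (type in AS_TYPES) {
      if (!any(cat_df$event_type == type)) next
      ev <- sim_build_table(cfg, cat_df, counts, samples, sp, type)
      if (cfg$boundary_cases && type == "SE" && sp$role == "hd" &&
          sp$ct == names(cfg$cell_types)[1])
        ev <- sim_force_boundaries(ev, cat_df, cfg)
      write_rmats_table(ev, file.path(cdir, paste0(type, ".MATS.JC.txt")))
      tables[[type]] <- ev
    }
    filt <- sim_truth_filters(tables)
    comp_truth[[sp$label]] <- list(label = sp$label, cell_type = sp$ct,
                                   role = sp$role, dir = cdir,
                                   group1 = sp$cond1, group2 = sp$cond2,
                                   coverage_pass = filt$coverage_pass,
                                   significant = filt$significant)
    comp_dirs[sp$label] <- cdir
  }

  gen <- sim_genome(cfg, cat_df)
  genome_path <- file.path(dir, "genome.fa")
  write_fasta(gen$genome, genome_path)
  boundaries <- sim_boundaries(cat_df)
  boundaries_path <- file.path(dir, "annotation_boundaries.tsv")
  write_annotation_boundaries(boundaries, boundaries_path)

  peaks <- sim_peaks(cfg, cat_df, truth_psi, dir)
  expr <- sim_expression(cfg, cat_df, samples, dir)

  truth <- list(
    seed = cfg$seed,
    events = cat_df[, c("key", "class", "event_type", "cluster", "strand",
                        "novel_ss", "gene_id", "contig")],
    true_psi = truth_psi$psi,
    hd_keys = truth_psi$hd_keys,
    drug_keys = truth_psi$drug_keys,
    rescued_keys = truth_psi$rescued_keys,
    low_coverage = low_cov,
    comparisons = comp_truth,
    samples = samples,
    motifs = list(five_prime = cfg$motif_5ss, three_prime = cfg$motif_3ss,
                  planted = gen$planted),
    rbp = list(bound_by_rbp = peaks$bound_by_rbp, n_pass = peaks$n_pass),
    expression = list(up_genes = expr$up_genes, down_genes = expr$down_genes,
                      comparisons = expr$comparisons),
    files = list(dir = dir, genome = genome_path,
                 boundaries = boundaries_path,
                 peak_manifest = peaks$manifest,
                 gene_counts = expr$path,
                 comparison_dirs = as.list(comp_dirs))
  )
  json <- truth
  json$true_psi <- data.frame(key = rownames(truth_psi$psi), truth_psi$psi,
                              check.names = FALSE)
  # paths inside the JSON are relative to `dir` so reruns are byte-identical
  relativize <- function(p) {
    pre <- paste0(normalizePath(dir, mustWork = FALSE), "/")
    p <- vapply(p, function(x) {
      xn <- normalizePath(x, mustWork = FALSE)
      if (startsWith(xn, pre)) substring(xn, nchar(pre) + 1L) else x
    }, "", USE.NAMES = FALSE)
    p
  }
  json$files <- lapply(json$files, function(x)
    if (is.list(x)) lapply(x, relativize) else relativize(x))
  json$files$dir <- "."
  for (nm in names(json$comparisons))
    json$comparisons[[nm]]$dir <- relativize(json$comparisons[[nm]]$dir)
  jsonlite::write_json(json, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  truth$files$truth_json <- file.path(dir, "truth.json")
  truth
}

#' Generate the small unit-test fixture
#'
#' A compact bundle (about 40 events on two contigs, one event of every AS
#' type, at least one planted masked cell, and the adversarial
#' filter-boundary rows) that generates in a few seconds.
#'
#' @param dir output directory (default: fresh temporary directory).
#' @param seed RNG seed.
#' @return the truth bundle from [generate_dataset()].
#' @export
small_fixture <- function(dir = tempfile("spliceRescue_fixture_"), seed = 7L) {
  cfg <- sim_config(
    seed = seed,
    cell_types = list(fibroblast = list(n_rep = 3L), neuron = list(n_rep = 3L)),
    n_background = c(SE = 8L, A3SS = 2L, A5SS = 2L, MXE = 2L, RI = 2L),
    n_hd = 8L, n_drug_clusters = c(4L, 4L), drug_cluster_delta = c(0.65, 0.35),
    rescue_fraction = 0.5, n_masked = 1L,
    hd_delta_range = c(0.25, 0.6), psi_sd = 0.03,
    n_expr_background = 16L, boundary_cases = TRUE)
  generate_dataset(cfg, dir)
}
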