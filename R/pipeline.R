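# End-to-end orchestration: filter -> significance -> clustering -> motif ->
# RBP -> rescue -> expression, with tab-separated per-stage outputs and a
# machine-readable summary.

#' Assemble a pipeline configuration
#'
#' @param comparisons named list (name = comparison label); each element a
#'   list with `dir` (directory holding `<TYPE>.MATS.JC.txt` tables), `role`
#'   (`"drug"` for vehicle-vs-drug, `"hd"` for control-vs-disease),
#'   `cell_type`, and optional `group1`/`group2` names.
#' @param genome path to the genome FASTA.
#' @param boundaries path to the annotation exon-boundary list.
#' @param peak_manifest path to the eCLIP peak manifest.
#' @param gene_counts path to the gene-count table.
#' @param expression_comparisons named list; each element a list with sample
#'   name vectors `drug` and `vehicle`.
#' @param coverage_min,fdr_max,delta_min,rescue_threshold,rescue_min_reads,
#'   peak_min_p,peak_min_lfc filtering thresholds (defaults 10, 0.05, 0.1,
#'   0.1, 10, 3, 3).
#' @param k,kmeans_seed,n_init,max_iter k-means hyperparameters (defaults
#'   10, 42, 10, 300).
#' @param flank,k_sizes motif window configuration (defaults 5 and 4/6/8).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(comparisons, genome = NULL, boundaries = NULL,
                            peak_manifest = NULL, gene_counts = NULL,
                            expression_comparisons = NULL,
                            coverage_min = 10, fdr_max = 0.05, delta_min = 0.1,
                            rescue_threshold = 0.1, rescue_min_reads = 10,
                            peak_min_p = 3, peak_min_lfc = 3,
                            k = 10, kmeans_seed = 42, n_init = 10,
                            max_iter = 300, flank = 5, k_sizes = c(4, 6, 8)) {
  stopifnot(is.list(comparisons), length(comparisons) >= 1L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Paths in the file are resolved relative to the file's directory. Keys
#' mirror the arguments of [pipeline_config()].
#'
#' @param path YAML config path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  fix <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  for (nm in names(raw$comparisons))
    raw$comparisons[[nm]]$dir <- fix(raw$comparisons[[nm]]$dir)
  for (nm in c("genome", "boundaries", "peak_manifest", "gene_counts"))
    raw[[nm]] <- fix(raw[[nm]])
  do.call(pipeline_config, raw)
}

#' Build a pipeline configuration from a synthetic truth bundle
#'
#' Convenience constructor pointing a [pipeline_config()] at the files
#' written by [generate_dataset()].
#'
#' @param truth the truth bundle returned by [generate_dataset()].
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_truth <- function(truth, ...) {
  comparisons <- lapply(truth$comparisons, function(ct)
    list(dir = ct$dir, role = ct$role, cell_type = ct$cell_type,
         group1 = ct$group1, group2 = ct$group2))
  expr_cmp <- list()
  for (cmp in truth$expression$comparisons) {
    parts <- strsplit(cmp, ":")[[1]]
    ct <- parts[1]; geno <- parts[2]
    expr_cmp[[cmp]] <- list(
      drug = truth$samples[[paste(ct, paste0(geno, "-Bran"), sep = ":")]],
      vehicle = truth$samples[[paste(ct, paste0(geno, "-DMSO"), sep = ":")]])
  }
  pipeline_config(comparisons = comparisons,
                  genome = truth$files$genome,
                  boundaries = truth$files$boundaries,
                  peak_manifest = truth$files$peak_manifest,
                  gene_counts = truth$files$gene_counts,
                  expression_comparisons = expr_cmp, ...)
}

#' Read all per-type rMATS tables of one comparison directory
#'
#' Looks for `<TYPE>.MATS.JC.txt` files for every AS type and bundles those
#' found into a [comparison_set()].
#'
#' @param dir directory containing the tables.
#' @param label comparison label.
#' @param group1,group2 sample-group names.
#' @return a [comparison_set()].
#' @export
read_comparison_dir <- function(dir, label, group1 = "group1", group2 = "group2") {
  tables <- list()
  for (type in AS_TYPES) {
    f <- file.path(dir, paste0(type, ".MATS.JC.txt"))
    if (file.exists(f)) tables[[type]] <- read_rmats_table(f, type)
  }
  if (length(tables) == 0L)
    stop_fmt("no rMATS tables found under '%s'", dir)
  comparison_set(tables, label, group1 %||% "group1", group2 %||% "group2")
}

#' Run the full downstream splicing pipeline
#'
#' Executes coverage filtering, significance calling, delta-PSI matrix
#' construction and clustering over the drug comparisons, splice-site k-mer
#' enrichment for the coherent drug-responsive inclusion clusters, RBP peak
#' enrichment for the disease comparisons, rescue quantification per cell
#' type, and expression ratios; writes per-stage tables plus `summary.json`
#' under `out_dir`. Reruns on identical inputs reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the summary (a nested list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  boundaries <- if (!is.null(config$boundaries))
    read_annotation_boundaries(config$boundaries) else NULL

  # stage 1-2: read, annotate, coverage-filter, significance-call
  covered <- list(); significant <- list()
  for (nm in names(config$comparisons)) {
    cc <- config$comparisons[[nm]]
    cs <- read_comparison_dir(cc$dir, nm, cc$group1, cc$group2)
    if (!is.null(boundaries)) cs <- annotate_novel_ss(cs, boundaries)
    cs <- coverage_filter(cs, config$coverage_min)
    covered[[nm]] <- cs
    sig <- suppressWarnings(significant_events(cs, config$fdr_max, config$delta_min))
    significant[[nm]] <- sig
    write_significant_events(sig, file.path(out_dir, paste0(
      "significant_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")))
  }
  roles <- vapply(config$comparisons, function(x) x$role, "")
  cell_types <- vapply(config$comparisons, function(x) x$cell_type %||% NA_character_, "")

  # stage 3: delta-PSI matrix + clustering over the drug comparisons
  drug_nms <- names(config$comparisons)[roles == "drug"]
  m <- build_delta_psi_matrix(covered[drug_nms], config$fdr_max, config$delta_min)
  k_use <- min(config$k, nrow(m$values))
  clustering_ok <- k_use >= 2
  ca <- NULL; cl_sum <- list()
  if (clustering_ok) {
    ca <- cluster_events(m, k = k_use, seed = config$kmeans_seed,
                         n_init = config$n_init, max_iter = config$max_iter)
    write_delta_psi_matrix(m, ca, file.path(out_dir, "delta_psi_matrix.tsv"))
    cl_sum <- lapply(0:(ca$k - 1L), function(cid) cluster_summary(m, ca, cid))
  }

  # stage 4: splice-site k-mer enrichment for coherent inclusion clusters
  coherent_keys <- unlist(lapply(cl_sum, function(s)
    if (isTRUE(s$coherent) && identical(s$direction, "included")) s$keys))
  kmer_rec <- NULL
  if (!is.null(config$genome) && length(coherent_keys)) {
    genome <- read_fasta(config$genome)
    pool <- do.call(rbind, lapply(covered[drug_nms], function(cs) cs$events))
    fg_events <- pool[!duplicated(pool$key) & pool$key %in% coherent_keys, ,
                      drop = FALSE]
    kmer_rec <- splice_site_kmer_enrichment(
      fg_events, genome,
      motif_window_config(config$flank, config$k_sizes))
    if (!is.null(kmer_rec))
      write_kmer_enrichment(kmer_rec, file.path(out_dir, "kmer_enrichment.tsv"))
  }

  # stage 5: RBP enrichment per disease comparison
  rbp_res <- list()
  if (!is.null(config$peak_manifest)) {
    manifest <- read_peak_manifest(config$peak_manifest)
    peaks <- filter_peaks(read_manifest_peaks(manifest),
                          config$peak_min_p, config$peak_min_lfc)
    for (nm in names(config$comparisons)[roles == "hd"]) {
      bg_ev <- covered[[nm]]$events
      regions <- event_regions(bg_ev)
      bound_by_rbp <- lapply(split(peaks, peaks$rbp_name), function(pk)
        events_bound(regions, pk))
      rbp_res[[nm]] <- rbp_enrichment(significant[[nm]]$events$key,
                                      bg_ev$key, bound_by_rbp)
      write_rbp_enrichment(rbp_res[[nm]], file.path(out_dir, paste0(
        "rbp_enrichment_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")))
    }
  }

  # stage 6: rescue per cell type (needs one hd + one HD drug comparison)
  rescue_res <- list()
  for (ct in unique(cell_types[roles == "hd"])) {
    hd_nm <- names(config$comparisons)[roles == "hd" & cell_types == ct][1]
    drug_ct <- names(config$comparisons)[roles == "drug" & cell_types == ct]
    drug_nm <- drug_ct[grepl("HD", drug_ct)][1]
    if (is.na(drug_nm)) next
    rec <- rescue_records(significant[[hd_nm]], covered[[drug_nm]],
                          rescue_threshold = config$rescue_threshold,
                          min_reads = config$rescue_min_reads)
    write_rescue_records(rec, file.path(out_dir, paste0(
      "rescue_", gsub("[^A-Za-z0-9._-]", "_", ct), ".tsv")))
    rescue_res[[ct]] <- list(records = rec,
                             summary = if (nrow(rec)) rescue_summary(rec))
  }

  # stage 7: expression
  expr_res <- NULL
  if (!is.null(config$gene_counts) && length(config$expression_comparisons)) {
    gc_tab <- read_gene_counts(config$gene_counts)
    rk <- rpkm(gc_tab)
    ratios <- log2_expression_ratios(rk, config$expression_comparisons)
    consistent <- suppressWarnings(consistent_direction_genes(ratios))
    utils::write.table(ratios, file.path(out_dir, "expression_log2_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    expr_res <- list(ratios = ratios, consistent = consistent)
  }

  summary <- list(
    n_significant = lapply(significant, function(cs) nrow(cs$events)),
    n_covered = lapply(covered, function(cs) nrow(cs$events)),
    matrix = list(n_events = nrow(m$values), n_masked_cells = sum(m$mask)),
    clusters = lapply(cl_sum, function(s) list(
      cluster = s$cluster_id, n = s$n_events,
      novel_ss_fraction = s$novel_ss_fraction,
      coherent = s$coherent, direction = s$direction)),
    top_kmers = if (!is.null(kmer_rec)) {
      top <- kmer_rec[kmer_rec$k == max(kmer_rec$k), ]
      lapply(split(top, top$site), function(d) utils::head(d$kmer, 3))
    },
    top_rbps = lapply(rbp_res, function(d) utils::head(d$rbp_name, 3)),
    rescue = lapply(rescue_res, function(r) {
      s <- r$summary
      if (is.null(s)) NULL else s[c("n_events", "mean_abs_diff_dmso",
                                    "mean_abs_diff_drug", "percent_reduction",
                                    "rescued_fraction", "ranksum_p")]
    }),
    consistent_expression = if (!is.null(expr_res)) expr_res$consistent
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(summary = summary, covered = covered,
                 significant = significant, matrix = m, clusters = ca,
                 cluster_summaries = cl_sum, kmer = kmer_rec, rbp = rbp_res,
                 rescue = rescue_res, expression = expr_res))
}
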