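# Delta-PSI matrix construction, masking, and k-means response clusters.

# build a bare delta_psi_matrix for direct clustering tests
toy_matrix <- function(values, mask = is.na(values), novel = NULL) {
  keys <- sprintf("k%03d", seq_len(nrow(values)))
  rownames(values) <- keys
  colnames(values) <- paste0("cmp", seq_len(ncol(values)))
  values[mask] <- NA_real_
  structure(list(values = values, mask = mask,
                 annotations = data.frame(
                   key = keys, event_type = "SE",
                   novel_ss = novel %||% rep(FALSE, nrow(values)),
                   stringsAsFactors = FALSE),
                 comparison_labels = colnames(values)),
            class = "delta_psi_matrix")
}

test_that("matrix rows are the union of significant events with coverage masking", {
  tr <- fx()
  drug_nms <- names(tr$comparisons)[vapply(tr$comparisons, function(x)
    x$role == "drug", TRUE)]
  covered <- lapply(drug_nms, function(nm)
    coverage_filter(read_bundle_comparison(tr, nm)))
  m <- build_delta_psi_matrix(covered)
  union_sig <- unique(unlist(lapply(drug_nms, function(nm)
    tr$comparisons[[nm]]$significant)))
  expect_setequal(rownames(m$values), union_sig)
  # cells masked exactly where coverage failed
  for (j in seq_along(drug_nms)) {
    cov_keys <- tr$comparisons[[drug_nms[j]]]$coverage_pass
    expect_equal(unname(m$mask[, j]), !(rownames(m$values) %in% cov_keys))
  }
  expect_gte(sum(m$mask), 1L)             # the planted undetected cell
  expect_true(all(rowSums(!m$mask) >= 1))
  # detection without significance still yields an unmasked cell
  detected_not_sig <- vapply(seq_along(drug_nms), function(j) {
    ct <- tr$comparisons[[drug_nms[j]]]
    any(!m$mask[, j] &
          !(rownames(m$values) %in% ct$significant))
  }, TRUE)
  expect_true(any(detected_not_sig))
})

test_that("two well-separated response blobs are recovered exactly at k = 2", {
  set.seed(1)
  v <- rbind(matrix(rnorm(40 * 4, -0.6, 0.03), ncol = 4),
             matrix(rnorm(40 * 4, 0.5, 0.03), ncol = 4))
  m <- toy_matrix(v)
  ca <- cluster_events(m, k = 2, seed = 42)
  expect_equal(ari(ca$labels, rep(1:2, each = 40)), 1)
  # determinism under the recorded seed
  ca2 <- cluster_events(m, k = 2, seed = 42)
  expect_identical(ca$labels, ca2$labels)
  expect_equal(sum(table(ca$labels)), nrow(v))
  expect_error(cluster_events(m, k = 1), "at least 2")
  expect_error(cluster_events(m, k = 500), "smaller k")
})

test_that("imputation never alters unmasked cells", {
  set.seed(2)
  v <- matrix(rnorm(20 * 4, 0, 0.3), ncol = 4)
  mask <- matrix(FALSE, 20, 4); mask[1, 2] <- TRUE; mask[5, 4] <- TRUE
  m <- toy_matrix(v, mask)
  before <- m$values
  invisible(cluster_events(m, k = 2, seed = 42, imputation_value = 7))
  expect_identical(m$values[!m$mask], before[!m$mask])
  expect_true(all(is.na(m$values[m$mask])))
})

test_that("cluster summaries report size, novelty fraction and coherence", {
  v <- rbind(matrix(-0.4, 5, 4),
             matrix(rep(c(0.4, -0.4, 0.4, -0.4), times = 5), ncol = 4,
                    byrow = TRUE))
  novel <- c(rep(TRUE, 3), rep(FALSE, 7))
  m <- toy_matrix(v, novel = novel)
  ca <- cluster_events(m, k = 2, seed = 42)
  cid <- ca$labels[["k001"]]
  s <- cluster_summary(m, ca, cid)
  expect_equal(s$n_events, 5L)
  expect_equal(s$novel_ss_fraction, 0.6)
  expect_true(s$coherent)
  expect_equal(s$direction, "included")
  s2 <- cluster_summary(m, ca, 1L - cid)
  expect_false(s2$coherent)
  expect_error(cluster_summary(m, ca, 99), "unknown cluster")
})

test_that("planted coherent inclusion clusters are flagged on the fixture", {
  tr <- fx()
  drug_nms <- names(tr$comparisons)[vapply(tr$comparisons, function(x)
    x$role == "drug", TRUE)]
  bd <- read_annotation_boundaries(tr$files$boundaries)
  covered <- lapply(drug_nms, function(nm)
    coverage_filter(annotate_novel_ss(read_bundle_comparison(tr, nm), bd)))
  m <- build_delta_psi_matrix(covered)
  ca <- cluster_events(m, k = 4, seed = 42)
  sums <- lapply(0:3, function(c) cluster_summary(m, ca, c))
  coherent_inc <- Filter(function(s) s$coherent && identical(s$direction, "included"),
                         sums)
  keys <- unlist(lapply(coherent_inc, `[[`, "keys"))
  # fully observed drug-induced events all sit in coherent inclusion clusters
  full <- rownames(m$values)[rowSums(m$mask) == 0]
  expect_true(all(intersect(tr$drug_keys, full) %in% keys))
  novel_frac <- vapply(coherent_inc, `[[`, 0, "novel_ss_fraction")
  expect_true(all(novel_frac > 0.5))
})
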