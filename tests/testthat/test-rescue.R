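# Rescue of disease-associated splicing under drug treatment.

# comparison set with explicit per-sample inclusion levels and uniform counts
make_quant_cs <- function(keys, psi1, psi2, totals = 25L, fdr = 0.01,
                          label = "toy") {
  n <- length(keys)
  ev <- data.frame(id = as.character(seq_len(n)), gene_id = keys,
                   gene_symbol = keys, chrom = "c1", strand = "+",
                   event_type = "SE", stringsAsFactors = FALSE)
  ev$coords <- lapply(seq_len(n), function(i)
    as.integer(c(1000 * i, 1000 * i + 100, 1000 * i - 300, 1000 * i - 150,
                 1000 * i + 250, 1000 * i + 400)))
  ev$ijc1 <- lapply(psi1, function(p) rep(as.integer(totals / 2), length(p)))
  ev$sjc1 <- lapply(psi1, function(p) rep(totals - as.integer(totals / 2), length(p)))
  ev$ijc2 <- lapply(psi2, function(p) rep(as.integer(totals / 2), length(p)))
  ev$sjc2 <- lapply(psi2, function(p) rep(totals - as.integer(totals / 2), length(p)))
  ev$inc_form_len <- 200L; ev$skip_form_len <- 100L
  ev$pvalue <- fdr; ev$fdr <- fdr
  ev$inc1 <- psi1; ev$inc2 <- psi2
  ev$inc_level_difference <- vapply(seq_len(n), function(i)
    mean(psi1[[i]]) - mean(psi2[[i]]), 0)
  ev$key <- keys
  comparison_set(ev, label)
}

test_that("rescue arithmetic and the strict corridor threshold", {
  hd <- significant_events(make_quant_cs(
    c("a", "b", "c"),
    psi1 = list(rep(0.8, 3), rep(0.6, 3), rep(0.7, 3)),      # Ctrl-DMSO
    psi2 = list(rep(0.5, 3), rep(0.2, 3), rep(0.3, 3))))     # HD-DMSO
  drug <- make_quant_cs(
    c("a", "b", "c"),
    psi1 = list(rep(0.5, 3), rep(0.2, 3), rep(0.3, 3)),      # HD-DMSO
    psi2 = list(rep(0.75, 3), rep(0.5, 3), rep(0.7, 3)))     # HD-drug
  rec <- rescue_records(hd, drug)
  expect_equal(rec$abs_diff_dmso, c(0.3, 0.4, 0.4))
  expect_equal(rec$abs_diff_drug, c(0.05, 0.1, 0.0))
  expect_equal(rec$rescued, c(TRUE, FALSE, TRUE))  # exactly 0.10 is NOT rescued
  expect_equal(rec$direction_in_hd, rep("excluded", 3))
})

test_that("events failing the strict >10 detection rule are excluded", {
  hd <- significant_events(make_quant_cs(
    c("a", "b"), psi1 = list(rep(0.8, 3), rep(0.8, 3)),
    psi2 = list(rep(0.4, 3), rep(0.4, 3)), totals = 25L))
  # drug comparison covers "a" with exactly 10 reads per sample (not > 10)
  drug <- make_quant_cs(c("a", "b"),
                        psi1 = list(rep(0.4, 3), rep(0.4, 3)),
                        psi2 = list(rep(0.8, 3), rep(0.8, 3)), totals = 25L)
  drug$events$ijc2[[1]] <- rep(5L, 3); drug$events$sjc2[[1]] <- rep(5L, 3)
  rec <- rescue_records(hd, drug)
  expect_equal(rec$key, "b")
  expect_equal(attr(rec, "n_excluded"), 1L)
})

test_that("rescue summary reports reduction, fraction and rank-sum shift", {
  hd <- significant_events(make_quant_cs(
    c("a", "b", "c"),
    psi1 = list(rep(0.9, 3), rep(0.8, 3), rep(0.7, 3)),
    psi2 = list(rep(0.4, 3), rep(0.5, 3), rep(0.3, 3))))
  drug_psi <- list(rep(0.9 - 0.35, 3), rep(0.8 - 0.25, 3), rep(0.7 - 0.3, 3))
  drug <- make_quant_cs(c("a", "b", "c"),
                        psi1 = list(rep(0.4, 3), rep(0.5, 3), rep(0.3, 3)),
                        psi2 = drug_psi)
  s <- rescue_summary(rescue_records(hd, drug))
  expect_equal(s$mean_abs_diff_dmso, 0.4)
  expect_equal(s$mean_abs_diff_drug, 0.3)
  expect_equal(s$percent_reduction, 25)
  expect_equal(s$rescued_fraction, 0)
  expect_equal(sum(s$partition), s$n_events)
  # order invariance
  rec <- rescue_records(hd, drug)
  expect_equal(rescue_summary(rec[3:1, ])$percent_reduction, 25)
  # no change -> no shift
  same <- make_quant_cs(c("a", "b", "c"),
                        psi1 = list(rep(0.4, 3), rep(0.5, 3), rep(0.3, 3)),
                        psi2 = list(rep(0.4, 3), rep(0.5, 3), rep(0.3, 3)))
  s0 <- rescue_summary(rescue_records(hd, same))
  expect_equal(s0$percent_reduction, 0)
  expect_gt(s0$ranksum_p, 0.5)
})

test_that("moving PSI toward control never un-rescues an event", {
  set.seed(9)
  psi_ctrl <- runif(30, 0.2, 0.8)
  psi_hd <- clamp_ <- pmin(pmax(psi_ctrl + sample(c(-1, 1), 30, TRUE) * 0.3, 0), 1)
  hd <- significant_events(make_quant_cs(
    sprintf("e%02d", 1:30),
    psi1 = lapply(psi_ctrl, rep, 3), psi2 = lapply(psi_hd, rep, 3)))
  step1 <- psi_hd + 0.4 * (psi_ctrl - psi_hd)
  step2 <- psi_hd + 0.8 * (psi_ctrl - psi_hd)   # strictly closer to control
  d1 <- make_quant_cs(sprintf("e%02d", 1:30),
                      psi1 = lapply(psi_hd, rep, 3), psi2 = lapply(step1, rep, 3))
  d2 <- make_quant_cs(sprintf("e%02d", 1:30),
                      psi1 = lapply(psi_hd, rep, 3), psi2 = lapply(step2, rep, 3))
  r1 <- rescue_records(hd, d1); r2 <- rescue_records(hd, d2)
  expect_true(all(r2$rescued[r1$rescued]))
})

test_that("planted rescue status is recovered for the fixture's disease events", {
  tr <- fx()
  hd_sig <- suppressWarnings(significant_events(coverage_filter(
    read_bundle_comparison(tr, "fibroblast:Ctrl-DMSO_vs_HD-DMSO"))))
  drug_cs <- coverage_filter(
    read_bundle_comparison(tr, "fibroblast:HD-DMSO_vs_HD-Bran"))
  rec <- rescue_records(hd_sig, drug_cs)
  planted <- rec[rec$key %in% tr$hd_keys, ]
  expect_gt(nrow(planted), 0)
  expect_equal(planted$rescued, planted$key %in% tr$rescued_keys)
})

test_that("overlap report distinguishes disjoint, identical and planted sets", {
  expect_equal(drug_targets_disease_events(c("a", "b"), c("c"))$jaccard, 0)
  expect_equal(drug_targets_disease_events(c("a", "b"), c("b", "a"))$jaccard, 1)
  set.seed(10)
  hd <- sprintf("h%03d", 1:100)
  drug <- c(sample(hd, 5), sprintf("d%03d", 1:95))
  rep_ <- drug_targets_disease_events(hd, drug)
  expect_equal(rep_$n_shared, 5L)
  expect_equal(rep_$jaccard, 5 / 195)
  # in the synthetic bundle the drug does not target the disease events
  tr <- fx()
  expect_equal(drug_targets_disease_events(tr$hd_keys, tr$drug_keys)$n_shared, 0L)
})
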