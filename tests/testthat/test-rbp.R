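# Peak filtering, event-region intersection, hypergeometric enrichment and
# the rescued-vs-unrescued Fisher comparison.

toy_peaks <- function(chrom, start, end, lfc = 5, nlp = 5, strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, name = "X",
             strand = strand, log2_fold_change = lfc, neg_log10_p = nlp,
             rbp_name = "X", cell_line = "cl", stringsAsFactors = FALSE)
}

test_that("peak significance thresholds are inclusive", {
  pk <- toy_peaks("c1", c(0, 10, 20), c(5, 15, 25),
                  lfc = c(3, 10, 2.99), nlp = c(3, 2.99, 10))
  kept <- filter_peaks(pk)
  expect_equal(kept$start, 0)          # (3.0, 3.0) retained, both others fail
  tr <- fx()
  manifest <- read_peak_manifest(tr$files$peak_manifest)
  for (i in seq_len(nrow(manifest))) {
    pk <- read_peaks(manifest$file[i], rbp_name = manifest$rbp_name[i])
    expect_equal(nrow(filter_peaks(pk)),
                 unname(tr$rbp$n_pass[manifest$rbp_name[i]]))
  }
})

test_that("event binding is half-open 1-bp-sensitive and multiplicity-free", {
  ev <- make_se_events(1000L, 1100L, chrom = "chr1")
  rg <- event_regions(ev)      # [700, 1400)
  expect_equal(events_bound(rg, toy_peaks("1", 1399, 1450)), ev$key)
  expect_length(events_bound(rg, toy_peaks("chr1", 1400, 1450)), 0)
  expect_equal(events_bound(rg, toy_peaks("chr1", c(800, 900), c(850, 950))),
               ev$key)         # one key despite two peaks

  set.seed(8)
  st <- seq(1000L, 40000L, by = 1000L)[1:40]
  ev <- make_se_events(st, st + 100L, chrom = "c1")
  rg <- event_regions(ev)
  ps <- sample.int(40000L, 15)
  pk <- toy_peaks("c1", ps, ps + sample(20:500, 15, TRUE))
  brute <- rg$key[vapply(seq_len(40), function(i)
    any(rg$start[i] < pk$end & pk$start < rg$end[i]), TRUE)]
  expect_setequal(events_bound(rg, pk), brute)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(hyper_upper_tail(4, 10, 4, 5), 6 / 252, tolerance = 1e-12)
  bg <- sprintf("e%02d", 1:10)
  rec <- rbp_enrichment(bg[1:5], bg, list(R = bg[1:4]))
  expect_equal(rec$pvalue, 6 / 252, tolerance = 1e-12)
  expect_equal(rec$fold_enrichment, (4 / 5) / (4 / 10))
  # k = 0 gives exactly 1
  rec0 <- rbp_enrichment(bg[5:8], bg, list(R = bg[1:4]))
  expect_identical(rec0$pvalue, 1)
  # K = 0 RBPs are omitted; foreground must be a subset
  expect_equal(nrow(rbp_enrichment(bg[1:2], bg, list(R = "zzz"))), 0L)
  expect_error(rbp_enrichment(c(bg[1], "zzz"), bg, list(R = bg[1])), "subset")

  for (N in c(6, 9, 12)) for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
    expect_equal(hyper_upper_tail(k, N, K, n), hyper_enum(k, N, K, n),
                 tolerance = 1e-9)
  }
})

test_that("the tail probability is monotone decreasing in k", {
  for (k in 1:8) expect_lte(hyper_upper_tail(k, 20, 8, 10),
                            hyper_upper_tail(k - 1, 20, 8, 10))
})

test_that("rescued-vs-unrescued binding comparison matches enumeration", {
  r <- sprintf("r%02d", 1:10); u <- sprintf("u%02d", 1:10)
  out <- rescued_vs_unrescued_binding(r, u, bound = c(r[1:9], u[1]))
  expect_equal(unname(out$table), matrix(c(9, 1, 1, 9), 2, byrow = TRUE))
  expect_equal(out$pvalue, fisher_enum(9, 1, 1, 9), tolerance = 1e-10)
  # equal binding fractions give odds ratio 1
  out2 <- rescued_vs_unrescued_binding(r, u, bound = c(r[1:5], u[1:5]))
  expect_equal(out2$odds_ratio, 1)
  expect_warning(out3 <- rescued_vs_unrescued_binding(character(0), u, u[1:3]),
                 "empty")
  expect_equal(out3$pvalue, 1)
  expect_error(rescued_vs_unrescued_binding(r, c(u, r[1]), u), "disjoint")
})

test_that("a rescue-preferential binder is detected on planted data", {
  tr <- big_bundle()
  hd_nm <- "fibroblast:Ctrl-DMSO_vs_HD-DMSO"
  cs <- coverage_filter(read_bundle_comparison(tr, hd_nm))
  manifest <- read_peak_manifest(tr$files$peak_manifest)
  peaks <- filter_peaks(read_manifest_peaks(manifest))
  qki <- peaks[peaks$rbp_name == "QKI", ]
  bound <- events_bound(event_regions(cs$events), qki)
  rescued <- intersect(tr$rescued_keys, cs$events$key)
  unrescued <- setdiff(tr$hd_keys, tr$rescued_keys)
  unrescued <- intersect(unrescued, cs$events$key)
  out <- rescued_vs_unrescued_binding(rescued, unrescued, bound)
  expect_lt(out$pvalue, 0.05)
  expect_gt(out$odds_ratio, 1)
  # binding truth recovered exactly from the planted peak placement
  expect_setequal(intersect(bound, tr$hd_keys),
                  intersect(tr$rbp$bound_by_rbp$QKI, cs$events$key) |>
                    intersect(tr$hd_keys))
})
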