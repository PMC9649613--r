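# Event model: PSI arithmetic, keys, filters, joins, overlap, BH.

test_that("compute_psi matches the length-normalised definition", {
  expect_equal(compute_psi(0, 25, 2, 1), 0)
  expect_equal(compute_psi(25, 0, 2, 1), 1)
  expect_equal(compute_psi(30, 10, 2, 1), (30 / 2) / ((30 / 2) + (10 / 1)))
  expect_true(is.na(compute_psi(0, 0, 2, 1)))
  expect_error(compute_psi(-1, 5, 2, 1), "non-negative")
  expect_error(compute_psi(1, 5, 0, 1), "positive")
})

test_that("event keys are deterministic, coordinate-sensitive and collision-free", {
  co <- c(100L, 200L, 0L, 50L, 300L, 400L)
  k1 <- event_key("SE", "chr1", "+", list(co))
  k2 <- event_key("SE", "chr1", "+", list(co))
  expect_identical(k1, k2)
  co2 <- co; co2[1] <- co2[1] + 1L
  expect_false(event_key("SE", "chr1", "+", list(co2)) == k1)
  expect_error(event_key("SE", "chr1", "+", list(co[1:4])), "6 coordinates")

  set.seed(1)
  starts <- sample.int(1e6, 100)
  keys <- make_se_events(starts, starts + sample(50:200, 100, TRUE))$key
  expect_equal(length(unique(keys)), 100L)
})

test_that("coverage filter requires the threshold in every sample", {
  cs <- make_toy_cs(keys = c("a", "b", "c"),
                    fdr = c(0.01, 0.01, 0.01), ild = c(0.5, 0.5, 0.5),
                    totals1 = list(c(10, 10), c(9, 50), c(50, 50)),
                    totals2 = list(c(10, 10), c(50, 50), c(50, 50)))
  kept <- coverage_filter(cs, 10)$events$key
  expect_setequal(kept, c("a", "c"))   # 10 in every sample passes; one 9 fails

  # brute-force oracle on a random toy set
  set.seed(42)
  totals1 <- replicate(20, sample(5:15, 3, TRUE), simplify = FALSE)
  totals2 <- replicate(20, sample(5:15, 3, TRUE), simplify = FALSE)
  cs <- make_toy_cs(keys = sprintf("e%02d", 1:20), fdr = rep(0.01, 20),
                    ild = rep(0.5, 20), totals1 = totals1, totals2 = totals2)
  expected <- sprintf("e%02d", which(vapply(1:20, function(i)
    all(c(totals1[[i]], totals2[[i]]) >= 10), TRUE)))
  expect_setequal(coverage_filter(cs, 10)$events$key, expected)
})

test_that("significance uses strict thresholds and the sign convention", {
  cs <- make_toy_cs(keys = c("a", "b", "c", "d"),
                    fdr = c(0.049, 0.05, 0.01, 0.01),
                    ild = c(-0.11, 0.5, 0.1, 0.2),
                    totals1 = rep(list(c(50, 50)), 4),
                    totals2 = rep(list(c(50, 50)), 4))
  sig <- significant_events(cs)
  expect_setequal(sig$events$key, c("a", "d"))
  expect_equal(sig$events$direction[sig$events$key == "a"], "included")
  expect_equal(sig$events$direction[sig$events$key == "d"], "excluded")
  # missing stats are skipped with a warning
  cs$events$fdr[3] <- NA
  expect_warning(significant_events(cs), "missing")
})

test_that("filters are idempotent and commute on the retained set", {
  tr <- fx()
  cs <- read_bundle_comparison(tr, names(tr$comparisons)[3])
  cov1 <- coverage_filter(cs)
  expect_equal(coverage_filter(cov1)$events$key, cov1$events$key)
  sig1 <- suppressWarnings(significant_events(cov1))
  expect_equal(suppressWarnings(significant_events(sig1))$events$key,
               sig1$events$key)
  # significance of the full set restricted to coverage-passing keys
  sig_all <- suppressWarnings(significant_events(cs))
  expect_setequal(sig1$events$key,
                  intersect(sig_all$events$key, cov1$events$key))
})

test_that("shared_events intersects keys per direction", {
  a <- make_toy_cs(keys = c("k1", "k2", "k3"), fdr = rep(0.01, 3),
                   ild = c(-0.5, -0.4, 0.3),
                   totals1 = rep(list(50), 3), totals2 = rep(list(50), 3))
  b <- make_toy_cs(keys = c("k2", "k3", "k4"), fdr = rep(0.01, 3),
                   ild = c(-0.2, 0.3, -0.9),
                   totals1 = rep(list(50), 3), totals2 = rep(list(50), 3))
  sa <- significant_events(a); sb <- significant_events(b)
  expect_equal(shared_events(sa, sb, "included"), "k2")
  expect_equal(shared_events(sa, sb, "excluded"), "k3")
  expect_length(shared_events(sa, make_toy_cs(
    keys = "z", fdr = 0.01, ild = -0.5,
    totals1 = list(50), totals2 = list(50)) |> significant_events(),
    "included"), 0)
})

test_that("interval overlap is half-open, 1-bp sensitive, naming-tolerant", {
  ev <- make_se_events(c(1000L, 2000L), c(1100L, 2100L), chrom = "chr1")
  expect_equal(overlap_with_intervals(
    ev, data.frame(chrom = "1", start = 1099, end = 1250)), ev$key[1])
  expect_length(overlap_with_intervals(
    ev, data.frame(chrom = "chr1", start = 1100, end = 1200)), 0)

  set.seed(7)
  st <- sample(seq(1000L, 50000L, by = 1000L), 30)
  ev <- make_se_events(st, st + sample(50:300, 30, TRUE), chrom = "chr1")
  iv <- data.frame(chrom = "chr1",
                   start = sample.int(50000L, 10), stringsAsFactors = FALSE)
  iv$end <- iv$start + sample(100:2000, 10, TRUE)
  got <- overlap_with_intervals(ev, iv)
  te <- do.call(rbind, lapply(ev$coords, function(cc) cc[1:2]))
  brute <- ev$key[vapply(seq_len(30), function(i)
    any(te[i, 1] < iv$end & iv$start < te[i, 2]), TRUE)]
  expect_setequal(got, brute)
})

test_that("BH adjustment matches hand computation", {
  expect_equal(recompute_bh_fdr(0.01), 0.01)
  expect_equal(recompute_bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(recompute_bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(recompute_bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("recomputed PSI agrees with emitted inclusion levels", {
  tr <- fx()
  for (nm in names(tr$comparisons)[c(1, 3)]) {
    cs <- read_bundle_comparison(tr, nm)
    ev <- cs$events
    for (i in seq_len(nrow(ev))) {
      p1 <- compute_psi(ev$ijc1[[i]], ev$sjc1[[i]],
                        ev$inc_form_len[i], ev$skip_form_len[i])
      d <- abs(p1 - ev$inc1[[i]])
      expect_true(all(is.na(d) | d <= 0.01))
    }
  }
})

test_that("novelty annotation flags exactly the unannotated exon boundaries", {
  tr <- fx()
  bd <- read_annotation_boundaries(tr$files$boundaries)
  cs <- annotate_novel_ss(read_bundle_comparison(tr, names(tr$comparisons)[1]), bd)
  truth_novel <- tr$events$key[tr$events$novel_ss]
  got <- cs$events$key[cs$events$novel_ss]
  expect_setequal(got, intersect(truth_novel, cs$events$key))
  expect_gte(length(got), 1L)
})
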