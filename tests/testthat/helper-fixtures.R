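# Shared fixtures (memoised per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

# small truth-annotated bundle with boundary cases (seed fixed once)
fx <- function() cached("fx", small_fixture(dir = file.path(tempdir(), "sr_fx"), seed = 7L))

# one-cell-type bundle with 1000 disease events, planted rescue fraction 0.5
big_bundle <- function() cached("big", generate_dataset(
  sim_config(seed = 5L, cell_types = list(fibroblast = list(n_rep = 4L)),
             n_background = c(SE = 150L), n_hd = 1000L,
             n_drug_clusters = c(20L, 20L)),
  file.path(tempdir(), "sr_big")))

# same design with no planted rescue and no drug effect on disease events
null_bundle <- function() cached("null", generate_dataset(
  sim_config(seed = 5L, cell_types = list(fibroblast = list(n_rep = 4L)),
             n_background = c(SE = 100L), n_hd = 500L,
             n_drug_clusters = c(10L, 10L), rescue_fraction = 0),
  file.path(tempdir(), "sr_null")))

# default-condition bundle (two cell types, 55 drug-induced events)
default_bundle <- function() cached("default", generate_dataset(
  sim_config(seed = 3L), file.path(tempdir(), "sr_default")))

read_bundle_comparison <- function(truth, label) {
  ct <- truth$comparisons[[label]]
  read_comparison_dir(ct$dir, label, ct$group1, ct$group2)
}

# ---- toy builders ---------------------------------------------------------

# minimal SE event rows (enough for keys, windows, regions, overlap)
make_se_events <- function(starts, ends, chrom = "c1", strand = "+") {
  n <- length(starts)
  strand <- rep_len(strand, n)
  chrom <- rep_len(chrom, n)
  ev <- data.frame(chrom = chrom, strand = strand, event_type = "SE",
                   stringsAsFactors = FALSE)
  ev$coords <- lapply(seq_len(n), function(i) {
    up <- c(starts[i] - 300L, starts[i] - 150L)
    down <- c(ends[i] + 150L, ends[i] + 300L)
    if (strand[i] == "-") { tmp <- up; up <- down; down <- tmp }
    as.integer(c(starts[i], ends[i], up, down))
  })
  ev$key <- event_key(ev$event_type, ev$chrom, ev$strand, ev$coords)
  ev
}

# a comparison_set built from scalar columns (counts given per group)
make_toy_cs <- function(keys, fdr, ild, totals1, totals2, label = "toy") {
  n <- length(keys)
  ev <- data.frame(id = as.character(seq_len(n)), gene_id = keys,
                   gene_symbol = keys, chrom = "c1", strand = "+",
                   event_type = "SE", stringsAsFactors = FALSE)
  ev$coords <- lapply(seq_len(n), function(i)
    as.integer(c(1000 * i, 1000 * i + 100, 1000 * i - 300, 1000 * i - 150,
                 1000 * i + 250, 1000 * i + 400)))
  ev$ijc1 <- lapply(totals1, function(t) as.integer(ceiling(t / 2)))
  ev$sjc1 <- lapply(totals1, function(t) as.integer(t - ceiling(t / 2)))
  ev$ijc2 <- lapply(totals2, function(t) as.integer(ceiling(t / 2)))
  ev$sjc2 <- lapply(totals2, function(t) as.integer(t - ceiling(t / 2)))
  ev$inc_form_len <- 200L; ev$skip_form_len <- 100L
  ev$pvalue <- fdr; ev$fdr <- fdr
  ev$inc1 <- lapply(seq_len(n), function(i) rep(0.5, length(totals1[[i]])))
  ev$inc2 <- lapply(seq_len(n), function(i) rep(0.5, length(totals2[[i]])))
  ev$inc_level_difference <- ild
  ev$key <- event_key(ev$event_type, ev$chrom, ev$strand, ev$coords)
  if (!missing(keys)) ev$key <- keys
  comparison_set(ev, label)
}

# ---- independent oracles --------------------------------------------------

# upper-tail hypergeometric by explicit enumeration with choose()
hyper_enum <- function(k, N, K, n) {
  i <- seq.int(max(k, max(0, n - (N - K))), min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# two-sided Fisher exact P by tail enumeration (probability-mass rule)
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  p_obs <- pr[match(a, xs)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# adjusted Rand index via mclust (partition-level comparison only)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
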