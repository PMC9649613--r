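# Splice-site windows and k-mer enrichment.

test_that("window extraction follows the centred-window convention", {
  # toy contig; exon [400,460) on the plus strand, flank 5
  set.seed(3)
  contig <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  genome <- c(c1 = contig)
  ev <- make_se_events(400L, 460L)
  win <- extract_windows(ev, genome, motif_window_config(flank = 5))
  fg <- win[win$role == "foreground", ]
  expect_equal(fg$sequence[fg$site == "three_prime"], substring(contig, 396, 405))
  expect_equal(fg$sequence[fg$site == "five_prime"], substring(contig, 456, 465))
  expect_true(all(nchar(win$sequence) == 10L))
  # background sits at the flanking exons' own splice sites
  bg <- win[win$role == "background", ]
  expect_equal(bg$sequence[bg$site == "three_prime"],
               substring(contig, 400 - 300 - 4, 400 - 300 + 5))
  expect_equal(bg$sequence[bg$site == "five_prime"],
               substring(contig, 460 + 300 - 4, 460 + 300 + 5))
})

test_that("minus-strand windows are reverse complements at mirrored boundaries", {
  set.seed(4)
  contig <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  genome <- c(c1 = contig)
  minus <- make_se_events(400L, 460L, strand = "-")
  win <- extract_windows(minus, genome, motif_window_config(flank = 5))
  fg <- win[win$role == "foreground", ]
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  # the 3' splice site of a minus-strand exon sits at its genomic end
  expect_equal(fg$sequence[fg$site == "three_prime"], rc(substring(contig, 456, 465)))
  expect_equal(fg$sequence[fg$site == "five_prime"], rc(substring(contig, 396, 405)))
})

test_that("windows off the contig end are skipped with a warning", {
  genome <- c(c1 = "ACGTACGTACGT")
  ev <- data.frame(chrom = "c1", strand = "+", event_type = "SE",
                   stringsAsFactors = FALSE)
  ev$coords <- list(c(2L, 8L, 0L, 1L, 10L, 12L))
  ev$key <- event_key("SE", "c1", "+", ev$coords)
  expect_warning(win <- extract_windows(ev, genome), "off contig end")
  expect_equal(nrow(win), 0L)
  ev$chrom <- "nope"
  expect_error(extract_windows(ev, genome), "absent")
})

test_that("k-mer counting matches a naive scan and handles N", {
  expect_equal(count_kmers("ACGTACGTAC", 8)$total, 3L)
  expect_equal(count_kmers("AAAA", 4)$counts, c(AAAA = 1L))
  expect_error(count_kmers("ACG", 4), "exceeds")
  # N-containing positions contribute nothing
  cn <- count_kmers("ACNGT", 2)
  expect_equal(sum(cn$counts), 2L)  # AC and GT only
  # naive oracle over random windows
  set.seed(5)
  wins <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 10, TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = ""), "")
  for (k in c(4, 6)) {
    got <- count_kmers(wins, k)
    naive <- table(unlist(lapply(wins, function(w)
      substring(w, 1:(nchar(w) - k + 1), k:nchar(w)))))
    naive <- naive[!grepl("N", names(naive))]
    expect_equal(got$total, sum(naive))
    expect_equal(got$counts[order(names(got$counts))],
                 c(unlist(naive))[order(names(naive))], ignore_attr = TRUE)
  }
})

test_that("enrichment is null for identical sets and matches enumeration", {
  fg <- list(counts = c(AAAA = 5L, CCCC = 10L), total = 15L)
  rec <- kmer_enrichment(fg, fg)
  expect_true(all(rec$odds_ratio == 1))
  expect_equal(rec$pvalue, rep(1, nrow(rec)))
  expect_equal(rec$relative_frequency_fg, rec$relative_frequency_bg)

  fg <- list(counts = c(AG = 8L), total = 100L)
  bg <- list(counts = c(AG = 1L), total = 400L)
  rec <- kmer_enrichment(fg, bg)
  expect_equal(rec$pvalue, fisher_enum(8, 92, 1, 399), tolerance = 1e-10)
  # relative frequencies over observed k-mers sum to 1 per side
  win <- c("ACGTACGTAC", "TTGACTGACT")
  cc <- count_kmers(win, 4)
  rec <- kmer_enrichment(cc, count_kmers(rev(win), 4))
  expect_equal(sum(rec$relative_frequency_fg), 1)
  expect_equal(sum(rec$relative_frequency_bg), 1)
})

test_that("planted splice-site motifs are recovered as top-ranked 8-mers", {
  cfgs <- sim_config(seed = 21, cell_types = list(fibroblast = list(n_rep = 3L)),
                     n_background = c(SE = 40L), n_hd = 10L,
                     n_drug_clusters = c(25L, 25L),
                     drug_cluster_delta = c(0.65, 0.35))
  tr <- generate_dataset(cfgs, tempfile())
  genome <- read_fasta(tr$files$genome)
  cs <- read_bundle_comparison(tr, "fibroblast:Ctrl-DMSO_vs_Ctrl-Bran")
  fg <- cs$events[cs$events$key %in% tr$drug_keys, ]
  rec <- splice_site_kmer_enrichment(fg, genome)
  r8 <- rec[rec$k == 8, ]
  expect_equal(r8$kmer[r8$site == "five_prime"][1], "AGAGTAAG")
  expect_equal(r8$kmer[r8$site == "three_prime"][1], "TTCAGTTT")
  expect_lt(r8$pvalue[r8$site == "five_prime"][1], 1e-4)
})

test_that("enrichment is invariant under genome reverse-complement + strand flip", {
  set.seed(6)
  contig <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  L <- nchar(contig)
  st <- c(400L, 900L, 1300L)
  ev <- make_se_events(st, st + 100L, strand = c("+", "-", "+"))
  rec1 <- splice_site_kmer_enrichment(ev, c(c1 = contig))

  rc_contig <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  # mirror every coordinate pair and swap starts/ends: [s,e) -> [L-e, L-s)
  ev2 <- ev
  ev2$strand <- ifelse(ev$strand == "+", "-", "+")
  ev2$coords <- lapply(ev$coords, function(cc) {
    s <- cc[seq(1, 6, 2)]; e <- cc[seq(2, 6, 2)]
    as.integer(rbind(L - e, L - s))
  })
  ev2$key <- event_key(ev2$event_type, ev2$chrom, ev2$strand, ev2$coords)
  rec2 <- splice_site_kmer_enrichment(ev2, c(c1 = rc_contig))
  for (k in c(4, 6, 8)) for (site in c("three_prime", "five_prime")) {
    a <- rec1[rec1$k == k & rec1$site == site, c("kmer", "fg_count", "bg_count")]
    b <- rec2[rec2$k == k & rec2$site == site, c("kmer", "fg_count", "bg_count")]
    expect_equal(a[order(a$kmer), ], b[order(b$kmer), ], ignore_attr = TRUE)
  }
})
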