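# Genomic distance, cis windowing, correlation screening and the
# cis/trans partition.

test_that("genomic distance is the gap between closest span ends", {
  d <- genomic_distance(list(chrom = "chr1", start = 1000, end = 2000),
                        list(chrom = "chr1", start = 2501, end = 3000))
  expect_identical(d$distance, 500L)
  expect_identical(d$orientation, "downstream")
  d <- genomic_distance(list(chrom = "chr1", start = 1000, end = 2000),
                        list(chrom = "chr1", start = 1500, end = 3000))
  expect_identical(d$distance, 0L)
  expect_identical(d$orientation, "overlapping")
  d <- genomic_distance(list(chrom = "chr1", start = 1000, end = 2000),
                        list(chrom = "chr2", start = 1500, end = 3000))
  expect_identical(d$distance, Inf)

  set.seed(9)
  for (i in 1:100) {
    a <- sort(sample.int(1e5, 2)); b <- sort(sample.int(1e5, 2))
    got <- genomic_distance(list(chrom = "chr1", start = a[1], end = a[2]),
                            list(chrom = "chr1", start = b[1], end = b[2]))
    expect_equal(got$distance,
                 brute_gap("chr1", a[1], a[2], "chr1", b[1], b[2]))
  }
})

test_that("the cis window is inclusive at exactly 100 kb", {
  lnc <- transcript_set(make_exons(
    list("lncA", "lA", "chr1", "+", 1000, 1400),
    list("lncA", "lA", "chr1", "+", 1600, 2000)))
  gene_at <- function(start, end) transcript_set(make_exons(
    list("codA.t1", "codA", "chr1", "-", start, end)))
  # gap of exactly 100000: emitted
  hit <- cis_pairs(lnc, gene_at(102001, 103000), window = 100000)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$distance, 100000L)
  # one bp further: not emitted
  expect_identical(nrow(cis_pairs(lnc, gene_at(102002, 103000),
                                  window = 100000)), 0L)
  # window 0 keeps only overlaps
  expect_identical(nrow(cis_pairs(lnc, gene_at(1500, 2500), window = 0)), 1L)
  expect_identical(nrow(cis_pairs(lnc, gene_at(2002, 2500), window = 0)), 0L)
})

test_that("a gene 94,591 bp away is called a cis target", {
  # the published example pair: a coding gene 94,591 bp upstream of its
  # co-located lncRNA
  lnc <- transcript_set(make_exons(
    list("LNC_003452", "l", "chr5", "+", 500000, 501000)))
  gene <- transcript_set(make_exons(
    list("ACCO3.t1", "ACCO3", "chr5", "+", 404000, 500000 - 94591 - 1)))
  hit <- cis_pairs(lnc, gene)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$distance, 94591L)
  expect_identical(hit$orientation, "upstream")
})

test_that("index-based cis search equals the all-pairs scan on random fixtures", {
  set.seed(404)
  for (i in 1:30) {
    ann <- random_annotation(15, 10, chrom_len = 3e5)
    coding_ids <- ann$transcripts$transcript_id[ann$transcripts$biotype == "coding"]
    lncs <- subset_transcripts(ann, setdiff(ann$transcripts$transcript_id,
                                            coding_ids))
    coding <- subset_transcripts(ann, coding_ids)
    window <- sample(c(0, 1000, 20000, 100000), 1)
    got <- cis_pairs(lncs, coding, window = window)
    want <- brute_cis(lncs, coding, window)
    expect_identical(got[, c("lncrna_id", "gene_id", "distance")],
                     structure(want, row.names = seq_len(nrow(want))),
                     info = paste("fixture", i, "window", window))
  }
})

test_that("pearson_with_p gives exact r at perfect linearity and matches cor.test", {
  x <- c(1, 2, 4, 8, 9, 12, 13, 15, 17, 20, 21, 25)
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  set.seed(15)
  for (i in 1:100) {
    a <- rnorm(12); b <- rnorm(12)
    got <- pearson_with_p(a, b)
    ct <- cor.test(a, b)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
    # symmetry and positive affine invariance
    swapped <- pearson_with_p(b, a)
    expect_equal(got$r, swapped$r, tolerance = 1e-15)
    scaled <- pearson_with_p(a, 3.7 * b + 11)
    expect_equal(got$r, scaled$r, tolerance = 1e-12)
  }

  const <- pearson_with_p(rep(1, 12), rnorm(12))
  expect_false(const$ok)
  expect_identical(const$reason, "constant_profile")
  expect_error(pearson_with_p(1:3, 1:4), "length")
  expect_error(pearson_with_p(1:2, 2:1), "n >= 3")
})

test_that("correlation screening applies strict thresholds", {
  design <- make_design()
  set.seed(21)
  base <- rnorm(12)
  lnc_vals <- rbind(L1 = 10 + base)
  g_vals <- rbind(G1 = 10 + base + rnorm(12, 0, 0.4), G2 = rexp(12))
  colnames(lnc_vals) <- colnames(g_vals) <- design$sample_id
  r_true <- cor(lnc_vals["L1", ], g_vals["G1", ])
  lnc <- make_expr(pmax(lnc_vals, 0)); gen <- make_expr(pmax(g_vals, 0))
  # threshold exactly at the observed r: strict > excludes the pair
  expect_identical(nrow(coexpression_pairs(lnc, gen, r_threshold = abs(r_true))), 0L)
  hits <- coexpression_pairs(lnc, gen, r_threshold = abs(r_true) - 1e-6)
  expect_identical(hits$gene_id, "G1")
  expect_equal(hits$r, r_true, tolerance = 1e-12)
  expect_identical(hits$sign, if (r_true > 0) "positive" else "negative")

  # agreement with the scalar op
  pw <- pearson_with_p(lnc_vals["L1", ], g_vals["G1", ])
  expect_equal(hits$r, pw$r, tolerance = 1e-12)
  expect_equal(hits$p, pw$p, tolerance = 1e-12)

  other_design <- make_design(stages = c("A", "B"), reps = 6)
  colnames(g_vals) <- other_design$sample_id
  expect_error(coexpression_pairs(lnc, expression_matrix(g_vals, other_design)),
               "sample axis")
})

test_that("constant profiles are skipped with a record, not an error", {
  design <- make_design()
  lnc_vals <- rbind(L1 = rep(4, 12), L2 = rexp(12))
  g_vals <- rbind(G1 = rexp(12))
  colnames(lnc_vals) <- colnames(g_vals) <- design$sample_id
  out <- coexpression_pairs(make_expr(lnc_vals), make_expr(g_vals))
  expect_true("L1" %in% attr(out, "skipped_constant"))
})

test_that("partition labels modes and conserves pair counts", {
  coexpr <- data.frame(lncrna_id = c("l1", "l1", "l2"),
                       gene_id = c("gA", "gB", "gC"),
                       r = c(0.99, -0.97, 0.98), p = c(1e-8, 1e-6, 1e-7),
                       sign = c("positive", "negative", "positive"))
  cis <- data.frame(lncrna_id = c("l1", "l3"), gene_id = c("gA", "gD"),
                    distance = c(50000L, 10L),
                    orientation = c("downstream", "upstream"))
  res <- partition_and_intersect(coexpr, cis)
  modes <- stats::setNames(res$pairs$mode,
                           paste(res$pairs$lncrna_id, res$pairs$gene_id))
  expect_identical(modes[["l1 gA"]], "coexpr_cis_both")
  expect_identical(modes[["l1 gB"]], "coexpr_trans")
  expect_identical(modes[["l3 gD"]], "cis_only")
  expect_identical(unname(res$counts["coexpr_trans"] +
                          res$counts["coexpr_cis_both"]),
                   nrow(coexpr))
  expect_identical(sum(res$counts), nrow(res$pairs))
})

test_that("zero-noise planted trans pairs are fully recovered at the thresholds", {
  cfg <- small_sim_config(seed = 37, trans_noise_sd = 0)
  sim <- simulate_dataset(cfg, withr::local_tempdir())
  ts <- sim$annotation
  coding_ids <- ts$transcripts$transcript_id[ts$transcripts$biotype == "coding"]
  gene_expr <- gene_level_fpkm(
    expression_matrix(sim$expression$values[coding_ids, ], sim$expression$design),
    data.frame(transcript_id = coding_ids,
               gene_id = ts$transcripts$gene_id[match(coding_ids,
                                                      ts$transcripts$transcript_id)]))
  lnc_expr <- expression_matrix(
    sim$expression$values[sim$truth$true_lncrna_ids, ], sim$expression$design)
  co <- coexpression_pairs(lnc_expr, gene_expr)
  key <- paste(co$lncrna_id, co$gene_id)
  planted <- paste(sim$truth$planted_trans_pairs$lncrna_id,
                   sim$truth$planted_trans_pairs$gene_id)
  expect_true(all(planted %in% key))
})
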