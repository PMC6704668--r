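# Candidate filters, ORF scanning, coding verdicts and positional
# classification.

test_that("candidate filters apply inclusive thresholds with one reason per reject", {
  ts <- transcript_set(make_exons(
    list("short", "g1", "chr1", "+", 1, 75),      # 150 bp over 2 exons
    list("short", "g1", "chr1", "+", 101, 175),
    list("mono", "g2", "chr1", "+", 1000, 1499),  # 1 exon
    list("low", "g3", "chr1", "+", 2000, 2199),   # fpkm below 0.5
    list("low", "g3", "chr1", "+", 2300, 2399),
    list("edge", "g4", "chr1", "+", 3000, 3099),  # exactly 200 bp, fpkm 0.5
    list("edge", "g4", "chr1", "+", 3200, 3299),
    list("orphan", "g5", "chr1", "+", 4000, 4400)))
  vals <- rbind(short = 3, mono = 3, low = 0.49, edge = 0.5)
  vals <- matrix(vals, 4, 12, dimnames = list(rownames(vals), make_design()$sample_id))
  expr <- make_expr(vals)
  flt <- filter_candidates(ts, expr)
  expect_setequal(flt$retained, "edge")
  got <- stats::setNames(flt$rejects$reason, flt$rejects$transcript_id)
  expect_identical(got[["short"]], "length")
  expect_identical(got[["mono"]], "exons")
  expect_identical(got[["low"]], "fpkm")
  expect_identical(got[["orphan"]], "no_expression")
  expect_identical(length(flt$retained) + nrow(flt$rejects),
                   nrow(ts$transcripts))
})

test_that("fpkm aggregation is max by default and mean on request", {
  ts <- transcript_set(make_exons(
    list("t1", "g1", "chr1", "+", 1, 150),
    list("t1", "g1", "chr1", "+", 201, 350)))
  vals <- matrix(c(5, rep(0, 11)), 1, 12,
                 dimnames = list("t1", make_design()$sample_id))
  expr <- make_expr(vals)
  expect_identical(filter_candidates(ts, expr)$retained, "t1")  # max = 5
  expect_identical(filter_candidates(ts, expr, fpkm_stat = "mean")$rejects$reason,
                   "fpkm")  # mean = 5/12 < 0.5
})

test_that("longest_orf matches an exhaustive start/stop pair scan", {
  expect_identical(longest_orf("CCCCCCCCCCCC")$length_nt, 0L)
  # one ORF end to end: ATG + 58 codons + TAA = 180 nt of a 200 nt seq
  seq <- paste0("AC", "ATG", paste(rep("GGC", 57), collapse = ""), "TAA",
                paste(rep("C", 24), collapse = ""))
  o <- longest_orf(seq)
  expect_identical(o$length_nt, 177L)
  expect_identical(o$length_nt, brute_longest_orf(seq))
  set.seed(101)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    expect_identical(longest_orf(s)$length_nt, brute_longest_orf(s),
                     info = paste("sequence", i))
  }
})

test_that("coding verdict is the conjunction of the two assessors", {
  ts <- transcript_set(make_exons(list("t1", "g1", "chr1", "+", 1, 600)))
  # ORF spanning 90% of 600 nt: both thresholds exceeded -> coding
  orf_nt <- 540
  seqs <- c(t1 = paste0(paste(rep("C", 30), collapse = ""), "ATG",
                        paste(rep("GGC", orf_nt / 3 - 2), collapse = ""), "TAA",
                        paste(rep("C", 30), collapse = "")))
  a <- assess_coding(ts, seqs)
  expect_identical(a$verdict, "coding")
  expect_false(a$assessor_a_noncoding)
  expect_false(a$assessor_b_noncoding)

  # no ATG at all -> ORF 0 -> noncoding by both
  ts2 <- transcript_set(make_exons(list("t2", "g2", "chr1", "+", 1, 300)))
  a2 <- assess_coding(ts2, c(t2 = paste(rep("C", 300), collapse = "")))
  expect_identical(a2$longest_orf_nt, 0L)
  expect_identical(a2$verdict, "noncoding")

  # external flags override the internal assessors; one coding vote vetoes
  a3 <- assess_coding(ts2, c(t2 = paste(rep("C", 300), collapse = "")),
                      external_flags = data.frame(
                        transcript_id = "t2", assessor_a_noncoding = FALSE,
                        assessor_b_noncoding = TRUE))
  expect_identical(a3$verdict, "coding")

  # flags alone suffice when no sequence is available
  a4 <- assess_coding(ts2, NULL, external_flags = data.frame(
    transcript_id = "t2", assessor_a_noncoding = TRUE,
    assessor_b_noncoding = TRUE))
  expect_identical(a4$verdict, "noncoding")
  expect_error(assess_coding(ts2, NULL, external_flags = data.frame(
    transcript_id = "t2", assessor_a_noncoding = TRUE,
    assessor_b_noncoding = NA)), "no spliced sequence")
})

test_that("positional classification follows the exonic-overlap rules", {
  coding <- transcript_set(make_exons(
    list("cod1", "gA", "chr1", "+", 200, 300),
    list("cod1", "gA", "chr1", "+", 500, 700)))
  cands <- transcript_set(make_exons(
    list("anti", "l1", "chr1", "-", 150, 250),   # 51 bp opposite overlap
    list("far", "l2", "chr1", "+", 5700, 6000),  # nearest gene 5 kb away
    list("sense", "l3", "chr1", "+", 250, 320),  # same-strand exonic
    list("intron", "l4", "chr1", "-", 350, 450)  # inside span, no exon hit
  ))
  cl <- classify_lncrnas(cands, coding)
  cls <- stats::setNames(cl$classes$lnc_class, cl$classes$transcript_id)
  expect_identical(cls[["anti"]], "antisense")
  expect_identical(cls[["far"]], "intergenic")
  rs <- stats::setNames(cl$excluded$reason, cl$excluded$transcript_id)
  expect_identical(rs[["sense"]], "sense_overlap")
  expect_identical(rs[["intron"]], "genic_overlap")
})

test_that("index-based classification equals the brute-force scan on random fixtures", {
  set.seed(202)
  for (i in 1:30) {
    ann <- random_annotation(12, 8)
    coding_ids <- ann$transcripts$transcript_id[ann$transcripts$biotype == "coding"]
    cand_ids <- setdiff(ann$transcripts$transcript_id, coding_ids)
    coding <- subset_transcripts(ann, coding_ids)
    cands <- subset_transcripts(ann, cand_ids)
    want <- brute_classify(cands, coding)
    got <- classify_lncrnas(cands, coding)
    got_all <- c(stats::setNames(got$classes$lnc_class, got$classes$transcript_id),
                 stats::setNames(got$excluded$reason, got$excluded$transcript_id))
    expect_identical(got_all[names(want)], want, info = paste("fixture", i))
  }
})

test_that("candidates on chromosomes absent from the annotation are an error", {
  coding <- transcript_set(make_exons(list("cod1", "gA", "chr1", "+", 200, 300)))
  cands <- transcript_set(make_exons(list("c1", "l1", "chr9", "+", 200, 500)))
  expect_error(classify_lncrnas(cands, coding), "chr9.*absent")
})

test_that("identification partitions every transcript and flags high expression", {
  cfg <- small_sim_config(seed = 31)
  sim <- simulate_dataset(cfg, withr::local_tempdir())
  ident <- identify_lncrnas(sim$annotation, sim$expression, sim$sequences)
  expect_identical(nrow(ident$lncrnas) + nrow(ident$rejects),
                   nrow(sim$annotation$transcripts))
  expect_setequal(ident$lncrnas$transcript_id, sim$truth$true_lncrna_ids)
  m <- match(ident$lncrnas$transcript_id, names(sim$truth$true_class))
  expect_identical(ident$lncrnas$lnc_class, unname(sim$truth$true_class[m]))
  mu <- rowMeans(sim$expression$values[ident$lncrnas$transcript_id, ])
  expect_identical(ident$lncrnas$highly_expressed, unname(mu > 100))
})
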