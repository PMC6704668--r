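# Gene aggregation, the Welch DE caller, Venn accounting and ddCt.

test_that("gene-level FPKM is the per-sample transcript sum", {
  design <- make_design()
  vals <- matrix(c(rep(2, 12), rep(3, 12), rep(7, 12)), 3, 12, byrow = TRUE,
                 dimnames = list(c("t1", "t2", "t3"), design$sample_id))
  expr <- make_expr(vals)
  map <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    gene_id = c("gA", "gA", "gB"))
  g <- gene_level_fpkm(expr, map)
  expect_equal(unname(g$values["gA", ]), rep(5, 12))
  expect_equal(unname(g$values["gB", ]), rep(7, 12))  # single transcript: identity

  set.seed(77)
  vals <- matrix(rexp(40 * 12), 40, 12,
                 dimnames = list(paste0("t", 1:40), design$sample_id))
  expr <- make_expr(vals)
  map <- data.frame(transcript_id = paste0("t", 1:40),
                    gene_id = paste0("g", sample(1:12, 40, replace = TRUE)))
  g <- gene_level_fpkm(expr, map)
  for (gene in unique(map$gene_id)) {
    members <- map$transcript_id[map$gene_id == gene]
    expect_equal(unname(g$values[gene, ]),
                 unname(colSums(vals[members, , drop = FALSE])))
  }
  expect_error(gene_level_fpkm(expr, map[-1, ]), "no gene mapping")
})

test_that("DE caller handles degenerate inputs and matches t.test", {
  design <- make_design()
  vals <- matrix(5, 2, 12, dimnames = list(c("flat", "x"), design$sample_id))
  set.seed(3)
  vals["x", ] <- rexp(12) + 1
  de <- differential_expression(make_expr(vals), "G", "C")
  flat <- de[de$feature_id == "flat", ]
  expect_equal(flat$log2fc, 0)
  expect_equal(flat$p, 1)  # zero variance in both groups, equal means
  expect_false(flat$is_de)

  # non-degenerate rows agree with stats::t.test on log2(FPKM+1)
  x <- de[de$feature_id == "x", ]
  tt <- t.test(log2(vals["x", design$stage == "C"] + 1),
               log2(vals["x", design$stage == "G"] + 1), var.equal = TRUE)
  expect_equal(x$p, tt$p.value, tolerance = 1e-12)
  expect_equal(x$log2fc, unname(diff(rev(tt$estimate))), tolerance = 1e-12)

  # Welch mode agrees with the unequal-variance t.test
  dew <- differential_expression(make_expr(vals), "G", "C", var_equal = FALSE)
  xw <- dew[dew$feature_id == "x", ]
  ttw <- t.test(log2(vals["x", design$stage == "C"] + 1),
                log2(vals["x", design$stage == "G"] + 1))
  expect_equal(xw$p, ttw$p.value, tolerance = 1e-12)
})

test_that("swapping stage labels negates log2fc and keeps p", {
  set.seed(11)
  design <- make_design()
  vals <- matrix(rexp(30 * 12, 0.2), 30, 12,
                 dimnames = list(paste0("f", 1:30), design$sample_id))
  expr <- make_expr(vals)
  ab <- differential_expression(expr, "G", "C")
  ba <- differential_expression(expr, "C", "G")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$q, ba$q)
})

test_that("DE requires known stages with enough replicates", {
  design <- make_design(stages = c("G", "R"), reps = 2)
  vals <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), design$sample_id))
  expr <- make_expr(vals, design)
  expect_error(differential_expression(expr, "G", "Z"), "absent from design")
  one_rep <- make_design(stages = c("G", "R"), reps = 1)
  vals1 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), one_rep$sample_id))
  expect_error(differential_expression(make_expr(vals1, one_rep), "G", "R"),
               "replicate")
})

test_that("venn accounting matches per-element membership tallies", {
  sets <- list(A = c("a", "b"), B = c("b", "c"), C = "b", D = c("b", "d"))
  v <- venn_accounting(sets)
  expect_identical(v$intersection_ids, "b")
  expect_identical(v$regions$count[v$regions$region == "A&B&C&D"], 1L)
  expect_identical(v$union_size, 4L)

  disjoint <- venn_accounting(list(A = c("x", "y"), B = c("z"), C = "w"))
  multi <- disjoint$regions[grepl("&", disjoint$regions$region), ]
  expect_true(all(multi$count == 0L))

  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    sets <- stats::setNames(lapply(seq_len(k), function(j)
      sample(letters, sample(3:15, 1))), LETTERS[seq_len(k)])
    v <- venn_accounting(sets)
    want <- brute_venn_regions(sets)
    for (region in v$regions$region)
      expect_identical(v$regions$count[v$regions$region == region],
                       as.integer(want[[region]] %||% 0L))
    # conservation: regions sum to the union; per-set regions sum to set size
    expect_identical(sum(v$regions$count), v$union_size)
    for (lab in names(sets)) {
      in_lab <- vapply(strsplit(v$regions$region, "&", fixed = TRUE),
                       function(r) lab %in% r, logical(1))
      expect_identical(sum(v$regions$count[in_lab]),
                       length(unique(sets[[lab]])))
    }
  }
  expect_error(venn_accounting(list(A = "x")), "2-4 sets")
  expect_error(venn_accounting(stats::setNames(list("x", "y"), c("A", "A"))),
               "unique")
})

test_that("highly-expressed flagging uses a strict mean threshold", {
  design <- make_design()
  vals <- rbind(at = rep(100, 12), above = rep(100.1, 12))
  colnames(vals) <- design$sample_id
  expect_identical(flag_highly_expressed(make_expr(vals)), "above")

  set.seed(8)
  vals <- matrix(rexp(50 * 12, 1 / 90), 50, 12,
                 dimnames = list(paste0("f", 1:50), design$sample_id))
  expect_setequal(flag_highly_expressed(make_expr(vals)),
                  rownames(vals)[rowMeans(vals) > 100])
})

test_that("2^-ddCt arithmetic matches the hand-stepped toy table", {
  ct <- data.frame(
    gene = rep(c("LNC_X", "GAPDH"), each = 4),
    sample = rep(c("s1", "s2", "s3", "s4"), 2),
    ct = c(30, 28, 26, 24, 20, 20, 19, 18))
  out <- ddct_relative_expression(ct, "LNC_X", "GAPDH", "s1")
  # dCt = 10, 8, 7, 6; ddCt vs s1 = 0, -2, -3, -4; 2^-ddCt = 1, 4, 8, 16
  expect_equal(out$delta_ct, c(10, 8, 7, 6))
  expect_equal(out$delta_delta_ct, c(0, -2, -3, -4))
  expect_equal(out$relative_expression, c(1, 4, 8, 16))

  expect_error(ddct_relative_expression(ct[ct$sample != "s3" | ct$gene != "GAPDH", ],
                                        "LNC_X", "GAPDH", "s1"),
               "missing reference")
  expect_error(ddct_relative_expression(ct, "LNC_X", "GAPDH", "s9"), "calibrator")
})
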