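# End-to-end orchestration: identify -> DE -> targets -> enrichment ->
# network, writing a reproducible run directory plus a machine-readable
# summary.

#' Pipeline run configuration
#'
#' Collects every threshold the analysis uses; no stage has hidden
#' defaults outside this object.
#'
#' @param min_length,min_exons,min_fpkm,fpkm_stat Candidate filters
#'   (see [filter_candidates()]).
#' @param orf_min_nt,orf_min_coverage Coding-potential thresholds (see
#'   [assess_coding()]).
#' @param high_fpkm Highly-expressed mean-FPKM threshold (strict >).
#' @param window cis window in bp (default 100000).
#' @param r_threshold,p_threshold Co-expression screening thresholds
#'   (strict, default 0.95 / 0.05).
#' @param coexpr_log2 Correlate log2(FPKM+1) instead of raw FPKM
#'   (default FALSE).
#' @param de_alpha Adjusted-p significance level for DE calling.
#' @param enrich_alpha Adjusted-p significance level for enrichment.
#' @param tf_fold_change,tf_min_fpkm Transcription-factor selection
#'   thresholds (fold change > 2, FPKM > 30).
#' @param comparisons Character vector of stage comparisons as
#'   `"A-vs-B"` (default the four ripening comparisons G-vs-R, R-vs-C,
#'   C-vs-P, G-vs-C).
#' @param network_comparison Comparison used to color node regulation
#'   (default `"G-vs-C"`).
#' @param reference_gene qPCR reference gene (default `"GAPDH"`).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(min_length = 200, min_exons = 2, min_fpkm = 0.5,
                       fpkm_stat = "max", orf_min_nt = 300,
                       orf_min_coverage = 0.35, high_fpkm = 100,
                       window = 100000, r_threshold = 0.95,
                       p_threshold = 0.05, coexpr_log2 = FALSE,
                       de_alpha = 0.05, enrich_alpha = 0.05,
                       tf_fold_change = 2, tf_min_fpkm = 30,
                       comparisons = c("G-vs-R", "R-vs-C", "C-vs-P", "G-vs-C"),
                       network_comparison = "G-vs-C",
                       reference_gene = "GAPDH") {
  cfg <- list(min_length = min_length, min_exons = min_exons,
              min_fpkm = min_fpkm, fpkm_stat = fpkm_stat,
              orf_min_nt = orf_min_nt, orf_min_coverage = orf_min_coverage,
              high_fpkm = high_fpkm, window = window,
              r_threshold = r_threshold, p_threshold = p_threshold,
              coexpr_log2 = isTRUE(coexpr_log2), de_alpha = de_alpha,
              enrich_alpha = enrich_alpha, tf_fold_change = tf_fold_change,
              tf_min_fpkm = tf_min_fpkm, comparisons = comparisons,
              network_comparison = network_comparison,
              reference_gene = reference_gene)
  pos <- c("min_length", "min_exons", "min_fpkm", "orf_min_nt",
           "orf_min_coverage", "high_fpkm", "r_threshold", "p_threshold",
           "de_alpha", "enrich_alpha", "tf_fold_change", "tf_min_fpkm")
  for (f in pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    lnc_stop("%s must be positive", f)
  if (!is.numeric(cfg$window) || cfg$window < 0)
    lnc_stop("window must be >= 0")
  if (!all(grepl("^[^-]+-vs-[^-]+$", cfg$comparisons)))
    lnc_stop("comparisons must look like 'A-vs-B'")
  structure(cfg, class = "run_config")
}

parse_comparison <- function(cmp) strsplit(cmp, "-vs-", fixed = TRUE)[[1]]

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    lnc_stop("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full lncRNA characterization pipeline
#'
#' Executes identification, differential expression with Venn
#' accounting, cis/trans target prediction, term enrichment, network
#' assembly with heatmap ordering, and (optionally) qPCR ddCt
#' validation, writing every intermediate table plus `summary.json`
#' into `out_dir`. Reruns on the same inputs and configuration are
#' byte-identical.
#'
#' @param gtf Path to the annotation GTF (assembled transcripts plus
#'   protein-coding reference, `gene_biotype "coding"` marking the
#'   latter).
#' @param expression Path to the transcript-level FPKM TSV.
#' @param samples Path to the sample sheet TSV.
#' @param fasta Optional path to spliced transcript sequences (needed
#'   unless `coding_flags` covers all candidates).
#' @param terms Optional gene-to-term TSV for enrichment.
#' @param coding_flags Optional external assessor flags TSV.
#' @param ppi Optional protein-protein interaction edge TSV
#'   (`node_a`, `node_b`).
#' @param node_kinds Optional node-kind TSV (`id`, `kind`) designating
#'   TFs.
#' @param qpcr Optional qPCR Ct TSV (`gene`, `sample`, `ct`).
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisible list of class `lnc_run` with all result tables and
#'   the `summary` list mirrored in `summary.json`.
#' @export
run_pipeline <- function(gtf, expression, samples, fasta = NULL, terms = NULL,
                         coding_flags = NULL, ppi = NULL, node_kinds = NULL,
                         qpcr = NULL, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- run_stage("read_inputs", {
    ts <- read_gtf(gtf)
    sheet <- read_sample_sheet(samples)
    expr <- read_expression(expression, sheet)
    seqs <- if (!is.null(fasta)) read_transcript_fasta(fasta) else NULL
    flags <- if (!is.null(coding_flags)) read_tsv(coding_flags) else NULL
    term_map <- if (!is.null(terms)) read_tsv(terms) else NULL
    ppi_tab <- if (!is.null(ppi)) read_tsv(ppi) else NULL
    kinds <- if (!is.null(node_kinds)) read_tsv(node_kinds) else NULL
    ct <- if (!is.null(qpcr)) read_tsv(qpcr) else NULL
    list(ts = ts, sheet = sheet, expr = expr, seqs = seqs, flags = flags,
         term_map = term_map, ppi = ppi_tab, kinds = kinds, ct = ct)
  })
  ts <- inputs$ts; expr <- inputs$expr

  ident <- run_stage("identify", identify_lncrnas(
    ts, expr, inputs$seqs, inputs$flags,
    min_length = config$min_length, min_exons = config$min_exons,
    min_fpkm = config$min_fpkm, fpkm_stat = config$fpkm_stat,
    orf_min_nt = config$orf_min_nt,
    orf_min_coverage = config$orf_min_coverage,
    high_fpkm = config$high_fpkm))
  lnc_ids <- ident$lncrnas$transcript_id

  coding_tx <- ts$transcripts$transcript_id[ts$transcripts$biotype == "coding"]
  coding_ts <- subset_transcripts(ts, coding_tx)
  gene_expr <- run_stage("gene_level_fpkm", {
    sub <- expression_matrix(expr$values[coding_tx, , drop = FALSE],
                             expr$design)
    gene_level_fpkm(sub, df0(
      transcript_id = coding_tx,
      gene_id = ts$transcripts$gene_id[match(coding_tx,
                                             ts$transcripts$transcript_id)]))
  })

  de <- run_stage("differential_expression", {
    lnc_expr <- expression_matrix(expr$values[lnc_ids, , drop = FALSE],
                                  expr$design)
    lnc_de <- lapply(config$comparisons, function(cmp) {
      ab <- parse_comparison(cmp)
      differential_expression(lnc_expr, ab[1], ab[2], alpha = config$de_alpha)
    })
    names(lnc_de) <- config$comparisons
    gene_de <- lapply(config$comparisons, function(cmp) {
      ab <- parse_comparison(cmp)
      differential_expression(gene_expr, ab[1], ab[2], alpha = config$de_alpha)
    })
    names(gene_de) <- config$comparisons
    list(lnc = lnc_de, gene = gene_de, lnc_expr = lnc_expr)
  })
  de_sets <- lapply(de$lnc, function(d) d$feature_id[d$is_de])
  venn <- run_stage("venn_accounting", venn_accounting(de_sets))

  targets_res <- run_stage("target_prediction", {
    lnc_ts <- subset_transcripts(ts, lnc_ids)
    cis <- cis_pairs(lnc_ts, coding_ts, window = config$window)
    co <- coexpression_pairs(de$lnc_expr, gene_expr,
                             r_threshold = config$r_threshold,
                             p_threshold = config$p_threshold,
                             log2_transform = config$coexpr_log2)
    part <- partition_and_intersect(co, cis)
    list(cis = cis, coexpr = co, pairs = part$pairs, counts = part$counts)
  })

  enr <- if (!is.null(inputs$term_map)) run_stage("enrichment", {
    population <- rownames(gene_expr$values)[
      apply(gene_expr$values, 1, max) >= config$min_fpkm]
    study <- intersect(unique(targets_res$pairs$gene_id), population)
    enrich(study, inputs$term_map, population, alpha = config$enrich_alpha)
  }) else NULL

  net <- run_stage("network", {
    kinds <- df0(id = c(lnc_ids, rownames(gene_expr$values)),
                 kind = c(rep("lncRNA", length(lnc_ids)),
                          rep("mRNA", nrow(gene_expr$values))))
    if (!is.null(inputs$kinds)) {
      m <- match(inputs$kinds$id, kinds$id)
      kinds$kind[m[!is.na(m)]] <- inputs$kinds$kind[!is.na(m)]
    }
    cmp_de <- rbind(de$lnc[[config$network_comparison]],
                    de$gene[[config$network_comparison]])
    network <- build_network(targets_res$pairs, cmp_de, kinds,
                             ppi_edges = inputs$ppi)
    tf_sel <- if (!is.null(inputs$kinds))
      select_tf_candidates(gene_expr, de$gene[[config$network_comparison]],
                           kinds, min_fold = config$tf_fold_change,
                           min_fpkm = config$tf_min_fpkm)
      else character(0)
    list(network = network, tf_selected = tf_sel, de_table = cmp_de)
  })

  heat <- run_stage("heatmap_order", {
    de_lnc_union <- unique(unlist(de_sets, use.names = FALSE))
    de_gene_union <- unique(unlist(lapply(de$gene, function(d)
      d$feature_id[d$is_de]), use.names = FALSE))
    feats <- c(de_lnc_union, de_gene_union)
    if (length(feats) >= 2L) {
      mat <- log2(rbind(de$lnc_expr$values[de_lnc_union, , drop = FALSE],
                        gene_expr$values[de_gene_union, , drop = FALSE]) + 1)
      ord <- hierarchical_order(mat)
      list(order = ord, mat = mat[ord$row_order, ord$col_order, drop = FALSE])
    } else NULL
  })

  qpcr_rel <- if (!is.null(inputs$ct)) run_stage("qpcr", {
    tgts <- setdiff(unique(inputs$ct$gene), config$reference_gene)
    calib <- expr$design$sample_id[1]
    do.call(rbind, lapply(tgts, function(g) {
      out <- ddct_relative_expression(inputs$ct, g, config$reference_gene,
                                      calib)
      cbind(df0(gene = rep(g, nrow(out))), out)
    }))
  }) else NULL

  # --- write the run directory -------------------------------------
  w <- function(df, name) write_tsv(df, file.path(out_dir, name))
  w(ident$lncrnas, "lncrna_records.tsv")
  w(ident$rejects, "rejects.tsv")
  for (cmp in config$comparisons) {
    w(de$lnc[[cmp]], sprintf("de_lncrna_%s.tsv", cmp))
    w(de$gene[[cmp]], sprintf("de_gene_%s.tsv", cmp))
  }
  w(venn$regions, "venn.tsv")
  writeLines(ident$lncrnas$transcript_id[ident$lncrnas$highly_expressed],
             file.path(out_dir, "highly_expressed.txt"))
  w(targets_res$cis, "cis_pairs.tsv")
  w(targets_res$coexpr, "coexpr_pairs.tsv")
  w(targets_res$pairs, "target_pairs.tsv")
  if (!is.null(enr)) w(enr, "enrichment.tsv")
  w(net$network$nodes, "nodes.tsv")
  w(net$network$edges, "edges.tsv")
  writeLines(sprintf("%s\t%s\t%s", net$network$edges$node_a,
                     net$network$edges$relation, net$network$edges$node_b),
             file.path(out_dir, "network.sif"))
  if (!is.null(heat)) {
    hm <- df0(feature_id = rownames(heat$mat))
    hm <- cbind(hm, as.data.frame(heat$mat, check.names = FALSE))
    w(hm, "heatmap_matrix.tsv")
  }
  if (!is.null(qpcr_rel)) w(qpcr_rel, "qpcr_relative.tsv")

  summary <- list(
    package_version = as.character(utils::packageVersion("lncripe")),
    config = unclass(config),
    counts = c(
      list(input_transcripts = nrow(ts$transcripts),
           retained_lncrnas = nrow(ident$lncrnas),
           rejected_transcripts = nrow(ident$rejects),
           intergenic_lncrnas = sum(ident$lncrnas$lnc_class == "intergenic"),
           antisense_lncrnas = sum(ident$lncrnas$lnc_class == "antisense"),
           highly_expressed_lncrnas = sum(ident$lncrnas$highly_expressed)),
      stats::setNames(lapply(de$lnc, function(d) sum(d$is_de)),
                      paste0("de_lncrnas_", names(de$lnc))),
      list(de_venn_union = venn$union_size,
           de_all_comparisons = length(venn$intersection_ids),
           cis_pairs = nrow(targets_res$cis),
           coexpr_pairs = nrow(targets_res$coexpr),
           target_pairs_cis_only = unname(targets_res$counts["cis_only"]),
           target_pairs_coexpr_trans = unname(targets_res$counts["coexpr_trans"]),
           target_pairs_coexpr_cis_both =
             unname(targets_res$counts["coexpr_cis_both"]),
           enriched_terms = if (!is.null(enr)) sum(enr$significant) else NA,
           network_nodes = nrow(net$network$nodes),
           network_edges = nrow(net$network$edges),
           tf_selected = length(net$tf_selected))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  res <- list(lncrnas = ident$lncrnas, rejects = ident$rejects,
              de_lncrna = de$lnc, de_gene = de$gene, venn = venn,
              cis = targets_res$cis, coexpr = targets_res$coexpr,
              target_pairs = targets_res$pairs,
              target_counts = targets_res$counts, enrichment = enr,
              network = net$network, tf_selected = net$tf_selected,
              heatmap = heat, qpcr = qpcr_rel, gene_expr = gene_expr,
              lnc_expr = de$lnc_expr, summary = summary, out_dir = out_dir)
  class(res) <- "lnc_run"
  invisible(res)
}

#' @export
print.lnc_run <- function(x, ...) {
  cts <- x$summary$counts
  cat("lncRNA pipeline run\n")
  cat(sprintf("  transcripts in: %d; lncRNAs: %d (%d intergenic, %d antisense)\n",
              cts$input_transcripts, cts$retained_lncrnas,
              cts$intergenic_lncrnas, cts$antisense_lncrnas))
  de_names <- grep("^de_lncrnas_", names(cts), value = TRUE)
  cat(sprintf("  DE lncRNAs: %s\n",
              paste(sprintf("%s %d", sub("de_lncrnas_", "", de_names),
                            unlist(cts[de_names])), collapse = ", ")))
  cat(sprintf("  target pairs: %d cis-only, %d trans, %d both; %s enriched terms\n",
              cts$target_pairs_cis_only, cts$target_pairs_coexpr_trans,
              cts$target_pairs_coexpr_cis_both,
              as.character(cts$enriched_terms)))
  cat(sprintf("  network: %d nodes, %d edges; outputs in %s\n",
              cts$network_nodes, cts$network_edges, x$out_dir))
  invisible(x)
}
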