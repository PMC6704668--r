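# Synthetic-data generator. Plants recoverable structure emulating the
# four-stage, three-replicate climacteric ripening design: coding genes,
# intergenic/antisense lncRNAs, decoy transcripts that each violate one
# candidate filter, cis pairs at known distances, trans pairs sharing a
# latent stage profile, two-block differential expression, and enriched
# terms. Expression is simulated directly on the FPKM scale (lognormal);
# read-level simulation is out of scope because the analysis consumes
# FPKM.

#' Simulation configuration
#'
#' Defaults encode the study design the pipeline targets: 4 ordered
#' stages (growing, ripening, climacteric, post-climacteric) x 3
#' replicates, a mixture of coding and noncoding transcripts with 14.3%
#' of true lncRNAs antisense, planted cis pairs inside the 100-kb
#' window, zero-noise planted trans pairs, a two-block (G,R vs C,P)
#' differential-expression structure with log2 effect size 3, and a few
#' planted enriched terms.
#'
#' @param seed Integer seed; one global seed drives independent
#'   sub-streams for layout, sequences, expression, terms and qPCR.
#' @param n_chromosomes,chrom_length Genome shape (bp per chromosome).
#' @param n_coding_genes Number of protein-coding genes.
#' @param frac_multi_transcript Fraction of coding genes given a second
#'   isoform (exercises gene-level FPKM summing).
#' @param n_lncrna_true Number of true lncRNAs.
#' @param frac_antisense Fraction of true lncRNAs placed with exonic
#'   opposite-strand overlap of a coding gene.
#' @param n_coding_decoys Transcripts passing all candidate filters but
#'   carrying a long ORF (must be vetoed as coding).
#' @param n_short_decoys,n_monoexon_decoys,n_lowexpr_decoys Decoys
#'   violating exactly the length, exon-count or expression filter.
#' @param stages Ordered stage labels (default G, R, C, P).
#' @param replicates_per_stage Biological replicates per stage.
#' @param n_planted_cis Intergenic lncRNAs placed at a known gap from a
#'   coding gene.
#' @param cis_distance_range bp interval the planted gaps are drawn
#'   from (within the 100-kb window by default).
#' @param n_planted_trans lncRNA-gene pairs sharing a latent stage
#'   profile; partner genes sit on a different chromosome so the pairs
#'   are genuinely trans.
#' @param trans_noise_sd Log2-scale noise added on top of the shared
#'   profile (0 gives correlation exactly +/-1).
#' @param n_planted_de,n_planted_de_genes True lncRNAs / coding genes
#'   given the two-block stage shift.
#' @param de_log2fc Planted log2 fold change between the stage blocks.
#' @param de_stage_jitter_sd Per-feature, per-stage log2 variability
#'   added to planted DE features so they share the block trend without
#'   being copies of one profile (as real co-regulated genes do).
#' @param rep_noise_sd Log2-scale replicate noise for unplanted
#'   features.
#' @param n_terms,n_enriched_terms Term universe size and number of
#'   terms over-represented among planted target genes.
#' @param terms_per_gene Background terms drawn per gene.
#' @param baseline_log2_expression_mean,baseline_log2_expression_sd
#'   Lognormal baseline parameters (log2 scale).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length = 8e6,
                       n_coding_genes = 150L,
                       frac_multi_transcript = 0.15,
                       n_lncrna_true = 70L,
                       frac_antisense = 0.143,
                       n_coding_decoys = 10L,
                       n_short_decoys = 8L,
                       n_monoexon_decoys = 8L,
                       n_lowexpr_decoys = 8L,
                       stages = c("G", "R", "C", "P"),
                       replicates_per_stage = 3L,
                       n_planted_cis = 15L,
                       cis_distance_range = c(5000L, 95000L),
                       n_planted_trans = 15L,
                       trans_noise_sd = 0,
                       n_planted_de = 30L,
                       n_planted_de_genes = 30L,
                       de_log2fc = 3,
                       de_stage_jitter_sd = 0.75,
                       rep_noise_sd = 0.2,
                       n_terms = 40L,
                       n_enriched_terms = 3L,
                       terms_per_gene = 3L,
                       baseline_log2_expression_mean = 3,
                       baseline_log2_expression_sd = 1.5) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_coding_genes = as.integer(n_coding_genes),
              frac_multi_transcript = frac_multi_transcript,
              n_lncrna_true = as.integer(n_lncrna_true),
              frac_antisense = frac_antisense,
              n_coding_decoys = as.integer(n_coding_decoys),
              n_short_decoys = as.integer(n_short_decoys),
              n_monoexon_decoys = as.integer(n_monoexon_decoys),
              n_lowexpr_decoys = as.integer(n_lowexpr_decoys),
              stages = as.character(stages),
              replicates_per_stage = as.integer(replicates_per_stage),
              n_planted_cis = as.integer(n_planted_cis),
              cis_distance_range = as.integer(cis_distance_range),
              n_planted_trans = as.integer(n_planted_trans),
              trans_noise_sd = trans_noise_sd,
              n_planted_de = as.integer(n_planted_de),
              n_planted_de_genes = as.integer(n_planted_de_genes),
              de_log2fc = de_log2fc,
              de_stage_jitter_sd = de_stage_jitter_sd,
              rep_noise_sd = rep_noise_sd,
              n_terms = as.integer(n_terms),
              n_enriched_terms = as.integer(n_enriched_terms),
              terms_per_gene = as.integer(terms_per_gene),
              baseline_log2_expression_mean = baseline_log2_expression_mean,
              baseline_log2_expression_sd = baseline_log2_expression_sd)
  counts <- c("n_chromosomes", "n_coding_genes", "n_lncrna_true",
              "n_coding_decoys", "n_short_decoys", "n_monoexon_decoys",
              "n_lowexpr_decoys", "replicates_per_stage", "n_planted_cis",
              "n_planted_trans", "n_planted_de", "n_planted_de_genes",
              "n_terms", "n_enriched_terms", "terms_per_gene")
  for (f in counts) if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
    lnc_stop("%s must be a non-negative count", f)
  if (cfg$n_chromosomes < 1L) lnc_stop("need at least one chromosome")
  if (cfg$frac_antisense < 0 || cfg$frac_antisense > 1)
    lnc_stop("frac_antisense must lie in [0, 1]")
  if (cfg$frac_multi_transcript < 0 || cfg$frac_multi_transcript > 1)
    lnc_stop("frac_multi_transcript must lie in [0, 1]")
  if (anyDuplicated(cfg$stages) || length(cfg$stages) < 2L)
    lnc_stop("stages must be >= 2 distinct labels")
  if (length(cfg$cis_distance_range) != 2L ||
      cfg$cis_distance_range[1] < 0L ||
      cfg$cis_distance_range[1] > cfg$cis_distance_range[2])
    lnc_stop("cis_distance_range must be an ordered non-negative interval")
  if (cfg$n_enriched_terms > cfg$n_terms)
    lnc_stop("n_enriched_terms (%d) exceeds n_terms (%d)",
             cfg$n_enriched_terms, cfg$n_terms)
  n_anti <- round(cfg$frac_antisense * cfg$n_lncrna_true)
  if (n_anti > cfg$n_coding_genes)
    lnc_stop("not enough coding genes to host %d antisense lncRNAs", n_anti)
  if (cfg$n_planted_cis > cfg$n_lncrna_true - n_anti)
    lnc_stop("n_planted_cis exceeds the number of intergenic lncRNAs")
  if (n_anti + cfg$n_planted_cis > cfg$n_coding_genes)
    lnc_stop("antisense hosts plus cis anchors exceed n_coding_genes")
  if (cfg$n_planted_trans + cfg$n_planted_de > cfg$n_lncrna_true)
    lnc_stop("trans and DE plantings exceed n_lncrna_true (they must be disjoint)")
  if (cfg$trans_noise_sd < 0 || cfg$rep_noise_sd < 0 ||
      cfg$de_stage_jitter_sd < 0)
    lnc_stop("noise standard deviations must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: seed %d; %d chromosomes x %.2g bp; ",
                     "%d coding genes, %d lncRNAs (%.1f%% antisense); ",
                     "%s x %d replicates\n"),
              x$seed, x$n_chromosomes, x$chrom_length, x$n_coding_genes,
              x$n_lncrna_true, 100 * x$frac_antisense,
              paste(x$stages, collapse = "/"), x$replicates_per_stage))
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  STOP_CODONS)

# Sequence containing one long ORF (ATG..stop) covering ~orf_frac of L.
coding_sequence <- function(L, orf_frac = 0.8) {
  orf_len <- max(306L, 3L * (as.integer(orf_frac * L) %/% 3L))
  if (orf_len > L - 6L) orf_len <- 3L * ((L - 6L) %/% 3L)
  lead <- (L - orf_len) %/% 2L
  body <- paste(sample(NONSTOP_CODONS, orf_len / 3L - 2L, replace = TRUE),
                collapse = "")
  paste0(random_dna(lead), "ATG", body, sample(STOP_CODONS, 1L),
         random_dna(L - lead - orf_len))
}

# Random sequence guaranteed below both coding-verdict thresholds: any
# ORF at or above the limits loses its start codon until none remains.
noncoding_sequence <- function(L, orf_min_nt = 300, orf_min_coverage = 0.35) {
  s <- random_dna(L)
  limit <- min(orf_min_nt, ceiling(orf_min_coverage * L))
  for (i in 1:200) {
    o <- longest_orf(s)
    if (o$length_nt < limit) return(s)
    substr(s, o$start, o$start) <- "C"
  }
  lnc_stop("could not generate a noncoding sequence of length %d", L)
}

# Relative exon layout: list(starts, ends, width, spliced)
exon_layout <- function(n_exons, exon_lens, intron_lens) {
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- 1L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i] - 1L
    pos <- ends[i] + (if (i < n_exons) intron_lens[i] else 0L) + 1L
  }
  list(starts = starts, ends = ends, width = ends[n_exons],
       spliced = sum(exon_lens))
}

#' Generate the synthetic genome annotation
#'
#' Places coding genes (multi-exon, long-ORF transcripts), true lncRNAs
#' (>= 200 bp spliced, >= 2 exons, no qualifying ORF; antisense ones
#' with >= 1 bp exonic overlap on the strand opposite a coding gene,
#' intergenic ones overlapping no gene), and decoy transcripts each
#' violating exactly one rule (too short, mono-exonic, long ORF, or —
#' at expression time — below the FPKM filter) on the simulated
#' chromosomes, then records the ground truth of every planting.
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (a [transcript_set()]), `sequences`
#'   (named spliced sequences) and `truth` (ground-truth list: lncRNA
#'   ids and classes, planted cis pairs with distances, planted trans
#'   pairs with signs, planted DE features and their stage blocks,
#'   planted enriched terms placeholder, decoy reasons, tx2gene map).
#' @export
generate_annotation <- function(config) {
  seeds <- derive_seeds(config$seed, 5L)
  with_seed(seeds[1], generate_annotation_impl(config))
}

generate_annotation_impl <- function(config) {
  n_anti <- round(config$frac_antisense * config$n_lncrna_true)
  n_inter <- config$n_lncrna_true - n_anti
  lnc_ids <- sprintf("LNC_%06d", seq_len(config$n_lncrna_true))
  gene_ids <- sprintf("MELO_G%05d", seq_len(config$n_coding_genes))

  lnc_shuffled <- sample(lnc_ids)
  anti_ids <- if (n_anti) lnc_shuffled[seq_len(n_anti)] else character(0)
  inter_ids <- setdiff(lnc_shuffled, anti_ids)
  cis_lnc <- if (config$n_planted_cis) sample(inter_ids, config$n_planted_cis)
             else character(0)

  gene_shuffled <- sample(gene_ids)
  anti_host <- if (n_anti) gene_shuffled[seq_len(n_anti)] else character(0)
  cis_gene <- if (config$n_planted_cis)
    gene_shuffled[n_anti + seq_len(config$n_planted_cis)] else character(0)
  names(anti_host) <- anti_ids
  cis_map <- df0(lncrna_id = cis_lnc, gene_id = cis_gene,
                 distance = if (length(cis_lnc))
                   as.integer(round(stats::runif(length(cis_lnc),
                                                 config$cis_distance_range[1],
                                                 config$cis_distance_range[2])))
                 else integer(0))

  # units: a coding gene (with attached antisense / cis lncRNA), a free
  # intergenic lncRNA, or a decoy
  units <- list()
  for (g in gene_ids) {
    attached_anti <- anti_ids[which(anti_host == g)]
    attached_cis <- cis_map[cis_map$gene_id == g, , drop = FALSE]
    units[[length(units) + 1L]] <- list(type = "gene", gene_id = g,
                                        anti = attached_anti,
                                        cis = attached_cis)
  }
  for (l in setdiff(inter_ids, cis_lnc))
    units[[length(units) + 1L]] <- list(type = "lnc", lnc_id = l)
  decoys <- df0(
    transcript_id = c(sprintf("DECOY_SHORT_%03d", seq_len(config$n_short_decoys)),
                      sprintf("DECOY_MONO_%03d", seq_len(config$n_monoexon_decoys)),
                      sprintf("DECOY_LOWEXPR_%03d", seq_len(config$n_lowexpr_decoys)),
                      sprintf("DECOY_ORF_%03d", seq_len(config$n_coding_decoys))),
    reason = c(rep("length", config$n_short_decoys),
               rep("exons", config$n_monoexon_decoys),
               rep("fpkm", config$n_lowexpr_decoys),
               rep("coding", config$n_coding_decoys)))
  for (i in seq_len(nrow(decoys)))
    units[[length(units) + 1L]] <- list(type = "decoy",
                                        id = decoys$transcript_id[i],
                                        reason = decoys$reason[i])

  units <- units[sample(length(units))]
  unit_chrom <- rep_len(seq_len(config$n_chromosomes), length(units))

  exon_rows <- list()
  seqs <- character(0)
  multi_tx_genes <- character(0)
  add_exons <- function(tx, gene, chrom, strand, starts, ends, biotype) {
    exon_rows[[length(exon_rows) + 1L]] <<-
      df0(transcript_id = tx, gene_id = gene, chrom = chrom, strand = strand,
          start = starts, end = ends, biotype = biotype)
  }

  cursor <- rep(10000, config$n_chromosomes)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))

  lnc_structure <- function() {
    n_ex <- sample(2:3, 1L)
    exon_layout(n_ex, sample(150:500, n_ex, replace = TRUE),
                sample(100:800, max(n_ex - 1L, 1L), replace = TRUE))
  }

  place_lnc <- function(lnc_id, chrom_i, at, strand) {
    lay <- lnc_structure()
    add_exons(lnc_id, paste0(lnc_id, ".g"), chrom_names[chrom_i], strand,
              at + lay$starts - 1L, at + lay$ends - 1L, "unknown")
    seqs[lnc_id] <<- noncoding_sequence(lay$spliced)
    at + lay$width - 1L
  }

  for (u in seq_along(units)) {
    unit <- units[[u]]
    ci <- unit_chrom[u]
    at <- as.integer(cursor[ci])
    end_at <- at
    if (unit$type == "gene") {
      n_ex <- sample(2:5, 1L)
      lay <- exon_layout(n_ex, sample(250:800, n_ex, replace = TRUE),
                         sample(200:2000, max(n_ex - 1L, 1L), replace = TRUE))
      strand <- sample(c("+", "-"), 1L)
      tx1 <- paste0(unit$gene_id, ".t1")
      add_exons(tx1, unit$gene_id, chrom_names[ci], strand,
                at + lay$starts - 1L, at + lay$ends - 1L, "coding")
      seqs[tx1] <- coding_sequence(lay$spliced)
      end_at <- at + lay$width - 1L
      if (n_ex >= 3L && stats::runif(1) < config$frac_multi_transcript) {
        tx2 <- paste0(unit$gene_id, ".t2")
        keep <- seq_len(n_ex - 1L)
        add_exons(tx2, unit$gene_id, chrom_names[ci], strand,
                  at + lay$starts[keep] - 1L, at + lay$ends[keep] - 1L,
                  "coding")
        seqs[tx2] <- coding_sequence(sum(lay$ends[keep] - lay$starts[keep] + 1L))
        multi_tx_genes <- c(multi_tx_genes, unit$gene_id)
      }
      if (length(unit$anti)) {
        # first lncRNA exon starts inside the gene's first exon
        # (opposite strand), second exon beyond the gene end
        a_id <- unit$anti[1]
        e1s <- at + sample.int(200L, 1L) - 1L
        e1e <- e1s + sample(150:400, 1L)
        e2s <- end_at + sample(200:600, 1L)
        e2e <- e2s + sample(150:400, 1L)
        add_exons(a_id, paste0(a_id, ".g"), chrom_names[ci],
                  if (strand == "+") "-" else "+",
                  c(e1s, e2s), c(e1e, e2e), "unknown")
        seqs[a_id] <- noncoding_sequence((e1e - e1s + 1L) + (e2e - e2s + 1L))
        end_at <- max(end_at, e2e)
      }
      if (nrow(unit$cis)) {
        for (j in seq_len(nrow(unit$cis))) {
          l_at <- end_at + unit$cis$distance[j] + 1L
          end_at <- place_lnc(unit$cis$lncrna_id[j], ci, l_at,
                              sample(c("+", "-"), 1L))
        }
      }
    } else if (unit$type == "lnc") {
      end_at <- place_lnc(unit$lnc_id, ci, at, sample(c("+", "-"), 1L))
    } else {
      strand <- sample(c("+", "-"), 1L)
      gid <- paste0(unit$id, ".g")
      if (unit$reason == "length") {
        lay <- exon_layout(2L, c(70L, 80L), sample(100:400, 1L))
        add_exons(unit$id, gid, chrom_names[ci], strand,
                  at + lay$starts - 1L, at + lay$ends - 1L, "unknown")
        seqs[unit$id] <- noncoding_sequence(lay$spliced)
      } else if (unit$reason == "exons") {
        lay <- exon_layout(1L, 400L, integer(0))
        add_exons(unit$id, gid, chrom_names[ci], strand,
                  at, at + 399L, "unknown")
        seqs[unit$id] <- noncoding_sequence(400L)
      } else if (unit$reason == "fpkm") {
        lay <- exon_layout(2L, c(200L, 300L), sample(100:400, 1L))
        add_exons(unit$id, gid, chrom_names[ci], strand,
                  at + lay$starts - 1L, at + lay$ends - 1L, "unknown")
        seqs[unit$id] <- noncoding_sequence(lay$spliced)
      } else {  # long ORF: passes every candidate filter, vetoed as coding
        lay <- exon_layout(2L, c(500L, 520L), sample(100:400, 1L))
        add_exons(unit$id, gid, chrom_names[ci], strand,
                  at + lay$starts - 1L, at + lay$ends - 1L, "unknown")
        seqs[unit$id] <- coding_sequence(lay$spliced)
      }
      end_at <- at + lay$width - 1L
    }
    cursor[ci] <- end_at + sample(5000:20000, 1L)
    if (cursor[ci] > config$chrom_length - 10000)
      lnc_stop(paste0("chromosome %s overflows at %.0f bp placing unit %d; ",
                      "increase chrom_length or reduce feature counts"),
               chrom_names[ci], cursor[ci], u)
  }

  ann <- transcript_set(do.call(rbind, exon_rows))
  tx <- ann$transcripts
  lnc_class <- stats::setNames(
    ifelse(lnc_ids %in% anti_ids, "antisense", "intergenic"), lnc_ids)

  # trans partners: single-isoform coding genes on a different
  # chromosome than the lncRNA
  lnc_pool <- sample(lnc_ids)
  trans_lnc <- if (config$n_planted_trans)
    lnc_pool[seq_len(config$n_planted_trans)] else character(0)
  de_lnc <- if (config$n_planted_de)
    lnc_pool[config$n_planted_trans + seq_len(config$n_planted_de)]
    else character(0)
  gene_chrom <- stats::setNames(
    tx$chrom[match(paste0(gene_ids, ".t1"), tx$transcript_id)], gene_ids)
  lnc_chrom <- stats::setNames(
    tx$chrom[match(lnc_ids, tx$transcript_id)], lnc_ids)
  eligible <- setdiff(gene_ids, multi_tx_genes)
  trans_gene <- character(length(trans_lnc))
  taken <- character(0)
  for (i in seq_along(trans_lnc)) {
    cand <- setdiff(eligible[gene_chrom[eligible] != lnc_chrom[trans_lnc[i]]],
                    taken)
    if (!length(cand))
      lnc_stop("cannot find a distinct-chromosome trans partner gene; need n_chromosomes >= 2")
    trans_gene[i] <- sample(cand, 1L)
    taken <- c(taken, trans_gene[i])
  }
  trans_pairs <- df0(lncrna_id = trans_lnc, gene_id = trans_gene,
                     sign = if (length(trans_lnc))
                       sample(c("positive", "negative"), length(trans_lnc),
                              replace = TRUE) else character(0))
  de_genes <- if (config$n_planted_de_genes)
    sample(setdiff(gene_ids, trans_gene), config$n_planted_de_genes)
    else character(0)

  n_st <- length(config$stages)
  block2 <- config$stages[(n_st %/% 2 + 1):n_st]
  de_feat <- c(de_lnc, de_genes)
  planted_de <- df0(
    feature_id = de_feat,
    feature_type = c(rep("lncRNA", length(de_lnc)),
                     rep("gene", length(de_genes))),
    direction = if (length(de_feat))
      sample(c(1, -1), length(de_feat), replace = TRUE) else numeric(0))

  truth <- list(
    true_lncrna_ids = lnc_ids,
    true_class = lnc_class,
    planted_cis_pairs = cis_map,
    planted_trans_pairs = trans_pairs,
    planted_de = planted_de,
    de_block_stages = block2,
    planted_enriched_terms = character(0),  # filled by generate_term_annotation
    decoys = decoys,
    coding_gene_ids = gene_ids,
    multi_transcript_genes = multi_tx_genes,
    tx2gene = df0(transcript_id = tx$transcript_id, gene_id = tx$gene_id))
  list(annotation = ann, sequences = seqs, truth = truth)
}

#' Generate the synthetic expression matrix
#'
#' Lognormal baseline expression on the FPKM scale with log2-normal
#' replicate noise; planted DE features are shifted by `de_log2fc`
#' between the two stage blocks; planted trans pairs share a latent
#' per-stage profile with additive log2 noise `trans_noise_sd`
#' (negative pairs are an exactly affine decreasing transform of their
#' partner, so zero noise gives r = -1 on the FPKM scale).
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_annotation()].
#' @return Transcript-level [expression_matrix()] with the
#'   stage/replicate design.
#' @export
generate_expression <- function(config, truth) {
  seeds <- derive_seeds(config$seed, 5L)
  with_seed(seeds[2], generate_expression_impl(config, truth))
}

generate_expression_impl <- function(config, truth) {
  tx2gene <- truth$tx2gene
  ids <- tx2gene$transcript_id
  known <- c(ids, truth$coding_gene_ids)
  for (f in c(truth$planted_trans_pairs$lncrna_id,
              truth$planted_trans_pairs$gene_id,
              truth$planted_de$feature_id))
    if (!f %in% known) lnc_stop("ground truth names unknown feature '%s'", f)

  stages <- config$stages
  reps <- config$replicates_per_stage
  design <- df0(sample_id = paste0(rep(stages, each = reps), seq_len(reps)),
                stage = rep(stages, each = reps),
                replicate = rep(seq_len(reps), length(stages)))
  ns <- nrow(design)
  stage_of <- design$stage

  base <- stats::rnorm(length(ids), config$baseline_log2_expression_mean,
                       config$baseline_log2_expression_sd)
  base <- pmax(base, 1)  # keep genuine features above the FPKM filter
  names(base) <- ids
  lowexpr <- truth$decoys$transcript_id[truth$decoys$reason == "fpkm"]
  base[lowexpr] <- log2(0.1)

  shift <- matrix(0, length(ids), ns, dimnames = list(ids, design$sample_id))
  de <- truth$planted_de
  for (i in seq_len(nrow(de))) {
    f <- de$feature_id[i]
    rows <- if (de$feature_type[i] == "gene")
      tx2gene$transcript_id[tx2gene$gene_id == f] else f
    jitter <- stats::rnorm(length(stages), 0, config$de_stage_jitter_sd)
    names(jitter) <- stages
    for (r in rows) {
      shift[r, ] <- jitter[stage_of]
      shift[r, stage_of %in% truth$de_block_stages] <-
        shift[r, stage_of %in% truth$de_block_stages] +
        de$direction[i] * config$de_log2fc
    }
  }

  eps <- matrix(stats::rnorm(length(ids) * ns, 0, config$rep_noise_sd),
                length(ids), ns)
  vals <- 2^(base + shift + eps)
  dimnames(vals) <- list(ids, design$sample_id)

  tp <- truth$planted_trans_pairs
  for (i in seq_len(nrow(tp))) {
    lnc <- tp$lncrna_id[i]
    gene_tx <- tx2gene$transcript_id[tx2gene$gene_id == tp$gene_id[i]]
    latent <- stats::rnorm(length(stages), 0, 1.5)
    names(latent) <- stages
    u <- 2^(base[lnc] + latent[stage_of])
    vals[lnc, ] <- u * 2^stats::rnorm(ns, 0, config$trans_noise_sd)
    if (tp$sign[i] == "positive") {
      g <- 2^(base[gene_tx[1]] + latent[stage_of])
    } else {
      w <- max(u) * 1.05 - u
      g <- (2^base[gene_tx[1]] / mean(w)) * w
    }
    vals[gene_tx[1], ] <- g * 2^stats::rnorm(ns, 0, config$trans_noise_sd)
  }

  expression_matrix(vals, design)
}

#' Generate the gene-to-term annotation table
#'
#' Background terms are assigned uniformly (`terms_per_gene` draws per
#' gene); each planted enriched term is additionally given to ~70% of
#' the planted target genes (the genes the planted cis and trans pairs
#' point at) and to a 5% background rate elsewhere, making it
#' recoverably over-represented in the target-gene study set.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_annotation()]; the planted
#'   enriched term ids are recorded into `truth` by the caller via the
#'   `planted_enriched_terms` attribute of the result.
#' @return data.frame `gene_id`, `term_id`, `term_name` with attribute
#'   `planted_enriched_terms`.
#' @export
generate_term_annotation <- function(config, truth) {
  seeds <- derive_seeds(config$seed, 5L)
  with_seed(seeds[3], {
    genes <- truth$coding_gene_ids
    n_bg <- config$n_terms - config$n_enriched_terms
    bg_terms <- sprintf("TERM_B%03d", seq_len(n_bg))
    en_terms <- sprintf("TERM_E%02d", seq_len(config$n_enriched_terms))
    rows <- list()
    if (n_bg > 0 && config$terms_per_gene > 0) {
      for (g in genes)
        rows[[length(rows) + 1L]] <-
          df0(gene_id = g,
              term_id = sample(bg_terms, min(config$terms_per_gene, n_bg)))
    }
    targets <- unique(c(truth$planted_cis_pairs$gene_id,
                        truth$planted_trans_pairs$gene_id))
    for (tm in en_terms) {
      hit <- if (length(targets))
        sample(targets, ceiling(0.7 * length(targets))) else character(0)
      others <- setdiff(genes, targets)
      bghit <- others[stats::runif(length(others)) < 0.05]
      ids <- unique(c(hit, bghit))
      if (length(ids))
        rows[[length(rows) + 1L]] <- df0(gene_id = ids, term_id = tm)
    }
    if (!length(rows)) {
      tab <- df0(gene_id = character(0), term_id = character(0),
                 term_name = character(0))
      attr(tab, "planted_enriched_terms") <- en_terms
      return(tab)
    }
    tab <- unique(do.call(rbind, rows))
    tab <- tab[order(tab$gene_id, tab$term_id), , drop = FALSE]
    tab$term_name <- ifelse(grepl("^TERM_E", tab$term_id),
                            sub("TERM_E", "planted process ", tab$term_id),
                            sub("TERM_B", "background process ", tab$term_id))
    rownames(tab) <- NULL
    attr(tab, "planted_enriched_terms") <- en_terms
    tab
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates validation assays for up to `n_targets` lncRNAs: target Ct
#' values decrease with log2 expression; the reference gene (GAPDH) is
#' stable across samples.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_annotation()].
#' @param expr Expression matrix from [generate_expression()].
#' @param n_targets Number of assayed lncRNAs (default 10).
#' @return data.frame `gene`, `sample`, `ct` including GAPDH rows.
#' @export
generate_qpcr <- function(config, truth, expr, n_targets = 10L) {
  seeds <- derive_seeds(config$seed, 5L)
  with_seed(seeds[4], {
    pool <- truth$planted_de$feature_id[truth$planted_de$feature_type == "lncRNA"]
    if (length(pool) < n_targets)
      pool <- unique(c(pool, truth$true_lncrna_ids))
    targets <- utils::head(pool, n_targets)
    samples <- colnames(expr$values)
    rows <- list(df0(gene = "GAPDH", sample = samples,
                     ct = 18 + stats::rnorm(length(samples), 0, 0.1)))
    for (g in targets)
      rows[[length(rows) + 1L]] <-
        df0(gene = g, sample = samples,
            ct = 28 - log2(expr$values[g, ] + 1) +
              stats::rnorm(length(samples), 0, 0.15))
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    ct
  })
}

#' Simulate a complete study dataset on disk
#'
#' Runs every generator stage and writes the standard input files:
#' `annotation.gtf`, `transcripts.fa`, `samples.tsv`, `expression.tsv`,
#' `terms.tsv`, `ppi.tsv`, `qpcr_ct.tsv` and `truth.json`. Identical
#' seed and configuration give byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisible list with the generated objects (`annotation`,
#'   `sequences`, `truth`, `expression`, `terms`, `ppi`, `qpcr`) and
#'   `paths` to the written files.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  truth <- ann$truth
  expr <- generate_expression(config, truth)
  terms <- generate_term_annotation(config, truth)
  truth$planted_enriched_terms <- attr(terms, "planted_enriched_terms")
  qpcr <- generate_qpcr(config, truth, expr)

  seeds <- derive_seeds(config$seed, 5L)
  ppi <- with_seed(seeds[5], {
    targets <- unique(c(truth$planted_cis_pairs$gene_id,
                        truth$planted_trans_pairs$gene_id))
    if (length(targets) >= 2L) {
      n_edges <- min(30L, choose(length(targets), 2L))
      pairs <- t(replicate(n_edges, sample(targets, 2L)))
      unique(df0(node_a = pmin(pairs[, 1], pairs[, 2]),
                 node_b = pmax(pairs[, 1], pairs[, 2])))
    } else df0(node_a = character(0), node_b = character(0))
  })

  paths <- list(gtf = file.path(dir, "annotation.gtf"),
                fasta = file.path(dir, "transcripts.fa"),
                samples = file.path(dir, "samples.tsv"),
                expression = file.path(dir, "expression.tsv"),
                terms = file.path(dir, "terms.tsv"),
                ppi = file.path(dir, "ppi.tsv"),
                qpcr = file.path(dir, "qpcr_ct.tsv"),
                truth = file.path(dir, "truth.json"))
  write_gtf(ann$annotation, paths$gtf)
  write_transcript_fasta(ann$sequences, paths$fasta)
  write_tsv(expr$design, paths$samples)
  write_expression(expr, paths$expression)
  write_tsv(terms[, c("gene_id", "term_id", "term_name")], paths$terms)
  write_tsv(ppi, paths$ppi)
  write_tsv(qpcr, paths$qpcr)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(annotation = ann$annotation, sequences = ann$sequences,
                 truth = truth, expression = expr, terms = terms, ppi = ppi,
                 qpcr = qpcr, paths = paths))
}
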