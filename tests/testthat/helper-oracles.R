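# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's index-based code paths: plain loops
# and set algebra only.

# Longest ORF by trying every (ATG, stop) codon pair in every forward
# frame and checking no in-frame stop intervenes.
brute_longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  if (n < 6L) return(best)
  codon_at <- function(p) substr(s, p, p + 2L)
  for (p in seq_len(n - 5L)) {
    if (codon_at(p) != "ATG") next
    q <- p + 3L
    while (q + 2L <= n) {
      if (codon_at(q) %in% stops) {
        best <- max(best, q + 2L - p + 1L)
        break
      }
      q <- q + 3L
    }
  }
  best
}

# O(n^2) interval arithmetic ------------------------------------------

spans_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

brute_gap <- function(chrom1, s1, e1, chrom2, s2, e2) {
  if (chrom1 != chrom2) return(Inf)
  if (spans_overlap(s1, e1, s2, e2)) return(0L)
  if (s2 > e1) s2 - e1 - 1L else s1 - e2 - 1L
}

# All-pairs cis scan over transcript spans vs gene spans (looped per
# lncRNA, the per-gene comparison vectorised; no interval index).
brute_cis <- function(lnc_ts, coding_ts, window) {
  lt <- lnc_ts$transcripts
  gs <- aggregate_gene_spans(coding_ts)
  out <- list()
  for (i in seq_len(nrow(lt))) {
    same <- gs$chrom == lt$chrom[i]
    gap <- pmax(gs$start - lt$end[i] - 1L, lt$start[i] - gs$end - 1L, 0L)
    keep <- same & gap <= window
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = lt$transcript_id[i], gene_id = gs$gene_id[keep],
        distance = as.integer(gap[keep]), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(lncrna_id = character(0),
                                      gene_id = character(0),
                                      distance = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
}

aggregate_gene_spans <- function(ts) {
  ex <- ts$exons
  genes <- unique(ex$gene_id)
  do.call(rbind, lapply(genes, function(g) {
    e <- ex[ex$gene_id == g, ]
    data.frame(gene_id = g, chrom = e$chrom[1], start = min(e$start),
               end = max(e$end), stringsAsFactors = FALSE)
  }))
}

# All-pairs positional classification mirroring the package's stated
# rule: same-strand exonic overlap -> sense_overlap; else opposite-
# strand exonic overlap -> antisense; else span overlap -> genic_overlap;
# else intergenic.
brute_classify <- function(candidates, coding) {
  cand_tx <- candidates$transcripts
  cand_ex <- candidates$exons
  cod_ex <- coding$exons
  gs <- aggregate_gene_spans(coding)
  cls <- character(nrow(cand_tx))
  names(cls) <- cand_tx$transcript_id
  for (id in cand_tx$transcript_id) {
    ce <- cand_ex[cand_ex$transcript_id == id, ]
    sense <- FALSE; anti <- FALSE
    for (i in seq_len(nrow(ce))) {
      hit <- ce$chrom[i] == cod_ex$chrom &
        ce$start[i] <= cod_ex$end & cod_ex$start <= ce$end[i]
      if (any(hit & ce$strand[i] == cod_ex$strand)) sense <- TRUE
      if (any(hit & ce$strand[i] != cod_ex$strand)) anti <- TRUE
    }
    if (sense) { cls[id] <- "sense_overlap"; next }
    if (anti) { cls[id] <- "antisense"; next }
    row <- cand_tx[cand_tx$transcript_id == id, ]
    genic <- any(row$chrom == gs$chrom &
                   row$start <= gs$end & gs$start <= row$end)
    cls[id] <- if (genic) "genic_overlap" else "intergenic"
  }
  cls
}

# Per-element membership tally for Venn regions.
brute_venn_regions <- function(sets) {
  labels <- names(sets)
  universe <- unique(unlist(sets))
  tally <- list()
  for (el in universe) {
    members <- labels[vapply(sets, function(s) el %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    tally[[key]] <- (tally[[key]] %||% 0L) + 1L
  }
  tally
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive hypergeometric upper tail: enumerate every size-n draw
# from a population whose first K items are successes.
brute_hyper <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Naive O(n^3) average-linkage agglomeration; returns the cophenetic
# distance matrix, which identifies the merge tree when heights are
# distinct.
naive_average_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  coph <- matrix(0, n, n)
  cd <- d  # cluster-level average distances
  while (sum(active) > 1L) {
    best <- Inf; bi <- bj <- 0L
    idx <- which(active)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      if (cd[i, j] < best) { best <- cd[i, j]; bi <- i; bj <- j }
    }
    mi <- clusters[[bi]]; mj <- clusters[[bj]]
    coph[mi, mj] <- best; coph[mj, mi] <- best
    merged <- c(mi, mj)
    clusters[[length(clusters) + 1L]] <- merged
    active[c(bi, bj)] <- FALSE
    active <- c(active, TRUE)
    new_cd_row <- numeric(length(clusters))
    for (t in which(active)) {
      if (t == length(clusters)) next
      mt <- clusters[[t]]
      new_cd_row[t] <- mean(d[merged, mt, drop = FALSE])
    }
    cd <- rbind(cbind(cd, 0), 0)
    cd[length(clusters), ] <- new_cd_row
    cd[, length(clusters)] <- new_cd_row
  }
  coph
}

# Breadth-first reachability for the subnetwork oracle.
brute_reachable <- function(edges, seeds, hops) {
  frontier <- seeds
  seen <- seeds
  for (h in seq_len(hops)) {
    if (!length(frontier)) break
    nb <- c(edges$node_b[edges$node_a %in% frontier],
            edges$node_a[edges$node_b %in% frontier])
    frontier <- setdiff(unique(nb), seen)
    seen <- union(seen, frontier)
  }
  seen
}

# Fixture builders ----------------------------------------------------

make_exons <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(transcript_id = r[[1]], gene_id = r[[2]], chrom = r[[3]],
               strand = r[[4]], start = as.integer(r[[5]]),
               end = as.integer(r[[6]]),
               biotype = if (length(r) >= 7) r[[7]] else "unknown",
               stringsAsFactors = FALSE)))
}

make_design <- function(stages = c("G", "R", "C", "P"), reps = 3) {
  data.frame(sample_id = paste0(rep(stages, each = reps), seq_len(reps)),
             stage = rep(stages, each = reps),
             replicate = rep(seq_len(reps), length(stages)),
             stringsAsFactors = FALSE)
}

make_expr <- function(values, design = make_design()) {
  expression_matrix(values, design)
}

# Random transcript set with `n_coding` coding genes and `n_cand`
# candidate features scattered on one chromosome (overlaps allowed).
random_annotation <- function(n_coding, n_cand, chrom_len = 1e6) {
  rows <- list()
  for (i in seq_len(n_coding)) {
    n_ex <- sample(1:3, 1)
    at <- sample.int(chrom_len - 5000L, 1)
    pos <- at
    strand <- sample(c("+", "-"), 1)
    for (e in seq_len(n_ex)) {
      len <- sample(100:600, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = sprintf("cod%03d", i), gene_id = sprintf("g%03d", i),
        chrom = "chr1", strand = strand, start = pos, end = pos + len,
        biotype = "coding", stringsAsFactors = FALSE)
      pos <- pos + len + sample(50:400, 1)
    }
  }
  for (i in seq_len(n_cand)) {
    n_ex <- sample(1:3, 1)
    at <- sample.int(chrom_len - 5000L, 1)
    pos <- at
    strand <- sample(c("+", "-"), 1)
    for (e in seq_len(n_ex)) {
      len <- sample(100:600, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = sprintf("cand%03d", i),
        gene_id = sprintf("candg%03d", i),
        chrom = "chr1", strand = strand, start = pos, end = pos + len,
        biotype = "unknown", stringsAsFactors = FALSE)
      pos <- pos + len + sample(50:400, 1)
    }
  }
  transcript_set(do.call(rbind, rows))
}

small_sim_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2, chrom_length = 4e6,
                   n_coding_genes = 40, n_lncrna_true = 20,
                   frac_antisense = 0.15, n_coding_decoys = 4,
                   n_short_decoys = 3, n_monoexon_decoys = 3,
                   n_lowexpr_decoys = 3, n_planted_cis = 5,
                   n_planted_trans = 5, n_planted_de = 8,
                   n_planted_de_genes = 8, n_terms = 20,
                   n_enriched_terms = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
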