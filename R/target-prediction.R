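# Target prediction: cis by genomic windowing, trans by correlation
# screening, and the partition/intersection of the two evidence groups.

#' Genomic distance and orientation between two spans
#'
#' Distance is the gap in bp between the closest ends of the two genomic
#' spans (0 when they overlap); orientation reports where the gene lies
#' relative to the lncRNA span in strand-agnostic genomic coordinates.
#' Features on different chromosomes are at infinite distance.
#'
#' @param lnc_span,gene_span Lists or one-row data.frames with `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @return List with `distance` (bp, `Inf` across chromosomes) and
#'   `orientation` (`upstream`, `downstream`, `overlapping`, or `NA`
#'   across chromosomes).
#' @export
genomic_distance <- function(lnc_span, gene_span) {
  if (lnc_span$chrom != gene_span$chrom)
    return(list(distance = Inf, orientation = NA_character_))
  if (gene_span$start > lnc_span$end)
    list(distance = as.integer(gene_span$start - lnc_span$end - 1),
         orientation = "downstream")
  else if (gene_span$end < lnc_span$start)
    list(distance = as.integer(lnc_span$start - gene_span$end - 1),
         orientation = "upstream")
  else
    list(distance = 0L, orientation = "overlapping")
}

#' Co-located (cis) lncRNA-gene pairs within a genomic window
#'
#' Emits every same-chromosome (lncRNA, coding gene) pair whose genomic
#' spans lie within `window` bp of each other (gap distance, inclusive
#' at exactly `window`; overlapping spans are at distance 0). The search
#' runs on an interval index, not all pairs.
#'
#' @param lncrnas [transcript_set()] of lncRNA transcripts.
#' @param coding [transcript_set()] of the protein-coding annotation;
#'   gene spans are the min-start..max-end over each gene's exons.
#' @param window Window size in bp (default 100000).
#' @return data.frame with `lncrna_id`, `gene_id`, `distance`,
#'   `orientation`.
#' @export
cis_pairs <- function(lncrnas, coding, window = 100000) {
  sp <- transcript_spans(lncrnas)
  gs <- gene_spans(coding)
  lnc_gr <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  gene_gr <- GenomicRanges::GRanges(gs$chrom, IRanges::IRanges(gs$start, gs$end))
  hits <- GenomicRanges::findOverlaps(lnc_gr, gene_gr, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(lnc_gr[qi], gene_gr[si])
  keep <- !is.na(d) & d <= window
  qi <- qi[keep]; si <- si[keep]; d <- d[keep]
  orient <- rep("overlapping", length(d))
  orient[gs$start[si] > sp$end[qi]] <- "downstream"
  orient[gs$end[si] < sp$start[qi]] <- "upstream"
  out <- df0(lncrna_id = sp$transcript_id[qi], gene_id = gs$gene_id[si],
             distance = as.integer(d), orientation = orient)
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a t-distribution p-value
#'
#' `r` is the sample Pearson correlation; the two-sided p-value comes
#' from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom, with p = 0 at `|r| = 1`. A constant profile makes the
#' correlation undefined: the result carries `ok = FALSE` and a reason
#' instead of raising an error, so screening loops can skip and log.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with `r`, `p`, `ok`, `reason`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) lnc_stop("profiles differ in length (%d vs %d)", n, length(y))
  if (n < 3L) lnc_stop("need n >= 3 samples, got %d", n)
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx <= 0 || sy <= 0)
    return(list(r = NA_real_, p = NA_real_, ok = FALSE,
                reason = "constant_profile"))
  r <- sum(dx * dy) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  p <- if (1 - r^2 <= .Machine$double.eps) 0
       else 2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)
  list(r = r, p = p, ok = TRUE, reason = NA_character_)
}

#' Co-expressed lncRNA-gene pairs by correlation screening
#'
#' Screens every lncRNA x gene profile pair and keeps those with
#' `|r| > r_threshold` and `p < p_threshold` (both strict, matching the
#' r > 0.95 / p < 0.05 screening rule). Correlation is computed on FPKM
#' as given by default; set `log2_transform` for log2(FPKM+1).
#' Constant profiles are excluded and reported, not errors.
#'
#' @param lnc_expr,gene_expr [expression_matrix()] objects sharing the
#'   same sample axis (order included).
#' @param r_threshold Absolute-correlation threshold (default 0.95).
#' @param p_threshold p-value threshold (default 0.05).
#' @param log2_transform Correlate log2(FPKM+1) instead of raw FPKM.
#' @return data.frame with `lncrna_id`, `gene_id`, `r`, `p`, `sign`;
#'   attribute `skipped_constant` lists features with constant profiles.
#' @export
coexpression_pairs <- function(lnc_expr, gene_expr, r_threshold = 0.95,
                               p_threshold = 0.05, log2_transform = FALSE) {
  if (!identical(colnames(lnc_expr$values), colnames(gene_expr$values)))
    lnc_stop("lncRNA and gene matrices must share the same sample axis")
  A <- t(lnc_expr$values); B <- t(gene_expr$values)
  if (log2_transform) { A <- log2(A + 1); B <- log2(B + 1) }
  n <- nrow(A)
  if (n < 3L) lnc_stop("need >= 3 samples for correlation screening")
  const_a <- apply(A, 2, stats::sd) == 0
  const_b <- apply(B, 2, stats::sd) == 0
  skipped <- c(colnames(A)[const_a], colnames(B)[const_b])
  A <- A[, !const_a, drop = FALSE]; B <- B[, !const_b, drop = FALSE]
  out <- df0(lncrna_id = character(0), gene_id = character(0),
             r = numeric(0), p = numeric(0), sign = character(0))
  if (ncol(A) && ncol(B)) {
    R <- stats::cor(A, B)
    R[R > 1] <- 1; R[R < -1] <- -1
    P <- matrix(0, nrow(R), ncol(R))
    sub <- abs(R) < 1
    P[sub] <- 2 * stats::pt(-abs(R[sub]) * sqrt((n - 2) / (1 - R[sub]^2)), n - 2)
    hit <- which(abs(R) > r_threshold & P < p_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      out <- df0(lncrna_id = rownames(R)[hit[, 1]],
                 gene_id = colnames(R)[hit[, 2]],
                 r = R[hit], p = P[hit],
                 sign = ifelse(R[hit] > 0, "positive", "negative"))
      out <- out[out$lncrna_id != out$gene_id, , drop = FALSE]
      out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "skipped_constant") <- skipped
  out
}

#' Partition correlated pairs by distance and intersect with cis pairs
#'
#' Every co-expressed pair is labeled `coexpr_cis_both` when it also
#' appears in the cis (co-located) set and `coexpr_trans` otherwise
#' (distance beyond the window or different chromosome); cis pairs
#' without co-expression support are labeled `cis_only`.
#'
#' @param coexpr Output of [coexpression_pairs()].
#' @param cis Output of [cis_pairs()].
#' @return List with `pairs` (data.frame `lncrna_id`, `gene_id`, `mode`,
#'   `distance`, `r`, `p`) and `counts` (named vector over the three
#'   modes; `coexpr_trans + coexpr_cis_both = nrow(coexpr)`).
#' @export
partition_and_intersect <- function(coexpr, cis) {
  ckey <- paste(coexpr$lncrna_id, coexpr$gene_id, sep = "\r")
  xkey <- paste(cis$lncrna_id, cis$gene_id, sep = "\r")
  in_cis <- ckey %in% xkey
  m <- match(ckey, xkey)
  co <- df0(lncrna_id = coexpr$lncrna_id, gene_id = coexpr$gene_id,
            mode = ifelse(in_cis, "coexpr_cis_both", "coexpr_trans"),
            distance = cis$distance[m], r = coexpr$r, p = coexpr$p)
  only <- !(xkey %in% ckey)
  cis_only <- df0(lncrna_id = cis$lncrna_id[only], gene_id = cis$gene_id[only],
                  mode = rep("cis_only", sum(only)),
                  distance = cis$distance[only],
                  r = rep(NA_real_, sum(only)), p = rep(NA_real_, sum(only)))
  pairs <- rbind(co, cis_only)
  rownames(pairs) <- NULL
  counts <- c(cis_only = sum(only),
              coexpr_trans = sum(!in_cis),
              coexpr_cis_both = sum(in_cis))
  list(pairs = pairs, counts = counts)
}
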