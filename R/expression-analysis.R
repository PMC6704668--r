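# Gene-level aggregation, pairwise stage differential expression, Venn
# accounting, highly-expressed flagging and 2^-ddCt arithmetic.

#' Gene-level FPKM by summing transcript FPKMs
#'
#' @param expr Transcript-level [expression_matrix()].
#' @param tx2gene data.frame with columns `transcript_id`, `gene_id`;
#'   every matrix row must map to exactly one gene.
#' @return Gene-level [expression_matrix()] where each gene value is the
#'   per-sample sum of its transcripts' FPKMs.
#' @export
gene_level_fpkm <- function(expr, tx2gene) {
  ids <- rownames(expr$values)
  m <- match(ids, tx2gene$transcript_id)
  if (anyNA(m))
    lnc_stop("transcript %s has no gene mapping", ids[which(is.na(m))[1]])
  if (anyDuplicated(tx2gene$transcript_id))
    lnc_stop("transcript %s maps to more than one gene",
             tx2gene$transcript_id[duplicated(tx2gene$transcript_id)][1])
  g <- tx2gene$gene_id[m]
  vals <- rowsum(expr$values, group = g, reorder = TRUE)
  expression_matrix(as.matrix(vals), expr$design)
}

#' Pairwise differential expression between two stages
#'
#' Two-sided t-test on `log2(FPKM + offset)` replicate values, with
#' Benjamini-Hochberg correction across all tested features of the
#' comparison. `log2fc` is mean(`stage_b`) - mean(`stage_a`) on the log2
#' scale, so swapping the stages negates it and leaves p unchanged.
#' When both groups have zero variance the p-value degenerates to 1 for
#' equal means and 0 otherwise.
#'
#' By default the test pools the two group variances (Student's t,
#' `n_a + n_b - 2` degrees of freedom): with three replicates per stage
#' the Satterthwaite degree-of-freedom estimate of Welch's t is so noisy
#' that the test becomes markedly conservative (realized null rejection
#' ~0.035 at the 0.05 level), whereas the pooled test is exactly
#' calibrated under the homoskedastic log-normal replicate model.
#' Set `var_equal = FALSE` for Welch's unequal-variance form.
#'
#' @param expr An [expression_matrix()].
#' @param stage_a,stage_b Stage labels; each needs >= 2 replicates.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param offset Pseudocount added before the log2 transform (default 1).
#' @param var_equal Pool the group variances (default TRUE); `FALSE`
#'   gives Welch's test.
#' @param fold_change_gate Optional linear fold-change gate; when set
#'   (e.g. 2), a feature is only called DE if additionally
#'   `|log2fc| > log2(gate)`. Off (`NULL`) by default; used for the
#'   transcription-factor selection mode.
#' @return data.frame with `feature_id`, `comparison`, `log2fc`, `p`,
#'   `q`, `is_de`.
#' @export
differential_expression <- function(expr, stage_a, stage_b, alpha = 0.05,
                                    offset = 1, fold_change_gate = NULL,
                                    var_equal = TRUE) {
  ia <- stage_columns(expr, stage_a)
  ib <- stage_columns(expr, stage_b)
  la <- log2(expr$values[, ia, drop = FALSE] + offset)
  lb <- log2(expr$values[, ib, drop = FALSE] + offset)
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  diff <- mb - ma
  if (var_equal) {
    pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- pooled * (1 / na + 1 / nb)
    dfree <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    dfree <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), dfree)
  degen <- se2 <= 0 | !is.finite(p)
  p[degen] <- ifelse(abs(diff[degen]) < 1e-12, 1, 0)
  q <- stats::p.adjust(p, method = "BH")
  is_de <- q < alpha
  if (!is.null(fold_change_gate))
    is_de <- is_de & abs(diff) > log2(fold_change_gate)
  df0(feature_id = rownames(expr$values),
      comparison = paste0(stage_a, "-vs-", stage_b),
      log2fc = unname(diff), p = unname(p), q = unname(q),
      is_de = unname(is_de))
}

#' Venn accounting over labeled DE id-sets
#'
#' @param de_sets Named list of 2-4 character vectors (e.g. the DE
#'   feature ids of each stage comparison). Labels must be unique.
#' @return List with `set_sizes`, `regions` (data.frame `region`,
#'   `count` for all 2^k - 1 membership patterns, labels joined by
#'   `&`), `union_size`, and `intersection_ids` (members of every set).
#' @export
venn_accounting <- function(de_sets) {
  k <- length(de_sets)
  if (k < 2L || k > 4L) lnc_stop("need 2-4 sets, got %d", k)
  labels <- names(de_sets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
    lnc_stop("sets must carry unique non-empty labels")
  de_sets <- lapply(de_sets, unique)
  universe <- unique(unlist(de_sets, use.names = FALSE))
  member <- vapply(de_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1, function(r) paste(labels[r], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labels, m, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  counts <- vapply(combos, function(cb) sum(pattern == cb), integer(1))
  list(set_sizes = lengths(de_sets),
       regions = df0(region = combos, count = counts),
       union_size = length(universe),
       intersection_ids = universe[rowSums(member) == k])
}

#' Flag highly expressed features
#'
#' @param expr An [expression_matrix()].
#' @param threshold Mean-FPKM threshold; a feature is flagged when its
#'   mean over all samples is strictly greater (default 100).
#' @return Character vector of flagged feature ids.
#' @export
flag_highly_expressed <- function(expr, threshold = 100) {
  mu <- rowMeans(expr$values)
  rownames(expr$values)[mu > threshold]
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt = dCt_sample -
#' dCt_calibrator`; relative expression `= 2^-ddCt`, so the calibrator
#' sample's own value is 1.
#'
#' @param measurements data.frame with columns `gene`, `sample`, `ct`
#'   (finite, > 0).
#' @param target Target gene name.
#' @param reference_gene Reference (housekeeping) gene, e.g. GAPDH; a
#'   Ct must be present for every target sample.
#' @param calibrator_sample Sample whose dCt anchors the scale.
#' @return data.frame with `sample`, `ct_target`, `ct_reference`,
#'   `delta_ct`, `delta_delta_ct`, `relative_expression`.
#' @export
ddct_relative_expression <- function(measurements, target, reference_gene,
                                     calibrator_sample) {
  need <- c("gene", "sample", "ct")
  if (!all(need %in% names(measurements)))
    lnc_stop("Ct table needs columns gene, sample, ct")
  ct <- measurements$ct
  if (any(!is.finite(ct)) || any(ct <= 0))
    lnc_stop("Ct values must be finite and > 0")
  tgt <- measurements[measurements$gene == target, ]
  if (!nrow(tgt)) lnc_stop("no Ct rows for target gene '%s'", target)
  ref <- measurements[measurements$gene == reference_gene, ]
  m <- match(tgt$sample, ref$sample)
  if (anyNA(m))
    lnc_stop("missing reference-gene Ct for sample %s",
             tgt$sample[which(is.na(m))[1]])
  dct <- tgt$ct - ref$ct[m]
  cal <- which(tgt$sample == calibrator_sample)
  if (!length(cal)) lnc_stop("calibrator sample '%s' absent", calibrator_sample)
  ddct <- dct - dct[cal[1]]
  df0(sample = tgt$sample, ct_target = tgt$ct, ct_reference = ref$ct[m],
      delta_ct = dct, delta_delta_ct = ddct,
      relative_expression = 2^(-ddct))
}
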