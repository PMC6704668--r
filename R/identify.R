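# Candidate filtering, coding-potential assessment and positional
# classification of lncRNAs.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame in the forward frames
#'
#' Scans the three forward frames of a spliced sequence for the longest
#' ATG-to-stop open reading frame. The reported length counts the
#' nucleotides from the ATG through the stop codon inclusive; an ATG
#' with no downstream in-frame stop is not an ORF.
#'
#' @param sequence Character scalar (A/C/G/T).
#' @return List with `length_nt` (0 if no ORF), `start` (1-based
#'   position of the ATG, `NA` if none) and `frame` (0..2, `NA` if none).
#' @export
longest_orf <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  best <- list(length_nt = 0L, start = NA_integer_, frame = NA_integer_)
  if (n < 6L) return(best)
  for (f in 0:2) {
    pos <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(pos) < 2L) next
    codons <- substring(s, pos, pos + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (!length(atg) || !length(stp)) next
    nxt <- stp[findInterval(atg, stp) + 1L]  # first stop strictly after the ATG
    ok <- !is.na(nxt)
    if (!any(ok)) next
    len <- (nxt[ok] - atg[ok] + 1L) * 3L
    i <- which.max(len)
    if (len[i] > best$length_nt)
      best <- list(length_nt = len[i], start = pos[atg[ok][i]], frame = f)
  }
  best
}

#' Apply the candidate lncRNA filters
#'
#' Retains transcripts whose spliced length is at least `min_length`,
#' whose exon count is at least `min_exons` and whose expression reaches
#' `min_fpkm` (by default the maximum
#' FPKM over all samples, so a transcript expressed at any one stage
#' counts; set `fpkm_stat = "mean"` for the mean). All thresholds are
#' inclusive. Every rejected transcript gets exactly one reason, checked
#' in the order `no_expression`, `length`, `exons`, `fpkm`.
#'
#' @param ts A [transcript_set()].
#' @param expr An [expression_matrix()] with one row per transcript
#'   (transcripts without a row are rejected with reason
#'   `no_expression`).
#' @param min_length Minimum spliced length in bp (default 200).
#' @param min_exons Minimum exon count (default 2).
#' @param min_fpkm Minimum FPKM (default 0.5).
#' @param fpkm_stat Aggregation over samples: `"max"` (default) or
#'   `"mean"`.
#' @return List with `retained` (character vector of transcript ids, in
#'   input order) and `rejects` (data.frame `transcript_id`, `reason`).
#' @export
filter_candidates <- function(ts, expr, min_length = 200, min_exons = 2,
                              min_fpkm = 0.5, fpkm_stat = c("max", "mean")) {
  fpkm_stat <- match.arg(fpkm_stat)
  tx <- ts$transcripts
  has_row <- tx$transcript_id %in% rownames(expr$values)
  stat <- rep(NA_real_, nrow(tx))
  if (any(has_row)) {
    sub <- expr$values[tx$transcript_id[has_row], , drop = FALSE]
    stat[has_row] <- if (fpkm_stat == "max") apply(sub, 1, max) else rowMeans(sub)
  }
  reason <- rep(NA_character_, nrow(tx))
  reason[!has_row] <- "no_expression"
  i <- is.na(reason) & tx$spliced_length < min_length
  reason[i] <- "length"
  i <- is.na(reason) & tx$n_exons < min_exons
  reason[i] <- "exons"
  i <- is.na(reason) & stat < min_fpkm
  reason[i] <- "fpkm"
  keep <- is.na(reason)
  list(retained = tx$transcript_id[keep],
       rejects = df0(transcript_id = tx$transcript_id[!keep],
                     reason = reason[!keep]))
}

#' Coding-potential assessment of candidate transcripts
#'
#' Two assessors vote on each transcript, mirroring the common
#' CPC + Pfam screen: assessor A flags a transcript noncoding when its
#' longest forward-frame ORF is shorter than `orf_min_nt`; assessor B
#' when that ORF covers less than `orf_min_coverage` of the spliced
#' length. The verdict is `noncoding` exactly when both assessors agree
#' it is noncoding. Externally computed flags (e.g. from real CPC / Pfam
#' runs) override the corresponding internal assessor per transcript.
#'
#' @param ts A [transcript_set()] of the transcripts to assess.
#' @param sequences Named character vector of spliced sequences. May be
#'   `NULL` for transcripts that have both external flags.
#' @param external_flags Optional data.frame with columns
#'   `transcript_id`, `assessor_a_noncoding`, `assessor_b_noncoding`
#'   (logical; `NA` leaves the internal call in place).
#' @param orf_min_nt ORF-length threshold in nt (default 300).
#' @param orf_min_coverage ORF-coverage threshold (default 0.35).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `longest_orf_nt`, `orf_coverage`, `assessor_a_noncoding`,
#'   `assessor_b_noncoding`, `verdict`.
#' @export
assess_coding <- function(ts, sequences = NULL, external_flags = NULL,
                          orf_min_nt = 300, orf_min_coverage = 0.35) {
  tx <- ts$transcripts
  n <- nrow(tx)
  ext_a <- ext_b <- rep(NA, n)
  if (!is.null(external_flags)) {
    m <- match(tx$transcript_id, external_flags$transcript_id)
    ext_a <- as.logical(external_flags$assessor_a_noncoding[m])
    ext_b <- as.logical(external_flags$assessor_b_noncoding[m])
  }
  orf_nt <- integer(n)
  cov <- numeric(n)
  for (i in seq_len(n)) {
    id <- tx$transcript_id[i]
    seq_i <- if (!is.null(sequences)) sequences[[id]] else NULL
    if (is.null(seq_i) || is.na(seq_i)) {
      if (is.na(ext_a[i]) || is.na(ext_b[i]))
        lnc_stop("transcript %s: no spliced sequence and incomplete external flags", id)
      orf_nt[i] <- NA_integer_
      cov[i] <- NA_real_
      next
    }
    if (nchar(seq_i) != tx$spliced_length[i])
      lnc_stop("transcript %s: sequence length %d != spliced length %d",
               id, nchar(seq_i), tx$spliced_length[i])
    orf_nt[i] <- longest_orf(seq_i)$length_nt
    cov[i] <- orf_nt[i] / tx$spliced_length[i]
  }
  a <- ifelse(is.na(ext_a), orf_nt < orf_min_nt, ext_a)
  b <- ifelse(is.na(ext_b), cov < orf_min_coverage, ext_b)
  df0(transcript_id = tx$transcript_id,
      longest_orf_nt = orf_nt,
      orf_coverage = cov,
      assessor_a_noncoding = a,
      assessor_b_noncoding = b,
      verdict = ifelse(a & b, "noncoding", "coding"))
}

#' Classify noncoding candidates as intergenic or antisense
#'
#' A candidate is antisense when one of its exons overlaps an exon of a
#' coding transcript on the opposite strand by at least 1 bp, and
#' intergenic when it overlaps no coding-gene span on either strand.
#' Candidates with same-strand exonic overlap are excluded (reason
#' `sense_overlap`: they read as unannotated isoforms, not lncRNAs);
#' candidates inside a coding-gene span with no exonic overlap are
#' excluded as `genic_overlap`. Exclusion takes precedence over the
#' antisense call.
#'
#' @param candidates [transcript_set()] of noncoding survivors of
#'   [filter_candidates()] and [assess_coding()].
#' @param coding [transcript_set()] of the protein-coding annotation.
#' @return List with `classes` (data.frame `transcript_id`,
#'   `lnc_class`) and `excluded` (data.frame `transcript_id`, `reason`).
#' @export
classify_lncrnas <- function(candidates, coding) {
  known <- unique(coding$transcripts$chrom)
  off <- setdiff(unique(candidates$transcripts$chrom), known)
  if (length(off))
    lnc_stop("candidate chromosome '%s' absent from the coding annotation", off[1])

  cand_ex <- exon_granges(candidates)
  cod_ex <- exon_granges(coding)
  hits <- GenomicRanges::findOverlaps(cand_ex, cod_ex, ignore.strand = TRUE)
  cand_tx <- cand_ex$transcript_id[S4Vectors::queryHits(hits)]
  same <- as.character(GenomicRanges::strand(cand_ex))[S4Vectors::queryHits(hits)] ==
    as.character(GenomicRanges::strand(cod_ex))[S4Vectors::subjectHits(hits)]
  sense_ids <- unique(cand_tx[same])
  anti_ids <- unique(cand_tx[!same])

  gs <- gene_spans(coding)
  span_gr <- GenomicRanges::GRanges(gs$chrom, IRanges::IRanges(gs$start, gs$end))
  sp <- transcript_spans(candidates)
  cand_gr <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  span_hit <- unique(sp$transcript_id[
    S4Vectors::queryHits(GenomicRanges::findOverlaps(cand_gr, span_gr,
                                                     ignore.strand = TRUE))])

  ids <- candidates$transcripts$transcript_id
  cls <- rep(NA_character_, length(ids))
  reason <- rep(NA_character_, length(ids))
  reason[ids %in% span_hit] <- "genic_overlap"
  cls[ids %in% anti_ids] <- "antisense"
  reason[ids %in% anti_ids] <- NA_character_
  reason[ids %in% sense_ids] <- "sense_overlap"
  cls[ids %in% sense_ids] <- NA_character_
  cls[is.na(cls) & is.na(reason)] <- "intergenic"

  list(classes = df0(transcript_id = ids[!is.na(cls)],
                     lnc_class = cls[!is.na(cls)]),
       excluded = df0(transcript_id = ids[!is.na(reason)],
                      reason = reason[!is.na(reason)]))
}

#' Identify lncRNAs end to end
#'
#' Runs [filter_candidates()], [assess_coding()] and
#' [classify_lncrnas()] and assembles the lncRNA record table. Every
#' input transcript ends up either as a retained lncRNA or as a reject
#' with exactly one reason (`no_expression`, `length`, `exons`, `fpkm`,
#' `coding`, `sense_overlap`, `genic_overlap`).
#'
#' @param ts All assembled transcripts as a [transcript_set()].
#' @param expr Transcript-level [expression_matrix()].
#' @param sequences Named spliced sequences (see [assess_coding()]).
#' @param external_flags Optional external assessor flags.
#' @param min_length,min_exons,min_fpkm,fpkm_stat Candidate filters, see
#'   [filter_candidates()].
#' @param orf_min_nt,orf_min_coverage Coding thresholds, see
#'   [assess_coding()].
#' @param high_fpkm Mean-FPKM threshold above which a lncRNA is flagged
#'   highly expressed (strict `>`, default 100).
#' @return List with `lncrnas` (data.frame `transcript_id`, `gene_id`,
#'   `lnc_class`, `longest_orf_nt`, `orf_coverage`, `mean_fpkm`,
#'   `highly_expressed`) and `rejects` (data.frame `transcript_id`,
#'   `reason`).
#' @export
identify_lncrnas <- function(ts, expr, sequences = NULL, external_flags = NULL,
                             min_length = 200, min_exons = 2, min_fpkm = 0.5,
                             fpkm_stat = "max", orf_min_nt = 300,
                             orf_min_coverage = 0.35, high_fpkm = 100) {
  flt <- filter_candidates(ts, expr, min_length, min_exons, min_fpkm, fpkm_stat)
  rejects <- flt$rejects
  coding_ann <- subset_transcripts(
    ts, ts$transcripts$transcript_id[ts$transcripts$biotype == "coding"])
  # transcripts already annotated as protein-coding are vetoed by the
  # annotation itself, not re-assessed
  ann_coding <- intersect(flt$retained, coding_ann$transcripts$transcript_id)
  rejects <- rbind(rejects, df0(transcript_id = ann_coding,
                                reason = rep("coding", length(ann_coding))))
  cand_ids <- setdiff(flt$retained, ann_coding)

  if (length(cand_ids)) {
    cand_ts <- subset_transcripts(ts, cand_ids)
    asmt <- assess_coding(cand_ts, sequences, external_flags,
                          orf_min_nt, orf_min_coverage)
    coding_ids <- asmt$transcript_id[asmt$verdict == "coding"]
    rejects <- rbind(rejects, df0(transcript_id = coding_ids,
                                  reason = rep("coding", length(coding_ids))))
    nc_ids <- asmt$transcript_id[asmt$verdict == "noncoding"]
  } else {
    asmt <- NULL
    nc_ids <- character(0)
  }

  if (length(nc_ids)) {
    nc_ts <- subset_transcripts(ts, nc_ids)
    cl <- classify_lncrnas(nc_ts, coding_ann)
    rejects <- rbind(rejects, cl$excluded)
    rec <- cl$classes
    m <- match(rec$transcript_id, ts$transcripts$transcript_id)
    mean_fpkm <- rowMeans(expr$values[rec$transcript_id, , drop = FALSE])
    am <- match(rec$transcript_id, asmt$transcript_id)
    lncrnas <- df0(transcript_id = rec$transcript_id,
                   gene_id = ts$transcripts$gene_id[m],
                   lnc_class = rec$lnc_class,
                   longest_orf_nt = asmt$longest_orf_nt[am],
                   orf_coverage = asmt$orf_coverage[am],
                   mean_fpkm = unname(mean_fpkm),
                   highly_expressed = unname(mean_fpkm) > high_fpkm)
  } else {
    lncrnas <- df0(transcript_id = character(0), gene_id = character(0),
                   lnc_class = character(0), longest_orf_nt = integer(0),
                   orf_coverage = numeric(0), mean_fpkm = numeric(0),
                   highly_expressed = logical(0))
  }
  list(lncrnas = lncrnas, rejects = rejects)
}
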