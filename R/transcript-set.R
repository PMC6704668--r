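#' Transcript model container
#'
#' Validated container for transcript models: one row per exon plus a
#' derived per-transcript table. Coordinates are 1-based inclusive (GTF
#' native) throughout the package; no half-open conversion is exposed.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`+` or `-`), `start`, `end`, and optionally
#'   `biotype` (`coding` or `unknown`, constant within a transcript).
#' @return An object of class `transcript_set`: a list with elements
#'   `exons` (sorted exon table) and `transcripts` (one row per
#'   transcript with `n_exons` and recomputed `spliced_length`).
#' @details Exons of a transcript must be on one chromosome and strand,
#'   satisfy `start <= end`, and be pairwise non-overlapping. The spliced
#'   length is always recomputed as the exon-length sum, never trusted
#'   from input.
#' @export
transcript_set <- function(exons) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) lnc_stop("exon table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!nrow(exons)) lnc_stop("exon table is empty")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (anyNA(exons$start) || anyNA(exons$end))
    lnc_stop("exon coordinates must be integers")
  bad <- which(exons$start > exons$end)
  if (length(bad))
    lnc_stop("exon start > end for transcript %s (%d > %d)",
             exons$transcript_id[bad[1]], exons$start[bad[1]], exons$end[bad[1]])
  if (any(exons$start < 1L)) lnc_stop("exon coordinates must be >= 1")
  if (!all(exons$strand %in% c("+", "-")))
    lnc_stop("transcript strand must be '+' or '-' (got '%s')",
             setdiff(unique(exons$strand), c("+", "-"))[1])
  if (is.null(exons$biotype)) exons$biotype <- "unknown"
  if (!all(exons$biotype %in% c("coding", "unknown")))
    lnc_stop("biotype must be 'coding' or 'unknown'")

  exons <- exons[order(exons$transcript_id, exons$start), c(need, "biotype")]
  rownames(exons) <- NULL

  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tx in names(by_tx)) {
    i <- by_tx[[tx]]
    for (col in c("gene_id", "chrom", "strand", "biotype")) {
      if (length(unique(exons[[col]][i])) != 1L)
        lnc_stop("transcript %s has inconsistent %s across its exons", tx, col)
    }
    if (length(i) > 1L) {
      s <- exons$start[i]; e <- exons$end[i]
      if (any(s[-1] <= e[-length(e)]))
        lnc_stop("transcript %s has overlapping exons", tx)
    }
  }

  first <- vapply(by_tx, `[`, integer(1), 1L)
  transcripts <- df0(
    transcript_id = names(by_tx),
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    biotype = exons$biotype[first],
    n_exons = lengths(by_tx),
    spliced_length = vapply(by_tx, function(i)
      sum(exons$end[i] - exons$start[i] + 1L), integer(1)),
    start = vapply(by_tx, function(i) min(exons$start[i]), integer(1)),
    end = vapply(by_tx, function(i) max(exons$end[i]), integer(1))
  )
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  tx <- x$transcripts
  cat(sprintf("transcript_set: %d transcripts (%d coding), %d exons, %d chromosome(s)\n",
              nrow(tx), sum(tx$biotype == "coding"), nrow(x$exons),
              length(unique(tx$chrom))))
  invisible(x)
}

# Subset a transcript_set to the given transcript ids (order preserved).
subset_transcripts <- function(ts, ids) {
  unknown <- setdiff(ids, ts$transcripts$transcript_id)
  if (length(unknown))
    lnc_stop("unknown transcript id(s): %s", paste(utils::head(unknown, 3), collapse = ", "))
  transcript_set(ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE])
}

# Exon-level GRanges (one range per exon, transcript_id/gene_id metadata).
exon_granges <- function(ts) {
  GenomicRanges::GRanges(
    seqnames = ts$exons$chrom,
    ranges = IRanges::IRanges(ts$exons$start, ts$exons$end),
    strand = ts$exons$strand,
    transcript_id = ts$exons$transcript_id,
    gene_id = ts$exons$gene_id
  )
}

# Per-gene genomic spans (min start .. max end over the gene's exons).
gene_spans <- function(ts) {
  ex <- ts$exons
  s <- tapply(ex$start, ex$gene_id, min)
  e <- tapply(ex$end, ex$gene_id, max)
  ch <- tapply(ex$chrom, ex$gene_id, function(v) v[1])
  genes <- names(s)
  df0(gene_id = genes, chrom = as.character(ch[genes]),
      start = as.integer(s[genes]), end = as.integer(e[genes]))
}

# Per-transcript genomic spans.
transcript_spans <- function(ts) {
  tx <- ts$transcripts
  df0(transcript_id = tx$transcript_id, chrom = tx$chrom,
      start = tx$start, end = tx$end)
}
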