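# GTF read/write. The dialect is the 9-column tab layout with gene_id /
# transcript_id (and optionally gene_biotype) attributes; only exon rows
# carry the transcript models. Parsing is line-based so that malformed
# input can be rejected with the offending line number.

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

#' Read transcript models from a GTF file
#'
#' @param path Path to a GTF file. Exon rows must carry `gene_id` and
#'   `transcript_id` attributes; a `gene_biotype` attribute of `coding`
#'   marks protein-coding transcripts.
#' @return A [transcript_set()].
#' @details Malformed rows are rejected, never coerced: an exon with
#'   `start > end`, a missing `transcript_id`, an unstranded (`.`) exon
#'   or a transcript with mixed strands all raise errors naming the file
#'   and line. Strand is required because antisense classification
#'   depends on it.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) lnc_stop("GTF file not found: %s", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) lnc_stop("%s: no feature lines", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    lnc_stop("%s line %d: expected 9 tab-separated fields, got %d",
             path, keep[which(nf != 9L)[1]], nf[nf != 9L][1])
  mat <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_exon <- mat[, 3] == "exon"
  if (!any(is_exon)) lnc_stop("%s: no exon features", path)
  lineno <- keep[is_exon]
  chrom <- mat[is_exon, 1]
  start <- suppressWarnings(as.integer(mat[is_exon, 4]))
  end <- suppressWarnings(as.integer(mat[is_exon, 5]))
  strand <- mat[is_exon, 7]
  attrs <- mat[is_exon, 9]

  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    lnc_stop("%s line %d: non-numeric exon coordinates", path, lineno[bad[1]])
  bad <- which(start > end)
  if (length(bad))
    lnc_stop("%s line %d: exon start > end (%d > %d)",
             path, lineno[bad[1]], start[bad[1]], end[bad[1]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    lnc_stop("%s line %d: exon strand '%s' (must be '+' or '-')",
             path, lineno[bad[1]], strand[bad[1]])

  tx <- gtf_attr(attrs, "transcript_id")
  gene <- gtf_attr(attrs, "gene_id")
  bad <- which(is.na(tx) | !nzchar(tx))
  if (length(bad))
    lnc_stop("%s line %d: missing transcript_id attribute", path, lineno[bad[1]])
  bad <- which(is.na(gene) | !nzchar(gene))
  if (length(bad))
    lnc_stop("%s line %d: missing gene_id attribute", path, lineno[bad[1]])
  biotype <- gtf_attr(attrs, "gene_biotype")
  biotype[is.na(biotype)] <- "unknown"

  mixed <- tapply(strand, tx, function(s) length(unique(s)) > 1L)
  if (any(mixed))
    lnc_stop("%s: transcript %s has exons on both strands",
             path, names(mixed)[which(mixed)[1]])

  transcript_set(df0(transcript_id = tx, gene_id = gene, chrom = chrom,
                     strand = strand, start = start, end = end,
                     biotype = biotype))
}

#' Write transcript models to a GTF file
#'
#' Emits one exon row per exon with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes; `read_gtf(write_gtf(ts))` is the identity
#' on validated transcript sets.
#'
#' @param ts A [transcript_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path) {
  ex <- ts$exons
  lines <- sprintf(
    '%s\tlncripe\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id, ex$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Read spliced transcript sequences from FASTA
#'
#' @param path FASTA file of spliced transcript sequences named by
#'   transcript id.
#' @return Named character vector of uppercase sequences.
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) lnc_stop("FASTA file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write spliced transcript sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
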