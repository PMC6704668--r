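# Expression matrices (FPKM) and sample sheets.

#' Expression matrix container
#'
#' @param values Numeric matrix of non-negative FPKM values, features in
#'   rows (rownames = feature ids), samples in columns (colnames =
#'   sample ids).
#' @param design data.frame with columns `sample_id`, `stage`,
#'   `replicate`; one row per sample, matching the matrix columns.
#' @return Object of class `expression_matrix`: list with `values` and
#'   `design` (columns reordered to the design's sample order).
#' @export
expression_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    lnc_stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    lnc_stop("values must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    lnc_stop("duplicate feature id: %s",
             rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    lnc_stop("duplicate sample id: %s",
             colnames(values)[duplicated(colnames(values))][1])
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    lnc_stop("missing value at feature %s, sample %s",
             rownames(values)[idx[1]], colnames(values)[idx[2]])
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    lnc_stop("negative expression at feature %s, sample %s",
             rownames(values)[idx[1]], colnames(values)[idx[2]])
  }
  design <- validate_sample_sheet(design)
  if (!setequal(design$sample_id, colnames(values)))
    lnc_stop("design samples and matrix columns differ")
  values <- values[, design$sample_id, drop = FALSE]
  structure(list(values = values, design = design), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  st <- table(x$design$stage)
  cat(sprintf("expression_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(st), st), collapse = ", ")))
  invisible(x)
}

validate_sample_sheet <- function(design) {
  need <- c("sample_id", "stage", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) lnc_stop("sample sheet lacks column(s): %s",
                             paste(miss, collapse = ", "))
  design <- df0(sample_id = as.character(design$sample_id),
                stage = as.character(design$stage),
                replicate = as.integer(design$replicate))
  if (anyDuplicated(design$sample_id))
    lnc_stop("duplicate sample id in sample sheet")
  key <- paste(design$stage, design$replicate)
  if (anyDuplicated(key))
    lnc_stop("duplicate (stage, replicate) pair: %s", key[duplicated(key)][1])
  design
}

#' Read a sample sheet TSV
#'
#' @param path TSV with columns `sample_id`, `stage`, `replicate`.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) validate_sample_sheet(read_tsv(path))

#' Read a feature-by-sample FPKM matrix
#'
#' @param path TSV whose first column holds feature ids and whose header
#'   names the samples.
#' @param sample_sheet Sample design data.frame (see
#'   [read_sample_sheet()]); every sheet sample must be present.
#' @param allow_extra Keep (`TRUE`) or reject (`FALSE`, default) matrix
#'   columns absent from the sheet. Kept extras are dropped from the
#'   returned matrix either way; the flag only controls whether they are
#'   an error.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, sample_sheet, allow_extra = FALSE) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  df <- read_tsv(path)
  if (ncol(df) < 2L) lnc_stop("%s: expected feature column plus samples", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    lnc_stop("%s: duplicated feature id '%s'", path, ids[duplicated(ids)][1])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      lnc_stop("%s: non-numeric value '%s' at feature %s, sample %s",
               path, vals[[j]][bad[1]], ids[bad[1]], names(vals)[j])
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  missing <- setdiff(sample_sheet$sample_id, colnames(m))
  if (length(missing))
    lnc_stop("%s: sample(s) missing from matrix: %s", path,
             paste(missing, collapse = ", "))
  extra <- setdiff(colnames(m), sample_sheet$sample_id)
  if (length(extra) && !allow_extra)
    lnc_stop("%s: unexpected sample column(s): %s", path,
             paste(extra, collapse = ", "))
  expression_matrix(m[, sample_sheet$sample_id, drop = FALSE], sample_sheet)
}

#' Write an expression matrix to TSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- df0(feature_id = rownames(expr$values))
  df <- cbind(df, as.data.frame(expr$values, check.names = FALSE))
  write_tsv(df, path)
}

#' FPKM from fragment counts
#'
#' Classical definition: `FPKM = count * 1e9 / (library_size * length)`.
#'
#' @param counts Numeric matrix of fragment counts (features x samples).
#' @param lengths Named numeric vector of spliced lengths in bp, one per
#'   feature row (> 0).
#' @param library_sizes Named numeric vector of total mapped fragments
#'   per sample column (> 0).
#' @param design Sample design data.frame.
#' @return An [expression_matrix()] of FPKM values.
#' @export
fpkm_from_counts <- function(counts, lengths, library_sizes, design) {
  if (!is.matrix(counts)) lnc_stop("counts must be a matrix")
  lengths <- lengths[rownames(counts)]
  library_sizes <- library_sizes[colnames(counts)]
  if (anyNA(lengths)) lnc_stop("missing length for feature %s",
                               rownames(counts)[which(is.na(lengths))[1]])
  if (anyNA(library_sizes)) lnc_stop("missing library size for sample %s",
                                     colnames(counts)[which(is.na(library_sizes))[1]])
  if (any(lengths <= 0)) lnc_stop("non-positive length for feature %s",
                                  rownames(counts)[which(lengths <= 0)[1]])
  if (any(library_sizes <= 0)) lnc_stop("non-positive library size for sample %s",
                                        colnames(counts)[which(library_sizes <= 0)[1]])
  fpkm <- sweep(counts * 1e9, 1, lengths, "/")
  fpkm <- sweep(fpkm, 2, library_sizes, "/")
  expression_matrix(fpkm, design)
}

# Stage -> column indices lookup with replicate checks.
stage_columns <- function(expr, stage, min_replicates = 2L) {
  idx <- which(expr$design$stage == stage)
  if (!length(idx)) lnc_stop("stage '%s' absent from design", stage)
  if (length(idx) < min_replicates)
    lnc_stop("stage '%s' has %d replicate(s); need >= %d",
             stage, length(idx), min_replicates)
  idx
}
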