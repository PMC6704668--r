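# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

lnc_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the previous RNG
#' state so callers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# One global seed drives independent sub-streams per generator stage.
derive_seeds <- function(seed, n) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    lnc_stop("seed must be a single integer")
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) lnc_stop("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

# data.frame constructor that never mangles strings or row names
df0 <- function(...) data.frame(..., stringsAsFactors = FALSE)
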