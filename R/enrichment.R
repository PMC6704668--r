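# Hypergeometric over-representation testing with BH-FDR.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric with `K` annotated genes in a
#' population of `N`, drawing a study set of size `n`:
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param k Study genes carrying the term.
#' @param n Study size.
#' @param K Population genes carrying the term.
#' @param N Population size.
#' @return The upper-tail probability (1 when `k = 0`).
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    lnc_stop("inconsistent counts: k=%s n=%s K=%s N=%s", k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j>=i}(p_(j) * m / j)` on the
#' ascending order, capped at 1 and mapped back to the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    lnc_stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Term over-representation of a study gene set
#'
#' One upper-tail hypergeometric test per term with at least one study
#' gene (terms with `k = 0` are not tested, which reduces the BH family
#' size `m`), BH-FDR across the tested terms, sorted by q then p.
#'
#' @param study_genes Character vector of study genes (e.g. predicted
#'   lncRNA target genes); must be a subset of the population.
#' @param term_map data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`; assignments outside the population are
#'   ignored.
#' @param population_genes Background gene universe.
#' @param alpha Significance level on q (default 0.05).
#' @return data.frame with `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `p`, `q`, `significant`.
#' @export
enrich <- function(study_genes, term_map, population_genes, alpha = 0.05) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  out_of_pop <- setdiff(study_genes, population_genes)
  if (length(out_of_pop))
    lnc_stop("study gene outside the population: %s", out_of_pop[1])
  empty <- df0(term_id = character(0), term_name = character(0),
               k = integer(0), n = integer(0), K = integer(0), N = integer(0),
               p = numeric(0), q = numeric(0), significant = logical(0))
  if (!length(study_genes)) return(empty)

  tm <- term_map[term_map$gene_id %in% population_genes, , drop = FALSE]
  tm <- unique(df0(gene_id = tm$gene_id, term_id = tm$term_id,
                   term_name = if (is.null(tm$term_name)) tm$term_id
                               else tm$term_name))
  if (!nrow(tm)) return(empty)
  N <- length(population_genes)
  n <- length(study_genes)
  Ktab <- table(tm$term_id)
  in_study <- tm[tm$gene_id %in% study_genes, , drop = FALSE]
  if (!nrow(in_study)) return(empty)
  ktab <- table(in_study$term_id)
  terms <- names(ktab)
  k <- as.integer(ktab)
  K <- as.integer(Ktab[terms])
  p <- vapply(seq_along(terms), function(i)
    hypergeometric_upper_tail(k[i], n, K[i], N), numeric(1))
  q <- benjamini_hochberg(p)
  nm <- tm$term_name[match(terms, tm$term_id)]
  out <- df0(term_id = terms, term_name = nm, k = k, n = n, K = K, N = N,
             p = p, q = q, significant = q < alpha)
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
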