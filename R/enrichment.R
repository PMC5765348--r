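#' @title Over-representation statistics with Bonferroni correction
#' @description One-sided upper-tail tests for whether a study set (e.g.
#'   Class I substrates) over-represents a gene family, category or
#'   annotation term relative to a background (by default, all features
#'   surviving the expression filter). Tails are evaluated through the
#'   log-space routines of the stats distributions.
#' @name enrichment
NULL

#' Hypergeometric upper tail P(X >= k)
#'
#' X counts term members among `n` draws without replacement from a
#' population of `N` features of which `K` carry the term.
#'
#' @param k observed hits in the study set.
#' @param n study-set size.
#' @param K term members in the background.
#' @param N background size.
#' @return P(X >= k).
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(k < 0) || any(n < 0) || any(K < 0) || any(N < 1) ||
      any(k > n) || any(n > N) || any(K > N) || any(k > K))
    stop("require 0 <= k <= min(n, K), n <= N, K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Binomial upper tail P(X >= k), X ~ Binomial(n, p0)
#'
#' @param k observed hits; `n` trials; `p0` null success probability.
#' @return P(X >= k).
#' @export
binomial_upper_tail <- function(k, n, p0) {
  if (any(k < 0) || any(k > n) || any(p0 <= 0) || any(p0 >= 1))
    stop("require 0 <= k <= n and p0 in (0, 1)")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value(s).
#' @param m_tests number of tests (>= 1).
#' @return min(1, m_tests * p_raw).
#' @export
bonferroni <- function(p_raw, m_tests) {
  if (any(m_tests < 1)) stop("m_tests must be >= 1")
  pmin(1, m_tests * p_raw)
}

#' Term over-representation in a study set
#'
#' @param study character vector of study-set feature ids.
#' @param background character vector of background ids (the tested
#'   universe; study must be a subset).
#' @param terms data.frame with columns `gene_id` and `term`.
#' @param m_tests Bonferroni divisor; defaults to the number of distinct
#'   terms tested (e.g. 2 for two gene families, 11 for the annotated gene
#'   categories).
#' @return An `enrichment_result` data.frame: term, k, n, K, N, p_raw,
#'   p_bonferroni, m_tests.
#' @export
test_enrichment <- function(study, background, terms, m_tests = NULL) {
  study <- unique(study); background <- unique(background)
  if (!all(study %in% background))
    stop("study set must be a subset of the background")
  stopifnot(all(c("gene_id", "term") %in% names(terms)))
  terms <- terms[terms$gene_id %in% background, , drop = FALSE]
  term_levels <- unique(as.character(terms$term))
  if (is.null(m_tests)) m_tests <- length(term_levels)
  N <- length(background); n <- length(study)
  rows <- lapply(term_levels, function(tm) {
    members <- unique(terms$gene_id[terms$term == tm])
    K <- length(members)
    k <- length(intersect(study, members))
    p <- hypergeom_upper_tail(k, n, K, N)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_raw = p,
               p_bonferroni = bonferroni(p, m_tests), m_tests = m_tests,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
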