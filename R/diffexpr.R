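#' @title Two-group negative-binomial differential abundance testing
#' @description Re-implementation of the classic count-based testing chain:
#'   trimmed-mean-of-M-values (TMM) normalization, conditional-likelihood
#'   estimation of the negative-binomial dispersion (variance = mu + phi *
#'   mu^2) with empirical-Bayes shrinkage of per-feature values toward the
#'   common value, a conditional exact test on group totals, and
#'   Benjamini-Hochberg FDR.
#' @name diffexpr
NULL

## ---- TMM ---------------------------------------------------------------

#' TMM normalization factors
#'
#' Per-sample scale factors from the weighted trimmed mean of per-feature
#' log2 ratios (M-values) against a reference sample, trimming the most
#' extreme 30% of M-values on each side and 5% of A-values (average log
#' abundance) on each side. Features with zero counts in either sample are
#' excluded. The reference sample is the one whose upper-quartile CPM is
#' closest to the mean upper-quartile. Factors are rescaled to geometric
#' mean 1, so effective library size = library_size * factor.
#'
#' @param cm a `count_matrix` with at least 2 samples.
#' @param logratio_trim,abundance_trim two-sided trim fractions for M and A.
#' @return A `norm_factors` object: numeric factors (named by sample) with
#'   attributes `effective_lib_sizes` and `ref_sample`.
#' @export
tmm_factors <- function(cm, logratio_trim = 0.3, abundance_trim = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  y <- cm$counts
  if (ncol(y) < 2) stop("TMM needs at least 2 samples")
  if (any(colSums(y) == 0)) stop("a sample has all-zero counts")
  libs <- cm$library_sizes
  q75 <- apply(y, 2, function(col) quantile(col[col > 0] / sum(col), 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(y)), function(s) {
    if (s == ref) return(1)
    .tmm_pair(y[, s], y[, ref], libs[s], libs[ref],
              logratio_trim, abundance_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(setNames(f, colnames(y)),
            effective_lib_sizes = setNames(libs * f, colnames(y)),
            ref_sample = colnames(y)[ref],
            class = "norm_factors")
}

#' Construct normalization factors directly
#'
#' Mostly useful to bypass TMM (all-1 factors) when libraries are already
#' comparable.
#'
#' @param cm a `count_matrix`.
#' @param factors per-sample scale factors (recycled); rescaled to
#'   geometric mean 1.
#' @return A `norm_factors` object as from [tmm_factors()].
#' @export
norm_factors <- function(cm, factors = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  f <- rep_len(factors, ncol(cm$counts))
  f <- f / exp(mean(log(f)))
  structure(setNames(f, colnames(cm$counts)),
            effective_lib_sizes = setNames(cm$library_sizes * f,
                                           colnames(cm$counts)),
            ref_sample = NA_character_,
            class = "norm_factors")
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  ## asymptotic (delta-method) variance of M; weights are its inverse
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & is.finite(v)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  n <- length(M)
  if (n == 0) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

## ---- library equalization ---------------------------------------------

#' Scale counts to a common effective library size
#'
#' Counts are multiplied by (geometric mean of effective library sizes) /
#' (own effective library size) and rounded half-to-even to integers, after
#' which samples are directly comparable and within-group totals are
#' sufficient for the conditional likelihood.
#'
#' @param cm a `count_matrix`.
#' @param norm a [tmm_factors()] result (NULL computes it).
#' @return list(counts = equalized integer matrix, common_lib = the common
#'   effective library size).
#' @export
equalize_libraries <- function(cm, norm = NULL) {
  if (is.null(norm)) norm <- tmm_factors(cm)
  eff <- attr(norm, "effective_lib_sizes")[colnames(cm$counts)]
  common <- exp(mean(log(eff)))
  scaled <- sweep(cm$counts, 2, common / eff, "*")
  list(counts = round(scaled), common_lib = common)
}

## ---- dispersion --------------------------------------------------------

.phi_grid <- function(lo = 1e-6, hi = 10, n = 121) exp(seq(log(lo), log(hi), length.out = n))

## conditional log-likelihood of one group, all features at once, for one phi:
## counts y_1..y_n per feature with equal library sizes, conditioned on the
## within-group total z. l(phi) = sum_i lgamma(y_i + r) - n lgamma(r)
## + lgamma(n r) - lgamma(z + n r) + lgamma(z + 1) - sum_i lgamma(y_i + 1),
## with r = 1/phi.
.cond_ll_group <- function(y, phi) {
  n <- ncol(y)
  r <- 1 / phi
  z <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) -
    lgamma(z + n * r) + lgamma(z + 1) - rowSums(lgamma(y + 1))
}

## interpolated maximum of a smooth function sampled on grid (in log space):
## parabola through the grid argmax and its neighbours.
.max_interp <- function(ll, grid) {
  i <- which.max(ll)
  if (i == 1 || i == length(grid)) return(grid[i])
  x <- log(grid[(i - 1):(i + 1)]); f <- ll[(i - 1):(i + 1)]
  d1 <- (f[3] - f[1]) / (x[3] - x[1])
  d2 <- ((f[3] - f[2]) / (x[3] - x[2]) - (f[2] - f[1]) / (x[2] - x[1])) /
    ((x[3] - x[1]) / 2)
  if (!is.finite(d2) || d2 >= 0) return(grid[i])
  exp(x[2] - d1 / d2)
}

#' Estimate negative-binomial dispersions by conditional likelihood
#'
#' Counts are first brought to a common effective library size (see
#' [equalize_libraries()]). The common dispersion maximizes the conditional
#' log-likelihood summed over features (conditioning on within-group totals)
#' over phi in \[1e-6, 10\]; per-feature (tagwise) dispersions maximize
#' l_f(phi) + prior_weight * mean_f l_f(phi), shrinking toward the common
#' value as prior_weight grows. Both maximizations use a log-spaced grid
#' with quadratic interpolation at the peak.
#'
#' @param cm a `count_matrix`.
#' @param groups two-level factor/character over samples; each level needs
#'   at least 2 samples.
#' @param prior_weight shrinkage weight (default 10).
#' @param norm optional precomputed [tmm_factors()].
#' @return A `dispersion_model`: list(common, tagwise (named), prior_weight).
#' @export
estimate_dispersions <- function(cm, groups, prior_weight = 10, norm = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2))
    stop("each group needs >= 2 replicates (conditional likelihood undefined)")
  eq <- equalize_libraries(cm, norm)
  y1 <- eq$counts[, groups == levels(groups)[1], drop = FALSE]
  y2 <- eq$counts[, groups == levels(groups)[2], drop = FALSE]
  grid <- .phi_grid()
  ll <- vapply(grid, function(p) .cond_ll_group(y1, p) + .cond_ll_group(y2, p),
               numeric(nrow(eq$counts)))
  if (nrow(eq$counts) == 1) ll <- matrix(ll, nrow = 1)
  lbar <- colMeans(ll)
  common <- .max_interp(lbar, grid)
  obj <- ll + matrix(prior_weight * lbar, nrow(ll), ncol(ll), byrow = TRUE)
  tagwise <- vapply(seq_len(nrow(obj)), function(f) .max_interp(obj[f, ], grid),
                    numeric(1))
  structure(list(common = common,
                 tagwise = setNames(tagwise, rownames(cm$counts)),
                 prior_weight = prior_weight),
            class = "dispersion_model")
}

## ---- exact test --------------------------------------------------------

## two-sided conditional exact p for one feature: group sums (y1, y2) with
## n1, n2 equalized samples, total s, dispersion phi. The conditional
## distribution over splits (a, s - a) uses NB-sum laws: sum of n iid
## NB(mu, phi) is NB(n mu, phi / n), i.e. size n / phi.
.exact_p <- function(y1, y2, n1, n2, phi, tie_tol = 1e-10) {
  s <- y1 + y2
  if (s == 0) return(1)
  a <- 0:s
  if (phi < 1e-8) {
    pr <- dbinom(a, size = s, prob = n1 / (n1 + n2))
  } else {
    mu1 <- s * n1 / (n1 + n2); mu2 <- s * n2 / (n1 + n2)
    pr <- dnbinom(a, size = n1 / phi, mu = mu1) *
      dnbinom(s - a, size = n2 / phi, mu = mu2)
  }
  tot <- sum(pr)
  if (tot == 0) return(1)
  obs <- pr[y1 + 1]
  min(1, sum(pr[pr <= obs * (1 + tie_tol)]) / tot)
}

#' Conditional negative-binomial exact test
#'
#' After scaling all samples to a common effective library size, each
#' feature's group totals (Y1, Y2) are compared conditionally on Y1 + Y2:
#' the two-sided p-value sums the probabilities of all splits no more
#' probable than the observed one, under NB-sum distributions with the
#' feature's tagwise dispersion. log2 fold-change is group2 over group1 on
#' group mean equalized counts with a prior count of 0.5 added to each
#' group mean.
#'
#' @param cm a `count_matrix`.
#' @param groups two-level factor; the first level is the baseline (logFC
#'   is level 2 over level 1).
#' @param disp a [estimate_dispersions()] result, or a single numeric
#'   dispersion applied to all features.
#' @param norm optional precomputed [tmm_factors()].
#' @return A `de_result` data.frame: feature_id, logFC, mean_cpm, pvalue, fdr.
#' @export
nb_exact_test <- function(cm, groups, disp = NULL, norm = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (is.null(norm)) norm <- tmm_factors(cm)
  if (is.null(disp)) disp <- estimate_dispersions(cm, groups, norm = norm)
  phi <- if (inherits(disp, "dispersion_model")) {
    disp$tagwise[rownames(cm$counts)]
  } else rep(as.numeric(disp), nrow(cm$counts))
  eq <- equalize_libraries(cm, norm)
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  Y1 <- rowSums(eq$counts[, g1, drop = FALSE])
  Y2 <- rowSums(eq$counts[, !g1, drop = FALSE])
  p <- vapply(seq_along(Y1),
              function(f) .exact_p(Y1[f], Y2[f], n1, n2, phi[f]),
              numeric(1))
  m1 <- Y1 / n1; m2 <- Y2 / n2
  logFC <- log2((m2 + 0.5) / (m1 + 0.5))
  logFC[Y1 + Y2 == 0] <- 0
  mean_cpm <- rowMeans(sweep(cm$counts, 2,
                             attr(norm, "effective_lib_sizes")[colnames(cm$counts)],
                             "/")) * 1e6
  res <- data.frame(feature_id = rownames(cm$counts), logFC = logFC,
                    mean_cpm = mean_cpm, pvalue = p, fdr = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

## ---- FDR ---------------------------------------------------------------

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' fdr_(i) = min over j >= i of m * p_(j) / j, capped at 1, mapped back to
#' the input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
}

#' Write/read a differential-abundance result table as TSV
#' @param de a `de_result`; `path` a file path.
#' @export
write_de <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de
#' @export
read_de <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("feature_id", "logFC", "pvalue", "fdr") %in% names(df)))
  class(df) <- c("de_result", "data.frame")
  df
}
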