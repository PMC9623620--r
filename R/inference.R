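#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, by inversion of the
#' binomial tails (computed in the standard beta-quantile form). The lower
#' bound is exactly 0 when `x = 0` and the upper bound exactly 1 when
#' `x = n`; the interval always contains `x / n`.
#'
#' @param x number of successes (0 to `n`).
#' @param n number of trials (at least 1).
#' @param conf_level two-sided confidence level.
#' @return named numeric vector `c(estimate, lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(69, 76)   # about (0.819, 0.962)
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, n >= 1, x >= 0, x <= n,
            conf_level > 0, conf_level < 1)
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(estimate = x / n, lower = lower, upper = upper)
}

#' Cohen's unweighted kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' binary classifications, with `p_o` the observed agreement and `p_e` the
#' agreement expected from the marginals.
#'
#' @param tab a 2x2 contingency table / matrix of counts (raters in rows and
#'   columns), or the count `a` when the four cell counts are given
#'   separately.
#' @param b,c,d optional cell counts `(a, b, c, d)` read row-wise: `a` both
#'   positive, `b` rows-positive only, `c` columns-positive only, `d` both
#'   negative.
#' @param allow_degenerate with a degenerate marginal (`p_e = 1`, e.g. one
#'   rater constant) kappa is undefined unless agreement is also perfect;
#'   `TRUE` returns `NA` instead of erroring in the undefined case (used when
#'   tabulating over many cutoffs, where boundary cutoffs are degenerate).
#' @return kappa (at most 1), or `NA` in the degenerate case when allowed.
#' @export
#' @examples
#' cohen_kappa(matrix(c(60, 10, 10, 20), 2, byrow = TRUE))  # 0.5
cohen_kappa <- function(tab, b = NULL, c = NULL, d = NULL,
                        allow_degenerate = FALSE) {
  if (!is.null(b)) tab <- matrix(c(tab, b, c, d), 2, 2, byrow = TRUE)
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  n <- sum(tab)
  if (n < 1) stop("empty agreement table")
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) return(1)
    if (allow_degenerate) return(NA_real_)
    stop("kappa undefined: chance agreement is 1 but observed agreement is not")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Exact McNemar test from discordant-pair counts
#'
#' Exact two-sided binomial test of the discordant counts: under the null of
#' marginal homogeneity, `b ~ Binomial(b + c, 1/2)`. The p-value doubles the
#' smaller tail, capped at 1. With no discordant pairs the test carries no
#' information and returns p = 1 with a message.
#'
#' @param b,c the two discordant cell counts of the paired 2x2 table.
#' @return the exact two-sided p-value.
#' @export
#' @examples
#' mcnemar_exact(0, 8)  # 2 * 0.5^8 = 0.0078125
mcnemar_exact <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) {
    message("McNemar: no discordant pairs; p = 1")
    return(1)
  }
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Pearson correlation with complete-case pairing
#'
#' Sample Pearson product-moment correlation with the usual two-sided t-test
#' on `n - 2` degrees of freedom, after dropping incomplete pairs.
#'
#' @param x,y aligned numeric vectors.
#' @return list with `r`, `p_value`, `n` (complete pairs).
#' @export
pearson_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("'x' has zero variance")
  if (stats::sd(y) == 0) stop("'y' has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Two-group rank-sum comparison
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test for independent samples:
#' exact enumeration when both groups have at most 10 observations and no
#' ties, otherwise the normal approximation with midranks for ties.
#'
#' @param group1,group2 numeric vectors.
#' @return list with `statistic` (Mann-Whitney U of group 1), `p_value`, and
#'   `method`.
#' @export
rank_sum_test <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  stopifnot(length(group1) >= 1, length(group2) >= 1)
  ties <- anyDuplicated(c(group1, group2)) > 0
  exact <- length(group1) <= 10 && length(group2) <= 10 && !ties
  wt <- suppressWarnings(stats::wilcox.test(group1, group2, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Per-class sample size for estimating a proportion
#'
#' Minimum number of subjects in one reference class needed to estimate a
#' proportion (an anticipated sensitivity or specificity) to a given absolute
#' precision: `n = ceiling(z^2 p (1 - p) / d^2)` with `z` the two-sided
#' standard-normal quantile of the confidence level.
#'
#' @param p anticipated proportion (e.g. 0.80).
#' @param precision absolute half-width of the interval (e.g. 0.10).
#' @param conf_level confidence level (e.g. 0.95).
#' @return the required per-class count.
#' @export
#' @examples
#' sample_size_prop(0.80, 0.10, 0.95)                  # 62
#' total_sample_size(sample_size_prop(0.80, 0.10), 0.25)  # 248
sample_size_prop <- function(p = 0.80, precision = 0.10, conf_level = 0.95) {
  stopifnot(p > 0, p < 1, precision > 0, precision <= 1,
            conf_level > 0.5, conf_level < 1)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ceiling(z^2 * p * (1 - p) / precision^2)
}

#' Total sample size from a per-class requirement and a prevalence
#'
#' Scales the per-class requirement (for the rarer, condition-positive class)
#' to a total study size under an anticipated prevalence:
#' `ceiling(per_class_n / prevalence)`.
#'
#' @param per_class_n subjects required in the condition-positive class.
#' @param prevalence anticipated prevalence of that class.
#' @return the minimal total sample size.
#' @export
total_sample_size <- function(per_class_n, prevalence) {
  stopifnot(per_class_n >= 1, prevalence > 0, prevalence < 1)
  ceiling(per_class_n / prevalence)
}

#' Intra-assay coefficient of variation from replicate measurements
#'
#' Within-sample repeatability summary: for each sample the coefficient of
#' variation `cv = sd / mean` over its replicates (n-1 denominator SD), and
#' the minimum, maximum and unweighted mean CV across samples.
#'
#' @param replicates a `data.frame` with columns `sample` (identifier) and
#'   `value` (replicate measurements), as produced by [synth_replicates()].
#' @return list with `per_sample` (`data.frame`: `sample`, `n_rep`, `mean`,
#'   `sd`, `cv`) and scalars `min_cv`, `max_cv`, `mean_cv`.
#' @export
intra_assay_cv <- function(replicates) {
  stopifnot(is.data.frame(replicates),
            all(c("sample", "value") %in% names(replicates)))
  per <- lapply(split(replicates$value, replicates$sample), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("each sample needs at least 2 replicates")
    m <- mean(v)
    if (m <= 0) stop("non-positive replicate mean; CV undefined")
    data.frame(n_rep = length(v), mean = m, sd = stats::sd(v),
               cv = stats::sd(v) / m)
  })
  tab <- do.call(rbind, per)
  tab <- cbind(sample = names(per), tab)
  rownames(tab) <- NULL
  list(per_sample = tab, min_cv = min(tab$cv), max_cv = max(tab$cv),
       mean_cv = mean(tab$cv))
}
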