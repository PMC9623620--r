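#' Youden's J statistic
#'
#' `J = Se + Sp - 1`, the vertical distance of an ROC operating point above
#' the chance diagonal; the classical cutoff-selection criterion.
#'
#' @param se,sp sensitivity and specificity as proportions in `[0, 1]`.
#' @return J, in `[-1, 1]`.
#' @export
youden_j <- function(se, sp) se + sp - 1

#' Distance from an ROC operating point to the ideal corner
#'
#' Euclidean distance between the operating point `(1 - Sp, Se)` and the
#' perfect-test corner `(0, 1)` of ROC space:
#' `d = sqrt((1 - Se)^2 + (1 - Sp)^2)`. With `squared = TRUE` returns
#' `d^2 = (1 - Se)^2 + (1 - Sp)^2`.
#'
#' @inheritParams youden_j
#' @param squared return the squared distance instead of the distance.
#' @return the (squared) corner distance.
#' @export
corner_distance <- function(se, sp, squared = FALSE) {
  d2 <- (1 - se)^2 + (1 - sp)^2
  if (squared) d2 else sqrt(d2)
}

trap_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

#' Empirical ROC curve of a continuous test against a binary reference
#'
#' Builds the empirical ROC curve over candidate cutoffs taken at the distinct
#' observed values, plus a sentinel yielding the all-negative classification.
#' Under `orientation = "lower_is_positive"` (the default, appropriate for
#' markers that *decrease* with disease, as all serum proxies of IgG do for
#' FTPI) a subject is called positive iff `value <= cutoff`; under
#' `"higher_is_positive"`, iff `value >= cutoff`. Pairs with a missing value
#' or label are dropped (complete-case per test).
#'
#' Because the orientation is a modelling statement, not something to detect
#' silently, the curve is rejected with an error when its AUC falls below 0.5
#' unless `check_direction = FALSE`.
#'
#' @param values numeric vector of test measurements.
#' @param labels reference classification, coercible to logical
#'   (`TRUE`/1 = condition positive).
#' @param orientation which tail of the test distribution indicates a
#'   positive.
#' @param test label used in printed and tabulated output.
#' @param check_direction error when AUC < 0.5 (likely mis-specified
#'   orientation)?
#' @return an object of class `ftpi_roc`: cutoffs in sweep order with their
#'   `(fpr, tpr)` points (starting at (0,0) and ending at (1,1)), class
#'   counts `n_pos`/`n_neg`, the retained positive/negative values, and the
#'   trapezoidal `auc`.
#' @seealso [roc_auc()], [cutoff_youden()], [performance_at()],
#'   [constrained_cutoffs()]
#' @export
#' @examples
#' r <- roc_curve(c(5, 9, 11, 15), c(TRUE, TRUE, FALSE, FALSE))
#' roc_auc(r)
#' cutoff_youden(r)
roc_curve <- function(values, labels,
                      orientation = c("lower_is_positive", "higher_is_positive"),
                      test = deparse(substitute(values)),
                      check_direction = TRUE) {
  orientation <- match.arg(orientation)
  test <- paste(as.character(test), collapse = "")
  if (nchar(test) > 40) test <- paste0(substr(test, 1, 37), "...")
  labels <- as.logical(labels)
  if (length(values) != length(labels))
    stop("'values' and 'labels' must be aligned")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1L || n_neg < 1L)
    stop("ROC undefined: need at least one positive and one negative label (have ",
         n_pos, " / ", n_neg, ")")

  u <- sort(unique(values))
  pos_tab <- tabulate(match(values[labels], u), nbins = length(u))
  neg_tab <- tabulate(match(values[!labels], u), nbins = length(u))
  if (orientation == "lower_is_positive") {
    cutoffs <- c(-Inf, u)
    tpr <- c(0, cumsum(pos_tab)) / n_pos
    fpr <- c(0, cumsum(neg_tab)) / n_neg
  } else {
    cutoffs <- c(Inf, rev(u))
    tpr <- c(0, cumsum(rev(pos_tab))) / n_pos
    fpr <- c(0, cumsum(rev(neg_tab))) / n_neg
  }
  auc <- trap_auc(fpr, tpr)
  if (check_direction && auc < 0.5)
    stop(sprintf(
      "AUC = %.3f < 0.5 for test '%s': orientation '%s' looks wrong; %s",
      auc, test, orientation,
      "flip it or pass check_direction = FALSE to keep it"))
  structure(list(test = test, orientation = orientation,
                 cutoffs = cutoffs, tpr = tpr, fpr = fpr,
                 n_pos = n_pos, n_neg = n_neg,
                 pos = values[labels], neg = values[!labels],
                 auc = auc),
            class = "ftpi_roc")
}

#' Area under an empirical ROC curve
#'
#' Trapezoidal area over the `(fpr, tpr)` polyline. For the empirical curve
#' this equals the Mann-Whitney pairwise statistic: the probability that a
#' random positive's value beats a random negative's under the curve's
#' orientation, counting ties as one half.
#'
#' @param roc an [roc_curve()] object.
#' @return the AUC, in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "ftpi_roc"))
  roc$auc
}

#' @export
print.ftpi_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC for '%s' (%s)\n", x$test, x$orientation))
  cat(sprintf("  %d positives, %d negatives, %d candidate cutoffs, AUC = %.3f\n",
              x$n_pos, x$n_neg, length(x$cutoffs), x$auc))
  invisible(x)
}

#' @export
plot.ftpi_roc <- function(x, add = FALSE, col = "black",
                          mark_youden = TRUE, ...) {
  if (!add) {
    graphics::plot(x$fpr, x$tpr, type = "l", col = col,
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1),
                   main = sprintf("%s (AUC = %.2f)", x$test, x$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  } else {
    graphics::lines(x$fpr, x$tpr, col = col, ...)
  }
  if (mark_youden) {
    j <- x$tpr + (1 - x$fpr) - 1
    i <- which.max(j)
    graphics::points(x$fpr[i], x$tpr[i], pch = 19, col = col)
  }
  invisible(x)
}

# confusion counts of the call (value vs cutoff under orientation) against
# the reference labels stored in the ROC object
confusion_at <- function(roc, cutoff) {
  call_pos <- function(v) {
    if (roc$orientation == "lower_is_positive") v <= cutoff else v >= cutoff
  }
  c(tp = sum(call_pos(roc$pos)), fn = sum(!call_pos(roc$pos)),
    fp = sum(call_pos(roc$neg)), tn = sum(!call_pos(roc$neg)))
}

#' Diagnostic performance at a given cutoff
#'
#' Evaluates sensitivity, specificity, exact (Clopper-Pearson) confidence
#' intervals, Youden's J, the corner distance (and its square), Cohen's kappa
#' against the reference classification, and carries the curve's AUC, all at
#' one pre-specified cutoff. Under `lower_is_positive` a subject is called
#' positive iff `value <= cutoff`.
#'
#' @param roc an [roc_curve()] object.
#' @param cutoff cutoff in test units (need not be an observed value).
#' @param conf_level confidence level for the exact binomial intervals.
#' @return a one-row `data.frame`: `test`, `cutoff`, `n_pos`, `n_neg`, `se`,
#'   `se_lo`, `se_hi`, `sp`, `sp_lo`, `sp_hi`, `j`, `dist`, `dist_sq`, `auc`,
#'   `kappa`.
#' @export
performance_at <- function(roc, cutoff, conf_level = 0.95) {
  stopifnot(inherits(roc, "ftpi_roc"), is.finite(cutoff) || is.infinite(cutoff))
  ct <- confusion_at(roc, cutoff)
  se <- ct[["tp"]] / roc$n_pos
  sp <- ct[["tn"]] / roc$n_neg
  se_ci <- clopper_pearson(ct[["tp"]], roc$n_pos, conf_level)
  sp_ci <- clopper_pearson(ct[["tn"]], roc$n_neg, conf_level)
  kap <- cohen_kappa(matrix(c(ct[["tp"]], ct[["fn"]], ct[["fp"]], ct[["tn"]]),
                            nrow = 2), allow_degenerate = TRUE)
  data.frame(test = roc$test, cutoff = cutoff,
             n_pos = roc$n_pos, n_neg = roc$n_neg,
             se = se, se_lo = se_ci[["lower"]], se_hi = se_ci[["upper"]],
             sp = sp, sp_lo = sp_ci[["lower"]], sp_hi = sp_ci[["upper"]],
             j = youden_j(se, sp),
             dist = corner_distance(se, sp),
             dist_sq = corner_distance(se, sp, squared = TRUE),
             auc = roc$auc, kappa = kap,
             stringsAsFactors = FALSE)
}

#' Youden-optimal cutoff
#'
#' Selects, among the curve's candidate cutoffs, the one maximizing Youden's
#' `J = Se + Sp - 1`. Ties on J are broken by the smaller corner distance,
#' then by the higher sensitivity, then by the smaller cutoff; the rule is
#' deterministic. The reported cutoff is an observed test value (not an
#' inter-value midpoint), so cutoffs stay on the instrument's reporting scale.
#'
#' @inheritParams performance_at
#' @return the [performance_at()] row of the selected cutoff.
#' @export
cutoff_youden <- function(roc, conf_level = 0.95) {
  stopifnot(inherits(roc, "ftpi_roc"))
  se <- roc$tpr; sp <- 1 - roc$fpr
  j <- youden_j(se, sp)
  d <- corner_distance(se, sp)
  ord <- order(-j, d, -se, roc$cutoffs)
  best <- ord[1L]
  performance_at(roc, roc$cutoffs[best], conf_level)
}

#' Specificity- and sensitivity-constrained decision thresholds
#'
#' Computes the confident rule-in / rule-out threshold pair: the *rule-in*
#' cutoff maximizes sensitivity among cutoffs whose specificity is at least
#' `min_sp` (a call on that side is a confident positive), and the *rule-out*
#' cutoff maximizes specificity among cutoffs whose sensitivity is at least
#' `min_se` (a confident negative). Under `lower_is_positive` the rule-in
#' cutoff never exceeds the rule-out cutoff; values between the two fall in
#' an explicit grey zone where no confident call is made. A side whose
#' constraint can only be met by the degenerate all-one-class rule is
#' reported as `NA` with a message.
#'
#' @inheritParams performance_at
#' @param min_sp minimum specificity for the rule-in side.
#' @param min_se minimum sensitivity for the rule-out side.
#' @return a one-row `data.frame`: `test`, `rule_in`, `rule_in_se`,
#'   `rule_in_sp`, `rule_out`, `rule_out_se`, `rule_out_sp`.
#' @export
constrained_cutoffs <- function(roc, min_sp = 0.95, min_se = 0.95) {
  stopifnot(inherits(roc, "ftpi_roc"), min_sp >= 0, min_sp < 1,
            min_se >= 0, min_se < 1)
  se <- roc$tpr; sp <- 1 - roc$fpr
  pick <- function(ok, primary, secondary) {
    if (!any(ok)) return(NA_integer_)
    idx <- which(ok)
    idx[order(-primary[idx], -secondary[idx])][1L]
  }
  i_in <- pick(sp >= min_sp & se > 0, se, sp)
  if (is.na(i_in))
    message(sprintf("test '%s': no cutoff achieves specificity >= %g with nonzero sensitivity",
                    roc$test, min_sp))
  i_out <- pick(se >= min_se & sp > 0, sp, se)
  if (is.na(i_out))
    message(sprintf("test '%s': no cutoff achieves sensitivity >= %g with nonzero specificity",
                    roc$test, min_se))
  data.frame(test = roc$test,
             rule_in = if (is.na(i_in)) NA_real_ else roc$cutoffs[i_in],
             rule_in_se = if (is.na(i_in)) NA_real_ else se[i_in],
             rule_in_sp = if (is.na(i_in)) NA_real_ else sp[i_in],
             rule_out = if (is.na(i_out)) NA_real_ else roc$cutoffs[i_out],
             rule_out_se = if (is.na(i_out)) NA_real_ else se[i_out],
             rule_out_sp = if (is.na(i_out)) NA_real_ else sp[i_out],
             stringsAsFactors = FALSE)
}
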