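# test panel evaluated by ftpi_eval: column, display label, optional age
# stratum (NULL = all ages)
ftpi_test_panel <- function(ggt_strata) {
  panel <- list(
    list(name = "stp_op", column = "stp_op", stratum = NULL),
    list(name = "brix",   column = "brix",   stratum = NULL),
    list(name = "stp_ba", column = "stp_ba", stratum = NULL),
    list(name = "glob",   column = "glob",   stratum = NULL),
    list(name = "ggt",    column = "ggt",    stratum = NULL))
  for (g in names(ggt_strata))
    panel[[length(panel) + 1L]] <- list(name = paste0("ggt_", g),
                                        column = "ggt", stratum = g)
  panel
}

#' Evaluate a panel of indirect FTPI tests against the RID-IgG reference
#'
#' Fits the full diagnostic-test-accuracy evaluation to a calf dataset:
#' applies the age filter, derives globulin and the binary FTPI reference
#' status (IgG below `ftpi_threshold`), and then, per indirect test on its own
#' complete cases, computes the test-IgG Pearson correlation, the empirical
#' ROC curve, the Youden-optimal cutoff with sensitivity/specificity (exact
#' binomial confidence intervals), corner distance, AUC and Cohen's kappa,
#' and the specificity-/sensitivity-constrained rule-in/rule-out threshold
#' pair. GGT is additionally evaluated within each age stratum, since its
#' serum activity declines steeply over the first week of life. The whole
#' procedure is deterministic: the same data and configuration reproduce the
#' same object.
#'
#' @param data a calf dataset ([read_calf_data()] or [synth_cohort()]).
#' @param ftpi_threshold reference IgG threshold (g/L) defining FTPI
#'   (positive iff `igg_rid < ftpi_threshold`).
#' @param conf_level level of the exact binomial confidence intervals.
#' @param constrained_sp,constrained_se constraints of the rule-in / rule-out
#'   thresholds.
#' @param age_window inclusive age window (days) for inclusion.
#' @param ggt_strata named list of age ranges stratifying the GGT analysis.
#' @param borderline_exclusion optional closed IgG interval (g/L) straddling
#'   the threshold; when given, a sensitivity analysis re-evaluates the
#'   frozen optimal cutoffs after discarding calves whose reference IgG falls
#'   in it (see [sensitivity_borderline()]).
#' @param fixed_cutoffs optional named numeric vector of pre-specified
#'   cutoffs (names among the test names) evaluated verbatim in addition to
#'   the optimal ones.
#' @param check_direction passed to [roc_curve()].
#' @return an object of class `ftpi_eval` with components `descriptives`,
#'   `correlations`, `performance` (one row per test / stratum),
#'   `constrained`, `fixed` (optional), `sensitivity` (optional), `rocs`,
#'   `prevalence`, `n`, `filter_counts`, `config`, `data` and `call`. Methods:
#'   [print()], [summary()], [coef()] (the optimal cutoffs), [predict()]
#'   (classify new calves) and [plot()] (ROC curves).
#' @export
#' @examples
#' fit <- ftpi_eval(synth_cohort(synth_config(seed = 7)))
#' fit
#' coef(fit)
ftpi_eval <- function(data,
                      ftpi_threshold = 10,
                      conf_level = 0.95,
                      constrained_sp = 0.95,
                      constrained_se = 0.95,
                      age_window = c(2, 6),
                      ggt_strata = list("2-3 d" = c(2, 3), "4-6 d" = c(4, 6)),
                      borderline_exclusion = NULL,
                      fixed_cutoffs = NULL,
                      check_direction = TRUE) {
  cl <- match.call()
  stopifnot(conf_level > 0, conf_level < 1,
            constrained_sp > 0, constrained_sp < 1,
            constrained_se > 0, constrained_se < 1,
            length(age_window) == 2, age_window[1] <= age_window[2])
  if (!is.null(borderline_exclusion)) {
    stopifnot(length(borderline_exclusion) == 2,
              borderline_exclusion[1] <= borderline_exclusion[2])
    if (ftpi_threshold < borderline_exclusion[1] ||
        ftpi_threshold > borderline_exclusion[2])
      stop("borderline_exclusion interval must contain the FTPI threshold")
  }

  n_input <- nrow(data)
  ds <- apply_age_filter(data, age_window[1], age_window[2])
  filter_counts <- attr(ds, "filter_counts")
  ds <- derive_fields(ds, ftpi_threshold, age_breaks = ggt_strata)

  status <- ds$ftpi_status
  n_pos <- sum(status, na.rm = TRUE)
  n_neg <- sum(!status, na.rm = TRUE)
  if (n_pos < 1 || n_neg < 1)
    stop(sprintf(
      "reference classification is single-class after filtering (%d FTPI+, %d FTPI-)",
      n_pos, n_neg))

  descriptives <- describe_calves(ds, c("igg_rid", "stp_ba", "alb", "brix",
                                        "stp_op", "glob", "ggt"))
  for (g in names(ggt_strata)) {
    sub <- ds[!is.na(ds$age_group) & ds$age_group == g, , drop = FALSE]
    row <- describe_calves(sub, "ggt")
    row$variable <- paste0("ggt_", g)
    descriptives <- rbind(descriptives, row)
  }

  corr_tests <- c("brix", "stp_op", "stp_ba", "glob", "ggt")
  correlations <- do.call(rbind, lapply(corr_tests, function(v) {
    pc <- pearson_cor(ds[[v]], ds$igg_rid)
    data.frame(test = v, r = pc$r, p_value = pc$p_value, n = pc$n)
  }))

  panel <- ftpi_test_panel(ggt_strata)
  rocs <- list(); perf <- list(); constr <- list()
  for (spec in panel) {
    sub <- ds
    if (!is.null(spec$stratum))
      sub <- ds[!is.na(ds$age_group) & ds$age_group == spec$stratum, , drop = FALSE]
    vals <- sub[[spec$column]]
    roc <- roc_curve(vals, sub$ftpi_status, "lower_is_positive",
                     test = spec$name, check_direction = check_direction)
    rocs[[spec$name]] <- roc
    perf[[spec$name]] <- cutoff_youden(roc, conf_level)
    constr[[spec$name]] <- constrained_cutoffs(roc, constrained_sp, constrained_se)
  }
  performance <- do.call(rbind, perf); rownames(performance) <- NULL
  constrained <- do.call(rbind, constr); rownames(constrained) <- NULL

  fixed <- NULL
  if (!is.null(fixed_cutoffs)) {
    bad <- setdiff(names(fixed_cutoffs), names(rocs))
    if (length(bad)) stop("fixed_cutoffs name(s) not in the test panel: ",
                          paste(bad, collapse = ", "))
    fixed <- do.call(rbind, lapply(names(fixed_cutoffs), function(nm)
      performance_at(rocs[[nm]], fixed_cutoffs[[nm]], conf_level)))
    rownames(fixed) <- NULL
  }

  fit <- structure(list(
    call = cl,
    config = list(ftpi_threshold = ftpi_threshold, conf_level = conf_level,
                  constrained_sp = constrained_sp, constrained_se = constrained_se,
                  age_window = age_window, ggt_strata = ggt_strata,
                  borderline_exclusion = borderline_exclusion,
                  fixed_cutoffs = fixed_cutoffs),
    data = ds, n = nrow(ds), n_input = n_input,
    filter_counts = filter_counts,
    prevalence = n_pos / (n_pos + n_neg),
    n_ftpi_pos = n_pos, n_ftpi_neg = n_neg,
    descriptives = descriptives, correlations = correlations,
    performance = performance, constrained = constrained,
    fixed = fixed, rocs = rocs, sensitivity = NULL,
    version = as.character(utils::packageVersion("ftpidta"))
  ), class = "ftpi_eval")

  if (!is.null(borderline_exclusion))
    fit$sensitivity <- sensitivity_borderline(fit, borderline_exclusion)
  fit
}

#' @export
print.ftpi_eval <- function(x, digits = 3, ...) {
  cat("FTPI diagnostic test evaluation\n")
  cat(sprintf("  %d calves analysed (of %d input), FTPI prevalence %.1f%% (%d/%d) at IgG < %g g/L\n",
              x$n, x$n_input, 100 * x$prevalence, x$n_ftpi_pos,
              x$n_ftpi_pos + x$n_ftpi_neg, x$config$ftpi_threshold))
  cat("\nYouden-optimal cutoffs:\n")
  p <- x$performance
  out <- data.frame(test = p$test, cutoff = p$cutoff,
                    se = sprintf("%.1f%% (%.1f-%.1f)", 100 * p$se, 100 * p$se_lo, 100 * p$se_hi),
                    sp = sprintf("%.1f%% (%.1f-%.1f)", 100 * p$sp, 100 * p$sp_lo, 100 * p$sp_hi),
                    J = round(p$j, 2), dist = round(p$dist, 2),
                    AUC = round(p$auc, 2), kappa = round(p$kappa, 2))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ftpi_eval <- function(object, ...) {
  structure(list(fit = object), class = "summary.ftpi_eval")
}

#' @export
print.summary.ftpi_eval <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nDescriptive statistics (complete cases per variable):\n")
  d <- fit$descriptives
  d[-1] <- lapply(d[-1], function(v) round(v, 2))
  print(d, row.names = FALSE)
  cat("\nTest-IgG Pearson correlations:\n")
  co <- fit$correlations
  co$r <- round(co$r, 2); co$p_value <- signif(co$p_value, 2)
  print(co, row.names = FALSE)
  cat(sprintf("\nConstrained thresholds (rule-in Sp >= %g, rule-out Se >= %g):\n",
              fit$config$constrained_sp, fit$config$constrained_se))
  print(fit$constrained, row.names = FALSE, digits = 3)
  if (!is.null(fit$fixed)) {
    cat("\nPre-specified cutoffs:\n")
    print(fit$fixed, row.names = FALSE, digits = 3)
  }
  if (!is.null(fit$sensitivity)) {
    cat(sprintf("\nBorderline-exclusion sensitivity analysis (IgG in [%g, %g] excluded, %d calves):\n",
                fit$config$borderline_exclusion[1], fit$config$borderline_exclusion[2],
                attr(fit$sensitivity, "n_excluded")))
    print(fit$sensitivity, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.ftpi_eval <- function(object, ...) {
  stats::setNames(object$performance$cutoff, object$performance$test)
}

#' Classify new calves with fitted thresholds
#'
#' Applies the fitted Youden cutoffs (`rule = "youden"`: binary
#' positive/negative calls) or the constrained rule-in/rule-out pair
#' (`rule = "constrained"`: positive / grey / negative, with the grey zone
#' between the two thresholds) to new measurements. All panel tests use the
#' lower-tail convention: a value at or below the cutoff is a positive call.
#'
#' @param object an [ftpi_eval()] fit.
#' @param newdata a `data.frame` with (some of) the panel's measurement
#'   columns; GGT stratum tests additionally need `age_days`.
#' @param rule which fitted thresholds to apply.
#' @param tests which panel tests to apply (default: all with available
#'   columns).
#' @param ... unused.
#' @return a `data.frame` of factor columns (one per test) with levels
#'   `positive`, `grey`, `negative`.
#' @export
predict.ftpi_eval <- function(object, newdata,
                              rule = c("youden", "constrained"),
                              tests = NULL, ...) {
  rule <- match.arg(rule)
  if (!"glob" %in% names(newdata) &&
      all(c("stp_ba", "alb") %in% names(newdata)))
    newdata$glob <- newdata$stp_ba - newdata$alb
  panel <- ftpi_test_panel(object$config$ggt_strata)
  names(panel) <- vapply(panel, `[[`, "", "name")
  if (is.null(tests))
    tests <- names(panel)[vapply(panel, function(s) s$column %in% names(newdata),
                                 TRUE)]
  out <- data.frame(row.names = seq_len(nrow(newdata)))
  for (nm in tests) {
    spec <- panel[[nm]]
    v <- newdata[[spec$column]]
    in_stratum <- rep(TRUE, length(v))
    if (!is.null(spec$stratum)) {
      rng <- object$config$ggt_strata[[spec$stratum]]
      in_stratum <- !is.na(newdata$age_days) &
        newdata$age_days >= rng[1] & newdata$age_days <= rng[2]
    }
    if (rule == "youden") {
      cut <- object$performance$cutoff[object$performance$test == nm]
      call <- ifelse(v <= cut, "positive", "negative")
    } else {
      cc <- object$constrained[object$constrained$test == nm, ]
      call <- ifelse(v <= cc$rule_in, "positive",
                     ifelse(v > cc$rule_out, "negative", "grey"))
    }
    call[!in_stratum] <- NA
    out[[nm]] <- factor(call, levels = c("positive", "grey", "negative"))
  }
  out
}

#' @export
plot.ftpi_eval <- function(x, tests = NULL, ...) {
  if (is.null(tests)) tests <- names(x$rocs)
  k <- length(tests)
  mfrow <- c(ceiling(k / 3), min(k, 3))
  old <- graphics::par(mfrow = mfrow, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in tests) plot(x$rocs[[nm]], ...)
  invisible(x)
}

#' Borderline-exclusion sensitivity analysis
#'
#' Quantifies the influence of reference-assay imprecision near the decision
#' threshold: calves whose RID-IgG lies in a closed interval straddling the
#' FTPI threshold are discarded and the main run's optimal cutoffs -- frozen,
#' not re-optimized -- are re-evaluated on the reduced data. Calves near the
#' threshold are the ones a slightly imprecise reference may misclassify, so
#' removing them typically improves apparent sensitivity and specificity.
#'
#' @param fit an [ftpi_eval()] object.
#' @param interval closed IgG interval (g/L) containing the FTPI threshold.
#' @param conf_level confidence level for the re-evaluated intervals.
#' @return a `data.frame` with one row per test: the frozen `cutoff`, reduced
#'   `se`/`sp` with confidence bounds, and `delta_se`/`delta_sp` relative to
#'   the main run; attribute `n_excluded` gives the number of discarded
#'   calves.
#' @export
sensitivity_borderline <- function(fit, interval = c(9, 11),
                                   conf_level = fit$config$conf_level) {
  stopifnot(inherits(fit, "ftpi_eval"), length(interval) == 2,
            interval[1] <= interval[2])
  thr <- fit$config$ftpi_threshold
  if (thr < interval[1] || thr > interval[2])
    stop("exclusion interval must straddle the FTPI threshold")
  ds <- fit$data
  drop <- !is.na(ds$igg_rid) & ds$igg_rid >= interval[1] & ds$igg_rid <= interval[2]
  sub <- ds[!drop, , drop = FALSE]
  if (sum(sub$ftpi_status, na.rm = TRUE) < 1 ||
      sum(!sub$ftpi_status, na.rm = TRUE) < 1)
    stop(sprintf("exclusion empties a reference class (%d FTPI+ / %d FTPI- left)",
                 sum(sub$ftpi_status, na.rm = TRUE),
                 sum(!sub$ftpi_status, na.rm = TRUE)))
  panel <- ftpi_test_panel(fit$config$ggt_strata)
  rows <- lapply(panel, function(spec) {
    dsub <- sub
    if (!is.null(spec$stratum))
      dsub <- sub[!is.na(sub$age_group) & sub$age_group == spec$stratum, , drop = FALSE]
    roc <- roc_curve(dsub[[spec$column]], dsub$ftpi_status, "lower_is_positive",
                     test = spec$name, check_direction = FALSE)
    cut <- fit$performance$cutoff[fit$performance$test == spec$name]
    performance_at(roc, cut, conf_level)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$delta_se <- out$se - fit$performance$se
  out$delta_sp <- out$sp - fit$performance$sp
  out <- out[, c("test", "cutoff", "n_pos", "n_neg", "se", "se_lo", "se_hi",
                 "sp", "sp_lo", "sp_hi", "delta_se", "delta_sp")]
  attr(out, "n_excluded") <- sum(drop)
  attr(out, "interval") <- interval
  out
}

#' Paired comparison of two tests by exact McNemar tests
#'
#' Compares how two indirect tests classify the same calves at their fitted
#' cutoffs, on the calves where both tests (and the reference) are observed.
#' Within reference-positive calves the discordant positive calls feed an
#' exact McNemar test of the sensitivities; within reference-negative calves,
#' of the specificities.
#'
#' @param fit an [ftpi_eval()] object.
#' @param test_a,test_b names of two panel tests.
#' @param cutoffs optional named numeric vector overriding the fitted Youden
#'   cutoffs for either test.
#' @return a list with the overlap size, per-class discordant counts
#'   (`b` = `test_a`-positive only, `c` = `test_b`-positive only) and the two
#'   exact p-values (`p_se`, `p_sp`).
#' @export
compare_tests_paired <- function(fit, test_a, test_b, cutoffs = NULL) {
  stopifnot(inherits(fit, "ftpi_eval"))
  panel <- ftpi_test_panel(fit$config$ggt_strata)
  names(panel) <- vapply(panel, `[[`, "", "name")
  for (nm in c(test_a, test_b))
    if (!nm %in% names(panel)) stop("unknown test: ", nm)
  get_cut <- function(nm) {
    if (!is.null(cutoffs) && nm %in% names(cutoffs)) return(cutoffs[[nm]])
    fit$performance$cutoff[fit$performance$test == nm]
  }
  ds <- fit$data
  col_a <- panel[[test_a]]$column; col_b <- panel[[test_b]]$column
  keep <- !is.na(ds[[col_a]]) & !is.na(ds[[col_b]]) & !is.na(ds$ftpi_status)
  for (nm in c(test_a, test_b)) {
    st <- panel[[nm]]$stratum
    if (!is.null(st)) keep <- keep & !is.na(ds$age_group) & ds$age_group == st
  }
  if (!any(keep)) stop("no overlapping complete cases for ", test_a, " and ", test_b)
  ds <- ds[keep, , drop = FALSE]
  pos_a <- ds[[col_a]] <= get_cut(test_a)
  pos_b <- ds[[col_b]] <= get_cut(test_b)
  tab <- function(mask) {
    c(b = sum(pos_a[mask] & !pos_b[mask]), c = sum(!pos_a[mask] & pos_b[mask]))
  }
  d_se <- tab(ds$ftpi_status)
  d_sp <- tab(!ds$ftpi_status)
  list(test_a = test_a, test_b = test_b,
       cutoff_a = get_cut(test_a), cutoff_b = get_cut(test_b),
       n_overlap = nrow(ds),
       se_discordant = d_se, p_se = mcnemar_exact(d_se[["b"]], d_se[["c"]]),
       sp_discordant = d_sp, p_sp = mcnemar_exact(d_sp[["b"]], d_sp[["c"]]))
}
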