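#' Configuration for the synthetic calf cohort generator
#'
#' Builds a generator configuration calibrated so that, in the population, the
#' synthetic cohort reproduces the study conditions the analysis assumes:
#'
#' * serum RID-IgG is log-normal, moment-matched to the target mean/SD
#'   (defaults 16.26 / 8.91 g/L), giving an FTPI prevalence of about 24% at
#'   the 10 g/L threshold;
#' * each indirect test is linear-Gaussian in IgG,
#'   `value = intercept + slope * IgG + noise`, with
#'   `slope = r * sd_test / sd_igg` and `noise_sd = sd_test * sqrt(1 - r^2)`,
#'   so the marginal mean/SD and the test-IgG Pearson correlation hit their
#'   targets exactly in expectation (defaults: Brix r = 0.73, optical total
#'   protein r = 0.74, analyzer total protein r = 0.87);
#' * albumin is built as `intercept + alpha * IgG + beta * e_STP + e_ALB`
#'   (with `e_STP` the analyzer-protein noise), with `alpha`, `beta` and
#'   `sd(e_ALB)` solved so that albumin's marginal mean/SD, the derived
#'   globulin's (`stp_ba - alb`) marginal SD, and the globulin-IgG correlation
#'   (default 0.89) are all exact; the albumin/total-protein correlation is
#'   then emergent (about 0.49 under the defaults);
#' * GGT activity is generated within age group (group means 640.46 and
#'   456.56 IU/L for 2-3 d and 4-6 d calves), with the within-group
#'   correlation inflated analytically so the pooled GGT-IgG correlation hits
#'   its target (default 0.67) despite the between-group mean shift;
#' * age groups follow the study proportions (including day-0/1, over-6-day
#'   and missing-age calves that the age filter later removes), allocated by
#'   largest-remainder apportionment so group counts are exact at the default
#'   cohort size;
#' * per-test missingness is completely at random, except GGT whose
#'   missingness rate differs by age group to match the published stratum
#'   sizes.
#'
#' @param n_calves number of calves to generate (default 258, the pre-filter
#'   cohort size).
#' @param n_herds nominal number of herds; herd sizes are drawn from 1-6
#'   calves (median 3) so the realised herd count is close to, not exactly,
#'   this value.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @param herd_sd SD of an additive herd effect on the log-IgG scale
#'   (default 0: no clustering, matching an analysis that ignores herd).
#' @param igg_mean,igg_sd target marginal mean and SD of RID-IgG (g/L).
#' @param igg_mixture optional two-component log-normal mixture for IgG,
#'   a list `list(weight, meanlog, sdlog)` with two-element `meanlog`/`sdlog`
#'   (first component = low-IgG subpopulation); overrides the moment-matched
#'   single log-normal when supplied.
#' @param test_targets data frame with columns `test`, `mean`, `sd`, `r`
#'   giving marginal targets and test-IgG correlations for the linear tests
#'   (`brix`, `stp_op`, `stp_ba`).
#' @param alb_mean,alb_sd albumin marginal targets (g/L).
#' @param glob_sd,glob_r derived-globulin marginal SD target and globulin-IgG
#'   correlation target.
#' @param ggt_r pooled GGT-IgG correlation target.
#' @param ggt_group_mean,ggt_group_sd,ggt_group_n named vectors (groups
#'   `"2-3"`, `"4-6"`) of GGT group means/SDs (IU/L) and observed stratum
#'   sizes; the stratum sizes set both the pooling weights of the correlation
#'   calibration and the age-dependent GGT missingness.
#' @param age_probs named probabilities over age classes
#'   `c("0-1", "2-3", "4-6", "7+", "missing")`.
#' @param missing_rates named per-test missingness probabilities (GGT is
#'   handled separately via `ggt_group_n`).
#' @param age_group_total number of calves in the two analysis age groups
#'   used, with `ggt_group_n`, to derive the GGT missingness rates.
#' @return an object of class `synth_config`: a list of the arguments plus the
#'   derived calibration (`calib`).
#' @seealso [synth_cohort()]
#' @export
#' @examples
#' cfg <- synth_config(seed = 42)
#' cfg$calib$igg[["sdlog"]]      # about 0.5125
#' head(synth_cohort(cfg))
synth_config <- function(n_calves = 258,
                         n_herds = max(1L, round(n_calves * 93 / 258)),
                         seed = 1,
                         herd_sd = 0,
                         igg_mean = 16.26, igg_sd = 8.91,
                         igg_mixture = NULL,
                         test_targets = data.frame(
                           test = c("brix", "stp_op", "stp_ba"),
                           mean = c(8.83, 57.36, 59.21),
                           sd   = c(1.11, 10.11, 8.91),
                           r    = c(0.73, 0.74, 0.87)),
                         alb_mean = 22.24, alb_sd = 3.21,
                         glob_sd = 7.84, glob_r = 0.89,
                         ggt_r = 0.67,
                         ggt_group_mean = c("2-3" = 640.46, "4-6" = 456.56),
                         ggt_group_sd   = c("2-3" = 350.31, "4-6" = 293.68),
                         ggt_group_n    = c("2-3" = 114, "4-6" = 86),
                         age_probs = c("0-1" = 3, "2-3" = 132, "4-6" = 113,
                                       "7+" = 3, "missing" = 7) / 258,
                         missing_rates = c(igg_rid = 0, stp_ba = 1/245,
                                           alb = 1/245, brix = 45/245,
                                           stp_op = 4/245),
                         age_group_total = c("2-3" = 132, "4-6" = 113)) {
  stopifnot(n_calves >= 1, n_herds >= 1, n_herds <= n_calves,
            herd_sd >= 0, igg_sd > 0, alb_sd > 0, glob_sd > 0,
            all(missing_rates >= 0 & missing_rates <= 1),
            abs(sum(age_probs) - 1) < 1e-8)
  if (any(abs(c(test_targets$r, glob_r, ggt_r)) >= 1))
    stop("correlation targets must lie strictly inside (-1, 1)")

  # IgG: log-normal moment matching
  sdlog <- sqrt(log(1 + (igg_sd / igg_mean)^2))
  meanlog <- log(igg_mean) - sdlog^2 / 2

  # linear tests: slope/intercept/noise from (mean, sd, r)
  lin <- test_targets
  lin$slope <- lin$r * lin$sd / igg_sd
  lin$intercept <- lin$mean - lin$slope * igg_mean
  lin$noise_sd <- lin$sd * sqrt(1 - lin$r^2)

  # albumin / globulin: solve alpha, beta, sd(e_ALB) so that
  #   var(ALB) = alb_sd^2, var(GLOB) = glob_sd^2, corr(GLOB, IgG) = glob_r
  # with STP_BA = a + b IgG + e_B fixed by its own calibration.
  stp <- lin[lin$test == "stp_ba", ]
  b <- stp$slope; s_b2 <- stp$noise_sd^2; s_i2 <- igg_sd^2
  alpha <- b - glob_r * glob_sd / igg_sd
  A <- alpha^2 * s_i2
  k2 <- (glob_r * glob_sd)^2
  beta <- (k2 + s_b2 - A - glob_sd^2 + alb_sd^2) / (2 * s_b2)
  alb_noise_var <- alb_sd^2 - A - beta^2 * s_b2
  if (alb_noise_var < 0)
    stop("infeasible albumin/globulin correlation targets (negative noise variance)")
  alb <- list(alpha = alpha, beta = beta, noise_sd = sqrt(alb_noise_var),
              intercept = alb_mean - alpha * igg_mean)

  # GGT: within-group linear-Gaussian, but (a) the pooled correlation over
  # the age mixture is diluted by the between-group mean shift, and (b) GGT
  # is physically non-negative so draws are left-censored at zero (~3% of
  # draws under this calibration), which biases moments and attenuates the
  # correlation. Both are corrected analytically: for a trial within-group
  # correlation, each group's intercept and noise SD are solved so the
  # *censored* mean/SD hit the targets exactly (quadrature over the IgG
  # marginal), the implied censored pooled correlation is computed, and the
  # within-group correlation is rescaled until the pooled target is met.
  w <- ggt_group_n / sum(ggt_group_n)
  mix_mean <- sum(w * ggt_group_mean)
  mix_var <- sum(w * (ggt_group_sd^2 + ggt_group_mean^2)) - mix_mean^2
  quad <- igg_quadrature(meanlog, sqrt(sdlog^2 + herd_sd^2), igg_mixture)
  igg_marg_sd <- sqrt(sum(quad$w * quad$I^2) - sum(quad$w * quad$I)^2)
  r_within <- ggt_r * sqrt(mix_var) / sum(w * ggt_group_sd)
  ggt <- data.frame(group = names(ggt_group_mean),
                    mean = as.numeric(ggt_group_mean),
                    sd = as.numeric(ggt_group_sd))
  for (iter in 1:6) {
    if (abs(r_within) >= 1)
      stop("infeasible pooled GGT correlation target (within-group r would exceed 1)")
    cov_g <- numeric(nrow(ggt))
    for (i in seq_len(nrow(ggt))) {
      slope <- r_within * ggt$sd[i] / igg_marg_sd
      naive_int <- ggt$mean[i] - slope * sum(quad$w * quad$I)
      naive_noise <- ggt$sd[i] * sqrt(max(1 - r_within^2, 1e-8))
      sol <- stats::optim(c(naive_int, log(naive_noise)), function(par) {
        mo <- censored_stats(par[1], slope, exp(par[2]), quad)
        (mo[["mean"]] - ggt$mean[i])^2 + (mo[["sd"]] - ggt$sd[i])^2
      }, control = list(reltol = 1e-14, maxit = 1000))
      ggt$slope[i] <- slope
      ggt$intercept[i] <- sol$par[1]
      ggt$noise_sd[i] <- exp(sol$par[2])
      cov_g[i] <- censored_stats(sol$par[1], slope, exp(sol$par[2]), quad)[["cov"]]
    }
    pooled_r <- sum(w * cov_g) / (igg_marg_sd * sqrt(mix_var))
    if (abs(pooled_r - ggt_r) < 1e-9) break
    r_within <- r_within * ggt_r / pooled_r
  }
  ggt$r_within <- r_within
  ggt_miss <- 1 - ggt_group_n / age_group_total[names(ggt_group_n)]

  structure(list(
    n_calves = n_calves, n_herds = n_herds, seed = seed, herd_sd = herd_sd,
    igg_mean = igg_mean, igg_sd = igg_sd, igg_mixture = igg_mixture,
    test_targets = test_targets,
    alb_mean = alb_mean, alb_sd = alb_sd, glob_sd = glob_sd, glob_r = glob_r,
    ggt_r = ggt_r, ggt_group_mean = ggt_group_mean,
    ggt_group_sd = ggt_group_sd, ggt_group_n = ggt_group_n,
    age_probs = age_probs, missing_rates = missing_rates,
    calib = list(igg = c(meanlog = meanlog, sdlog = sdlog),
                 linear = lin, alb = alb, ggt = ggt,
                 ggt_missing = ggt_miss)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic calf cohort configuration\n")
  cat(sprintf("  calves: %d  (nominal herds: %d, herd_sd = %g)  seed: %d\n",
              x$n_calves, x$n_herds, x$herd_sd, x$seed))
  cat(sprintf("  IgG ~ logN(%.4f, %.4f)  [mean %.2f, SD %.2f g/L]\n",
              x$calib$igg[["meanlog"]], x$calib$igg[["sdlog"]],
              x$igg_mean, x$igg_sd))
  cat("  test-IgG correlation targets: ",
      paste(sprintf("%s %.2f", c(x$test_targets$test, "glob", "ggt"),
                    c(x$test_targets$r, x$glob_r, x$ggt_r)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Simpson-rule quadrature over the IgG marginal (log-normal or two-component
# mixture): returns nodes I and weights w with sum(w) = 1
igg_quadrature <- function(meanlog, sdlog, mixture = NULL, n_nodes = 401) {
  z <- seq(-8, 8, length.out = n_nodes)
  h <- z[2] - z[1]
  simp <- c(1, rep(c(4, 2), (n_nodes - 3) / 2), 4, 1) * h / 3
  comp <- function(ml, sl) list(I = exp(ml + sl * z), w = simp * stats::dnorm(z))
  if (is.null(mixture)) {
    q <- comp(meanlog, sdlog)
  } else {
    q1 <- comp(mixture$meanlog[1], mixture$sdlog[1])
    q2 <- comp(mixture$meanlog[2], mixture$sdlog[2])
    q <- list(I = c(q1$I, q2$I),
              w = c(mixture$weight * q1$w, (1 - mixture$weight) * q2$w))
  }
  q$w <- q$w / sum(q$w)
  q
}

# mean, SD, and covariance with IgG of max(intercept + slope * IgG + e, 0),
# e ~ N(0, noise_sd), over the IgG quadrature
censored_stats <- function(intercept, slope, noise_sd, quad) {
  mu <- intercept + slope * quad$I
  r <- mu / noise_sd
  m1v <- mu * stats::pnorm(r) + noise_sd * stats::dnorm(r)
  m2v <- (mu^2 + noise_sd^2) * stats::pnorm(r) + mu * noise_sd * stats::dnorm(r)
  m1 <- sum(quad$w * m1v)
  m2 <- sum(quad$w * m2v)
  EI <- sum(quad$w * quad$I)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)),
    cov = sum(quad$w * quad$I * m1v) - EI * m1)
}

# largest-remainder apportionment of n among classes with probabilities p
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a synthetic calf cohort
#'
#' Draws a cohort from the generating model described in [synth_config()]:
#' ages by exact apportionment over the study's age classes, herds of 1-6
#' calves (median 3), log-normal IgG (optionally with an additive herd effect
#' on the log scale), linear-Gaussian indirect tests, age-group-dependent GGT
#' and per-test missingness. Measurements are truncated at zero (only GGT is
#' materially affected, in about 2% of draws). `stp_ba` and `alb` are emitted
#' separately; calculated globulin is left to [derive_fields()].
#'
#' @param cfg a [synth_config()] object.
#' @return a calf dataset (`data.frame` in canonical column layout) of
#'   `cfg$n_calves` rows, deterministic given `cfg` (including its seed).
#' @export
synth_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_calves
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  # ages: exact apportionment, then random assignment to calves
  classes <- names(cfg$age_probs)
  counts <- apportion(n, cfg$age_probs)
  cls <- sample(rep(classes, counts))
  age <- rep(NA_integer_, n)
  age[cls == "0-1"] <- sample(0:1, sum(cls == "0-1"), replace = TRUE)
  age[cls == "2-3"] <- sample(2:3, sum(cls == "2-3"), replace = TRUE)
  age[cls == "4-6"] <- sample(4:6, sum(cls == "4-6"), replace = TRUE)
  age[cls == "7+"]  <- sample(7:10, sum(cls == "7+"), replace = TRUE)

  # herds: sizes 1-6 with median 3; realised herd count is emergent
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, sample(1:6, max(16L, ceiling(n / 2)), replace = TRUE,
                             prob = c(0.18, 0.25, 0.27, 0.17, 0.09, 0.04)))
  n_h <- which(cumsum(sizes) >= n)[1L]
  sizes <- sizes[seq_len(n_h)]
  sizes[n_h] <- sizes[n_h] - (sum(sizes) - n)
  herd <- sample(rep(seq_len(n_h), sizes))

  # reference IgG (g/L), with optional herd effect on the log scale
  herd_eff <- if (cfg$herd_sd > 0) stats::rnorm(n_h, 0, cfg$herd_sd) else rep(0, n_h)
  if (is.null(cfg$igg_mixture)) {
    igg <- exp(stats::rnorm(n, cfg$calib$igg[["meanlog"]] + herd_eff[herd],
                            cfg$calib$igg[["sdlog"]]))
  } else {
    m <- cfg$igg_mixture
    comp <- 1L + stats::rbinom(n, 1L, 1 - m$weight)
    igg <- exp(stats::rnorm(n, m$meanlog[comp] + herd_eff[herd], m$sdlog[comp]))
  }

  # linear tests
  lin <- cfg$calib$linear
  draw_lin <- function(test) {
    p <- lin[lin$test == test, ]
    p$intercept + p$slope * igg + stats::rnorm(n, 0, p$noise_sd)
  }
  e_b <- stats::rnorm(n, 0, lin$noise_sd[lin$test == "stp_ba"])
  stp_ba <- lin$intercept[lin$test == "stp_ba"] +
    lin$slope[lin$test == "stp_ba"] * igg + e_b
  a <- cfg$calib$alb
  alb <- a$intercept + a$alpha * igg + a$beta * e_b +
    stats::rnorm(n, 0, a$noise_sd)
  brix <- draw_lin("brix")
  stp_op <- draw_lin("stp_op")

  # GGT: group-wise calibration; excluded-age calves borrow the nearest
  # group's parameters (they are dropped by the age filter anyway)
  gg <- cfg$calib$ggt
  grp <- ifelse(cls == "2-3" | cls == "0-1", "2-3",
                ifelse(cls %in% c("4-6", "7+"), "4-6", NA))
  w23 <- cfg$age_probs[["2-3"]] / (cfg$age_probs[["2-3"]] + cfg$age_probs[["4-6"]])
  grp[is.na(grp)] <- ifelse(stats::runif(sum(is.na(grp))) < w23, "2-3", "4-6")
  gi <- match(grp, gg$group)
  ggt <- gg$intercept[gi] + gg$slope[gi] * igg + stats::rnorm(n, 0, gg$noise_sd[gi])

  ds <- data.frame(
    herd_id = sprintf("H%03d", herd),
    calf_id = sprintf("C%05d", seq_len(n)),
    age_days = age,
    igg_rid = igg, stp_ba = stp_ba, alb = alb, brix = brix,
    stp_op = stp_op, ggt = ggt, stringsAsFactors = FALSE)

  # physical truncation at zero (measurements cannot be negative)
  for (v in ftpi_measurements) ds[[v]] <- pmax(ds[[v]], 0)
  ds$brix <- pmin(ds$brix, 29.99)

  # per-test missingness: MCAR, except GGT which is age-group dependent
  for (v in names(cfg$missing_rates)) {
    r <- cfg$missing_rates[[v]]
    if (r > 0) ds[[v]][stats::runif(n) < r] <- NA_real_
  }
  miss_g <- cfg$calib$ggt_missing[grp]
  ds$ggt[stats::runif(n) < miss_g] <- NA_real_

  validate_calf_data(ds)
  set_provenance(ds, sprintf("synthetic cohort: n = %d, seed = %d", n, cfg$seed))
}

#' Generate replicate measurements for repeatability assessment
#'
#' For each true concentration, draws `n_rep` replicate measurements with
#' multiplicative Gaussian error of the given coefficient of variation,
#' emulating an intra-assay repeatability experiment (repeated measures of
#' independent serum samples spanning the assay's working range).
#'
#' @param true_values numeric vector of true concentrations (g/L).
#' @param cv within-sample coefficient of variation (fraction, e.g. 0.062).
#' @param n_rep replicates per sample (at least 2).
#' @param seed integer seed.
#' @return a `data.frame` with columns `sample`, `true_value`, `replicate`,
#'   `value`.
#' @seealso [intra_assay_cv()]
#' @export
synth_replicates <- function(true_values, cv, n_rep = 10, seed = 1) {
  stopifnot(cv >= 0, n_rep >= 2, all(true_values > 0))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  k <- length(true_values)
  out <- data.frame(
    sample = rep(seq_len(k), each = n_rep),
    true_value = rep(true_values, each = n_rep),
    replicate = rep(seq_len(n_rep), times = k))
  out$value <- out$true_value * (1 + stats::rnorm(nrow(out), 0, cv))
  out$value <- pmax(out$value, 0)
  out
}
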