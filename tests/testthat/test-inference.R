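test_that("Clopper-Pearson equals the tail-bisection oracle exhaustively", {
  for (n in c(1, 2, 5, 10, 17, 25)) {
    for (k in 0:n) {
      ci <- clopper_pearson(k, n)
      oracle <- cp_bisection_oracle(k, n)
      expect_equal(unname(ci["lower"]), unname(oracle["lower"]),
                   tolerance = 1e-9, label = sprintf("lower k=%d n=%d", k, n))
      expect_equal(unname(ci["upper"]), unname(oracle["upper"]),
                   tolerance = 1e-9, label = sprintf("upper k=%d n=%d", k, n))
      expect_true(ci["lower"] <= k / n + 1e-12 && ci["upper"] >= k / n - 1e-12)
    }
  }
})

test_that("Clopper-Pearson boundaries, symmetry and the study's interval", {
  expect_equal(unname(clopper_pearson(0, 10)["lower"]), 0)
  expect_equal(unname(clopper_pearson(10, 10)["upper"]), 1)
  ci5 <- clopper_pearson(5, 10)
  expect_equal(unname(ci5["lower"]), 1 - unname(ci5["upper"]), tolerance = 1e-12)
  # 69/76 reproduces the published sensitivity interval 81.9-96.2%
  ci <- clopper_pearson(69, 76)
  expect_equal(round(100 * unname(ci["lower"]), 1), 81.9)
  expect_equal(round(100 * unname(ci["upper"]), 1), 96.2)
  expect_error(clopper_pearson(3, 0), "n")
})

test_that("exact interval coverage is at least nominal (analytic check)", {
  n <- 40
  for (p in seq(0.1, 0.9, by = 0.1)) {
    covered <- vapply(0:n, function(k) {
      ci <- clopper_pearson(k, n, 0.95)
      ci["lower"] <= p && p <= ci["upper"]
    }, TRUE)
    expect_gte(sum(stats::dbinom(0:n, n, p) * covered), 0.95)
  }
})

test_that("Cohen's kappa: worked values, rater symmetry, oracle equality", {
  expect_equal(cohen_kappa(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(cohen_kappa(matrix(c(25, 25, 25, 25), 2)), 0)
  # p_o = 0.8, p_e = (70*70 + 30*30)/100^2 = 0.58 -> kappa = 0.22/0.42
  expect_equal(cohen_kappa(60, 10, 10, 20), 11 / 21, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(cohen_kappa(tab), kappa_oracle(tab), tolerance = 1e-12)
    expect_equal(cohen_kappa(tab), cohen_kappa(t(tab)), tolerance = 1e-12)
  }
  # independent implementation cross-check
  tab <- matrix(c(37, 9, 4, 26), 2)
  expect_equal(cohen_kappa(tab),
               e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
  # degenerate marginals: perfect one-cell agreement is 1; a constant rater
  # earns exactly chance-level agreement, kappa = 0
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 0), 2)), 1)
  expect_equal(cohen_kappa(matrix(c(10, 0, 5, 0), 2)), 0)
})

test_that("exact McNemar agrees with binomial enumeration and is symmetric", {
  expect_equal(mcnemar_exact(7, 7), 1)
  expect_equal(mcnemar_exact(0, 8), 2 * 0.5^8)
  expect_equal(mcnemar_exact(1, 5), mcnemar_enumeration_oracle(1, 5))
  for (b in 0:6) for (cc in 0:6) {
    expect_equal(mcnemar_exact(b, cc), mcnemar_enumeration_oracle(b, cc),
                 tolerance = 1e-12, label = sprintf("b=%d c=%d", b, cc))
    expect_equal(mcnemar_exact(b, cc), mcnemar_exact(cc, b))
  }
  expect_message(p0 <- mcnemar_exact(0, 0), "no discordant")
  expect_equal(p0, 1)
})

test_that("Pearson correlation matches the direct-formula oracle", {
  x <- c(1, 3, 4, 6, 8, 9)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(7)
  y <- x + rnorm(6)
  got <- pearson_cor(x, y)
  oracle <- pearson_oracle(x, y)
  expect_equal(got$r, oracle$r, tolerance = 1e-12)
  expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
  # complete-case pairing
  got2 <- pearson_cor(c(x, NA), c(y, 5))
  expect_equal(got2$r, oracle$r, tolerance = 1e-12)
  expect_equal(got2$n, 6)
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "3 complete pairs")
})

test_that("rank-sum comparison: exact enumeration and the GGT age contrast", {
  # identical groups carry no evidence
  expect_gte(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  # most extreme ordering of C(6,3) = 20 splits, two-sided
  rs <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rs$p_value, 0.1)
  expect_equal(rs$method, "exact")
  # the generator builds in the age decline of GGT
  ds <- derive_fields(apply_age_filter(synth_cohort(synth_config(seed = 1))))
  g23 <- ds$ggt[ds$age_group == "2-3 d"]
  g46 <- ds$ggt[ds$age_group == "4-6 d"]
  expect_lt(rank_sum_test(g23, g46)$p_value, 0.001)
})

test_that("sample-size planning reproduces the design numbers", {
  expect_equal(sample_size_prop(0.80, 0.10, 0.95), 62)
  expect_equal(total_sample_size(62, 0.25), 248)
  expect_equal(sample_size_prop(0.50, 0.10, 0.95), 97)
  expect_equal(total_sample_size(62, 0.5), 124)
  expect_equal(total_sample_size(1, 0.33), 4)
  expect_equal(sample_size_prop(0.5, 1, 0.95), 1)
  # monotone in precision, maximized at p = 1/2
  sizes <- vapply(c(0.05, 0.1, 0.2), function(d) sample_size_prop(0.8, d), 1)
  expect_true(all(diff(sizes) <= 0))
  expect_gte(sample_size_prop(0.5, 0.1), sample_size_prop(0.3, 0.1))
  expect_gte(sample_size_prop(0.5, 0.1), sample_size_prop(0.8, 0.1))
})

test_that("intra-assay CV summarises replicate repeatability", {
  expect_equal(intra_assay_cv(data.frame(sample = 1, value = c(10, 10, 10)))$mean_cv, 0)
  cv2 <- intra_assay_cv(data.frame(sample = 1, value = c(9, 11)))
  expect_equal(cv2$mean_cv, sqrt(2) / 10, tolerance = 1e-12)
  # five samples engineered to known CVs: pairs {m(1-d), m(1+d)} have
  # cv = d * sqrt(2), so d = cv / sqrt(2) reproduces the target exactly
  cvs <- c(0.048, 0.055, 0.060, 0.065, 0.082)
  reps <- do.call(rbind, lapply(seq_along(cvs), function(i) {
    d <- cvs[i] / sqrt(2)
    data.frame(sample = i, value = 10 * c(1 - d, 1 + d))
  }))
  got <- intra_assay_cv(reps)
  expect_equal(got$min_cv, 0.048, tolerance = 1e-12)
  expect_equal(got$max_cv, 0.082, tolerance = 1e-12)
  expect_equal(round(100 * got$mean_cv, 1), 6.2)
  expect_error(intra_assay_cv(data.frame(sample = 1, value = 5)), "2 replicates")
  expect_error(intra_assay_cv(data.frame(sample = 1, value = c(0, 0))),
               "non-positive")
})
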