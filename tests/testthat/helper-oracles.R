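# Independent oracles used to cross-check the implementation. These are
# deliberately brute-force / first-principles and share no code with R/.

# AUC as the Mann-Whitney pairwise probability over all pos x neg pairs
auc_pairwise_oracle <- function(values, labels, orientation = "lower_is_positive") {
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  pos <- values[labels]; neg <- values[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    win <- if (orientation == "lower_is_positive") p < q else p > q
    total <- total + win + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Clopper-Pearson by bisection on the binomial tail probabilities
cp_bisection_oracle <- function(k, n, conf_level = 0.95, tol = 1e-12) {
  alpha <- 1 - conf_level
  bisect <- function(f) {
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else
    bisect(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) < alpha / 2)
  upper <- if (k == n) 1 else
    1 - bisect(function(q) stats::pbinom(k, n, 1 - q) < alpha / 2)
  c(lower = lower, upper = upper)
}

# exact two-sided McNemar by enumeration of Binomial(b + c, 1/2)
mcnemar_enumeration_oracle <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  probs <- stats::dbinom(0:n, n, 0.5)
  m <- min(b, c)
  # doubling the smaller tail == summing both symmetric tails at p = 1/2
  min(1, sum(probs[seq_len(m + 1)]) + sum(probs[seq(n + 1 - m, n + 1)]))
}

# textbook covariance / SD formula for Pearson's r, plus the t-based p-value
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t), n - 2))
}

kappa_oracle <- function(tab) {
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  (po - pe) / (1 - pe)
}

# random labelled instance with ties, for ROC property tests
random_roc_instance <- function(seed, n_max = 30) {
  set.seed(seed)
  n <- sample(6:n_max, 1)
  repeat {
    labels <- stats::runif(n) < 0.4
    if (any(labels) && !all(labels)) break
  }
  values <- round(stats::rnorm(n, ifelse(labels, -0.5, 0.5)), 1) # ties likely
  list(values = values, labels = labels)
}

# small CSV fixture on disk
write_toy_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
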