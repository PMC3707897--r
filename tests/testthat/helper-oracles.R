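# Independent oracles, deliberately naive; used only to check package code.

# dense-grid minimum squared distance from a point to a curve (no refinement
# cleverness shared with the implementation)
brute_min_sqdist <- function(r, d, curve, step = 1e-4) {
  g <- seq(-1, 1, by = step)
  min((r - g)^2 + (d - curve(g))^2)
}

# literal leave-one-out loop over lm fits of a given formula degree
brute_loo_vertical <- function(points, degree) {
  n <- nrow(points)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    train <- points[-i, ]
    fit <- stats::lm(mean_d ~ poly(r, degree, raw = TRUE), data = train)
    pred <- stats::predict(fit, newdata = points[i, , drop = FALSE])
    errs[i] <- abs(pred - points$mean_d[i])
  }
  mean(errs)
}

# exact two-sided sign-test p-value by binomial enumeration
enum_sign_p <- function(n_pos, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= stats::dbinom(n_pos, n, 0.5) + 1e-12])
}

# Mann-Whitney U for x by direct pair counting (ties count 0.5)
enum_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Friedman chi-squared by hand ranking (no ties assumed handled by rank())
hand_friedman <- function(mat) {
  R <- t(apply(mat, 1, rank))
  n <- nrow(mat); k <- ncol(mat)
  12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
}
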