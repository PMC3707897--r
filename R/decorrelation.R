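#' Pearson correlation between two activation patterns
#'
#' Thin wrapper around [stats::cor()] with the validity checks the analysis
#' relies on: equal lengths of at least 3 and non-constant inputs. Sample
#' (n - 1) moments are used throughout the package, so ratios of variances and
#' covariances are normalisation-invariant.
#'
#' @param x,y Numeric pattern vectors of equal length >= 3.
#' @return Pearson r in \eqn{[-1, 1]}.
#' @export
pattern_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("pattern vectors must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant pattern vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Per-voxel measured modulation index d_M
#'
#' The modulation index compares the response to simultaneous center-surround
#' stimulation, m(C,S), with the unweighted sum of the component responses:
#' \deqn{d_M = \frac{(C + S) - m(C,S)}{C + S}.}
#' `d_M = 0` means no interaction (linear summation); `d_M = 1` full
#' suppression (the combined response disappears); `d_M = -1` facilitation so
#' strong that the response doubles. Positive values indicate suppressive,
#' negative values facilitative interaction.
#'
#' Voxels whose denominator magnitude falls below `denom_epsilon` are flagged
#' (their count is reported) but their d_M values are retained: extreme values
#' are part of the measurement and are not discarded. Only voxels with
#' `C + S` exactly 0 get an undefined (`NA`) index and are excluded from
#' summary means.
#'
#' @param C,S,m Aligned numeric vectors of percent-BOLD changes: center alone,
#'   surround alone, and the combined presentation.
#' @param denom_epsilon Flagging threshold for near-zero denominators
#'   (percent-BOLD units; default 1e-9).
#' @return A tibble with one row per voxel: `d_m`, `denominator`, `flagged`
#'   (near-zero denominator) and `undefined` (exactly zero denominator).
#' @examples
#' measured_d(C = c(1, 0.5), S = c(0.5, 0.5), m = c(0, 2))
#' @export
measured_d <- function(C, S, m, denom_epsilon = 1e-9) {
  n <- length(C)
  if (length(S) != n || length(m) != n) {
    stop("`C`, `S` and `m` must be aligned per voxel (equal lengths)",
         call. = FALSE)
  }
  den <- C + S
  undefined <- den == 0
  d <- ifelse(undefined, NA_real_, (den - m) / den)
  tibble::tibble(
    d_m = d,
    denominator = den,
    flagged = abs(den) < denom_epsilon,
    undefined = undefined
  )
}

#' Closed-form fully-decorrelating coefficient d_T
#'
#' A single scalar d in \eqn{[-1, 1]} can remove the correlation between any
#' two non-degenerate response patterns C and S via the symmetric mixing
#' `C' = C - d*S`, `S' = S - d*C`. Setting `cov(C', S') = 0` gives the
#' quadratic \eqn{(1 + d^2)\,\mathrm{cov}(C,S) - d\,(\mathrm{var}(C) +
#' \mathrm{var}(S)) = 0}, whose root inside \eqn{[-1, 1]} is
#' \deqn{d_T = \frac{\mathrm{var}(C) + \mathrm{var}(S) -
#'   \sqrt{(\mathrm{var}(C) + \mathrm{var}(S))^2 - 4\,\mathrm{cov}(C,S)^2}}
#'   {2\,\mathrm{cov}(C,S)},}
#' with `d_T = 0` when `cov(C, S) = 0` (the continuous extension). The other
#' quadratic root is the reciprocal of this one and lies outside the bound.
#'
#' @param C,S Numeric pattern vectors, equal length >= 3, both non-constant.
#' @return An object of class `cd_decorrelation`: a list with `d_t`,
#'   `residual_correlation` (Pearson r of the decorrelated pair; `NA` when a
#'   decorrelated pattern is constant, as happens at |r| = 1), `c_prime`,
#'   `s_prime`, and the moments `var_c`, `var_s`, `cov_cs`.
#' @examples
#' sol <- theoretical_d(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' sol$d_t                   # 1/3
#' sol$residual_correlation  # 0
#' @export
theoretical_d <- function(C, S) {
  if (length(C) != length(S) || length(C) < 3) {
    stop("`C` and `S` must have equal length >= 3", call. = FALSE)
  }
  vC <- stats::var(C)
  vS <- stats::var(S)
  if (vC == 0 || vS == 0) {
    stop("degenerate input: `C` and `S` must both be non-constant",
         call. = FALSE)
  }
  cv <- stats::cov(C, S)
  if (cv == 0) {
    d <- 0
  } else {
    disc <- (vC + vS)^2 - 4 * cv^2
    disc <- max(disc, 0) # guard tiny negative round-off at |r| ~ 1
    d <- (vC + vS - sqrt(disc)) / (2 * cv)
    d <- max(-1, min(1, d))
  }
  c_prime <- C - d * S
  s_prime <- S - d * C
  res <- if (stats::var(c_prime) == 0 || stats::var(s_prime) == 0) {
    NA_real_
  } else {
    stats::cor(c_prime, s_prime)
  }
  structure(
    list(d_t = d, residual_correlation = res,
         c_prime = c_prime, s_prime = s_prime,
         var_c = vC, var_s = vS, cov_cs = cv),
    class = "cd_decorrelation"
  )
}

#' @export
print.cd_decorrelation <- function(x, ...) {
  cat("<cd_decorrelation> d_t =", format(x$d_t, digits = 6),
      "| residual r =", format(x$residual_correlation, digits = 3),
      "| n =", length(x$c_prime), "\n")
  invisible(x)
}

#' Brute-force search for the decorrelating coefficient
#'
#' Independent verification route for [theoretical_d()]: a dense grid search
#' over d in \eqn{[-1, 1]} minimising the absolute Pearson correlation of the
#' mixed patterns `(C - d*S, S - d*C)`, followed by bisection on the signed
#' correlation in the bracketing interval. It never touches the closed form.
#'
#' @inheritParams theoretical_d
#' @param grid_step Grid spacing for the coarse search (default 1e-4).
#' @param tol Bisection tolerance (default 1e-8).
#' @return The decorrelating coefficient found by search.
#' @export
theoretical_d_search <- function(C, S, grid_step = 1e-4, tol = 1e-8) {
  if (length(C) != length(S) || length(C) < 3) {
    stop("`C` and `S` must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(C) == 0 || stats::var(S) == 0) {
    stop("degenerate input: `C` and `S` must both be non-constant",
         call. = FALSE)
  }
  corr_at <- function(d) {
    cp <- C - d * S
    sp <- S - d * C
    if (stats::var(cp) == 0 || stats::var(sp) == 0) return(NA_real_)
    stats::cor(cp, sp)
  }
  grid <- seq(-1, 1, by = grid_step)
  # the same per-grid-point correlation, evaluated as matrix columns so a
  # fine grid stays affordable: column g holds (C - d_g S, S - d_g C)
  CP <- outer(C, rep(1, length(grid))) - outer(S, grid)
  SP <- outer(S, rep(1, length(grid))) - outer(C, grid)
  CPc <- sweep(CP, 2, colMeans(CP))
  SPc <- sweep(SP, 2, colMeans(SP))
  denom <- sqrt(colSums(CPc^2) * colSums(SPc^2))
  vals <- ifelse(denom == 0, NA_real_, colSums(CPc * SPc) / denom)
  best <- which.min(abs(vals))
  lo <- max(1L, best - 1L)
  hi <- min(length(grid), best + 1L)
  if (is.na(vals[lo]) || is.na(vals[hi]) || sign(vals[lo]) == sign(vals[hi])) {
    return(grid[best]) # no sign change to bisect (e.g. tangent at |d| = 1)
  }
  stats::uniroot(corr_at, lower = grid[lo], upper = grid[hi],
                 tol = tol)$root
}

#' CD-model curve: predicted d_T as a function of pattern correlation
#'
#' Expresses the decorrelating coefficient through the Pearson correlation r
#' between the center and surround patterns and the ratio of their variances
#' \eqn{\rho = \mathrm{var}(S)/\mathrm{var}(C)}:
#' \deqn{d_T(r, \rho) = \frac{1 + \rho - \sqrt{(1 + \rho)^2 - 4 r^2 \rho}}
#'   {2 r \sqrt{\rho}},}
#' with value 0 at r = 0 (continuous extension). For equal variances this
#' reduces to \eqn{(1 - \sqrt{1 - r^2})/r}. The curve depends on the
#' variances only through their ratio and is odd in r.
#'
#' @param r Numeric vector of Pearson correlations, |r| <= 1.
#' @param variance_ratio Positive scalar var(S)/var(C) (default 1).
#' @return Predicted d_T values.
#' @examples
#' cd_curve(0.6) # 1/3
#' @export
cd_curve <- function(r, variance_ratio = 1) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  }
  if (variance_ratio <= 0) {
    stop("`variance_ratio` must be positive", call. = FALSE)
  }
  rho <- variance_ratio
  disc <- pmax((1 + rho)^2 - 4 * r^2 * rho, 0)
  out <- (1 + rho - sqrt(disc)) / (2 * r * sqrt(rho))
  out[r == 0] <- 0
  out
}
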