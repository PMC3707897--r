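#' Orthogonal-distance R-squared of a curve on (r, d) scatter data
#'
#' Goodness of fit for a curve relating pattern correlation to modulation
#' index when both coordinates carry measurement error: the residual
#' sum-of-squares numerator uses the squared minimum Euclidean distance from
#' each point to the curve, while the denominator is the summed squared
#' Euclidean distance of the points to their centroid,
#' \eqn{R^2 = 1 - \sum_i \min_t \|y_i - f(t)\|^2 / \sum_i \|y_i - \bar y\|^2.}
#' Distances are minimised by a dense grid over the curve parameter
#' \eqn{r \in [-1, 1]} with local refinement; r and d are treated as
#' commensurate axes (both dimensionless in \eqn{[-1, 1]}).
#'
#' @param points Data frame with columns `r` and `mean_d` (>= 3 rows).
#' @param curve Function mapping r to the curve's d value.
#' @param grid_step Parameter grid spacing (default 1e-3).
#' @param refine_tol Local-refinement tolerance on the parameter (default 1e-6).
#' @return R-squared (can be negative for a poor curve).
#' @export
orthogonal_r_squared <- function(points, curve, grid_step = 1e-3,
                                 refine_tol = 1e-6) {
  pts <- as.data.frame(points)
  if (nrow(pts) < 3) stop("need at least 3 points", call. = FALSE)
  num <- sum(curve_sq_distances(pts$r, pts$mean_d, curve, grid_step, refine_tol))
  den <- sum((pts$r - mean(pts$r))^2 + (pts$mean_d - mean(pts$mean_d))^2)
  if (den == 0) {
    stop("all points identical: orthogonal R-squared undefined", call. = FALSE)
  }
  1 - num / den
}

# Squared minimum Euclidean distance from each point to the curve.
curve_sq_distances <- function(r, d, curve, grid_step = 1e-3,
                               refine_tol = 1e-6) {
  grid <- seq(-1, 1, by = grid_step)
  cd <- curve(grid)
  vapply(seq_along(r), function(i) {
    sq <- (r[i] - grid)^2 + (d[i] - cd)^2
    j <- which.min(sq)
    lo <- grid[max(1L, j - 1L)]
    hi <- grid[min(length(grid), j + 1L)]
    opt <- stats::optimize(
      function(t) (r[i] - t)^2 + (d[i] - curve(t))^2,
      lower = lo, upper = hi, tol = refine_tol
    )
    min(opt$objective, sq[j])
  }, numeric(1))
}

#' Polynomial and linear fits of the modulation scatter
#'
#' Ordinary least squares of the mean modulation index on the pattern
#' correlation: `fit_polynomial()` fits \eqn{d = a_1 + a_2 r + a_3 r^2 + a_4
#' r^3} (degree 3, four free parameters); `fit_linear()` fits
#' \eqn{d = a_1 + a_2 r} (two free parameters).
#'
#' @param points Data frame with columns `r` and `mean_d`.
#' @param degree Polynomial degree (default 3).
#' @return An object of class `cd_curve_fit`: list with `model`,
#'   `coefficients` (ascending powers, `a1` = intercept) and `predict`
#'   (function of r).
#' @export
fit_polynomial <- function(points, degree = 3) {
  pts <- as.data.frame(points)
  if (nrow(pts) < degree + 2) {
    stop("need at least ", degree + 2, " points for a degree-", degree,
         " polynomial fit", call. = FALSE)
  }
  fit <- stats::lm(mean_d ~ stats::poly(r, degree, raw = TRUE), data = pts)
  cf <- unname(stats::coef(fit))
  if (any(is.na(cf))) {
    stop("rank-deficient design: polynomial fit undetermined ",
         "(are all r values equal?)", call. = FALSE)
  }
  names(cf) <- paste0("a", seq_along(cf))
  structure(
    list(
      model = paste0("POLY", degree),
      coefficients = cf,
      predict = function(r) drop(outer(r, 0:degree, `^`) %*% cf)
    ),
    class = "cd_curve_fit"
  )
}

#' @rdname fit_polynomial
#' @export
fit_linear <- function(points) {
  pts <- as.data.frame(points)
  if (nrow(pts) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(pts$r) == 0) {
    stop("degenerate design: all r values equal", call. = FALSE)
  }
  out <- fit_polynomial(pts, degree = 1)
  out$model <- "LINFIT"
  out
}

#' @export
print.cd_curve_fit <- function(x, ...) {
  cat("<cd_curve_fit>", x$model, ":",
      paste(names(x$coefficients), "=",
            format(x$coefficients, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# Fitter factories: a fitter maps a points data frame to a predict function.
# Parameter-free fitters ignore the data.
model_fitters <- function(variance_ratio = 1) {
  list(
    CD = list(
      k = 0L,
      fit = function(points) function(r) cd_curve(r, variance_ratio)
    ),
    LINEAR_IDENTITY = list(
      k = 0L,
      fit = function(points) function(r) r
    ),
    POLY3 = list(
      k = 4L,
      fit = function(points) fit_polynomial(points, 3)$predict
    ),
    LINFIT = list(
      k = 2L,
      fit = function(points) fit_linear(points)$predict
    )
  )
}

#' Leave-one-out cross-validated error of a fitted curve
#'
#' For each point: refit the curve on the remaining points, then record the
#' held-out point's error from the refit curve; the result is the average of
#' these errors. For a parameter-free model the refit is independent of the
#' data, so the LOO error equals the plain mean per-point error.
#'
#' @param points Data frame with columns `r` and `mean_d`.
#' @param fitter Function mapping a points data frame to a predict function
#'   of r (see [fit_polynomial()]; e.g. `function(p) fit_linear(p)$predict`).
#' @param metric `"vertical"` (absolute predicted-minus-observed d, default)
#'   or `"orthogonal"` (Euclidean distance to the refit curve).
#' @return Mean held-out error.
#' @export
loo_cv_error <- function(points, fitter,
                         metric = c("vertical", "orthogonal")) {
  metric <- match.arg(metric)
  pts <- as.data.frame(points)
  n <- nrow(pts)
  errs <- vapply(seq_len(n), function(i) {
    pred <- tryCatch(fitter(pts[-i, , drop = FALSE]),
                     error = function(e) {
                       stop("fitter failed on fold ", i, ": ",
                            conditionMessage(e), call. = FALSE)
                     })
    point_error(pts$r[i], pts$mean_d[i], pred, metric)
  }, numeric(1))
  mean(errs)
}

point_error <- function(r, d, predict_fn, metric) {
  if (metric == "vertical") {
    abs(predict_fn(r) - d)
  } else {
    sqrt(curve_sq_distances(r, d, predict_fn))
  }
}

#' Normalise per-point errors within groups
#'
#' Divides each error by the maximum error of its group, so the largest error
#' in every group maps to exactly 1 and errors become comparable across
#' conditions of different scale. An all-zero group is defined as all zeros.
#'
#' @param errors Numeric vector of non-negative errors.
#' @param groups Grouping vector (same length); `NULL` treats all errors as
#'   one group.
#' @return Normalised errors.
#' @examples
#' normalized_errors(c(1, 2, 4)) # 0.25 0.50 1.00
#' @export
normalized_errors <- function(errors, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, length(errors))
  stopifnot(length(groups) == length(errors), all(errors >= 0))
  out <- numeric(length(errors))
  for (g in unique(groups)) {
    idx <- groups == g
    mx <- max(errors[idx])
    out[idx] <- if (mx > 0) errors[idx] / mx else 0
  }
  out
}

#' Least-squares AIC
#'
#' Gaussian-likelihood AIC on least-squares residuals,
#' \eqn{\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2k}. Lower is better; model
#' comparisons are reported as rank order. A zero RSS yields `-Inf` with a
#' warning (a perfect fit dominates any comparison).
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n Number of points (>= 2).
#' @param k Number of free parameters.
#' @return AIC value.
#' @examples
#' aic_ls(1.5, n = 15, k = 2) # 15 * log(0.1) + 4
#' @export
aic_ls <- function(rss, n, k) {
  stopifnot(rss >= 0, n >= 2, k >= 0)
  if (rss == 0) {
    warning("RSS is 0: AIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * k
}

#' Predicted combined response under MAX, AVERAGE or CD combination rules
#'
#' The MAX rule predicts the combined response as the voxel-wise maximum of
#' the component responses; the AVERAGE rule as their mean; the CD rule as
#' `(1 - d_T) * (C + S)` with the decorrelating coefficient computed from the
#' same voxels. The prediction error is the Euclidean norm of the difference
#' from the observed combined response.
#'
#' @param C,S,m Aligned numeric vectors: component responses and observed
#'   combined response.
#' @param model One or more of `"MAX"`, `"AVERAGE"`, `"CD"`.
#' @return A tibble with one row per model: `model`, `error_norm`, and a
#'   list-column `predicted`.
#' @export
response_model_prediction <- function(C, S, m,
                                      model = c("MAX", "AVERAGE", "CD")) {
  model <- match.arg(model, several.ok = TRUE)
  n <- length(C)
  if (length(S) != n || length(m) != n) {
    stop("`C`, `S` and `m` must be aligned (equal lengths)", call. = FALSE)
  }
  preds <- lapply(model, function(mod) {
    switch(mod,
      MAX = pmax(C, S),
      AVERAGE = (C + S) / 2,
      CD = (1 - theoretical_d(C, S)$d_t) * (C + S)
    )
  })
  tibble::tibble(
    model = model,
    error_norm = vapply(preds, function(p) sqrt(sum((p - m)^2)), numeric(1)),
    predicted = preds
  )
}

#' Compare candidate correlation-modulation models on a scatter
#'
#' Fits and scores the four candidate relations between pattern correlation r
#' and mean modulation index d on per-subject scatter data: the CD curve
#' (zero free parameters), the slope-one identity line d = r (zero free
#' parameters), a third-order polynomial (four free parameters) and a free
#' linear fit (two free parameters). Each model is scored by its per-point
#' errors, residual sum of squares, orthogonal-distance R-squared,
#' leave-one-out cross-validated error, group-normalised mean error, and
#' least-squares AIC; models are ranked by AIC with ties broken toward fewer
#' parameters, and all pairwise winners are reported.
#'
#' @param points A data frame with columns `r` and `mean_d` (one row per
#'   subject), e.g. from [modulation_scatter()]; >= 6 rows.
#' @param metric Per-point/LOO error metric, `"vertical"` (default) or
#'   `"orthogonal"`. The orthogonal metric is always used for the
#'   orthogonal R-squared.
#' @param variance_ratio var(S)/var(C) used by the CD curve (default 1).
#' @return An object of class `cd_model_comparison`; see [tidy()] and
#'   [glance()] methods, and `$results`, `$pairwise`.
#' @examples
#' pts <- tibble::tibble(r = seq(-0.2, 0.9, length.out = 8),
#'                       mean_d = cd_curve(seq(-0.2, 0.9, length.out = 8)))
#' compare_models(pts)$results
#' @export
compare_models <- function(points, metric = c("vertical", "orthogonal"),
                           variance_ratio = 1) {
  metric <- match.arg(metric)
  pts <- as.data.frame(points)
  if (nrow(pts) < 6) stop("need at least 6 points", call. = FALSE)
  n <- nrow(pts)
  fitters <- model_fitters(variance_ratio)

  rows <- purrr::imap(fitters, function(f, name) {
    pred <- f$fit(pts)
    resid <- pred(pts$r) - pts$mean_d
    errs <- vapply(seq_len(n),
                   function(i) point_error(pts$r[i], pts$mean_d[i], pred, metric),
                   numeric(1))
    rss <- sum(resid^2)
    tibble::tibble(
      model = name,
      k = f$k,
      rss = rss,
      mean_error = mean(errs),
      loo_error = loo_cv_error(pts, f$fit, metric),
      orth_r_squared = orthogonal_r_squared(pts, pred),
      aic = suppressWarnings(aic_ls(rss, n, f$k)),
      point_errors = list(errs)
    )
  })
  results <- dplyr::bind_rows(rows)

  # normalise per-point errors jointly (max over all models on this scatter = 1)
  all_err <- unlist(results$point_errors)
  grp <- rep(1L, length(all_err))
  norm_all <- normalized_errors(all_err, grp)
  split_idx <- rep(seq_len(nrow(results)), each = n)
  results$normalized_mean_error <-
    vapply(split(norm_all, split_idx), mean, numeric(1))

  # rank by AIC, ties toward fewer parameters
  ord <- order(results$aic, results$k)
  results$rank <- match(seq_len(nrow(results)), ord)

  combos <- utils::combn(results$model, 2)
  pairwise <- tibble::tibble(
    model_a = combos[1, ], model_b = combos[2, ],
    winner = vapply(seq_len(ncol(combos)), function(i) {
      a <- results[results$model == combos[1, i], ]
      b <- results[results$model == combos[2, i], ]
      if (a$aic < b$aic) a$model
      else if (b$aic < a$aic) b$model
      else if (a$k <= b$k) a$model else b$model
    }, character(1))
  )

  structure(
    list(results = results, pairwise = pairwise, points = pts,
         metric = metric, variance_ratio = variance_ratio),
    class = "cd_model_comparison"
  )
}

#' @export
print.cd_model_comparison <- function(x, ...) {
  cat("<cd_model_comparison>", nrow(x$points), "points, metric:",
      x$metric, "\n")
  print(dplyr::select(x$results, "model", "k", "rss", "loo_error",
                      "orth_r_squared", "aic", "rank"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model comparison into one row per candidate model
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return Tibble with model name, parameter count, errors, R-squared, AIC
#'   and rank.
#' @export
tidy.cd_model_comparison <- function(x, ...) {
  dplyr::select(x$results, "model", "k", "rss", "mean_error", "loo_error",
                "normalized_mean_error", "orth_r_squared", "aic", "rank")
}

#' One-row summary of a model comparison
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return Tibble with the number of points, the AIC-best model, its AIC and
#'   orthogonal R-squared, and the error metric used.
#' @export
glance.cd_model_comparison <- function(x, ...) {
  best <- x$results[x$results$rank == 1, ]
  tibble::tibble(
    n_points = nrow(x$points),
    best_model = best$model,
    best_aic = best$aic,
    best_orth_r_squared = best$orth_r_squared,
    metric = x$metric
  )
}
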