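test_that("orthogonal R-squared matches its definition and a brute-force oracle", {
  curve <- function(r) cd_curve(r)
  # points exactly on the curve
  on_curve <- tibble::tibble(r = c(-0.5, 0, 0.3, 0.6, 0.9),
                             mean_d = curve(c(-0.5, 0, 0.3, 0.6, 0.9)))
  expect_equal(orthogonal_r_squared(on_curve, curve), 1, tolerance = 1e-8)
  # constant curve through the centroid of a d-varying cloud
  pts <- tibble::tibble(r = rep(0.4, 5), mean_d = c(-2, -1, 0, 1, 2))
  expect_equal(orthogonal_r_squared(pts, function(r) rep(0, length(r))),
               0, tolerance = 1e-6)
  # hand-placed points vs the fine-grid oracle
  hand <- tibble::tibble(r = c(-0.3, 0.1, 0.45, 0.7, 0.95),
                         mean_d = c(0.2, -0.15, 0.5, 0.1, 0.8))
  num <- sum(vapply(seq_len(5), function(i) {
    brute_min_sqdist(hand$r[i], hand$mean_d[i], curve)
  }, numeric(1)))
  den <- sum((hand$r - mean(hand$r))^2 + (hand$mean_d - mean(hand$mean_d))^2)
  expect_equal(orthogonal_r_squared(hand, curve), 1 - num / den,
               tolerance = 1e-6)
  expect_error(
    orthogonal_r_squared(tibble::tibble(r = rep(0.2, 4),
                                        mean_d = rep(0.1, 4)), curve),
    "identical"
  )
  # orthogonal distance never exceeds vertical distance
  vert <- (hand$mean_d - curve(hand$r))^2
  orth <- vapply(seq_len(5), function(i) {
    brute_min_sqdist(hand$r[i], hand$mean_d[i], curve)
  }, numeric(1))
  expect_true(all(orth <= vert + 1e-12))
})

test_that("polynomial and linear fits recover known coefficients", {
  r <- seq(-0.8, 0.9, length.out = 9)
  cubic <- tibble::tibble(r = r, mean_d = 0.2 - 0.5 * r + 0.1 * r^2 + 0.8 * r^3)
  fit <- fit_polynomial(cubic, 3)
  expect_equal(unname(fit$coefficients), c(0.2, -0.5, 0.1, 0.8),
               tolerance = 1e-10)
  # odd-symmetric data kill the even coefficients
  r_sym <- c(r, -r)
  sym <- tibble::tibble(r = r_sym, mean_d = r_sym^3)
  fs <- fit_polynomial(sym, 3)
  expect_equal(unname(fs$coefficients[c(1, 3)]), c(0, 0), tolerance = 1e-10)
  # residuals orthogonal to the design columns (normal equations)
  withr::with_seed(5, {
    pts <- tibble::tibble(r = runif(6, -1, 1), mean_d = rnorm(6))
  })
  f6 <- fit_polynomial(pts, 3)
  resid <- pts$mean_d - f6$predict(pts$r)
  for (p in 0:3) expect_equal(sum(resid * pts$r^p), 0, tolerance = 1e-8)
  # linear fit: identity-line data
  ident <- tibble::tibble(r = r, mean_d = r)
  fl <- fit_linear(ident)
  expect_equal(unname(fl$coefficients), c(0, 1), tolerance = 1e-12)
  expect_error(fit_linear(tibble::tibble(r = rep(0.3, 5), mean_d = 1:5)),
               "degenerate|rank")
  expect_error(fit_polynomial(cubic[1:4, ], 3), "at least 5")
})

test_that("LOO error equals an explicit refit loop and collapses for fixed curves", {
  withr::with_seed(8, {
    pts <- tibble::tibble(r = runif(9, -0.8, 0.9),
                          mean_d = rnorm(9, 0, 0.4))
  })
  expect_equal(loo_cv_error(pts, function(p) fit_polynomial(p, 3)$predict),
               brute_loo_vertical(pts, 3), tolerance = 1e-10)
  expect_equal(loo_cv_error(pts, function(p) fit_linear(p)$predict),
               brute_loo_vertical(pts, 1), tolerance = 1e-10)
  # parameter-free model: LOO error is the plain mean per-point error
  cd_fit <- function(p) function(r) cd_curve(r)
  expect_equal(loo_cv_error(pts, cd_fit),
               mean(abs(cd_curve(pts$r) - pts$mean_d)), tolerance = 1e-12)
  # exact cubic: POLY3 LOO error is 0
  exact <- tibble::tibble(r = seq(-0.9, 0.9, length.out = 8),
                          mean_d = 0.1 + 0.3 * seq(-0.9, 0.9, length.out = 8)^3)
  expect_equal(loo_cv_error(exact, function(p) fit_polynomial(p, 3)$predict),
               0, tolerance = 1e-9)
})

test_that("error normalisation is per group with max mapping to 1", {
  expect_equal(normalized_errors(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(normalized_errors(c(3)), 1)
  expect_equal(normalized_errors(c(0, 0)), c(0, 0))
  out <- normalized_errors(c(1, 2, 10, 20), groups = c("a", "a", "b", "b"))
  expect_equal(out, c(0.5, 1, 0.5, 1)) # cross-group ratios not preserved
})

test_that("least-squares AIC follows n*log(RSS/n) + 2k", {
  expect_equal(aic_ls(1.5, 15, 2), 15 * log(0.1) + 4)
  # equal RSS: parameter counts separate models by 2*dk
  expect_equal(aic_ls(2, 10, 4) - aic_ls(2, 10, 0), 8)
  # strictly increasing in RSS at fixed n, k
  rss <- c(0.5, 1, 2, 4)
  expect_true(all(diff(vapply(rss, aic_ls, numeric(1), n = 12, k = 0)) > 0))
  expect_warning(val <- aic_ls(0, 10, 1), "-Inf")
  expect_equal(val, -Inf)
})

test_that("response-combination models separate their own generative data", {
  # identical components: MAX and AVERAGE coincide with the components
  C <- c(0.4, 0.8, 1.2, -0.2, 0.6)
  pred <- response_model_prediction(C, C, C, c("MAX", "AVERAGE"))
  expect_equal(pred$predicted[[1]], C)
  expect_equal(pred$predicted[[2]], C)
  # each noiseless rule is matched by its own model with zero error norm
  for (rule in c("MAX", "AVERAGE", "CD")) {
    st <- tiny_study(n_subjects = 1, noise_sd = 0, interaction_rule = rule,
                     seed = 77)
    v <- st$voxels
    res <- response_model_prediction(v$C, v$S_N, v$m_C_SN)
    expect_equal(res$error_norm[res$model == rule], 0, tolerance = 1e-9)
    expect_true(all(res$error_norm[res$model != rule] > 0.1))
  }
})

test_that("compare_models ranks candidates and reports pairwise winners", {
  pts <- rule_scatter("CD", seed = 2024, n = 30)
  cmp <- compare_models(pts)
  res <- tidy(cmp)
  expect_setequal(res$model, c("CD", "LINEAR_IDENTITY", "POLY3", "LINFIT"))
  expect_equal(res$k[match(c("CD", "LINEAR_IDENTITY", "POLY3", "LINFIT"),
                           res$model)], c(0, 0, 4, 2))
  expect_equal(sort(res$rank), 1:4)
  # the normalisation puts the largest per-point error at exactly 1
  expect_equal(max(unlist(cmp$results$point_errors) /
                     max(unlist(cmp$results$point_errors))), 1)
  expect_equal(nrow(cmp$pairwise), 6)
  expect_equal(glance(cmp)$n_points, 30)
  # parameter-free LOO equals plain mean error
  expect_equal(res$loo_error[res$model == "CD"],
               res$mean_error[res$model == "CD"], tolerance = 1e-12)
  # a line d = 0.5 r is better served by the free linear fit than by CD
  lin_pts <- rule_scatter("LINFIT", seed = 3030, n = 30)
  lin_res <- tidy(compare_models(lin_pts))
  expect_lt(lin_res$aic[lin_res$model == "LINFIT"],
            lin_res$aic[lin_res$model == "CD"])
  # feasibility edge: 6 points still fit the cubic
  expect_s3_class(compare_models(rule_scatter("CD", 1, n = 6)),
                  "cd_model_comparison")
  expect_error(compare_models(rule_scatter("CD", 1, n = 5)), "at least 6")
})
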