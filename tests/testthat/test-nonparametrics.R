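test_that("sign contingency classifies voxels exhaustively and exclusively", {
  v <- tiny_study(seed = 33)$voxels
  cont <- sign_contingency(v, "VOI_AVA", "near")
  expect_equal(cont$n_suppression_same + cont$n_suppression_diff +
                 cont$n_facilitation_same + cont$n_facilitation_diff +
                 cont$n_excluded,
               cont$n_total)
  # all-positive responses with positive modulation: only suppression/same
  allpos <- v[1:20, ]
  allpos$C <- 1; allpos$S_N <- 0.5; allpos$m_C_SN <- 1 # d_M = 1/3 > 0
  c2 <- sign_contingency(allpos, "VOI_AVA", "near")
  expect_equal(c2$n_suppression_same, 20)
  expect_equal(c2$n_suppression_diff + c2$n_facilitation_same +
                 c2$n_facilitation_diff + c2$n_excluded, 0)
  # pure CD data with positive d_true: facilitation cells are empty
  st <- tiny_study(n_subjects = 1, noise_sd = 0, d_true = 0.3, seed = 33)
  c3 <- sign_contingency(st$voxels, "VOI_AVA", "near")
  expect_equal(c3$n_facilitation_same + c3$n_facilitation_diff, 0)
  # subject-mean counts average the per-subject tables
  st2 <- tiny_study(n_subjects = 3, seed = 34)
  pooled <- sign_contingency(st2$voxels, "VOI_AVA", "near")
  avg <- sign_contingency(st2$voxels, "VOI_AVA", "near",
                          summary = "subject_mean")
  expect_equal(avg$n_total * 3, pooled$n_total)
})

test_that("noisy data link sign agreement to modulation sign", {
  # suppressive voxels should over-represent sign-agreeing C/S pairs:
  # odds ratio > 1 across seeds
  ors <- vapply(1:20, function(s) {
    st <- tiny_study(n_subjects = 2, seed = 400 + s)
    ct <- sign_contingency(st$voxels, "VOI_AVA", "near")
    (ct$n_suppression_same * ct$n_facilitation_diff) /
      max(1, ct$n_suppression_diff * ct$n_facilitation_same)
  }, numeric(1))
  expect_true(mean(ors > 1) >= 0.9)
})

test_that("sign test is the exact binomial and matches enumeration", {
  expect_equal(sign_test(rep(1, 8))$p_value, 2 * (1 / 2)^8)
  expect_equal(sign_test(c(-1, -1, 1, 1))$p_value, 1)
  # zeros are dropped before testing
  expect_equal(sign_test(c(0, 0, rep(1, 8)))$p_value, 2 * (1 / 2)^8)
  expect_error(sign_test(c(0, 0)), "undefined")
  withr::with_seed(61, {
    for (i in 1:25) {
      n <- sample(3:12, 1)
      x <- rnorm(n) + runif(1, -1, 1)
      got <- sign_test(x)
      expect_equal(got$p_value, enum_sign_p(got$n_positive, got$n),
                   tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney U matches direct pair counting", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.8, 2.9, 4.4)
  got <- mann_whitney_u(x, y)
  expect_equal(got$u, enum_u(x, y))
  expect_true(got$exact)
  # identical samples: U = n*m/2; disjoint samples: U = 0 or n*m
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$u, 4.5)
  expect_equal(mann_whitney_u(c(1, 2), c(5, 6, 7))$u, 0)
  expect_equal(mann_whitney_u(c(5, 6, 7), c(1, 2))$u, 6)
  # large/tied samples switch to the corrected normal approximation
  withr::with_seed(62, {
    big <- mann_whitney_u(round(rnorm(40), 1), round(rnorm(40), 1))
  })
  expect_false(big$exact)
  expect_true(big$p_value > 0 && big$p_value <= 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("two-sample KS statistic is the ECDF supremum distance", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$d, 1)
  withr::with_seed(63, {
    x <- rnorm(30); y <- rnorm(25, 1)
  })
  manual <- max(abs(ecdf(x)(sort(c(x, y))) - ecdf(y)(sort(c(x, y)))))
  expect_equal(ks_two_sample(x, y)$d, manual)
  expect_error(ks_two_sample(1, c(1, 2)), "length >= 2")
})

test_that("Friedman test matches hand ranking and its closed-form maximum", {
  m <- matrix(c(1, 2, 3,
                2, 3, 1,
                1, 3, 2), nrow = 3, byrow = TRUE)
  expect_equal(friedman_blocks(m)$statistic, hand_friedman(m))
  # identical columns: statistic 0
  m0 <- matrix(rep(c(1, 2, 5), 3), nrow = 3)
  expect_equal(friedman_blocks(m0)$statistic, 0)
  # strictly ordered columns in every block: maximum n*(k-1)
  n <- 6; k <- 4
  mo <- matrix(rep(1:k, each = n), nrow = n) + runif(n * k, 0, 0.1)
  mo <- t(apply(mo, 1, sort))
  expect_equal(friedman_blocks(mo)$statistic, n * (k - 1))
  # long format and incomplete blocks
  long <- tidyr::expand_grid(block = 1:3, treatment = c("a", "b", "c"))
  long$value <- as.vector(t(m)) # row-major to match the grid order
  expect_equal(friedman_blocks(long)$statistic, friedman_blocks(m)$statistic)
  expect_error(friedman_blocks(long[-1, ]), "ncomplete")
})

test_that("sign and rank tests hold their nominal type-I level", {
  withr::with_seed(64, {
    reject_sign <- reject_mw <- logical(2000)
    for (i in 1:2000) {
      x <- rnorm(12)
      y <- rnorm(12)
      reject_sign[i] <- sign_test(x)$p_value < 0.05
      reject_mw[i] <- mann_whitney_u(x, y)$p_value < 0.05
    }
  })
  expect_lte(mean(reject_sign), 0.06)
  expect_lte(mean(reject_mw), 0.06)
})

test_that("chance level is the equiprobable guessing rate in percent", {
  expect_equal(chance_level(4), 25)
  expect_equal(chance_level(2), 50)
  expect_equal(chance_level(100), 1)
  expect_error(chance_level(1), "at least 2")
})
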