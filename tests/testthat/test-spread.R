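test_that("eccentricity profiles average as defined at both levels", {
  v <- tiny_study(seed = 71)$voxels
  # constant data: profile constant with zero SE
  vc <- v
  vc[c("C", "S_N", "S_F", "m_C_SN", "m_C_SF")] <- 2.5
  p <- eccentricity_profile(vc, "V1", "C", "subject", subject = 1)
  expect_equal(p$mean, rep(2.5, 5))
  expect_equal(p$se, rep(0, 5))
  expect_equal(p$ecc_deg, c(1.65, 3.15, 5.05, 7.4, 10.35))
  # group profile is the mean of the subject profiles (balanced design)
  pg <- eccentricity_profile(v, "V2", "S_N", "group")
  subj <- lapply(unique(v$subject), function(s) {
    eccentricity_profile(v, "V2", "S_N", "subject", subject = s)$mean
  })
  expect_equal(pg$mean, Reduce(`+`, subj) / length(subj))
  expect_error(eccentricity_profile(v[v$ring != 3, ], "V1", "C",
                                    "subject", subject = 1), "ring 3")
  expect_error(eccentricity_profile(v, "V1", "bogus"), "condition")
})

test_that("zero crossings match the closed-form roots of fitted parabolas", {
  g <- study_geometry()
  ecc <- ring_eccentricities(g)
  mk_profile <- function(means) {
    p <- tibble::tibble(ring = 1:5, ecc_deg = ecc, mean = means,
                        se = 0, n = 2, area = "V1", condition = "C",
                        level = "group")
    class(p) <- c("cd_profile", class(p))
    attr(p, "geometry") <- g
    p
  }
  # exact line crossing zero at 7 degrees
  cr <- zero_crossing(mk_profile(7 - ecc), "peripheral", 2.3, n_boot = 0)
  expect_equal(cr$crossing_deg, 7, tolerance = 1e-9)
  expect_equal(cr$censored, "none")
  # exact parabola with analytic roots: y = (E - 3)(E - 9)/10
  parab <- (ecc - 3) * (ecc - 9) / 10
  cr2 <- zero_crossing(mk_profile(parab), "peripheral", 2.3, n_boot = 0)
  expect_equal(cr2$crossing_deg, 3, tolerance = 1e-9)
  cr3 <- zero_crossing(mk_profile(parab), "central", 10, n_boot = 0)
  expect_equal(cr3$crossing_deg, 9, tolerance = 1e-9)
  # all-positive profile: censored beyond the sampled range
  cr4 <- zero_crossing(mk_profile(rep(1, 5) + 0.1 * ecc), "peripheral", 4,
                       n_boot = 0)
  expect_equal(cr4$censored, "high")
  expect_true(is.na(cr4$crossing_deg))
  expect_match(cr4$label, ">12")
  # censoring is symmetric: the mirrored profile censors on the central side
  cr5 <- zero_crossing(mk_profile(rep(1, 5) + 0.1 * rev(ecc)), "central", 8,
                       n_boot = 0)
  expect_equal(cr5$censored, "low")
  expect_match(cr5$label, "<1")
})

test_that("group crossings carry a bootstrap CI and respond to direction", {
  st <- tiny_study(n_subjects = 6, seed = 81)
  prof <- eccentricity_profile(st$voxels, "V1", "C", "group")
  cr <- zero_crossing(prof, "peripheral", 2.3, n_boot = 100, seed = 5)
  cr_rep <- zero_crossing(prof, "peripheral", 2.3, n_boot = 100, seed = 5)
  expect_equal(cr, cr_rep) # seeded bootstrap is reproducible
  expect_equal(cr$censored, "none")
  expect_true(cr$ci_lo_censored != "none" || cr$ci_lo_deg <= cr$crossing_deg)
  expect_true(cr$ci_hi_censored != "none" || cr$ci_hi_deg >= cr$crossing_deg)
})

test_that("cortical spread conversion is Schwartz-consistent and censoring-aware", {
  g <- study_geometry()
  expect_equal(spread_mm(2.3, 2.3, g)$spread_mm, 0)
  expect_equal(spread_mm(2.3, 7.7, g)$spread_mm, 17 * log(8.7 / 3.3))
  # doubling k doubles every spread
  g2 <- study_geometry(magnification_k = 34)
  expect_equal(spread_mm(2.3, 7.7, g2)$spread_mm,
               2 * spread_mm(2.3, 7.7, g)$spread_mm)
  # censored central crossing from 8.7 deg: lower bound 17*log(9.7/2)
  fake <- tibble::tibble(direction = "central", reference_edge_deg = 8.7,
                         crossing_deg = NA_real_, censored = "low",
                         ci_lo_deg = NA, ci_lo_censored = "low",
                         ci_hi_deg = NA, ci_hi_censored = "low", label = "<1")
  class(fake) <- c("cd_crossing", class(fake))
  out <- spread_mm(8.7, fake, g)
  expect_equal(out$spread_mm, 17 * log(9.7 / 2))
  expect_true(out$lower_bound)
})

test_that("fixed-size resampling error has the stated structure", {
  # zero-noise CD data: every repeat's mean d_M equals d_true exactly, so
  # the error reduces to the dispersion of the subsample decorrelating
  # coefficient around d_true
  st <- tiny_study(n_subjects = 1, noise_sd = 0, voxels_per_ring_per_area = 40,
                   seed = 91)
  d_true <- st$ground_truth$d_true$d_true[1]
  res <- resampling_error(st$voxels, "VOI_C", "near", seed = 3)
  reps <- res$repeats[[1]]
  expect_equal(reps$mean_d_m, rep(d_true, 100), tolerance = 1e-10)
  expect_equal(res$mean_sq_error, mean((d_true - reps$d_t)^2),
               tolerance = 1e-12)
  # same seed twice: identical
  expect_equal(res, resampling_error(st$voxels, "VOI_C", "near", seed = 3))
  expect_error(resampling_error(st$voxels[1:10, ], "VOI_C", "near"),
               "only")
  # seeded 3-level noise trend: measurement noise monotonically inflates
  # the spread of the resampled VOI means
  sds <- vapply(c(0.05, 0.15, 0.4), function(ns) {
    stn <- tiny_study(n_subjects = 2, noise_sd = ns, seed = 9)
    reps <- resampling_error(stn$voxels, "VOI_ring2", "near",
                             seed = 5)$repeats[[1]]
    sd(reps$mean_d_m)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("resampling errors are comparable across ring VOIs on homogeneous data", {
  # voxels drawn iid regardless of ring label: the fixed selection size
  # should leave no systematic error difference between ring VOIs
  withr::with_seed(77, {
    n <- 500
    C <- rnorm(n, 1, 0.3)
    S <- rnorm(n, 0.8, 0.3)
    m <- 0.7 * (C + S) + rnorm(n, 0, 0.1)
  })
  tab <- tibble::tibble(
    subject = 1, hemisphere = "R", area = "V1", ring = rep(1:5, each = 100),
    eccentricity_deg = 5, C = C, S_N = S, S_F = S, m_C_SN = m, m_C_SF = m
  )
  errs <- vapply(paste0("VOI_ring", 1:5), function(voi) {
    resampling_error(tab, voi, "near", theta = 0, seed = 7)$mean_sq_error
  }, numeric(1))
  expect_lt(max(errs) / min(errs), 2)
})

test_that("the spread report covers every area-condition-direction cell", {
  st <- tiny_study(n_subjects = 4, seed = 25)
  rep <- bold_spread_report(st$voxels, n_boot = 20, seed = 2)
  expect_equal(nrow(rep), 3 * 4) # 3 areas x 4 condition/direction specs
  expect_true(all(rep$spread_mm >= 0))
  expect_true(all(rep$censored %in% c("none", "low", "high")))
})
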