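# Shared fixtures: small studies and hand-sized inputs built in code.

worked_C <- c(1, 2, 3, 4)
worked_S <- c(2, 1, 4, 3)

# a small, cheap study; override any config field via ...
tiny_study <- function(n_subjects = 2, voxels_per_ring_per_area = 20,
                       seed = 101, ...) {
  generate_study(
    generation_config(n_subjects = n_subjects,
                      voxels_per_ring_per_area = voxels_per_ring_per_area,
                      seed = seed, ...)
  )
}

# scatter points drawn from a known generative rule with noise on d
rule_scatter <- function(rule, seed, n = 60, noise_sd = 0.05) {
  withr::with_seed(seed, {
    r <- stats::runif(n, -0.2, 0.9)
    d0 <- switch(rule,
      CD = cd_curve(r),
      LINEAR_IDENTITY = r,
      LINFIT = 0.1 + 0.5 * r,
      POLY3 = 0.05 - 0.4 * r + 0.3 * r^2 + 1.2 * r^3
    )
    tibble::tibble(r = r, mean_d = d0 + stats::rnorm(n, 0, noise_sd))
  })
}
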