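#' Configuration for the synthetic voxel-table generator
#'
#' Parameterises [generate_study()]. The generator emulates the condition-level
#' structure of a multi-subject center/surround fMRI experiment: per-voxel
#' percent-BOLD-change estimates for five conditions (C, S_N, S_F, m(C,S_N),
#' m(C,S_F)) with retinotopically localised positive responses, long-range
#' positive spread that turns negative with cortical distance, a controllable
#' correlation between center and surround activation patterns, and a chosen
#' ground-truth interaction rule producing the combined responses.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param voxels_per_ring_per_area Voxels drawn per eccentricity ring per area
#'   (default 40, giving roughly 200 voxels per area per subject with the
#'   default five rings).
#' @param interaction_rule One of `"CD"`, `"MAX"`, `"AVERAGE"`, `"LINEAR"`:
#'   how the combined response m(C,S) is built from the component responses.
#'   CD: `m = (C - d*S) + (S - d*C) = (1 - d) * (C + S)`; LINEAR: `C + S`;
#'   MAX: voxel-wise `max(C, S)`; AVERAGE: voxel-wise `(C + S) / 2`.
#' @param d_true Decorrelation coefficient used by the CD rule: a number in
#'   \eqn{[-1, 1]}, or `"auto"` (default) to use the fully-decorrelating
#'   coefficient [theoretical_d()] of each subject's noiseless component
#'   patterns, so the generated data sit exactly on the CD curve.
#' @param peak_amplitude Peak percent-BOLD change of the noiseless response
#'   template inside the stimulus representation (default 1.05, a typical
#'   percent-signal-change scale for low-contrast gratings at 3 T).
#' @param spread_sigma_mm Width (SD, mm) of the positive lobe of the cortical
#'   point-spread profile (default 6).
#' @param negative_lobe_gain Relative gain of the wide negative lobe, in
#'   `[0, 1)` (default 0.3). With 0 the template is everywhere non-negative.
#' @param negative_lobe_ratio Width ratio of the negative to the positive lobe
#'   (default 3).
#' @param noise_sd SD of independent Gaussian noise added to every condition
#'   estimate (percent-BOLD units; default 0.15).
#' @param shared_noise_sd SD of a single shared Gaussian draw per voxel added
#'   to C, S and m alike (default 0), emulating temporally correlated noise
#'   that enters every condition estimate of a voxel.
#' @param amplitude_jitter_sd Per-subject log-normal amplitude jitter (sdlog;
#'   default 0.15), applied per condition.
#' @param offset_jitter_mm_sd Per-subject jitter (SD, mm) of each stimulus
#'   representation along the cortical axis (default 1.5). Together with the
#'   amplitude jitter this produces the between-subject spread of
#'   pattern correlations.
#' @param target_correlation Optional Pearson correlation to realise between
#'   the noiseless C and S_N templates over suprathreshold voxels; when set,
#'   `spread_sigma_mm` is retuned by a deterministic search.
#' @param theta Suprathreshold magnitude (percent BOLD) used when tuning
#'   `target_correlation` (default 0.2).
#' @param seed Integer seed; all randomness flows from it through named
#'   substreams keyed by (subject, area, stage), so adding areas does not
#'   perturb existing subjects.
#'
#' @return An object of class `cd_generation_config`.
#' @export
generation_config <- function(n_subjects = 15,
                              voxels_per_ring_per_area = 40,
                              interaction_rule = c("CD", "MAX", "AVERAGE", "LINEAR"),
                              d_true = "auto",
                              peak_amplitude = 1.05,
                              spread_sigma_mm = 6,
                              negative_lobe_gain = 0.3,
                              negative_lobe_ratio = 3,
                              noise_sd = 0.15,
                              shared_noise_sd = 0,
                              amplitude_jitter_sd = 0.15,
                              offset_jitter_mm_sd = 1.5,
                              target_correlation = NULL,
                              theta = 0.2,
                              seed = 1L) {
  interaction_rule <- match.arg(interaction_rule)
  stopifnot(
    n_subjects >= 1, voxels_per_ring_per_area >= 1,
    peak_amplitude > 0, spread_sigma_mm > 0,
    negative_lobe_gain >= 0, negative_lobe_gain < 1,
    negative_lobe_ratio > 1,
    noise_sd >= 0, shared_noise_sd >= 0,
    amplitude_jitter_sd >= 0, offset_jitter_mm_sd >= 0
  )
  if (is.character(d_true)) {
    if (!identical(d_true, "auto")) {
      stop('`d_true` must be numeric in [-1, 1] or "auto"', call. = FALSE)
    }
  } else if (!is.numeric(d_true) || abs(d_true) > 1) {
    stop('`d_true` must be numeric in [-1, 1] or "auto"', call. = FALSE)
  }
  if (!is.null(target_correlation) &&
      (abs(target_correlation) >= 1 || !is.finite(target_correlation))) {
    stop("`target_correlation` must be a finite correlation in (-1, 1)",
         call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      voxels_per_ring_per_area = as.integer(voxels_per_ring_per_area),
      interaction_rule = interaction_rule,
      d_true = d_true,
      peak_amplitude = peak_amplitude,
      spread_sigma_mm = spread_sigma_mm,
      negative_lobe_gain = negative_lobe_gain,
      negative_lobe_ratio = negative_lobe_ratio,
      noise_sd = noise_sd,
      shared_noise_sd = shared_noise_sd,
      amplitude_jitter_sd = amplitude_jitter_sd,
      offset_jitter_mm_sd = offset_jitter_mm_sd,
      target_correlation = target_correlation,
      theta = theta,
      seed = as.integer(seed)
    ),
    class = "cd_generation_config"
  )
}

#' @export
print.cd_generation_config <- function(x, ...) {
  cat("<cd_generation_config>\n")
  cat("  subjects:", x$n_subjects,
      " voxels/ring/area:", x$voxels_per_ring_per_area, "\n")
  cat("  rule:", x$interaction_rule, " d_true:",
      if (is.character(x$d_true)) x$d_true else format(x$d_true), "\n")
  cat("  template: peak", x$peak_amplitude, "%, sigma",
      x$spread_sigma_mm, "mm, negative lobe gain", x$negative_lobe_gain, "\n")
  cat("  noise sd:", x$noise_sd, " shared noise sd:", x$shared_noise_sd, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Deterministic substream seed derivation, kept below 2^31.
substream_seed <- function(seed, subject = 0L, area = 0L, stage = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + subject * 69621 + area * 16807 + stage * 30269 + 11) %% m
  as.integer(s)
}

# Difference-of-Gaussians point-spread profile on the cortical axis.
# `dist_mm` is the cortical distance from the stimulus representation
# (0 for voxels retinotopically inside the stimulus).
dog_profile <- function(dist_mm, peak_amplitude, spread_sigma_mm,
                        negative_lobe_gain, negative_lobe_ratio) {
  s1 <- spread_sigma_mm
  s2 <- negative_lobe_ratio * spread_sigma_mm
  scale <- peak_amplitude / (1 - negative_lobe_gain)
  scale * (exp(-dist_mm^2 / (2 * s1^2)) -
             negative_lobe_gain * exp(-dist_mm^2 / (2 * s2^2)))
}

#' Noiseless response template for a stimulus annulus
#'
#' Evaluates the center-surround (difference-of-Gaussians) cortical
#' point-spread profile at a set of voxel eccentricities: the response is
#' maximal (equal to `peak_amplitude`) for voxels retinotopically inside the
#' stimulus extent, decays with cortical distance from the stimulus
#' representation, and — when `negative_lobe_gain > 0` — crosses zero and turns
#' negative at large distances, emulating the negative BOLD ring around a
#' focal activation. With `negative_lobe_gain = 0` the template is everywhere
#' non-negative.
#'
#' @param voxel_eccentricities_deg Non-empty numeric vector of voxel
#'   eccentricities (degrees).
#' @param stimulus_extent_deg Length-2 (inner, outer) eccentricity of the
#'   stimulus annulus, within the geometry's ring range.
#' @inheritParams generation_config
#' @param geometry A [study_geometry()].
#' @param offset_mm Optional shift (mm) of the stimulus representation along
#'   the cortical axis (used for per-subject retinotopic jitter).
#' @return Numeric vector of noiseless percent-BOLD changes.
#' @seealso [template_zero_crossing_mm()] for the analytic sign flip distance.
#' @export
response_template <- function(voxel_eccentricities_deg,
                              stimulus_extent_deg,
                              geometry = study_geometry(),
                              peak_amplitude = 1.05,
                              spread_sigma_mm = 6,
                              negative_lobe_gain = 0.3,
                              negative_lobe_ratio = 3,
                              offset_mm = 0) {
  if (length(voxel_eccentricities_deg) == 0) {
    stop("`voxel_eccentricities_deg` must be non-empty", call. = FALSE)
  }
  rng <- range(geometry$ring_borders)
  if (stimulus_extent_deg[1] < rng[1] || stimulus_extent_deg[2] > rng[2]) {
    stop("stimulus extent must lie within the geometry's ring range",
         call. = FALSE)
  }
  pos <- cortical_position(voxel_eccentricities_deg, geometry)
  edge <- cortical_position(stimulus_extent_deg, geometry) + offset_mm
  dist <- pmax(0, pmax(edge[1] - pos, pos - edge[2]))
  dog_profile(dist, peak_amplitude, spread_sigma_mm,
              negative_lobe_gain, negative_lobe_ratio)
}

#' Analytic zero-crossing distance of the response template
#'
#' Cortical distance (mm) from the stimulus representation at which the
#' difference-of-Gaussians template changes sign. Defined only for
#' `negative_lobe_gain > 0`.
#'
#' @inheritParams generation_config
#' @return Distance in mm.
#' @export
template_zero_crossing_mm <- function(spread_sigma_mm = 6,
                                      negative_lobe_gain = 0.3,
                                      negative_lobe_ratio = 3) {
  if (negative_lobe_gain <= 0) {
    stop("the template has no sign change when `negative_lobe_gain` is 0",
         call. = FALSE)
  }
  s1 <- spread_sigma_mm
  s2 <- negative_lobe_ratio * spread_sigma_mm
  sqrt(2 * s1^2 * s2^2 * log(1 / negative_lobe_gain) / (s2^2 - s1^2))
}

# Tune spread_sigma_mm so that the noiseless C and S_N templates, evaluated
# on a dense grid matching the generator's sampling density (equal numbers of
# points per ring, uniform in cortical position within each ring) and
# restricted to suprathreshold voxels, realise the requested correlation.
tune_spread_sigma <- function(config, geometry, n_grid_per_ring = 200) {
  b <- geometry$ring_borders
  pos <- unlist(lapply(seq_len(length(b) - 1L), function(r) {
    seq(cortical_position(b[r], geometry),
        cortical_position(b[r + 1], geometry),
        length.out = n_grid_per_ring)
  }))
  ecc <- cortical_eccentricity(pos, geometry)
  corr_at <- function(sigma) {
    C <- response_template(ecc, geometry$center_stim, geometry,
                           config$peak_amplitude, sigma,
                           config$negative_lobe_gain, config$negative_lobe_ratio)
    S <- response_template(ecc, geometry$near_surround_stim, geometry,
                           config$peak_amplitude, sigma,
                           config$negative_lobe_gain, config$negative_lobe_ratio)
    keep <- abs(C) >= config$theta | abs(S) >= config$theta
    if (sum(keep) < 3) return(NA_real_)
    stats::cor(C[keep], S[keep])
  }
  obj <- function(sigma) {
    r <- corr_at(sigma)
    if (is.na(r)) 1e6 else abs(r - config$target_correlation)
  }
  opt <- stats::optimize(obj, interval = c(0.5, 40), tol = 1e-4)
  if (opt$objective > 0.05) {
    stop("could not tune `spread_sigma_mm` to realise target correlation ",
         config$target_correlation, " (best |error| = ",
         signif(opt$objective, 3), ")", call. = FALSE)
  }
  opt$minimum
}

#' Generate a synthetic multi-subject voxel table
#'
#' Draws voxel eccentricities uniformly in cortical position within each
#' eccentricity ring (emulating approximately uniform cortical sampling under
#' cortical magnification), builds noiseless C, S_N and S_F patterns from
#' [response_template()] with per-subject amplitude and retinotopic-offset
#' jitter, combines them into m(C,S_N) and m(C,S_F) according to the
#' configured interaction rule, and finally adds independent measurement noise
#' to every condition estimate plus, optionally, one shared draw per voxel
#' added to all conditions alike.
#'
#' @param config A [generation_config()].
#' @param geometry A [study_geometry()].
#' @return An object of class `cd_study`: a list with
#'   \describe{
#'     \item{`voxels`}{tibble with columns `subject`, `hemisphere`, `area`,
#'       `ring`, `eccentricity_deg`, `C`, `S_N`, `S_F`, `m_C_SN`, `m_C_SF`.}
#'     \item{`ground_truth`}{list with the interaction rule, the per-subject
#'       `d_true` used for each surround, the noiseless condition table, and
#'       the (possibly retuned) configuration and geometry.}
#'   }
#' @examples
#' study <- generate_study(generation_config(n_subjects = 2, seed = 7))
#' dplyr::count(study$voxels, subject, area)
#' @export
generate_study <- function(config = generation_config(),
                           geometry = study_geometry()) {
  stopifnot(inherits(config, "cd_generation_config"),
            inherits(geometry, "cd_geometry"))
  if (!is.null(config$target_correlation)) {
    config$spread_sigma_mm <- tune_spread_sigma(config, geometry)
  }
  borders <- geometry$ring_borders
  n_rings <- length(borders) - 1L
  areas <- geometry$areas
  template_for <- function(ecc, extent, amp_mult, offset) {
    amp_mult * response_template(
      ecc, extent, geometry,
      peak_amplitude = config$peak_amplitude,
      spread_sigma_mm = config$spread_sigma_mm,
      negative_lobe_gain = config$negative_lobe_gain,
      negative_lobe_ratio = config$negative_lobe_ratio,
      offset_mm = offset
    )
  }

  subject_tables <- vector("list", config$n_subjects)
  d_rows <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    # subject-level jitter draws (stage 0, area 0)
    withr::with_seed(substream_seed(config$seed, s, 0L, 0L), {
      amp <- exp(stats::rnorm(3, 0, config$amplitude_jitter_sd))
      off <- stats::rnorm(3, 0, config$offset_jitter_mm_sd)
    })
    area_parts <- vector("list", length(areas))
    for (a in seq_along(areas)) {
      withr::with_seed(substream_seed(config$seed, s, a, 1L), {
        pos <- unlist(lapply(seq_len(n_rings), function(r) {
          stats::runif(config$voxels_per_ring_per_area,
                       cortical_position(borders[r], geometry),
                       cortical_position(borders[r + 1], geometry))
        }))
      })
      ecc <- cortical_eccentricity(pos, geometry)
      ring <- rep(seq_len(n_rings), each = config$voxels_per_ring_per_area)
      area_parts[[a]] <- tibble::tibble(
        subject = s, hemisphere = "R", area = areas[a], ring = ring,
        eccentricity_deg = ecc,
        C0 = template_for(ecc, geometry$center_stim, amp[1], off[1]),
        SN0 = template_for(ecc, geometry$near_surround_stim, amp[2], off[2]),
        SF0 = template_for(ecc, geometry$far_surround_stim, amp[3], off[3])
      )
    }
    subj <- dplyr::bind_rows(area_parts)

    d_for <- function(S0) {
      if (identical(config$d_true, "auto")) {
        theoretical_d(subj$C0, S0)$d_t
      } else {
        config$d_true
      }
    }
    combine <- function(C0, S0, d) {
      switch(config$interaction_rule,
        CD = (1 - d) * (C0 + S0),
        LINEAR = C0 + S0,
        MAX = pmax(C0, S0),
        AVERAGE = (C0 + S0) / 2
      )
    }
    d_near <- d_for(subj$SN0)
    d_far <- d_for(subj$SF0)
    subj$mN0 <- combine(subj$C0, subj$SN0, d_near)
    subj$mF0 <- combine(subj$C0, subj$SF0, d_far)
    d_rows[[s]] <- tibble::tibble(
      subject = s, surround = c("near", "far"), d_true = c(d_near, d_far)
    )

    # measurement noise (stage 2), per area so substreams stay area-local
    noisy <- lapply(seq_along(areas), function(a) {
      part <- subj[subj$area == areas[a], ]
      n <- nrow(part)
      withr::with_seed(substream_seed(config$seed, s, a, 2L), {
        eps <- matrix(stats::rnorm(5 * n, 0, config$noise_sd), nrow = n)
        eta <- if (config$shared_noise_sd > 0) {
          stats::rnorm(n, 0, config$shared_noise_sd)
        } else {
          numeric(n)
        }
      })
      part$C <- part$C0 + eps[, 1] + eta
      part$S_N <- part$SN0 + eps[, 2] + eta
      part$S_F <- part$SF0 + eps[, 3] + eta
      part$m_C_SN <- part$mN0 + eps[, 4] + eta
      part$m_C_SF <- part$mF0 + eps[, 5] + eta
      part
    })
    subject_tables[[s]] <- dplyr::bind_rows(noisy)
  }

  full <- dplyr::bind_rows(subject_tables)
  voxels <- dplyr::select(
    full, "subject", "hemisphere", "area", "ring", "eccentricity_deg",
    "C", "S_N", "S_F", "m_C_SN", "m_C_SF"
  )
  noiseless <- dplyr::select(
    full, "subject", "hemisphere", "area", "ring", "eccentricity_deg",
    C = "C0", S_N = "SN0", S_F = "SF0", m_C_SN = "mN0", m_C_SF = "mF0"
  )
  structure(
    list(
      voxels = voxels,
      ground_truth = list(
        interaction_rule = config$interaction_rule,
        d_true = dplyr::bind_rows(d_rows),
        noiseless = noiseless,
        config = config,
        geometry = geometry
      )
    ),
    class = "cd_study"
  )
}

#' @export
print.cd_study <- function(x, ...) {
  cat("<cd_study> rule:", x$ground_truth$interaction_rule,
      "|", nrow(x$voxels), "voxels,",
      length(unique(x$voxels$subject)), "subjects,",
      length(unique(x$voxels$area)), "areas\n")
  print(x$voxels, n = 5)
  invisible(x)
}
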