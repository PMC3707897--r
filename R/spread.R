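#' Eccentricity profile of BOLD change for one area and condition
#'
#' Averages a condition's percent-BOLD change per eccentricity ring, either
#' within one subject (mean and SE across voxels) or at the group level
#' (per-subject ring means first, then mean and SE across subjects). Group
#' profiles carry the per-subject ring means as the `"subject_means"`
#' attribute so that [zero_crossing()] can bootstrap over subjects.
#'
#' @param table A voxel table (see [generate_study()]).
#' @param area Area label to profile.
#' @param condition Condition column: one of `"C"`, `"S_N"`, `"S_F"`,
#'   `"m_C_SN"`, `"m_C_SF"`.
#' @param level `"group"` (default) or `"subject"`.
#' @param subject Subject id, required when `level = "subject"` and the table
#'   holds several subjects.
#' @param geometry A [study_geometry()] (ring representative eccentricities).
#' @param convention Abscissa convention for [ring_eccentricities()].
#' @return A tibble of class `cd_profile`: `ring`, `ecc_deg`, `mean`, `se`,
#'   `n`, plus `area`, `condition`, `level` columns.
#' @export
eccentricity_profile <- function(table, area, condition,
                                 level = c("group", "subject"),
                                 subject = NULL,
                                 geometry = study_geometry(),
                                 convention = c("midpoint", "log_midpoint")) {
  level <- match.arg(level)
  convention <- match.arg(convention)
  cond_cols <- c("C", "S_N", "S_F", "m_C_SN", "m_C_SF")
  if (!condition %in% cond_cols) {
    stop("`condition` must be one of: ", paste(cond_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- table[table$area == area, , drop = FALSE]
  if (nrow(rows) == 0) stop("no voxels in area '", area, "'", call. = FALSE)
  ecc <- ring_eccentricities(geometry, convention)
  rings <- seq_along(ecc)

  subj_means <- rows |>
    dplyr::group_by(.data$subject, .data$ring) |>
    dplyr::summarise(
      mean = mean(.data[[condition]]),
      sd = stats::sd(.data[[condition]]),
      n = dplyr::n(),
      .groups = "drop"
    )

  if (level == "subject") {
    if (is.null(subject)) {
      ids <- unique(rows$subject)
      if (length(ids) > 1) {
        stop("`subject` must be given when the table holds several subjects",
             call. = FALSE)
      }
      subject <- ids
    }
    prof <- subj_means[subj_means$subject == subject, , drop = FALSE]
    missing <- setdiff(rings, prof$ring)
    if (length(missing)) {
      stop("ring ", paste(missing, collapse = ", "),
           " has no voxels for subject ", subject, " in area '", area, "'",
           call. = FALSE)
    }
    prof <- prof[order(prof$ring), ]
    out <- tibble::tibble(
      ring = prof$ring, ecc_deg = ecc[prof$ring],
      mean = prof$mean, se = prof$sd / sqrt(prof$n), n = prof$n
    )
  } else {
    grp <- subj_means |>
      dplyr::group_by(.data$ring) |>
      dplyr::summarise(
        m = mean(.data$mean),
        se = stats::sd(.data$mean) / sqrt(dplyr::n()),
        n = dplyr::n(),
        .groups = "drop"
      )
    missing <- setdiff(rings, grp$ring)
    if (length(missing)) {
      stop("ring ", paste(missing, collapse = ", "),
           " is empty in area '", area, "'", call. = FALSE)
    }
    bad <- grp$ring[grp$n < 2]
    if (length(bad)) {
      stop("ring ", paste(bad, collapse = ", "),
           " represented by fewer than 2 subjects in area '", area, "'",
           call. = FALSE)
    }
    grp <- grp[order(grp$ring), ]
    out <- tibble::tibble(
      ring = grp$ring, ecc_deg = ecc[grp$ring],
      mean = grp$m, se = grp$se, n = grp$n
    )
  }
  out$area <- area
  out$condition <- condition
  out$level <- level
  class(out) <- c("cd_profile", class(out))
  attr(out, "subject_means") <- subj_means
  attr(out, "geometry") <- geometry
  out
}

# Real roots of a quadratic fit of `mean` on `ecc_deg`; returns numeric(0)
# when only complex roots exist. Falls back to the linear root when the
# quadratic coefficient vanishes.
quadratic_roots <- function(ecc, y) {
  cf <- stats::lm(y ~ ecc + I(ecc^2))$coefficients
  a <- cf[[3]]; b <- cf[[2]]; c <- cf[[1]]
  if (!is.finite(a) || abs(a) < 1e-12) {
    if (!is.finite(b) || abs(b) < 1e-12) return(numeric(0))
    return(-c / b)
  }
  disc <- b^2 - 4 * a * c
  if (disc < 0) return(numeric(0))
  (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
}

# Pick the root nearest to the reference edge in the travel direction, with
# censoring at the sampled eccentricity range.
pick_crossing <- function(roots, direction, reference_edge, range_deg) {
  cand <- if (direction == "peripheral") {
    sort(roots[roots >= reference_edge])
  } else {
    sort(roots[roots <= reference_edge], decreasing = TRUE)
  }
  censored_side <- if (direction == "peripheral") "high" else "low"
  if (length(cand) == 0) {
    return(list(crossing = NA_real_, censored = censored_side))
  }
  cr <- cand[1]
  if (cr > range_deg[2]) return(list(crossing = NA_real_, censored = "high"))
  if (cr < range_deg[1]) return(list(crossing = NA_real_, censored = "low"))
  list(crossing = cr, censored = "none")
}

#' Eccentricity at which a BOLD profile crosses zero
#'
#' Fits a second-degree polynomial to the ring means of an eccentricity
#' profile and returns the real root nearest to the stimulus edge in the
#' stated travel direction. When no crossing occurs within the sampled
#' eccentricities the estimate is censored (`"<1 deg"` or `">12 deg"` at the
#' default ring borders). For group-level profiles a 95% percentile-bootstrap
#' confidence interval over subjects is computed with `n_boot` resamples.
#'
#' @param profile A [eccentricity_profile()] result (>= 3 rings).
#' @param direction `"peripheral"` (crossing beyond the reference edge) or
#'   `"central"` (crossing inside it).
#' @param reference_edge Stimulus edge eccentricity in degrees from which the
#'   spread is measured (outer edge for peripheral, inner for central).
#' @param n_boot Bootstrap resamples for the CI (default 1000; 0 disables).
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble of class `cd_crossing`: `direction`,
#'   `reference_edge_deg`, `crossing_deg` (`NA` when censored), `censored`
#'   (`"none"`, `"low"`, `"high"`), `ci_lo_deg`, `ci_lo_censored`,
#'   `ci_hi_deg`, `ci_hi_censored`, `label` (printed form, e.g.
#'   `"7.0 (3.8 - >12)"`).
#' @export
zero_crossing <- function(profile,
                          direction = c("peripheral", "central"),
                          reference_edge,
                          n_boot = 1000, seed = 1L) {
  direction <- match.arg(direction)
  if (nrow(profile) < 3) stop("need at least 3 rings", call. = FALSE)
  if (any(!is.finite(profile$mean))) {
    stop("profile means must be finite", call. = FALSE)
  }
  geometry <- attr(profile, "geometry") %||% study_geometry()
  range_deg <- range(geometry$ring_borders)

  est <- pick_crossing(quadratic_roots(profile$ecc_deg, profile$mean),
                       direction, reference_edge, range_deg)

  ci <- list(lo = NA_real_, lo_cens = NA_character_,
             hi = NA_real_, hi_cens = NA_character_)
  sm <- attr(profile, "subject_means")
  if (n_boot > 0 && !is.null(sm) && profile$level[1] == "group") {
    subjects <- unique(sm$subject)
    ecc_by_ring <- stats::setNames(profile$ecc_deg, profile$ring)
    wide <- sm |>
      dplyr::filter(.data$ring %in% profile$ring) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "ring",
                         values_from = "mean") |>
      as.data.frame()
    ring_cols <- as.character(sort(profile$ring))
    mat <- as.matrix(wide[, ring_cols, drop = FALSE])
    ecc <- ecc_by_ring[ring_cols]
    boot_vals <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(mat), replace = TRUE)
        y <- colMeans(mat[idx, , drop = FALSE])
        cr <- pick_crossing(quadratic_roots(ecc, y), direction,
                            reference_edge, range_deg)
        if (cr$censored == "high") Inf
        else if (cr$censored == "low") -Inf
        else cr$crossing
      }, numeric(1))
    })
    q <- stats::quantile(boot_vals, c(0.025, 0.975), names = FALSE, type = 1)
    as_cens <- function(v) {
      if (v == Inf) list(val = NA_real_, cens = "high")
      else if (v == -Inf) list(val = NA_real_, cens = "low")
      else list(val = v, cens = "none")
    }
    lo <- as_cens(q[1]); hi <- as_cens(q[2])
    ci <- list(lo = lo$val, lo_cens = lo$cens, hi = hi$val, hi_cens = hi$cens)
  }

  fmt <- function(val, cens) {
    if (identical(cens, "high")) paste0(">", range_deg[2])
    else if (identical(cens, "low")) paste0("<", range_deg[1])
    else if (is.na(val)) "NA"
    else format(round(val, 1))
  }
  out <- tibble::tibble(
    direction = direction,
    reference_edge_deg = reference_edge,
    crossing_deg = est$crossing,
    censored = est$censored,
    ci_lo_deg = ci$lo, ci_lo_censored = ci$lo_cens,
    ci_hi_deg = ci$hi, ci_hi_censored = ci$hi_cens,
    label = paste0(fmt(est$crossing, est$censored), " (",
                   fmt(ci$lo, ci$lo_cens), " - ", fmt(ci$hi, ci$hi_cens), ")")
  )
  class(out) <- c("cd_crossing", class(out))
  attr(out, "geometry") <- geometry
  out
}

#' Cortical spread between a stimulus edge and a zero crossing
#'
#' Converts the visual-field separation between a stimulus edge and an
#' estimated zero-crossing eccentricity to cortical millimetres via the
#' Schwartz mapping, `|pos(crossing) - pos(edge)|`. A censored crossing
#' yields a lower bound: the distance to the sampled eccentricity limit,
#' flagged with `lower_bound = TRUE`.
#'
#' @param reference_edge Stimulus edge eccentricity (degrees).
#' @param crossing A [zero_crossing()] row, or a numeric crossing in degrees.
#' @param geometry A [study_geometry()].
#' @return A one-row tibble: `spread_mm`, `lower_bound`.
#' @export
spread_mm <- function(reference_edge, crossing,
                      geometry = study_geometry()) {
  if (is.numeric(crossing)) {
    return(tibble::tibble(
      spread_mm = cortical_distance(reference_edge, crossing, geometry),
      lower_bound = FALSE
    ))
  }
  stopifnot(inherits(crossing, "cd_crossing"))
  rng <- range(geometry$ring_borders)
  if (crossing$censored == "none") {
    tibble::tibble(
      spread_mm = cortical_distance(reference_edge, crossing$crossing_deg,
                                    geometry),
      lower_bound = FALSE
    )
  } else {
    lim <- if (crossing$censored == "high") rng[2] else rng[1]
    tibble::tibble(
      spread_mm = cortical_distance(reference_edge, lim, geometry),
      lower_bound = TRUE
    )
  }
}

#' Fixed-size resampling error between mean d_M and d_T within a VOI
#'
#' The goodness of fit of the decorrelation prediction depends on the number
#' of voxels in a VOI; resampling a fixed number of voxels makes the error
#' comparable across VOIs. Per repeat, `n_voxels` suprathreshold voxels are
#' sampled without replacement, and the squared difference between their mean
#' measured modulation index and the decorrelating coefficient computed on
#' the same sampled voxels is recorded; the result averages over repeats.
#'
#' @inheritParams voi_modulation
#' @param n_voxels Voxels per resample (default 20).
#' @param n_repeats Number of resamples (default 100).
#' @param seed Seed for the resampling.
#' @return A one-row tibble: `voi`, `surround`, `n_voxels`, `n_repeats`,
#'   `mean_sq_error`.
#' @export
resampling_error <- function(table, voi = "VOI_C",
                             surround = c("near", "far"),
                             n_voxels = 20, n_repeats = 100, seed = 1L,
                             theta = 0.2, denom_epsilon = 1e-9,
                             geometry = study_geometry()) {
  surround <- match.arg(surround)
  rows <- select_voi(table, voi, theta, geometry)
  if (nrow(rows) < n_voxels) {
    stop("VOI '", voi, "' has only ", nrow(rows),
         " suprathreshold voxels; need ", n_voxels, call. = FALSE)
  }
  cols <- surround_columns(surround)
  reps <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_repeats), function(i) {
      idx <- sample.int(nrow(rows), n_voxels)
      C <- rows$C[idx]
      S <- rows[[cols$S]][idx]
      m <- rows[[cols$m]][idx]
      dm <- measured_d(C, S, m, denom_epsilon)
      tibble::tibble(
        mean_d_m = mean(dm$d_m[!dm$undefined]),
        d_t = theoretical_d(C, S)$d_t
      )
    })
  })
  reps <- dplyr::bind_rows(reps)
  tibble::tibble(
    voi = voi, surround = surround,
    n_voxels = n_voxels, n_repeats = n_repeats,
    mean_sq_error = mean((reps$mean_d_m - reps$d_t)^2),
    repeats = list(reps)
  )
}

#' Table of zero crossings and cortical spreads per area and condition
#'
#' Convenience wrapper reproducing the shape of a spread report: for each
#' area and each of the stimulus conditions it profiles the group data,
#' estimates the zero crossing in the natural travel direction(s), and
#' converts the spread to cortical millimetres.
#'
#' @param table A voxel table.
#' @param geometry A [study_geometry()].
#' @param n_boot,seed Passed to [zero_crossing()].
#' @param theta Unused placeholder for API symmetry (profiles use all voxels).
#' @return Tibble with one row per area x condition x direction.
#' @export
bold_spread_report <- function(table, geometry = study_geometry(),
                               n_boot = 1000, seed = 1L, theta = 0) {
  specs <- list(
    list(condition = "C", direction = "peripheral",
         edge = geometry$center_stim[2]),
    list(condition = "S_N", direction = "central",
         edge = geometry$near_surround_stim[1]),
    list(condition = "S_N", direction = "peripheral",
         edge = geometry$near_surround_stim[2]),
    list(condition = "S_F", direction = "central",
         edge = geometry$far_surround_stim[1])
  )
  purrr::map(unique(table$area), function(ar) {
    purrr::map(specs, function(sp) {
      prof <- eccentricity_profile(table, ar, sp$condition,
                                   level = "group", geometry = geometry)
      cr <- zero_crossing(prof, sp$direction, sp$edge, n_boot, seed)
      mm <- spread_mm(sp$edge, cr, geometry)
      tibble::tibble(
        area = ar, condition = sp$condition, direction = sp$direction,
        reference_edge_deg = sp$edge,
        crossing_deg = cr$crossing_deg, censored = cr$censored,
        label = cr$label,
        spread_mm = mm$spread_mm, spread_is_lower_bound = mm$lower_bound
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
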