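#' Names of the available voxel-of-interest (VOI) selection rules
#'
#' Three families of VOI are supported, mirroring the usual selection schemes:
#' condition-active sets (`VOI_C`, `VOI_SN`, `VOI_SF`, and `VOI_AVA`, the union
#' over all five conditions), eccentricity-ring sets (`VOI_ring1` ...,
#' one per ring of the geometry), and functional-area sets (`VOI_V1`, ...).
#'
#' @param geometry A [study_geometry()] (supplies ring count and area labels).
#' @return Character vector of valid rule names.
#' @export
voi_names <- function(geometry = study_geometry()) {
  n_rings <- length(geometry$ring_borders) - 1L
  c("VOI_C", "VOI_SN", "VOI_SF", "VOI_AVA",
    paste0("VOI_ring", seq_len(n_rings)),
    paste0("VOI_", geometry$areas))
}

#' Select voxels of interest from a voxel table
#'
#' Applies one of the rules listed by [voi_names()]. Activity thresholding is
#' emulated by absolute response magnitude: a voxel is suprathreshold for a
#' condition when `|response| >= theta`. Condition VOIs threshold on their
#' defining condition (`VOI_AVA` on any of the five); ring and area VOIs
#' select by label and additionally require suprathreshold activity in at
#' least one condition (so that `theta = 0` reduces them to pure label
#' selections).
#'
#' @param table A voxel table (tibble with the canonical columns, see
#'   [generate_study()]).
#' @param voi Rule name, one of [voi_names()].
#' @param theta Suprathreshold magnitude in percent-BOLD units (default 0.2,
#'   matched to the default generator amplitude scale). `theta = 0` disables
#'   thresholding.
#' @param geometry A [study_geometry()] used to enumerate valid names.
#' @return The subset of rows passing the rule.
#' @export
select_voi <- function(table, voi, theta = 0.2,
                       geometry = study_geometry()) {
  valid <- voi_names(geometry)
  if (!is.character(voi) || length(voi) != 1 || !(voi %in% valid)) {
    stop("unknown VOI rule ", deparse(voi), "; valid rules: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  cond_cols <- c("C", "S_N", "S_F", "m_C_SN", "m_C_SF")
  supra <- function(col) abs(table[[col]]) >= theta
  any_supra <- Reduce(`|`, lapply(cond_cols, supra))
  keep <- switch(voi,
    VOI_C = supra("C"),
    VOI_SN = supra("S_N"),
    VOI_SF = supra("S_F"),
    VOI_AVA = any_supra,
    {
      if (grepl("^VOI_ring", voi)) {
        ring <- as.integer(sub("^VOI_ring", "", voi))
        table$ring == ring & (theta == 0 | any_supra)
      } else {
        area <- sub("^VOI_", "", voi)
        table$area == area & (theta == 0 | any_supra)
      }
    }
  )
  table[keep, , drop = FALSE]
}

# Resolve a surround label to its component and combined-response columns.
surround_columns <- function(surround = c("near", "far")) {
  surround <- match.arg(surround)
  if (surround == "near") {
    list(S = "S_N", m = "m_C_SN")
  } else {
    list(S = "S_F", m = "m_C_SF")
  }
}

#' Mean modulation index and pattern correlation within a VOI
#'
#' Restricts the table to a VOI, computes the per-voxel measured modulation
#' index [measured_d()] for the chosen surround, and summarises it together
#' with the Pearson correlation between the C and S patterns over the same
#' voxels and the VOI's fully-decorrelating coefficient [theoretical_d()].
#' Flagged (near-zero denominator) voxels are retained in the mean; only
#' exactly-undefined voxels are excluded.
#'
#' @inheritParams select_voi
#' @param surround `"near"` or `"far"`.
#' @param denom_epsilon Passed to [measured_d()].
#' @param exclude_flagged If `TRUE`, voxels flagged for a near-zero
#'   denominator are also excluded from the mean and SE (default `FALSE`:
#'   extreme d_M values are retained).
#' @return A one-row tibble: `voi`, `surround`, `n_voxels`, `n_flagged`,
#'   `n_undefined`, `mean_d_m`, `se_d_m`, `r_cs` (pattern correlation),
#'   `d_t`.
#' @examples
#' study <- generate_study(generation_config(n_subjects = 3, seed = 1))
#' voi_modulation(study$voxels, "VOI_C", "near")
#' @export
voi_modulation <- function(table, voi = "VOI_C",
                           surround = c("near", "far"),
                           theta = 0.2,
                           denom_epsilon = 1e-9,
                           exclude_flagged = FALSE,
                           geometry = study_geometry()) {
  surround <- match.arg(surround)
  rows <- select_voi(table, voi, theta, geometry)
  if (nrow(rows) < 3) {
    stop("VOI '", voi, "' selects fewer than 3 voxels (", nrow(rows), ")",
         call. = FALSE)
  }
  cols <- surround_columns(surround)
  dm <- measured_d(rows$C, rows[[cols$S]], rows[[cols$m]], denom_epsilon)
  keep <- !dm$undefined
  if (exclude_flagged) keep <- keep & !dm$flagged
  vals <- dm$d_m[keep]
  sol <- theoretical_d(rows$C, rows[[cols$S]])
  tibble::tibble(
    voi = voi,
    surround = surround,
    n_voxels = nrow(rows),
    n_flagged = sum(dm$flagged),
    n_undefined = sum(dm$undefined),
    mean_d_m = mean(vals),
    se_d_m = stats::sd(vals) / sqrt(length(vals)),
    r_cs = pattern_correlation(rows$C, rows[[cols$S]]),
    d_t = sol$d_t
  )
}

#' Per-subject correlation/modulation scatter for a VOI
#'
#' Builds the group-level scatter relating the pattern correlation r(C, S) to
#' the mean measured modulation index: one point per subject, computed within
#' the subject's own VOI voxels. This is the input to [compare_models()].
#'
#' @inheritParams voi_modulation
#' @return A tibble of class `cd_scatter` with one row per subject:
#'   `subject`, `r`, `mean_d`, `se`, `condition` (VOI x surround label).
#' @export
modulation_scatter <- function(table, voi = "VOI_C",
                               surround = c("near", "far"),
                               theta = 0.2,
                               denom_epsilon = 1e-9,
                               geometry = study_geometry()) {
  surround <- match.arg(surround)
  pts <- table |>
    dplyr::group_split(.data$subject) |>
    purrr::map(function(sub) {
      res <- voi_modulation(sub, voi, surround, theta, denom_epsilon,
                            geometry = geometry)
      tibble::tibble(
        subject = sub$subject[1],
        r = res$r_cs,
        mean_d = res$mean_d_m,
        se = res$se_d_m,
        condition = paste(voi, surround, sep = "_")
      )
    }) |>
    dplyr::bind_rows()
  class(pts) <- c("cd_scatter", class(pts))
  pts
}
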