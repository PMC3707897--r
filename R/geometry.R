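#' Study geometry: eccentricity rings, stimulus extents and cortical magnification
#'
#' Bundles the spatial layout of a center/near-surround/far-surround experiment:
#' the borders of the eccentricity rings used for voxel selection, the angular
#' extents of the three stimulus annuli, the cortical areas analysed, and the
#' parameters of the Schwartz log cortical-magnification mapping.
#'
#' Defaults follow the standard annular layout: five rings with borders at
#' 1, 2.3, 4.0, 6.1, 8.7 and 12 degrees eccentricity; a center stimulus from
#' 1 to 2.3 deg, a near surround from 2.5 to 4.0 deg (leaving a small gap),
#' and a far surround from 8.7 to 12 deg; areas V1-V3; magnification
#' parameters a = 1 deg, k = 17 mm.
#'
#' @param ring_borders Strictly increasing numeric vector of 6 ring border
#'   eccentricities in degrees.
#' @param center_stim,near_surround_stim,far_surround_stim Length-2 numeric
#'   vectors, inner and outer eccentricity (degrees) of each stimulus annulus.
#' @param areas Character vector of functional area labels.
#' @param magnification_a Schwartz mapping parameter a (degrees), > 0.
#' @param magnification_k Schwartz mapping parameter k (mm), > 0.
#'
#' @return An object of class `cd_geometry` (a list with the above fields).
#' @examples
#' geom <- study_geometry()
#' cortical_position(2.3, geom)
#' @export
study_geometry <- function(ring_borders = c(1, 2.3, 4.0, 6.1, 8.7, 12),
                           center_stim = c(1.0, 2.3),
                           near_surround_stim = c(2.5, 4.0),
                           far_surround_stim = c(8.7, 12.0),
                           areas = c("V1", "V2", "V3"),
                           magnification_a = 1,
                           magnification_k = 17) {
  stopifnot(is.numeric(ring_borders), length(ring_borders) >= 3)
  if (any(diff(ring_borders) <= 0)) {
    stop("`ring_borders` must be strictly increasing", call. = FALSE)
  }
  check_extent <- function(x, name) {
    if (length(x) != 2 || x[1] >= x[2]) {
      stop("`", name, "` must be an increasing (inner, outer) pair", call. = FALSE)
    }
    rng <- range(ring_borders)
    if (x[1] < rng[1] || x[2] > rng[2]) {
      stop("`", name, "` must lie within the ring borders", call. = FALSE)
    }
  }
  check_extent(center_stim, "center_stim")
  check_extent(near_surround_stim, "near_surround_stim")
  check_extent(far_surround_stim, "far_surround_stim")
  if (center_stim[2] >= near_surround_stim[1]) {
    stop("center and near surround must be separated by a positive gap",
         call. = FALSE)
  }
  if (magnification_a <= 0 || magnification_k <= 0) {
    stop("magnification parameters a and k must be positive", call. = FALSE)
  }
  structure(
    list(
      ring_borders = as.numeric(ring_borders),
      center_stim = as.numeric(center_stim),
      near_surround_stim = as.numeric(near_surround_stim),
      far_surround_stim = as.numeric(far_surround_stim),
      areas = as.character(areas),
      magnification_a = as.numeric(magnification_a),
      magnification_k = as.numeric(magnification_k)
    ),
    class = "cd_geometry"
  )
}

#' @export
print.cd_geometry <- function(x, ...) {
  cat("<cd_geometry>\n")
  cat("  rings (deg):", paste(x$ring_borders, collapse = " | "), "\n")
  cat("  center:", paste(x$center_stim, collapse = "-"),
      " near surround:", paste(x$near_surround_stim, collapse = "-"),
      " far surround:", paste(x$far_surround_stim, collapse = "-"), "deg\n")
  cat("  areas:", paste(x$areas, collapse = ", "), "\n")
  cat("  magnification: a =", x$magnification_a, "deg, k =",
      x$magnification_k, "mm\n")
  invisible(x)
}

#' Cortical position of an eccentricity under the Schwartz log mapping
#'
#' Maps visual-field eccentricity E (degrees) to a 1-D cortical position in
#' millimetres, `k * log((E + a) / a)`. The mapping is strictly increasing, so
#' the cortical distance between two eccentricities is the difference of their
#' positions (see [cortical_distance()]).
#'
#' @param eccentricity_deg Numeric vector of eccentricities in degrees, >= 0
#'   (position 0 mm at the E -> 0 limit).
#' @param geometry A [study_geometry()] object supplying a and k.
#' @return Numeric vector of cortical positions in mm.
#' @examples
#' g <- study_geometry()
#' cortical_distance(2.3, 7.7, g) # 17 * log(8.7 / 3.3)
#' @export
cortical_position <- function(eccentricity_deg, geometry = study_geometry()) {
  stopifnot(inherits(geometry, "cd_geometry"))
  if (any(!is.finite(eccentricity_deg)) || any(eccentricity_deg < 0)) {
    stop("eccentricity must be finite and non-negative (degrees)", call. = FALSE)
  }
  geometry$magnification_k *
    log((eccentricity_deg + geometry$magnification_a) / geometry$magnification_a)
}

#' Inverse of the Schwartz mapping: eccentricity at a cortical position
#'
#' @param position_mm Numeric vector of cortical positions in mm, >= 0.
#' @inheritParams cortical_position
#' @return Eccentricities in degrees.
#' @export
cortical_eccentricity <- function(position_mm, geometry = study_geometry()) {
  stopifnot(inherits(geometry, "cd_geometry"))
  if (any(!is.finite(position_mm)) || any(position_mm < 0)) {
    stop("cortical position must be finite and non-negative (mm)", call. = FALSE)
  }
  geometry$magnification_a *
    (exp(position_mm / geometry$magnification_k) - 1)
}

#' Cortical distance between two eccentricities
#'
#' @param ecc1_deg,ecc2_deg Eccentricities in degrees.
#' @inheritParams cortical_position
#' @return Absolute cortical distance in mm.
#' @export
cortical_distance <- function(ecc1_deg, ecc2_deg, geometry = study_geometry()) {
  abs(cortical_position(ecc2_deg, geometry) - cortical_position(ecc1_deg, geometry))
}

#' Representative eccentricity of each ring
#'
#' The profile and zero-crossing machinery places each eccentricity ring at a
#' single representative abscissa. The default is the arithmetic midpoint of
#' the ring borders; a logarithmic midpoint (midpoint in cortical coordinates,
#' mapped back to degrees) is available as an option.
#'
#' @inheritParams cortical_position
#' @param convention `"midpoint"` (arithmetic, default) or `"log_midpoint"`.
#' @return Numeric vector, one representative eccentricity (degrees) per ring.
#' @export
ring_eccentricities <- function(geometry = study_geometry(),
                                convention = c("midpoint", "log_midpoint")) {
  convention <- match.arg(convention)
  b <- geometry$ring_borders
  lo <- b[-length(b)]
  hi <- b[-1]
  switch(convention,
    midpoint = (lo + hi) / 2,
    log_midpoint = cortical_eccentricity(
      (cortical_position(lo, geometry) + cortical_position(hi, geometry)) / 2,
      geometry
    )
  )
}
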