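voxel_table_columns <- c("subject", "hemisphere", "area", "ring",
                         "eccentricity_deg", "C", "S_N", "S_F",
                         "m_C_SN", "m_C_SF")

#' Read and validate a voxel table from delimited text
#'
#' The canonical interchange format is comma-separated text with a dot
#' decimal and the header `subject, hemisphere, area, ring, eccentricity_deg,
#' C, S_N, S_F, m_C_SN, m_C_SF`. Validation reports missing columns,
#' non-numeric condition cells (with line numbers) and duplicated
#' (subject, hemisphere, area, row) keys.
#'
#' @param path Path to a CSV voxel table.
#' @return A validated tibble.
#' @export
read_voxel_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(voxel_table_columns, names(tab))
  if (length(missing)) {
    stop("voxel table schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("subject", "ring", "eccentricity_deg",
                "C", "S_N", "S_F", "m_C_SN", "m_C_SF")
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(vals) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop("voxel table schema error in '", path, "': non-numeric '", col,
           "' at data line(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
    if (anyNA(vals)) {
      stop("voxel table schema error in '", path, "': missing '", col,
           "' value at data line(s) ",
           paste(utils::head(which(is.na(vals)), 5), collapse = ", "),
           call. = FALSE)
    }
    tab[[col]] <- vals
  }
  tab[voxel_table_columns]
}

#' Write a voxel table (and optional ground truth) to disk
#'
#' Writes the table as comma-separated text; when a `cd_study` is given, its
#' generation ground truth (interaction rule, per-subject d_true, generator
#' settings) is written alongside as a JSON sidecar `<path>.truth.json`.
#'
#' @param x A voxel table tibble or a `cd_study` from [generate_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxel_table <- function(x, path) {
  if (inherits(x, "cd_study")) {
    gt <- x$ground_truth
    truth <- list(
      interaction_rule = gt$interaction_rule,
      d_true = gt$d_true,
      config = gt$config[setdiff(names(gt$config), "target_correlation")],
      ring_borders = gt$geometry$ring_borders,
      areas = gt$geometry$areas
    )
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    x <- x$voxels
  }
  readr::write_csv(x[voxel_table_columns], path, progress = FALSE)
  invisible(path)
}

#' Build a voxel table from per-condition NIfTI percent-change maps
#'
#' Optional adapter for real data: reads one NIfTI volume of percent-BOLD
#' change per condition, extracts the voxels of a mask, and assembles the
#' canonical tabular schema. All volumes must share the mask's grid. Requires
#' the RNifti package.
#'
#' @param volumes Named character vector of NIfTI paths; names must be the
#'   five condition columns `C`, `S_N`, `S_F`, `m_C_SN`, `m_C_SF`.
#' @param mask Path to a NIfTI mask (non-zero voxels are extracted).
#' @param labels Optional data frame with one row per mask voxel (in
#'   column-major voxel order) providing `subject`, `hemisphere`, `area`,
#'   `ring`, `eccentricity_deg`; defaults fill subject 1, hemisphere "R",
#'   area "V1", ring 1, eccentricity NA.
#' @return A voxel table tibble.
#' @export
import_nifti_summary <- function(volumes, mask, labels = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("import_nifti_summary() requires the RNifti package", call. = FALSE)
  }
  need <- c("C", "S_N", "S_F", "m_C_SN", "m_C_SF")
  if (!all(need %in% names(volumes))) {
    stop("`volumes` must be named with all of: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  msk <- RNifti::readNifti(mask)
  keep <- which(as.array(msk) != 0)
  if (length(keep) == 0) stop("mask selects no voxels", call. = FALSE)
  vals <- lapply(need, function(cond) {
    vol <- RNifti::readNifti(volumes[[cond]])
    if (!identical(dim(vol), dim(msk))) {
      stop("grid mismatch between mask and '", cond, "' volume",
           call. = FALSE)
    }
    as.array(vol)[keep]
  })
  names(vals) <- need
  n <- length(keep)
  if (is.null(labels)) {
    labels <- tibble::tibble(
      subject = rep(1, n), hemisphere = "R", area = "V1",
      ring = rep(1, n), eccentricity_deg = NA_real_
    )
  }
  if (nrow(labels) != n) {
    stop("`labels` must have one row per mask voxel (", n, ")", call. = FALSE)
  }
  dplyr::bind_cols(tibble::as_tibble(labels), tibble::as_tibble(vals))
}
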