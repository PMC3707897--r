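#' Run the full analysis pipeline and write a report bundle
#'
#' Ties the stages together: obtain a voxel table (either read from
#' `input_table` or generated synthetically), compute per-VOI modulation
#' summaries, build the per-subject correlation/modulation scatters and the
#' four-model comparison for each requested condition, estimate the
#' eccentricity zero crossings and cortical spreads, tabulate the
#' response-sign contingency with the Mann-Whitney comparison, and write
#' everything as delimited text plus a JSON manifest carrying versions,
#' seeds and a configuration hash. Any stage error aborts with the stage
#' name; outputs written before the failure are preserved.
#'
#' @param out_dir Output directory (created if needed).
#' @param input_table Optional path to an existing voxel-table CSV; when
#'   `NULL` (default) a synthetic study is generated from `config`.
#' @param config A [generation_config()] used when generating.
#' @param geometry A [study_geometry()].
#' @param vois Character vector of VOI rules to summarise.
#' @param scatter_vois Named list mapping scatter conditions to
#'   `list(voi, surround)`; defaults to the four canonical panels
#'   (center VOI with near and far surround, each surround VOI with its own
#'   surround).
#' @param theta Suprathreshold magnitude for VOI selection.
#' @param n_boot Bootstrap resamples for crossing CIs.
#' @param seed Seed for generation, bootstrap and resampling.
#' @param overwrite Allow overwriting existing report files (default FALSE).
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(out_dir,
                         input_table = NULL,
                         config = generation_config(),
                         geometry = study_geometry(),
                         vois = c("VOI_C", "VOI_SN", "VOI_SF", "VOI_AVA"),
                         scatter_vois = NULL,
                         theta = 0.2,
                         n_boot = 200,
                         seed = 1L,
                         overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    table = file.path(out_dir, "voxel_table.csv"),
    modulation = file.path(out_dir, "modulation.csv"),
    scatter = file.path(out_dir, "scatter.csv"),
    comparison = file.path(out_dir, "model_comparison.csv"),
    spread = file.path(out_dir, "spread.csv"),
    signs = file.path(out_dir, "signs.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  existing <- unlist(paths)[file.exists(unlist(paths))]
  if (length(existing) && !overwrite) {
    stop("output files exist (use `overwrite = TRUE`): ",
         paste(basename(existing), collapse = ", "), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  valid <- voi_names(geometry)
  bad <- setdiff(vois, valid)
  if (length(bad)) {
    stop("pipeline stage 'configure' failed: unknown VOI ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  table <- stage("input", {
    if (is.null(input_table)) {
      config$seed <- as.integer(seed)
      study <- generate_study(config, geometry)
      write_voxel_table(study, paths$table)
      study$voxels
    } else {
      read_voxel_table(input_table)
    }
  })
  message("pipeline: ", nrow(table), " voxels, ",
          length(unique(table$subject)), " subjects, areas: ",
          paste(unique(table$area), collapse = ", "))

  modulation <- stage("modulation", {
    tidyr::expand_grid(voi = vois, surround = c("near", "far")) |>
      purrr::pmap(function(voi, surround) {
        voi_modulation(table, voi, surround, theta, geometry = geometry)
      }) |>
      dplyr::bind_rows()
  })
  readr::write_csv(modulation, paths$modulation, progress = FALSE)

  if (is.null(scatter_vois)) {
    scatter_vois <- list(
      VOI_C_near = list(voi = "VOI_C", surround = "near"),
      VOI_C_far = list(voi = "VOI_C", surround = "far"),
      VOI_SN_near = list(voi = "VOI_SN", surround = "near"),
      VOI_SF_far = list(voi = "VOI_SF", surround = "far")
    )
  }
  scatter <- stage("scatter", {
    purrr::imap(scatter_vois, function(sp, nm) {
      sc <- modulation_scatter(table, sp$voi, sp$surround, theta,
                               geometry = geometry)
      sc$condition <- nm
      sc
    }) |> dplyr::bind_rows()
  })
  readr::write_csv(scatter, paths$scatter, progress = FALSE)

  comparison <- stage("compare", {
    scatter |>
      dplyr::group_split(.data$condition) |>
      purrr::map(function(pts) {
        res <- tidy(compare_models(pts))
        res$condition <- pts$condition[1]
        res
      }) |>
      dplyr::bind_rows()
  })
  readr::write_csv(comparison, paths$comparison, progress = FALSE)

  spread <- stage("spread", {
    bold_spread_report(table, geometry, n_boot = n_boot, seed = seed)
  })
  readr::write_csv(spread, paths$spread, progress = FALSE)

  signs <- stage("signs", {
    cont <- purrr::map(c("near", "far"), function(sur) {
      sign_contingency(table, "VOI_AVA", sur, theta, geometry = geometry)
    }) |> dplyr::bind_rows()
    mw <- purrr::map(c("near", "far"), function(sur) {
      grp <- d_m_by_sign(table, "VOI_AVA", sur, theta, geometry = geometry)
      dplyr::bind_cols(
        tibble::tibble(surround = sur),
        mann_whitney_u(grp$same_sign, grp$different_sign)
      )
    }) |> dplyr::bind_rows()
    dplyr::left_join(cont, mw, by = "surround")
  })
  readr::write_csv(signs, paths$signs, progress = FALSE)

  manifest <- list(
    package = "cdbold",
    version = as.character(utils::packageVersion("cdbold")),
    seed = as.integer(seed),
    theta = theta,
    n_boot = n_boot,
    vois = vois,
    input = if (is.null(input_table)) "synthetic" else input_table,
    config_hash = rlang::hash(list(config = unclass(config),
                                   geometry = unclass(geometry),
                                   vois = vois, theta = theta,
                                   seed = as.integer(seed))),
    n_voxels = nrow(table),
    n_subjects = length(unique(table$subject))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    table = table, modulation = modulation, scatter = scatter,
    comparison = comparison, spread = spread, signs = signs,
    manifest = manifest, paths = paths
  ))
}
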