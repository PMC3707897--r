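#' Response-sign versus modulation-sign contingency of a VOI
#'
#' Classifies each VOI voxel by whether its center and surround responses
#' have the same or different signs, and by the sign of its measured
#' modulation index (suppressive `d_M > 0`, facilitative `d_M < 0`). Voxels
#' with an exactly zero C or S response, or with `d_M` zero or undefined, are
#' excluded from the 2x2 counts and reported separately; the classification
#' of the remaining voxels is exhaustive and exclusive.
#'
#' @inheritParams voi_modulation
#' @param summary `"pooled"` (default): counts pooled over all subjects in
#'   the table; `"subject_mean"`: the per-subject counts averaged across
#'   subjects (the two conventions for reporting "average number of voxels").
#' @return A one-row tibble: `n_suppression_same`, `n_suppression_diff`,
#'   `n_facilitation_same`, `n_facilitation_diff`, `n_excluded`, `n_total`,
#'   plus `voi`, `surround`, `summary`.
#' @export
sign_contingency <- function(table, voi = "VOI_AVA",
                             surround = c("near", "far"),
                             theta = 0.2, denom_epsilon = 1e-9,
                             summary = c("pooled", "subject_mean"),
                             geometry = study_geometry()) {
  surround <- match.arg(surround)
  summary <- match.arg(summary)
  rows <- select_voi(table, voi, theta, geometry)
  if (nrow(rows) == 0) stop("VOI '", voi, "' is empty", call. = FALSE)
  cols <- surround_columns(surround)

  count_one <- function(part) {
    dm <- measured_d(part$C, part[[cols$S]], part[[cols$m]], denom_epsilon)
    sC <- sign(part$C)
    sS <- sign(part[[cols$S]])
    excluded <- sC == 0 | sS == 0 | is.na(dm$d_m) | dm$d_m == 0
    same <- sC == sS
    supp <- dm$d_m > 0
    keep <- !excluded
    tibble::tibble(
      n_suppression_same = sum(keep & supp & same),
      n_suppression_diff = sum(keep & supp & !same),
      n_facilitation_same = sum(keep & !supp & same),
      n_facilitation_diff = sum(keep & !supp & !same),
      n_excluded = sum(excluded),
      n_total = nrow(part)
    )
  }

  counts <- if (summary == "pooled") {
    count_one(rows)
  } else {
    rows |>
      dplyr::group_split(.data$subject) |>
      purrr::map(count_one) |>
      dplyr::bind_rows() |>
      dplyr::summarise(dplyr::across(dplyr::everything(), mean))
  }
  dplyr::bind_cols(
    tibble::tibble(voi = voi, surround = surround, summary = summary),
    counts
  )
}

#' Modulation index split by response-sign agreement
#'
#' Returns the per-voxel d_M values of a VOI in two groups — voxels whose C
#' and S responses share a sign and voxels whose signs differ — ready for a
#' Mann-Whitney comparison of the two distributions.
#'
#' @inheritParams sign_contingency
#' @return A list with numeric vectors `same_sign` and `different_sign`.
#' @export
d_m_by_sign <- function(table, voi = "VOI_AVA",
                        surround = c("near", "far"),
                        theta = 0.2, denom_epsilon = 1e-9,
                        geometry = study_geometry()) {
  surround <- match.arg(surround)
  rows <- select_voi(table, voi, theta, geometry)
  cols <- surround_columns(surround)
  dm <- measured_d(rows$C, rows[[cols$S]], rows[[cols$m]], denom_epsilon)
  sC <- sign(rows$C)
  sS <- sign(rows[[cols$S]])
  ok <- sC != 0 & sS != 0 & !is.na(dm$d_m)
  list(
    same_sign = dm$d_m[ok & sC == sS],
    different_sign = dm$d_m[ok & sC != sS]
  )
}

#' Exact two-sided sign test against a zero median
#'
#' Exact binomial sign test of the null hypothesis that the values come from
#' a continuous distribution with the hypothesised median. Exact zeros (ties
#' with the hypothesised median) are dropped before testing.
#'
#' @param values Numeric vector.
#' @param hypothesized_median Null median (default 0).
#' @return A one-row tibble: `n_positive`, `n`, `p_value`.
#' @examples
#' sign_test(rep(1, 8))$p_value # 2 * (1/2)^8
#' @export
sign_test <- function(values, hypothesized_median = 0) {
  x <- values[values != hypothesized_median]
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    stop("sign test undefined: no values differ from the hypothesised median",
         call. = FALSE)
  }
  npos <- sum(x > hypothesized_median)
  bt <- stats::binom.test(npos, length(x), p = 0.5,
                          alternative = "two.sided")
  tibble::tibble(n_positive = npos, n = length(x), p_value = bt$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples under the null that both
#' come from identical continuous distributions with equal medians. The exact
#' distribution is used for small samples without ties (`n * m <= 400`);
#' otherwise the normal approximation with tie correction applies.
#'
#' @param x,y Non-empty numeric samples.
#' @return A one-row tibble: `u` (the U statistic for `x`), `p_value`,
#'   `n_x`, `n_y`, `exact` (whether the exact distribution was used).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    n_x = length(x), n_y = length(y),
    exact = exact
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided test based on the supremum distance between the two empirical
#' distribution functions, with the asymptotic p-value.
#'
#' @param x,y Numeric samples of length >= 2.
#' @return A one-row tibble: `d` (the KS statistic), `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples must have length >= 2", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble::tibble(
    d = unname(kt$statistic),
    p_value = kt$p.value,
    n_x = length(x), n_y = length(y)
  )
}

#' Friedman rank test for complete blocked data
#'
#' Rank-based test for differences between conditions measured repeatedly on
#' the same subjects (blocks), with average ranks for ties and the chi-squared
#' approximation. Accepts either a subjects-by-conditions matrix or a long
#' data frame with `block`, `treatment` and `value` columns; blocks must be
#' complete.
#'
#' @param data Matrix (rows = blocks/subjects, columns = conditions) or long
#'   data frame with columns `block`, `treatment`, `value`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
friedman_blocks <- function(data) {
  if (is.data.frame(data) && all(c("block", "treatment", "value") %in%
                                 names(data))) {
    wide <- tidyr::pivot_wider(data, id_cols = "block",
                               names_from = "treatment",
                               values_from = "value")
    data <- as.matrix(wide[, -1, drop = FALSE])
  }
  data <- as.matrix(data)
  if (nrow(data) < 2 || ncol(data) < 2) {
    stop("need at least 2 blocks and 2 conditions", call. = FALSE)
  }
  if (any(is.na(data))) {
    stop("incomplete blocks: every block must have every condition",
         call. = FALSE)
  }
  ft <- stats::friedman.test(data)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {
    # complete within-block ties (e.g. identical columns): no evidence of
    # any condition difference, so the rank statistic is 0
    stat <- 0
    p <- 1
  }
  tibble::tibble(
    statistic = stat,
    df = unname(ft$parameter),
    p_value = p
  )
}

#' Chance level of an n-alternative forced choice
#'
#' Guessing probability, in percent, for a report among `n` equiprobable
#' alternatives (e.g. 25% for counting 1-4 target letters).
#'
#' @param n_alternatives Integer >= 2.
#' @return Probability in percent.
#' @examples
#' chance_level(4) # 25
#' @export
chance_level <- function(n_alternatives) {
  if (!is.numeric(n_alternatives) || n_alternatives < 2) {
    stop("`n_alternatives` must be at least 2", call. = FALSE)
  }
  100 / n_alternatives
}
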