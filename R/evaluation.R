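#' Pair chronological and dental ages
#'
#' Joins a cohort's chronological ages (CA) with one set of dental-age
#' estimates (DA) by subject id, producing the per-subject table the
#' evaluation metrics operate on.
#'
#' @param cohort a cohort tibble.
#' @param estimates an estimate tibble (from [estimate_age_sum()],
#'   [predict_ages()], ...), with columns `id`, `dental_age` and
#'   optionally `method`.
#' @return a tibble with columns `id`, `sex`, `age` (CA),
#'   `dental_age` (DA), `method`.
#' @export
paired_ages <- function(cohort, estimates) {
  cohort <- tibble::as_tibble(cohort)
  estimates <- tibble::as_tibble(estimates)
  if (!all(c("id", "dental_age") %in% names(estimates))) {
    abort("`estimates` needs columns id and dental_age")
  }
  out <- dplyr::inner_join(
    dplyr::select(cohort, "id", "sex", "age"),
    dplyr::select(estimates, "id", "dental_age",
                  dplyr::any_of("method")),
    by = "id"
  )
  if (!"method" %in% names(out)) out$method <- "unknown"
  if (nrow(out) == 0) abort("no overlapping subject ids")
  out
}

#' Age deviation (DA - CA)
#'
#' The signed estimation error per subject: positive values are
#' overestimates, negative values underestimates.
#'
#' @param pairs a paired-ages tibble (see [paired_ages()]).
#' @return a list with `per_subject` (the input plus an `ad` column)
#'   and `summary` (one-row tibble: `mean_ad`, `sd_ad`, `n`).
#' @export
age_deviation <- function(pairs) {
  if (nrow(pairs) == 0) abort("empty paired ages")
  per <- dplyr::mutate(tibble::as_tibble(pairs),
                       ad = .data$dental_age - .data$age)
  list(
    per_subject = per,
    summary = tibble::tibble(
      mean_ad = mean(per$ad),
      sd_ad = if (nrow(per) > 1) sd(per$ad) else NA_real_,
      n = nrow(per)
    )
  )
}

#' Mean absolute error, optionally capped by chronological age
#'
#' `mae(pairs, cap)` averages |DA - CA| over subjects with CA strictly
#' below `cap` (in years); `cap = NULL` retains everyone. Published
#' comparisons report both MAE(<18) and MAE(<16).
#'
#' @param pairs a paired-ages tibble.
#' @param age_cap upper CA cap in years, or `NULL` for no cap.
#' @return the MAE in years.
#' @examples
#' p <- tibble::tibble(id = c("a", "b"), sex = "female",
#'                     age = c(10, 10), dental_age = c(11, 9))
#' mae(p) # 1, while the mean signed deviation is 0
#' @export
mae <- function(pairs, age_cap = NULL) {
  keep <- if (is.null(age_cap)) rep(TRUE, nrow(pairs)) else pairs$age < age_cap
  if (!any(keep)) abort("no subjects below the age cap")
  mean(abs(pairs$dental_age[keep] - pairs$age[keep]))
}

#' Regression error metrics
#'
#' MSE, RMSE, MAE and the coefficient of determination of the
#' predictions against the true ages:
#' `R2 = 1 - sum((DA - CA)^2) / sum((CA - mean(CA))^2)`.
#'
#' @param pairs a paired-ages tibble with at least two subjects.
#' @return a one-row tibble with columns `mse`, `rmse`, `mae`, `r2`, `n`.
#' @export
regression_metrics <- function(pairs) {
  if (nrow(pairs) < 2) abort("need at least two subjects")
  ad <- pairs$dental_age - pairs$age
  ss_tot <- sum((pairs$age - mean(pairs$age))^2)
  if (ss_tot == 0) abort("zero variance in chronological age; R2 undefined")
  mse <- mean(ad^2)
  tibble::tibble(
    mse = mse, rmse = sqrt(mse), mae = mean(abs(ad)),
    r2 = 1 - sum(ad^2) / ss_tot, n = nrow(pairs)
  )
}

#' Paired t-test of dental vs chronological age
#'
#' Tests whether the mean age deviation differs from zero:
#' `t = mean(AD) / (sd(AD) / sqrt(n))` on `n - 1` degrees of freedom,
#' two-sided.
#'
#' @param pairs a paired-ages tibble with at least two subjects.
#' @return a one-row tibble with `t`, `df`, `p` and the significance
#'   tier `signif` (`"***"` p < 0.001, `"**"` < 0.01, `"*"` < 0.05,
#'   `""` otherwise).
#' @export
paired_t_test <- function(pairs) {
  ad <- pairs$dental_age - pairs$age
  n <- length(ad)
  if (n < 2) abort("need at least two subjects")
  s <- sd(ad)
  if (s == 0) abort("degenerate test: zero variance in age deviation")
  t <- mean(ad) / (s / sqrt(n))
  p <- 2 * pt(abs(t), df = n - 1, lower.tail = FALSE)
  tibble::tibble(
    t = t, df = n - 1, p = p,
    signif = dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                              p < 0.05 ~ "*", TRUE ~ "")
  )
}

#' Cohen's kappa for two rating sequences
#'
#' Chance-corrected agreement between two raters' stage assignments:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` and
#' chance agreement `pe` from the raters' marginal distributions.
#' The optional linear-weighted variant credits near-misses between
#' ordinal categories.
#'
#' @param ratings_a,ratings_b equal-length vectors of categories
#'   (e.g. stage letters).
#' @param weighted use linearly weighted kappa (categories compared by
#'   their position in `levels`).
#' @param levels category levels; defaults to the union of observed
#'   values, sorted (use [stage_levels()] for stages).
#' @return the kappa coefficient.
#' @examples
#' cohens_kappa(c("A", "B", "B"), c("A", "B", "B")) # 1
#' @export
cohens_kappa <- function(ratings_a, ratings_b, weighted = FALSE,
                         levels = NULL) {
  if (length(ratings_a) != length(ratings_b)) {
    abort("rating sequences must have equal length")
  }
  if (length(ratings_a) == 0) abort("empty rating sequences")
  levels <- levels %||% sort(unique(c(ratings_a, ratings_b)))
  a <- factor(ratings_a, levels = levels)
  b <- factor(ratings_b, levels = levels)
  if (anyNA(a) || anyNA(b)) abort("ratings outside the given levels")
  tab <- table(a, b) / length(a)
  k <- length(levels)
  w <- if (weighted) {
    1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  } else {
    diag(k)
  }
  po <- sum(w * tab)
  pe <- sum(w * outer(rowSums(tab), colSums(tab)))
  if (abs(1 - pe) < 1e-12) abort("degenerate kappa: chance agreement is 1")
  (po - pe) / (1 - pe)
}

#' Per-age-group mean absolute error
#'
#' MAE within each one-year age bin (see [age_bins()]); bins with no
#' subjects are omitted rather than reported as zero.
#'
#' @param pairs a paired-ages tibble.
#' @return a tibble with columns `age_bin`, `mae`, `n` (one row per
#'   populated bin, in bin order).
#' @export
per_group_mae <- function(pairs) {
  binned <- bin_by_age(pairs)
  binned |>
    dplyr::mutate(abs_ad = abs(.data$dental_age - .data$age)) |>
    dplyr::group_by(.data$age_bin) |>
    dplyr::summarise(mae = mean(.data$abs_ad), n = dplyr::n(),
                     .groups = "drop")
}

#' Model-fit report across methods and sexes
#'
#' Summarizes one or more sets of paired ages the way comparative
#' dental-age studies tabulate them: per method and sex, mean (sd) of
#' CA, DA and AD, the paired-t p value with significance tier, and MAE
#' under the 18- and 16-year caps.
#'
#' @param pairs_tbl a paired-ages tibble (multiple methods may be
#'   stacked; rows are grouped by `method` and `sex`).
#' @return a tibble with one row per (method, sex).
#' @export
fit_report <- function(pairs_tbl) {
  pairs_tbl <- tibble::as_tibble(pairs_tbl)
  pairs_tbl |>
    dplyr::group_by(.data$method, .data$sex) |>
    dplyr::group_modify(function(g, key) {
      tt <- paired_t_test(g)
      tibble::tibble(
        n = nrow(g),
        ca_mean = mean(g$age), ca_sd = sd(g$age),
        da_mean = mean(g$dental_age), da_sd = sd(g$dental_age),
        ad_mean = mean(g$dental_age - g$age),
        ad_sd = sd(g$dental_age - g$age),
        p = tt$p, signif = tt$signif,
        mae_under_18 = mae(g, 18), mae_under_16 = mae(g, 16)
      )
    }) |>
    dplyr::ungroup()
}

#' Learner-performance report across splits
#'
#' Tabulates MSE, RMSE, MAE and R-squared per learner, sex and dataset
#' split, the layout used to compare machine-learning age models on
#' training and testing sets.
#'
#' @param pairs_tbl a paired-ages tibble with additional column
#'   `split` (`"training"`/`"testing"`); `method` labels the learner.
#' @return a tibble with one row per (method, sex, split).
#' @export
learner_report <- function(pairs_tbl) {
  pairs_tbl <- tibble::as_tibble(pairs_tbl)
  if (!"split" %in% names(pairs_tbl)) abort("`pairs_tbl` needs a split column")
  pairs_tbl |>
    dplyr::group_by(.data$method, .data$sex, .data$split) |>
    dplyr::group_modify(function(g, key) regression_metrics(g)) |>
    dplyr::ungroup()
}
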