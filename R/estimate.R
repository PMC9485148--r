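#' Estimate dental age by direct score summation
#'
#' For an `age_sum` (Willems-type) table, a subject's dental age DA is
#' the sum of the seven per-tooth scores of the attained stages. Each
#' subject's sex must match the table's sex; use
#' [estimate_with_tables()] to apply a sex-specific pair of tables to a
#' mixed cohort.
#'
#' @param cohort a cohort tibble (see [read_staging_csv()]) whose
#'   records all have `sex == table$sex`.
#' @param table an `age_sum` [score_table()].
#' @param on_missing policy for missing (unscorable) teeth:
#'   `"error"` (default; the summation presumes seven scores) or
#'   `"skip"` (sum the scorable teeth only and flag the estimate as
#'   `partial`).
#' @return a tibble with columns `id`, `sex`, `age` (CA),
#'   `dental_age` (DA), `method` and `partial`.
#' @examples
#' tabs <- modified_score_tables()
#' coh <- tibble::tibble(
#'   id = "S1", sex = "male", age = 10.7,
#'   t31 = "H", t32 = "H", t33 = "G", t34 = "F", t35 = "E",
#'   t36 = "H", t37 = "E"
#' )
#' estimate_age_sum(coh, tabs$male)
#' @export
estimate_age_sum <- function(cohort, table,
                             on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(table, "score_table"))
  if (table$kind != "age_sum") {
    abort("`table` must be an age_sum table; use estimate_age_maturity() for maturity tables")
  }
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) {
    return(tibble::tibble(
      id = character(), sex = character(), age = numeric(),
      dental_age = numeric(), method = character(), partial = logical()
    ))
  }
  if (any(cohort$sex != table$sex)) {
    abort(paste0("cohort contains records whose sex does not match the '",
                 table$sex, "' table"))
  }

  stage_mat <- as.matrix(cohort[tooth_columns()])
  n <- nrow(stage_mat)
  scores <- matrix(NA_real_, n, 7)
  for (j in seq_len(7)) {
    stage <- stage_mat[, j]
    scorable <- !is.na(stage)
    cell <- rep(NA_real_, n)
    cell[scorable] <- table$scores[tooth_ids()[j], stage[scorable]]
    absent <- scorable & is.na(cell)
    if (any(absent)) {
      i <- which(absent)[1]
      abort(paste0(
        "absent cell: tooth ", tooth_ids()[j], ", stage ", stage[i],
        " has no score in table '", table$name, "' (subject ",
        cohort$id[i], ")"
      ))
    }
    scores[, j] <- cell
  }

  any_missing <- rowSums(is.na(stage_mat)) > 0
  if (on_missing == "error" && any(any_missing)) {
    abort(paste0(
      "missing stage(s) for subject(s): ",
      paste(head(cohort$id[any_missing], 5), collapse = ", "),
      "; use on_missing = \"skip\" to sum scorable teeth only"
    ))
  }

  tibble::tibble(
    id = cohort$id, sex = cohort$sex, age = cohort$age,
    dental_age = rowSums(scores, na.rm = TRUE),
    method = table$name,
    partial = any_missing
  )
}

#' Estimate dental age via maturity-score conversion
#'
#' For a `maturity` (Demirjian-type) table, the summed per-tooth scores
#' give a maturity score M, which is converted to a dental age by
#' piecewise-linear interpolation of a sex-specific conversion curve.
#' Maturity scores outside the curve's knot range are clamped to the
#' endpoint ages and the estimate flagged (`clamped`).
#'
#' @inheritParams estimate_age_sum
#' @param table a `maturity` [score_table()].
#' @param conv a [maturity_conversion()] with `conv$sex == table$sex`.
#' @return a tibble with columns `id`, `sex`, `age`, `maturity_score`,
#'   `dental_age`, `method`, `partial`, `clamped`.
#' @export
estimate_age_maturity <- function(cohort, table, conv,
                                  on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(table, "score_table"), inherits(conv, "maturity_conversion"))
  if (table$kind != "maturity") abort("`table` must be a maturity table")
  if (conv$sex != table$sex) abort("conversion sex does not match table sex")
  if (nrow(conv$knots) == 0) abort("empty maturity conversion")

  sums <- estimate_age_sum(
    cohort,
    score_table(table$sex, table$scores, kind = "age_sum", name = table$name),
    on_missing = on_missing
  )
  m <- sums$dental_age
  kx <- conv$knots[, 1]
  ky <- conv$knots[, 2]
  da <- if (length(kx) == 1) rep(ky, length(m)) else {
    approx(kx, ky, xout = pmin(pmax(m, min(kx)), max(kx)), ties = "ordered")$y
  }
  tibble::tibble(
    id = sums$id, sex = sums$sex, age = sums$age,
    maturity_score = m,
    dental_age = da,
    method = table$name,
    partial = sums$partial,
    clamped = m < min(kx) | m > max(kx)
  )
}

#' Apply sex-specific score tables across a mixed cohort
#'
#' Splits the cohort by sex, applies the matching table, and returns
#' the combined estimates in the cohort's row order.
#'
#' @inheritParams estimate_age_sum
#' @param tables a named list with `score_table` elements `female` and
#'   `male`, e.g. [modified_score_tables()].
#' @param method optional method label overriding the tables' names.
#' @return as [estimate_age_sum()].
#' @export
estimate_with_tables <- function(cohort, tables, method = NULL,
                                 on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  if (!all(sex_levels() %in% names(tables))) {
    abort("`tables` must have elements 'female' and 'male'")
  }
  cohort <- tibble::as_tibble(cohort)
  out <- purrr::map(sex_levels(), function(s) {
    sub <- cohort[cohort$sex == s, , drop = FALSE]
    estimate_age_sum(sub, tables[[s]], on_missing = on_missing)
  })
  est <- dplyr::bind_rows(out)
  est <- est[match(cohort$id, est$id), , drop = FALSE]
  if (!is.null(method)) est$method <- method
  est
}
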