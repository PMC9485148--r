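#' Read and write staged-tooth cohort tables
#'
#' A cohort is a tibble with one row per subject and columns `id`
#' (unique identifier), `sex` (`"female"`/`"male"`), `age`
#' (chronological age in decimal years, CA) and `t31`...`t37`
#' (Demirjian stage letters A-H; `NA` = tooth unscorable or absent).
#' The on-disk format is a UTF-8 CSV with header
#' `id,sex,age,t31,...,t37` and empty cells for missing stages.
#'
#' Validation enforces the study's inclusion rules: 2.00 <= CA < 18.00,
#' unique ids, valid stage letters, and at most three missing teeth per
#' subject (subjects with more are excluded upstream as "multiple
#' mandibular teeth missing").
#'
#' @param path file path of the staging CSV.
#' @param strict if `TRUE` (default) any invariant violation is an
#'   error; if `FALSE`, offending rows are dropped with a warning
#'   naming them.
#' @return `read_staging_csv()` returns a validated cohort tibble with
#'   row order preserved.
#' @seealso [validate_cohort()], [bin_by_age()], [split_train_test()]
#' @export
read_staging_csv <- function(path, strict = TRUE) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      sex = readr::col_character(),
      age = readr::col_double(),
      .default = readr::col_character()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
  need <- c("id", "sex", "age", tooth_columns())
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("staging CSV is missing column(s): ", paste(miss, collapse = ", ")))
  }
  validate_cohort(raw[need], strict = strict)
}

#' @rdname read_staging_csv
#' @param cohort a cohort tibble.
#' @export
write_staging_csv <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a staged-tooth cohort
#'
#' Checks the cohort invariants described in [read_staging_csv()]:
#' required columns, chronological age in \[2, 18), stage letters in
#' A-H, at most three missing teeth per subject, unique subject ids.
#'
#' @inheritParams read_staging_csv
#' @param cohort a data frame with columns `id`, `sex`, `age`,
#'   `t31`...`t37`.
#' @return the validated cohort as a tibble (rows dropped and a warning
#'   issued in lenient mode).
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  cohort <- tibble::as_tibble(cohort)
  need <- c("id", "sex", "age", tooth_columns())
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("cohort is missing column(s): ", paste(miss, collapse = ", ")))
  }
  cohort <- cohort[need]
  cohort$id <- as.character(cohort$id)

  stage_mat <- as.matrix(cohort[tooth_columns()])
  bad_letter <- !is.na(stage_mat) & !(stage_mat %in% stage_levels())
  if (any(bad_letter)) {
    rows <- which(apply(bad_letter, 1, any))
    abort(paste0(
      "malformed stage letter(s) in row(s): ",
      paste(head(rows, 10), collapse = ", ")
    ))
  }

  problems <- character(nrow(cohort))
  ok_sex <- cohort$sex %in% sex_levels()
  problems[!ok_sex] <- "sex must be 'female' or 'male'"
  ok_age <- !is.na(cohort$age) & cohort$age >= 2 & cohort$age < 18
  problems[ok_sex & !ok_age] <- "chronological age outside [2.00, 18.00)"
  n_missing <- rowSums(is.na(stage_mat))
  ok_missing <- n_missing <= 3
  problems[ok_sex & ok_age & !ok_missing] <- "more than three missing teeth"

  bad <- problems != ""
  if (any(bad)) {
    msg <- paste0(
      "invalid record(s): ",
      paste(sprintf("row %d (id %s): %s", which(bad), cohort$id[bad],
                    problems[bad])[seq_len(min(5, sum(bad)))],
            collapse = "; "),
      if (sum(bad) > 5) sprintf(" ... and %d more", sum(bad) - 5) else ""
    )
    if (strict) abort(msg)
    warn(paste0("dropping ", sum(bad), " record(s); ", msg))
    cohort <- cohort[!bad, , drop = FALSE]
  }

  if (anyDuplicated(cohort$id)) {
    dups <- unique(cohort$id[duplicated(cohort$id)])
    msg <- paste0("duplicated subject id(s): ", paste(head(dups, 5), collapse = ", "))
    if (strict) abort(msg)
    warn(paste0("dropping duplicated ids; ", msg))
    cohort <- cohort[!duplicated(cohort$id), , drop = FALSE]
  }
  cohort
}

#' One-year age bins over the study range
#'
#' Standard bins are half-open one-year intervals \[x, x + 1) covering
#' \[2, 18), labelled the way sample-distribution tables print them
#' ("2.00-2.99", ..., "17.00-17.99"). A subject with CA = 2.00 falls in
#' the first bin; CA = 2.99 also falls in the first bin.
#'
#' @return `age_bins()` returns a tibble with columns `label`, `lower`
#'   (inclusive) and `upper` (exclusive).
#' @examples
#' age_bins()
#' @export
age_bins <- function() {
  lower <- 2:17
  tibble::tibble(
    label = sprintf("%.2f-%.2f", lower, lower + 0.99),
    lower = as.numeric(lower),
    upper = as.numeric(lower + 1)
  )
}

#' @rdname age_bins
#' @param cohort a cohort tibble.
#' @return `bin_by_age()` returns the cohort with an `age_bin` factor
#'   column (levels in bin order).
#' @export
bin_by_age <- function(cohort) {
  bins <- age_bins()
  idx <- findInterval(cohort$age, c(bins$lower, 18))
  if (any(idx < 1 | idx > nrow(bins))) {
    abort("chronological age outside the binning range [2, 18)")
  }
  dplyr::mutate(
    tibble::as_tibble(cohort),
    age_bin = factor(bins$label[idx], levels = bins$label)
  )
}

#' Sample-distribution summary by age group and sex
#'
#' Counts subjects per one-year age bin and sex, in the layout of a
#' study's sample-distribution table (rows: age groups plus a total;
#' columns: female, male, both).
#'
#' @param cohort a cohort tibble.
#' @return a tibble with columns `age_group`, `female`, `male`, `both`.
#' @export
age_bin_summary <- function(cohort) {
  binned <- bin_by_age(cohort)
  counts <- binned |>
    dplyr::count(.data$age_bin, .data$sex, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n", values_fill = 0L)
  for (s in sex_levels()) {
    if (!s %in% names(counts)) counts[[s]] <- 0L
  }
  counts <- counts |>
    dplyr::transmute(
      age_group = as.character(.data$age_bin),
      female = .data$female, male = .data$male,
      both = .data$female + .data$male
    )
  dplyr::bind_rows(
    counts,
    tibble::tibble(
      age_group = "Total",
      female = sum(counts$female), male = sum(counts$male),
      both = sum(counts$both)
    )
  )
}

#' Seeded train/test split
#'
#' Randomly partitions a cohort into a training and a test set.
#' The training size is `round(n * ratio)` (half-up); the split is a
#' disjoint partition whose union is the input, and is deterministic
#' given the seed.
#'
#' @param cohort a nonempty cohort tibble.
#' @param ratio training fraction in (0, 1); the default 0.75 is the
#'   conventional 3:1 train:test split.
#' @param seed integer seed controlling the randomization.
#' @return a list with tibbles `train` and `test`.
#' @examples
#' coh <- generate_cohort(cohort_spec(counts = tibble::tibble(
#'   age_group = "9.00-9.99", female = 6, male = 6)), seed = 1)$cohort
#' sp <- split_train_test(coh, ratio = 0.75, seed = 42)
#' nrow(sp$train); nrow(sp$test)
#' @export
split_train_test <- function(cohort, ratio = 0.75, seed = 1L) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1) {
    abort("`ratio` must be a single number strictly between 0 and 1")
  }
  n <- nrow(cohort)
  if (n == 0) abort("cohort is empty")
  n_train <- floor(n * ratio + 0.5)
  idx <- with_seed_(seed, sample.int(n, n_train))
  list(
    train = cohort[sort(idx), , drop = FALSE],
    test = cohort[setdiff(seq_len(n), idx), , drop = FALSE]
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
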