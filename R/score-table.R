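#' Score tables for staged-tooth age estimation
#'
#' A score table maps each (tooth, stage) cell to a numeric score.
#' Two kinds exist:
#' \describe{
#'   \item{`age_sum`}{Willems-type: scores are in years and the sum of
#'     the seven per-tooth scores directly gives the dental age.}
#'   \item{`maturity`}{Demirjian-type: scores are maturity points; the
#'     summed maturity score is converted to an age through a
#'     sex-specific conversion curve (see [maturity_conversion()]).}
#' }
#' Cells printed as dashes in published tables (stages never observed
#' in the source population, typically early stages completed before
#' the cohort's entry age) are *absent* and stored as `NA`; looking one
#' up is an error.
#'
#' @param sex `"female"` or `"male"`: the population the table applies to.
#' @param scores a 7 x 8 numeric matrix, rows named by [tooth_ids()]
#'   and columns by [stage_levels()]; `NA` marks an absent cell.
#' @param kind `"age_sum"` or `"maturity"`.
#' @param name provenance string.
#' @return an object of class `score_table`.
#' @seealso [modified_score_tables()], [lookup_score()],
#'   [estimate_age_sum()], [read_score_table()]
#' @export
score_table <- function(sex, scores, kind = c("age_sum", "maturity"),
                        name = "unnamed") {
  kind <- match.arg(kind)
  sex <- match.arg(sex, sex_levels())
  scores <- as.matrix(scores)
  if (!identical(dim(scores), c(7L, 8L))) {
    abort("`scores` must be a 7 x 8 matrix (teeth x stages)")
  }
  if (is.null(rownames(scores))) rownames(scores) <- tooth_ids()
  if (is.null(colnames(scores))) colnames(scores) <- stage_levels()
  if (!identical(rownames(scores), tooth_ids()) ||
      !identical(colnames(scores), stage_levels())) {
    abort("`scores` must have rows 31..37 and columns A..H, in order")
  }
  if (any(is.nan(scores))) abort("score table contains NaN")
  storage.mode(scores) <- "double"
  structure(
    list(name = name, sex = sex, kind = kind, scores = scores),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %s (%s, kind = %s)\n", x$name, x$sex, x$kind))
  print(round(x$scores, 3))
  invisible(x)
}

#' @export
format.score_table <- function(x, ...) {
  sprintf("<score_table: %s, %s, %s>", x$name, x$sex, x$kind)
}

#' Tidy a score table into a long tibble
#'
#' @param x a [score_table()].
#' @param ... unused.
#' @return a tibble with columns `tooth`, `stage`, `score` (absent
#'   cells have `NA` score).
#' @method tidy score_table
#' @export
tidy.score_table <- function(x, ...) {
  tibble::tibble(
    tooth = rep(tooth_ids(), times = 8L),
    stage = rep(stage_levels(), each = 7L),
    score = as.vector(x$scores)
  )
}

#' Look up one (tooth, stage) score
#'
#' @param table a [score_table()].
#' @param tooth one of [tooth_ids()].
#' @param stage one of [stage_levels()]; a missing stage (`NA`) is not
#'   lookupable and raises an error.
#' @return the numeric score of the cell.
#' @examples
#' male <- modified_score_tables()$male
#' lookup_score(male, "34", "D") # 1.44
#' @export
lookup_score <- function(table, tooth, stage) {
  stopifnot(inherits(table, "score_table"))
  if (length(tooth) != 1 || length(stage) != 1) {
    abort("`tooth` and `stage` must be scalars")
  }
  if (is.na(stage)) abort("cannot look up a missing stage")
  if (!tooth %in% tooth_ids()) abort(paste0("unknown tooth: ", tooth))
  if (!stage %in% stage_levels()) abort(paste0("unknown stage: ", stage))
  val <- table$scores[tooth, stage]
  if (is.na(val)) {
    abort(paste0("absent cell: tooth ", tooth, ", stage ", stage,
                 " has no score in table '", table$name, "'"))
  }
  unname(val)
}

#' Score-table JSON serialization
#'
#' Tables are stored as JSON objects
#' `{name, sex, kind, scores: {"31": {"A": number|null, ...}, ...}}`,
#' with absent cells serialized as `null`. The round trip is lossless.
#'
#' @param path file path of the JSON table.
#' @return `read_score_table()` returns a [score_table()].
#' @export
read_score_table <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("name", "sex", "kind", "scores")) {
    if (is.null(obj[[f]])) abort(paste0("score-table JSON missing field: ", f))
  }
  miss <- setdiff(tooth_ids(), names(obj$scores))
  if (length(miss) > 0) {
    abort(paste0("score-table JSON missing tooth row(s): ",
                 paste(miss, collapse = ", ")))
  }
  m <- matrix(NA_real_, 7, 8, dimnames = list(tooth_ids(), stage_levels()))
  for (t in tooth_ids()) {
    row <- obj$scores[[t]]
    miss_s <- setdiff(stage_levels(), names(row))
    if (length(miss_s) > 0) {
      abort(paste0("tooth ", t, " is missing stage cell(s): ",
                   paste(miss_s, collapse = ", ")))
    }
    for (s in stage_levels()) {
      v <- row[[s]]
      if (!is.null(v)) {
        if (!is.numeric(v) || length(v) != 1 || is.nan(v) || !is.finite(v)) {
          abort(paste0("non-finite score at tooth ", t, ", stage ", s))
        }
        m[t, s] <- v
      }
    }
  }
  score_table(sex = obj$sex, scores = m, kind = obj$kind, name = obj$name)
}

#' @rdname read_score_table
#' @param table a [score_table()].
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  scores <- purrr::map(
    setNames(tooth_ids(), tooth_ids()),
    function(t) {
      purrr::map(setNames(stage_levels(), stage_levels()), function(s) {
        v <- table$scores[t, s]
        if (is.na(v)) NULL else v
      })
    }
  )
  jsonlite::write_json(
    list(name = table$name, sex = table$sex, kind = table$kind, scores = scores),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

# Printed cells of the reweighted southern-China age-sum tables.
# Dashes (stages not observed in the 2-18 y source population) are NA;
# dashed cells are left-anchored to the early stages, values fill the
# trailing stages.
modified_male_scores_ <- function() {
  m <- rbind(
    "31" = c(NA, NA, 0.90, 0.80, 0.80, 1.00, 1.11, 1.17),
    "32" = c(NA, NA, 0.43, 0.49, 0.57, 0.84, 1.02, 1.27),
    "33" = c(NA, NA, NA, 0.03, 0.24, 0.37, 0.85, 1.48),
    "34" = c(0.19, 0.72, 0.97, 1.44, 1.91, 2.62, 3.14, 3.66),
    "35" = c(0.05, 0.03, 0.07, 0.16, 0.20, 0.27, 0.24, 0.70),
    "36" = c(NA, NA, NA, 1.07, 1.77, 2.49, 3.03, 3.34),
    "37" = c(0.17, 0.46, 0.69, 0.77, 1.27, 1.94, 2.40, 4.03)
  )
  colnames(m) <- stage_levels()
  m
}

modified_female_scores_ <- function() {
  m <- rbind(
    "31" = c(NA, NA, 1.86, 2.23, 2.38, 2.87, 3.25, 3.20),
    "32" = c(NA, NA, NA, 0.30, 0.33, 0.50, 0.80, 0.71),
    "33" = c(NA, NA, 0.63, 0.57, 0.65, 1.14, 1.81, 2.11),
    "34" = c(-1.10, -0.17, 0.19, 0.47, 0.69, 1.47, 1.83, 2.53),
    "35" = c(-0.20, 0.01, 0.29, 0.18, 0.37, 0.37, 0.58, 1.60),
    "36" = c(NA, NA, NA, 0.63, 0.92, 1.59, 1.86, 2.26),
    "37" = c(0.11, 0.09, 0.17, 0.26, 0.54, 1.05, 1.71, 3.30)
  )
  colnames(m) <- stage_levels()
  m
}

#' Built-in reweighted (southern-China) score tables
#'
#' The sex-specific age-sum score tables produced by non-intercept
#' regression reweighting of the Willems scores on a southern-China
#' juvenile cohort. Summing the seven per-tooth scores of a subject's
#' attained stages gives the dental age in years directly. Cells for
#' stages never observed in the source population are absent.
#'
#' @return a named list with `score_table` elements `female` and `male`.
#' @examples
#' tabs <- modified_score_tables()
#' lookup_score(tabs$female, "37", "H") # 3.30
#' @export
modified_score_tables <- function() {
  list(
    female = score_table("female", modified_female_scores_(),
                         kind = "age_sum", name = "modified_southern_china"),
    male = score_table("male", modified_male_scores_(),
                       kind = "age_sum", name = "modified_southern_china")
  )
}

#' Maturity-to-age conversion curve
#'
#' Demirjian-type estimation converts a summed maturity score to a
#' dental age through a sex-specific monotone curve, represented here
#' by interpolation knots (score, age). Between knots the age is
#' piecewise-linear in the score; outside the knot range it is clamped
#' to the endpoint ages and the estimate flagged.
#'
#' @param sex `"female"` or `"male"`.
#' @param knots a two-column matrix or data frame: column 1 maturity
#'   scores (strictly increasing), column 2 ages in years
#'   (nondecreasing).
#' @return an object of class `maturity_conversion`.
#' @export
maturity_conversion <- function(sex, knots) {
  sex <- match.arg(sex, sex_levels())
  knots <- as.matrix(knots)
  if (ncol(knots) != 2 || nrow(knots) < 1) {
    abort("`knots` must have two columns (score, age) and at least one row")
  }
  if (nrow(knots) > 1) {
    if (any(diff(knots[, 1]) <= 0)) abort("maturity scores must be strictly increasing")
    if (any(diff(knots[, 2]) < 0)) abort("conversion ages must be nondecreasing")
  }
  structure(
    list(sex = sex, knots = unname(knots)),
    class = "maturity_conversion"
  )
}

#' @rdname read_score_table
#' @export
read_maturity_conversion <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$sex) || is.null(obj$knots)) {
    abort("conversion JSON must have fields sex and knots")
  }
  maturity_conversion(obj$sex, obj$knots)
}

#' @rdname read_score_table
#' @param conv a [maturity_conversion()].
#' @export
write_maturity_conversion <- function(conv, path) {
  jsonlite::write_json(
    list(sex = conv$sex, knots = conv$knots),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}
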