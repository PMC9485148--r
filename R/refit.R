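#' Design matrix for score-table reweighting
#'
#' The reweighting procedure regresses chronological age on stage-score
#' predictors *without an intercept*. Two design strategies exist:
#' \describe{
#'   \item{`per_tooth`}{7 columns; column t holds the base table's
#'     score for tooth t's attained stage. The fitted coefficients are
#'     per-tooth scale factors applied to the base scores.}
#'   \item{`per_cell`}{one 0/1 indicator column per (tooth, stage) cell
#'     observed in the data; the fitted coefficients *are* the new cell
#'     scores.}
#' }
#' Records with any missing (unscorable) stage are excluded from the
#' fit and counted.
#'
#' @param cohort a single-sex cohort tibble matching `base$sex`.
#' @param base the base [score_table()] (required and consulted only
#'   for `per_tooth`).
#' @param strategy `"per_cell"` or `"per_tooth"`.
#' @return a list with elements `x` (matrix, labelled columns), `y`
#'   (chronological ages), `strategy`, `n_excluded`.
#' @seealso [refit_score_table()]
#' @export
build_design_matrix <- function(cohort, base = NULL,
                                strategy = c("per_cell", "per_tooth")) {
  strategy <- match.arg(strategy)
  cohort <- tibble::as_tibble(cohort)
  if (strategy == "per_tooth") stopifnot(inherits(base, "score_table"))
  if (!is.null(base) && any(cohort$sex != base$sex)) {
    abort("cohort sex does not match the base table's sex")
  }

  stage_mat <- as.matrix(cohort[tooth_columns()])
  usable <- rowSums(is.na(stage_mat)) == 0
  n_excluded <- sum(!usable)
  cohort <- cohort[usable, , drop = FALSE]
  stage_mat <- stage_mat[usable, , drop = FALSE]
  if (nrow(cohort) == 0) abort("no usable records (all have missing stages)")

  if (strategy == "per_tooth") {
    x <- matrix(NA_real_, nrow(cohort), 7, dimnames = list(NULL, tooth_ids()))
    for (j in seq_len(7)) {
      cell <- base$scores[tooth_ids()[j], stage_mat[, j]]
      if (anyNA(cell)) {
        i <- which(is.na(cell))[1]
        abort(paste0("absent base cell: tooth ", tooth_ids()[j], ", stage ",
                     stage_mat[i, j], " (subject ", cohort$id[i], ")"))
      }
      x[, j] <- cell
    }
  } else {
    cells <- sort(unique(paste0(
      rep(tooth_ids(), each = nrow(stage_mat)), ":", as.vector(stage_mat)
    )))
    x <- matrix(0, nrow(cohort), length(cells), dimnames = list(NULL, cells))
    for (j in seq_len(7)) {
      lab <- paste0(tooth_ids()[j], ":", stage_mat[, j])
      x[cbind(seq_len(nrow(x)), match(lab, cells))] <- 1
    }
  }
  list(x = x, y = cohort$age, strategy = strategy, n_excluded = n_excluded)
}

#' Least squares without an intercept
#'
#' Solves `min ||y - X b||^2` with no intercept column. The default QR
#' path requires a full-column-rank design and errors otherwise, naming
#' the aliased columns. The `"minimum-norm"` path solves via the SVD
#' pseudoinverse and returns the minimum-norm least-squares solution;
#' it is the appropriate solver for per-cell indicator designs, which
#' are structurally rank-deficient (each tooth's indicators sum to one
#' for every record, so any two teeth's column sums coincide).
#'
#' @param x numeric design matrix with labelled columns.
#' @param y numeric response (chronological ages).
#' @param method `"qr"` or `"minimum-norm"`.
#' @return named numeric vector of coefficients.
#' @examples
#' fit_nonintercept_ols(cbind(a = c(1, 2, 3)), c(2, 4, 7)) # 31/14
#' @export
fit_nonintercept_ols <- function(x, y, method = c("qr", "minimum-norm")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) abort("nrow(x) must equal length(y)")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (method == "qr") {
    dec <- qr(x)
    if (dec$rank < ncol(x)) {
      dep <- colnames(x)[dec$pivot[(dec$rank + 1):ncol(x)]]
      abort(paste0("singular design: dependent column(s) ",
                   paste(dep, collapse = ", ")))
    }
    b <- qr.coef(dec, y)
  } else {
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * max(dim(x)) * .Machine$double.eps
    b <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    b <- drop(b)
    names(b) <- colnames(x)
  }
  b
}

#' Turn fitted coefficients into a modified score table
#'
#' Under `per_tooth`, every non-absent base cell (t, s) becomes
#' `b_t * base(t, s)`. Under `per_cell`, cell (t, s) takes the
#' coefficient of its indicator column; cells with no coefficient
#' (stages never observed in the fitting data) are absent, mirroring
#' the dashed cells of published tables.
#'
#' @param coeffs named coefficients from [fit_nonintercept_ols()].
#' @param base the base [score_table()] (`per_tooth` only).
#' @param strategy `"per_cell"` or `"per_tooth"`.
#' @param sex table sex (defaults to `base$sex` when available).
#' @param name provenance string for the new table.
#' @return an `age_sum` [score_table()].
#' @export
derive_modified_table <- function(coeffs, base = NULL,
                                  strategy = c("per_cell", "per_tooth"),
                                  sex = NULL, name = NULL) {
  strategy <- match.arg(strategy)
  sex <- sex %||% base$sex
  if (is.null(sex)) abort("`sex` must be given when no base table is")
  name <- name %||% paste0("refit_", strategy)
  m <- matrix(NA_real_, 7, 8, dimnames = list(tooth_ids(), stage_levels()))
  if (strategy == "per_tooth") {
    stopifnot(inherits(base, "score_table"))
    if (!setequal(names(coeffs), tooth_ids())) {
      abort("per_tooth coefficients must be labelled by the 7 tooth ids")
    }
    m <- base$scores * coeffs[tooth_ids()]
  } else {
    parts <- strsplit(names(coeffs), ":", fixed = TRUE)
    ok <- lengths(parts) == 2 &
      vapply(parts, function(p) p[1] %in% tooth_ids() && p[2] %in% stage_levels(),
             logical(1))
    if (!all(ok)) {
      abort(paste0("unrecognized per_cell coefficient label(s): ",
                   paste(names(coeffs)[!ok], collapse = ", ")))
    }
    for (i in seq_along(coeffs)) {
      m[parts[[i]][1], parts[[i]][2]] <- coeffs[i]
    }
  }
  score_table(sex, m, kind = "age_sum", name = name)
}

#' Reweight a score table to a cohort by non-intercept regression
#'
#' Fits chronological age on stage-score predictors without an
#' intercept (per sex) and derives a modified age-sum score table, the
#' procedure used to adapt the Willems scores to a local population.
#' The default `per_cell` strategy refits every observed (tooth, stage)
#' cell freely, which is what published modified tables' within-row
#' sign changes require; `per_tooth` fits one scale factor per tooth
#' applied to the base scores.
#'
#' @inheritParams build_design_matrix
#' @param base base [score_table()]; required for `per_tooth`, used for
#'   provenance (and sex) otherwise.
#' @param sex table sex when no base table is supplied.
#' @return an object of class `dae_refit` with elements
#'   `coefficients`, `modified_table`, `residual_sd` (years), `n`,
#'   `n_excluded`, `strategy`, `sex`.
#' @examples
#' tabs <- modified_score_tables()
#' coh <- generate_cohort(seed = 1)$cohort
#' fit <- refit_score_table(dplyr::filter(coh, sex == "male"),
#'                          base = tabs$male)
#' glance(fit)
#' @export
refit_score_table <- function(cohort, base = NULL,
                              strategy = c("per_cell", "per_tooth"),
                              sex = NULL) {
  strategy <- match.arg(strategy)
  cohort <- tibble::as_tibble(cohort)
  sex <- sex %||% base$sex %||% unique(cohort$sex)
  if (length(sex) != 1) abort("cohort mixes sexes; supply a single-sex cohort")
  if (any(cohort$sex != sex)) abort("cohort contains records of the wrong sex")

  dm <- build_design_matrix(cohort, base = base, strategy = strategy)
  b <- fit_nonintercept_ols(
    dm$x, dm$y,
    method = if (strategy == "per_cell") "minimum-norm" else "qr"
  )
  r <- dm$y - drop(dm$x %*% b)
  rank <- qr(dm$x)$rank
  res_sd <- sqrt(sum(r^2) / max(1, length(dm$y) - rank))
  structure(
    list(
      coefficients = b,
      modified_table = derive_modified_table(
        b, base = base, strategy = strategy, sex = sex,
        name = paste0("refit_", strategy,
                      if (!is.null(base)) paste0("(", base$name, ")") else "")
      ),
      residuals = r,
      residual_sd = res_sd,
      n = length(dm$y),
      n_excluded = dm$n_excluded,
      rank = rank,
      strategy = strategy,
      sex = sex
    ),
    class = "dae_refit"
  )
}

#' @export
print.dae_refit <- function(x, ...) {
  cat(sprintf(
    "<dae_refit> %s, %s: %d coefficients, n = %d (%d excluded), residual sd = %.3f y\n",
    x$strategy, x$sex, length(x$coefficients), x$n, x$n_excluded, x$residual_sd
  ))
  invisible(x)
}

#' Tidy and summarize refit results
#'
#' @param x a `dae_refit` from [refit_score_table()].
#' @param ... unused.
#' @return `tidy()` gives one row per coefficient (`term`, `tooth`,
#'   `stage`, `estimate`); `glance()` a one-row model summary.
#' @method tidy dae_refit
#' @export
tidy.dae_refit <- function(x, ...) {
  term <- names(x$coefficients)
  if (x$strategy == "per_cell") {
    parts <- strsplit(term, ":", fixed = TRUE)
    tooth <- vapply(parts, `[`, "", 1)
    stage <- vapply(parts, `[`, "", 2)
  } else {
    tooth <- term
    stage <- NA_character_
  }
  tibble::tibble(term = term, tooth = tooth, stage = stage,
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.dae_refit
#' @method glance dae_refit
#' @export
glance.dae_refit <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy, sex = x$sex, n = x$n, n_excluded = x$n_excluded,
    n_terms = length(x$coefficients), rank = x$rank,
    residual_sd = x$residual_sd
  )
}
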