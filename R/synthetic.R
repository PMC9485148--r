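#' Reference cohort size structure
#'
#' Per-bin, per-sex subject counts of the southern-China study
#' population (n = 1477: 833 female, 644 male, one-year bins over
#' 2.00-17.99 years). Used as the default size/age structure for
#' synthetic cohorts.
#'
#' @return a tibble with columns `age_group`, `female`, `male`.
#' @export
table1_counts <- function() {
  tibble::tibble(
    age_group = age_bins()$label,
    female = c(5L, 19L, 33L, 49L, 59L, 53L, 41L, 37L, 37L, 64L, 123L,
               111L, 60L, 69L, 36L, 37L),
    male = c(1L, 11L, 39L, 45L, 52L, 43L, 38L, 34L, 38L, 51L, 94L,
             73L, 40L, 42L, 28L, 15L)
  )
}

#' Specification of a synthetic cohort
#'
#' @param counts a tibble with columns `age_group` (labels from
#'   [age_bins()]), `female` and `male` subject counts. Defaults to the
#'   reference study structure, [table1_counts()].
#' @return an object of class `cohort_spec`. Ages are sampled
#'   uniformly within each bin.
#' @export
cohort_spec <- function(counts = table1_counts()) {
  counts <- tibble::as_tibble(counts)
  need <- c("age_group", "female", "male")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs columns age_group, female, male")
  }
  bad <- setdiff(counts$age_group, age_bins()$label)
  if (length(bad) > 0) {
    abort(paste0("unknown age group label(s): ", paste(bad, collapse = ", ")))
  }
  if (any(counts$female < 0 | counts$male < 0)) abort("counts must be >= 0")
  if (sum(counts$female) + sum(counts$male) == 0) abort("empty cohort spec")
  structure(list(counts = counts), class = "cohort_spec")
}

#' Default stage-attainment parameters
#'
#' The synthetic maturation model: per sex and tooth, eight
#' nondecreasing mean stage-attainment ages tau_A ... tau_H (years),
#' spaced along a fast-early, slow-late power curve (crown stages pass
#' quickly, root completion drags); stages completed before age 2 are
#' undefined (`NA`), mirroring the dashed early-stage cells of
#' population score tables. A subject's development is shifted by a
#' shared tempo offset (`Normal(0, offset_sd)`) plus independent
#' per-tooth jitter (`Normal(0, jitter_sd)`), and each subject belongs
#' to one of two developmental profiles: *concordant*, or
#' *posterior-delayed* (probability `lag_prob`), in which the
#' posterior tooth field (bicuspids and molars) lags the anterior
#' field by `lag_years`. The profile mixture puts genuine
#' joint-pattern (non-additive) age information into the data: the
#' anterior/posterior discrepancy identifies the profile, and the
#' correct reading of the posterior stages depends on it. Female
#' trajectories run slightly earlier than male, the usual direction of
#' sexual dimorphism in dental development. Values are versioned
#' constants shipped with the package (synthetic calibration
#' constants, not published population parameters).
#'
#' @param version parameter-set version (only `1` exists).
#' @return an object of class `maturation_params`: per sex, a 7 x 8
#'   `tau` matrix, the per-tooth `field` assignment, `offset_sd`,
#'   `jitter_sd`, `lag_years` and `lag_prob`.
#' @export
default_maturation_params <- function(version = 1L) {
  path <- system.file("extdata",
                      sprintf("maturation_params_v%d.csv", version),
                      package = "dentage", mustWork = TRUE)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  per_sex <- purrr::map(setNames(sex_levels(), sex_levels()), function(s) {
    sub <- raw[raw$sex == s, , drop = FALSE]
    sub <- sub[match(tooth_ids(), as.character(sub$tooth)), , drop = FALSE]
    tau <- as.matrix(sub[paste0("tau_", stage_levels())])
    dimnames(tau) <- list(tooth_ids(), stage_levels())
    list(tau = tau,
         field = setNames(sub$field, tooth_ids()),
         offset_sd = sub$offset_sd[1], jitter_sd = sub$jitter_sd[1],
         lag_years = sub$lag_years[1], lag_prob = sub$lag_prob[1])
  })
  structure(c(per_sex, list(version = version)), class = "maturation_params")
}

#' @export
print.maturation_params <- function(x, ...) {
  cat(sprintf("<maturation_params> v%d; offset sd %.2f y, jitter sd %.2f y\n",
              x$version, x$female$offset_sd, x$female$jitter_sd))
  invisible(x)
}

# Stage letters for effective ages `eff` (length n) of one tooth given
# its attainment ages `tau` (length 8, NA = attained before age 2).
# Teeth with undefined early stages are never observed below their
# first in-range stage (the meaning of a dashed early cell), so the
# stage floor is the first defined stage.
stages_from_tau_ <- function(eff, tau) {
  floor_stage <- if (anyNA(tau)) sum(is.na(tau)) + 1L else 1L
  tau[is.na(tau)] <- -Inf
  cnt <- rowSums(outer(eff, tau, ">="))
  stage_levels()[pmax(floor_stage, cnt)]
}

#' Generate a synthetic staged-tooth cohort with known ground truth
#'
#' Emulates a staged radiograph cohort: subjects are drawn per (sex,
#' age bin) according to the spec, with ages uniform within bins. Each
#' subject receives a shared developmental tempo offset `delta ~
#' Normal(0, offset_sd)`, a developmental profile (posterior-delayed
#' with probability `lag_prob`, which sets a lag of `lag_years` on the
#' posterior tooth field), and independent per-tooth jitter `eps ~
#' Normal(0, jitter_sd)`. A tooth's attained stage is the highest
#' stage whose attainment age is at most the tooth's effective age
#' `age + delta + eps - lag` (never below the tooth's first in-range
#' stage; capped at H). Deterministic given the seed.
#'
#' The generator reproduces three properties real staging data shows:
#' ordinal monotone stage progression with age, between-tooth
#' correlation within subject (via the shared offset and the profile),
#' and nonlinear joint-pattern age information (stage saturation plus
#' the anterior/posterior asynchrony mixture).
#'
#' @param spec a [cohort_spec()].
#' @param params a [default_maturation_params()] object.
#' @param seed integer seed.
#' @return a list with `cohort` (a standard cohort tibble) and `truth`
#'   (per subject: `id`, `delta`, `profile`, and the per-tooth
#'   jitters `eps_t31`...`eps_t37`).
#' @examples
#' out <- generate_cohort(seed = 1)
#' nrow(out$cohort) # 1477
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            params = default_maturation_params(),
                            seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(params, "maturation_params"))
  bins <- age_bins()
  with_seed_(seed, {
    per_sex <- purrr::map(sex_levels(), function(s) {
      counts <- spec$counts[[s]]
      n <- sum(counts)
      if (n == 0) return(NULL)
      lower <- bins$lower[match(spec$counts$age_group, bins$label)]
      ages <- runif(n, rep(lower, counts), rep(lower, counts) + 1)
      p <- params[[s]]
      delta <- rnorm(n, 0, p$offset_sd)
      lagged <- runif(n) < p$lag_prob
      eps <- matrix(rnorm(n * 7, 0, p$jitter_sd), n, 7)
      stages <- vapply(seq_len(7), function(j) {
        lag <- if (p$field[j] == "posterior") p$lag_years * lagged else 0
        stages_from_tau_(ages + delta + eps[, j] - lag, p$tau[j, ])
      }, character(n))
      prefix <- if (s == "female") "F" else "M"
      coh <- tibble::tibble(
        id = sprintf("%s%04d", prefix, seq_len(n)),
        sex = s, age = ages
      )
      coh[tooth_columns()] <- as.data.frame(matrix(stages, n, 7),
                                            stringsAsFactors = FALSE)
      truth <- tibble::tibble(
        id = coh$id, delta = delta,
        profile = ifelse(lagged, "posterior_delayed", "concordant")
      )
      truth[paste0("eps_", tooth_columns())] <- as.data.frame(eps)
      list(cohort = coh, truth = truth)
    })
    per_sex <- purrr::compact(per_sex)
    list(
      cohort = dplyr::bind_rows(purrr::map(per_sex, "cohort")),
      truth = dplyr::bind_rows(purrr::map(per_sex, "truth"))
    )
  })
}

#' Generate a cohort that exactly satisfies an additive score model
#'
#' Draws stage patterns as [generate_cohort()] does, then *sets* each
#' subject's chronological age to the sum of the table's scores for
#' its stages plus `Normal(0, noise_sd)` noise. With `noise_sd = 0`
#' the age-sum estimator reproduces CA exactly, which makes this the
#' fixture generator for reweighting-recovery tests. Stage patterns
#' that hit an absent table cell are redrawn (`on_absent =
#' "resample"`, the default) or raise an error.
#'
#' Note the resulting ages need not lie in the \[2, 18) staging range;
#' the output is a regression fixture, not a screened cohort.
#'
#' @inheritParams generate_cohort
#' @param table an `age_sum` [score_table()]; only subjects of
#'   `table$sex` are generated from the spec's counts.
#' @param noise_sd sd (years) of the additive age noise.
#' @param on_absent `"resample"` or `"error"`.
#' @return a cohort tibble for `table$sex`.
#' @export
generate_from_score_table <- function(table, spec = cohort_spec(),
                                      noise_sd = 0,
                                      params = default_maturation_params(),
                                      seed = 1L,
                                      on_absent = c("resample", "error")) {
  on_absent <- match.arg(on_absent)
  stopifnot(inherits(table, "score_table"))
  if (table$kind != "age_sum") abort("`table` must be an age_sum table")
  s <- table$sex
  bins <- age_bins()
  counts <- spec$counts[[s]]
  n <- sum(counts)
  if (n == 0) abort(paste0("spec has no ", s, " subjects"))
  lower_all <- rep(bins$lower[match(spec$counts$age_group, bins$label)], counts)
  p <- params[[s]]

  with_seed_(seed, {
    draw <- function(lower) {
      m <- length(lower)
      ages <- runif(m, lower, lower + 1)
      delta <- rnorm(m, 0, p$offset_sd)
      lagged <- runif(m) < p$lag_prob
      stages <- vapply(seq_len(7), function(j) {
        eps <- rnorm(m, 0, p$jitter_sd)
        lag <- if (p$field[j] == "posterior") p$lag_years * lagged else 0
        stages_from_tau_(ages + delta + eps - lag, p$tau[j, ])
      }, character(m))
      matrix(stages, m, 7)
    }
    stage_mat <- draw(lower_all)
    score_of <- function(sm) {
      out <- matrix(NA_real_, nrow(sm), 7)
      for (j in seq_len(7)) out[, j] <- table$scores[tooth_ids()[j], sm[, j]]
      out
    }
    scores <- score_of(stage_mat)
    bad <- rowSums(is.na(scores)) > 0
    if (any(bad) && on_absent == "error") {
      abort(paste0(sum(bad), " subject(s) hit absent table cells"))
    }
    tries <- 0L
    while (any(bad) && tries < 100L) {
      redraw <- draw(lower_all[bad])
      stage_mat[bad, ] <- redraw
      scores[bad, ] <- score_of(redraw)
      bad <- rowSums(is.na(scores)) > 0
      tries <- tries + 1L
    }
    if (any(bad)) abort("could not avoid absent cells after 100 resampling rounds")

    age <- rowSums(scores) + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    coh <- tibble::tibble(
      id = sprintf("T%04d", seq_len(n)), sex = s, age = age
    )
    coh[tooth_columns()] <- as.data.frame(stage_mat, stringsAsFactors = FALSE)
    coh
  })
}
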