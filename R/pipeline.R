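derive_seed_ <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + offset
}

#' Run the full estimation study on one cohort
#'
#' Reproduces the end-to-end design of comparative dental-age studies:
#' \enumerate{
#'   \item score-model estimation on the full cohort (per sex) and a
#'     model-fit report (CA/DA/AD means, paired-t p, capped MAEs);
#'   \item a seeded train/test split, native-learner training on the
#'     training split only, and a learner report (MSE/RMSE/MAE/R2 per
#'     learner, sex and split);
#'   \item per-age-group MAE series for every method and learner.
#' }
#' One global seed fans out to stage-specific seeds
#' (`seed * 1000 + offset`, offsets: 7 cohort generation, 101 split,
#' 200 + learner index for training), so each stage is independently
#' reproducible.
#'
#' @param cohort a cohort tibble, or `NULL` to generate the default
#'   synthetic cohort (reference size structure) from the seed.
#' @param methods subset of `"demirjian"`, `"willems"`, `"modified"`,
#'   `"refit"`. `"modified"` uses the built-in reweighted tables;
#'   `"refit"` reweights per sex on the full cohort
#'   (strategy `refit_strategy`); `"demirjian"`/`"willems"` require the
#'   corresponding published tables in `score_tables` (and
#'   `conversions` for the maturity-kind Demirjian tables), which this
#'   package does not ship.
#' @param learners subset of [train_learner()] names; `character(0)`
#'   skips the machine-learning stage.
#' @param score_tables named list: per method name, a list with
#'   `score_table` elements `female` and `male`.
#' @param conversions named list of [maturity_conversion()] pairs for
#'   maturity-kind tables.
#' @param ratio training fraction (default 3:1 train:test).
#' @param seed global integer seed.
#' @param refit_strategy passed to [refit_score_table()].
#' @param out_dir if non-`NULL`, reports are written there as CSV
#'   (plus a JSON run manifest) and listed with checksums in the
#'   manifest.
#' @return an object of class `dae_study`: list with `cohort_summary`,
#'   `fit_report`, `learner_report`, `bin_mae`, `estimates`,
#'   `refits`, `split_ids` and `manifest`.
#' @examples
#' \donttest{
#' study <- run_study(learners = "knn", seed = 1)
#' study$fit_report
#' }
#' @export
run_study <- function(cohort = NULL,
                      methods = c("modified", "refit"),
                      learners = learner_names(),
                      score_tables = NULL, conversions = NULL,
                      ratio = 0.75, seed = 1L,
                      refit_strategy = c("per_cell", "per_tooth"),
                      out_dir = NULL) {
  refit_strategy <- match.arg(refit_strategy)
  if (length(methods) > 0) {
    methods <- match.arg(methods, c("demirjian", "willems", "modified", "refit"),
                         several.ok = TRUE)
  }
  if (length(learners) > 0) {
    learners <- match.arg(learners, learner_names(), several.ok = TRUE)
  }
  if (length(methods) == 0 && length(learners) == 0) {
    abort("at least one method or learner is required")
  }
  t0 <- Sys.time()
  timing <- list()
  tick <- function(stage, t_start) {
    timing[[stage]] <<- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  }

  generated <- is.null(cohort)
  if (generated) {
    cohort <- generate_cohort(seed = derive_seed_(seed, 7L))$cohort
  }
  cohort <- validate_cohort(cohort)
  summary_tbl <- age_bin_summary(cohort)

  # --- score-model estimates on the full cohort -----------------------
  ts <- Sys.time()
  refits <- list()
  estimates <- purrr::map(methods, function(m) {
    if (m == "modified") {
      return(estimate_with_tables(cohort, modified_score_tables(),
                                  method = "modified"))
    }
    if (m == "refit") {
      per_sex <- purrr::map(setNames(sex_levels(), sex_levels()), function(s) {
        refit_score_table(cohort[cohort$sex == s, , drop = FALSE],
                          base = modified_score_tables()[[s]],
                          strategy = refit_strategy)
      })
      refits <<- per_sex
      tabs <- purrr::map(per_sex, "modified_table")
      return(estimate_with_tables(cohort, tabs, method = "refit"))
    }
    tabs <- score_tables[[m]]
    if (is.null(tabs)) {
      abort(paste0("method '", m, "' needs its score tables in `score_tables`"))
    }
    if (tabs$female$kind == "maturity") {
      conv <- conversions[[m]]
      if (is.null(conv)) {
        abort(paste0("maturity-kind method '", m, "' needs `conversions`"))
      }
      est <- purrr::map(sex_levels(), function(s) {
        estimate_age_maturity(cohort[cohort$sex == s, , drop = FALSE],
                              tabs[[s]], conv[[s]])
      })
      est <- dplyr::bind_rows(est)
      est$method <- m
      est[c("id", "sex", "age", "dental_age", "method")]
    } else {
      estimate_with_tables(cohort, tabs, method = m)
    }
  })
  estimates <- dplyr::bind_rows(estimates)
  fit_rep <- if (nrow(estimates) > 0) fit_report(estimates) else NULL
  tick("score_models", ts)

  # --- learner training on the split ----------------------------------
  ts <- Sys.time()
  learner_rep <- NULL
  learner_pairs <- NULL
  split <- NULL
  if (length(learners) > 0) {
    split <- split_train_test(cohort, ratio = ratio,
                              seed = derive_seed_(seed, 101L))
    learner_pairs <- purrr::imap(setNames(learners, learners), function(l, nm) {
      model <- train_learner(split$train, l,
                             seed = derive_seed_(seed, 200L + match(l, learner_names())))
      dplyr::bind_rows(
        dplyr::mutate(predict_ages(model, split$train), split = "training"),
        dplyr::mutate(predict_ages(model, split$test), split = "testing")
      )
    })
    learner_pairs <- dplyr::bind_rows(learner_pairs)
    learner_rep <- learner_report(learner_pairs)
  }
  tick("learners", ts)

  # --- per-age-group MAE ----------------------------------------------
  bin_sources <- list()
  if (nrow(estimates) > 0) {
    bin_sources$full <- estimates |>
      dplyr::group_by(.data$method) |>
      dplyr::group_modify(function(g, key) per_group_mae(g)) |>
      dplyr::ungroup() |>
      dplyr::mutate(split = "full")
  }
  if (!is.null(learner_pairs)) {
    bin_sources$test <- learner_pairs |>
      dplyr::filter(.data$split == "testing") |>
      dplyr::group_by(.data$method) |>
      dplyr::group_modify(function(g, key) per_group_mae(g)) |>
      dplyr::ungroup() |>
      dplyr::mutate(split = "testing")
  }
  bin_mae <- dplyr::bind_rows(bin_sources)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dentage")),
    seed = seed,
    derived_seeds = list(cohort = derive_seed_(seed, 7L),
                         split = derive_seed_(seed, 101L)),
    cohort_generated = generated,
    n = nrow(cohort), ratio = ratio,
    methods = methods, learners = learners,
    refit_strategy = refit_strategy,
    timing_sec = timing,
    files = list()
  )

  study <- structure(
    list(
      cohort_summary = summary_tbl,
      fit_report = fit_rep,
      learner_report = learner_rep,
      bin_mae = bin_mae,
      estimates = estimates,
      learner_pairs = learner_pairs,
      refits = refits,
      split_ids = if (!is.null(split)) list(train = split$train$id,
                                            test = split$test$id),
      manifest = manifest
    ),
    class = "dae_study"
  )

  if (!is.null(out_dir)) {
    study <- write_study_reports(study, out_dir)
  }
  study
}

#' @rdname run_study
#' @param study a `dae_study`.
#' @export
write_study_reports <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(tbl, name) {
    if (is.null(tbl)) return()
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tbl, path, progress = FALSE)
    files <<- c(files, path)
  }
  emit(study$cohort_summary, "cohort_summary")
  emit(study$fit_report, "fit_report")
  emit(study$learner_report, "learner_report")
  emit(study$bin_mae, "bin_mae")
  study$manifest$files <- purrr::map(
    setNames(files, basename(files)),
    function(f) list(md5 = unname(tools::md5sum(f)))
  )
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(study)
}

#' @export
print.dae_study <- function(x, ...) {
  cat(sprintf("<dae_study> n = %d; methods: %s; learners: %s\n",
              x$manifest$n, paste(x$manifest$methods, collapse = ", "),
              if (length(x$manifest$learners)) {
                paste(x$manifest$learners, collapse = ", ")
              } else "none"))
  if (!is.null(x$fit_report)) {
    cat("\nModel fit (full cohort):\n")
    print(as.data.frame(x$fit_report), digits = 3)
  }
  if (!is.null(x$learner_report)) {
    cat("\nLearners (train/test split):\n")
    print(as.data.frame(x$learner_report), digits = 3)
  }
  invisible(x)
}

#' @method glance dae_study
#' @export
glance.dae_study <- function(x, ...) {
  tibble::tibble(
    n = x$manifest$n, seed = x$manifest$seed, ratio = x$manifest$ratio,
    n_methods = length(x$manifest$methods),
    n_learners = length(x$manifest$learners)
  )
}

#' Rank estimation methods by error
#'
#' Orders all methods of a study by MAE per sex: learners by their
#' test-split MAE, score models by their full-cohort MAE (the way
#' published comparisons are made), with deltas to the best method.
#'
#' @param study a `dae_study` from [run_study()].
#' @return a tibble with columns `sex`, `method`, `source`, `mae`,
#'   `rank`, `delta_to_best`.
#' @export
compare_methods <- function(study) {
  stopifnot(inherits(study, "dae_study"))
  parts <- list()
  if (!is.null(study$fit_report)) {
    parts$models <- study$fit_report |>
      dplyr::transmute(.data$sex, .data$method, source = "full_cohort",
                       mae = .data$mae_under_18)
  }
  if (!is.null(study$learner_report)) {
    parts$learners <- study$learner_report |>
      dplyr::filter(.data$split == "testing") |>
      dplyr::transmute(.data$sex, .data$method, source = "test_split",
                       mae = .data$mae)
  }
  if (length(parts) == 0) abort("study contains no reports to compare")
  dplyr::bind_rows(parts) |>
    dplyr::group_by(.data$sex) |>
    dplyr::arrange(.data$mae, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  delta_to_best = .data$mae - .data$mae[1]) |>
    dplyr::ungroup()
}
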