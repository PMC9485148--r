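# Shared fixtures, built in code at test time.

# A score table with every cell defined (random but reproducible).
random_full_table <- function(sex = "male", seed = 1, name = "random") {
  set.seed(seed)
  m <- matrix(round(runif(56, -1, 4), 3), 7, 8,
              dimnames = list(tooth_ids(), stage_levels()))
  score_table(sex, m, kind = "age_sum", name = name)
}

# A random single-sex cohort of arbitrary stage patterns.
random_cohort <- function(n, sex = "male", seed = 1, p_missing = 0) {
  set.seed(seed)
  coh <- tibble::tibble(
    id = sprintf("R%05d", seq_len(n)),
    sex = sex,
    age = runif(n, 2, 18)
  )
  for (cl in tooth_columns()) {
    st <- sample(stage_levels(), n, replace = TRUE)
    if (p_missing > 0) st[runif(n) < p_missing] <- NA
    coh[[cl]] <- st
  }
  coh
}

# A tiny fixed mixed-sex cohort with hand-set stages.
toy_cohort <- function() {
  tibble::tibble(
    id = c("S1", "S2", "S3", "S4"),
    sex = c("male", "male", "female", "female"),
    age = c(10.68, 5.25, 12.01, 3.50),
    t31 = c("H", "E", "H", "C"),
    t32 = c("H", "D", "H", "C"),
    t33 = c("G", "D", "H", "D"),
    t34 = c("F", "C", "G", "A"),
    t35 = c("E", "B", "F", "A"),
    t36 = c("H", "E", "H", "D"),
    t37 = c("E", "B", "F", "A")
  )
}

# Noise-free maturation parameters (deterministic stage patterns).
zero_noise_params <- function() {
  p <- default_maturation_params()
  for (s in c("female", "male")) {
    p[[s]]$offset_sd <- 0
    p[[s]]$jitter_sd <- 0
    p[[s]]$lag_prob <- 0
  }
  p
}

# Stage-encoded features and ages for learner tests.
learner_fixture <- function(n = 1000, seed = 7) {
  coh <- generate_cohort(seed = seed)$cohort
  set.seed(seed)
  idx <- sort(sample.int(nrow(coh), n))
  coh[idx, , drop = FALSE]
}
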