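# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small, fast run: one fear-down participant, modest noise
quick_run <- function() fixture("quick_run", function() {
  cfg <- sim_config(seed = 101, obs_noise_sd = 0.1, neural_noise_sd = 0.02)
  g <- group_spec("fear", "down")
  set.seed(5)
  p <- default_neural_params(g, jitter_sd = 0)
  simulate_run_closed_loop(p, g, cfg, reg_amp = -0.1, seed = 101)
})

# a miniature cohort for structural/pipeline tests (2 per group, 2 runs)
mini_cohort <- function() fixture("mini_cohort", function() {
  simulate_cohort(sim_config(n_per_group = 2, n_runs = 2, seed = 7),
                  effect_scenario("study"))
})

# the full study-scale cohort (4 x 16 participants, 4 runs each); used by
# the structural and orthogonalization acceptance checks
study_cohort <- function() fixture("study_cohort", function() {
  simulate_cohort(sim_config(seed = 20260930), effect_scenario("study"))
})

# synthetic block-beta table: 2 groups x n participants x 4 runs (1 block
# row per run), with configurable fixed effects and variance components
make_beta_table <- function(n = 16, run_effects = c(0, 0, 0, 0),
                            group_effect = 0, interaction = c(0, 0, 0, 0),
                            subj_sd = 0.5, resid_sd = 0.5,
                            condition = "fear") {
  grp <- c(paste0(condition, "-down"), paste0(condition, "-up"))
  congr <- c(condition == "fear", condition == "happy")
  rows <- list()
  pid <- 0
  for (gi in 1:2) {
    for (s in seq_len(n)) {
      pid <- pid + 1
      u <- rnorm(1, 0, subj_sd)
      for (r in 1:4) {
        mu <- run_effects[r] + (gi - 1) * group_effect +
          (gi - 1) * interaction[r] + u
        rows[[length(rows) + 1]] <- data.frame(
          participant = sprintf("s%03d", pid), group = grp[gi],
          condition = condition, congruent = congr[gi], run = r,
          block = 1L, beta = mu + rnorm(1, 0, resid_sd))
      }
    }
  }
  do.call(rbind, rows)
}

# deterministic AR(1) stream generator for chain tests
make_ar1 <- function(n, rho, sd = 1, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, 0, sd)
  x
}
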