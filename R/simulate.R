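#' Experimental group specification
#'
#' Four groups cross the displayed emotion (happy, fear) with the instructed
#' regulation direction (up, down). A group is task-congruent when the
#' instructed direction matches the hedonically preferred stimulus change
#' (happy-up, fear-down); congruent groups have loop polarity +1 (higher
#' amygdala signal makes the expression more intense), incongruent groups -1.
#'
#' @param condition "happy" or "fear".
#' @param direction "up" or "down".
#' @return An object of class `group_spec` with fields condition, direction,
#'   label, congruent, polarity.
#' @export
#' @examples
#' group_spec("fear", "down")$polarity  # +1
group_spec <- function(condition = c("happy", "fear"),
                       direction = c("up", "down")) {
  condition <- match.arg(condition)
  direction <- match.arg(direction)
  congruent <- (condition == "happy" && direction == "up") ||
    (condition == "fear" && direction == "down")
  structure(list(condition = condition, direction = direction,
                 label = paste(condition, direction, sep = "-"),
                 congruent = congruent,
                 polarity = if (congruent) 1L else -1L),
            class = "group_spec")
}

#' The four group labels in canonical order
#' @return character vector.
#' @export
group_labels <- function() c("happy-up", "happy-down", "fear-down", "fear-up")

group_from_label <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1L]]
  group_spec(parts[1L], parts[2L])
}

#' Effect scenario: which groups truly regulate, and how strongly
#'
#' Per group and run, `reg_amp` is the amplitude of an instructed-regulation
#' drive added to the amygdala's input during regulation blocks (positive =
#' upregulation effort succeeding, negative = downregulation), `habituation`
#' is a per-block linear decrement of that drive within a run (block b
#' receives `reg_amp + habituation * (b - 1)`), and `b_scale` scales the
#' modulatory coupling matrices (training-related connectivity change).
#' Psychometric shifts are added to every participant's post-training score.
#'
#' The "study" preset encodes the qualitative pattern the simulator targets:
#' modest successful regulation with late-run decline and within-run
#' habituation in the fear groups, weaker effects in the happy groups, and
#' no psychometric change. The "null" preset zeroes every effect.
#'
#' @param name "study" or "null", or NULL when supplying matrices directly.
#' @param reg_amp,habituation,b_scale optional 4x4 numeric matrices
#'   (rows = groups in [group_labels()] order, columns = runs).
#' @param psych_shift optional named numeric vector with entries panas_pos,
#'   panas_neg, sds.
#' @return An object of class `effect_scenario`.
#' @export
effect_scenario <- function(name = c("study", "null"), reg_amp = NULL,
                            habituation = NULL, b_scale = NULL,
                            psych_shift = NULL) {
  g <- group_labels()
  mk <- function(m) {
    m <- matrix(m, 4, 4, byrow = TRUE, dimnames = list(g, paste0("run", 1:4)))
    m
  }
  if (is.null(reg_amp) && is.null(habituation) && is.null(b_scale)) {
    name <- match.arg(name)
    if (name == "study") {
      reg_amp <- mk(c(0.20, 0.20, 0.20, 0.20,      # happy-up
                      -0.05, -0.05, -0.05, -0.05,  # happy-down
                      -0.10, -0.15, -0.30, -0.30,  # fear-down
                      0.25, 0.25, 0.10, -0.05))    # fear-up
      habituation <- mk(c(0, 0, 0, 0,
                          0, 0, 0, -0.02,
                          0, 0, -0.06, -0.10,
                          0.02, 0.02, 0, -0.08))
      b_scale <- mk(c(1.0, 1.1, 1.2, 1.3,
                      1.0, 1.0, 1.0, 1.0,
                      1.2, 1.1, 0.9, 0.7,
                      1.0, 1.0, 0.9, 0.9))
    } else {
      reg_amp <- habituation <- mk(rep(0, 16))
      b_scale <- mk(rep(1, 16))
    }
  } else {
    name <- if (is.character(name)) name[1L] else "custom"
    if (is.null(reg_amp)) reg_amp <- mk(rep(0, 16))
    if (is.null(habituation)) habituation <- mk(rep(0, 16))
    if (is.null(b_scale)) b_scale <- mk(rep(1, 16))
    reg_amp <- mk(reg_amp); habituation <- mk(habituation)
    b_scale <- mk(b_scale)
  }
  if (is.null(psych_shift))
    psych_shift <- c(panas_pos = 0, panas_neg = 0, sds = 0)
  structure(list(name = name, reg_amp = reg_amp, habituation = habituation,
                 b_scale = b_scale, psych_shift = psych_shift),
            class = "effect_scenario")
}

scenario_row <- function(scenario, label) {
  if (!label %in% rownames(scenario$reg_amp))
    .stopf("scenario does not define group '%s'", label)
  label
}

#' Simulate one closed-loop neurofeedback run
#'
#' Per TR: the currently displayed morph index (lagged one volume, starting
#' at 0) sets the stimulus-intensity input; the latent neural states are
#' integrated across the TR; the amygdala BOLD observation is produced by
#' causal HRF convolution plus measurement noise; the online chain consumes
#' it and, via the group's loop polarity, emits the morph index displayed
#' from the next volume on. Baseline blocks have no face input and a neutral
#' display. Dummy volumes are simulated but discarded from all outputs.
#'
#' @param params a [neural_params()] object (the run's ground truth).
#' @param group a [group_spec()].
#' @param config a [sim_config()].
#' @param chain a [chain_settings()].
#' @param reg_amp amplitude of the instructed-regulation drive added to the
#'   amygdala during regulation blocks.
#' @param reg_hab per-block linear change of that drive within the run.
#' @param seed integer seed for this run's noise draws.
#' @return An object of class `run_recording`: list with `volumes` (one row
#'   per retained volume), `design`, `neural_truth` (regions x fine-grid,
#'   including the dummy period; for tests), `hrf`, and metadata.
#' @export
simulate_run_closed_loop <- function(params, group, config = sim_config(),
                                     chain = chain_settings(),
                                     reg_amp = 0, reg_hab = 0, seed = 1L) {
  config <- validate_sim_config(config)
  design <- make_block_design(config)
  stride <- as.integer(round(config$tr / config$integration_dt))
  n_vol <- design$n_volumes
  n_dummy <- design$dummy_volumes
  n_keep <- n_vol - n_dummy
  n_steps <- n_vol * stride
  dt <- config$integration_dt
  hrf <- build_chrf(tr = config$tr, dt = dt)
  kern <- hrf$kernel_dt
  L <- length(kern)
  kern_rev <- rev(kern)

  cond <- volume_conditions(design)             # retained volumes only
  blk <- regulation_block_index(design)
  set.seed(seed)

  Z <- matrix(0, 4, n_steps)
  z <- rep(0, 4)
  state <- chain_init(chain)
  no_extra <- matrix(0, 0, 0)

  vol <- data.frame(t = (seq_len(n_keep) - 1) * config$tr,
                    condition = cond, block = blk,
                    V1 = NA_real_, FFA = NA_real_, Amy = NA_real_,
                    mOFC = NA_real_,
                    amy_raw = NA_real_, despiked = NA_real_,
                    detrended = NA_real_, whitened = NA_real_,
                    normalized = NA_real_, was_spike = NA,
                    morph = NA_integer_, u_face = NA_real_,
                    u_int = NA_real_)
  display_morph <- 0L  # initial display before any feedback

  for (v in seq_len(n_vol)) {
    retained <- v > n_dummy
    r <- v - n_dummy
    is_reg <- retained && cond[r] == "regulation"
    u_face <- if (is_reg) 1 else 0
    u_int <- if (is_reg) display_morph / 30 else 0
    extra <- no_extra
    if (is_reg && (reg_amp != 0 || reg_hab != 0)) {
      drive <- reg_amp + reg_hab * (blk[r] - 1L)
      extra <- matrix(0, 4, stride)
      extra[3L, ] <- drive
    }
    zz <- integrate_bilinear_cpp(params$A, params$B_face, params$B_int,
                                 params$C, rep(u_face, stride),
                                 rep(u_int, stride), extra, dt, z,
                                 config$neural_noise_sd, 50)
    idx <- ((v - 1L) * stride + 1L):(v * stride)
    Z[, idx] <- zz
    z <- zz[, stride]
    # causal HRF observation at the end of this volume's TR
    tpos <- v * stride
    w0 <- max(1L, tpos - L + 1L)
    seg <- Z[, w0:tpos, drop = FALSE]
    bold <- as.vector(seg %*% kern_rev[(L - (tpos - w0)):L]) * dt
    meas <- bold + rnorm(4, 0, config$obs_noise_sd)
    if (retained) {
      vol[r, c("V1", "FFA", "Amy", "mOFC")] <- meas
      vol$amy_raw[r] <- meas[3L]
      pr <- process_volume(state, meas[3L], r)
      state <- pr$state
      s <- pr$sample
      vol$despiked[r] <- s$despiked
      vol$detrended[r] <- s$detrended
      vol$whitened[r] <- s$whitened
      vol$normalized[r] <- s$normalized
      vol$was_spike[r] <- s$was_spike
      morph <- signal_to_morph_index(s$normalized, group$polarity)
      vol$morph[r] <- morph
      vol$u_face[r] <- u_face
      vol$u_int[r] <- u_int
      display_morph <- morph  # displayed from the next volume on
    }
  }
  motion <- motion_nuisance(n_keep)
  vol <- cbind(vol, motion)
  structure(list(volumes = vol, design = design, neural_truth = Z,
                 hrf = hrf, stride = stride, group = group,
                 reg_amp = reg_amp, reg_hab = reg_hab, seed = seed,
                 config = config),
            class = "run_recording")
}

# Six smooth, low-amplitude random-walk series standing in for realignment
# parameter estimates; only used to exercise the offline GLM's nuisance
# columns.
motion_nuisance <- function(n) {
  m <- vapply(1:6, function(i) {
    w <- cumsum(rnorm(n, 0, 0.01))
    as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 1, circular = TRUE))
  }, numeric(n))
  colnames(m) <- paste0("motion", 1:6)
  as.data.frame(m)
}

#' @export
print.run_recording <- function(x, ...) {
  cat(sprintf("<run_recording> %s, %d retained volumes, seed %d\n",
              x$group$label, nrow(x$volumes), x$seed))
  invisible(x)
}

#' Simulate a full four-group cohort
#'
#' Generates `4 * n_per_group` participants with balanced group labels,
#' per-participant neural ground truth (population template plus
#' between-subject jitter), four closed-loop runs each, face assignments,
#' and pre/post psychometric scores (PANAS positive/negative, SDS). All
#' seeds derive deterministically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param scenario an [effect_scenario()].
#' @param chain a [chain_settings()].
#' @param jitter_sd between-subject SD on the free couplings.
#' @param efficacy_sd between-subject SD of the regulation-efficacy factor:
#'   each participant's instructed-regulation drive (amplitude and
#'   habituation) is scaled by a draw from N(1, efficacy_sd), truncated to
#'   [0, 2], so some participants barely regulate and others over-achieve.
#' @param stimulus_set optional [make_stimulus_set()] data.frame.
#' @return An object of class `cohort_dataset`: list with `participants`
#'   (each holding id, group, params, runs, psych, faces), `config`,
#'   `scenario`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            scenario = effect_scenario("study"),
                            chain = chain_settings(), jitter_sd = 0.03,
                            efficacy_sd = 0.5, stimulus_set = NULL) {
  config <- validate_sim_config(config)
  if (is.null(stimulus_set))
    stimulus_set <- make_stimulus_set(seed = config$seed %% 10000L + 1L)
  master <- as.numeric(config$seed)
  labels <- group_labels()
  for (lb in labels) scenario_row(scenario, lb)
  participants <- list()
  pidx <- 0L
  for (lb in labels) {
    grp <- group_from_label(lb)
    for (k in seq_len(config$n_per_group)) {
      pidx <- pidx + 1L
      pid <- sprintf("sub-%03d", pidx)
      pseed <- as.integer((master * 2003 + pidx * 97) %% 2147483629)
      set.seed(pseed)
      base <- default_neural_params(grp, b_scale = 1, jitter_sd = jitter_sd)
      efficacy <- min(2, max(0, rnorm(1, 1, efficacy_sd)))
      psych <- draw_psychometrics(scenario$psych_shift)
      faces <- assign_faces(pseed + 1L, stimulus_set,
                            n_blocks = config$n_blocks_per_kind,
                            n_runs = config$n_runs)
      runs <- vector("list", config$n_runs)
      for (run in seq_len(config$n_runs)) {
        bs <- scenario$b_scale[lb, run]
        prun <- base
        prun$B_face <- base$B_face * bs
        prun$B_int <- base$B_int * bs
        rseed <- as.integer((master * 1009 + pidx * 131 + run * 7) %%
                              2147483629)
        runs[[run]] <- simulate_run_closed_loop(
          prun, grp, config, chain,
          reg_amp = efficacy * scenario$reg_amp[lb, run],
          reg_hab = efficacy * scenario$habituation[lb, run],
          seed = rseed)
      }
      participants[[pidx]] <- list(id = pid, group = grp, params = base,
                                   efficacy = efficacy, runs = runs,
                                   psych = psych, faces = faces)
    }
  }
  structure(list(participants = participants, config = config,
                 scenario = scenario, stimulus_set = stimulus_set),
            class = "cohort_dataset")
}

draw_psychometrics <- function(shift) {
  pre <- c(panas_pos = rnorm(1, 30, 5), panas_neg = rnorm(1, 15, 4),
           sds = rnorm(1, 35, 7))
  post <- pre + shift[names(pre)] + rnorm(3, 0, 2)
  data.frame(scale = names(pre), pre = as.numeric(pre),
             post = as.numeric(post), row.names = NULL)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(vapply(x$participants, function(p) p$group$label, ""))
  cat(sprintf("<cohort_dataset> %d participants (%s), %d runs each, seed %d\n",
              length(x$participants),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              x$config$n_runs, x$config$seed))
  invisible(x)
}
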