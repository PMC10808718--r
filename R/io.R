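#' Experiment configuration
#'
#' A serializable bundle of the simulation configuration, chain settings,
#' scenario name and master seed. Round-trips losslessly through YAML;
#' unknown keys are rejected on read.
#'
#' @param sim a [sim_config()].
#' @param chain a [chain_settings()].
#' @param scenario scenario name ("study" or "null").
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(), chain = chain_settings(),
                              scenario = "study") {
  structure(list(sim = unclass(sim), chain = unclass(chain),
                 scenario = scenario),
            class = "experiment_config")
}

#' Write an experiment configuration to a YAML file
#' @param config an [experiment_config()].
#' @param path output file path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read an experiment configuration back from YAML
#'
#' @param path file written by [write_experiment_config()].
#' @return An `experiment_config`; unknown keys raise an error.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("sim", "chain", "scenario")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) .stopf("unknown config keys: %s",
                            paste(extra, collapse = ", "))
  sim_keys <- names(formals(sim_config))
  chain_keys <- names(formals(chain_settings))
  bad_sim <- setdiff(names(raw$sim), sim_keys)
  bad_chain <- setdiff(names(raw$chain), chain_keys)
  if (length(bad_sim) || length(bad_chain))
    .stopf("unknown config keys: %s",
           paste(c(bad_sim, bad_chain), collapse = ", "))
  experiment_config(do.call(sim_config, raw$sim),
                    do.call(chain_settings, raw$chain),
                    raw$scenario %||% "study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seed_header <- function(seed) {
  sprintf("# faceloop %s seed=%d",
          as.character(utils::packageVersion("faceloop")), seed)
}

write_tsv_with_header <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(seed_header(seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by this package (skipping the seed
#' header comment)
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write a run's events file (BIDS events dialect)
#'
#' Columns onset, duration, trial_type in seconds, time origin at the first
#' retained volume.
#'
#' @param design a [make_block_design()] result.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @export
write_events_tsv <- function(design, path, seed = 0L) {
  ev <- data.frame(onset = design$blocks$onset,
                   duration = design$blocks$duration,
                   trial_type = design$blocks$kind)
  write_tsv_with_header(ev, path, seed)
}

#' Write a run's per-volume table (ROI series, chain trace, morph, inputs,
#' motion)
#' @param run a `run_recording`.
#' @param path output path.
#' @export
write_roi_tsv <- function(run, path) {
  write_tsv_with_header(run$volumes, path, run$seed)
}

#' Simulate a cohort and write it to a dataset directory
#'
#' Writes, per participant and run, an events TSV, a per-volume ROI/trace
#' TSV, plus `participants.tsv` (group and psychometric scores),
#' `ground_truth.jsonl` (one JSON record of neural parameters per
#' participant), the experiment config, and `manifest.json` with the master
#' seed, package version and file counts.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return the cohort (invisibly); side effect: files under `out_dir`.
#' @export
simulate_dataset <- function(config = experiment_config(), out_dir,
                             force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    .stopf("output directory '%s' is not empty (use force = TRUE)", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- do.call(sim_config, config$sim)
  chain <- do.call(chain_settings, config$chain)
  cohort <- simulate_cohort(sim, effect_scenario(config$scenario), chain)
  n_files <- 0L
  gt_con <- file(file.path(out_dir, "ground_truth.jsonl"), "w")
  prows <- list()
  for (p in cohort$participants) {
    for (run in seq_along(p$runs)) {
      rec <- p$runs[[run]]
      stem <- sprintf("%s_run-%d", p$id, run)
      write_events_tsv(rec$design,
                       file.path(out_dir, paste0(stem, "_events.tsv")),
                       rec$seed)
      write_roi_tsv(rec, file.path(out_dir, paste0(stem, "_roi.tsv")))
      n_files <- n_files + 2L
    }
    writeLines(jsonlite::toJSON(list(
      id = p$id, group = p$group$label,
      A = p$params$A, B_face = p$params$B_face,
      B_int = p$params$B_int, C = p$params$C), digits = NA), gt_con)
    prows[[length(prows) + 1L]] <- data.frame(
      participant = p$id, group = p$group$label,
      condition = p$group$condition, direction = p$group$direction,
      congruent = p$group$congruent,
      panas_pos_pre = p$psych$pre[1], panas_pos_post = p$psych$post[1],
      panas_neg_pre = p$psych$pre[2], panas_neg_post = p$psych$post[2],
      sds_pre = p$psych$pre[3], sds_post = p$psych$post[3])
  }
  close(gt_con)
  write_tsv_with_header(do.call(rbind, prows),
                        file.path(out_dir, "participants.tsv"), sim$seed)
  write_experiment_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list(seed = sim$seed,
                   package = "faceloop",
                   version = as.character(utils::packageVersion("faceloop")),
                   n_participants = length(cohort$participants),
                   n_runs = sim$n_runs,
                   n_run_records = length(cohort$participants) * sim$n_runs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

#' Load a dataset directory back into a cohort-like structure
#'
#' Reads the per-run tables written by [simulate_dataset()]. Missing files
#' are enumerated in the error message.
#'
#' @param dataset_dir directory written by [simulate_dataset()].
#' @return list with `participants` (id, group, runs as data.frames),
#'   `config`, `manifest`.
#' @export
read_dataset <- function(dataset_dir) {
  man_path <- file.path(dataset_dir, "manifest.json")
  cfg_path <- file.path(dataset_dir, "config.yaml")
  part_path <- file.path(dataset_dir, "participants.tsv")
  missing <- c(man_path, cfg_path, part_path)[!file.exists(
    c(man_path, cfg_path, part_path))]
  if (length(missing))
    .stopf("missing dataset files: %s", paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(man_path)
  config <- read_experiment_config(cfg_path)
  ptab <- read_tsv_table(part_path)
  sim <- do.call(sim_config, config$sim)
  participants <- lapply(seq_len(nrow(ptab)), function(i) {
    pid <- ptab$participant[i]
    runs <- lapply(seq_len(sim$n_runs), function(run) {
      f <- file.path(dataset_dir, sprintf("%s_run-%d_roi.tsv", pid, run))
      if (!file.exists(f)) .stopf("missing dataset files: %s", f)
      read_tsv_table(f)
    })
    list(id = pid, group = group_from_label(ptab$group[i]), runs = runs,
         psych = data.frame(
           scale = c("panas_pos", "panas_neg", "sds"),
           pre = as.numeric(ptab[i, c("panas_pos_pre", "panas_neg_pre",
                                      "sds_pre")]),
           post = as.numeric(ptab[i, c("panas_pos_post", "panas_neg_post",
                                       "sds_post")])))
  })
  list(participants = participants, config = config, manifest = manifest,
       sim = sim)
}

#' Run the offline analysis chain on a dataset directory
#'
#' Recomputes block betas and habituation slopes from the stored
#' Kalman-processed traces, fits the run-by-group mixed models per
#' condition, the habituation t-tests, and the psychometric mixed models,
#' and writes CSV results plus a run log.
#'
#' @param dataset_dir directory written by [simulate_dataset()].
#' @param out_dir results directory (default `<dataset_dir>/results`).
#' @return list of the result tables (invisibly).
#' @export
analyze_dataset <- function(dataset_dir, out_dir = file.path(dataset_dir,
                                                             "results")) {
  ds <- read_dataset(dataset_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- ds$sim
  design <- make_block_design(sim)
  hrf <- build_chrf(tr = sim$tr, dt = sim$integration_dt)
  rows <- list()
  for (p in ds$participants) {
    for (run in seq_along(p$runs)) {
      betas <- extract_block_betas(p$runs[[run]]$despiked, design, hrf)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p$id, group = p$group$label,
        condition = p$group$condition, congruent = p$group$congruent,
        run = run, block = seq_along(betas), beta = as.numeric(betas))
    }
  }
  betas <- do.call(rbind, rows)
  slopes <- habituation_slopes(betas)
  hab <- test_habituation(slopes)
  seed <- sim$seed
  write_csv_with_header(betas, file.path(out_dir, "block_betas.csv"), seed,
                        "beta in processed-signal units")
  write_csv_with_header(slopes, file.path(out_dir, "habituation_slopes.csv"),
                        seed, "slope in beta units per block")
  write_csv_with_header(hab, file.path(out_dir, "habituation_tests.csv"),
                        seed, "one-sample t vs 0, df = n - 1")
  log <- c(seed_header(seed),
           sprintf("participants: %d", length(ds$participants)),
           "block betas: despiked (Kalman-processed) trace, motion excluded",
           "LMM: per-run mean beta ~ run * group + (1 | participant), REML,",
           "  Satterthwaite df, run 1 and congruent group as references")
  lmms <- list()
  psych <- do.call(rbind, lapply(ds$participants, function(p)
    data.frame(participant = p$id, group = p$group$label,
               congruent = p$group$congruent, scale = p$psych$scale,
               pre = p$psych$pre, post = p$psych$post)))
  for (cond in c("happy", "fear")) {
    res <- fit_condition_lmm(betas, cond)
    lmms[[cond]] <- res
    write_csv_with_header(res$fixed,
                          file.path(out_dir, sprintf("lmm_%s.csv", cond)),
                          seed, sprintf("condition %s, %s", cond,
                                        res$method))
    log <- c(log, sprintf("condition %s: method %s", cond, res$method))
    for (sc in c("panas_pos", "panas_neg", "sds")) {
      pres <- fit_psychometric_lmm(psych, sc, cond)
      write_csv_with_header(
        pres$fixed,
        file.path(out_dir, sprintf("psych_%s_%s.csv", cond, sc)),
        seed, sprintf("scale %s, condition %s, %s", sc, cond, pres$method))
    }
  }
  writeLines(log, file.path(out_dir, "analysis_log.txt"))
  invisible(list(betas = betas, slopes = slopes, habituation = hab,
                 lmm = lmms))
}

write_csv_with_header <- function(df, path, seed, note = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(seed_header(seed), note), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by the analysis pipeline (skipping the seed header)
#' @param path file path.
#' @return data.frame.
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the DCM/BMA stage on a dataset directory
#'
#' Re-simulating nothing, this reconstructs each selected run's inputs from
#' the stored tables, inverts the requested model space per subject and
#' run, and writes a model-space manifest, a BMA table in the standard
#' connection x run layout, and group-comparison t-tables for the FFA->Amy
#' and mOFC->Amy totals.
#'
#' @param dataset_dir directory written by [simulate_dataset()].
#' @param out_dir results directory.
#' @param models "full" (128 models) or "reduced".
#' @param n_models model count when `models = "reduced"`.
#' @param runs runs to analyse (default 1 and 4).
#' @param groups group labels to analyse (default all four).
#' @return list with per-group BMA tables and comparisons (invisibly).
#' @export
dcm_dataset <- function(dataset_dir, out_dir = file.path(dataset_dir,
                                                         "dcm"),
                        models = c("reduced", "full"), n_models = 8,
                        runs = c(1, 4), groups = group_labels()) {
  models <- match.arg(models)
  ds <- read_dataset(dataset_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- if (models == "full") enumerate_model_space() else
    reduced_model_space(n_models)
  if (models == "reduced" && n_models > 128) .stopf("model subset out of range")
  manifest <- data.frame(
    model_id = vapply(space, `[[`, 0L, "id"),
    mask = vapply(space, function(m)
      paste(as.integer(m$bits), collapse = ""), ""))
  seed <- ds$sim$seed
  write_csv_with_header(manifest, file.path(out_dir, "model_space.csv"),
                        seed, "7-bit edge mask over candidate connections")
  sim <- ds$sim
  hrf <- build_chrf(tr = sim$tr, dt = sim$integration_dt)
  n_lead <- sim$n_dummy
  tables <- list()
  totals <- list()
  for (g in groups) {
    parts <- Filter(function(p) p$group$label == g, ds$participants)
    if (!length(parts)) .stopf("no participants in group '%s'", g)
    analysis <- list()
    for (run in runs) {
      fits <- lapply(parts, function(p) {
        d <- p$runs[[run]]
        data <- t(as.matrix(d[, ROI_NAMES]))
        uf <- c(rep(0, n_lead), d$u_face)
        ui <- c(rep(0, n_lead), d$u_int)
        f <- lapply(space, function(m)
          invert_dcm(m, data, uf, ui, hrf, sim$tr, n_lead = n_lead))
        list(fits = f, F = vapply(f, `[[`, 0, "F"))
      })
      Fm <- do.call(rbind, lapply(fits, `[[`, "F"))
      w <- model_weights(Fm)
      res <- bma(lapply(fits, `[[`, "fits"), w)
      analysis[[as.character(run)]] <- list(bma = res, F_matrix = Fm)
      for (e in c("FFA->Amy", "mOFC->Amy")) {
        ei <- match(e, DCM_EDGES$name)
        ti <- DCM_EDGES$target[ei]; si <- DCM_EDGES$source[ei]
        totals[[length(totals) + 1L]] <- data.frame(
          connection = e, group = g, run = run,
          participant = vapply(parts, `[[`, "", "id"),
          value = vapply(res$subjects, function(s) s$total[ti, si], 0))
      }
    }
    tables[[g]] <- bma_table(analysis, g)
  }
  big <- do.call(rbind, tables)
  write_csv_with_header(big, file.path(out_dir, "bma_table.csv"), seed,
                        "A/B1/B2/total per connection; SD is between-subject")
  tot <- do.call(rbind, totals)
  comps <- list()
  for (e in unique(tot$connection)) {
    d <- tot[tot$connection == e, ]
    cc <- compare_connectivity(
      data.frame(participant = d$participant, group = d$group,
                 run = d$run, value = d$value), runs = runs)
    cc$within$connection <- e
    cc$between$connection <- e
    comps[[e]] <- cc
  }
  within <- do.call(rbind, lapply(comps, `[[`, "within"))
  between <- do.call(rbind, lapply(comps, `[[`, "between"))
  write_csv_with_header(within, file.path(out_dir, "dcm_within_group.csv"),
                        seed, "paired t, run comparisons of totals")
  write_csv_with_header(between, file.path(out_dir, "dcm_between_group.csv"),
                        seed, "Welch and paired-style variants reported")
  invisible(list(bma = tables, within = within, between = between,
                 manifest = manifest))
}
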