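#' Build the alternating baseline/regulation block design for one run
#'
#' Blocks strictly alternate starting with baseline. Onsets are in seconds
#' with the time origin at the first retained (post-dummy) volume. The
#' volume count is derived from the design (plus dummies and any optional
#' rest padding), not fixed to an acquisition constant.
#'
#' @param config a [sim_config()].
#' @return An object of class `block_design`: a list with `blocks` (a
#'   data.frame of onset, duration, kind), `n_volumes` (total including
#'   dummies), `dummy_volumes`, and `task_duration` in seconds.
#' @export
#' @examples
#' d <- make_block_design(sim_config())
#' d$task_duration  # 240
make_block_design <- function(config) {
  config <- validate_sim_config(config)
  nb <- config$n_blocks_per_kind
  onset <- config$rest_pre
  rows <- vector("list", 2L * nb)
  for (i in seq_len(nb)) {
    rows[[2L * i - 1L]] <- data.frame(onset = onset,
                                      duration = config$baseline_len,
                                      kind = "baseline")
    onset <- onset + config$baseline_len
    rows[[2L * i]] <- data.frame(onset = onset,
                                 duration = config$regulation_len,
                                 kind = "regulation")
    onset <- onset + config$regulation_len
  }
  blocks <- do.call(rbind, rows)
  task_duration <- onset + config$rest_post
  n_task_vol <- task_duration / config$tr
  if (abs(n_task_vol - round(n_task_vol)) > 1e-9)
    .stopf("task duration (%g s) is not a whole number of TRs", task_duration)
  structure(list(blocks = blocks,
                 n_volumes = as.integer(round(n_task_vol)) + config$n_dummy,
                 dummy_volumes = config$n_dummy,
                 task_duration = task_duration,
                 tr = config$tr),
            class = "block_design")
}

#' Per-volume block labels for a design
#'
#' @param design a [make_block_design()] result.
#' @return Character vector, one entry per retained volume: "baseline",
#'   "regulation", or "rest" (padding).
#' @export
volume_conditions <- function(design) {
  n_task <- design$n_volumes - design$dummy_volumes
  times <- (seq_len(n_task) - 1L) * design$tr  # volume start times
  lab <- rep("rest", n_task)
  for (i in seq_len(nrow(design$blocks))) {
    b <- design$blocks[i, ]
    inb <- times >= b$onset - 1e-9 & times < b$onset + b$duration - 1e-9
    lab[inb] <- b$kind
  }
  lab
}

#' Index of the regulation block (1..n) each retained volume falls in, NA
#' outside regulation blocks.
#' @param design a [make_block_design()] result.
#' @return Integer vector, one entry per retained volume.
#' @export
regulation_block_index <- function(design) {
  n_task <- design$n_volumes - design$dummy_volumes
  times <- (seq_len(n_task) - 1L) * design$tr
  idx <- rep(NA_integer_, n_task)
  reg <- design$blocks[design$blocks$kind == "regulation", , drop = FALSE]
  for (i in seq_len(nrow(reg))) {
    b <- reg[i, ]
    idx[times >= b$onset - 1e-9 & times < b$onset + b$duration - 1e-9] <- i
  }
  idx
}
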