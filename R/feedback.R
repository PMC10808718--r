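#' Map a normalized amygdala signal to a discrete morph index
#'
#' The face continuum has 31 display states, indices 0..30: 0 is the
#' neutral expression (0% valence) and 30 the full emotional expression
#' (100%). For the positive loop polarity (task-congruent groups) a higher
#' normalized signal yields a higher index; the negative polarity mirrors
#' the mapping. Rounding is half-away-from-zero so 0.5 * 30 maps to 15 on
#' every platform.
#'
#' @param normalized value in [0, 1].
#' @param polarity +1 or -1.
#' @return integer morph index in 0..30.
#' @export
#' @examples
#' signal_to_morph_index(1, +1)  # 30
#' signal_to_morph_index(1, -1)  # 0
signal_to_morph_index <- function(normalized, polarity = 1L) {
  if (!is.finite(normalized) || normalized < 0 || normalized > 1)
    .stopf("normalized signal must lie in [0, 1]")
  if (!polarity %in% c(-1L, 1L, -1, 1)) .stopf("polarity must be +1 or -1")
  s <- if (polarity > 0) normalized else 1 - normalized
  as.integer(floor(30 * s + 0.5)) # half-away-from-zero for s >= 0
}

#' A synthetic face stimulus set
#'
#' Stand-in for a photographic face database: each face is an abstract
#' parameter vector (landmark-like coordinates) in a neutral and a fully
#' emotional configuration, so the geometry of morphing is testable without
#' images. Genders are balanced as `floor(n/2)` female.
#'
#' @param n number of faces.
#' @param n_params length of each parameter vector.
#' @param seed integer seed.
#' @return data.frame with id, gender and parameter columns
#'   (`neutral_1..k`, `emotional_1..k`).
#' @export
make_stimulus_set <- function(n = 30, n_params = 8, seed = 1L) {
  set.seed(seed)
  gender <- rep(c("f", "m"), length.out = n)
  neutral <- matrix(rnorm(n * n_params), n)
  emotional <- neutral + matrix(rnorm(n * n_params, 1, 0.5), n)
  out <- data.frame(id = sprintf("face-%02d", seq_len(n)), gender = gender)
  colnames(neutral) <- paste0("neutral_", seq_len(n_params))
  colnames(emotional) <- paste0("emotional_", seq_len(n_params))
  cbind(out, neutral, emotional)
}

#' Linearly blend a face between its neutral and emotional configuration
#'
#' @param face one row of a stimulus set (or a list with `neutral_params`
#'   and `emotional_params` numeric vectors of equal length).
#' @param morph_index integer in 0..30.
#' @return blended numeric parameter vector.
#' @export
blend_face <- function(face, morph_index) {
  if (!is.finite(morph_index) || morph_index < 0 || morph_index > 30)
    .stopf("morph_index must lie in 0..30")
  if (is.data.frame(face)) {
    neutral <- as.numeric(face[grep("^neutral_", names(face))])
    emotional <- as.numeric(face[grep("^emotional_", names(face))])
  } else {
    neutral <- face$neutral_params
    emotional <- face$emotional_params
  }
  if (length(neutral) != length(emotional) || length(neutral) == 0)
    .stopf("neutral and emotional parameter vectors must have equal length")
  w <- morph_index / 30
  (1 - w) * neutral + w * emotional
}

#' Assign unique, gender-balanced faces to a participant's blocks
#'
#' One face per regulation block: `n_blocks * n_runs` distinct identities
#' per participant (no repeats across runs), with equal numbers of male and
#' female faces.
#'
#' @param seed integer seed for the participant's permutation.
#' @param stimulus_set a [make_stimulus_set()] data.frame.
#' @param n_blocks regulation blocks per run.
#' @param n_runs runs per participant.
#' @return character vector of face ids, length n_blocks * n_runs, in
#'   presentation order.
#' @export
assign_faces <- function(seed, stimulus_set, n_blocks = 4, n_runs = 4) {
  need <- n_blocks * n_runs
  if (need %% 2L != 0L) .stopf("need an even number of blocks for gender balance")
  half <- need %/% 2L
  f <- stimulus_set$id[stimulus_set$gender == "f"]
  m <- stimulus_set$id[stimulus_set$gender == "m"]
  if (length(f) < half || length(m) < half)
    .stopf("stimulus set too small: need %d faces per gender, have %d f / %d m",
           half, length(f), length(m))
  set.seed(seed)
  chosen <- c(sample(f, half), sample(m, half))
  sample(chosen, need)
}
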