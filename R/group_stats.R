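#' Run-by-group linear mixed model for one condition
#'
#' For one emotion condition (its congruent and incongruent group), the
#' per-run mean amygdala beta (mean of the four block betas) is modelled
#' with run, group and their interaction as fixed effects and a random
#' intercept per participant, fitted by REML with Satterthwaite denominator
#' degrees of freedom (lmerTest). Treatment coding uses run 1 and the
#' task-congruent group as references. If the fit is singular the model is
#' refit as ordinary least squares with a warning and residual df.
#'
#' @param betas a [block_beta_table()] data.frame restricted to (or
#'   containing) one condition.
#' @param condition "happy" or "fear".
#' @return An object of class `lmm_result`: list with `fixed` (term,
#'   estimate, se, df, t, p), `anova` (F tests), `varcor`, `method`,
#'   `model`.
#' @export
fit_condition_lmm <- function(betas, condition = c("happy", "fear")) {
  condition <- match.arg(condition)
  d <- betas[betas$condition == condition, , drop = FALSE]
  if (!nrow(d)) .stopf("no rows for condition '%s'", condition)
  d <- aggregate(beta ~ participant + group + congruent + run, d, mean)
  if (length(unique(d$run)) < 2L) .stopf("at least 2 runs required")
  if (length(unique(d$participant)) < 2L)
    .stopf("at least 2 participants required")
  d$run <- factor(d$run)
  # congruent group as the reference level
  glev <- unique(d[, c("group", "congruent")])
  ref <- glev$group[glev$congruent][1L]
  d$group <- stats::relevel(factor(d$group), ref = ref)
  fit_lmm_table(beta ~ run * group + (1 | participant), d)
}

# shared REML + Satterthwaite fitting path, with an OLS fallback for
# singular fits
fit_lmm_table <- function(formula, data) {
  fit <- suppressMessages(
    lmerTest::lmer(formula, data = data, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE)))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular mixed-model fit; falling back to OLS with residual df")
    fixed_form <- lme4::nobars(formula)
    ols <- lm(fixed_form, data = data)
    sm <- summary(ols)$coefficients
    fixed <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], df = ols$df.residual, t = sm[, 3],
                        p = sm[, 4], row.names = NULL)
    return(structure(list(fixed = fixed, anova = anova(ols),
                          varcor = NULL, method = "OLS-fallback",
                          model = ols),
                     class = "lmm_result"))
  }
  sm <- coef(summary(fit))  # Satterthwaite df from lmerTest
  fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  an <- suppressMessages(stats::anova(fit))  # Satterthwaite type III
  structure(list(fixed = fixed, anova = an,
                 varcor = as.data.frame(lme4::VarCorr(fit)),
                 method = "REML-Satterthwaite", model = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> (%s)\n", x$method))
  f <- x$fixed
  f$estimate <- round(f$estimate, 3); f$se <- round(f$se, 3)
  f$df <- round(f$df, 1); f$t <- round(f$t, 2); f$p <- signif(f$p, 3)
  print(f, row.names = FALSE)
  invisible(x)
}

#' Group-level habituation tests
#'
#' Per group and run, a two-sided one-sample t-test of the participant
#' habituation slopes against zero (df = group size - 1). Groups with zero
#' slope variance are flagged as degenerate (t undefined).
#'
#' @param slopes a [habituation_slopes()] data.frame.
#' @return data.frame (group, run, n, mean_slope, sd, t, df, p, degenerate).
#' @export
test_habituation <- function(slopes) {
  key <- interaction(slopes$group, slopes$run, drop = TRUE)
  rows <- lapply(split(slopes, key), function(d) {
    n <- nrow(d)
    if (n < 2L) .stopf("fewer than 2 participants in %s run %d",
                       d$group[1L], d$run[1L])
    s <- sd(d$slope)
    if (s < 1e-12) {
      # identically-zero slopes are a clean null (t = 0); equal nonzero
      # slopes leave t undefined and are flagged
      zero <- abs(mean(d$slope)) < 1e-12
      return(data.frame(group = d$group[1L], run = d$run[1L], n = n,
                        mean_slope = mean(d$slope), sd = s,
                        t = if (zero) 0 else NA_real_,
                        df = n - 1L, p = if (zero) 1 else NA_real_,
                        degenerate = !zero))
    }
    tt <- t.test(d$slope, mu = 0)
    data.frame(group = d$group[1L], run = d$run[1L], n = n,
               mean_slope = mean(d$slope), sd = s,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$run), ]
}

#' Pre/post psychometric mixed model
#'
#' Per scale (PANAS positive, PANAS negative, SDS) and condition, a mixed
#' model of the score on time (pre vs post), group congruency and their
#' interaction, with a random intercept per participant. Participants with
#' a missing timepoint are dropped with a warning.
#'
#' @param scores data.frame with columns participant, group, congruent,
#'   scale, pre, post (as produced by [psychometric_table()]).
#' @param scale one of "panas_pos", "panas_neg", "sds".
#' @param condition "happy" or "fear"; participants of other conditions are
#'   ignored.
#' @return An `lmm_result`.
#' @export
fit_psychometric_lmm <- function(scores, scale = c("panas_pos", "panas_neg",
                                                   "sds"),
                                 condition = c("happy", "fear")) {
  scale <- match.arg(scale)
  condition <- match.arg(condition)
  d <- scores[scores$scale == scale &
                startsWith(scores$group, condition), , drop = FALSE]
  if (!nrow(d)) .stopf("no rows for scale '%s' in condition '%s'",
                       scale, condition)
  miss <- !complete.cases(d[, c("pre", "post")])
  if (any(miss)) {
    warning(sprintf("dropping %d participant(s) with a missing timepoint",
                    sum(miss)))
    d <- d[!miss, , drop = FALSE]
  }
  long <- rbind(
    data.frame(participant = d$participant, group = d$group,
               congruent = d$congruent, time = "pre", score = d$pre),
    data.frame(participant = d$participant, group = d$group,
               congruent = d$congruent, time = "post", score = d$post))
  long$time <- factor(long$time, levels = c("pre", "post"))
  long$group <- factor(ifelse(long$congruent, "congruent", "incongruent"),
                       levels = c("congruent", "incongruent"))
  fit_lmm_table(score ~ time * group + (1 | participant), long)
}

#' Psychometric score table of a cohort
#'
#' @param cohort a [simulate_cohort()] dataset.
#' @return data.frame (participant, group, congruent, scale, pre, post).
#' @export
psychometric_table <- function(cohort) {
  do.call(rbind, lapply(cohort$participants, function(p) {
    data.frame(participant = p$id, group = p$group$label,
               congruent = p$group$congruent, scale = p$psych$scale,
               pre = p$psych$pre, post = p$psych$post)
  }))
}

#' Compare connectivity summaries within and between groups
#'
#' Within each group, a paired t-test of the per-participant connection
#' values between two runs (df = n - 1). Between groups, each pair is
#' compared on the later run's values twice: with a Welch two-sample
#' t-test, and with a "paired-style" statistic that plugs the two group
#' summaries into `(m1 - m2) / sqrt((s1^2 + s2^2)/n)` with df = n - 1
#' (the convention used in the source literature for these tables; it
#' assumes an independence surrogate for the unprinted pairing covariance).
#' Both are reported.
#'
#' @param values data.frame with columns participant, group, run, value
#'   (one row per participant x run for a single connection).
#' @param runs length-2 vector of run labels to compare (default 1 and 4).
#' @return list with `within` and `between` data.frames.
#' @export
compare_connectivity <- function(values, runs = c(1, 4)) {
  stopifnot(length(runs) == 2L)
  d1 <- values[values$run == runs[1L], ]
  d2 <- values[values$run == runs[2L], ]
  groups <- sort(unique(values$group))
  within <- do.call(rbind, lapply(groups, function(g) {
    a <- d1[d1$group == g, ]
    b <- d2[d2$group == g, ]
    a <- a[order(a$participant), ]; b <- b[order(b$participant), ]
    if (nrow(a) != nrow(b) || !all(a$participant == b$participant))
      .stopf("unbalanced pairs in group %s", g)
    if (sd(b$value - a$value) < 1e-12) {
      return(data.frame(group = g, n = nrow(a),
                        mean_run1 = mean(a$value), mean_run2 = mean(b$value),
                        t = 0, df = nrow(a) - 1L, p = 1))
    }
    tt <- t.test(b$value, a$value, paired = TRUE)
    data.frame(group = g, n = nrow(a), mean_run1 = mean(a$value),
               mean_run2 = mean(b$value), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  pairs <- if (length(groups) > 1L) utils::combn(groups, 2L) else
    matrix(character(0), 2, 0)
  between <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    a <- d2$value[d2$group == g1]
    b <- d2$value[d2$group == g2]
    welch <- t.test(a, b)
    n <- min(length(a), length(b))
    t_pair <- (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / n)
    data.frame(group1 = g1, group2 = g2, run = runs[2L],
               mean1 = mean(a), sd1 = sd(a), mean2 = mean(b), sd2 = sd(b),
               t_welch = unname(welch$statistic),
               df_welch = unname(welch$parameter), p_welch = welch$p.value,
               t_paired_style = t_pair, df_paired_style = n - 1L,
               p_paired_style = 2 * pt(-abs(t_pair), n - 1L))
  }))
  list(within = within, between = between)
}

#' Optional Holm correction column
#'
#' Adds `p_holm` to any results table with a `p` column. The primary
#' reporting is uncorrected; this is an opt-in.
#'
#' @param table data.frame with a `p` column.
#' @return the table with an extra `p_holm` column.
#' @export
add_holm <- function(table) {
  if (!"p" %in% names(table)) .stopf("no p column")
  table$p_holm <- stats::p.adjust(table$p, method = "holm")
  table
}
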