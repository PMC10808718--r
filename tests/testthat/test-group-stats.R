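test_that("the condition LMM uses run 1 and the congruent group as
           references with Satterthwaite df near the balanced closed form", {
  set.seed(41)
  d <- make_beta_table(n = 16)
  res <- fit_condition_lmm(d, "fear")
  expect_equal(res$method, "REML-Satterthwaite")
  expect_equal(nrow(res$fixed), 8)  # 1 + 3 + 1 + 3
  # balanced random-intercept design: within-subject df = 2*16*3 - 3 - 3 = 90
  run_rows <- grepl("^run", res$fixed$term) & !grepl(":", res$fixed$term)
  expect_equal(res$fixed$df[run_rows], rep(90, 3), tolerance = 0.02)
  # reference = congruent fear-down group: its label is absorbed
  expect_false(any(grepl("fear-down", res$fixed$term)))
  expect_true(all(res$fixed$p >= 0 & res$fixed$p <= 1))
  expect_equal(res$fixed$t, res$fixed$estimate / res$fixed$se,
               tolerance = 1e-8)
})

test_that("a noiseless fixed-effect pattern is recovered exactly", {
  set.seed(42)
  d <- make_beta_table(n = 6, run_effects = c(0, -0.2, -0.5, -0.5),
                       group_effect = 0.3, subj_sd = 0, resid_sd = 0)
  res <- suppressWarnings(fit_condition_lmm(d, "fear"))
  est <- setNames(res$fixed$estimate, res$fixed$term)
  expect_equal(unname(est["run2"]), -0.2, tolerance = 1e-6)
  expect_equal(unname(est["run3"]), -0.5, tolerance = 1e-6)
  g_term <- grep("group", names(est), value = TRUE)
  g_term <- g_term[!grepl(":", g_term)]
  expect_equal(unname(est[g_term]), 0.3, tolerance = 1e-6)
})

test_that("the LMM rejects degenerate designs", {
  set.seed(43)
  d <- make_beta_table(n = 16)
  expect_error(fit_condition_lmm(d[d$run == 1, ], "fear"), "2 runs")
  expect_error(fit_condition_lmm(d[0, ], "fear"), "no rows")
})

test_that("habituation t-tests carry df = n - 1 and flag degenerate input", {
  mk <- function(slopes) data.frame(
    participant = sprintf("s%02d", seq_along(slopes)), group = "fear-down",
    run = 4L, slope = slopes, intercept = 0)
  z <- test_habituation(mk(rep(0, 16)))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_false(z$degenerate)
  cst <- test_habituation(mk(rep(-0.5, 16)))
  expect_true(cst$degenerate)
  expect_true(is.na(cst$t))
  expect_equal(cst$df, 15)
  set.seed(44)
  r <- test_habituation(mk(rnorm(16, -0.8, 0.85)))
  expect_equal(r$df, 15)
  expect_error(test_habituation(mk(numeric(1))), "fewer than 2")
})

test_that("the habituation t statistic sits in its analytic regime", {
  # slopes ~ -0.8 + N(0, 0.85), n = 16: E[t] ~= -0.8 / (0.85/4) = -3.76
  set.seed(45)
  ts <- replicate(1000, {
    s <- rnorm(16, -0.8, 0.85)
    mean(s) / (sd(s) / 4)
  })
  expect_equal(mean(ts), -3.76, tolerance = 0.08)
})

test_that("psychometric LMMs recover injected time effects", {
  base <- data.frame(participant = sprintf("s%02d", 1:8),
                     group = rep(c("fear-down", "fear-up"), each = 4),
                     congruent = rep(c(TRUE, FALSE), each = 4),
                     scale = "sds", pre = seq(30, 44, by = 2))
  same <- transform(base, post = pre)
  r0 <- suppressWarnings(fit_psychometric_lmm(same, "sds", "fear"))
  t_row <- r0$fixed$term == "timepost"
  expect_equal(r0$fixed$estimate[t_row], 0, tolerance = 1e-8)
  up <- transform(base, post = pre + 5)
  r5 <- suppressWarnings(fit_psychometric_lmm(up, "sds", "fear"))
  expect_equal(r5$fixed$estimate[r5$fixed$term == "timepost"], 5,
               tolerance = 1e-6)
  # a missing timepoint drops the participant with a warning
  holes <- up
  holes$post[1] <- NA
  expect_warning(fit_psychometric_lmm(holes, "sds", "fear"), "missing")
})

test_that("connectivity comparisons report paired, Welch and
           paired-style variants", {
  set.seed(46)
  vals <- expand.grid(participant = sprintf("s%02d", 1:16),
                      group = c("happy-up", "happy-down"), run = c(1, 4))
  vals$value <- rnorm(nrow(vals), 0.3, 0.2)
  cc <- compare_connectivity(vals)
  expect_equal(nrow(cc$within), 2)
  expect_equal(cc$within$df, c(15, 15))
  expect_equal(nrow(cc$between), 1)
  expect_equal(cc$between$df_paired_style, 15)
  # identical run values give a zero paired t
  same <- vals
  same$value <- rep(seq_len(32) / 10, 2)
  cc0 <- compare_connectivity(same)
  expect_equal(cc0$within$t, c(0, 0))
  expect_equal(cc0$within$p, c(1, 1))
})

test_that("plugging printed group summaries into the paired-style formula
           reproduces the reported magnitude regime", {
  # construct samples with exactly M = 0.83, SD = 0.21 and M = 0.19,
  # SD = 0.23 at n = 16, then compare on the later run
  set.seed(47)
  mk <- function(m, s, g) {
    x <- rnorm(16)
    x <- (x - mean(x)) / sd(x) * s + m
    data.frame(participant = sprintf("%s%02d", g, 1:16), group = g,
               run = 4, value = x)
  }
  d <- rbind(mk(0.83, 0.21, "happy-up"), mk(0.19, 0.23, "happy-down"),
             transform(mk(0.5, 0.2, "happy-up"), run = 1),
             transform(mk(0.5, 0.2, "happy-down"), run = 1))
  cc <- compare_connectivity(d)
  t_ref <- 8.30
  expect_gt(abs(cc$between$t_paired_style), t_ref * 0.8)
  expect_lt(abs(cc$between$t_paired_style), t_ref * 1.2)
  expect_equal(cc$between$df_paired_style, 15)
})

test_that("small-n comparisons keep honest df bookkeeping", {
  d <- expand.grid(participant = c("a", "b"), group = c("g1", "g2"),
                   run = c(1, 4))
  set.seed(48)
  d$value <- rnorm(8)
  cc <- compare_connectivity(d)
  expect_equal(cc$within$df, c(1, 1))
  expect_equal(cc$between$df_paired_style, 1)
  expect_gt(cc$between$p_paired_style, 0.01)  # wide p at df = 1
})

test_that("Holm correction is available as an opt-in column", {
  tab <- data.frame(p = c(0.01, 0.02, 0.5))
  out <- add_holm(tab)
  expect_equal(out$p_holm, p.adjust(tab$p, "holm"))
  expect_error(add_holm(data.frame(x = 1)), "no p column")
})
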