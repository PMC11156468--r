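# Outcome scoring, summaries, sensitivity, transitions, session QC.

test_that("score_outcomes implements the outcome taxonomy", {
  cases <- list(
    # rule, modality, licks, expected
    list("touch", "tactile", lick_df(0.5, "right"), "hit"),
    list("touch", "tactile", lick_df(0.5, "left"), "false_alarm"),
    list("touch", "tactile", lick_df(), "miss"),
    list("touch", "visual", lick_df(0.5, "right"), "false_alarm"),
    list("touch", "visual", lick_df(), "correct_rejection"),
    list("light", "visual", lick_df(0.4, "left"), "hit"),
    list("light", "visual", lick_df(0.4, "right"), "false_alarm"),
    list("light", "tactile", lick_df(1.2, "left"), "false_alarm"),
    list("light", "tactile", lick_df(), "correct_rejection"),
    # censor-window lick censors the trial
    list("touch", "tactile", lick_df(-0.1, "right"), "censored"),
    # grace-window licks are ignored for scoring
    list("touch", "tactile", lick_df(0.05, "right"), "miss"),
    list("touch", "visual", lick_df(0.05, "right"), "correct_rejection"),
    # first answer-window lick determines the port
    list("touch", "tactile", lick_df(c(0.5, 0.9), c("left", "right")),
         "false_alarm"),
    # licks after the answer window do not count
    list("touch", "tactile", lick_df(2.5, "right"), "miss"))
  tr <- make_trials(
    block_rule = vapply(cases, `[[`, "", 1),
    modality = vapply(cases, `[[`, "", 2),
    licks = lapply(cases, `[[`, 3))
  out <- score_outcomes(tr)
  expect_identical(out$outcome, vapply(cases, `[[`, "", 4))
})

test_that("modality 'none' outside laser-only trials is structural", {
  tr <- make_trials("touch", "none")
  expect_error(score_outcomes(tr), "modality 'none'")
  tr2 <- make_trials("touch", "none", laser = "laser_only_short")
  expect_true(is.na(score_outcomes(tr2)$outcome))
})

test_that("outcome_summary reproduces the percent-correct identity", {
  expect_equal(percent_correct(0.36, 0.38), 74)
  expect_equal(percent_correct(0.35, 0.40), 75)
  # 100 trials per rule with exact outcome fractions
  mk <- function(rule, n_hit, n_cr, n_miss, n_fa) {
    mod <- if (rule == "touch") "tactile" else "visual"
    other <- if (rule == "touch") "visual" else "tactile"
    port <- if (rule == "touch") "right" else "left"
    make_trials(
      rep(rule, n_hit + n_cr + n_miss + n_fa),
      c(rep(mod, n_hit), rep(other, n_cr), rep(mod, n_miss),
        rep(other, n_fa)),
      c(rep(list(lick_df(0.5, port)), n_hit),
        rep(list(lick_df()), n_cr + n_miss),
        rep(list(lick_df(0.5, port)), n_fa)))
  }
  tr <- rbind(mk("touch", 36, 38, 13, 13), mk("light", 35, 40, 14, 11))
  tr <- score_outcomes(tr)
  os <- outcome_summary(tr)
  expect_equal(os$touch$percent_correct, 74)
  expect_equal(os$light$percent_correct, 75)
  expect_equal(os$touch$hit_rate + os$touch$cr_rate + os$touch$miss_rate +
                 os$touch$fa_rate, 1, tolerance = 1e-9)
  # all hits -> 100%
  all_hit <- score_outcomes(mk("touch", 10, 0, 0, 0))
  expect_equal(outcome_summary(all_hit)$touch$percent_correct, 100)
  expect_true("light" %in% outcome_summary(all_hit)$empty_rules)
})

test_that("detection sensitivity is hit rate minus cross-modal FA rate", {
  mk_block <- function(n_sig_lick, n_sig, n_dis_lick, n_dis) {
    make_trials(
      rep("touch", n_sig + n_dis),
      c(rep("tactile", n_sig), rep("visual", n_dis)),
      c(rep(list(lick_df(0.5, "right")), n_sig_lick),
        rep(list(lick_df()), n_sig - n_sig_lick),
        rep(list(lick_df(0.5, "right")), n_dis_lick),
        rep(list(lick_df()), n_dis - n_dis_lick)))
  }
  tr <- score_outcomes(mk_block(8, 10, 2, 10))
  s <- detection_sensitivity(tr, "tactile")
  expect_equal(s$sensitivity, 0.6)
  # perfect performance -> 1; symmetric licking -> 0
  expect_equal(detection_sensitivity(score_outcomes(mk_block(10, 10, 0, 10)),
                                     "tactile")$sensitivity, 1)
  expect_equal(detection_sensitivity(score_outcomes(mk_block(5, 10, 5, 10)),
                                     "tactile")$sensitivity, 0)
  # antisymmetry: swapping the lick patterns negates sensitivity
  sw <- detection_sensitivity(score_outcomes(mk_block(2, 10, 8, 10)),
                              "tactile")
  expect_equal(sw$sensitivity, -s$sensitivity)
  # empty cell -> missing marker
  empty <- score_outcomes(make_trials("light", "visual"))
  expect_true(detection_sensitivity(empty, "tactile")$missing)
})

test_that("delta_sensitivity recovers a simulated laser deficit", {
  cfg <- task_config(laser_pre_frac = 0.3)
  ag <- agent_config(laser_hit_penalty = 0.3)
  trs <- do.call(rbind, lapply(1:6, function(s) {
    sch <- generate_schedule(cfg, session_id = sprintf("s%d", s),
                             mouse_id = sprintf("m%d", (s - 1) %% 3 + 1),
                             seed = 900 + s)
    simulate_agent(sch, ag, cfg, seed = 900 + s)
  }))
  d <- delta_sensitivity(trs, "tactile", "laser_pre", "control", cfg,
                         n_iter = 300, seed = 1)
  expect_lt(abs(d$estimate - (-0.3)), 0.12)
  expect_true(d$hi < 0)  # CI excludes 0 at this effect size
  # identical conditions -> delta 0, CI contains 0
  d0 <- delta_sensitivity(trs, "tactile", "control", "control", cfg,
                          n_iter = 200, seed = 1)
  expect_equal(d0$estimate, 0)
  expect_true(d0$lo <= 0 && d0$hi >= 0)
})

test_that("laser_only_lick_change handles constructed cases", {
  # licks only in the post-laser response window with P = 0.4
  n <- 20
  licks <- c(rep(list(lick_df(1.0, "right")), 8), rep(list(lick_df()), 12))
  tr <- make_trials(rep("touch", n), rep("none", n), licks,
                    laser = "laser_only_short")
  tr$outcome <- NA_character_
  r <- laser_only_lick_change(tr, n_iter = 100, seed = 1)
  expect_equal(r$estimate, 0.4)
  # no licks anywhere -> 0
  tr2 <- make_trials(rep("touch", n), rep("none", n),
                     laser = "laser_only_long")
  expect_equal(laser_only_lick_change(tr2, n_iter = 50,
                                      seed = 1)$estimate, 0)
  # no laser-only trials -> missing marker
  expect_true(laser_only_lick_change(
    make_trials("touch", "tactile"))$missing)
})

test_that("parse_transitions implements the early/late split", {
  mk <- function(outcomes2) {
    n1 <- 3
    tr <- make_trials(
      c(rep("touch", n1), rep("light", length(outcomes2))),
      rep("tactile", n1 + length(outcomes2)),
      block_index = c(rep(1L, n1), rep(2L, length(outcomes2))))
    tr$outcome <- c(rep("hit", n1), outcomes2)
    tr
  }
  # [FA, miss, hit]: early = {first}, late = {second, third}
  p <- parse_transitions(mk(c("false_alarm", "miss", "hit")))[[1]]
  expect_equal(p$early_trials, 4L)
  expect_equal(p$late_trials, c(5L, 6L))
  expect_equal(p$first_hit, 6L)
  expect_equal(p$direction, "touch_to_light")
  # [hit]: transition = {1}, late empty
  p <- parse_transitions(mk("hit"))[[1]]
  expect_equal(p$early_trials, 4L)
  expect_length(p$late_trials, 0)
  # [miss, FA, FA, hit]: early = {1, 2}, late = {3, 4}
  p <- parse_transitions(mk(c("miss", "false_alarm", "false_alarm",
                              "hit")))[[1]]
  expect_equal(p$early_trials, c(4L, 5L))
  expect_equal(p$late_trials, c(6L, 7L))
  # no FA before first hit -> all early
  p <- parse_transitions(mk(c("miss", "miss", "hit")))[[1]]
  expect_equal(p$early_trials, c(4L, 5L, 6L))
  # no hit at all -> open transition
  p <- parse_transitions(mk(c("miss", "false_alarm")))[[1]]
  expect_false(p$complete)
  # early and late partition the period
  p <- parse_transitions(mk(c("false_alarm", "hit")))[[1]]
  expect_length(intersect(p$early_trials, p$late_trials), 0)
})

test_that("parse_transitions only depends on the block pair", {
  sess <- fixture_session()
  p_all <- parse_transitions(sess$trials)
  two <- sess$trials[sess$trials$block_index %in% c(1, 2), ]
  p_two <- parse_transitions(two)[[1]]
  expect_identical(p_two$early_trials, p_all[[1]]$early_trials)
  expect_identical(p_two$first_hit, p_all[[1]]$first_hit)
  # idempotence
  expect_identical(parse_transitions(sess$trials), p_all)
})

test_that("transition_lick_curves tracks the behavioral switch", {
  trs <- do.call(rbind, lapply(1:4, function(s) {
    sess <- simulate_session(seed = 600 + s, pop = NULL,
                             session_id = sprintf("s%d", s),
                             mouse_id = sprintf("m%d", (s %% 2) + 1))
    sess$trials
  }))
  tl <- transition_lick_curves(trs, offsets = -5:12, n_iter = 50,
                               seed = 1)
  expect_true(all(tl$curves$probability >= 0 & tl$curves$probability <= 1))
  # default agent switches before or at the cue
  expect_lte(median(tl$first_hit$trial_in_block), 9)
  # right licks dominate late in blocks entered under the touch rule
  late_touch <- tl$curves[tl$curves$direction == "light_to_touch" &
                            tl$curves$offset == 12, ]
  expect_gt(late_touch$probability[late_touch$port == "right"],
            late_touch$probability[late_touch$port == "left"])
})

test_that("session_qc trims 20 trials and applies thresholds", {
  sess <- fixture_session()
  qc <- session_qc(sess$trials)
  expect_equal(nrow(qc$trials), nrow(sess$trials) - 20L)
  expect_true(qc$keep)
  # short session dropped
  short <- sess$trials[1:15, ]
  expect_false(session_qc(short)$keep)
  # a chance-level session fails the 60% threshold
  n <- 120
  bad <- make_trials(rep(c("touch", "light"), each = n / 2),
                     rep(c("tactile", "visual"), n / 2))
  bad$outcome <- rep(c("false_alarm", "miss"), n / 2)
  bad$outcome[seq(1, n, by = 3)] <- "hit"   # ~33% correct
  expect_false(session_qc(bad)$keep)
  expect_match(paste(session_qc(bad)$reasons, collapse = " "), "60%")
  # laser catch rate > 75% drops the session
  good <- sess$trials
  catch <- make_trials(rep("touch", 40), rep("none", 40),
                       licks = rep(list(lick_df(0.5, "right")), 40),
                       laser = "laser_only_short")
  catch$trial_index <- max(good$trial_index) + seq_len(40)
  catch$outcome <- NA_character_
  catch$latent_rule <- "touch"
  withlaser <- rbind(good, catch[names(good)])
  res <- session_qc(withlaser)
  expect_false(res$keep)
  expect_match(paste(res$reasons, collapse = " "), "laser catch")
})
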