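# Task schedule, behavioral agent, and Poisson spiking generator.

test_that("schedule obeys block, run-length, cue and ITI structure", {
  lens <- c(); runs_ok <- TRUE; gaps <- c()
  for (s in 1:50) {
    sch <- generate_schedule(task_config(), seed = s)
    blens <- table(sch$block_index)
    lens <- c(lens, as.integer(blens))
    expect_true(all(blens >= 54 & blens <= 66))
    # rules strictly alternate
    rules <- sch$block_rule[!duplicated(sch$block_index)]
    expect_true(all(rules[-1] != rules[-length(rules)]))
    # cue exactly at trial 9 of each block
    expect_identical(which(sch$cue), which(sch$trial_in_block == 9L))
    # no modality run exceeds 4
    r <- rle(sch$modality)
    runs_ok <- runs_ok && max(r$lengths) <= 4
    gaps <- c(gaps, diff(sch$stim_onset))
    # trials ordered, trial_in_block resets
    expect_true(!is.unsorted(sch$stim_onset, strictly = TRUE))
    expect_true(all(sch$trial_in_block[sch$block_index !=
      c(0, sch$block_index[-nrow(sch)])] == 1L))
  }
  expect_true(runs_ok)
  expect_gt(mean(lens), 58); expect_lt(mean(lens), 62)
  expect_true(all(gaps >= 3.5))
  expect_equal(mean(gaps - 3.5), 4, tolerance = 0.05)
})

test_that("max_run = 1 forces strict modality alternation", {
  sch <- generate_schedule(task_config(max_run = 1L), seed = 7)
  expect_true(all(sch$modality[-1] != sch$modality[-nrow(sch)]))
})

test_that("ITI exponential component passes a KS test against Exp(4)", {
  gaps <- unlist(lapply(1:30, function(s)
    diff(generate_schedule(task_config(), seed = 1000 + s)$stim_onset)))
  ks <- suppressWarnings(ks.test(gaps - 3.5, "pexp", rate = 1 / 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid config fields raise errors naming the field", {
  expect_error(task_config(max_run = 0), "max_run")
  expect_error(task_config(block_len_range = c(10, 5)), "block_len_range")
  expect_error(task_config(iti_exp_mean = -1), "iti_exp_mean")
  expect_error(agent_config(p_hit = 1.2), "p_hit")
  expect_error(population_config(area_profile = "V1-like"),
               "area_profile")
  expect_error(population_config(rule_rotation = 2), "rule_rotation")
})

test_that("identical seeds give bit-identical sessions", {
  a <- simulate_session(seed = 11, pop = population_config(n_units = 5))
  b <- simulate_session(seed = 11, pop = population_config(n_units = 5))
  expect_identical(a$trials, b$trials)
  expect_identical(a$spikes$spikes, b$spikes$spikes)
  c <- simulate_session(seed = 12, pop = population_config(n_units = 5))
  expect_false(identical(a$trials$stim_onset, c$trials$stim_onset))
})

test_that("agent follows the old rule until feedback, then switches", {
  cfg <- task_config(n_blocks = 4L)
  # Never switches on feedback: first hit of any later block must be at or
  # after the cue trial, because under the old rule the agent either
  # false-alarms (old-relevant stimulus) or misses (new-relevant).
  ag0 <- agent_config(p_switch_after_feedback = 0)
  for (s in 1:5) {
    tr <- simulate_agent(generate_schedule(cfg, seed = s), ag0, cfg,
                         seed = s)
    for (p in parse_transitions(tr)) {
      if (!p$complete) next
      tib <- tr$trial_in_block[tr$trial_index == p$first_hit]
      expect_gte(tib, cfg$cue_trial)
    }
  }
  # Deterministic agent with instant feedback switching: after the first
  # unrewarded answer of a block, everything is correct.
  ag1 <- agent_config(p_hit = 1, p_fa = 0, p_switch_after_feedback = 1,
                      p_prestim_lick = 0)
  tr <- simulate_agent(generate_schedule(cfg, seed = 3), ag1, cfg,
                       seed = 3)
  for (b in unique(tr$block_index)[-1]) {
    blk <- tr[tr$block_index == b, ]
    fa <- which(blk$outcome == "false_alarm")
    from <- if (length(fa)) min(fa) + 1L else
      which(blk$trial_in_block == 9L)
    if (from <= nrow(blk))
      expect_true(all(blk$outcome[from:nrow(blk)] %in%
                        c("hit", "correct_rejection")))
  }
  # Latent rule is recorded and adoption happens at most at the cue.
  expect_true(all(tr$latent_rule %in% c("touch", "light")))
  adoption <- attr(tr, "adoption")
  expect_true(all(adoption <= task_config()$cue_trial))
})

test_that("default agent performs ~75% correct under both rules", {
  res <- sapply(1:20, function(s) {
    sess <- simulate_session(seed = 500 + s, pop = NULL)
    os <- outcome_summary(sess$trials)
    c(os$touch$percent_correct, os$light$percent_correct)
  })
  expect_gt(mean(res[1, ]), 70); expect_lt(mean(res[1, ]), 80)
  expect_gt(mean(res[2, ]), 70); expect_lt(mean(res[2, ]), 80)
})

test_that("spike counts follow the Poisson law at fixed rate", {
  pop <- population_config(n_units = 8, baseline_meanlog = log(5),
                           baseline_sdlog = 0, frac_rule_mod = 0,
                           frac_touch_resp = 0, frac_light_resp = 0,
                           frac_choice = 0)
  counts <- c()
  for (s in 1:4) {
    sess <- simulate_session(seed = 200 + s, pop = pop)
    tens <- bin_rates(sess$spikes, sess$trials, c(-1, 0), 1)
    counts <- rbind(counts, apply(tens$values, 1, identity))
  }
  # every unit fires at the same fixed 5 Hz rate, so all ~10^4
  # unit-trials pool into one Poisson sample
  pooled <- as.vector(counts)
  expect_gt(length(pooled), 1e4)
  expect_true(var(pooled) / mean(pooled) > 0.9 &&
                var(pooled) / mean(pooled) < 1.1)
})

test_that("generator effect switches act as expected on spiking", {
  # no rule modulation -> block-type AUC ~ 0.5 across units
  pop0 <- population_config(n_units = 12, frac_rule_mod = 0,
                            rule_gain = 1)
  sess <- simulate_session(seed = 77, pop = pop0)
  clean <- exclude_prestim_lick_trials(sess$trials)
  pre <- bin_rates(sess$spikes, clean, c(-0.1, 0), 0.1)
  g <- xmodal:::contrast_groups(clean, "rule")
  aucs <- sapply(seq_len(12), function(u) {
    f <- pre$values[u, , 1]
    trial_auc(f[pre$trial_index %in% g$a], f[pre$trial_index %in% g$b])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # negative amplitude is clipped with a warning
  popn <- population_config(n_units = 2, evoked_amp = -5)
  expect_warning(simulate_spikes(sess$trials, popn, task_config(),
                                 seed = 1), "clipped")
})
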