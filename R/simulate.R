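# Synthetic task generator: schedule, behavioral agent, Poisson spiking.

rule_modality <- c(touch = "tactile", light = "visual")
rule_port <- c(touch = "right", light = "left")

#' Generate a session's trial schedule (stimuli and timing only)
#'
#' Blocks of alternating `touch`/`light` rules with uniformly drawn lengths,
#' randomly interleaved tactile/visual stimuli subject to a cap on
#' same-modality runs (enforced by a rejection-free sequential draw: when the
#' last `max_run` trials share a modality the other is forced), inter-trial
#' intervals equal to a fixed floor plus an exponential draw, and the switch
#' cue flagged on a fixed trial of every block. Laser conditions are
#' assigned per the config's laser fractions; laser-only trials carry no
#' sensory stimulus (`modality == "none"`).
#'
#' @param cfg A [task_config()].
#' @param session_id,mouse_id Identifiers stored per trial.
#' @param seed Optional integer seed (falls back to `cfg$seed`).
#' @return A trial table: one row per trial with columns `session_id`,
#'   `mouse_id`, `block_index`, `block_rule`, `trial_index`,
#'   `trial_in_block`, `modality`, `stim_onset`, `licks` (list-column),
#'   `laser`, `cue`, `outcome` (NA until scored).
#' @export
generate_schedule <- function(cfg = task_config(), session_id = "s1",
                              mouse_id = "m1", seed = NULL) {
  if (!inherits(cfg, "task_config"))
    config_error("cfg", "must be a task_config object")
  with_seed(seed %||% cfg$seed, {
    n_blocks <- cfg$n_blocks %||% sample(4:6, 1L)
    block_len <- sample(seq(cfg$block_len_range[1], cfg$block_len_range[2]),
                        n_blocks, replace = TRUE)
    first_rule <- sample(c("touch", "light"), 1L)
    rules <- rep(c(first_rule, setdiff(c("touch", "light"), first_rule)),
                 length.out = n_blocks)
    n_trials <- sum(block_len)
    block_index <- rep(seq_len(n_blocks), block_len)
    trial_in_block <- unlist(lapply(block_len, seq_len), use.names = FALSE)

    # Sequential modality draw with forced alternation at the run cap.
    modality <- character(n_trials)
    for (i in seq_len(n_trials)) {
      if (i > cfg$max_run &&
          length(unique(modality[(i - cfg$max_run):(i - 1)])) == 1L) {
        modality[i] <- setdiff(c("tactile", "visual"), modality[i - 1])
      } else {
        modality[i] <- sample(c("tactile", "visual"), 1L)
      }
    }

    gaps <- cfg$iti_fixed + stats::rexp(n_trials, rate = 1 / cfg$iti_exp_mean)
    stim_onset <- cumsum(gaps)

    laser <- rep("none", n_trials)
    p_lo <- cfg$laser_only_frac
    p_pre <- cfg$laser_pre_frac
    p_post <- cfg$laser_post_frac
    if (p_lo + p_pre + p_post > 0) {
      u <- stats::runif(n_trials)
      laser[u < p_lo] <- ifelse(stats::runif(sum(u < p_lo)) < 0.5,
                                "laser_only_short", "laser_only_long")
      laser[u >= p_lo & u < p_lo + p_pre] <- "pre"
      laser[u >= p_lo + p_pre & u < p_lo + p_pre + p_post] <- "post"
      modality[laser %in% c("laser_only_short", "laser_only_long")] <- "none"
    }

    data.frame(
      session_id = session_id, mouse_id = mouse_id,
      block_index = block_index,
      block_rule = rules[block_index],
      trial_index = seq_len(n_trials),
      trial_in_block = trial_in_block,
      modality = modality,
      stim_onset = stim_onset,
      licks = I(rep(list(data.frame(time = numeric(0),
                                    port = character(0))), n_trials)),
      laser = laser,
      cue = trial_in_block == cfg$cue_trial,
      outcome = NA_character_,
      stringsAsFactors = FALSE)
  })
}

#' Simulate the behavioral agent on a schedule
#'
#' The agent holds a latent rule state. Within a block it licks the current
#' rule's port with probability `p_hit` after a stimulus its rule treats as
#' relevant and with probability `p_fa` after an irrelevant one. After a
#' block switch it keeps following the old rule until its first unrewarded
#' lick (the first feedback that the rule changed), then adopts the new rule
#' with per-trial probability `p_switch_after_feedback`, and always at the
#' cue trial. Spontaneous pre-stimulus licks are added on a fraction
#' `p_prestim_lick` of trials. The latent rule and per-block adoption trials
#' are recorded so that simulated spiking and decoding share one ground
#' truth.
#'
#' @param schedule Trial table from [generate_schedule()].
#' @param agent An [agent_config()].
#' @param cfg The [task_config()] used for the schedule (scoring windows).
#' @param seed Optional integer seed.
#' @return The trial table with `licks`, `outcome`, and `latent_rule`
#'   filled; attribute `adoption` holds per-block adoption trial indices.
#' @export
simulate_agent <- function(schedule, agent = agent_config(),
                           cfg = task_config(), seed = NULL) {
  assert_trial_table(schedule)
  if (!inherits(agent, "agent_config"))
    config_error("agent", "must be an agent_config object")
  if (length(unique(schedule$block_rule)) < 1L ||
      is.unsorted(schedule$block_index))
    structural_error("schedule lacks block structure")
  with_seed(seed, {
    n <- nrow(schedule)
    latent <- character(n)
    licks <- vector("list", n)
    outcome <- character(n)
    cur_rule <- schedule$block_rule[1]
    feedback <- FALSE     # unrewarded lick seen since last block switch?
    adoption <- integer(max(schedule$block_index))
    adoption[schedule$block_index[1]] <- 1L

    for (i in seq_len(n)) {
      new_block <- i > 1L &&
        schedule$block_index[i] != schedule$block_index[i - 1L]
      if (new_block) feedback <- FALSE
      blk_rule <- schedule$block_rule[i]
      if (cur_rule != blk_rule) {
        adopt <- schedule$trial_in_block[i] >= cfg$cue_trial ||
          (feedback && stats::runif(1) < agent$p_switch_after_feedback)
        if (adopt) {
          cur_rule <- blk_rule
          adoption[schedule$block_index[i]] <- schedule$trial_in_block[i]
        }
      } else if (new_block) {
        adoption[schedule$block_index[i]] <- 1L
      }
      latent[i] <- cur_rule

      lk <- data.frame(time = numeric(0), port = character(0),
                       stringsAsFactors = FALSE)
      if (stats::runif(1) < agent$p_prestim_lick) {
        lk <- rbind(lk, data.frame(time = stats::runif(1, -1, 0),
                                   port = sample(c("left", "right"), 1L),
                                   stringsAsFactors = FALSE))
      }
      mod <- schedule$modality[i]
      p_hit_i <- agent$p_hit
      if (schedule$laser[i] %in% c("pre", "post"))
        p_hit_i <- max(0, p_hit_i - agent$laser_hit_penalty)
      p_lick <- if (mod == rule_modality[[cur_rule]]) p_hit_i else agent$p_fa
      if (stats::runif(1) < p_lick) {
        lat <- agent$lick_latency(1L)
        lk <- rbind(lk, data.frame(time = lat, port = rule_port[[cur_rule]],
                                   stringsAsFactors = FALSE))
      }
      licks[[i]] <- lk
      outcome[i] <- score_one_trial(blk_rule, mod, lk, cfg)

      # Feedback: agent licked in the answer window but was not rewarded.
      answered <- any(lk$time >= cfg$answer_window[1] &
                      lk$time <= cfg$answer_window[2])
      if (answered && !identical(outcome[i], "hit")) feedback <- TRUE
    }
    out <- schedule
    out$licks <- I(licks)
    out$outcome <- outcome
    out$latent_rule <- latent
    attr(out, "adoption") <- adoption
    out
  })
}

# Inverse-CDF sampler for the half-sine evoked kernel A*sin(pi*t/d) on
# [0, d]: integral 2*A*d/pi, CDF (1 - cos(pi*t/d))/2.
sample_evoked_times <- function(n, d) (d / pi) * acos(1 - 2 * stats::runif(n))

#' Simulate Poisson spike trains for a population
#'
#' Each unit fires as an inhomogeneous Poisson process whose rate is the sum
#' of (i) a baseline, multiplied by `rule_gain` whenever the agent's latent
#' rule matches the unit's preferred rule (rule-modulated units only) --
#' baseline changes therefore track behavioral, not nominal, block
#' adoption; (ii) a half-sine evoked transient over the stimulus duration
#' for modality-matched units, scaled by `relevance_gain` when the stimulus
#' is relevant under the latent rule; and (iii) a linear ramp from 100 ms
#' before the first answer lick to the lick for choice units on lick trials.
#' Independent Poisson components are summed, which is exact for Poisson
#' processes. Negative amplitudes are clipped at zero with a warning.
#'
#' @param trials Scored trial table from [simulate_agent()].
#' @param pop A [population_config()].
#' @param cfg The [task_config()] (stimulus duration, answer window).
#' @param seed Optional integer seed (falls back to `pop$seed`).
#' @return A `spike_set`: list with `units` (metadata data.frame including
#'   ground-truth modulation flags and supplied QC metrics) and `spikes`
#'   (list of sorted spike-time vectors, seconds from session start).
#' @export
simulate_spikes <- function(trials, pop = population_config(),
                            cfg = task_config(), seed = NULL) {
  assert_trial_table(trials)
  if (!inherits(pop, "population_config"))
    config_error("pop", "must be a population_config object")
  if (is.null(trials$latent_rule))
    structural_error("trials must be simulated by simulate_agent() first")
  clip <- FALSE
  amps <- c(pop$evoked_amp, pop$choice_amp)
  if (any(amps < 0)) {
    clip <- TRUE
    warning("negative kernel amplitude clipped at 0")
  }
  evoked_amp <- max(0, pop$evoked_amp)
  choice_amp <- max(0, pop$choice_amp)

  with_seed(seed %||% pop$seed, {
    n_units <- pop$n_units
    base <- stats::rlnorm(n_units, pop$baseline_meanlog, pop$baseline_sdlog)
    rule_mod <- stats::runif(n_units) < pop$frac_rule_mod
    # Half of rule-modulated units prefer each rule.
    pref <- rep(NA_character_, n_units)
    idx <- which(rule_mod)
    if (length(idx)) {
      half <- sample(idx, floor(length(idx) / 2))
      pref[idx] <- "touch"; pref[half] <- "light"
    }
    touch_resp <- stats::runif(n_units) < pop$frac_touch_resp
    light_resp <- stats::runif(n_units) < pop$frac_light_resp
    choice_resp <- stats::runif(n_units) < pop$frac_choice
    # Per-unit evoked amplitude patterns. Pattern 1 is expressed when the
    # stimulus is relevant under the agent's rule; in the irrelevant
    # context a fraction rule_rotation of units instead express an
    # independent amplitude, so the population evoked pattern rotates
    # between rule contexts by recruiting a partly different set of
    # units (pattern correlation falls linearly in rule_rotation).
    amp1 <- matrix(stats::rgamma(2 * n_units, shape = 2,
                                 scale = evoked_amp / 2),
                   n_units, 2)   # columns: tactile, visual
    amp2 <- matrix(stats::rgamma(2 * n_units, shape = 2,
                                 scale = evoked_amp / 2),
                   n_units, 2)
    sw <- matrix(stats::runif(2 * n_units) < pop$rule_rotation,
                 n_units, 2)
    amp_irrel <- ifelse(sw, amp2, amp1)

    # Latent-rule segments: trial i's latent rule governs the interval
    # between onset midpoints, so each pre-stimulus window sits inside the
    # segment of its own trial.
    onsets <- trials$stim_onset
    n_tr <- length(onsets)
    bounds <- c(0, (onsets[-n_tr] + onsets[-1]) / 2, onsets[n_tr] + 4)
    seg_len <- diff(bounds)
    seg_rule <- trials$latent_rule
    t_end <- bounds[n_tr + 1]

    spikes <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      rates <- rep(base[u], n_tr)
      if (rule_mod[u]) rates[seg_rule == pref[u]] <- base[u] * pop$rule_gain
      counts <- stats::rpois(n_tr, rates * seg_len)
      st <- unlist(lapply(seq_len(n_tr), function(s)
        stats::runif(counts[s], bounds[s], bounds[s + 1])),
        use.names = FALSE)

      # Evoked transient.
      resp_mask <- (trials$modality == "tactile" & touch_resp[u]) |
        (trials$modality == "visual" & light_resp[u])
      for (i in which(resp_mask)) {
        mcol <- if (trials$modality[i] == "tactile") 1L else 2L
        relevant <- trials$modality[i] ==
          rule_modality[[trials$latent_rule[i]]]
        amp <- if (relevant) pop$relevance_gain * amp1[u, mcol]
               else amp_irrel[u, mcol]
        if (evoked_amp == 0) amp <- 0
        m <- stats::rpois(1, 2 * amp * cfg$stim_duration / pi)
        if (m > 0)
          st <- c(st, onsets[i] + sample_evoked_times(m, cfg$stim_duration))
      }

      # Choice ramp locked to the first answer-window lick.
      if (choice_resp[u] && choice_amp > 0) {
        for (i in seq_len(n_tr)) {
          lk <- trials$licks[[i]]
          ans <- lk$time[lk$time >= cfg$answer_window[1] &
                         lk$time <= cfg$answer_window[2]]
          if (!length(ans)) next
          t_lick <- min(ans)
          m <- stats::rpois(1, choice_amp * 0.1 / 2)
          if (m > 0)
            st <- c(st, onsets[i] + t_lick - 0.1 +
                      0.1 * sqrt(stats::runif(m)))
        }
      }
      st <- sort(st[st >= 0 & st <= t_end])
      # Absolute refractory period (2 ms): without it a Poisson train's
      # ISI-violation rate (~rate x 1.5 ms) would trip the QC threshold.
      repeat {
        bad <- which(diff(st) < 0.002) + 1L
        if (!length(bad)) break
        st <- st[-bad[c(TRUE, diff(bad) > 1L)]]
      }
      spikes[[u]] <- st
    }
    units <- data.frame(
      unit_id = sprintf("%s_u%03d", trials$session_id[1], seq_len(n_units)),
      area = pop$area_profile,
      baseline = base, rule_mod = rule_mod, pref_rule = pref,
      touch_resp = touch_resp, light_resp = light_resp,
      choice_resp = choice_resp,
      l_ratio = stats::runif(n_units, 0, 0.08),  # supplied QC pass-through
      drift_um = stats::runif(n_units, 0, 30),
      stringsAsFactors = FALSE)
    names(spikes) <- units$unit_id
    structure(list(units = units, spikes = spikes, t_end = t_end,
                   clipped = clip),
              class = "spike_set")
  })
}

#' Simulate one complete session (schedule, behavior, spiking)
#'
#' Splits a single master seed into independent per-stage streams.
#'
#' @inheritParams generate_schedule
#' @param agent An [agent_config()].
#' @param pop A [population_config()], or `NULL` to skip spiking.
#' @param seed Master integer seed.
#' @return List with `trials` (scored trial table) and `spikes`
#'   (`spike_set` or `NULL`).
#' @export
simulate_session <- function(cfg = task_config(), agent = agent_config(),
                             pop = population_config(), seed = 1L,
                             session_id = "s1", mouse_id = "m1") {
  sched <- generate_schedule(cfg, session_id, mouse_id,
                             seed = derive_seed(seed, "schedule"))
  trials <- simulate_agent(sched, agent, cfg,
                           seed = derive_seed(seed, "agent"))
  spikes <- if (!is.null(pop))
    simulate_spikes(trials, pop, cfg, seed = derive_seed(seed, "spikes"))
  list(trials = trials, spikes = spikes)
}

#' Simulate a multi-session, multi-mouse experiment
#'
#' @param n_sessions Number of sessions.
#' @param n_mice Number of mice the sessions are spread over.
#' @param cfg,agent,pop Stage configurations (see [simulate_session()]).
#' @param seed Master integer seed.
#' @return List of session objects as returned by [simulate_session()].
#' @export
simulate_experiment <- function(n_sessions = 10L, n_mice = 4L,
                                cfg = task_config(), agent = agent_config(),
                                pop = population_config(), seed = 1L) {
  mice <- sprintf("m%02d", rep(seq_len(n_mice), length.out = n_sessions))
  lapply(seq_len(n_sessions), function(s)
    simulate_session(cfg, agent, pop,
                     seed = derive_seed(seed, paste0("session", s)),
                     session_id = sprintf("s%03d", s), mouse_id = mice[s]))
}
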