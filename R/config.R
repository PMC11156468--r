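#' Task configuration for the cross-modal sensory selection task
#'
#' Describes the trial scheduling rules of the task: block-alternating
#' stimulus-response rules, randomly interleaved tactile/visual stimuli with
#' a cap on same-modality runs, an exponential inter-trial interval on top
#' of a fixed floor, and the switch cue delivered on a fixed trial of every
#' block.
#'
#' @param n_blocks Number of rule blocks per session, or `NULL` to draw
#'   uniformly from 4-6 per session (the task's stated range).
#' @param block_len_range Integer pair: block lengths are drawn uniformly on
#'   this range (default 54-66 trials, mean 60).
#' @param max_run Maximum number of consecutive same-modality trials
#'   (default 4).
#' @param iti_fixed Fixed component of the inter-trial interval, seconds.
#' @param iti_exp_mean Mean of the exponential ITI component, seconds.
#' @param stim_duration Stimulus duration, seconds (default 0.15).
#' @param answer_window Seconds pair relative to stimulus onset during which
#'   a lick counts as a response (default 0.1-2).
#' @param grace_window Seconds pair: licks here are ignored for scoring.
#' @param censor_window Seconds pair: licks here censor the trial.
#' @param cue_trial Trial-in-block on which the switch cue is delivered.
#' @param laser_pre_frac,laser_post_frac Fractions of stimulus trials given
#'   pre-/post-stimulus-onset optogenetic inhibition (default 0: no opto).
#' @param laser_only_frac Fraction of trials that are laser-only catch
#'   trials with no sensory stimulus (default 0).
#' @param seed Optional integer seed stored with the config.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_blocks = NULL,
                        block_len_range = c(54L, 66L),
                        max_run = 4L,
                        iti_fixed = 3.5,
                        iti_exp_mean = 4.0,
                        stim_duration = 0.15,
                        answer_window = c(0.1, 2.0),
                        grace_window = c(0, 0.1),
                        censor_window = c(-0.2, 0),
                        cue_trial = 9L,
                        laser_pre_frac = 0,
                        laser_post_frac = 0,
                        laser_only_frac = 0,
                        seed = NULL) {
  if (!is.null(n_blocks) &&
      (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1))
    config_error("n_blocks", "must be a positive integer or NULL")
  if (!is.numeric(block_len_range) || length(block_len_range) != 2L ||
      block_len_range[1] > block_len_range[2] ||
      block_len_range[1] < 1 || block_len_range[2] > 1e4)
    config_error("block_len_range",
                 "must be an ordered integer pair within [1, 10^4]")
  if (!is.numeric(max_run) || length(max_run) != 1L || max_run < 1)
    config_error("max_run", "must be an integer >= 1")
  if (!is.numeric(iti_fixed) || iti_fixed < 0)
    config_error("iti_fixed", "must be a nonnegative number of seconds")
  if (!is.numeric(iti_exp_mean) || iti_exp_mean <= 0)
    config_error("iti_exp_mean", "must be a positive number of seconds")
  if (!is.numeric(stim_duration) || stim_duration <= 0)
    config_error("stim_duration", "must be a positive number of seconds")
  check_window(answer_window, "answer_window")
  check_window(grace_window, "grace_window")
  check_window(censor_window, "censor_window")
  if (!is.numeric(cue_trial) || cue_trial < 1)
    config_error("cue_trial", "must be a positive integer")
  check_prob(laser_pre_frac, "laser_pre_frac")
  check_prob(laser_post_frac, "laser_post_frac")
  check_prob(laser_only_frac, "laser_only_frac")
  if (laser_pre_frac + laser_post_frac + laser_only_frac > 1)
    config_error("laser_only_frac", "laser fractions must sum to <= 1")
  structure(list(
    n_blocks = if (is.null(n_blocks)) NULL else as.integer(n_blocks),
    block_len_range = as.integer(block_len_range),
    max_run = as.integer(max_run),
    iti_fixed = iti_fixed, iti_exp_mean = iti_exp_mean,
    stim_duration = stim_duration,
    answer_window = answer_window, grace_window = grace_window,
    censor_window = censor_window,
    cue_trial = as.integer(cue_trial),
    laser_pre_frac = laser_pre_frac, laser_post_frac = laser_post_frac,
    laser_only_frac = laser_only_frac,
    seed = seed), class = "task_config")
}

#' Behavioral agent configuration
#'
#' Parameterizes a stochastic agent that performs the task at a target
#' steady-state performance and switches rules through feedback: after a
#' block switch the agent keeps following the old rule until its first
#' unrewarded lick, then adopts the new rule with a per-trial probability,
#' and deterministically at the cue trial.
#'
#' @param p_hit Probability of licking the correct port given a stimulus the
#'   agent's current rule treats as relevant (default 0.75, yielding ~75%
#'   correct at steady state together with `p_fa`).
#' @param p_fa Probability of licking given a stimulus the agent's rule
#'   treats as irrelevant (default 0.25).
#' @param p_switch_after_feedback Per-trial probability of adopting the new
#'   rule once post-switch feedback (an unrewarded lick) has occurred.
#' @param p_prestim_lick Probability that a trial carries a spontaneous lick
#'   in the second before stimulus onset (default 0.25, matching the ~25%
#'   of trials excluded by the pre-stimulus lick filter).
#' @param lick_latency Function `(n) -> seconds` drawing lick latencies with
#'   support above the grace period (default 0.1 s + gamma(2, scale 0.15)).
#' @param laser_hit_penalty Reduction of `p_hit` on laser-inhibition trials
#'   (default 0; used to emulate optogenetic detection deficits).
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(p_hit = 0.75,
                         p_fa = 0.25,
                         p_switch_after_feedback = 0.5,
                         p_prestim_lick = 0.25,
                         lick_latency = function(n)
                           0.1 + stats::rgamma(n, shape = 2, scale = 0.15),
                         laser_hit_penalty = 0) {
  check_prob(p_hit, "p_hit")
  check_prob(p_fa, "p_fa")
  check_prob(p_switch_after_feedback, "p_switch_after_feedback")
  check_prob(p_prestim_lick, "p_prestim_lick")
  if (!is.function(lick_latency))
    config_error("lick_latency", "must be a function of n")
  if (!is.numeric(laser_hit_penalty) || laser_hit_penalty < 0 ||
      laser_hit_penalty > 1)
    config_error("laser_hit_penalty", "must be in [0, 1]")
  structure(list(p_hit = p_hit, p_fa = p_fa,
                 p_switch_after_feedback = p_switch_after_feedback,
                 p_prestim_lick = p_prestim_lick,
                 lick_latency = lick_latency,
                 laser_hit_penalty = laser_hit_penalty),
            class = "agent_config")
}

# Area-profile default fractions. Rule-modulated fractions follow the
# reported per-area percentages of pre-stimulus rule-discriminating units;
# stimulus-responsive fractions are set so that evoked discriminability has
# the qualitative sensory-to-motor gradient of the recorded areas.
area_profiles <- list(
  "S1-like"  = list(frac_rule_mod = 0.045, frac_touch_resp = 0.60,
                    frac_light_resp = 0.05),
  "S2-like"  = list(frac_rule_mod = 0.025, frac_touch_resp = 0.50,
                    frac_light_resp = 0.10),
  "MM-like"  = list(frac_rule_mod = 0.214, frac_touch_resp = 0.30,
                    frac_light_resp = 0.15),
  "ALM-like" = list(frac_rule_mod = 0.102, frac_touch_resp = 0.25,
                    frac_light_resp = 0.05))

#' Population (spiking) configuration
#'
#' Parameterizes the Poisson rate model of a simulated population: log-normal
#' baseline rates, a multiplicative pre-stimulus rule gain for a fraction of
#' units, a half-sine evoked transient for stimulus-responsive units scaled
#' up when the stimulus is relevant under the agent's current rule, and a
#' lick-locked linear ramp on lick trials for choice-responsive units.
#'
#' @param n_units Number of simultaneously recorded units.
#' @param area_profile One of `"S1-like"`, `"S2-like"`, `"MM-like"`,
#'   `"ALM-like"`; selects default modulation fractions.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-unit
#'   baseline rates in spikes/s (defaults log(8) and 0.7).
#' @param frac_rule_mod Fraction of units with rule-dependent baseline;
#'   `NULL` takes the area profile's value.
#' @param rule_gain Multiplicative baseline change in a unit's preferred-rule
#'   blocks (default 2).
#' @param frac_touch_resp,frac_light_resp Fractions of tactile-/visual-
#'   responsive units; `NULL` takes the area profile's values.
#' @param evoked_amp Peak evoked transient amplitude, spikes/s (default 20).
#' @param relevance_gain Multiplier on the evoked response when the stimulus
#'   is relevant under the agent's current rule (default 1.5).
#' @param choice_amp Peak lick-locked ramp amplitude, spikes/s (default 10).
#' @param frac_choice Fraction of units with the choice ramp (default 0.3).
#' @param rule_rotation Rotation of the population evoked pattern between
#'   rule contexts, as a mixing weight in [0, 1]: 0 keeps the relevant- and
#'   irrelevant-context patterns identical up to the relevance gain, 1
#'   replaces the irrelevant-context pattern with an independent one
#'   (default 0.5).
#' @param seed Optional integer seed stored with the config.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_units = 40L,
                              area_profile = "MM-like",
                              baseline_meanlog = log(8),
                              baseline_sdlog = 0.7,
                              frac_rule_mod = NULL,
                              rule_gain = 2.0,
                              frac_touch_resp = NULL,
                              frac_light_resp = NULL,
                              evoked_amp = 20,
                              relevance_gain = 1.5,
                              choice_amp = 10,
                              frac_choice = 0.3,
                              rule_rotation = 0.5,
                              seed = NULL) {
  if (!area_profile %in% names(area_profiles))
    config_error("area_profile",
                 paste("must be one of", paste(names(area_profiles),
                                               collapse = ", ")))
  prof <- area_profiles[[area_profile]]
  frac_rule_mod <- frac_rule_mod %||% prof$frac_rule_mod
  frac_touch_resp <- frac_touch_resp %||% prof$frac_touch_resp
  frac_light_resp <- frac_light_resp %||% prof$frac_light_resp
  if (!is.numeric(n_units) || n_units < 1)
    config_error("n_units", "must be a positive integer")
  check_prob(frac_rule_mod, "frac_rule_mod")
  check_prob(frac_touch_resp, "frac_touch_resp")
  check_prob(frac_light_resp, "frac_light_resp")
  check_prob(frac_choice, "frac_choice")
  check_prob(rule_rotation, "rule_rotation")
  for (f in c("rule_gain", "evoked_amp", "relevance_gain", "choice_amp")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      config_error(f, "must be a number")
  }
  structure(list(n_units = as.integer(n_units), area_profile = area_profile,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 frac_rule_mod = frac_rule_mod, rule_gain = rule_gain,
                 frac_touch_resp = frac_touch_resp,
                 frac_light_resp = frac_light_resp,
                 evoked_amp = evoked_amp, relevance_gain = relevance_gain,
                 choice_amp = choice_amp, frac_choice = frac_choice,
                 rule_rotation = rule_rotation,
                 seed = seed), class = "population_config")
}
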