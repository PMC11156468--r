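# Behavioral scoring, performance, sensitivity, and rule-transition parsing.

# First lick inside the answer window, or NA. Later licks are ignored for
# outcome and port determination.
first_answer_lick <- function(licks, cfg) {
  ans <- licks[licks$time >= cfg$answer_window[1] &
               licks$time <= cfg$answer_window[2], , drop = FALSE]
  if (!nrow(ans)) return(NULL)
  ans[which.min(ans$time), , drop = FALSE]
}

# Outcome of a single stimulus trial. Censor-window licks censor the trial;
# grace-window licks are ignored; the first answer-window lick determines
# the port.
score_one_trial <- function(block_rule, modality, licks, cfg) {
  if (modality == "none") return(NA_character_)
  if (any(licks$time >= cfg$censor_window[1] &
          licks$time < cfg$censor_window[2])) return("censored")
  lk <- first_answer_lick(licks, cfg)
  relevant <- modality == rule_modality[[block_rule]]
  if (relevant) {
    if (is.null(lk)) return("miss")
    if (lk$port == rule_port[[block_rule]]) "hit" else "false_alarm"
  } else {
    if (is.null(lk)) "correct_rejection" else "false_alarm"
  }
}

#' Score trial outcomes
#'
#' Fills the `outcome` column from rule, modality and licks: a lick at the
#' rewarded port within the answer window on a relevant stimulus is a hit;
#' no qualifying lick on a relevant stimulus is a miss; any answer-window
#' lick on an irrelevant stimulus, or a lick to the incorrect port, is a
#' false alarm; withholding on an irrelevant stimulus is a correct
#' rejection. Licks during the grace window are ignored; trials with a lick
#' in the censor window are marked `censored` and are excluded from all
#' downstream rates. Laser-only trials (no sensory stimulus) receive `NA`.
#'
#' @param trials Trial table with `block_rule`, `modality`, `licks`.
#' @param cfg The [task_config()] defining the scoring windows.
#' @return The trial table with the `outcome` column filled.
#' @export
score_outcomes <- function(trials, cfg = task_config()) {
  assert_trial_table(trials)
  bad <- trials$modality == "none" &
    !trials$laser %in% c("laser_only_short", "laser_only_long")
  if (any(bad))
    structural_error("trial with modality 'none' outside a laser-only trial")
  trials$outcome <- vapply(seq_len(nrow(trials)), function(i)
    score_one_trial(trials$block_rule[i], trials$modality[i],
                    trials$licks[[i]], cfg), character(1))
  trials
}

scored_stim_trials <- function(trials) {
  trials[!is.na(trials$outcome) & trials$outcome != "censored" &
           trials$modality != "none", , drop = FALSE]
}

#' Summarize trial outcomes per rule
#'
#' Outcome fractions (hit, miss, false alarm, correct rejection) and percent
#' correct, per rule and overall, over scored non-censored stimulus trials.
#' Percent correct is 100 * (hits + correct rejections) / total.
#'
#' @param trials Scored trial table.
#' @return List with per-rule rows (`touch`, `light`), an `overall` percent
#'   correct, and `empty_rules` naming rules with zero trials.
#' @export
outcome_summary <- function(trials) {
  tt <- scored_stim_trials(trials)
  per_rule <- lapply(c(touch = "touch", light = "light"), function(r) {
    x <- tt[tt$block_rule == r, ]
    n <- nrow(x)
    if (n == 0)
      return(list(hit_rate = NA_real_, miss_rate = NA_real_,
                  fa_rate = NA_real_, cr_rate = NA_real_,
                  percent_correct = NA_real_, n_trials = 0L))
    f <- function(o) sum(x$outcome == o) / n
    list(hit_rate = f("hit"), miss_rate = f("miss"),
         fa_rate = f("false_alarm"), cr_rate = f("correct_rejection"),
         percent_correct = 100 * (f("hit") + f("correct_rejection")),
         n_trials = n)
  })
  overall <- if (nrow(tt)) {
    100 * mean(tt$outcome %in% c("hit", "correct_rejection"))
  } else NA_real_
  empty <- names(per_rule)[vapply(per_rule,
                                  function(p) p$n_trials == 0L, logical(1))]
  structure(list(touch = per_rule$touch, light = per_rule$light,
                 overall_percent_correct = overall, empty_rules = empty),
            class = "outcome_summary")
}

#' Percent correct from outcome fractions
#'
#' The printed formula applied directly to hit and correct-rejection
#' fractions.
#' @param hit_rate,cr_rate Fractions of trials.
#' @return Percent correct (0-100).
#' @export
percent_correct <- function(hit_rate, cr_rate) 100 * (hit_rate + cr_rate)

map_laser_condition <- function(condition) {
  switch(condition,
         control = "none", sham = "none",
         laser_pre = "pre", laser_post = "post",
         config_error("condition", "unknown laser condition"))
}

#' Detection sensitivity for one modality
#'
#' Cross-modal task: tactile sensitivity is the probability of a right lick
#' given a tactile stimulus minus the probability of a right lick given a
#' visual stimulus, both within respond-to-touch blocks; visual sensitivity
#' is the left-lick analogue within respond-to-light blocks. Simple
#' detection task: hit rate (Go) minus false-alarm rate (NoGo).
#'
#' @param trials Scored trial table.
#' @param modality `"tactile"` or `"visual"`.
#' @param condition `"control"`, `"sham"`, `"laser_pre"` or `"laser_post"`.
#' @param cfg The [task_config()] (answer window).
#' @param task `"cross"` (default) or `"simple"` (Go/NoGo detection).
#' @return List with `sensitivity`, `hit_rate`, `fa_rate`, `n_hit_trials`,
#'   `n_fa_trials`, `missing` (TRUE when a cell is empty).
#' @export
detection_sensitivity <- function(trials, modality = "tactile",
                                  condition = "control",
                                  cfg = task_config(), task = "cross") {
  tt <- trials[!is.na(trials$outcome) & trials$outcome != "censored", ]
  tt <- tt[tt$laser == map_laser_condition(condition), ]
  lick_port <- vapply(tt$licks, function(lk) {
    a <- first_answer_lick(lk, cfg)
    if (is.null(a)) NA_character_ else a$port
  }, character(1))
  if (task == "simple") {
    go <- tt$modality == "tactile"
    nogo <- tt$modality == "none"
    if (!any(go) || !any(nogo))
      return(list(sensitivity = NA_real_, hit_rate = NA_real_,
                  fa_rate = NA_real_, n_hit_trials = sum(go),
                  n_fa_trials = sum(nogo), missing = TRUE))
    hr <- mean(!is.na(lick_port[go]))
    fr <- mean(!is.na(lick_port[nogo]))
  } else {
    rule <- if (modality == "tactile") "touch" else "light"
    port <- rule_port[[rule]]
    blk <- tt$block_rule == rule & tt$modality != "none"
    sig <- blk & tt$modality == rule_modality[[rule]]
    dis <- blk & tt$modality != rule_modality[[rule]]
    if (!any(sig) || !any(dis))
      return(list(sensitivity = NA_real_, hit_rate = NA_real_,
                  fa_rate = NA_real_, n_hit_trials = sum(sig),
                  n_fa_trials = sum(dis), missing = TRUE))
    hr <- mean(!is.na(lick_port[sig]) & lick_port[sig] == port)
    fr <- mean(!is.na(lick_port[dis]) & lick_port[dis] == port)
    go <- sig; nogo <- dis
  }
  list(sensitivity = hr - fr, hit_rate = hr, fa_rate = fr,
       n_hit_trials = sum(go), n_fa_trials = sum(nogo), missing = FALSE)
}

#' Change in detection sensitivity between two conditions
#'
#' Per-session sensitivities are computed for both conditions, differenced,
#' and summarized with a hierarchical bootstrap over mice then sessions.
#' Significance is declared when the 95% CI excludes zero.
#'
#' @param trials Scored trial table, possibly spanning several sessions and
#'   mice (distinguished by `session_id` / `mouse_id`).
#' @param modality `"tactile"` or `"visual"`.
#' @param condition_a,condition_b Condition labels as in
#'   [detection_sensitivity()]; the difference is a minus b.
#' @param cfg The [task_config()].
#' @param task `"cross"` or `"simple"`.
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed.
#' @return A `resample_ci` (see [hierarchical_bootstrap()]), or a missing
#'   marker when a condition has no usable sessions.
#' @export
delta_sensitivity <- function(trials, modality = "tactile",
                              condition_a = "laser_pre",
                              condition_b = "control",
                              cfg = task_config(), task = "cross",
                              n_iter = 1000L, seed = NULL) {
  rows <- lapply(split(trials, trials$session_id), function(ss) {
    a <- detection_sensitivity(ss, modality, condition_a, cfg, task)
    b <- detection_sensitivity(ss, modality, condition_b, cfg, task)
    if (a$missing || b$missing) return(NULL)
    data.frame(mouse_id = ss$mouse_id[1], session_id = ss$session_id[1],
               delta = a$sensitivity - b$sensitivity,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df))
    return(list(estimate = NA_real_, missing = TRUE))
  levels <- c("mouse_id", "session_id")
  if (length(unique(df$mouse_id)) == 1L) {
    warning("single mouse: CI degenerates to a session-level bootstrap")
    levels <- "session_id"
  }
  hierarchical_bootstrap(df, function(d) mean(d$delta), levels,
                         n_iter = n_iter, seed = seed)
}

laser_only_windows <- function(laser) {
  # Windows in seconds relative to the trial's nominal stimulus onset.
  # Short trains run -0.8..0 (pre-type), long trains 0..2 (post-type).
  if (laser == "laser_only_short")
    list(response = c(0, 2), iti = c(-2.8, -0.8))
  else list(response = c(2, 4), iti = c(-2, 0))
}

#' Lick-probability change on laser-only catch trials
#'
#' Compares the probability of licking during the response window (0-2 s
#' from laser offset) with the probability of licking during the preceding
#' intertrial interval (2 s before laser onset), per session, with a
#' mouse-level hierarchical bootstrap CI.
#'
#' @param trials Scored trial table containing laser-only trials.
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed.
#' @return A `resample_ci` over the per-session probability differences, or
#'   a missing marker when no laser-only trials exist.
#' @export
laser_only_lick_change <- function(trials, n_iter = 1000L, seed = NULL) {
  lo <- trials[trials$laser %in% c("laser_only_short", "laser_only_long"), ]
  if (!nrow(lo)) return(list(estimate = NA_real_, missing = TRUE))
  any_lick_in <- function(lk, w) any(lk$time >= w[1] & lk$time <= w[2])
  rows <- lapply(split(lo, lo$session_id), function(ss) {
    p <- vapply(seq_len(nrow(ss)), function(i) {
      w <- laser_only_windows(ss$laser[i])
      c(any_lick_in(ss$licks[[i]], w$response),
        any_lick_in(ss$licks[[i]], w$iti))
    }, logical(2))
    data.frame(mouse_id = ss$mouse_id[1], session_id = ss$session_id[1],
               delta = mean(p[1, ]) - mean(p[2, ]), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  levels <- if (length(unique(df$mouse_id)) > 1L)
    c("mouse_id", "session_id") else "session_id"
  hierarchical_bootstrap(df, function(d) mean(d$delta), levels,
                         n_iter = n_iter, seed = seed)
}

#' Parse rule transitions of a session
#'
#' For every block switch, the transition period spans the first trial of
#' the new block through its first hit, inclusive. The period is split at
#' the first false alarm: trials up to and including the first FA are
#' "early" (feedback arrives with that trial's outcome), later transition
#' trials are "late". Blocks without an FA before the first hit are all
#' early; blocks with no hit at all are flagged open and should be excluded
#' from rank-correlation analyses.
#'
#' @param trials Scored trial table for one session.
#' @return List of transition parses, one per block switch, each with
#'   `block_index`, `direction`, `switch_trial` (trial index of the new
#'   block's first trial), `first_fa`, `first_hit` (trial indices or NA),
#'   `early_trials`, `late_trials` (trial-index sets), and `complete`.
#' @export
parse_transitions <- function(trials) {
  assert_trial_table(trials)
  if (all(is.na(trials$outcome)))
    structural_error("trials must be scored before parsing transitions")
  blocks <- sort(unique(trials$block_index))
  out <- list()
  for (b in blocks[-1]) {
    blk <- trials[trials$block_index == b, ]
    prev_rule <- trials$block_rule[trials$block_index == b - 1][1]
    scored <- blk[!is.na(blk$outcome) & blk$outcome != "censored", ]
    hit_i <- scored$trial_index[scored$outcome == "hit"]
    fa_i <- scored$trial_index[scored$outcome == "false_alarm"]
    first_hit <- if (length(hit_i)) min(hit_i) else NA_integer_
    complete <- !is.na(first_hit)
    period <- if (complete) {
      scored$trial_index[scored$trial_index <= first_hit]
    } else scored$trial_index
    first_fa <- if (length(fa_i) && complete && min(fa_i) <= first_hit) {
      min(fa_i)
    } else if (length(fa_i) && !complete) min(fa_i) else NA_integer_
    early <- if (is.na(first_fa)) period else period[period <= first_fa]
    late <- setdiff(period, early)
    out[[length(out) + 1L]] <- list(
      block_index = b,
      direction = paste0(prev_rule, "_to_", blk$block_rule[1]),
      switch_trial = blk$trial_index[1],
      first_fa = first_fa, first_hit = first_hit,
      early_trials = early, late_trials = late,
      complete = complete)
  }
  out
}

#' Lick probabilities around block switches and first-hit histogram
#'
#' Right- and left-lick probabilities by trial offset from the block switch
#' (offset 1 = first trial of the new block; offsets <= 0 reach into the
#' old block), averaged across switches within mouse and then across mice,
#' with a bootstrap CI over mice. Also returns the distribution of the
#' trial-in-block of each block's first hit, per transition direction.
#'
#' @param trials Scored trial table (may span sessions/mice).
#' @param offsets Integer trial offsets to evaluate.
#' @param cfg The [task_config()].
#' @param n_iter Bootstrap iterations for the mouse-level CI.
#' @param seed Integer seed.
#' @return List with `curves` (data.frame: direction, offset, port,
#'   probability, lo, hi) and `first_hit` (data.frame: direction,
#'   trial_in_block).
#' @export
transition_lick_curves <- function(trials, offsets = -10:15,
                                   cfg = task_config(), n_iter = 200L,
                                   seed = NULL) {
  per_mouse <- list(); first_hit <- list()
  for (ss in split(trials, trials$session_id)) {
    parses <- parse_transitions(ss)
    ports <- vapply(ss$licks, function(lk) {
      a <- first_answer_lick(lk, cfg)
      if (is.null(a)) NA_character_ else a$port
    }, character(1))
    for (p in parses) {
      sw_row <- which(ss$trial_index == p$switch_trial)
      rows <- sw_row + offsets - 1L
      ok <- rows >= 1 & rows <= nrow(ss)
      for (port in c("right", "left")) {
        per_mouse[[length(per_mouse) + 1L]] <- data.frame(
          mouse_id = ss$mouse_id[1], direction = p$direction,
          offset = offsets[ok], port = port,
          lick = as.numeric(!is.na(ports[rows[ok]]) &
                              ports[rows[ok]] == port),
          stringsAsFactors = FALSE)
      }
      if (p$complete)
        first_hit[[length(first_hit) + 1L]] <- data.frame(
          direction = p$direction,
          trial_in_block = ss$trial_in_block[ss$trial_index == p$first_hit],
          stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, per_mouse)
  if (is.null(long)) structural_error("no block switches found")
  agg_m <- stats::aggregate(lick ~ mouse_id + direction + offset + port,
                            long, mean)
  curves <- do.call(rbind, lapply(
    split(agg_m, list(agg_m$direction, agg_m$offset, agg_m$port),
          drop = TRUE),
    function(g) {
      ci <- hierarchical_bootstrap(
        data.frame(mouse_id = g$mouse_id, v = g$lick),
        function(d) mean(d$v), "mouse_id", n_iter = n_iter, seed = seed)
      data.frame(direction = g$direction[1], offset = g$offset[1],
                 port = g$port[1], probability = mean(g$lick),
                 lo = ci$lo, hi = ci$hi, stringsAsFactors = FALSE)
    }))
  rownames(curves) <- NULL
  list(curves = curves, first_hit = do.call(rbind, first_hit))
}

#' Session quality control
#'
#' Removes the last 20 trials, then applies the study's inclusion
#' thresholds to the trimmed session: overall performance >= 60% correct,
#' both block-rule performances >= 55%, and both modality hit rates >= 35%.
#' For optogenetic sessions, thresholds are computed on non-laser trials
#' only, and sessions whose laser catch rate exceeds 75% or the hit rate
#' are dropped.
#'
#' @param trials Scored trial table for one session.
#' @param cfg The [task_config()].
#' @return List with `keep` (logical), `reasons` (character), and `trials`
#'   (the trimmed table).
#' @export
session_qc <- function(trials, cfg = task_config()) {
  reasons <- character(0)
  if (nrow(trials) <= 20) {
    return(list(keep = FALSE, reasons = "session shorter than 20 trials",
                trials = trials[0, ]))
  }
  tt <- trials[seq_len(nrow(trials) - 20L), ]
  base <- scored_stim_trials(tt[tt$laser == "none", ])
  if (!nrow(base))
    return(list(keep = FALSE, reasons = "no scorable non-laser trials",
                trials = tt))
  overall <- 100 * mean(base$outcome %in% c("hit", "correct_rejection"))
  if (overall < 60)
    reasons <- c(reasons, sprintf("overall performance %.1f%% < 60%%",
                                  overall))
  for (r in intersect(c("touch", "light"), unique(base$block_rule))) {
    x <- base[base$block_rule == r, ]
    pc <- 100 * mean(x$outcome %in% c("hit", "correct_rejection"))
    if (pc < 55)
      reasons <- c(reasons, sprintf("%s-block performance %.1f%% < 55%%",
                                    r, pc))
  }
  hit_rates <- c()
  for (m in c("tactile", "visual")) {
    r <- if (m == "tactile") "touch" else "light"
    x <- base[base$block_rule == r & base$modality == m, ]
    if (!nrow(x)) next
    hr <- 100 * sum(x$outcome == "hit") /
      max(1L, sum(x$outcome %in% c("hit", "miss")))
    hit_rates <- c(hit_rates, hr)
    if (hr < 35)
      reasons <- c(reasons, sprintf("%s hit rate %.1f%% < 35%%", m, hr))
  }
  lo <- tt[tt$laser %in% c("laser_only_short", "laser_only_long"), ]
  if (nrow(lo)) {
    answered <- vapply(lo$licks, function(lk)
      !is.null(first_answer_lick(lk, cfg)), logical(1))
    catch <- 100 * mean(answered)
    if (catch > 75)
      reasons <- c(reasons, sprintf("laser catch rate %.1f%% > 75%%", catch))
    else if (length(hit_rates) && catch > min(hit_rates))
      reasons <- c(reasons, "laser catch rate exceeds hit rate")
  }
  list(keep = length(reasons) == 0L, reasons = reasons, trials = tt)
}
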