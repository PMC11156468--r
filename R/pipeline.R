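# End-to-end orchestration: simulate -> score/QC -> preprocess -> discrim
# -> decode -> geometry -> consolidated report.

#' Pipeline configuration
#'
#' Stage toggles and per-stage parameter blocks mirroring each module's
#' defaults. Unknown keys are rejected so typos fail loudly. Every
#' stochastic stage receives a seed derived from the single master seed.
#'
#' @param n_sessions,n_mice Simulated experiment size.
#' @param area Area profile label for the population generator.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param stages Character subset of
#'   `c("simulate", "behavior", "preprocess", "discrim", "decode",
#'   "geometry")`.
#' @param task,agent,pop Stage configs ([task_config()], [agent_config()],
#'   [population_config()]); `pop`'s `area_profile` is overridden by
#'   `area`.
#' @param n_boot,n_perm,n_shuffle Resampling sizes used by the analysis
#'   stages.
#' @param ... Rejected; present to catch unknown keys.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_sessions = 4L, n_mice = 2L,
                            area = "MM-like", seed = 1L, out_dir = NULL,
                            stages = c("simulate", "behavior",
                                       "preprocess", "discrim", "decode",
                                       "geometry"),
                            task = task_config(), agent = agent_config(),
                            pop = NULL, n_boot = 200L, n_perm = 200L,
                            n_shuffle = 20L, ...) {
  extra <- list(...)
  if (length(extra))
    config_error(names(extra)[1], "unknown pipeline configuration key")
  known <- c("simulate", "behavior", "preprocess", "discrim", "decode",
             "geometry")
  bad <- setdiff(stages, known)
  if (length(bad)) config_error("stages", paste("unknown stage:", bad[1]))
  pop <- pop %||% population_config(area_profile = area)
  pop$area_profile <- area
  structure(list(n_sessions = n_sessions, n_mice = n_mice, area = area,
                 seed = seed, out_dir = out_dir, stages = stages,
                 task = task, agent = agent, pop = pop, n_boot = n_boot,
                 n_perm = n_perm, n_shuffle = n_shuffle),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %%
            .Machine$integer.max)
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Executes the enabled stages in dependency order on a simulated
#' multi-session experiment and returns a consolidated report; optionally
#' writes per-stage CSV/JSON artifacts. Stage seeds are derived from the
#' master seed, and the report records the package version, a config
#' hash, and all stage seeds, so reruns are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with one element per enabled stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(meta = list(
    package_version = as.character(utils::packageVersion("xmodal")),
    config_hash = config_hash(config), seed = config$seed,
    stage_seeds = list()))
  seeds <- function(stage) {
    s <- derive_seed(config$seed, stage)
    out$meta$stage_seeds[[stage]] <<- s
    s
  }
  emit <- function(name, obj) {
    if (is.null(config$out_dir)) return(invisible())
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(obj, file.path(config$out_dir,
                                        paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  if (!"simulate" %in% config$stages)
    structural_error("pipeline requires the simulate stage")
  sessions <- simulate_experiment(config$n_sessions, config$n_mice,
                                  config$task, config$agent, config$pop,
                                  seed = seeds("simulate"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in sessions) {
      write_trial_table(s$trials, file.path(
        config$out_dir, paste0(s$trials$session_id[1], "_trials.csv")))
      if (!is.null(s$spikes))
        write_spike_set(s$spikes, file.path(
          config$out_dir, paste0(s$trials$session_id[1], "_spikes.csv")))
    }
  }

  if ("behavior" %in% config$stages) {
    qc <- lapply(sessions, function(s) session_qc(s$trials, config$task))
    kept <- vapply(qc, `[[`, logical(1), "keep")
    all_trials <- do.call(rbind, lapply(which(kept), function(i)
      qc[[i]]$trials))
    out$behavior <- list(
      sessions_kept = sum(kept), sessions_total = length(sessions),
      summary = unclass(outcome_summary(all_trials)))
    tl <- transition_lick_curves(all_trials, cfg = config$task,
                                 n_iter = 100L,
                                 seed = seeds("behavior"))
    out$behavior$first_hit_median <-
      stats::median(tl$first_hit$trial_in_block)
    # Downstream stages use QC-passed, trimmed sessions.
    sessions <- lapply(which(kept), function(i) {
      s <- sessions[[i]]
      s$trials <- qc[[i]]$trials
      s
    })
    emit("behavior", out$behavior)
  }

  per_session <- lapply(sessions, function(s) {
    env <- list(trials = s$trials)
    if (!is.null(s$spikes)) {
      sp <- unit_qc_filter(s$spikes)
      env$spikes <- sp
      if ("preprocess" %in% config$stages && length(sp$spikes)) {
        clean <- exclude_prestim_lick_trials(s$trials)
        env$trials_clean <- clean
        tens <- bin_rates(sp, clean, window = c(-0.1, 0.15),
                          bin_size = 0.01, sigma = 0.05)
        env$tensor <- soft_normalize(tens)
        env$tensor_pre <- soft_normalize(
          bin_rates(sp, clean, window = c(-0.1, 0), bin_size = 0.1))
        env$tensor_post <- soft_normalize(
          bin_rates(sp, clean, window = c(0, 0.1), bin_size = 0.1))
      }
    }
    env
  })

  if ("discrim" %in% config$stages) {
    sd_seed <- seeds("discrim")
    res <- lapply(per_session, function(e) {
      if (is.null(e$tensor_pre)) return(NULL)
      d <- prestim_discrim(e$tensor_pre, e$trials_clean, "rule",
                           n_boot = config$n_boot, seed = sd_seed)
      data.frame(session_id = e$trials$session_id[1],
                 frac_significant = mean(d$significant),
                 mean_auc = mean(d$auc), stringsAsFactors = FALSE)
    })
    out$discrim <- do.call(rbind, res)
    emit("discrim", out$discrim)
  }

  if ("decode" %in% config$stages) {
    dc_seed <- seeds("decode")
    res <- lapply(per_session, function(e) {
      if (is.null(e$tensor_pre)) return(NULL)
      d <- decode(e$tensor_pre, e$trials_clean, target = "rule",
                  classifier = "lda", n_shuffle = config$n_shuffle,
                  seed = dc_seed)
      data.frame(session_id = e$trials$session_id[1],
                 accuracy = d$accuracy,
                 accuracy_shuffled = d$accuracy_shuffled,
                 n_units = d$n_units, stringsAsFactors = FALSE)
    })
    out$decode <- do.call(rbind, res)
    # Transition tracking per direction.
    tr <- lapply(per_session, function(e) {
      if (is.null(e$tensor_pre)) return(NULL)
      parses <- parse_transitions(e$trials)
      lapply(c("touch_to_light", "light_to_touch"), function(dir)
        transition_classify(e$tensor_pre, e$trials_clean, parses, dir,
                            seed = dc_seed))
    })
    tr <- Filter(Negate(is.null), tr)
    if (length(tr)) {
      out$transition <- lapply(c(1, 2), function(j) {
        rs <- lapply(tr, `[[`, j)
        rs <- Filter(function(r) !isTRUE(r$missing), rs)
        if (length(rs) < 2L) return(NULL)
        ci <- transition_tau_summary(rs, n_iter = 200L, seed = dc_seed)
        list(direction = rs[[1]]$direction, mean_tau = ci$estimate,
             lo = ci$lo, hi = ci$hi, significant = ci$significant)
      })
    }
    emit("decode", out$decode)
  }

  if ("geometry" %in% config$stages) {
    gm_seed <- seeds("geometry")
    res <- lapply(per_session, function(e) {
      if (is.null(e$tensor)) return(NULL)
      ov <- subspace_overlap(e$tensor, e$trials_clean, seed = gm_seed)
      if (isTRUE(ov$missing)) return(NULL)
      data.frame(session_id = e$trials$session_id[1],
                 overlap_tCR = ov$overlap_tCR,
                 overlap_control_tHit = ov$overlap_control_tHit,
                 overlap_prestim_tCR = ov$overlap_prestim_tCR,
                 stringsAsFactors = FALSE)
    })
    out$geometry <- do.call(rbind, res)
    dists <- lapply(per_session, function(e) {
      if (is.null(e$tensor)) return(NULL)
      mdl <- try(fit_trajectory_pca(e$tensor, e$trials_clean),
                 silent = TRUE)
      if (inherits(mdl, "try-error")) return(NULL)
      try(trajectory_distance(mdl, e$tensor, e$trials_clean),
          silent = TRUE)
    })
    dists <- Filter(function(d) is.numeric(d), dists)
    if (length(dists) >= 4L)
      out$geometry_split <- split_distance_permutation(
        dists, n_perm = config$n_perm, seed = gm_seed)[c("p", "observed")]
    emit("geometry", out$geometry)
  }

  if (!is.null(config$out_dir))
    emit("report", out[setdiff(names(out), "meta")])
  class(out) <- "pipeline_report"
  out
}
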