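# Shared fixtures, all built in code. A single moderately sized simulated
# session is memoized and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture_session <- function() {
  if (is.null(.fixture_env$sess)) {
    sess <- simulate_session(seed = 42,
                             pop = population_config(n_units = 20),
                             session_id = "fix1", mouse_id = "mA")
    sp <- unit_qc_filter(sess$spikes)
    clean <- exclude_prestim_lick_trials(sess$trials)
    .fixture_env$sess <- list(
      trials = sess$trials, spikes = sp, clean = clean,
      pre = soft_normalize(bin_rates(sp, clean, c(-0.1, 0), 0.1)),
      post = soft_normalize(bin_rates(sp, clean, c(0, 0.1), 0.1)),
      full = soft_normalize(bin_rates(sp, clean, c(-0.1, 0.15), 0.01,
                                      sigma = 0.05)))
  }
  .fixture_env$sess
}

lick_df <- function(time = numeric(0), port = character(0)) {
  data.frame(time = time, port = port, stringsAsFactors = FALSE)
}

# Minimal hand-built trial table.
make_trials <- function(block_rule, modality, licks = NULL,
                        outcome = NULL, block_index = NULL,
                        laser = "none", session_id = "t1",
                        mouse_id = "m1") {
  n <- length(block_rule)
  block_index <- block_index %||% rep(1L, n)
  tib <- stats::ave(seq_len(n), block_index, FUN = seq_along)
  df <- data.frame(
    session_id = session_id, mouse_id = mouse_id,
    block_index = block_index, block_rule = block_rule,
    trial_index = seq_len(n), trial_in_block = tib,
    modality = modality, stim_onset = 10 * seq_len(n),
    licks = I(licks %||% rep(list(lick_df()), n)),
    laser = rep(laser, length.out = n),
    cue = tib == 9L,
    outcome = outcome %||% rep(NA_character_, n),
    stringsAsFactors = FALSE)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built rate tensor (units x trials x bins array).
make_tensor <- function(values, bin_starts, bin_size,
                        trial_index = seq_len(dim(values)[2]),
                        unit_ids = sprintf("u%02d", seq_len(dim(values)[1])),
                        normalized = TRUE) {
  structure(list(values = values, bin_size = bin_size,
                 window = c(bin_starts[1],
                            bin_starts[length(bin_starts)] + bin_size),
                 align = "stim_onset", sigma = 0, normalized = normalized,
                 norm_params = NULL, unit_ids = unit_ids,
                 trial_index = trial_index, bin_starts = bin_starts),
            class = "rate_tensor")
}

# Hand-built spike set.
make_spike_set <- function(spike_list, t_end = NULL, l_ratio = 0.05,
                           drift_um = 10) {
  n <- length(spike_list)
  ids <- sprintf("u%02d", seq_len(n))
  names(spike_list) <- ids
  structure(list(
    units = data.frame(unit_id = ids, area = "toy",
                       l_ratio = rep(l_ratio, length.out = n),
                       drift_um = rep(drift_um, length.out = n),
                       stringsAsFactors = FALSE),
    spikes = spike_list,
    t_end = t_end %||% max(unlist(spike_list), 1)),
    class = "spike_set")
}
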