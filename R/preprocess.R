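# Spike-train preprocessing: unit QC, binning, smoothing, soft normalization.

#' Unit quality-control filter
#'
#' Computes the inter-spike-interval violation rate (fraction of ISIs below
#' 1.5 ms; threshold 0.5%) and the presence ratio (fraction of ten equal
#' session segments containing at least one spike; threshold 90%) from the
#' spike trains, and applies supplied L-ratio (<= 0.1) and cumulative drift
#' (<= 40 um) thresholds as pass-throughs. A unit is kept only if all four
#' checks pass; a missing supplied metric keeps the unit with a warning.
#'
#' @param spikes A `spike_set`.
#' @param session_span Numeric pair: session start and end, seconds
#'   (defaults to `c(0, spikes$t_end)`).
#' @param isi_threshold,isi_window,presence_threshold,l_ratio_max,drift_max
#'   QC thresholds; defaults are the study's.
#' @return The `spike_set` restricted to passing units, with a `qc`
#'   data.frame (per-unit metrics and verdicts) attached.
#' @export
unit_qc_filter <- function(spikes, session_span = NULL,
                           isi_threshold = 0.005, isi_window = 0.0015,
                           presence_threshold = 0.9,
                           l_ratio_max = 0.1, drift_max = 40) {
  stopifnot(inherits(spikes, "spike_set"))
  span <- session_span %||% c(0, spikes$t_end)
  edges <- seq(span[1], span[2], length.out = 11L)
  qc <- do.call(rbind, lapply(seq_along(spikes$spikes), function(u) {
    st <- spikes$spikes[[u]]
    isi <- diff(st)
    viol <- if (length(isi)) mean(isi < isi_window) else 0
    seg <- findInterval(st, edges, rightmost.closed = TRUE)
    presence <- length(unique(seg[seg >= 1 & seg <= 10])) / 10
    data.frame(unit_id = spikes$units$unit_id[u],
               isi_violation_rate = viol, presence_ratio = presence,
               stringsAsFactors = FALSE)
  }))
  lr <- spikes$units$l_ratio
  dr <- spikes$units$drift_um
  if (is.null(lr) || anyNA(lr)) {
    warning("L-ratio unavailable for some units; kept with flag")
    lr <- ifelse(is.null(lr), NA_real_, lr)
  }
  if (is.null(dr) || anyNA(dr))
    warning("drift metric unavailable for some units; kept with flag")
  pass_l <- if (is.null(lr)) rep(TRUE, nrow(qc)) else is.na(lr) | lr <= l_ratio_max
  pass_d <- if (is.null(dr)) rep(TRUE, nrow(qc)) else is.na(dr) | dr <= drift_max
  qc$l_ratio <- if (is.null(lr)) NA_real_ else lr
  qc$drift_um <- if (is.null(dr)) NA_real_ else dr
  qc$pass <- qc$isi_violation_rate <= isi_threshold &
    qc$presence_ratio >= presence_threshold & pass_l & pass_d
  keep <- which(qc$pass)
  out <- spikes
  out$units <- spikes$units[keep, , drop = FALSE]
  out$spikes <- spikes$spikes[keep]
  out$qc <- qc
  out
}

# Gaussian kernel truncated at +/- 3 sigma. Each input bin's mass is
# spread over the in-range output bins with weights renormalized to one,
# so the total (and hence the trace's time mean) is conserved exactly.
smooth_gauss <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (x[i] == 0) next
    j <- max(1L, i - half):min(n, i + half)
    w <- k[j - i + half + 1L]
    out[j] <- out[j] + x[i] * w / sum(w)
  }
  out
}

#' Bin spike trains into an event-aligned rate tensor
#'
#' Spike counts in half-open bins `[t, t + bin)` relative to an alignment
#' event, divided by the bin size to yield spikes/s, optionally smoothed
#' along time with a Gaussian kernel (truncated at three standard
#' deviations and renormalized at the edges, which preserves each trace's
#' time mean).
#'
#' @param spikes A `spike_set`.
#' @param trials Trial table; the alignment event time is taken from
#'   `align_event` (default `"stim_onset"`).
#' @param window Seconds pair relative to the event, half-open.
#' @param bin_size Bin width in seconds; must divide the window length.
#' @param sigma Gaussian smoothing SD in seconds, or `NULL`/0 for none.
#' @param align_event Column of `trials` holding event times.
#' @return A `rate_tensor`: list with `values` (array units x trials x
#'   bins), `bin_size`, `window`, `align`, `sigma`, `normalized`,
#'   `unit_ids`, `trial_index`, `bin_starts`.
#' @export
bin_rates <- function(spikes, trials, window = c(-0.1, 0.15),
                      bin_size = 0.01, sigma = NULL,
                      align_event = "stim_onset") {
  stopifnot(inherits(spikes, "spike_set"))
  assert_trial_table(trials)
  len <- window[2] - window[1]
  n_bins <- round(len / bin_size)
  if (abs(n_bins * bin_size - len) > 1e-9)
    config_error("bin_size", "window length must be a multiple of bin_size")
  ev <- trials[[align_event]]
  keep <- which(!is.na(ev))
  if (length(keep) < nrow(trials))
    message(sprintf("bin_rates: %d trials lack event '%s' and were omitted",
                    nrow(trials) - length(keep), align_event))
  edges <- window[1] + bin_size * (0:n_bins)
  n_units <- length(spikes$spikes)
  vals <- array(0, dim = c(n_units, length(keep), n_bins))
  for (u in seq_len(n_units)) {
    st <- spikes$spikes[[u]]
    for (ti in seq_along(keep)) {
      rel <- st - ev[keep[ti]]
      rel <- rel[rel >= window[1] & rel < window[2]]
      if (length(rel)) {
        # small epsilon guards against spikes exactly on a bin edge
        # landing one bin low through floating-point rounding
        b <- floor((rel - window[1]) / bin_size + 1e-7) + 1L
        b[b > n_bins] <- n_bins
        cnt <- tabulate(b, nbins = n_bins)
        vals[u, ti, ] <- cnt / bin_size
      }
    }
    if (!is.null(sigma) && sigma > 0) {
      sb <- sigma / bin_size
      for (ti in seq_along(keep))
        vals[u, ti, ] <- smooth_gauss(vals[u, ti, ], sb)
    }
  }
  structure(list(values = vals, bin_size = bin_size, window = window,
                 align = align_event, sigma = sigma %||% 0,
                 normalized = FALSE, norm_params = NULL,
                 unit_ids = spikes$units$unit_id,
                 trial_index = trials$trial_index[keep],
                 bin_starts = edges[-length(edges)]),
            class = "rate_tensor")
}

#' Soft-normalize a rate tensor
#'
#' Per unit, over all trials and bins of the tensor: subtract the mean and
#' divide by (range + 5). The 5 spikes/s floor keeps low-rate units from
#' being inflated and bounds the output inside (-1, 1). The per-unit mean
#' and range are stored so the transform is exactly invertible.
#'
#' @param tensor A `rate_tensor` (unnormalized).
#' @return The normalized `rate_tensor` with `norm_params` attached.
#' @export
soft_normalize <- function(tensor) {
  stopifnot(inherits(tensor, "rate_tensor"))
  if (tensor$normalized) structural_error("tensor is already normalized")
  v <- tensor$values
  n_units <- dim(v)[1]
  mu <- numeric(n_units); rg <- numeric(n_units)
  for (u in seq_len(n_units)) {
    x <- v[u, , ]
    mu[u] <- mean(x)
    rg[u] <- max(x) - min(x)
    v[u, , ] <- (x - mu[u]) / (rg[u] + 5)
  }
  tensor$values <- v
  tensor$normalized <- TRUE
  tensor$norm_params <- data.frame(unit_id = tensor$unit_ids,
                                   mean = mu, range = rg)
  tensor
}

#' Invert soft normalization
#' @param tensor A normalized `rate_tensor`.
#' @return The tensor on the original spikes/s scale.
#' @export
soft_denormalize <- function(tensor) {
  stopifnot(inherits(tensor, "rate_tensor"), tensor$normalized)
  v <- tensor$values
  p <- tensor$norm_params
  for (u in seq_len(dim(v)[1]))
    v[u, , ] <- v[u, , ] * (p$range[u] + 5) + p$mean[u]
  tensor$values <- v
  tensor$normalized <- FALSE
  tensor$norm_params <- NULL
  tensor
}

#' Remove trials with pre-stimulus licking
#'
#' Drops trials containing any lick in the given window relative to
#' stimulus onset (default the second before onset), the study's filter for
#' movement effects on pre-stimulus activity.
#'
#' @param trials Trial table.
#' @param window Seconds pair relative to stimulus onset.
#' @return The filtered trial table.
#' @export
exclude_prestim_lick_trials <- function(trials, window = c(-1, 0)) {
  assert_trial_table(trials)
  has_lick <- vapply(trials$licks, function(lk)
    any(lk$time >= window[1] & lk$time < window[2]), logical(1))
  trials[!has_lick, , drop = FALSE]
}

#' Subset a rate tensor to given trials (by trial index)
#' @param tensor A `rate_tensor`.
#' @param trial_index Trial indices to keep.
#' @return The subset `rate_tensor`.
#' @export
tensor_subset_trials <- function(tensor, trial_index) {
  keep <- which(tensor$trial_index %in% trial_index)
  tensor$values <- tensor$values[, keep, , drop = FALSE]
  tensor$trial_index <- tensor$trial_index[keep]
  tensor
}
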