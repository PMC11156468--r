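# Ideal-observer (ROC/AUC) discriminability of single units, with
# bootstrap CIs, Bonferroni significance rules, and the PSTH permutation
# test.

#' Trial-by-trial AUC of an ideal observer
#'
#' Area under the ROC curve for discriminating two sets of per-trial values
#' via the Mann-Whitney identity: `AUC = P(X_b > X_a) + 0.5 P(X_b = X_a)`
#' over all cross-pairs. Values above 0.5 mean higher activity in group
#' `b`. Computed from ranks, which is exact including ties.
#'
#' @param a,b Numeric vectors of per-trial values (group `b` is the
#'   "preferred" direction).
#' @return The AUC in [0, 1], or `NA` if either group is empty.
#' @export
trial_auc <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(NA_real_)
  r <- rank(c(a, b))
  (sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2) / (na * nb)
}

# Stratified bootstrap percentile CI for the AUC of two groups.
auc_boot_ci <- function(a, b, n_boot = 1000L, level = 0.95) {
  boots <- vapply(seq_len(n_boot), function(i)
    trial_auc(a[sample.int(length(a), replace = TRUE)],
              b[sample.int(length(b), replace = TRUE)]), numeric(1))
  alpha <- 1 - level
  stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                  na.rm = TRUE)
}

# Trial index sets (positions within tensor$trial_index) for a named
# contrast. Group b is the "high" convention group.
contrast_groups <- function(trials, contrast) {
  oc <- trials$outcome
  correct <- !is.na(oc) & oc %in% c("hit", "correct_rejection")
  switch(contrast,
    "tHit_vs_tCR" = {
      tact <- trials$modality == "tactile" & correct
      list(a = trials$trial_index[tact & trials$block_rule == "light"],
           b = trials$trial_index[tact & trials$block_rule == "touch"])
    },
    "rule" = list(
      a = trials$trial_index[correct & trials$block_rule == "light"],
      b = trials$trial_index[correct & trials$block_rule == "touch"]),
    "stimulus" = list(
      a = trials$trial_index[correct & trials$modality == "visual"],
      b = trials$trial_index[correct & trials$modality == "tactile"]),
    "tHit_vs_tFA" = {
      tact <- trials$modality == "tactile" & !is.na(oc)
      list(a = trials$trial_index[tact & oc == "false_alarm" &
                                    trials$block_rule == "light"],
           b = trials$trial_index[tact & oc == "hit" &
                                    trials$block_rule == "touch"])
    },
    config_error("contrast", "unknown contrast"))
}

#' Per-bin evoked discriminability with the consecutive-bin rule
#'
#' For each unit and time bin, the AUC between the two trial groups of the
#' contrast (default tactile hits vs tactile correct rejections) with a
#' stratified bootstrap CI at a Bonferroni-corrected 95% level. The
#' correction spans the unit's bins times the number of units in the area
#' (`n_comparisons`, defaulting to bins x units in the tensor). A unit is
#' significant when its CI excludes 0.5 in at least `min_consecutive`
#' consecutive bins.
#'
#' @param tensor A `rate_tensor` covering the analysis window (10 ms bins,
#'   typically 0-150 ms).
#' @param trials Scored trial table matching the tensor.
#' @param contrast Contrast label (see Details of [prestim_discrim()]).
#' @param window Seconds pair restricting the tensor's bins.
#' @param n_boot Bootstrap iterations per bin.
#' @param n_comparisons Total Bonferroni comparisons; `NULL` = bins x units.
#' @param min_consecutive Consecutive significant bins required (default 3).
#' @param seed Integer seed.
#' @return Data frame: `unit_id`, `bin_start`, `auc`, `lo`, `hi`,
#'   `bin_significant`, plus per-unit attribute `significant` and the same
#'   flag replicated in column `unit_significant`.
#' @export
evoked_discrim <- function(tensor, trials, contrast = "tHit_vs_tCR",
                           window = c(0, 0.15), n_boot = 1000L,
                           n_comparisons = NULL, min_consecutive = 3L,
                           seed = NULL) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable CIs")
  g <- contrast_groups(trials, contrast)
  ia <- which(tensor$trial_index %in% g$a)
  ib <- which(tensor$trial_index %in% g$b)
  if (length(ia) < 2L || length(ib) < 2L)
    structural_error("need at least 2 trials per class")
  ratio <- max(length(ia), length(ib)) / min(length(ia), length(ib))
  if (ratio > 50) warning("class imbalance exceeds 50:1")
  bins <- which(tensor$bin_starts >= window[1] - 1e-9 &
                  tensor$bin_starts < window[2] - 1e-9)
  n_units <- dim(tensor$values)[1]
  m <- n_comparisons %||% (length(bins) * n_units)
  level <- 1 - bonferroni(m = m, alpha = 0.05)
  with_seed(seed, {
    res <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      auc <- lo <- hi <- numeric(length(bins))
      for (k in seq_along(bins)) {
        va <- tensor$values[u, ia, bins[k]]
        vb <- tensor$values[u, ib, bins[k]]
        auc[k] <- trial_auc(va, vb)
        ci <- auc_boot_ci(va, vb, n_boot, level)
        lo[k] <- ci[1]; hi[k] <- ci[2]
      }
      sig_bin <- lo > 0.5 | hi < 0.5
      runs <- rle(sig_bin)
      unit_sig <- any(runs$values & runs$lengths >= min_consecutive)
      res[[u]] <- data.frame(unit_id = tensor$unit_ids[u],
                             bin_start = tensor$bin_starts[bins],
                             auc = auc, lo = lo, hi = hi,
                             bin_significant = sig_bin,
                             unit_significant = unit_sig,
                             stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    attr(out, "contrast") <- contrast
    attr(out, "conf_level") <- level
    out
  })
}

#' Single-bin pre-stimulus discriminability
#'
#' AUC of a single window-averaged bin (typically the 100 ms before
#' stimulus onset) per unit, for the `"rule"` contrast (respond-to-touch vs
#' respond-to-light, correct trials) or the `"stimulus"` contrast (tactile
#' vs visual, correct trials). Significant when the Bonferroni-corrected
#' 95% bootstrap CI (correction across units) excludes 0.5. Trials with
#' pre-stimulus licks should already have been removed for pre-stimulus
#' windows.
#'
#' @param tensor A `rate_tensor` whose bins cover the analysis window
#'   (e.g. one 100 ms bin).
#' @param trials Scored trial table.
#' @param contrast `"rule"`, `"stimulus"`, or any contrast label known to
#'   the package.
#' @param n_boot Bootstrap iterations.
#' @param n_comparisons Bonferroni comparisons; `NULL` = number of units.
#' @param seed Integer seed.
#' @return Data frame: `unit_id`, `auc`, `lo`, `hi`, `significant`.
#' @export
prestim_discrim <- function(tensor, trials, contrast = "rule",
                            n_boot = 1000L, n_comparisons = NULL,
                            seed = NULL) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable CIs")
  g <- contrast_groups(trials, contrast)
  ia <- which(tensor$trial_index %in% g$a)
  ib <- which(tensor$trial_index %in% g$b)
  if (length(ia) < 2L || length(ib) < 2L)
    structural_error("need at least 2 trials per class")
  n_units <- dim(tensor$values)[1]
  m <- n_comparisons %||% n_units
  level <- 1 - bonferroni(m = m, alpha = 0.05)
  # Window average collapses the tensor to one value per unit and trial.
  feat <- apply(tensor$values, c(1, 2), mean)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_units), function(u) {
      va <- feat[u, ia]; vb <- feat[u, ib]
      ci <- auc_boot_ci(va, vb, n_boot, level)
      data.frame(unit_id = tensor$unit_ids[u], auc = trial_auc(va, vb),
                 lo = ci[1], hi = ci[2],
                 significant = ci[1] > 0.5 | ci[2] < 0.5,
                 stringsAsFactors = FALSE)
    }))
    attr(out, "contrast") <- contrast
    attr(out, "conf_level") <- level
    out
  })
}

#' PSTH permutation test between two trial groups
#'
#' Per unit, the Euclidean distance between the two groups' mean PSTHs
#' over the window bins is compared with a null built by permuting trial
#' labels. The p-value is one-tailed with the add-one convention;
#' significance is alpha = 0.05 after Bonferroni correction across units.
#'
#' @param tensor A `rate_tensor`.
#' @param trials Scored trial table.
#' @param contrast Contrast naming the two groups (default tactile hits vs
#'   tactile false alarms).
#' @param window Seconds pair restricting the tensor's bins.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Data frame: `unit_id`, `distance`, `p`, `significant`,
#'   `low_power` (fewer than five trials in either group).
#' @export
psth_permutation_test <- function(tensor, trials, contrast = "tHit_vs_tFA",
                                  window = c(0, 0.25), n_perm = 1000L,
                                  seed = NULL) {
  g <- contrast_groups(trials, contrast)
  ia <- which(tensor$trial_index %in% g$a)
  ib <- which(tensor$trial_index %in% g$b)
  if (!length(ia) || !length(ib))
    structural_error("both groups must be non-empty")
  low_power <- length(ia) < 5L || length(ib) < 5L
  bins <- which(tensor$bin_starts >= window[1] - 1e-9 &
                  tensor$bin_starts < window[2] - 1e-9)
  n_units <- dim(tensor$values)[1]
  idx <- c(ia, ib); na <- length(ia)
  with_seed(seed, {
    perms <- lapply(seq_len(n_perm), function(i) sample(idx))
    out <- do.call(rbind, lapply(seq_len(n_units), function(u) {
      m <- matrix(tensor$values[u, , bins], nrow = dim(tensor$values)[2])
      d_obs <- sqrt(sum((colMeans(m[ia, , drop = FALSE]) -
                           colMeans(m[ib, , drop = FALSE]))^2))
      d_null <- vapply(perms, function(pm) {
        pa <- pm[seq_len(na)]; pb <- pm[-seq_len(na)]
        sqrt(sum((colMeans(m[pa, , drop = FALSE]) -
                    colMeans(m[pb, , drop = FALSE]))^2))
      }, numeric(1))
      data.frame(unit_id = tensor$unit_ids[u], distance = d_obs,
                 p = (1 + sum(d_null >= d_obs)) / (n_perm + 1),
                 stringsAsFactors = FALSE)
    }))
    out$significant <- bonferroni(out$p, n_units) < 0.05
    out$low_power <- low_power
    out
  })
}

#' Correlation between pre-stimulus rule AUC and evoked AUC
#'
#' Pearson correlation, across units, between pre-stimulus rule
#' discriminability and early evoked (tHit vs tCR) discriminability,
#' restricted to units with significant pre-stimulus rule selectivity.
#'
#' @param rule_auc Data frame from [prestim_discrim()] (rule contrast).
#' @param evoked_auc Data frame with per-unit `unit_id` and `auc` for the
#'   evoked window (e.g. window-mean of [evoked_discrim()] bins 0-50 ms).
#' @param significant_only Restrict to pre-stimulus-significant units.
#' @return List with `r`, `p`, `n`, or a missing marker when fewer than
#'   three units remain.
#' @export
prestim_evoked_correlation <- function(rule_auc, evoked_auc,
                                       significant_only = TRUE) {
  keep <- if (significant_only) rule_auc$unit_id[rule_auc$significant]
          else rule_auc$unit_id
  x <- rule_auc$auc[match(keep, rule_auc$unit_id)]
  y <- evoked_auc$auc[match(keep, evoked_auc$unit_id)]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(list(r = NA_real_, p = NA_real_, n = sum(ok),
                                missing = TRUE))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       missing = FALSE)
}
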