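# Population geometry: trajectory PCA and distances, subspace overlap via
# variance alignment, and stimulus/choice coding dimensions.

# Trial indices of the canonical condition labels.
condition_trials <- function(trials, label) {
  oc <- trials$outcome
  tact <- trials$modality == "tactile"
  vis <- trials$modality == "visual"
  switch(label,
         tHit = trials$trial_index[tact & !is.na(oc) & oc == "hit"],
         tCR = trials$trial_index[tact & !is.na(oc) &
                                    oc == "correct_rejection"],
         vHit = trials$trial_index[vis & !is.na(oc) & oc == "hit"],
         vCR = trials$trial_index[vis & !is.na(oc) &
                                    oc == "correct_rejection"],
         config_error("conditions", paste("unknown condition", label)))
}

tensor_bins <- function(tensor, window) {
  b <- which(tensor$bin_starts >= window[1] - 1e-9 &
               tensor$bin_starts < window[2] - 1e-9)
  if (!length(b)) config_error("window", "no tensor bins in window")
  b
}

# Trial-averaged trajectory: time bins x units.
avg_trajectory <- function(tensor, trial_idx, bins) {
  rows <- which(tensor$trial_index %in% trial_idx)
  if (!length(rows)) return(NULL)
  t(apply(tensor$values[, rows, bins, drop = FALSE], c(1, 3), mean))
}

#' PCA subspace of trial-averaged condition trajectories
#'
#' Concatenates the trial-averaged trajectories of the requested
#' conditions (time points as observations, units as variables), centers
#' by the column means of the fitted data, and returns the top-`k`
#' principal components. The same center is reused for any later
#' projection.
#'
#' @param tensor A (typically soft-normalized) `rate_tensor`.
#' @param trials Scored trial table.
#' @param conditions Condition labels (default `c("tHit", "tCR")`).
#' @param window Seconds pair (default -0.1 to 0.15).
#' @param k Number of components (default 3; truncated with a warning if
#'   fewer units).
#' @return A `subspace_model`: list with `basis` (units x k, orthonormal),
#'   `center`, `var_explained` (all components), `k`, `window`, `bins`,
#'   `source`.
#' @export
fit_trajectory_pca <- function(tensor, trials,
                               conditions = c("tHit", "tCR"),
                               window = c(-0.1, 0.15), k = 3L) {
  bins <- tensor_bins(tensor, window)
  mats <- lapply(conditions, function(cc)
    avg_trajectory(tensor, condition_trials(trials, cc), bins))
  if (any(vapply(mats, is.null, logical(1))))
    structural_error("a requested condition has no trials")
  X <- do.call(rbind, mats)
  n_units <- ncol(X)
  if (n_units < k) {
    warning(sprintf("only %d units; basis truncated", n_units))
    k <- n_units
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(basis = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, var_explained = ve, k = k,
                 window = window, bins = bins,
                 source = paste(conditions, collapse = "+")),
            class = "subspace_model")
}

project_trial <- function(tensor, model, row, bins) {
  m <- t(tensor$values[, row, bins])        # time x units
  sweep(m, 2, model$center) %*% model$basis # time x k
}

#' Mean pairwise distance between two conditions' trajectories
#'
#' Projects every single trial of each condition into the model's
#' component space and computes, at each matching time point, the
#' Euclidean distance for all cross-condition trial pairs, averaged over
#' pairs.
#'
#' @param model A `subspace_model` from [fit_trajectory_pca()].
#' @param tensor The `rate_tensor` the model was fit on.
#' @param trials Scored trial table.
#' @param conditions Length-2 condition labels (default tHit vs tCR).
#' @return Numeric vector of per-time-point mean distances, with
#'   attribute `bin_starts`.
#' @export
trajectory_distance <- function(model, tensor, trials,
                                conditions = c("tHit", "tCR")) {
  bins <- model$bins
  ra <- which(tensor$trial_index %in%
                condition_trials(trials, conditions[1]))
  rb <- which(tensor$trial_index %in%
                condition_trials(trials, conditions[2]))
  if (!length(ra) || !length(rb))
    structural_error("a condition has zero trials")
  pa <- lapply(ra, function(r) project_trial(tensor, model, r, bins))
  pb <- lapply(rb, function(r) project_trial(tensor, model, r, bins))
  n_t <- length(bins)
  d <- numeric(n_t)
  for (t in seq_len(n_t)) {
    A <- do.call(rbind, lapply(pa, function(m) m[t, ]))
    B <- do.call(rbind, lapply(pb, function(m) m[t, ]))
    # mean over all pairs of ||a - b||
    G <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d[t] <- mean(sqrt(pmax(G, 0)))
  }
  attr(d, "bin_starts") <- tensor$bin_starts[bins]
  d
}

#' Permutation test comparing top- and bottom-half distance curves
#'
#' Sessions are ranked by their mean pre-stimulus distance and split at the
#' median (with an odd count, the median session joins the bottom group).
#' The statistic is the Euclidean distance between the two groups' mean
#' post-stimulus distance curves; the null shuffles group labels.
#'
#' @param dist_list List of per-session distance vectors (equal length,
#'   with `bin_starts` attributes from [trajectory_distance()]).
#' @param pre_window,post_window Seconds pairs.
#' @param n_perm Number of label shuffles (default 1000).
#' @param seed Integer seed.
#' @return List with `p`, `observed`, `top_mean`, `bottom_mean`,
#'   `top_sessions`.
#' @export
split_distance_permutation <- function(dist_list, pre_window = c(-0.1, 0),
                                       post_window = c(0, 0.15),
                                       n_perm = 1000L, seed = NULL) {
  if (length(dist_list) < 4L)
    structural_error("need at least 4 sessions")
  bs <- attr(dist_list[[1]], "bin_starts")
  pre <- which(bs >= pre_window[1] - 1e-9 & bs < pre_window[2] - 1e-9)
  post <- which(bs >= post_window[1] - 1e-9 & bs < post_window[2] - 1e-9)
  M <- do.call(rbind, lapply(dist_list, as.numeric))
  pre_mean <- rowMeans(M[, pre, drop = FALSE])
  n <- nrow(M)
  ord <- order(pre_mean)
  n_bottom <- ceiling(n / 2)   # median session goes to the bottom group
  bottom <- ord[seq_len(n_bottom)]
  top <- ord[(n_bottom + 1):n]
  stat <- function(top_idx) {
    other <- setdiff(seq_len(n), top_idx)
    sqrt(sum((colMeans(M[top_idx, post, drop = FALSE]) -
                colMeans(M[other, post, drop = FALSE]))^2))
  }
  obs <- stat(top)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat(sample.int(n, length(top))), numeric(1)))
  list(p = (1 + sum(null >= obs)) / (n_perm + 1), observed = obs,
       top_mean = colMeans(M[top, , drop = FALSE]),
       bottom_mean = colMeans(M[bottom, , drop = FALSE]),
       top_sessions = top)
}

# Fraction of a dataset's variance (about its own time-mean, so that mean
# offsets from the reference center do not masquerade as dynamics)
# captured by a basis.
varexp_on_basis <- function(X, basis, center = NULL) {
  Y <- sweep(X, 2, colMeans(X))
  tot <- sum(Y^2)
  if (tot < 1e-12) return(NA_real_)
  sum((Y %*% basis)^2) / tot
}

own_topk_varexp <- function(X, k) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  kk <- min(k, ncol(pc$rotation))
  varexp_on_basis(X, pc$rotation[, seq_len(kk), drop = FALSE])
}

#' Subspace overlap between tactile-hit and tactile-CR activity
#'
#' Tactile-hit trials are split (seeded, 50/50) into reference and control
#' groups. A PCA on the trial-averaged reference activity (stimulus
#' window) defines the reference top-`k` subspace. The overlap of a
#' dataset is the ratio of its variance captured by the reference basis to
#' the variance captured by its own top-`k` basis. Returned for tCR, for
#' the held-out control tHit group, and for pre-stimulus tCR activity
#' projected on the same reference basis. Sessions with fewer than 10
#' units are excluded.
#'
#' @param tensor A soft-normalized `rate_tensor` covering both windows.
#' @param trials Scored trial table.
#' @param window Stimulus window (default 0-0.15 s).
#' @param pre_window Pre-stimulus window (default -0.1-0 s).
#' @param k Number of components (default 3).
#' @param seed Integer seed for the reference/control split.
#' @return An `overlap_result`: list with `overlap_tCR`,
#'   `overlap_control_tHit`, `overlap_prestim_tCR`, `n_units`,
#'   `ref_trials`, `control_trials`; or a missing marker if excluded.
#' @export
subspace_overlap <- function(tensor, trials, window = c(0, 0.15),
                             pre_window = c(-0.1, 0), k = 3L,
                             seed = NULL) {
  n_units <- dim(tensor$values)[1]
  if (n_units < 10L)
    return(list(missing = TRUE,
                reason = "fewer than 10 units", n_units = n_units))
  bins <- tensor_bins(tensor, window)
  pre_bins <- tensor_bins(tensor, pre_window)
  th <- condition_trials(trials, "tHit")
  tc <- condition_trials(trials, "tCR")
  th <- th[th %in% tensor$trial_index]
  tc <- tc[tc %in% tensor$trial_index]
  if (length(th) < 4L || length(tc) < 2L)
    return(list(missing = TRUE, reason = "too few trials",
                n_units = n_units))
  with_seed(seed, {
    ref <- sample(th, floor(length(th) / 2))
    ctl <- setdiff(th, ref)
    X_ref <- avg_trajectory(tensor, ref, bins)
    pc <- stats::prcomp(X_ref, center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$rotation))
    basis <- pc$rotation[, seq_len(kk), drop = FALSE]
    center <- pc$center
    ov <- function(X) {
      if (is.null(X)) return(NA_real_)
      num <- varexp_on_basis(X, basis, center)
      den <- own_topk_varexp(X, kk)
      if (is.na(num) || is.na(den) || den < 1e-12) return(NA_real_)
      num / den
    }
    X_tcr <- avg_trajectory(tensor, tc, bins)
    X_ctl <- avg_trajectory(tensor, ctl, bins)
    X_pre <- avg_trajectory(tensor, tc, pre_bins)
    structure(list(overlap_tCR = ov(X_tcr),
                   overlap_control_tHit = ov(X_ctl),
                   overlap_prestim_tCR = ov(X_pre),
                   n_units = n_units, ref_trials = ref,
                   control_trials = ctl, missing = FALSE),
              class = "overlap_result")
  })
}

#' Correlation between pre- and post-stimulus subspace overlaps
#'
#' Pearson correlation across sessions of the tCR subspace overlaps
#' computed in the pre- and post-stimulus windows.
#'
#' @param pre,post Numeric vectors of per-session overlaps.
#' @return List with `r`, `p`, `n`, or a missing marker below 3 sessions.
#' @export
prepost_overlap_correlation <- function(pre, post) {
  ok <- !is.na(pre) & !is.na(post)
  if (sum(ok) < 3L)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok), missing = TRUE))
  ct <- stats::cor.test(pre[ok], post[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       missing = FALSE)
}

# Response label of each trial: first answer-window lick port, or
# "no_lick" (misses and correct rejections count as a choice).
trial_response <- function(trials, cfg = task_config()) {
  vapply(trials$licks, function(lk) {
    a <- first_answer_lick(lk, cfg)
    if (is.null(a)) "no_lick" else paste0(a$port, "_lick")
  }, character(1))
}

# Sub-condition recipes. Each rule context averages two modality cells,
# each cell itself an equal-weight average of two response sub-cells.
cd_recipe <- function(contrast, rule_context, recipe) {
  lick <- if (rule_context == "touch") "right_lick" else "left_lick"
  if (recipe == "lick_nolick") {
    if (contrast == "stimulus") {
      list(a = list(c("tactile", lick), c("tactile", "no_lick")),
           b = list(c("visual", lick), c("visual", "no_lick")))
    } else {
      list(a = list(c("tactile", lick), c("visual", lick)),
           b = list(c("tactile", "no_lick"), c("visual", "no_lick")))
    }
  } else if (recipe == "lick_lick") {
    if (contrast == "stimulus") {
      list(a = list(c("tactile", "right_lick"), c("tactile", "left_lick")),
           b = list(c("visual", "right_lick"), c("visual", "left_lick")))
    } else {
      list(a = list(c("tactile", "right_lick"), c("visual", "right_lick")),
           b = list(c("tactile", "left_lick"), c("visual", "left_lick")))
    }
  } else config_error("recipe", "must be lick_nolick or lick_lick")
}

#' Stimulus or choice coding dimension
#'
#' The unit-norm population direction separating two condition averages:
#' the time-resolved difference of the two sides' mean trajectories,
#' averaged over the analysis window. Each side is the equal-weight
#' average of two (modality, response) sub-condition means per the recipe
#' tables; an empty sub-condition is dropped from its side's average with
#' a flag. Misses and correct rejections count as the "no-lick" choice.
#'
#' @param tensor A soft-normalized `rate_tensor`.
#' @param trials Scored trial table.
#' @param contrast `"stimulus"` or `"choice"`.
#' @param rule_context `"touch"` or `"light"` (which blocks to use).
#' @param recipe `"lick_nolick"` (hit/no-lick recipe) or `"lick_lick"`
#'   (right- vs left-lick control recipe).
#' @param window Seconds pair (default 0-0.15).
#' @param cfg The [task_config()] (answer window for response labels).
#' @param response Optional precomputed response labels (internal).
#' @return A `coding_dimension`: list with unit-norm `vector`, `contrast`,
#'   `rule_context`, `recipe`, `window`, `incomplete` (sub-conditions
#'   dropped), or a degenerate marker when the difference is zero.
#' @export
coding_dimension <- function(tensor, trials, contrast = "stimulus",
                             rule_context = "touch",
                             recipe = "lick_nolick", window = c(0, 0.15),
                             cfg = task_config(), response = NULL) {
  bins <- tensor_bins(tensor, window)
  blk <- trials[trials$block_rule == rule_context &
                  trials$modality != "none" &
                  !is.na(trials$outcome) & trials$outcome != "censored", ]
  resp <- response %||% trial_response(blk, cfg)
  rc <- cd_recipe(contrast, rule_context, recipe)
  incomplete <- character(0)
  side_mean <- function(cells, side) {
    mats <- list()
    for (cell in cells) {
      idx <- blk$trial_index[blk$modality == cell[1] & resp == cell[2]]
      m <- avg_trajectory(tensor, idx, bins)
      if (is.null(m)) {
        incomplete <<- c(incomplete,
                         paste(side, cell[1], cell[2], sep = ":"))
      } else mats[[length(mats) + 1L]] <- m
    }
    if (!length(mats)) return(NULL)
    Reduce(`+`, mats) / length(mats)
  }
  ma <- side_mean(rc$a, "a")
  mb <- side_mean(rc$b, "b")
  if (is.null(ma) || is.null(mb))
    structural_error("a CD side has no populated sub-condition")
  nu <- colMeans(ma - mb)   # average the time-resolved difference
  nrm <- sqrt(sum(nu^2))
  if (nrm < 1e-12)
    return(list(vector = NULL, degenerate = TRUE, contrast = contrast,
                rule_context = rule_context, recipe = recipe))
  structure(list(vector = nu / nrm, contrast = contrast,
                 rule_context = rule_context, recipe = recipe,
                 window = window, incomplete = incomplete,
                 degenerate = FALSE),
            class = "coding_dimension")
}

#' Alignment between two coding dimensions
#'
#' The magnitude of the dot product between two unit vectors (0 =
#' orthogonal, 1 = aligned). When a `null_fn` is supplied (a function of
#' the iteration index returning a shuffled-label |dot|), a shuffle null
#' distribution and its 95% interval are attached, with significance
#' declared when the observed value exceeds the null's upper bound.
#'
#' @param cd_a,cd_b `coding_dimension` objects (or bare numeric vectors of
#'   equal length).
#' @param null_fn Optional function `(i) -> numeric(1)`.
#' @param n_shuffle Null draws (default 1000).
#' @param seed Integer seed.
#' @return List with `dot`, and when a null is computed `null`,
#'   `null_ci`, `significant`.
#' @export
cd_alignment <- function(cd_a, cd_b, null_fn = NULL, n_shuffle = 1000L,
                         seed = NULL) {
  va <- if (inherits(cd_a, "coding_dimension")) cd_a$vector else cd_a
  vb <- if (inherits(cd_b, "coding_dimension")) cd_b$vector else cd_b
  if (length(va) != length(vb))
    structural_error("coding dimensions have mismatched dimensions")
  out <- list(dot = abs(sum(va * vb)))
  if (!is.null(null_fn)) {
    null <- with_seed(seed, vapply(seq_len(n_shuffle), null_fn,
                                   numeric(1)))
    ci <- stats::quantile(null, c(0.025, 0.975), names = FALSE,
                          na.rm = TRUE)
    out$null <- null
    out$null_ci <- ci
    out$significant <- out$dot > ci[2]
  }
  out
}

#' Rule-context CD alignment with a trial-label shuffle null
#'
#' Computes the CDs of both rule contexts for a session, their |dot|, and
#' a null where the (modality, response) labels are permuted across each
#' context's trials before recomputing the CDs.
#'
#' @inheritParams coding_dimension
#' @param n_shuffle Shuffle draws.
#' @param seed Integer seed.
#' @return As [cd_alignment()], plus the two CDs.
#' @export
cd_rule_alignment <- function(tensor, trials, contrast = "stimulus",
                              recipe = "lick_nolick", window = c(0, 0.15),
                              cfg = task_config(), n_shuffle = 1000L,
                              seed = NULL) {
  cds <- lapply(c("touch", "light"), function(rc)
    coding_dimension(tensor, trials, contrast, rc, recipe, window, cfg))
  if (any(vapply(cds, function(x) isTRUE(x$degenerate), logical(1))))
    return(list(dot = NA_real_, degenerate = TRUE))
  shuffle_one <- function(i) {
    v <- lapply(c("touch", "light"), function(rc) {
      blk <- trials[trials$block_rule == rc & trials$modality != "none" &
                      !is.na(trials$outcome) &
                      trials$outcome != "censored", ]
      resp <- trial_response(blk, cfg)
      # Permute the joint (modality, response) labels across trials.
      pm <- sample.int(nrow(blk))
      blk2 <- blk
      blk2$modality <- blk$modality[pm]
      cd <- coding_dimension(tensor, blk2, contrast, rc, recipe, window,
                             cfg, response = resp[pm])
      if (isTRUE(cd$degenerate)) NULL else cd$vector
    })
    if (any(vapply(v, is.null, logical(1)))) return(NA_real_)
    abs(sum(v[[1]] * v[[2]]))
  }
  res <- cd_alignment(cds[[1]], cds[[2]], null_fn = shuffle_one,
                      n_shuffle = n_shuffle, seed = seed)
  res$cd_touch <- cds[[1]]
  res$cd_light <- cds[[2]]
  res
}
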