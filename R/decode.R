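# Cross-validated population decoding, shuffle controls, and
# rule-transition classification.

tensor_features <- function(tensor, window = NULL) {
  # One feature per unit: the window-mean rate of each trial.
  bins <- if (is.null(window)) seq_along(tensor$bin_starts) else
    which(tensor$bin_starts >= window[1] - 1e-9 &
            tensor$bin_starts < window[2] - 1e-9)
  if (!length(bins)) config_error("window", "no tensor bins in window")
  f <- apply(tensor$values[, , bins, drop = FALSE], c(1, 2), mean)
  t(f)  # trials x units
}

fit_classifier <- function(x, y, classifier, seed = NULL, n_trees = 500L) {
  switch(classifier,
         lda = fit_lda(x, y),
         svm = fit_svm(x, y, seed = seed),
         rf = fit_bagged_trees(x, y, n_trees = n_trees, seed = seed),
         config_error("classifier", "must be lda, svm or rf"))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

cv_accuracy <- function(x, y, k, classifier, seed) {
  fold <- stratified_folds(y, k)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f; te <- fold == f
    if (!any(te) || length(unique(y[tr])) < 2L) return(NA_real_)
    mdl <- fit_classifier(x[tr, , drop = FALSE], y[tr], classifier, seed)
    mean(predict(mdl, x[te, , drop = FALSE]) == y[te])
  }, numeric(1))
  acc
}

#' Decode task rule or stimulus type from population activity
#'
#' Stratified 10-fold cross-validated classification accuracy from
#' soft-normalized single-trial population features (one window-mean value
#' per unit), using correct trials only. A shuffle control permutes the
#' trial labels and reruns the identical cross-validation; it is repeated
#' and averaged.
#'
#' @param tensor A (typically soft-normalized) `rate_tensor`.
#' @param trials Scored trial table.
#' @param target `"rule"` (respond-to-touch vs respond-to-light) or
#'   `"stimulus"` (tactile vs visual).
#' @param window Seconds pair selecting the tensor bins (`NULL` = all).
#' @param classifier `"lda"`, `"svm"` or `"rf"`.
#' @param k Cross-validation folds (default 10; reduced with a warning
#'   when a class has fewer trials than folds).
#' @param n_shuffle Shuffle-control repetitions (default 100).
#' @param seed Integer seed.
#' @param n_trees Trees for the `rf` classifier.
#' @return A `decoding_result`: list with `accuracy`, `accuracy_shuffled`,
#'   `fold_accuracies`, `target`, `classifier`, `n_trials`, `n_units`.
#' @export
decode <- function(tensor, trials, target = "rule", window = NULL,
                   classifier = "lda", k = 10L, n_shuffle = 100L,
                   seed = NULL, n_trees = 500L) {
  oc <- trials$outcome
  correct <- trials[!is.na(oc) & oc %in% c("hit", "correct_rejection"), ]
  keep <- tensor$trial_index %in% correct$trial_index
  x <- tensor_features(tensor, window)[keep, , drop = FALSE]
  ti <- tensor$trial_index[keep]
  lab <- switch(target,
                rule = correct$block_rule[match(ti, correct$trial_index)],
                stimulus = correct$modality[match(ti, correct$trial_index)],
                config_error("target", "must be rule or stimulus"))
  y <- factor(lab)
  if (nlevels(y) < 2L)
    return(structure(list(accuracy = NA_real_,
                          accuracy_shuffled = NA_real_,
                          fold_accuracies = NA_real_, target = target,
                          classifier = classifier, n_trials = length(y),
                          n_units = ncol(x)), class = "decoding_result"))
  min_class <- min(table(y))
  if (min_class < k) {
    k <- max(2L, min_class)
    warning(sprintf("fewer trials than folds; folds reduced to %d", k))
  }
  with_seed(seed, {
    folds <- cv_accuracy(x, y, k, classifier, seed = NULL)
    shuf <- vapply(seq_len(n_shuffle), function(i) {
      ys <- sample(y)
      mean(cv_accuracy(x, ys, k, classifier, seed = NULL), na.rm = TRUE)
    }, numeric(1))
    structure(list(accuracy = mean(folds, na.rm = TRUE),
                   accuracy_shuffled = mean(shuf),
                   fold_accuracies = folds, target = target,
                   classifier = classifier, n_trials = length(y),
                   n_units = ncol(x)), class = "decoding_result")
  })
}

#' Kendall's rank correlation (tau-b)
#'
#' Tie-corrected Kendall's tau of a value sequence against its own order
#' (or against a supplied ordering), computed by pair enumeration.
#'
#' @param values Numeric vector (>= 3 values).
#' @param order Optional numeric vector of the same length; defaults to
#'   `seq_along(values)`.
#' @return Tau in [-1, 1]; 0 (with a warning) when all values are tied.
#' @export
kendalls_tau <- function(values, order = seq_along(values)) {
  n <- length(values)
  if (n < 3L) structural_error("kendalls_tau needs at least 3 values")
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dx <- values[j] - values[i]; dy <- order[j] - order[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tx) * (n0 - ty))
  if (denom == 0) {
    warning("all values tied; tau set to 0")
    return(0)
  }
  (conc - disc) / denom
}

#' Classify rule-transition trials from pre-stimulus population state
#'
#' Trains an LDA on 90% of the correct non-transition trials of a session
#' (pre-stimulus window features) and classifies four ordered trial
#' periods around each block switch of a given direction: held-out correct
#' trials before the switch, early-transition trials, late-transition
#' trials, and held-out correct trials after the block's first hit. The
#' fraction classified as "respond-to-touch" is computed per period
#' (pooled over the session's switches of that direction) and summarized
#' by Kendall's tau against period order. Transition trials never enter
#' the training set.
#'
#' @param tensor A soft-normalized pre-stimulus `rate_tensor`.
#' @param trials Scored trial table for the session.
#' @param parses Output of [parse_transitions()] (complete parses used).
#' @param direction `"touch_to_light"` or `"light_to_touch"`.
#' @param holdout Fraction of correct non-transition trials held out
#'   (default 0.1).
#' @param seed Integer seed.
#' @return A `transition_result`: list with `fractions` (named length-4:
#'   pre, early, late, post), `tau`, `direction`, `n_test` per period; or
#'   a missing marker when fewer than 3 periods are populated.
#' @export
transition_classify <- function(tensor, trials, parses,
                                direction = "touch_to_light",
                                holdout = 0.1, seed = NULL) {
  parses <- Filter(function(p) p$complete, parses)
  dirs <- vapply(parses, `[[`, character(1), "direction")
  sel <- parses[dirs == direction]
  if (!length(sel))
    return(list(fractions = NULL, tau = NA_real_, direction = direction,
                missing = TRUE))
  transition_trials <- unlist(lapply(parses, function(p)
    c(p$early_trials, p$late_trials)))
  oc <- trials$outcome
  correct_idx <- trials$trial_index[!is.na(oc) &
                                      oc %in% c("hit", "correct_rejection")]
  train_pool <- setdiff(correct_idx, transition_trials)
  with_seed(seed, {
    n_hold <- max(1L, round(holdout * length(train_pool)))
    hold <- sample(train_pool, n_hold)
    train <- setdiff(train_pool, hold)
    x <- tensor_features(tensor)
    row_of <- function(idx) match(idx, tensor$trial_index)
    tr_rows <- row_of(train); tr_rows <- tr_rows[!is.na(tr_rows)]
    y <- factor(trials$block_rule[match(tensor$trial_index[tr_rows],
                                        trials$trial_index)],
                levels = c("light", "touch"))
    if (nlevels(droplevels(y)) < 2L)
      return(list(fractions = NULL, tau = NA_real_,
                  direction = direction, missing = TRUE))
    mdl <- fit_lda(x[tr_rows, , drop = FALSE], y)
    frac_touch <- function(idx) {
      rows <- row_of(idx); rows <- rows[!is.na(rows)]
      if (!length(rows)) return(NA_real_)
      mean(predict(mdl, x[rows, , drop = FALSE]) == "touch")
    }
    pre_idx <- post_idx <- integer(0)
    early_idx <- late_idx <- integer(0)
    for (p in sel) {
      blk <- trials$block_index[match(p$switch_trial, trials$trial_index)]
      pre_idx <- c(pre_idx, intersect(
        hold, trials$trial_index[trials$block_index == blk - 1L]))
      post_idx <- c(post_idx, intersect(
        hold, trials$trial_index[trials$block_index == blk &
                                   trials$trial_index > p$first_hit]))
      early_idx <- c(early_idx, p$early_trials)
      late_idx <- c(late_idx, p$late_trials)
    }
    periods <- list(pre = pre_idx, early = early_idx, late = late_idx,
                    post = post_idx)
    fr <- vapply(periods, frac_touch, numeric(1))
    n_test <- vapply(periods, function(ix)
      sum(!is.na(row_of(ix))), integer(1))
    ok <- !is.na(fr)
    if (sum(ok) < 3L)
      return(list(fractions = fr, tau = NA_real_, direction = direction,
                  n_test = n_test, missing = TRUE))
    tau <- kendalls_tau(fr[ok], order = which(ok))
    list(fractions = fr, tau = tau, direction = direction,
         n_test = n_test, missing = FALSE)
  })
}

#' Summarize transition-tracking tau across sessions
#'
#' Mean Kendall's tau over sessions with a hierarchical bootstrap CI;
#' significant when the CI excludes zero.
#'
#' @param results List of per-session `transition_result`s (one
#'   direction).
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed.
#' @return A `resample_ci` over session taus.
#' @export
transition_tau_summary <- function(results, n_iter = 1000L, seed = NULL) {
  taus <- vapply(results, function(r)
    if (isTRUE(r$missing)) NA_real_ else r$tau, numeric(1))
  taus <- taus[!is.na(taus)]
  if (!length(taus)) structural_error("no complete transition results")
  hierarchical_bootstrap(data.frame(session = seq_along(taus), tau = taus),
                         function(d) mean(d$tau), "session",
                         n_iter = n_iter, seed = seed, significant_vs = 0)
}
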