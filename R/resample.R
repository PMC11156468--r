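# Hierarchical bootstrap, permutation tests, Bonferroni utilities.

#' Hierarchical bootstrap confidence interval
#'
#' Resamples with replacement at each level of a nesting hierarchy
#' top-down (e.g. mice, then sessions within each resampled mouse, then
#' rows within each resampled session), recomputes the statistic per
#' iteration, and returns a percentile 95% interval. This respects
#' non-independence of observations within a group; with positively
#' correlated groups the interval is wider than a naive pooled bootstrap.
#'
#' @param data Data frame; one row per lowest-level observation.
#' @param statistic Function `data.frame -> numeric(1)`.
#' @param levels Character vector of grouping columns, outermost first.
#'   Rows within the innermost group are resampled as the final level.
#' @param n_iter Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param resample_rows Resample rows within the innermost groups
#'   (default TRUE); group sizes are preserved.
#' @param significant_vs Optional reference value; the verdict is whether
#'   the CI excludes it.
#' @return A `resample_ci`: list with `estimate`, `lo`, `hi`, `n_iter`,
#'   `levels`, `boot` (iteration statistics), and optionally
#'   `significant` / `reference`.
#' @export
hierarchical_bootstrap <- function(data, statistic, levels,
                                   n_iter = 1000L, seed = NULL,
                                   conf = 0.95, resample_rows = TRUE,
                                   significant_vs = NULL) {
  stopifnot(is.data.frame(data), is.function(statistic))
  missing_lv <- setdiff(levels, names(data))
  if (length(missing_lv))
    config_error("levels", paste("not columns of data:",
                                 paste(missing_lv, collapse = ", ")))
  if (!nrow(data)) structural_error("no observations to resample")

  # Precompute the nested index tree once; per iteration only integer
  # indices are resampled, not data frames.
  build_tree <- function(idx, lv) {
    if (!length(lv)) return(idx)
    lapply(split(idx, data[[lv[1]]][idx], drop = TRUE), build_tree,
           lv = lv[-1])
  }
  draw <- function(node) {
    if (!is.list(node)) {
      if (!resample_rows || length(node) == 1L) return(node)
      return(node[sample.int(length(node), replace = TRUE)])
    }
    take <- sample.int(length(node), replace = TRUE)
    unlist(lapply(node[take], draw), use.names = FALSE)
  }
  tree <- build_tree(seq_len(nrow(data)), levels)

  est <- statistic(data)
  boot <- with_seed(seed, vapply(seq_len(n_iter), function(i)
    statistic(data[draw(tree), , drop = FALSE]), numeric(1)))
  a <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  out <- structure(list(estimate = est, lo = qs[1], hi = qs[2],
                        n_iter = n_iter, levels = levels, boot = boot),
                   class = "resample_ci")
  if (!is.null(significant_vs)) {
    out$reference <- significant_vs
    out$significant <- significant_vs < out$lo || significant_vs > out$hi
  }
  out
}

#' @export
print.resample_ci <- function(x, ...) {
  cat(sprintf("estimate %.4g, 95%% CI [%.4g, %.4g] (%d iterations; %s)\n",
              x$estimate, x$lo, x$hi, x$n_iter,
              paste(x$levels, collapse = " > ")))
  if (!is.null(x$significant))
    cat(sprintf("  vs %.4g: %s\n", x$reference,
                if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Permutation test on a statistic of two groups
#'
#' Pools the two groups, permutes labels `n_perm` times, and computes an
#' add-one p-value: `p = (1 + #{null >= observed}) / (n_perm + 1)` for the
#' one-tailed "greater" alternative (or the mirrored / doubled versions).
#' The p-value is never exactly zero.
#'
#' @param group_a,group_b Numeric vectors (or lists of rows for a custom
#'   statistic over index sets).
#' @param statistic Function `(a, b) -> numeric(1)`; default difference of
#'   means.
#' @param n_perm Number of permutations (default 1000).
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @param seed Integer seed.
#' @return List with `p`, `observed`, `null` (the permuted statistics).
#' @export
permutation_test <- function(group_a, group_b,
                             statistic = function(a, b) mean(a) - mean(b),
                             n_perm = 1000L, tail = "greater",
                             seed = NULL) {
  if (!length(group_a) || !length(group_b))
    structural_error("permutation test requires two non-empty groups")
  obs <- statistic(group_a, group_b)
  pool <- c(group_a, group_b)
  na <- length(group_a)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    statistic(pool[idx], pool[-idx])
  }, numeric(1)))
  p <- switch(tail,
              greater = (1 + sum(null >= obs)) / (n_perm + 1),
              less = (1 + sum(null <= obs)) / (n_perm + 1),
              two.sided = min(1, 2 * min(
                (1 + sum(null >= obs)) / (n_perm + 1),
                (1 + sum(null <= obs)) / (n_perm + 1))),
              config_error("tail", "must be greater, less or two.sided"))
  list(p = p, observed = obs, null = null)
}

#' Bonferroni correction
#'
#' Adjusts p-values (`p' = min(1, m p)`) or a CI level
#' (`alpha' = alpha / m`) for `m` comparisons.
#'
#' @param p Numeric vector of p-values, or `NULL` when adjusting a level.
#' @param m Number of comparisons (>= 1).
#' @param alpha Familywise level to adjust when `p` is `NULL`.
#' @return Adjusted p-values, or the per-comparison alpha.
#' @export
bonferroni <- function(p = NULL, m, alpha = 0.05) {
  if (!is.numeric(m) || m < 1) config_error("m", "must be >= 1")
  if (is.null(p)) return(alpha / m)
  pmin(1, m * p)
}
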