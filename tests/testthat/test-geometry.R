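# Trajectory PCA, distances, subspace overlap, coding dimensions.

# Build a tensor whose single trials equal their condition mean plus
# optional noise; conditions are tHit (touch-block tactile hits) and tCR.
two_cond_tensor <- function(mean_hit, mean_cr, n_per = 6, noise = 0,
                            seed = 1) {
  set.seed(seed)
  n_units <- ncol(mean_hit); n_bins <- nrow(mean_hit)
  v <- array(0, dim = c(n_units, 2 * n_per, n_bins))
  for (i in seq_len(n_per)) {
    v[, i, ] <- t(mean_hit + noise * matrix(rnorm(length(mean_hit)),
                                            n_bins))
    v[, n_per + i, ] <- t(mean_cr + noise * matrix(rnorm(length(mean_cr)),
                                                   n_bins))
  }
  tr <- make_trials(rep(c("touch", "light"), each = n_per),
                    rep("tactile", 2 * n_per))
  tr$outcome <- rep(c("hit", "correct_rejection"), each = n_per)
  list(tensor = make_tensor(v, bin_starts = seq(-0.1, by = 0.01,
                                                length.out = n_bins),
                            bin_size = 0.01),
       trials = tr)
}

test_that("trajectory PCA recovers planted structure", {
  # rank-1 condition difference: PC1 aligns with the difference vector
  n_bins <- 25; n_units <- 6
  base <- matrix(0, n_bins, n_units)
  diffv <- c(1, -2, 0.5, 0, 3, -1); diffv <- diffv / sqrt(sum(diffv^2))
  m_hit <- base + outer(sin(seq_len(n_bins) / 4), diffv)
  d <- two_cond_tensor(m_hit, base)
  mdl <- fit_trajectory_pca(d$tensor, d$trials)
  expect_gt(abs(sum(mdl$basis[, 1] * diffv)), 0.99)
  expect_true(all(diff(mdl$var_explained) < 1e-9))
  expect_equal(unname(crossprod(mdl$basis)), diag(3), tolerance = 1e-8)
  # data confined to a 2-plane: exactly two nonzero variance shares
  m2 <- outer(seq_len(n_bins) / n_bins, c(1, 0, 0, 0, 0, 0)) +
    outer(cos(seq_len(n_bins) / 3), c(0, 1, 0, 0, 0, 0))
  d2 <- two_cond_tensor(m2, m2 * 0.5)
  mdl2 <- fit_trajectory_pca(d2$tensor, d2$trials)
  expect_equal(sum(mdl2$var_explained > 1e-12), 2)
  expect_equal(sum(mdl2$var_explained), 1, tolerance = 1e-9)
})

test_that("trajectory distances obey identity, offset, and rotation", {
  n_bins <- 25; n_units <- 5
  m <- outer(sin(seq_len(n_bins) / 3), c(1, 2, 0, -1, 0.5))
  # identical trajectories -> zero distance
  d0 <- two_cond_tensor(m, m)
  mdl0 <- fit_trajectory_pca(d0$tensor, d0$trials)
  expect_equal(max(abs(trajectory_distance(mdl0, d0$tensor, d0$trials))),
               0, tolerance = 1e-9)
  # constant offset with norm 5 -> distance 5 at every time point
  off <- c(3, 4, 0, 0, 0)
  d1 <- two_cond_tensor(m, sweep(m, 2, off, "+"))
  mdl1 <- fit_trajectory_pca(d1$tensor, d1$trials)
  expect_equal(as.numeric(trajectory_distance(mdl1, d1$tensor,
                                              d1$trials)),
               rep(5, n_bins), tolerance = 1e-9)
  # joint rotation of both conditions leaves distances unchanged
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  d2 <- two_cond_tensor(m %*% Q, sweep(m, 2, off, "+") %*% Q)
  mdl2 <- fit_trajectory_pca(d2$tensor, d2$trials)
  expect_equal(as.numeric(trajectory_distance(mdl2, d2$tensor,
                                              d2$trials)),
               rep(5, n_bins), tolerance = 1e-9)
})

test_that("pre-stimulus rule separation increases trajectory distance", {
  dists <- sapply(c(1, 3), function(gain) {
    pop <- population_config(n_units = 15, frac_rule_mod = 0.8,
                             rule_gain = gain)
    sess <- simulate_session(seed = 21, pop = pop)
    clean <- exclude_prestim_lick_trials(sess$trials)
    full <- soft_normalize(bin_rates(unit_qc_filter(sess$spikes), clean,
                                     c(-0.1, 0.15), 0.01, sigma = 0.05))
    mdl <- fit_trajectory_pca(full, clean)
    dd <- trajectory_distance(mdl, full, clean)
    mean(dd[attr(dd, "bin_starts") < 0])
  })
  expect_gt(dists[2], dists[1])
})

test_that("PCA projection energy is maximal on the own basis", {
  set.seed(11)
  for (i in 1:10) {
    X <- matrix(rnorm(30 * 6), 30, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
    own <- xmodal:::own_topk_varexp(X, 3)
    Q <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
    expect_gte(own + 1e-9, xmodal:::varexp_on_basis(X, Q))
    # self-overlap of any dataset is exactly 1
    pc <- prcomp(X)
    expect_equal(xmodal:::varexp_on_basis(
      X, pc$rotation[, 1:3]) / own, 1, tolerance = 1e-9)
  }
})

test_that("subspace overlap separates aligned from orthogonal activity", {
  # 12 units; reference tHit spans units 1-3 (rank 3), tCR units 10-12,
  # so the reference top-3 basis is well determined and orthogonal to the
  # tCR dynamics
  n_bins <- 15
  tcourse <- function(f) cbind(sin(seq_len(n_bins) / f),
                               cos(seq_len(n_bins) / f),
                               seq_len(n_bins) / n_bins)
  m_hit <- cbind(tcourse(2) %*% diag(c(3, 2, 1.5)), matrix(0, n_bins, 9))
  m_cr <- cbind(matrix(0, n_bins, 9), tcourse(3) %*% diag(c(2, 3, 1)))
  d <- two_cond_tensor(m_hit, m_cr, n_per = 8, noise = 0.02, seed = 2)
  d$tensor$bin_starts <- seq(0, by = 0.01, length.out = n_bins)
  ov <- subspace_overlap(d$tensor, d$trials, window = c(0, 0.1),
                         pre_window = c(0.1, 0.15), seed = 1)
  expect_lt(ov$overlap_tCR, 0.1)
  expect_gt(ov$overlap_control_tHit, 0.9)
  # tCR identical to tHit -> overlap near 1
  d2 <- two_cond_tensor(m_hit, m_hit, n_per = 8, noise = 0.01, seed = 3)
  d2$tensor$bin_starts <- seq(0, by = 0.01, length.out = n_bins)
  ov2 <- subspace_overlap(d2$tensor, d2$trials, window = c(0, 0.1),
                          pre_window = c(0.1, 0.15), seed = 1)
  expect_gt(ov2$overlap_tCR, 0.9)
  # fewer than 10 units -> excluded
  d3 <- two_cond_tensor(m_hit[, 1:6], m_cr[, 4:9], n_per = 4)
  expect_true(subspace_overlap(d3$tensor, d3$trials,
                               window = c(-0.1, 0.05),
                               pre_window = c(-0.1, 0))$missing)
})

test_that("overlap deficit grows with the generator rotation", {
  cfg6 <- task_config(n_blocks = 6)
  deltas <- sapply(c(0, 1), function(rot) {
    mean(sapply(1:3, function(s) {
      # high-SNR recording so the two levels separate with few replicates
      pop <- population_config(n_units = 40, rule_rotation = rot,
                               evoked_amp = 40,
                               baseline_meanlog = log(5),
                               frac_touch_resp = 0.6,
                               frac_light_resp = 0.3)
      sess <- simulate_session(cfg = cfg6,
                               seed = 50 * s + round(10 * rot), pop = pop)
      clean <- exclude_prestim_lick_trials(sess$trials)
      full <- soft_normalize(bin_rates(unit_qc_filter(sess$spikes),
                                       clean, c(-0.1, 0.15), 0.01,
                                       sigma = 0.05))
      ov <- subspace_overlap(full, clean, seed = 1)
      ov$overlap_tCR - ov$overlap_control_tHit
    }))
  })
  expect_lt(deltas[2], deltas[1])
  expect_lt(deltas[2], -0.1)
})

test_that("split_distance_permutation calibrates and detects", {
  base <- sin(seq_len(25) / 3) + 2
  mk <- function(shift, noise, seed) {
    set.seed(seed)
    d <- base + shift + rnorm(25, 0, noise)
    attr(d, "bin_starts") <- seq(-0.1, by = 0.01, length.out = 25)
    d
  }
  # all sessions statistically identical -> large p
  null_list <- lapply(1:10, function(i) mk(0, 0.05, i))
  expect_gt(split_distance_permutation(null_list, n_perm = 300,
                                       seed = 1)$p, 0.05)
  # half the sessions strongly shifted -> p at the resolution floor (a
  # random relabeling can re-draw the observed split, so the smallest
  # attainable p is slightly above 1/(n_perm + 1))
  shift_list <- c(lapply(1:5, function(i) mk(0, 0.05, i)),
                  lapply(6:10, function(i) mk(5, 0.05, i)))
  res <- split_distance_permutation(shift_list, n_perm = 300, seed = 1)
  expect_lt(res$p, 0.025)
  expect_error(split_distance_permutation(shift_list[1:3]), "4 sessions")
})

test_that("coding dimensions follow the half-weight recipe", {
  # 2 units; tactile-right-lick mean (2,0), tactile-no-lick (0,0),
  # visual means 0 -> x_tactile = (1,0), CD = (1,0)
  n_bins <- 5
  mk_cell <- function(vec) matrix(rep(vec, each = n_bins), n_bins)
  v <- array(0, dim = c(2, 8, n_bins))
  cells <- list(mk_cell(c(2, 0)), mk_cell(c(0, 0)),   # tactile lick/none
                mk_cell(c(0, 0)), mk_cell(c(0, 0)))   # visual lick/none
  for (i in 1:4) {
    v[, 2 * i - 1, ] <- t(cells[[i]]); v[, 2 * i, ] <- t(cells[[i]])
  }
  tr <- make_trials(rep("touch", 8),
                    rep(c("tactile", "tactile", "visual", "visual"),
                        each = 2))
  tr$licks <- I(c(rep(list(lick_df(0.5, "right")), 2),
                  rep(list(lick_df()), 2),
                  rep(list(lick_df(0.5, "right")), 2),
                  rep(list(lick_df()), 2)))
  tr <- score_outcomes(tr)
  tens <- make_tensor(v, bin_starts = seq(0, by = 0.01,
                                          length.out = n_bins),
                      bin_size = 0.01)
  cd <- coding_dimension(tens, tr, "stimulus", "touch")
  expect_equal(cd$vector, c(1, 0))
  # choice CD: right-lick cells (2,0)&(0,0) vs no-lick (0,0)&(0,0)
  cd_c <- coding_dimension(tens, tr, "choice", "touch")
  expect_equal(cd_c$vector, c(1, 0))
  # scaling all rates leaves the normalized CD fixed
  tens2 <- tens; tens2$values <- tens$values * 7
  expect_equal(coding_dimension(tens2, tr, "stimulus", "touch")$vector,
               cd$vector)
  # equal condition means -> degenerate marker
  tens0 <- tens; tens0$values[] <- 1
  expect_true(coding_dimension(tens0, tr, "stimulus",
                               "touch")$degenerate)
})

test_that("cd_alignment matches analytic and Monte-Carlo expectations", {
  e1 <- c(1, 0, 0, 0); e2 <- c(0, 1, 0, 0)
  expect_equal(cd_alignment(e1, e1)$dot, 1)
  expect_equal(cd_alignment(e1, e2)$dot, 0)
  expect_error(cd_alignment(e1, c(1, 0)), "mismatch")
  # random unit vectors in n dims: E|dot| ~ sqrt(2 / (pi n))
  set.seed(12)
  n <- 20
  dots <- replicate(3000, {
    a <- rnorm(n); b <- rnorm(n)
    abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  })
  expect_equal(mean(dots), sqrt(2 / (pi * n)), tolerance = 0.02)
  # shuffle null wiring
  al <- cd_alignment(e1, e1, null_fn = function(i) runif(1, 0, 0.3),
                     n_shuffle = 100, seed = 1)
  expect_true(al$significant)
})

test_that("rule-context CD alignment on simulated data", {
  sess <- fixture_session()
  al <- cd_rule_alignment(sess$full, sess$trials, "stimulus",
                          n_shuffle = 50, seed = 2)
  expect_true(al$dot >= 0 && al$dot <= 1)
  expect_true(all(al$null >= 0 & al$null <= 1, na.rm = TRUE))
})

test_that("pre/post overlap correlation behaves", {
  x <- seq(0.2, 0.9, length.out = 10)
  expect_equal(prepost_overlap_correlation(x, x)$r, 1)
  expect_true(prepost_overlap_correlation(x[1:2], x[1:2])$missing)
})
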