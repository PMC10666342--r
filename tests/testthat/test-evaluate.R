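# Evaluation: ROI flatness curves, interpretability correlation, SPC-vs-FPC
# residuals, statistical report helpers.

test_that("identical movies give a perfectly flat curve; scaling is equivariant", {
  sw <- constant_sweep(rep(4, 12))
  roi <- matrix(TRUE, 4, 4)
  ec <- roi_mean_vs_offset(sw, roi)
  expect_equal(ec$flatness_sd, 0)
  expect_equal(ec$flatness_range, 0)
  expect_equal(ec$curve$mean_intensity, rep(4, 12))
  fx <- tiny_sweep(seed = 1, n_phases = 3, size = 16)
  roi2 <- heart_roi(fx$scene)
  e1 <- roi_mean_vs_offset(fx$sweep, roi2)
  doubled <- fx$sweep
  doubled$movies <- lapply(doubled$movies, function(m) { m$data <- 2 * m$data; m })
  e2 <- roi_mean_vs_offset(doubled, roi2)
  expect_equal(e2$curve$mean_intensity, 2 * e1$curve$mean_intensity)
  expect_equal(e2$flatness_sd, 2 * e1$flatness_sd)
  expect_error(roi_mean_vs_offset(fx$sweep, matrix(FALSE, 16, 16)), "empty ROI")
})

test_that("interpretability identity case gives R^2 = 1, slope 1, intercept 0", {
  fx <- tiny_sweep(seed = 1, n_phases = 3, size = 16)
  spc <- spc_combine(fx$sweep)
  orig <- fx$sweep$movies[[2]]
  vl <- vi_label(spc, orig)
  # feeding the SPC label as the "AS output" and the VI label as the map
  # reproduces the defining identity exactly
  cr <- interpretability_correlation(vl$data, spc$data, orig,
                                     eps = vl$eps, floor_frac = 0.05)
  expect_equal(cr$r_squared, 1, tolerance = 1e-9)
  expect_equal(cr$slope, 1, tolerance = 1e-6)
  expect_equal(cr$intercept, 0, tolerance = 1e-6)
  expect_lt(cr$p_value, 1e-6)
})

test_that("an independent random VI map decorrelates (Monte-Carlo null)", {
  fx <- tiny_sweep(seed = 2, n_phases = 2, size = 160)
  spc <- spc_combine(fx$sweep)
  orig <- fx$sweep$movies[[6]]   # on-resonance movie: most voxels in-slice
  set.seed(123)
  rnd <- array(runif(length(spc$data)), dim = dim(spc$data))
  cr <- interpretability_correlation(rnd, spc$data, orig)
  expect_gte(cr$n_voxels, 1e4)
  expect_lt(cr$r_squared, 0.05)
  # constant map is rejected
  cst <- array(0.5, dim = dim(spc$data))
  expect_error(interpretability_correlation(cst, spc$data, orig), "constant")
})

test_that("interpretability correlation is invariant to joint voxel permutation", {
  fx <- tiny_sweep(seed = 3, n_phases = 2, size = 16)
  spc <- spc_combine(fx$sweep)
  orig <- fx$sweep$movies[[12]]
  vl <- vi_label(spc, orig)$data
  as_out <- fpc_combine(fx$sweep)$data
  cr1 <- interpretability_correlation(vl, as_out, orig, eps = 1e-3)
  set.seed(9)
  perm <- sample(16 * 16)
  shuffle <- function(a) {
    out <- a
    for (p in seq_len(dim(a)[1])) out[p, , ] <- matrix(a[p, , ][perm], 16, 16)
    out
  }
  o2 <- orig; o2$data <- shuffle(orig$data)
  cr2 <- interpretability_correlation(shuffle(vl), shuffle(as_out), o2,
                                      eps = 1e-3)
  expect_equal(cr2$r_squared, cr1$r_squared, tolerance = 1e-12)
  expect_equal(cr2$slope, cr1$slope, tolerance = 1e-12)
})

test_that("SPC vs FPC: both suppress bands, only SPC avoids ghost build-up", {
  fx <- tiny_sweep(seed = 1)
  masks <- ground_truth_masks(fx$scene, fx$sweep$offsets_hz)
  ref <- clean_reference(fx$scene)
  rep_g <- compare_spc_fpc(fx$sweep, masks, ref, fx$scene)
  expect_setequal(rep_g$method, c("original", "SPC", "FPC"))
  g <- function(r, m, col) r[r$method == m, col]
  # ghost-bearing sweep: FPC accumulates ghost energy, SPC largely avoids it
  expect_gt(g(rep_g, "FPC", "ghost_residual"), g(rep_g, "SPC", "ghost_residual"))
  # both suppress banding relative to the original movies
  expect_lt(g(rep_g, "SPC", "band_residual"), g(rep_g, "original", "band_residual"))
  expect_lt(g(rep_g, "FPC", "band_residual"), g(rep_g, "original", "band_residual"))
  # ghost-free sweep: full-range cycling is at least as good on bands
  sc <- fx$scene
  swn <- render_sweep(sc, 12, ghost_gain = 0, seed = 1)
  rep_n <- compare_spc_fpc(swn, masks, ref, sc)
  expect_lte(g(rep_n, "FPC", "band_residual"), g(rep_n, "SPC", "band_residual"))
  expect_lt(g(rep_n, "SPC", "band_residual"), g(rep_n, "original", "band_residual"))
  expect_error(compare_spc_fpc(fx$sweep, list(band = masks$band), ref), "masks")
})

test_that("an all-constant sweep has zero residuals everywhere", {
  sw <- constant_sweep(rep(2, 12), dims = c(2, 4, 4))
  masks <- list(band = array(c(TRUE, FALSE), dim = c(2, 4, 4)),
                ghost = array(c(FALSE, TRUE), dim = c(2, 4, 4)))
  ref <- array(2, dim = c(2, 4, 4))
  rep0 <- compare_spc_fpc(sw, masks, ref)
  expect_equal(rep0$band_residual, rep(0, 3), tolerance = 1e-12)
  expect_equal(rep0$ghost_residual, rep(0, 3), tolerance = 1e-12)
})

test_that("flatness of the SPC label curve never exceeds the worst movie's", {
  for (sd in 1:3) {
    fx <- tiny_sweep(seed = sd, n_phases = 3, size = 16)
    roi <- heart_roi(fx$scene)
    per_movie <- vapply(fx$sweep$movies, function(m) {
      mean(m$data[1, , ][roi])
    }, numeric(1))
    worst_spread <- max(per_movie) - min(per_movie)
    spc <- spc_combine(fx$sweep)
    # the SPC label is one image: its "curve" across offsets is constant,
    # and its deviation from any movie is bounded by the sweep's spread
    expect_lte(abs(mean(spc$data[1, , ][roi]) - mean(per_movie)), worst_spread)
  }
})

test_that("Wilcoxon wrappers agree with an exact permutation oracle", {
  # signed-rank: enumerate all 2^n sign assignments of the paired diffs
  a <- c(3.1, 4.5, 2.2, 5.0, 3.8, 4.1, 2.9)
  b <- c(2.5, 4.9, 1.85, 4.2, 3.1, 3.0, 3.4)
  res <- paired_score_stats(a, b, paired = TRUE, exact = TRUE)
  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_oracle <- mean(abs(v_all - n * (n + 1) / 4) >= abs(v_obs - n * (n + 1) / 4))
  expect_equal(res$statistic, v_obs)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  # identical vectors: no information against the null
  same <- paired_score_stats(c(1, 2, 3), c(1, 2, 3))
  expect_true(is.na(same$p_value) || same$p_value > 0.99)
  expect_error(paired_score_stats(1, 2), "n >= 2")
})

test_that("Bland-Altman of y against itself is exactly null", {
  y <- c(55.2, 60.1, 48.7, 52.3, 59.9)
  ba <- bland_altman(y, y)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)
  ba2 <- bland_altman(y, y - 2)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$loa_upper - ba2$loa_lower, 0, tolerance = 1e-12)
})

test_that("ICC(2,1) recovers known agreement structure", {
  set.seed(5)
  subj <- rnorm(30, 0, 2)
  ratings <- sapply(1:3, function(r) subj + rnorm(30, 0, 0.5))
  hi <- icc_agreement(ratings)
  expect_gt(hi$icc, 0.8)
  noise <- sapply(1:3, function(r) rnorm(30))
  lo <- icc_agreement(noise)
  expect_lt(lo$icc, 0.3)
  # perfect agreement
  expect_equal(icc_agreement(cbind(subj, subj))$icc, 1, tolerance = 1e-12)
  expect_error(icc_agreement(matrix(1, 1, 3)), "at least 2")
})
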