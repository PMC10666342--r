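# SPC / FPC combination and the sigmoid voxel-identity label.

test_that("SPC selects exactly the five central offsets on the baseline grid", {
  fx <- tiny_sweep(seed = 1)
  spc <- spc_combine(fx$sweep)
  expect_length(spc$source_offsets_hz, 5)
  expect_setequal(round(spc$source_offsets_hz, 1), c(-55, -27.5, 0, 27.5, 55))
  fpc <- fpc_combine(fx$sweep)
  expect_length(fpc$source_offsets_hz, 12)
  # a sweep with no offsets inside the band is rejected
  off_center <- constant_sweep(c(1, 3), offsets = c(-10, 10))
  expect_error(spc_combine(off_center, central_band_hz = 5), "no offsets")
})

test_that("combines equal the voxelwise arithmetic mean (toy and constant sweeps)", {
  sw <- constant_sweep(c(1, 3), offsets = c(-10, 10))
  spc <- spc_combine(sw, central_band_hz = 20)
  expect_equal(spc$data, array(2, dim = c(2, 4, 4)))
  swc <- constant_sweep(rep(7, 12))
  expect_equal(fpc_combine(swc)$data, array(7, dim = c(2, 4, 4)))
  expect_equal(spc_combine(swc)$data, array(7, dim = c(2, 4, 4)))
})

test_that("combines match a brute-force mean oracle on random sweeps", {
  set.seed(42)
  sp <- default_seq_params()
  offs <- sweep_offsets(12, sp$tr_ms)
  movies <- lapply(offs, function(f) {
    structure(list(data = array(runif(3 * 6 * 6), dim = c(3, 6, 6)),
                   offset_hz = f, tr_ms = sp$tr_ms, te_ms = sp$te_ms,
                   flip_deg = 60, pe_axis = "row"), class = "cine_movie")
  })
  sw <- cinebands:::new_frequency_sweep(movies)
  # oracle: explicit elementwise mean over the stacked arrays
  stack <- simplify2array(lapply(movies, function(m) m$data))
  expect_equal(fpc_combine(sw)$data, apply(stack, 1:3, mean),
               tolerance = 1e-12)
  sel <- which(abs(offs) <= 55 + 1e-9)
  expect_equal(spc_combine(sw)$data, apply(stack[, , , sel], 1:3, mean),
               tolerance = 1e-12)
})

test_that("combines commute with scalar multiplication of the sweep", {
  fx <- tiny_sweep(seed = 2, n_phases = 3, size = 16)
  scaled <- fx$sweep
  scaled$movies <- lapply(scaled$movies, function(m) { m$data <- 3 * m$data; m })
  expect_equal(spc_combine(scaled)$data, 3 * spc_combine(fx$sweep)$data,
               tolerance = 1e-12)
  expect_equal(fpc_combine(scaled)$data, 3 * fpc_combine(fx$sweep)$data,
               tolerance = 1e-12)
})

test_that("vi_label matches the closed-form logistic at key ratios", {
  dims <- c(1, 2, 2)
  orig <- array(1, dim = dims)
  # spc == original -> exactly 0.5
  expect_equal(vi_label(array(1, dims), orig)$data, array(0.5, dims))
  # deep band: spc = 10 x original -> sigmoid(9)
  expect_equal(vi_label(array(10, dims), orig)$data,
               array(1 / (1 + exp(-9)), dims), tolerance = 1e-12)
  # bright flow: ratio -> 0 gives the lower bound sigmoid(-1) ~ 0.2689
  expect_equal(vi_label(array(0, dims), orig)$data,
               array(1 / (1 + exp(1)), dims), tolerance = 1e-12)
  expect_error(vi_label(array(1, c(1, 3, 3)), orig), "shape mismatch")
})

test_that("vi_label stays strictly inside (sigmoid(-1), 1) and is monotone", {
  set.seed(7)
  dims <- c(2, 8, 8)
  spc <- array(runif(prod(dims), 0, 5), dims)
  # keep ratios below the saturation clamp so strict monotonicity is
  # observable in double precision
  orig <- array(runif(prod(dims), 0.5, 5), dims)
  v <- vi_label(spc, orig, eps = 1e-3)$data
  expect_true(all(v > 1 / (1 + exp(1)) - 1e-12))
  expect_true(all(v < 1))
  # strictly increasing in spc, strictly decreasing in original
  v_up <- vi_label(spc + 0.1, orig, eps = 1e-3)$data
  v_dn <- vi_label(spc, orig + 0.1, eps = 1e-3)$data
  expect_true(all(v_up > v))
  expect_true(all(v_dn < v))
})

test_that("vi_label separates band from ghost voxels on a simulated sweep", {
  fx <- tiny_sweep(seed = 1)
  masks <- ground_truth_masks(fx$scene, fx$sweep$offsets_hz)
  spc <- spc_combine(fx$sweep)
  band_means <- c(); ghost_means <- c()
  for (m in fx$sweep$movies) {
    v <- vi_label(spc, m)$data
    band_means <- c(band_means, mean(v[masks$band]))
    ghost_means <- c(ghost_means, mean(v[masks$ghost]))
  }
  expect_gt(mean(band_means), 0.5)
  expect_lt(mean(ghost_means), 0.5)
})

test_that("preprocess normalizes, is invertible and rejects empty movies", {
  fx <- tiny_sweep(seed = 1, n_phases = 3, size = 16)
  m <- fx$sweep$movies[[6]]
  pm <- preprocess(m)
  expect_equal(stats::quantile(pm$data, 0.99, names = FALSE), 1)
  rt <- unpreprocess(pm)
  expect_equal(rt$data, m$data, tolerance = 1e-12)
  # idempotent up to the recorded factor
  pm2 <- preprocess(pm)
  expect_equal(attr(pm2, "norm_factor"), 1, tolerance = 1e-12)
  # constant movie scales to 1
  cm <- constant_sweep(5, offsets = 0)$movies[[1]]
  expect_true(all(preprocess(cm)$data == 1))
  zm <- cm; zm$data[] <- 0
  expect_error(preprocess(zm), "all-zero")
  # centre crop
  pc <- preprocess(m, crop = c(8, 8))
  expect_equal(dim(pc$data), c(3, 8, 8))
})
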