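# Phantom construction, cine rendering, flow ghosts, dataset generation.

test_that("phantom generation is deterministic and respects its invariants", {
  geo <- tiny_geometry()
  a <- make_phantom(geo, seed = 4)
  b <- make_phantom(geo, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$label_volume,
                         make_phantom(geo, seed = 5)$label_volume))
  # flow voxels are exactly the flow-tissue voxels
  tp <- a$tissue_params
  flow_ids <- tp$id[tp$flows]
  expect_identical(a$flow_mask, array(a$label_volume %in% flow_ids,
                                      dim = dim(a$label_volume)))
  expect_true(all(is.finite(a$field_map)))
  expect_true(all(a$label_volume %in% tp$id))
})

test_that("zero motion amplitude freezes the heart across phases", {
  geo <- tiny_geometry()
  geo$motion_amp <- 0
  sc <- make_phantom(geo, seed = 1)
  for (p in 2:sc$n_phases) {
    expect_identical(sc$label_volume[p, , ], sc$label_volume[1, , ])
  }
  # and with motion the blood pool contracts at mid-cycle
  sc2 <- tiny_scene(seed = 1)
  areas <- vapply(seq_len(sc2$n_phases),
                  function(p) sum(sc2$label_volume[p, , ] == 2L), numeric(1))
  expect_lt(min(areas), areas[1])
  expect_equal(which.min(areas), end_systole_phase(sc2))
})

test_that("invalid geometry is rejected with a descriptive failure", {
  geo <- tiny_geometry()
  geo$lv_outer_frac <- 0.7
  expect_error(make_phantom(geo), "radii exceed the image")
  geo2 <- tiny_geometry()
  geo2$lv_inner_frac <- geo2$lv_outer_frac + 0.01
  expect_error(make_phantom(geo2), "smaller than lv_outer_frac")
})

test_that("rendering with a field map cancelling the offset removes all bands", {
  sc <- tiny_scene(seed = 2)
  offset <- 110
  sc$field_map[] <- -offset
  banded <- render_cine(sc, offset, noise_sigma = 0)
  sc0 <- sc; sc0$field_map[] <- 0
  onres <- render_cine(sc0, 0, noise_sigma = 0)
  expect_equal(banded$data, onres$data, tolerance = 1e-12)
})

test_that("noiseless renders are invariant under offset shifts of 1/TR", {
  sc <- tiny_scene(seed = 3)
  sp <- default_seq_params()
  m1 <- render_cine(sc, 27.5, sp, noise_sigma = 0)
  m2 <- render_cine(sc, 27.5 + 1000 / sp$tr_ms, sp, noise_sigma = 0)
  expect_equal(m1$data, m2$data, tolerance = 1e-12)
})

test_that("a band placed over the heart darkens the heart ROI below half", {
  sc <- tiny_scene(seed = 1)
  roi <- heart_roi(sc)
  onres <- render_cine(sc, 0, noise_sigma = 0)
  # the offset that puts beta ~ pi over the heart (heart field ~ ramp only)
  heart_field <- mean(sc$field_map[roi])
  band_offset <- 1000 / (2 * default_seq_params()$tr_ms) - heart_field
  banded <- render_cine(sc, band_offset, noise_sigma = 0)
  expect_lt(mean(banded$data[1, , ][roi]), 0.5 * mean(onres$data[1, , ][roi]))
})

test_that("flow ghosts are additive, band-conditioned and PE-directed", {
  sc <- tiny_scene(seed = 1)
  roi <- heart_roi(sc)
  band_offset <- 1000 / (2 * default_seq_params()$tr_ms) -
    mean(sc$field_map[roi])
  m <- render_cine(sc, band_offset, noise_sigma = 0)
  # gain 0 is the identity
  expect_identical(add_flow_artifact(m, sc, ghost_gain = 0), m)
  # with a band through the blood pool, total intensity strictly increases
  g <- add_flow_artifact(m, sc, ghost_count = 3, ghost_gain = 0.6)
  expect_gt(sum(g$data), sum(m$data))
  expect_true(all(g$data >= 0))
  # ghosts spread along the phase-encoding axis: rows gain energy at
  # shifted positions, not only inside the flow mask
  added <- g$data - m$data
  expect_gt(sum(added[!sc$flow_mask]), 0)
})

test_that("ghosts vanish when flow and bands are disjoint", {
  sc <- tiny_scene(seed = 1)
  sc$field_map[] <- 0                      # on resonance everywhere
  m <- render_cine(sc, 0, noise_sigma = 0) # no band anywhere
  g <- add_flow_artifact(m, sc, ghost_count = 3, ghost_gain = 0.6)
  # band weight at beta = 0 is exactly 0, so no ghost energy is injected
  expect_equal(g$data, m$data, tolerance = 1e-10)
})

test_that("pe_axis controls the ghost replication axis", {
  sc <- tiny_scene(seed = 1)
  src <- array(0, dim = c(2, 8, 8)); src[1, 3, 5] <- 1
  reps_row <- cinebands:::replicate_ghosts(src, 1, "row")
  reps_col <- cinebands:::replicate_ghosts(src, 1, "col")
  expect_equal(which(reps_row[1, , ] > 0, arr.ind = TRUE)[1, ],
               c(row = 7, col = 5))
  expect_equal(which(reps_col[1, , ] > 0, arr.ind = TRUE)[1, ],
               c(row = 3, col = 1))
  m <- render_cine(sc, 0, noise_sigma = 0)
  m$pe_axis <- "diag"
  expect_error(add_flow_artifact(m, sc), "pe_axis")
})

test_that("sweep offsets form the 27.5 Hz grid covering the banding period", {
  tr <- default_seq_params()$tr_ms
  offs <- sweep_offsets(12, tr)
  expect_equal(diff(offs), rep(27.5, 11), tolerance = 1e-9)
  expect_equal(max(offs), 1000 / (2 * tr), tolerance = 1e-9)
  expect_true(min(offs) > -1000 / (2 * tr))
  expect_setequal(round(abs(offs), 1),
                  c(137.5, 110, 82.5, 55, 27.5, 0, 165))
  expect_error(sweep_offsets(1, tr), ">= 2")
})

test_that("generate_dataset produces the full study layout and a manifest", {
  # manifest size does not depend on image geometry, so use a minimal one
  geo <- phantom_geometry(n_row = 8, n_col = 8, n_phases = 2)
  cfg <- dataset_config(n_subjects = 18, n_slices = 3, n_offsets = 12,
                        geometry = geo, ghost_count = 1)
  coll <- generate_dataset(cfg, seed = 0)
  expect_equal(nrow(coll$manifest), 648)
  expect_equal(length(coll$sweeps), 54)
  expect_equal(length(unique(coll$manifest$subject)), 18)
  # per-sweep offsets are the 12-point grid
  expect_equal(unique(table(coll$manifest$sweep_index)), 12L)
  expect_error(generate_dataset(dataset_config(n_offsets = 1, geometry = geo)),
               ">= 2")
})

test_that("dataset generation is deterministic in (config, seed)", {
  geo <- phantom_geometry(n_row = 8, n_col = 8, n_phases = 2)
  cfg <- dataset_config(n_subjects = 2, n_slices = 1, n_offsets = 4,
                        geometry = geo)
  a <- generate_dataset(cfg, seed = 9)
  b <- generate_dataset(cfg, seed = 9)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$sweeps, b$sweeps)
})

test_that("every sweep exposes a trainable banding signal in the heart", {
  for (sd in 1:3) {
    fx <- tiny_sweep(seed = sd)
    ec <- roi_mean_vs_offset(fx$sweep, heart_roi(fx$scene))
    expect_lt(min(ec$curve$mean_intensity),
              0.7 * max(ec$curve$mean_intensity))
  }
})
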