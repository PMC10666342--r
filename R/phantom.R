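#' Geometry configuration for the numerical cardiac phantom
#'
#' Defaults emulate a mid-ventricular short-axis slice: a contracting
#' left-ventricular myocardial ring with a blood pool, a descending-aorta
#' analog (through-plane flow), a subcutaneous fat rim and a liver-like
#' abdominal background. The off-resonance field map is a smooth in-plane
#' ramp plus a localized susceptibility-like Gaussian blob, so dark bands
#' sweep across the heart at the extreme frequency offsets but spare it at
#' the central ones.
#'
#' @param n_row,n_col in-plane matrix size.
#' @param n_phases number of cardiac phases in the cine loop.
#' @param lv_center LV centre as a fraction of (row, col) extent.
#' @param lv_outer_frac,lv_inner_frac outer/inner myocardial radii at
#'   end-diastole, as a fraction of `min(n_row, n_col)`.
#' @param aorta_center,aorta_frac centre and radius of the aorta analog.
#' @param fat_frac thickness of the subcutaneous fat rim (fraction).
#' @param motion_amp fractional systolic contraction of the LV radii.
#' @param ramp_hz total field-map ramp across the image, in Hz.
#' @param blob_hz,blob_sigma_frac amplitude (Hz) and width (fraction) of
#'   the susceptibility blob.
#' @param pe_axis phase-encoding axis: `"row"` or `"col"`.
#' @param jitter fractional random per-subject variation of radii, centre
#'   and field map applied by [make_phantom()].
#' @return a list of class `phantom_geometry`.
#' @export
phantom_geometry <- function(n_row = 48, n_col = 48, n_phases = 25,
                             lv_center = c(0.42, 0.45),
                             lv_outer_frac = 0.22, lv_inner_frac = 0.13,
                             aorta_center = c(0.72, 0.70), aorta_frac = 0.07,
                             fat_frac = 0.06, motion_amp = 0.30,
                             ramp_hz = 110, blob_hz = 140,
                             blob_sigma_frac = 0.12,
                             pe_axis = "row", jitter = 0.08) {
  cfg <- list(n_row = n_row, n_col = n_col, n_phases = n_phases,
              lv_center = lv_center, lv_outer_frac = lv_outer_frac,
              lv_inner_frac = lv_inner_frac, aorta_center = aorta_center,
              aorta_frac = aorta_frac, fat_frac = fat_frac,
              motion_amp = motion_amp, ramp_hz = ramp_hz, blob_hz = blob_hz,
              blob_sigma_frac = blob_sigma_frac, pe_axis = pe_axis,
              jitter = jitter)
  class(cfg) <- "phantom_geometry"
  cfg
}

# Tissue IDs used by the phantom. 0 = air/background (zero proton density).
TISSUE_IDS <- c(background = 0L, myocardium = 1L, blood = 2L, fat = 3L,
                abdomen = 4L)

#' Default tissue relaxation parameters (3T)
#'
#' T1/T2 in milliseconds and relative proton density for the four phantom
#' tissues plus background.
#' @return data.frame with columns `tissue`, `id`, `t1_ms`, `t2_ms`, `pd`,
#'   `flows` (whether spins move through-plane).
#' @export
default_tissue_params <- function() {
  data.frame(
    tissue = c("background", "myocardium", "blood", "fat", "abdomen"),
    id     = c(0L, 1L, 2L, 3L, 4L),
    t1_ms  = c(1, 1400, 1900, 370, 800),
    t2_ms  = c(1, 45, 250, 130, 40),
    pd     = c(0, 0.85, 1.0, 0.95, 0.8),
    flows  = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Periodic contraction weight in [0,1]: 0 at end-diastole (phase 1),
# maximal at mid-cycle (end-systole), smooth and periodic over the loop.
contraction_weight <- function(n_phases) {
  t <- seq_len(n_phases) - 1L
  sin(pi * t / n_phases)^2
}

#' Generate a ground-truth cardiac phantom scene
#'
#' Builds the tissue label volume over the cardiac cycle, the through-plane
#' flow mask, and the static off-resonance field map. Deterministic for a
#' fixed `(config, seed)`; the seed drives small per-subject variations of
#' geometry and field map (controlled by `config$jitter`).
#'
#' @param config a [phantom_geometry()] configuration.
#' @param seed integer seed.
#' @return a list of class `phantom_scene` with elements `label_volume`
#'   (integer array, phases x H x W), `tissue_params`, `flow_mask` (logical
#'   array, same shape), `field_map` (H x W, Hz), `n_phases`, `pe_axis`,
#'   `config`, `seed`.
#' @export
make_phantom <- function(config = phantom_geometry(), seed = 0L) {
  stopifnot(inherits(config, "phantom_geometry"))
  H <- config$n_row; W <- config$n_col; P <- config$n_phases
  if (P < 1) stop("n_phases must be >= 1")
  rmin <- min(H, W)
  if (config$lv_outer_frac >= 0.5 || config$aorta_frac >= 0.5) {
    stop("phantom radii exceed the image: lv_outer_frac and aorta_frac must be < 0.5")
  }
  if (config$lv_inner_frac >= config$lv_outer_frac) {
    stop("lv_inner_frac must be smaller than lv_outer_frac")
  }
  if (!config$pe_axis %in% c("row", "col")) stop("pe_axis must be 'row' or 'col'")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  j <- config$jitter
  jit <- function(x, s = j) x * (1 + stats::runif(1, -s, s))

  ctr <- c(jit(config$lv_center[1], j / 2), jit(config$lv_center[2], j / 2))
  r_out0 <- jit(config$lv_outer_frac) * rmin
  r_in0 <- jit(config$lv_inner_frac) * rmin
  a_ctr <- c(jit(config$aorta_center[1], j / 2), jit(config$aorta_center[2], j / 2))
  a_r <- jit(config$aorta_frac) * rmin
  ramp <- jit(config$ramp_hz)
  ramp_angle <- stats::runif(1, -pi / 6, pi / 6)
  blob_amp <- jit(config$blob_hz)
  blob_ctr <- c(stats::runif(1, 0.15, 0.30), stats::runif(1, 0.55, 0.85))

  row_f <- (seq_len(H) - 0.5) / H
  col_f <- (seq_len(W) - 0.5) / W
  RW <- matrix(row_f, H, W)
  CW <- matrix(col_f, H, W, byrow = TRUE)

  # static field map: in-plane ramp + localized blob (Hz)
  u <- cos(ramp_angle) * (CW - 0.5) + sin(ramp_angle) * (RW - 0.5)
  sig <- config$blob_sigma_frac
  blob <- blob_amp * exp(-((RW - blob_ctr[1])^2 + (CW - blob_ctr[2])^2) / (2 * sig^2))
  field_map <- ramp * u + blob

  # distance maps (in pixels) from LV centre and aorta centre
  dr <- outer((seq_len(H) - 0.5) - ctr[1] * H, rep(1, W))
  dc <- outer(rep(1, H), (seq_len(W) - 0.5) - ctr[2] * W)
  d_lv <- sqrt(dr^2 + dc^2)
  dra <- outer((seq_len(H) - 0.5) - a_ctr[1] * H, rep(1, W))
  dca <- outer(rep(1, H), (seq_len(W) - 0.5) - a_ctr[2] * W)
  d_ao <- sqrt(dra^2 + dca^2)

  # body ellipse and fat rim
  e <- ((RW - 0.5)^2 / 0.45^2 + (CW - 0.5)^2 / 0.47^2)
  body <- e <= 1
  fat <- e <= 1 & e >= (1 - 2 * config$fat_frac / 0.45)

  cw <- contraction_weight(P)
  amp <- config$motion_amp
  label_volume <- array(TISSUE_IDS[["background"]], dim = c(P, H, W))
  flow_mask <- array(FALSE, dim = c(P, H, W))
  for (p in seq_len(P)) {
    r_out <- r_out0 * (1 - 0.5 * amp * cw[p])   # epicardium moves less
    r_in <- r_in0 * (1 - amp * cw[p])           # wall thickens in systole
    lab <- matrix(TISSUE_IDS[["background"]], H, W)
    lab[body] <- TISSUE_IDS[["abdomen"]]
    lab[fat] <- TISSUE_IDS[["fat"]]
    lab[d_lv <= r_out] <- TISSUE_IDS[["myocardium"]]
    lab[d_lv <= r_in] <- TISSUE_IDS[["blood"]]
    lab[d_ao <= a_r] <- TISSUE_IDS[["blood"]]
    label_volume[p, , ] <- lab
    flow_mask[p, , ] <- lab == TISSUE_IDS[["blood"]]
  }

  scene <- list(label_volume = label_volume,
                tissue_params = default_tissue_params(),
                flow_mask = flow_mask, field_map = field_map,
                n_phases = P, pe_axis = config$pe_axis,
                config = config, seed = as.integer(seed))
  class(scene) <- "phantom_scene"
  scene
}

# Save/restore the global RNG state so that generators are pure in (config,
# seed) without disturbing the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default bSSFP sequence parameters
#'
#' TR is 1000/330 ms (~3.03 ms) so that a 12-offset sweep has exactly
#' 27.5 Hz spacing; TE = TR/2; flip angle 60 degrees.
#' @return list with `tr_ms`, `te_ms`, `flip_deg`.
#' @export
default_seq_params <- function() {
  tr <- 1000 / 330
  list(tr_ms = tr, te_ms = tr / 2, flip_deg = 60)
}

# Construct a cine_movie object with validation.
new_cine_movie <- function(data, offset_hz, tr_ms, te_ms, flip_deg, pe_axis) {
  stopifnot(length(dim(data)) == 3)
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("cine movie data must be finite and non-negative (magnitude images)")
  }
  if (tr_ms <= 0) stop("tr_ms must be positive")
  if (flip_deg <= 0 || flip_deg > 90) stop("flip_deg must be in (0, 90]")
  structure(list(data = data, offset_hz = offset_hz, tr_ms = tr_ms,
                 te_ms = te_ms, flip_deg = flip_deg, pe_axis = pe_axis),
            class = "cine_movie")
}

#' Render one cine movie of a phantom at a given frequency offset
#'
#' Each voxel's intensity is the steady-state bSSFP magnitude
#' ([bssfp_profile()]) evaluated at its local off-resonance
#' (`field_map + offset_hz`) with its tissue's T1/T2 and scaled by proton
#' density, plus Rician noise (magnitude of complex Gaussian noise with
#' per-channel standard deviation `noise_sigma`).
#'
#' @param scene a [make_phantom()] scene.
#' @param offset_hz centre-frequency offset in Hz.
#' @param seq_params list with `tr_ms`, `te_ms`, `flip_deg`
#'   (default [default_seq_params()]).
#' @param noise_sigma Rician noise scale in the same arbitrary units as the
#'   signal; 0 disables noise.
#' @param seed integer seed for the noise.
#' @return a `cine_movie`.
#' @export
render_cine <- function(scene, offset_hz, seq_params = default_seq_params(),
                        noise_sigma = 0, seed = 0L) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  P <- scene$n_phases
  H <- dim(scene$field_map)[1]; W <- dim(scene$field_map)[2]
  tp <- scene$tissue_params
  # per-tissue spectral response at each voxel's local off-resonance
  offres <- scene$field_map + offset_hz          # H x W
  sig_by_tissue <- array(0, dim = c(nrow(tp), H, W))
  for (k in seq_len(nrow(tp))) {
    if (tp$pd[k] <= 0) next
    sig_by_tissue[k, , ] <- tp$pd[k] * bssfp_profile(
      offres, seq_params$tr_ms, seq_params$te_ms, seq_params$flip_deg,
      tp$t1_ms[k], tp$t2_ms[k])
  }
  id_row <- match(0:(nrow(tp) - 1L), tp$id)      # tissue id -> row
  data <- array(0, dim = c(P, H, W))
  for (p in seq_len(P)) {
    lab <- scene$label_volume[p, , ]
    rows <- id_row[lab + 1L]
    idx <- cbind(rows, as.vector(row(lab)), as.vector(col(lab)))
    data[p, , ] <- matrix(sig_by_tissue[idx], H, W)
  }
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    n1 <- array(stats::rnorm(length(data), 0, noise_sigma), dim = dim(data))
    n2 <- array(stats::rnorm(length(data), 0, noise_sigma), dim = dim(data))
    data <- sqrt((data + n1)^2 + n2^2)
  }
  new_cine_movie(data, offset_hz, seq_params$tr_ms, seq_params$te_ms,
                 seq_params$flip_deg, scene$pe_axis)
}

# Band weight in [0,1] at each voxel for a given offset: 1 at the centre of
# a dark band, 0 far from it. Uses the voxel's own tissue profile,
# normalized by that tissue's spectral maximum.
band_weight <- function(scene, offset_hz, seq_params = default_seq_params()) {
  P <- scene$n_phases
  H <- dim(scene$field_map)[1]; W <- dim(scene$field_map)[2]
  tp <- scene$tissue_params
  offres <- scene$field_map + offset_hz
  grid <- seq(0, banding_period_hz(seq_params$tr_ms), length.out = 256)
  wmap <- array(0, dim = c(nrow(tp), H, W))
  for (k in seq_len(nrow(tp))) {
    if (tp$pd[k] <= 0) next
    prof <- bssfp_profile(offres, seq_params$tr_ms, seq_params$te_ms,
                          seq_params$flip_deg, tp$t1_ms[k], tp$t2_ms[k])
    pmax_k <- max(bssfp_profile(grid, seq_params$tr_ms, seq_params$te_ms,
                                seq_params$flip_deg, tp$t1_ms[k], tp$t2_ms[k]))
    wmap[k, , ] <- 1 - prof / pmax_k
  }
  id_row <- match(0:(nrow(tp) - 1L), tp$id)
  out <- array(0, dim = c(P, H, W))
  for (p in seq_len(P)) {
    lab <- scene$label_volume[p, , ]
    rows <- id_row[lab + 1L]
    idx <- cbind(rows, as.vector(row(lab)), as.vector(col(lab)))
    out[p, , ] <- matrix(wmap[idx], H, W)
  }
  out
}

#' Add through-plane flow ghosts to a rendered movie
#'
#' Spins flowing through a dark band are not in the imaged steady state and
#' produce bright ghost replicas along the phase-encoding direction. The
#' ghost source at each flow voxel is its band weight (1 at a band centre, 0
#' away from bands) times the on-resonance blood signal; the source is
#' replicated `ghost_count` times at equispaced circular shifts along the
#' phase-encoding axis and added with amplitude `ghost_gain`.
#'
#' @param movie a rendered `cine_movie`.
#' @param scene the `phantom_scene` the movie was rendered from.
#' @param ghost_count number of ghost replicas (>= 0).
#' @param ghost_gain ghost amplitude as a fraction of the on-resonance blood
#'   signal (>= 0).
#' @return a `cine_movie` with ghosts added (intensities remain >= 0).
#' @export
add_flow_artifact <- function(movie, scene, ghost_count = 3, ghost_gain = 0.6) {
  stopifnot(inherits(movie, "cine_movie"), inherits(scene, "phantom_scene"))
  if (ghost_count < 0) stop("ghost_count must be >= 0")
  if (ghost_gain < 0) stop("ghost_gain must be >= 0")
  if (!movie$pe_axis %in% c("row", "col")) {
    stop("pe_axis must be one of the in-plane axes ('row' or 'col')")
  }
  if (ghost_count == 0 || ghost_gain == 0) return(movie)
  src <- flow_ghost_source(movie, scene)
  data <- movie$data + ghost_gain * replicate_ghosts(src, ghost_count, movie$pe_axis)
  data[data < 0] <- 0
  new_cine_movie(data, movie$offset_hz, movie$tr_ms, movie$te_ms,
                 movie$flip_deg, movie$pe_axis)
}

# Ghost source image: flow voxels weighted by local band weight and scaled
# by the unbanded (on-resonance) blood signal.
flow_ghost_source <- function(movie, scene) {
  sp <- list(tr_ms = movie$tr_ms, te_ms = movie$te_ms, flip_deg = movie$flip_deg)
  bw <- band_weight(scene, movie$offset_hz, sp)
  tp <- scene$tissue_params
  bl <- tp[tp$tissue == "blood", ]
  s_blood <- bl$pd * bssfp_profile(0, sp$tr_ms, sp$te_ms, sp$flip_deg,
                                   bl$t1_ms, bl$t2_ms)
  src <- array(0, dim = dim(movie$data))
  src[scene$flow_mask] <- bw[scene$flow_mask] * s_blood
  src
}

# Sum of circularly shifted copies of src along the PE axis, at shifts
# k * L/(n+1), k = 1..n.
replicate_ghosts <- function(src, n, pe_axis) {
  ax <- if (pe_axis == "row") 2L else 3L
  L <- dim(src)[ax]
  out <- array(0, dim = dim(src))
  for (k in seq_len(n)) {
    s <- round(k * L / (n + 1)) %% L
    out <- out + circ_shift(src, s, ax)
  }
  out
}

circ_shift <- function(x, s, axis) {
  if (s == 0) return(x)
  L <- dim(x)[axis]
  idx <- ((seq_len(L) - 1L - s) %% L) + 1L
  if (axis == 2L) x[, idx, , drop = FALSE] else x[, , idx, drop = FALSE]
}

#' Offset grid of a frequency sweep
#'
#' Arithmetic grid of `n_offsets` frequencies with spacing
#' `1/(n_offsets * TR)` covering the half-open banding period
#' `(-1/(2 TR), 1/(2 TR)]`. With 12 offsets and TR ~3.03 ms this is
#' (-137.5, -110, ..., 0, ..., 137.5, 165) Hz.
#'
#' @param n_offsets number of offsets (>= 2).
#' @param tr_ms repetition time in ms.
#' @return numeric vector, strictly increasing.
#' @export
sweep_offsets <- function(n_offsets, tr_ms) {
  if (n_offsets < 2) stop("n_offsets must be >= 2")
  delta <- 1000 / (n_offsets * tr_ms)
  (seq_len(n_offsets) - ceiling(n_offsets / 2)) * delta
}

# Construct a frequency_sweep from a list of movies.
new_frequency_sweep <- function(movies) {
  stopifnot(length(movies) >= 1)
  offs <- vapply(movies, function(m) m$offset_hz, numeric(1))
  o <- order(offs)
  movies <- movies[o]; offs <- offs[o]
  if (any(diff(offs) <= 0)) stop("offsets must be distinct")
  dims <- vapply(movies, function(m) dim(m$data), integer(3))
  if (any(dims != dims[, 1])) stop("all movies in a sweep must share geometry")
  trs <- vapply(movies, function(m) m$tr_ms, numeric(1))
  if (any(abs(trs - trs[1]) > 1e-9)) stop("all movies in a sweep must share TR")
  structure(list(movies = movies, offsets_hz = offs, geometry = dims[, 1]),
            class = "frequency_sweep")
}

#' Render a full frequency sweep of a phantom
#'
#' @param scene a `phantom_scene`.
#' @param n_offsets number of centre-frequency offsets (default 12).
#' @param seq_params sequence parameters.
#' @param noise_sigma Rician noise scale; the default
#'   `noise_frac * blood on-resonance signal` is applied when `NULL`.
#' @param noise_frac noise as a fraction of the on-resonance blood signal
#'   (default 0.02).
#' @param ghost_count,ghost_gain flow-ghost parameters
#'   (see [add_flow_artifact()]); `ghost_gain = 0` disables ghosts.
#' @param seed integer seed.
#' @return a `frequency_sweep`.
#' @export
render_sweep <- function(scene, n_offsets = 12,
                         seq_params = default_seq_params(),
                         noise_sigma = NULL, noise_frac = 0.02,
                         ghost_count = 3, ghost_gain = 0.6, seed = 0L) {
  offs <- sweep_offsets(n_offsets, seq_params$tr_ms)
  if (is.null(noise_sigma)) {
    tp <- scene$tissue_params
    bl <- tp[tp$tissue == "blood", ]
    s_blood <- bl$pd * bssfp_profile(0, seq_params$tr_ms, seq_params$te_ms,
                                     seq_params$flip_deg, bl$t1_ms, bl$t2_ms)
    noise_sigma <- noise_frac * s_blood
  }
  movies <- vector("list", n_offsets)
  for (i in seq_along(offs)) {
    m <- render_cine(scene, offs[i], seq_params, noise_sigma,
                     seed = as.integer(seed) * 131L + i)
    if (ghost_gain > 0 && ghost_count > 0) {
      m <- add_flow_artifact(m, scene, ghost_count, ghost_gain)
    }
    movies[[i]] <- m
  }
  new_frequency_sweep(movies)
}

#' Generate a multi-subject synthetic frequency-sweep dataset
#'
#' Produces `n_subjects * n_slices` frequency sweeps, each of `n_offsets`
#' movies, with per-subject randomized phantom geometry and field map, plus
#' a manifest listing every movie. Mirrors the layout of a training corpus
#' of 18 subjects x 3 slices x 12 offsets = 648 movies.
#'
#' @param config list with `n_subjects`, `n_slices`, `n_offsets`, optional
#'   `geometry` ([phantom_geometry()]), `seq_params`, `noise_frac`,
#'   `ghost_count`, `ghost_gain`. See [dataset_config()].
#' @param seed integer seed; everything is deterministic given
#'   `(config, seed)`.
#' @return list of class `sweep_collection`: `sweeps` (list, one per
#'   subject/slice), `manifest` (data.frame with one row per movie:
#'   subject, slice, offset_hz, tr_ms, movie_id), `scenes`, `config`,
#'   `seed`.
#' @export
generate_dataset <- function(config = dataset_config(), seed = 0L) {
  ns <- config$n_subjects; nl <- config$n_slices; no <- config$n_offsets
  if (no < 2) stop("n_offsets must be >= 2")
  sp <- config$seq_params
  sweeps <- list(); scenes <- list()
  rows <- list()
  k <- 0L
  for (s in seq_len(ns)) {
    for (l in seq_len(nl)) {
      k <- k + 1L
      sub_seed <- as.integer(seed) * 7919L + s * 101L + l
      geo <- config$geometry
      scene <- make_phantom(geo, seed = sub_seed)
      sw <- render_sweep(scene, n_offsets = no, seq_params = sp,
                         noise_frac = config$noise_frac,
                         ghost_count = config$ghost_count,
                         ghost_gain = config$ghost_gain, seed = sub_seed)
      sweeps[[k]] <- sw; scenes[[k]] <- scene
      rows[[k]] <- data.frame(subject = s, slice = l,
                              offset_hz = sw$offsets_hz,
                              tr_ms = sp$tr_ms, sweep_index = k,
                              movie_index = seq_len(no),
                              movie_id = sprintf("sub%02d_sl%d_off%+06.1f",
                                                 s, l, sw$offsets_hz))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(sweeps = sweeps, scenes = scenes, manifest = manifest,
                 config = config, seed = as.integer(seed)),
            class = "sweep_collection")
}

#' Dataset configuration for [generate_dataset()]
#'
#' @param n_subjects,n_slices,n_offsets dataset layout; the study layout is
#'   18 x 3 x 12.
#' @param geometry phantom geometry shared by all subjects (per-subject
#'   jitter is applied inside [make_phantom()]).
#' @param seq_params sequence parameters.
#' @param noise_frac Rician noise as a fraction of the on-resonance blood
#'   signal.
#' @param ghost_count,ghost_gain flow-ghost model parameters.
#' @return list of class `dataset_config`.
#' @export
dataset_config <- function(n_subjects = 18, n_slices = 3, n_offsets = 12,
                           geometry = phantom_geometry(),
                           seq_params = default_seq_params(),
                           noise_frac = 0.02, ghost_count = 3,
                           ghost_gain = 0.6) {
  structure(list(n_subjects = n_subjects, n_slices = n_slices,
                 n_offsets = n_offsets, geometry = geometry,
                 seq_params = seq_params, noise_frac = noise_frac,
                 ghost_count = ghost_count, ghost_gain = ghost_gain),
            class = "dataset_config")
}
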