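# Shared fixtures. Everything is generated in code; sizes are kept small so
# the whole suite stays fast.

tiny_geometry <- function(n_phases = 6, size = 32) {
  phantom_geometry(n_row = size, n_col = size, n_phases = n_phases)
}

tiny_scene <- function(seed = 1, ...) {
  make_phantom(tiny_geometry(...), seed = seed)
}

tiny_sweep <- function(seed = 1, n_offsets = 12, ghost_gain = 0.6, ...) {
  sc <- tiny_scene(seed = seed, ...)
  list(scene = sc,
       sweep = render_sweep(sc, n_offsets = n_offsets, ghost_gain = ghost_gain,
                            seed = seed))
}

# A toy sweep built directly from constant arrays, bypassing the renderer.
constant_sweep <- function(values, offsets = NULL, dims = c(2, 4, 4)) {
  if (is.null(offsets)) {
    offsets <- sweep_offsets(length(values), default_seq_params()$tr_ms)
  }
  sp <- default_seq_params()
  movies <- lapply(seq_along(values), function(i) {
    structure(list(data = array(values[i], dim = dims), offset_hz = offsets[i],
                   tr_ms = sp$tr_ms, te_ms = sp$te_ms, flip_deg = sp$flip_deg,
                   pe_axis = "row"), class = "cine_movie")
  })
  cinebands:::new_frequency_sweep(movies)
}

# Independent steady-state oracle: iterate the Bloch equations (alternating
# RF phase, relaxation + precession over TR) to convergence and read the
# transverse magnitude at TE. Used to cross-check the closed-form profile.
bloch_steady_state <- function(offres_hz, tr_ms, te_ms, flip_deg,
                               t1_ms, t2_ms, n_iter = 5000) {
  a <- flip_deg * pi / 180
  rx <- function(ang) matrix(c(1, 0, 0,
                               0, cos(ang), sin(ang),
                               0, -sin(ang), cos(ang)), 3, 3)
  beta <- 2 * pi * offres_hz * tr_ms / 1000
  rz <- function(b) matrix(c(cos(b), sin(b), 0,
                             -sin(b), cos(b), 0,
                             0, 0, 1), 3, 3)
  e1 <- exp(-tr_ms / t1_ms); e2 <- exp(-tr_ms / t2_ms)
  relax <- diag(c(e2, e2, e1)); recov <- c(0, 0, 1 - e1)
  m <- c(0, 0, 1); s <- 1
  for (i in seq_len(n_iter)) {
    m <- rx(s * a) %*% m
    m <- relax %*% (rz(beta) %*% m) + recov
    s <- -s
  }
  m <- rx(a) %*% m
  e1e <- exp(-te_ms / t1_ms); e2e <- exp(-te_ms / t2_ms)
  me <- diag(c(e2e, e2e, e1e)) %*% (rz(beta * te_ms / tr_ms) %*% m) +
    c(0, 0, 1 - e1e)
  sqrt(me[1]^2 + me[2]^2)
}
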