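#' Short-range phase-cycling (SPC) combination
#'
#' Voxelwise arithmetic mean of the movies acquired at the central
#' frequency offsets (`|offset| <= central_band_hz`). On the baseline
#' 12-offset / 27.5 Hz grid the default band of 55 Hz selects exactly the
#' five offsets {0, +-27.5, +-55} Hz. Because the central frequencies
#' rarely place a dark band over the heart, their mean suppresses banding
#' without recruiting the flow ghosts that contaminate the extreme offsets.
#'
#' @param sweep a `frequency_sweep`.
#' @param central_band_hz half-width of the central band (default 55).
#' @return list of class `spc_label`: `data` (movie-shaped array),
#'   `source_offsets_hz`.
#' @export
spc_combine <- function(sweep, central_band_hz = 55) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  if (central_band_hz < 0) stop("central_band_hz must be >= 0")
  sel <- which(abs(sweep$offsets_hz) <= central_band_hz + 1e-9)
  if (length(sel) == 0) {
    stop("no offsets within +-", central_band_hz, " Hz; cannot build an SPC label")
  }
  combine_movies(sweep$movies[sel], sweep$offsets_hz[sel])
}

#' Full-range phase-cycling (FPC) combination
#'
#' Voxelwise mean of all movies in the sweep. Removes banding thoroughly
#' but averages in the flow ghosts present at extreme offsets.
#'
#' @param sweep a `frequency_sweep`.
#' @return an `spc_label` whose sources are the whole sweep.
#' @export
fpc_combine <- function(sweep) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  if (length(sweep$movies) == 0) stop("empty sweep")
  combine_movies(sweep$movies, sweep$offsets_hz)
}

combine_movies <- function(movies, offsets) {
  acc <- array(0, dim = dim(movies[[1]]$data))
  for (m in movies) acc <- acc + m$data
  structure(list(data = acc / length(movies), source_offsets_hz = offsets),
            class = "spc_label")
}

#' Sigmoid voxel-identity (VI) training label
#'
#' Elementwise `sigmoid(SPC / original - 1)` with the denominator clamped
#' at `eps`. Dark-band voxels (original much darker than the SPC combine)
#' map toward 1; bright flow-ghost voxels (original brighter than SPC) map
#' down toward the lower bound `sigmoid(-1) ~ 0.269`; artifact-free voxels
#' map to exactly 0.5 where SPC equals the original.
#'
#' @param spc an `spc_label` (or movie-shaped array).
#' @param original the original `cine_movie` (or movie-shaped array).
#' @param eps denominator clamp; default `1e-3` times the original's 99th
#'   percentile.
#' @return list of class `vi_label` with element `data` in (0, 1).
#' @export
vi_label <- function(spc, original, eps = NULL) {
  s <- if (inherits(spc, "spc_label")) spc$data else spc
  o <- if (inherits(original, "cine_movie")) original$data else original
  if (!identical(dim(s), dim(o))) {
    stop("shape mismatch between SPC label and original movie")
  }
  if (is.null(eps)) eps <- 1e-3 * stats::quantile(o, 0.99, names = FALSE)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  # clamp the logit argument so deep-band ratios cannot round to exactly 1
  # in double precision; sigmoid(30) is still < 1
  data <- sigmoid(pmin(s / pmax(o, eps) - 1, 30))
  structure(list(data = data, eps = eps), class = "vi_label")
}

#' Normalize a cine movie to approximately [0, 1]
#'
#' Scales intensities by the movie's 99th percentile (a robust maximum) and
#' optionally centre-crops to a target matrix. The normalization factor is
#' recorded so outputs can be mapped back with [unpreprocess()].
#'
#' @param movie a `cine_movie`.
#' @param crop optional `c(rows, cols)` centre crop.
#' @return a `cine_movie` with attribute `norm_factor` (and `crop_offset`
#'   when cropped).
#' @export
preprocess <- function(movie, crop = NULL) {
  stopifnot(inherits(movie, "cine_movie"))
  f <- stats::quantile(movie$data, 0.99, names = FALSE)
  if (f <= 0) stop("cannot normalize an all-zero movie")
  data <- movie$data / f
  off <- c(0L, 0L)
  if (!is.null(crop)) {
    d <- dim(data)
    if (any(crop > d[2:3])) stop("crop larger than the movie")
    off <- as.integer(floor((d[2:3] - crop) / 2))
    data <- data[, off[1] + seq_len(crop[1]), off[2] + seq_len(crop[2]),
                 drop = FALSE]
  }
  out <- new_cine_movie(data, movie$offset_hz, movie$tr_ms, movie$te_ms,
                        movie$flip_deg, movie$pe_axis)
  attr(out, "norm_factor") <- f
  attr(out, "crop_offset") <- off
  out
}

#' Undo the intensity normalization of [preprocess()]
#'
#' @param movie a preprocessed `cine_movie` (or array).
#' @param norm_factor the recorded factor; taken from the movie's attribute
#'   when omitted.
#' @return movie with original intensity scale (cropping is not undone).
#' @export
unpreprocess <- function(movie, norm_factor = attr(movie, "norm_factor")) {
  if (is.null(norm_factor)) stop("no norm_factor recorded on this movie")
  if (inherits(movie, "cine_movie")) {
    out <- movie
    out$data <- movie$data * norm_factor
    attr(out, "norm_factor") <- NULL
    out
  } else {
    movie * norm_factor
  }
}
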