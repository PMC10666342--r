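#' Steady-state bSSFP magnitude signal
#'
#' Classical closed-form steady-state magnitude of a balanced SSFP sequence
#' (Freeman-Hill form, RF phase alternation convention) as a function of
#' off-resonance frequency. The signal is periodic in off-resonance with
#' period `1000/tr_ms` Hz and minimal -- the dark band -- where the
#' per-repetition precession angle `beta = 2*pi*offres_hz*tr_ms/1000`
#' equals pi (mod 2*pi). The returned magnitude includes `exp(-TE/T2)`
#' decay at the echo.
#'
#' All arguments are vectorized and recycled against each other.
#'
#' @param offres_hz off-resonance frequency in Hz.
#' @param tr_ms,te_ms repetition and echo time in milliseconds. The usual
#'   balanced choice is `te_ms = tr_ms/2`.
#' @param flip_deg excitation flip angle in degrees, in (0, 90].
#' @param t1_ms,t2_ms longitudinal and transverse relaxation times in
#'   milliseconds; requires `t1 >= t2 > 0`.
#' @return numeric vector of signal magnitudes (arbitrary units, for unit
#'   proton density).
#' @examples
#' # a blood-like voxel: bright on resonance, dark at the band
#' bssfp_profile(0,   3.03, 1.515, 60, 1900, 250)
#' bssfp_profile(165, 3.03, 1.515, 60, 1900, 250)
#' @export
bssfp_profile <- function(offres_hz, tr_ms, te_ms, flip_deg, t1_ms, t2_ms) {
  if (any(t2_ms <= 0) || any(t1_ms <= 0)) {
    stop("relaxation times t1_ms and t2_ms must be positive")
  }
  if (any(t1_ms < t2_ms)) stop("t1_ms must be >= t2_ms")
  if (any(tr_ms <= 0)) stop("tr_ms must be positive")
  if (any(flip_deg <= 0 | flip_deg > 90)) stop("flip_deg must be in (0, 90]")
  e1 <- exp(-tr_ms / t1_ms)
  e2 <- exp(-tr_ms / t2_ms)
  ca <- cos(flip_deg * pi / 180)
  sa <- sin(flip_deg * pi / 180)
  beta <- 2 * pi * offres_hz * tr_ms / 1000
  cb <- cos(beta)
  # RF phase alternation shifts the spectral response by pi, putting the
  # pass-band on resonance and the band at beta = pi.
  num <- sqrt(1 + 2 * e2 * cb + e2^2)
  den <- (1 - e1 * ca) * (1 + e2 * cb) - (e1 - ca) * (e2 + cb) * e2
  sa * (1 - e1) * num / den * exp(-te_ms / t2_ms)
}

# Off-resonance at which beta = pi, i.e. the centre of the dark band:
# half the banding period 1/TR.
banding_period_hz <- function(tr_ms) 1000 / tr_ms
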