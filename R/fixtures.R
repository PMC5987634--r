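# Synthetic fixtures with closed-form ground truth.  Every generated object
# carries its truth alongside the data so downstream metrics can be tested
# without running the simulator.

#' Ideal two-segment current dipole
#'
#' Builds a pair of short (\code{seg_length} <= 1 um) colinear segments on
#' the x axis separated by \code{d}, carrying opposite currents
#' \code{+I w(t)} (source, at +d/2) and \code{-I w(t)} (sink, at -d/2), so
#' the total current is zero at every instant.  The result is shaped like a
#' \code{sim_result} and can be passed straight to
#' \code{\link{field_from_simulation}}.
#'
#' @param I Dipole current intensity (nA).
#' @param d Sink--source separation (um), > 0.
#' @param waveform Time course w(t) (dimensionless); default a constant 1.
#' @param dt Sample interval of the waveform (ms).
#' @param seg_length Length of each source segment (um, <= 1).
#' @return List with \code{time}, \code{I_membrane} (time x 2),
#'   \code{morphology}, and ground truth \code{moment} (nA um),
#'   \code{center}, \code{axis}.
#' @export
make_dipole_currents <- function(I, d, waveform = 1, dt = 0.01,
                                 seg_length = 0.5) {
  if (d <= 0) stop("d must be > 0")
  stopifnot(seg_length > 0, seg_length <= 1)
  h <- seg_length / 2
  morph <- data.frame(
    section = c("axon", "axon"),
    x0 = c(-d / 2 - h, d / 2 - h), y0 = 0, z0 = 0,
    x1 = c(-d / 2 + h, d / 2 + h), y1 = 0, z1 = 0,
    diam = 1)
  morph$length <- segment_lengths(morph)
  morph$area <- segment_areas(morph)
  morph$index <- 1:2
  w <- waveform
  list(time = (seq_along(w) - 1) * dt,
       I_membrane = cbind(-I * w, I * w),   # sink at -d/2, source at +d/2
       morphology = morph,
       moment = I * d, center = c(0, 0, 0), axis = "x")
}

#' Synthetic biphasic EAP-like waveform
#'
#' Difference-of-Gaussians trough-then-peak trace with analytically known
#' peak-to-peak amplitude and width at half peak-to-peak amplitude.  The
#' trough Gaussian has amplitude 2/3 vpp and the peak Gaussian 1/3 vpp,
#' centred 6 standard deviations apart so their overlap is negligible
#' (< 1e-7 relative); the half-amplitude threshold then cuts the trough
#' Gaussian at 1/4 of its height, giving
#' \code{width = 2 sigma sqrt(2 log 4)}, i.e.
#' \code{sigma = width / (2 sqrt(2 log 4))}.  An optional leading positive
#' bump of \code{positivity_fraction * vpp} is placed 6 sigma before the
#' trough to emulate the initial positivity of axonally initiated spikes.
#'
#' @param vpp Target peak-to-peak amplitude (uV), > 0.
#' @param width Target width at half peak-to-peak amplitude (ms), > 0.
#' @param positivity_fraction Amplitude of the leading positive bump as a
#'   fraction of vpp (0 disables it; must be < 1/3 so the bump never becomes
#'   the global maximum).
#' @param dt Sample interval (ms); must be smaller than \code{width}.
#' @return List with \code{time}, \code{trace}, and ground truth \code{vpp},
#'   \code{width}, \code{has_initial_positivity}, \code{t_trough},
#'   \code{t_peak}.
#' @export
make_biphasic_waveform <- function(vpp, width, positivity_fraction = 0,
                                   dt = 0.01) {
  stopifnot(vpp > 0, width > 0,
            positivity_fraction >= 0, positivity_fraction < 1 / 3)
  if (dt >= width) stop("dt must be smaller than the requested width")
  sigma <- width / (2 * sqrt(2 * log(4)))
  A <- 2 / 3 * vpp        # trough depth
  B <- 1 / 3 * vpp        # peak height
  t0 <- 10 * sigma        # trough centre
  t1 <- t0 + 6 * sigma    # peak centre
  tb <- t0 - 6 * sigma    # positivity bump centre
  time <- seq(0, t1 + 5 * sigma, by = dt)
  trace <- -A * exp(-(time - t0)^2 / (2 * sigma^2)) +
    B * exp(-(time - t1)^2 / (2 * sigma^2)) +
    positivity_fraction * vpp * exp(-(time - tb)^2 / (2 * sigma^2))
  list(time = time, trace = trace,
       vpp = vpp, width = width,
       has_initial_positivity = positivity_fraction > 0,
       t_trough = t0, t_peak = t1)
}

#' Synthetic power-law amplitude profile
#'
#' Log-spaced distances with amplitudes \code{c0 r^k}, optionally corrupted
#' by multiplicative lognormal noise.  A seed is mandatory whenever the noise
#' level is positive, so identical specifications generate identical data.
#'
#' @param k Planted exponent.
#' @param n_points Number of points (>= 3).
#' @param noise_sd Standard deviation of the log-amplitude noise.
#' @param seed RNG seed (required when \code{noise_sd > 0}).
#' @param c0 Amplitude scale (uV at r = 1 um).
#' @param range Distance range (um).
#' @return List with \code{distances}, \code{amplitudes}, and the ground
#'   truth \code{k_true}, \code{c0}, \code{noise_sd}, \code{seed}.
#' @export
make_powerlaw_profile <- function(k, n_points = 20, noise_sd = 0,
                                  seed = NULL, c0 = 1e6,
                                  range = c(50, 1000)) {
  stopifnot(n_points >= 3)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is mandatory when noise_sd > 0")
  r <- log_spaced(range[1], range[2], n_points)
  noise <- if (noise_sd > 0) {
    set.seed(seed)
    exp(stats::rnorm(n_points, 0, noise_sd))
  } else rep(1, n_points)
  list(distances = r, amplitudes = c0 * r^k * noise,
       k_true = k, c0 = c0, noise_sd = noise_sd, seed = seed)
}
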