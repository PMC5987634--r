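# Waveform and spatial statistics of extracellular action potentials.

#' Peak-to-peak amplitude
#'
#' \code{max(trace) - min(trace)} over the whole analysis window.
#'
#' @param trace Numeric time series (uV), at least two samples.
#' @return Peak-to-peak amplitude (uV, >= 0).
#' @export
peak_to_peak <- function(trace) {
  if (length(trace) < 2) stop("trace must contain at least 2 samples")
  max(trace) - min(trace)
}

#' Spike width at half peak-to-peak amplitude
#'
#' Identifies the dominant extremum (largest absolute value) of a
#' baseline-subtracted trace, sets the threshold half of the peak-to-peak
#' amplitude away from that extremum (towards baseline), and returns the time
#' between the two threshold crossings bracketing the extremum, with linear
#' interpolation between samples.  Errors if the trace never crosses the
#' threshold on one side of the extremum (a truncated width is never
#' returned).
#'
#' @param trace Baseline-subtracted time series with a dominant extremum.
#' @param time Sample times (ms), same length as \code{trace}.
#' @return Width in ms.
#' @export
width_at_half_amplitude <- function(trace, time) {
  stopifnot(length(trace) == length(time), length(trace) >= 3)
  vpp <- peak_to_peak(trace)
  if (vpp <= 0) stop("flat trace has no width")
  ipk <- which.max(abs(trace))
  s <- sign(trace[ipk])
  thr <- trace[ipk] - s * vpp / 2
  # g > 0 at the extremum; crossings are sign changes of g
  g <- s * (trace - thr)
  left <- which(g[seq_len(ipk - 1)] < 0)
  if (length(left) == 0)
    stop("threshold never crossed before the dominant extremum")
  il <- max(left)
  right <- which(g[(ipk + 1):length(g)] < 0)
  if (length(right) == 0)
    stop("threshold never crossed after the dominant extremum")
  ir <- ipk + min(right)
  cross <- function(i, j) {
    time[i] + (time[j] - time[i]) * (0 - g[i]) / (g[j] - g[i])
  }
  cross(ir - 1, ir) - cross(il, il + 1)
}

# Indices of strict-left / weak-right local maxima above a height floor.
local_maxima <- function(x, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > min_height]
}

#' Detect an initial positive deflection
#'
#' Returns TRUE when a positive local maximum exceeding a configurable
#' fraction of the peak-to-peak amplitude occurs before the global trough of
#' a baseline-subtracted trace.  This is the extracellular hallmark of the
#' axial current drawn by the AIS at spike onset: electrodes over the soma
#' see the somatic return current as a sharp positivity preceding the
#' negative spike.
#'
#' @param trace Baseline-subtracted time series (uV).
#' @param time Sample times (ms).
#' @param ap_reference_time Optional: only deflections at or after this time
#'   are considered.
#' @param fraction Detection threshold as a fraction of the peak-to-peak
#'   amplitude (default 0.05).
#' @return List with \code{detected} (flag), \code{amplitude} (uV) and
#'   \code{time} (ms) of the largest qualifying deflection (NA when none).
#' @export
detect_initial_positivity <- function(trace, time, ap_reference_time = NULL,
                                      fraction = 0.05) {
  stopifnot(length(trace) == length(time))
  vpp <- max(trace) - min(trace)
  none <- list(detected = FALSE, amplitude = NA_real_, time = NA_real_)
  if (vpp <= 0) return(none)
  itrough <- which.min(trace)
  cand <- local_maxima(trace, min_height = fraction * vpp)
  cand <- cand[cand < itrough]
  if (!is.null(ap_reference_time))
    cand <- cand[time[cand] >= ap_reference_time]
  if (length(cand) == 0) return(none)
  best <- cand[which.max(trace[cand])]
  list(detected = TRUE, amplitude = trace[best], time = time[best])
}

#' Fit a power-law decay exponent
#'
#' Ordinary least squares of \code{log10(amplitude)} on
#' \code{log10(distance)} restricted to a fit range; the slope estimates the
#' exponent k of the \code{r^k} decay law.
#'
#' @param distances Recording distances (um), all > 0.
#' @param amplitudes Amplitudes (uV), all > 0.
#' @param fit_range Two-element range (um) of distances entering the fit;
#'   at least 3 points must fall inside.
#' @return An \code{exponent_fit}: list with \code{k}, \code{intercept},
#'   \code{stderr_k}, \code{residual_rms}, \code{fit_range},
#'   \code{n_points}.
#' @export
fit_power_law <- function(distances, amplitudes, fit_range = c(200, 1000)) {
  stopifnot(length(distances) == length(amplitudes),
            length(fit_range) == 2, fit_range[1] < fit_range[2])
  if (any(distances <= 0) || any(amplitudes <= 0))
    stop("distances and amplitudes must all be > 0")
  sel <- distances >= fit_range[1] & distances <= fit_range[2]
  if (sum(sel) < 3)
    stop("fewer than 3 points inside the fit range [",
         fit_range[1], ", ", fit_range[2], "] um")
  lx <- log10(distances[sel])
  ly <- log10(amplitudes[sel])
  fit <- stats::lm(ly ~ lx)
  res <- stats::residuals(fit)
  n <- length(lx)
  # slope standard error from the OLS algebra (vcov warns on perfect fits)
  se_k <- sqrt(sum(res^2) / (n - 2) / sum((lx - mean(lx))^2))
  structure(list(k = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 stderr_k = se_k,
                 residual_rms = sqrt(mean(res^2)),
                 fit_range = fit_range,
                 n_points = sum(sel)),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("power-law fit: k = %.4f (se %.4f), %d points in [%g, %g] um\n",
              x$k, x$stderr_k, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Phase plot of a membrane-potential trace
#'
#' Pairs each voltage sample with its central-difference time derivative
#' (one-sided at the ends).  The shape of the (V, dV/dt) trajectory at spike
#' onset distinguishes axonal from somatic initiation: lateral current from a
#' distally initiated spike makes the somatic dV/dt rise abruptly (the
#' "kink"), whereas a somatically initiated spike accelerates smoothly.
#'
#' @param v Uniformly sampled membrane potential (mV), at least 3 samples.
#' @param dt Sampling interval (ms).
#' @return data.frame with columns \code{Vm} (mV) and \code{dVdt} (mV/ms).
#' @export
phase_plot <- function(v, dt) {
  n <- length(v)
  if (n < 3) stop("phase plot needs at least 3 samples")
  stopifnot(dt > 0)
  dvdt <- numeric(n)
  dvdt[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  dvdt[1] <- (v[2] - v[1]) / dt
  dvdt[n] <- (v[n] - v[n - 1]) / dt
  data.frame(Vm = v, dVdt = dvdt)
}

#' Phase-plot onset rapidity
#'
#' Slope of the phase trajectory d(dV/dt)/dV at spike onset, estimated where
#' dV/dt first sustainedly exceeds \code{at_dvdt} on the upstroke of the
#' largest depolarisation.  Axonally initiated somatic spikes have a much
#' larger onset rapidity (the kink) than somatically initiated ones.
#'
#' @param v Membrane potential trace (mV).
#' @param dt Sampling interval (ms).
#' @param at_dvdt Onset criterion (mV/ms).
#' @return Onset rapidity in 1/ms.
#' @export
onset_rapidity <- function(v, dt, at_dvdt = 10) {
  pp <- phase_plot(v, dt)
  ipk <- which.max(pp$Vm)
  up <- seq_len(ipk)
  i0 <- which(pp$dVdt[up] >= at_dvdt)
  if (length(i0) == 0) stop("dV/dt never reaches ", at_dvdt, " mV/ms")
  i <- i0[1]
  if (i < 2) i <- 2
  (pp$dVdt[i + 1] - pp$dVdt[i - 1]) / (pp$Vm[i + 1] - pp$Vm[i - 1])
}
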