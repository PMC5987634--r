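# Line-source-approximation forward model: infinite, homogeneous, isotropic,
# purely resistive medium (quasi-static).  Potentials in uV for currents in
# nA, distances in um, conductivity in S/m.

#' Electrode positions
#'
#' @param x,y,z Coordinates in um (recycled to a common length).
#' @param label Optional electrode labels.
#' @return data.frame with columns x, y, z, label.
#' @export
electrode_points <- function(x, y = 0, z = 0, label = NULL) {
  df <- data.frame(x = x, y = y, z = z)
  df$label <- if (is.null(label))
    sprintf("e%02d_x%g_y%g_z%g", seq_len(nrow(df)), df$x, df$y, df$z)
  else label
  df
}

#' Logarithmically spaced distances
#'
#' @param from,to Range limits (um), both > 0.
#' @param n Number of points.
#' @export
log_spaced <- function(from, to, n) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

# Dimensionless line integral int_0^L ds / |x_e - p(s)| for a unit-current
# line source.  x is the electrode's axial coordinate (um, measured from the
# segment start), h its perpendicular distance from the axis (um).
lsa_integral <- function(L, x, h) {
  if (h < 1e-9) {
    if (x > -1e-9 && x < L + 1e-9)
      stop("electrode lies on the source axis segment (singular)")
    if (x > L / 2) x <- L - x          # integral is symmetric in x -> L - x
    log((L - x) / (-x))
  } else {
    asinh((L - x) / h) - asinh(-x / h)
  }
}

#' Potential of a uniform line source
#'
#' Closed-form line-source approximation: the extracellular potential of a
#' cylindrical segment carrying current \code{I} uniformly along its axis,
#' \code{V = I / (4 pi sigma L) * int_0^L ds / |x_e - p(s)|}, evaluated with
#' the standard logarithmic/asinh closed form.  An electrode on the source
#' axis segment itself is a genuine singularity and raises an error (no
#' silent clamping).
#'
#' @param source One segment: a one-row morphology data.frame or a list with
#'   fields x0, y0, z0, x1, y1, z1.
#' @param I Segment current (nA), uniform along the segment.
#' @param electrode Electrode position: numeric xyz of length 3 or a one-row
#'   data.frame with x, y, z.
#' @param sigma Extracellular conductivity (S/m).
#' @return Potential in uV.
#' @export
line_source_potential <- function(source, I, electrode, sigma = 0.3) {
  stopifnot(sigma > 0)
  if (is.data.frame(electrode)) electrode <- c(electrode$x[1], electrode$y[1],
                                               electrode$z[1])
  p0 <- c(source$x0[1], source$y0[1], source$z0[1])
  p1 <- c(source$x1[1], source$y1[1], source$z1[1])
  L <- sqrt(sum((p1 - p0)^2))
  stopifnot(L > 0)
  u <- (p1 - p0) / L
  w <- electrode - p0
  x <- sum(w * u)
  h <- sqrt(max(sum(w * w) - x^2, 0))
  1000 * I / (4 * pi * sigma * L) * lsa_integral(L, x, h)
}

#' Potential of a point current source
#'
#' \code{V = I / (4 pi sigma r)}; the kernel is symmetric under exchanging
#' source and electrode positions.
#'
#' @param I Current (nA).
#' @param r Source--electrode distance (um), > 0.
#' @param sigma Extracellular conductivity (S/m).
#' @return Potential in uV.
#' @export
point_source_potential <- function(I, r, sigma = 0.3) {
  stopifnot(all(r > 0), sigma > 0)
  1000 * I / (4 * pi * sigma * r)
}

#' Far-field potential of a current dipole
#'
#' Closed form \code{V = I d cos(theta) / (4 pi sigma r^2)} for a current
#' sink/source pair of intensity \code{I} separated by \code{d}.  Valid only
#' in the far field, i.e. for \code{r} much larger than \code{d}.
#'
#' @param I Dipole current intensity (nA).
#' @param d Sink--source separation (um).
#' @param r Distance from the dipole (um), > 0.
#' @param theta Angle from the dipole axis (radians).
#' @param sigma Extracellular conductivity (S/m).
#' @return Potential in uV.
#' @export
dipole_potential <- function(I, d, r, theta, sigma = 0.3) {
  stopifnot(sigma > 0)
  if (any(r <= 0)) stop("r must be > 0")
  1000 * I * d * cos(theta) / (4 * pi * sigma * r^2)
}

# Kernel matrix (uV per nA): one row per segment, one column per electrode.
# Singularities are re-raised naming the offending electrode and segment.
lsa_kernel <- function(morphology, electrodes, sigma = 0.3) {
  ne <- nrow(electrodes)
  ns <- nrow(morphology)
  K <- matrix(0, ns, ne)
  for (e in seq_len(ne)) {
    pos <- c(electrodes$x[e], electrodes$y[e], electrodes$z[e])
    for (s in seq_len(ns)) {
      K[s, e] <- tryCatch(
        line_source_potential(morphology[s, ], 1, pos, sigma),
        error = function(err) stop("electrode '", electrodes$label[e],
                                   "' vs segment ", s, ": ",
                                   conditionMessage(err), call. = FALSE))
    }
  }
  K
}

#' Extracellular field of a simulated neuron
#'
#' Sums the line-source potentials of all segments,
#' \code{V_ext(e, t) = sum_i line_source_potential(segment_i,
#' I_membrane[t, i], e, sigma)}.  The map is linear in the currents.
#'
#' @param result A \code{sim_result} (or any list with \code{time},
#'   \code{I_membrane} and \code{morphology}, e.g. a fixture from
#'   \code{\link{make_dipole_currents}}).
#' @param electrodes data.frame from \code{\link{electrode_points}}.
#' @param sigma Extracellular conductivity (S/m); 0.3 S/m by default.
#' @return A \code{field_recording}: list with \code{electrodes},
#'   \code{time} (ms), \code{V_ext} (uV, time x electrode) and \code{sigma}.
#' @export
field_from_simulation <- function(result, electrodes, sigma = 0.3) {
  I <- result$I_membrane
  morph <- result$morphology
  if (ncol(I) != nrow(morph))
    stop("current matrix has ", ncol(I), " columns but morphology has ",
         nrow(morph), " segments")
  K <- lsa_kernel(morph, electrodes, sigma)
  structure(list(electrodes = electrodes, time = result$time,
                 V_ext = I %*% K, sigma = sigma),
            class = "field_recording")
}

#' Remove the pre-spike baseline from a recording
#'
#' Per electrode, subtracts the mean potential over the window from 2 to 1 ms
#' before the AP peak.  Idempotent up to floating-point tolerance.
#'
#' @param recording A \code{field_recording}.
#' @param ap_peak_time AP peak time (ms); the window
#'   \code{[ap_peak_time - 2, ap_peak_time - 1]} must lie inside the
#'   recording.
#' @return The recording with the baseline removed (and stored in attribute
#'   \code{baseline}).
#' @export
subtract_baseline <- function(recording, ap_peak_time) {
  t <- recording$time
  w0 <- ap_peak_time - 2
  w1 <- ap_peak_time - 1
  if (w0 < t[1] - 1e-9 || w1 > t[length(t)] + 1e-9)
    stop("baseline window [", w0, ", ", w1, "] ms outside the recorded range")
  idx <- t >= w0 - 1e-9 & t <= w1 + 1e-9
  base <- colMeans(recording$V_ext[idx, , drop = FALSE])
  recording$V_ext <- sweep(recording$V_ext, 2, base, `-`)
  attr(recording, "baseline") <- base
  recording
}

#' Convert a field recording to a data.frame
#'
#' One column per electrode (named by the electrode labels, which encode the
#' positions) plus a leading time column; suitable for
#' \code{\link{write_table}}.
#'
#' @param x A \code{field_recording}.
#' @param ... Unused.
#' @export
as.data.frame.field_recording <- function(x, ...) {
  df <- as.data.frame(x$V_ext)
  names(df) <- x$electrodes$label
  cbind(data.frame(time = x$time), df)
}
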