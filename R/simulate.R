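# Cable-equation solver.  Internal unit system: mV, ms, nA, MOhm, uS, nF, um.

#' Passive membrane and cytoplasm parameters
#'
#' @param Ra Axial resistivity (Ohm cm), > 0.
#' @param Cm Specific membrane capacitance (uF/cm^2), > 0.
#' @param temperature Nominal temperature in degrees C (bookkeeping only; no
#'   temperature dependence is modelled).
#' @return A \code{passive_params} list.
#' @export
passive_params <- function(Ra = 150, Cm = 1, temperature = 37) {
  stopifnot(Ra > 0, Cm > 0)
  structure(list(Ra = Ra, Cm = Cm, temperature = temperature),
            class = "passive_params")
}

#' Current-step stimulus
#'
#' @param target_segment Segment index receiving the step; \code{NULL} means
#'   the middle soma segment.
#' @param amplitude Step amplitude (nA).
#' @param onset Step onset (ms).
#' @param duration Step duration (ms), > 0.
#' @return A \code{stimulus_spec} list.
#' @export
stimulus_spec <- function(target_segment = NULL, amplitude = 1.3,
                          onset = 5, duration = 1) {
  stopifnot(duration > 0)
  structure(list(target_segment = target_segment, amplitude = amplitude,
                 onset = onset, duration = duration),
            class = "stimulus_spec")
}

# Coupling conductance (uS) across each inter-segment boundary: the two
# half-segment cytoplasmic resistances in series.
# R_half [MOhm] = Ra [Ohm cm] * (L/2) / (pi (d/2)^2) * 1e-2   (L, d in um)
axial_conductances <- function(morph, Ra) {
  L <- segment_lengths(morph)
  rhalf <- Ra * 1e-2 * (L / 2) / (pi * (morph$diam / 2)^2)
  n <- nrow(morph)
  if (n < 2) return(numeric(0))
  1 / (rhalf[-n] + rhalf[-1])
}

# Weighted chain Laplacian L (uS) such that (V %*% L)[, i] is the net axial
# current flowing INTO segment i (nA).  Rows/cols sum to zero exactly, which
# is what makes the source configuration monopole-free.
axial_laplacian <- function(a, n) {
  L <- matrix(0, n, n)
  for (b in seq_along(a)) {
    L[b, b] <- L[b, b] - a[b]
    L[b + 1, b + 1] <- L[b + 1, b + 1] - a[b]
    L[b, b + 1] <- L[b, b + 1] + a[b]
    L[b + 1, b] <- L[b + 1, b] + a[b]
  }
  L
}

# Tridiagonal solve (Thomas algorithm).  lower[i] multiplies x[i-1] in row i,
# upper[i] multiplies x[i+1].
solve_tridiag <- function(lower, diag, upper, rhs) {
  n <- length(rhs)
  if (n == 1) return(rhs / diag)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    denom <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Per-segment channel conductances (uS) and conductance-weighted reversal
# (uS mV) at the current gating state.
segment_conductances <- function(area, layout, gates) {
  gNa <- layout$gNa_bar * gates$m^3 * gates$h * area * 1e-6
  gK <- layout$gK_bar * gates$n^4 * area * 1e-6
  gL <- layout$g_leak * area * 1e-6
  list(G = gNa + gK + gL,
       GE = gNa * layout$E_Na + gK * layout$E_K + gL * layout$E_leak)
}

#' Resting state of the model
#'
#' Fixed-point computation of the resting potential: gating variables are set
#' to their steady state at the current voltage and the steady-state cable
#' equation is solved, iterating (with damping) to convergence.  Simulations
#' start from this state, so traces are flat until the stimulus.
#'
#' @inheritParams simulate_neuron
#' @param tol Convergence tolerance on the voltage (mV).
#' @param max_iter Iteration cap.
#' @return List with per-segment \code{V} and gating states.
#' @export
resting_state <- function(morphology, layout, passive = passive_params(),
                          kinetics = default_kinetics(),
                          tol = 1e-10, max_iter = 500) {
  n <- nrow(morphology)
  area <- morphology$area
  a <- axial_conductances(morphology, passive$Ra)
  aL <- c(0, a); aR <- c(a, 0)
  V <- rep(layout$E_leak, n)
  for (iter in seq_len(max_iter)) {
    gates <- hh_steady(V, kinetics)
    sc <- segment_conductances(area, layout, gates)
    if (max(sc$G) == 0) break   # fully passive-less model: any V is steady
    Vnew <- solve_tridiag(-aL, sc$G + aL + aR, -aR, sc$GE)
    if (max(abs(Vnew - V)) < tol) {
      V <- Vnew
      break
    }
    V <- 0.5 * V + 0.5 * Vnew
  }
  list(V = V, gates = hh_steady(V, kinetics))
}

#' Integrate the compartmental cable equation
#'
#' Integrates
#' \code{Cm A_i dV_i/dt = -I_ion,i A_i + sum_j (V_j - V_i)/R_ij + I_inj,i}
#' over the segment chain with Hodgkin--Huxley channels, using the
#' Crank--Nicolson scheme on the tridiagonal cable system with staggered
#' (exponential-Euler) gating updates.  The scheme is unconditionally stable;
#' \code{dt} larger than 0.025 ms is rejected because the gating dynamics are
#' no longer resolved.
#'
#' The returned net transmembrane current per segment,
#' \code{I_membrane[t, i] = sum_j (V_j - V_i)/R_ij}, is the axial inflow,
#' i.e. the capacitive plus ionic membrane current with the injected current
#' assigned (as an extracellular sink) to its target segment.  Summed over
#' segments it is zero at machine precision at every time step, so the
#' extracellular source configuration is monopole-free.  \code{I_axial[t, b]}
#' is the current crossing boundary \code{b} (between segments \code{b} and
#' \code{b + 1}), positive when flowing from the distal (axonal) side towards
#' the soma.
#'
#' @param morphology Segment chain (see \code{\link{build_soma_axon}}).
#' @param layout A \code{\link{channel_layout}} matching the morphology.
#' @param passive \code{\link{passive_params}}.
#' @param stim \code{\link{stimulus_spec}}.
#' @param dt Time step (ms); must be positive and at most 0.025.
#' @param t_stop End of simulation (ms); must exceed the stimulus onset.
#' @param kinetics \code{\link{default_kinetics}} or a loaded rate table.
#' @return A \code{sim_result}: list with \code{time} (ms), \code{Vm} (mV,
#'   time x segment), \code{I_membrane} (nA, time x segment),
#'   \code{I_axial} (nA, time x boundary), the model description, and the
#'   soma--axon junction boundary index.
#' @export
simulate_neuron <- function(morphology, layout, passive = passive_params(),
                            stim = stimulus_spec(), dt = 0.005, t_stop = 20,
                            kinetics = default_kinetics()) {
  if (dt <= 0) stop("dt must be > 0")
  if (dt > 0.025) stop("dt = ", dt, " ms rejected: must be <= 0.025 ms")
  if (t_stop <= stim$onset) stop("t_stop must exceed the stimulus onset")
  n <- nrow(morphology)
  stopifnot(length(layout$g_leak) == n)
  area <- morphology$area
  cvec <- passive$Cm * area * 1e-5            # nF
  a <- axial_conductances(morphology, passive$Ra)
  aL <- c(0, a); aR <- c(a, 0)
  asum <- aL + aR
  target <- stim$target_segment
  if (is.null(target)) {
    soma <- which(morphology$section == "soma")
    if (length(soma) == 0) soma <- seq_len(n)
    target <- soma[ceiling(length(soma) / 2)]
  }

  rest <- resting_state(morphology, layout, passive, kinetics)
  V <- rest$V
  gates <- rest$gates

  nt <- ceiling(t_stop / dt)
  time <- (0:nt) * dt
  Vm <- matrix(NA_real_, nt + 1, n)
  Vm[1, ] <- V
  cdt <- cvec / dt

  for (step in seq_len(nt)) {
    # staggered gating update (exact for frozen voltage)
    for (g in c("m", "h", "n")) {
      r <- hh_rates(V, kinetics, g)
      tot <- r$alpha + r$beta
      xinf <- r$alpha / tot
      gates[[g]] <- xinf + (gates[[g]] - xinf) * exp(-dt * tot)
    }
    sc <- segment_conductances(area, layout, gates)
    t_mid <- (step - 0.5) * dt
    inj <- numeric(n)
    if (t_mid >= stim$onset && t_mid < stim$onset + stim$duration)
      inj[target] <- stim$amplitude
    half <- 0.5 * (sc$G + asum)
    rhs <- (cdt - half) * V +
      0.5 * (aL * c(0, V[-n]) + aR * c(V[-1], 0)) + sc$GE + inj
    V <- solve_tridiag(-0.5 * aL, cdt + half, -0.5 * aR, rhs)
    if (any(!is.finite(V)))
      stop("non-finite membrane potential at step ", step,
           " (t = ", format(step * dt), " ms)")
    Vm[step + 1, ] <- V
  }

  Lap <- axial_laplacian(a, n)
  I_membrane <- Vm %*% Lap
  I_axial <- if (n > 1) {
    sweep(Vm[, -1, drop = FALSE] - Vm[, -n, drop = FALSE], 2, a, `*`)
  } else matrix(0, nt + 1, 0)

  structure(list(time = time, Vm = Vm, I_membrane = I_membrane,
                 I_axial = I_axial,
                 morphology = morphology, layout = layout,
                 passive = passive, stim = stim, kinetics = kinetics,
                 dt = dt, junction = junction_index(morphology),
                 resting_V = rest$V),
            class = "sim_result")
}

# Somatic voltage trace used for AP detection: middle soma segment.
soma_trace <- function(result) {
  soma <- which(result$morphology$section == "soma")
  result$Vm[, soma[ceiling(length(soma) / 2)]]
}

#' Detect the somatic action potential
#'
#' Finds the somatic AP peak (the global maximum of the mid-soma voltage) and
#' checks that it crosses \code{threshold}; errors if no AP is present.
#'
#' @param result A \code{sim_result}.
#' @param threshold Detection threshold (mV) the somatic peak must exceed.
#' @return List with \code{time} (ms), \code{index} (time index) and
#'   \code{Vm} (mV) of the somatic peak.
#' @export
detect_ap <- function(result, threshold = 0) {
  v <- soma_trace(result)
  i <- which.max(v)
  if (v[i] < threshold)
    stop("no somatic AP detected: peak Vm = ", round(v[i], 2),
         " mV < threshold ", threshold, " mV")
  list(time = result$time[i], index = i, Vm = v[i])
}

#' Axial current at the soma--axon junction
#'
#' Extracts the axial current crossing a boundary (by default the soma--axon
#' junction), positive when flowing from the axon towards the soma, with time
#' re-referenced so that the somatic AP peak sits at \code{align_to}.
#'
#' @param result A \code{sim_result} containing at least one somatic AP.
#' @param boundary Boundary index; default the soma--axon junction.
#' @param align_to Time (ms) at which the somatic AP peak is placed.
#' @param threshold AP detection threshold passed to \code{\link{detect_ap}}.
#' @return data.frame with columns \code{time} (ms) and \code{current} (nA).
#' @export
axial_current_trace <- function(result, boundary = NULL, align_to = 0.5,
                                threshold = 0) {
  if (is.null(boundary)) boundary <- result$junction
  if (boundary < 1 || boundary > ncol(result$I_axial))
    stop("boundary index out of range")
  ap <- detect_ap(result, threshold)
  data.frame(time = result$time - ap$time + align_to,
             current = result$I_axial[, boundary])
}
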