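# Hodgkin-Huxley-type channel kinetics.  All voltage dependence lives in a
# single rate table (one row per gate and direction) so alternative
# parameterisations -- e.g. published AIS sodium-channel kinetics -- can be
# loaded from a file and dropped in without touching the solver.

#' Default Hodgkin--Huxley rate table
#'
#' Classical squid-type m/h/n rate functions expressed against a mammalian
#' resting potential (the voltage axis is shifted by \code{v_shift} so the
#' passive resting potential sits at -70 mV), with per-gate rate factors
#' \code{gate_scales} re-timing the gates for an axon-initial-segment sodium
#' channel at body temperature: near-instantaneous activation (m), slow
#' inactivation that outlasts the upstroke (h), and a fast delayed rectifier
#' (n).  This places spike initiation in the critical-resistive-coupling
#' regime, where the AIS acts as a voltage source driving axial current into
#' the soma -- the regime in which the axial current scales inversely with
#' the soma--AIS distance.
#'
#' Rate functional forms, evaluated at the shifted voltage
#' \code{u = V - v_shift}:
#' \itemize{
#'   \item \code{linoid}:  \code{a (u - vhalf) / (1 - exp(-(u - vhalf)/k))}
#'   \item \code{expon}:   \code{a exp((u - vhalf)/k)}
#'   \item \code{sigmoid}: \code{a / (1 + exp(-(u - vhalf)/k))}
#' }
#'
#' @param rate_scale Global multiplicative factor applied to every rate.
#' @param v_shift Voltage shift in mV applied to the rate table (the rates
#'   are evaluated at \code{V - v_shift}).
#' @param gate_scales Named numeric vector of per-gate rate factors
#'   (names m, h, n).
#' @return An object of class \code{hh_kinetics}: the rate table, the gate
#'   powers (m^3 h for Na, n^4 for K), and the scalars above.
#' @export
default_kinetics <- function(rate_scale = 1, v_shift = -5,
                             gate_scales = c(m = 36, h = 1.2, n = 8)) {
  rates <- data.frame(
    gate  = c("m", "m", "h", "h", "n", "n"),
    which = c("alpha", "beta", "alpha", "beta", "alpha", "beta"),
    form  = c("linoid", "expon", "expon", "sigmoid", "linoid", "expon"),
    a     = c(0.1, 4, 0.07, 1, 0.01, 0.125),
    vhalf = c(-40, -65, -65, -35, -55, -65),
    k     = c(10, -18, -20, 10, 10, -80),
    stringsAsFactors = FALSE)
  new_kinetics(rates, rate_scale, v_shift, gate_scales)
}

new_kinetics <- function(rates, rate_scale, v_shift,
                         gate_scales = c(m = 1, h = 1, n = 1)) {
  stopifnot(is.data.frame(rates),
            all(c("gate", "which", "form", "a", "vhalf", "k") %in% names(rates)),
            rate_scale > 0)
  gate_scales <- unlist(gate_scales)
  stopifnot(all(c("m", "h", "n") %in% names(gate_scales)),
            all(gate_scales > 0))
  for (g in c("m", "h", "n")) for (w in c("alpha", "beta"))
    if (sum(rates$gate == g & rates$which == w) != 1)
      stop("rate table needs exactly one '", w, "' row for gate '", g, "'")
  structure(list(rates = rates,
                 rate_scale = rate_scale,
                 v_shift = v_shift,
                 gate_scales = gate_scales[c("m", "h", "n")],
                 powers = c(m = 3, h = 1, n = 4)),
            class = "hh_kinetics")
}

#' Load a user-supplied rate table
#'
#' Reads a kinetics parameterisation from a YAML file with keys
#' \code{rate_scale}, \code{v_shift} and \code{rates} (a list of rows with
#' fields gate/which/form/a/vhalf/k).  This is the hook for dropping in
#' published channel kinetics in place of the defaults.
#'
#' @param path YAML file path.
#' @return An \code{hh_kinetics} object.
#' @seealso \code{\link{write_kinetics}} for the inverse.
#' @export
read_kinetics <- function(path) {
  spec <- yaml::read_yaml(path)
  rates <- do.call(rbind, lapply(spec$rates, function(r)
    data.frame(gate = r$gate, which = r$which, form = r$form,
               a = r$a, vhalf = r$vhalf, k = r$k)))
  gs <- if (is.null(spec$gate_scales)) c(m = 1, h = 1, n = 1)
        else unlist(spec$gate_scales)
  new_kinetics(rates,
               rate_scale = if (is.null(spec$rate_scale)) 1 else spec$rate_scale,
               v_shift = if (is.null(spec$v_shift)) 0 else spec$v_shift,
               gate_scales = gs)
}

#' @rdname read_kinetics
#' @param kinetics An \code{hh_kinetics} object to serialise.
#' @export
write_kinetics <- function(kinetics, path) {
  stopifnot(inherits(kinetics, "hh_kinetics"))
  rows <- lapply(seq_len(nrow(kinetics$rates)), function(i)
    as.list(kinetics$rates[i, ]))
  yaml::write_yaml(list(rate_scale = kinetics$rate_scale,
                        v_shift = kinetics$v_shift,
                        gate_scales = as.list(kinetics$gate_scales),
                        rates = rows), path)
  invisible(path)
}

# x/(1 - exp(-x)) with a series expansion through the removable singularity
safe_linoid <- function(x) {
  out <- x / (1 - exp(-x))
  small <- abs(x) < 1e-5
  if (any(small)) out[small] <- 1 + x[small] / 2 + x[small]^2 / 12
  out
}

rate_eval <- function(form, a, vhalf, k, u) {
  x <- u - vhalf
  switch(form,
         linoid  = a * k * safe_linoid(x / k),
         expon   = a * exp(x / k),
         sigmoid = a / (1 + exp(-x / k)),
         stop("unknown rate form: ", form))
}

# alpha and beta (1/ms) for one gate at membrane potentials v (mV)
hh_rates <- function(v, kinetics, gate) {
  u <- v - kinetics$v_shift
  r <- kinetics$rates
  arow <- r[r$gate == gate & r$which == "alpha", ]
  brow <- r[r$gate == gate & r$which == "beta", ]
  s <- kinetics$rate_scale * kinetics$gate_scales[[gate]]
  list(alpha = s * rate_eval(arow$form, arow$a, arow$vhalf, arow$k, u),
       beta = s * rate_eval(brow$form, brow$a, brow$vhalf, brow$k, u))
}

# steady-state activation alpha/(alpha+beta) for all gates
hh_steady <- function(v, kinetics) {
  lapply(setNames(nm = c("m", "h", "n")), function(g) {
    r <- hh_rates(v, kinetics, g)
    r$alpha / (r$alpha + r$beta)
  })
}

#' Ionic current density from gating state
#'
#' Evaluates the Hodgkin--Huxley ionic current density per segment,
#' \code{gNa_bar m^3 h (V - E_Na) + gK_bar n^4 (V - E_K) + g_leak (V - E_leak)},
#' for given membrane potentials and gating states.  Pure function; the
#' gating dynamics live in \code{\link{simulate_neuron}}.
#'
#' @param Vm Membrane potential per segment (mV).
#' @param gating_states List with elements \code{m}, \code{h}, \code{n}
#'   (each per-segment, in [0, 1]).
#' @param layout A \code{\link{channel_layout}}.
#' @return Outward ionic current density per segment in pA/um^2.
#' @export
hh_currents <- function(Vm, gating_states, layout) {
  g <- gating_states
  stopifnot(all(unlist(g) >= 0), all(unlist(g) <= 1))
  # pS/um^2 * mV = fA/um^2; 1e-3 converts to pA/um^2
  1e-3 * (layout$gNa_bar * g$m^3 * g$h * (Vm - layout$E_Na) +
          layout$gK_bar * g$n^4 * (Vm - layout$E_K) +
          layout$g_leak * (Vm - layout$E_leak))
}
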