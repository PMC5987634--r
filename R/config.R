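# Declarative run configuration, validation, manifests, and delimited-text
# table I/O.

#' Default run configuration
#'
#' One flat nested list holding every tunable default: model geometry,
#' channel densities, kinetics, passive parameters, stimulus, solver
#' settings, field conductivity, metric conventions and the per-experiment
#' protocols.  Experiment functions take such a list; \code{\link{load_config}}
#' merges a YAML file and/or dotted-key overrides into it.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    model = list(ais_start = 45, ais_length = 5, include_dendrite = FALSE,
                 channel_config = "ais_initiation",
                 soma_diam = 20, soma_length = 30, n_soma = 6,
                 axon_diam = 1, axon_length = 50, n_axon = 10,
                 dend_diam = 2, dend_length = 400, n_dend = 8),
    channels = list(gNa_bar = 256000, gK_bar = 48000, g_leak = 0.3,
                    E_Na = 50, E_K = -77, E_leak = -70,
                    somatic_gNa_bar = 2000, somatic_gK_bar = 1000),
    kinetics = list(rate_scale = 1, v_shift = -5,
                    m_scale = 36, h_scale = 1.2, n_scale = 8, file = NULL),
    passive = list(Ra = 150, Cm = 1, temperature = 37),
    stimulus = list(target_segment = NULL, amplitude = 1.3, onset = 5,
                    duration = 1),
    solver = list(dt = 0.005, t_stop = 20),
    field = list(sigma = 0.3),
    metrics = list(fit_range = c(200, 1000), positivity_fraction = 0.05,
                   ap_threshold = 0),
    experiments = list(
      exponent = list(ais_positions = c(0, 20, 45), n_electrodes = 20,
                      horizontal_start = 65, vertical_start = 50,
                      line_end = 1000),
      axial = list(ais_positions = seq(5, 45, by = 5), align_to = 0.5),
      width = list(ais_positions = seq(0, 45, by = 5),
                   perpendicular_sites = c(30, 100),
                   axial_sites = c(30, 100)),
      maps = list(ais_start = 10, stim_amplitude = 5,
                  times_rel = c(-0.15, 0, 0.4),
                  grid_x = seq(-120, 120, by = 10),
                  grid_y = seq(10, 80, by = 10))),
    seed = 1L)
}

merge_config <- function(base, user, prefix = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown configuration key '", prefix, nm, "'")
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key '", prefix, nm, "' must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(prefix, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

set_config_key <- function(config, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- config
  # walk down to validate the path exists
  for (i in seq_along(parts)) {
    if (!parts[i] %in% names(node))
      stop("unknown configuration key '", key, "'")
    if (i < length(parts)) node <- node[[parts[i]]]
  }
  config[[parts]] <- value
  config
}

#' Load and validate a run configuration
#'
#' Starts from \code{\link{default_config}}, merges an optional YAML file and
#' then optional dotted-key overrides (e.g.
#' \code{overrides = list("passive.Ra" = 100)}), and validates every field.
#' Unknown keys are rejected, never ignored.
#'
#' @param path Optional YAML configuration file.
#' @param overrides Named list of dotted-key overrides applied after the
#'   file.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) config <- merge_config(config, user)
  }
  for (key in names(overrides))
    config <- set_config_key(config, key, overrides[[key]])
  validate_config(config)
}

#' Validate a configuration list
#'
#' @param config Configuration list (see \code{\link{default_config}}).
#' @return The configuration, invisibly usable; stops with a message naming
#'   the offending field and constraint.
#' @export
validate_config <- function(config) {
  check <- function(ok, field, constraint) {
    if (!ok) stop("configuration field '", field, "' violates: ", constraint)
  }
  m <- config$model
  check(m$ais_start >= 0, "model.ais_start", "must be >= 0")
  check(m$ais_length > 0, "model.ais_length", "must be > 0")
  p <- config$passive
  check(p$Ra > 0, "passive.Ra", "must be > 0")
  check(p$Cm > 0, "passive.Cm", "must be > 0")
  s <- config$stimulus
  check(s$duration > 0, "stimulus.duration", "must be > 0")
  sol <- config$solver
  check(sol$dt > 0 && sol$dt <= 0.025, "solver.dt",
        "must be in (0, 0.025] ms")
  check(sol$t_stop > s$onset, "solver.t_stop",
        "must exceed the stimulus onset")
  check(config$field$sigma > 0, "field.sigma", "must be > 0")
  met <- config$metrics
  check(length(met$fit_range) == 2 && met$fit_range[1] < met$fit_range[2],
        "metrics.fit_range", "must be an increasing pair")
  check(met$positivity_fraction >= 0 && met$positivity_fraction < 1,
        "metrics.positivity_fraction", "must be in [0, 1)")
  pos_max <- m$axon_length - m$ais_length
  for (ex in c("exponent", "axial", "width")) {
    pos <- config$experiments[[ex]]$ais_positions
    check(all(pos >= 0 & pos <= pos_max),
          paste0("experiments.", ex, ".ais_positions"),
          paste0("must lie in [0, ", pos_max, "] um"))
  }
  check(all(config$experiments$axial$ais_positions > 0),
        "experiments.axial.ais_positions",
        "must be > 0 (log of the distance is taken)")
  check(config$experiments$maps$stim_amplitude > 0,
        "experiments.maps.stim_amplitude", "must be > 0")
  check(config$experiments$maps$ais_start >= 0 &&
          config$experiments$maps$ais_start <= pos_max,
        "experiments.maps.ais_start",
        paste0("must lie in [0, ", pos_max, "] um"))
  config
}

kinetics_from_config <- function(config) {
  if (!is.null(config$kinetics$file)) return(read_kinetics(config$kinetics$file))
  default_kinetics(rate_scale = config$kinetics$rate_scale,
                   v_shift = config$kinetics$v_shift,
                   gate_scales = c(m = config$kinetics$m_scale,
                                   h = config$kinetics$h_scale,
                                   n = config$kinetics$n_scale))
}

#' Build and simulate the configured model
#'
#' Assembles the morphology, channel layout, passive parameters, stimulus and
#' kinetics described by a configuration and runs one simulation.  Arguments
#' override the corresponding config entries (used by the experiment drivers
#' to scan AIS positions).
#'
#' @param config Configuration list.
#' @param ais_start,channel_config,include_dendrite Optional overrides of the
#'   model block.
#' @param stim_amplitude Optional override of the stimulus amplitude (nA);
#'   used by the dipole-map experiment, whose dendrite-bearing model needs a
#'   stronger step.
#' @return A \code{sim_result}.
#' @export
run_from_config <- function(config, ais_start = NULL, channel_config = NULL,
                            include_dendrite = NULL, stim_amplitude = NULL) {
  m <- config$model
  if (!is.null(ais_start)) m$ais_start <- ais_start
  if (!is.null(channel_config)) m$channel_config <- channel_config
  if (!is.null(include_dendrite)) m$include_dendrite <- include_dendrite
  ch <- config$channels
  if (m$channel_config == "somatic_initiation") {
    # the contrast model uses somatic-grade densities, not AIS-grade ones
    ch$gNa_bar <- ch$somatic_gNa_bar
    ch$gK_bar <- ch$somatic_gK_bar
  }
  built <- build_soma_axon(ais_start = m$ais_start,
                           ais_length = m$ais_length,
                           include_dendrite = m$include_dendrite,
                           channel_config = m$channel_config,
                           soma_diam = m$soma_diam,
                           soma_length = m$soma_length, n_soma = m$n_soma,
                           axon_diam = m$axon_diam,
                           axon_length = m$axon_length, n_axon = m$n_axon,
                           dend_diam = m$dend_diam,
                           dend_length = m$dend_length, n_dend = m$n_dend,
                           gNa_bar = ch$gNa_bar, gK_bar = ch$gK_bar,
                           g_leak = ch$g_leak,
                           E_Na = ch$E_Na, E_K = ch$E_K, E_leak = ch$E_leak)
  simulate_neuron(built$morphology, built$layout,
                  passive = passive_params(Ra = config$passive$Ra,
                                           Cm = config$passive$Cm,
                                           temperature = config$passive$temperature),
                  stim = stimulus_spec(
                    target_segment = config$stimulus$target_segment,
                    amplitude = if (is.null(stim_amplitude))
                      config$stimulus$amplitude else stim_amplitude,
                    onset = config$stimulus$onset,
                    duration = config$stimulus$duration),
                  dt = config$solver$dt, t_stop = config$solver$t_stop,
                  kinetics = kinetics_from_config(config))
}

# Polynomial rolling hash (mod 2^31 - 1) over the canonical YAML
# serialisation of the config; reproducible across platforms.
config_hash <- function(config) {
  s <- yaml::as.yaml(config)
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the configuration hash, package version, solver settings,
#' timestamp and intended output paths.  Written before any result table, so
#' a run can be replayed from its manifest alone.
#'
#' @param config Configuration list of the run.
#' @param dir Output directory (created if needed).
#' @param outputs Character vector of result paths the run will write.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, dir, outputs = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(list(
    package = "aisfield",
    version = as.character(utils::packageVersion("aisfield")),
    created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    config_hash = config_hash(config),
    solver = config$solver,
    outputs = as.list(outputs),
    config = config), path)
  invisible(path)
}

#' Write a delimited-text table
#'
#' Tab-separated values with a header, fixed column order and
#' locale-independent numeric formatting at 17 significant digits, so that
#' \code{\link{read_table_file}} reproduces the written doubles bit for bit.
#' NaN and NA are written as empty fields and read back as missing.
#'
#' @param df data.frame of results.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      col <- sprintf("%.17g", out[[j]])
      col[!is.finite(out[[j]]) & !is.infinite(out[[j]])] <- ""  # NA / NaN
      out[[j]] <- col
    }
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a table written by \code{write_table}
#'
#' @param path File path.
#' @return data.frame with numeric columns restored.
#' @export
read_table_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.character(col)) {
      ok <- is.na(col) | grepl("^[-+0-9.eE]+$", col)
      if (all(ok) && any(!is.na(col))) {
        num <- suppressWarnings(as.numeric(col))
        if (!any(is.na(num) & !is.na(col))) df[[j]] <- num
      }
    }
  }
  df
}
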