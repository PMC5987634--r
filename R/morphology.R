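# Morphologies are plain data.frames, one row per cylindrical segment,
# ordered along an unbranched chain: (optional dendrite tip) -> soma -> distal
# axon.  Consecutive rows share an endpoint.  Coordinates in um; the model
# axis is x, the soma is centred at the origin, the axon extends towards -x
# and the optional dendrite towards +x.

SECTION_LABELS <- c("soma", "axon", "ais", "dendrite")

new_morphology <- function(df) {
  df$index <- seq_len(nrow(df))
  class(df) <- c("morphology", "data.frame")
  df
}

#' Validate a segment chain
#'
#' Checks the invariants of a morphology: positive lengths and diameters,
#' known section labels, and chain connectivity (each segment's end point is
#' the next segment's start point).
#'
#' @param morph A morphology data.frame as returned by
#'   \code{\link{build_soma_axon}} or \code{\link{read_swc}}.
#' @param tol Connectivity tolerance in um.
#' @return The morphology, invisibly; stops on violation.
#' @export
validate_morphology <- function(morph, tol = 1e-6) {
  stopifnot(is.data.frame(morph), nrow(morph) >= 1)
  need <- c("section", "x0", "y0", "z0", "x1", "y1", "z1", "diam")
  missing <- setdiff(need, names(morph))
  if (length(missing) > 0)
    stop("morphology is missing columns: ", paste(missing, collapse = ", "))
  if (!all(morph$section %in% SECTION_LABELS))
    stop("unknown section label(s): ",
         paste(setdiff(unique(morph$section), SECTION_LABELS), collapse = ", "))
  len <- segment_lengths(morph)
  if (any(len <= 0)) stop("all segments must have length > 0")
  if (any(morph$diam <= 0)) stop("all segments must have diameter > 0")
  n <- nrow(morph)
  if (n > 1) {
    gap <- sqrt((morph$x1[-n] - morph$x0[-1])^2 +
                (morph$y1[-n] - morph$y0[-1])^2 +
                (morph$z1[-n] - morph$z0[-1])^2)
    if (any(gap > tol))
      stop("segments ", paste(which(gap > tol), collapse = ", "),
           " do not share an endpoint with their successor")
  }
  invisible(morph)
}

segment_lengths <- function(morph) {
  sqrt((morph$x1 - morph$x0)^2 + (morph$y1 - morph$y0)^2 +
       (morph$z1 - morph$z0)^2)
}

# Lateral (side-wall) membrane area per segment, um^2.
segment_areas <- function(morph) pi * morph$diam * segment_lengths(morph)

#' Build the reduced soma--axon model
#'
#' Constructs the simplified morphology used throughout the package: a
#' cylindrical soma (20 um diameter x 30 um length, 6 segments) centred at
#' the origin and an axon (1 um diameter x 50 um length, 10 segments)
#' extending towards -x, with a short AIS placed on the axon at a chosen
#' distance from the soma.  Optionally a passive dendrite (2 um x 400 um)
#' extends towards +x.  The axon is re-segmented so that the AIS edges
#' coincide with segment nodes, and is extended distally if
#' \code{ais_start + ais_length} exceeds its nominal length, so the AIS
#' always fits.
#'
#' Channel placement follows \code{channel_config}: \code{"ais_initiation"}
#' puts all Na and K channels on the AIS segments only (axonal spike
#' initiation); \code{"somatic_initiation"} puts them on the soma segments
#' only, a reduced analogue of models in which the sodium density of the AIS
#' is lowered below the somatic density so that the spike starts in the soma.
#' The leak conductance is uniform.
#'
#' @param ais_start Distance (um) from the somatic end of the axon to the
#'   proximal edge of the AIS.  Must be >= 0.
#' @param ais_length AIS length in um (> 0).
#' @param include_dendrite Add a passive dendrite on the far side of the soma.
#' @param channel_config \code{"ais_initiation"} or \code{"somatic_initiation"}.
#' @param soma_diam,soma_length,n_soma Soma cylinder geometry and segment count.
#' @param axon_diam,axon_length,n_axon Axon cylinder geometry and segment count.
#' @param dend_diam,dend_length,n_dend Dendrite geometry (used only when
#'   \code{include_dendrite} is TRUE).
#' @param gNa_bar,gK_bar Maximal Na/K conductance densities (pS/um^2) on the
#'   active section.  The defaults give the 5-um AIS the total conductance of
#'   a full-length (30--50 um) axon initial segment at literature densities
#'   (about 4 uS of Na), which puts spike initiation in the
#'   critical-resistive-coupling regime.
#' @param g_leak Uniform leak conductance density (pS/um^2).
#' @param E_Na,E_K,E_leak Reversal potentials (mV).
#' @return A list with elements \code{morphology} (segment data.frame) and
#'   \code{layout} (a \code{channel_layout}).
#' @examples
#' m <- build_soma_axon(ais_start = 45, ais_length = 5)
#' subset(m$morphology, section == "ais")
#' @export
build_soma_axon <- function(ais_start = 45, ais_length = 5,
                            include_dendrite = FALSE,
                            channel_config = c("ais_initiation",
                                               "somatic_initiation"),
                            soma_diam = 20, soma_length = 30, n_soma = 6,
                            axon_diam = 1, axon_length = 50, n_axon = 10,
                            dend_diam = 2, dend_length = 400, n_dend = 8,
                            gNa_bar = 256000, gK_bar = 48000, g_leak = 0.3,
                            E_Na = 50, E_K = -77, E_leak = -70) {
  channel_config <- match.arg(channel_config)
  if (ais_start < 0) stop("ais_start must be >= 0 (um from the soma)")
  if (ais_length <= 0) stop("ais_length must be > 0")
  ais_end <- ais_start + ais_length
  if (ais_end > axon_length) axon_length <- ais_end   # extend axon distally

  half <- soma_length / 2
  pieces <- list()
  if (include_dendrite) {
    dn <- seq(half + dend_length, half, length.out = n_dend + 1)
    pieces$dend <- data.frame(section = "dendrite",
                              x0 = dn[-(n_dend + 1)], x1 = dn[-1],
                              diam = dend_diam)
  }
  sn <- seq(half, -half, length.out = n_soma + 1)
  pieces$soma <- data.frame(section = "soma",
                            x0 = sn[-(n_soma + 1)], x1 = sn[-1],
                            diam = soma_diam)
  # axon arc-length nodes, with the AIS edges forced onto nodes
  an <- sort(unique(c(seq(0, axon_length, length.out = n_axon + 1),
                      ais_start, ais_end)))
  an <- an[c(TRUE, diff(an) > 1e-6)]
  if (abs(an[length(an)] - axon_length) > 1e-6) an <- c(an, axon_length)
  mid <- (an[-1] + an[-length(an)]) / 2
  sec <- ifelse(mid > ais_start - 1e-9 & mid < ais_end + 1e-9, "ais", "axon")
  pieces$axon <- data.frame(section = sec,
                            x0 = -half - an[-length(an)], x1 = -half - an[-1],
                            diam = axon_diam)
  geo <- do.call(rbind, pieces)
  morph <- data.frame(section = geo$section,
                      x0 = geo$x0, y0 = 0, z0 = 0,
                      x1 = geo$x1, y1 = 0, z1 = 0,
                      diam = geo$diam, row.names = NULL)
  morph$length <- segment_lengths(morph)
  morph$area <- segment_areas(morph)
  morph <- new_morphology(morph)
  validate_morphology(morph)
  layout <- channel_layout(morph, channel_config,
                           gNa_bar = gNa_bar, gK_bar = gK_bar,
                           g_leak = g_leak,
                           E_Na = E_Na, E_K = E_K, E_leak = E_leak)
  list(morphology = morph, layout = layout)
}

#' Per-segment channel conductance densities
#'
#' Builds a channel layout for a morphology: maximal Na and K conductance
#' densities on the active section (AIS for \code{"ais_initiation"}, soma for
#' \code{"somatic_initiation"}), a uniform leak, and the reversal potentials.
#'
#' @inheritParams build_soma_axon
#' @param morph A morphology data.frame.
#' @return A \code{channel_layout}: list with per-segment vectors
#'   \code{gNa_bar}, \code{gK_bar}, \code{g_leak} (pS/um^2) and scalars
#'   \code{E_Na}, \code{E_K}, \code{E_leak} (mV).
#' @export
channel_layout <- function(morph,
                           channel_config = c("ais_initiation",
                                              "somatic_initiation"),
                           gNa_bar = 256000, gK_bar = 48000, g_leak = 0.3,
                           E_Na = 50, E_K = -77, E_leak = -70) {
  channel_config <- match.arg(channel_config)
  stopifnot(gNa_bar >= 0, gK_bar >= 0, g_leak >= 0)
  n <- nrow(morph)
  target <- if (channel_config == "ais_initiation") "ais" else "soma"
  active <- morph$section == target
  if (!any(active))
    stop("morphology has no '", target, "' segments for channel_config = ",
         channel_config)
  structure(list(gNa_bar = ifelse(active, gNa_bar, 0),
                 gK_bar = ifelse(active, gK_bar, 0),
                 g_leak = rep(g_leak, n),
                 E_Na = E_Na, E_K = E_K, E_leak = E_leak,
                 channel_config = channel_config),
            class = "channel_layout")
}

# Index of the last soma segment; the boundary between it and the next
# segment is the soma-axon junction.
junction_index <- function(morph) {
  soma <- which(morph$section == "soma")
  if (length(soma) == 0) stop("morphology has no soma segments")
  max(soma)
}

ais_segments <- function(morph) which(morph$section == "ais")

# x coordinate of the AIS centre (for electrode/map placement)
ais_center_x <- function(morph) {
  i <- ais_segments(morph)
  if (length(i) == 0) stop("morphology has no AIS segments")
  mean(c(morph$x0[i], morph$x1[i]))
}

#' Read a morphology from an SWC file (geometry only)
#'
#' Minimal reader for the standard SWC format (columns: index, type, x, y, z,
#' radius, parent).  Only unbranched morphologies are supported, since the
#' solver integrates a single chain.  Imported sections are passive until a
#' channel layout is supplied.  Type codes 1, 2, 3/4 map to soma, axon and
#' dendrite; other codes map to dendrite.
#'
#' @param path Path to an SWC file.
#' @return A morphology data.frame (one row per parent-child segment).
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (nrow(tab) < 2) stop("SWC file must contain at least two sample points")
  kids <- table(tab$parent[tab$parent > 0])
  if (any(kids > 1))
    stop("branched SWC morphologies are not supported (single chain only)")
  root <- tab$id[tab$parent == -1]
  if (length(root) != 1) stop("SWC file must have exactly one root point")
  # walk the chain from the root
  child_of <- setNames(tab$id, tab$parent)
  order_ids <- root
  repeat {
    nxt <- tab$id[tab$parent == order_ids[length(order_ids)]]
    if (length(nxt) == 0) break
    order_ids <- c(order_ids, nxt)
  }
  tab <- tab[match(order_ids, tab$id), ]
  sec_map <- function(code) {
    ifelse(code == 1, "soma", ifelse(code == 2, "axon", "dendrite"))
  }
  n <- nrow(tab)
  morph <- data.frame(section = sec_map(tab$type[-1]),
                      x0 = tab$x[-n], y0 = tab$y[-n], z0 = tab$z[-n],
                      x1 = tab$x[-1], y1 = tab$y[-1], z1 = tab$z[-1],
                      diam = 2 * tab$radius[-1])
  morph$length <- segment_lengths(morph)
  morph$area <- segment_areas(morph)
  morph <- new_morphology(morph)
  validate_morphology(morph)
  morph
}
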