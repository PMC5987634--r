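test_that("default soma-axon build matches the reference geometry", {
  m <- build_soma_axon(ais_start = 45, ais_length = 5)
  morph <- m$morphology
  expect_equal(nrow(morph), 16)
  expect_equal(sum(morph$section == "soma"), 6)
  expect_equal(sum(morph$section %in% c("axon", "ais")), 10)
  # soma cylinder 20 x 30 um centred at the origin, lateral area pi d L
  soma <- morph[morph$section == "soma", ]
  expect_equal(sum(soma$area), pi * 20 * 30, tolerance = 1e-12)
  expect_equal(range(c(soma$x0, soma$x1)), c(-15, 15))
  # AIS occupies the distal-most span [45, 50] um of the axon
  ais <- morph[morph$section == "ais", ]
  expect_equal(sum(ais$length), 5, tolerance = 1e-9)
  expect_equal(min(-ais$x0) - 15, 45, tolerance = 1e-9)
  expect_equal(max(-ais$x1) - 15, 50, tolerance = 1e-9)
  validate_morphology(morph)
})

test_that("an AIS abutting the soma shares a node with the distal soma segment", {
  m <- build_soma_axon(ais_start = 0, ais_length = 5)
  morph <- m$morphology
  first_ais <- min(which(morph$section == "ais"))
  expect_equal(first_ais, junction_index(morph) + 1)
  expect_equal(morph$x0[first_ais], morph$x1[junction_index(morph)])
})

test_that("axon is re-segmented so AIS edges coincide with nodes", {
  m <- build_soma_axon(ais_start = 12, ais_length = 5)
  morph <- m$morphology
  apos <- -(c(morph$x0, morph$x1)) - 15     # arc length along the axon
  apos <- apos[apos > -1e-9]
  expect_true(any(abs(apos - 12) < 1e-9))
  expect_true(any(abs(apos - 17) < 1e-9))
  ais <- morph[morph$section == "ais", ]
  expect_equal(sum(ais$length), 5, tolerance = 1e-9)
  validate_morphology(morph)
})

test_that("axon is extended distally when the AIS would not fit", {
  m <- build_soma_axon(ais_start = 48, ais_length = 5)
  morph <- m$morphology
  axon <- morph[morph$section %in% c("axon", "ais"), ]
  expect_equal(sum(axon$length), 53, tolerance = 1e-9)
})

test_that("invalid AIS placement is rejected", {
  expect_error(build_soma_axon(ais_start = -5), "ais_start")
  expect_error(build_soma_axon(ais_length = 0), "ais_length")
})

test_that("channel placement follows the initiation configuration", {
  m <- build_soma_axon(ais_start = 20, channel_config = "ais_initiation")
  on <- m$layout$gNa_bar > 0 | m$layout$gK_bar > 0
  expect_true(all(m$morphology$section[on] == "ais"))
  expect_true(all(m$layout$g_leak > 0))
  s <- build_soma_axon(ais_start = 20, channel_config = "somatic_initiation")
  on <- s$layout$gNa_bar > 0 | s$layout$gK_bar > 0
  expect_true(all(s$morphology$section[on] == "soma"))
})

test_that("dendrite option prepends a passive colinear chain", {
  m <- build_soma_axon(include_dendrite = TRUE)
  morph <- m$morphology
  dend <- morph[morph$section == "dendrite", ]
  expect_equal(nrow(dend), 8)
  expect_equal(sum(dend$length), 400, tolerance = 1e-9)
  expect_true(all(m$layout$gNa_bar[morph$section == "dendrite"] == 0))
  validate_morphology(morph)
})

test_that("SWC round trip recovers an unbranched geometry", {
  path <- tempfile(fileext = ".swc")
  writeLines(c(
    "# synthetic three-point chain",
    "1 1 0 0 0 5 -1",
    "2 2 -10 0 0 0.5 1",
    "3 2 -25 0 0 0.5 2"), path)
  morph <- read_swc(path)
  expect_equal(nrow(morph), 2)
  expect_equal(morph$section, c("axon", "axon"))
  expect_equal(morph$length, c(10, 15))
  expect_equal(morph$diam, c(1, 1))

  branched <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 2 -10 0 0 1 1", "3 2 10 0 0 1 1"),
             branched)
  expect_error(read_swc(branched), "branched")
})
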