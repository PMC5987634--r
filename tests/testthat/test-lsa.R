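seg <- function(x0, y0, z0, x1, y1, z1) {
  data.frame(x0 = x0, y0 = y0, z0 = z0, x1 = x1, y1 = y1, z1 = z1)
}

test_that("line-source closed form agrees with adaptive quadrature", {
  set.seed(42)
  for (i in 1:20) {
    p0 <- runif(3, -30, 30)
    p1 <- p0 + runif(3, 1, 40)
    s <- seg(p0[1], p0[2], p0[3], p1[1], p1[2], p1[3])
    e <- runif(3, -200, 200)
    # keep a safe distance from the axis segment
    if (abs(line_dist <- sqrt(sum((e - p0)^2))) < 5) e <- e + 50
    v1 <- line_source_potential(s, 1.7, e)
    v2 <- lsa_quadrature(s, 1.7, e)
    expect_lt(abs(v1 - v2) / abs(v2), 1e-6)
  }
  # electrode exactly on the extended axis, beyond the end: still finite
  s <- seg(0, 0, 0, 10, 0, 0)
  v1 <- line_source_potential(s, 1, c(25, 0, 0))
  v2 <- lsa_quadrature(s, 1, c(25, 0, 0))
  expect_lt(abs(v1 - v2) / abs(v2), 1e-6)
})

test_that("line source converges to a point source in the far field", {
  L <- 10
  s <- seg(0, 0, 0, L, 0, 0)
  r <- 100 * L
  e <- c(L / 2, r, 0)    # perpendicular bisector
  v_line <- line_source_potential(s, 2, e)
  v_point <- point_source_potential(2, r)
  expect_lt(abs(v_line - v_point) / v_point, 1e-4)
})

test_that("potential is symmetric across the perpendicular bisector plane", {
  s <- seg(-5, 0, 0, 5, 0, 0)
  va <- line_source_potential(s, 1, c(3, 20, 0))
  vb <- line_source_potential(s, 1, c(-3, 20, 0))
  expect_equal(va, vb, tolerance = 1e-12)
})

test_that("an electrode on the source segment raises a singularity error", {
  s <- seg(0, 0, 0, 10, 0, 0)
  expect_error(line_source_potential(s, 1, c(5, 0, 0)), "singular")
  m <- build_soma_axon()
  bad <- electrode_points(x = 0, y = 0, label = "inside_soma")
  res <- default_sim(45)
  expect_error(field_from_simulation(res, bad), "inside_soma")
})

test_that("dipole closed form has the textbook structure", {
  # perpendicular direction gives exactly zero
  expect_equal(dipole_potential(1, 50, 200, pi / 2), 0)
  # inverse-square distance dependence
  expect_equal(dipole_potential(1, 50, 100, 0) /
                 dipole_potential(1, 50, 200, 0), 4)
  # independent hand evaluation of I d / (4 pi sigma r^2)
  expect_equal(dipole_potential(1, 50, 100, 0, sigma = 0.3),
               1000 * 1 * 50 / (4 * pi * 0.3 * 100^2), tolerance = 1e-12)
  expect_error(dipole_potential(1, 50, 0, 0), "r")
})

test_that("the field map is linear and superposable", {
  res <- default_sim(45)
  el <- electrode_points(x = c(100, 300), y = c(0, 50))
  rec <- field_from_simulation(res, el)
  # zero currents give zero potentials
  zero <- res
  zero$I_membrane <- res$I_membrane * 0
  expect_true(all(field_from_simulation(zero, el)$V_ext == 0))
  # doubling all currents doubles all potentials exactly
  twice <- res
  twice$I_membrane <- 2 * res$I_membrane
  expect_equal(field_from_simulation(twice, el)$V_ext, 2 * rec$V_ext,
               tolerance = 1e-12)
  # superposition at machine precision
  a <- res; a$I_membrane <- res$I_membrane * 0.3
  b <- res; b$I_membrane <- res$I_membrane * 0.7
  expect_equal(field_from_simulation(a, el)$V_ext +
                 field_from_simulation(b, el)$V_ext,
               rec$V_ext, tolerance = 1e-12)
})

test_that("segment-count mismatch is rejected", {
  res <- default_sim(45)
  broken <- res
  broken$I_membrane <- res$I_membrane[, -1]
  expect_error(field_from_simulation(broken, electrode_points(100)),
               "segments")
})

test_that("opposite short segments reproduce the dipole closed form", {
  d <- 40
  dip <- make_dipole_currents(I = 2, d = d, waveform = 1)
  r <- 20 * d
  el <- electrode_points(x = r)    # on the dipole axis, theta = 0
  v <- field_from_simulation(dip, el)$V_ext[1, 1]
  v_ref <- dipole_potential(2, d, r, 0)
  expect_lt(abs(v - v_ref) / abs(v_ref), 0.01)
})

test_that("baseline subtraction removes the pre-spike mean and is idempotent", {
  res <- default_sim(45)
  ap <- detect_ap(res)
  rec <- field_from_simulation(res, electrode_points(x = 0, y = 30))
  # constant trace maps to zero
  const <- rec
  const$V_ext[] <- 3.7
  expect_true(all(abs(subtract_baseline(const, ap$time)$V_ext) < 1e-12))
  # idempotence
  once <- subtract_baseline(rec, ap$time)
  twice <- subtract_baseline(once, ap$time)
  # idempotent to floating tolerance, measured on the scale of the signal
  expect_lt(max(abs(twice$V_ext - once$V_ext)),
            1e-12 * max(abs(once$V_ext)))
  # ramp with a hand-computed window mean
  ramp <- rec
  ramp$V_ext[, 1] <- rec$time
  out <- subtract_baseline(ramp, ap$time)
  idx <- rec$time >= ap$time - 2 & rec$time <= ap$time - 1
  expect_equal(out$V_ext[, 1], rec$time - mean(rec$time[idx]),
               tolerance = 1e-9)
  # window falling before the recording start errors
  expect_error(subtract_baseline(rec, 1), "window")
})
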