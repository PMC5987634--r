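test_that("a fully passive model without stimulus stays at its initial state", {
  m <- build_soma_axon(gNa_bar = 0, gK_bar = 0, g_leak = 0)
  res <- simulate_neuron(m$morphology, m$layout,
                         stim = stimulus_spec(amplitude = 0),
                         dt = 0.025, t_stop = 6)
  expect_true(all(abs(res$Vm - res$Vm[1, 1]) < 1e-9))
  expect_true(all(abs(res$I_membrane) < 1e-9))
})

test_that("a single passive compartment follows the RC charging curve", {
  morph <- data.frame(section = "soma", x0 = 0, y0 = 0, z0 = 0,
                      x1 = 10, y1 = 0, z1 = 0, diam = 10)
  morph$length <- 10
  morph$area <- pi * 10 * 10
  morph$index <- 1L
  class(morph) <- c("morphology", "data.frame")
  g_leak <- 10   # pS/um^2 -> tau = 10 * Cm / g_leak = 1 ms
  layout <- channel_layout(morph, "somatic_initiation",
                           gNa_bar = 0, gK_bar = 0, g_leak = g_leak)
  I <- 0.01
  res <- simulate_neuron(morph, layout,
                         stim = stimulus_spec(target_segment = 1,
                                              amplitude = I, onset = 1,
                                              duration = 8),
                         dt = 0.005, t_stop = 7)
  G <- g_leak * morph$area * 1e-6            # uS
  tau <- 1                                    # ms
  t5 <- 1 + 5 * tau
  v_num <- res$Vm[which.min(abs(res$time - t5)), 1]
  v_ref <- layout$E_leak + (I / G) * (1 - exp(-5))
  expect_lt(abs(v_num - v_ref) / abs(I / G), 0.005)
})

test_that("net transmembrane current is conserved during the spike", {
  for (l in c(5, 45)) {
    res <- default_sim(l)
    imbalance <- max(abs(rowSums(res$I_membrane)))
    expect_lt(imbalance, 1e-4 * max(abs(res$I_membrane)))
  }
})

test_that("halving the time step barely moves the somatic AP", {
  res1 <- default_sim(45)
  cfg <- default_config()
  cfg$solver$dt <- 0.0025
  res2 <- cached("sim_dt_0.0025", run_from_config(cfg))
  v1 <- res1$Vm[, 3]; v2 <- res2$Vm[, 3]
  expect_lt(abs(max(v1) - max(v2)), 0.5)
  expect_lt(abs(res1$time[which.max(v1)] - res2$time[which.max(v2)]),
            2 * res1$dt)
})

test_that("spike initiation site follows the channel configuration", {
  res <- default_sim(45)
  ais <- which(res$morphology$section == "ais")
  t_ais <- res$time[which.max(res$Vm[, ais[length(ais)]])]
  t_soma <- res$time[which.max(res$Vm[, 3])]
  expect_gt(t_soma - t_ais, 0.3)   # AIS spike clearly precedes the soma

  som <- default_sim(45, "somatic_initiation")
  ais <- which(som$morphology$section == "ais")
  t_ais <- som$time[which.max(som$Vm[, ais[length(ais)]])]
  t_soma <- som$time[which.max(som$Vm[, 3])]
  # soma and passive AIS are nearly synchronous (cable delay only)
  expect_lt(abs(t_soma - t_ais), 0.15)
})

test_that("time-step limits and degenerate protocols are rejected", {
  m <- build_soma_axon()
  expect_error(simulate_neuron(m$morphology, m$layout, dt = 0.05),
               "rejected")
  expect_error(simulate_neuron(m$morphology, m$layout, dt = 0),
               "dt")
  expect_error(simulate_neuron(m$morphology, m$layout,
                               stim = stimulus_spec(onset = 5), t_stop = 4),
               "onset")
  expect_error(stimulus_spec(duration = 0))
})

test_that("axial current matches its defining voltage difference", {
  res <- default_sim(45)
  j <- res$junction
  # independent reconstruction of the junction coupling conductance
  Ra <- res$passive$Ra
  rh <- function(L, d) Ra * 1e-2 * (L / 2) / (pi * (d / 2)^2)
  a <- 1 / (rh(res$morphology$length[j], res$morphology$diam[j]) +
            rh(res$morphology$length[j + 1], res$morphology$diam[j + 1]))
  expect_equal(res$I_axial[, j],
               (res$Vm[, j + 1] - res$Vm[, j]) * a, tolerance = 1e-12)
})

test_that("axial current is zero in a symmetric resting model", {
  m <- build_soma_axon(gNa_bar = 0, gK_bar = 0)
  res <- simulate_neuron(m$morphology, m$layout,
                         stim = stimulus_spec(amplitude = 0),
                         dt = 0.025, t_stop = 6)
  expect_true(all(abs(res$I_axial) < 1e-10))
})

test_that("peak axial current decreases with soma-AIS distance", {
  i5 <- max(default_sim(5)$I_axial[, default_sim(5)$junction])
  i45 <- max(default_sim(45)$I_axial[, default_sim(45)$junction])
  expect_gt(i5, i45)
})

test_that("axial_current_trace aligns the somatic AP and detects its absence", {
  res <- default_sim(45)
  tr <- axial_current_trace(res, align_to = 0.5)
  ap <- detect_ap(res)
  expect_equal(tr$time[ap$index], 0.5)
  m <- build_soma_axon()
  quiet <- simulate_neuron(m$morphology, m$layout,
                           stim = stimulus_spec(amplitude = 0.01),
                           t_stop = 8)
  expect_error(axial_current_trace(quiet), "no somatic AP")
})

test_that("resting state is a fixed point of the dynamics", {
  m <- build_soma_axon(ais_start = 20)
  res <- simulate_neuron(m$morphology, m$layout,
                         stim = stimulus_spec(amplitude = 0), t_stop = 6)
  drift <- max(abs(res$Vm[nrow(res$Vm), ] - res$Vm[1, ]))
  expect_lt(drift, 1e-6)
})
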