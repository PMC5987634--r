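# Shared simulation cache: the default-configuration model is expensive
# enough that test files reuse runs instead of re-simulating.
sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = sim_cache))
    assign(key, force(expr), envir = sim_cache)
  get(key, envir = sim_cache)
}

default_sim <- function(ais_start = 45, channel_config = "ais_initiation") {
  cached(paste0("sim_", channel_config, "_", ais_start),
         run_from_config(default_config(), ais_start = ais_start,
                         channel_config = channel_config))
}

# independent evaluation of the rate functional forms, used as the oracle
# for gating steady states
rate_oracle <- function(row, u) {
  x <- u - row$vhalf
  switch(row$form,
         linoid  = ifelse(abs(x) < 1e-12, row$a * row$k,   # limit at the pole
                          row$a * x / (1 - exp(-x / row$k))),
         expon   = row$a * exp(x / row$k),
         sigmoid = row$a / (1 + exp(-x / row$k)))
}

# brute-force quadrature of the line-source integral via stats::integrate
lsa_quadrature <- function(source, I, electrode, sigma = 0.3) {
  p0 <- c(source$x0[1], source$y0[1], source$z0[1])
  p1 <- c(source$x1[1], source$y1[1], source$z1[1])
  L <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / L
  f <- Vectorize(function(s) {
    p <- p0 + s * u
    1 / sqrt(sum((electrode - p)^2))
  })
  q <- stats::integrate(f, 0, L, rel.tol = 1e-10, abs.tol = 0)
  1000 * I / (4 * pi * sigma * L) * q$value
}
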