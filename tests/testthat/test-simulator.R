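test_that("leak-only membrane decays monotonically toward rest", {
  net <- toy_network()
  net$background$rate_hz <- c(0, 0)
  # start from rest; inject a brief subthreshold pulse, then watch decay
  prot <- striatobot:::new_protocol("pulse", 500,
    striatobot:::block_row("all", "all", "all", "dc", amplitude_pA = 100,
                           t_start_ms = 0, t_stop_ms = 50))
  spk <- simulate_network(net, prot,
                          simulation_config(duration_ms = 500, seed = 1,
                                            record_ids = 1L))
  V <- spk$potentials[, 1]
  expect_equal(nrow(spk$spikes), 0)
  tail_V <- V[60:500]
  expect_true(all(diff(tail_V) <= 1e-12))         # monotone decay
  expect_lt(abs(tail_V[length(tail_V)] - net$params$D1$V_rest), 0.5)
})

test_that("constant-current fixed point matches the closed form", {
  # D1, I = 140 pA: V_inf = V_rest + I/g_L = -87.2 + 140/9, subthreshold
  net <- toy_network()
  net$background$rate_hz <- c(0, 0)
  prot <- striatobot:::new_protocol("dc", 3000,
    striatobot:::block_row("all", "D1", "all", "dc", amplitude_pA = 140,
                           t_start_ms = 0, t_stop_ms = 3000))
  spk <- simulate_network(net, prot,
                          simulation_config(duration_ms = 3000, seed = 1,
                                            record_ids = 1L))
  expect_equal(nrow(spk$spikes), 0)
  expect_equal(unname(spk$potentials[3000, 1]), -87.2 + 140 / 9,
               tolerance = 1e-6)
})

test_that("rheobase separates silence from firing and D2 exceeds D1", {
  d1 <- msn_parameters("D1"); d2 <- msn_parameters("D2")
  expect_equal(rheobase(d1), 9 * 37.2)
  expect_equal(rheobase(d2), 4.5 * 35.4)
  cur <- c(100, 150, 200, 300, 400, 600)
  f1 <- fi_curve(d1, cur, duration_ms = 3000)
  f2 <- fi_curve(d2, cur, duration_ms = 3000)
  expect_true(all(f1$rate_hz[cur < rheobase(d1)] == 0))
  expect_true(all(f2$rate_hz[cur < rheobase(d2)] == 0))
  expect_gt(f2$rate_hz[cur == 400], 0)
  # F-I curves monotone, with D2 at or above D1 at every common current
  expect_true(all(diff(f1$rate_hz) >= 0))
  expect_true(all(diff(f2$rate_hz) >= 0))
  expect_true(all(f2$rate_hz >= f1$rate_hz))
})

test_that("background Poisson drive has Poisson count statistics", {
  # empirical mean of per-neuron background event counts: use a passive
  # neuron (threshold raised out of reach) and count conductance via rate
  # of a silent network -- instead check the spike output of a population
  # of independent neurons driven hard, versus CLT bounds on Poisson input.
  net <- toy_network(n_per_type = 25L)  # 200 neurons
  net$synapses <- net$synapses[0, ]
  net$background <- background_input(rate_D1 = 80, rate_D2 = 80,
                                     n_sources = 1L)
  # count event-steps via spikes: a huge, near-instantaneous conductance
  # (tau_syn_ex -> 0) makes every step with >= 1 background event produce
  # exactly one spike, with no carry-over to the next step
  net$background$weight_nS <- 1e5
  net$params <- list(D1 = msn_parameters("D1", t_ref = 0, tau_syn_ex = 0.01),
                     D2 = msn_parameters("D2", t_ref = 0, tau_syn_ex = 0.01))
  spk <- simulate_network(net, NULL,
                          simulation_config(duration_ms = 10000, seed = 2))
  # each neuron spikes whenever >=1 background event lands in a 1 ms step:
  # per-step hit probability is 1 - exp(-lambda), lambda = 0.08
  n_steps <- 10000; n_neu <- 200
  p_hit <- 1 - exp(-0.08)
  total <- nrow(spk$spikes)
  mu <- n_steps * n_neu * p_hit
  sigma <- sqrt(n_steps * n_neu * p_hit * (1 - p_hit))
  expect_lt(abs(total - mu), 4 * sigma)
  expect_error(background_input(rate_D1 = -5), "rate")
})

test_that("simulation is reproducible and respects the refractory period", {
  net <- hemisphere_network(1)
  cfg <- simulation_config(duration_ms = 3000, seed = 123)
  a <- simulate_network(net, NULL, cfg)
  b <- simulate_network(net, NULL, cfg)
  expect_identical(a$spikes, b$spikes)
  isi_ok <- vapply(split(a$spikes$time_ms, a$spikes$neuron_id),
                   function(tt) length(tt) < 2 || min(diff(tt)) >= 2,
                   logical(1))
  expect_true(all(isi_ok))
  # different seed -> different realization
  c_ <- simulate_network(net, NULL, simulation_config(duration_ms = 3000,
                                                      seed = 124))
  expect_false(identical(a$spikes, c_$spikes))
})

test_that("all weights zeroed and no background yields zero spikes", {
  net <- toy_network()
  net$background$rate_hz <- c(0, 0)
  net$synapses$weight_nS <- 0
  spk <- simulate_network(net, NULL, simulation_config(duration_ms = 1000,
                                                       seed = 1))
  expect_equal(nrow(spk$spikes), 0)
})

test_that("background-only D1 population rate is below the D2 rate", {
  net <- hemisphere_network(1)
  spk <- simulate_network(net, NULL, simulation_config(duration_ms = 10000,
                                                       seed = 21))
  nn <- net$neurons
  r1 <- sum(spk$spikes$neuron_id %in% nn$id[nn$type == "D1"]) / 1440 / 10
  r2 <- sum(spk$spikes$neuron_id %in% nn$id[nn$type == "D2"]) / 1440 / 10
  expect_gt(r1, 0.05)     # not silent
  expect_lt(r1, r2)       # D1 below D2
})

test_that("compiled integrator matches an independent reference at fine dt", {
  # deterministic toy network: DC drive above rheobase, full synapse table,
  # no background; reference is a plain-R forward-Euler integrator written
  # independently of the compiled exponential-Euler path
  net <- toy_network(seed = 4, n_per_type = 4L)
  net$background$rate_hz <- c(0, 0)
  dt <- 0.01
  dur <- 5000
  I <- ifelse(net$neurons$type == "D1", 380, 200)  # above both rheobases
  prot <- striatobot:::new_protocol("dc", dur,
    rbind(striatobot:::block_row("all", "D1", "all", "dc",
                                 amplitude_pA = 380, t_start_ms = 0,
                                 t_stop_ms = dur),
          striatobot:::block_row("all", "D2", "all", "dc",
                                 amplitude_pA = 200, t_start_ms = 0,
                                 t_stop_ms = dur)))
  spk <- simulate_network(net, prot,
                          simulation_config(dt = dt, duration_ms = dur,
                                            seed = 1))
  ref <- ref_lif(net, I, dur, dt)
  n <- nrow(net$neurons)
  counts <- tabulate(spk$spikes$neuron_id, nbins = n)
  counts_ref <- tabulate(ref$neuron_id, nbins = n)
  expect_gt(sum(counts_ref), 100)  # the oracle actually fires
  expect_true(all(abs(counts - counts_ref) <= 1))
})

test_that("population rates are stable under dt refinement", {
  net <- toy_network(seed = 4, n_per_type = 4L)
  net$background$rate_hz <- c(0, 0)
  mk <- function(dt) {
    prot <- striatobot:::new_protocol("dc", 5000,
      striatobot:::block_row("all", "all", "all", "dc", amplitude_pA = 380,
                             t_start_ms = 0, t_stop_ms = 5000))
    spk <- simulate_network(net, prot,
                            simulation_config(dt = dt, duration_ms = 5000,
                                              seed = 1))
    nrow(spk$spikes)
  }
  n1 <- mk(0.2); n2 <- mk(0.1)
  expect_lt(abs(n1 - n2) / n2, 0.05)
})

test_that("membrane stays within the physical bounds", {
  net <- toy_network(seed = 2)
  prot <- striatobot:::new_protocol("dc", 2000,
    striatobot:::block_row("all", "all", "all", "dc", amplitude_pA = 500,
                           t_start_ms = 500, t_stop_ms = 1500))
  spk <- simulate_network(net, prot,
                          simulation_config(duration_ms = 2000, seed = 3,
                                            record_ids = c(1L, 5L)))
  V <- spk$potentials
  p <- net$params$D1
  expect_true(all(V >= min(p$V_reset, p$E_in) - 1e-9))
  expect_true(all(V <= p$E_ex + 1e-9))
})
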