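# small synthetic spike_data builder for analysis-only tests
fake_spikes <- function(events, net, duration_ms = 1000, dt = 1) {
  structure(list(spikes = events, network = net, dt = dt,
                 duration_ms = duration_ms, seed = 0L),
            class = "spike_data")
}

test_that("binned rates convert counts to spikes/s per neuron", {
  net <- toy_network()    # 2x2 grid, 2 per type
  ev <- data.frame(neuron_id = c(1L, 1L, 2L),
                   time_ms = c(100, 150, 700))
  spk <- fake_spikes(ev, net, duration_ms = 1000)
  br <- binned_rates(spk, bin_ms = 200, by = "channel_type")
  # channel 1 D1 group has 2 neurons; bin 1 holds two spikes ->
  # 2 / 0.2 s / 2 neurons = 5 Hz
  b1 <- br[br$channel == 1 & br$type == "D1" & br$t_mid_ms == 100, ]
  expect_equal(b1$rate_hz, 5)
  b4 <- br[br$channel == 1 & br$type == "D1" & br$t_mid_ms == 700, ]
  expect_equal(b4$rate_hz, 2.5)
  expect_true(all(br$rate_hz[br$type == "D2"] == 0))
  # group sizes cover the roster
  expect_equal(length(unique(paste(br$channel, br$type))), 8)
  hr <- binned_rates(spk, bin_ms = 200, by = "hemisphere_type")
  # total spikes recovered: 8 D1 neurons in the hemisphere group
  expect_equal(sum(hr$rate_hz[hr$type == "D1"]) * 0.2 * 8, 3)
})

test_that("calcium filter mirrors the motor filter at tau = 300 ms", {
  tr <- calcium_filter(50, 1000)
  expect_equal(max(tr), 1 / 0.3, tolerance = 1e-9)
  expect_equal(which.max(tr), 50)
  expect_true(all(calcium_filter(numeric(0), 300) == 0))
  # linearity over superposed trains
  a <- calcium_filter(c(100, 400), 1000)
  expect_equal(a, calcium_filter(100, 1000) + calcium_filter(400, 1000))
})

test_that("Pearson routines agree with a direct covariance oracle", {
  set.seed(7)
  for (k in 1:5) {
    x <- rnorm(200) + seq(0, 2, length.out = 200)
    y <- 0.4 * x + rnorm(200)
    expect_equal(stats::cor(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
  # the same identity on actual filtered traces
  t1 <- calcium_filter(sort(runif(50, 0, 2000)), 2000)
  t2 <- calcium_filter(sort(runif(50, 0, 2000)), 2000)
  expect_equal(stats::cor(t1, t2), pearson_oracle(t1, t2), tolerance = 1e-12)
})

test_that("pairwise correlations: identical trains correlate at 1, independent near 0", {
  net <- hemisphere_network(1)
  spk <- simulate_network(net, NULL, simulation_config(duration_ms = 20000,
                                                       seed = 31))
  cs <- pairwise_correlation_histograms(spk, n_sample = 150,
                                        transient_ms = 0, seed = 1)
  expect_true(all(cs$pairs$r >= -1 & cs$pairs$r <= 1))
  # unordered distinct pairs of the non-silent sample
  expect_equal(nrow(cs$pairs), choose(cs$n_sample - cs$n_silent, 2))
  expect_warning(
    pairwise_correlation_histograms(spk, n_sample = 10000, transient_ms = 0),
    "roster")
  # independent homogeneous Poisson trains: |r| small over 200 s
  net2 <- toy_network()
  set.seed(9)
  ev <- do.call(rbind, lapply(1:8, function(i)
    data.frame(neuron_id = i, time_ms = sort(runif(600, 0, 2e5)))))
  spk2 <- fake_spikes(ev, net2, duration_ms = 2e5)
  cs2 <- pairwise_correlation_histograms(spk2, n_sample = 8,
                                         transient_ms = 0)
  expect_true(all(abs(cs2$pairs$r) < 0.05))
})

test_that("correlation summaries are invariant to relabeling within channels", {
  net <- toy_network(n_per_type = 4L)
  set.seed(3)
  ev <- do.call(rbind, lapply(1:32, function(i)
    data.frame(neuron_id = i, time_ms = sort(runif(50, 0, 1e4)))))
  spk <- fake_spikes(ev, net, duration_ms = 1e4)
  cs <- pairwise_correlation_histograms(spk, n_sample = 32, transient_ms = 0)
  # permute neuron labels within channel 1 D1 (ids 1..4): swap 1 and 2
  ev2 <- ev
  ev2$neuron_id[ev$neuron_id == 1L] <- 99L
  ev2$neuron_id[ev$neuron_id == 2L] <- 1L
  ev2$neuron_id[ev2$neuron_id == 99L] <- 2L
  cs2 <- pairwise_correlation_histograms(fake_spikes(ev2, net, 1e4),
                                         n_sample = 32, transient_ms = 0)
  h <- function(x) sort(round(x$pairs$r[x$pairs$category == "within"], 10))
  expect_equal(h(cs), h(cs2))
})

test_that("subsampled correlation matrices are symmetric with unit diagonal", {
  net <- hemisphere_network(1)
  spk <- simulate_network(net, NULL, simulation_config(duration_ms = 10000,
                                                       seed = 33))
  m <- correlation_matrix_subsample(spk, stride = 5, transient_ms = 0)
  expect_equal(dim(m$D1_D1), c(288, 288))   # 8 per channel x 36 channels
  expect_equal(length(m$ids_D1), 288)
  live <- !is.na(diag(m$D2_D2))
  expect_true(all(diag(m$D2_D2)[live] == 1))
  expect_equal(m$D2_D2, t(m$D2_D2))
})

test_that("instantaneous correlation detects identity, shuffle and window errors", {
  set.seed(11)
  x <- as.numeric(stats::filter(rnorm(5000), 0.98, method = "recursive"))
  ic <- instantaneous_correlation(x, x, window_ms = 1000)
  expect_true(all(abs(ic$r - 1) < 1e-12))
  expect_error(instantaneous_correlation(x, x, window_ms = 10000), "longer")
  y <- as.numeric(stats::filter(rnorm(5000), 0.98, method = "recursive"))
  icy <- instantaneous_correlation(x, y, window_ms = 2000)
  expect_true(mean(abs(icy$r)) < 0.9)   # unrelated traces are not locked
})

test_that("shuffling preserves per-neuron counts and kills correlations", {
  net <- hemisphere_network(1)
  spk <- simulate_network(net, NULL, simulation_config(duration_ms = 20000,
                                                       seed = 35))
  sh <- shuffle_spikes(spk, seed = 1)
  expect_equal(table(sh$spikes$neuron_id), table(spk$spikes$neuron_id))
  # shuffled population traces fluctuate around zero correlation, while the
  # original D1/D2 populations are genuinely (negatively) correlated
  d1 <- population_trace(sh, "D1"); d2 <- population_trace(sh, "D2")
  ic <- instantaneous_correlation(d1, d2, window_ms = 6000, dt = spk$dt)
  expect_lt(abs(mean(ic$r, na.rm = TRUE)), 0.15)
  r1 <- population_trace(spk, "D1"); r2 <- population_trace(spk, "D2")
  icr <- instantaneous_correlation(r1, r2, window_ms = 6000, dt = spk$dt)
  expect_lt(mean(icr$r, na.rm = TRUE), mean(ic$r, na.rm = TRUE))
})

test_that("winning channel and selected action follow the agreement rule", {
  net <- full_network(1)
  ch <- action_channels(net$grid)
  nn <- net$neurons
  id_of <- function(hemi, chan) nn$id[nn$hemisphere == hemi &
                                        nn$channel == chan & nn$type == "D2"]
  # hemisphere L: channel turn_left D2 fires heavily during [0, 500];
  # turn_right during (500, 1000]; hemisphere R agrees in the first half,
  # disagrees in the second
  mk <- function(ids, t0, t1, n = 200)
    data.frame(neuron_id = rep(ids[1:5], length.out = n),
               time_ms = seq(t0 + 1, t1, length.out = n))
  ev <- rbind(mk(id_of("L", ch["turn_left"]), 0, 500),
              mk(id_of("L", ch["turn_right"]), 500, 1000),
              mk(id_of("R", ch["turn_left"]), 0, 500),
              mk(id_of("R", ch["turn_left"]), 500, 1000))
  spk <- fake_spikes(ev, net, duration_ms = 1000)
  wL <- winning_channel(spk, ch, "L", window_ms = 250, step_ms = 250)
  wR <- winning_channel(spk, ch, "R", window_ms = 250, step_ms = 250)
  expect_equal(as.character(wL$winner), c("turn_left", "turn_left",
                                          "turn_right", "turn_right"))
  act <- selected_action(wL, wR)
  expect_equal(as.character(act$action), c("turn_left", "turn_left",
                                           "none", "none"))
  # equal activity in both channels -> none
  ev2 <- rbind(mk(id_of("L", ch["turn_left"]), 0, 1000),
               mk(id_of("L", ch["turn_right"]), 0, 1000))
  w2 <- winning_channel(fake_spikes(ev2, net, 1000), ch, "L",
                        window_ms = 250, step_ms = 250)
  expect_true(all(as.character(w2$winner) == "none"))
})

test_that("coactive sets and recruitment distances handle the base cases", {
  net <- toy_network()
  empty <- fake_spikes(data.frame(neuron_id = integer(),
                                  time_ms = numeric()), net, 1000)
  expect_equal(length(coactive_neurons(empty, c(0, 1000))), 0)
  ev <- data.frame(neuron_id = 1:8, time_ms = rep(c(100, 900), 4))
  spk <- fake_spikes(ev, net, 1000)
  expect_equal(coactive_neurons(spk, c(0, 500)), c(1L, 3L, 5L, 7L))
  # same-channel antagonist-only neuron -> distance 0
  # toy grid 2x2: ids 1-4 channel 1 (D1 1:2, D2 3:4), 5-8 channel 2...
  rd <- recruitment_distances(control_ids = 1L, antagonist_ids = c(1L, 3L),
                              net = net, downsample = Inf)
  expect_equal(rd$distances, 0)
  rd2 <- recruitment_distances(1L, c(1L, 5L), net, downsample = Inf)
  expect_equal(rd2$distances, 1)
  expect_error(recruitment_distances(integer(0), 1L, net), "empty control")
  expect_equal(distance_mode(c(0, 1, 1, sqrt(2))), 1)
  expect_true(is.na(distance_mode(numeric(0))))
})

test_that("mean correction zeroes the mean and preserves correlations", {
  x <- rnorm(100) + 5
  expect_equal(mean(mean_corrected(x)), 0)
  expect_equal(mean_corrected(rep(3, 10)), rep(0, 10))
  y <- rnorm(100)
  expect_equal(stats::cor(x, y), stats::cor(mean_corrected(x), y),
               tolerance = 1e-12)
  m <- cbind(x, y)
  expect_equal(colMeans(mean_corrected(m)), c(x = 0, y = 0),
               tolerance = 1e-12)
})

test_that("positive mode finds the secondary positive peak", {
  set.seed(1)
  r <- c(rnorm(4000, -0.05, 0.1), rnorm(800, 0.6, 0.08))
  expect_equal(positive_mode(r), 0.6, tolerance = 0.05)
  r2 <- rnorm(2000, -0.2, 0.1)   # no positive lobe: falls back to global
  expect_lt(positive_mode(r2), 0)
})
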