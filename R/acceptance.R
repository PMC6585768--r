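#' Headline quantities of the model
#'
#' Recomputes, from scratch, the three headline simulation outcomes:
#'
#' * `t1` — location of the positive mode of the within-channel D1-D1 and
#'   D2-D2 Pearson correlation histograms (calcium-filtered trains, 300 ms)
#'   under background-only drive of one hemisphere with the non-monotonic
#'   kernel. Expected near 0.6.
#' * `t2` — mode of the distribution of wrapped channel distances between
#'   neurons recruited only under the simulated GABA antagonist and their
#'   nearest control-recruited neighbours (non-monotonic kernel, 5 trials).
#'   Expected 1.0 (about 40 um).
#' * `t5` — maximum linear velocity command over a full bilateral-D1 run.
#'   Bounded above by 2 m/s by the sigmoid.
#'
#' @param seed Master seed; each target derives its own sub-seed.
#' @param t1_duration_ms Background-only run length for `t1`. The reference
#'   analysis uses 200 s; 50 s and above gives a stable histogram. Default
#'   100000 (100 s).
#' @param n_trials Trials for `t2` (default 5).
#' @return Named list; each element has `value` and `n` (problem size).
#' @export
acceptance_targets <- function(seed = 1L, t1_duration_ms = 1e5,
                               n_trials = 5) {
  seed <- as.integer(seed)

  # t1: within-channel co-activation peak under background only
  net1 <- build_hemisphere(seed = seed)
  spk1 <- simulate_network(net1, NULL,
                           simulation_config(duration_ms = t1_duration_ms,
                                             seed = seed + 1L))
  cs <- pairwise_correlation_histograms(spk1, n_sample = 500,
                                        transient_ms = 0, seed = seed + 2L)
  pr <- cs$pairs
  r_within <- pr$r[pr$category == "within" & pr$type_pair %in%
                     c("D1-D1", "D2-D2")]
  t1 <- list(value = positive_mode(r_within), n = length(r_within))

  # t2: recruitment-distance mode, non-monotonic kernel
  rec <- run_recruitment_experiment("non_monotonic", n_trials = n_trials,
                                    seed = seed + 10L)
  t2 <- list(value = rec$mode, n = length(rec$distances))

  # t5: velocity bound over a bilateral D1 run
  run <- run_paradigm("bilateral_D1", seed = seed + 20L)
  t5 <- list(value = max(run$commands$v), n = nrow(run$commands))

  list(t1 = t1, t2 = t2, t5 = t5)
}
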