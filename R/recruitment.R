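#' Recruitment distances between antagonist-only and control neurons
#'
#' For every neuron recruited only in the antagonist bout (not in control),
#' the wrapped Euclidean channel distance to the nearest control-recruited
#' neuron. Before the distance computation the recorded population is
#' down-sampled to `downsample` neurons (mimicking the limited field of view
#' of the imaging experiment); both sets are restricted to the sample.
#'
#' @param control_ids,antagonist_ids Neuron ids from [coactive_neurons()]
#'   on the control and antagonist bouts.
#' @param net The `striatal_network` the ids refer to.
#' @param downsample Number of neurons kept (default 500; `Inf` keeps all).
#' @param seed Optional seed for the down-sampling.
#' @return Object of class `recruitment_result`: list with `distances`
#'   (channel units; multiply by `net$grid$spacing_um` for um),
#'   `control_set`, `antagonist_only_set`, `coactive_counts`.
#' @export
recruitment_distances <- function(control_ids, antagonist_ids, net,
                                  downsample = 500, seed = NULL) {
  if (!length(control_ids)) stop("empty control set: no reference neurons")
  nn <- net$neurons
  if (!is.null(seed)) set.seed(seed)
  pool <- nn$id
  if (is.finite(downsample) && downsample < length(pool))
    pool <- sort(sample(pool, downsample))
  ctrl <- intersect(control_ids, pool)
  anta <- intersect(antagonist_ids, pool)
  only <- setdiff(anta, ctrl)
  dmat <- channel_distance_matrix(net$grid)
  ch_ctrl <- nn$channel[match(ctrl, nn$id)]
  ch_only <- nn$channel[match(only, nn$id)]
  dists <- if (length(only) && length(ctrl))
    apply(dmat[ch_only, ch_ctrl, drop = FALSE], 1, min)
  else numeric(0)
  structure(list(distances = unname(dists),
                 control_set = ctrl, antagonist_only_set = only,
                 coactive_counts = c(control = length(ctrl),
                                     antagonist = length(anta))),
            class = "recruitment_result")
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf("<recruitment_result> %d control, %d antagonist-only, mode d = %s\n",
              length(x$control_set), length(x$antagonist_only_set),
              if (length(x$distances)) format(distance_mode(x$distances))
              else "NA"))
  invisible(x)
}

#' Mode of a set of channel distances
#'
#' Wrapped channel distances take discrete values (0, 1, sqrt(2), 2, ...);
#' the mode is the most frequent value.
#'
#' @param distances Numeric vector of channel distances.
#' @return The most frequent value.
#' @export
distance_mode <- function(distances) {
  if (!length(distances)) return(NA_real_)
  tb <- table(round(distances, 6))
  as.numeric(names(tb)[which.max(tb)])
}

#' Run the GABA-antagonist recruitment experiment
#'
#' Builds a fresh single hemisphere per trial (seed + trial index), runs
#' the disinhibition protocol ([make_gaba_experiment()]), identifies the
#' neurons active during the control and antagonist bouts, and computes the
#' nearest-neighbour recruitment distances.
#'
#' The slice-like condition uses the nominal (single-source) background
#' rates directly, scaled to 25% by the protocol: unlike the freely-behaving
#' paradigms, this experiment requires the near-silent spontaneous state of
#' an in-vitro preparation, in which the 140 pA pulse leaves the average
#' neuron subthreshold and recruitment is gated by lateral inhibition --
#' the regime the experiment is designed to probe.
#'
#' @param kernel_mode `"non_monotonic"` or `"monotonic"`.
#' @param n_trials Number of network instances/seeds (default 5).
#' @param seed Base seed; trial t uses `seed + t - 1`.
#' @param downsample Down-sampling size for the distance analysis (500).
#' @param bout_pad_ms Response window kept after stimulus offset (50 ms).
#' @param background Background input of the slice network; default the
#'   nominal rates with `n_sources = 1`.
#' @param dt Integration step in ms.
#' @return Object of class `recruitment_experiment`: list with `trials`
#'   (list of `recruitment_result`), `distances` (pooled), `mode`,
#'   `coactive_counts` (matrix trials x 2), `kernel_mode`.
#' @export
run_recruitment_experiment <- function(kernel_mode = "non_monotonic",
                                       n_trials = 5, seed = 1L,
                                       downsample = 500, bout_pad_ms = 50,
                                       background = background_input(n_sources = 1L),
                                       dt = 1.0) {
  protocol <- make_gaba_experiment()
  b <- protocol$blocks
  win_ctrl <- c(b$t_start_ms[1], b$t_stop_ms[1] + bout_pad_ms)
  win_anta <- c(b$t_start_ms[2], b$t_stop_ms[2] + bout_pad_ms)
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    s <- seed + tr - 1L
    net <- build_hemisphere(kernel = connectivity_kernel(kernel_mode),
                            background = background, seed = s)
    spk <- simulate_network(net, protocol,
                            simulation_config(dt = dt,
                                              duration_ms = protocol$duration_ms,
                                              seed = s))
    ctrl <- coactive_neurons(spk, win_ctrl)
    anta <- coactive_neurons(spk, win_anta)
    trials[[tr]] <- recruitment_distances(ctrl, anta, net,
                                          downsample = downsample, seed = s)
  }
  pooled <- unlist(lapply(trials, `[[`, "distances"))
  counts <- t(vapply(trials, `[[`, numeric(2), "coactive_counts"))
  structure(list(trials = trials, distances = pooled,
                 mode = distance_mode(pooled),
                 coactive_counts = counts, kernel_mode = kernel_mode),
            class = "recruitment_experiment")
}

#' @export
print.recruitment_experiment <- function(x, ...) {
  cat(sprintf("<recruitment_experiment> %s kernel, %d trials, distance mode = %s\n",
              x$kernel_mode, length(x$trials), format(x$mode)))
  invisible(x)
}

#' Trial-averaged recruitment-distance histogram
#'
#' Relative frequency of each discrete channel distance, averaged over
#' trials, with the across-trial standard deviation.
#'
#' @param exp A `recruitment_experiment`.
#' @return data.frame with `distance`, `mean_freq`, `sd_freq`.
#' @export
recruitment_histogram <- function(exp) {
  vals <- sort(unique(round(exp$distances, 6)))
  per_trial <- vapply(exp$trials, function(tr) {
    d <- round(tr$distances, 6)
    if (!length(d)) return(rep(0, length(vals)))
    vapply(vals, function(v) mean(d == v), numeric(1))
  }, numeric(length(vals)))
  per_trial <- matrix(per_trial, nrow = length(vals))
  data.frame(distance = vals,
             mean_freq = rowMeans(per_trial),
             sd_freq = apply(per_trial, 1, stats::sd))
}
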