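#' Binned population firing rates
#'
#' Spike counts in fixed bins divided by bin width and group size, i.e.
#' spikes/s per neuron, grouped by channel x type or hemisphere x type.
#'
#' @param spk A `spike_data` object.
#' @param bin_ms Bin width in ms (default 200).
#' @param by `"channel_type"` or `"hemisphere_type"`.
#' @return data.frame with columns `hemisphere`, (`channel`,) `type`,
#'   `t_mid_ms`, `rate_hz`.
#' @export
binned_rates <- function(spk, bin_ms = 200,
                         by = c("channel_type", "hemisphere_type")) {
  by <- match.arg(by)
  nn <- spk$network$neurons
  n_bins <- ceiling(spk$duration_ms / bin_ms)
  mids <- (seq_len(n_bins) - 0.5) * bin_ms
  key <- if (by == "channel_type")
    interaction(nn$hemisphere, nn$channel, nn$type, drop = FALSE)
  else
    interaction(nn$hemisphere, nn$type, drop = FALSE)
  groups <- levels(key)
  out <- vector("list", length(groups))
  sp_key <- key[match(spk$spikes$neuron_id, nn$id)]
  bin_of <- pmin(pmax(ceiling(spk$spikes$time_ms / bin_ms), 1L), n_bins)
  for (g in seq_along(groups)) {
    n_g <- sum(key == groups[g])
    if (n_g == 0) {
      warning("empty group ", groups[g])
      next
    }
    counts <- tabulate(bin_of[sp_key == groups[g]], nbins = n_bins)
    parts <- strsplit(groups[g], ".", fixed = TRUE)[[1]]
    df <- data.frame(hemisphere = parts[1], t_mid_ms = mids,
                     rate_hz = counts / (bin_ms / 1000) / n_g,
                     stringsAsFactors = FALSE)
    if (by == "channel_type") {
      df$channel <- as.integer(parts[2]); df$type <- parts[3]
    } else df$type <- parts[2]
    out[[g]] <- df
  }
  do.call(rbind, out)
}

#' Calcium-like filtered spike train
#'
#' Exponential filter with a 300 ms time constant, matching the decay of
#' GCaMP6f calcium transients; used for all pairwise correlation analyses.
#' Same kernel normalisation as [exp_filter_trace()].
#'
#' @inheritParams exp_filter_trace
#' @export
calcium_filter <- function(times, duration_ms, dt = 1, tau_ms = 300)
  exp_filter_trace(times, duration_ms, dt, tau_ms)

# matrix of filtered traces (samples x neurons) for the given ids and window
filtered_traces <- function(spk, ids, window_ms = NULL, dt = NULL,
                            tau_ms = 300) {
  if (is.null(dt)) dt <- spk$dt
  if (is.null(window_ms)) window_ms <- c(0, spk$duration_ms)
  sp <- spk$spikes
  keep <- sp$neuron_id %in% ids
  sp <- sp[keep, , drop = FALSE]
  n_t <- as.integer(round((window_ms[2] - window_ms[1]) / dt))
  tr <- matrix(0, nrow = n_t, ncol = length(ids))
  colnames(tr) <- as.character(ids)
  sp_by <- split(sp$time_ms, factor(sp$neuron_id, levels = ids))
  for (j in seq_along(ids)) {
    # filter over the full recording, then cut the window, so that filter
    # state at the window start reflects earlier spikes
    full <- exp_filter_trace(sp_by[[j]], spk$duration_ms, dt, tau_ms)
    i0 <- as.integer(round(window_ms[1] / dt))
    tr[, j] <- full[(i0 + 1):(i0 + n_t)]
  }
  tr
}

#' Pairwise correlation summary by spatial distance
#'
#' Randomly samples `n_sample` neurons of one hemisphere, filters each spike
#' train with the calcium kernel (tau = 300 ms), and computes the Pearson
#' correlation coefficient of every unordered distinct pair over the given
#' phase window (minus a transient-exclusion margin at each end). Pairs are
#' classified by MSN type pair (D1-D1, D2-D2, D1-D2) and by the wrapped
#' channel distance category of their channels. Silent (zero-variance)
#' trains are dropped and their count recorded.
#'
#' @param spk A `spike_data` object.
#' @param n_sample Neurons to sample (default 500; capped at the roster
#'   size with a warning).
#' @param window_ms Phase window `c(start, stop)` in ms; default the whole
#'   run.
#' @param transient_ms Margin excluded at each end of the window (default
#'   500; set 0 to keep all).
#' @param hemisphere Hemisphere to sample from (default `"L"`).
#' @param seed Optional seed for the neuron sample.
#' @return Object of class `correlation_summary`: list with `pairs`
#'   (data.frame `i`, `j`, `type_pair`, `category`, `r`), `n_sample`,
#'   `n_silent`, `window_ms`.
#' @export
pairwise_correlation_histograms <- function(spk, n_sample = 500,
                                            window_ms = NULL,
                                            transient_ms = 500,
                                            hemisphere = "L", seed = NULL) {
  nn <- spk$network$neurons
  pool <- nn$id[nn$hemisphere == hemisphere]
  if (n_sample > length(pool)) {
    warning("n_sample larger than roster; using all ", length(pool),
            " neurons")
    n_sample <- length(pool)
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- sort(sample(pool, n_sample))
  if (is.null(window_ms)) window_ms <- c(0, spk$duration_ms)
  window_ms <- window_ms + c(transient_ms, -transient_ms)
  stopifnot(window_ms[2] > window_ms[1])
  tr <- filtered_traces(spk, ids, window_ms)
  sds <- apply(tr, 2, stats::sd)
  silent <- sds == 0
  ids_live <- ids[!silent]
  tr <- tr[, !silent, drop = FALSE]
  R <- stats::cor(tr)
  # pair metadata
  info <- nn[match(ids_live, nn$id), ]
  catm <- channel_category_matrix(spk$network$grid,
                                  diagonal = spk$network$kernel$diagonal)
  ut <- which(upper.tri(R), arr.ind = TRUE, useNames = FALSE)
  ti <- info$type[ut[, 1]]; tj <- info$type[ut[, 2]]
  type_pair <- ifelse(ti == tj, paste0(ti, "-", tj), "D1-D2")
  cat_i <- catm[cbind(info$channel[ut[, 1]], info$channel[ut[, 2]])]
  pairs <- data.frame(
    i = ids_live[ut[, 1]], j = ids_live[ut[, 2]],
    type_pair = type_pair,
    category = c("within", "near", "far")[cat_i],
    r = R[ut], stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, n_sample = n_sample,
                 n_silent = sum(silent), window_ms = window_ms),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("<correlation_summary> %d pairs from %d neurons (%d silent dropped)\n",
              nrow(x$pairs), x$n_sample, x$n_silent))
  invisible(x)
}

#' Location of the positive mode of a correlation histogram
#'
#' Kernel density estimate of the coefficients; returns the location of the
#' highest local density maximum above `lower` (default 0.2, separating the
#' secondary positive peak from the dominant lobe around or below zero).
#' A candidate maximum counts as a genuine lobe only if its density exceeds
#' `min_height` times the global density maximum; otherwise (no positive
#' lobe, only tail noise) the global mode is returned.
#'
#' @param r Vector of correlation coefficients.
#' @param lower Left edge of the positive lobe searched.
#' @param bw Density bandwidth (default 0.05).
#' @param min_height Minimum relative density of an accepted positive lobe.
#' @return Location of the mode.
#' @export
positive_mode <- function(r, lower = 0.2, bw = 0.05, min_height = 0.05) {
  d <- stats::density(r, bw = bw, from = -1, to = 1, n = 1024)
  y <- d$y
  loc <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- loc[d$x[loc] > lower & y[loc] >= min_height * max(y)]
  if (!length(cand)) return(d$x[which.max(y)])
  d$x[cand[which.max(y[cand])]]
}

#' Correlation matrices of every k-th neuron, channel by channel
#'
#' Deterministically subsamples every `stride`-th neuron of each channel and
#' type (8 per channel at the default stride 5) of one hemisphere, orders
#' them channel-by-channel, and returns the Pearson correlation matrices of
#' the calcium-filtered trains for D1-D1, D2-D2 and D1-D2, so that the
#' within/near-channel block structure (checkerboard under global
#' stimulation) is visible.
#'
#' @inheritParams pairwise_correlation_histograms
#' @param stride Subsampling stride within each channel and type.
#' @return List with matrices `D1_D1`, `D2_D2`, `D1_D2` and the id vectors
#'   `ids_D1`, `ids_D2`.
#' @export
correlation_matrix_subsample <- function(spk, stride = 5, window_ms = NULL,
                                         transient_ms = 500,
                                         hemisphere = "L") {
  nn <- spk$network$neurons
  sub_ids <- function(type) {
    ids <- nn$id[nn$hemisphere == hemisphere & nn$type == type]
    ch <- nn$channel[match(ids, nn$id)]
    unlist(lapply(split(ids, ch), function(v)
      v[seq(1, length(v), by = stride)]), use.names = FALSE)
  }
  ids1 <- sub_ids("D1"); ids2 <- sub_ids("D2")
  if (is.null(window_ms)) window_ms <- c(0, spk$duration_ms)
  window_ms <- window_ms + c(transient_ms, -transient_ms)
  tr1 <- filtered_traces(spk, ids1, window_ms)
  tr2 <- filtered_traces(spk, ids2, window_ms)
  sd0 <- function(m) apply(m, 2, stats::sd) == 0
  # keep silent traces in place (correlation NA) to preserve the grid layout
  list(D1_D1 = suppressWarnings(stats::cor(tr1)),
       D2_D2 = suppressWarnings(stats::cor(tr2)),
       D1_D2 = suppressWarnings(stats::cor(tr1, tr2)),
       ids_D1 = ids1, ids_D2 = ids2,
       n_silent = sum(sd0(tr1)) + sum(sd0(tr2)))
}

#' Population activity trace of one type
#'
#' Calcium-filtered (tau = 300 ms) summed spike train of all neurons of a
#' type in a hemisphere, optionally per channel.
#'
#' @param spk A `spike_data` object.
#' @param type `"D1"` or `"D2"`.
#' @param hemisphere Hemisphere label.
#' @param channel Optional channel restriction.
#' @param tau_ms Filter constant (default 300).
#' @return Numeric trace sampled at `spk$dt`.
#' @export
population_trace <- function(spk, type, hemisphere = "L", channel = NULL,
                             tau_ms = 300) {
  nn <- spk$network$neurons
  sel <- nn$hemisphere == hemisphere & nn$type == type
  if (!is.null(channel)) sel <- sel & nn$channel %in% channel
  ids <- nn$id[sel]
  exp_filter_trace(spk$spikes$time_ms[spk$spikes$neuron_id %in% ids],
                   spk$duration_ms, spk$dt, tau_ms)
}

#' Sliding-window instantaneous correlation of two traces
#'
#' Pearson correlation of two population traces within a sliding window.
#' The window is typically 0.3x (shorter than) or 1.2x (longer than) the
#' stimulation time.
#'
#' @param trace1,trace2 Equal-length traces sampled at `dt`.
#' @param window_ms Window size in ms (must not exceed the recording).
#' @param step_ms Slide step (default 100 ms).
#' @param dt Sampling step of the traces in ms.
#' @return data.frame with `t_mid_ms` and `r`.
#' @export
instantaneous_correlation <- function(trace1, trace2, window_ms,
                                      step_ms = 100, dt = 1) {
  stopifnot(length(trace1) == length(trace2))
  n <- length(trace1)
  w <- as.integer(round(window_ms / dt))
  if (w > n) stop("window longer than the recording")
  step <- max(1L, as.integer(round(step_ms / dt)))
  starts <- seq(1L, n - w + 1L, by = step)
  r <- vapply(starts, function(s) {
    a <- trace1[s:(s + w - 1L)]; b <- trace2[s:(s + w - 1L)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  }, numeric(1))
  data.frame(t_mid_ms = (starts - 1 + w / 2) * dt, r = r)
}

#' Shuffle control: redraw spike times uniformly
#'
#' Returns a copy of the spike data in which every neuron's spike times are
#' redrawn uniformly over the recording, preserving per-neuron spike
#' counts. Destroys temporal alignment while keeping rates, so filtered
#' traces of shuffled data are uncorrelated.
#'
#' @param spk A `spike_data` object.
#' @param seed Optional seed.
#' @return A `spike_data` object.
#' @export
shuffle_spikes <- function(spk, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- spk$spikes
  sp$time_ms <- stats::runif(nrow(sp), 0, spk$duration_ms)
  o <- order(sp$neuron_id, sp$time_ms)
  spk$spikes <- sp[o, , drop = FALSE]
  rownames(spk$spikes) <- NULL
  spk
}

#' Instantaneous D1-D2 population correlation with shuffle control
#'
#' Computes the sliding-window correlation between the filtered D1 and D2
#' population activities of one hemisphere, for a set of window sizes given
#' as multiples of the stimulation duration, plus the same curves for
#' uniformly shuffled spike trains.
#'
#' @param spk A `spike_data` object.
#' @param stim_window_ms Stimulation window `c(start, stop)` defining the
#'   stimulation duration.
#' @param window_factors Window sizes as multiples of the stimulation
#'   duration (default `c(0.3, 1.2)`).
#' @param hemisphere Hemisphere label.
#' @param step_ms Slide step.
#' @param shuffle_seed Seed for the shuffle control.
#' @return data.frame with `window_factor`, `t_mid_ms`, `r`, `r_shuffled`.
#' @export
instantaneous_population_correlation <- function(spk,
                                                 stim_window_ms = c(5000, 15000),
                                                 window_factors = c(0.3, 1.2),
                                                 hemisphere = "L",
                                                 step_ms = 100,
                                                 shuffle_seed = 1L) {
  d1 <- population_trace(spk, "D1", hemisphere)
  d2 <- population_trace(spk, "D2", hemisphere)
  sh <- shuffle_spikes(spk, seed = shuffle_seed)
  d1s <- population_trace(sh, "D1", hemisphere)
  d2s <- population_trace(sh, "D2", hemisphere)
  stim_dur <- diff(stim_window_ms)
  out <- lapply(window_factors, function(wf) {
    w <- wf * stim_dur
    a <- instantaneous_correlation(d1, d2, w, step_ms, spk$dt)
    b <- instantaneous_correlation(d1s, d2s, w, step_ms, spk$dt)
    data.frame(window_factor = wf, t_mid_ms = a$t_mid_ms, r = a$r,
               r_shuffled = b$r)
  })
  do.call(rbind, out)
}

#' Winning channel from windowed D2 activity
#'
#' Compares the D2 spike counts of two channels of one hemisphere within a
#' sliding window; the channel with the higher count wins if the relative
#' difference `|nA - nB| / ((nA + nB)/2)` exceeds `margin`, otherwise no
#' winner is declared ("none", the gray areas).
#'
#' @param spk A `spike_data` object.
#' @param channels Length-2 named or unnamed channel indices `c(A, B)`.
#' @param hemisphere Hemisphere label.
#' @param window_ms Sliding window (default 250).
#' @param step_ms Slide step (default 50).
#' @param margin Relative-difference threshold for a clear winner (0.05).
#' @return data.frame with `t_mid_ms` and `winner` (factor with the two
#'   channel labels and `"none"`).
#' @export
winning_channel <- function(spk, channels, hemisphere = "L",
                            window_ms = 250, step_ms = 50, margin = 0.05) {
  stopifnot(length(channels) == 2)
  labs <- if (!is.null(names(channels))) names(channels)
          else as.character(channels)
  nn <- spk$network$neurons
  counts_in <- function(ch) {
    ids <- nn$id[nn$hemisphere == hemisphere & nn$channel == ch &
                 nn$type == "D2"]
    spk$spikes$time_ms[spk$spikes$neuron_id %in% ids]
  }
  tA <- counts_in(channels[[1]]); tB <- counts_in(channels[[2]])
  starts <- seq(0, spk$duration_ms - window_ms, by = step_ms)
  nA <- vapply(starts, function(s) sum(tA > s & tA <= s + window_ms),
               numeric(1))
  nB <- vapply(starts, function(s) sum(tB > s & tB <= s + window_ms),
               numeric(1))
  rel <- abs(nA - nB) / pmax((nA + nB) / 2, .Machine$double.eps)
  winner <- ifelse(nA + nB == 0 | rel <= margin, "none",
                   ifelse(nA > nB, labs[1], labs[2]))
  data.frame(t_mid_ms = starts + window_ms / 2,
             winner = factor(winner, levels = c(labs, "none")))
}

#' Selected action from per-hemisphere winners
#'
#' An action is selected in a window only when both hemispheres agree on
#' the same winning channel label; otherwise `"none"`.
#'
#' @param winners_L,winners_R data.frames from [winning_channel()] on the
#'   same time grid.
#' @return data.frame with `t_mid_ms` and `action`.
#' @export
selected_action <- function(winners_L, winners_R) {
  stopifnot(nrow(winners_L) == nrow(winners_R))
  wl <- as.character(winners_L$winner); wr <- as.character(winners_R$winner)
  act <- ifelse(wl != "none" & wl == wr, wl, "none")
  data.frame(t_mid_ms = winners_L$t_mid_ms,
             action = factor(act, levels = levels(winners_L$winner)))
}

#' Neurons active during a stimulation bout
#'
#' @param spk A `spike_data` object.
#' @param window_ms Bout window `c(start, stop)` in ms.
#' @return Integer vector of neuron ids with at least one spike in the
#'   window.
#' @export
coactive_neurons <- function(spk, window_ms) {
  sp <- spk$spikes
  sort(unique(sp$neuron_id[sp$time_ms > window_ms[1] &
                           sp$time_ms <= window_ms[2]]))
}

#' Mean-corrected traces
#'
#' Subtracts each trace's mean over the (stimulation) window; used before
#' plotting or correlating population activity during stimulation.
#'
#' @param x Numeric vector or matrix (traces in columns).
#' @return Same shape, each trace with zero mean.
#' @export
mean_corrected <- function(x) {
  if (is.matrix(x)) sweep(x, 2, colMeans(x)) else x - mean(x)
}
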