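#' Simulation configuration
#'
#' @param dt Integration step in ms (default 1.0, the model's stated
#'   resolution; can be reduced for convergence checks).
#' @param duration_ms Total simulated time in ms.
#' @param seed Integer seed driving all randomness of the run (background and
#'   stimulus Poisson trains).
#' @param record_ids Optional neuron ids whose membrane potential is recorded
#'   every step.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1.0, duration_ms = 20000, seed = 1L,
                              record_ids = NULL) {
  stopifnot(dt > 0, duration_ms >= dt)
  structure(list(dt = dt, duration_ms = duration_ms, seed = as.integer(seed),
                 record_ids = record_ids),
            class = "simulation_config")
}

delay_steps <- function(delay_ms, dt) pmax(1L, as.integer(floor(delay_ms / dt + 0.5)))

# resolve a protocol block selector to neuron ids
resolve_targets <- function(net, hemisphere, type, channels) {
  nn <- net$neurons
  sel <- rep(TRUE, nrow(nn))
  if (!identical(hemisphere, "all"))
    sel <- sel & nn$hemisphere %in% strsplit(hemisphere, "", fixed = TRUE)[[1]]
  if (!identical(type, "all")) sel <- sel & nn$type == type
  if (!identical(channels, "all")) {
    ch <- as.integer(strsplit(as.character(channels), ",", fixed = TRUE)[[1]])
    sel <- sel & nn$channel %in% ch
  }
  nn$id[sel]
}

#' Run a network simulation
#'
#' Integrates the conductance-based LIF dynamics of the whole network with
#' per-neuron independent background Poisson input, the timed DC-current and
#' Poisson-input blocks of `protocol`, and the protocol's network modifiers
#' (inhibitory-weight scaling from a given time, background scaling).
#' Deterministic given `config$seed`.
#'
#' @param net A `striatal_network`.
#' @param protocol A `stimulus_protocol` or `NULL` (background only).
#' @param config A [simulation_config()]. Its `duration_ms` defaults to the
#'   protocol duration when a protocol is given.
#' @return Object of class `spike_data`: list with `spikes` (data.frame
#'   `neuron_id`, `time_ms`), `network`, `dt`, `duration_ms`, `seed` and,
#'   if requested, `potentials` (steps x recorded neurons matrix).
#' @export
simulate_network <- function(net, protocol = NULL,
                             config = simulation_config()) {
  dt <- config$dt
  duration <- config$duration_ms
  if (!is.null(protocol)) {
    if (is.null(duration) || duration < protocol$duration_ms)
      duration <- protocol$duration_ms
    bad <- protocol$blocks$t_stop_ms > duration + 1e-9
    if (!is.null(protocol$blocks) && nrow(protocol$blocks) && any(bad))
      stop("protocol block extends beyond the simulation duration")
  }
  n_steps <- as.integer(round(duration / dt))

  nn <- net$neurons
  n <- nrow(nn)
  par_of <- function(field) {
    vapply(nn$type, function(ty) net$params[[ty]][[field]], numeric(1),
           USE.NAMES = FALSE)
  }
  neuron <- list(
    V_rest = par_of("V_rest"), V_thresh = par_of("V_thresh"),
    C_m = par_of("C_m"), g_L = par_of("g_L"),
    tau_syn_ex = par_of("tau_syn_ex"), tau_syn_in = par_of("tau_syn_in"),
    E_ex = par_of("E_ex"), E_in = par_of("E_in"),
    V_reset = par_of("V_reset"), t_ref = par_of("t_ref")
  )

  syn <- net$synapses[net$synapses$weight_nS > 0, , drop = FALSE]
  syn <- syn[order(syn$pre), , drop = FALSE]
  counts <- tabulate(syn$pre, nbins = n)
  syn_offset <- c(0L, cumsum(counts))

  bg_scale <- 1
  inh_scale_from <- -1
  inh_scale_factor <- 1
  dc_blocks <- list()
  poisson_blocks <- list()
  if (!is.null(protocol)) {
    mods <- protocol$modifiers
    if (!is.null(mods$background_scale)) bg_scale <- mods$background_scale
    if (!is.null(mods$inh_scale)) {
      inh_scale_factor <- mods$inh_scale
      inh_scale_from <- if (is.null(mods$inh_scale_from_ms)) 0 else
        mods$inh_scale_from_ms
    }
    bl <- protocol$blocks
    if (!is.null(bl) && nrow(bl)) {
      for (r in seq_len(nrow(bl))) {
        tg <- resolve_targets(net, bl$hemisphere[r], bl$type[r], bl$channels[r])
        if (!length(tg)) stop("protocol block selector matches no neurons")
        start <- as.integer(round(bl$t_start_ms[r] / dt))
        stop_ <- as.integer(round(bl$t_stop_ms[r] / dt))
        if (bl$kind[r] == "dc") {
          dc_blocks[[length(dc_blocks) + 1L]] <-
            list(targets0 = tg - 1L, amp = bl$amplitude_pA[r],
                 start = start, stop = stop_)
        } else {
          poisson_blocks[[length(poisson_blocks) + 1L]] <-
            list(targets0 = tg - 1L, lambda = bl$rate_hz[r] * dt / 1000,
                 w = bl$weight_nS[r], start = start, stop = stop_)
        }
      }
    }
  }

  bg <- net$background
  if (is.null(bg$n_sources)) bg$n_sources <- 1L
  bg_rate <- bg$rate_hz[match(nn$type, bg$type)] *
    bg$n_sources[match(nn$type, bg$type)] * bg_scale
  bg_lambda <- bg_rate * dt / 1000
  bg_w <- bg$weight_nS[match(nn$type, bg$type)]

  rec <- if (is.null(config$record_ids)) integer(0) else
    as.integer(config$record_ids) - 1L

  set.seed(config$seed)
  out <- lif_simulate_cpp(neuron, syn_offset, syn$post - 1L, syn$weight_nS,
                          delay_steps(syn$delay_ms, dt),
                          bg_lambda, bg_w, dc_blocks, poisson_blocks,
                          dt, n_steps, inh_scale_from, inh_scale_factor, rec)

  res <- list(
    spikes = data.frame(neuron_id = out$neuron_id, time_ms = out$time_ms),
    network = net, dt = dt, duration_ms = duration, seed = config$seed,
    protocol = if (is.null(protocol)) NULL else protocol$name
  )
  if (!is.null(out$potentials)) {
    colnames(out$potentials) <- as.character(config$record_ids)
    res$potentials <- out$potentials
  }
  structure(res, class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d spikes from %d neurons over %g ms (dt=%g, seed=%d)\n",
              nrow(x$spikes), nrow(x$network$neurons), x$duration_ms, x$dt,
              x$seed))
  invisible(x)
}

#' Write spikes as CSV
#' @param spk A `spike_data` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_spikes <- function(spk, path) {
  utils::write.csv(spk$spikes, path, row.names = FALSE)
  invisible(path)
}

#' F-I curve of an isolated MSN
#'
#' Firing rate (spike count / duration) of a single neuron with no synapses
#' and no background under a constant current, for each current in
#' `currents`. All currents are simulated in one call as independent
#' neurons.
#'
#' @param params A [msn_parameters()] object.
#' @param currents Currents in pA.
#' @param duration_ms Simulated time per current.
#' @param dt Integration step in ms.
#' @return data.frame with columns `I_pA` and `rate_hz`.
#' @export
fi_curve <- function(params, currents, duration_ms = 5000, dt = 1.0) {
  n <- length(currents)
  rep_f <- function(field) rep(params[[field]], n)
  neuron <- list(V_rest = rep_f("V_rest"), V_thresh = rep_f("V_thresh"),
                 C_m = rep_f("C_m"), g_L = rep_f("g_L"),
                 tau_syn_ex = rep_f("tau_syn_ex"),
                 tau_syn_in = rep_f("tau_syn_in"),
                 E_ex = rep_f("E_ex"), E_in = rep_f("E_in"),
                 V_reset = rep_f("V_reset"), t_ref = rep_f("t_ref"))
  n_steps <- as.integer(round(duration_ms / dt))
  dc <- lapply(seq_len(n), function(i)
    list(targets0 = i - 1L, amp = currents[i], start = 0L, stop = n_steps))
  out <- lif_simulate_cpp(neuron, integer(n + 1), integer(0), numeric(0),
                          integer(0), numeric(n), numeric(n), dc, list(),
                          dt, n_steps, -1, 1, integer(0))
  counts <- tabulate(out$neuron_id, nbins = n)
  data.frame(I_pA = currents, rate_hz = counts / (duration_ms / 1000))
}
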