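#' Exponentially filtered spike-train trace
#'
#' Causal convolution of a spike train with the kernel
#' `(1/tau) * exp(-t/tau)` for `t >= 0` (unit integral, so a population
#' train of N neurons firing at r spikes/s yields a trace fluctuating
#' around `N * r`). The trace is sampled on the simulation grid: a spike at
#' time `t` contributes `1/tau` to its bin and decays by `exp(-dt/tau)` per
#' subsequent bin.
#'
#' @param times Spike times in ms (any order; summed over the population).
#' @param duration_ms Length of the trace.
#' @param dt Sampling step in ms (default 1).
#' @param tau_ms Filter time constant in ms.
#' @return Numeric vector of length `duration_ms/dt`, in spikes/s.
#' @export
exp_filter_trace <- function(times, duration_ms, dt = 1, tau_ms = 200) {
  n <- as.integer(round(duration_ms / dt))
  counts <- numeric(n)
  if (length(times)) {
    bins <- pmin(pmax(ceiling(times / dt), 1L), n)
    tb <- tabulate(bins, nbins = n)
    counts <- tb
  }
  tau_s <- tau_ms / 1000
  as.numeric(stats::filter(counts / tau_s, exp(-dt / tau_ms),
                           method = "recursive"))
}

#' Bounded sigmoid of the motor equations
#'
#' `Sig(x) = 2 / (1 + exp(-4x + 4))`: strictly increasing, `Sig(1) = 1`,
#' limits 0 and 2. Bounds the action commands, hence the linear velocity,
#' to `(0, 2)`.
#'
#' @param x Numeric.
#' @return Values in `(0, 2)`.
#' @export
motor_sigmoid <- function(x) 2 / (1 + exp(-4 * x + 4))

#' Action commands from filtered channel rates
#'
#' `a_l = Sig(S_D1/N_D1 * f_r^D1 - S_D2/N_D2 * f_r^D2)` where `f_r` are the
#' filtered population rates of the *right* hemisphere's 'turn left'
#' channel (contralateral encoding), and symmetrically for `a_r` from the
#' left hemisphere's 'turn right' channel. D1 activity pushes its motor
#' ("Go"), D2 activity pulls it down ("No-Go").
#'
#' @param f_r_D1,f_r_D2 Filtered D1/D2 population rates (spikes/s, summed
#'   over the channel population) of the right hemisphere's 'turn left'
#'   channel.
#' @param f_l_D1,f_l_D2 Same for the left hemisphere's 'turn right' channel.
#' @param params A [motor_parameters()] object.
#' @return List with components `a_l`, `a_r` in `(0, 2)`.
#' @export
action_commands <- function(f_r_D1, f_r_D2, f_l_D1, f_l_D2,
                            params = motor_parameters()) {
  if (any(c(f_r_D1, f_r_D2, f_l_D1, f_l_D2) < 0))
    stop("population rates must be non-negative")
  a_l <- motor_sigmoid(params$S_D1 / params$N_D1 * f_r_D1 -
                       params$S_D2 / params$N_D2 * f_r_D2)
  a_r <- motor_sigmoid(params$S_D1 / params$N_D1 * f_l_D1 -
                       params$S_D2 / params$N_D2 * f_l_D2)
  list(a_l = a_l, a_r = a_r)
}

#' Velocity and rotation from the action commands
#'
#' `v = (a_l + a_r)/2` (m/s) and `theta = a_l - a_r` (rad/s). Since the
#' commands are sigmoid-bounded to `(0, 2)`, `v < 2` m/s and
#' `theta` lies in `(-2, 2)`, inside `[-pi, pi]`. Positive `theta` turns
#' the robot left.
#'
#' @param a_l,a_r Action commands in `(0, 2)`.
#' @return List with `v` and `theta`.
#' @export
velocity_rotation <- function(a_l, a_r) {
  if (any(a_l < 0 | a_l > 2 | a_r < 0 | a_r > 2))
    stop("action commands out of range (0, 2)")
  list(v = (a_l + a_r) / 2, theta = a_l - a_r)
}

#' Motor command trace from a simulation
#'
#' Filters the spike trains of the designated action channels with the
#' motor filter (tau = 200 ms) and applies the action/velocity equations at
#' every simulation step.
#'
#' @param spk A `spike_data` object.
#' @param channels Action channels from [action_channels()].
#' @param params A [motor_parameters()] object.
#' @return data.frame with columns `t_ms`, `a_l`, `a_r`, `v`, `theta`.
#' @export
motor_commands <- function(spk, channels = action_channels(spk$network$grid),
                           params = motor_parameters()) {
  nn <- spk$network$neurons
  pick <- function(hemi, ch, type) {
    ids <- nn$id[nn$hemisphere == hemi & nn$channel == ch & nn$type == type]
    exp_filter_trace(spk$spikes$time_ms[spk$spikes$neuron_id %in% ids],
                     spk$duration_ms, spk$dt, params$tau_ms)
  }
  f_r_D1 <- pick("R", channels[["turn_left"]], "D1")
  f_r_D2 <- pick("R", channels[["turn_left"]], "D2")
  f_l_D1 <- pick("L", channels[["turn_right"]], "D1")
  f_l_D2 <- pick("L", channels[["turn_right"]], "D2")
  a <- action_commands(f_r_D1, f_r_D2, f_l_D1, f_l_D2, params)
  vt <- velocity_rotation(a$a_l, a$a_r)
  data.frame(t_ms = seq_len(length(a$a_l)) * spk$dt,
             a_l = a$a_l, a_r = a$a_r, v = vt$v, theta = vt$theta)
}

#' Integrate a planar unicycle trajectory
#'
#' Ideal kinematics (no inertia, no slip): `heading' = theta`,
#' `x' = v cos(heading)`, `y' = v sin(heading)`, explicit Euler on the
#' command grid.
#'
#' @param commands data.frame with `t_ms`, `v` (m/s) and `theta` (rad/s),
#'   e.g. from [motor_commands()].
#' @param x0,y0,heading0 Initial pose.
#' @return data.frame `t_ms`, `v`, `theta`, `x`, `y`, `heading`.
#' @export
integrate_trajectory <- function(commands, x0 = 0, y0 = 0, heading0 = 0) {
  t <- commands$t_ms
  dt_s <- diff(c(0, t)) / 1000
  heading <- heading0 + cumsum(commands$theta * dt_s)
  x <- x0 + cumsum(commands$v * cos(heading) * dt_s)
  y <- y0 + cumsum(commands$v * sin(heading) * dt_s)
  data.frame(t_ms = t, v = commands$v, theta = commands$theta,
             x = x, y = y, heading = heading)
}

#' Path length of a trajectory over a time window
#'
#' @param traj Trajectory data.frame from [integrate_trajectory()].
#' @param window_ms Optional `c(start, stop)` in ms; default whole run.
#' @return Total path length in metres.
#' @export
path_length <- function(traj, window_ms = NULL) {
  if (!is.null(window_ms))
    traj <- traj[traj$t_ms > window_ms[1] & traj$t_ms <= window_ms[2], ]
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Net heading change over a time window
#' @inheritParams path_length
#' @return Heading change in radians (positive = net left turn).
#' @export
heading_change <- function(traj, window_ms = NULL) {
  if (!is.null(window_ms))
    traj <- traj[traj$t_ms > window_ms[1] & traj$t_ms <= window_ms[2], ]
  traj$heading[nrow(traj)] - traj$heading[1]
}

#' Run a complete paradigm: build, simulate, transform, integrate
#'
#' Convenience pipeline. Builds the two-hemisphere network (unless one is
#' supplied), simulates the named paradigm, computes motor commands and the
#' robot trajectory.
#'
#' @param paradigm Paradigm name from [list_paradigms()] or a
#'   `stimulus_protocol`.
#' @param seed Integer seed used for both network construction and
#'   simulation.
#' @param net Optional prebuilt `striatal_network`.
#' @param kernel_mode Connectivity kernel mode for network construction.
#' @param sever_d2d2 If `TRUE`, sever the D2-D2 connections between the two
#'   action channels before simulating.
#' @param dt Integration step (ms).
#' @param duration_ms Optional duration override.
#' @return List of class `paradigm_run` with `spikes`, `commands`,
#'   `trajectory`, `network`, `protocol`.
#' @export
run_paradigm <- function(paradigm, seed = 1L, net = NULL,
                         kernel_mode = "non_monotonic", sever_d2d2 = FALSE,
                         dt = 1.0, duration_ms = NULL) {
  protocol <- if (inherits(paradigm, "stimulus_protocol")) paradigm
              else make_paradigm(paradigm)
  if (is.null(net))
    net <- build_network(kernel = connectivity_kernel(kernel_mode),
                         seed = seed)
  ch <- action_channels(net$grid)
  if (sever_d2d2)
    net <- sever_connections(net, "D2", "D2", unname(ch))
  dur <- if (is.null(duration_ms)) protocol$duration_ms else duration_ms
  spk <- simulate_network(net, protocol,
                          simulation_config(dt = dt, duration_ms = dur,
                                            seed = seed))
  cmd <- motor_commands(spk, ch)
  traj <- integrate_trajectory(cmd)
  structure(list(spikes = spk, commands = cmd, trajectory = traj,
                 network = net, protocol = protocol,
                 action_channels = ch, seed = seed),
            class = "paradigm_run")
}

#' @export
print.paradigm_run <- function(x, ...) {
  cat(sprintf("<paradigm_run> %s (seed %d): %d spikes, path %.2f m\n",
              x$protocol$name, x$seed, nrow(x$spikes$spikes),
              path_length(x$trajectory)))
  invisible(x)
}

#' Write the trajectory as CSV
#' @param run A `paradigm_run` (or trajectory data.frame).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(run, path) {
  traj <- if (inherits(run, "paradigm_run")) {
    cbind(run$trajectory[, c("t_ms")], run$commands[, c("a_l", "a_r")],
          run$trajectory[, c("v", "theta", "x", "y", "heading")])
  } else run
  if (is.data.frame(traj) && !("t_ms" %in% names(traj)))
    names(traj)[1] <- "t_ms"
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
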