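#' Medium spiny neuron parameters
#'
#' Conductance-based leaky integrate-and-fire parameters for the two MSN
#' types. The membrane constants (resting potential, threshold, capacitance,
#' leak) were tuned against experimentally measured F-I curves; D2-MSNs have
#' a smaller capacitance and leak conductance and are therefore more
#' excitable (lower rheobase) than D1-MSNs.
#'
#' The reversal potentials, reset and refractory period are conventional
#' completions of the conductance-LIF model: `E_ex = 0` mV, `E_in = -74` mV
#' (GABA-A reversal in MSNs, above rest but well below threshold, so
#' "inhibition" is shunting/depolarising near rest and hyperpolarising near
#' threshold), `V_reset = V_rest` and `t_ref = 2` ms. All are overridable.
#'
#' @param type `"D1"` or `"D2"`.
#' @param ... Named overrides of individual fields.
#' @return A list of class `neuron_parameters` with fields `V_rest`,
#'   `V_thresh` (mV), `C_m` (pF), `g_L` (nS), `tau_syn_ex`, `tau_syn_in`
#'   (ms), `E_ex`, `E_in`, `V_reset` (mV), `t_ref` (ms).
#' @export
#' @examples
#' msn_parameters("D2")$g_L  # 4.5 nS
msn_parameters <- function(type = c("D1", "D2"), ...) {
  type <- match.arg(type)
  p <- if (type == "D1") {
    list(V_rest = -87.2, V_thresh = -50, C_m = 195, g_L = 9,
         tau_syn_ex = 5, tau_syn_in = 10,
         E_ex = 0, E_in = -74, V_reset = -87.2, t_ref = 2)
  } else {
    list(V_rest = -85.4, V_thresh = -50, C_m = 159, g_L = 4.5,
         tau_syn_ex = 5, tau_syn_in = 10,
         E_ex = 0, E_in = -74, V_reset = -85.4, t_ref = 2)
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p$type <- type
  validate_neuron_parameters(p)
  structure(p, class = "neuron_parameters")
}

validate_neuron_parameters <- function(p) {
  stopifnot(p$V_rest < p$V_thresh, p$C_m > 0, p$g_L > 0,
            p$tau_syn_ex > 0, p$tau_syn_in > 0,
            p$E_in <= p$V_thresh, p$V_thresh < p$E_ex, p$t_ref >= 0)
  invisible(p)
}

#' Rheobase current of a conductance-LIF neuron
#'
#' Minimal constant current that reaches threshold:
#' `g_L * (V_thresh - V_rest)`. With default parameters: 334.8 pA for D1,
#' 159.3 pA for D2.
#'
#' @param params A [msn_parameters()] object.
#' @return Current in pA.
#' @export
rheobase <- function(params) params$g_L * (params$V_thresh - params$V_rest)

#' Background input parameters
#'
#' Independent excitatory Poisson spike trains delivered one-per-neuron.
#' D1-MSNs receive a higher rate than D2-MSNs to compensate for their lower
#' excitability and stronger inhibition from D2-MSNs, tuned so that the D1
#' population still fires below the D2 population on average.
#'
#' Each neuron receives `n_sources` independent such generators (equivalent
#' to one generator at `n_sources` times the rate). A single 80 spikes/s x
#' 2.5 nS source cannot depolarise an MSN (rheobase 335/159 pA) anywhere
#' near threshold, so the multiplicity is the calibration knob: the default
#' of 4 restores the intended fluctuation-driven operating point (D1 about
#' 0.5 spikes/s, D2 about 1.4 spikes/s under background only).
#'
#' @param rate_D1,rate_D2 Poisson rates in spikes/s per source (defaults 80
#'   and 57).
#' @param weight_nS Synaptic conductance jump per background spike (2.5 nS).
#' @param n_sources Independent sources per neuron (default 4).
#' @return A data.frame with columns `type`, `rate_hz`, `weight_nS`,
#'   `n_sources`.
#' @export
background_input <- function(rate_D1 = 80, rate_D2 = 57, weight_nS = 2.5,
                             n_sources = 4L) {
  stopifnot(rate_D1 >= 0, rate_D2 >= 0, weight_nS >= 0, n_sources >= 0)
  data.frame(type = c("D1", "D2"), rate_hz = c(rate_D1, rate_D2),
             weight_nS = weight_nS, n_sources = as.integer(n_sources))
}

#' Motor transformation parameters
#'
#' Constants of the spike-to-motor readout: per-type scaling factors
#' (`S_D1 = 2`, `S_D2 = 0.4`, giving more weight to the sparse D1 activity),
#' population sizes of the designated action channels, and the time constant
#' of the exponential rate filter (200 ms).
#'
#' @param S_D1,S_D2 Scaling constants of the action equations.
#' @param N_D1,N_D2 Number of D1/D2 neurons per channel.
#' @param tau_ms Motor filter time constant in ms.
#' @param v_max Maximal linear velocity in m/s (upper bound of the sigmoid).
#' @return A list of class `motor_parameters`.
#' @export
motor_parameters <- function(S_D1 = 2.0, S_D2 = 0.4, N_D1 = 40L, N_D2 = 40L,
                             tau_ms = 200, v_max = 2.0) {
  stopifnot(S_D1 > 0, S_D2 > 0, N_D1 > 0, N_D2 > 0, tau_ms > 0, v_max > 0)
  structure(list(S_D1 = S_D1, S_D2 = S_D2, N_D1 = as.integer(N_D1),
                 N_D2 = as.integer(N_D2), tau_ms = tau_ms, v_max = v_max),
            class = "motor_parameters")
}
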