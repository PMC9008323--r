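#' Conductance-based LIF neuron parameters
#'
#' Parameter set for a leaky integrate-and-fire neuron with an excitatory
#' (and optional inhibitory) conductance channel and an adaptive firing
#' threshold. The membrane obeys
#' \deqn{\tau_m \frac{dV}{dt} = -(V - V_L) - \frac{g_E}{g_L}(V - V_E)
#'       - \frac{g_I}{g_L}(V - V_I)}
#' where conductances are expressed in units of the leak conductance
#' \eqn{g_L}, so only the ratio enters the dynamics. Each synaptic channel
#' decays exponentially (\eqn{\tau_E \, dg_E/dt = -g_E}) and is incremented
#' by the synaptic weight when a presynaptic spike arrives. On a threshold
#' crossing the membrane is reset to \eqn{V_L}, a refractory period of
#' \code{T0} ms begins, and the firing threshold jumps by
#' \code{V_thr_delta} before decaying back toward \code{V_thr_base} with
#' time constant \code{tau_thr} (spike-rate homeostasis).
#'
#' @param tau_m membrane time constant, ms (the ratio \eqn{C_m/g_L}).
#' @param V_L leak (and reset) potential, mV.
#' @param V_E excitatory reversal potential, mV.
#' @param V_I inhibitory reversal potential, mV.
#' @param tau_E excitatory conductance decay time constant, ms.
#' @param tau_I inhibitory conductance decay time constant, ms.
#' @param V_thr_base resting firing threshold, mV.
#' @param V_thr_delta per-spike threshold increment, mV (0 disables the
#'   adaptive threshold).
#' @param tau_thr threshold decay time constant, ms.
#' @param T0 absolute refractory period, ms. During the refractory period
#'   the membrane is clamped at \code{V_L} and the neuron cannot fire.
#' @param strict_refractory if \code{TRUE}, synaptic increments arriving
#'   during the refractory period are discarded as well; by default
#'   conductance keeps accumulating and only integration and firing are
#'   suspended.
#' @return an object of class \code{neuron_params}.
#' @export
#' @examples
#' p <- neuron_params()
#' s <- neuron_state(p)
#' s <- deliver_spike(s, 0.3)
#' s <- decay_neuron(s, p, dt = 1)
neuron_params <- function(tau_m = 20, V_L = -65, V_E = 0, V_I = -80,
                          tau_E = 5, tau_I = 10,
                          V_thr_base = -52, V_thr_delta = 0.05,
                          tau_thr = 1e4, T0 = 5,
                          strict_refractory = FALSE) {
  stopifnot(tau_m > 0, tau_E > 0, tau_I > 0, tau_thr > 0, T0 >= 0,
            V_thr_delta >= 0)
  if (!(V_E > V_thr_base && V_thr_base > V_L))
    stop("require V_E > V_thr_base > V_L for an excitable neuron")
  structure(list(tau_m = tau_m, V_L = V_L, V_E = V_E, V_I = V_I,
                 tau_E = tau_E, tau_I = tau_I,
                 V_thr_base = V_thr_base, V_thr_delta = V_thr_delta,
                 tau_thr = tau_thr, T0 = T0,
                 strict_refractory = isTRUE(strict_refractory)),
            class = "neuron_params")
}

#' Initial state of a single LIF neuron
#'
#' @param params a \code{\link{neuron_params}} object.
#' @return a \code{neuron_state} list with membrane potential \code{V} at
#'   rest, zero conductances, threshold at base, no refractory time, and
#'   \code{t_last_spike = -Inf} (the "never spiked" sentinel; any finite
#'   time minus \code{-Inf} is \code{Inf}, the never-spiked limit used by
#'   the plasticity rule).
#' @export
neuron_state <- function(params) {
  structure(list(V = params$V_L, g_E = 0, g_I = 0,
                 V_thr = params$V_thr_base,
                 t_ref_left = 0, t_last_spike = -Inf),
            class = "neuron_state")
}

## Vectorised membrane update with conductances held constant over the step
## at their exact step-average, g * (tau/dt) * (1 - exp(-dt/tau)) (the mean
## of the exponentially decaying conductance across the interval). Then
## dV/dt = -((1 + gE + gI) V - (VL + gE VE + gI VI)) / tau_m
## is linear in V, so V relaxes exponentially toward
## Vinf = (VL + gE VE + gI VI) / (1 + gE + gI) with rate (1+gE+gI)/tau_m.
.integrate_V <- function(V, g_E, g_I, params, dt) {
  gE <- g_E * (params$tau_E / dt) * (1 - exp(-dt / params$tau_E))
  gI <- g_I * (params$tau_I / dt) * (1 - exp(-dt / params$tau_I))
  gtot <- 1 + gE + gI
  Vinf <- (params$V_L + gE * params$V_E + gI * params$V_I) / gtot
  Vinf + (V - Vinf) * exp(-dt * gtot / params$tau_m)
}

#' Advance a neuron's passive dynamics by one time step
#'
#' Applies exact exponential decay to the synaptic conductances and the
#' adaptive threshold, and integrates the membrane equation with the
#' conductances held at their start-of-step values (piecewise-constant
#' conductance). No spikes are delivered here; incoming spikes are applied
#' at step boundaries by \code{\link{deliver_spike}}. While refractory, the
#' membrane is clamped at \code{V_L} and the remaining refractory time is
#' reduced by \code{dt}.
#'
#' @param state a \code{\link{neuron_state}}.
#' @param params a \code{\link{neuron_params}}.
#' @param dt step length, ms; must be positive.
#' @return the updated state.
#' @export
decay_neuron <- function(state, params, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  if (state$t_ref_left > 0) {
    state$V <- params$V_L
    state$t_ref_left <- max(0, state$t_ref_left - dt)
  } else {
    state$V <- .integrate_V(state$V, state$g_E, state$g_I, params, dt)
  }
  state$g_E <- state$g_E * exp(-dt / params$tau_E)
  state$g_I <- state$g_I * exp(-dt / params$tau_I)
  state$V_thr <- params$V_thr_base +
    (state$V_thr - params$V_thr_base) * exp(-dt / params$tau_thr)
  state
}

#' Deliver a presynaptic spike to a neuron
#'
#' Increments the excitatory conductance by the synaptic weight (in units
#' of the leak conductance). Several spikes arriving within one step
#' superpose linearly. The inhibitory channel is addressed with
#' \code{channel = "inhibitory"} and increments \code{g_I} instead.
#'
#' @param state a \code{\link{neuron_state}}.
#' @param weight synaptic weight, dimensionless; must be non-negative.
#' @param channel \code{"excitatory"} (default) or \code{"inhibitory"}.
#' @return the updated state.
#' @export
deliver_spike <- function(state, weight, channel = c("excitatory", "inhibitory")) {
  channel <- match.arg(channel)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0)
    stop("weight must be a single non-negative number")
  if (channel == "excitatory") state$g_E <- state$g_E + weight
  else state$g_I <- state$g_I + weight
  state
}

#' Threshold crossing, reset and threshold adaptation
#'
#' If the membrane potential exceeds the current threshold and the neuron
#' is not refractory, the neuron fires: \code{V} is reset to \code{V_L},
#' the refractory clock is set to \code{T0}, the threshold jumps by
#' \code{V_thr_delta}, and the spike time is recorded. Otherwise the state
#' is returned unchanged.
#'
#' @param state a \code{\link{neuron_state}}.
#' @param params a \code{\link{neuron_params}}.
#' @param t current time, ms.
#' @return a list with elements \code{state} and \code{fired} (logical).
#' @export
check_fire <- function(state, params, t) {
  fired <- state$t_ref_left <= 0 && state$V > state$V_thr
  if (fired) {
    state$V <- params$V_L
    state$t_ref_left <- params$T0
    state$V_thr <- state$V_thr + params$V_thr_delta
    state$t_last_spike <- t
  }
  list(state = state, fired = fired)
}
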