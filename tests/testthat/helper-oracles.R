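## Independent oracles used by the tests. These deliberately avoid the
## package's integration path.

## Explicit-Euler simulation of a single conductance-based LIF neuron with
## dynamic threshold, driven by an input spike script through one synapse.
## Spikes are delivered on the (fine) grid at ceiling(t/dt); an increment
## affects the membrane from the following substep.
euler_lif <- function(times, w, p, duration, dt = 0.01) {
  n <- ceiling(duration / dt)
  add <- numeric(n)
  dstep <- pmax(1L, ceiling(times / dt))
  for (s in dstep[dstep <= n]) add[s] <- add[s] + w
  V <- p$V_L; gE <- 0; Vthr <- p$V_thr_base; ref <- 0
  out <- numeric(0)
  for (s in seq_len(n)) {
    t <- s * dt
    if (ref > 0) {
      V <- p$V_L
      ref <- max(0, ref - dt)
    } else {
      V <- V + dt * (-(V - p$V_L) - gE * (V - p$V_E)) / p$tau_m
    }
    gE <- gE - dt * gE / p$tau_E
    Vthr <- Vthr - dt * (Vthr - p$V_thr_base) / p$tau_thr
    gE <- gE + add[s]
    if (ref <= 0 && V > Vthr) {
      out <- c(out, t)
      V <- p$V_L
      ref <- p$T0
      Vthr <- Vthr + p$V_thr_delta
    }
  }
  out
}

## Closed-form expected cumulative weight change for equal-rate independent
## Poisson pre/post trains: at a post spike the time since the last pre
## spike is exponential with rate r (memoryless), so
## E[exp(-ISI/tau_p)] = r tau_p / (1000 + r tau_p) with r in Hz and tau_p
## in ms, and pre-never-spiked contributes the exact zero limit of the
## same expression. Expected number of post spikes is r * duration.
expected_total_dw <- function(rate_hz, params, duration_s, w0) {
  rt <- rate_hz * params$tau_p
  per_spike <- params$eta * w0 * (1 - w0) *
    (params$alpha + params$beta * rt / (1000 + rt))
  rate_hz * duration_s * per_spike
}

## deterministic strong-volley input script: every volley drives a steep
## suprathreshold crossing, so spike times are insensitive to step size
volley_script <- function() {
  v <- seq(20, 980, by = 30) + 5 * sin(seq_len(33))
  sort(c(v, v + 0.7, v + 1.4))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

## minimal one-synapse network: one source neuron -> one LIF neuron
single_synapse_net <- function(w, params = neuron_params(), dt = 0.5,
                               plasticity = NULL) {
  build_network(
    list(layer("in", 1, type = "source"), layer("out", 1, params)),
    list(projection("in", "out", matrix(w, 1, 1), plasticity = plasticity)),
    dt = dt, seed = 1L)
}
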