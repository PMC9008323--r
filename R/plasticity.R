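#' Parameters of the modified STDP rule
#'
#' The weight update applied to a synapse when its postsynaptic neuron
#' fires is
#' \deqn{\Delta w = \eta\,(\alpha + \beta e^{-ISI/\tau_p})\, w (1 - w)
#'       \quad \mathrm{if}\; ISI > 0, \qquad \Delta w = 0 \;\mathrm{else},}
#' with \eqn{ISI = t_{post} - t_{pre}} the difference between the most
#' recent post- and presynaptic spike times (nearest-spike pairing, not
#' all-to-all). The negative bias \eqn{\alpha} realises heterosynaptic
#' long-term depression: synapses whose presynaptic neuron has been silent
#' for a long time (or has never spiked, the \eqn{ISI \to \infty} limit)
#' are depressed by \eqn{\eta \alpha w (1-w)} every time the postsynaptic
#' neuron fires. The multiplicative factor \eqn{w(1-w)} soft-bounds the
#' weight to \eqn{[0, 1]}. For \eqn{\alpha < 0 < \beta} the rule
#' potentiates exactly when \eqn{0 < ISI < \tau_p \ln(\beta / -\alpha)}.
#'
#' @param eta learning rate, dimensionless, positive.
#' @param alpha bias term, dimensionless; normally negative (heterosynaptic
#'   LTD). A warning is issued when the LTP/LTD boundary is degenerate
#'   (\code{alpha >= 0} or \code{alpha + beta <= 0}).
#' @param beta LTP amplitude, dimensionless; normally positive.
#' @param tau_p LTP time constant, ms, positive.
#' @return an object of class \code{plasticity_params}.
#' @export
#' @examples
#' pp <- plasticity_params(eta = 0.01, alpha = -0.1, beta = 1, tau_p = 50)
#' delta_w(5, 0.5, pp)     # short positive ISI: potentiation
#' delta_w(300, 0.5, pp)   # long ISI: depression
#' delta_w(-10, 0.5, pp)   # pre after post: no change
#' delta_w(Inf, 0.5, pp)   # silent presynaptic neuron: pure LTD
plasticity_params <- function(eta, alpha, beta, tau_p) {
  stopifnot(is.numeric(eta), eta > 0, is.numeric(tau_p), tau_p > 0)
  if (alpha >= 0 || alpha + beta <= 0)
    warning("no LTP/LTD boundary: expected alpha < 0 and alpha + beta > 0")
  structure(list(eta = eta, alpha = alpha, beta = beta, tau_p = tau_p),
            class = "plasticity_params")
}

#' Weight change for a given pre/post spike-time difference
#'
#' Vectorised over \code{isi} and \code{w} (recycled to a common length).
#' \code{isi = Inf} encodes a presynaptic neuron that has never spiked and
#' yields the pure heterosynaptic-LTD limit
#' \eqn{\eta \alpha w (1-w)}. \code{isi <= 0} (including a simultaneous
#' pre/post pair) yields exactly 0.
#'
#' @param isi postsynaptic minus presynaptic last-spike time, ms; may be
#'   \code{Inf}.
#' @param w current weight(s), each in \eqn{[0, 1]}.
#' @param params a \code{\link{plasticity_params}} object.
#' @return the weight change(s), same length as the recycled inputs.
#' @export
delta_w <- function(isi, w, params) {
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  fac <- params$alpha + params$beta * exp(-isi / params$tau_p)
  fac[isi <= 0] <- 0
  params$eta * fac * w * (1 - w)
}

#' ISI at which the rule changes sign
#'
#' For \eqn{\alpha < 0 < \beta} the update is zero at
#' \eqn{ISI^{*} = \tau_p \ln(\beta / -\alpha)}: potentiation below,
#' depression above.
#'
#' @param params a \code{\link{plasticity_params}}.
#' @return the zero-crossing ISI in ms (\code{NA} if no sign change).
#' @export
isi_zero_crossing <- function(params) {
  if (params$alpha >= 0 || params$alpha + params$beta <= 0) return(NA_real_)
  params$tau_p * log(params$beta / (-params$alpha))
}

## nearest preceding pre spike for each post spike; 0 index -> never (Inf ISI)
.nearest_isi <- function(t_post, t_pre) {
  idx <- findInterval(t_post, t_pre)
  isi <- rep(Inf, length(t_post))
  has <- idx > 0L
  isi[has] <- t_post[has] - t_pre[idx[has]]
  isi
}

#' Cumulative weight drift under independent Poisson pre/post firing
#'
#' Monte-Carlo characterisation of the plasticity rule: for each firing
#' rate, independent homogeneous Poisson presynaptic and postsynaptic
#' spike trains of the same rate are simulated for \code{duration}
#' seconds, the rule is applied at every postsynaptic spike (nearest-spike
#' ISI against the latest presynaptic spike), and the cumulative weight
#' change is accumulated. Two accumulation modes are provided:
#' \code{"live"} lets the weight evolve from \code{w0} (soft bounds
#' active, as during training), \code{"fixed"} evaluates every update at
#' \code{w0} and sums the increments (linearised drift, directly
#' comparable to the closed-form expectation over the exponential ISI
#' density). Low rates produce net depression, high rates net
#' potentiation; the crossover rate decreases as \code{tau_p} grows.
#'
#' @param params a \code{\link{plasticity_params}}.
#' @param rates firing rates to probe, Hz (pre rate = post rate).
#' @param duration simulated time per trial, seconds.
#' @param n_trials independent trials per rate.
#' @param w0 starting weight.
#' @param mode \code{"live"} or \code{"fixed"} (see above).
#' @param seed integer seed; every trial draws from one seeded stream.
#' @return a data frame with one row per rate: \code{rate_hz},
#'   \code{mean_dw}, \code{sd_dw}, \code{n_trials}, \code{mode},
#'   \code{w0}, \code{tau_p_ms}, \code{seed}.
#' @export
freq_sweep <- function(params, rates, duration = 100, n_trials = 50,
                       w0 = 0.5, mode = c("live", "fixed"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(rates) == 0L) stop("empty rate list")
  stopifnot(duration > 0, n_trials >= 1, w0 >= 0, w0 <= 1)
  set.seed(seed)
  dur_ms <- duration * 1000
  out <- lapply(rates, function(r) {
    dws <- vapply(seq_len(n_trials), function(k) {
      if (r <= 0) return(0)
      pre <- poisson_train(r, dur_ms)
      post <- poisson_train(r, dur_ms)
      if (length(post) == 0L) return(0)
      isi <- .nearest_isi(post, pre)
      fac <- params$eta * (params$alpha + params$beta * exp(-isi / params$tau_p))
      fac[isi <= 0] <- 0
      if (mode == "fixed") {
        sum(fac) * w0 * (1 - w0)
      } else {
        w <- w0
        for (f in fac) w <- w + f * w * (1 - w)
        w - w0
      }
    }, numeric(1))
    data.frame(rate_hz = r, mean_dw = mean(dws),
               sd_dw = stats::sd(dws), n_trials = n_trials)
  })
  out <- do.call(rbind, out)
  out$mode <- mode
  out$w0 <- w0
  out$tau_p_ms <- params$tau_p
  out$seed <- seed
  out
}
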