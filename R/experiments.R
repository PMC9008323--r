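## ---------------------------------------------------------------------------
## Reproducible experiment pipelines: plasticity frequency sweep, Pavlov
## conditioning demo, iris hold-out classification, synthetic spike-pattern
## classification, and the digit (image) pipeline.
## ---------------------------------------------------------------------------

#' Frequency sweep of the plasticity rule across LTP time constants
#'
#' Runs \code{\link{freq_sweep}} for each \code{tau_p} and summarises the
#' mean cumulative weight change per rate, together with the rate at
#' which the mean drift changes sign (linear interpolation between grid
#' points). Defaults follow the rule characterisation protocol:
#' \eqn{\alpha = -0.1}, \eqn{\beta = 1}, \eqn{\eta = 0.01}, 100 s of
#' equal-rate independent Poisson pre/post firing, 50 trials per rate.
#'
#' @param tau_p LTP time constants to probe, ms.
#' @param rates rate grid, Hz.
#' @param eta,alpha,beta plasticity constants.
#' @param duration seconds per trial.
#' @param n_trials trials per rate.
#' @param w0 starting weight.
#' @param mode accumulation mode, see \code{\link{freq_sweep}}.
#' @param seed integer seed.
#' @return list with \code{sweep} (tidy data frame over rate x tau_p) and
#'   \code{zero_crossings} (data frame tau_p_ms, rate_hz).
#' @export
run_fig_sweep <- function(tau_p = c(10, 20, 50, 100),
                          rates = c(0.5, 1, 2, 4, 8, 16, 32, 50),
                          eta = 0.01, alpha = -0.1, beta = 1,
                          duration = 100, n_trials = 50, w0 = 0.5,
                          mode = "live", seed = 1L) {
  sweeps <- lapply(seq_along(tau_p), function(i) {
    pp <- plasticity_params(eta, alpha, beta, tau_p[i])
    freq_sweep(pp, rates, duration, n_trials, w0, mode,
               seed = seed + i)
  })
  sweep <- do.call(rbind, sweeps)
  zc <- vapply(tau_p, function(tp) {
    s <- sweep[sweep$tau_p_ms == tp, ]
    .sign_change_rate(s$rate_hz, s$mean_dw)
  }, numeric(1))
  list(sweep = sweep,
       zero_crossings = data.frame(tau_p_ms = tau_p, rate_hz = zc))
}

## first negative-to-positive sign change, linearly interpolated
.sign_change_rate <- function(x, y) {
  for (i in seq_len(length(y) - 1L)) {
    if (y[i] < 0 && y[i + 1L] >= 0)
      return(x[i] + (x[i + 1L] - x[i]) * (-y[i]) / (y[i + 1L] - y[i]))
  }
  NA_real_
}

#' Pavlov conditioning demonstration
#'
#' A minimal associative-learning fixture: one unconditioned input
#' ("meat", strong frozen synapse), one to-be-conditioned input ("bell")
#' and one never-paired input ("other sound"), both with weak plastic
#' synapses onto a single output ("drooling") neuron. Three phases are
#' simulated: pre-pairing (bell alone), pairing (meat + bell together,
#' \code{n_pair} presentations), and post-pairing (bell alone again).
#' Pairing potentiates the bell synapse (the bell and the meat-driven
#' output fire together) while the silent never-paired input is depressed
#' by heterosynaptic LTD every time the output fires.
#'
#' @param n_pair number of paired presentations.
#' @param stim_rate input firing rate during a presentation, Hz.
#' @param w0 initial plastic weight of the bell and other-sound synapses.
#' @param uncond_weight frozen weight of the meat synapse.
#' @param eta,alpha,beta,tau_p plasticity constants for the conditioning.
#' @param t_present,t_gap presentation and gap durations, ms.
#' @param n_probe bell-alone presentations in the pre and post phases.
#' @param output_params \code{\link{neuron_params}} of the drooling
#'   neuron; threshold adaptation is off by default so the conditioned
#'   response isolates the synaptic change.
#' @param seed integer seed.
#' @return list with \code{weights} (per-presentation trajectory of the
#'   bell and other synapses), \code{pre_spikes} / \code{post_spikes}
#'   (output spike counts per bell-alone presentation before and after
#'   pairing), and the final \code{network}.
#' @export
run_pavlov <- function(n_pair = 40, stim_rate = 100, w0 = 0.25,
                       uncond_weight = 2, eta = 0.05, alpha = -0.1,
                       beta = 1, tau_p = 50, t_present = 200, t_gap = 50,
                       n_probe = 5,
                       output_params = neuron_params(V_thr_delta = 0),
                       seed = 1L) {
  pp <- plasticity_params(eta, alpha, beta, tau_p)
  net <- build_network(
    list(layer("meat", 1, type = "source"),
         layer("sounds", 2, type = "source"),   # 1 = bell, 2 = other
         layer("drool", 1, output_params)),
    list(projection("meat", "drool", matrix(uncond_weight, 1, 1)),
         projection("sounds", "drool", matrix(w0, 2, 1), plasticity = pp)),
    seed = seed)
  set.seed(seed)
  bell <- list(kind = "rate", rates = c(stim_rate, 0))
  ## probes use deterministic periodic spiking so the conditioned response
  ## is an all-or-none readout rather than a Poisson draw
  bell_probe <- list(kind = "rate", rates = c(stim_rate, 0), regular = TRUE)
  probe_phase <- function(net) {
    counts <- integer(n_probe)
    for (i in seq_len(n_probe)) {
      r <- run_network(net, list(sounds = bell_probe), t_present,
                       record = "drool", learn = FALSE)
      net <- reset_interval(r$network, t_gap)
      counts[i] <- nrow(r$spikes)
    }
    list(network = net, counts = counts)
  }
  pre <- probe_phase(net)
  net <- pre$network
  wtraj <- matrix(NA_real_, n_pair + 1L, 2,
                  dimnames = list(NULL, c("bell", "other")))
  wtraj[1, ] <- net$projections[["sounds->drool"]]$w[, 1]
  for (i in seq_len(n_pair)) {
    stim <- list(meat = list(kind = "rate", rates = stim_rate),
                 sounds = bell)
    r <- run_network(net, stim, t_present, record = "drool", learn = TRUE)
    net <- reset_interval(r$network, t_gap)
    wtraj[i + 1L, ] <- net$projections[["sounds->drool"]]$w[, 1]
  }
  post <- probe_phase(net)
  list(weights = wtraj, pre_spikes = pre$counts, post_spikes = post$counts,
       network = post$network)
}

#' Synthetic labelled spike-pattern dataset
#'
#' Desk-scale stand-in for image data: each class is a fixed spike
#' pattern over \code{n_inputs} input neurons — a random subset
#' (\code{active_fraction}) fires at \code{rate_hi} Hz, the rest at
#' \code{rate_lo} Hz. A fraction \code{overlap} of each class's active
#' set is shared between all classes. Samples of a class share the rate
#' pattern; only the Poisson realisation differs between presentations.
#'
#' @param n_classes number of classes.
#' @param n_inputs input-layer size.
#' @param active_fraction fraction of inputs active per class.
#' @param rate_hi,rate_lo active / background firing rates, Hz.
#' @param overlap fraction of the active set shared across classes, in
#'   \eqn{[0, 1]}.
#' @param n_per_class samples per class.
#' @param seed integer seed (same seed, same dataset).
#' @return list with \code{samples} (labelled stimulus list for layer
#'   \code{"input"}), \code{patterns} (inputs x classes rate matrix) and
#'   the generating arguments.
#' @export
make_synthetic_patterns <- function(n_classes, n_inputs,
                                    active_fraction = 0.2, rate_hi = 40,
                                    rate_lo = 0, overlap = 0,
                                    n_per_class = 20, seed = 1L) {
  stopifnot(overlap >= 0, overlap <= 1, rate_hi > rate_lo, rate_lo >= 0)
  n_active <- max(1L, round(active_fraction * n_inputs))
  n_shared <- round(overlap * n_active)
  n_own <- n_active - n_shared
  if (n_shared + n_classes * n_own > n_inputs)
    stop("infeasible overlap/active_fraction for n_inputs")
  set.seed(seed)
  pool <- sample.int(n_inputs)
  shared <- pool[seq_len(n_shared)]
  rest <- if (n_shared > 0) pool[-seq_len(n_shared)] else pool
  patterns <- matrix(rate_lo, n_inputs, n_classes)
  for (k in seq_len(n_classes)) {
    own <- rest[(k - 1L) * n_own + seq_len(n_own)]
    patterns[c(shared, own), k] <- rate_hi
  }
  samples <- list()
  for (k in seq_len(n_classes))
    for (j in seq_len(n_per_class))
      samples[[length(samples) + 1L]] <- list(
        stimulus = list(input = list(kind = "rate", rates = patterns[, k])),
        label = k)
  list(samples = samples, patterns = patterns,
       spec = list(n_classes = n_classes, n_inputs = n_inputs,
                   active_fraction = active_fraction, rate_hi = rate_hi,
                   rate_lo = rate_lo, overlap = overlap,
                   n_per_class = n_per_class, seed = seed))
}

#' Single-layer supervised classification of synthetic spike patterns
#'
#' Builds an input -> output network with a teacher layer, trains with
#' ALSA on a training split of a synthetic pattern set and evaluates on a
#' held-out split. With disjoint class supports (zero overlap, silent
#' background) this is a fully separable task.
#'
#' @param patterns result of \code{\link{make_synthetic_patterns}}.
#' @param train_frac fraction of samples (per class order as generated)
#'   used for training.
#' @param protocol a \code{\link{training_protocol}}.
#' @param init weight-initialisation range for the plastic projection.
#' @param eta,alpha,beta,tau_p plasticity constants.
#' @param teacher_weight frozen teacher synapse weight.
#' @param output_params \code{\link{neuron_params}} for the output layer.
#' @param seed weight-initialisation seed.
#' @return list with \code{accuracy}, \code{confusion} and \code{network}.
#' @export
run_synthetic <- function(patterns, train_frac = 0.7,
                          protocol = training_protocol(),
                          init = c(0.2, 0.3), eta = 0.015, alpha = -0.1,
                          beta = 1, tau_p = 50, teacher_weight = 2,
                          output_params = neuron_params(V_thr_delta = 0.1,
                                                        tau_thr = 2000),
                          seed = 1L) {
  k <- patterns$spec$n_classes
  n_in <- patterns$spec$n_inputs
  labels <- vapply(patterns$samples, `[[`, integer(1), "label")
  idx_train <- unlist(lapply(seq_len(k), function(cl) {
    i <- which(labels == cl)
    i[seq_len(round(train_frac * length(i)))]
  }))
  idx_test <- setdiff(seq_along(labels), idx_train)
  pp <- plasticity_params(eta, alpha, beta, tau_p)
  net <- build_network(
    list(layer("input", n_in, type = "source"),
         layer("output", k, output_params)),
    list(projection("input", "output", init, plasticity = pp)),
    seed = seed)
  net <- attach_teacher(net, "output", k, weight = teacher_weight)
  set.seed(seed)
  order_train <- sample(idx_train)
  tr <- train_supervised(net, patterns$samples[order_train], protocol)
  ev <- evaluate_network(tr$network, patterns$samples[idx_test], protocol)
  list(accuracy = ev$accuracy, confusion = ev$confusion,
       network = tr$network, log = tr$log)
}

## class-balanced assignment of iris-style data into 5 groups
.holdout_groups <- function(labels, n_groups = 5L, seed = 1L) {
  set.seed(seed)
  g <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))
    g[i] <- rep(seq_len(n_groups), length.out = length(i))
  }
  g
}

#' Iris hold-out classification with ALSA
#'
#' The 150-flower Fisher iris table (bundled with R) is encoded with four
#' groups of triangle-code neurons (12 per feature, 48 in total, peak
#' rate \code{h} = 20 Hz, half-width \code{w} = 2 center spacings), fed
#' through a fully plastic 48 x 3 projection to three output neurons,
#' and trained with a 20 Hz teacher. The data are split into five
#' class-balanced groups of 30; four groups train, the held-out group is
#' the test set. Several trials differing only in the random initial
#' weights are run, and the confusion matrix is averaged over trials.
#'
#' @param x feature matrix (default: the four iris measurements).
#' @param labels integer class labels in 1..3 (default: iris species).
#' @param n_trials number of trials (different weight-init seeds).
#' @param epochs passes over the 120 training samples per trial.
#' @param fold index (1-5) of the held-out group.
#' @param rotate_folds if \code{TRUE} trial \code{t} holds out fold
#'   \code{((t-1) mod 5) + 1} instead of the fixed \code{fold}.
#' @param teacher_rate teacher firing rate, Hz.
#' @param n_per_feature,half_width,peak_rate encoder parameters.
#' @param eta,alpha,beta,tau_p plasticity constants.
#' @param init uniform weight-initialisation range.
#' @param teacher_weight frozen teacher synapse weight.
#' @param output_params \code{\link{neuron_params}} of the output layer.
#' @param curve_every if not \code{NULL}, held-out accuracy is also
#'   measured every this many training presentations (accuracy-vs-samples
#'   learning curves; roughly doubles the runtime).
#' @param dt simulation step, ms.
#' @param seed root seed (controls the group split and per-trial streams).
#' @return list with \code{trials} (per-trial fold and final accuracy),
#'   \code{mean_accuracy}, \code{confusion} (trial-averaged), and
#'   \code{curves} (data frame, or NULL).
#' @export
run_iris <- function(x = NULL, labels = NULL, n_trials = 4, epochs = 4,
                     fold = 1, rotate_folds = FALSE, teacher_rate = 20,
                     n_per_feature = 12, half_width = 2, peak_rate = 20,
                     eta = 0.015, alpha = -0.1, beta = 1, tau_p = 50,
                     init = c(0.2, 0.3), teacher_weight = 2,
                     output_params = neuron_params(V_thr_delta = 0.1,
                                                   tau_thr = 5000),
                     eval_encoder = c("regular", "poisson"),
                     curve_every = NULL, dt = 0.5, seed = 1L) {
  eval_encoder <- match.arg(eval_encoder)
  if (is.null(x)) {
    x <- as.matrix(datasets::iris[, 1:4])
    labels <- datasets::iris$Species
  }
  class_names <- if (is.factor(labels)) levels(labels)
                 else as.character(sort(unique(labels)))
  labels <- as.integer(factor(labels))
  stopifnot(ncol(x) >= 1, length(labels) == nrow(x))
  k <- length(unique(labels))
  groups <- .holdout_groups(labels, 5L, seed)
  pp <- plasticity_params(eta, alpha, beta, tau_p)
  n_code <- ncol(x) * n_per_feature

  trials <- data.frame(trial = seq_len(n_trials), fold = NA_integer_,
                       accuracy = NA_real_)
  conf_sum <- matrix(0, k, k + 1L)
  curves <- list()
  for (t in seq_len(n_trials)) {
    f <- if (rotate_folds) ((t - 1L) %% 5L) + 1L else fold
    trials$fold[t] <- f
    idx_train <- which(groups != f)
    idx_test <- which(groups == f)
    enc_train <- encode_features(x[idx_train, , drop = FALSE],
                                 n_per_feature, half_width, peak_rate)
    enc_test <- encode_features(x[idx_test, , drop = FALSE],
                                n_per_feature, half_width, peak_rate,
                                ranges = enc_train$ranges)
    as_samples <- function(rates, labs, regular) lapply(seq_along(labs),
      function(i) list(stimulus = list(encoding = list(
                         kind = "rate", rates = rates[i, ],
                         regular = regular)),
                       label = labs[i]))
    train_samples <- as_samples(enc_train$rates, labels[idx_train], FALSE)
    test_samples <- as_samples(enc_test$rates, labels[idx_test],
                               eval_encoder == "regular")

    trial_seed <- seed * 100L + t
    net <- build_network(
      list(layer("encoding", n_code, type = "source"),
           layer("output", k, output_params)),
      list(projection("encoding", "output", init, plasticity = pp)),
      dt = dt, seed = trial_seed)
    net <- attach_teacher(net, "output", k, weight = teacher_weight)

    proto <- training_protocol(teacher_rate = teacher_rate, epochs = 1,
                               seed = trial_seed)
    seen <- 0L
    set.seed(trial_seed)
    ord_all <- lapply(seq_len(epochs), function(e) sample(length(train_samples)))
    for (ep in seq_len(epochs)) {
      ord <- ord_all[[ep]]
      if (is.null(curve_every)) {
        proto$seed <- trial_seed + ep
        tr <- train_supervised(net, train_samples[ord], proto)
        net <- tr$network
        seen <- seen + length(ord)
      } else {
        chunks <- split(ord, ceiling(seq_along(ord) / curve_every))
        for (ch in chunks) {
          proto$seed <- trial_seed + ep * 131L + seen
          tr <- train_supervised(net, train_samples[ch], proto)
          net <- tr$network
          seen <- seen + length(ch)
          ev <- evaluate_network(net, test_samples, proto)
          curves[[length(curves) + 1L]] <-
            data.frame(trial = t, fold = f, samples_seen = seen,
                       accuracy = ev$accuracy)
        }
      }
    }
    ev <- evaluate_network(net, test_samples,
                           training_protocol(teacher_rate = 0,
                                             seed = trial_seed + 997L))
    trials$accuracy[t] <- ev$accuracy
    conf_sum <- conf_sum + ev$confusion
  }
  dimnames(conf_sum) <- list(true = class_names,
                             pred = c(class_names, "abstain"))
  list(trials = trials, mean_accuracy = mean(trials$accuracy),
       confusion = conf_sum / n_trials,
       curves = if (length(curves)) do.call(rbind, curves) else NULL)
}
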