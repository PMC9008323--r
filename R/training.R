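#' Presentation protocol for training and evaluation
#'
#' @param t_present stimulus duration per sample, ms.
#' @param t_gap silent interval between samples, ms (conductances and
#'   membranes relax; adaptive thresholds decay but are not reset).
#' @param teacher_rate firing rate of the active teacher neuron during
#'   supervised training, Hz.
#' @param epochs passes over the sample list.
#' @param seed integer seed; set once at the start of a training or
#'   evaluation run so Poisson encoders and teacher spikes are
#'   reproducible.
#' @return a \code{training_protocol} object.
#' @export
training_protocol <- function(t_present = 200, t_gap = 50,
                              teacher_rate = 20, epochs = 1, seed = 1L) {
  stopifnot(t_present > 0, t_gap >= 0, teacher_rate >= 0, epochs >= 1)
  structure(list(t_present = t_present, t_gap = t_gap,
                 teacher_rate = teacher_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)), class = "training_protocol")
}

#' Attach a teacher layer to an output layer
#'
#' Adds a source layer with one neuron per class and frozen one-to-one
#' excitatory synapses onto the output layer. During supervised training
#' only the teacher neuron of the current sample's class is driven, which
#' induces spikes in the corresponding output neuron; all weight changes
#' are still produced by the local plasticity rule. The teacher weight is
#' deliberately strong so a single teacher spike reliably drives its
#' output neuron.
#'
#' @param net a \code{snn_network}.
#' @param output_layer name of the output layer; must have exactly
#'   \code{n_classes} neurons.
#' @param n_classes number of classes.
#' @param weight frozen teacher synapse weight (conductance jump per
#'   teacher spike, units of the leak conductance).
#' @return the network with a \code{teacher} layer attached.
#' @export
attach_teacher <- function(net, output_layer, n_classes, weight = 2) {
  if (!is.null(net$teacher)) stop("a teacher layer is already attached")
  if (!output_layer %in% names(net$layers)) stop("unknown output layer")
  if (net$layers[[output_layer]]$size != n_classes)
    stop("output layer size does not match n_classes")
  tl <- layer("teacher", n_classes, type = "source")
  st <- list(V = rep(tl$params$V_L, n_classes),
             g_E = numeric(n_classes), g_I = numeric(n_classes),
             V_thr = rep(tl$params$V_thr_base, n_classes),
             ref = numeric(n_classes), last_spike = rep(-Inf, n_classes))
  net$layers$teacher <- c(tl, st)
  net$projections[[paste0("teacher->", output_layer)]] <-
    list(pre = "teacher", post = output_layer,
         w = diag(weight, n_classes), plasticity = NULL, sign = "excitatory")
  net$teacher <- list(layer = "teacher", output = output_layer,
                      n_classes = n_classes)
  net
}

## one labelled sample = list(stimulus = <named stimulus list>, label = int)
.check_samples <- function(samples, n_classes = NULL) {
  if (!length(samples)) stop("empty sample set")
  for (s in samples) {
    if (is.null(s$stimulus)) stop("sample without stimulus")
    if (!is.null(n_classes) && !is.null(s$label) &&
        (s$label < 1 || s$label > n_classes))
      stop("label out of range")
  }
  invisible(TRUE)
}

#' Supervised training with a teacher layer (ALSA)
#'
#' For each labelled sample the encoded stimulus is presented for
#' \code{t_present} ms while the teacher neuron of the sample's class is
#' driven as a Poisson source at \code{teacher_rate} Hz, inducing spikes
#' in the corresponding output neuron. Synapses from active inputs to the
#' induced output neuron are potentiated (short positive ISI), synapses
#' from silent inputs are depressed (heterosynaptic LTD), and synapses
#' onto output neurons that do not fire are untouched. Samples are
#' separated by a silent, plasticity-frozen gap of \code{t_gap} ms.
#' Setting \code{teacher_rate = 0} makes this identical to
#' \code{\link{train_unsupervised}} on the same seed.
#'
#' @param net a \code{snn_network} with a teacher attached
#'   (\code{\link{attach_teacher}}).
#' @param samples list of samples, each \code{list(stimulus = <named
#'   stimulus list>, label = <class index in 1..n_classes>)}.
#' @param protocol a \code{\link{training_protocol}}.
#' @return a list with \code{network} (trained) and \code{log}, a data
#'   frame with one row per presentation (epoch, sample, label, output
#'   spike counts as a matrix column).
#' @export
train_supervised <- function(net, samples, protocol) {
  if (is.null(net$teacher)) stop("no teacher attached; call attach_teacher()")
  k <- net$teacher$n_classes
  .check_samples(samples, k)
  out_layer <- net$teacher$output
  set.seed(protocol$seed)
  logs <- vector("list", protocol$epochs * length(samples))
  li <- 0L
  for (ep in seq_len(protocol$epochs)) {
    for (si in seq_along(samples)) {
      s <- samples[[si]]
      stim <- s$stimulus
      if (protocol$teacher_rate > 0) {
        tr <- numeric(k)
        tr[s$label] <- protocol$teacher_rate
        stim$teacher <- list(kind = "rate", rates = tr)
      }
      res <- run_network(net, stim, protocol$t_present,
                         record = out_layer, learn = TRUE)
      net <- reset_interval(res$network, protocol$t_gap)
      cnt <- tabulate(res$spikes$neuron[res$spikes$layer == out_layer], k)
      li <- li + 1L
      logs[[li]] <- c(epoch = ep, sample = si, label = s$label, cnt)
    }
  }
  log <- as.data.frame(do.call(rbind, logs))
  names(log) <- c("epoch", "sample", "label",
                  paste0("out", seq_len(k)))
  list(network = net, log = log)
}

#' Unsupervised training (no teacher)
#'
#' The same presentation loop as \code{\link{train_supervised}} but
#' without any teacher drive: postsynaptic firing is determined entirely
#' by the input, lateral inhibition and the adaptive thresholds, and the
#' plastic weights self-organise (winner-take-all feature learning).
#'
#' @param net a \code{snn_network}.
#' @param samples list of samples; labels, if present, are ignored.
#' @param protocol a \code{\link{training_protocol}}.
#' @param record_layer optional layer whose per-presentation spike counts
#'   are logged (e.g. the feature layer, for homeostasis checks).
#' @return list with \code{network} and \code{counts} (presentations x
#'   neurons matrix of spike counts for \code{record_layer}, or NULL).
#' @export
train_unsupervised <- function(net, samples, protocol, record_layer = NULL) {
  .check_samples(samples)
  set.seed(protocol$seed)
  counts <- NULL
  if (!is.null(record_layer))
    counts <- matrix(0L, protocol$epochs * length(samples),
                     net$layers[[record_layer]]$size)
  li <- 0L
  for (ep in seq_len(protocol$epochs)) {
    for (si in seq_along(samples)) {
      res <- run_network(net, samples[[si]]$stimulus, protocol$t_present,
                         record = record_layer %||% character(0), learn = TRUE)
      net <- reset_interval(res$network, protocol$t_gap)
      li <- li + 1L
      if (!is.null(record_layer))
        counts[li, ] <- tabulate(
          res$spikes$neuron[res$spikes$layer == record_layer],
          ncol(counts))
    }
  }
  list(network = net, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict the class of one encoded sample
#'
#' Presents the stimulus for \code{t_present} ms with the teacher silent
#' and plasticity frozen, then reads out the class as the output neuron
#' with the most spikes. Ties are broken by the earliest first spike,
#' then by the lowest neuron index; if no output neuron spikes at all the
#' prediction is \code{NA} (abstention, counted as an error by
#' \code{\link{evaluate_network}}).
#'
#' @param net a trained \code{snn_network}.
#' @param stimulus named stimulus list for the input layer(s).
#' @param protocol a \code{\link{training_protocol}}.
#' @return list with \code{class} (integer or NA), \code{counts},
#'   \code{first_spike} (per-class, ms, Inf if silent), and
#'   \code{network} (state after the presentation and gap).
#' @export
predict_sample <- function(net, stimulus, protocol) {
  if (is.null(net$teacher)) stop("no teacher/output binding; call attach_teacher()")
  out_layer <- net$teacher$output
  k <- net$teacher$n_classes
  res <- run_network(net, stimulus, protocol$t_present,
                     record = out_layer, learn = FALSE)
  net <- reset_interval(res$network, protocol$t_gap)
  sp <- res$spikes[res$spikes$layer == out_layer, ]
  counts <- tabulate(sp$neuron, k)
  first <- rep(Inf, k)
  if (nrow(sp))
    for (j in unique(sp$neuron)) first[j] <- min(sp$time[sp$neuron == j])
  cls <- NA_integer_
  if (any(counts > 0)) {
    best <- which(counts == max(counts))
    if (length(best) > 1L) best <- best[order(first[best], best)][1]
    cls <- best[1]
  }
  list(class = cls, counts = counts, first_spike = first, network = net)
}

#' Accuracy and confusion matrix on labelled samples
#'
#' Evaluation never changes weights (plasticity is frozen during both the
#' presentations and the gaps); adaptive thresholds continue to evolve
#' unless frozen at their trained values with \code{freeze_thresholds}.
#'
#' @param net a trained \code{snn_network}.
#' @param samples labelled samples as in \code{\link{train_supervised}}.
#' @param protocol a \code{\link{training_protocol}}.
#' @param freeze_thresholds if \code{TRUE}, adaptive thresholds are
#'   pinned at their current values for the whole evaluation (the
#'   per-spike increment and decay are disabled by restoring thresholds
#'   after every presentation).
#' @return list with \code{accuracy} (abstentions count as errors),
#'   \code{confusion} (true class rows, predicted columns plus an
#'   \code{abstain} column), \code{predictions}, and \code{network}.
#' @export
evaluate_network <- function(net, samples, protocol, freeze_thresholds = FALSE) {
  if (is.null(net$teacher)) stop("no teacher/output binding")
  k <- net$teacher$n_classes
  .check_samples(samples, k)
  set.seed(protocol$seed + 1L)
  thr0 <- lapply(net$layers, `[[`, "V_thr")
  conf <- matrix(0L, k, k + 1L,
                 dimnames = list(true = paste0("c", seq_len(k)),
                                 pred = c(paste0("c", seq_len(k)), "abstain")))
  preds <- integer(length(samples))
  for (si in seq_along(samples)) {
    pr <- predict_sample(net, samples[[si]]$stimulus, protocol)
    net <- pr$network
    if (freeze_thresholds)
      for (nm in names(net$layers)) net$layers[[nm]]$V_thr <- thr0[[nm]]
    preds[si] <- pr$class
    truth <- samples[[si]]$label
    col <- if (is.na(pr$class)) k + 1L else pr$class
    conf[truth, col] <- conf[truth, col] + 1L
  }
  correct <- sum(diag(conf[, seq_len(k), drop = FALSE]))
  list(accuracy = correct / length(samples), confusion = conf,
       predictions = preds, network = net)
}

#' Checksum of all weight matrices
#'
#' Convenience for asserting that an operation (e.g. evaluation) left
#' every synapse untouched.
#'
#' @param net a \code{snn_network}.
#' @return a single numeric hash-like summary (sum of weights and of
#'   squared weights per projection, concatenated).
#' @export
weight_checksum <- function(net) {
  unlist(lapply(net$projections, function(p) c(sum(p$w), sum(p$w^2))))
}
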