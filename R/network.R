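#' Homogeneous Poisson spike train
#'
#' Event times in \code{[0, duration)} ms, generated from exponential
#' inter-event intervals. When \code{seed} is supplied the generator is
#' seeded first; otherwise the current RNG stream is used (so callers that
#' seed once can draw many trains reproducibly).
#'
#' @param rate firing rate, Hz; must be non-negative.
#' @param duration train length, ms.
#' @param seed optional integer seed.
#' @return numeric vector of spike times in ms, strictly increasing.
#' @export
poisson_train <- function(rate, duration, seed = NULL) {
  if (rate < 0) stop("rate must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0 || duration <= 0) return(numeric(0))
  ## expected count + safety margin, then top up if the tail falls short
  n_guess <- max(10, ceiling(rate * duration / 1000 * 1.5 + 10))
  t <- cumsum(stats::rexp(n_guess, rate / 1000))
  while (t[length(t)] < duration)
    t <- c(t, t[length(t)] + cumsum(stats::rexp(n_guess, rate / 1000)))
  t[t < duration]
}

#' Define a network layer
#'
#' A layer is either a population of LIF neurons (\code{type = "lif"},
#' simulated with \code{\link{neuron_params}} dynamics) or a spike source
#' (\code{type = "source"}) whose spikes are prescribed by the stimulus —
#' encoders and teacher populations are sources.
#'
#' @param name layer identifier.
#' @param size number of neurons, at least 1.
#' @param params a \code{\link{neuron_params}} (ignored for sources).
#' @param type \code{"lif"} or \code{"source"}.
#' @return a \code{snn_layer} description used by \code{\link{build_network}}.
#' @export
layer <- function(name, size, params = neuron_params(), type = c("lif", "source")) {
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1L, size >= 1)
  structure(list(name = name, size = as.integer(size),
                 params = params, type = type), class = "snn_layer")
}

#' Define a projection between two layers
#'
#' @param pre,post layer names.
#' @param init either a numeric matrix of weights with dimensions
#'   (pre size, post size), or a length-2 vector \code{c(lo, hi)} from
#'   which initial weights are drawn uniformly at build time.
#' @param plasticity a \code{\link{plasticity_params}} object, or
#'   \code{NULL} for a frozen (non-plastic) projection.
#' @param normalize optional target column sum for divisive weight
#'   normalization: after each plasticity update the incoming weights of
#'   the neuron that fired are rescaled to this total (then capped at 1).
#'   Keeps the template matching of competing neurons norm-fair during
#'   winner-take-all feature learning.
#' @param sign \code{"excitatory"} or \code{"inhibitory"}. Inhibitory
#'   projections are never plastic. An inhibitory projection with
#'   \code{pre == post} (lateral inhibition) gets a zero diagonal so
#'   neurons do not inhibit themselves.
#' @return a \code{snn_projection} description.
#' @export
projection <- function(pre, post, init, plasticity = NULL,
                       sign = c("excitatory", "inhibitory"),
                       normalize = NULL) {
  sign <- match.arg(sign)
  if (sign == "inhibitory" && !is.null(plasticity))
    stop("inhibitory projections are frozen in this model")
  if (!is.null(normalize) && normalize <= 0)
    stop("normalize must be a positive column-sum target")
  if (!is.matrix(init)) {
    if (length(init) != 2L || init[1] >= init[2])
      stop("init must be a weight matrix or an increasing range c(lo, hi)")
  }
  structure(list(pre = pre, post = post, init = init,
                 plasticity = plasticity, sign = sign,
                 normalize = normalize),
            class = "snn_projection")
}

#' Assemble a network from layer and projection descriptions
#'
#' Weight matrices specified as ranges are drawn uniformly under
#' \code{seed}; matrices given explicitly are used as-is. Projections must
#' reference declared layers.
#'
#' @param layers list of \code{\link{layer}} descriptions.
#' @param projections list of \code{\link{projection}} descriptions.
#' @param dt simulation step, ms.
#' @param seed integer seed for weight initialisation.
#' @return an object of class \code{snn_network}.
#' @export
build_network <- function(layers, projections = list(), dt = 0.5, seed = 1L) {
  stopifnot(dt > 0)
  set.seed(seed)
  lnames <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(lnames)) stop("duplicate layer names")
  lay <- lapply(layers, function(l) {
    st <- list(V = rep(l$params$V_L, l$size),
               g_E = numeric(l$size), g_I = numeric(l$size),
               V_thr = rep(l$params$V_thr_base, l$size),
               ref = numeric(l$size),
               last_spike = rep(-Inf, l$size))
    c(l, st)
  })
  names(lay) <- lnames
  proj <- lapply(projections, function(p) {
    if (!(p$pre %in% lnames) || !(p$post %in% lnames))
      stop("projection references unknown layer: ", p$pre, " -> ", p$post)
    np <- lay[[p$pre]]$size
    nq <- lay[[p$post]]$size
    if (is.matrix(p$init)) {
      if (!all(dim(p$init) == c(np, nq))) stop("weight matrix has wrong shape")
      w <- p$init
    } else {
      w <- matrix(stats::runif(np * nq, p$init[1], p$init[2]), np, nq)
    }
    if (p$sign == "inhibitory" && p$pre == p$post) diag(w) <- 0
    list(pre = p$pre, post = p$post, w = w,
         plasticity = p$plasticity, sign = p$sign,
         normalize = p$normalize)
  })
  names(proj) <- vapply(proj, function(p) paste0(p$pre, "->", p$post), character(1))
  structure(list(layers = lay, projections = proj, time = 0, dt = dt,
                 teacher = NULL), class = "snn_network")
}

## stimulus normalisation: each element is either
##   list(kind = "rate",   rates = <Hz per neuron>)
##   list(kind = "spikes", spikes = data.frame(neuron, time)) (time relative
##                          to the start of this run, ms)
.check_stimulus <- function(net, stimulus) {
  if (is.null(stimulus)) return(list())
  if (!all(names(stimulus) %in% names(net$layers)))
    stop("stimulus references unknown layers: ",
         paste(setdiff(names(stimulus), names(net$layers)), collapse = ", "))
  for (nm in names(stimulus)) {
    s <- stimulus[[nm]]
    if (!is.list(s) || is.null(s$kind)) stop("malformed stimulus for layer ", nm)
    if (s$kind == "rate" && length(s$rates) != net$layers[[nm]]$size)
      stop("rate vector length does not match layer ", nm)
  }
  stimulus
}

#' Run the simulation clock
#'
#' Advances the network by \code{duration} ms in steps of \code{dt}. Each
#' step applies, in order: emission of scripted/Poisson spikes by source
#' layers and delivery of those spikes together with LIF spikes of the
#' previous step (one-step propagation delay for LIF-to-LIF synapses);
#' passive decay and membrane integration of every LIF layer (exponential
#' conductance/threshold decay, analytic membrane update with the
#' conductance held at its exact step average), so that an increment
#' delivered in a step drives the membrane within that same step;
#' threshold-crossing checks for LIF layers; and — when
#' \code{learn = TRUE} — the plasticity update of every plastic incoming
#' projection of each neuron that fired (nearest-spike ISI against the
#' presynaptic last-spike cache, silent presynaptic neurons contributing
#' the heterosynaptic-LTD limit). LIF spikes propagate with one step of
#' delay. Scripted source spikes keep their exact event times in the
#' last-spike cache, so a scripted pre spike resolved to the same step as
#' a postsynaptic spike retains its true positive spike-time difference;
#' a rate-emitted pre spike coinciding with a post spike has ISI 0 and
#' produces no update (strict inequality of the rule).
#'
#' @param net a \code{snn_network}.
#' @param stimulus named list (by source-layer name); each element is
#'   either \code{list(kind = "rate", rates = <Hz vector>)} for Poisson
#'   emission or \code{list(kind = "spikes", spikes = data.frame(neuron,
#'   time))} with times in ms relative to the start of this call.
#' @param duration time to simulate, ms.
#' @param record character vector of layer names whose spikes are recorded.
#' @param learn whether plastic projections are updated.
#' @return a list with \code{network} (updated state) and \code{spikes}
#'   (data frame \code{time}, \code{layer}, \code{neuron}, times
#'   non-decreasing).
#' @export
run_network <- function(net, stimulus = NULL, duration,
                        record = names(net$layers), learn = TRUE) {
  stopifnot(inherits(net, "snn_network"), duration > 0)
  stimulus <- .check_stimulus(net, stimulus)
  dt <- net$dt
  n_steps <- ceiling(duration / dt)
  t0 <- net$time

  lay <- net$layers
  proj <- net$projections
  lnames <- names(lay)
  nlay <- length(lay)

  ## per-layer step constants
  is_lif <- vapply(lay, function(l) l$type == "lif", logical(1))
  decE <- vapply(lay, function(l) exp(-dt / l$params$tau_E), numeric(1))
  decI <- vapply(lay, function(l) exp(-dt / l$params$tau_I), numeric(1))
  decThr <- vapply(lay, function(l) exp(-dt / l$params$tau_thr), numeric(1))

  ## projections grouped by pre layer (for delivery) and post layer (for
  ## plasticity); weights pulled into a local list for in-place updates
  W <- lapply(proj, function(p) p$w)
  out_of <- lapply(lnames, function(nm)
    which(vapply(proj, function(p) p$pre == nm, logical(1))))
  plast_in <- lapply(lnames, function(nm)
    which(vapply(proj, function(p)
      p$post == nm && !is.null(p$plasticity), logical(1))))
  names(out_of) <- names(plast_in) <- lnames

  ## scripted spikes bucketed by step index
  script <- vector("list", nlay)
  rates_p <- vector("list", nlay)   # per-step Bernoulli probability
  rng_state <- vector("list", nlay) # per-source-layer RNG substream
  for (nm in names(stimulus)) {
    s <- stimulus[[nm]]
    li <- match(nm, lnames)
    if (s$kind == "rate" && isTRUE(s$regular)) {
      ## deterministic periodic emission: neuron at rate f spikes at
      ## (k - 1/2) / f seconds, k = 1, 2, ...
      sp <- do.call(rbind, lapply(which(s$rates > 0), function(i) {
        t1 <- 500 / s$rates[i]
        if (t1 > n_steps * dt) return(NULL)
        data.frame(neuron = i,
                   time = seq(t1, n_steps * dt, by = 1000 / s$rates[i]))
      }))
      s <- list(kind = "spikes",
                spikes = sp %||% data.frame(neuron = integer(0),
                                            time = numeric(0)))
    }
    if (s$kind == "rate") {
      rates_p[[li]] <- pmin(1, s$rates * dt / 1000)
      ## independent substream per stimulated layer, derived from the run
      ## stream: changing one layer's stimulus (e.g. the teacher rate)
      ## leaves every other layer's spike realisation unchanged
      sd_l <- as.integer(floor(stats::runif(1) * 2^31 - 2^30))
      cur <- .Random.seed
      set.seed(sd_l)
      rng_state[[li]] <- .Random.seed
      .Random.seed <<- cur
    } else {
      sp <- s$spikes
      if (nrow(sp)) {
        if (any(sp$neuron < 1 | sp$neuron > lay[[li]]$size))
          stop("scripted spike neuron index out of range for layer ", nm)
        step_idx <- pmax(1L, ceiling(sp$time / dt))
        keep <- step_idx <= n_steps
        ## keep the exact event times: the nearest-spike cache uses them so
        ## that a pre spike and a post spike resolved to the same step
        ## retain their true positive spike-time difference
        by_step <- split(
          data.frame(neuron = as.integer(sp$neuron[keep]),
                     time = t0 + pmin(sp$time[keep], step_idx[keep] * dt)),
          step_idx[keep])
        full <- vector("list", n_steps)
        full[as.integer(names(by_step))] <- by_step
        script[[li]] <- full
      }
    }
  }

  ## mutable state pulled out of the list-of-lists
  V <- lapply(lay, `[[`, "V"); gE <- lapply(lay, `[[`, "g_E")
  gI <- lapply(lay, `[[`, "g_I"); Vthr <- lapply(lay, `[[`, "V_thr")
  refr <- lapply(lay, `[[`, "ref"); lastsp <- lapply(lay, `[[`, "last_spike")

  rec_mask <- lnames %in% record
  rec_t <- list(); rec_l <- list(); rec_n <- list(); rec_k <- 0L

  pending <- vector("list", nlay)   # spikes emitted last step, by layer

  for (step in seq_len(n_steps)) {
    t <- t0 + step * dt

    ## 1. source-layer emission (delivered and integrated this step)
    emitted <- vector("list", nlay)
    for (li in seq_len(nlay)) {
      fired <- integer(0)
      ftime <- numeric(0)
      if (!is.null(rates_p[[li]])) {
        cur <- .Random.seed
        .Random.seed <<- rng_state[[li]]
        fired <- which(stats::runif(lay[[li]]$size) < rates_p[[li]])
        rng_state[[li]] <- .Random.seed
        .Random.seed <<- cur
        ftime <- rep(t, length(fired))
      }
      if (!is.null(script[[li]])) {
        sc <- script[[li]][[step]]
        if (!is.null(sc)) {
          new <- !(sc$neuron %in% fired)
          fired <- c(fired, sc$neuron[new])
          ftime <- c(ftime, sc$time[new])
        }
      }
      if (length(fired)) {
        lastsp[[li]][fired] <- ftime
        emitted[[li]] <- fired
        if (rec_mask[li]) {
          rec_k <- rec_k + 1L
          rec_t[[rec_k]] <- ftime
          rec_l[[rec_k]] <- rep(lnames[li], length(fired))
          rec_n[[rec_k]] <- fired
        }
      }
    }

    ## 2. deliver source spikes of this step plus LIF spikes of the
    ## previous step; increments enter the conductance before integration
    for (li in seq_len(nlay)) {
      idx <- c(pending[[li]], emitted[[li]])
      if (length(idx) == 0L) next
      for (pi in out_of[[li]]) {
        po <- match(proj[[pi]]$post, lnames)
        inc <- if (length(idx) == 1L) W[[pi]][idx, ]
               else colSums(W[[pi]][idx, , drop = FALSE])
        if (lay[[po]]$params$strict_refractory) inc[refr[[po]] > 0] <- 0
        if (proj[[pi]]$sign == "excitatory") gE[[po]] <- gE[[po]] + inc
        else gI[[po]] <- gI[[po]] + inc
      }
    }
    new_pending <- vector("list", nlay)

    ## 3. passive decay / membrane integration over (t - dt, t]
    for (li in seq_len(nlay)) {
      if (!is_lif[li]) next
      p <- lay[[li]]$params
      rf <- refr[[li]] > 0
      if (any(rf)) {
        v <- V[[li]]
        act <- !rf
        v[act] <- .integrate_V(v[act], gE[[li]][act], gI[[li]][act], p, dt)
        v[rf] <- p$V_L
        V[[li]] <- v
        refr[[li]] <- pmax(0, refr[[li]] - dt)
      } else {
        V[[li]] <- .integrate_V(V[[li]], gE[[li]], gI[[li]], p, dt)
      }
      gE[[li]] <- gE[[li]] * decE[li]
      gI[[li]] <- gI[[li]] * decI[li]
      Vthr[[li]] <- p$V_thr_base + (Vthr[[li]] - p$V_thr_base) * decThr[li]
    }

    ## 4. threshold crossings + plasticity
    for (li in seq_len(nlay)) {
      if (!is_lif[li]) next
      fired <- which(refr[[li]] <= 0 & V[[li]] > Vthr[[li]])
      if (!length(fired)) next
      p <- lay[[li]]$params
      V[[li]][fired] <- p$V_L
      refr[[li]][fired] <- p$T0
      Vthr[[li]][fired] <- Vthr[[li]][fired] + p$V_thr_delta
      lastsp[[li]][fired] <- t
      new_pending[[li]] <- c(new_pending[[li]], fired)
      if (rec_mask[li]) {
        rec_k <- rec_k + 1L
        rec_t[[rec_k]] <- rep(t, length(fired))
        rec_l[[rec_k]] <- rep(lnames[li], length(fired))
        rec_n[[rec_k]] <- fired
      }
      if (learn && length(plast_in[[li]])) {
        for (pi in plast_in[[li]]) {
          pp <- proj[[pi]]$plasticity
          pr <- match(proj[[pi]]$pre, lnames)
          isi <- t - lastsp[[pr]]
          fac <- pp$eta * (pp$alpha + pp$beta * exp(-isi / pp$tau_p))
          fac[isi <= 0] <- 0
          wm <- W[[pi]]
          nrm <- proj[[pi]]$normalize
          for (j in fired) {
            wc <- wm[, j]
            wc <- wc + fac * wc * (1 - wc)
            if (!is.null(nrm)) wc <- pmin(1, wc * (nrm / sum(wc)))
            wm[, j] <- wc
          }
          W[[pi]] <- wm
        }
      }
    }
    pending <- new_pending
  }

  ## write state back
  for (li in seq_len(nlay)) {
    net$layers[[li]]$V <- V[[li]]; net$layers[[li]]$g_E <- gE[[li]]
    net$layers[[li]]$g_I <- gI[[li]]; net$layers[[li]]$V_thr <- Vthr[[li]]
    net$layers[[li]]$ref <- refr[[li]]
    net$layers[[li]]$last_spike <- lastsp[[li]]
  }
  for (pi in seq_along(proj)) net$projections[[pi]]$w <- W[[pi]]
  net$time <- t0 + n_steps * dt

  spikes <- if (rec_k) {
    data.frame(time = unlist(rec_t), layer = unlist(rec_l),
               neuron = unlist(rec_n))
  } else {
    data.frame(time = numeric(0), layer = character(0), neuron = integer(0))
  }
  list(network = net, spikes = spikes)
}

#' Silent inter-sample interval
#'
#' Simulates \code{gap} ms with no stimulus and plasticity disabled:
#' membrane potentials and conductances relax toward rest, adaptive
#' thresholds keep decaying toward base (they are not reset). With no
#' postsynaptic spikes no weight can change; disabling learning makes that
#' a hard guarantee.
#'
#' @param net a \code{snn_network}.
#' @param gap interval length, ms; \code{gap = 0} returns the network
#'   unchanged.
#' @return the relaxed network.
#' @export
reset_interval <- function(net, gap) {
  if (gap < 0) stop("gap must be non-negative")
  if (gap == 0) return(net)
  run_network(net, NULL, gap, record = character(0), learn = FALSE)$network
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network> t =", x$time, "ms, dt =", x$dt, "ms\n")
  for (l in x$layers)
    cat(sprintf("  layer %-10s %5d neurons (%s)\n", l$name, l$size, l$type))
  for (p in x$projections)
    cat(sprintf("  proj  %s -> %s [%d x %d] %s%s\n", p$pre, p$post,
                nrow(p$w), ncol(p$w), p$sign,
                if (is.null(p$plasticity)) ", frozen" else ", plastic"))
  invisible(x)
}
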