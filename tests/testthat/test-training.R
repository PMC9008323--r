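## small supervised fixture: 12 inputs, 2 classes with disjoint supports
mk_fixture <- function(seed = 1L, rate_hi = 40, init = c(0.2, 0.3)) {
  pat <- matrix(0, 12, 2)
  pat[1:4, 1] <- rate_hi
  pat[9:12, 2] <- rate_hi
  pp <- plasticity_params(0.02, -0.1, 1, 50)
  net <- build_network(
    list(layer("input", 12, type = "source"),
         layer("output", 2, neuron_params(V_thr_delta = 0.1,
                                          tau_thr = 5000))),
    list(projection("input", "output", init, plasticity = pp)),
    seed = seed)
  net <- attach_teacher(net, "output", 2)
  list(net = net, pat = pat,
       samples = lapply(rep(1:2, 10), function(k)
         list(stimulus = list(input = list(kind = "rate",
                                           rates = pat[, k])),
              label = k)))
}

test_that("teacher attachment enforces the one-to-one class mapping", {
  net <- build_network(list(layer("input", 4, type = "source"),
                            layer("output", 3)),
                       list(projection("input", "output", c(0.2, 0.3))))
  net <- attach_teacher(net, "output", 3, weight = 2)
  expect_equal(net$layers$teacher$size, 3)
  w <- net$projections[["teacher->output"]]$w
  expect_equal(w, diag(2, 3))
  expect_null(net$projections[["teacher->output"]]$plasticity)
  expect_error(attach_teacher(net, "output", 3), "already")
  net2 <- build_network(list(layer("input", 4, type = "source"),
                             layer("output", 3)), list())
  expect_error(attach_teacher(net2, "output", 4), "does not match")
  expect_error(attach_teacher(net2, "nope", 3), "unknown")
})

test_that("supervised training potentiates pattern synapses and depresses silent ones", {
  ## weak initialisation: outputs fire only when the teacher induces them
  fx <- mk_fixture(init = c(0.08, 0.14))
  w0 <- fx$net$projections[["input->output"]]$w
  ## a long inter-sample gap keeps the nearest-spike ISI of the previous
  ## sample's inputs beyond the potentiation window
  tr <- train_supervised(fx$net, fx$samples,
                         training_protocol(t_gap = 250, epochs = 1, seed = 2))
  w1 <- tr$network$projections[["input->output"]]$w
  ## active inputs onto their own class output strengthen
  expect_gt(mean(w1[1:4, 1]), mean(w0[1:4, 1]))
  expect_gt(mean(w1[9:12, 2]), mean(w0[9:12, 2]))
  ## silent inputs onto a firing output weaken (heterosynaptic LTD)
  expect_lt(mean(w1[9:12, 1]), mean(w0[9:12, 1]))
  expect_lt(mean(w1[1:4, 2]), mean(w0[1:4, 2]))
  ## training log: one row per presentation with output counts
  expect_equal(nrow(tr$log), 20)
  expect_true(all(c("label", "out1", "out2") %in% names(tr$log)))
  expect_error(train_supervised(tr$network,
                                list(list(stimulus = list(), label = 7)),
                                training_protocol()), "label out of range")
})

test_that("weights onto output neurons of never-presented classes stay untouched", {
  ## weak initial weights keep the idle output below threshold even for
  ## coincident input spikes, so only the teacher can make it fire
  fx <- mk_fixture(rate_hi = 30, init = c(0.08, 0.14))
  w0 <- fx$net$projections[["input->output"]]$w
  only1 <- Filter(function(s) s$label == 1, fx$samples)
  tr <- train_supervised(fx$net, only1, training_protocol(epochs = 1, seed = 3))
  w1 <- tr$network$projections[["input->output"]]$w
  expect_gt(mean(w1[1:4, 1]), mean(w0[1:4, 1]))
  ## class-2 output never fires, so its whole incoming column is unchanged
  expect_identical(w1[, 2], w0[, 2])
})

test_that("the teacher signal is the only difference between the two modes", {
  fx <- mk_fixture()
  proto0 <- training_protocol(teacher_rate = 0, epochs = 1, seed = 5)
  sup <- train_supervised(fx$net, fx$samples, proto0)
  uns <- train_unsupervised(fx$net, fx$samples, proto0)
  expect_identical(sup$network$projections[["input->output"]]$w,
                   uns$network$projections[["input->output"]]$w)
  expect_identical(sup$network$layers$output$V,
                   uns$network$layers$output$V)
})

test_that("training without any input changes no weights", {
  fx <- mk_fixture()
  silent <- lapply(1:4, function(i)
    list(stimulus = list(input = list(kind = "rate", rates = rep(0, 12))),
         label = 1))
  tr <- train_supervised(fx$net, silent,
                         training_protocol(teacher_rate = 0, epochs = 2,
                                           seed = 1))
  expect_identical(tr$network$projections[["input->output"]]$w,
                   fx$net$projections[["input->output"]]$w)
})

test_that("readout takes the most active output with declared tie-breaks", {
  ## frozen one-to-one drive lets scripted inputs dictate output counts
  net <- build_network(
    list(layer("input", 2, type = "source"),
         layer("output", 2, neuron_params(V_thr_delta = 0, T0 = 25))),
    list(projection("input", "output", diag(5, 2))))
  net <- attach_teacher(net, "output", 2, weight = 2)
  proto <- training_protocol(t_present = 100, t_gap = 20, seed = 1)

  ## 3 strong volleys to neuron 1, 1 to neuron 2: clear argmax
  stim <- list(input = list(kind = "spikes", spikes = data.frame(
    neuron = c(1, 1, 1, 2), time = c(10, 40, 70, 20))))
  pr <- predict_sample(net, stim, proto)
  expect_equal(pr$class, 1L)
  expect_equal(pr$counts, c(3, 1))

  ## equal counts: earlier first spike wins
  stim2 <- list(input = list(kind = "spikes", spikes = data.frame(
    neuron = c(2, 1, 2, 1), time = c(10, 30, 50, 70) + c(0, 20, 0, 20))))
  pr2 <- predict_sample(net, stim2, proto)
  expect_equal(pr2$counts, c(2, 2))
  expect_equal(pr2$class, 2L)

  ## no output spikes at all: abstention
  pr3 <- predict_sample(net, list(input = list(kind = "rate",
                                               rates = c(0, 0))), proto)
  expect_true(is.na(pr3$class))
})

test_that("evaluation reports accuracy and a conserved confusion matrix", {
  fx <- mk_fixture()
  tr <- train_supervised(fx$net, fx$samples,
                         training_protocol(epochs = 2, seed = 2))
  ev <- evaluate_network(tr$network, fx$samples,
                         training_protocol(teacher_rate = 0, seed = 9))
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(rowSums(ev$confusion)), c(10, 10))
  expect_equal(unname(diag(ev$confusion[, 1:2])), c(10, 10))
  expect_error(evaluate_network(tr$network, list(), training_protocol()),
               "empty")
})

test_that("evaluation never changes a synapse", {
  fx <- mk_fixture()
  tr <- train_supervised(fx$net, fx$samples,
                         training_protocol(epochs = 1, seed = 2))
  before <- weight_checksum(tr$network)
  ev <- evaluate_network(tr$network, fx$samples,
                         training_protocol(teacher_rate = 0, seed = 10))
  expect_identical(weight_checksum(ev$network), before)
  for (nm in names(tr$network$projections))
    expect_identical(ev$network$projections[[nm]]$w,
                     tr$network$projections[[nm]]$w)
})

test_that("unsupervised winner-take-all neurons specialise on distinct patterns", {
  pp <- plasticity_params(0.05, -0.3, 1.3, 20)
  n_in <- 20
  pat <- matrix(0, n_in, 2); pat[1:8, 1] <- 60; pat[13:20, 2] <- 60
  net <- build_network(
    list(layer("input", n_in, type = "source"),
         layer("feat", 2, neuron_params(V_thr_delta = 1, tau_thr = 5e4))),
    list(projection("input", "feat", c(0.2, 0.4), plasticity = pp),
         projection("feat", "feat", matrix(2, 2, 2), sign = "inhibitory")),
    seed = 3)
  samples <- lapply(rep(1:2, 30), function(k)
    list(stimulus = list(input = list(kind = "rate", rates = pat[, k]))))
  set.seed(9)
  samples <- sample(samples)
  tu <- train_unsupervised(net, samples,
                           training_protocol(teacher_rate = 0, seed = 4),
                           record_layer = "feat")
  w <- tu$network$projections[["input->feat"]]$w
  pref <- c(cosine(w[, 1], pat[, 1]) > cosine(w[, 1], pat[, 2]),
            cosine(w[, 2], pat[, 1]) > cosine(w[, 2], pat[, 2]))
  expect_equal(sum(pref), 1)  # one neuron per pattern
  expect_equal(dim(tu$counts), c(60, 2))
})

test_that("identical samples pull weight columns onto the shared support", {
  pp <- plasticity_params(0.05, -0.3, 1.3, 20)
  pat <- c(rep(60, 6), rep(0, 6))
  net <- build_network(
    list(layer("input", 12, type = "source"),
         layer("feat", 2, neuron_params(V_thr_delta = 0.5, tau_thr = 1e4))),
    list(projection("input", "feat", c(0.2, 0.4), plasticity = pp)),
    seed = 6)
  w0 <- net$projections[["input->feat"]]$w
  samples <- lapply(1:25, function(i)
    list(stimulus = list(input = list(kind = "rate", rates = pat))))
  tu <- train_unsupervised(net, samples,
                           training_protocol(teacher_rate = 0, seed = 7))
  w1 <- tu$network$projections[["input->feat"]]$w
  on <- pat > 0
  expect_gt(mean(w1[on, ]), mean(w0[on, ]))
  expect_lt(mean(w1[!on, ]), mean(w0[!on, ]))
  expect_gt(cosine(rowMeans(w1), as.numeric(on)),
            cosine(rowMeans(w0), as.numeric(on)))
})
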