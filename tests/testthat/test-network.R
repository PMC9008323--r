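test_that("poisson trains have the right first-order statistics", {
  expect_identical(poisson_train(0, 1000), numeric(0))
  expect_error(poisson_train(-5, 100), "non-negative")
  n <- vapply(1:20, function(s) length(poisson_train(20, 1e5, seed = s)),
              numeric(1))
  ## 2000 expected; ~95% band
  expect_true(all(abs(n - 2000) < 4 * sqrt(2000)))
  t <- poisson_train(20, 1e5, seed = 1)
  expect_true(all(diff(t) > 0))
  expect_lt(abs(mean(diff(t)) - 50) / 50, 0.05)
})

test_that("network construction validates its description", {
  expect_error(build_network(list(layer("a", 3), layer("a", 2))), "duplicate")
  expect_error(
    build_network(list(layer("a", 3)),
                  list(projection("a", "b", c(0.1, 0.2)))), "unknown layer")
  expect_error(projection("a", "b", c(0.3, 0.2)), "increasing")
  expect_error(projection("a", "a", c(0.1, 0.2), sign = "inhibitory",
                          plasticity = plasticity_params(0.01, -0.1, 1, 50)),
               "frozen")
  expect_error(
    build_network(list(layer("a", 3), layer("b", 2)),
                  list(projection("a", "b", matrix(0.5, 4, 2)))), "shape")
  ## initial weights honour the requested range and seed
  net <- build_network(list(layer("a", 10, type = "source"), layer("b", 5)),
                       list(projection("a", "b", c(0.2, 0.3))), seed = 3)
  w <- net$projections[["a->b"]]$w
  expect_true(all(w >= 0.2 & w <= 0.3))
  net2 <- build_network(list(layer("a", 10, type = "source"), layer("b", 5)),
                        list(projection("a", "b", c(0.2, 0.3))), seed = 3)
  expect_identical(w, net2$projections[["a->b"]]$w)
  ## lateral inhibition excludes self-connections
  net3 <- build_network(list(layer("f", 4)),
                        list(projection("f", "f", matrix(1, 4, 4),
                                        sign = "inhibitory")))
  expect_true(all(diag(net3$projections[["f->f"]]$w) == 0))
})

test_that("a quiescent network produces no spikes", {
  net <- build_network(list(layer("a", 5, type = "source"), layer("b", 3)))
  r <- run_network(net, NULL, 500)
  expect_equal(nrow(r$spikes), 0)
  expect_error(run_network(net, list(zzz = list(kind = "rate", rates = 1)),
                           100), "unknown layers")
})

test_that("output rate increases with input rate through a strong synapse", {
  counts <- vapply(c(20, 80, 200), function(rate) {
    net <- single_synapse_net(1, neuron_params(V_thr_delta = 0))
    set.seed(5)
    r <- run_network(net, list(`in` = list(kind = "rate", rates = rate)),
                     3000, record = "out")
    sum(r$spikes$layer == "out")
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("simulation is deterministic under a fixed seed with frozen weights", {
  mk <- function() {
    net <- build_network(
      list(layer("src", 6, type = "source"), layer("post", 4)),
      list(projection("src", "post", c(0.4, 0.9))), seed = 11)
    set.seed(123)
    run_network(net, list(src = list(kind = "rate", rates = rep(40, 6))),
                1000, record = c("src", "post"))
  }
  r1 <- mk(); r2 <- mk()
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$network$layers$post$V, r2$network$layers$post$V)
})

test_that("replaying a recorded source train reproduces downstream spikes", {
  net <- build_network(
    list(layer("src", 6, type = "source"), layer("post", 4)),
    list(projection("src", "post", c(0.4, 0.9))), seed = 11)
  set.seed(77)
  r1 <- run_network(net, list(src = list(kind = "rate", rates = rep(40, 6))),
                    1000, record = c("src", "post"))
  rec <- r1$spikes[r1$spikes$layer == "src", c("neuron", "time")]
  r2 <- run_network(net, list(src = list(kind = "spikes",
                                         spikes = rec)),
                    1000, record = c("src", "post"))
  expect_identical(r1$spikes, r2$spikes)
})

test_that("regular rate stimuli emit deterministic periodic trains", {
  net <- build_network(list(layer("src", 2, type = "source"), layer("post", 1)),
                       list(projection("src", "post", matrix(0.1, 2, 1))))
  r <- run_network(net, list(src = list(kind = "rate", rates = c(50, 0),
                                        regular = TRUE)),
                   1000, record = "src")
  tt <- r$spikes$time
  expect_equal(length(tt), 50)
  expect_true(all(r$spikes$neuron == 1))
  expect_equal(diff(tt), rep(20, 49))
})

test_that("silent gaps relax the state but never reset the adaptive threshold", {
  p <- neuron_params(V_thr_delta = 2, tau_thr = 1e4)
  net <- single_synapse_net(1.5, p)
  set.seed(3)
  r <- run_network(net, list(`in` = list(kind = "rate", rates = 200)), 500,
                   record = "out")
  net <- r$network
  thr_before <- net$layers$out$V_thr
  expect_gt(thr_before, p$V_thr_base)

  expect_identical(reset_interval(net, 0), net)
  net2 <- reset_interval(net, 400)
  expect_lt(abs(net2$layers$out$V - p$V_L), 1e-6)
  expect_lt(net2$layers$out$g_E, 1e-6)
  ## threshold decayed but not reset: still well above base for tau_thr = 10 s
  expect_lt(net2$layers$out$V_thr, thr_before)
  expect_gt(net2$layers$out$V_thr,
            p$V_thr_base + 0.5 * (thr_before - p$V_thr_base))
  expect_error(reset_interval(net, -1), "non-negative")
})

test_that("mutual inhibition makes the first spiker suppress its rival", {
  ## two LIF neurons share a strong input; asymmetric feedforward weights
  ## let neuron 1 fire first, and strong mutual inhibition then keeps
  ## neuron 2 quiet
  net <- build_network(
    list(layer("src", 1, type = "source"),
         layer("pair", 2, neuron_params(V_thr_delta = 0))),
    list(projection("src", "pair", matrix(c(1.4, 1.1), 1, 2)),
         projection("pair", "pair", matrix(8, 2, 2), sign = "inhibitory")))
  set.seed(2)
  r <- run_network(net, list(src = list(kind = "rate", rates = 120,
                                        regular = TRUE)),
                   1000, record = "pair")
  n1 <- sum(r$spikes$neuron == 1)
  n2 <- sum(r$spikes$neuron == 2)
  expect_gt(n1, 10)
  expect_lt(n2, n1 / 4)

  ## without inhibition both fire comparably
  net0 <- build_network(
    list(layer("src", 1, type = "source"),
         layer("pair", 2, neuron_params(V_thr_delta = 0))),
    list(projection("src", "pair", matrix(c(1.4, 1.1), 1, 2))))
  set.seed(2)
  r0 <- run_network(net0, list(src = list(kind = "rate", rates = 120,
                                          regular = TRUE)),
                    1000, record = "pair")
  expect_gt(sum(r0$spikes$neuron == 2), n1 / 2)
})

test_that("threshold adaptation narrows the firing-rate dispersion of a population", {
  ## heterogeneous feedforward weights; with adaptation the strongly driven
  ## neurons slow down and the weakly driven ones keep firing
  run_pop <- function(delta) {
    net <- build_network(
      list(layer("src", 1, type = "source"),
           layer("pop", 8, neuron_params(V_thr_delta = delta,
                                         tau_thr = 3000))),
      list(projection("src", "pop",
                      matrix(seq(0.9, 2.3, length.out = 8), 1, 8))))
    set.seed(8)
    r <- run_network(net, list(src = list(kind = "rate", rates = 80)),
                     8000, record = "pop")
    tabulate(r$spikes$neuron, 8)
  }
  with_homeo <- run_pop(1.5)
  without <- run_pop(0)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(with_homeo), cv(without))
})
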