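test_that("initialization hits the requested spectral radius exactly", {
  cfg <- reservoir_config(n_neurons = 200, spectral_radius = 1.4,
                          init_seed = 4)
  net <- init_reservoir(cfg)
  expect_lt(abs(spectral_radius(net$W) - 1.4) / 1.4, 1e-10)
  expect_true(all(abs(net$w_in) <= 1))
  # rescaling formula on a hand-checkable case: the 2x2 exchange matrix has
  # spectral radius 1, so scaling to 0.5 halves every entry
  W_random <- matrix(c(0, 1, 1, 0), 2, 2)
  W <- W_random * (0.5 / spectral_radius(W_random))
  expect_equal(W, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("connection density matches the Bernoulli target", {
  cfg <- reservoir_config(n_neurons = 500, density = 0.1, init_seed = 8)
  net <- init_reservoir(cfg)
  frac <- Matrix::nnzero(net$W) / 500^2
  se <- sqrt(0.1 * 0.9 / 500^2)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("single-step semantics follow the update equations", {
  # zero drive leaves the state unchanged in integrator form
  net0 <- make_net(matrix(0, 3, 3), rep(0, 3), update_rule = "integrator")
  x <- c(0.2, -0.5, 1.1)
  expect_identical(reservoir_step(x, net0, 0.7), x)
  # one neuron: x(1) = tanh(W_in u) = tanh(0.5)
  net1 <- make_net(matrix(0, 1, 1), 1, update_rule = "standard")
  expect_equal(reservoir_step(0, net1, 0.5), tanh(0.5))
  expect_equal(tanh(0.5), 0.46212, tolerance = 1e-5)
})

test_that("Oja updates match hand arithmetic and conserve sparsity", {
  W <- matrix(c(0, 1, 0, 0), 2, 2)  # single connection W[2,1]... column-major
  net <- make_net(W, c(0, 0))
  # alpha = 0: no change
  n2 <- oja_update(net, c(1, 1), 0)
  expect_identical(n2$W@x, net$W@x)
  # fixed point: x_i = x_j = W_ij = 1 gives dW = 0
  Wfp <- matrix(c(0, 1, 0, 0), 2, 2)
  nfp <- oja_update(make_net(Wfp, c(0, 0)), c(1, 1), 0.1)
  expect_equal(as.matrix(nfp$W), Wfp)
  # decay: x_i = 1, x_j = 0, W_ij = 1, alpha = 0.1 -> 0.9
  # connection is W[2,1] (i = 2 postsynaptic, j = 1 presynaptic)
  ndec <- oja_update(make_net(Wfp, c(0, 0)), c(0, 1), 0.1)
  expect_equal(as.matrix(ndec$W)[2, 1], 0.9)
})

test_that("compiled trials reproduce the brute-force R loop", {
  set.seed(21)
  n <- 12
  K <- 25
  W <- matrix(rnorm(n * n) * (runif(n * n) < 0.4), n, n)
  W <- W * (0.9 / max(Mod(eigen(W)$values)))
  w_in <- runif(n, -1, 1)
  u <- test_input(K)
  cases <- expand.grid(rule = c("standard", "integrator"),
                       sigma = c(0, 1e-2),
                       plastic = c(FALSE, TRUE),
                       timing = c("simultaneous", "prepost"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    net <- make_net(W, w_in, noise_sigma = cs$sigma, update_rule = cs$rule,
                    oja_timing = cs$timing)
    got <- run_trial(net, u, trial_seed = 5, plastic = cs$plastic,
                     alpha = 1e-3)
    want <- reference_trial(net, u, trial_seed = 5, plastic = cs$plastic,
                            alpha = 1e-3)
    expect_equal(got$states, want$states, tolerance = 1e-12,
                 info = paste(cs, collapse = "/"))
    expect_equal(got$net$W@x, want$net$W@x, tolerance = 1e-12,
                 info = paste(cs, collapse = "/"))
  }
})

test_that("plasticity preserves the sparsity pattern structurally", {
  cfg <- reservoir_config(n_neurons = 100, spectral_radius = 1.2,
                          init_seed = 3)
  net <- init_reservoir(cfg)
  before <- list(i = net$W@i, p = net$W@p)
  tr <- run_trial(net, test_input(200), 9, plastic = TRUE, alpha = 1e-3)
  expect_identical(tr$net$W@i, before$i)
  expect_identical(tr$net$W@p, before$p)
  expect_false(identical(tr$net$W@x, net$W@x))
})

test_that("trials are deterministic and weights untouched without plasticity", {
  cfg <- reservoir_config(n_neurons = 80, spectral_radius = 1.0,
                          init_seed = 6)
  net <- init_reservoir(cfg)
  u <- test_input(300)
  a <- run_trial(net, u, 17)
  b <- run_trial(net, u, 17)
  expect_identical(a$states, b$states)
  expect_identical(a$net$W@x, net$W@x)
})

test_that("batched evaluation matches one-at-a-time trials bit for bit", {
  cfg <- reservoir_config(n_neurons = 60, spectral_radius = 1.1,
                          init_seed = 10)
  net <- init_reservoir(cfg)
  K <- 150
  U <- cbind(test_input(K, 1), test_input(K, 2), test_input(K, 3))
  w_out <- rnorm(60) / 60
  bt <- run_test_batch(net, U, seeds = c(4, 5, 6), w_out,
                       node_ids = c(2, 33))
  for (r in 1:3) {
    tr <- run_trial(net, U[, r], trial_seed = c(4, 5, 6)[r])
    expect_identical(bt$nodes[[1]][, r], tr$states[, 2])
    expect_identical(bt$nodes[[2]][, r], tr$states[, 33])
    expect_equal(bt$y[, r], as.numeric(tr$states %*% w_out),
                 tolerance = 1e-12)
  }
})

test_that("the trial RNG stream is N(0,1) and U(-1,1) distributed", {
  z <- plasticESN:::rng_stream_cpp(2e5, 123, "norm")
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.01)
  expect_gt(suppressWarnings(ks.test(z, pnorm)$p.value), 0.01)
  u <- plasticESN:::rng_stream_cpp(2e5, 123, "unif")
  expect_true(all(u >= -1 & u <= 1))
  expect_gt(suppressWarnings(
    ks.test(u, punif, min = -1, max = 1)$p.value), 0.01)
})

test_that("reservoirs converge under drive at low radius, diverge at high", {
  u <- test_input(2000, seed = 31)
  # ordered regime: different initial states, same input -> same trajectory
  cfg <- reservoir_config(n_neurons = 500, spectral_radius = 0.1,
                          noise_sigma = 0, input_gain = 0.1, init_seed = 2,
                          update_rule = "standard")
  net <- init_reservoir(cfg)
  U <- cbind(u, u)
  bt <- run_test_batch(net, U, seeds = c(100, 200), c(rep(0, 499), 1),
                       node_ids = c(7))
  post <- 201:1000
  expect_gt(cor(bt$nodes[[1]][post, 1], bt$nodes[[1]][post, 2]), 0.99)
  # chaotic regime: trajectories decorrelate
  cfg2 <- reservoir_config(n_neurons = 500, spectral_radius = 2.0,
                           noise_sigma = 0, input_gain = 0.1, init_seed = 2,
                           update_rule = "standard")
  net2 <- init_reservoir(cfg2)
  n_rep <- 20
  U2 <- matrix(rep(u, 2 * n_rep), ncol = 2 * n_rep)
  bt2 <- run_test_batch(net2, U2, seeds = 1000 + seq_len(2 * n_rep),
                        c(rep(0, 499), 1), node_ids = c(7))
  rs <- vapply(seq_len(n_rep), function(i) {
    cor(bt2$nodes[[1]][post, 2 * i - 1], bt2$nodes[[1]][post, 2 * i])
  }, numeric(1))
  # mean pair correlation statistically indistinguishable from 0
  expect_lt(abs(mean(rs)), 2.5 * sd(rs) / sqrt(n_rep) + 0.05)
})

test_that("network snapshots round-trip bit-exactly", {
  net <- init_reservoir(reservoir_config(n_neurons = 40, spectral_radius = 1.1,
                                         init_seed = 2))
  tr <- run_trial(net, test_input(100), 5, plastic = TRUE, alpha = 1e-3)
  f <- tempfile(fileext = ".rds")
  save_network(tr$net, f)
  back <- load_network(f)
  expect_identical(back$W@x, tr$net$W@x)
  expect_identical(back$w_in, tr$net$w_in)
  expect_identical(back$config, tr$net$config)
  unlink(f)
})
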