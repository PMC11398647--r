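# Hand-built reservoir from an explicit dense weight matrix, bypassing the
# random initializer, for exact small-scale checks.
make_net <- function(W, w_in, noise_sigma = 0, input_gain = 1,
                     update_rule = "standard", oja_timing = "simultaneous") {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  cfg <- reservoir_config(
    n_neurons = nrow(W), density = max(Matrix::nnzero(W), 1) / nrow(W)^2,
    spectral_radius = max(spectral_radius(W), 1e-6),
    noise_sigma = noise_sigma, input_gain = input_gain,
    update_rule = update_rule, oja_timing = oja_timing, init_seed = 1L
  )
  structure(list(W = W, w_in = w_in, config = cfg,
                 rho_initial = cfg$spectral_radius),
            class = "reservoir_net")
}

# Brute-force R reference for a full trial: explicit step-by-step loop over
# reservoir_step / oja_update, with the initial state and noise taken from the
# same per-trial stream as the compiled core.
reference_trial <- function(net, u, trial_seed, plastic = FALSE,
                            alpha = 1e-7) {
  n <- net$config$n_neurons
  K <- length(u)
  u <- u * net$config$input_gain
  sigma <- net$config$noise_sigma
  stream <- plasticESN:::trial_stream_cpp(n, K, trial_seed)
  x <- stream$x0
  draws <- stream$noise
  states <- matrix(NA_real_, K, n)
  for (k in seq_len(K)) {
    x_old <- x
    x <- reservoir_step(x, net, u[k], noise = sigma * draws[k, ])
    if (plastic && alpha != 0) {
      if (net$config$oja_timing == "prepost") {
        net <- oja_update_prepost(net, x, x_old, alpha)
      } else {
        net <- oja_update(net, x, alpha)
      }
    }
    states[k, ] <- x
  }
  list(states = states, net = net)
}

# pre/post variant of the Oja reference (presynaptic x_j at time k,
# postsynaptic x_i at time k+1)
oja_update_prepost <- function(net, x_new, x_old, alpha) {
  W <- net$W
  j_idx <- rep(seq_len(ncol(W)), diff(W@p))
  i_idx <- W@i + 1L
  xi <- x_new[i_idx]
  xj <- x_old[j_idx]
  W@x <- W@x + alpha * xi * (xj - xi * W@x)
  net$W <- W
  net
}

# a short processed-like input series (unit RMS white noise)
test_input <- function(K, seed = 1) {
  set.seed(seed)
  u <- rnorm(K)
  u / sqrt(mean(u^2))
}
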