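#' Plastic echo-state reservoir
#'
#' A sparse random tanh recurrent network whose recurrent matrix W evolves
#' under Oja's Hebbian rule while the input weights stay fixed.  The state
#' update over one input sample is the textbook echo-state form
#' \deqn{x(k+1) = \tanh(W(k) x(k) + W^{in} u(k+1)) + \varepsilon}
#' in the default "standard" mode, or the integrator variant
#' \deqn{x(k+1) = x(k) + \tanh(W(k) x(k) + W^{in} u(k+1)) + \varepsilon}
#' in "integrator" mode (kept for comparison; its states drift without bound and
#' destabilize the plasticity, see the methods vignette), with \eqn{\varepsilon \sim N(0, \sigma^2 I)} modelling
#' intrinsic neural noise.  Oja's rule
#' \deqn{\Delta W_{ij} = \alpha x_i (x_j - x_i W_{ij})}
#' is applied to the existing synapses after every step when plasticity is on.
#'
#' @name reservoir
NULL

#' Reservoir configuration
#'
#' @param n_neurons number of reservoir units (default 500).
#' @param density connection density of the sparse recurrent matrix
#'   (default 0.1).
#' @param spectral_radius desired spectral radius of W after rescaling.
#' @param noise_sigma standard deviation of the per-step intrinsic Gaussian
#'   noise (default 1e-3).
#' @param input_gain multiplier applied to the (unit-RMS) stimulus at
#'   presentation (default 0.1, placing the consistency transition of the
#'   driven network near spectral radius 1.2-1.6).
#' @param update_rule `"standard"` for the textbook echo-state update
#'   (default), `"integrator"` for the integrator variant with the additive x(k)
#'   term.
#' @param oja_timing which activations enter the plasticity rule:
#'   `"simultaneous"` (default) uses x_i(k+1) and x_j(k+1); `"prepost"`
#'   pairs the presynaptic activation x_j(k) with the postsynaptic
#'   activation x_i(k+1) it helped produce, imprinting the temporal
#'   transition structure of the driven trajectory.
#' @param init_seed seed for weight initialization.
#' @return a `reservoir_config` list.
#' @export
reservoir_config <- function(n_neurons = 500, density = 0.1,
                             spectral_radius = 1.0, noise_sigma = 1e-3,
                             input_gain = 0.1,
                             update_rule = c("standard", "integrator"),
                             oja_timing = c("simultaneous", "prepost"),
                             init_seed = 1L) {
  update_rule <- match.arg(update_rule)
  oja_timing <- match.arg(oja_timing)
  stopifnot(n_neurons >= 1, density > 0, density <= 1,
            spectral_radius > 0, noise_sigma >= 0)
  structure(list(n_neurons = n_neurons, density = density,
                 spectral_radius = spectral_radius, noise_sigma = noise_sigma,
                 input_gain = input_gain, update_rule = update_rule,
                 oja_timing = oja_timing,
                 init_seed = as.integer(init_seed)),
            class = "reservoir_config")
}

#' Spectral radius of a matrix
#'
#' Largest absolute eigenvalue, by dense eigendecomposition (exact for the
#' network sizes used here).
#'
#' @param W a square matrix (dense or `Matrix` sparse).
#' @return nonnegative real.
#' @export
spectral_radius <- function(W) {
  max(Mod(eigen(as.matrix(W), only.values = TRUE)$values))
}

#' Initialize a plastic reservoir network
#'
#' Draws a Bernoulli(`density`) sparsity mask and U(-1, 1) nonzero weights,
#' rescales so the spectral radius equals `config$spectral_radius` exactly
#' (relative error below 1e-10), and draws U(-1, 1) input weights.
#'
#' @param config a [reservoir_config()].
#' @return a `reservoir_net`: list with sparse `W` (`Matrix::dgCMatrix`),
#'   `w_in`, `config`, and `rho_initial`.
#' @export
init_reservoir <- function(config) {
  stopifnot(inherits(config, "reservoir_config"))
  n <- config$n_neurons
  set.seed(config$init_seed)
  for (attempt in 1:20) {
    mask <- matrix(runif(n * n) < config$density, n, n)
    vals <- matrix(runif(n * n, -1, 1), n, n)
    W_random <- vals * mask
    rho0 <- spectral_radius(W_random)
    if (rho0 > 0) break
  }
  if (rho0 == 0) stop("degenerate draw: random matrix has zero spectral radius")
  W <- W_random * (config$spectral_radius / rho0)
  w_in <- runif(n, -1, 1)
  structure(list(
    W = methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                    "CsparseMatrix"),
    w_in = w_in,
    config = config,
    rho_initial = config$spectral_radius
  ), class = "reservoir_net")
}

#' One reservoir state update (reference implementation)
#'
#' Pure-R single-step update used for unit semantics and as a cross-check of
#' the compiled trial loop; simulations use [run_trial()].
#'
#' @param x state vector at time k.
#' @param net a `reservoir_net`.
#' @param u_next input sample u(k+1) (already including any input gain).
#' @param noise vector of per-neuron noise draws (default zeros).
#' @return state vector at time k+1.
#' @export
reservoir_step <- function(x, net, u_next, noise = 0) {
  drive <- tanh(as.numeric(net$W %*% x) + net$w_in * u_next) + noise
  out <- if (net$config$update_rule == "integrator") x + drive else drive
  if (any(!is.finite(out))) stop("numerical overflow in reservoir step")
  out
}

#' One Oja plasticity update (reference implementation)
#'
#' Applies \eqn{\Delta W_{ij} = \alpha x_i (x_j - x_i W_{ij})} to the
#' existing nonzero entries of W only, so the sparsity pattern is conserved.
#'
#' @param net a `reservoir_net`.
#' @param x state vector (simultaneous activations).
#' @param alpha learning rate.
#' @return the network with updated `W`.
#' @export
oja_update <- function(net, x, alpha) {
  W <- net$W
  j_idx <- rep(seq_len(ncol(W)), diff(W@p))
  i_idx <- W@i + 1L
  xi <- x[i_idx]
  xj <- x[j_idx]
  W@x <- W@x + alpha * xi * (xj - xi * W@x)
  net$W <- W
  net
}

#' Simulate one stimulus presentation
#'
#' Runs the reservoir over all samples of a processed stimulus.  The trial
#' seed selects an independent RNG stream that first yields the initial state
#' x(0) ~ U(-1, 1)^N and then the per-step intrinsic noise, so a trial is a
#' pure function of (network, stimulus, seed) and batched evaluation of the
#' same seed reproduces it bit for bit.  Oja's rule is optionally applied
#' after every step using the post-step activations.  The compiled core does
#' the stepping.
#'
#' @param net a `reservoir_net`.
#' @param stimulus a stimulus list with a `processed` [waveform], or a bare
#'   numeric input series.
#' @param trial_seed seed fixing x(0) and the noise trajectory.
#' @param plastic apply Oja's rule during this trial.
#' @param alpha Oja learning rate (default 1e-7).
#' @return list with `states` (K x N matrix, row k = x(k) after consuming
#'   u(k)), `net` (possibly updated weights), `overflow` flag.
#' @export
run_trial <- function(net, stimulus, trial_seed, plastic = FALSE,
                      alpha = 1e-7) {
  u <- if (is.numeric(stimulus)) stimulus else stimulus$processed$samples
  u <- u * net$config$input_gain
  W <- net$W
  res <- run_trial_cpp(W@x, W@i, W@p, net$config$n_neurons, net$w_in,
                       u, trial_seed, net$config$noise_sigma,
                       alpha, plastic, net$config$update_rule == "integrator",
                       net$config$oja_timing == "prepost")
  if (res$overflow) {
    warning(sprintf("reservoir overflow at step %d (rho = %g)",
                    res$overflow_k, net$config$spectral_radius))
  }
  if (plastic) {
    W@x <- res$w
    net$W <- W
  }
  list(states = res$states, net = net, overflow = res$overflow)
}

#' Simulate many frozen-network test runs at once
#'
#' Batched counterpart of [run_trial()] for evaluation: plasticity off, one
#' stimulus and one seed per run.  Each run's RNG stream is identical to what
#' [run_trial()] would use for the same seed, so the trajectories agree bit
#' for bit; only the readout output series and a set of sampled node series
#' are returned.
#'
#' @param net a `reservoir_net`.
#' @param inputs K x R matrix of processed input series (one column per run,
#'   input gain not yet applied).
#' @param seeds length-R vector of per-run trial seeds.
#' @param w_out readout weight vector.
#' @param node_ids indices of reservoir nodes whose series are recorded.
#' @param chunk runs are simulated in chunks of this many columns (cache
#'   sizing); the result is independent of the chunking.
#' @return list with `y` (K x R), `nodes` (list of K x R matrices, one per
#'   node id), `overflow` (logical per run).
#' @export
run_test_batch <- function(net, inputs, seeds, w_out,
                           node_ids = integer(0), chunk = 64L) {
  stopifnot(ncol(inputs) == length(seeds))
  W <- net$W
  R <- length(seeds)
  one <- function(idx) {
    run_batch_cpp(W@x, W@i, W@p, net$config$n_neurons, net$w_in,
                  inputs[, idx, drop = FALSE] * net$config$input_gain,
                  as.numeric(seeds[idx]),
                  net$config$noise_sigma, as.numeric(w_out),
                  as.integer(node_ids),
                  net$config$update_rule == "integrator")
  }
  if (R <= chunk) return(one(seq_len(R)))
  # large batches are processed in cache-sized chunks; per-run streams make
  # the split exact
  parts <- lapply(split(seq_len(R), ceiling(seq_len(R) / chunk)), one)
  list(
    y = do.call(cbind, lapply(parts, `[[`, "y")),
    nodes = lapply(seq_along(node_ids), function(m) {
      do.call(cbind, lapply(parts, function(p) p$nodes[[m]]))
    }),
    overflow = do.call(c, lapply(parts, `[[`, "overflow"))
  )
}

#' Save or restore a reservoir network snapshot
#'
#' Serializes the full network state (sparse weights, input weights,
#' configuration) so that a training run can be resumed or audited; the
#' round trip is bit-exact.
#'
#' @param net a `reservoir_net`.
#' @param file path to write to / read from.
#' @return `load_network` returns the restored `reservoir_net`.
#' @export
save_network <- function(net, file) {
  stopifnot(inherits(net, "reservoir_net"))
  saveRDS(net, file)
  invisible(file)
}

#' @rdname save_network
#' @export
load_network <- function(file) {
  net <- readRDS(file)
  stopifnot(inherits(net, "reservoir_net"))
  net
}
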