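#' Linear readout trained by minibatch gradient descent
#'
#' The output neuron computes \eqn{y(k) = W^{out} x(k)} and is trained for
#' one-step-ahead prediction of the input, \eqn{d(k) = u(k+1)}, by one (or a
#' configurable number of) gradient step(s) on the per-trial minibatch
#' \deqn{E_n = \frac{1}{K_n} \sum_{k \in D_n} \tfrac12 (d(k) - y(k))^2.}
#'
#' @name readout
NULL

#' Create a readout
#'
#' @param n_neurons reservoir size.
#' @param init initial weights: `"zeros"` (default) or a numeric vector.
#' @return a `readout` list with `w_out` (length-N vector).
#' @export
new_readout <- function(n_neurons, init = "zeros") {
  w <- if (is.numeric(init)) {
    stopifnot(length(init) == n_neurons)
    as.numeric(init)
  } else {
    numeric(n_neurons)
  }
  structure(list(w_out = w), class = "readout")
}

#' Readout training configuration
#'
#' @param eta gradient-descent learning rate (default 0.01).
#' @param steps_per_minibatch gradient steps applied per trial (default 1,
#'   i.e. pure online minibatch descent).
#' @param optimize master switch; when `FALSE` the readout is never updated
#'   (the no-optimization variant).
#' @return a `training_config` list.
#' @export
training_config <- function(eta = 0.01, steps_per_minibatch = 1L,
                            optimize = TRUE) {
  stopifnot(eta > 0, steps_per_minibatch >= 0)
  structure(list(eta = eta,
                 steps_per_minibatch = as.integer(steps_per_minibatch),
                 optimize = isTRUE(optimize)),
            class = "training_config")
}

#' Readout output for one state vector
#'
#' @param readout a `readout`.
#' @param x state vector.
#' @return scalar y = W_out . x
#' @export
compute_output <- function(readout, x) {
  if (length(readout$w_out) != length(x)) stop("dimension mismatch")
  sum(readout$w_out * x)
}

#' One-step-ahead prediction targets for a stimulus
#'
#' d(k) = u(k+1); the final sample has no target, so a length-K stimulus
#' yields K-1 targets.
#'
#' @param stimulus stimulus list with `processed` waveform, or numeric series.
#' @return numeric target series of length K-1.
#' @export
one_step_targets <- function(stimulus) {
  u <- if (is.numeric(stimulus)) stimulus else stimulus$processed$samples
  u[-1]
}

#' Build the per-trial minibatch from a recorded state trajectory
#'
#' The state after consuming u(k) predicts u(k+1), so row k of the state
#' matrix pairs with target d(k) = u(k+1) and the last state is dropped.
#'
#' @param states K x N state matrix from [run_trial()].
#' @param stimulus the presented stimulus (or its numeric input series,
#'   without input gain).
#' @return list with `X` ((K-1) x N) and `d` (length K-1).
#' @export
prediction_batch <- function(states, stimulus) {
  d <- one_step_targets(stimulus)
  K <- length(d) + 1
  stopifnot(nrow(states) == K)
  list(X = states[-K, , drop = FALSE], d = d)
}

#' Mean half-squared prediction error of a minibatch
#'
#' @param readout a `readout`.
#' @param batch list with `X`, `d` (see [prediction_batch()]).
#' @return E_n = (1/K_n) sum_k 0.5 (d(k) - y(k))^2
#' @export
minibatch_error <- function(readout, batch) {
  if (length(batch$d) == 0) stop("empty minibatch")
  y <- as.numeric(batch$X %*% readout$w_out)
  mean(0.5 * (batch$d - y)^2)
}

#' One gradient-descent step on a minibatch
#'
#' The gradient of E_n with respect to W_out is
#' -(1/K_n) sum_k (d(k) - y(k)) x(k); the weights move against it scaled by
#' eta.
#'
#' @param readout a `readout`.
#' @param batch list with `X`, `d`.
#' @param eta learning rate.
#' @return updated `readout`.
#' @export
gradient_step <- function(readout, batch, eta) {
  y <- as.numeric(batch$X %*% readout$w_out)
  resid <- batch$d - y
  grad <- -as.numeric(crossprod(batch$X, resid)) / length(batch$d)
  readout$w_out <- readout$w_out - eta * grad
  readout
}

#' Train the readout on one trial (pseudo-online minibatch descent)
#'
#' Applies `steps_per_minibatch` gradient steps on the trial's minibatch;
#' a no-op when optimization is switched off.
#'
#' @param readout a `readout`.
#' @param states K x N state matrix of the trial.
#' @param stimulus the presented stimulus.
#' @param config a [training_config()].
#' @return updated `readout`.
#' @export
train_readout_online <- function(readout, states, stimulus, config) {
  if (!config$optimize || config$steps_per_minibatch == 0) return(readout)
  batch <- prediction_batch(states, stimulus)
  for (i in seq_len(config$steps_per_minibatch)) {
    readout <- gradient_step(readout, batch, config$eta)
  }
  readout
}
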