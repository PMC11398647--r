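#' Full simulation experiment: paired training, evaluation, sweep
#'
#' The study design: for each spectral radius, two reservoirs sharing the same
#' random weights, input weights, stimulus session, presentation order and
#' per-trial seeds are trained on the 20-stimulus NRD session — one with Oja
#' plasticity (Hebbian arm) and one without (non-Hebbian arm).  Both arms
#' optionally train a linear readout by minibatch gradient descent during the
#' session.  Evaluation then freezes plasticity and optimization and presents
#' each test stimulus from fresh initial states, measuring inter-segment
#' consistency (output and node level) and prediction error, with a paired
#' sign-flip surrogate test comparing the arms at each radius.
#'
#' @name experiment
NULL

#' Sweep configuration
#'
#' @param radii spectral radii to sweep (default 0.1 to 2.0 in steps of 0.1).
#' @param n_neurons reservoir size (default 500).
#' @param density recurrent connection density (default 0.1).
#' @param alpha Oja learning rate (default 1e-7).
#' @param noise_sigma intrinsic noise SD (default 1e-3).
#' @param input_gain input gain applied to unit-RMS stimuli (default 0.1).
#' @param update_rule reservoir update form, `"standard"` (default) or
#'   `"integrator"` (see [reservoir_config()]).
#' @param oja_timing plasticity timing, `"simultaneous"` (default) or
#'   `"prepost"` (see [reservoir_config()]).
#' @param eta readout learning rate (default 0.01).
#' @param optimize_readout train the readout during the session (default
#'   TRUE); when FALSE consistency is evaluated at the reservoir-node level.
#' @param n_test_runs test presentations per stimulus kind (default 200).
#' @param test_kinds stimulus kinds evaluated at test (default RN and RefRN;
#'   add "N"/"RefN" for the control comparisons).
#' @param node_sample_size number of randomly sampled reservoir nodes for
#'   node-level consistency (default 5).
#' @param n_surrogates surrogates for the rank-order test (default 5000).
#' @param track_rho recompute the spectral radius after training (dense
#'   eigendecomposition per arm and radius); switch off when the drift table
#'   is not needed.
#' @param master_seed seed from which every other seed is derived.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(radii = seq(0.1, 2.0, by = 0.1),
                         n_neurons = 500, density = 0.1,
                         alpha = 1e-7, noise_sigma = 1e-3, input_gain = 0.1,
                         update_rule = c("standard", "integrator"),
                         oja_timing = c("simultaneous", "prepost"),
                         eta = 0.01, optimize_readout = TRUE,
                         n_test_runs = 200,
                         test_kinds = c("RN", "RefRN"),
                         node_sample_size = 5, n_surrogates = 5000,
                         track_rho = TRUE, master_seed = 1L) {
  update_rule <- match.arg(update_rule)
  oja_timing <- match.arg(oja_timing)
  stopifnot(length(radii) >= 1, all(radii > 0), n_test_runs >= 1,
            all(test_kinds %in% STIM_KINDS))
  structure(list(radii = radii, n_neurons = n_neurons, density = density,
                 alpha = alpha, noise_sigma = noise_sigma,
                 input_gain = input_gain, update_rule = update_rule,
                 oja_timing = oja_timing,
                 eta = eta, optimize_readout = optimize_readout,
                 n_test_runs = n_test_runs, test_kinds = test_kinds,
                 node_sample_size = node_sample_size,
                 n_surrogates = n_surrogates, track_rho = isTRUE(track_rho),
                 master_seed = as.integer(master_seed)),
            class = "sweep_config")
}

arm_names <- c("hebbian", "nonhebbian")

#' Train a paired Hebbian/non-Hebbian reservoir at one spectral radius
#'
#' Both arms are initialized from the same seed (identical W_random, W_in),
#' see the same session in the same order, and share per-trial initial-state
#' and noise seeds; they differ only in whether Oja's rule runs during the
#' trials.
#'
#' @param radius desired spectral radius.
#' @param session a `stimulus_session`.
#' @param config a [sweep_config()].
#' @return a `trained_pair`: per arm a list with `net`, `readout`,
#'   `rho_before`, `rho_after`, `train_errors` (per-trial minibatch error),
#'   plus `radius` and `failed` flag.
#' @export
train_pair <- function(radius, session, config) {
  rc <- reservoir_config(
    n_neurons = config$n_neurons, density = config$density,
    spectral_radius = radius, noise_sigma = config$noise_sigma,
    input_gain = config$input_gain, update_rule = config$update_rule,
    oja_timing = config$oja_timing,
    init_seed = derive_seed(config$master_seed, "net")
  )
  tc <- training_config(eta = config$eta, optimize = config$optimize_readout)
  base_net <- init_reservoir(rc)
  out <- list(radius = radius, failed = FALSE)
  for (arm in arm_names) {
    plastic <- arm == "hebbian"
    net <- base_net
    readout <- new_readout(config$n_neurons)
    errs <- numeric(length(session$stimuli))
    overflow <- FALSE
    for (t in seq_along(session$stimuli)) {
      stim <- session$stimuli[[t]]
      trial_seed <- derive_seed(config$master_seed, "train_trial", t)
      tr <- run_trial(net, stim, trial_seed, plastic = plastic,
                      alpha = config$alpha)
      if (tr$overflow) { overflow <- TRUE; break }
      net <- tr$net
      batch <- prediction_batch(tr$states, stim)
      errs[t] <- minibatch_error(readout, batch)
      readout <- train_readout_online(readout, tr$states, stim, tc)
    }
    out[[arm]] <- list(
      net = net, readout = readout,
      rho_before = radius,
      rho_after = if (overflow || !isTRUE(config$track_rho)) NA_real_ else
        spectral_radius(net$W),
      train_errors = errs, overflow = overflow
    )
    if (overflow) out$failed <- TRUE
  }
  class(out) <- "trained_pair"
  out
}

#' Evaluate a trained pair on the test corpus
#'
#' Plasticity and readout optimization are halted; every test run starts from
#' a fresh seeded initial state.  The two arms see the same stimuli but draw
#' independent initial states and noise; observations are paired by run
#' index.
#'
#' @param pair a `trained_pair`.
#' @param test_set a `test_set` covering `config$test_kinds`.
#' @param config a [sweep_config()].
#' @return list: `consistency` (long data.frame: radius, plastic, kind, run,
#'   level, node_id, r), `run_rmse` (per-run RMSE scalars), `rmse_series`
#'   (per-condition per-time RMSE), `inter_trial` (per condition), node ids.
#' @export
evaluate_pair <- function(pair, test_set, config) {
  if (pair$failed) stop("cannot evaluate a failed (overflowed) pair")
  node_ids <- sample_nodes(config)
  n_runs <- min(config$n_test_runs, test_set$n_runs)
  kinds <- intersect(config$test_kinds, test_set$kinds)
  # every test run starts from its own initial state and noise stream; the
  # two arms get independent streams (they share only the stimuli), so the
  # run-paired differences carry genuine trial-to-trial variability
  arm_seeds <- lapply(arm_names, function(arm) {
    vapply(seq_len(n_runs), function(r) {
      derive_seed(config$master_seed, "test_trial", arm, r)
    }, integer(1))
  })
  names(arm_seeds) <- arm_names
  cons <- list()
  rrmse <- list()
  series_acc <- list()
  itc <- list()
  for (kind in kinds) {
    K <- length(test_set[[kind]][[1]]$processed$samples)
    U <- vapply(test_set[[kind]][seq_len(n_runs)],
                function(s) s$processed$samples, numeric(K))
    for (arm in arm_names) {
      plastic <- arm == "hebbian"
      bt <- run_test_batch(pair[[arm]]$net, U, arm_seeds[[arm]],
                           pair[[arm]]$readout$w_out, node_ids)
      y <- bt$y
      resid <- U[-1, , drop = FALSE] - y[-K, , drop = FALSE]
      r_out <- columnwise_intersegment(y)
      node_r <- vapply(bt$nodes, columnwise_intersegment,
                       numeric(n_runs))  # n_runs x M
      key <- paste(arm, kind, sep = ".")
      out_df <- data.frame(radius = pair$radius, plastic = plastic,
                           kind = kind, run = seq_len(n_runs),
                           level = "output", node_id = NA_integer_,
                           r = r_out)
      cons[[key]] <- if (length(node_ids) == 0) out_df else rbind(
        out_df,
        data.frame(radius = pair$radius, plastic = plastic, kind = kind,
                   run = rep(seq_len(n_runs), times = length(node_ids)),
                   level = "node",
                   node_id = rep(node_ids, each = n_runs),
                   r = as.numeric(node_r))
      )
      rrmse[[key]] <- sqrt(colMeans(resid^2))
      series_acc[[key]] <- sqrt(rowMeans(resid^2))
      itc[[key]] <- if (n_runs >= 2) {
        as.numeric(inter_trial_consistency(
          lapply(seq_len(n_runs), function(i) y[, i]), window = 200))
      } else NA_real_
    }
  }
  list(consistency = do.call(rbind, cons),
       run_rmse = rrmse, rmse_series = series_acc, inter_trial = itc,
       node_ids = node_ids, n_runs = n_runs, radius = pair$radius)
}

# inter-segment correlation of every column of a K x R series matrix;
# zero-variance windows give NA
columnwise_intersegment <- function(y, window = 200, segment = 1000) {
  w1 <- y[1:window, , drop = FALSE]
  w2 <- y[(segment + 1):(segment + window), , drop = FALSE]
  s1 <- apply(w1, 2, sd)
  s2 <- apply(w2, 2, sd)
  out <- rep(NA_real_, ncol(y))
  ok <- s1 > 0 & s2 > 0
  if (any(ok)) {
    m1 <- sweep(w1[, ok, drop = FALSE], 2, colMeans(w1[, ok, drop = FALSE]))
    m2 <- sweep(w2[, ok, drop = FALSE], 2, colMeans(w2[, ok, drop = FALSE]))
    out[ok] <- colSums(m1 * m2) / ((window - 1) * s1[ok] * s2[ok])
  }
  out
}

sample_nodes <- function(config) {
  set.seed(derive_seed(config$master_seed, "nodes"))
  sort(sample(config$n_neurons, config$node_sample_size))
}

#' Per-run consistency statistic for the paired test
#'
#' Output-level inter-segment correlation when the readout was optimized;
#' mean over the sampled reservoir nodes otherwise (the zero-initialized,
#' never-optimized readout outputs a constant, whose correlation is
#' undefined).
#'
#' @param consistency long consistency table from [evaluate_pair()].
#' @param kind stimulus kind.
#' @param plastic arm selector.
#' @param level `"output"` or `"node"`.
#' @return numeric vector ordered by run index.
#' @keywords internal
per_run_consistency <- function(consistency, kind, plastic, level) {
  sub <- consistency[consistency$kind == kind &
                       consistency$plastic == plastic &
                       consistency$level == level, ]
  if (level == "node") {
    agg <- tapply(sub$r, sub$run, mean, na.rm = TRUE)
    as.numeric(agg[order(as.integer(names(agg)))])
  } else {
    sub$r[order(sub$run)]
  }
}

#' Run the full spectral-radius sweep
#'
#' Builds one stimulus session and one test corpus (shared across all radii
#' and both arms), trains the paired reservoirs at every radius, evaluates
#' them, and runs the paired surrogate tests with Bonferroni correction over
#' radius levels x stimulus comparisons.
#'
#' @param config a [sweep_config()].
#' @param session optionally a pre-built `stimulus_session` (rebuilt from the
#'   master seed when NULL).
#' @param test_set optionally a pre-built `test_set`.
#' @param progress print one line per radius.
#' @return a `sweep_results` list: `consistency`, `tests`, `error_tests`,
#'   `rmse`, `nrmse_runs`, `inter_trial`, `rho_drift`, `train_errors`,
#'   `failed_radii`, `config`.
#' @export
run_sweep <- function(config, session = NULL, test_set = NULL,
                      progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (is.null(session)) session <- nrd_session(config$master_seed)
  if (is.null(test_set)) {
    test_set <- build_test_set(session, n_runs = config$n_test_runs,
                               seed = derive_seed(config$master_seed, "test"),
                               kinds = config$test_kinds)
  }
  level <- if (config$optimize_readout) "output" else "node"
  comparisons <- intersect(c("RN", "RefRN", "RefN", "N"), config$test_kinds)
  m <- length(config$radii) * length(comparisons)

  cons_all <- list(); tests <- list(); err_tests <- list()
  rmse_rows <- list(); nrmse_runs <- list(); itc_rows <- list()
  rho_rows <- list(); terr_rows <- list(); failed <- numeric(0)

  for (ri in seq_along(config$radii)) {
    rho <- config$radii[ri]
    pair <- train_pair(rho, session, config)
    for (arm in arm_names) {
      rho_rows[[length(rho_rows) + 1L]] <- data.frame(
        radius = rho, arm = arm, rho_before = pair[[arm]]$rho_before,
        rho_after = pair[[arm]]$rho_after)
      terr_rows[[length(terr_rows) + 1L]] <- data.frame(
        radius = rho, arm = arm,
        trial = seq_along(pair[[arm]]$train_errors),
        E_n = pair[[arm]]$train_errors)
    }
    if (pair$failed) {
      failed <- c(failed, rho)
      if (progress) message(sprintf("radius %.1f: overflow, skipped", rho))
      next
    }
    ev <- evaluate_pair(pair, test_set, config)
    cons_all[[ri]] <- ev$consistency

    # paired consistency tests, Hebbian vs non-Hebbian per stimulus kind
    for (kind in comparisons) {
      a <- per_run_consistency(ev$consistency, kind, TRUE, level)
      b <- per_run_consistency(ev$consistency, kind, FALSE, level)
      st <- paired_surrogate_test(
        a, b, n_surrogates = config$n_surrogates,
        seed = derive_seed(config$master_seed, "surr", ri, kind))
      tests[[length(tests) + 1L]] <- data.frame(
        radius = rho, comparison = kind, level = level,
        observed_diff = st$observed_diff,
        percentile_rank = st$percentile_rank,
        p_raw = st$p_raw, p_adj = bonferroni_adjust(st$p_raw, m),
        n_surrogates = st$n_surrogates, m = m)
    }

    # prediction error: per-condition RMSE series, NRMSE normalization over
    # the four Hebb/non-Hebb x RN/RefRN conditions at this radius
    if (all(c("RN", "RefRN") %in% config$test_kinds)) {
      keys <- c("hebbian.RN", "hebbian.RefRN",
                "nonhebbian.RN", "nonhebbian.RefRN")
      norm <- mean(unlist(ev$rmse_series[keys]))
      for (key in keys) {
        arm <- sub("\\..*", "", key); kind <- sub(".*\\.", "", key)
        rmse_rows[[length(rmse_rows) + 1L]] <- data.frame(
          radius = rho, arm = arm, kind = kind,
          mean_rmse = mean(ev$rmse_series[[key]]),
          mean_nrmse = mean(ev$rmse_series[[key]]) / norm)
        nrmse_runs[[length(nrmse_runs) + 1L]] <- data.frame(
          radius = rho, arm = arm, kind = kind,
          run = seq_along(ev$run_rmse[[key]]),
          nrmse = ev$run_rmse[[key]] / norm)
      }
      # RefRN vs RN prediction-error difference within each arm
      for (arm in arm_names) {
        a <- ev$run_rmse[[paste0(arm, ".RefRN")]] / norm
        b <- ev$run_rmse[[paste0(arm, ".RN")]] / norm
        st <- paired_surrogate_test(
          a, b, n_surrogates = config$n_surrogates,
          seed = derive_seed(config$master_seed, "surr_err", ri, arm))
        err_tests[[length(err_tests) + 1L]] <- data.frame(
          radius = rho, arm = arm, observed_diff = st$observed_diff,
          p_raw = st$p_raw,
          p_adj = bonferroni_adjust(st$p_raw, length(config$radii) * 2))
      }
    }

    for (key in names(ev$inter_trial)) {
      itc_rows[[length(itc_rows) + 1L]] <- data.frame(
        radius = rho, arm = sub("\\..*", "", key),
        kind = sub(".*\\.", "", key), inter_trial_r = ev$inter_trial[[key]])
    }
    if (progress) message(sprintf("radius %.1f done", rho))
  }

  structure(list(
    consistency = do.call(rbind, cons_all),
    tests = do.call(rbind, tests),
    error_tests = do.call(rbind, err_tests),
    rmse = do.call(rbind, rmse_rows),
    nrmse_runs = do.call(rbind, nrmse_runs),
    inter_trial = do.call(rbind, itc_rows),
    rho_drift = do.call(rbind, rho_rows),
    train_errors = do.call(rbind, terr_rows),
    failed_radii = failed,
    config = config
  ), class = "sweep_results")
}

#' Mean Hebbian-minus-non-Hebbian consistency difference per radius
#'
#' The headline selectivity curve: for one stimulus kind, the difference of
#' mean per-run inter-segment correlation between the Hebbian and
#' non-Hebbian arm at each radius.
#'
#' @param results a `sweep_results`.
#' @param kind stimulus kind (default "RefRN").
#' @param level `"output"`, `"node"`, or NULL to use the level matching the
#'   sweep's readout setting.
#' @return data.frame with `radius`, `diff`, `mean_hebb`, `mean_nonhebb`.
#' @export
selectivity_curve <- function(results, kind = "RefRN", level = NULL) {
  if (is.null(level)) {
    level <- if (results$config$optimize_readout) "output" else "node"
  }
  cons <- results$consistency
  radii <- sort(unique(cons$radius))
  rows <- lapply(radii, function(rho) {
    sub <- cons[cons$radius == rho, ]
    a <- per_run_consistency(sub, kind, TRUE, level)
    b <- per_run_consistency(sub, kind, FALSE, level)
    data.frame(radius = rho, diff = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
               mean_hebb = mean(a, na.rm = TRUE),
               mean_nonhebb = mean(b, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
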