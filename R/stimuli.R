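#' Stimulus synthesis for the noise repetition-detection (NRD) task
#'
#' The stimulus corpus consists of four classes of 1 s white-noise tokens:
#' fresh noise (N), fresh repeated noise (RN, one 0.5 s token concatenated
#' twice), referenced noise (RefN, one fixed N realization re-occurring across
#' trials) and referenced repeated noise (RefRN, one fixed RN realization
#' re-occurring across trials).  Raw tokens are Gaussian white noise at 44 kHz,
#' passed through an A-weighting filter, resampled to 2 kHz, and rescaled to
#' unit RMS.
#'
#' @name stimuli
NULL

STIM_KINDS <- c("N", "RN", "RefN", "RefRN")
RAW_FS <- 44000
PROC_FS <- 2000
STIM_DUR <- 1

#' Construct a waveform object
#'
#' @param samples numeric vector of amplitudes.
#' @param fs sampling rate in Hz.
#' @return a `waveform` (list with `samples`, `fs`).
#' @export
waveform <- function(samples, fs) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs), class = "waveform")
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Generate seeded Gaussian white noise
#'
#' @param n_samples number of samples (>= 0).
#' @param seed integer seed; the waveform is a pure function of it.
#' @param fs sampling rate attached to the result (Hz).
#' @return a [waveform] of i.i.d. N(0, 1) samples.
#' @export
generate_white_noise <- function(n_samples, seed, fs = RAW_FS) {
  if (length(n_samples) != 1L || n_samples < 0) {
    stop("n_samples must be a single non-negative count")
  }
  set.seed(seed)
  waveform(rnorm(n_samples), fs)
}

#' Generate one raw 1 s stimulus at 44 kHz
#'
#' For the repeated kinds (RN, RefRN) a single 22,000-sample token is drawn
#' and concatenated twice, so the second half equals the first half
#' bit-exactly.  For the non-repeated kinds (N, RefN) a single fresh
#' 44,000-sample realization is drawn.
#'
#' @param kind one of `"N"`, `"RN"`, `"RefN"`, `"RefRN"`.
#' @param seed realization seed.
#' @return a [waveform] of 44,000 samples at 44 kHz.
#' @export
make_raw_stimulus <- function(kind, seed) {
  kind <- match.arg(kind, STIM_KINDS)
  n_raw <- RAW_FS * STIM_DUR
  if (kind %in% c("RN", "RefRN")) {
    half <- generate_white_noise(n_raw / 2, seed)
    waveform(c(half$samples, half$samples), RAW_FS)
  } else {
    generate_white_noise(n_raw, seed)
  }
}

#' Digital A-weighting filter coefficients
#'
#' Discretizes the standard analog A-weighting transfer function (zeros at DC,
#' double poles at 20.6 Hz and 12194 Hz, single poles at 107.7 Hz and
#' 737.9 Hz) by the bilinear transform at the given rate, then rescales the
#' numerator so the gain at exactly 1 kHz is unity.
#'
#' @param fs sampling rate in Hz (>= 8 kHz so the filter is well-conditioned).
#' @return list with `b`, `a` polynomial coefficients.
#' @keywords internal
a_weighting_coefficients <- function(fs) {
  if (fs < 8000) stop("fs too low for a well-conditioned A-weighting filter")
  f_pole <- c(20.598997, 107.65265, 737.86223, 12194.217)
  w <- 2 * pi * f_pole
  s_zeros <- rep(0, 4)
  s_poles <- c(-w[1], -w[1], -w[2], -w[3], -w[4], -w[4])
  zz <- signal::bilinear(s_zeros, s_poles, w[4]^2, T = 1 / fs)
  arma <- signal::as.Arma(zz)
  # exact unity gain at 1 kHz
  z <- exp(2i * pi * 1000 / fs)
  gain <- Mod(sum(arma$b * z^-(seq_along(arma$b) - 1)) /
                sum(arma$a * z^-(seq_along(arma$a) - 1)))
  list(b = arma$b / gain, a = arma$a)
}

#' Apply the A-weighting filter to a waveform
#'
#' @param w a [waveform] with `fs >= 8000` Hz.
#' @return filtered [waveform], same length and rate.
#' @export
a_weighting <- function(w) {
  stopifnot(inherits(w, "waveform"))
  co <- a_weighting_coefficients(w$fs)
  waveform(as.numeric(signal::filter(co$b, co$a, w$samples)), w$fs)
}

# Kaiser-windowed anti-aliasing FIR for one decimation ratio; cached because
# design is much more expensive than the (FFT) filtering itself.
.fir_cache <- new.env(parent = emptyenv())

resample_fir <- function(fs_in, fs_out) {
  key <- paste(fs_in, fs_out, sep = ">")
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  nyq <- fs_out / 2
  # passband to 0.9 Nyquist, stopband from Nyquist; ~70 dB Kaiser
  beta <- 7.0
  trans <- 2 * pi * (0.1 * nyq) / fs_in
  n_taps <- ceiling((beta / 0.1102 + 8.7) / (2.285 * trans))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1  # odd length -> integer delay
  cutoff <- 0.95 * nyq / (fs_in / 2)
  h <- signal::fir1(n_taps - 1, cutoff, type = "low",
                    window = signal::kaiser(n_taps, beta))
  h <- h / sum(h)  # exact unity DC gain
  .fir_cache[[key]] <- h
  h
}

#' Resample a waveform to a lower rate
#'
#' Anti-alias low-pass filtering (Kaiser-windowed FIR, zero-phase by
#' group-delay compensation with edge replication) followed by decimation.
#' Only integer decimation ratios are supported, which covers the 44 kHz to
#' 2 kHz pipeline.
#'
#' @param w a [waveform].
#' @param fs_out target rate in Hz, must divide `w$fs` and be lower.
#' @return [waveform] at `fs_out` with `round(length(w) * fs_out / w$fs)`
#'   samples.
#' @export
resample_waveform <- function(w, fs_out) {
  stopifnot(inherits(w, "waveform"))
  if (fs_out >= w$fs) stop("fs_out must be below the input rate")
  q <- w$fs / fs_out
  if (abs(q - round(q)) > 1e-9) stop("only integer decimation ratios supported")
  q <- round(q)
  h <- resample_fir(w$fs, fs_out)
  delay <- (length(h) - 1) / 2
  x <- w$samples
  # edge replication keeps constants exactly constant and confines transients
  xp <- c(rep(x[1], delay), x, rep(x[length(x)], delay))
  y <- as.numeric(signal::fftfilt(h, xp))
  y <- y[(2 * delay + 1):(2 * delay + length(x))]
  n_out <- round(length(x) * fs_out / w$fs)
  waveform(y[1 + (seq_len(n_out) - 1) * q], fs_out)
}

#' Process a raw stimulus: A-weighting, resampling, unit-RMS normalization
#'
#' @param raw a 44 kHz [waveform].
#' @param fs_out processed rate (default 2 kHz).
#' @param normalize rescale the processed waveform to unit RMS (default TRUE),
#'   so the reservoir input power does not depend on filter gain conventions.
#' @return processed [waveform].
#' @export
process_stimulus <- function(raw, fs_out = PROC_FS, normalize = TRUE) {
  out <- resample_waveform(a_weighting(raw), fs_out)
  if (normalize) {
    rms <- sqrt(mean(out$samples^2))
    if (rms > 0) out$samples <- out$samples / rms
  }
  out
}

#' Build one stimulus (raw + processed) of a given kind
#'
#' @param kind stimulus kind.
#' @param seed realization seed.
#' @param keep_raw keep the 44 kHz raw waveform in the result (default FALSE
#'   to keep large corpora light).
#' @return list with `kind`, `seed`, `processed` (and optionally `raw`).
#' @export
make_stimulus <- function(kind, seed, keep_raw = FALSE) {
  raw <- make_raw_stimulus(kind, seed)
  out <- list(kind = kind, seed = seed, processed = process_stimulus(raw))
  if (keep_raw) out$raw <- raw
  out
}

#' Build the 20-stimulus NRD training session
#'
#' Five realizations of each of the four kinds.  All five RefRN presentations
#' share one frozen realization (`ref_rn_seed`); likewise RefN
#' (`ref_n_seed`).  N and RN presentations are statistically independent fresh
#' draws.  Presentation order is a seeded uniform shuffle constrained so the
#' final presentation is an N stimulus.
#'
#' @param ref_rn_seed,ref_n_seed seeds of the frozen referenced realizations.
#' @param order_seed seed of the presentation-order shuffle.
#' @param fresh_seeds integer vector of 10 seeds for the five N and five RN
#'   fresh realizations.
#' @return a `stimulus_session`: list with `stimuli` (ordered list of 20),
#'   `kinds`, and the seeds used.
#' @export
build_session <- function(ref_rn_seed, ref_n_seed, order_seed, fresh_seeds) {
  stopifnot(length(fresh_seeds) == 10)
  n_seeds <- fresh_seeds[1:5]
  rn_seeds <- fresh_seeds[6:10]
  ref_rn <- make_stimulus("RefRN", ref_rn_seed)
  ref_n <- make_stimulus("RefN", ref_n_seed)
  pool <- c(
    lapply(n_seeds, function(s) make_stimulus("N", s)),
    lapply(rn_seeds, function(s) make_stimulus("RN", s)),
    rep(list(ref_n), 5),
    rep(list(ref_rn), 5)
  )
  set.seed(order_seed)
  n_positions <- 1:5  # indices of the N stimuli in the pool
  last <- sample(n_positions, 1)
  rest <- sample(setdiff(seq_along(pool), last))
  ord <- c(rest, last)
  stimuli <- pool[ord]
  structure(list(
    stimuli = stimuli,
    kinds = vapply(stimuli, `[[`, character(1), "kind"),
    ref_rn_seed = ref_rn_seed, ref_n_seed = ref_n_seed,
    order_seed = order_seed, fresh_seeds = fresh_seeds
  ), class = "stimulus_session")
}

#' Build an NRD session from a single master seed
#'
#' Convenience wrapper deriving all realization and order seeds from one
#' master seed with [derive_seed()].
#'
#' @param master_seed integer master seed.
#' @return a `stimulus_session`.
#' @export
nrd_session <- function(master_seed) {
  build_session(
    ref_rn_seed = derive_seed(master_seed, "ref", "RefRN"),
    ref_n_seed = derive_seed(master_seed, "ref", "RefN"),
    order_seed = derive_seed(master_seed, "order"),
    fresh_seeds = c(
      vapply(1:5, function(i) derive_seed(master_seed, "train", "N", i), 1L),
      vapply(1:5, function(i) derive_seed(master_seed, "train", "RN", i), 1L)
    )
  )
}

#' Build the test corpus
#'
#' Per stimulus kind, `n_runs` stimuli.  N and RN test realizations are fresh
#' (their seeds are disjoint from the training seeds by construction and
#' checked); RefN and RefRN test stimuli are exactly the frozen training
#' realizations.  Since the referenced stimuli are identical across runs they
#' are stored once and recycled.
#'
#' @param session a `stimulus_session`.
#' @param n_runs number of test runs per kind (default 200).
#' @param seed seed stream for the fresh test realizations.
#' @param kinds which stimulus kinds to include (default all four); restricting
#'   the set avoids synthesizing fresh realizations that an analysis does not
#'   evaluate.
#' @return a `test_set`: list with per-kind stimulus lists, `kinds` and
#'   `n_runs`.
#' @export
build_test_set <- function(session, n_runs = 200, seed = 1,
                           kinds = STIM_KINDS) {
  stopifnot(inherits(session, "stimulus_session"), n_runs >= 1,
            all(kinds %in% STIM_KINDS))
  used <- c(session$fresh_seeds, session$ref_rn_seed, session$ref_n_seed)
  fresh <- function(kind, i) {
    s <- derive_seed(seed, "test", kind, i)
    while (s %in% used) s <- derive_seed(s, "collision")
    make_stimulus(kind, s)
  }
  out <- list()
  if ("N" %in% kinds) {
    out$N <- lapply(seq_len(n_runs), function(i) fresh("N", i))
  }
  if ("RN" %in% kinds) {
    out$RN <- lapply(seq_len(n_runs), function(i) fresh("RN", i))
  }
  if ("RefN" %in% kinds) {
    ref_n <- session$stimuli[[match("RefN", session$kinds)]]
    out$RefN <- rep(list(ref_n), n_runs)
  }
  if ("RefRN" %in% kinds) {
    ref_rn <- session$stimuli[[match("RefRN", session$kinds)]]
    out$RefRN <- rep(list(ref_rn), n_runs)
  }
  out$kinds <- intersect(STIM_KINDS, kinds)
  out$n_runs <- n_runs
  out$seed <- seed
  structure(out, class = "test_set")
}
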