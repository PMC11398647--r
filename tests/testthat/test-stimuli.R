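test_that("white noise generation is Gaussian, sized, and reproducible", {
  expect_equal(length(generate_white_noise(0, 1)), 0)
  w <- generate_white_noise(44000, 7)
  expect_equal(length(w), 44000)
  expect_identical(w$samples, generate_white_noise(44000, 7)$samples)
  big <- generate_white_noise(1e5, 11)$samples
  expect_lt(abs(mean(big)), 4 / sqrt(1e5))
  expect_lt(abs(var(big) - 1), 0.05)
  expect_error(generate_white_noise(-1, 1), "non-negative")
})

test_that("raw stimuli repeat their half-tokens exactly when required", {
  rn <- make_raw_stimulus("RN", 3)$samples
  expect_length(rn, 44000)
  expect_identical(rn[1:22000], rn[22001:44000])
  refrn <- make_raw_stimulus("RefRN", 3)$samples
  expect_identical(refrn, rn)  # same construction, same seed
  n <- make_raw_stimulus("N", 3)$samples
  expect_length(n, 44000)
  expect_lt(abs(cor(n[1:22000], n[22001:44000])), 0.05)
})

test_that("A-weighting kills DC, is flat at 1 kHz, peaks near 3 kHz", {
  fs <- 44000
  # constant input is a step at t = 0; after the slow 20.6 Hz poles settle
  # (~340-sample time constant) the output must vanish
  dc <- a_weighting(waveform(rep(1, 20000), fs))$samples
  expect_lt(max(abs(dc[10000:20000])), 1e-4)

  t <- (0:(fs - 1)) / fs
  tone <- a_weighting(waveform(sin(2 * pi * 1000 * t), fs))$samples
  steady <- tone[20000:40000]
  gain_db <- 20 * log10((max(steady) - min(steady)) / 2)
  expect_lt(abs(gain_db), 0.2)

  noise <- a_weighting(generate_white_noise(fs, 5))$samples
  sp <- spec.pgram(ts(noise, frequency = fs), spans = 101, plot = FALSE)
  peak_hz <- sp$freq[which.max(sp$spec)]
  expect_gt(peak_hz, 2000)
  expect_lt(peak_hz, 4000)

  expect_error(a_weighting(waveform(rnorm(100), 4000)), "too low")
})

test_that("resampling decimates with DC preservation and passband fidelity", {
  fs <- 44000
  out <- resample_waveform(generate_white_noise(fs, 1), 2000)
  expect_equal(length(out), 2000)
  expect_equal(out$fs, 2000)

  const <- resample_waveform(waveform(rep(3.5, fs), fs), 2000)
  expect_equal(const$samples, rep(3.5, 2000), tolerance = 1e-9)

  t <- (0:(fs - 1)) / fs
  tone <- resample_waveform(waveform(sin(2 * pi * 900 * t), fs), 2000)
  t2 <- (0:1999) / 2000
  expected <- sin(2 * pi * 900 * t2)
  mid <- 200:1800
  expect_lt(max(abs(tone$samples[mid] - expected[mid])), 0.01)

  expect_error(resample_waveform(waveform(rnorm(100), 2000), 44000), "below")
})

test_that("processed stimuli are unit-RMS and keep the repeat structure", {
  st <- make_stimulus("RefRN", 13)
  p <- st$processed$samples
  expect_length(p, 2000)
  expect_equal(sqrt(mean(p^2)), 1, tolerance = 1e-12)
  # repetition survives filtering away from segment onsets
  # (0-based windows [200,1000) and [1200,2000))
  r <- cor(p[201:1000], p[1201:2000])
  expect_gt(r, 0.95)
  # fresh noise has no such structure
  pn <- make_stimulus("N", 13)$processed$samples
  expect_lt(abs(cor(pn[201:1000], pn[1201:2000])), 0.2)
})

test_that("training sessions have the required composition and order", {
  s <- build_session(ref_rn_seed = 1, ref_n_seed = 2, order_seed = 3,
                     fresh_seeds = 101:110)
  expect_length(s$stimuli, 20)
  expect_equal(as.vector(table(s$kinds)[c("N", "RN", "RefN", "RefRN")]),
               rep(5L, 4))
  expect_identical(s$kinds[20], "N")
  refs <- s$stimuli[s$kinds == "RefRN"]
  for (i in 2:5) expect_identical(refs[[i]]$processed$samples,
                                  refs[[1]]$processed$samples)
  s2 <- build_session(1, 2, 3, 101:110)
  expect_identical(
    lapply(s$stimuli, `[[`, "processed"),
    lapply(s2$stimuli, `[[`, "processed")
  )
  s3 <- nrd_session(99)
  expect_identical(s3$kinds[20], "N")
})

test_that("test sets keep referenced realizations and refresh the others", {
  s <- nrd_session(5)
  ts <- build_test_set(s, n_runs = 8, seed = 77)
  expect_length(ts$RefRN, 8)
  ref_train <- s$stimuli[[match("RefRN", s$kinds)]]
  for (i in 1:8) expect_identical(ts$RefRN[[i]]$processed$samples,
                                  ref_train$processed$samples)
  rn_test_seeds <- vapply(ts$RN, `[[`, numeric(1), "seed")
  expect_length(intersect(rn_test_seeds, s$fresh_seeds), 0)
  n_test_seeds <- vapply(ts$N, `[[`, numeric(1), "seed")
  expect_length(intersect(n_test_seeds, s$fresh_seeds), 0)
  # restricting kinds skips the others
  ts2 <- build_test_set(s, n_runs = 3, seed = 77, kinds = c("RN", "RefRN"))
  expect_null(ts2$N)
  expect_length(ts2$RN, 3)
})
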