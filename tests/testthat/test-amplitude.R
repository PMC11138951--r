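test_that("amplitude bins split [0,100]% into 10 closed-open intervals", {
  expect_equal(amplitude_bin(0), 1)
  expect_equal(amplitude_bin(37), 4)   # [30, 40)% is the fourth bin
  expect_equal(amplitude_bin(30), 4)
  expect_equal(amplitude_bin(99.9), 10)
  expect_equal(amplitude_bin(100), 10) # top edge closed
})

test_that("log-normal fits recover known parameters (seeded simulation)", {
  set.seed(99)
  mu <- -0.5; sig <- 0.4
  lf_ref <- 10
  cycles <- lapply(1:5000, function(i) {
    lf <- runif(1, 3.01, 3.9)  # all cycles in the [30,40)% bin of ref 10
    list(lf_amplitude = lf,
         ff_amplitudes = lf * rlnorm(1, mu, sig),
         rest_amplitudes = lf * rlnorm(1, -2, 0.3))
  })
  model <- fit_amplitude_model(cycles, lf_amps = runif(50, 1, 10),
                               lf_ref = lf_ref)
  expect_lt(abs(model$ff_bins[4, "meanlog"] - mu), abs(mu) * 0.05)
  expect_lt(abs(model$ff_bins[4, "sdlog"] - sig), sig * 0.05)
  # single populated bin: all others inherit its parameters
  expect_true(all(apply(model$ff_bins, 1, identical, model$ff_bins[4, ])))
  expect_true(all(model$ff_bins[, "sdlog"] > 0))
  expect_equal(nrow(model$ff_bins), 10)
  expect_equal(nrow(model$rest_bins), 10)
})

test_that("empty observations are rejected", {
  expect_error(fit_amplitude_model(list(), numeric(0), numeric(0)),
               "without any observations")
})

test_that("amplitude draws are positive, conditional and reproducible", {
  model <- default_amplitude_model()
  set.seed(7); a <- sample_amplitude(model, "FF", lf_amplitude_pct = 55)
  set.seed(7); b <- sample_amplitude(model, "FF", lf_amplitude_pct = 55)
  expect_identical(a, b)
  expect_gt(a, 0)
  expect_error(sample_amplitude(model, "FF"), "lf_amplitude_pct")

  # degenerate log-normal: sdlog ~ 0 collapses onto exp(meanlog)
  m2 <- model
  m2$lf_params <- c(meanlog = log(2), sdlog = 1e-12)
  expect_equal(sample_amplitude(m2, "LF"), 2, tolerance = 1e-6)

  # Monte-Carlo: empirical log-mean within 3 standard errors of meanlog
  set.seed(11)
  bin <- amplitude_bin(15)
  draws <- replicate(1e4, sample_amplitude(model, "REST", 15))
  mu <- model$rest_bins[bin, "meanlog"]; sd <- model$rest_bins[bin, "sdlog"]
  expect_lt(abs(mean(log(draws)) - mu), 3 * sd / sqrt(1e4))
})

test_that("synthesized pools respect the segment invariants", {
  pools <- local_pools()
  for (kind in names(pools)) {
    for (seg in pools[[kind]]) expect_no_error(validate_segment(seg))
  }
  lens <- vapply(pools$LP, length, numeric(1))
  expect_true(all(lens < 25))
  expect_true(all(vapply(pools$LF, length, numeric(1)) >= 25))
})

test_that("far-field morphologies keep >90% of power below 100 Hz", {
  pools <- local_pools()
  for (seg in pools$FF[1:8]) {
    x <- seg$samples
    sp <- Mod(stats::fft(x))^2
    freqs <- (seq_along(sp) - 1) / length(sp) * 1000
    half <- freqs <= 500
    below <- sum(sp[half][freqs[half] < 100]) / sum(sp[half])
    expect_gt(below, 0.9)
  }
})

test_that("pool synthesis is deterministic under a fixed seed", {
  set.seed(31); p1 <- synth_segment_pool("LF", 5)
  set.seed(31); p2 <- synth_segment_pool("LF", 5)
  expect_identical(p1, p2)
})
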