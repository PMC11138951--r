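test_that("stimulus-response matching follows the first-in-window rule", {
  cfg <- decrement_config()
  stims <- iv("STIM", c(0, 500), c(4, 504), frame = 1000)
  resp <- iv("LF", c(120, 620), c(160, 660), frame = 1000)
  pairs <- match_stim_response(stims, resp, cfg)
  expect_equal(pairs$delta_t, c(120, 120))

  resp2 <- iv("LF", c(100, 520), c(140, 560), frame = 1000)
  pairs2 <- match_stim_response(stims, resp2, cfg)
  expect_equal(pairs2$delta_t, c(100, 20))

  # absent response
  none <- match_stim_response(stims, iv("LF", 120, 160, frame = 1000), cfg)
  expect_s3_class(none, "decrement_report")
  expect_equal(none$exclusion_reason, "no_response")

  # a single stimulus cannot define a drive + extrastimulus
  one <- match_stim_response(iv("STIM", 0, 4, frame = 1000), resp, cfg)
  expect_equal(one$exclusion_reason, "uncoordinated")

  # too-distant response
  far <- match_stim_response(
    iv("STIM", c(0, 1000), c(4, 1004), frame = 3000),
    iv("LF", c(400, 1400), c(440, 1440), frame = 3000), cfg)
  expect_equal(far$exclusion_reason, "too_distant")

  # spurious extra detections are resolved by drive-train consistency
  stims3 <- iv("STIM", c(0, 500, 1000), c(4, 504, 1004), frame = 2000)
  noisy <- iv("LF", c(55, 120, 618, 1122), c(75, 160, 658, 1162),
              frame = 2000)
  pairs3 <- match_stim_response(stims3, noisy, cfg)
  expect_equal(pairs3$delta_t, c(120, 118, 122))

  # a drive train without a common latency is uncoordinated
  erratic <- match_stim_response(stims3,
    iv("LF", c(100, 750, 1040), c(140, 790, 1080), frame = 2000), cfg)
  expect_equal(erratic$exclusion_reason, "uncoordinated")
})

test_that("pacing origin is decided by immediate adjacency", {
  stims <- iv("STIM", c(0, 500), c(4, 504), frame = 1000)
  lf_late <- iv("LF", c(120, 620), c(160, 660), frame = 1000)
  ff_adj <- iv("FF", c(15, 515), c(80, 580), frame = 1000)
  expect_equal(stim_origin(stims, lf_late, ff_adj), "ventricular_pacing")

  lf_adj <- iv("LF", c(10, 510), c(45, 545), frame = 1000)
  ff_late <- iv("FF", c(200, 700), c(280, 780), frame = 1000)
  expect_equal(stim_origin(stims, lf_adj, ff_late), "atrial_pacing")

  nothing <- stim_origin(stims, iv(frame = 1000), iv(frame = 1000))
  expect_s3_class(nothing, "decrement_report")
  expect_equal(nothing$exclusion_reason, "uncoordinated")
})

test_that("cross-correlation lag is exact on shifts and signs anticorrelation", {
  set.seed(3)
  a <- c(numeric(50), sin(seq(0, 6 * pi, length.out = 60)) *
           exp(-seq(0, 3, length.out = 60)), numeric(50))
  expect_equal(xcorr_lag(a, a)$lag_ms, 0)
  expect_equal(xcorr_lag(a, a)$peak, 1, tolerance = 1e-9)

  shift <- function(x, k) if (k > 0) c(numeric(k), x[1:(length(x) - k)]) else
    c(x[(1 - k):length(x)], numeric(-k))
  for (k in c(-20, -5, 5, 20))
    expect_equal(xcorr_lag(a, shift(a, k), max_lag_ms = 40)$lag_ms, k)

  neg <- xcorr_lag(a, -a)
  expect_equal(neg$lag_ms, 0)
  expect_equal(neg$peak, -1, tolerance = 1e-9)

  z <- xcorr_lag(numeric(30), a)
  expect_equal(z$lag_ms, 0); expect_equal(z$peak, 0)
})

test_that("decrement classification applies the strict 10 ms rule", {
  cfg <- decrement_config()
  mk <- function(dts) data.frame(stim_onset = seq_along(dts) * 500,
                                 resp_onset = seq_along(dts) * 500 + dts,
                                 resp_offset = seq_along(dts) * 500 + dts + 40,
                                 delta_t = dts)
  expect_equal(classify_decrement(mk(c(120, 135)), cfg)$label, "decremental")
  expect_equal(classify_decrement(mk(c(120, 128)), cfg)$label,
               "non_decremental")
  expect_equal(classify_decrement(mk(c(120, 130)), cfg)$label,
               "non_decremental")     # exactly 10 ms is not decremental
  expect_equal(classify_decrement(mk(120), cfg)$label, "excluded")

  # invariant to a global time translation of all events
  p <- mk(c(120, 135))
  p2 <- p; p2$stim_onset <- p2$stim_onset + 5000
  p2$resp_onset <- p2$resp_onset + 5000; p2$resp_offset <- p2$resp_offset + 5000
  expect_equal(classify_decrement(p2, cfg)$corrected_decrement_ms,
               classify_decrement(p, cfg)$corrected_decrement_ms)

  # dissimilar response morphology excludes the excerpt
  set.seed(4)
  w1 <- sin(seq(0, 4 * pi, length.out = 50))
  w2 <- rnorm(50)
  rep <- classify_decrement(mk(c(120, 135)), cfg, waveforms = list(w1, w2))
  expect_equal(rep$exclusion_reason, "morphology_mismatch")
})

test_that("the xcorr correction repairs onset-detection jitter", {
  cfg <- decrement_config()
  burst <- c(numeric(20), sin(seq(0, 8 * pi, length.out = 50)), numeric(20))
  # the S2 response onset was detected 6 ms late: delta_t inflated by 6,
  # and the extracted waveform starts 6 samples into the burst
  pairs <- data.frame(stim_onset = c(500, 1000),
                      resp_onset = c(620, 1146),
                      resp_offset = c(710, 1236),
                      delta_t = c(120, 146))
  w_prev <- burst
  w_last <- c(burst[7:length(burst)], numeric(6))
  rep <- classify_decrement(pairs, cfg, waveforms = list(w_prev, w_last))
  expect_equal(rep$raw_decrement_ms, 26)
  expect_equal(rep$xcorr_lag_ms, -6)
  expect_equal(rep$corrected_decrement_ms, 20)
  expect_equal(rep$label, "decremental")
})

test_that("the oracle pipeline recovers programmed decrements end to end", {
  pools <- local_pools()
  for (case in list(list(dec = 20, want = "decremental"),
                    list(dec = 0, want = "non_decremental"),
                    list(dec = 10, want = "non_decremental"))) {
    set.seed(100 + case$dec)
    rec <- generate_clinical_recording(
      protocol_config(decrement_ms = case$dec), pools)
    rep <- run_decrement_pipeline(rec, use_oracle = TRUE)
    expect_equal(rep$label, case$want)
    if (case$want != "excluded")
      expect_equal(rep$corrected_decrement_ms, case$dec, tolerance = 4)
  }
  # loss of capture after S2: the response is absent
  set.seed(140)
  rec <- generate_clinical_recording(protocol_config(capture_s2 = FALSE),
                                     pools)
  rep <- run_decrement_pipeline(rec, use_oracle = TRUE)
  expect_equal(rep$label, "excluded")
  expect_equal(rep$exclusion_reason, "no_response")
})
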