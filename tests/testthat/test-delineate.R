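test_that("binarization follows the >= convention", {
  p <- matrix(0.4, 3, 5)
  expect_true(all(binarize(p) == 0))
  expect_true(all(binarize(matrix(0.5, 3, 5)) == 1))
  expect_true(all(binarize(p, threshold = 0) == 1))
})

test_that("mask runs become intervals with merge and length cleanup", {
  m <- make_mask(7, lf = list(c(2, 5)))
  ints <- mask_to_intervals(m, min_len = 3, merge_gap = 2)
  expect_equal(ints$onset, 2); expect_equal(ints$offset, 5)

  # 0110011: gap of exactly 2 zeros is NOT closed (strictly-smaller rule)
  m2 <- matrix(0L, 3, 7); m2[2, c(2, 3, 6, 7)] <- 1L
  ints2 <- mask_to_intervals(m2, min_len = 2, merge_gap = 2)
  expect_equal(ints2$onset, c(1, 5))
  expect_equal(ints2$offset, c(3, 7))
  # but a 1-sample gap is closed
  m3 <- matrix(0L, 3, 7); m3[2, c(2, 3, 5, 6, 7)] <- 1L
  ints3 <- mask_to_intervals(m3, min_len = 2, merge_gap = 2)
  expect_equal(ints3$onset, 1); expect_equal(ints3$offset, 7)

  # a 2-sample run is dropped at min_len 3
  m4 <- matrix(0L, 3, 10); m4[1, 4:5] <- 1L
  expect_equal(nrow(mask_to_intervals(m4, min_len = 3)), 0)
})

test_that("interval/mask rendering round-trips clean interval sets", {
  set.seed(1)
  for (rep in 1:10) {
    n <- 200
    ints <- iv(c("STIM", "LF", "LF", "FF"),
               c(10, 40, 90, 120), c(20, 70, 110, 180), frame = n)
    m <- intervals_to_mask(ints, n)
    back <- mask_to_intervals(m, min_len = 3, merge_gap = 2)
    expect_equal(back$onset, ints$onset)
    expect_equal(back$offset, ints$offset)
    expect_equal(back$kind, ints$kind)
  }
})

test_that("pacing-spike cleanup removes swallowed detections only", {
  ints <- iv(c("STIM", "LF", "LF"), c(98, 100, 300), c(112, 110, 350),
             frame = 400)
  out <- clean_pacing_spikes(ints)
  expect_equal(out$kind, c("LF", "STIM"))
  expect_equal(out$onset[out$kind == "LF"], 300)
  # disjoint LF untouched; without stims the call is the identity
  no_stim <- iv(c("LF", "FF"), c(5, 50), c(30, 90), frame = 100)
  expect_equal(nrow(clean_pacing_spikes(no_stim)), 2)
})

test_that("QRS windows are centred, padded and exactly invertible", {
  sig <- matrix(rnorm(8000 * 2), ncol = 2)
  w <- window_by_qrs(sig, 5000, window_len = 1024)[[1]]
  expect_equal(w$offset, 4488)   # [4488, 5512)
  expect_equal(w$pad_left, 0)
  expect_equal(w$data[1, 1], sig[4489, 1])

  we <- window_by_qrs(sig, 100, window_len = 1024)[[1]]
  expect_equal(we$pad_left, 412)
  expect_true(all(we$data[1:412, ] == 0))

  # round trip: window-local -> recording -> window-local
  local_onset <- 500
  rec_onset <- local_onset + w$offset
  expect_equal(rec_onset - w$offset, local_onset)
  expect_error(window_by_qrs(sig, integer(0)), "fiducials")
})

test_that("majority voting fuses synchronous leads and drops outliers", {
  per_lead <- lapply(1:5, function(l)
    iv("LF", c(100, 101, 99, 100, 400)[l], c(150, 152, 148, 151, 460)[l],
       lead = l, frame = 1000))
  cons <- vote_across_leads(per_lead, "LF", tolerance_ms = 20, min_leads = 3)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$onset, 100)   # median of the 4-lead cluster
  expect_gte(cons$onset, 99); expect_lte(cons$onset, 101)

  # identical intervals in all leads: consensus equals them
  same <- lapply(1:5, function(l) iv("FF", 200, 260, lead = l, frame = 1000))
  cs <- vote_across_leads(same, "FF")
  expect_equal(cs$onset, 200); expect_equal(cs$offset, 260)

  # two supporting leads are not enough at min_leads = 3
  two <- lapply(1:2, function(l) iv("LF", 100, 150, lead = l, frame = 1000))
  expect_equal(nrow(vote_across_leads(two, "LF")), 0)

  # permutation invariance in lead order
  perm <- sample(per_lead)
  expect_equal(vote_across_leads(perm, "LF")$onset, cons$onset)
})

test_that("the built-in QRS detector recovers synthetic barycenters", {
  set.seed(2)
  rec <- generate_clinical_recording(protocol_config(), local_pools())
  found <- detect_qrs(rec$surface, rec$fs)
  expect_equal(length(found), length(rec$qrs_barycenters))
  expect_true(all(abs(found - rec$qrs_barycenters) <= 10))
})
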