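test_that("crop_segments reads mask runs into typed segments", {
  sig <- seq(0.1, 0.9, length.out = 9)
  mask <- make_mask(9, lf = list(c(3, 7)))
  out <- crop_segments(sig, mask)
  expect_length(out$LF, 1)
  expect_equal(out$LF[[1]]$samples, sig[4:7])
  expect_equal(attr(out$LF[[1]], "start"), 3)
  expect_length(out$REST, 2)
  expect_length(out$STIM, 0)

  # all-zero mask: one REST segment spanning the whole signal
  out0 <- crop_segments(sig, matrix(0L, 3, 9))
  expect_length(out0$REST, 1)
  expect_equal(out0$REST[[1]]$samples, sig)
})

test_that("disjoint runs are cropped in order (run-enumeration oracle)", {
  set.seed(1)
  for (rep in 1:20) {
    n <- 60
    sig <- rnorm(n)
    ff_ch <- as.integer(runif(n) < 0.3)
    mask <- matrix(0L, 3, n); mask[3, ] <- ff_ch
    out <- crop_segments(sig, mask)
    # oracle: brute-force run enumeration
    runs <- list(); cur <- NULL
    for (i in seq_len(n)) {
      if (ff_ch[i] == 1 && is.null(cur)) cur <- i
      if ((ff_ch[i] == 0 || i == n) && !is.null(cur)) {
        end <- if (ff_ch[i] == 1) i else i - 1
        runs <- c(runs, list(c(cur, end))); cur <- NULL
      }
    }
    expect_length(out$FF, length(runs))
    for (k in seq_along(runs))
      expect_equal(out$FF[[k]]$samples, sig[runs[[k]][1]:runs[[k]][2]])
  }
})

test_that("cropped segments partition the signal exactly", {
  set.seed(2)
  n <- 200
  sig <- rnorm(n)
  mask <- make_mask(n, stim = list(c(10, 15)), lf = list(c(40, 80)),
                    ff = list(c(120, 170)))
  out <- crop_segments(sig, mask)
  segs <- do.call(c, out)
  starts <- vapply(segs, function(s) attr(s, "start"), numeric(1))
  rebuilt <- unname(unlist(lapply(segs[order(starts)], function(s) s$samples)))
  expect_identical(rebuilt, sig)
})

test_that("stim/LF overlap is flagged and stim takes precedence", {
  sig <- rnorm(20)
  mask <- make_mask(20, stim = list(c(5, 10)), lf = list(c(8, 15)))
  expect_warning(out <- crop_segments(sig, mask), "precedence")
  expect_equal(attr(out$LF[[1]], "start"), 10)  # LF truncated to after stim
  expect_error(crop_segments(sig[1:10], mask), "does not match")
})

test_that("low-pass filter matches the closed-form Butterworth magnitude", {
  # digital (bilinear-transform) order-n Butterworth magnitude:
  # |H(f)| = 1 / sqrt(1 + (tan(pi f/fs) / tan(pi fc/fs))^(2n))
  for (f in c(10, 100, 400)) {
    t <- (0:999) / 1000
    seg <- egm_segment(sin(2 * pi * f * t), "FF", normalize = FALSE)
    out <- lowpass_ff_rest(seg)
    measured <- max(abs(out$samples[501:1000]))
    theory <- 1 / sqrt(1 + (tan(pi * f / 1000) / tan(pi * 100 / 1000))^4)
    expect_lt(abs(measured - theory), 0.01)
  }
  z <- lowpass_ff_rest(egm_segment(numeric(50), "REST", normalize = FALSE))
  expect_equal(z$samples, numeric(50))
  expect_error(lowpass_ff_rest(egm_segment(rnorm(30), "LF")), "only to FF")
})

test_that("zero correction subtracts the endpoint line and nothing else", {
  s0 <- egm_segment(c(0, 0.5, -0.2, 0), "LF", normalize = FALSE)
  expect_equal(zero_correct(s0)$samples, s0$samples)
  sc <- egm_segment(rep(3.3, 7), "FF", normalize = FALSE)
  expect_equal(zero_correct(sc)$samples, numeric(7))
  ramp <- egm_segment(seq(0, 1, length.out = 11), "FF", normalize = FALSE)
  expect_equal(zero_correct(ramp)$samples, numeric(11))
  expect_error(zero_correct(egm_segment(1, "FF", normalize = FALSE)),
               "fewer than 2")
})

test_that("the 25-sample rule splits local activations strictly", {
  mk <- function(n) egm_segment(c(0, rnorm(n - 2), 0), "LF", normalize = FALSE)
  sp <- split_lf_lp(list(mk(24), mk(25), mk(60), mk(10)))
  expect_equal(lengths(lapply(sp$lf, `[[`, "samples")), c(25, 60))
  expect_equal(lengths(lapply(sp$lp, `[[`, "samples")), c(24, 10))
  expect_true(all(vapply(sp$lp, function(s) s$kind == "LP", logical(1))))
  empty <- split_lf_lp(list())
  expect_length(empty$lf, 0)
  expect_length(empty$lp, 0)
})
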