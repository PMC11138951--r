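test_that("registry rules are seeded draws with the configured rates", {
  cfg <- synth_config()
  set.seed(5); a <- draw_registry_rules(cfg)
  set.seed(5); b <- draw_registry_rules(cfg)
  expect_identical(a, b)
  expect_true(a$rr_ms >= 400 && a$rr_ms <= 1000)

  set.seed(6)
  hits <- mean(replicate(1e4, draw_registry_rules(cfg)$has_stimulation))
  expect_lt(abs(hits - cfg$p_stim), 0.02)

  cfg1 <- synth_config(p_stim = 1)
  set.seed(7)
  expect_true(all(replicate(50, draw_registry_rules(cfg1)$has_stimulation)))
})

test_that("cycle rules honour shared morphology and omission settings", {
  pools <- local_pools()
  model <- default_amplitude_model()
  cfg <- synth_config(p_same_morphology = 1)
  set.seed(8)
  reg <- draw_registry_rules(cfg)
  rules <- draw_cycle_rules(reg, pools, model, cfg)
  idx <- lapply(rules, function(r)
    vapply(r$placements, function(p) paste(p$kind, p$pool_index),
           character(1)))
  expect_identical(idx[[1]], idx[[2]])
  expect_identical(idx[[1]], idx[[3]])

  cfg0 <- synth_config(p_lf = 0, p_ff = 0, lp_rate = 0, p_stim = 0)
  set.seed(9)
  reg0 <- draw_registry_rules(cfg0)
  rules0 <- draw_cycle_rules(reg0, pools, model, cfg0)
  expect_true(all(vapply(rules0, function(r) length(r$placements) == 0,
                         logical(1))))

  # late-potential count is Poisson with the configured mean
  cfg_lp <- synth_config(p_lf = 0, p_ff = 0, p_stim = 0, lp_rate = 0.3)
  set.seed(10)
  reg_lp <- draw_registry_rules(synth_config(p_stim = 0,
                                             p_same_morphology = 0))
  counts <- replicate(3000, {
    r <- draw_cycle_rules(reg_lp, pools, model, cfg_lp)
    length(r[[1]]$placements)
  })
  expect_lt(abs(mean(counts) - 0.3), 0.3 * 0.05 + 3 * sqrt(0.3 / 3000))
})

test_that("resampling follows the stated rounding and range rules", {
  seg <- local_pools()$LF[[1]]
  expect_equal(resample_segment(seg, 1)$samples, seg$samples)
  n <- length(seg$samples)
  expect_length(resample_segment(seg, 0.75)$samples, round(n * 0.75))
  s100 <- egm_segment(c(0, rnorm(98), 0), "LF", normalize = FALSE)
  expect_length(resample_segment(s100, 0.75)$samples, 75)
  # linear interpolation preserves affine signals
  ramp <- egm_segment(seq(0, 1, length.out = 50), "FF", normalize = FALSE)
  r <- resample_segment(ramp, 1.2)
  expect_equal(r$samples, seq(0, 1, length.out = 60), tolerance = 1e-9)
  expect_error(resample_segment(seg, 0.5), "0.75")
})

test_that("mixup combines, renormalizes, and survives cancellation", {
  pools <- local_pools()
  a <- pools$LF[[1]]; b <- pools$LF[[2]]
  expect_equal(mixup(a, b, 1)$samples, a$samples)
  b_res <- interp_to_length(b$samples, length(a$samples))
  m0 <- mixup(a, b, 0)
  expect_equal(m0$samples, b_res / max(abs(b_res)), tolerance = 1e-12)
  neg <- a; neg$samples <- -a$samples
  expect_equal(mixup(a, neg, 0.5)$samples, a$samples)  # cancellation fallback
  ff <- pools$FF[[1]]
  expect_error(mixup(a, ff, 0.5), "same kind")
})

test_that("cycle composition places segments at the programmed indices", {
  pools <- local_pools()
  empty_rules <- structure(list(
    placements = list(),
    rest = list(indices = rep(1, 20),
                amplitudes = rep(0.01, 20)),
    merge_ff_into_lf = FALSE, lf_amplitude = 1), class = "cycle_rules")
  out <- compose_cycle(empty_rules, pools, 500)
  expect_length(out$signal, 500)
  expect_equal(nrow(out$intervals), 0)

  # one LF of length 50 at 50% of a 1000-sample cycle sits at [475, 525)
  lf50 <- egm_segment(c(0, rnorm(48), 0), "LF")
  pools2 <- pools; pools2$LF <- list(lf50)
  rules <- empty_rules
  rules$placements <- list(list(kind = "LF", pool_index = 1, amplitude = 2,
                                position_pct = 50, resample_factor = 1,
                                mixup_partner = NA, mixup_lambda = 0))
  out2 <- compose_cycle(rules, pools2, 1000)
  expect_equal(out2$intervals$onset, 475)
  expect_equal(out2$intervals$offset, 525)

  # overlapping LF and FF add up; both intervals recorded on own channels
  ff80 <- egm_segment(c(0, rnorm(78), 0), "FF")
  pools2$FF <- list(ff80)
  rules$placements <- c(rules$placements,
                        list(list(kind = "FF", pool_index = 1, amplitude = 1,
                                  position_pct = 50, resample_factor = 1,
                                  mixup_partner = NA, mixup_lambda = 0)))
  rules$rest$amplitudes <- rep(0, 20)  # silent baseline isolates the sum
  out3 <- compose_cycle(rules, pools2, 1000)
  expect_setequal(out3$intervals$kind, c("LF", "FF"))
  expected <- numeric(1000)
  expected[476:525] <- expected[476:525] + lf50$samples * 2
  st <- round(0.5 * (1000 - 80))
  expected[(st + 1):(st + 80)] <- expected[(st + 1):(st + 80)] + ff80$samples
  expect_equal(out3$signal, expected)
})

test_that("trace assembly is the identity on the central cycle when bare", {
  pools <- local_pools()
  model <- default_amplitude_model()
  cfg <- synth_config()
  set.seed(12)
  reg <- draw_registry_rules(cfg)
  reg$left_keep_pct <- 0; reg$right_keep_pct <- 0
  reg$noise_sigma <- 0; reg$wander_amp <- 0
  rules <- draw_cycle_rules(reg, pools, model, cfg)
  cycles <- lapply(rules, compose_cycle, pools = pools,
                   rr_samples = round(reg$rr_ms))
  trace <- assemble_trace(cycles, reg)
  expect_identical(trace$signal, cycles[[2]]$signal)
  want <- canonicalize_intervals(
    as_egm_intervals(cycles[[2]]$intervals, trace$n))
  expect_equal(trace$intervals$onset, want$onset)
  expect_equal(trace$intervals$offset, want$offset)
})

test_that("interval lengths survive the coordinate shift into the crop", {
  pools <- local_pools()
  model <- default_amplitude_model()
  cfg <- synth_config(p_stim = 0)
  set.seed(13)
  reg <- draw_registry_rules(cfg)
  reg$noise_sigma <- 0; reg$wander_amp <- 0
  rules <- draw_cycle_rules(reg, pools, model, cfg)
  cycles <- lapply(rules, compose_cycle, pools = pools,
                   rr_samples = round(reg$rr_ms))
  trace <- assemble_trace(cycles, reg)
  left_n <- round(reg$left_keep_pct / 100 * length(cycles[[1]]$signal))
  c2 <- canonicalize_intervals(as_egm_intervals(cycles[[2]]$intervals,
                                                length(cycles[[2]]$signal)))
  for (i in seq_len(nrow(c2))) {
    hit <- trace$intervals[trace$intervals$onset == c2$onset[i] + left_n, ,
                           drop = FALSE]
    expect_gte(nrow(hit), 1)
    expect_true(any(hit$offset - hit$onset >= c2$offset[i] - c2$onset[i]))
  }
})

test_that("additive noise has the configured relative scale", {
  pools <- local_pools()
  model <- default_amplitude_model()
  cfg <- synth_config()
  set.seed(14)
  reg <- draw_registry_rules(cfg)
  reg$left_keep_pct <- 0; reg$right_keep_pct <- 0
  reg$wander_amp <- 0; reg$noise_sigma <- 0.1
  reg$rr_ms <- 10000  # long cycle: enough samples to estimate the sd
  rules <- draw_cycle_rules(reg, pools, model, cfg)
  cycles <- lapply(rules, compose_cycle, pools = pools, rr_samples = 10000)
  trace <- assemble_trace(cycles, reg)
  resid <- trace$signal - cycles[[2]]$signal
  peak <- max(abs(cycles[[2]]$signal))
  expect_lt(abs(sd(resid) - 0.1 * peak), 0.01 * peak)
})

test_that("dataset generation is reproducible and internally consistent", {
  d1 <- generate_dataset(6, seed = 77)
  d2 <- generate_dataset(6, seed = 77)
  expect_identical(d1, d2)
  for (tr in d1) {
    expect_equal(dim(tr$mask), c(3L, tr$n))
    expect_identical(tr$mask, intervals_to_mask(tr$intervals, tr$n))
    # bijection: every mask run is exactly one interval and vice versa
    for (ch in 1:3) {
      runs <- egmseg:::run_lengths(tr$mask[ch, ])
      ints <- tr$intervals[tr$intervals$kind == MASK_CHANNELS[ch], ,
                           drop = FALSE]
      expect_equal(runs$onset, ints$onset)
      expect_equal(runs$offset, ints$offset)
    }
  }
})

test_that("stimulated-trace frequency tracks the configured probability", {
  d <- generate_dataset(300, seed = 123, config = synth_config(p_stim = 0.3))
  frac <- mean(vapply(d, function(tr) tr$registry$has_stimulation,
                      logical(1)))
  expect_lt(abs(frac - 0.3), 0.09)
})
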