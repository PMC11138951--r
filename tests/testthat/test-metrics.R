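test_that("detection matching agrees with the exhaustive oracle", {
  set.seed(17)
  for (rep in 1:60) {
    inst <- random_instance()
    md <- match_detections(inst$pred, inst$gt, "LF")
    oracle <- brute_force_match(inst$pred, inst$gt, "LF")
    expect_equal(unname(md$counts[["TP"]]), oracle$count)
    expect_equal(sum(md$tp$overlap), oracle$overlap)
  }
})

test_that("matching basics: identity, partial overlap, competition", {
  same <- iv(c("LF", "LF"), c(10, 50), c(20, 80), frame = 100)
  md <- match_detections(same, same, "LF")
  expect_equal(unname(md$counts), c(2, 0, 0))

  md2 <- match_detections(iv("LF", 10, 20, frame = 100),
                          iv("LF", 15, 25, frame = 100), "LF")
  expect_equal(unname(md2$counts[["TP"]]), 1)
  expect_equal(md2$tp$overlap, 5)

  # one prediction overlapping two references: larger overlap wins
  pred <- iv("LF", 10, 30, frame = 100)
  gt <- iv(c("LF", "LF"), c(5, 25), c(13, 60), frame = 100)
  md3 <- match_detections(pred, gt, "LF")
  expect_equal(md3$tp$gt_onset, 25)   # overlap 5 beats overlap 3
  expect_equal(unname(md3$counts[["FN"]]), 1)
  # equal overlaps: the earlier reference wins the tie
  gt_tie <- iv(c("LF", "LF"), c(5, 25), c(15, 60), frame = 100)
  expect_equal(match_detections(pred, gt_tie, "LF")$tp$gt_onset, 5)
})

test_that("the LF-within-FF filter drops only fully contained FPs", {
  gt <- iv("FF", 40, 100, frame = 200)
  fps <- iv(c("LF", "LF", "LF"), c(50, 95, 150), c(60, 105, 160),
            frame = 200)
  kept <- filter_lf_within_ff(fps, gt)
  expect_equal(kept$onset, c(95, 150))  # straddling + outside survive
  expect_equal(nrow(filter_lf_within_ff(fps, iv(frame = 200))), 3)
})

test_that("filtering can only raise precision and never touches recall", {
  set.seed(23)
  for (rep in 1:40) {
    inst <- random_instance()
    ff <- iv("FF", c(30, 150), c(120, 260), frame = 300)
    gt <- as_egm_intervals(rbind(as.data.frame(inst$gt), as.data.frame(ff)),
                           300)
    rep_m <- delineation_metrics(inst$pred, gt,
                                 variant = c("raw", "filtered"))
    raw <- rep_m[rep_m$variant == "raw" & rep_m$kind == "LF", ]
    fil <- rep_m[rep_m$variant == "filtered", ]
    if (!is.na(raw$precision) && !is.na(fil$precision))
      expect_gte(fil$precision, raw$precision)
    expect_equal(fil$recall, raw$recall)
  }
})

test_that("merged LF+FF metrics absorb cross-class confusion", {
  pred <- iv("LF", 100, 160, frame = 300)
  gt <- iv("FF", 100, 160, frame = 300)
  out <- delineation_metrics(pred, gt)
  raw_lf <- out[out$variant == "raw" & out$kind == "LF", ]
  merged <- out[out$variant == "merged", ]
  expect_equal(raw_lf$TP, 0)           # FP for LF, FN for FF when raw
  expect_equal(merged$TP, 1)           # one merged true positive
  expect_equal(merged$dice, 100)

  disjoint <- delineation_metrics(iv("LF", 0, 10, frame = 300),
                                  iv("FF", 200, 250, frame = 300))
  expect_equal(disjoint[disjoint$variant == "merged", "TP"], 0)
})

test_that("delineation errors use the signed ms and population-SD convention", {
  tp <- data.frame(pred_onset = c(105, 95), pred_offset = c(208, 200),
                   gt_onset = c(100, 100), gt_offset = c(200, 200))
  err <- delineation_errors(tp)
  expect_equal(err$onset_errors, c(5, -5))
  expect_equal(unname(err$summary["onset_mean"]), 0)
  expect_equal(unname(err$summary["onset_sd"]), 5)   # population (n) SD
  expect_equal(unname(err$summary["offset_mean"]), 4)
  empty <- delineation_errors(tp[0, ])
  expect_true(all(is.na(empty$summary)))
})

test_that("hard Dice handles the boundary conventions", {
  a <- make_mask(20, lf = list(c(0, 10)))
  expect_equal(unname(sample_dice(a, a)), c(100, 100, 100))
  b <- make_mask(20, lf = list(c(10, 20)))
  expect_equal(unname(sample_dice(a, b))[2], 0)
  # half overlap: |A|=10, |B|=10, inter 5 -> 50%
  cc <- make_mask(20, lf = list(c(5, 15)))
  expect_equal(unname(sample_dice(a, cc))[2], 50)
})
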