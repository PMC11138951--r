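test_that("Dice loss hits its documented anchor values", {
  n <- 200
  tgt <- matrix(0, 3, n)
  tgt[2, 50:120] <- 1
  expect_lt(dice_loss(tgt, tgt), 0.01)          # perfect prediction

  far <- matrix(0, 3, n); far[2, 150:200] <- 1  # disjoint, both large
  d <- dice_loss(far[2, , drop = FALSE], tgt[2, , drop = FALSE])
  expect_gt(d, 0.98)

  # hand case: pred covers 0-9, target 5-14 -> Dice 2*5/(10+10) = 0.5
  p <- matrix(0, 1, 30); p[1, 1:10] <- 1
  t2 <- matrix(0, 1, 30); t2[1, 6:15] <- 1
  expect_equal(dice_loss(p, t2, eps = 1e-12), 0.5, tolerance = 1e-6)

  expect_error(dice_loss(p, matrix(0, 1, 10)), "identical shape")
})

test_that("Dice loss is bounded, masked, and channel-permutation symmetric", {
  set.seed(1)
  p <- matrix(runif(3 * 100), 3)
  t2 <- matrix(rbinom(3 * 100, 1, 0.3), 3)
  l <- dice_loss(p, t2)
  expect_gte(l, 0); expect_lte(l, 1)
  perm <- c(3, 1, 2)
  expect_equal(dice_loss(p[perm, ], t2[perm, ]), l)
  # masked positions do not contribute
  m <- rep(1, 100); m[41:60] <- 0
  p2 <- p; p2[, 41:60] <- runif(60)
  expect_equal(dice_loss(p, t2, loss_mask = m),
               dice_loss(p2, t2, loss_mask = m))
})

test_that("sensitivity loss rewards edges near reference boundaries", {
  n <- 300
  tgt <- matrix(0, 3, n); tgt[2, 100:160] <- 1
  expect_identical(sensitivity_loss(tgt, tgt), 0)
  expect_gt(sensitivity_loss(matrix(0, 3, n), tgt), 0.99)
  expect_equal(sensitivity_loss(matrix(0, 3, n), matrix(0, 3, n)), 0)

  # a predicted edge 5 samples off, within a 10-sample tolerance: near-zero
  off5 <- matrix(0, 3, n); off5[2, 105:165] <- 1
  expect_lt(sensitivity_loss(off5, tgt, tolerance = 10), 0.05)
})

test_that("sensitivity loss is non-increasing as an edge approaches", {
  n <- 400
  tgt <- matrix(0, 1, n); tgt[1, 200:260] <- 1
  losses <- vapply(seq(40, 0, by = -5), function(shift) {
    p <- matrix(0, 1, n); p[1, (200 + shift):(260 + shift)] <- 1
    sensitivity_loss(p, tgt, tolerance = 10)
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-9))
})

test_that("loss gradients match finite differences", {
  set.seed(2)
  n <- 60
  P <- matrix(runif(3 * n), 3)
  Tg <- matrix(rbinom(3 * n, 1, 0.3), 3)
  M <- rep(1, n); M[1:5] <- 0
  dc <- egmseg:::dice_core(P, Tg, M)
  g <- dc$grad()
  eps <- 1e-7
  for (j in sample(length(P), 6)) {
    Pp <- P; Pp[j] <- Pp[j] + eps
    Pm <- P; Pm[j] <- Pm[j] - eps
    num <- (egmseg:::dice_core(Pp, Tg, M)$loss -
            egmseg:::dice_core(Pm, Tg, M)$loss) / (2 * eps)
    expect_equal(g[j], num, tolerance = 1e-4)
  }
  sc <- egmseg:::sens_core(t(P), t(Tg), 5)
  gs <- sc$grad()
  for (j in sample(length(P), 6)) {
    Pp <- P; Pp[j] <- Pp[j] + eps
    Pm <- P; Pm[j] <- Pm[j] - eps
    num <- (egmseg:::sens_core(t(Pp), t(Tg), 5)$loss -
            egmseg:::sens_core(t(Pm), t(Tg), 5)$loss) / (2 * eps)
    expect_equal(t(gs)[j], num, tolerance = 1e-4)
  }
})
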