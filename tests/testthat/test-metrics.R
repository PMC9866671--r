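test_that("alpha weights are one minus the class proportions", {
  # proportions as in a pooled tube-formation dataset: tubes are rare
  expect_equal(unname(derive_alpha(c(0.69, 0.26, 0.05))),
               c(0.31, 0.74, 0.95))
  expect_equal(unname(derive_alpha(rep(1 / 3, 3))), rep(2 / 3, 3))
  expect_equal(unname(derive_alpha(c(1, 0, 0))), c(0, 1, 1))
  expect_error(derive_alpha(c(0.5, 0.2, 0.2)), "sum")
})

probs_from_mask <- function(mask, p_true = 0.9) {
  lab <- unclass(mask)
  probs <- array((1 - p_true) / 2, dim = c(dim(lab), 3))
  for (c in 1:3) probs[, , c][lab == c - 1L] <- p_true
  probs
}

test_that("focal loss vanishes for perfect predictions", {
  msk <- random_mask(8, 8, seed = 2)
  probs <- probs_from_mask(msk, p_true = 1)
  alpha <- c(0.31, 0.74, 0.95)
  loss <- focal_loss(probs, msk, alpha, gamma = 0.5)
  eps <- 1e-7
  expect_lte(loss, 3 * max(alpha) * sqrt(eps) * abs(log(1 - eps)))
  expect_gte(loss, 0)
})

test_that("gamma = 0 reduces to alpha-weighted binary cross-entropy", {
  for (s in 1:5) {
    msk <- random_mask(6, 6, seed = s)
    set.seed(s)
    raw <- array(runif(6 * 6 * 3), dim = c(6, 6, 3))
    probs <- raw / as.vector(raw[, , 1] + raw[, , 2] + raw[, , 3])
    alpha <- runif(3)
    # independent oracle: sum over classes of weighted BCE on the binary
    # channel indicators, averaged over pixels
    lab <- unclass(msk)
    bce <- 0
    for (c in 1:3) {
      y <- as.numeric(lab == c - 1L)
      p <- pmin(pmax(probs[, , c], 1e-7), 1 - 1e-7)
      bce <- bce + sum(-alpha[c] * (y * log(p) + (1 - y) * log(1 - p)))
    }
    bce <- bce / 36
    expect_equal(focal_loss(probs, msk, alpha, gamma = 0), bce,
                 tolerance = 1e-9)
  }
})

test_that("the single-pixel focal value matches the scalar formula", {
  msk <- class_mask(matrix(2L, 1, 1)) # truth = tube
  probs <- array(c(0.05, 0.05, 0.9), dim = c(1, 1, 3))
  alpha <- c(0.31, 0.74, 0.95)
  # scalar oracle: tube term with pt = 0.9 plus two other-class terms with
  # pt = 0.95, all at gamma = 0.5
  expected <- -0.95 * sqrt(0.1) * log(0.9) +
    -0.31 * sqrt(0.05) * log(0.95) +
    -0.74 * sqrt(0.05) * log(0.95)
  expect_equal(focal_loss(probs, msk, alpha, gamma = 0.5), expected,
               tolerance = 1e-6)
  expect_equal(expected, 0.04369503, tolerance = 1e-6)
})

test_that("focal loss is monotone in pt and positive when imperfect", {
  msk <- class_mask(matrix(2L, 1, 1))
  alpha <- rep(1, 3)
  losses <- vapply(seq(0.3, 0.95, by = 0.05), function(p) {
    probs <- array(c((1 - p) / 2, (1 - p) / 2, p), dim = c(1, 1, 3))
    focal_loss(probs, msk, alpha, gamma = 0.5)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_true(all(losses > 0))
})

test_that("the focal gradient matches finite differences", {
  msk <- random_mask(4, 4, seed = 3)
  set.seed(3)
  raw <- array(runif(48, 0.05, 1), dim = c(4, 4, 3))
  probs <- raw / as.vector(raw[, , 1] + raw[, , 2] + raw[, , 3])
  alpha <- c(0.31, 0.74, 0.95)
  for (gamma in c(0, 0.5, 2)) {
    g <- angioquant:::focal_grad_p(probs, msk, alpha, gamma)
    for (k in c(1, 20, 48)) {
      h <- 1e-6
      up <- probs; up[k] <- up[k] + h
      dn <- probs; dn[k] <- dn[k] - h
      fd <- (focal_loss(up, msk, alpha, gamma) -
               focal_loss(dn, msk, alpha, gamma)) / (2 * h)
      expect_equal(g[k], fd, tolerance = 1e-4)
    }
  }
})

test_that("per-class IoU follows the set-count definition", {
  msk <- random_mask(8, 8, seed = 4)
  for (c in 0:2) expect_equal(iou_class(msk, msk, c), 1)
  # 10 truth px and 10 pred px overlapping on 5
  t_ <- matrix(0L, 5, 10); t_[1, 1:10] <- 1L
  p_ <- matrix(0L, 5, 10); p_[1, 6:10] <- 1L; p_[2, 1:5] <- 1L
  expect_equal(iou_class(class_mask(t_), class_mask(p_), 1L), 5 / 15)
  # empty truth, nonempty pred
  e <- class_mask(matrix(0L, 4, 4))
  f <- matrix(0L, 4, 4); f[1, 1:4] <- 2L
  expect_equal(iou_class(e, class_mask(f), 2L), 0)
  # class absent from both masks scores 1 (vacuous agreement)
  expect_equal(iou_class(e, e, 2L), 1)
})

test_that("IoU2 and IoU3 summarise per-class IoUs as defined", {
  msk <- random_mask(8, 8, seed = 5)
  expect_equal(iou_summary(msk, msk, "three"), 1)
  expect_equal(iou_summary(msk, msk, "two"), 1)
  bg <- class_mask(matrix(0L, 4, 4))
  tube <- class_mask(matrix(2L, 4, 4))
  expect_equal(iou_summary(bg, tube, "three"), 0)
  expect_equal(iou_summary(bg, tube, "two"), 0)
  expect_error(iou_summary(bg, tube, "four"))
  # random-mask oracle: explicit set counting
  for (s in 1:5) {
    t_ <- random_mask(8, 8, seed = 100 + s)
    p_ <- random_mask(8, 8, seed = 200 + s)
    per_class <- vapply(0:2, function(c) {
      a <- unclass(t_) == c; b <- unclass(p_) == c
      if (sum(a | b) == 0) NA_real_ else sum(a & b) / sum(a | b)
    }, numeric(1))
    expect_equal(iou_summary(t_, p_, "three"),
                 mean(per_class, na.rm = TRUE))
    ct <- unclass(t_) > 0; cp <- unclass(p_) > 0
    iou2 <- mean(c(sum(!ct & !cp) / sum(!ct | !cp),
                   sum(ct & cp) / sum(ct | cp)))
    expect_equal(iou_summary(t_, p_, "two"), iou2)
    # symmetry
    expect_equal(iou_summary(t_, p_, "three"), iou_summary(p_, t_, "three"))
    expect_equal(iou_summary(t_, p_, "two"), iou_summary(p_, t_, "two"))
  }
})

test_that("node/tube relabelling leaves IoU2 invariant but not IoU3", {
  t_ <- matrix(0L, 4, 4); t_[1, ] <- 1L; t_[2, ] <- 2L
  truth <- class_mask(t_)
  swapped <- t_; swapped[t_ == 1L] <- 2L; swapped[t_ == 2L] <- 1L
  pred <- class_mask(swapped)
  expect_equal(iou_summary(truth, pred, "two"), 1)
  expect_lt(iou_summary(truth, pred, "three"), 1)
})

test_that("corrupting predictions never raises IoU3", {
  set.seed(6)
  truth <- random_mask(12, 12, seed = 6)
  pred <- unclass(truth)
  last <- iou_summary(truth, class_mask(pred), "three")
  correct <- which(pred == unclass(truth))
  for (step in 1:8) {
    flip <- sample(correct, 4)
    correct <- setdiff(correct, flip)
    pred[flip] <- (unclass(truth)[flip] + sample(1:2, 4, TRUE)) %% 3L
    now <- iou_summary(truth, class_mask(pred), "three")
    expect_lte(now, last + 1e-12)
    last <- now
  }
})

test_that("iou_report emits one tidy row per image", {
  d <- tibble::tibble(
    id = c("a", "b"),
    truth = list(random_mask(8, 8, seed = 1), random_mask(8, 8, seed = 2)),
    pred = list(random_mask(8, 8, seed = 1), random_mask(8, 8, seed = 3)))
  rep <- iou_report(d)
  expect_named(rep, c("id", "iou_background", "iou_nodes", "iou_tubes",
                      "iou3", "iou2"))
  expect_equal(rep$iou3[1], 1)
  expect_lt(rep$iou3[2], 1)
})
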