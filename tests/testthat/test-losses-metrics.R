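ns <- asNamespace("dsnet")

test_that("soft Dice loss hits its closed-form extremes", {
  # perfect hard prediction -> -1 within epsilon tolerance
  y <- ns$one_hot(array(sample(0:3, 4^3, TRUE), c(4, 4, 4, 1)), 4L)
  expect_equal(dice_loss(y, y), -1, tolerance = 1e-4)

  # disjoint single-class masks -> ~0
  p <- array(0, c(4, 4, 4, 2, 1)); t <- array(0, c(4, 4, 4, 2, 1))
  p[, , 1:2, 1, 1] <- 1; p[, , 3:4, 2, 1] <- 1   # predicts class 2 right half
  t[, , 3:4, 1, 1] <- 1; t[, , 1:2, 2, 1] <- 1   # truth is the opposite
  expect_equal(dice_loss(p, t), 0, tolerance = 1e-4)
})

test_that("soft Dice loss equals an independent per-class accumulation", {
  set.seed(9)
  d <- c(3, 4, 5, 3, 2)
  logits <- array(rnorm(prod(d)), d)
  p <- ns$softmax_channels(logits)
  y <- ns$one_hot(array(sample(0:2, prod(d[c(1:3, 5)]), TRUE), d[c(1:3, 5)]),
                  3L)
  sp <- loss_spec()
  got <- dice_loss(p, y, sp)
  # brute-force: explicit scalar loops
  acc <- 0
  for (n in 1:2) for (ci in 1:3) {
    num <- 0; den <- 0
    for (i in 1:3) for (j in 1:4) for (k in 1:5) {
      num <- num + 2 * p[i, j, k, ci, n] * y[i, j, k, ci, n]
      den <- den + p[i, j, k, ci, n] + y[i, j, k, ci, n]
    }
    acc <- acc - (num + sp$smooth) / (den + sp$smooth)
  }
  expect_equal(got, acc / 6, tolerance = 1e-9)
  expect_gte(got, -1); expect_lte(got, 1e-9)
})

test_that("total loss is the weighted sum of its branch losses", {
  set.seed(10)
  lab <- array(sample(0:3, 4^3, TRUE), c(4, 4, 4, 1))
  bl <- array(rnorm(4^3 * 2), c(4, 4, 4, 2, 1))
  sl <- array(rnorm(4^3 * 4), c(4, 4, 4, 4, 1))
  sp <- loss_spec()
  l1 <- dice_loss(ns$softmax_channels(bl),
                  ns$one_hot((lab > 0) * 1L, 2L), sp)
  l2 <- dice_loss(ns$softmax_channels(sl), ns$one_hot(lab, 4L), sp)
  expect_equal(total_loss(bl, sl, lab, sp), 0.5 * l1 + 0.5 * l2,
               tolerance = 1e-12)
  # degenerate weight: binary branch drops out
  expect_equal(total_loss(NULL, sl, lab, loss_spec(lambda1 = 0, lambda2 = 1)),
               l2, tolerance = 1e-12)
  # perfect prediction on both branches -> -1
  ysub <- ns$one_hot(lab, 4L) * 20 - 10
  ybin <- ns$one_hot((lab > 0) * 1L, 2L) * 20 - 10
  expect_equal(total_loss(ybin, ysub, lab, sp), -1, tolerance = 1e-3)
  expect_error(total_loss(NULL, sl, lab, sp), "binary")
})

test_that("dice loss agrees with -dice_coefficient on hard binary inputs", {
  set.seed(11)
  for (rep in 1:5) {
    a <- random_mask(c(5, 5, 5)); b <- random_mask(c(5, 5, 5))
    p <- ns$one_hot(array(as.integer(a), c(5, 5, 5, 1)), 2L)
    y <- ns$one_hot(array(as.integer(b), c(5, 5, 5, 1)), 2L)
    # foreground-class term of the loss vs the overlap coefficient
    fg_dice <- 2 * sum(a & b) / (sum(a) + sum(b))
    bg_dice <- 2 * sum(!a & !b) / (sum(!a) + sum(!b))
    expect_equal(dice_loss(p, y), -(fg_dice + bg_dice) / 2,
                 tolerance = 1e-3)
    expect_equal(fg_dice, dice_coefficient(a, b))
  }
})

test_that("dice_coefficient follows set arithmetic exactly", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE  # 8 voxels
  b <- array(FALSE, c(4, 4, 4)); b[1:2, 1:2, 2:3] <- TRUE  # 8 voxels, 4 shared
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  expect_equal(dice_coefficient(a & FALSE, b & FALSE), 1)  # both empty
  expect_equal(dice_coefficient(a, b & FALSE), 0)          # one empty
  expect_error(dice_coefficient(a, array(TRUE, c(3, 3, 3))), "grid")
  set.seed(12)
  for (rep in 1:100) {
    x <- random_mask(c(4, 5, 3), runif(1, 0.1, 0.9))
    y <- random_mask(c(4, 5, 3), runif(1, 0.1, 0.9))
    expect_identical(dice_coefficient(x, y),
                     2 * sum(x & y) / (sum(x) + sum(y)))
  }
})

test_that("hd95 reproduces hand-computable distances", {
  a <- array(FALSE, c(12, 8, 8)); b <- a
  a[3, 4, 4] <- TRUE
  b[8, 4, 4] <- TRUE   # 5 voxels apart along D at 0.4 mm -> 2.0 mm
  expect_equal(as.numeric(hd95(a, b, c(0.4, 0.4, 0.4))), 2.0)
  expect_equal(as.numeric(hd95(a, a, c(0.4, 0.4, 0.4))), 0)
  und <- hd95(a, a & FALSE, c(0.4, 0.4, 0.4))
  expect_true(is.na(und))
  expect_false(attr(und, "defined"))
})

test_that("hd95 and the Hausdorff distance match a brute-force oracle", {
  set.seed(13)
  for (rep in 1:50) {
    a <- random_mask(c(6, 6, 6), runif(1, 0.1, 0.5))
    b <- random_mask(c(6, 6, 6), runif(1, 0.1, 0.5))
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- c(0.4, 0.4, 0.4)
    expect_equal(as.numeric(hd95(a, b, sp)), ref_hd(a, b, sp, 0.95),
                 tolerance = 1e-9)
    h95 <- as.numeric(hd95(a, b, sp))
    hfull <- as.numeric(hausdorff_distance(a, b, sp))
    expect_lte(h95, hfull + 1e-12)
    expect_equal(hfull, ref_hd(a, b, sp, 1), tolerance = 1e-9)
    # symmetry
    expect_equal(as.numeric(hd95(b, a, sp)), h95, tolerance = 1e-12)
  }
})

test_that("evaluate reports per-structure and union scores", {
  ph <- generate_phantom(phantom_config(seed = 21L, n_distractors = 0L))
  truth <- ph$labels
  perfect <- evaluate(truth, truth)
  expect_identical(perfect$structure, c("CA1-3", "CA4/DG", "SUB",
                                        "Hippocampus"))
  expect_equal(perfect$dice, rep(1, 4))
  expect_equal(perfect$hd95, rep(0, 4))

  # drop one label entirely: Dice 0 and undefined HD95 for that structure
  pred <- truth
  pred$labels[pred$labels == 2L] <- 1L
  ev <- evaluate(pred, truth)
  expect_equal(ev$dice[ev$structure == "CA4/DG"], 0)
  expect_false(ev$hd95_defined[ev$structure == "CA4/DG"])
  # union is unaffected by relabelling within the organ
  expect_equal(ev$dice[ev$structure == "Hippocampus"], 1)

  # union mask construction matches set arithmetic after a perturbation
  pred2 <- truth
  surf <- which(ns$cpp_boundary(array(as.integer(truth$labels == 1L),
                                      dim(truth$labels)),
                                dim(truth$labels)))
  grown <- truth$labels
  # dilate label 1 by one voxel along +D
  idx <- which(truth$labels == 1L, arr.ind = TRUE)
  up <- idx; up[, 1] <- pmin(up[, 1] + 1L, dim(grown)[1])
  sel <- grown[up] == 0L
  grown[up[sel, , drop = FALSE]] <- 1L
  pred2$labels <- grown
  ev2 <- evaluate(pred2, truth)
  a1 <- truth$labels == 1L; b1 <- grown == 1L
  expect_equal(ev2$dice[1], 2 * sum(a1 & b1) / (sum(a1) + sum(b1)))
  au <- truth$labels > 0L; bu <- grown > 0L
  expect_equal(ev2$dice[4], 2 * sum(au & bu) / (sum(au) + sum(bu)))
})

test_that("metrics reports serialize to JSON and CSV", {
  dirn <- withr::local_tempdir()
  ph <- generate_phantom(phantom_config(seed = 22L))
  ev <- evaluate(ph$labels, ph$labels)
  jp <- write_metrics(ev, file.path(dirn, "m.json"))
  cp <- write_metrics(ev, file.path(dirn, "m.csv"))
  expect_equal(jsonlite::read_json(jp, simplifyVector = TRUE)$dice,
               ev$dice)
  expect_equal(read.csv(cp)$dice, ev$dice)
})
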