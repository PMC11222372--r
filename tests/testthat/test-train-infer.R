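ns <- asNamespace("dsnet")

test_that("polynomial schedule matches its closed form", {
  expect_equal(poly_lr(0, 1000), 0.001)
  expect_equal(poly_lr(1000, 1000), 0)
  expect_equal(poly_lr(500, 1000, lr0 = 0.001, power = 0.9),
               0.001 * 0.5^0.9)
  lrs <- poly_lr(0:100, 100)
  expect_true(all(diff(lrs) <= 0))
  expect_error(poly_lr(0, 0), "positive")
  expect_error(poly_lr(5, 4), "iter")
})

test_that("patch sampling is uniform, identical for image and labels", {
  set.seed(18)
  vol <- array(rnorm(10 * 10 * 10 * 2), c(10, 10, 10, 2))
  lab <- array(sample(0:3, 1000, TRUE), c(10, 10, 10))
  # volume exactly patch-sized -> identity crop
  pt <- sample_patch(vol, lab, c(10L, 10L, 10L))
  expect_identical(pt$x, vol)
  expect_identical(pt$y, lab)
  # determinism under a fixed seed
  set.seed(99); a <- sample_patch(vol, lab, c(6L, 6L, 6L))
  set.seed(99); b <- sample_patch(vol, lab, c(6L, 6L, 6L))
  expect_identical(a$corner, b$corner)
  expect_identical(a$x, b$x)
  # image and labels crop from the same corner
  idx <- lapply(1:3, function(ax) a$corner[ax] + 1:6)
  expect_identical(a$y, array(lab[idx[[1]], idx[[2]], idx[[3]]], c(6, 6, 6)))
  # corner histogram uniform over the 5^3 valid positions (4 sigma)
  set.seed(20)
  draws <- 4000
  counts <- integer(125)
  small_lab <- array(0L, c(12, 12, 12))
  small_vol <- array(0, c(12, 12, 12, 1))
  for (i in seq_len(draws)) {
    ct <- sample_patch(small_vol, small_lab, c(8L, 8L, 8L))$corner
    key <- 1 + ct[1] + 5 * ct[2] + 25 * ct[3]
    counts[key] <- counts[key] + 1L
  }
  p0 <- 1 / 125
  sigma <- sqrt(draws * p0 * (1 - p0))
  expect_true(all(abs(counts - draws * p0) <= 4 * sigma))
  # undersized volumes are padded, never an error
  pt2 <- sample_patch(array(0, c(4, 4, 4, 1)), array(0L, c(4, 4, 4)),
                      c(8L, 8L, 8L))
  expect_identical(dim(pt2$y), c(8L, 8L, 8L))
})

test_that("augmentation honours its degenerate and involution cases", {
  set.seed(21)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  y <- array(sample(0:3, 8^3, TRUE), c(8, 8, 8))
  # degenerate config -> exact identity
  cfg_id <- train_config(mirror_prob = 0, intensity_shift_range = c(0, 0),
                         scale_range = c(1, 1), patch_size = 8L)
  ag <- augment(x, y, cfg_id)
  expect_identical(ag$x, x); expect_identical(ag$y, y)
  # mirror prob 1 applied twice is the identity
  cfg_m <- train_config(mirror_prob = 1, intensity_shift_range = c(0, 0),
                        scale_range = c(1, 1), patch_size = 8L)
  ag1 <- augment(x, y, cfg_m)
  ag2 <- augment(ag1$x, ag1$y, cfg_m)
  expect_equal(ag2$x, x); expect_identical(ag2$y, y)
  # labels never gain classes
  cfg_s <- train_config(mirror_prob = 0.5, scale_range = c(0.9, 1.1),
                        patch_size = 8L)
  for (i in 1:5) {
    agi <- augment(x, y, cfg_s)
    expect_true(all(unique(as.vector(agi$y)) %in% 0:3))
    expect_identical(dim(agi$x), dim(x))
  }
})

test_that("down-scaling shrinks foreground volume by about the cube of the factor", {
  # ball of radius 10 in a 32^3 patch
  ball <- dsnet:::sphere_mask(c(32, 32, 32), c(15.5, 15.5, 15.5), 10)
  y <- array(as.integer(ball), c(32, 32, 32))
  x <- array(as.numeric(ball), c(32, 32, 32, 1))
  cfg <- train_config(mirror_prob = 0, intensity_shift_range = c(0, 0),
                      scale_range = c(0.9, 0.9), patch_size = 32L)
  set.seed(22)
  ag <- augment(x, y, cfg)
  ratio <- sum(ag$y) / sum(y)
  expect_lt(abs(ratio - 0.9^3), 0.1 * 0.9^3)
})

test_that("a short training run descends and keeps the last checkpoints", {
  ph <- generate_phantom(tiny_phantom_config(seed = 30L))
  cfg <- train_config(patch_size = 16L, batch_size = 1L, max_epochs = 10L,
                      keep_last_k_checkpoints = 4L, seed = 7L,
                      scale_range = c(1, 1), mirror_prob = 0)
  mcfg <- micro_model_config()
  fit <- dsnet_train(list(list(volume = ph$volume, labels = ph$labels)),
                     mcfg, cfg)
  expect_true(all(is.finite(fit$loss_curve)))
  expect_lt(fit$loss_curve[10], fit$loss_curve[1])
  # ring buffer keeps epochs 7..10
  expect_identical(vapply(fit$checkpoints, `[[`, 0L, "epoch"), 7:10)
  # the recorded lr trace is exactly the schedule
  expect_equal(fit$lr_trace,
               poly_lr(0:(length(fit$lr_trace) - 1), length(fit$lr_trace),
                       cfg$lr0, cfg$poly_power))
})

test_that("window tiling partitions the padded grid", {
  # the full-size preprocessing grid: 267 x 182 x 174 with 128^3 windows
  sw <- sliding_windows(c(267, 182, 174), 128)
  expect_identical(sw$n_windows, c(3L, 2L, 2L))
  expect_identical(nrow(sw$corners), 12L)
  expect_identical(sw$padded, c(384L, 256L, 256L))
  # every voxel of the padded grid covered exactly once
  swc <- sliding_windows(c(33, 17, 9), 16)
  cover <- array(0L, swc$padded)
  for (t in seq_len(nrow(swc$corners))) {
    id <- swc$corners[t, 1] + 1:16
    ih <- swc$corners[t, 2] + 1:16
    iw <- swc$corners[t, 3] + 1:16
    cover[id, ih, iw] <- cover[id, ih, iw] + 1L
  }
  expect_true(all(cover == 1L))
})

test_that("sliding-window reassembly is lossless for a constant-output model", {
  v <- new_volume(array(rnorm(11 * 9 * 10), c(11, 9, 10)), channels = "t1w")
  mcfg1 <- micro_model_config(in_channels = 1L)
  set.seed(23)
  # zero both heads: logits are the head biases -> constant class probs
  m1 <- dsnet_model(mcfg1, 8L)
  m1$modules$head_sub$params$W[] <- 0
  m1$modules$head_sub$params$b <- c(2, -1, 0.5, 0)
  m1$modules$head_bin$params$W[] <- 0
  m1$modules$head_bin$params$b <- c(1, -1)
  fit1 <- list(model = m1, checkpoints = list(list(state = model_state(m1),
                                                   epoch = 1L)))
  pr <- sliding_window_predict(v, fit1, window = 8L)
  want <- exp(c(2, -1, 0.5, 0)); want <- want / sum(want)
  expect_identical(dim(pr$subfield), c(11L, 9L, 10L, 4L))
  for (ci in 1:4)
    expect_equal(max(abs(pr$subfield[, , , ci] - want[ci])), 0,
                 tolerance = 1e-12)
  # probabilities sum to one everywhere
  expect_equal(apply(pr$subfield, 1:3, sum),
               array(1, c(11, 9, 10)), tolerance = 1e-12)
})

test_that("averaging identical checkpoints equals a single checkpoint", {
  set.seed(24)
  mcfg <- micro_model_config(in_channels = 1L)
  m <- dsnet_model(mcfg, 8L)
  st <- model_state(m)
  v <- new_volume(array(rnorm(8^3), c(8, 8, 8)), channels = "t1w")
  fit1 <- list(model = m, checkpoints = list(list(state = st, epoch = 1L)))
  p1 <- sliding_window_predict(v, fit1, window = 8L)
  fit4 <- list(model = m,
               checkpoints = rep(list(list(state = st, epoch = 1L)), 4))
  p4 <- sliding_window_predict(v, fit4, window = 8L)
  expect_equal(p4$subfield, p1$subfield, tolerance = 1e-12)
  expect_error(sliding_window_predict(v, list(model = m,
                                              checkpoints = list())),
               "checkpoint")
})

test_that("connected-component filtering enforces the strict size threshold", {
  g <- c(40, 40, 60)
  lab <- array(0L, g)
  # three rectangular components: 999, 1000 and 5000 voxels
  lab[1:9, 1:10, 1:11] <- 1L          # 990
  lab[1:9, 1, 12] <- 1L               # +9 -> 999
  lab[1:10, 12:21, 21:30] <- 2L       # 1000
  lab[1:20, 25:34, 36:60] <- 3L       # 5000
  lm <- new_labelmap(lab, spacing = c(0.4, 0.4, 0.4))
  out <- cc_filter(lm, min_voxels = 1000L)
  expect_identical(sum(out$labels == 1L), 0L)
  expect_identical(sum(out$labels == 2L), 1000L)
  expect_identical(sum(out$labels == 3L), 5000L)
  rem <- attr(out, "removed")
  expect_identical(rem$size, 999L)
  expect_equal(rem$volume_mm3, 999 * 0.4^3)
  # all components below threshold -> empty foreground
  all_small <- cc_filter(lm, min_voxels = 10000L)
  expect_identical(sum(all_small$labels > 0L), 0L)
  # filtering never creates foreground and is idempotent
  expect_true(all(out$labels[lm$labels == 0L] == 0L))
  again <- cc_filter(out, min_voxels = 1000L)
  expect_identical(again$labels, out$labels)
})

test_that("component labelling agrees with a reference flood fill", {
  set.seed(25)
  mask <- array(runif(14^3) < 0.2, c(14, 14, 14))
  got <- ns$cpp_cc_label(array(as.integer(mask), dim(mask)), dim(mask))
  want <- ref_cc_label(mask)
  # same partition: label images identical up to renaming
  expect_identical(sort(unique(as.vector(got))), sort(unique(as.vector(want))))
  expect_true(all(tapply(got[mask], want[mask],
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(want[mask], got[mask],
                         function(v) length(unique(v))) == 1))
})

test_that("phantom distractors are removed while the organ survives", {
  cfg <- phantom_config(seed = 31L, n_distractors = 5L,
                        distractor_size_range = c(50L, 500L))
  ph <- generate_phantom(cfg)
  # build a "prediction" that contains the truth plus the distractor blobs
  pred <- ph$labels
  pred$labels[ph$distractors == 1L & pred$labels == 0L] <- 1L
  out <- cc_filter(pred, min_voxels = 1000L)
  expect_identical(out$labels, ph$labels$labels)
  expect_identical(nrow(attr(out, "removed")), 5L)
})
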