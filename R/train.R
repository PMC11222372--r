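#' Training configuration
#'
#' Optimization and augmentation settings: Adam with a polynomial
#' learning-rate schedule `lr0 * (1 - t/T)^power`, random patch cropping,
#' per-axis random mirroring, additive intensity shifts on the standardized
#' scale, random isotropic scaling, L2 weight decay, and retention of the
#' last `keep_last_k_checkpoints` epoch checkpoints for output averaging at
#' inference.
#'
#' @param lr0 initial learning rate.
#' @param poly_power exponent of the polynomial schedule.
#' @param batch_size samples per optimization step.
#' @param patch_size cubic patch edge (or integer triple) in voxels.
#' @param max_epochs training epochs (full passes over the dataset).
#' @param weight_decay L2 regularization coefficient.
#' @param mirror_prob per-axis mirroring probability.
#' @param intensity_shift_range additive shift interval (unit-variance scale).
#' @param scale_range isotropic zoom interval.
#' @param keep_last_k_checkpoints checkpoints retained for averaging.
#' @param seed RNG seed driving initialization, sampling and augmentation.
#' @return a `dsnet_train_config` list.
#' @export
train_config <- function(lr0 = 0.001, poly_power = 0.9, batch_size = 4L,
                         patch_size = 128L, max_epochs = 8000L,
                         weight_decay = 1e-5, mirror_prob = 0.5,
                         intensity_shift_range = c(-0.1, 0.1),
                         scale_range = c(0.9, 1.1),
                         keep_last_k_checkpoints = 4L, seed = 1L) {
  stopifnot(intensity_shift_range[1] <= intensity_shift_range[2],
            scale_range[1] <= scale_range[2], scale_range[1] > 0)
  structure(list(lr0 = lr0, poly_power = poly_power,
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(if (length(patch_size) == 1)
                   rep(patch_size, 3) else patch_size),
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay, mirror_prob = mirror_prob,
                 intensity_shift_range = intensity_shift_range,
                 scale_range = scale_range,
                 keep_last_k_checkpoints = as.integer(keep_last_k_checkpoints),
                 seed = as.integer(seed)),
            class = "dsnet_train_config")
}

#' Polynomial learning-rate schedule
#'
#' `lr0 * (1 - iter/total)^power`: starts at `lr0`, decays monotonically to 0.
#'
#' @param iter step index, `0 <= iter <= total`.
#' @param total total number of steps (> 0).
#' @param lr0 initial learning rate.
#' @param power polynomial exponent.
#' @return the learning rate.
#' @export
poly_lr <- function(iter, total, lr0 = 0.001, power = 0.9) {
  if (total <= 0) stop("total step count must be positive")
  if (any(iter < 0 | iter > total)) stop("iter must lie in [0, total]")
  lr0 * (1 - iter / total)^power
}

#' Random patch extraction
#'
#' Draws a uniformly random corner over all valid positions and crops image
#' and labels identically. Volumes smaller than the patch are first
#' symmetrically zero-padded (labels with background).
#'
#' @param vol_arr numeric array (D, H, W, C).
#' @param lab_arr integer array (D, H, W).
#' @param patch_size integer triple.
#' @return list with `x` (patch array) and `y` (label patch).
#' @export
sample_patch <- function(vol_arr, lab_arr, patch_size) {
  g <- dim(lab_arr)
  pad <- pmax(0, patch_size - g)
  if (any(pad > 0)) {
    lo <- floor(pad / 2); hi <- pad - lo
    box <- list(min_corner = c(0, 0, 0), max_corner = g)
    class(box) <- "dsnet_bbox"
    vol_arr <- crop_pad_array(vol_arr, box, g + pad, fill = 0)
    lab_arr <- crop_pad_array(lab_arr, box, g + pad, fill = 0L)
    g <- g + pad
  }
  corner <- vapply(1:3, function(a)
    if (g[a] == patch_size[a]) 0L
    else sample.int(g[a] - patch_size[a] + 1L, 1L) - 1L, 0L)
  idx <- lapply(1:3, function(a) corner[a] + seq_len(patch_size[a]))
  list(x = vol_arr[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE],
       y = array(lab_arr[idx[[1]], idx[[2]], idx[[3]]], patch_size),
       corner = corner)
}

#' Patch augmentation
#'
#' Independent per-axis mirroring (labels mirrored identically), one
#' additive intensity shift per channel drawn uniformly from
#' `intensity_shift_range`, and one isotropic zoom drawn from `scale_range`
#' (trilinear for intensities, nearest-neighbour for labels) followed by a
#' centre crop/pad back to the patch size.
#'
#' @param x patch array (D, H, W, C).
#' @param y label array (D, H, W).
#' @param cfg a [train_config()].
#' @return list with augmented `x` and `y`.
#' @export
augment <- function(x, y, cfg) {
  p <- dim(y)
  for (a in 1:3) {
    if (runif(1) < cfg$mirror_prob) {
      ridx <- rev(seq_len(p[a]))
      if (a == 1) { x <- x[ridx, , , , drop = FALSE]; y <- y[ridx, , , drop = FALSE] }
      if (a == 2) { x <- x[, ridx, , , drop = FALSE]; y <- y[, ridx, , drop = FALSE] }
      if (a == 3) { x <- x[, , ridx, , drop = FALSE]; y <- y[, , ridx, drop = FALSE] }
    }
  }
  shifts <- runif(dim(x)[4], cfg$intensity_shift_range[1],
                  cfg$intensity_shift_range[2])
  for (ci in seq_len(dim(x)[4])) x[, , , ci] <- x[, , , ci] + shifts[ci]
  s <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
  if (abs(s - 1) > 1e-12) {
    zdim <- pmax(1L, as.integer(round(p * s)))
    xz <- array(0, c(zdim, dim(x)[4]))
    for (ci in seq_len(dim(x)[4]))
      xz[, , , ci] <- cpp_resize3d(x[, , , ci], p, zdim, FALSE)
    yz <- array(as.integer(round(cpp_resize3d(y + 0, p, zdim, TRUE))), zdim)
    box <- list(min_corner = c(0, 0, 0), max_corner = zdim)
    class(box) <- "dsnet_bbox"
    x <- crop_pad_array(xz, box, p, fill = 0)
    y <- array(as.integer(crop_pad_array(yz, box, p, fill = 0L)), p)
  }
  list(x = x, y = y)
}

#' Train the network
#'
#' Adam optimization of the dual Dice loss over randomly cropped, augmented
#' patches, with the polynomial learning-rate schedule, L2 weight decay and
#' retention of the last k epoch checkpoints. Fully deterministic given the
#' config seed. Training aborts with an error naming the epoch if the loss
#' becomes non-finite.
#'
#' @param dataset list of subjects (`volume` + `labels`), e.g. from
#'   [generate_cohort()] or [flip_double()].
#' @param model_cfg a [model_config()].
#' @param cfg a [train_config()].
#' @param loss a [loss_spec()].
#' @param normalize z-score each subject's channels before training.
#' @param verbose print one line per `verbose` epochs (0 = silent).
#' @return a `dsnet_fit`: list with `model`, `checkpoints` (list of
#'   `state`/`epoch`), `loss_curve`, `lr_trace`, and the configs.
#' @export
dsnet_train <- function(dataset, model_cfg = model_config(),
                        cfg = train_config(), loss = loss_spec(),
                        normalize = TRUE, verbose = 0L) {
  if (!length(dataset)) stop("empty training dataset")
  if (!model_cfg$dual_branch && loss$lambda1 > 0)
    stop("single-branch model cannot optimize a binary-branch loss; ",
         "set lambda1 = 0")
  set.seed(cfg$seed)
  model <- dsnet_model(model_cfg, cfg$patch_size)
  vols <- lapply(dataset, function(s) {
    v <- if (normalize) zscore_normalize(s$volume) else s$volume
    v$data
  })
  labs <- lapply(dataset, function(s) s$labels$labels)
  ns <- length(dataset)
  steps_per_epoch <- ceiling(ns / cfg$batch_size)
  total_steps <- cfg$max_epochs * steps_per_epoch
  loss_curve <- numeric(cfg$max_epochs)
  lr_trace <- numeric(total_steps)
  checkpoints <- list()
  step <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(ns)
    ep_losses <- numeric(steps_per_epoch)
    for (b in seq_len(steps_per_epoch)) {
      ids <- perm[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, ns)]
      xb <- array(0, c(cfg$patch_size, model_cfg$in_channels, length(ids)))
      yb <- array(0L, c(cfg$patch_size, length(ids)))
      for (j in seq_along(ids)) {
        pt <- sample_patch(vols[[ids[j]]], labs[[ids[j]]], cfg$patch_size)
        ag <- augment(pt$x, pt$y, cfg)
        xb[, , , , j] <- ag$x
        yb[, , , j] <- ag$y
      }
      out <- dsnet_forward(model, xb, training = TRUE)
      fw <- total_loss_fw(out$binary, out$subfield, yb, loss)
      if (!is.finite(fw$loss))
        stop("non-finite loss at epoch ", epoch, "; training diverged")
      ep_losses[b] <- fw$loss
      gr <- total_loss_bw(fw, loss)
      model_zero_grads(model)
      dsnet_backward(model, gr$d_subfield, gr$d_binary)
      lr <- poly_lr(step, total_steps, cfg$lr0, cfg$poly_power)
      lr_trace[step + 1L] <- lr
      adam_step(model, lr, weight_decay = cfg$weight_decay)
      step <- step + 1L
    }
    loss_curve[epoch] <- mean(ep_losses)
    checkpoints <- c(checkpoints,
                     list(list(state = model_state(model), epoch = epoch)))
    if (length(checkpoints) > cfg$keep_last_k_checkpoints)
      checkpoints <- checkpoints[-1]
    if (verbose > 0 && (epoch %% verbose == 0 || epoch == 1))
      cat(sprintf("epoch %d  loss %.4f  lr %.2e\n", epoch,
                  loss_curve[epoch], lr))
  }
  structure(list(model = model, checkpoints = checkpoints,
                 loss_curve = loss_curve, lr_trace = lr_trace,
                 model_cfg = model_cfg, train_cfg = cfg, loss_spec = loss,
                 normalize = normalize),
            class = "dsnet_fit")
}

#' @export
print.dsnet_fit <- function(x, ...) {
  ne <- length(x$loss_curve)
  cat(sprintf("<dsnet_fit> %d epochs, final loss %.4f, %d checkpoints (epochs %s)\n",
              ne, x$loss_curve[ne], length(x$checkpoints),
              paste(vapply(x$checkpoints, `[[`, 0L, "epoch"),
                    collapse = ",")))
  invisible(x)
}
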