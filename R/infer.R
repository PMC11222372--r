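#' Non-overlapping window tiling of a grid
#'
#' Computes the symmetric zero-padding that brings a grid to a multiple of
#' the window size and the corners of the disjoint windows that partition
#' the padded grid: every padded voxel is covered by exactly one window.
#'
#' @param grid_shape integer triple (D, H, W).
#' @param window window size, length 1 or 3.
#' @return list with `padded` (padded grid shape), `n_windows` (per axis)
#'   and `corners` (matrix of 0-based window corners, one row per window).
#' @export
sliding_windows <- function(grid_shape, window) {
  window <- as.integer(if (length(window) == 1) rep(window, 3) else window)
  padded <- as.integer(ceiling(grid_shape / window) * window)
  nt <- padded %/% window
  corners <- as.matrix(expand.grid(d = (seq_len(nt[1]) - 1L) * window[1],
                                   h = (seq_len(nt[2]) - 1L) * window[2],
                                   w = (seq_len(nt[3]) - 1L) * window[3]))
  list(padded = padded, n_windows = nt, corners = corners, window = window)
}

#' Non-overlapping sliding-window prediction with checkpoint averaging
#'
#' The volume is symmetrically zero-padded to a multiple of the window size
#' (the extra voxel on the high side), tiled by disjoint windows, and each
#' window's per-class softmax output is averaged arithmetically over all
#' retained checkpoints. Tiles are reassembled and the padding cropped, so
#' every voxel is covered by exactly one window and the output probabilities
#' sum to 1 per voxel.
#'
#' @param v a `dsnet_volume` (same channel set the model was trained on).
#' @param fit a `dsnet_fit` from [dsnet_train()], or a list with `model` and
#'   `checkpoints`.
#' @param window window size (defaults to the model's patch size).
#' @param normalize z-score the volume first (must match training).
#' @return list with `subfield` probabilities (D, H, W, n_classes) and, for
#'   dual-branch models, `binary` probabilities (D, H, W, 2).
#' @export
sliding_window_predict <- function(v, fit, window = NULL, normalize = TRUE) {
  model <- fit$model
  ckpts <- fit$checkpoints
  if (!length(ckpts)) stop("no checkpoints to average")
  window <- as.integer(window %||% model$patch)
  if (length(window) == 1) window <- rep(window, 3)
  if (normalize) v <- zscore_normalize(v)
  g <- grid_shape(v)
  sw <- sliding_windows(g, window)
  box <- structure(list(min_corner = c(0, 0, 0), max_corner = g),
                   class = "dsnet_bbox")
  arr <- crop_pad_array(v$data, box, sw$padded, fill = 0)
  nC_sub <- model$cfg$n_classes_subfield
  dual <- model$cfg$dual_branch
  sub_out <- array(0, c(sw$padded, nC_sub))
  bin_out <- if (dual) array(0, c(sw$padded, model$cfg$n_classes_binary))
  for (t in seq_len(nrow(sw$corners))) {
    id <- sw$corners[t, 1] + seq_len(window[1])
    ih <- sw$corners[t, 2] + seq_len(window[2])
    iw <- sw$corners[t, 3] + seq_len(window[3])
    xw <- array(arr[id, ih, iw, , drop = FALSE],
                c(window, dim(arr)[4], 1L))
    sub_acc <- 0; bin_acc <- 0
    for (ck in ckpts) {
      load_model_state(model, ck$state)
      out <- dsnet_forward(model, xw, training = FALSE)
      sub_acc <- sub_acc + softmax_channels(out$subfield)
      if (dual) bin_acc <- bin_acc + softmax_channels(out$binary)
    }
    sub_out[id, ih, iw, ] <- sub_acc[, , , , 1] / length(ckpts)
    if (dual) bin_out[id, ih, iw, ] <- bin_acc[, , , , 1] / length(ckpts)
  }
  crop <- lapply(1:3, function(a) seq_len(g[a]))
  out <- list(subfield = sub_out[crop[[1]], crop[[2]], crop[[3]], ,
                                 drop = FALSE])
  if (dual) out$binary <- bin_out[crop[[1]], crop[[2]], crop[[3]], ,
                                  drop = FALSE]
  out
}

#' Hard labels from averaged probabilities
#'
#' Argmax over the subfield classes (ties broken toward the lowest class
#' index), optionally followed by [cc_filter()].
#'
#' @param probs array (D, H, W, n_classes) of class probabilities (class 1 =
#'   background).
#' @param spacing,origin grid geometry for the returned label map.
#' @param min_voxels connected-component threshold; 0 disables filtering.
#' @return a `dsnet_labelmap`.
#' @export
probs_to_labelmap <- function(probs, spacing = c(0.4, 0.4, 0.4),
                              origin = c(0, 0, 0), min_voxels = 1000L) {
  d <- dim(probs)
  M <- matrix(probs, ncol = d[4])
  lab <- array(max.col(M, ties.method = "first") - 1L, d[1:3])
  lm <- new_labelmap(lab, spacing = spacing, origin = origin)
  if (min_voxels > 0) lm <- cc_filter(lm, min_voxels)
  lm
}

#' Connected-component false-positive filter
#'
#' Labels the connected components (26-connectivity) of the binary union
#' mask `label > 0` and relabels every component smaller than `min_voxels`
#' voxels to background, across all subfield labels. Components at or above
#' the threshold are untouched. The removed components are reported in the
#' `removed` attribute with voxel counts and physical volumes.
#'
#' @param pred a `dsnet_labelmap`.
#' @param min_voxels strict threshold: components with size < `min_voxels`
#'   are removed (default 1000, i.e. 64 mm^3 at 0.4 mm isotropic voxels).
#' @return the filtered `dsnet_labelmap` with attribute `removed` (a
#'   data.frame of `size` and `volume_mm3`).
#' @export
cc_filter <- function(pred, min_voxels = 1000L) {
  stopifnot(inherits(pred, "dsnet_labelmap"))
  comp <- cpp_cc_label(array(as.integer(pred$labels > 0L), dim(pred$labels)),
                       dim(pred$labels))
  sizes <- tabulate(comp)
  vox_mm3 <- prod(pred$spacing)
  small <- which(sizes < min_voxels & sizes > 0)
  out <- pred
  if (length(small))
    out$labels[comp %in% small] <- 0L
  attr(out, "removed") <- data.frame(size = sizes[small],
                                     volume_mm3 = sizes[small] * vox_mm3)
  out
}

#' End-to-end prediction for one subject
#'
#' Sliding-window inference, checkpoint averaging, argmax and
#' connected-component filtering in one call.
#'
#' @inheritParams sliding_window_predict
#' @param min_voxels component threshold passed to [cc_filter()]; 0 disables.
#' @return a `dsnet_labelmap` of predicted subfields.
#' @export
dsnet_predict <- function(v, fit, window = NULL, normalize = TRUE,
                          min_voxels = 1000L) {
  pr <- sliding_window_predict(v, fit, window = window, normalize = normalize)
  probs_to_labelmap(pr$subfield, spacing = v$spacing, origin = v$origin,
                    min_voxels = min_voxels)
}
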