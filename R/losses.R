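#' Loss weighting and smoothing for the dual Dice objective
#'
#' @param lambda1 weight of the binary (whole-hippocampus) branch loss.
#' @param lambda2 weight of the multi-class (subfield) branch loss.
#' @param smooth epsilon added to the numerator and denominator of each
#'   per-class soft Dice term, guarding 0/0 for absent classes.
#' @return a `dsnet_loss_spec` list.
#' @export
loss_spec <- function(lambda1 = 0.5, lambda2 = 0.5, smooth = 1e-5) {
  if (lambda1 < 0 || lambda2 < 0 || lambda1 + lambda2 <= 0)
    stop("loss weights must be non-negative with a positive sum")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, smooth = smooth),
            class = "dsnet_loss_spec")
}

softmax_channels <- function(logits) {
  d <- dim(logits); C <- d[4]
  mx <- logits[, , , 1, , drop = FALSE]
  for (ci in seq_len(C)[-1]) mx <- pmax(mx, logits[, , , ci, , drop = FALSE])
  e <- logits
  for (ci in seq_len(C)) e[, , , ci, ] <- exp(logits[, , , ci, ] - mx[, , , 1, ])
  s <- e[, , , 1, , drop = FALSE]
  for (ci in seq_len(C)[-1]) s <- s + e[, , , ci, , drop = FALSE]
  for (ci in seq_len(C)) e[, , , ci, ] <- e[, , , ci, ] / s[, , , 1, ]
  e
}

one_hot <- function(labels, n_classes) {
  # labels: integer array (D, H, W, N) with values 0..n_classes-1
  d <- dim(labels)
  out <- array(0, c(d[1:3], n_classes, d[4]))
  for (ci in seq_len(n_classes))
    out[, , , ci, ] <- (labels == ci - 1L) * 1
  out
}

#' Soft Dice loss
#'
#' The negated soft Dice coefficient, averaged over classes and batch:
#' for each sample and class, `(2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)`
#' with voxelwise products summed over the spatial grid. Perfect hard
#' predictions give -1; disjoint masks give ~0.
#'
#' @param pred_probs per-class probability array (D, H, W, C, N); must sum to
#'   1 over classes at every voxel.
#' @param target one-hot array of the same shape.
#' @param spec a [loss_spec()] (only `smooth` is used).
#' @return scalar in `[-1, 0]`.
#' @export
dice_loss <- function(pred_probs, target, spec = loss_spec()) {
  dice_loss_fw(pred_probs, target, spec$smooth)$loss
}

dice_loss_fw <- function(p, y, eps) {
  if (!identical(dim(p), dim(y))) stop("prediction/target shape mismatch")
  d <- dim(p); C <- d[4]; N <- d[5]
  num <- matrix(0, C, N); den <- matrix(0, C, N)
  for (n in seq_len(N)) for (ci in seq_len(C)) {
    pp <- p[, , , ci, n]; yy <- y[, , , ci, n]
    num[ci, n] <- 2 * sum(pp * yy) + eps
    den[ci, n] <- sum(pp) + sum(yy) + eps
  }
  list(loss = -mean(num / den), num = num, den = den)
}

# Gradient of dice_loss with respect to the probabilities.
dice_loss_bw <- function(p, y, fw) {
  d <- dim(p); C <- d[4]; N <- d[5]
  dp <- array(0, d)
  scale <- -1 / (C * N)
  for (n in seq_len(N)) for (ci in seq_len(C)) {
    dp[, , , ci, n] <- scale * (2 * y[, , , ci, n] / fw$den[ci, n] -
                                  fw$num[ci, n] / fw$den[ci, n]^2)
  }
  dp
}

# d(loss)/d(logits) given d(loss)/d(probs), through the channel softmax.
softmax_bw <- function(probs, dprobs) {
  d <- dim(probs); C <- d[4]
  s <- probs[, , , 1, , drop = FALSE] * dprobs[, , , 1, , drop = FALSE]
  for (ci in seq_len(C)[-1])
    s <- s + probs[, , , ci, , drop = FALSE] * dprobs[, , , ci, , drop = FALSE]
  out <- array(0, d)
  for (ci in seq_len(C))
    out[, , , ci, ] <- probs[, , , ci, ] * (dprobs[, , , ci, ] - s[, , , 1, ])
  out
}

#' Combined dual-branch loss
#'
#' `lambda1 * L_binary + lambda2 * L_subfield`, each term a [dice_loss()] on
#' the corresponding branch's softmax probabilities. The binary target is
#' `label > 0`; the subfield target is the 4-class one-hot encoding.
#'
#' @param binary_logits logits (D, H, W, 2, N), or NULL for single-branch
#'   models (then `lambda1` must be 0).
#' @param subfield_logits logits (D, H, W, 4, N).
#' @param labels integer array (D, H, W, N) with values 0..3.
#' @param spec a [loss_spec()].
#' @return scalar loss.
#' @export
total_loss <- function(binary_logits, subfield_logits, labels,
                       spec = loss_spec()) {
  total_loss_fw(binary_logits, subfield_logits, labels, spec)$loss
}

total_loss_fw <- function(binary_logits, subfield_logits, labels, spec) {
  if (length(dim(labels)) == 3L) dim(labels) <- c(dim(labels), 1L)
  nsub <- dim(subfield_logits)[4]
  y_sub <- one_hot(labels, nsub)
  p_sub <- softmax_channels(subfield_logits)
  fw_sub <- dice_loss_fw(p_sub, y_sub, spec$smooth)
  out <- list(p_sub = p_sub, y_sub = y_sub, fw_sub = fw_sub)
  if (spec$lambda1 > 0) {
    if (is.null(binary_logits))
      stop("binary branch logits required when lambda1 > 0")
    y_bin <- one_hot((labels > 0L) * 1L, dim(binary_logits)[4])
    p_bin <- softmax_channels(binary_logits)
    fw_bin <- dice_loss_fw(p_bin, y_bin, spec$smooth)
    out$p_bin <- p_bin; out$y_bin <- y_bin; out$fw_bin <- fw_bin
    out$loss <- spec$lambda1 * fw_bin$loss + spec$lambda2 * fw_sub$loss
  } else {
    out$loss <- spec$lambda2 * fw_sub$loss
  }
  out
}

total_loss_bw <- function(fw, spec) {
  d_sub <- softmax_bw(fw$p_sub,
                      spec$lambda2 * dice_loss_bw(fw$p_sub, fw$y_sub,
                                                  fw$fw_sub))
  d_bin <- NULL
  if (!is.null(fw$p_bin))
    d_bin <- softmax_bw(fw$p_bin,
                        spec$lambda1 * dice_loss_bw(fw$p_bin, fw$y_bin,
                                                    fw$fw_bin))
  list(d_subfield = d_sub, d_binary = d_bin)
}
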