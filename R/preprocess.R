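#' Foreground bounding box with margin
#'
#' Scans one or more label maps, takes the union of all foreground voxels,
#' expands the box by `margin` voxels in every direction and clips it to the
#' grid. Coordinates are 0-based with inclusive lower / exclusive upper
#' corners.
#'
#' @param labels a `dsnet_labelmap` or list of them (all on the same grid).
#' @param margin expansion in voxels (default 32).
#' @return a `dsnet_bbox`: list with `min_corner` and `max_corner`.
#' @export
compute_bounding_box <- function(labels, margin = 32L) {
  if (inherits(labels, "dsnet_labelmap")) labels <- list(labels)
  g <- grid_shape(labels[[1]])
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (lm in labels) {
    stopifnot(inherits(lm, "dsnet_labelmap"))
    idx <- which(lm$labels > 0L, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    lo <- pmin(lo, apply(idx, 2, min) - 1)   # to 0-based
    hi <- pmax(hi, apply(idx, 2, max) - 1)
  }
  if (any(!is.finite(lo))) stop("all label maps are background-only")
  box <- list(min_corner = pmax(0, lo - margin),
              max_corner = pmin(g, hi + 1 + margin))
  class(box) <- "dsnet_bbox"
  box
}

#' @export
print.dsnet_bbox <- function(x, ...) {
  cat(sprintf("<dsnet_bbox> [%s) x [%s) x [%s)\n",
              paste(c(x$min_corner[1], x$max_corner[1]), collapse = ", "),
              paste(c(x$min_corner[2], x$max_corner[2]), collapse = ", "),
              paste(c(x$min_corner[3], x$max_corner[3]), collapse = ", ")))
  invisible(x)
}

# symmetric pad/trim of index range [0, n) to length target;
# the extra voxel goes on the high side when the difference is odd.
pad_trim_axis <- function(n, target) {
  diff <- target - n
  lo <- floor(abs(diff) / 2) * sign(diff)
  hi <- (abs(diff) - floor(abs(diff) / 2)) * sign(diff)
  c(lo, hi)  # padding (positive) or trimming (negative) at each end
}

crop_pad_array <- function(arr, box, target = NULL, fill = 0) {
  nd <- length(dim(arr))
  idx <- lapply(1:3, function(a)
    seq.int(box$min_corner[a] + 1, box$max_corner[a]))
  args <- c(list(arr), idx, rep(list(quote(expr = )), nd - 3),
            list(drop = FALSE))
  out <- do.call(`[`, args)
  if (is.null(target)) return(out)
  for (a in 1:3) {
    n <- dim(out)[a]
    pt <- pad_trim_axis(n, target[a])
    if (all(pt == 0)) next
    keep <- seq.int(max(1, 1 - pt[1]), min(n, n + pt[2]))
    d2 <- dim(out); d2[a] <- target[a]
    new <- array(fill, d2)
    pos <- seq.int(max(1, 1 + pt[1]), length.out = length(keep))
    src <- vector("list", nd); dst <- vector("list", nd)
    for (k in seq_len(nd)) {
      src[[k]] <- if (k == a) keep else seq_len(dim(out)[k])
      dst[[k]] <- if (k == a) pos else seq_len(d2[k])
    }
    new <- do.call(`[<-`, c(list(new), dst,
                            list(do.call(`[`, c(list(out), src,
                                                list(drop = FALSE))))))
    out <- new
  }
  out
}

#' Crop to a bounding box and fit to a target shape
#'
#' Crops the grid to `box`, then symmetrically zero-pads or trims each axis
#' to `target_shape` (the extra voxel on the high side when odd). Labels are
#' never interpolated. A warning is issued when trimming removes foreground.
#'
#' @param x a `dsnet_volume` or `dsnet_labelmap`.
#' @param box a [compute_bounding_box()] result.
#' @param target_shape integer triple, or NULL to keep the box extent.
#' @return object of the same class on the new grid.
#' @export
crop_to_box <- function(x, box, target_shape = NULL) {
  stopifnot(inherits(box, "dsnet_bbox"))
  g <- grid_shape(x)
  if (any(box$min_corner < 0) || any(box$max_corner > g) ||
      any(box$min_corner >= box$max_corner))
    stop("bounding box invalid for this grid")
  new_origin <- x$origin + box$min_corner * x$spacing
  if (!is.null(target_shape)) {
    ext <- box$max_corner - box$min_corner
    off <- vapply(1:3, function(a) pad_trim_axis(ext[a], target_shape[a])[1],
                  0)
    new_origin <- new_origin - off * x$spacing
  }
  if (inherits(x, "dsnet_labelmap")) {
    lab <- crop_pad_array(x$labels, box, target_shape, fill = 0L)
    out <- new_labelmap(array(as.integer(lab), dim(lab)),
                        spacing = x$spacing, origin = new_origin,
                        legend = x$legend)
    if (sum(out$labels > 0) < sum(crop_pad_array(x$labels, box) > 0))
      warning("target shape trims foreground voxels")
    out
  } else {
    dat <- crop_pad_array(x$data, box, target_shape, fill = 0)
    new_volume(dat, channels = x$channels, spacing = x$spacing,
               origin = new_origin)
  }
}

#' Histogram matching of intensity channels
#'
#' Maps each channel of `src` through the monotone piecewise-linear transform
#' that carries its empirical quantile function onto the reference's,
#' evaluated at `n_quantiles` evenly spaced quantiles.
#'
#' @param src,ref `dsnet_volume`s with the same channel set.
#' @param n_quantiles number of quantile anchors (default 256).
#' @return `src` with matched intensities.
#' @export
histogram_match <- function(src, ref, n_quantiles = 256L) {
  stopifnot(inherits(src, "dsnet_volume"), inherits(ref, "dsnet_volume"))
  if (!identical(src$channels, ref$channels))
    stop("source and reference must share the channel set")
  probs <- seq(0, 1, length.out = n_quantiles)
  out <- src
  for (i in seq_along(src$channels)) {
    s <- as.vector(src$data[, , , i])
    r <- as.vector(ref$data[, , , i])
    if (diff(range(r)) < 1e-12)
      stop("reference channel '", src$channels[i], "' is constant")
    if (diff(range(s)) < 1e-12) {
      out$data[, , , i] <- stats::median(r)
      next
    }
    sq <- quantile(s, probs, names = FALSE)
    rq <- quantile(r, probs, names = FALSE)
    keep <- !duplicated(sq)
    sq2 <- sq[keep]
    rq2 <- vapply(split(rq, cumsum(keep)), mean, 0)
    mapped <- if (length(sq2) == 1L) rep(rq2, length(s))
              else approx(sq2, rq2, xout = s, rule = 2)$y
    out$data[, , , i] <- array(mapped, dim(src$data)[1:3])
  }
  out
}

flip_w <- function(x) {
  if (inherits(x, "dsnet_labelmap")) {
    W <- dim(x$labels)[3]
    x$labels <- x$labels[, , W:1, drop = FALSE]
    dim(x$labels) <- grid_shape(x)
  } else {
    W <- dim(x$data)[3]
    x$data <- x$data[, , W:1, , drop = FALSE]
  }
  x
}

#' Double a training set by left-right mirroring
#'
#' Appends to the dataset a copy of every subject mirrored along the W
#' (left-right) axis; labels are mirrored identically and keep their
#' subfield identities.
#'
#' @param dataset list of subjects, each a list with `volume` and `labels`.
#' @return list of length `2 * length(dataset)`.
#' @export
flip_double <- function(dataset) {
  if (!length(dataset)) stop("empty dataset")
  c(dataset, lapply(dataset, function(s) {
    s$volume <- flip_w(s$volume)
    s$labels <- flip_w(s$labels)
    s
  }))
}
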