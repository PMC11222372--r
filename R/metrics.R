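#' Dice overlap coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks score 1 (perfect
#' agreement on absence); one empty mask scores 0.
#'
#' @param a,b logical or 0/1 arrays on the same grid.
#' @return a fraction in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks are not on the same grid")
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

mask_surface_coords <- function(mask, spacing) {
  bd <- cpp_boundary(array(as.integer(mask > 0), dim(mask)), dim(mask))
  idx <- which(bd, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, `*`)
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Directed distances are computed between the surface-voxel sets of the two
#' masks (foreground voxels with a face-adjacent background neighbour) in
#' physical millimetres. The directed distances from both directions are
#' pooled, sorted ascending, and the lower nearest-rank 95th percentile is
#' returned. `hausdorff_distance()` returns the maximum instead.
#'
#' @param a,b binary masks on the same grid.
#' @param spacing voxel size in mm per axis.
#' @param percentile percentile of the pooled distances (0.95).
#' @return distance in mm, or `NA` (with attribute `defined = FALSE`) when
#'   either mask is empty.
#' @export
hd95 <- function(a, b, spacing = c(0.4, 0.4, 0.4), percentile = 0.95) {
  if (!identical(dim(a), dim(b))) stop("masks are not on the same grid")
  if (sum(a > 0) == 0 || sum(b > 0) == 0)
    return(structure(NA_real_, defined = FALSE))
  A <- mask_surface_coords(a, spacing)
  B <- mask_surface_coords(b, spacing)
  pooled <- sort(c(cpp_min_dists(A, B), cpp_min_dists(B, A)))
  k <- max(1L, ceiling(percentile * length(pooled)))
  structure(pooled[k], defined = TRUE)
}

#' @rdname hd95
#' @export
hausdorff_distance <- function(a, b, spacing = c(0.4, 0.4, 0.4)) {
  h <- hd95(a, b, spacing, percentile = 1)
  h
}

#' Per-structure segmentation metrics
#'
#' Dice and HD95 for each subfield label (CA1-3, CA4/DG, SUB) and for the
#' whole hippocampus, computed on the union mask `label > 0`. A structure
#' missing from the prediction scores Dice 0 and an undefined (NA) HD95.
#'
#' @param pred,truth `dsnet_labelmap` objects on the same grid with the same
#'   legend.
#' @param spacing voxel spacing in mm (defaults to the truth's).
#' @return data.frame with columns `structure`, `label`, `dice`, `hd95`,
#'   `hd95_defined`.
#' @export
evaluate <- function(pred, truth, spacing = NULL) {
  stopifnot(inherits(pred, "dsnet_labelmap"), inherits(truth, "dsnet_labelmap"))
  check_same_grid(pred, truth)
  if (!identical(unname(unlist(pred$legend)), unname(unlist(truth$legend))))
    stop("label legends differ between prediction and truth")
  spacing <- spacing %||% truth$spacing
  keys <- as.integer(names(truth$legend))
  rows <- lapply(keys, function(k) {
    a <- truth$labels == k; b <- pred$labels == k
    h <- hd95(b, a, spacing)
    data.frame(structure = unname(truth$legend[[as.character(k)]]),
               label = k, dice = dice_coefficient(a, b),
               hd95 = as.numeric(h),
               hd95_defined = isTRUE(attr(h, "defined")))
  })
  a <- truth$labels > 0; b <- pred$labels > 0
  h <- hd95(b, a, spacing)
  rows <- c(rows, list(data.frame(structure = "Hippocampus", label = NA_integer_,
                                  dice = dice_coefficient(a, b),
                                  hd95 = as.numeric(h),
                                  hd95_defined = isTRUE(attr(h, "defined")))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dsnet_metrics", "data.frame")
  out
}

#' Serialize a metrics report
#'
#' @param report a data.frame from [evaluate()] (or several rbind-ed ones).
#' @param path output file; `.json` writes JSON, anything else CSV.
#' @return invisibly, the path.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
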