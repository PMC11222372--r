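#' Grid containers: intensity volumes and label maps
#'
#' A `dsnet_volume` holds one or more co-registered 3D intensity channels on a
#' common voxel grid; a `dsnet_labelmap` holds an integer segmentation on the
#' same kind of grid. Index order is (D, H, W) = (axial slice, row, column),
#' 0.4 mm isotropic by default. The label legend is fixed to the three
#' hippocampal subfields: 1 = CA1-3, 2 = CA4/DG, 3 = SUB; 0 is background.
#'
#' @param data numeric array, either (D, H, W) for a single channel or
#'   (D, H, W, C).
#' @param channels character vector of modality names, one per channel
#'   (e.g. `c("t1w", "t2w")`).
#' @param spacing numeric length-3, voxel size in mm along (D, H, W).
#' @param origin numeric length-3, world coordinate (mm) of voxel (0, 0, 0).
#' @return `new_volume()` returns a `dsnet_volume`; `new_labelmap()` a
#'   `dsnet_labelmap`.
#' @examples
#' v <- new_volume(array(rnorm(8^3), c(8, 8, 8)), channels = "t1w")
#' dim(v$data)
#' @export
new_volume <- function(data, channels = NULL,
                       spacing = c(0.4, 0.4, 0.4), origin = c(0, 0, 0)) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[4]))
  if (length(channels) != dim(data)[4])
    stop("channels must name every channel of `data`")
  if (any(!is.finite(data))) stop("volume contains non-finite voxels")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(data = data, channels = as.character(channels),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "dsnet_volume")
}

#' @rdname new_volume
#' @param labels integer array (D, H, W) of label values.
#' @param legend named list or vector mapping label values to structure names.
#' @export
new_labelmap <- function(labels, spacing = c(0.4, 0.4, 0.4),
                         origin = c(0, 0, 0), legend = subfield_legend()) {
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (any(is.na(labels))) stop("label map contains NA voxels")
  keys <- as.integer(names(legend))
  bad <- setdiff(unique(as.vector(labels)), c(0L, keys))
  if (length(bad))
    stop("label values outside legend: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), legend = legend),
            class = "dsnet_labelmap")
}

#' @rdname new_volume
#' @export
subfield_legend <- function() {
  c(`1` = "CA1-3", `2` = "CA4/DG", `3` = "SUB")
}

#' @export
print.dsnet_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dsnet_volume> %d x %d x %d, channels: %s, spacing %s mm\n",
              d[1], d[2], d[3], paste(x$channels, collapse = "/"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.dsnet_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = c(0L, as.integer(names(x$legend)))))
  cat(sprintf("<dsnet_labelmap> %d x %d x %d, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x")))
  cat("  voxels:", paste(sprintf("%s=%d", c("bg", unlist(x$legend)), tab),
                         collapse = ", "), "\n")
  invisible(x)
}

grid_shape <- function(x) {
  if (inherits(x, "dsnet_volume")) dim(x$data)[1:3] else dim(x$labels)[1:3]
}

check_same_grid <- function(a, b) {
  if (!identical(grid_shape(a), grid_shape(b)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("objects are not on the same voxel grid")
  invisible(TRUE)
}

#' Read a NIfTI image as a volume or label map
#'
#' Files are read in (D, H, W) index order with spacing and origin taken from
#' the header. Integer-valued files (or `as_labels = TRUE`) become label maps;
#' anything else becomes a single-channel intensity volume. Multi-channel
#' volumes are stored as one file per modality and paired by filename suffix
#' (`_t1w`, `_t2w`, ...): see [read_volume_channels()].
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_labels force interpretation as a label map.
#' @return a [new_volume()] or [new_labelmap()] object.
#' @export
read_nifti <- function(path, as_labels = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop(path, ": expected a 3D image")
  arr <- array(as.vector(img), dim(img))
  if (any(!is.finite(arr))) stop(path, ": image contains non-finite voxels")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  hdr <- RNifti::niftiHeader(img)
  int_dtype <- hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L)
  is_lab <- if (is.na(as_labels)) {
    int_dtype && all(arr == round(arr)) && min(arr) >= 0 && max(arr) <= 3
  } else as_labels
  if (is_lab) {
    new_labelmap(array(as.integer(round(arr)), dim(arr)),
                 spacing = sp, origin = org)
  } else {
    ch <- sub("\\.nii(\\.gz)?$", "", basename(path))
    ch <- if (grepl("_[A-Za-z0-9]+$", ch)) sub("^.*_", "", ch) else "ch1"
    new_volume(arr, channels = ch, spacing = sp, origin = org)
  }
}

#' @rdname read_nifti
#' @param paths named character vector of per-channel files; names become
#'   channel names (defaults to filename suffixes).
#' @export
read_volume_channels <- function(paths) {
  vols <- lapply(paths, read_nifti, as_labels = FALSE)
  ref <- vols[[1]]
  arr <- array(0, c(grid_shape(ref), length(vols)))
  for (i in seq_along(vols)) {
    check_same_grid(ref, vols[[i]])
    arr[, , , i] <- vols[[i]]$data[, , , 1]
  }
  ch <- if (!is.null(names(paths))) names(paths)
        else vapply(vols, function(v) v$channels[1], "")
  new_volume(arr, channels = ch, spacing = ref$spacing, origin = ref$origin)
}

#' Write a volume or label map to NIfTI
#'
#' Labels are stored as unsigned 8-bit integers (lossless for the 4-class
#' legend); intensity channels as 32-bit floats or better. A multi-channel
#' volume is written as one file per channel with the channel name appended
#' (`<stem>_t1w.nii.gz`, ...).
#'
#' @param obj a `dsnet_volume` or `dsnet_labelmap`.
#' @param path output path (`.nii` or `.nii.gz`). For multi-channel volumes,
#'   the stem onto which channel suffixes are appended.
#' @param datatype storage type for intensity data.
#' @return invisibly, the file path(s) written.
#' @export
write_nifti <- function(obj, path, datatype = "float") {
  UseMethod("write_nifti")
}

nifti_with_geometry <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  img
}

#' @export
write_nifti.dsnet_labelmap <- function(obj, path, datatype = "uint8") {
  img <- nifti_with_geometry(obj$labels, obj$spacing, obj$origin)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @export
write_nifti.dsnet_volume <- function(obj, path, datatype = "float") {
  nch <- length(obj$channels)
  if (nch == 1L) {
    img <- nifti_with_geometry(obj$data[, , , 1], obj$spacing, obj$origin)
    RNifti::writeNifti(img, path, datatype = datatype)
    return(invisible(path))
  }
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  ext <- if (grepl("\\.nii$", path)) ".nii" else ".nii.gz"
  out <- character(nch)
  for (i in seq_len(nch)) {
    out[i] <- paste0(stem, "_", obj$channels[i], ext)
    img <- nifti_with_geometry(obj$data[, , , i], obj$spacing, obj$origin)
    RNifti::writeNifti(img, out[i], datatype = datatype)
  }
  invisible(out)
}

#' Z-score standardize each channel of a volume
#'
#' Centers every channel to mean 0 and scales it to unit variance over all
#' voxels. Applied before patch sampling so that the additive intensity-shift
#' augmentation range (+/- 0.1) is expressed on a unit-variance scale.
#'
#' @param v a `dsnet_volume`.
#' @return a `dsnet_volume` with standardized channels.
#' @export
zscore_normalize <- function(v) {
  stopifnot(inherits(v, "dsnet_volume"))
  out <- v
  for (i in seq_along(v$channels)) {
    ch <- v$data[, , , i]
    s <- sd(as.vector(ch)) * sqrt((length(ch) - 1) / length(ch))
    if (!is.finite(s) || s < 1e-12)
      stop("channel '", v$channels[i], "' is constant; cannot standardize ",
           "(is the phantom or config degenerate?)")
    out$data[, , , i] <- (ch - mean(ch)) / s
  }
  out
}
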