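## ---------------------------------------------------------------------------
## Grayscale images, slice stacks, boundary extraction
## ---------------------------------------------------------------------------

#' Grayscale image container
#'
#' Pixels are stored as a numeric matrix (rows = image rows, top first).
#' The physical coordinate convention is fixed throughout the package:
#' pixel centres, origin at the lower-left pixel centre, x rightward and
#' y upward, scaled by `spacing`. Column `j`, row `i` of an `ny x nx` matrix
#' sits at `x = (j - 1) * dx`, `y = (ny - i) * dy`.
#'
#' @param pixels numeric matrix of intensities.
#' @param spacing physical pixel size `c(dx, dy)`.
#' @return An object of class `grayscale_image`.
#' @export
grayscale_image <- function(pixels, spacing = c(1, 1)) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  stopifnot(length(spacing) == 2, all(spacing > 0))
  structure(list(pixels = pixels, spacing = as.numeric(spacing)),
            class = "grayscale_image")
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("Grayscale image %d x %d, values in [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Ordered stack of image slices
#'
#' @param slices list of [grayscale_image()] objects with identical shape.
#' @param z_positions strictly increasing slice positions (physical units).
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, z_positions) {
  stopifnot(length(slices) == length(z_positions), length(slices) >= 1)
  if (any(diff(z_positions) <= 0)) stop("z_positions must be increasing")
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must have the same shape")
  structure(list(slices = slices, z_positions = as.numeric(z_positions)),
            class = "slice_stack")
}

#' Min-max normalisation of a grayscale image
#'
#' Rescales intensities to \[0, 1\]; the uptake threshold of the boundary
#' extraction (default 0.6) is defined on this normalised scale.
#'
#' @param img a [grayscale_image()].
#' @return The normalised image.
#' @export
normalize_grayscale <- function(img) {
  stopifnot(inherits(img, "grayscale_image"))
  rng <- range(img$pixels)
  if (diff(rng) == 0) stop("degenerate input: constant image")
  grayscale_image((img$pixels - rng[1]) / diff(rng), img$spacing)
}

#' Superimpose selected slices into a 2D-combined image
#'
#' Pixel-wise mean (or maximum) of the selected slices, then min-max
#' normalised. The mean preserves relative uptake across slices, matching
#' common summed-projection practice; the maximum is available by flag.
#'
#' @param stack a [slice_stack()].
#' @param indices slice indices to combine.
#' @param method `"mean"` (default) or `"max"`.
#' @return A normalised [grayscale_image()].
#' @export
combine_slices <- function(stack, indices, method = c("mean", "max")) {
  stopifnot(inherits(stack, "slice_stack"))
  method <- match.arg(method)
  if (length(indices) == 0) stop("indices must be nonempty")
  if (any(indices < 1 | indices > length(stack$slices)))
    stop("slice index out of range")
  arrs <- lapply(stack$slices[indices], function(s) s$pixels)
  acc <- Reduce(if (method == "mean") `+` else pmax, arrs)
  if (method == "mean") acc <- acc / length(arrs)
  normalize_grayscale(grayscale_image(acc, stack$slices[[1]]$spacing))
}

## matrix indices -> physical coordinates (pixel centres, y upward)
pixel_coords <- function(rows, cols, nrow_img, spacing) {
  cbind(x = (cols - 1) * spacing[1], y = (nrow_img - rows) * spacing[2])
}

#' Extract ROI boundary points from a normalised image
#'
#' Thresholds the image (strictly greater than `threshold`), keeps connected
#' components of at least `min_size` pixels, and returns the physical
#' coordinates of boundary pixels: foreground pixels 4-adjacent to
#' background (or to the image border).
#'
#' @param img a normalised [grayscale_image()].
#' @param threshold uptake threshold on the normalised scale (default 0.6).
#' @param min_size minimum component size in pixels (speckle suppression).
#' @return An n x 2 matrix of boundary points (columns `x`, `y`).
#' @export
extract_boundary <- function(img, threshold = 0.6, min_size = 10L) {
  stopifnot(inherits(img, "grayscale_image"))
  mask <- img$pixels > threshold
  if (!any(mask)) stop("empty ROI: no pixel above threshold")
  lbl <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lbl[lbl > 0])
  keep <- which(sizes >= min_size)
  if (!length(keep)) stop("empty ROI: all components below minimum size")
  fg <- matrix(lbl %in% keep, nrow(mask), ncol(mask))
  ## 4-neighbour erosion by hand: a boundary pixel has a background
  ## neighbour or touches the border
  pad <- matrix(FALSE, nrow(fg) + 2, ncol(fg) + 2)
  pad[2:(nrow(fg) + 1), 2:(ncol(fg) + 1)] <- fg
  core <- pad[2:(nrow(fg) + 1), 2:(ncol(fg) + 1)] &
    pad[1:nrow(fg), 2:(ncol(fg) + 1)] &
    pad[3:(nrow(fg) + 2), 2:(ncol(fg) + 1)] &
    pad[2:(nrow(fg) + 1), 1:ncol(fg)] &
    pad[2:(nrow(fg) + 1), 3:(ncol(fg) + 2)]
  boundary <- fg & !core
  idx <- which(boundary, arr.ind = TRUE)
  pixel_coords(idx[, 1], idx[, 2], nrow(img$pixels), img$spacing)
}

#' Split boundary points into left and right ROIs
#'
#' Two-means clustering on the x coordinate (deterministic: centres start
#' at the extreme x values). When either side would hold fewer than 6
#' points the function falls back to a single ROI with a warning.
#'
#' @param points n x 2 or n x 3 matrix of boundary points.
#' @return List with elements `left`, `right` (matrices; `right` is `NULL`
#'   in the single-ROI fallback) and `split` (logical).
#' @export
split_left_right <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  x <- points[, 1]
  if (diff(range(x)) == 0) {
    warning("lateralization failed: no x spread; returning a single ROI")
    return(list(left = points, right = NULL, split = FALSE))
  }
  km <- stats::kmeans(x, centers = matrix(range(x), 2, 1))
  left_cl <- which.min(km$centers)
  left <- points[km$cluster == left_cl, , drop = FALSE]
  right <- points[km$cluster != left_cl, , drop = FALSE]
  if (nrow(left) < 6 || nrow(right) < 6) {
    warning("lateralization failed: a side has fewer than 6 points; ",
            "returning a single ROI")
    return(list(left = points, right = NULL, split = FALSE))
  }
  list(left = left, right = right, split = TRUE)
}

#' Collect per-slice boundary points into a 3D cloud
#'
#' Runs [extract_boundary()] on each selected slice and lifts the points to
#' 3D using the slice z positions.
#'
#' @param stack a [slice_stack()].
#' @param indices slice indices to use.
#' @param threshold uptake threshold (default 0.6).
#' @param min_size minimum component size per slice.
#' @return An n x 3 matrix of points (columns `x`, `y`, `z`).
#' @export
stack_boundaries <- function(stack, indices, threshold = 0.6,
                             min_size = 10L) {
  stopifnot(inherits(stack, "slice_stack"))
  if (length(indices) == 0) stop("indices must be nonempty")
  if (any(indices < 1 | indices > length(stack$slices)))
    stop("slice index out of range")
  out <- vector("list", length(indices))
  for (j in seq_along(indices)) {
    i <- indices[j]
    pts <- tryCatch(
      extract_boundary(stack$slices[[i]], threshold, min_size),
      error = function(e) stop(sprintf("slice %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    out[[j]] <- cbind(pts, z = stack$z_positions[i])
  }
  do.call(rbind, out)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel files are averaged to one channel.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param spacing physical pixel size.
#' @return A [grayscale_image()].
#' @export
read_grayscale <- function(path, spacing = c(1, 1)) {
  ext <- tolower(sub(".*\\.", "", path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  grayscale_image(arr, spacing)
}

#' Write a grayscale image to PNG
#'
#' @param img a [grayscale_image()] with values in \[0, 1\].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_grayscale <- function(img, path) {
  stopifnot(inherits(img, "grayscale_image"))
  png::writePNG(pmin(pmax(img$pixels, 0), 1), path)
  invisible(path)
}
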