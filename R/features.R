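## ---------------------------------------------------------------------------
## Feature sets
## ---------------------------------------------------------------------------

#' Feature vector container
#'
#' @param set_id feature set identifier (1 to 5).
#' @param names character vector of stable feature names.
#' @param values numeric vector, same length as `names`.
#' @return An object of class `feature_vector`.
#' @export
feature_vector <- function(set_id, names, values) {
  stopifnot(length(names) == length(values))
  expected <- c(`1` = 9L, `2` = 12L, `3` = 22L, `4` = 21L, `5` = 43L)
  if (!as.character(set_id) %in% names(expected))
    stop("set_id must be 1..5")
  if (length(values) != expected[[as.character(set_id)]])
    stop(sprintf("feature set %s must have %d values, got %d", set_id,
                 expected[[as.character(set_id)]], length(values)))
  structure(list(set_id = as.integer(set_id), names = names,
                 values = stats::setNames(as.numeric(values), names)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("Feature set %d (%d features)\n", x$set_id, length(x$values)))
  print(x$values)
  invisible(x)
}

## default ROI / background masks: thresholded region dilated by 2 px for
## the ROI; everything at least 6 px away from it for the background
default_uptake_masks <- function(img, threshold = 0.6) {
  mask <- img$pixels > threshold
  if (!any(mask)) stop("empty mask: no pixel above threshold")
  roi <- EBImage::dilate(mask * 1, EBImage::makeBrush(5, "disc")) > 0
  far <- EBImage::dilate(mask * 1, EBImage::makeBrush(13, "disc")) > 0
  list(roi = roi, background = !far)
}

#' Grayscale uptake features (Set 1)
#'
#' Nine features from a normalised 2D-combined image: the proportions of
#' supra-threshold pixels (value >= 0.60) falling into the eight bins
#' \[0.60, 0.65), ..., \[0.95, 1.00\], and the ratio of mean uptake near
#' the ROI to mean background uptake. The bin proportions form a
#' probability vector by construction.
#'
#' @param img a normalised [grayscale_image()].
#' @param roi_mask,background_mask optional logical matrices; when omitted
#'   they default to the thresholded region dilated by 2 px and the
#'   complement of its 6 px dilation.
#' @param threshold uptake threshold used for the bins and default masks.
#' @return A [feature_vector()] with `set_id = 1`.
#' @export
grayscale_features <- function(img, roi_mask = NULL, background_mask = NULL,
                               threshold = 0.6) {
  stopifnot(inherits(img, "grayscale_image"))
  px <- img$pixels
  if (min(px) < -1e-9 || max(px) > 1 + 1e-9)
    stop("image must be normalised to [0, 1]")
  if (is.null(roi_mask) || is.null(background_mask)) {
    masks <- default_uptake_masks(img, threshold)
    if (is.null(roi_mask)) roi_mask <- masks$roi
    if (is.null(background_mask)) background_mask <- masks$background
  }
  if (!any(roi_mask) || !any(background_mask)) stop("empty mask")
  if (any(roi_mask & background_mask)) stop("masks must be disjoint")
  supra <- px[px >= threshold]
  if (!length(supra)) stop("no supra-threshold pixels")
  edges <- seq(threshold, 1, length.out = 9L)
  bins <- findInterval(supra, edges, rightmost.closed = TRUE)
  bins[bins > 8L] <- 8L
  props <- tabulate(bins, nbins = 8L) / length(supra)
  bg_mean <- mean(px[background_mask])
  if (bg_mean == 0) stop("zero background mean")
  ratio <- mean(px[roi_mask]) / bg_mean
  feature_vector(1L,
                 c(sprintf("gs_bin_%02d", 1:8), "gs_uptake_ratio"),
                 c(props, ratio))
}

#' Ellipse coefficient features (Set 2)
#'
#' The six gauge-normalised conic coefficients of the left then right
#' fitted ellipse, in the fixed order A, B, C, D, E, F.
#'
#' @param left,right [ellipse_params()] objects normalised to `A + C = 1`.
#' @return A [feature_vector()] with `set_id = 2`.
#' @export
ellipse_features <- function(left, right) {
  for (p in list(left, right)) {
    th <- unclass(p)
    if (abs(th[["A"]] + th[["C"]] - 1) > 1e-6)
      stop("ellipse parameters must be gauge-normalised (A + C = 1)")
  }
  feature_vector(2L,
                 c(paste0("el_L_", c("A", "B", "C", "D", "E", "F")),
                   paste0("el_R_", c("A", "B", "C", "D", "E", "F"))),
                 c(unclass(left), unclass(right)))
}

#' Cashew coefficient features (Set 3)
#'
#' The eleven parameters (a, b, c, d, s, tx, ty, tz, theta_x, theta_y,
#' theta_z) of the left then right fitted surface. Angles enter as raw
#' values in \[0, 2pi); no circular encoding is applied.
#'
#' @param left,right [cashew_params()] objects.
#' @return A [feature_vector()] with `set_id = 3`.
#' @export
cashew_features <- function(left, right) {
  nm <- c("a", "b", "c", "d", "s", "tx", "ty", "tz",
          "theta_x", "theta_y", "theta_z")
  feature_vector(3L,
                 c(paste0("cw_L_", nm), paste0("cw_R_", nm)),
                 c(unclass(left), unclass(right)))
}

#' Assemble a feature set from its components
#'
#' Sets 4 and 5 are unions: Set 4 = Sets 1 + 2 (21 features), Set 5 = Sets
#' 1 + 2 + 3 (43 features). Components are concatenated in set-number
#' order with their stable names.
#'
#' @param set_id target set (1 to 5).
#' @param grayscale,ellipse,cashew component [feature_vector()]s as
#'   required by the target set.
#' @return A [feature_vector()].
#' @export
assemble_set <- function(set_id, grayscale = NULL, ellipse = NULL,
                         cashew = NULL) {
  need <- switch(as.character(set_id),
                 `1` = list(grayscale), `2` = list(ellipse),
                 `3` = list(cashew),
                 `4` = list(grayscale, ellipse),
                 `5` = list(grayscale, ellipse, cashew),
                 stop("set_id must be 1..5"))
  if (any(vapply(need, is.null, logical(1))))
    stop("missing component for feature set ", set_id)
  feature_vector(set_id,
                 unlist(lapply(need, `[[`, "names")),
                 unlist(lapply(need, `[[`, "values"), use.names = FALSE))
}

#' Cubic polynomial grayscale surface
#'
#' Ordinary least squares of the pixel intensities on the ten cubic
#' monomials of the physical pixel coordinates:
#' \deqn{f(x,y) = p_{00} + p_{10}x + p_{01}y + p_{20}x^2 + p_{11}xy
#'   + p_{02}y^2 + p_{30}x^3 + p_{21}x^2y + p_{12}xy^2 + p_{03}y^3.}
#'
#' @param img a [grayscale_image()] with at least 10 pixels.
#' @return Named vector of the ten coefficients in the printed order, with
#'   the fit residual sum of squares as attribute `"rss"`.
#' @export
fit_poly_surface <- function(img) {
  stopifnot(inherits(img, "grayscale_image"))
  px <- img$pixels
  if (length(px) < 10) stop("need at least 10 pixels")
  idx <- which(!is.na(px), arr.ind = TRUE)
  co <- pixel_coords(idx[, 1], idx[, 2], nrow(px), img$spacing)
  x <- co[, 1]; y <- co[, 2]
  X <- cbind(1, x, y, x^2, x * y, y^2, x^3, x^2 * y, x * y^2, y^3)
  fit <- stats::lm.fit(X, as.numeric(px))
  if (fit$rank < 10) stop("rank-deficient design: degenerate image geometry")
  out <- stats::setNames(fit$coefficients,
                         c("p00", "p10", "p01", "p20", "p11", "p02",
                           "p30", "p21", "p12", "p03"))
  attr(out, "rss") <- sum(fit$residuals^2)
  out
}
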