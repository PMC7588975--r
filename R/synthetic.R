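## ---------------------------------------------------------------------------
## Synthetic phantoms and cohorts
## ---------------------------------------------------------------------------

#' Build ellipse coefficients from centre, semi-axes and orientation
#'
#' Convenience constructor for generators and tests: the ellipse with
#' centre `(cx, cy)`, semi-axes `rx, ry` and rotation `angle` (radians,
#' counter-clockwise), returned in the `A + C = 1` gauge.
#'
#' @param cx,cy centre.
#' @param rx,ry positive semi-axes.
#' @param angle orientation in radians.
#' @return An [ellipse_params()] object.
#' @export
ellipse_from_geometry <- function(cx, cy, rx, ry, angle = 0) {
  stopifnot(rx > 0, ry > 0)
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)
  Q <- R %*% diag(c(1 / rx^2, 1 / ry^2)) %*% t(R)
  ctr <- c(cx, cy)
  lin <- -2 * Q %*% ctr
  f0 <- as.numeric(t(ctr) %*% Q %*% ctr) - 1
  ellipse_params(Q[1, 1], Q[1, 2], Q[2, 2], lin[1], lin[2], f0)
}

#' Sample noisy points on an ellipse
#'
#' Points at evenly spaced parameter angles of the affine map from the unit
#' circle (angle-uniform after the affine mapping), plus isotropic Gaussian
#' displacement.
#'
#' @param params an [ellipse_params()] object.
#' @param n number of points.
#' @param noise_sd standard deviation of the isotropic displacement.
#' @param seed integer seed.
#' @return An n x 2 matrix of points.
#' @export
sample_ellipse_points <- function(params, n, noise_sd = 0, seed = 1L) {
  stopifnot(n >= 1, noise_sd >= 0)
  if (!inherits(params, "ellipse_params"))
    params <- do.call(ellipse_params, as.list(unclass(params)))
  th <- unclass(params)
  ctr <- ellipse_center(params)
  f0 <- ellipse_value(params, ctr)
  Q <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  if (f0 >= 0 || any(eg$values <= 0)) stop("degenerate ellipse")
  ax <- sqrt(-f0 / eg$values)
  t_ang <- 2 * pi * (seq_len(n) - 1L) / n
  pts <- cbind(ax[1] * cos(t_ang), ax[2] * sin(t_ang)) %*% t(eg$vectors)
  pts <- sweep(pts, 2, -ctr)
  if (noise_sd > 0) {
    pts <- pts + withr::with_seed(as.integer(seed),
                                  matrix(rnorm(2 * n, sd = noise_sd), n, 2))
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Sample noisy points on a cashew-shaped surface
#'
#' [sample_surface()] plus isotropic Gaussian displacement.
#'
#' @param params a [cashew_params()] object.
#' @param n number of points.
#' @param noise_sd displacement standard deviation.
#' @param seed integer seed.
#' @return An n x 3 matrix of points.
#' @export
sample_cashew_points <- function(params, n, noise_sd = 0, seed = 1L) {
  stopifnot(n >= 1, noise_sd >= 0)
  surf <- cashew_surface(params)
  pts <- sample_surface(surf, n, seed = seed)
  if (noise_sd > 0) {
    pts <- pts + withr::with_seed(as.integer(seed) + 1L,
                                  matrix(rnorm(3 * n, sd = noise_sd), n, 3))
  }
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Phantom specification
#'
#' Describes a synthetic uptake image: one or two bright shapes (ellipses
#' in 2D, cashew surfaces in 3D) on a dim background. Intensity falls off
#' smoothly with the surface value, `background + (peak - background) *
#' exp(-max(Psi, 0) / lambda)`, with `lambda` calibrated per shape so that
#' the 0.6 level sits within about half a pixel of the true zero set.
#'
#' @param size image size in pixels `c(nx, ny)`.
#' @param left,right shape parameters per side ([ellipse_params()] or
#'   [cashew_params()]; `right` may be `NULL`).
#' @param peak peak intensity in (0.6, 1\]; one value or one per side.
#' @param background background level in \[0, 0.4).
#' @param noise_sd Gaussian pixel noise level.
#' @param spacing physical pixel size.
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size, left, right = NULL, peak = 0.95,
                         background = 0.2, noise_sd = 0.02,
                         spacing = c(1, 1), seed = 1L) {
  stopifnot(length(size) == 2, all(size >= 8))
  if (any(peak <= 0.6) || any(peak > 1))
    stop("peak must lie in (0.6, 1]")
  if (background < 0 || background >= 0.4)
    stop("background must lie in [0, 0.4)")
  if (length(peak) == 1) peak <- rep(peak, 2)
  structure(list(size = as.integer(size), left = left, right = right,
                 peak = peak, background = background, noise_sd = noise_sd,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "phantom_spec")
}

## lambda such that the exp falloff crosses 0.6 a small fraction of a pixel
## outside the zero set:
## lambda = 0.15 px * |grad Psi| / log((peak - bg)/(0.6 - bg))
falloff_lambda <- function(surface, peak, background, px_size) {
  pts <- sample_surface(surface, 64L, seed = 1L)
  g <- surface$gradient(pts)
  if (is.null(dim(g))) g <- matrix(g, 1)
  gn <- stats::median(sqrt(rowSums(g^2)))
  0.15 * px_size * gn / log((peak - background) / (0.6 - background))
}

render_side_2d <- function(surface, coords, peak, background, px_size) {
  lam <- falloff_lambda(surface, peak, background, px_size)
  psi <- surface$value(coords)
  background + (peak - background) * exp(-pmax(psi, 0) / lam)
}

#' Render a 2D phantom image
#'
#' @param spec a [phantom_spec()] whose shapes are ellipses.
#' @return A [grayscale_image()] with values in \[0, 1\].
#' @export
render_phantom_2d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$size[1]; ny <- spec$size[2]
  grid <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  coords <- pixel_coords(grid$row, grid$col, ny, spec$spacing)
  img <- matrix(spec$background, ny, nx)
  sides <- Filter(Negate(is.null), list(spec$left, spec$right))
  exts <- c((nx - 1) * spec$spacing[1], (ny - 1) * spec$spacing[2])
  for (i in seq_along(sides)) {
    surf <- ellipse_surface(sides[[i]])
    on_surf <- sample_surface(surf, 32L, seed = 1L)
    if (any(on_surf < -1e-9) || any(on_surf[, 1] > exts[1] + 1e-9) ||
        any(on_surf[, 2] > exts[2] + 1e-9))
      stop("shape exceeds image bounds")
    v <- render_side_2d(surf, coords, spec$peak[i], spec$background,
                        mean(spec$spacing))
    img <- pmax(img, matrix(v, ny, nx))
  }
  if (spec$noise_sd > 0) {
    img <- img + withr::with_seed(spec$seed,
                                  matrix(rnorm(ny * nx, sd = spec$noise_sd),
                                         ny, nx))
  }
  grayscale_image(pmin(pmax(img, 0), 1), spec$spacing)
}

#' Render a 3D phantom as a slice stack
#'
#' Each slice is the planar section of the 3D intensity field at its z
#' position, so a stack of slices through a cashew-shaped uptake region
#' reproduces the multi-slice acquisition the 3D fitting consumes.
#'
#' @param spec a [phantom_spec()] whose shapes are cashew surfaces.
#' @param z_positions increasing slice positions.
#' @return A [slice_stack()].
#' @export
render_phantom_3d <- function(spec, z_positions) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(diff(z_positions) <= 0)) stop("z_positions must be increasing")
  nx <- spec$size[1]; ny <- spec$size[2]
  grid <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  coords2 <- pixel_coords(grid$row, grid$col, ny, spec$spacing)
  sides <- Filter(Negate(is.null), list(spec$left, spec$right))
  surfs <- lapply(sides, cashew_surface)
  lams <- vapply(seq_along(surfs), function(i)
    falloff_lambda(surfs[[i]], spec$peak[i], spec$background,
                   mean(spec$spacing)), numeric(1))
  slices <- vector("list", length(z_positions))
  for (k in seq_along(z_positions)) {
    img <- matrix(spec$background, ny, nx)
    for (i in seq_along(surfs)) {
      psi <- surfs[[i]]$value(cbind(coords2, z_positions[k]))
      v <- spec$background + (spec$peak[i] - spec$background) *
        exp(-pmax(psi, 0) / lams[i])
      img <- pmax(img, matrix(v, ny, nx))
    }
    if (spec$noise_sd > 0) {
      img <- img + withr::with_seed(spec$seed + k,
                                    matrix(rnorm(ny * nx,
                                                 sd = spec$noise_sd),
                                           ny, nx))
    }
    slices[[k]] <- grayscale_image(pmin(pmax(img, 0), 1), spec$spacing)
  }
  slice_stack(slices, z_positions)
}

## class geometry of the synthetic cohort: class 0 carries elongated,
## high-uptake shapes (healthy cashew/comma pattern); class 1 carries
## compact, dimmer shapes (degenerated oval/sphere pattern). `mix` in
## [0, 1] interpolates from the class-0 prototype to the class-1 one.
cohort_subject_params <- function(mix, jitter, rng_mat) {
  ## rng_mat: row of pre-drawn N(0,1) jitter variables
  j <- function(k, sd) rng_mat[k] * sd * jitter
  ## 2D ellipses on a 96 x 96 image
  rx <- (7 + mix * 3.5) * (1 + j(1, 0.06))
  ry <- (15 - mix * 3.5) * (1 + j(2, 0.06))
  ang_l <- 0.15 + j(3, 0.5)
  ang_r <- -0.15 + j(4, 0.5)
  left2 <- ellipse_from_geometry(30 + j(5, 1.5), 48 + j(6, 1.5),
                                 rx, ry, ang_l)
  right2 <- ellipse_from_geometry(66 + j(7, 1.5), 48 + j(8, 1.5),
                                  rx * (1 + j(9, 0.04)),
                                  ry * (1 + j(10, 0.04)), ang_r)
  ## 3D cashews on 72 x 72 slices
  a3 <- (0.75 - mix * 0.45) * (1 + j(11, 0.05))
  b3 <- (0.28 + mix * 0.22) * (1 + j(12, 0.05))
  s3 <- 0.075 * (1 + j(13, 0.05))
  c3 <- max(0, 0.1 * (1 - mix) + j(14, 0.02))
  d3 <- max(0, 0.05 * (1 - mix) + j(15, 0.02))
  left3 <- cashew_params(min(a3, 1), min(b3, 1), min(c3, 0.5), min(d3, 0.5),
                         s = s3, tx = 20 + j(16, 1), ty = 36 + j(17, 1),
                         tz = 0 + j(18, 0.2),
                         theta_x = j(19, 0.15), theta_y = j(20, 0.15),
                         theta_z = j(21, 0.3))
  right3 <- cashew_params(min(a3 * (1 + j(22, 0.04)), 1),
                          min(b3 * (1 + j(23, 0.04)), 1),
                          min(c3, 0.5), min(d3, 0.5),
                          s = s3, tx = 52 + j(24, 1), ty = 36 + j(25, 1),
                          tz = 0 + j(26, 0.2),
                          theta_x = j(27, 0.15), theta_y = j(28, 0.15),
                          theta_z = j(29, 0.3))
  peak <- max(0.7, min(1, 0.95 - mix * 0.15 + j(30, 0.02)))
  list(left2 = left2, right2 = right2, left3 = left3, right3 = right3,
       peak = peak)
}

#' Generate a labelled synthetic cohort
#'
#' Emulates a two-class uptake-imaging cohort: class 0 subjects carry
#' elongated, bright shapes (the healthy comma/cashew pattern), class 1
#' subjects compact, dimmer shapes (the degenerated oval/sphere pattern).
#' Each subject gets a 2D-combined image (two ellipses, 96 x 96) and a
#' 4-slice stack (two cashew surfaces, 72 x 72). The class prototypes are
#' interpolated per subject by a mixing coefficient whose spread defines
#' four strata: clear cases (`normal`, `abnormal`) sit near the prototypes
#' and borderline cases (`nearly_normal`, `potentially_abnormal`) between
#' them, with stratum proportions within class following the reference
#' cohort (174:127 and 256:77).
#'
#' @param n_subjects cohort size (>= 20).
#' @param class_balance fraction of subjects in class 1.
#' @param seed integer master seed.
#' @param noise_sd pixel noise level of the rendered images.
#' @return List with `subjects` (list of per-subject records: `image`,
#'   `stack`, `truth`) and `labels` (data frame with `id`, `label`,
#'   `stratum`).
#' @export
generate_cohort <- function(n_subjects = 120L, class_balance = 0.525,
                            seed = 1L, noise_sd = 0.02) {
  if (n_subjects < 20) stop("need at least 20 subjects")
  n1 <- round(n_subjects * class_balance)
  n0 <- n_subjects - n1
  if (n0 < 4 || n1 < 4) stop("infeasible class balance")
  n_norm <- round(n0 * 174 / (174 + 127))
  n_abn <- round(n1 * 256 / (256 + 77))
  strata <- c(rep("normal", n_norm), rep("nearly_normal", n0 - n_norm),
              rep("abnormal", n_abn), rep("potentially_abnormal", n1 - n_abn))
  labels <- c(rep(0L, n0), rep(1L, n1))
  mix_range <- list(normal = c(0, 0.12), nearly_normal = c(0.2, 0.38),
                    potentially_abnormal = c(0.55, 0.72),
                    abnormal = c(0.8, 1))
  withr::with_seed(as.integer(seed), {
    ord <- sample.int(n_subjects)
    strata <- strata[ord]; labels <- labels[ord]
    subjects <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      rng <- rnorm(30)
      mr <- mix_range[[strata[i]]]
      mix <- runif(1, mr[1], mr[2])
      prm <- cohort_subject_params(mix, jitter = 1, rng_mat = rng)
      sp2 <- phantom_spec(c(96L, 96L), prm$left2, prm$right2,
                          peak = prm$peak, background = 0.2,
                          noise_sd = noise_sd,
                          seed = as.integer(seed) + 1000L + i)
      sp3 <- phantom_spec(c(72L, 72L), prm$left3, prm$right3,
                          peak = prm$peak, background = 0.2,
                          noise_sd = noise_sd,
                          seed = as.integer(seed) + 2000L + i)
      subjects[[i]] <- list(
        id = sprintf("subj_%03d", i),
        image = render_phantom_2d(sp2),
        stack = render_phantom_3d(sp3, z_positions = c(-1.8, -0.6, 0.6, 1.8)),
        truth = c(prm, list(mix = mix)))
    }
    list(subjects = subjects,
         labels = data.frame(id = vapply(subjects, `[[`, "", "id"),
                             label = labels, stratum = strata,
                             stringsAsFactors = FALSE))
  })
}
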