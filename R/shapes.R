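#' @useDynLib roifit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd uniroot
NULL

## ---------------------------------------------------------------------------
## Parameter containers
## ---------------------------------------------------------------------------

#' Conic coefficients of an ellipse
#'
#' Builds the parameter vector of the implicit ellipse equation
#' \deqn{\Psi(x, y) = A x^2 + 2 B x y + C y^2 + D x + E y + F,}
#' requiring the ellipse condition \eqn{B^2 < AC}. The representation is
#' scale-degenerate (any positive multiple describes the same curve); the
#' fixed gauge used throughout the package is \eqn{A + C = 1}, which makes
#' the coefficients identifiable when used as classification features.
#'
#' @param A,B,C,D,E,F real conic coefficients.
#' @param normalize if `TRUE` (default) rescale so that `A + C == 1`.
#' @return An object of class `ellipse_params` (named numeric vector).
#' @export
ellipse_params <- function(A, B, C, D = 0, E = 0, F = 0, normalize = TRUE) {
  th <- c(A = A, B = B, C = C, D = D, E = E, F = F)
  if (!all(is.finite(th))) stop("ellipse coefficients must be finite")
  if (all(th == 0)) stop("ellipse coefficients must not all be zero")
  if (th[["A"]] + th[["C"]] < 0) th <- -th
  if (th[["B"]]^2 >= th[["A"]] * th[["C"]])
    stop("not an ellipse: requires B^2 < A*C")
  if (normalize) th <- th / (th[["A"]] + th[["C"]])
  structure(th, class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat("Ellipse  Ax^2 + 2Bxy + Cy^2 + Dx + Ey + F = 0\n")
  print(unclass(x)); invisible(x)
}

#' Parameters of the cashew-shaped quartic surface
#'
#' The base surface is the zero set of
#' \deqn{\Psi_0(x,y,z) = (1.5x^2 + y^2 + z^2 + a^2 - b^2)^2
#'                     - 4a^2((x-c)^2 + (y-d)^2)}
#' with \eqn{a,b,c,d \in [0,1]}. The general surface applies, to a world
#' point \eqn{x}, translation by `t = (tx,ty,tz)`, rotation by the matrix
#' [rotation_matrix()] and scaling by `s > 0`:
#' \eqn{\Psi(x) = \Psi_0(s M (x - t))}.
#'
#' @param a,b,c,d base shape coefficients in \[0,1\].
#' @param s positive scale factor (world units to base units).
#' @param tx,ty,tz translation (world units).
#' @param theta_x,theta_y,theta_z rotation angles in radians, stored in
#'   \[0, 2pi).
#' @return An object of class `cashew_params` (named numeric vector of
#'   length 11).
#' @export
cashew_params <- function(a, b, c = 0, d = 0, s = 1,
                          tx = 0, ty = 0, tz = 0,
                          theta_x = 0, theta_y = 0, theta_z = 0) {
  base <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (!all(is.finite(base)) || any(base < 0) || any(base > 1))
    stop("a, b, c, d must lie in [0, 1]")
  s <- unname(s)
  if (!is.finite(s) || s <= 0) stop("scale s must be positive")
  ang <- unname(c(theta_x, theta_y, theta_z)) %% (2 * pi)
  th <- c(base, s = s, tx = unname(tx), ty = unname(ty), tz = unname(tz),
          theta_x = ang[1], theta_y = ang[2], theta_z = ang[3])
  if (!all(is.finite(th))) stop("cashew parameters must be finite")
  structure(th, class = "cashew_params")
}

#' @export
print.cashew_params <- function(x, ...) {
  cat("Cashew-shaped quartic surface, Psi(x) = Psi0(s M (x - t))\n")
  print(unclass(x)); invisible(x)
}

## ---------------------------------------------------------------------------
## Pointwise evaluation
## ---------------------------------------------------------------------------

as_point_matrix <- function(p, dim) {
  if (is.null(dim(p))) {
    if (length(p) != dim)
      stop(sprintf("expected %dD point(s), got length %d", dim, length(p)))
    p <- matrix(p, nrow = 1)
  }
  p <- as.matrix(p)
  if (ncol(p) != dim)
    stop(sprintf("expected %dD point(s), got %d columns", dim, ncol(p)))
  storage.mode(p) <- "double"
  p
}

#' Evaluate the implicit ellipse equation
#'
#' @param params an [ellipse_params()] object (or coercible numeric vector).
#' @param p a 2D point or an n x 2 matrix of points.
#' @return Numeric vector of values of \eqn{A x^2 + 2Bxy + Cy^2 + Dx + Ey + F}.
#' @export
ellipse_value <- function(params, p) {
  th <- unclass(params)
  p <- as_point_matrix(p, 2L)
  x <- p[, 1]; y <- p[, 2]
  unname(th[1] * x^2 + 2 * th[2] * x * y + th[3] * y^2 +
           th[4] * x + th[5] * y + th[6])
}

#' Gradient of the implicit ellipse equation
#'
#' Analytic spatial gradient \eqn{(2Ax + 2By + D,\; 2Bx + 2Cy + E)}, used by
#' the flashlight search to construct tangent lines and surface normals.
#'
#' @inheritParams ellipse_value
#' @return An n x 2 matrix of gradients (a plain length-2 vector when `p` is
#'   a single point).
#' @export
ellipse_gradient <- function(params, p) {
  th <- unclass(params)
  p <- as_point_matrix(p, 2L)
  g <- cbind(2 * th[1] * p[, 1] + 2 * th[2] * p[, 2] + th[4],
             2 * th[2] * p[, 1] + 2 * th[3] * p[, 2] + th[5])
  if (nrow(g) == 1L) g[1, ] else g
}

#' Rotation matrix used by the cashew-shaped surface
#'
#' Product of the three axis rotations in the fixed order
#' \eqn{M = R_x(\theta_x) R_y(\theta_y) R_z(\theta_z)}:
#' \preformatted{
#' Rx = | 1    0        0      |  Ry = | cos 0 -sin |  Rz = | cos  sin 0 |
#'      | 0  cos(tx)  sin(tx)  |       |  0  1   0  |       | -sin cos 0 |
#'      | 0 -sin(tx)  cos(tx)  |       | sin 0  cos |       |  0    0  1 |
#' }
#' The result is orthogonal with determinant one.
#'
#' @param theta_x,theta_y,theta_z rotation angles in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(theta_x, theta_y, theta_z) {
  cx <- cos(theta_x); sx <- sin(theta_x)
  cy <- cos(theta_y); sy <- sin(theta_y)
  cz <- cos(theta_z); sz <- sin(theta_z)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

#' Euler angles of a rotation matrix
#'
#' Inverse of [rotation_matrix()] for the package's fixed composition order
#' (gimbal-locked configurations resolve with `theta_z = 0`). Angles are
#' returned in \[0, 2pi).
#'
#' @param M a 3 x 3 rotation matrix.
#' @return Numeric vector `c(theta_x, theta_y, theta_z)`.
#' @export
rotation_angles <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == 3L))
  sy <- -M[1, 3]
  if (abs(sy) < 1 - 1e-10) {
    theta_y <- asin(sy)
    theta_x <- atan2(M[2, 3], M[3, 3])
    theta_z <- atan2(M[1, 2], M[1, 1])
  } else {
    theta_y <- if (sy > 0) pi / 2 else -pi / 2
    theta_x <- atan2(-M[3, 2], M[2, 2])
    theta_z <- 0
  }
  c(theta_x, theta_y, theta_z) %% (2 * pi)
}

#' Evaluate the base cashew quartic
#'
#' @param base numeric vector `c(a, b, c, d)` of base-shape coefficients.
#' @param p a 3D point or an n x 3 matrix of points.
#' @return Numeric vector of values of
#'   \eqn{(1.5x^2 + y^2 + z^2 + a^2 - b^2)^2 - 4a^2((x-c)^2 + (y-d)^2)}.
#' @export
cashew_base_value <- function(base, p) {
  p <- as_point_matrix(p, 3L)
  a <- base[[1]]; b <- base[[2]]; cc <- base[[3]]; dd <- base[[4]]
  q <- 1.5 * p[, 1]^2 + p[, 2]^2 + p[, 3]^2 + a^2 - b^2
  q^2 - 4 * a^2 * ((p[, 1] - cc)^2 + (p[, 2] - dd)^2)
}

cashew_transform <- function(params, p) {
  th <- unclass(params)
  M <- rotation_matrix(th[["theta_x"]], th[["theta_y"]], th[["theta_z"]])
  p <- as_point_matrix(p, 3L)
  u <- sweep(p, 2, c(th[["tx"]], th[["ty"]], th[["tz"]])) %*% t(M) * th[["s"]]
  u
}

#' Evaluate the general cashew-shaped surface
#'
#' Applies the rigid transform of [cashew_params()] and evaluates the base
#' quartic: \eqn{\Psi(p) = \Psi_0(s M (p - t))}.
#'
#' @param params a [cashew_params()] object.
#' @param p a 3D point or an n x 3 matrix of points.
#' @return Numeric vector of surface values.
#' @export
cashew_value <- function(params, p) {
  th <- unclass(params)
  if (th[["s"]] <= 0) stop("scale s must be positive")
  cashew_base_value(th[1:4], cashew_transform(params, p))
}

#' Gradient of the general cashew-shaped surface
#'
#' Chain rule on [cashew_value()]: with \eqn{u = s M (p - t)},
#' \eqn{\nabla_p \Psi = s M^\top \nabla_u \Psi_0(u)}.
#'
#' @inheritParams cashew_value
#' @return An n x 3 matrix of gradients (plain vector for a single point).
#' @export
cashew_gradient <- function(params, p) {
  th <- unclass(params)
  p <- as_point_matrix(p, 3L)
  M <- rotation_matrix(th[["theta_x"]], th[["theta_y"]], th[["theta_z"]])
  u <- sweep(p, 2, c(th[["tx"]], th[["ty"]], th[["tz"]])) %*% t(M) * th[["s"]]
  a <- th[["a"]]; b <- th[["b"]]
  q <- 1.5 * u[, 1]^2 + u[, 2]^2 + u[, 3]^2 + a^2 - b^2
  gu <- cbind(2 * q * 3 * u[, 1] - 8 * a^2 * (u[, 1] - th[["c"]]),
              2 * q * 2 * u[, 2] - 8 * a^2 * (u[, 2] - th[["d"]]),
              2 * q * 2 * u[, 3])
  g <- th[["s"]] * gu %*% M
  if (nrow(g) == 1L) g[1, ] else g
}

## ---------------------------------------------------------------------------
## Implicit surface contract
## ---------------------------------------------------------------------------

#' Implicit surface object
#'
#' Bundles a scalar field `value` and its spatial `gradient` into the
#' contract consumed by the flashlight-searching distance algorithm. Both
#' functions must accept an n x `dim` matrix of points; `value` returns a
#' length-n vector and `gradient` an n x `dim` matrix.
#'
#' @param value function mapping points to surface values.
#' @param gradient function mapping points to gradients.
#' @param dim spatial dimension, 2 or 3.
#' @param family optional family tag (`"ellipse"`, `"cashew"`) enabling the
#'   compiled fast path of [fs_distance()].
#' @param params optional parameter object for tagged families.
#' @param interior optional interior reference point used by
#'   [sample_surface()] and the automatic search-radius heuristic.
#' @return An object of class `implicit_surface`.
#' @export
implicit_surface <- function(value, gradient, dim, family = NULL,
                             params = NULL, interior = NULL) {
  stopifnot(is.function(value), is.function(gradient), dim %in% c(2L, 3L))
  structure(list(value = value, gradient = gradient, dim = as.integer(dim),
                 family = family, params = params, interior = interior),
            class = "implicit_surface")
}

#' @export
print.implicit_surface <- function(x, ...) {
  cat(sprintf("Implicit surface (%dD%s)\n", x$dim,
              if (is.null(x$family)) "" else paste0(", family: ", x$family)))
  invisible(x)
}

#' Centre of an ellipse
#'
#' Solves the stationary-point system of the conic quadratic form.
#'
#' @param params an [ellipse_params()] object.
#' @return Length-2 numeric vector.
#' @export
ellipse_center <- function(params) {
  th <- unclass(params)
  Q <- matrix(c(2 * th[1], 2 * th[2], 2 * th[2], 2 * th[3]), 2, 2)
  as.numeric(solve(Q, -c(th[4], th[5])))
}

#' Semi-axes of an ellipse
#'
#' @param params an [ellipse_params()] object.
#' @return Numeric vector of the two semi-axis lengths (decreasing).
#' @export
ellipse_axes <- function(params) {
  th <- unclass(params)
  ctr <- ellipse_center(params)
  f0 <- ellipse_value(params, ctr)
  Q <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
  ev <- eigen(Q, symmetric = TRUE)$values
  if (f0 >= 0) stop("degenerate ellipse (empty or single-point zero set)")
  sort(sqrt(-f0 / ev), decreasing = TRUE)
}

#' Build an implicit surface from ellipse coefficients
#'
#' @param params an [ellipse_params()] object.
#' @return An [implicit_surface()] with family `"ellipse"`.
#' @export
ellipse_surface <- function(params) {
  if (!inherits(params, "ellipse_params"))
    params <- do.call(ellipse_params, as.list(unclass(params)))
  implicit_surface(function(p) ellipse_value(params, p),
                   function(p) ellipse_gradient(params, p),
                   2L, family = "ellipse", params = params,
                   interior = ellipse_center(params))
}

#' Build an implicit surface from cashew parameters
#'
#' @param params a [cashew_params()] object.
#' @return An [implicit_surface()] with family `"cashew"`.
#' @export
cashew_surface <- function(params) {
  if (!inherits(params, "cashew_params"))
    params <- do.call(cashew_params, as.list(unclass(params)))
  implicit_surface(function(p) cashew_value(params, p),
                   function(p) cashew_gradient(params, p),
                   3L, family = "cashew", params = params,
                   interior = unclass(params)[c("tx", "ty", "tz")])
}

## A rough linear extent of the surface, used for automatic search ranges.
surface_extent <- function(surface) {
  if (identical(surface$family, "ellipse")) {
    return(2 * max(ellipse_axes(surface$params)))
  }
  if (identical(surface$family, "cashew")) {
    th <- unclass(surface$params)
    return(2 * (th[["a"]] + th[["b"]] + sqrt(th[["c"]]^2 + th[["d"]]^2) + 0.1) /
             th[["s"]])
  }
  1
}

surface_interior <- function(surface) {
  if (!is.null(surface$interior)) return(as.numeric(surface$interior))
  stop("surface has no interior reference point; supply one")
}

## Fast value evaluator: compiled for the tagged families, else the R one.
surface_fast_value <- function(surface) {
  fam <- switch(surface$family %||% "", ellipse = 1L, cashew = 2L, NULL)
  if (is.null(fam)) return(surface$value)
  par <- as.numeric(unclass(surface$params))
  function(P) .surface_value_cpp(fam, par, P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Surface sampling
## ---------------------------------------------------------------------------

random_directions <- function(n, dim) {
  d <- matrix(rnorm(n * dim), n, dim)
  d / sqrt(rowSums(d^2))
}

#' Sample points on an implicit surface
#'
#' Draws random directions from an interior reference point and root-finds
#' the surface value along each ray by vectorised bisection. Directions
#' whose ray never changes sign within the search range are redrawn, so the
#' sample density follows the solid angle subtended at the interior point.
#'
#' @param surface an [implicit_surface()].
#' @param n number of points.
#' @param seed integer seed; equal seeds give identical samples.
#' @param interior optional interior point overriding the surface default.
#' @param range ray search range; defaults to four surface extents.
#' @return An n x dim matrix of points with `|value| < 1e-9`.
#' @export
sample_surface <- function(surface, n, seed = 1L, interior = NULL,
                           range = NULL) {
  stopifnot(n >= 1)
  p0 <- if (is.null(interior)) surface_interior(surface) else interior
  L <- if (is.null(range)) 4 * surface_extent(surface) else range
  dim <- surface$dim
  withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, n, dim)
    filled <- 0L
    chunk <- 20000L
    for (round in 1:500) {
      if (filled >= n) break
      m <- min(chunk, n - filled)
      dirs <- random_directions(m, dim)
      fam <- switch(surface$family %||% "", ellipse = 1L, cashew = 2L, NULL)
      hit <- if (is.null(fam)) {
        ray_random_root(surface, p0, dirs, L)
      } else {
        .ray_random_root_cpp(fam, as.numeric(unclass(surface$params)),
                             p0, dirs, L, 128L)
      }
      ok <- which(is.finite(hit))
      if (length(ok)) {
        take <- ok[seq_len(min(length(ok), n - filled))]
        out[filled + seq_along(take), ] <-
          matrix(p0, length(take), dim, byrow = TRUE) +
          dirs[take, , drop = FALSE] * hit[take]
        filled <- filled + length(take)
      }
      if (round > 5 && filled == 0L)
        stop("infeasible surface: no ray from the interior point hits it")
    }
    if (filled < n)
      stop("infeasible surface: no ray from the interior point hits it")
    out
  })
}

## One ray root (c > 0 with Psi(p0 + c*dir) = 0) per direction, picked
## uniformly at random among all sign-change brackets along the ray so the
## whole surface is reachable; refined by vectorised bisection. NA when the
## ray never changes sign within (0, L].
ray_random_root <- function(surface, p0, dirs, L, n_scan = 128L,
                            n_bisect = 80L) {
  m <- nrow(dirs)
  dim <- ncol(dirs)
  value <- surface_fast_value(surface)
  cs <- c(L / (100 * n_scan), seq(L / n_scan, L, length.out = n_scan))
  base <- matrix(p0, m, dim, byrow = TRUE)
  vals <- matrix(NA_real_, m, length(cs))
  for (j in seq_along(cs)) vals[, j] <- value(base + dirs * cs[j])
  flips <- vals[, -ncol(vals), drop = FALSE] * vals[, -1, drop = FALSE] < 0
  first <- apply(flips, 1, function(r) {
    w <- which(r)
    if (length(w)) w[sample.int(length(w), 1L)] else NA_integer_
  })
  hit <- rep(NA_real_, m)
  ok <- which(!is.na(first))
  if (!length(ok)) return(hit)
  dlo <- cs[first[ok]]
  dhi <- cs[first[ok] + 1L]
  dd <- dirs[ok, , drop = FALSE]
  bo <- base[ok, , drop = FALSE]
  flo <- value(bo + dd * dlo)
  for (b in seq_len(n_bisect)) {
    mid <- 0.5 * (dlo + dhi)
    fm <- value(bo + dd * mid)
    left <- flo * fm <= 0
    dhi[left] <- mid[left]
    dlo[!left] <- mid[!left]
    flo[!left] <- fm[!left]
  }
  hit[ok] <- 0.5 * (dlo + dhi)
  hit
}
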