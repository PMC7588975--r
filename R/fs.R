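## ---------------------------------------------------------------------------
## Flashlight-searching (FS) point-to-surface Euclidean distance
## ---------------------------------------------------------------------------

#' Configuration of the flashlight-searching algorithm
#'
#' Tunables of the FS distance. `NULL` entries are resolved automatically
#' from the geometry at hand: the reference scale is the bounding-box
#' diagonal of the query points (falling back to the surface extent), the
#' initial search-ball radius `r` is 0.1 of that scale, and the tangent probe
#' distance `delta` is 0.05 of it.
#'
#' @param r initial radius of the sign-constant ball around the query point
#'   (halved automatically until the surface value keeps one sign on it).
#' @param delta tangent-plane probe distance; shrunk by `delta_shrink`
#'   whenever no probe improves the distance.
#' @param k number of tangent-plane probes (2 in 2D, 8 in 3D by default).
#' @param tau stopping tolerance on `1 - G(x)`, where `G` is the cosine of
#'   the acute angle between the query-to-foot vector and the surface normal.
#' @param max_iter iteration cap.
#' @param delta_shrink multiplicative shrink factor in (0, 1).
#' @param range ray root-search half-range; defaults to 4 reference scales.
#' @param n_scan subdivisions of the root scan over `[-range, range]`.
#' @param grid_2d,grid_3d number of ball-boundary directions inspected when
#'   choosing the initial ray (angular grid in 2D, Fibonacci sphere in 3D).
#' @return An object of class `fs_config`.
#' @export
fs_config <- function(r = NULL, delta = NULL, k = NULL, tau = 1e-8,
                      max_iter = 200L, delta_shrink = 0.5, range = NULL,
                      n_scan = 512L, grid_2d = 360L, grid_3d = 1962L) {
  stopifnot(tau > 0, tau < 1, max_iter >= 1,
            delta_shrink > 0, delta_shrink < 1)
  if (!is.null(r)) stopifnot(r > 0)
  if (!is.null(delta)) stopifnot(delta > 0)
  structure(list(r = r, delta = delta, k = k, tau = tau,
                 max_iter = as.integer(max_iter),
                 delta_shrink = delta_shrink, range = range,
                 n_scan = as.integer(n_scan), grid_2d = as.integer(grid_2d),
                 grid_3d = as.integer(grid_3d)),
            class = "fs_config")
}

## Fill the data-dependent defaults given a surface and query points.
resolve_fs_config <- function(surface, P, config = fs_config()) {
  if (is.null(config)) config <- fs_config()
  P <- as_point_matrix(P, surface$dim)
  scale <- tryCatch(surface_extent(surface), error = function(e) NA_real_)
  if (nrow(P) >= 2) {
    diag_len <- sqrt(sum((apply(P, 2, max) - apply(P, 2, min))^2))
    if (diag_len > 0) scale <- max(scale, diag_len, na.rm = TRUE)
  }
  if (!is.finite(scale) || scale <= 0) scale <- 1
  config$scale <- scale
  if (is.null(config$r)) config$r <- 0.1 * scale
  if (is.null(config$delta)) config$delta <- 0.05 * scale
  if (is.null(config$k)) config$k <- if (surface$dim == 2L) 2L else 8L
  if (is.null(config$range)) config$range <- 4 * scale
  stopifnot(config$k >= 2L)
  if (surface$dim == 3L) stopifnot(config$k >= 4L)
  config
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

ball_grid <- function(dim, config) {
  if (dim == 2L) {
    ang <- seq(0, 2 * pi, length.out = config$grid_2d + 1L)[-1L]
    cbind(cos(ang), sin(ang))
  } else {
    fibonacci_sphere(config$grid_3d)
  }
}

#' Ray-surface intersection parameters
#'
#' Finds the roots `c` of \eqn{\Psi(p + c \cdot direction) = 0} by scanning
#' `n_scan` subdivisions of `[-range, range]` for sign changes and refining
#' each bracket by bisection. Roots are returned sorted by `|c|` (nearest
#' the ray origin first).
#'
#' @param surface an [implicit_surface()].
#' @param p ray origin.
#' @param direction nonzero ray direction (not necessarily unit length).
#' @param range,n_scan search range and resolution; default from
#'   [fs_config()] resolved on `p`.
#' @return Numeric vector of root parameters `c` (empty when no sign change
#'   is found in range).
#' @export
ray_intersect <- function(surface, p, direction, range = NULL,
                          n_scan = 512L) {
  p <- as.numeric(p)
  direction <- as.numeric(direction)
  dn <- sqrt(sum(direction^2))
  if (dn == 0) stop("ray direction must be nonzero")
  if (is.null(range)) {
    cfg <- resolve_fs_config(surface, matrix(p, 1))
    range <- cfg$range / dn
  }
  cs <- seq(-range, range, length.out = n_scan + 1L)
  pts <- matrix(p, length(cs), surface$dim, byrow = TRUE) +
    outer(cs, direction)
  v <- surface$value(pts)
  roots <- numeric(0)
  flip <- which(v[-length(v)] * v[-1] < 0)
  for (j in flip) {
    f <- function(c) surface$value(p + c * direction)
    rt <- uniroot(f, lower = cs[j], upper = cs[j + 1], tol = 1e-15)$root
    ## polish by bisection until |Psi| < 1e-10 (relative to gradient scale)
    roots <- c(roots, rt)
  }
  exact <- which(v == 0)
  if (length(exact)) roots <- c(roots, cs[exact])
  roots[order(abs(roots))]
}

#' Initial surface point of the FS algorithm
#'
#' Step 1 of the FS scheme: inspect the boundary of a ball of radius `r`
#' around the query point `p`, require the surface value to keep one sign on
#' it (halving `r` as needed), aim at the boundary point minimising
#' \eqn{|\Psi|}, and take the surface root nearest `p` along that ray.
#'
#' @param surface an [implicit_surface()].
#' @param p query point (must be off the surface).
#' @param r initial ball radius.
#' @param config optional [fs_config()] (grid resolution, scan range).
#' @return A surface point (numeric vector).
#' @export
initial_point <- function(surface, p, r, config = NULL) {
  p <- as.numeric(p)
  config <- resolve_fs_config(surface, matrix(p, 1), config)
  g0 <- as.numeric(surface$gradient(p))
  psi_p <- surface$value(p)
  gn <- sqrt(sum(g0^2))
  if (gn > 0 && abs(psi_p) / gn < 1e-10)
    stop("query point lies on the surface")
  grid <- ball_grid(surface$dim, config)
  for (attempt in 1:45) {
    vals <- surface$value(matrix(p, nrow(grid), surface$dim, byrow = TRUE) +
                            r * grid)
    same_sign <- if (psi_p > 0) all(vals > 0) else all(vals < 0)
    if (same_sign) break
    r <- r / 2
    if (r < 1e-12 * config$r)
      stop("could not find a sign-constant ball around the query point")
  }
  if (!same_sign) stop("could not find a sign-constant ball around the query point")
  ## aim at the boundary point minimising |Psi|; if that ray misses, fall
  ## back to the next-best directions before giving up
  ord <- order(abs(vals))[seq_len(min(64L, nrow(grid)))]
  for (i in ord) {
    dir <- grid[i, ]
    roots <- ray_intersect(surface, p, dir, range = config$range,
                           n_scan = config$n_scan)
    if (!length(roots))
      roots <- ray_intersect(surface, p, dir, range = 4 * config$range,
                             n_scan = config$n_scan)
    if (length(roots)) return(p + roots[1] * dir)
  }
  stop("initialization failure: ray misses the surface")
}

#' Normal alignment at a surface point
#'
#' The stopping functional of the FS algorithm: the cosine of the acute
#' angle between the vector from the surface point `x` to the query point
#' `p` and the surface normal at `x`. Equals 1 exactly at a foot of the
#' perpendicular.
#'
#' @param surface an [implicit_surface()].
#' @param p query point, distinct from `x`.
#' @param x a point on the surface.
#' @return Alignment value in \[0, 1\].
#' @export
alignment <- function(surface, p, x) {
  p <- as.numeric(p); x <- as.numeric(x)
  g <- as.numeric(surface$gradient(x))
  gn <- sqrt(sum(g^2))
  if (gn == 0) stop("degenerate normal: zero gradient at x")
  v <- p - x
  vn <- sqrt(sum(v^2))
  if (vn == 0) stop("p must differ from x")
  abs(sum(v * g)) / (vn * gn)
}

#' One tangent-probe step of the FS algorithm
#'
#' Places probe points on the tangent plane at `x_m` at distance `delta`
#' (the two in-plane directions in 2D; `k` evenly spaced directions on the
#' tangent circle in 3D), maps each back to the surface along the ray from
#' the query point `p`, and returns the candidate closest to `p` (or `x_m`
#' itself when no candidate improves).
#'
#' @param surface an [implicit_surface()].
#' @param p query point.
#' @param x_m current surface point.
#' @param delta probe distance.
#' @param k number of probes (3D).
#' @param config optional [fs_config()].
#' @return The next surface point.
#' @export
fs_step <- function(surface, p, x_m, delta, k = NULL, config = NULL) {
  p <- as.numeric(p); x_m <- as.numeric(x_m)
  config <- resolve_fs_config(surface, rbind(p, x_m), config)
  if (is.null(k)) k <- config$k
  g <- as.numeric(surface$gradient(x_m))
  gn <- sqrt(sum(g^2))
  if (gn == 0) stop("zero gradient at x_m")
  nx <- g / gn
  if (surface$dim == 2L) {
    t1 <- c(-nx[2], nx[1])
    probes <- rbind(x_m + delta * t1, x_m - delta * t1)
  } else {
    e <- if (abs(nx[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    t1 <- e - sum(e * nx) * nx
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nx[2] * t1[3] - nx[3] * t1[2],
            nx[3] * t1[1] - nx[1] * t1[3],
            nx[1] * t1[2] - nx[2] * t1[1])
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    probes <- matrix(x_m, k, 3, byrow = TRUE) +
      delta * (outer(cos(ang), t1) + outer(sin(ang), t2))
  }
  d_cur <- sqrt(sum((p - x_m)^2))
  best <- x_m
  best_d <- d_cur
  any_hit <- FALSE
  for (j in seq_len(nrow(probes))) {
    u <- probes[j, ] - p
    roots <- ray_intersect(surface, p, u, range = config$range /
                             sqrt(sum(u^2)), n_scan = config$n_scan)
    if (!length(roots)) next
    any_hit <- TRUE
    y <- p + roots[1] * u
    dy <- sqrt(sum((p - y)^2))
    if (dy < best_d) { best <- y; best_d <- dy }
  }
  if (!any_hit) stop("step failure: all probe rays miss the surface")
  best
}

fs_result <- function(distance, foot, iterations, final_alignment, tau) {
  structure(list(distance = distance, foot = foot, iterations = iterations,
                 final_alignment = final_alignment,
                 converged = (1 - final_alignment) < tau),
            class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("FS distance: %.8g (%d iterations, alignment %.10f%s)\n",
              x$distance, x$iterations, x$final_alignment,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

## Reference R implementation of the full FS iteration (any surface).
fs_distance_r <- function(surface, p, config = NULL) {
  p <- as.numeric(p)
  config <- resolve_fs_config(surface, matrix(p, 1), config)
  x <- initial_point(surface, p, config$r, config)
  delta <- config$delta
  dist <- sqrt(sum((p - x)^2))
  iters <- 0L
  for (it in seq_len(config$max_iter)) {
    al <- alignment(surface, p, x)
    if (1 - al < config$tau) break
    x_new <- tryCatch(fs_step(surface, p, x, delta, config$k, config),
                      error = function(e) NULL)
    iters <- it
    if (is.null(x_new) || identical(x_new, x) ||
        sqrt(sum((p - x_new)^2)) >= dist) {
      delta <- delta * config$delta_shrink
      if (delta < 1e-14 * config$delta) break
    } else {
      x <- x_new
      dist <- sqrt(sum((p - x)^2))
    }
  }
  fs_result(dist, x, iters, alignment(surface, p, x), config$tau)
}

## Batched compiled path for the tagged parametric families.
fs_distance_batch <- function(surface, P, config = NULL) {
  P <- as_point_matrix(P, surface$dim)
  config <- resolve_fs_config(surface, P, config)
  family <- switch(surface$family, ellipse = 1L, cashew = 2L,
                   stop("no compiled path for this surface family"))
  par <- as.numeric(unclass(surface$params))
  grid <- ball_grid(surface$dim, config)
  interior <- tryCatch(surface_interior(surface),
                       error = function(e) rep(NA_real_, surface$dim))
  .fs_batch_cpp(family, par, P, grid, config$r, config$delta,
                config$k, config$tau, config$max_iter, config$delta_shrink,
                config$range, as.integer(config$n_scan / 2L), 1e-8,
                as.numeric(interior))
}

#' Euclidean distance from a point to an implicit surface
#'
#' Runs the full FS iteration: initialisation by ball search
#' ([initial_point()]), tangent-probe descent ([fs_step()]) with automatic
#' probe shrinking, and the normal-alignment stopping rule
#' `1 - G(x) < tau`. The per-iteration distance sequence is non-increasing.
#' Surfaces of the two built-in families (`"ellipse"`, `"cashew"`) are
#' dispatched to a compiled implementation; any other [implicit_surface()]
#' uses the plain R path.
#'
#' @param surface an [implicit_surface()].
#' @param p query point off the surface.
#' @param config an [fs_config()] (optional).
#' @return An `fs_result`: `distance`, `foot` (the surface point realising
#'   it), `iterations`, `final_alignment`, and a `converged` flag.
#' @export
fs_distance <- function(surface, p, config = NULL) {
  if (!is.null(surface$family) &&
      surface$family %in% c("ellipse", "cashew")) {
    config <- resolve_fs_config(surface, matrix(as.numeric(p), 1), config)
    res <- fs_distance_batch(surface, matrix(as.numeric(p), 1), config)
    if (!res$ok[1]) stop("initialization failure: FS could not start")
    return(fs_result(res$distance[1], as.numeric(res$foot[1, ]),
                     res$iterations[1], res$alignment[1], config$tau))
  }
  fs_distance_r(surface, p, config)
}

#' Brute-force point-to-surface distance
#'
#' Independent oracle for [fs_distance()]: minimum distance from `p` to a
#' large random sample of surface points ([sample_surface()]). The estimate
#' upper-bounds the true distance and converges to it from above as
#' `n_samples` grows.
#'
#' @param surface an [implicit_surface()].
#' @param p query point.
#' @param n_samples sample size.
#' @param seed integer seed.
#' @return Estimated distance (numeric scalar).
#' @export
brute_force_distance <- function(surface, p, n_samples = 1e5, seed = 1L) {
  pts <- sample_surface(surface, n_samples, seed = seed)
  p <- as.numeric(p)
  d2 <- rowSums(sweep(pts, 2, p)^2)
  sqrt(min(d2))
}

#' Total FS loss of a point set
#'
#' The shape-fitting objective: the sum over boundary points of their FS
#' distance to the surface. Points already on the surface (first-order
#' distance below `1e-8`) contribute zero without running the search; any
#' unrecoverable FS failure makes the loss `+Inf` so that optimisers treat
#' the parameter vector as infeasible.
#'
#' @param surface an [implicit_surface()].
#' @param points n x dim matrix of boundary points.
#' @param config an [fs_config()] (optional).
#' @return Nonnegative total loss (possibly `Inf`).
#' @export
total_loss <- function(surface, points, config = NULL) {
  points <- as_point_matrix(points, surface$dim)
  if (nrow(points) < 1) stop("at least one point is required")
  if (!is.null(surface$family) &&
      surface$family %in% c("ellipse", "cashew")) {
    res <- fs_distance_batch(surface, points, config)
    if (any(!res$ok)) return(Inf)
    return(sum(res$distance))
  }
  tot <- 0
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    g <- as.numeric(surface$gradient(p))
    gn <- sqrt(sum(g^2))
    if (gn > 0 && abs(surface$value(p)) / gn < 1e-8) next
    r <- tryCatch(fs_distance_r(surface, p, config),
                  error = function(e) NULL)
    if (is.null(r)) return(Inf)
    tot <- tot + r$distance
  }
  tot
}
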