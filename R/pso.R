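## ---------------------------------------------------------------------------
## Particle swarm optimisation and the two shape-fitting criteria
## ---------------------------------------------------------------------------

#' Particle swarm optimiser configuration
#'
#' Controls of the swarm update
#' \deqn{v_i^{t+1} = \omega v_i^t + c_1 r_1 (P_i^t - x_i^t)
#'                  + c_2 r_2 (G^t - x_i^t), \quad
#'       x_i^{t+1} = x_i^t + v_i^{t+1},}
#' with fresh uniform \eqn{r_1, r_2 \in [0,1]} per particle per iteration.
#' Defaults follow the study settings: 100 particles, \eqn{c_1 = 1},
#' \eqn{c_2 = 2}, \eqn{\omega = 0.5}.
#'
#' @param n_particles swarm size (at least 2).
#' @param omega inertia weight.
#' @param c1,c2 cognitive and social acceleration constants.
#' @param max_iter iteration cap.
#' @param seed integer seed; runs are reproducible given the seed.
#' @param stop_tol relative-change tolerance: the run stops early when the
#'   best objective changes by less than `stop_tol` (relatively) over 20
#'   consecutive iterations.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 100L, omega = 0.5, c1 = 1, c2 = 2,
                       max_iter = 200L, seed = 1L, stop_tol = 1e-6) {
  stopifnot(n_particles >= 2, c1 > 0, c2 > 0, max_iter >= 1)
  structure(list(n_particles = as.integer(n_particles), omega = omega,
                 c1 = c1, c2 = c2, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), stop_tol = stop_tol),
            class = "pso_config")
}

#' Minimise an objective with a particle swarm
#'
#' Plain bound-constrained PSO. Positions are clamped to `bounds` and the
#' offending velocity component is zeroed; objectives may return `Inf` to
#' mark infeasible parameter vectors. The global-best objective sequence is
#' non-increasing by construction.
#'
#' @param objective function mapping a parameter vector to a finite value or
#'   `Inf`.
#' @param bounds 2 x d matrix: first row lower, second row upper bounds.
#' @param config a [pso_config()].
#' @param init_box optional 2 x d matrix delimiting the initialisation box
#'   (defaults to `bounds`).
#' @param init_center optional parameter vector (or matrix of row vectors)
#'   seeded verbatim as the first particle(s).
#' @return List with `par` (best position), `value` (best objective) and
#'   `trajectory` (best objective after each iteration).
#' @export
pso_minimize <- function(objective, bounds, config = pso_config(),
                         init_box = NULL, init_center = NULL) {
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2, all(bounds[1, ] < bounds[2, ]))
  d <- ncol(bounds)
  if (is.null(init_box)) init_box <- bounds
  n <- config$n_particles
  withr::with_seed(config$seed, {
    X <- matrix(runif(n * d, init_box[1, ], init_box[2, ]),
                n, d, byrow = TRUE)
    if (!is.null(init_center)) {
      centers <- if (is.matrix(init_center)) init_center
                 else matrix(init_center, 1)
      nc <- min(nrow(centers), n)
      X[seq_len(nc), ] <- centers[seq_len(nc), , drop = FALSE]
    }
    X <- pmin(pmax(X, matrix(bounds[1, ], n, d, byrow = TRUE)),
              matrix(bounds[2, ], n, d, byrow = TRUE))
    V <- matrix(0, n, d)
    f <- apply(X, 1, objective)
    if (all(!is.finite(f)))
      stop("initialization error: all particles infeasible")
    Pb <- X; fP <- f
    gi <- which.min(fP)
    G <- Pb[gi, ]; fG <- fP[gi]
    trajectory <- numeric(0)
    stall <- 0L
    lo <- matrix(bounds[1, ], n, d, byrow = TRUE)
    hi <- matrix(bounds[2, ], n, d, byrow = TRUE)
    for (t in seq_len(config$max_iter)) {
      r1 <- runif(n); r2 <- runif(n)
      Gm <- matrix(G, n, d, byrow = TRUE)
      V <- config$omega * V + config$c1 * r1 * (Pb - X) +
        config$c2 * r2 * (Gm - X)
      X <- X + V
      below <- X < lo; above <- X > hi
      V[below | above] <- 0
      X[below] <- lo[below]; X[above] <- hi[above]
      f <- apply(X, 1, objective)
      upd <- which(f < fP)
      if (length(upd)) { Pb[upd, ] <- X[upd, , drop = FALSE]; fP[upd] <- f[upd] }
      prev <- fG
      gi <- which.min(fP)
      if (fP[gi] < fG) { G <- Pb[gi, ]; fG <- fP[gi] }
      trajectory <- c(trajectory, fG)
      rel <- if (is.finite(prev) && prev != 0) (prev - fG) / abs(prev)
             else if (is.finite(prev)) prev - fG else Inf
      stall <- if (rel < config$stop_tol) stall + 1L else 0L
      if (stall >= 20L) break
    }
    list(par = as.numeric(G), value = fG, trajectory = trajectory)
  })
}

## ---------------------------------------------------------------------------
## Initial estimates
## ---------------------------------------------------------------------------

conic_matrix <- function(th) {
  matrix(c(th[1], th[2], th[4] / 2,
           th[2], th[3], th[5] / 2,
           th[4] / 2, th[5] / 2, th[6]), 3, 3)
}

conic_from_matrix <- function(Q) {
  c(Q[1, 1], Q[1, 2], Q[2, 2], 2 * Q[1, 3], 2 * Q[2, 3], Q[3, 3])
}

#' Direct least-squares ellipse estimate
#'
#' Closed-form algebraic conic fit with the ellipse-specific constraint
#' (Halir--Flusser stabilisation of the Fitzgibbon method), used to centre
#' the particle swarm. Data are shifted to their centroid and rescaled
#' before fitting for conditioning; the returned coefficients are in the
#' original coordinates, gauge-normalised to `A + C = 1`.
#'
#' @param points n x 2 matrix of boundary points (n >= 6, not collinear).
#' @return An [ellipse_params()] object.
#' @export
initial_ellipse_estimate <- function(points) {
  points <- as_point_matrix(points, 2L)
  if (nrow(points) < 6) stop("degenerate input: need at least 6 points")
  ctr <- colMeans(points)
  sc <- mean(sqrt(rowSums(sweep(points, 2, ctr)^2)))
  if (sc == 0) stop("degenerate input: identical points")
  u <- sweep(points, 2, ctr) / sc
  if (min(svd(sweep(u, 2, colMeans(u)))$d) < 1e-10)
    stop("degenerate input: points are collinear")
  x <- u[, 1]; y <- u[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  a1 <- NULL
  for (j in 1:3) {
    v <- Re(ev$vectors[, j])
    cond <- 4 * v[1] * v[3] - v[2]^2
    if (is.finite(cond) && cond > 0) { a1 <- v; break }
  }
  if (is.null(a1)) stop("degenerate input: no ellipse solution")
  a2 <- Tm %*% a1
  ## conic in scaled coords: a1[1] x^2 + a1[2] xy + a1[3] y^2 + a2[1] x + ...
  th_u <- c(a1[1], a1[2] / 2, a1[3], a2[1], a2[2], a2[3])
  ## map back: u = (p - ctr)/sc  via projective transform
  Tmat <- matrix(c(1 / sc, 0, -ctr[1] / sc,
                   0, 1 / sc, -ctr[2] / sc,
                   0, 0, 1), 3, 3, byrow = TRUE)
  Q <- t(Tmat) %*% conic_matrix(th_u) %*% Tmat
  th <- conic_from_matrix(Q)
  ellipse_params(th[1], th[2], th[3], th[4], th[5], th[6])
}

#' Moment-based initial cashew estimate
#'
#' Centres the surface at the cloud centroid, sets the scale to the
#' reciprocal RMS radius, aligns the rotation with the principal axes of
#' the cloud (largest variance on the base y axis, smallest on z), and uses
#' neutral base-shape defaults `a = 0.7, b = 0.3, c = d = 0`.
#'
#' @param points n x 3 matrix (n >= 12).
#' @return A [cashew_params()] object.
#' @export
initial_cashew_estimate <- function(points) {
  points <- as_point_matrix(points, 3L)
  if (nrow(points) < 12) stop("degenerate input: need at least 12 points")
  ctr <- colMeans(points)
  centered <- sweep(points, 2, ctr)
  rms <- sqrt(mean(rowSums(centered^2)))
  if (rms < 1e-12) stop("degenerate input: zero RMS radius")
  eg <- eigen(stats::cov(centered), symmetric = TRUE)
  V <- eg$vectors # columns ordered by decreasing variance
  ## base-frame anisotropy of the quartic: y extent >= x extent >= z extent
  R <- rbind(V[, 2], V[, 1], V[, 3]) # rows: world directions of base x,y,z
  if (det(R) < 0) R[3, ] <- -R[3, ]
  ang <- rotation_angles(R)
  cashew_params(a = 0.7, b = 0.3, c = 0, d = 0, s = 1 / rms,
                tx = ctr[1], ty = ctr[2], tz = ctr[3],
                theta_x = ang[1], theta_y = ang[2], theta_z = ang[3])
}

## ---------------------------------------------------------------------------
## Fitting criteria
## ---------------------------------------------------------------------------

#' Fit an ellipse by PSO over the FS loss
#'
#' Minimises the total FS distance of the boundary points to the conic zero
#' set over the six coefficients. Particles start uniformly in a box
#' centred at [initial_ellipse_estimate()] (half-width 50% per coordinate,
#' floored at 10% of the largest coefficient so near-zero coordinates still
#' move); parameter vectors violating \eqn{B^2 < AC} receive an infinite
#' loss. The returned coefficients are gauge-normalised to `A + C = 1`.
#'
#' @param points n x 2 matrix of boundary points (n >= 6).
#' @param pso_config a [pso_config()].
#' @param fs_config an [fs_config()] (optional).
#' @return List with `params` ([ellipse_params()]), `loss` (total FS loss)
#'   and `init` (the algebraic estimate).
#' @export
fit_ellipse <- function(points, pso_config = roifit::pso_config(),
                        fs_config = NULL) {
  points <- as_point_matrix(points, 2L)
  init <- initial_ellipse_estimate(points)
  th0 <- as.numeric(unclass(init))
  half <- pmax(0.5 * abs(th0), 0.1 * max(abs(th0)))
  box <- rbind(th0 - half, th0 + half)
  objective <- function(th) {
    if (th[2]^2 >= th[1] * th[3]) return(Inf)
    s <- tryCatch(ellipse_surface(ellipse_params(th[1], th[2], th[3], th[4],
                                                 th[5], th[6],
                                                 normalize = FALSE)),
                  error = function(e) NULL)
    if (is.null(s)) return(Inf)
    tryCatch(total_loss(s, points, fs_config), error = function(e) Inf)
  }
  res <- pso_minimize(objective, bounds = box, config = pso_config,
                      init_center = th0)
  th <- res$par
  params <- ellipse_params(th[1], th[2], th[3], th[4], th[5], th[6])
  list(params = params, loss = res$value, init = init,
       trajectory = res$trajectory)
}

## Cheap vectorised surrogate of the FS loss for the cashew family: mean
## point-to-surface distance estimated by a few Newton projection steps
## along the gradient in the base frame (capped for robustness, converted
## to world units). Tracks the true FS loss closely near the surface and
## costs a fraction of a millisecond, so a swarm can afford thousands of
## surrogate evaluations when hunting for the right basin.
cashew_proj_loss <- function(th, points) {
  a <- th[1]; b <- th[2]; cc <- th[3]; dd <- th[4]; sv <- th[5]
  if (sv <= 0 || any(th[1:4] < 0) || any(th[1:4] > 1)) return(Inf)
  M <- rotation_matrix(th[9], th[10], th[11])
  u <- sweep(points, 2, th[6:8]) %*% t(M) * sv
  x <- u
  for (k in 1:6) {
    q <- 1.5 * x[, 1]^2 + x[, 2]^2 + x[, 3]^2 + a^2 - b^2
    psi <- q^2 - 4 * a^2 * ((x[, 1] - cc)^2 + (x[, 2] - dd)^2)
    g1 <- 6 * q * x[, 1] - 8 * a^2 * (x[, 1] - cc)
    g2 <- 4 * q * x[, 2] - 8 * a^2 * (x[, 2] - dd)
    g3 <- 4 * q * x[, 3]
    gn2 <- pmax(g1^2 + g2^2 + g3^2, 1e-12)
    step <- psi / gn2
    len <- abs(step) * sqrt(gn2)
    fac <- pmin(1, 0.3 / pmax(len, 1e-12))
    x <- x - cbind(step * g1, step * g2, step * g3) * fac
  }
  d <- sqrt(rowSums((x - u)^2))
  q <- 1.5 * x[, 1]^2 + x[, 2]^2 + x[, 3]^2 + a^2 - b^2
  psi <- q^2 - 4 * a^2 * ((x[, 1] - cc)^2 + (x[, 2] - dd)^2)
  g1 <- 6 * q * x[, 1] - 8 * a^2 * (x[, 1] - cc)
  g2 <- 4 * q * x[, 2] - 8 * a^2 * (x[, 2] - dd)
  g3 <- 4 * q * x[, 3]
  gn <- pmax(sqrt(g1^2 + g2^2 + g3^2), 1e-9)
  mean(pmin(d + abs(psi) / gn, 2)) / sv
}

## Ring-geometry initial estimate: the cashew is a (broken) tube around a
## ring, so a circle fitted to the cloud in its principal plane (Kasa
## algebraic fit) estimates the ring centre (translation), ring radius
## (a / s) and tube thickness (b / s) directly.
cashew_geometric_init <- function(points) {
  ctr <- colMeans(points)
  centered <- sweep(points, 2, ctr)
  eg <- eigen(stats::cov(centered), symmetric = TRUE)
  Pc <- centered %*% eg$vectors
  xy <- Pc[, 1:2, drop = FALSE]; z <- Pc[, 3]
  A <- cbind(2 * xy, 1)
  sol <- qr.solve(A, rowSums(xy^2))
  c0 <- sol[1:2]
  R <- sqrt(max(sol[3] + sum(c0^2), 1e-12))
  radial <- sqrt(rowSums(sweep(xy, 2, c0)^2)) - R
  r_tube <- sqrt(mean(radial^2 + (z - mean(z))^2))
  t_world <- as.numeric(ctr + eg$vectors %*% c(c0, mean(z)))
  R3 <- rbind(eg$vectors[, 2], eg$vectors[, 1], eg$vectors[, 3])
  if (det(R3) < 0) R3[3, ] <- -R3[3, ]
  s <- 0.7 / max(R, 1e-9)
  a <- min(max(0.95 * s * R, 0.05), 0.95)
  b <- min(max(s * r_tube, 0.05), 0.95)
  list(a = a, b = b, s = s, t = t_world, R3 = R3,
       R = max(R, 1e-9), r_tube = r_tube)
}

## Surrogate-stage swarm: locates the basin of the optimum on the projection
## loss before the (much more expensive) FS-loss swarm refines it.
##
## Seeding rationale. The base quartic with c = d = 0 is even in every
## coordinate, so sixteen frames (eight in-plane orientations times a flip
## about the in-plane x axis) describe the same seed shape but different
## parameter branches once c, d > 0; since c and d are constrained to be
## nonnegative, only the correctly oriented frame can reach an asymmetric
## optimum. A small asymmetric (c, d) in the seeds breaks the tie so that
## ranking selects the right frame. The ring fit pins only the ratio a / s
## (the family is scale-degenerate along (a,b,c,d,s) -> lambda*(a,b,c,d,s)),
## so seeds cover two a levels and two ring-radius corrections.
cashew_presearch <- function(points, init, seed = 1L, n_particles = 80L,
                             max_iter = 250L, polish = 10L,
                             polish_maxit = 2000L, polish_restarts = 2L) {
  th0 <- as.numeric(unclass(init))
  geo <- cashew_geometric_init(points)
  seeds <- matrix(th0, 1)
  F1 <- diag(c(1, -1, -1))
  for (k in 0:7) for (fl in 1:2) {
    phi <- k * pi / 4
    Rz <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    Rf <- if (fl == 1) Rz %*% geo$R3 else F1 %*% Rz %*% geo$R3
    ang <- rotation_angles(Rf)
    for (a_c in c(0.65, 0.8)) for (m in c(1, 1.15)) {
      s_c <- a_c / (geo$R * m)
      b_c <- min(max(s_c * geo$r_tube, 0.05), 0.95)
      seeds <- rbind(seeds, c(a_c, b_c, 0.06, 0.03, s_c, geo$t, ang))
    }
  }
  bb_lo <- apply(points, 2, min); bb_hi <- apply(points, 2, max)
  ext <- bb_hi - bb_lo
  s_ref <- geo$s
  lower <- c(0, 0, 0, 0, s_ref / 4, bb_lo - 0.1 * ext - 1e-6, 0, 0, 0)
  upper <- c(1, 1, 0.5, 0.5, s_ref * 4, bb_hi + 0.1 * ext + 1e-6,
             2 * pi, 2 * pi, 2 * pi)
  ## polish objective: evaluate at the clamped parameter vector and add a
  ## quadratic penalty for the excursion, so Nelder-Mead stays in the box
  ## and the returned (clamped) vector has the value that was minimised
  obj <- function(th) {
    thc <- pmin(pmax(th, lower), upper)
    v <- cashew_proj_loss(thc, points)
    if (!is.finite(v)) return(1e6)
    v * (1 + 10 * sum((th - thc)^2))
  }
  res <- pso_minimize(function(th) cashew_proj_loss(th, points),
                      bounds = rbind(lower, upper),
                      config = pso_config(n_particles = n_particles,
                                          max_iter = max_iter,
                                          seed = seed, stop_tol = 1e-8),
                      init_center = seeds)
  ## local Nelder-Mead polish of the swarm best and the top-ranked seeds
  ## (the surrogate is cheap, so polishing costs little)
  cand <- rbind(res$par, seeds)
  cand <- cand[order(apply(cand, 1, obj))[seq_len(min(polish, nrow(cand)))], ,
               drop = FALSE]
  best <- res$par; best_v <- obj(res$par)
  for (i in seq_len(nrow(cand))) {
    o <- list(par = cand[i, ])
    for (r in seq_len(polish_restarts))
      o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                        control = list(maxit = polish_maxit, reltol = 1e-10))
    if (o$value < best_v) { best <- o$par; best_v <- o$value }
  }
  th <- pmin(pmax(best, lower), upper)
  cashew_params(th[1], th[2], th[3], th[4], th[5], th[6], th[7], th[8],
                th[9], th[10], th[11])
}

## The cashew family is scale-degenerate: (a,b,c,d,s) -> lambda*(a,b,c,d,s)
## leaves the zero set unchanged (Psi0(lambda*u; lambda*theta) =
## lambda^4 * Psi0(u; theta)). Fix the gauge a + b = 1 so that fitted
## coefficients are identifiable and comparable across subjects.
cashew_gauge <- function(params) {
  th <- unclass(params)
  lam <- 1 / (th[["a"]] + th[["b"]])
  if (!is.finite(lam) || lam <= 0) return(params)
  sc <- pmin(th[1:4] * lam, 1) # a,b,c,d stay inside [0,1]
  cashew_params(sc[[1]], sc[[2]], sc[[3]], sc[[4]], s = th[["s"]] * lam,
                tx = th[["tx"]], ty = th[["ty"]], tz = th[["tz"]],
                theta_x = th[["theta_x"]], theta_y = th[["theta_y"]],
                theta_z = th[["theta_z"]])
}

#' Fit a cashew-shaped surface by PSO over the FS loss
#'
#' Minimises the total FS distance over the 11-dimensional parameter vector
#' (base shape, scale, translation, rotation). Bounds: `a,b,c,d` in
#' \[0,1\], angles in \[0,2pi\], scale within a factor 10 of the initial
#' estimate, translation within the cloud bounding box.
#'
#' @param points n x 3 matrix of boundary points (n >= 12).
#' @param pso_config a [pso_config()].
#' @param fs_config an [fs_config()] (optional).
#' @param presearch named list overriding the surrogate-stage effort
#'   (`n_particles`, `max_iter`, `polish`, `polish_maxit`); see Details.
#' @details The swarm is centred by a two-stage initialisation: a
#'   ring-geometry estimate seeds a swarm on a cheap projection-distance
#'   surrogate of the FS loss, and the surrogate optimum becomes the centre
#'   of the (expensive) FS-loss swarm. This keeps the final optimisation,
#'   which is the printed update rule on the true objective, inside the
#'   right basin at a fraction of the cost.
#' @return List with `params` ([cashew_params()]), `loss` and `init`.
#' @export
fit_cashew <- function(points, pso_config = roifit::pso_config(),
                       fs_config = NULL, presearch = list()) {
  points <- as_point_matrix(points, 3L)
  init <- initial_cashew_estimate(points)
  pre_args <- utils::modifyList(
    list(points = points, init = init, seed = pso_config$seed),
    presearch)
  center <- do.call(cashew_presearch, pre_args)
  th0 <- as.numeric(unclass(center))
  bb_lo <- apply(points, 2, min); bb_hi <- apply(points, 2, max)
  pad <- 0.1 * (bb_hi - bb_lo) + 1e-6
  lower <- c(0, 0, 0, 0, th0[5] / 10, bb_lo - pad, 0, 0, 0)
  upper <- c(1, 1, 1, 1, th0[5] * 10, bb_hi + pad, 2 * pi, 2 * pi, 2 * pi)
  box_lo <- pmax(lower, c(th0[1:4] - 0.08, th0[5] * 0.9, th0[6:8] -
                            0.05 * (bb_hi - bb_lo) - 1e-6, th0[9:11] - 0.2))
  box_hi <- pmin(upper, c(th0[1:4] + 0.08, th0[5] * 1.1, th0[6:8] +
                            0.05 * (bb_hi - bb_lo) + 1e-6, th0[9:11] + 0.2))
  objective <- function(th) {
    if (th[5] <= 0) return(Inf)
    s <- tryCatch(cashew_surface(cashew_params(th[1], th[2], th[3], th[4],
                                               th[5], th[6], th[7], th[8],
                                               th[9], th[10], th[11])),
                  error = function(e) NULL)
    if (is.null(s)) return(Inf)
    tryCatch(total_loss(s, points, fs_config), error = function(e) Inf)
  }
  res <- pso_minimize(objective, bounds = rbind(lower, upper),
                      config = pso_config,
                      init_box = rbind(box_lo, box_hi), init_center = th0)
  th <- res$par
  params <- cashew_gauge(
    cashew_params(th[1], th[2], th[3], th[4], th[5], th[6], th[7],
                  th[8], th[9], th[10], th[11]))
  list(params = params, loss = res$value, init = init,
       trajectory = res$trajectory)
}
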