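# Shared fixtures: random well-conditioned surfaces and generic test shapes.

unit_circle <- function() ellipse_surface(ellipse_params(1, 0, 1, 0, 0, -1))

# sphere of given radius as a generic (non-family) implicit surface
sphere_surface <- function(radius = 1) {
  implicit_surface(
    value = function(p) {
      p <- roifit:::as_point_matrix(p, 3L)
      rowSums(p^2) - radius^2
    },
    gradient = function(p) {
      p <- roifit:::as_point_matrix(p, 3L)
      g <- 2 * p
      if (nrow(g) == 1L) g[1, ] else g
    },
    dim = 3L, interior = c(0, 0, 0))
}

# random ellipse with semi-axes in [0.5, 2], centre in [-1, 1]^2
random_ellipse <- function() {
  ellipse_from_geometry(runif(1, -1, 1), runif(1, -1, 1),
                        runif(1, 0.5, 2), runif(1, 0.5, 2),
                        runif(1, 0, pi))
}

# random well-conditioned cashew surface
random_cashew <- function() {
  cashew_params(a = runif(1, 0.5, 0.9), b = runif(1, 0.15, 0.4),
                c = runif(1, 0, 0.2), d = runif(1, 0, 0.15),
                s = runif(1, 0.7, 1.5),
                tx = runif(1, -0.5, 0.5), ty = runif(1, -0.5, 0.5),
                tz = runif(1, -0.5, 0.5),
                theta_x = runif(1, 0, 2 * pi),
                theta_y = runif(1, 0, 2 * pi),
                theta_z = runif(1, 0, 2 * pi))
}

# query point at moderate distance from a surface, off the zero set
random_query_point <- function(surface, spread) {
  repeat {
    p <- runif(surface$dim, -spread, spread) +
      roifit:::surface_interior(surface)
    g <- surface$gradient(p)
    gn <- sqrt(sum(as.numeric(g)^2))
    if (gn > 1e-6 && abs(surface$value(p)) / gn > 1e-3) return(p)
  }
}

# symmetric Hausdorff distance between two point sets (small n)
hausdorff_points <- function(A, B) {
  D <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B))
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

# central finite difference gradient of a surface value field
fd_gradient <- function(surface, p, h = 1e-6) {
  vapply(seq_along(p), function(i) {
    e <- rep(0, length(p)); e[i] <- h
    (surface$value(p + e) - surface$value(p - e)) / (2 * h)
  }, numeric(1))
}
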