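test_that("ellipse value matches the conic formula at hand-checked points", {
  circ <- ellipse_params(1, 0, 1, 0, 0, -1, normalize = FALSE)
  expect_equal(ellipse_value(circ, c(1, 0)), 0)
  expect_equal(ellipse_value(circ, c(0, 0)), -1)
  expect_equal(ellipse_value(circ, c(2, 0)), 3)
  # vectorised evaluation agrees with pointwise
  pts <- matrix(rnorm(10), 5, 2)
  expect_equal(ellipse_value(circ, pts),
               apply(pts, 1, function(p) ellipse_value(circ, p)))
})

test_that("ellipse construction rejects non-ellipses and fixes the gauge", {
  expect_error(ellipse_params(1, 2, 1, 0, 0, -1), "B\\^2 < A\\*C")
  expect_error(ellipse_params(1, 1, 1, 0, 0, -1), "B\\^2 < A\\*C")
  expect_error(ellipse_params(0, 0, 0, 0, 0, 0), "zero")
  th <- ellipse_params(2, 0.2, 1, 0.4, -0.6, -3)
  expect_equal(unname(th[1] + th[3]), 1)
})

test_that("ellipse gradient is analytic and matches finite differences", {
  circ <- ellipse_params(1, 0, 1, 0, 0, -1, normalize = FALSE)
  expect_equal(ellipse_gradient(circ, c(1, 0)), c(2, 0))
  expect_equal(ellipse_gradient(circ, c(0, 0)), c(0, 0))
  withr::with_seed(42, {
    for (i in 1:20) {
      params <- random_ellipse()
      s <- ellipse_surface(params)
      p <- rnorm(2)
      expect_equal(as.numeric(s$gradient(p)), fd_gradient(s, p),
                   tolerance = 1e-6)
    }
  })
})

test_that("rotation matrix follows the printed axis convention", {
  expect_equal(rotation_matrix(0, 0, 0), diag(3))
  expect_equal(rotation_matrix(0, 0, pi / 2),
               matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:10) {
      ang <- runif(3, 0, 2 * pi)
      M <- rotation_matrix(ang[1], ang[2], ang[3])
      expect_equal(t(M) %*% M, diag(3), tolerance = 1e-12)
      expect_equal(det(M), 1, tolerance = 1e-12)
      # the composition order is Rx Ry Rz: entry (1,3) is -sin(theta_y)
      expect_equal(M[1, 3], -sin(ang[2]), tolerance = 1e-12)
      # angle extraction round-trips
      ang2 <- rotation_angles(M)
      expect_equal(rotation_matrix(ang2[1], ang2[2], ang2[3]), M,
                   tolerance = 1e-9)
    }
  })
})

test_that("cashew base value reproduces the quartic term by term", {
  expect_equal(cashew_base_value(c(0.5, 0.5, 0, 0), c(0, 0, 0)), 0)
  expect_equal(cashew_base_value(c(1, 0, 0, 0), c(0, 0, 0)), 1)
  withr::with_seed(11, {
    for (i in 1:20) {
      base <- runif(4)
      p <- rnorm(3)
      q <- 1.5 * p[1]^2 + p[2]^2 + p[3]^2 + base[1]^2 - base[2]^2
      expected <- q * q -
        4 * base[1]^2 * ((p[1] - base[3])^2 + (p[2] - base[4])^2)
      expect_equal(cashew_base_value(base, p), expected)
    }
  })
})

test_that("cashew value composes scale, rotation and translation", {
  base <- c(a = 0.7, b = 0.3, c = 0.1, d = 0.05)
  ident <- cashew_params(0.7, 0.3, 0.1, 0.05)
  p <- c(0.4, -0.2, 0.3)
  expect_equal(cashew_value(ident, p), cashew_base_value(base, p))
  # translation equivariance
  tr <- cashew_params(0.7, 0.3, 0.1, 0.05, tx = 1, ty = -2, tz = 0.5)
  expect_equal(cashew_value(tr, p + c(1, -2, 0.5)),
               cashew_base_value(base, p))
  # full composition vs independent assembly
  withr::with_seed(13, {
    for (i in 1:10) {
      prm <- random_cashew()
      th <- unclass(prm)
      x <- rnorm(3)
      M <- rotation_matrix(th["theta_x"], th["theta_y"], th["theta_z"])
      u <- as.numeric(th["s"] * M %*% (x - th[c("tx", "ty", "tz")]))
      expect_equal(cashew_value(prm, x), cashew_base_value(th[1:4], u),
                   tolerance = 1e-12)
    }
  })
})

test_that("cashew parameter validation enforces the documented ranges", {
  expect_error(cashew_params(1.2, 0.3), "\\[0, 1\\]")
  expect_error(cashew_params(0.5, 0.3, s = 0), "positive")
  expect_error(cashew_params(0.5, 0.3, s = -1), "positive")
  th <- cashew_params(0.5, 0.3, theta_x = 7)
  expect_lt(th[["theta_x"]], 2 * pi)
})

test_that("cashew gradient matches finite differences and symmetry", {
  withr::with_seed(17, {
    prm <- random_cashew()
    s <- cashew_surface(prm)
    for (i in 1:100) {
      p <- roifit:::surface_interior(s) + rnorm(3, sd = 0.8)
      g <- as.numeric(s$gradient(p))
      expect_equal(g, fd_gradient(s, p, h = 1e-5), tolerance = 1e-6)
    }
  })
  # axis symmetry: with c = d = 0 the base gradient at (0, y, 0) has no
  # x or z component
  sym <- cashew_params(0.8, 0.3)
  g <- cashew_gradient(sym, c(0, 0.6, 0))
  expect_equal(g[c(1, 3)], c(0, 0))
  # chain rule in the scale: base gradient at the mapped point times s
  p <- c(0.4, 0.8, 0.1)
  g1 <- cashew_gradient(cashew_params(0.8, 0.3, s = 1), p)
  g2 <- cashew_gradient(cashew_params(0.8, 0.3, s = 2), 0.5 * p)
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
})

test_that("transform group: rotating by M then M^T recovers base values", {
  withr::with_seed(19, {
    ang <- runif(3, 0, 2 * pi)
    M <- rotation_matrix(ang[1], ang[2], ang[3])
    prm <- cashew_params(0.75, 0.3, 0.1, 0, theta_x = ang[1],
                         theta_y = ang[2], theta_z = ang[3])
    base <- c(0.75, 0.3, 0.1, 0)
    for (i in 1:10) {
      u <- rnorm(3)
      # world point whose body coordinates are u
      x <- as.numeric(t(M) %*% u)
      expect_equal(cashew_value(prm, x), cashew_base_value(base, u),
                   tolerance = 1e-12)
    }
  })
})

test_that("chord convexity holds on valid ellipses (sublevel set)", {
  withr::with_seed(23, {
    params <- random_ellipse()
    pts <- sample_ellipse_points(params, 200)
    for (i in 1:1000) {
      ab <- sample(200, 2)
      alpha <- runif(1)
      mid <- alpha * pts[ab[1], ] + (1 - alpha) * pts[ab[2], ]
      expect_lte(ellipse_value(params, mid), 1e-12)
    }
  })
})

test_that("sample_surface returns on-surface, seeded, reproducible points", {
  circ <- unit_circle()
  s4 <- sample_surface(circ, 4, seed = 3)
  expect_equal(nrow(s4), 4)
  expect_true(all(abs(rowSums(s4^2) - 1) < 1e-9))
  expect_identical(sample_surface(circ, 50, seed = 9),
                   sample_surface(circ, 50, seed = 9))
  cw <- cashew_surface(cashew_params(0.8, 0.3))
  sc <- sample_surface(cw, 200, seed = 5)
  expect_lt(max(abs(cashew_value(cw$params, sc))), 1e-9)
})

test_that("ellipse centre, axes and geometry constructor are consistent", {
  prm <- ellipse_from_geometry(2, -1, 1.5, 0.5, pi / 6)
  expect_equal(ellipse_center(prm), c(2, -1), tolerance = 1e-10)
  expect_equal(ellipse_axes(prm), c(1.5, 0.5), tolerance = 1e-10)
  # the sampled points satisfy the conic
  pts <- sample_ellipse_points(prm, 50)
  expect_lt(max(abs(ellipse_value(prm, pts))), 1e-10)
})
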