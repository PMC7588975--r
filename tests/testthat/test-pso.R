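test_that("pso_minimize solves a separable quadratic and is seeded", {
  bounds <- rbind(rep(-5, 3), rep(5, 3))
  cfg <- pso_config(n_particles = 30L, max_iter = 200L, seed = 4L)
  res <- pso_minimize(function(x) sum(x^2), bounds, cfg)
  expect_lt(res$value, 1e-4)
  res2 <- pso_minimize(function(x) sum(x^2), bounds, cfg)
  expect_identical(res$par, res2$par)
  # global-best trajectory is non-increasing
  expect_true(all(diff(res$trajectory) <= 1e-15))
})

test_that("a particle at the optimum with zero velocity stays put", {
  # one-particle algebra of the velocity update: with v = 0 and P = G = x
  # the new velocity is exactly zero, so the position cannot move; check
  # through the swarm by seeding the optimum and observing the best value
  bounds <- rbind(rep(-1, 2), rep(1, 2))
  res <- pso_minimize(function(x) sum((x - 0.3)^2), bounds,
                      pso_config(n_particles = 5L, max_iter = 50L,
                                 seed = 2L),
                      init_center = c(0.3, 0.3))
  expect_equal(res$par, c(0.3, 0.3))
  expect_equal(res$value, 0)
})

test_that("pso handles infeasible regions and errors when all start Inf", {
  bounds <- rbind(c(-2, -2), c(2, 2))
  res <- pso_minimize(function(x) if (x[1] < 0) Inf else sum(x^2), bounds,
                      pso_config(n_particles = 40L, max_iter = 120L,
                                 seed = 3L))
  expect_lt(res$value, 1e-2)
  expect_error(pso_minimize(function(x) Inf, bounds,
                            pso_config(n_particles = 5L, max_iter = 5L,
                                       seed = 1L)),
               "infeasible")
})

test_that("direct ellipse estimate recovers noiseless conics", {
  # unit circle in the A + C = 1 gauge
  circ_pts <- sample_ellipse_points(ellipse_params(1, 0, 1, 0, 0, -1), 40)
  est <- initial_ellipse_estimate(circ_pts)
  expect_equal(as.numeric(unclass(est)), c(0.5, 0, 0.5, 0, 0, -0.5),
               tolerance = 1e-8)
  withr::with_seed(53, {
    for (i in 1:10) {
      prm <- random_ellipse()
      pts <- sample_ellipse_points(prm, 60)
      est <- initial_ellipse_estimate(pts)
      expect_equal(as.numeric(unclass(est)), as.numeric(unclass(prm)),
                   tolerance = 1e-6)
    }
  })
  expect_error(initial_ellipse_estimate(cbind(1:6, 2 * (1:6))),
               "collinear")
  expect_error(initial_ellipse_estimate(cbind(1:5, rnorm(5))),
               "at least 6")
})

test_that("fit_ellipse recovers a known ellipse and is deterministic", {
  truth <- ellipse_params(0.6, 0.1, 0.4, 0.2, -0.1, -0.5)
  pts <- sample_ellipse_points(truth, 100)
  cfg <- pso_config(n_particles = 20L, max_iter = 50L, seed = 5L)
  fit <- fit_ellipse(pts, cfg)
  expect_lt(fit$loss, 1e-2 * 4) # noiseless: essentially zero total loss
  expect_equal(as.numeric(unclass(fit$params)),
               as.numeric(unclass(truth)), tolerance = 1e-3)
  fit2 <- fit_ellipse(pts, cfg)
  expect_identical(unclass(fit$params), unclass(fit2$params))
  # the optimum cannot be worse than the initial estimate
  s_init <- ellipse_surface(fit$init)
  expect_lte(fit$loss, total_loss(s_init, pts) + 1e-9)
})

test_that("moment-based cashew estimate follows its contract", {
  prm <- cashew_params(0.8, 0.3, 0.1, 0, s = 1.2, tx = 0.5, ty = -0.2,
                       tz = 0.8)
  pts <- sample_cashew_points(prm, 150, seed = 2)
  est <- initial_cashew_estimate(pts)
  ext <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  expect_lt(sqrt(sum((unclass(est)[c("tx", "ty", "tz")] -
                        colMeans(pts))^2)), 1e-9)
  # centroid itself is within a modest fraction of the cloud extent of t
  expect_lt(sqrt(sum((unclass(est)[c("tx", "ty", "tz")] -
                        c(0.5, -0.2, 0.8))^2)), 0.35 * ext)
  # returned rotation is orthonormal
  th <- unclass(est)
  M <- rotation_matrix(th[["theta_x"]], th[["theta_y"]], th[["theta_z"]])
  expect_equal(t(M) %*% M, diag(3), tolerance = 1e-10)
  expect_error(initial_cashew_estimate(pts[1:10, ]), "at least 12")
  expect_error(initial_cashew_estimate(matrix(1, 12, 3)), "zero RMS")
})

test_that("fit_cashew recovers a known surface at reduced budget", {
  truth <- cashew_params(0.78, 0.3, 0.1, 0.05, s = 1, tx = 0.2, ty = -0.1,
                         tz = 0.3, theta_x = 0.2, theta_y = 6,
                         theta_z = 0.3)
  pts <- sample_cashew_points(truth, 120, noise_sd = 0.01, seed = 3)
  cfg <- pso_config(n_particles = 10L, max_iter = 15L, seed = 6L)
  fit <- fit_cashew(pts, cfg, fs_config = fs_config(tau = 1e-6,
                                                    max_iter = 40L,
                                                    n_scan = 256L,
                                                    grid_3d = 240L),
                    presearch = list(n_particles = 40L, max_iter = 80L,
                                     polish = 4L, polish_maxit = 1000L))
  expect_lt(fit$loss / nrow(pts), 0.05)
  fit2 <- fit_cashew(pts, cfg, fs_config = fs_config(tau = 1e-6,
                                                     max_iter = 40L,
                                                     n_scan = 256L,
                                                     grid_3d = 240L),
                     presearch = list(n_particles = 40L, max_iter = 80L,
                                      polish = 4L, polish_maxit = 1000L))
  expect_identical(unclass(fit$params), unclass(fit2$params))
})
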