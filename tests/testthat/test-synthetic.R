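test_that("ellipse point sampler hits the curve and scales with noise", {
  prm <- ellipse_params(0.6, 0.1, 0.4, 0.2, -0.1, -0.5)
  pts <- sample_ellipse_points(prm, 75)
  expect_equal(nrow(pts), 75)
  expect_lt(max(abs(ellipse_value(prm, pts))), 1e-9)
  # noisy points: RMS FS distance to the curve tracks the injected sd
  s <- ellipse_surface(prm)
  noisy <- sample_ellipse_points(prm, 150, noise_sd = 0.01, seed = 8)
  d <- roifit:::fs_distance_batch(s, noisy)$distance
  rms <- sqrt(mean(d^2))
  expect_gt(rms, 0.01 * 0.6)
  expect_lt(rms, 0.01 * 1.4)
  expect_identical(sample_ellipse_points(prm, 30, 0.05, seed = 4),
                   sample_ellipse_points(prm, 30, 0.05, seed = 4))
})

test_that("cashew point sampler is on-surface, seeded, scale-consistent", {
  prm <- cashew_params(0.8, 0.3, 0.1, 0)
  pts <- sample_cashew_points(prm, 100, seed = 5)
  expect_lt(max(abs(cashew_value(prm, pts))), 1e-9)
  expect_identical(pts, sample_cashew_points(prm, 100, seed = 5))
  # doubling s halves the spatial extent of the cloud
  prm2 <- cashew_params(0.8, 0.3, 0.1, 0, s = 2)
  pts2 <- sample_cashew_points(prm2, 400, seed = 6)
  pts1 <- sample_cashew_points(prm, 400, seed = 6)
  ext <- function(m) apply(m, 2, max) - apply(m, 2, min)
  expect_equal(ext(pts1), 2 * ext(pts2), tolerance = 0.1)
})

test_that("2D phantom renders shapes recoverable by boundary extraction", {
  left <- ellipse_from_geometry(30, 48, 7, 15, 0.15)
  right <- ellipse_from_geometry(66, 48, 10, 12, -0.1)
  sp <- phantom_spec(c(96, 96), left, right, peak = 0.95,
                     background = 0.2, noise_sd = 0, seed = 2)
  img <- render_phantom_2d(sp)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  pts <- extract_boundary(img, 0.6)
  lr <- split_left_right(pts)
  dl <- roifit:::fs_distance_batch(ellipse_surface(left), lr$left)$distance
  dr <- roifit:::fs_distance_batch(ellipse_surface(right), lr$right)$distance
  expect_lt(max(dl), 2)
  expect_lt(max(dr), 2)
  # noiseless interior area at the threshold matches the analytic area
  area <- sum(img$pixels > 0.6)
  analytic <- pi * 7 * 15 + pi * 10 * 12
  expect_lt(abs(area - analytic) / analytic, 0.05)
  # seeded reproducibility with noise
  spn <- phantom_spec(c(96, 96), left, right, noise_sd = 0.02, seed = 9)
  expect_identical(render_phantom_2d(spn)$pixels,
                   render_phantom_2d(spn)$pixels)
  # shapes outside the canvas are rejected
  bad <- phantom_spec(c(32, 32), ellipse_from_geometry(30, 16, 8, 8), NULL)
  expect_error(render_phantom_2d(bad), "bounds")
})

test_that("3D phantom slices section the surface coherently", {
  cw <- cashew_params(0.75, 0.28, 0.1, 0.05, s = 0.075, tx = 30, ty = 30)
  sp <- phantom_spec(c(64, 64), cw, NULL, peak = 0.95, background = 0.2,
                     noise_sd = 0, seed = 3)
  zs <- c(-2.4, -0.8, 0.8, 2.4)
  st <- render_phantom_3d(sp, zs)
  expect_length(st$slices, 4)
  # the central slices cut the tube nearer its equator: larger area
  areas <- vapply(st$slices, function(s) sum(s$pixels > 0.6), numeric(1))
  expect_gt(min(areas[2:3]), max(areas[c(1, 4)]))
  # boundary round trip: points near the true zero set
  pts <- stack_boundaries(st, 1:4)
  d <- roifit:::fs_distance_batch(cashew_surface(cw), pts)$distance
  expect_lt(stats::quantile(d, 0.95), 2)
  expect_identical(render_phantom_3d(sp, zs)$slices[[2]]$pixels,
                   st$slices[[2]]$pixels)
})

test_that("cohort generation is labelled, stratified and reproducible", {
  co <- generate_cohort(n_subjects = 24, class_balance = 0.5, seed = 12)
  expect_equal(nrow(co$labels), 24)
  expect_equal(sum(co$labels$label == 1), 12)
  # strata map onto labels as documented
  expect_setequal(unique(co$labels$stratum[co$labels$label == 0]),
                  c("normal", "nearly_normal"))
  expect_setequal(unique(co$labels$stratum[co$labels$label == 1]),
                  c("abnormal", "potentially_abnormal"))
  co2 <- generate_cohort(n_subjects = 24, class_balance = 0.5, seed = 12)
  expect_identical(co$subjects[[3]]$image$pixels,
                   co2$subjects[[3]]$image$pixels)
  expect_identical(co$labels, co2$labels)
  expect_error(generate_cohort(10), "at least 20")
})

test_that("class geometry separates: fitted ellipse shapes differ by class", {
  co <- generate_cohort(n_subjects = 20, class_balance = 0.5, seed = 31)
  ecc <- vapply(seq_along(co$subjects), function(i) {
    img <- normalize_grayscale(co$subjects[[i]]$image)
    lr <- split_left_right(extract_boundary(img, 0.6))
    est <- initial_ellipse_estimate(lr$left)
    ax <- ellipse_axes(est)
    ax[1] / ax[2]
  }, numeric(1))
  is_norm <- co$labels$label == 0
  # elongation (axis ratio) separates the classes cleanly at generator
  # effect size
  expect_gt(mean(ecc[is_norm]), mean(ecc[!is_norm]) + 0.3)
})

test_that("round-trip identifiability: noiseless fit recovers the truth", {
  withr::with_seed(83, {
    prm <- random_ellipse()
    pts <- sample_ellipse_points(prm, 100)
    fit <- fit_ellipse(pts, pso_config(n_particles = 15L, max_iter = 30L,
                                       seed = 3L))
    expect_equal(as.numeric(unclass(fit$params)),
                 as.numeric(unclass(prm)), tolerance = 1e-3)
  })
})
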