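## ---------------------------------------------------------------------------
## End-to-end pipeline: images -> boundaries -> fits -> features -> evaluation
## ---------------------------------------------------------------------------

## deterministic per-stage seed derivation from one master seed (double
## arithmetic; stays well below .Machine$integer.max)
derive_seed <- function(master, stage, i = 0L) {
  as.integer((as.numeric(master) * 1009 + as.numeric(stage) * 9973 +
                as.numeric(i) * 7919) %% 2147483
             + 1)
}

## thin a point cloud to at most n_max points (deterministic)
downsample_points <- function(points, n_max) {
  n <- nrow(points)
  if (n <= n_max) return(points)
  points[round(seq(1, n, length.out = n_max)), , drop = FALSE]
}

#' Default per-subject fitting budgets
#'
#' Reduced optimisation budgets used when fitting every subject of a
#' cohort, where hundreds of fits are required: fewer particles and
#' iterations, capped boundary point counts, and coarser FS search grids.
#' All entries can be overridden.
#'
#' @return Named list of budget settings.
#' @export
cohort_budget <- function() {
  list(
    ellipse_particles = 12L, ellipse_iters = 25L, ellipse_max_pts = 70L,
    cashew_particles = 10L, cashew_iters = 15L, cashew_max_pts = 60L,
    fs2d = fs_config(tau = 1e-6, max_iter = 40L, n_scan = 256L,
                     grid_2d = 90L),
    fs3d = fs_config(tau = 1e-6, max_iter = 40L, n_scan = 256L,
                     grid_3d = 240L),
    presearch = list(n_particles = 24L, max_iter = 50L, polish = 3L,
                     polish_maxit = 800L, polish_restarts = 1L))
}

#' Compute all feature sets for one subject
#'
#' Runs the full per-subject pipeline: normalise the 2D-combined image,
#' extract and lateralise boundary points, fit one ellipse per side, fit
#' one cashew surface per side to the slice-stack boundaries, compute the
#' grayscale features, and assemble Sets 1 to 5.
#'
#' @param image the subject's 2D-combined [grayscale_image()].
#' @param stack the subject's [slice_stack()].
#' @param seed integer seed for the optimisers.
#' @param budget list of budgets, see [cohort_budget()].
#' @param threshold uptake threshold.
#' @return Named list of [feature_vector()]s (`set1` .. `set5`) plus the
#'   fitted parameter objects in `fits`.
#' @export
subject_features <- function(image, stack, seed = 1L,
                             budget = cohort_budget(), threshold = 0.6) {
  img <- normalize_grayscale(image)
  pts2 <- extract_boundary(img, threshold)
  lr2 <- split_left_right(pts2)
  if (!lr2$split) stop("2D lateralization failed")
  fit_side_2d <- function(pts, side_seed) {
    fit_ellipse(downsample_points(pts, budget$ellipse_max_pts),
                pso_config(n_particles = budget$ellipse_particles,
                           max_iter = budget$ellipse_iters,
                           seed = side_seed),
                fs_config = budget$fs2d)
  }
  f2l <- fit_side_2d(lr2$left, derive_seed(seed, 1L))
  f2r <- fit_side_2d(lr2$right, derive_seed(seed, 2L))

  pts3 <- stack_boundaries(stack, seq_along(stack$slices), threshold)
  lr3 <- split_left_right(pts3)
  if (!lr3$split) stop("3D lateralization failed")
  fit_side_3d <- function(pts, side_seed) {
    fit_cashew(downsample_points(pts, budget$cashew_max_pts),
               pso_config(n_particles = budget$cashew_particles,
                          max_iter = budget$cashew_iters, seed = side_seed),
               fs_config = budget$fs3d, presearch = budget$presearch)
  }
  f3l <- fit_side_3d(lr3$left, derive_seed(seed, 3L))
  f3r <- fit_side_3d(lr3$right, derive_seed(seed, 4L))

  set1 <- grayscale_features(img, threshold = threshold)
  set2 <- ellipse_features(f2l$params, f2r$params)
  set3 <- cashew_features(f3l$params, f3r$params)
  list(set1 = set1, set2 = set2, set3 = set3,
       set4 = assemble_set(4L, grayscale = set1, ellipse = set2),
       set5 = assemble_set(5L, grayscale = set1, ellipse = set2,
                           cashew = set3),
       fits = list(ellipse_left = f2l$params, ellipse_right = f2r$params,
                   cashew_left = f3l$params, cashew_right = f3r$params))
}

#' Compute feature matrices for a whole cohort
#'
#' @param cohort output of [generate_cohort()] (or a list with the same
#'   structure built from real images).
#' @param seed integer master seed.
#' @param budget per-subject budgets, see [cohort_budget()].
#' @param verbose print progress.
#' @return List with `features` (named list of matrices `set1` .. `set5`)
#'   and `labels` (the cohort label frame).
#' @export
cohort_features <- function(cohort, seed = 1L, budget = cohort_budget(),
                            verbose = FALSE) {
  subjects <- cohort$subjects
  n <- length(subjects)
  per_set <- list(set1 = NULL, set2 = NULL, set3 = NULL, set4 = NULL,
                  set5 = NULL)
  for (i in seq_len(n)) {
    sf <- subject_features(subjects[[i]]$image, subjects[[i]]$stack,
                           seed = derive_seed(seed, 5L, i), budget = budget)
    for (nm in names(per_set))
      per_set[[nm]] <- rbind(per_set[[nm]], sf[[nm]]$values)
    if (verbose && i %% 10 == 0)
      message(sprintf("  features: %d / %d subjects", i, n))
  }
  for (nm in names(per_set)) rownames(per_set[[nm]]) <- cohort$labels$id
  list(features = per_set, labels = cohort$labels)
}

#' Run the full synthetic pipeline
#'
#' Generates a labelled cohort, computes all feature sets, evaluates them
#' under the repeated stratified hold-out protocol, and writes every
#' artifact (feature CSVs, labels, per-round metrics, summary, run log) to
#' `out_dir`. Reruns with the same configuration are identical.
#'
#' @param config named list (or path to a YAML file) with any of:
#'   `n_subjects`, `class_balance`, `rounds`, `seed`, `sets` (feature sets
#'   to evaluate), `out_dir`, `noise_sd`, plus optional `budget` overrides.
#' @return Invisibly, a list with `features`, `labels` and `evaluation`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_subjects = 120L, class_balance = 0.525, rounds = 20L,
                   seed = 1L, sets = c("set1", "set2", "set3", "set4",
                                       "set5"),
                   out_dir = "roifit_run", noise_sd = 0.02,
                   verbose = TRUE)
  bad <- setdiff(names(config), c(names(defaults), "budget"))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  budget <- utils::modifyList(cohort_budget(), cfg$budget %||% list())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("roifit run, seed %d", cfg$seed),
                 sprintf("n_subjects=%d rounds=%d noise_sd=%g",
                         cfg$n_subjects, cfg$rounds, cfg$noise_sd))
  if (cfg$verbose) message("generating cohort ...")
  cohort <- generate_cohort(cfg$n_subjects, cfg$class_balance,
                            seed = derive_seed(cfg$seed, 10L),
                            noise_sd = cfg$noise_sd)
  utils::write.csv(cohort$labels,
                   file.path(cfg$out_dir, "labels.csv"), row.names = FALSE)
  if (cfg$verbose) message("computing features ...")
  cf <- cohort_features(cohort, seed = derive_seed(cfg$seed, 20L),
                        budget = budget, verbose = cfg$verbose)
  for (nm in names(cf$features))
    utils::write.csv(data.frame(id = cohort$labels$id, cf$features[[nm]],
                                check.names = FALSE),
                     file.path(cfg$out_dir, paste0("features_", nm, ".csv")),
                     row.names = FALSE)
  if (cfg$verbose) message("evaluating ...")
  ev <- repeated_holdout(cf$features[cfg$sets], cohort$labels$label,
                         cohort$labels$stratum, rounds = cfg$rounds,
                         seed = derive_seed(cfg$seed, 30L))
  utils::write.csv(ev$per_round, file.path(cfg$out_dir, "per_round.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$summary, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(set = rownames(ev$selection_counts),
                              ev$selection_counts, check.names = FALSE),
                   file.path(cfg$out_dir, "selection_counts.csv"),
                   row.names = FALSE)
  writeLines(c(log_lines, sprintf("finished %s", format(Sys.time()))),
             file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(features = cf$features, labels = cohort$labels,
                 evaluation = ev))
}

#' Read a boundary point cloud from CSV
#'
#' Expects a header `x,y` (2D) or `x,y,z` (3D), one point per row.
#'
#' @param path CSV path.
#' @return Numeric matrix of points.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("point CSV must have columns x,y[,z]")
  cols <- intersect(c("x", "y", "z"), names(df))
  as.matrix(df[cols])
}

#' Write fitted shape parameters to JSON
#'
#' @param params an [ellipse_params()] or [cashew_params()] object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(as.list(unclass(params)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read shape parameters from JSON or YAML
#'
#' @param path input path written by [write_params_json()] (or YAML with
#'   the same field names).
#' @param type `"ellipse"` or `"cashew"`.
#' @return The parameter object.
#' @export
read_params <- function(path, type = c("ellipse", "cashew")) {
  type <- match.arg(type)
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (type == "ellipse") do.call(ellipse_params, lst)
  else do.call(cashew_params, lst)
}
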