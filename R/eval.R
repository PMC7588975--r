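## ---------------------------------------------------------------------------
## Evaluation protocol: metrics, stratified splits, classifier selection,
## repeated hold-out, paired tests
## ---------------------------------------------------------------------------

#' @importFrom stats predict
NULL

#' Binary classification metrics
#'
#' Accuracy, sensitivity, specificity and their geometric mean:
#' `ACC = (TP + TN) / total`, `SEN = TP / P`, `SPE = TN / N`,
#' `GM = sqrt(SEN * SPE)`. The positive class is labelled 1.
#'
#' @param truth,predicted 0/1 vectors of equal length; both classes must be
#'   present in `truth`.
#' @return Named list with `ACC`, `SEN`, `SPE`, `GM`.
#' @export
compute_metrics <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (length(unique(truth)) < 2)
    stop("undefined metric: truth contains a single class")
  tp <- sum(truth == 1 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  sen <- tp / sum(truth == 1)
  spe <- tn / sum(truth == 0)
  list(ACC = (tp + tn) / length(truth), SEN = sen, SPE = spe,
       GM = sqrt(sen * spe))
}

#' Stratified train/test split
#'
#' Splits subjects so that each stratum contributes the same proportion to
#' the test set (test counts rounded per stratum, half away from zero, and
#' kept strictly inside the stratum).
#'
#' @param strata character or factor vector of stratum labels.
#' @param test_fraction fraction held out for testing.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(strata, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  strata <- as.character(strata)
  tab <- table(strata)
  if (any(tab < 5)) stop("every stratum needs at least 5 subjects")
  withr::with_seed(as.integer(seed), {
    test <- integer(0)
    for (s in names(tab)) {
      idx <- which(strata == s)
      n_test <- floor(length(idx) * test_fraction + 0.5)
      n_test <- max(1L, min(n_test, length(idx) - 1L))
      test <- c(test, sample(idx, n_test))
    }
    list(train = setdiff(seq_along(strata), test), test = sort(test))
  })
}

## stratified fold assignment (by label) for k-fold CV
stratified_folds <- function(labels, k = 5L) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## ---------------------------------------------------------------------------
## Classifier contract and default adapters
## ---------------------------------------------------------------------------

#' Define a pluggable classifier
#'
#' The evaluation harness owns no learning mathematics; classifiers enter
#' through this contract: a `fit(X, y, params)` function returning a model,
#' a `predict(model, X)` function returning 0/1 labels, and a `grid` of
#' candidate tuning settings (each a named list) explored by 5-fold CV.
#'
#' @param name display name.
#' @param fit function of `(X, y, params)`.
#' @param predict function of `(model, X)`.
#' @param grid list of tuning settings; `list(list())` when untuned.
#' @return An object of class `roifit_classifier`.
#' @export
classifier <- function(name, fit, predict, grid = list(list())) {
  stopifnot(is.function(fit), is.function(predict), length(grid) >= 1)
  structure(list(name = name, fit = fit, predict = predict, grid = grid),
            class = "roifit_classifier")
}

#' Default classifier candidates
#'
#' The six standard candidates: SVM, naive Bayes, random forest, gradient
#' boosting, logistic regression and LDA, each wrapped behind the
#' [classifier()] contract. Tuned candidates (SVM, RF, XGB) carry grids of
#' five settings centred at the wrapped implementations' defaults.
#'
#' @param ntree random forest size (kept moderate for speed).
#' @return Named list of [classifier()] objects, in registration order.
#' @export
default_classifiers <- function(ntree = 200L) {
  drop_const <- function(X) X[, apply(X, 2, function(c) diff(range(c)) > 0),
                              drop = FALSE]
  list(
    SVM = classifier("SVM",
      fit = function(X, y, p)
        e1071::svm(X, factor(y, levels = c(0, 1)), cost = p$cost,
                   kernel = "radial", scale = apply(X, 2, sd) > 0),
      predict = function(m, X) as.integer(as.character(predict(m, X))),
      grid = lapply(c(0.25, 0.5, 1, 2, 4), function(co) list(cost = co))),
    NB = classifier("NB",
      fit = function(X, y, p) {
        X <- X + matrix(rnorm(length(X), sd = 1e-9), nrow(X))
        e1071::naiveBayes(X, factor(y, levels = c(0, 1)))
      },
      predict = function(m, X) as.integer(as.character(predict(m, X)))),
    RF = classifier("RF",
      fit = function(X, y, p) {
        mtry <- max(1L, min(ncol(X), round(sqrt(ncol(X)) * p$mtry_mult)))
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = ntree, mtry = mtry)
      },
      predict = function(m, X) as.integer(as.character(predict(m, X))),
      grid = lapply(c(0.5, 0.75, 1, 1.5, 2),
                    function(mm) list(mtry_mult = mm))),
    XGB = classifier("XGB",
      fit = function(X, y, p)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = p$eta,
                        max_depth = 3L, nthread = 1L),
          data = xgboost::xgb.DMatrix(as.matrix(X), label = y,
                                      nthread = 1L),
          nrounds = 40L, verbose = 0),
      predict = function(m, X)
        as.integer(predict(m, xgboost::xgb.DMatrix(as.matrix(X),
                                                   nthread = 1L)) > 0.5),
      grid = lapply(c(0.05, 0.1, 0.2, 0.3, 0.5), function(e) list(eta = e))),
    LR = classifier("LR",
      fit = function(X, y, p) {
        df <- data.frame(drop_const(X), y = y)
        suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
      },
      predict = function(m, X)
        as.integer(suppressWarnings(
          predict(m, data.frame(X), type = "response")) > 0.5)),
    LDA = classifier("LDA",
      fit = function(m_X, y, p) {
        X <- m_X + matrix(rnorm(length(m_X), sd = 1e-9), nrow(m_X))
        ## probability-vector features are collinear by construction; LDA
        ## handles that, so its collinearity warning is expected noise
        suppressWarnings(MASS::lda(X, grouping = factor(y, levels = c(0, 1))))
      },
      predict = function(m, X)
        as.integer(as.character(predict(m, X)$class)))
  )
}

cv_accuracy <- function(cand, params, X, y, fold) {
  k <- max(fold)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2) next
    m <- cand$fit(X[tr, , drop = FALSE], y[tr], params)
    pr <- cand$predict(m, X[te, , drop = FALSE])
    correct <- correct + sum(pr == y[te])
  }
  correct / length(y)
}

#' Select a classifier by stratified 5-fold cross-validation
#'
#' For each candidate, every tuning setting in its grid is scored by
#' stratified 5-fold CV accuracy on the training data and the best setting
#' retained; the candidate with the highest CV accuracy wins (ties broken
#' by registration order) and is refit on the full training set.
#'
#' @param X training feature matrix.
#' @param y training 0/1 labels.
#' @param candidates named list of [classifier()] objects.
#' @param seed integer seed (fold assignment and stochastic learners).
#' @param k number of folds.
#' @return List with `model`, `name`, `cv_accuracy`, `params` and
#'   `predict` (a function of a feature matrix).
#' @export
select_classifier <- function(X, y, candidates = default_classifiers(),
                              seed = 1L, k = 5L) {
  stopifnot(length(candidates) >= 2)
  X <- as.matrix(X)
  y <- as.integer(y)
  withr::with_seed(as.integer(seed), {
    fold <- stratified_folds(y, k)
    best <- NULL
    for (nm in names(candidates)) {
      cand <- candidates[[nm]]
      for (params in cand$grid) {
        acc <- cv_accuracy(cand, params, X, y, fold)
        if (is.null(best) || acc > best$cv_accuracy) {
          best <- list(name = nm, cv_accuracy = acc, params = params)
        }
      }
    }
    cand <- candidates[[best$name]]
    model <- cand$fit(X, y, best$params)
    list(model = model, name = best$name, cv_accuracy = best$cv_accuracy,
         params = best$params,
         predict = function(newX) cand$predict(model, as.matrix(newX)))
  })
}

#' Repeated stratified hold-out evaluation
#'
#' The full protocol: in each round, an 80/20 stratified split is drawn,
#' the classifier is selected by 5-fold CV on the training part
#' ([select_classifier()]), refit, and scored on the held-out part. The
#' identical split and fold seeds are reused for every feature set within
#' a round, so per-round accuracies are paired across sets.
#'
#' @param feature_sets named list of feature matrices (rows = subjects,
#'   aligned across sets).
#' @param labels 0/1 vector.
#' @param strata stratum labels for the stratified split.
#' @param rounds number of rounds (>= 2).
#' @param seed integer master seed.
#' @param candidates named list of [classifier()] objects.
#' @param test_fraction held-out fraction.
#' @return List with `per_round` (long data frame of test metrics),
#'   `summary` (mean, SD and percentile 95% CI per set and metric) and
#'   `selection_counts` (sets x candidates matrix).
#' @export
repeated_holdout <- function(feature_sets, labels, strata, rounds = 100L,
                             seed = 1L, candidates = default_classifiers(),
                             test_fraction = 0.2) {
  stopifnot(rounds >= 2, length(feature_sets) >= 1)
  if (is.null(names(feature_sets)))
    names(feature_sets) <- paste0("set", seq_along(feature_sets))
  labels <- as.integer(labels)
  rows <- list()
  counts <- matrix(0L, length(feature_sets), length(candidates),
                   dimnames = list(names(feature_sets), names(candidates)))
  for (r in seq_len(rounds)) {
    sp <- stratified_split(strata, test_fraction, seed = seed + 17L * r)
    for (nm in names(feature_sets)) {
      X <- as.matrix(feature_sets[[nm]])
      sel <- select_classifier(X[sp$train, , drop = FALSE],
                               labels[sp$train], candidates,
                               seed = seed + 31L * r)
      pred <- sel$predict(X[sp$test, , drop = FALSE])
      met <- compute_metrics(labels[sp$test], pred)
      counts[nm, sel$name] <- counts[nm, sel$name] + 1L
      rows[[length(rows) + 1L]] <-
        data.frame(round = r, set = nm, classifier = sel$name,
                   ACC = met$ACC, SEN = met$SEN, SPE = met$SPE, GM = met$GM,
                   stringsAsFactors = FALSE)
    }
  }
  per_round <- do.call(rbind, rows)
  summarise <- function(v)
    c(AVE = mean(v), SD = sd(v),
      CI_lo = unname(stats::quantile(v, 0.025)),
      CI_hi = unname(stats::quantile(v, 0.975)))
  summary <- do.call(rbind, lapply(names(feature_sets), function(nm) {
    sub <- per_round[per_round$set == nm, ]
    do.call(rbind, lapply(c("ACC", "SEN", "SPE", "GM"), function(me) {
      st <- summarise(sub[[me]])
      data.frame(set = nm, measure = me, AVE = st[["AVE"]], SD = st[["SD"]],
                 CI_lo = st[["CI_lo"]], CI_hi = st[["CI_hi"]],
                 stringsAsFactors = FALSE)
    }))
  }))
  list(per_round = per_round, summary = summary, selection_counts = counts)
}

#' Paired t-test on per-round accuracies
#'
#' Two-sided paired t-test comparing the per-round test accuracies of two
#' feature sets evaluated on identical splits.
#'
#' @param acc_a,acc_b numeric vectors of equal length (>= 2).
#' @return The p-value.
#' @export
paired_t_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("length mismatch")
  if (length(acc_a) < 2) stop("need at least 2 paired values")
  d <- acc_a - acc_b
  if (sd(d) == 0)
    stop("degenerate test: zero variance of paired differences")
  stats::t.test(acc_a, acc_b, paired = TRUE)$p.value
}
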