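test_that("metric formulas match hand-computed confusion tables", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(ACC = 1, SEN = 1, SPE = 1, GM = 1))
  # TP=50 TN=40 FP=10 FN=0
  truth <- c(rep(1, 50), rep(0, 50))
  pred <- c(rep(1, 50), rep(1, 10), rep(0, 40))
  m <- compute_metrics(truth, pred)
  expect_equal(m$ACC, 0.9)
  expect_equal(m$SEN, 1)
  expect_equal(m$SPE, 0.8)
  expect_equal(m$GM, sqrt(0.8))
  # the all-positive predictor has zero specificity, hence zero GM
  allpos <- compute_metrics(c(1, 0, 1, 0), c(1, 1, 1, 1))
  expect_equal(allpos$SPE, 0)
  expect_equal(allpos$GM, 0)
  expect_error(compute_metrics(c(1, 1), c(1, 0)), "single class")
})

test_that("metric identities hold on fuzzed confusion tables", {
  withr::with_seed(89, {
    gm_err <- acc_err <- 0
    checked <- 0L
    for (i in 1:10000) {
      tp <- sample(0:30, 1); fn <- sample(0:30, 1)
      tn <- sample(0:30, 1); fp <- sample(0:30, 1)
      if (tp + fn == 0 || tn + fp == 0) next
      truth <- rep(c(1, 0), c(tp + fn, tn + fp))
      pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
      m <- compute_metrics(truth, pred)
      gm_err <- max(gm_err, abs(m$GM^2 - m$SEN * m$SPE))
      acc_err <- max(acc_err, abs(m$ACC - (tp + tn) / length(truth)))
      checked <- checked + 1L
    }
    expect_gt(checked, 9000)
    expect_lt(gm_err, 1e-12)
    expect_lt(acc_err, 1e-12)
  })
})

test_that("stratified split keeps stratum proportions and partitions", {
  strata <- rep(c("normal", "nearly_normal", "potentially_abnormal",
                  "abnormal"), c(174, 127, 77, 256))
  sp <- stratified_split(strata, 0.2, seed = 1)
  test_tab <- table(strata[sp$test])
  expect_equal(as.integer(test_tab[c("normal", "nearly_normal",
                                     "potentially_abnormal", "abnormal")]),
               c(35L, 25L, 15L, 51L))
  expect_setequal(c(sp$train, sp$test), seq_along(strata))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(stratified_split(strata, 0.2, seed = 7),
                   stratified_split(strata, 0.2, seed = 7))
  expect_error(stratified_split(rep(c("a", "b"), c(3, 50))), "at least 5")
})

test_that("stratum proportions are preserved over many seeds", {
  strata <- rep(c("a", "b", "c", "d"), c(40, 30, 20, 60))
  for (seed in 1:100) {
    sp <- stratified_split(strata, 0.2, seed = seed)
    tab <- table(strata[sp$test])
    expect_equal(as.integer(tab[c("a", "b", "c", "d")]), c(8L, 6L, 4L, 12L))
  }
})

test_that("classifier selection picks the stronger candidate", {
  withr::with_seed(97, {
    X <- matrix(rnorm(200), 100, 2)
    y <- as.integer(X[, 1] + 0.2 * rnorm(100) > 0)
    cands <- list(
      good = classifier("good",
        fit = function(X, y, p) glm.fit(cbind(1, X), y,
                                        family = binomial()),
        predict = function(m, X)
          as.integer(cbind(1, X) %*% m$coefficients > 0)),
      const = classifier("const",
        fit = function(X, y, p) NULL,
        predict = function(m, X) rep(0L, nrow(X))))
    sel <- select_classifier(X, y, cands, seed = 5)
    expect_equal(sel$name, "good")
    expect_gt(sel$cv_accuracy, 0.8)
    sel2 <- select_classifier(X, y, cands, seed = 5)
    expect_identical(sel$cv_accuracy, sel2$cv_accuracy)
    # the chosen CV accuracy is the maximum over candidates
    accs <- vapply(names(cands), function(nm) {
      s <- select_classifier(X, y, cands[c(nm, setdiff(names(cands), nm))],
                             seed = 5)
      s$cv_accuracy
    }, numeric(1))
    expect_equal(sel$cv_accuracy, max(accs))
  })
})

test_that("default candidates run end to end on small separable data", {
  withr::with_seed(101, {
    X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 3), 30, 2))
    colnames(X) <- c("f1", "f2")
    y <- rep(c(0L, 1L), each = 30)
    sel <- select_classifier(X, y, default_classifiers(ntree = 50L),
                             seed = 11)
    expect_gt(sel$cv_accuracy, 0.9)
    pred <- sel$predict(X)
    expect_gt(mean(pred == y), 0.9)
  })
})

test_that("repeated hold-out pairs splits across sets and counts picks", {
  withr::with_seed(103, {
    n <- 80
    X_good <- cbind(sig = rep(c(-2, 2), each = n / 2) + rnorm(n, sd = 0.3),
                    jnk = rnorm(n))
    X_noise <- matrix(rnorm(2 * n), n, 2,
                      dimnames = list(NULL, c("a", "b")))
    y <- rep(c(0L, 1L), each = n / 2)
    strata <- rep(c("s1", "s2", "s3", "s4"), n / 4)
    cands <- default_classifiers(ntree = 50L)[c("LR", "LDA")]
    ev <- repeated_holdout(list(good = X_good, noise = X_noise), y, strata,
                           rounds = 4, seed = 3, candidates = cands)
    expect_equal(sum(ev$selection_counts["good", ]), 4)
    expect_equal(nrow(ev$per_round), 8)
    acc_good <- ev$per_round$ACC[ev$per_round$set == "good"]
    acc_noise <- ev$per_round$ACC[ev$per_round$set == "noise"]
    expect_gt(mean(acc_good), mean(acc_noise))
    expect_equal(mean(acc_good), 1)
    # summary table carries the four measures per set
    expect_equal(nrow(ev$summary), 8)
    ev2 <- repeated_holdout(list(good = X_good, noise = X_noise), y,
                            strata, rounds = 4, seed = 3,
                            candidates = cands)
    expect_identical(ev$summary, ev2$summary)
  })
})

test_that("paired t-test matches the closed-form statistic", {
  # textbook-style example with a known t statistic
  a <- c(30.02, 29.99, 30.11, 29.97, 30.01, 29.99)
  b <- c(29.89, 29.93, 29.72, 29.98, 30.02, 29.98)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
  expect_equal(paired_t_test(a, b), p_manual, tolerance = 1e-12)
  expect_error(paired_t_test(b + 0.1, b), "zero variance")
  expect_error(paired_t_test(1:3, 1:4), "length")
})

test_that("paired t-test holds its type-I error under the null", {
  withr::with_seed(107, {
    rejections <- 0L
    n_sim <- 1000L
    for (i in seq_len(n_sim)) {
      base <- runif(50, 0.7, 0.9)
      a <- base + rnorm(50, sd = 0.02)
      b <- base + rnorm(50, sd = 0.02)
      if (paired_t_test(a, b) < 0.05) rejections <- rejections + 1L
    }
    expect_gt(rejections / n_sim, 0.03)
    expect_lt(rejections / n_sim, 0.07)
  })
})
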