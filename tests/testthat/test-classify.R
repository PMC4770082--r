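test_that("roc/pr curves match the brute-force pairwise oracle, ties included", {
  withr::with_seed(31, {
    for (i in 1:5) {
      n <- sample(20:200, 1)
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
      if (length(unique(labels)) < 2) next
      scores <- sample(seq(-3, 3, by = 0.5), n, replace = TRUE) # heavy ties
      ev <- roc_pr_curves(scores, labels)
      expect_equal(ev$auc_roc, auc_pair_oracle(scores, labels), tolerance = 1e-13)
      # monotone-transform invariance and sign reversal
      ev2 <- roc_pr_curves(exp(scores / 2), labels)
      expect_equal(ev2$auc_roc, ev$auc_roc, tolerance = 1e-13)
      ev3 <- roc_pr_curves(-scores, labels)
      expect_equal(ev3$auc_roc, 1 - ev$auc_roc, tolerance = 1e-13)
    }
  })
  # degenerate/trivial cases
  expect_equal(roc_pr_curves(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE))$auc_roc, 1)
  expect_error(roc_pr_curves(1:4, rep(TRUE, 4)), "both classes")
})

test_that("operating points honour their criteria", {
  perfect <- roc_pr_curves(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  for (cr in c("youden", "specificity", "precision")) {
    op <- operating_points(perfect, cr)
    expect_equal(op$sensitivity, 1)
    expect_equal(op$specificity, 1)
    expect_equal(op$precision, 1)
  }
  # random scores at fixed specificity 0.95: sensitivity near 0.05
  withr::with_seed(8, {
    sens <- vapply(1:200, function(i) {
      ev <- roc_pr_curves(rnorm(200), rep(c(TRUE, FALSE), 100))
      operating_points(ev, "specificity", target = 0.95)$sensitivity
    }, numeric(1))
    expect_equal(mean(sens), 0.05, tolerance = 0.4)
  })
  # infeasible constraint reported, not silently clamped
  one_sided <- roc_pr_curves(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
  op <- operating_points(one_sided, "precision", target = 0.999)
  expect_false(op$feasible)
})

test_that("sensitivity recomputed from confusion counts matches the curve", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  ev <- roc_pr_curves(scores, labels)
  thr <- 0.6
  tp <- sum(scores >= thr & labels); fn <- sum(scores < thr & labels)
  i <- which(ev$roc$threshold == thr)
  expect_equal(ev$roc$tpr[i], tp / (tp + fn))
})

test_that("fold assignment is stratified, disjoint, and standardization is train-only", {
  y <- rep(c(TRUE, FALSE), c(30, 50))
  f <- withr::with_seed(2, embryomech:::make_folds(y, 10))
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f, y)[, "TRUE"] == 3))
  expect_true(all(table(f, y)[, "FALSE"] == 5))
  X <- matrix(rnorm(160), 80, 2)
  st <- embryomech:::standardizer(X[f != 1, , drop = FALSE])
  expect_equal(st$center, colMeans(X[f != 1, ]))
  # out-of-fold discipline: corrupting one fold-1 row must leave the
  # scores of the other fold-1 rows untouched, because their model and
  # standardization are learned from folds 2..k only (a leaky pipeline
  # that standardizes on all rows would shift them)
  i_bad <- which(f == 1)[1]
  X2 <- X; X2[i_bad, ] <- 1e6
  s1 <- embryomech:::oof_scores(X, y, f, 1, 1)
  s2 <- embryomech:::oof_scores(X2, y, f, 1, 1)
  others <- setdiff(which(f == 1), i_bad)
  expect_equal(s1[others], s2[others], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(s1[i_bad], s2[i_bad])))
})

test_that("hyperparameter tuning is deterministic and solves separable data", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
    y <- rep(c(FALSE, TRUE), each = 30)
  })
  t1 <- tune_hyperparams(X, y, seed = 3)
  t2 <- tune_hyperparams(X, y, seed = 3)
  expect_identical(t1[c("cost", "sigma")], t2[c("cost", "sigma")])
  expect_equal(t1$cv_accuracy, 1.0)
  expect_error(tune_hyperparams(X, rep(TRUE, 60), seed = 1), "both classes")
})

test_that("MC cross-validation separates the synthetic cohort and respects seeds", {
  coh <- sample_cohort(cohort_spec("human", n_viable = 40, n_nonviable = 60,
                                  seed = 13))
  fm <- feature_matrix(coh, c("k1", "log_eta1", "k0"))
  m1 <- mc_cross_validate(fm$X, fm$y, cost = 4, sigma = 1, n_mc = 10, seed = 9)
  m2 <- mc_cross_validate(fm$X, fm$y, cost = 4, sigma = 1, n_mc = 10, seed = 9)
  expect_identical(m1$per_rep, m2$per_rep)
  expect_gt(m1$auc_roc_mean, 0.7) # mechanics clearly separate the classes
  # perfectly separated scores give AUC 1 regardless of folds
  Xs <- matrix(c(rnorm(30, -8), rnorm(30, 8)), ncol = 1)
  ys <- rep(c(FALSE, TRUE), each = 30)
  ms <- mc_cross_validate(Xs, ys, cost = 4, sigma = 2, n_mc = 3, seed = 1)
  expect_equal(ms$auc_roc_mean, 1.0)
  expect_equal(ms$auc_pr_mean, 1.0)
})

test_that("label noise degrades AUC monotonically", {
  aucs <- vapply(c(0.05, 0.2, 0.4), function(ln) {
    coh <- sample_cohort(cohort_spec("human", n_viable = 60, n_nonviable = 60,
                                     label_noise = ln, seed = 17))
    fm <- feature_matrix(coh, c("k1", "log_eta1", "k0"))
    mc_cross_validate(fm$X, fm$y, cost = 4, sigma = 1, n_mc = 10, seed = 2)$auc_roc_mean
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("forward selection finds the informative feature first", {
  withr::with_seed(19, {
    n <- 80
    y <- rep(c(TRUE, FALSE), each = n / 2)
    X <- cbind(signal = ifelse(y, 2, -2) + rnorm(n, 0, 0.8),
               noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  })
  path <- forward_feature_select(X, y, seed = 23)
  expect_identical(path$feature[1], "signal")
  # adding pure-noise features must not raise the CV AUC appreciably
  expect_lt(max(path$auc_roc[-1]), path$auc_roc[1] + 0.05)
})

test_that("feature joining is id-safe and column-order independent", {
  coh <- sample_cohort(cohort_spec("human", n_viable = 30, n_nonviable = 30,
                                   seed = 29))
  mech <- feature_matrix(coh, c("k1", "log_eta1", "k0"))
  cc <- feature_matrix(coh, c("c1", "c2"))
  comb <- combine_features(mech, cc)
  expect_identical(colnames(comb$X), c("k1", "log_eta1", "k0", "c1", "c2"))
  bad <- cc; rownames(bad$X)[1] <- "ZZZ"
  expect_error(combine_features(mech, bad), "ZZZ")
  # shuffling columns leaves the CV result unchanged at the same seed
  a <- mc_cross_validate(comb$X, comb$y, cost = 2, sigma = 1, n_mc = 3, seed = 5)
  b <- mc_cross_validate(comb$X[, c(4, 2, 5, 1, 3)], comb$y,
                         cost = 2, sigma = 1, n_mc = 3, seed = 5)
  expect_equal(a$auc_roc_mean, b$auc_roc_mean, tolerance = 1e-12)
  # combining informative modalities does not lose signal
  m_only <- mc_cross_validate(mech$X, mech$y, cost = 2, sigma = 1, n_mc = 5, seed = 7)
  both <- mc_cross_validate(comb$X, comb$y, cost = 2, sigma = 1, n_mc = 5, seed = 7)
  expect_gt(both$auc_roc_mean, m_only$auc_roc_mean - 0.05)
})

test_that("the trained classifier predicts new embryos from the same process", {
  coh <- sample_cohort(cohort_spec("human", n_viable = 50, n_nonviable = 70, seed = 37))
  fm <- feature_matrix(coh, c("k1", "log_eta1", "k0"))
  clf <- train_classifier(fm$X, fm$y, cost = 4, sigma = 1)
  fresh <- sample_cohort(cohort_spec("human", n_viable = 40, n_nonviable = 40, seed = 38))
  fm2 <- feature_matrix(fresh, c("k1", "log_eta1", "k0"))
  s <- predict(clf, fm2$X)
  expect_gt(roc_pr_curves(s, fm2$y)$auc_roc, 0.8)
})
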