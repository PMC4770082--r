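# Viability classification: SVM with an RBF kernel on standardized
# mechanical (and optionally cell-cycle) features, tuned by k-fold
# cross-validation, evaluated by Monte-Carlo repeated CV with pooled
# out-of-fold ROC/PR curves, and ranked by greedy forward feature
# selection. Standardization and tuning only ever see training rows.

#' Build a feature matrix from a cohort table
#'
#' Selects feature columns from a cohort data.frame and applies the
#' conventional transforms: `log_eta1` is the natural log of `eta1`
#' (viscosities separate on a log scale). Mechanical candidates are
#' `k1`, `log_eta1`, `k0`, `eta0`; cell-cycle candidates `c1`, `c2`,
#' `c3`.
#'
#' @param cohort data.frame with cohort columns (see [sample_cohort()]).
#' @param features character vector of feature names to keep.
#' @param label column used as the class label (default `"blastocyst"`).
#' @return list `X` (numeric matrix, rownames = embryo ids), `y`
#'   (logical vector, `TRUE` = viable).
#' @export
feature_matrix <- function(cohort,
                           features = c("k1", "log_eta1", "k0", "eta0"),
                           label = "blastocyst") {
  avail <- cohort
  if ("eta1" %in% names(avail)) avail$log_eta1 <- log(avail$eta1)
  missing <- setdiff(features, names(avail))
  if (length(missing))
    stop("feature_matrix: unknown features: ", paste(missing, collapse = ", "))
  X <- as.matrix(avail[, features, drop = FALSE])
  if (anyNA(X)) stop("feature_matrix: missing values in features")
  rownames(X) <- cohort$embryo_id
  y <- as.logical(cohort[[label]])
  list(X = X, y = y)
}

#' Join mechanical and cell-cycle feature matrices by embryo id
#'
#' @param mechanical,cellcycle outputs of [feature_matrix()] (labels must
#'   agree on shared ids).
#' @return A combined `list(X, y)` on the common embryos.
#' @export
combine_features <- function(mechanical, cellcycle) {
  ida <- rownames(mechanical$X); idb <- rownames(cellcycle$X)
  if (!setequal(ida, idb)) {
    off <- c(setdiff(ida, idb), setdiff(idb, ida))
    stop("combine_features: embryo ids do not match: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  ord <- match(ida, idb)
  if (!all(mechanical$y == cellcycle$y[ord]))
    stop("combine_features: labels disagree between inputs")
  list(X = cbind(mechanical$X, cellcycle$X[ord, , drop = FALSE]),
       y = mechanical$y)
}

# stratified fold assignment; deterministic given the RNG state
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    if (length(i) < k) stop("make_folds: a class has fewer members than folds")
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

# z-scoring parameters learned on training rows only
standardizer <- function(Xtr) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}
apply_standardizer <- function(X, st) scale(X, center = st$center, scale = st$scale)

svm_fit <- function(Xtr, ytr, cost, sigma) {
  e1071::svm(Xtr, factor(ytr, levels = c(FALSE, TRUE)),
             kernel = "radial", gamma = 1 / (2 * sigma^2), cost = cost,
             scale = FALSE)
}

# decision scores oriented so that larger = viable (TRUE)
svm_scores <- function(model, Xte) {
  pr <- stats::predict(model, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (colnames(dv)[1] == "FALSE/TRUE") -dv[, 1] else dv[, 1]
}

# out-of-fold decision scores for one fold assignment
oof_scores <- function(X, y, fold, cost, sigma) {
  scores <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    st <- standardizer(X[tr, , drop = FALSE])
    m <- svm_fit(apply_standardizer(X[tr, , drop = FALSE], st), y[tr], cost, sigma)
    scores[!tr] <- svm_scores(m, apply_standardizer(X[!tr, , drop = FALSE], st))
  }
  scores
}

#' Default RBF-SVM hyperparameter grid
#'
#' Log-spaced grid over the box constraint `c` and kernel width `sigma`
#' (the RBF is `exp(-||u - v||^2 / (2 sigma^2))`).
#'
#' @param cost,sigma grid values.
#' @export
svm_grid <- function(cost = 2^seq(-3, 9, by = 2), sigma = 2^seq(-5, 3, by = 2)) {
  expand.grid(cost = cost, sigma = sigma)
}

#' Tune the SVM box constraint and RBF sigma by k-fold cross-validation
#'
#' Evaluates every grid point by stratified k-fold CV accuracy (threshold
#' at decision value 0) and returns the best point. Ties are broken
#' toward smaller `c`, then larger `sigma` — the smoother model, which
#' guards against overfitting when several settings reach the same CV
#' accuracy.
#'
#' @param X feature matrix; `y` logical labels (both classes present,
#'   each with at least `k_folds` members).
#' @param y logical class labels.
#' @param k_folds folds (default 10).
#' @param grid data.frame `cost`, `sigma` (default [svm_grid()]).
#' @param seed integer seed for the fold assignment.
#' @return list `cost`, `sigma`, `cv_accuracy`, plus the full `grid`
#'   with per-point accuracies.
#' @export
tune_hyperparams <- function(X, y, k_folds = 10, grid = svm_grid(), seed = 1L) {
  if (length(unique(y)) < 2) stop("tune_hyperparams: both classes must be present")
  withr::with_seed(seed, {
    fold <- make_folds(y, k_folds)
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      s <- oof_scores(X, y, fold, grid$cost[i], grid$sigma[i])
      mean((s > 0) == y)
    }, numeric(1))
    grid$cv_accuracy <- acc
    # best accuracy, ties -> smaller c, then larger sigma
    ord <- order(-grid$cv_accuracy, grid$cost, -grid$sigma)
    best <- grid[ord[1], ]
    list(cost = best$cost, sigma = best$sigma, cv_accuracy = best$cv_accuracy,
         grid = grid)
  })
}

#' Train the viability classifier on a full cohort
#'
#' Standardizes the selected features, trains the RBF SVM at the given
#' (or tuned) hyperparameters and returns a self-contained classifier.
#'
#' @param X,y features and logical labels.
#' @param cost,sigma hyperparameters; tuned via [tune_hyperparams()]
#'   when `NULL`.
#' @param seed seed for tuning folds.
#' @return A `trained_classifier`: `model`, `standardizer`, `features`,
#'   `cost`, `sigma`.
#' @export
train_classifier <- function(X, y, cost = NULL, sigma = NULL, seed = 1L) {
  if (is.null(cost) || is.null(sigma)) {
    tuned <- tune_hyperparams(X, y, seed = seed)
    cost <- tuned$cost; sigma <- tuned$sigma
  }
  st <- standardizer(X)
  m <- svm_fit(apply_standardizer(X, st), y, cost, sigma)
  structure(list(model = m, standardizer = st, features = colnames(X),
                 cost = cost, sigma = sigma),
            class = "trained_classifier")
}

#' @rdname train_classifier
#' @param object a `trained_classifier`; `newX` feature matrix.
#' @param newX feature matrix with the training columns.
#' @param ... unused.
#' @export
predict.trained_classifier <- function(object, newX, ...) {
  svm_scores(object$model, apply_standardizer(newX[, object$features, drop = FALSE],
                                              object$standardizer))
}

#' ROC and PR curves with trapezoidal AUCs
#'
#' Sweeps the decision threshold over the unique scores (equal scores
#' collapse into a single threshold, so ties are handled by grouping),
#' anchors the ROC at (0,0) and (1,1), and integrates both curves by the
#' trapezoid rule. The resulting `auc_roc` equals the Mann-Whitney
#' statistic `P(score+ > score-) + 0.5 P(=)`.
#'
#' @param scores real-valued classifier scores (larger = positive).
#' @param labels logical labels, both classes present.
#' @return An `eval_result`: `roc` (data.frame `fpr`, `tpr`,
#'   `threshold`), `pr` (`recall`, `precision`, `threshold`), `auc_roc`,
#'   `auc_pr`.
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("roc_pr_curves: both classes must be present")
  np <- sum(labels); nn <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  # cumulative counts predicted positive at score >= t
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  roc <- data.frame(fpr = c(fpr, 1), tpr = c(tpr, 1),
                    threshold = c(Inf, thr, -Inf))
  auc_roc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  prec <- tp / pmax(tp + fp, 1)
  rec <- tp / np
  pr <- data.frame(recall = c(0, rec), precision = c(prec[1], prec),
                   threshold = c(Inf, thr))
  auc_pr <- sum(diff(pr$recall) * (utils::head(pr$precision, -1) + utils::tail(pr$precision, -1)) / 2)
  structure(list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> AUC_ROC =", round(x$auc_roc, 4),
      " AUC_PR =", round(x$auc_pr, 4), "\n")
  invisible(x)
}

#' Operating point of a classifier at a chosen criterion
#'
#' @param eval an [roc_pr_curves()] result.
#' @param criterion `"youden"` (maximise sensitivity + specificity - 1),
#'   `"specificity"` (highest sensitivity subject to specificity >=
#'   `target`), or `"precision"` (highest recall subject to precision >=
#'   `target`).
#' @param target constraint level for the two constrained criteria.
#' @return list `sensitivity`, `specificity`, `precision`, `threshold`,
#'   `criterion`; `feasible = FALSE` (with all-NA metrics) when the
#'   constraint cannot be met.
#' @export
operating_points <- function(eval, criterion = c("youden", "specificity", "precision"),
                             target = 0.95) {
  criterion <- match.arg(criterion)
  roc <- eval$roc; pr <- eval$pr
  # align precision with roc rows via thresholds (roc has one extra anchor)
  prec_at <- function(thr) {
    i <- match(thr, pr$threshold)
    ifelse(is.na(i), NA_real_, pr$precision[i])
  }
  spec <- 1 - roc$fpr
  sens <- roc$tpr
  cand <- switch(criterion,
    youden = which.max(sens + spec - 1),
    specificity = {
      ok <- which(spec >= target)
      if (!length(ok)) NA_integer_ else ok[which.max(sens[ok])]
    },
    precision = {
      okp <- which(pr$precision >= target & is.finite(pr$threshold))
      if (!length(okp)) NA_integer_
      else match(pr$threshold[okp[which.max(pr$recall[okp])]], roc$threshold)
    })
  if (is.na(cand))
    return(list(sensitivity = NA_real_, specificity = NA_real_,
                precision = NA_real_, threshold = NA_real_,
                criterion = criterion, feasible = FALSE))
  list(sensitivity = sens[cand], specificity = spec[cand],
       precision = prec_at(roc$threshold[cand]), threshold = roc$threshold[cand],
       criterion = criterion, feasible = TRUE)
}

#' Monte-Carlo repeated cross-validated ROC/PR evaluation
#'
#' Repeats stratified k-fold cross-validation `n_mc` times with
#' reshuffled fold assignments. Within each repetition the out-of-fold
#' decision scores of all embryos are pooled into one ROC and one PR
#' curve; the function returns the across-repetition mean and s.d. of
#' both AUCs, plus the pooled curves of the first repetition for
#' plotting.
#'
#' @param X,y features and logical labels.
#' @param cost,sigma SVM hyperparameters (tune first with
#'   [tune_hyperparams()]).
#' @param n_mc Monte-Carlo repetitions (default 100).
#' @param k_folds folds per repetition (default 10).
#' @param seed integer seed.
#' @return list `auc_roc_mean`, `auc_roc_sd`, `auc_pr_mean`, `auc_pr_sd`,
#'   `per_rep` (data.frame), `curves` (first repetition `eval_result`).
#' @export
mc_cross_validate <- function(X, y, cost = 1, sigma = 1, n_mc = 100,
                              k_folds = 10, seed = 1L) {
  if (length(unique(y)) < 2) stop("mc_cross_validate: both classes must be present")
  withr::with_seed(seed, {
    reps <- lapply(seq_len(n_mc), function(r) {
      fold <- make_folds(y, k_folds)
      s <- oof_scores(X, y, fold, cost, sigma)
      roc_pr_curves(s, y)
    })
    aucs <- data.frame(rep = seq_len(n_mc),
                       auc_roc = vapply(reps, `[[`, numeric(1), "auc_roc"),
                       auc_pr = vapply(reps, `[[`, numeric(1), "auc_pr"))
    list(auc_roc_mean = mean(aucs$auc_roc), auc_roc_sd = stats::sd(aucs$auc_roc),
         auc_pr_mean = mean(aucs$auc_pr), auc_pr_sd = stats::sd(aucs$auc_pr),
         per_rep = aucs, curves = reps[[1]])
  })
}

#' Greedy forward feature selection by cross-validated AUC
#'
#' Starting from the empty set, each remaining feature is tried in turn:
#' hyperparameters are re-tuned for the candidate feature set and its
#' stratified k-fold out-of-fold AUC_ROC computed; the feature giving the
#' largest AUC is added. The loop continues until every feature is
#' ranked, so the full AUC-vs-size path is returned and the optimal
#' number of features can be read off the plateau.
#'
#' Within a step, every candidate is evaluated on the same `n_rep` fold
#' assignments (a paired design): the dominant noise source — which rows
#' land in which fold — then cancels out of the candidate comparison,
#' which stabilises the greedy choice far more than extra repetitions
#' would.
#'
#' @param X,y features and logical labels.
#' @param k_folds folds for both tuning and evaluation.
#' @param grid hyperparameter grid (smaller than the default tuning grid
#'   to keep the inner re-tuning affordable).
#' @param n_rep fold reshuffles averaged per candidate evaluation
#'   (default 3; the paired design makes additional repetitions largely
#'   unproductive).
#' @param seed integer seed.
#' @return data.frame `step`, `feature`, `auc_roc` (CV AUC of the set up
#'   to and including that feature).
#' @export
forward_feature_select <- function(X, y, k_folds = 10,
                                   grid = svm_grid(cost = 2^c(-1, 3, 7),
                                                   sigma = 2^c(-3, 0, 3)),
                                   n_rep = 3, seed = 1L) {
  if (ncol(X) < 2) stop("forward_feature_select: need >= 2 candidate features")
  withr::with_seed(seed, {
    remaining <- colnames(X)
    chosen <- character(0)
    path <- data.frame(step = integer(0), feature = character(0),
                       auc_roc = numeric(0))
    while (length(remaining)) {
      # shared fold assignments across this step's candidates
      tune_seed <- sample.int(2^30, 1)
      folds <- replicate(n_rep, make_folds(y, k_folds), simplify = FALSE)
      aucs <- vapply(remaining, function(f) {
        Xs <- X[, c(chosen, f), drop = FALSE]
        tuned <- tune_hyperparams(Xs, y, k_folds = k_folds, grid = grid,
                                  seed = tune_seed)
        mean(vapply(folds, function(fd)
          roc_pr_curves(oof_scores(Xs, y, fd, tuned$cost, tuned$sigma), y)$auc_roc,
          numeric(1)))
      }, numeric(1))
      best <- remaining[which.max(aucs)]
      chosen <- c(chosen, best)
      remaining <- setdiff(remaining, best)
      path <- rbind(path, data.frame(step = length(chosen), feature = best,
                                     auc_roc = max(aucs)))
    }
    path
  })
}
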