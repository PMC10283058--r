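#' The seven classification algorithms of the model comparison
#' @export
ML_ALGORITHMS <- c("SVM", "DT", "NB", "Logi", "LDA", "KNN", "LASSO")

#' Stratified discovery/validation split
#'
#' Randomly partitions samples into discovery and validation sets at
#' the requested ratio within each class (default 2:1), reproducibly
#' under a seed. Per-class discovery counts are `round(ratio * n)`, so
#' they sit within one sample of the exact ratio.
#'
#' @param ids sample identifiers.
#' @param labels class labels, same length.
#' @param ratio discovery fraction (default 2/3).
#' @param seed integer seed.
#' @return list of class `split_plan`: discovery, validation, ratio,
#'   seed, per-class counts.
#' @export
split_discovery_validation <- function(ids, labels, ratio = 2 / 3,
                                       seed = 1L) {
  stopifnot(length(ids) == length(labels))
  labels <- factor(labels)
  small <- table(labels) < 3
  if (any(small))
    stop("classes with < 3 samples: ",
         paste(names(small)[small], collapse = ", "))
  set.seed(seed)
  disc <- unlist(lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    sample(idx, round(ratio * length(idx)))
  }))
  plan <- list(discovery = ids[sort(disc)],
               validation = ids[setdiff(seq_along(ids), disc)],
               ratio = ratio, seed = seed,
               counts = table(labels, seq_along(ids) %in% disc))
  class(plan) <- "split_plan"
  plan
}

# internal stratified-CV accuracy of a fit/predict pair, for grids
.cv_accuracy <- function(x, y, fit_predict, folds) {
  fold <- .stratified_folds(y, folds)
  correct <- 0L
  for (f in seq_len(max(fold))) {
    tr <- fold != f; te <- fold == f
    pr <- fit_predict(x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE])
    correct <- correct + sum(pr == y[te])
  }
  correct / length(y)
}

#' Train one of the seven pairwise classifiers
#'
#' Fits a binary classifier on discovery data, choosing
#' hyperparameters (where the algorithm has any) by stratified k-fold
#' cross-validation on the discovery set only. Grids: SVM — linear and
#' radial kernels, cost in {0.1, 1, 10}; KNN — k in {3, 5, 7, 9}; DT —
#' cost-complexity pruning at the CV-minimal error; LASSO — lambda
#' path by `cv.glmnet`. NB, Logi and LDA have no tuned parameters.
#' Constant-feature-only input falls back to a flagged majority-class
#' scorer.
#'
#' @param algorithm one of [ML_ALGORITHMS].
#' @param mat discovery samples x features matrix.
#' @param labels binary labels (factor; second level = positive).
#' @param folds CV folds for hyperparameter choice (default 10).
#' @param seed seed for fold assignment.
#' @return object of class `pairwise_model` with `$score(newdata)`
#'   returning positive-class probabilities in `[0, 1]`, `$predict
#'   (newdata)` returning labels at 0.5, and fields algorithm, levels,
#'   hyperparameters.
#' @export
train_pairwise <- function(algorithm, mat, labels, folds = 10L, seed = 1L) {
  algorithm <- match.arg(algorithm, ML_ALGORITHMS)
  y <- factor(labels)
  stopifnot(nlevels(y) == 2)
  folds <- min(folds, min(table(y)))
  set.seed(seed)
  pos <- levels(y)[2]
  x <- as.matrix(mat)

  informative <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!any(informative)) {
    maj <- names(which.max(table(y)))
    p_pos <- mean(y == pos)
    obj <- list(algorithm = algorithm, levels = levels(y),
                hyperparameters = list(degenerate = "majority-class"),
                score = function(newdata)
                  rep(p_pos, nrow(as.matrix(newdata))),
                fallback_majority = maj)
    obj$predict <- function(newdata)
      factor(rep(maj, nrow(as.matrix(newdata))), levels = levels(y))
    class(obj) <- "pairwise_model"
    return(obj)
  }
  x <- x[, informative, drop = FALSE]
  keep_cols <- colnames(x)

  hyper <- list()
  score_fun <- switch(algorithm,
    SVM = {
      grid <- expand.grid(kernel = c("linear", "radial"),
                          cost = c(0.1, 1, 10),
                          stringsAsFactors = FALSE)
      acc <- vapply(seq_len(nrow(grid)), function(g) {
        .cv_accuracy(x, y, function(xt, yt, xv) {
          fit <- e1071::svm(xt, yt, kernel = grid$kernel[g],
                            cost = grid$cost[g])
          stats::predict(fit, xv)
        }, folds)
      }, numeric(1))
      best <- which.max(acc)
      hyper <- list(kernel = grid$kernel[best], cost = grid$cost[best],
                    cv_accuracy = acc[best])
      fit <- e1071::svm(x, y, kernel = grid$kernel[best],
                        cost = grid$cost[best], probability = TRUE)
      function(newdata) {
        pr <- stats::predict(fit, newdata[, keep_cols, drop = FALSE],
                             probability = TRUE)
        attr(pr, "probabilities")[, pos]
      }
    },
    DT = {
      fit <- rpart::rpart(y ~ ., data = data.frame(x, y = y),
                          method = "class",
                          control = rpart::rpart.control(xval = folds,
                                                         cp = 1e-4))
      cp_tab <- fit$cptable
      best_cp <- cp_tab[which.min(cp_tab[, "xerror"]), "CP"]
      fit <- rpart::prune(fit, cp = best_cp)
      hyper <- list(cp = best_cp)
      function(newdata)
        stats::predict(fit, data.frame(newdata[, keep_cols,
                                               drop = FALSE]))[, pos]
    },
    NB = {
      fit <- e1071::naiveBayes(x, y)
      function(newdata)
        stats::predict(fit, newdata[, keep_cols, drop = FALSE],
                       type = "raw")[, pos]
    },
    Logi = {
      df <- data.frame(x, y = y)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      function(newdata)
        suppressWarnings(stats::predict(fit,
          data.frame(newdata[, keep_cols, drop = FALSE]),
          type = "response"))
    },
    LDA = {
      fit <- suppressWarnings(MASS::lda(x, grouping = y))
      function(newdata)
        stats::predict(fit,
                       newdata[, keep_cols, drop = FALSE])$posterior[, pos]
    },
    KNN = {
      ks <- c(3L, 5L, 7L, 9L)
      ks <- ks[ks <= nrow(x) - ceiling(nrow(x) / folds)]
      if (!length(ks)) ks <- 1L
      acc <- vapply(ks, function(k) {
        .cv_accuracy(x, y, function(xt, yt, xv)
          class::knn(xt, xv, yt, k = k), folds)
      }, numeric(1))
      k_best <- ks[which.max(acc)]
      hyper <- list(k = k_best, cv_accuracy = max(acc))
      function(newdata) {
        pr <- class::knn(x, newdata[, keep_cols, drop = FALSE], y,
                         k = k_best, prob = TRUE)
        vote <- attr(pr, "prob")
        ifelse(pr == pos, vote, 1 - vote)
      }
    },
    LASSO = {
      fit <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = folds,
                               type.measure = "deviance")
      hyper <- list(lambda = fit$lambda.min)
      function(newdata)
        drop(stats::predict(fit, newdata[, keep_cols, drop = FALSE],
                            s = "lambda.min", type = "response"))
    })

  obj <- list(algorithm = algorithm, levels = levels(y),
              hyperparameters = hyper, score = score_fun)
  obj$predict <- function(newdata) {
    s <- obj$score(as.matrix(newdata))
    factor(ifelse(s >= 0.5, levels(y)[2], levels(y)[1]),
           levels = levels(y))
  }
  class(obj) <- "pairwise_model"
  obj
}

#' Classifier evaluation report
#'
#' Confusion matrix plus accuracy, precision, recall/sensitivity,
#' specificity, F-measure, Cohen's kappa (chance agreement from the
#' marginals) and, when scores are supplied, AUC by the rank
#' (Mann-Whitney) formulation with ties counted one half, along with
#' ROC points swept over the observed score thresholds.
#'
#' @param truth true binary labels (factor; second level = positive).
#' @param predicted predicted labels (optional if `scores` given;
#'   then thresholded at `cutoff`).
#' @param scores positive-class scores in `[0, 1]` (optional).
#' @param cutoff threshold for labels from scores (default 0.5,
#'   `>=` = positive).
#' @return list of class `evaluation_report`.
#' @export
evaluate <- function(truth, predicted = NULL, scores = NULL,
                     cutoff = 0.5) {
  truth <- factor(truth)
  stopifnot(nlevels(truth) == 2)
  lv <- levels(truth); pos <- lv[2]
  if (is.null(predicted)) {
    if (is.null(scores)) stop("need predicted labels or scores")
    predicted <- factor(ifelse(scores >= cutoff, lv[2], lv[1]),
                        levels = lv)
  } else predicted <- factor(predicted, levels = lv)
  stopifnot(length(predicted) == length(truth))
  cm <- table(truth = truth, predicted = predicted)
  tp <- cm[pos, pos]; tn <- cm[lv[1], lv[1]]
  fp <- cm[lv[1], pos]; fn <- cm[pos, lv[1]]
  n <- sum(cm)
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else 0

  auc <- NA_real_; roc <- NULL
  flag <- character()
  if (length(unique(truth)) < 2) flag <- "single true class: AUC undefined"
  if (!is.null(scores) && length(unique(truth)) == 2) {
    auc <- auc_rank(scores, truth == pos)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    roc <- t(vapply(thr, function(t0) {
      pred_pos <- scores >= t0
      c(threshold = t0,
        fpr = sum(pred_pos & truth != pos) / sum(truth != pos),
        tpr = sum(pred_pos & truth == pos) / sum(truth == pos))
    }, numeric(3)))
  }
  structure(list(confusion = cm, accuracy = accuracy,
                 precision = precision, recall = recall,
                 sensitivity = recall, specificity = specificity,
                 f_measure = f1, kappa = kappa, auc = auc,
                 roc = roc, n = n, flags = flag),
            class = "evaluation_report")
}

#' Area under the ROC curve by the rank formulation
#'
#' Mann-Whitney statistic: mean over positive/negative pairs of the
#' indicator that the positive scores higher, ties counted one half.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores.
#' @param positive logical, TRUE for positive instances.
#' @return AUC in `[0, 1]`; NA if either class is absent.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation on", x$n, "samples\n")
  print(x$confusion)
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  specificity %.3f\n",
              x$accuracy, x$precision, x$recall, x$specificity))
  cat(sprintf("F-measure %.3f  kappa %.3f  AUC %s\n", x$f_measure, x$kappa,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

# per-feature z-scoring with statistics learned on one (discovery) set
.block_standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

#' Single- versus multi-omics pairwise prediction comparison
#'
#' For each algorithm and each feature source — metabolites alone,
#' peptides alone, and their combination (concatenated after
#' per-feature z-scoring within each modality block, so neither
#' block's intensity scale dominates) — trains on the discovery split
#' and evaluates on validation, reporting the per-algorithm metrics
#' and the across-algorithm mean accuracy per source.
#'
#' @param met,pep samples x features matrices (same row order),
#'   log2 intensities recommended.
#' @param labels binary labels.
#' @param algorithms subset of [ML_ALGORITHMS] (default all seven).
#' @param split a `split_plan` from [split_discovery_validation()];
#'   if NULL one is created from `seed`.
#' @param folds CV folds (default 10).
#' @param seed seed for splitting and fold draws.
#' @return list: `metrics` tibble (algorithm, source, accuracy,
#'   f_measure, kappa, precision, auc), `mean_accuracy` named vector
#'   over sources, `split`.
#' @export
compare_single_vs_multiomics <- function(met, pep, labels,
                                         algorithms = ML_ALGORITHMS,
                                         split = NULL, folds = 10L,
                                         seed = 1L) {
  if (!identical(rownames(met), rownames(pep)))
    stop("sample ids differ between modalities: ",
         paste(utils::head(c(setdiff(rownames(met), rownames(pep)),
                             setdiff(rownames(pep), rownames(met)))),
               collapse = ", "))
  y <- factor(labels)
  ids <- rownames(met)
  if (is.null(split))
    split <- split_discovery_validation(ids, y, seed = seed)
  tr <- ids %in% split$discovery
  te <- !tr
  y_tr <- droplevels(y[tr]); y_te <- factor(y[te], levels = levels(y_tr))

  met_z <- .block_standardize(met[tr, , drop = FALSE],
                              met[te, , drop = FALSE])
  pep_z <- .block_standardize(pep[tr, , drop = FALSE],
                              pep[te, , drop = FALSE])
  sources <- list(
    met = list(train = met_z$train, test = met_z$test),
    pep = list(train = pep_z$train, test = pep_z$test),
    combined = list(train = cbind(met_z$train, pep_z$train),
                    test = cbind(met_z$test, pep_z$test)))

  rows <- list()
  for (alg in algorithms) {
    for (src in names(sources)) {
      mdl <- train_pairwise(alg, sources[[src]]$train, y_tr,
                            folds = folds, seed = seed)
      sc <- mdl$score(sources[[src]]$test)
      ev <- evaluate(y_te, scores = sc)
      rows[[paste(alg, src)]] <- tibble::tibble(
        algorithm = alg, source = src, accuracy = ev$accuracy,
        precision = ev$precision, f_measure = ev$f_measure,
        kappa = ev$kappa, auc = ev$auc)
    }
  }
  metrics <- do.call(rbind, rows)
  mean_acc <- tapply(metrics$accuracy, metrics$source, mean)
  list(metrics = metrics,
       mean_accuracy = mean_acc[c("met", "pep", "combined")],
       split = split)
}
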