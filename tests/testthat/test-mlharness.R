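test_that("stratified splitting respects the 2:1 contract and seed", {
  ids <- paste0("s", 1:18)
  y <- rep(c("HC", "T2DM"), each = 9)
  p1 <- split_discovery_validation(ids, y, seed = 5)
  expect_length(p1$discovery, 12L)
  expect_length(p1$validation, 6L)
  expect_setequal(c(p1$discovery, p1$validation), ids)
  tab <- table(y[match(p1$discovery, ids)])
  expect_equal(as.vector(tab), c(6L, 6L))
  p2 <- split_discovery_validation(ids, y, seed = 5)
  expect_identical(p1$discovery, p2$discovery)
  # 10 per class: within one of the exact ratio
  ids2 <- paste0("s", 1:20)
  y2 <- rep(c("a", "b"), each = 10)
  p3 <- split_discovery_validation(ids2, y2, seed = 1)
  n_disc <- table(y2[match(p3$discovery, ids2)])
  expect_true(all(abs(n_disc - 20 / 3) <= 1))
  expect_error(split_discovery_validation(paste0("s", 1:5),
                                          c("a", "a", "a", "b", "b")),
               "b")
})

test_that("evaluation metrics match hand-worked confusion matrices", {
  # confusion [[45,5],[10,40]] with balanced marginals
  truth <- factor(rep(c("neg", "pos"), each = 50), levels = c("neg",
                                                              "pos"))
  pred <- factor(c(rep("neg", 45), rep("pos", 5),
                   rep("neg", 10), rep("pos", 40)),
                 levels = c("neg", "pos"))
  ev <- evaluate(truth, pred)
  expect_equal(ev$accuracy, 0.85)
  expect_equal(ev$kappa, 0.70, tolerance = 1e-12)
  # TP=40, FP=10, FN=5 (TN free): precision 0.8, F = 2PR/(P+R)
  truth2 <- factor(c(rep("pos", 45), rep("neg", 55)),
                   levels = c("neg", "pos"))
  pred2 <- factor(c(rep("pos", 40), rep("neg", 5),
                    rep("pos", 10), rep("neg", 45)),
                  levels = c("neg", "pos"))
  ev2 <- evaluate(truth2, pred2)
  expect_equal(ev2$precision, 0.8)
  expect_equal(ev2$f_measure, 2 * 0.8 * (40 / 45) / (0.8 + 40 / 45),
               tolerance = 1e-12)
  expect_equal(round(ev2$f_measure, 3), 0.842)
  # perfect scores
  ev3 <- evaluate(truth, scores = as.numeric(truth == "pos"))
  expect_equal(ev3$auc, 1)
  expect_equal(ev3$accuracy, 1)
  expect_equal(ev3$kappa, 1)
})

test_that("metrics agree with brute force on random confusion matrices", {
  set.seed(7)
  for (i in 1:200) {
    cm <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (sum(cm) == 0 || any(rowSums(cm) == 0)) next
    truth <- factor(rep(c("neg", "pos"), rowSums(cm)),
                    levels = c("neg", "pos"))
    pred <- factor(c(rep(c("neg", "pos"), cm[1, ]),
                     rep(c("neg", "pos"), cm[2, ])),
                   levels = c("neg", "pos"))
    ev <- evaluate(truth, pred)
    expect_equal(ev$kappa, bf_kappa(table(truth, pred)), tolerance = 1e-12)
    expect_equal(ev$accuracy, sum(diag(cm)) / sum(cm))
  }
})

test_that("rank AUC equals the pair-counting oracle and is monotone-invariant", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    sc <- round(runif(n), 2)          # force some ties
    pos <- runif(n) > 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(sc, pos), bf_auc(sc, pos), tolerance = 1e-12)
    expect_equal(auc_rank(qlogis(pmin(pmax(sc, 1e-6), 1 - 1e-6)), pos),
                 auc_rank(sc, pos), tolerance = 1e-12)
  }
  expect_true(is.na(auc_rank(runif(5), rep(TRUE, 5))))
})

make_pair_data <- function(n_per = 30, p_signal = 6, p_noise = 24,
                           delta = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  x <- matrix(rnorm(n * (p_signal + p_noise)), n)
  y <- factor(rep(c("ctrl", "case"), each = n_per),
              levels = c("ctrl", "case"))
  x[y == "case", seq_len(p_signal)] <-
    x[y == "case", seq_len(p_signal)] + delta
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  rownames(x) <- paste0("s", seq_len(n))
  list(x = x, y = y)
}

test_that("all seven algorithms learn a separable problem", {
  d <- make_pair_data(n_per = 45, delta = 4, seed = 11)
  plan <- split_discovery_validation(rownames(d$x), d$y, seed = 11)
  tr <- rownames(d$x) %in% plan$discovery
  for (alg in ML_ALGORITHMS) {
    mdl <- train_pairwise(alg, d$x[tr, ], d$y[tr], seed = 3)
    sc <- mdl$score(d$x[!tr, ])
    expect_true(all(sc >= 0 & sc <= 1), label = alg)
    ev <- evaluate(d$y[!tr], scores = sc)
    expect_gte(ev$accuracy, 0.95)
  }
})

test_that("shuffled labels give chance-level validation accuracy", {
  d <- make_pair_data(n_per = 40, delta = 3, seed = 13)
  set.seed(13)
  y_perm <- sample(d$y)
  plan <- split_discovery_validation(rownames(d$x), y_perm, seed = 13)
  tr <- rownames(d$x) %in% plan$discovery
  for (alg in c("SVM", "LDA", "KNN", "LASSO")) {
    # glmnet may emit convergence chatter on label-free data
    mdl <- suppressWarnings(train_pairwise(alg, d$x[tr, ], y_perm[tr],
                                           seed = 5))
    ev <- evaluate(y_perm[!tr], predicted = mdl$predict(d$x[!tr, ]))
    # n = 27 validation samples: 3 binomial SDs around 0.5
    expect_gt(ev$accuracy, 0.5 - 3 * sqrt(0.25 / 27))
    expect_lt(ev$accuracy, 0.5 + 3 * sqrt(0.25 / 27))
  }
})

test_that("constant features trigger the flagged majority fallback", {
  x <- matrix(1, 20, 4, dimnames = list(paste0("s", 1:20),
                                        paste0("f", 1:4)))
  y <- factor(rep(c("a", "b"), c(14, 6)))
  mdl <- train_pairwise("SVM", x, y, seed = 1)
  expect_equal(mdl$hyperparameters$degenerate, "majority-class")
  expect_true(all(mdl$predict(x) == "a"))
})

test_that("discovery-only CV is immune to a validation-leakage canary", {
  # a feature equal to the labels on validation rows only must not
  # lift discovery-CV accuracy above the no-signal baseline
  d <- make_pair_data(n_per = 30, p_signal = 0, p_noise = 10, seed = 17)
  plan <- split_discovery_validation(rownames(d$x), d$y, seed = 17)
  tr <- rownames(d$x) %in% plan$discovery
  canary <- numeric(nrow(d$x))
  canary[!tr] <- as.numeric(d$y[!tr] == "case")
  x2 <- cbind(d$x, canary = canary)
  mdl <- train_pairwise("KNN", x2[tr, ], d$y[tr], seed = 7)
  expect_lt(mdl$hyperparameters$cv_accuracy, 0.75)
})

test_that("multi-omics fusion behaves on duplicated and mismatched input", {
  d <- make_pair_data(n_per = 24, p_signal = 4, p_noise = 8, delta = 2.5,
                      seed = 19)
  cmp <- compare_single_vs_multiomics(d$x, d$x, d$y,
                                      algorithms = c("LDA", "LASSO"),
                                      seed = 19)
  # identical modalities: combined equals single within seed noise
  expect_lt(abs(cmp$mean_accuracy[["combined"]] -
                  cmp$mean_accuracy[["met"]]), 0.1)
  bad <- d$x; rownames(bad)[1] <- "zzz"
  expect_error(compare_single_vs_multiomics(d$x, bad, d$y), "differ")
})
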