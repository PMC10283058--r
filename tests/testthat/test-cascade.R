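make_layer <- function(panel, coefficients, intercept, cutoff, index = 1L,
                       semantics = "disease") {
  list(index = index, panel = panel, coefficients = coefficients,
       intercept = intercept, cutoff = cutoff, lambda = 0.01,
       rule = "1se", positive_semantics = semantics)
}

# hand-built cascade on three score features, linear in each layer
toy_cascade <- function() {
  structure(list(
    layers = list(
      make_layer("g1", c(g1 = 4), 0, 0.5, 1L, "disease"),
      make_layer("g2", c(g2 = 4), 0, 0.5, 2L, "DKD"),
      make_layer("g3", c(g3 = 4), 0, 0.5, 3L, "EARLY_DKD")),
    log2_transform = FALSE,
    provenance = list(seed = 1L, folds = 10L, lambda_rule = "1se",
                      cutoff_method = "youden",
                      survivor_training = FALSE)),
    class = "cascade_model")
}

test_that("routing follows the layered stop rules", {
  m <- toy_cascade()
  x <- rbind(hc    = c(g1 = -2, g2 =  2, g3 =  2),
             t2dm  = c(g1 =  2, g2 = -2, g3 =  2),
             early = c(g1 =  2, g2 =  2, g3 =  2),
             other = c(g1 =  2, g2 =  2, g3 = -2),
             at_cut = c(g1 = 0, g2 =  2, g3 =  2))
  pr <- predict_cascade(m, x)
  expect_equal(as.character(pr$terminal),
               c("HC", "T2DM", "EARLY_DKD", "DKD_OTHER", "EARLY_DKD"))
  expect_equal(pr$stopped_at, c(1L, 2L, 3L, 3L, 3L))
  # layers beyond the stop are never scored
  expect_true(is.na(pr$score2[1]))
  expect_true(is.na(pr$score3[2]))
  # score exactly at the cutoff routes positive (>= semantics)
  expect_equal(pr$score1[5], 0.5)
  expect_false(pr$terminal[5] == "HC")
})

test_that("terminal labels partition any input", {
  set.seed(1)
  m <- toy_cascade()
  x <- matrix(rnorm(300 * 3), 300, 3,
              dimnames = list(NULL, c("g1", "g2", "g3")))
  pr <- predict_cascade(m, x)
  expect_equal(nrow(pr), 300L)
  expect_false(anyNA(pr$terminal))
  expect_equal(sum(table(pr$terminal)), 300L)
})

test_that("increasing a positively weighted feature never lowers the score", {
  m <- toy_cascade()
  x <- matrix(seq(-3, 3, length.out = 50), ncol = 1,
              dimnames = list(NULL, "g1"))
  x <- cbind(x, g2 = 0, g3 = 0)
  pr <- predict_cascade(m, x)
  expect_true(all(diff(pr$score1) >= 0))
  # missing panel features are an error
  expect_error(predict_cascade(m, x[, 1:2]), "missing panel")
})

test_that("cutoff selection matches an exhaustive threshold scan", {
  sc <- c(0.1, 0.2, 0.8, 0.9)
  pos <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(as.numeric(choose_cutoff(sc, pos)), 0.8)
  expect_equal(as.numeric(choose_cutoff(sc, pos, method = "fixed")), 0.5)
  # identical distributions: uninformative flag, median returned
  sc2 <- rep(c(0.3, 0.6), 4)
  cut2 <- choose_cutoff(sc2, rep(c(TRUE, FALSE), each = 4))
  expect_true("uninformative" %in% attr(cut2, "flags"))
  expect_equal(as.numeric(cut2), median(sc2))
  # single positive: its score, flagged low-n
  cut3 <- choose_cutoff(c(0.2, 0.3, 0.9), c(FALSE, FALSE, TRUE))
  expect_equal(as.numeric(cut3), 0.9)
  expect_true("low_n" %in% attr(cut3, "flags"))
  expect_error(choose_cutoff(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
  # random instances against a brute-force scan over observed scores
  set.seed(2)
  for (i in 1:50) {
    s <- round(runif(20), 2)
    p <- runif(20) > 0.5
    if (!any(p) || all(p)) next
    thr <- sort(unique(s))
    j <- vapply(thr, function(t0)
      mean(s[p] >= t0) + mean(s[!p] < t0) - 1, numeric(1))
    if (max(j) <= 0) next
    expect_equal(as.numeric(choose_cutoff(s, p)),
                 thr[which(j == max(j))[1]])
  }
})

test_that("LASSO panel selection finds a planted predictor among noise", {
  set.seed(3)
  hits <- vapply(1:10, function(i) {
    n <- 80
    x <- matrix(rnorm(n * 200), n, 200,
                dimnames = list(NULL, paste0("f", 1:200)))
    y <- factor(rep(c("a", "b"), each = n / 2))
    x[y == "b", 1] <- x[y == "b", 1] + 3
    sel <- select_panel_lasso(x, y, seed = i)
    "f1" %in% sel$panel
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("duplicated informative features split the L1 coefficient mass", {
  set.seed(4)
  n <- 100
  sig <- rnorm(n)
  y <- factor(ifelse(sig + rnorm(n, 0, 0.5) > 0, "b", "a"))
  x1 <- cbind(s = sig, matrix(rnorm(n * 4), n, 4))
  colnames(x1) <- c("s", paste0("n", 1:4))
  f1 <- select_panel_lasso(x1, y, lambda_rule = "min", seed = 1)
  x2 <- cbind(s1 = sig, s2 = sig, matrix(rnorm(n * 4), n, 4))
  colnames(x2) <- c("s1", "s2", paste0("n", 1:4))
  f2 <- select_panel_lasso(x2, y, lambda_rule = "min", seed = 1)
  dup_mass <- sum(abs(f2$coefficients[intersect(c("s1", "s2"),
                                                names(f2$coefficients))]))
  single_mass <- abs(f1$coefficients[["s"]])
  expect_lt(abs(dup_mass - single_mass) / single_mass, 0.5)
})

test_that("an all-noise panel is rejected with the last useful lambda", {
  set.seed(5)
  x <- matrix(rnorm(60 * 100), 60, 100,
              dimnames = list(NULL, paste0("f", 1:100)))
  y <- factor(rep(c("a", "b"), each = 30))
  expect_error(select_panel_lasso(x, y, lambda_rule = "1se", seed = 1),
               "nonempty panel")
})

test_that("cascade fitting demands all five groups", {
  set.seed(6)
  x <- matrix(2^rnorm(40 * 10, 10, 1), 40, 10,
              dimnames = list(paste0("s", 1:40), paste0("f", 1:10)))
  expect_error(fit_cascade(x, rep("HC", 40)), "missing")
  expect_error(fit_cascade(x, rep(c("HC", "T2DM"), 20)), "missing")
})

test_that("fitted cascade recovers the planted stage structure", {
  cfg <- cohort_config(n_per_group = c(HC = 60, T2DM = 60, GREY = 20,
                                       EARLY_DKD = 45, OVERT_DKD = 30),
                       n_met_features = 80, n_pep_features = 60,
                       n_qc_per_batch = 2, seed = 21)
  co <- generate_cohort(cfg)
  cm <- cohort_matrix(co)
  plan <- split_discovery_validation(names(cm$groups), cm$groups,
                                     seed = 21)
  set.seed(21)
  model <- fit_cascade(cm$mat[plan$discovery, ], cm$groups[plan$discovery],
                       seed = 21)
  for (l in model$layers) expect_lte(length(l$panel), 40L)
  pred <- predict_cascade(model, cm$mat[plan$validation, ])
  truth <- cascade_truth(cm$groups[plan$validation])
  expect_gt(macro_recall(truth, pred$terminal), 0.6)
  gz <- grey_zone_report(model, cm$mat[plan$validation, ],
                         cm$groups[plan$validation])
  expect_gte(gz$grey_routed_past_layer2, 0)
  expect_equal(gz$n_grey, sum(cm$groups[plan$validation] == "GREY"))
  expect_error(grey_zone_report(model, cm$mat[1:4, ],
                                rep("T2DM", 4)), "GREY")
})

test_that("JSON serialization round-trips to identical predictions", {
  m <- toy_cascade()
  path <- tempfile(fileext = ".json")
  cascade_to_json(m, path)
  m2 <- cascade_from_json(path)
  set.seed(7)
  x <- matrix(rnorm(1000 * 3), 1000, 3,
              dimnames = list(NULL, c("g1", "g2", "g3")))
  p1 <- predict_cascade(m, x)
  p2 <- predict_cascade(m2, x)
  expect_identical(p1$terminal, p2$terminal)
  expect_equal(p1$score1, p2$score1)
  expect_equal(p1$stopped_at, p2$stopped_at)
})
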