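#' Terminal classes of the three-layer diagnostic cascade
#'
#' Layer 1 separates healthy controls from any disease; layer 2
#' separates T2DM from DKD (grey-zone, early, overt); layer 3
#' separates early DKD from the remaining DKD (grey-zone or overt),
#' which terminates as `DKD_OTHER`.
#' @export
CASCADE_CLASSES <- c("HC", "T2DM", "EARLY_DKD", "DKD_OTHER")

#' Map the five cohort groups to the cascade's terminal classes
#' @param groups character vector of group labels.
#' @return factor over [CASCADE_CLASSES].
#' @export
cascade_truth <- function(groups) {
  out <- ifelse(groups %in% c("GREY", "OVERT_DKD"), "DKD_OTHER", groups)
  factor(out, levels = CASCADE_CLASSES)
}

#' Sparse biomarker panel by L1-penalized logistic regression
#'
#' Fits the LASSO path with `glmnet::cv.glmnet` and returns the panel
#' of features with nonzero coefficients at the selected lambda
#' (1-SE rule by default, which favours sparse panels; `"min"` uses
#' the CV-minimal lambda).
#'
#' @param mat samples x features matrix.
#' @param labels binary labels (factor; second level = positive).
#' @param folds CV folds (default 10).
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param seed seed for the CV fold draw.
#' @return list: panel (feature ids), coefficients (named), intercept,
#'   lambda, rule. Errors if the selected lambda zeroes every
#'   coefficient, reporting the largest lambda with a nonempty panel.
#' @export
select_panel_lasso <- function(mat, labels, folds = 10L,
                               lambda_rule = c("1se", "min"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  y <- factor(labels)
  stopifnot(nlevels(y) == 2)
  folds <- min(folds, min(table(y)))
  if (min(table(y)) < folds) stop("need >= folds samples per class")
  set.seed(seed)
  fit <- glmnet::cv.glmnet(as.matrix(mat), y, family = "binomial",
                           nfolds = folds)
  s <- if (lambda_rule == "1se") fit$lambda.1se else fit$lambda.min
  beta <- as.matrix(stats::coef(fit, s = s))
  nz <- which(beta[-1, 1] != 0)
  if (!length(nz)) {
    nzero <- fit$nzero
    ok <- which(nzero > 0)
    largest <- if (length(ok)) max(fit$lambda[ok]) else NA_real_
    stop("all coefficients zero at the selected lambda; largest lambda ",
         "with a nonempty panel: ", format(largest))
  }
  list(panel = rownames(beta)[-1][nz],
       coefficients = stats::setNames(beta[-1, 1][nz],
                                      rownames(beta)[-1][nz]),
       intercept = beta[1, 1], lambda = s, rule = lambda_rule,
       levels = levels(y))
}

#' Choose a score cutoff on discovery data
#'
#' `"youden"` maximizes sensitivity + specificity - 1 over the
#' observed score thresholds (prediction positive at score >= t), ties
#' broken toward the smaller threshold; `"fixed"` returns 0.5. If no
#' threshold improves on chance (max J <= 0) the median score is
#' returned with an `uninformative` flag; a class with a single sample
#' flags `low_n`.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param positive logical, TRUE for positive-class samples.
#' @param method `"youden"` (default) or `"fixed"`.
#' @return cutoff with attribute `flags` (possibly empty).
#' @export
choose_cutoff <- function(scores, positive, method = c("youden", "fixed")) {
  method <- match.arg(method)
  positive <- as.logical(positive)
  if (!any(positive) || all(positive))
    stop("both classes must be present")
  flags <- character()
  if (min(sum(positive), sum(!positive)) < 2) flags <- c(flags, "low_n")
  if (method == "fixed")
    return(structure(0.5, flags = flags))
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t0) {
    sens <- mean(scores[positive] >= t0)
    spec <- mean(scores[!positive] < t0)
    sens + spec - 1
  }, numeric(1))
  if (max(j) <= 0) {
    flags <- c(flags, "uninformative")
    return(structure(stats::median(scores), flags = flags))
  }
  structure(thr[which(j == max(j))[1]], flags = flags)
}

.layer_score <- function(layer, mat) {
  missing <- setdiff(layer$panel, colnames(mat))
  if (length(missing))
    stop("missing panel features: ", paste(missing, collapse = ", "))
  eta <- layer$intercept +
    drop(mat[, layer$panel, drop = FALSE] %*% layer$coefficients)
  stats::plogis(eta)
}

#' Fit the three-layer stepwise diagnostic cascade
#'
#' Trains three L1-penalized logistic scorers on discovery data:
#' layer 1 — HC versus all disease; layer 2 — T2DM versus DKD
#' (grey-zone, early and overt); layer 3 — early DKD versus the other
#' DKD states. By default each layer trains on the true labels of the
#' relevant discovery samples (avoiding error propagation during
#' training while keeping sequential routing at prediction time);
#' `survivor_training = TRUE` instead trains layers 2-3 only on
#' samples the previous layers routed onward. Per-layer cutoffs are
#' chosen on the discovery scores (Youden by default). Features are
#' log2-scaled internally when `log2_transform` is TRUE.
#'
#' @param mat samples x features matrix (all five groups present).
#' @param groups group labels from [DKD_GROUPS], same order as rows.
#' @param folds,lambda_rule,seed passed to [select_panel_lasso()]
#'   (lambda falls back from "1se" to "min" if the sparse rule empties
#'   the panel).
#' @param cutoff_method passed to [choose_cutoff()].
#' @param survivor_training train layers 2-3 on routed survivors.
#' @param log2_transform log2 the matrix first (default TRUE).
#' @return object of class `cascade_model`: `layers` (each with
#'   panel, coefficients, intercept, cutoff, lambda, rule, positive
#'   class semantics), `log2_transform`, provenance (seed, folds).
#' @export
fit_cascade <- function(mat, groups, folds = 10L, lambda_rule = "1se",
                        cutoff_method = "youden",
                        survivor_training = FALSE,
                        log2_transform = TRUE, seed = 1L) {
  groups <- as.character(groups)
  stopifnot(nrow(mat) == length(groups))
  missing_groups <- setdiff(DKD_GROUPS, unique(groups))
  if (length(missing_groups))
    stop("all five groups required in discovery data; missing: ",
         paste(missing_groups, collapse = ", "))
  x <- if (log2_transform) log2(mat) else mat

  layer_defs <- list(
    list(index = 1L, neg = "HC",
         pos = c("T2DM", "GREY", "EARLY_DKD", "OVERT_DKD"),
         positive_semantics = "disease"),
    list(index = 2L, neg = "T2DM", pos = c("GREY", "EARLY_DKD", "OVERT_DKD"),
         positive_semantics = "DKD"),
    list(index = 3L, neg = c("GREY", "OVERT_DKD"), pos = "EARLY_DKD",
         positive_semantics = "EARLY_DKD"))

  surviving <- rep(TRUE, nrow(x))
  layers <- vector("list", 3L)
  for (ld in layer_defs) {
    in_layer <- groups %in% c(ld$neg, ld$pos)
    if (survivor_training && ld$index > 1) in_layer <- in_layer & surviving
    y <- factor(ifelse(groups[in_layer] %in% ld$pos, "pos", "neg"),
                levels = c("neg", "pos"))
    if (min(table(y)) < 2)
      stop("layer ", ld$index, ": fewer than 2 samples on one side")
    sel <- tryCatch(
      select_panel_lasso(x[in_layer, , drop = FALSE], y, folds = folds,
                         lambda_rule = lambda_rule, seed = seed + ld$index),
      error = function(e) {
        if (identical(lambda_rule, "1se"))
          select_panel_lasso(x[in_layer, , drop = FALSE], y, folds = folds,
                             lambda_rule = "min", seed = seed + ld$index)
        else stop(e)
      })
    layer <- list(index = ld$index, panel = sel$panel,
                  coefficients = sel$coefficients,
                  intercept = sel$intercept, lambda = sel$lambda,
                  rule = sel$rule,
                  positive_semantics = ld$positive_semantics)
    sc <- .layer_score(layer, x[in_layer, , drop = FALSE])
    layer$cutoff <- as.numeric(choose_cutoff(sc, y == "pos",
                                             method = cutoff_method))
    layers[[ld$index]] <- layer
    if (survivor_training) {
      all_sc <- .layer_score(layer, x)
      surviving <- surviving & (all_sc >= layer$cutoff)
    }
  }
  structure(list(layers = layers, log2_transform = log2_transform,
                 provenance = list(seed = seed, folds = folds,
                                   lambda_rule = lambda_rule,
                                   cutoff_method = cutoff_method,
                                   survivor_training = survivor_training)),
            class = "cascade_model")
}

#' Route samples through the cascade
#'
#' Each sample is scored by layer 1; a score below the cutoff stops as
#' HC, otherwise the sample proceeds to layer 2 (stop below cutoff:
#' T2DM), then layer 3 (score >= cutoff: EARLY_DKD, else DKD_OTHER).
#' Scores exactly at a cutoff route positive (>= semantics). Layers a
#' sample never reaches are reported as NA.
#'
#' @param model a `cascade_model`.
#' @param mat samples x features matrix containing all panel features.
#' @return tibble: sample_id, score1, score2, score3, stopped_at,
#'   terminal (factor over [CASCADE_CLASSES]).
#' @export
predict_cascade <- function(model, mat) {
  stopifnot(inherits(model, "cascade_model"))
  x <- if (model$log2_transform) log2(mat) else mat
  n <- nrow(x)
  s1 <- .layer_score(model$layers[[1]], x)
  s2 <- .layer_score(model$layers[[2]], x)
  s3 <- .layer_score(model$layers[[3]], x)
  c1 <- model$layers[[1]]$cutoff
  c2 <- model$layers[[2]]$cutoff
  c3 <- model$layers[[3]]$cutoff
  terminal <- ifelse(s1 < c1, "HC",
               ifelse(s2 < c2, "T2DM",
                ifelse(s3 >= c3, "EARLY_DKD", "DKD_OTHER")))
  stopped <- ifelse(s1 < c1, 1L, ifelse(s2 < c2, 2L, 3L))
  tibble::tibble(
    sample_id = rownames(mat) %||% as.character(seq_len(n)),
    score1 = unname(s1),
    score2 = unname(ifelse(stopped >= 2, s2, NA_real_)),
    score3 = unname(ifelse(stopped >= 3, s3, NA_real_)),
    stopped_at = unname(stopped),
    terminal = factor(unname(terminal), levels = CASCADE_CLASSES))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grey-zone routing report
#'
#' Measures how often grey-zone samples (abnormal microalbumin,
#' UACR-negative) are routed past layer 2, i.e. called DKD rather than
#' T2DM — the cascade's answer to patients missed by the standard
#' UACR metric — together with the full per-true-group predicted-class
#' ratio table.
#'
#' @param model a `cascade_model`.
#' @param mat samples x features matrix.
#' @param groups true group labels.
#' @return list: `grey_routed_past_layer2` (fraction), `n_grey`,
#'   `routing_table` (true group x terminal class row proportions).
#' @export
grey_zone_report <- function(model, mat, groups) {
  groups <- as.character(groups)
  if (!any(groups == "GREY")) stop("no GREY samples present")
  pred <- predict_cascade(model, mat)
  grey <- groups == "GREY"
  routed <- !(pred$terminal[grey] %in% c("HC", "T2DM"))
  tab <- prop.table(table(true = groups, predicted = pred$terminal),
                    margin = 1)
  list(grey_routed_past_layer2 = mean(routed), n_grey = sum(grey),
       routing_table = tab)
}

#' Serialize a cascade model to JSON
#' @param model a `cascade_model`.
#' @param path file path; if NULL the JSON string is returned.
#' @return path (invisibly) or JSON string.
#' @export
cascade_to_json <- function(model, path = NULL) {
  payload <- list(
    class = "cascade_model",
    log2_transform = model$log2_transform,
    provenance = model$provenance,
    layers = lapply(model$layers, function(l) list(
      index = l$index, panel = l$panel,
      coefficients = unname(l$coefficients), intercept = l$intercept,
      cutoff = l$cutoff, lambda = l$lambda, rule = l$rule,
      positive_semantics = l$positive_semantics)))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Load a cascade model from JSON
#' @param path file path or JSON string.
#' @return a `cascade_model`.
#' @export
cascade_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  layers <- lapply(payload$layers, function(l) {
    panel <- unlist(l$panel)
    list(index = as.integer(l$index), panel = panel,
         coefficients = stats::setNames(unlist(l$coefficients), panel),
         intercept = l$intercept, cutoff = l$cutoff, lambda = l$lambda,
         rule = l$rule, positive_semantics = l$positive_semantics)
  })
  structure(list(layers = layers,
                 log2_transform = payload$log2_transform,
                 provenance = lapply(payload$provenance, unlist)),
            class = "cascade_model")
}
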