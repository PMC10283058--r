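#' Principal component analysis of a feature matrix
#'
#' Thin wrapper over [stats::prcomp()] with centring always on and
#' unit-variance scaling optional, returning scores, loadings and
#' explained-variance ratios.
#'
#' @param mat samples x features numeric matrix.
#' @param n_components number of components to keep.
#' @param scale unit-variance scale features (default FALSE).
#' @return list of class `pca_model`: scores, loadings,
#'   explained_variance_ratio, center, scale.
#' @export
fit_pca <- function(mat, n_components = 2L, scale = FALSE) {
  n_components <- min(n_components, nrow(mat) - 1L, ncol(mat))
  if (n_components < 1) stop("matrix too small for PCA")
  sds <- apply(mat, 2, stats::sd)
  if (all(sds == 0)) stop("constant matrix: zero variance")
  if (scale && any(sds == 0))
    stop("cannot unit-variance scale constant features")
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_components),
                                        drop = FALSE],
                 explained_variance_ratio = evr[seq_len(n_components)],
                 center = pc$center,
                 scale = if (scale) pc$scale else NULL),
            class = "pca_model")
}

# centre/scale helpers shared by O-PLS fit and predict
.autoscale <- function(mat, scale) {
  ctr <- colMeans(mat)
  scl <- if (scale) {
    s <- apply(mat, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, ncol(mat))
  list(x = sweep(sweep(mat, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Orthogonal projections to latent structures discriminant analysis
#'
#' O-PLS for a binary response: iteratively extracts components that
#' capture X variation orthogonal to the class code, deflates them
#' from X, then fits a single predictive PLS component on the filtered
#' matrix. With `n_orthogonal = 0` the model reduces exactly to
#' single-component PLS1. The class is coded -1/+1 (second factor
#' level positive); features are unit-variance scaled by default
#' (disable with `scale = FALSE`).
#'
#' @param mat samples x features matrix.
#' @param labels factor (or coercible) with exactly two levels, each
#'   with >= 2 samples.
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param scale unit-variance scaling (default TRUE).
#' @param tol,max_iter NIPALS convergence control (used for the
#'   generality of the iteration; with a univariate response the weight
#'   vector is available in closed form after one pass).
#' @return list of class `oplsda_model`: predictive scores/weights/
#'   loadings (t, w, p) and response loading c; orthogonal score/
#'   weight/loading matrices (t_ortho, w_ortho, p_ortho); `r2x` per
#'   component (predictive first), `r2y`, class levels and coding;
#'   centring/scaling for prediction.
#' @export
fit_oplsda <- function(mat, labels, n_orthogonal = 1L, scale = TRUE,
                       tol = 1e-10, max_iter = 500L) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes required")
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples")
  y <- ifelse(labels == levels(labels)[2], 1, -1)
  y <- y - mean(y)
  sc <- .autoscale(mat, scale)
  X0 <- sc$x
  rk <- qr(X0)$rank
  if (n_orthogonal >= rk)
    stop("n_orthogonal must be < rank of the centred matrix (max ",
         rk - 1L, ")")
  ssx_total <- sum(X0^2)
  X <- X0

  w <- drop(crossprod(X, y)); w <- w / sqrt(sum(w^2))
  To <- Wo <- Po <- NULL
  r2x_ortho <- numeric()
  if (n_orthogonal > 0) {
    To <- matrix(0, nrow(X), n_orthogonal)
    Wo <- matrix(0, ncol(X), n_orthogonal)
    Po <- matrix(0, ncol(X), n_orthogonal)
    for (k in seq_len(n_orthogonal)) {
      t_pred <- drop(X %*% w)
      p <- drop(crossprod(X, t_pred)) / sum(t_pred^2)
      w_o <- p - drop(crossprod(w, p)) * w
      nw <- sqrt(sum(w_o^2))
      if (nw < tol) {
        # no orthogonal variation left in the loading direction
        To <- To[, seq_len(k - 1), drop = FALSE]
        Wo <- Wo[, seq_len(k - 1), drop = FALSE]
        Po <- Po[, seq_len(k - 1), drop = FALSE]
        break
      }
      w_o <- w_o / nw
      t_o <- drop(X %*% w_o)
      p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
      X <- X - tcrossprod(t_o, p_o)
      To[, k] <- t_o; Wo[, k] <- w_o; Po[, k] <- p_o
      r2x_ortho <- c(r2x_ortho, sum(t_o^2) * sum(p_o^2) / ssx_total)
      w <- drop(crossprod(X, y)); w <- w / sqrt(sum(w^2))
    }
  }
  t_pred <- drop(X %*% w)
  p_pred <- drop(crossprod(X, t_pred)) / sum(t_pred^2)
  c_load <- sum(y * t_pred) / sum(t_pred^2)
  r2x_pred <- sum(t_pred^2) * sum(p_pred^2) / ssx_total
  resid <- X - tcrossprod(t_pred, p_pred)
  r2y <- 1 - sum((y - t_pred * c_load)^2) / sum(y^2)

  structure(list(t = t_pred, w = w, p = p_pred, c = c_load,
                 t_ortho = To, w_ortho = Wo, p_ortho = Po,
                 r2x = c(predictive = r2x_pred,
                         if (length(r2x_ortho))
                           stats::setNames(r2x_ortho,
                             paste0("orthogonal", seq_along(r2x_ortho)))),
                 r2y = r2y,
                 ss_total = ssx_total, ss_residual = sum(resid^2),
                 levels = levels(labels), y_centered = y,
                 center = sc$center, scale = sc$scale,
                 n_orthogonal = if (is.null(To)) 0L else ncol(To)),
            class = "oplsda_model")
}

#' Predictive and orthogonal scores for new samples
#'
#' @param object an `oplsda_model`.
#' @param newdata samples x features matrix with the training columns.
#' @param ... unused.
#' @return list with `t` (predictive score), `t_ortho` (matrix),
#'   `y_hat` (predicted class code).
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  X <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  if (object$n_orthogonal > 0) {
    for (k in seq_len(object$n_orthogonal)) {
      t_o <- drop(X %*% object$w_ortho[, k])
      X <- X - tcrossprod(t_o, object$p_ortho[, k])
    }
  }
  t_pred <- drop(X %*% object$w)
  list(t = t_pred, y_hat = t_pred * object$c)
}

#' Cross-validated predictive ability (Q2) of an O-PLS model
#'
#' Q2 = 1 - PRESS/TSS over held-out class codes, with stratified folds
#' (each fold keeps both classes; folds are re-balanced if a class
#' would vanish from a fold).
#'
#' @param mat samples x features matrix.
#' @param labels binary labels.
#' @param n_orthogonal orthogonal components.
#' @param folds number of CV folds (default 7).
#' @param scale unit-variance scaling (default TRUE).
#' @param seed optional seed for the fold assignment.
#' @return numeric Q2.
#' @export
oplsda_q2 <- function(mat, labels, n_orthogonal = 1L, folds = 7L,
                      scale = TRUE, seed = NULL) {
  if (folds < 2) stop("folds must be >= 2")
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("two classes required (TSS undefined)")
  if (!is.null(seed)) set.seed(seed)
  fold <- .stratified_folds(labels, folds)
  y_all <- ifelse(labels == levels(labels)[2], 1, -1)
  press <- 0
  for (f in seq_len(max(fold))) {
    tr <- fold != f; te <- fold == f
    m <- fit_oplsda(mat[tr, , drop = FALSE], labels[tr],
                    n_orthogonal = n_orthogonal, scale = scale)
    y_tr <- ifelse(labels[tr] == levels(labels)[2], 1, -1)
    y_hat <- predict(m, mat[te, , drop = FALSE])$y_hat + mean(y_tr)
    press <- press + sum((y_all[te] - y_hat)^2)
  }
  tss <- sum((y_all - mean(y_all))^2)
  1 - press / tss
}

# stratified fold assignment guaranteeing both classes per fold where
# class sizes allow; folds capped at the smaller class size
.stratified_folds <- function(labels, folds) {
  labels <- factor(labels)
  folds <- min(folds, min(table(labels)))
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}
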