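#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: q_(i) = min over j >= i of
#' (m p_(j) / j), capped at 1, reported in input order (delegates to
#' [stats::p.adjust()] after validating the input domain).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# vectorized two-sample t-tests over matrix columns (features);
# rows are samples. Returns list(mean_a, mean_b, t, df, p).
.col_ttests <- function(xa, xb, var_equal = FALSE) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  t <- (mb - ma) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    same <- degenerate & (mb == ma)
    t[same] <- 0; p[same] <- 1; df[same] <- na + nb - 2
    diffm <- degenerate & (mb != ma)
    t[diffm] <- sign(mb - ma)[diffm] * Inf
    p[diffm] <- .Machine$double.xmin
  }
  list(mean_a = ma, mean_b = mb, t = t, df = df, p = p,
       degenerate = degenerate & (mb != ma))
}

#' Per-feature two-sample t-tests on log2 intensities
#'
#' Tests every feature between two sample groups on the log2 scale
#' (Welch unequal-variance by default; set `var_equal = TRUE` for the
#' pooled-variance Student test). The log2 fold change is the
#' difference of group means of log2 intensities (B minus A).
#'
#' @param mat samples x features matrix of positive intensities (or
#'   already-log2 values with `log2_transform = FALSE`).
#' @param ids_a,ids_b row names of the two groups (contrast A vs B).
#' @param var_equal pooled-variance Student test instead of Welch.
#' @param log2_transform take log2 of the matrix first (default TRUE).
#' @param contrast label stored with the result.
#' @return tibble of class `differential_result`: feature_id, log2fc,
#'   t, p, q (BH-adjusted), degenerate flag.
#' @export
ttest_features <- function(mat, ids_a, ids_b, var_equal = FALSE,
                           log2_transform = TRUE,
                           contrast = "A_vs_B") {
  stopifnot(all(ids_a %in% rownames(mat)), all(ids_b %in% rownames(mat)))
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stop("need >= 2 samples per group")
  x <- if (log2_transform) log2(mat) else mat
  r <- .col_ttests(x[ids_a, , drop = FALSE], x[ids_b, , drop = FALSE],
                   var_equal = var_equal)
  out <- tibble::tibble(feature_id = colnames(mat),
                        contrast = contrast,
                        log2fc = unname(r$mean_b - r$mean_a),
                        t = unname(r$t), p = unname(r$p),
                        q = unname(bh_adjust(r$p)),
                        degenerate = unname(r$degenerate))
  class(out) <- c("differential_result", class(out))
  out
}

#' Stepwise-regulated features: intersection over pairwise contrasts
#'
#' A feature is stepwise-regulated when it is significant (BH q below
#' the threshold, strict) in every pairwise disease contrast of the
#' supplied family. Also reports Venn region counts over the
#' per-contrast significant sets and, optionally, restricts to
#' features whose fold-change direction is consistent across all
#' contrasts (monotone regulation along the stage axis).
#'
#' @param results list of `differential_result` tibbles (named by
#'   contrast if possible).
#' @param q_threshold significance threshold on q (default 0.05).
#' @param require_monotone keep only features whose log2fc sign agrees
#'   across all contrasts (default FALSE).
#' @return list of class `stepwise_set`: `features` (ids), `directions`
#'   (per-feature consensus sign over contrasts), `per_contrast`
#'   (significant ids per contrast), `venn_counts` (named by binary
#'   membership pattern).
#' @export
stepwise_intersection <- function(results, q_threshold = 0.05,
                                  require_monotone = FALSE) {
  if (!length(results)) stop("need >= 1 contrast")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- vapply(seq_along(results), function(i)
      if (!is.null(results[[i]]$contrast)) results[[i]]$contrast[1]
      else paste0("contrast", i), character(1))
  sig <- lapply(results, function(r) r$feature_id[r$q < q_threshold])
  inter <- Reduce(intersect, sig)
  if (require_monotone && length(inter)) {
    signs <- vapply(results, function(r)
      sign(r$log2fc[match(inter, r$feature_id)]), numeric(length(inter)))
    signs <- matrix(signs, nrow = length(inter))
    mono <- apply(signs, 1, function(s) all(s == s[1]) && s[1] != 0)
    inter <- inter[mono]
  }
  directions <- if (length(inter)) {
    sapply(inter, function(f) {
      s <- vapply(results, function(r) sign(r$log2fc[match(f, r$feature_id)]),
                  numeric(1))
      if (all(s >= 0)) 1 else if (all(s <= 0)) -1 else 0
    })
  } else numeric()

  all_feats <- unique(unlist(sig))
  patt <- vapply(all_feats, function(f)
    paste0(as.integer(vapply(sig, function(s) f %in% s, logical(1))),
           collapse = ""), character(1))
  venn <- table(patt)
  structure(list(features = inter, directions = directions,
                 per_contrast = sig,
                 venn_counts = as.list(venn),
                 q_threshold = q_threshold),
            class = "stepwise_set")
}

#' Feature-clinical covariate correlation screen
#'
#' Correlates every feature (log2 intensity) with every clinical
#' covariate, flagging associations with |r| above the screening
#' threshold. Spearman rank correlation by default (robust to the
#' skewed albuminuria measures); Pearson available.
#'
#' @param mat samples x features matrix of positive intensities.
#' @param covariates data frame of numeric covariates, rows matching
#'   `rownames(mat)`.
#' @param method "spearman" (default) or "pearson".
#' @param r_threshold flag threshold on |r| (default 0.3).
#' @param log2_transform log2 the matrix first (default TRUE).
#' @return tibble: feature_id, covariate, r, p, flagged, undefined.
#' @export
clinical_correlation <- function(mat, covariates, method = "spearman",
                                 r_threshold = 0.3, log2_transform = TRUE) {
  stopifnot(nrow(covariates) == nrow(mat))
  x <- if (log2_transform) log2(mat) else mat
  res <- do.call(rbind, lapply(names(covariates), function(cv) {
    v <- covariates[[cv]]
    if (length(unique(v[!is.na(v)])) < 2) {
      return(tibble::tibble(feature_id = colnames(x), covariate = cv,
                            r = NA_real_, p = NA_real_, flagged = FALSE,
                            undefined = TRUE))
    }
    rp <- vapply(seq_len(ncol(x)), function(j) {
      ct <- suppressWarnings(stats::cor.test(x[, j], v, method = method,
                                             exact = FALSE))
      c(ct$estimate, ct$p.value)
    }, numeric(2))
    tibble::tibble(feature_id = colnames(x), covariate = cv,
                   r = rp[1, ], p = rp[2, ],
                   flagged = abs(rp[1, ]) > r_threshold, undefined = FALSE)
  }))
  res
}
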