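# Independent brute-force oracles, written from the definitions and
# kept deliberately naive (loops, enumeration) so they share no code
# path with the package implementations they check.

bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

bf_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (po - pe) / (1 - pe)
}

bf_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

bf_hyper_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(vapply(js, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

bf_bicor <- function(x, y) {
  med_x <- median(x); med_y <- median(y)
  mad_x <- median(abs(x - med_x)); mad_y <- median(abs(y - med_y))
  num <- 0; den_x <- 0; den_y <- 0
  for (i in seq_along(x)) {
    ux <- (x[i] - med_x) / (9 * mad_x)
    uy <- (y[i] - med_y) / (9 * mad_y)
    wx <- if (abs(ux) < 1) (1 - ux^2)^2 else 0
    wy <- if (abs(uy) < 1) (1 - uy^2)^2 else 0
    ax <- (x[i] - med_x) * wx
    ay <- (y[i] - med_y) * wy
    num <- num + ax * ay
    den_x <- den_x + ax^2
    den_y <- den_y + ay^2
  }
  num / sqrt(den_x * den_y)
}

# single-linkage m/z clustering via hclust, for align_features checks
bf_single_linkage_nfeatures <- function(mzs, tol) {
  if (length(mzs) == 1) return(1L)
  hc <- hclust(dist(mzs), method = "single")
  length(unique(cutree(hc, h = tol)))
}

# brute-force peak scan applying the local-max + windowed-MAD S/N rule
# point by point
bf_peak_scan <- function(y, snr_threshold = 3, window = 51L) {
  n <- length(y)
  half <- (window - 1L) %/% 2L
  hits <- integer()
  for (i in 2:(n - 1)) {
    if (!(y[i] > y[i - 1] && y[i] > y[i + 1])) next
    win <- y[max(1, i - half):min(n, i + half)]
    noise <- 1.4826 * median(abs(win - median(win)))
    snr <- if (noise > 0) y[i] / noise else if (y[i] > 0) Inf else 0
    if (snr > snr_threshold) hits <- c(hits, i)
  }
  hits
}

# macro-averaged recall over the cascade terminal classes
macro_recall <- function(truth, predicted) {
  lv <- levels(truth)
  mean(vapply(lv, function(cl) {
    idx <- truth == cl
    if (!any(idx)) return(NA_real_)
    mean(predicted[idx] == cl)
  }, numeric(1)), na.rm = TRUE)
}

# small helper: replicate-averaged biological matrix + group labels
cohort_matrix <- function(cohort) {
  bio <- cohort$samples$sample_id[!cohort$samples$is_qc]
  avg <- average_replicates(cohort$intensities, cohort$replicate_map)
  list(mat = avg[bio, , drop = FALSE],
       groups = stats::setNames(cohort$samples$group[!cohort$samples$is_qc],
                                bio))
}

# all pairwise contrasts among the four staged groups
stage_contrasts <- function() {
  grps <- c("HC", "T2DM", "EARLY_DKD", "OVERT_DKD")
  cmb <- combn(grps, 2)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

stepwise_from_cohort <- function(cohort, q_threshold = 0.05) {
  cm <- cohort_matrix(cohort)
  diffs <- lapply(stage_contrasts(), function(ct)
    ttest_features(cm$mat, names(cm$groups)[cm$groups == ct[1]],
                   names(cm$groups)[cm$groups == ct[2]],
                   contrast = paste(ct, collapse = " vs ")))
  stepwise_intersection(diffs, q_threshold = q_threshold)
}
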