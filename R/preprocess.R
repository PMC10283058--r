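#' Pick peaks from a spectrum at a signal-to-noise threshold
#'
#' Retains every strict local maximum whose intensity exceeds
#' `snr_threshold` times the local noise scale, with the noise scale
#' estimated as `1.4826 * MAD` of the intensity in a sliding window
#' centred on each point (robust to peaks inside the window).
#'
#' @param spectrum list with ascending numeric `mz` and non-negative
#'   `intensity` of equal length (as produced by [emit_spectra()]).
#' @param snr_threshold S/N threshold, default 3.
#' @param window odd sliding-window size in grid points (default 51).
#' @return tibble with columns mz, intensity, snr (class `peak_list`).
#'   Empty or constant spectra yield zero rows.
#' @export
pick_peaks <- function(spectrum, snr_threshold = 3, window = 51L) {
  mz <- spectrum$mz; y <- spectrum$intensity
  stopifnot(length(mz) == length(y), !is.unsorted(mz, strictly = TRUE))
  n <- length(y)
  out <- tibble::tibble(mz = numeric(), intensity = numeric(),
                        snr = numeric())
  class(out) <- c("peak_list", class(out))
  if (n < 3) return(out)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                     y[2:(n - 1)] > y[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(out)
  half <- (as.integer(window) - 1L) %/% 2L
  noise <- vapply(cand, function(i) {
    win <- y[max(1L, i - half):min(n, i + half)]
    stats::mad(win)                        # 1.4826 * median |x - median|
  }, numeric(1))
  snr <- ifelse(noise > 0, y[cand] / noise, ifelse(y[cand] > 0, Inf, 0))
  keep <- snr > snr_threshold
  out <- tibble::tibble(mz = mz[cand[keep]], intensity = y[cand[keep]],
                        snr = snr[keep])
  class(out) <- c("peak_list", class(out))
  out
}

#' Align peak lists across samples into a feature matrix
#'
#' Single-linkage grouping of all observed m/z values: pooled peaks are
#' sorted and split wherever the gap between neighbours exceeds the
#' tolerance, so peaks within tolerance of a chain share one feature.
#' Each input list contributes at most one observation per feature (the
#' most intense if several of its peaks land in the same feature);
#' positions not observed in a list are missing (NA).
#'
#' @param peaklists named list of peak lists (tibbles with mz,
#'   intensity); names become row names of the matrix.
#' @param tolerance alignment tolerance; interpreted in Da when
#'   `ppm = FALSE` (default 0.05, suited to metabolite fingerprints) or
#'   in parts-per-million when `ppm = TRUE` (e.g. 500 ppm for
#'   linear-mode peptide profiles, where mass error grows with mass).
#' @param ppm logical; tolerance in ppm instead of Da.
#' @param prefix feature-id prefix, default "ft".
#' @return matrix (lists x features) with consensus-m/z feature ids;
#'   attribute `consensus_mz` carries the numeric centres.
#' @export
align_features <- function(peaklists, tolerance = 0.05, ppm = FALSE,
                           prefix = "ft") {
  if (!length(peaklists)) stop("need at least one peak list")
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (is.null(names(peaklists)))
    names(peaklists) <- paste0("L", seq_along(peaklists))
  pooled <- do.call(rbind, lapply(names(peaklists), function(nm) {
    pl <- peaklists[[nm]]
    if (!nrow(pl)) return(NULL)
    data.frame(list = nm, mz = pl$mz, intensity = pl$intensity)
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    m <- matrix(numeric(), length(peaklists), 0,
                dimnames = list(names(peaklists), NULL))
    attr(m, "consensus_mz") <- numeric()
    return(m)
  }
  ord <- order(pooled$mz)
  pooled <- pooled[ord, ]
  gap_tol <- if (ppm) tolerance * 1e-6 * pooled$mz[-1] else tolerance
  breaks <- which(diff(pooled$mz) > gap_tol)
  feat_of <- cumsum(c(1L, as.integer(seq_len(nrow(pooled) - 1) %in% breaks)))
  if (nrow(pooled) == 1) feat_of <- 1L
  n_feat <- max(feat_of)
  centres <- vapply(seq_len(n_feat),
                    function(f) stats::median(pooled$mz[feat_of == f]),
                    numeric(1))
  digits <- if (ppm) 2 else 4
  ids <- sprintf(paste0(prefix, "_%.", digits, "f"), centres)
  ids <- make.unique(ids, sep = "_")
  mat <- matrix(NA_real_, length(peaklists), n_feat,
                dimnames = list(names(peaklists), ids))
  for (k in seq_len(nrow(pooled))) {
    i <- pooled$list[k]; j <- feat_of[k]
    if (is.na(mat[i, j]) || pooled$intensity[k] > mat[i, j])
      mat[i, j] <- pooled$intensity[k]
  }
  attr(mat, "consensus_mz") <- stats::setNames(centres, ids)
  mat
}

#' Filter sparse features and impute remaining missing values
#'
#' Keeps features observed in at least `min_prop` of the rows and
#' imputes remaining missing entries with half the feature's minimum
#' observed value (a standard floor for below-detection intensities).
#'
#' @param mat samples x features matrix, NAs allowed.
#' @param min_prop minimum observed fraction per feature (default 0.7).
#' @return complete matrix; dropped feature ids in attribute `dropped`.
#' @export
filter_impute <- function(mat, min_prop = 0.7) {
  obs <- colMeans(!is.na(mat))
  keep <- obs >= min_prop
  out <- mat[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    miss <- is.na(out[, j])
    if (any(miss)) out[miss, j] <- min(out[!miss, j]) / 2
  }
  attr(out, "dropped") <- colnames(mat)[!keep]
  out
}

#' Quantile cubic-spline intensity normalization
#'
#' For each sample, fits a monotone cubic spline between the sample's
#' log2-intensity quantiles and the reference's quantiles (knots at
#' evenly spaced probabilities) and applies the mapping to the sample's
#' log2 intensities, so that every normalized sample's quantile curve
#' matches the reference. The mapping is monotone (Hyman-filtered
#' cubic), hence within-sample rank order is preserved; beyond the knot
#' range it continues linearly with the end-point slope.
#'
#' @param mat samples x features matrix of positive intensities
#'   (complete; run [filter_impute()] first).
#' @param reference `"median_all"` (default) — per-feature median over
#'   all rows; `"median_qc"` — median over `qc_rows`; or a row name.
#' @param qc_rows row names of QC injections (for `"median_qc"`).
#' @param n_knots interior knots (default 7).
#' @return normalized matrix, same shape; attribute `fallback_rows`
#'   lists samples normalized by median scaling because they had too
#'   few distinct values to anchor a spline.
#' @export
cubic_spline_normalize <- function(mat, reference = "median_all",
                                   qc_rows = NULL, n_knots = 7L) {
  stopifnot(nrow(mat) >= 2, all(mat > 0), !anyNA(mat))
  lx <- log2(mat)
  ref <- if (identical(reference, "median_all")) {
    apply(lx, 2, stats::median)
  } else if (identical(reference, "median_qc")) {
    if (is.null(qc_rows)) stop("qc_rows required for reference='median_qc'")
    apply(lx[qc_rows, , drop = FALSE], 2, stats::median)
  } else {
    if (!reference %in% rownames(mat)) stop("reference sample not found")
    lx[reference, ]
  }
  probs <- seq(0, 1, length.out = n_knots + 2L)
  # order-statistic quantiles (type 1) commute exactly with monotone
  # maps, which makes re-normalization against the same reference a
  # no-op
  ref_q <- stats::quantile(ref, probs, names = FALSE, type = 1)
  fallback <- character()
  out <- lx
  for (i in seq_len(nrow(lx))) {
    xi <- lx[i, ]
    xq <- stats::quantile(xi, probs, names = FALSE, type = 1)
    keep <- !duplicated(xq)
    if (sum(keep) < 4) {                   # too flat: median scaling
      out[i, ] <- xi - stats::median(xi) + stats::median(ref)
      fallback <- c(fallback, rownames(lx)[i])
      next
    }
    f <- stats::splinefun(xq[keep], ref_q[keep], method = "hyman")
    yi <- f(xi)
    lo <- xi < xq[1];  hi <- xi > xq[length(xq)]
    if (any(lo)) yi[lo] <- f(xq[1]) + f(xq[1], deriv = 1) * (xi[lo] - xq[1])
    if (any(hi)) {
      xe <- xq[length(xq)]
      yi[hi] <- f(xe) + f(xe, deriv = 1) * (xi[hi] - xe)
    }
    out[i, ] <- yi
  }
  res <- 2^out
  attr(res, "fallback_rows") <- fallback
  res
}

#' Average technical replicates into one row per biological sample
#'
#' @param mat rows = replicate measurements, columns = features.
#' @param replicate_map data frame with columns `row` (matching
#'   rownames of `mat`) and `sample_id`. If NULL, sample ids are parsed
#'   from rownames of the form `<sample>_r<k>`.
#' @return samples x features matrix of replicate means (NAs ignored;
#'   a feature missing in all replicates stays NA).
#' @export
average_replicates <- function(mat, replicate_map = NULL) {
  if (is.null(replicate_map)) {
    sid <- sub("_r[0-9]+$", "", rownames(mat))
  } else {
    if (!all(replicate_map$row %in% rownames(mat)))
      stop("replicate_map references rows absent from the matrix")
    sid <- replicate_map$sample_id[match(rownames(mat), replicate_map$row)]
  }
  if (anyNA(sid)) stop("rows without a sample assignment")
  grp <- factor(sid, levels = unique(sid))
  cnt <- rowsum((!is.na(mat)) * 1, grp)
  tot <- rowsum(ifelse(is.na(mat), 0, mat), grp)
  out <- tot / cnt                               # 0/0 -> NaN -> NA
  out[cnt == 0] <- NA_real_
  rownames(out) <- levels(grp)
  out
}

#' Platform quality-control report
#'
#' Computes the reproducibility metrics used to qualify the MS
#' platform: Spearman rank correlation between two technical replicates
#' of the pooled QC sample, median intra-batch and inter-batch relative
#' standard deviation (RSD, 100 x SD/mean) over features of the QC
#' injections, and the RSD of the internal-standard intensity ratio
#' across all rows.
#'
#' @param mat rows = replicate measurements (or QC injections),
#'   columns = features; positive intensities.
#' @param qc_rows row names of QC measurements.
#' @param is_ids two internal-standard feature ids (optional).
#' @param batch named vector: batch of each QC row.
#' @param thresholds pass thresholds: spearman (>=), intra/inter/is RSD
#'   (<=), in percent.
#' @return list of class `qc_report`: replicate_spearman,
#'   intra_batch_rsd_median, inter_batch_rsd_median,
#'   internal_standard_ratio_rsd, pass_flags, notes.
#' @export
qc_report <- function(mat, qc_rows, is_ids = NULL, batch,
                      thresholds = c(spearman = 0.8, intra = 15,
                                     inter = 25, is_ratio = 25)) {
  stopifnot(all(qc_rows %in% rownames(mat)))
  qc <- mat[qc_rows, , drop = FALSE]
  b <- batch[qc_rows]
  if (length(unique(b)) < 2)
    stop("inter-batch RSD needs QC measurements in >= 2 batches")
  notes <- character()

  rsd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) return(NA_real_)
    100 * stats::sd(x) / mean(x)
  }

  # replicate concordance: first two QC injections of the first batch
  b1 <- qc_rows[b == sort(unique(b))[1]]
  if (length(b1) >= 2) {
    sp <- stats::cor(qc[b1[1], ], qc[b1[2], ], method = "spearman")
  } else {
    sp <- NA_real_
    notes <- c(notes, "single QC replicate: Spearman undefined")
  }

  intra <- vapply(sort(unique(b)), function(bb) {
    sub <- qc[b == bb, , drop = FALSE]
    stats::median(apply(sub, 2, rsd), na.rm = TRUE)
  }, numeric(1))
  intra_med <- stats::median(intra)

  batch_means <- rowsum(qc, b) / as.vector(table(b))
  inter_med <- stats::median(apply(batch_means, 2, rsd), na.rm = TRUE)

  is_rsd <- NA_real_
  if (!is.null(is_ids)) {
    stopifnot(length(is_ids) == 2, all(is_ids %in% colnames(mat)))
    ratio <- mat[, is_ids[1]] / mat[, is_ids[2]]
    is_rsd <- rsd(ratio)
  }

  flags <- c(replicate_spearman = isTRUE(sp >= thresholds[["spearman"]]),
             intra_batch = isTRUE(intra_med <= thresholds[["intra"]]),
             inter_batch = isTRUE(inter_med <= thresholds[["inter"]]),
             internal_standard_ratio =
               is.null(is_ids) || isTRUE(is_rsd <= thresholds[["is_ratio"]]))
  structure(list(replicate_spearman = sp,
                 intra_batch_rsd_median = intra_med,
                 intra_batch_rsd_per_batch = intra,
                 inter_batch_rsd_median = inter_med,
                 internal_standard_ratio_rsd = is_rsd,
                 pass_flags = flags, notes = notes),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n",
      sprintf("  replicate Spearman: %.3f\n", x$replicate_spearman),
      sprintf("  intra-batch median RSD: %.2f%%\n", x$intra_batch_rsd_median),
      sprintf("  inter-batch median RSD: %.2f%%\n", x$inter_batch_rsd_median),
      sprintf("  internal-standard ratio RSD: %.2f%%\n",
              x$internal_standard_ratio_rsd),
      "  pass: ", paste(names(x$pass_flags)[x$pass_flags], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
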