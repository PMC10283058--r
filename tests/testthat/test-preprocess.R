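# zero-baseline noise trace; the picker accepts any real-valued trace
make_noise_spectrum <- function(n, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(mz = seq(100, by = 0.01, length.out = n),
       intensity = rnorm(n, 0, sd))
}

test_that("a single strong spike is picked at its m/z and nothing else", {
  set.seed(1)
  mz <- seq(100, 110, by = 0.01)
  y <- rnorm(length(mz), 0, 1)
  i0 <- which.min(abs(mz - 104.03))
  y[i0] <- 50
  pk <- pick_peaks(list(mz = mz, intensity = y), snr_threshold = 10)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$mz - 104.03), 0.011)
  expect_gt(pk$snr, 10)
})

test_that("degenerate spectra yield empty peak lists", {
  mz <- seq(1, 100)
  expect_equal(nrow(pick_peaks(list(mz = mz, intensity = rep(0, 100)))), 0L)
  expect_equal(nrow(pick_peaks(list(mz = mz, intensity = rep(5, 100)))), 0L)
  expect_equal(nrow(pick_peaks(list(mz = numeric(), intensity = numeric()))),
               0L)
})

test_that("picker agrees with a brute-force point-by-point scan", {
  for (s in 1:5) {
    sp <- make_noise_spectrum(10000, seed = s)
    pk <- pick_peaks(sp, snr_threshold = 3, window = 51)
    bf <- bf_peak_scan(sp$intensity, snr_threshold = 3, window = 51)
    expect_identical(nrow(pk), length(bf))
    expect_equal(pk$mz, sp$mz[bf])
  }
})

test_that("lowering the S/N threshold never removes a peak", {
  sp <- make_noise_spectrum(5000, seed = 3)
  sp$intensity[c(500, 1500, 3000)] <- c(20, 8, 4)
  hi <- pick_peaks(sp, snr_threshold = 5)
  lo <- pick_peaks(sp, snr_threshold = 2)
  expect_true(all(hi$mz %in% lo$mz))
  expect_gte(nrow(lo), nrow(hi))
})

test_that("noise-only traces rarely produce S/N > 3 peaks", {
  # analytic bound: a point is a spurious peak only if it is a local
  # maximum exceeding 3x the local noise scale; for Gaussian noise the
  # per-point rate is below ~0.4%
  set.seed(21)
  n_points <- 0L; n_peaks <- 0L
  for (s in 1:30) {
    sp <- make_noise_spectrum(1000)
    n_points <- n_points + 1000L
    n_peaks <- n_peaks + nrow(pick_peaks(sp, snr_threshold = 3))
  }
  expect_lt(n_peaks / n_points, 0.005)
})

test_that("feature alignment merges within tolerance and splits beyond", {
  pl <- function(mz) tibble::tibble(mz = mz, intensity = rep(100,
                                                             length(mz)))
  m1 <- align_features(list(a = pl(100.000), b = pl(100.004)),
                       tolerance = 0.01)
  expect_equal(ncol(m1), 1L)
  expect_equal(sum(!is.na(m1)), 2L)
  m2 <- align_features(list(a = pl(100.00), b = pl(100.20)),
                       tolerance = 0.01)
  expect_equal(ncol(m2), 2L)
})

test_that("alignment feature count matches single-linkage clustering", {
  set.seed(5)
  for (rep in 1:5) {
    lists <- lapply(1:50, function(i) {
      k <- sample(3:12, 1)
      tibble::tibble(mz = sort(runif(k, 100, 110)),
                     intensity = runif(k, 10, 100))
    })
    names(lists) <- paste0("s", 1:50)
    tol <- 0.05
    mat <- align_features(lists, tolerance = tol)
    all_mz <- unlist(lapply(lists, `[[`, "mz"))
    expect_equal(ncol(mat), bf_single_linkage_nfeatures(all_mz, tol))
  }
})

test_that("alignment is invariant to the order of input peak lists", {
  set.seed(8)
  lists <- lapply(1:10, function(i)
    tibble::tibble(mz = sort(runif(5, 100, 105)),
                   intensity = runif(5, 10, 100)))
  names(lists) <- paste0("s", 1:10)
  m1 <- align_features(lists, tolerance = 0.05)
  m2 <- align_features(rev(lists), tolerance = 0.05)
  expect_equal(ncol(m1), ncol(m2))
  expect_equal(m1[rownames(m2), colnames(m2)], m2, ignore_attr = TRUE)
  expect_error(align_features(lists, tolerance = 0), "tolerance")
})

test_that("spline normalization is an identity for the reference itself", {
  set.seed(2)
  mat <- matrix(2^rnorm(5 * 200, 14, 2), 5, 200,
                dimnames = list(paste0("s", 1:5), paste0("f", 1:200)))
  ref <- apply(log2(mat), 2, median)
  mat[1, ] <- 2^ref
  out <- cubic_spline_normalize(mat, reference = "s1")
  expect_lt(max(abs(out[1, ] / mat[1, ] - 1)), 1e-9)
})

test_that("spline normalization removes a constant multiplicative shift", {
  set.seed(4)
  base <- 2^rnorm(300, 14, 2)
  mat <- rbind(ref = base, shifted = base * 2)
  colnames(mat) <- paste0("f", 1:300)
  out <- cubic_spline_normalize(mat, reference = "ref")
  rel_err <- abs(out["shifted", ] - base) / base
  expect_lt(median(rel_err), 0.01)
})

test_that("normalization is idempotent and preserves within-sample ranks", {
  set.seed(6)
  mat <- matrix(2^rnorm(6 * 250, 14, 1.5), 6, 250,
                dimnames = list(paste0("s", 1:6), paste0("f", 1:250)))
  mat[2, ] <- mat[2, ] * 3          # global intensity drift
  once <- cubic_spline_normalize(mat, reference = "s1")
  for (i in 1:6)
    expect_equal(rank(once[i, ]), rank(mat[i, ]))
  # re-normalizing against the same reference is a no-op
  twice <- cubic_spline_normalize(once, reference = "s1")
  expect_lt(max(abs(log2(twice) - log2(once))) /
              max(abs(log2(once))), 1e-6)
})

test_that("a near-constant sample falls back to median scaling", {
  set.seed(9)
  mat <- matrix(2^rnorm(3 * 100, 14, 2), 3, 100,
                dimnames = list(paste0("s", 1:3), paste0("f", 1:100)))
  mat[3, ] <- 1000
  out <- cubic_spline_normalize(mat)
  expect_true("s3" %in% attr(out, "fallback_rows"))
})

test_that("replicate averaging equals a direct group-by mean", {
  m <- matrix(c(10, 20, 30), 3, 1,
              dimnames = list(c("a_r1", "a_r2", "a_r3"), "f1"))
  expect_equal(unname(average_replicates(m)["a", 1]), 20)
  one <- matrix(5, 1, 1, dimnames = list("b_r1", "f1"))
  expect_equal(unname(average_replicates(one)["b", 1]), 5)
  set.seed(12)
  big <- matrix(runif(30 * 8), 30, 8,
                dimnames = list(paste0("s", rep(1:10, each = 3), "_r",
                                       rep(1:3, 10)),
                                paste0("f", 1:8)))
  big[2, 3] <- NA
  avg <- average_replicates(big)
  for (s in paste0("s", 1:10)) {
    rows <- big[paste0(s, "_r", 1:3), , drop = FALSE]
    for (j in 1:8)
      expect_equal(avg[s, j], mean(rows[, j], na.rm = TRUE))
  }
  bad_map <- data.frame(row = "nope", sample_id = "x")
  expect_error(average_replicates(big, bad_map), "absent")
})

test_that("QC metrics match hand computation", {
  # two identical QC replicate rows -> Spearman 1; feature (90,100,110)
  # across three QC injections in one batch -> RSD exactly 10%
  v <- runif(50, 10, 100)
  mat <- rbind(q1 = v, q2 = v,
               q3 = v * 0.9, q4 = v, q5 = v * 1.1)
  colnames(mat) <- paste0("f", 1:50)
  batch <- c(q1 = 1, q2 = 1, q3 = 2, q4 = 2, q5 = 2)
  rep_ <- qc_report(mat, qc_rows = rownames(mat), batch = batch)
  expect_equal(rep_$replicate_spearman, 1)
  expect_equal(rep_$intra_batch_rsd_per_batch[[2]],
               unname(100 * sd(c(90, 100, 110)) / 100))
  expect_error(qc_report(mat, rownames(mat), batch = rep(1, 5) |>
                           setNames(rownames(mat))), "2 batches")
})

test_that("QC report equals brute-force recomputation on a random fixture", {
  set.seed(31)
  mat <- matrix(2^rnorm(8 * 40, 10, 1), 8, 40,
                dimnames = list(paste0("q", 1:8), paste0("f", 1:40)))
  batch <- setNames(rep(1:2, each = 4), rownames(mat))
  rep_ <- qc_report(mat, rownames(mat), batch = batch)
  rsd <- function(x) 100 * sd(x) / mean(x)
  intra_bf <- median(vapply(seq_len(2), function(b) {
    sub <- mat[batch == b, ]
    median(apply(sub, 2, rsd))
  }, numeric(1)))
  expect_equal(rep_$intra_batch_rsd_median, intra_bf)
  bmeans <- rbind(colMeans(mat[1:4, ]), colMeans(mat[5:8, ]))
  expect_equal(rep_$inter_batch_rsd_median,
               median(apply(bmeans, 2, rsd)))
  expect_equal(rep_$replicate_spearman,
               cor(mat["q1", ], mat["q2", ], method = "spearman"))
})

test_that("sparse features are dropped and the rest floor-imputed", {
  mat <- matrix(c(1, 2, NA, 4,
                  NA, NA, NA, 8,
                  3, 6, 9, 12), 4, 3,
                dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  out <- filter_impute(mat, min_prop = 0.7)
  expect_equal(colnames(out), c("a", "c"))
  expect_equal(attr(out, "dropped"), "b")
  expect_equal(unname(out["s3", "a"]), 0.5)   # half the minimum observed
})
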