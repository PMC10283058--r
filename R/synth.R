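#' @importFrom stats rnorm runif qnorm pnorm median mad sd quantile
#' @importFrom tibble tibble as_tibble
NULL

#' Disease groups of the cohort
#'
#' The five clinical classes: healthy controls (HC), type 2 diabetes
#' without albuminuria (T2DM), grey-zone diabetics (abnormal urinary
#' microalbumin but UACR-negative), early DKD (microalbuminuria) and
#' overt DKD (macroalbuminuria or reduced filtration).
#'
#' @export
DKD_GROUPS <- c("HC", "T2DM", "GREY", "EARLY_DKD", "OVERT_DKD")

# Disease-stage position of each group on the HC -> overt axis.
# GREY sits between T2DM and early DKD; its exact fraction is a
# configurable model choice (grey_step_fraction).
.stage_index <- c(HC = 0, T2DM = 1, EARLY_DKD = 2, OVERT_DKD = 3)

#' Configuration for the synthetic urine multi-omics cohort
#'
#' Defines the cohort composition and the generative model for the
#' metabolite fingerprint (m/z 20-350) and peptide profile
#' (m/z 600-20000) intensity tables. Intensities follow a log2-normal
#' model: `2^(baseline + group shift + batch shift + noise)` per
#' technical replicate, so a planted log2 fold change is exact by
#' construction and the technical coefficient of variation equals
#' `noise_cv`.
#'
#' @param n_per_group named integer vector of sample counts, names from
#'   [DKD_GROUPS]. Default is the 501-sample model-establishment cohort
#'   (152 HC, 149 T2DM, 39 grey-zone, 106 early DKD, 55 overt DKD).
#' @param n_met_features number of metabolite features (default 227).
#' @param n_pep_features number of peptide features (default 206).
#' @param n_stepwise_met planted stepwise-regulated metabolites (10).
#' @param n_stepwise_pep planted stepwise-regulated peptides (6).
#' @param effect_log2fc mean per-stage log2 increment of planted
#'   features (default 0.5). Per feature and stage the realized
#'   increment is `effect_log2fc * U(0.5, 1.5)` so the stage contrasts
#'   are not collinear across the panel.
#' @param grey_step_fraction position of the grey-zone group between
#'   the T2DM and early-DKD shifts (0.5 = half-way, the default; 0
#'   makes grey-zone molecularly identical to T2DM).
#' @param noise_cv technical coefficient of variation (default 0.15).
#' @param n_replicates technical replicates per sample (default 3).
#' @param n_batches number of measurement batches (default 2).
#' @param batch_sd_log2 SD of the per-batch, per-feature additive log2
#'   shift (default 0.25). Internal-standard channels are exempt.
#' @param n_qc_per_batch injections of the pooled QC sample per batch
#'   (default 8).
#' @param seed integer random seed.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(HC = 152, T2DM = 149, GREY = 39,
                                          EARLY_DKD = 106, OVERT_DKD = 55),
                          n_met_features = 227,
                          n_pep_features = 206,
                          n_stepwise_met = 10,
                          n_stepwise_pep = 6,
                          effect_log2fc = 0.5,
                          grey_step_fraction = 0.5,
                          noise_cv = 0.15,
                          n_replicates = 3,
                          n_batches = 2,
                          batch_sd_log2 = 0.25,
                          n_qc_per_batch = 8,
                          seed = 1L) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% DKD_GROUPS))
    stop("n_per_group must be named with groups from: ",
         paste(DKD_GROUPS, collapse = ", "))
  if (any(n_per_group < 0))
    stop("group counts must be non-negative")
  zero <- names(n_per_group)[n_per_group == 0]
  if (length(zero))
    warning("groups with 0 samples: ", paste(zero, collapse = ", "),
            "; downstream stages referencing them will fail")
  counts <- c(n_met_features, n_pep_features, n_replicates, n_batches,
              n_qc_per_batch)
  if (any(counts < 1)) stop("all feature/replicate/batch counts must be >= 1")
  if (n_stepwise_met > n_met_features || n_stepwise_pep > n_pep_features)
    stop("planted feature counts cannot exceed feature counts")
  if (noise_cv <= 0) stop("noise_cv must be > 0")
  structure(list(
    n_per_group = n_per_group, n_met_features = n_met_features,
    n_pep_features = n_pep_features, n_stepwise_met = n_stepwise_met,
    n_stepwise_pep = n_stepwise_pep, effect_log2fc = effect_log2fc,
    grey_step_fraction = grey_step_fraction, noise_cv = noise_cv,
    n_replicates = n_replicates, n_batches = n_batches,
    batch_sd_log2 = batch_sd_log2, n_qc_per_batch = n_qc_per_batch,
    seed = as.integer(seed)), class = "cohort_config")
}

# log2-scale SD giving a log-normal technical CV exactly equal to cv
.log2_sd_for_cv <- function(cv) sqrt(log1p(cv^2)) / log(2)

# truncated normal via inverse-CDF; deterministic given the RNG stream
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Sample clinical covariates consistent with the KDIGO group definitions
#'
#' Draws age, sex, BMI, eGFR, UACR and urinary microalbumin (mALB) from
#' truncated normals whose bounds enforce the recruiting definitions:
#' HC and T2DM are albuminuria-negative with preserved filtration
#' (UACR < 3 mg/mmol, mALB < 30 mg/g, eGFR >= 60); grey-zone has
#' abnormal microalbumin with negative UACR (mALB >= 30, UACR < 3,
#' eGFR >= 60); early DKD has microalbuminuria (3 <= UACR < 30,
#' eGFR >= 60); overt DKD has macroalbuminuria (UACR >= 30, eGFR free
#' to fall below 60). Location parameters trend with stage: eGFR
#' decreases and UACR/mALB increase from HC to overt DKD.
#'
#' @param group one of [DKD_GROUPS].
#' @param n number of samples to draw.
#' @return tibble with columns age, sex, bmi, egfr, uacr, malb.
#' @export
generate_clinical <- function(group, n = 1L) {
  group <- match.arg(group, DKD_GROUPS)
  p <- switch(group,
    HC        = list(age = c(52, 10), egfr = c(105, 12, 60, 150),
                     uacr = c(0.8, 0.6, 0, 2.999), malb = c(10, 6, 0, 29.9)),
    T2DM      = list(age = c(56, 10), egfr = c(100, 12, 60, 150),
                     uacr = c(1.2, 0.7, 0, 2.999), malb = c(15, 7, 0, 29.9)),
    GREY      = list(age = c(58, 10), egfr = c(92, 12, 60, 150),
                     uacr = c(1.8, 0.7, 0, 2.999), malb = c(60, 25, 30, 300)),
    EARLY_DKD = list(age = c(59, 10), egfr = c(85, 12, 60, 150),
                     uacr = c(10, 6, 3, 29.99), malb = c(90, 40, 30, 500)),
    OVERT_DKD = list(age = c(61, 10), egfr = c(55, 18, 10, 110),
                     uacr = c(60, 30, 30, 400), malb = c(300, 150, 30, 2000)))
  tibble(
    age  = round(.rtruncnorm(n, p$age[1], p$age[2], 25, 85)),
    sex  = sample(c("F", "M"), n, replace = TRUE),
    bmi  = round(.rtruncnorm(n, 24.5, 3, 16, 40), 1),
    egfr = round(.rtruncnorm(n, p$egfr[1], p$egfr[2], p$egfr[3], p$egfr[4]), 1),
    uacr = round(.rtruncnorm(n, p$uacr[1], p$uacr[2], p$uacr[3], p$uacr[4]), 2),
    malb = round(.rtruncnorm(n, p$malb[1], p$malb[2], p$malb[3], p$malb[4]), 1))
}

# per-group log2 shift for one feature, from its per-stage increments.
# increments: named c(T2DM=, EARLY_DKD=, OVERT_DKD=) cumulative deltas.
.group_shifts <- function(increments, sign, grey_frac) {
  cum <- cumsum(increments)                       # stages 1..3
  shifts <- c(HC = 0, T2DM = cum[[1]], EARLY_DKD = cum[[2]],
              OVERT_DKD = cum[[3]])
  shifts["GREY"] <- shifts[["T2DM"]] +
    grey_frac * (shifts[["EARLY_DKD"]] - shifts[["T2DM"]])
  sign * shifts[DKD_GROUPS]
}

#' Generate a synthetic urine multi-omics cohort
#'
#' Builds the full cohort the downstream analysis assumes: samples with
#' KDIGO-consistent covariates, metabolite and peptide feature
#' specifications with a planted subset of monotonically
#' stepwise-regulated features, two internal-standard channels, pooled
#' QC injections, and a replicate-level intensity table following the
#' log2-normal model described in [cohort_config()]. The majority of
#' planted metabolites are down-regulated with disease stage and the
#' majority of planted peptides up-regulated, mirroring the direction
#' bias seen in urine of diabetic kidney disease patients.
#'
#' @param config a [cohort_config()].
#' @return object of class `dkd_cohort`: list with `samples` (tibble,
#'   one row per biological sample + QC rows), `features` (tibble of
#'   feature specs), `intensities` (rows = sample x replicate, columns
#'   = features, strictly positive), `truth` (planted stepwise feature
#'   ids), `internal_standard_ids`, and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cfg <- config

  ## ---- features -----------------------------------------------------
  met_mz <- sort(runif(cfg$n_met_features, 20, 350))
  pep_mz <- sort(runif(cfg$n_pep_features, 600, 20000))
  feat <- tibble(
    feature_id = c(sprintf("met_%.4f", met_mz), sprintf("pep_%.2f", pep_mz)),
    modality   = rep(c("met", "pep"), c(cfg$n_met_features, cfg$n_pep_features)),
    mz         = c(met_mz, pep_mz),
    baseline_log2 = rnorm(cfg$n_met_features + cfg$n_pep_features, 14, 1.5),
    regulation = "null")
  if (anyDuplicated(feat$feature_id))
    feat$feature_id <- make.unique(feat$feature_id, sep = "_")
  n_feat <- nrow(feat)

  # internal standards: first two metabolite channels not planted;
  # spiked at a fixed, comparable concentration -> technical noise only
  is_idx <- c(1L, 2L)
  is_ids <- feat$feature_id[is_idx]
  feat$baseline_log2[is_idx] <- c(14, 13.5)

  met_pool <- setdiff(which(feat$modality == "met"), is_idx)
  pep_pool <- which(feat$modality == "pep")
  sw_met <- sample(met_pool, cfg$n_stepwise_met)
  sw_pep <- sample(pep_pool, cfg$n_stepwise_pep)

  # direction bias: most metabolites fall, most peptides rise with stage
  n_met_dn <- ceiling(0.7 * cfg$n_stepwise_met)
  n_pep_up <- ceiling(0.7 * cfg$n_stepwise_pep)
  met_sign <- rep(c(-1, 1), c(n_met_dn, cfg$n_stepwise_met - n_met_dn))
  pep_sign <- rep(c(1, -1), c(n_pep_up, cfg$n_stepwise_pep - n_pep_up))
  sw_idx  <- c(sw_met, sw_pep)
  sw_sign <- c(met_sign, pep_sign)
  feat$regulation[sw_idx] <- ifelse(sw_sign > 0, "stepwise_up", "stepwise_down")

  # per-group shift matrix (features x groups), planted rows only
  shift <- matrix(0, n_feat, length(DKD_GROUPS),
                  dimnames = list(feat$feature_id, DKD_GROUPS))
  for (j in seq_along(sw_idx)) {
    inc <- cfg$effect_log2fc * runif(3, 0.5, 1.5)
    shift[sw_idx[j], ] <- .group_shifts(inc, sw_sign[j],
                                        cfg$grey_step_fraction)
  }

  ## ---- samples ------------------------------------------------------
  groups <- names(cfg$n_per_group)[cfg$n_per_group > 0]
  samples <- do.call(rbind, lapply(groups, function(g) {
    n <- cfg$n_per_group[[g]]
    cbind(tibble(sample_id = character(n), group = g), generate_clinical(g, n))
  }))
  n_bio <- nrow(samples)
  ord <- sample.int(n_bio)                        # randomize run order
  samples <- samples[ord, ]
  samples$sample_id <- sprintf("S%04d", seq_len(n_bio))
  samples$batch <- rep_len(seq_len(cfg$n_batches), n_bio)
  samples$is_qc <- FALSE

  # pooled QC rows, n_qc_per_batch per batch
  qc <- tibble(sample_id = sprintf("QC_b%d_i%d",
                                   rep(seq_len(cfg$n_batches),
                                       each = cfg$n_qc_per_batch),
                                   rep(seq_len(cfg$n_qc_per_batch),
                                       cfg$n_batches)),
               group = "QC", age = NA_real_, sex = NA_character_,
               bmi = NA_real_, egfr = NA_real_, uacr = NA_real_,
               malb = NA_real_,
               batch = rep(seq_len(cfg$n_batches), each = cfg$n_qc_per_batch),
               is_qc = TRUE)
  samples <- rbind(samples[, names(qc)], qc)

  ## ---- intensities --------------------------------------------------
  batch_shift <- matrix(rnorm(cfg$n_batches * n_feat, 0, cfg$batch_sd_log2),
                        cfg$n_batches, n_feat)
  batch_shift[, is_idx] <- 0                     # IS exempt from batch drift
  noise_sd <- .log2_sd_for_cv(cfg$noise_cv)

  # pooled QC composition = average biological log2 level per feature
  grp_of_bio <- samples$group[!samples$is_qc]
  pooled_mean <- feat$baseline_log2 +
    colMeans(shift[, grp_of_bio, drop = FALSE] |> t())

  n_rows <- nrow(samples) * cfg$n_replicates
  row_sample <- rep(samples$sample_id, each = cfg$n_replicates)
  row_rep    <- rep(seq_len(cfg$n_replicates), nrow(samples))
  row_batch  <- rep(samples$batch, each = cfg$n_replicates)
  row_group  <- rep(samples$group, each = cfg$n_replicates)

  mu <- matrix(0, n_rows, n_feat)
  bio <- row_group != "QC"
  mu[bio, ]  <- rep(feat$baseline_log2, each = sum(bio)) +
    t(shift[, row_group[bio], drop = FALSE])
  if (any(!bio)) mu[!bio, ] <- rep(pooled_mean, each = sum(!bio))
  mu <- mu + batch_shift[row_batch, , drop = FALSE]
  mu[, is_idx] <- rep(feat$baseline_log2[is_idx], each = n_rows)

  log2i <- mu + matrix(rnorm(n_rows * n_feat, 0, noise_sd), n_rows, n_feat)
  intensities <- 2^log2i
  dimnames(intensities) <- list(paste0(row_sample, "_r", row_rep),
                                feat$feature_id)

  structure(list(samples = as_tibble(samples), features = feat,
                 intensities = intensities,
                 replicate_map = tibble(row = rownames(intensities),
                                        sample_id = row_sample,
                                        replicate = row_rep,
                                        batch = row_batch),
                 group_shifts = shift,
                 truth = feat$feature_id[sw_idx],
                 internal_standard_ids = is_ids,
                 config = cfg),
            class = "dkd_cohort")
}

#' @export
print.dkd_cohort <- function(x, ...) {
  n_bio <- sum(!x$samples$is_qc)
  cat("Synthetic DKD urine cohort\n",
      " samples: ", n_bio, " biological + ", sum(x$samples$is_qc),
      " QC injections; ", x$config$n_replicates, " replicates each\n",
      " features: ", sum(x$features$modality == "met"), " metabolite + ",
      sum(x$features$modality == "pep"), " peptide (",
      length(x$truth), " planted stepwise)\n", sep = "")
  print(table(x$samples$group[!x$samples$is_qc]))
  invisible(x)
}

#' Render replicate intensities as synthetic spectra
#'
#' Projects one modality's feature intensities onto an m/z grid: each
#' feature becomes a Gaussian peak centred at its m/z with amplitude
#' proportional to the replicate's intensity, over additive Gaussian
#' baseline noise. Intended as fixture source for the peak picker.
#'
#' @param cohort a `dkd_cohort`.
#' @param rows which intensity rows (sample_replicate names or indices)
#'   to render; default all.
#' @param modality "met" or "pep".
#' @param grid_step m/z grid spacing (default 0.01 Da for metabolites,
#'   1 Da for peptides).
#' @param peak_width Gaussian SD of peaks (default 0.05 Da / 2 Da).
#' @param amp_scale amplitude per intensity unit (default 1).
#' @param noise_sd baseline noise SD, in amplitude units; default 1/50
#'   of the median peak amplitude.
#' @return list of spectra, each a list with `mz`, `intensity`,
#'   `sample_id`, `replicate`, `modality`. Features whose centres sit
#'   closer than `2 * peak_width` trigger a warning record in the
#'   `overlap_warnings` attribute.
#' @export
emit_spectra <- function(cohort, rows = NULL, modality = c("met", "pep"),
                         grid_step = NULL, peak_width = NULL,
                         amp_scale = 1, noise_sd = NULL) {
  stopifnot(inherits(cohort, "dkd_cohort"))
  modality <- match.arg(modality)
  fsel <- cohort$features$modality == modality
  mzs <- cohort$features$mz[fsel]
  if (is.null(grid_step)) grid_step <- if (modality == "met") 0.01 else 1
  if (is.null(peak_width)) peak_width <- if (modality == "met") 0.05 else 2
  if (is.null(rows)) rows <- rownames(cohort$intensities)
  if (is.numeric(rows)) rows <- rownames(cohort$intensities)[rows]

  overlaps <- which(diff(sort(mzs)) < 2 * peak_width)
  warn <- if (length(overlaps))
    sprintf("%d feature pairs closer than 2 x peak width (%g)",
            length(overlaps), peak_width) else character()

  rng <- range(mzs) + c(-1, 1) * 10 * peak_width
  grid <- seq(rng[1], rng[2], by = grid_step)
  spectra <- lapply(rows, function(r) {
    amps <- amp_scale * cohort$intensities[r, fsel]
    if (is.null(noise_sd)) noise_sd <- median(amps) / 50
    y <- rnorm(length(grid), 0, noise_sd)
    for (j in seq_along(mzs)) {
      win <- which(abs(grid - mzs[j]) < 6 * peak_width)
      y[win] <- y[win] + amps[j] * exp(-((grid[win] - mzs[j])^2) /
                                         (2 * peak_width^2))
    }
    parts <- strsplit(r, "_r(?=[0-9]+$)", perl = TRUE)[[1]]
    list(mz = grid, intensity = pmax(y, 0), sample_id = parts[1],
         replicate = as.integer(parts[2]), modality = modality)
  })
  names(spectra) <- rows
  attr(spectra, "overlap_warnings") <- warn
  spectra
}

#' Write a cohort to plain-text files
#'
#' @param cohort a `dkd_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written: feature matrix CSV (rows =
#'   sample_replicate), metadata TSV, and truth JSON.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat_path <- file.path(dir, "feature_matrix.csv")
  meta_path <- file.path(dir, "metadata.tsv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(data.frame(row = rownames(cohort$intensities),
                              cohort$intensities, check.names = FALSE),
                   mat_path, row.names = FALSE)
  meta <- merge(cohort$replicate_map, cohort$samples, by = "sample_id")
  utils::write.table(meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(truth = cohort$truth,
                            internal_standard_ids =
                              cohort$internal_standard_ids),
                       truth_path)
  invisible(c(mat_path, meta_path, truth_path))
}
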