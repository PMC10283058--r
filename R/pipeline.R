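#' Default pipeline configuration
#'
#' Nested list of per-stage parameters for [run_pipeline()]. Stages
#' run in the fixed dependency order: simulate, preprocess,
#' differential, multivariate, harness, cascade, network, pathway.
#' All randomness flows from the single global `seed` via per-stage
#' derived seeds (`seed * 100 + stage index`).
#'
#' @param stages subset of the eight stage names to run (dependencies
#'   of a requested stage are added automatically).
#' @param seed global seed (small integer).
#' @param cohort a [cohort_config()]; its own seed is overridden by
#'   the derived simulate-stage seed.
#' @param q_threshold significance threshold for differential stages.
#' @param harness_pair two group labels for the single- vs multi-omics
#'   comparison (default T2DM vs EARLY_DKD).
#' @param gmt optional GMT file path for the pathway stage (when NULL
#'   the stage scores synthetic pathway sets built over the planted
#'   features).
#' @return list of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "preprocess", "differential",
                                  "multivariate", "harness", "cascade",
                                  "network", "pathway"),
                       seed = 1L, cohort = cohort_config(),
                       q_threshold = 0.05,
                       harness_pair = c("T2DM", "EARLY_DKD"),
                       gmt = NULL) {
  order_all <- c("simulate", "preprocess", "differential", "multivariate",
                 "harness", "cascade", "network", "pathway")
  stages <- match.arg(stages, order_all, several.ok = TRUE)
  # every later stage needs the matrix from simulate+preprocess and
  # the differential results feed network/pathway
  need <- unique(c("simulate", "preprocess",
                   if (any(stages %in% c("network", "pathway", "harness",
                                         "differential"))) "differential",
                   stages))
  stages <- order_all[order_all %in% need]
  if (!is.null(gmt) && !file.exists(gmt)) stop("missing input: ", gmt)
  structure(list(stages = stages, seed = as.integer(seed),
                 cohort = cohort, q_threshold = q_threshold,
                 harness_pair = harness_pair, gmt = gmt),
            class = "run_config")
}

.stage_seed <- function(config, stage) {
  order_all <- c("simulate", "preprocess", "differential", "multivariate",
                 "harness", "cascade", "network", "pathway")
  config$seed * 100L + match(stage, order_all)
}

# the six pairwise contrasts among the four staged groups
.pairwise_contrasts <- function() {
  grps <- c("HC", "T2DM", "EARLY_DKD", "OVERT_DKD")
  cmb <- utils::combn(grps, 2)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

#' Replicate-average, normalize and log a cohort into analysis matrices
#'
#' Standard preprocessing applied to a generated cohort: cubic-spline
#' quantile normalization of the replicate-level table (per modality),
#' QC report, replicate averaging, and the split into metabolite and
#' peptide matrices of biological samples.
#'
#' @param cohort a `dkd_cohort`.
#' @return list: `matrix` (biological samples x all features,
#'   normalized intensities), `met`, `pep` (modality submatrices),
#'   `groups` (named by sample id), `qc` (list of per-modality
#'   `qc_report`s), `covariates` (tibble).
#' @export
preprocess_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "dkd_cohort"))
  feat <- cohort$features
  qc_rows_all <- cohort$replicate_map$row[
    cohort$replicate_map$sample_id %in%
      cohort$samples$sample_id[cohort$samples$is_qc]]
  batch_of <- stats::setNames(cohort$replicate_map$batch,
                              cohort$replicate_map$row)
  norm <- cohort$intensities
  qc <- list()
  for (mod in c("met", "pep")) {
    cols <- feat$feature_id[feat$modality == mod]
    norm[, cols] <- cubic_spline_normalize(cohort$intensities[, cols,
                                                              drop = FALSE])
    is_ids <- if (mod == "met") cohort$internal_standard_ids else NULL
    qc[[mod]] <- qc_report(norm[, cols, drop = FALSE], qc_rows_all,
                           is_ids = is_ids, batch = batch_of)
  }
  avg <- average_replicates(norm, cohort$replicate_map)
  bio <- cohort$samples[!cohort$samples$is_qc, ]
  avg <- avg[bio$sample_id, , drop = FALSE]
  list(matrix = avg,
       met = avg[, feat$feature_id[feat$modality == "met"], drop = FALSE],
       pep = avg[, feat$feature_id[feat$modality == "pep"], drop = FALSE],
       groups = stats::setNames(bio$group, bio$sample_id),
       qc = qc,
       covariates = bio)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in dependency order on a synthetic
#' cohort, writing plain CSV/TSV/JSON outputs and a reproducibility
#' manifest (stage parameters, derived seeds, output checksums) to
#' `out_dir`. A stage failure aborts with the stage name; outputs of
#' completed stages are retained and marked in the manifest.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly (list; also written as
#'   manifest.json).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("uromics")),
                   seed = config$seed, stages = list())
  outputs <- character()
  note <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)
  state <- new.env()

  run_stage <- function(stage, fn) {
    note("stage ", stage)
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      .write_manifest(manifest, outputs, out_dir)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- list(
      status = "ok", seed = .stage_seed(config, stage),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2),
      outputs = res)
    outputs <<- c(outputs, res)
  }

  if ("simulate" %in% config$stages) run_stage("simulate", function() {
    cfg <- config$cohort
    cfg$seed <- .stage_seed(config, "simulate")
    state$cohort <- generate_cohort(cfg)
    write_cohort(state$cohort, file.path(out_dir, "cohort"))
  })

  if ("preprocess" %in% config$stages) run_stage("preprocess", function() {
    state$pp <- preprocess_cohort(state$cohort)
    p1 <- file.path(out_dir, "feature_matrix_normalized.csv")
    utils::write.csv(data.frame(sample_id = rownames(state$pp$matrix),
                                state$pp$matrix, check.names = FALSE),
                     p1, row.names = FALSE)
    p2 <- file.path(out_dir, "qc_report.json")
    jsonlite::write_json(lapply(state$pp$qc, function(q)
      q[c("replicate_spearman", "intra_batch_rsd_median",
          "inter_batch_rsd_median", "internal_standard_ratio_rsd",
          "pass_flags")]), p2, auto_unbox = TRUE, digits = NA)
    c(p1, p2)
  })

  if ("differential" %in% config$stages) run_stage("differential",
                                                   function() {
    groups <- state$pp$groups
    state$diff <- lapply(.pairwise_contrasts(), function(ct) {
      ids_a <- names(groups)[groups == ct[1]]
      ids_b <- names(groups)[groups == ct[2]]
      ttest_features(state$pp$matrix, ids_a, ids_b,
                     contrast = paste(ct[1], "vs", ct[2]))
    })
    names(state$diff) <- vapply(state$diff, function(d) d$contrast[1],
                                character(1))
    state$stepwise <- stepwise_intersection(state$diff,
                                            q_threshold =
                                              config$q_threshold)
    p1 <- file.path(out_dir, "differential_results.csv")
    utils::write.csv(do.call(rbind, state$diff), p1, row.names = FALSE)
    p2 <- file.path(out_dir, "stepwise_features.json")
    jsonlite::write_json(list(features = state$stepwise$features,
                              venn_counts = state$stepwise$venn_counts),
                         p2, auto_unbox = TRUE)
    c(p1, p2)
  })

  if ("multivariate" %in% config$stages) run_stage("multivariate",
                                                   function() {
    groups <- state$pp$groups
    pair <- config$harness_pair
    sel <- names(groups)[groups %in% pair]
    x <- log2(state$pp$matrix[sel, , drop = FALSE])
    set.seed(.stage_seed(config, "multivariate"))
    m <- fit_oplsda(x, factor(groups[sel], levels = pair),
                    n_orthogonal = 1)
    q2 <- oplsda_q2(x, factor(groups[sel], levels = pair),
                    n_orthogonal = 1,
                    seed = .stage_seed(config, "multivariate"))
    pca <- fit_pca(x, 2)
    p1 <- file.path(out_dir, "oplsda_scores.csv")
    utils::write.csv(data.frame(sample_id = sel, group = groups[sel],
                                t_predictive = m$t,
                                t_orthogonal1 = m$t_ortho[, 1]),
                     p1, row.names = FALSE)
    p2 <- file.path(out_dir, "multivariate_summary.json")
    jsonlite::write_json(list(r2x = as.list(m$r2x), r2y = m$r2y, q2 = q2,
                              pca_explained_variance =
                                pca$explained_variance_ratio),
                         p2, auto_unbox = TRUE, digits = NA)
    c(p1, p2)
  })

  if ("harness" %in% config$stages) run_stage("harness", function() {
    groups <- state$pp$groups
    pair <- config$harness_pair
    sel <- names(groups)[groups %in% pair]
    markers <- state$stepwise$features
    if (length(markers) < 2) markers <- colnames(state$pp$matrix)
    met_ids <- intersect(markers, colnames(state$pp$met))
    pep_ids <- intersect(markers, colnames(state$pp$pep))
    cmp <- compare_single_vs_multiomics(
      log2(state$pp$met[sel, met_ids, drop = FALSE]),
      log2(state$pp$pep[sel, pep_ids, drop = FALSE]),
      factor(groups[sel], levels = pair),
      seed = .stage_seed(config, "harness"))
    state$harness <- cmp
    p1 <- file.path(out_dir, "ml_comparison.csv")
    utils::write.csv(cmp$metrics, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "ml_mean_accuracy.json")
    jsonlite::write_json(as.list(cmp$mean_accuracy), p2,
                         auto_unbox = TRUE, digits = NA)
    c(p1, p2)
  })

  if ("cascade" %in% config$stages) run_stage("cascade", function() {
    groups <- state$pp$groups
    plan <- split_discovery_validation(names(groups), groups,
                                       seed = .stage_seed(config,
                                                          "cascade"))
    set.seed(.stage_seed(config, "cascade"))
    model <- fit_cascade(state$pp$matrix[plan$discovery, , drop = FALSE],
                         groups[plan$discovery],
                         seed = .stage_seed(config, "cascade"))
    pred <- predict_cascade(model,
                            state$pp$matrix[plan$validation, ,
                                            drop = FALSE])
    pred$true_group <- groups[plan$validation]
    state$cascade <- list(model = model, pred = pred, plan = plan)
    p1 <- file.path(out_dir, "cascade_model.json")
    cascade_to_json(model, p1)
    p2 <- file.path(out_dir, "cascade_predictions.csv")
    utils::write.csv(pred, p2, row.names = FALSE)
    c(p1, p2)
  })

  if ("network" %in% config$stages) run_stage("network", function() {
    groups <- state$pp$groups
    feats <- state$stepwise$features
    if (length(feats) < 3) feats <- colnames(state$pp$matrix)[1:10]
    paths <- character()
    for (g in c("T2DM", "EARLY_DKD", "OVERT_DKD")) {
      rows <- names(groups)[groups == g]
      net <- correlation_network(log2(state$pp$matrix), feats, rows)
      p <- file.path(out_dir, paste0("network_", g, ".tsv"))
      utils::write.table(net$edges, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      paths <- c(paths, p)
    }
    paths
  })

  if ("pathway" %in% config$stages) run_stage("pathway", function() {
    universe <- colnames(state$pp$matrix)
    pathways <- if (!is.null(config$gmt)) read_gmt(config$gmt) else {
      # synthetic sets: planted features plus random fillers
      set.seed(.stage_seed(config, "pathway"))
      list(planted_stepwise = state$cohort$truth,
           random_a = sample(universe, 20),
           random_b = sample(universe, 20))
    }
    enr <- enrich_hypergeometric(state$stepwise$features, pathways,
                                 universe)
    diff1 <- state$diff[["T2DM vs EARLY_DKD"]]
    jg <- vapply(names(pathways), function(pw) {
      m <- match(intersect(pathways[[pw]], diff1$feature_id),
                 diff1$feature_id)
      if (!length(m)) return(NA_real_)
      as.numeric(jg_score(diff1$log2fc[m], diff1$p[m]))
    }, numeric(1))
    enr$jg_score <- jg[enr$pathway]
    p1 <- file.path(out_dir, "pathway_scores.csv")
    utils::write.csv(enr, p1, row.names = FALSE)
    p1
  })

  manifest <- .write_manifest(manifest, outputs, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, outputs, out_dir) {
  manifest$checksums <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
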