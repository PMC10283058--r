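#' Biweight midcorrelation
#'
#' Robust correlation based on Tukey biweights around medians: values
#' are median-centred, weighted by `(1 - u^2)^2` for `|u| < 1` with
#' `u = deviation / (9 * MAD)` (MAD unscaled here, i.e. the raw median
#' absolute deviation), and correlated by the normalized weighted
#' cross-product. When either vector has zero MAD the function falls
#' back to Pearson correlation and flags it.
#'
#' @param x,y numeric vectors, length >= 4.
#' @return correlation in `[-1, 1]` with attribute `fallback_pearson`
#'   (logical).
#' @export
bicor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  weighted_dev <- function(v) {
    m <- stats::median(v)
    madv <- stats::median(abs(v - m))
    if (madv == 0) return(NULL)
    u <- (v - m) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - m) * w
  }
  a <- weighted_dev(x); b <- weighted_dev(y)
  if (is.null(a) || is.null(b)) {
    r <- stats::cor(x, y)
    return(structure(r, fallback_pearson = TRUE))
  }
  denom <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (denom == 0) stop("degenerate input: all weights vanish")
  structure(sum(a * b) / denom, fallback_pearson = FALSE)
}

# Student-t p-value for a correlation at n observations
.cor_p <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}

#' Within-group feature-feature biweight midcorrelation network
#'
#' All pairwise biweight midcorrelations among the selected features
#' within one sample group; edges are kept when `|r|` exceeds
#' `r_threshold` and the Student-t p-value (n - 2 df) is below
#' `p_threshold`. Positive and negative edge counts summarize the
#' group's co-regulation structure.
#'
#' @param mat samples x features matrix (log2 recommended).
#' @param features feature ids to correlate (default all columns).
#' @param group_rows row names of the group's samples (>= 4).
#' @param r_threshold absolute correlation threshold (default 0.3).
#' @param p_threshold p-value threshold (default 0.05).
#' @return list: `edges` tibble (feature_a, feature_b, r, p, sign),
#'   `n_positive`, `n_negative`, `n_samples`.
#' @export
correlation_network <- function(mat, features = colnames(mat),
                                group_rows = rownames(mat),
                                r_threshold = 0.3, p_threshold = 0.05) {
  if (length(group_rows) < 4)
    stop("need >= 4 samples in the group")
  x <- mat[group_rows, features, drop = FALSE]
  k <- ncol(x)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      r <- as.numeric(bicor(x[, i], x[, j]))
      p <- .cor_p(r, nrow(x))
      if (abs(r) > r_threshold && p < p_threshold)
        out[[length(out) + 1]] <- tibble::tibble(
          feature_a = features[i], feature_b = features[j],
          r = r, p = p, sign = ifelse(r > 0, "positive", "negative"))
    }
  }
  edges <- if (length(out)) do.call(rbind, out) else
    tibble::tibble(feature_a = character(), feature_b = character(),
                   r = numeric(), p = numeric(), sign = character())
  list(edges = edges,
       n_positive = sum(edges$sign == "positive"),
       n_negative = sum(edges$sign == "negative"),
       n_samples = length(group_rows))
}

#' Signed pathway perturbation (JG) score
#'
#' Stouffer-type aggregate of member-level perturbation: each member's
#' two-sided p-value is mapped to a signed normal quantile
#' `z_i = sign(log2fc_i) * qnorm(1 - p_i / 2)` and the score is
#' `sum(z_i) / sqrt(k)` for a pathway of k members, so coherent
#' up-regulation yields a large positive score, coherent
#' down-regulation a large negative one, and balanced changes cancel.
#'
#' @param log2fc member log2 fold changes (or, alternatively, pass
#'   signed z-scores via `z`).
#' @param p member two-sided p-values; p = 0 is capped at 1e-300 and
#'   flagged.
#' @param z optional signed z-scores, overriding `log2fc`/`p`.
#' @return score with attribute `capped` (logical).
#' @export
jg_score <- function(log2fc = NULL, p = NULL, z = NULL) {
  if (is.null(z)) {
    stopifnot(!is.null(log2fc), !is.null(p),
              length(log2fc) == length(p))
    if (!length(p)) stop("pathway must have >= 1 member")
    capped <- p <= 0
    p[capped] <- 1e-300
    z <- sign(log2fc) * stats::qnorm(p / 2, lower.tail = FALSE)
  } else capped <- rep(FALSE, length(z))
  stopifnot(all(is.finite(z)))
  structure(sum(z) / sqrt(length(z)), capped = any(capped))
}

#' Hypergeometric pathway over-representation
#'
#' One-sided upper-tail hypergeometric test per pathway: with a
#' universe of N features, K pathway members in the universe, n
#' selected features and k selected members, the p-value is
#' `P(X >= k)` for X hypergeometric(N, K, n). BH adjustment across
#' pathways.
#'
#' @param selected character vector of selected feature ids (must be
#'   within the universe).
#' @param pathways named list of member id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all testable feature ids.
#' @return tibble: pathway, k (selected members), K (members in
#'   universe), n, N, p, q, members (comma-joined selected members).
#' @export
enrich_hypergeometric <- function(selected, pathways, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  selected <- unique(intersect(selected, universe))
  n <- length(selected); N <- length(universe)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], universe)
    K <- length(members)
    hit <- intersect(members, selected)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(pathway = pw, k = k, K = K, n = n, N = N, p = p,
                   members = paste(hit, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), ]
}

#' Joint metabolite + peptide-source-protein pathway enrichment
#'
#' Hypergeometric over-representation on the pooled namespace: the
#' universe is the union of the metabolite and protein universes
#' (disjoint id spaces) and pathway sets may annotate either entity
#' type, so a pathway can score through metabolite hits, protein hits,
#' or both.
#'
#' @param met_hits,prot_hits selected metabolite / protein ids.
#' @param pathways named list of member vectors over both namespaces.
#' @param met_universe,prot_universe the two testable universes.
#' @return tibble as [enrich_hypergeometric()] plus per-type hit
#'   counts k_met, k_prot.
#' @export
joint_enrichment <- function(met_hits, prot_hits, pathways,
                             met_universe, prot_universe) {
  universe <- union(met_universe, prot_universe)
  res <- enrich_hypergeometric(c(met_hits, prot_hits), pathways, universe)
  hitlists <- strsplit(res$members, ",", fixed = TRUE)
  res$k_met <- vapply(hitlists, function(h)
    sum(h %in% met_universe), integer(1))
  res$k_prot <- vapply(hitlists, function(h)
    sum(h %in% prot_universe), integer(1))
  res
}

#' Read pathway sets from a GMT file
#'
#' Uses `fgsea::gmtPathways` when available, else a minimal parser
#' (tab-separated: name, description, members...).
#'
#' @param path GMT file path.
#' @return named list of member id vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' Write pathway sets to a GMT file
#' @param pathways named list of member vectors.
#' @param path output path.
#' @param descriptions optional descriptions (default "na").
#' @return path, invisibly.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(pathways))
  lines <- vapply(seq_along(pathways), function(i)
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
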