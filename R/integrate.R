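## The integrative core: screen ECM metrics by Spearman correlation with
## the anti-TME score, combine the selected metrics into a per-sample
## structure index, scale group means for radar comparison, and rank
## matrisome genes as candidate targets across two tumor models.

#' Spearman rank correlation with undefined-value handling
#'
#' Pairs with a missing value in either vector are dropped. Without ties
#' the p-value comes from the exact permutation distribution of the rank
#' statistic (computed exactly for small n, and by the standard AS 89
#' approximation of that distribution for larger n); with ties the
#' t-approximation is used. A constant vector gives an undefined result
#' (`NA` with a note), never a silent zero.
#'
#' @param x,y numeric vectors of equal length.
#' @return List: `r`, `p`, `n` (complete pairs), `note` (`NA` or a
#'   reason the correlation is undefined).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4)
    return(list(r = NA_real_, p = NA_real_, n = n,
                note = "fewer than 4 complete pairs"))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n,
                note = "constant vector"))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = !ties))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, note = NA_character_)
}

#' Screen metrics by correlation with a per-sample score
#'
#' Computes the Spearman correlation of every metric column against the
#' score vector and classifies each metric as `positive`
#' (`r >= r_thresh` and `p <= p_thresh`), `negative`
#' (`r <= -r_thresh` and `p <= p_thresh`) or `none`. Metrics with fewer
#' than 4 complete pairs or constant values are flagged in the `note`
#' column rather than silently dropped.
#'
#' @param metrics data.frame or matrix, samples x metrics; rows aligned
#'   with `scores`.
#' @param scores numeric vector, one score per sample.
#' @param r_thresh correlation magnitude floor (default 0.5).
#' @param p_thresh p-value ceiling (default 0.05).
#' @return Data.frame: `metric`, `spearman_r`, `p_value`, `n`, `sign`,
#'   `note`.
#' @export
select_correlated_metrics <- function(metrics, scores, r_thresh = 0.5,
                                      p_thresh = 0.05) {
  metrics <- as.data.frame(metrics)
  stopifnot(nrow(metrics) == length(scores))
  rows <- lapply(names(metrics), function(m) {
    sc <- spearman_cor(metrics[[m]], scores)
    sign <- if (is.na(sc$r)) "none"
      else if (sc$r >= r_thresh && sc$p <= p_thresh) "positive"
      else if (sc$r <= -r_thresh && sc$p <= p_thresh) "negative"
      else "none"
    data.frame(metric = m, spearman_r = sc$r, p_value = sc$p, n = sc$n,
               sign = sign, note = sc$note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sample structure index from selected metric sets
#'
#' Each selected metric is min-max scaled to [0, 1] across samples (or
#' z-scored with `scaling = "zscore"`); the index for a sample is
#' `(mean of scaled positively-correlated metrics + delta) /
#'  (mean of scaled negatively-correlated metrics + delta)`. The
#' smoothing constant `delta` keeps the ratio finite when a sample
#' scales to 0 on every negative metric. The index is invariant to
#' affine rescaling of any raw metric.
#'
#' @param metrics data.frame or matrix, samples x metrics (rownames are
#'   sample ids).
#' @param positive,negative disjoint character vectors of metric names.
#' @param delta smoothing constant (default 0.1).
#' @param scaling `"minmax"` (default) or `"zscore"`.
#' @return Object of class `structure_index`: list with `index` (named
#'   per-sample vector), `positive`, `negative`, `scaling` (per-metric
#'   min/max record), `delta`.
#' @export
structure_index <- function(metrics, positive, negative, delta = 0.1,
                            scaling = c("minmax", "zscore")) {
  scaling <- match.arg(scaling)
  metrics <- as.data.frame(metrics)
  if (length(positive) == 0 || length(negative) == 0)
    stop("positive and negative metric sets must both be nonempty")
  if (length(intersect(positive, negative)))
    stop("positive and negative metric sets must be disjoint")
  sel <- c(positive, negative)
  missing <- setdiff(sel, names(metrics))
  if (length(missing))
    stop("metrics not in table: ", paste(missing, collapse = ", "))
  scaled <- list()
  record <- data.frame(metric = sel, min = NA_real_, max = NA_real_)
  for (i in seq_along(sel)) {
    v <- metrics[[sel[i]]]
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(diff(rng)) || diff(rng) == 0)
      stop("metric does not vary across samples: ", sel[i])
    record$min[i] <- rng[1]; record$max[i] <- rng[2]
    scaled[[sel[i]]] <- if (scaling == "minmax")
      (v - rng[1]) / diff(rng)
    else
      (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  }
  pos_mean <- rowMeans(as.data.frame(scaled[positive]), na.rm = TRUE)
  neg_mean <- rowMeans(as.data.frame(scaled[negative]), na.rm = TRUE)
  idx <- (pos_mean + delta) / (neg_mean + delta)
  names(idx) <- rownames(metrics)
  structure(list(index = idx, positive = positive, negative = negative,
                 scaling = record, delta = delta, scaling_mode = scaling),
            class = "structure_index")
}

#' @export
print.structure_index <- function(x, ...) {
  cat("structure_index over", length(x$index), "samples;",
      length(x$positive), "positive /", length(x$negative),
      "negative metrics; delta =", x$delta, "\n")
  invisible(x)
}

#' Rank matrisome genes as candidate targets across two models
#'
#' For each gene, the Spearman correlation of its expression with the
#' structure index is computed in each model. A gene is a candidate when
#' the association is strong and significant in model A
#' (`|r_A| >= r_thresh`, `p_A <= p_thresh`) but not significant in model
#' B (`p_B > p_thresh`); both directions are retained with their sign.
#' Genes constant in a model get an undefined (`NA`) correlation there
#' and cannot be candidates. Matrisome genes absent from the expression
#' universe are reported in the `missing_genes` attribute.
#'
#' @param expr_a,expr_b numeric matrices, genes x samples, one per model.
#' @param index_a,index_b structure-index vectors aligned with the
#'   corresponding matrix columns.
#' @param matrisome character vector of matrisome gene ids.
#' @param r_thresh,p_thresh screen thresholds (defaults 0.5, 0.05).
#' @return Data.frame sorted by `|r_modelA|` descending: `gene`,
#'   `r_modelA`, `p_modelA`, `r_modelB`, `p_modelB`, `direction`,
#'   `candidate`.
#' @export
rank_matrisome_targets <- function(expr_a, index_a, expr_b, index_b,
                                   matrisome, r_thresh = 0.5,
                                   p_thresh = 0.05) {
  stopifnot(is.matrix(expr_a), is.matrix(expr_b),
            ncol(expr_a) == length(index_a),
            ncol(expr_b) == length(index_b))
  if (sum(!is.na(index_a)) < 4 || sum(!is.na(index_b)) < 4)
    stop("each model needs at least 4 samples with index values")
  present <- intersect(matrisome,
                       intersect(rownames(expr_a), rownames(expr_b)))
  missing <- setdiff(matrisome, present)
  rows <- lapply(present, function(g) {
    a <- spearman_cor(expr_a[g, ], index_a)
    b <- spearman_cor(expr_b[g, ], index_b)
    cand <- !is.na(a$r) && abs(a$r) >= r_thresh && a$p <= p_thresh &&
      !is.na(b$p) && b$p > p_thresh
    data.frame(gene = g, r_modelA = a$r, p_modelA = a$p,
               r_modelB = b$r, p_modelB = b$p,
               direction = if (is.na(a$r)) "none"
                           else if (a$r >= 0) "positive" else "negative",
               candidate = cand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$r_modelA), out$gene), ]
  rownames(out) <- NULL
  attr(out, "missing_genes") <- missing
  out
}

#' Scale group means for radar comparison
#'
#' Per metric, group means are scaled to `(value - min) / (max - min)`
#' over the groups; when a metric is identical across groups every group
#' maps to 1.
#'
#' @param group_means matrix or data.frame, groups x metrics.
#' @return Data.frame of the same shape with values in [0, 1].
#' @export
radar_scale <- function(group_means) {
  gm <- as.data.frame(group_means)
  if (nrow(gm) < 2) stop("need at least 2 groups")
  out <- gm
  for (m in names(gm)) {
    rng <- range(gm[[m]])
    out[[m]] <- if (diff(rng) == 0) rep(1, nrow(gm))
                else (gm[[m]] - rng[1]) / diff(rng)
  }
  out
}

#' Run the full metric-screen / structure-index / target-ranking pipeline
#'
#' Convenience wrapper over the integrative stages, operating on a
#' cohort as produced by [simulate_cohort()] (or any list with the same
#' shape): scores the expression of each model with the signature
#' collection, screens the model-A metric panel against the model-A
#' anti-TME score, computes the structure index for both models with the
#' model-A-selected metric sets, and ranks the given genes as candidate
#' targets.
#'
#' @param cohort list with `expr` (genes x samples), `samples`
#'   (data.frame with `sample`, `model` columns), `metrics` (samples x
#'   metrics data.frame).
#' @param sigs a [signature_collection()].
#' @param target_genes genes to rank (default: all genes).
#' @param r_thresh,p_thresh screen thresholds.
#' @param delta structure-index smoothing constant.
#' @return List: `scores` (per-sample score table), `screen` (metric
#'   correlation table, model A), `positive`, `negative`, `index_a`,
#'   `index_b`, `targets` (or `NULL` when a metric set came up empty, in
#'   which case `error` records the failure).
#' @export
structure_pipeline <- function(cohort, sigs, target_genes = NULL,
                               r_thresh = 0.5, p_thresh = 0.05,
                               delta = 0.1) {
  smp <- cohort$samples
  a_ids <- smp$sample[smp$model == "A"]
  b_ids <- smp$sample[smp$model == "B"]
  scores <- score_collection(cohort$expr, sigs)
  anti <- scores[["anti_TME"]]
  names(anti) <- rownames(scores)
  screen <- select_correlated_metrics(cohort$metrics[a_ids, , drop = FALSE],
                                      anti[a_ids], r_thresh, p_thresh)
  pos <- screen$metric[screen$sign == "positive"]
  neg <- screen$metric[screen$sign == "negative"]
  if (length(pos) == 0 || length(neg) == 0) {
    return(list(scores = scores, screen = screen, positive = pos,
                negative = neg, index_a = NULL, index_b = NULL,
                targets = NULL,
                error = "metric screen produced an empty positive or negative set"))
  }
  idx_a <- structure_index(cohort$metrics[a_ids, , drop = FALSE],
                           pos, neg, delta)
  idx_b <- structure_index(cohort$metrics[b_ids, , drop = FALSE],
                           pos, neg, delta)
  if (is.null(target_genes)) target_genes <- rownames(cohort$expr)
  targets <- rank_matrisome_targets(
    cohort$expr[, a_ids, drop = FALSE], idx_a$index,
    cohort$expr[, b_ids, drop = FALSE], idx_b$index,
    target_genes, r_thresh, p_thresh)
  list(scores = scores, screen = screen, positive = pos, negative = neg,
       index_a = idx_a, index_b = idx_b, targets = targets, error = NULL)
}
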