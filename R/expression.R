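## Bulk expression preprocessing and per-sample gene-set scoring: cpm
## detection filter, log2 RPKM, the ssGSEA running-sum statistic, the
## composite anti-TME score, gene K-means clustering, and the
## hypergeometric over-representation test.

#' Read gene sets from a GMT file
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (second GMT column).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' A collection of gene signatures with a composite anti-TME set
#'
#' The anti-tumor-microenvironment (anti-TME) signature is the union of
#' the member sets -- by default those named `M1`, `Th1`,
#' `Anti_tumor_cytokines` and `B_cells` -- with duplicates counted once.
#'
#' @param sets named list of nonempty character vectors.
#' @param anti_tme_members names of the sets whose union forms the
#'   composite anti-TME signature.
#' @return An object of class `signature_collection`.
#' @export
signature_collection <- function(sets,
                                 anti_tme_members = c("M1", "Th1",
                                                      "Anti_tumor_cytokines",
                                                      "B_cells")) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(lengths(sets) == 0)) stop("gene sets must be nonempty")
  missing <- setdiff(anti_tme_members, names(sets))
  if (length(missing))
    stop("anti-TME member sets not found: ", paste(missing, collapse = ", "))
  structure(list(sets = sets, anti_tme_members = anti_tme_members),
            class = "signature_collection")
}

#' Genes of the composite anti-TME signature (exact union, no duplicates)
#' @param sigs a [signature_collection()].
#' @return Character vector.
#' @export
anti_tme_genes <- function(sigs) {
  stopifnot(inherits(sigs, "signature_collection"))
  sort(unique(unlist(sigs$sets[sigs$anti_tme_members], use.names = FALSE)))
}

#' Filter genes by counts-per-million detection
#'
#' Keeps a gene if its cpm (`count * 1e6 / library_size`) is at least
#' `cpm_min` in at least `ceiling(sample_fraction * n_samples)` samples;
#' the fraction rule is inclusive, so with 4 samples a gene detected in
#' exactly 1 sample meets the 25% default.
#'
#' @param counts integer matrix, genes x samples (rownames = gene ids).
#' @param cpm_min cpm detection threshold (default 1).
#' @param sample_fraction required fraction of samples (default 0.25).
#' @return The filtered count matrix.
#' @export
cpm_filter <- function(counts, cpm_min = 1, sample_fraction = 0.25) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("zero library size")
  v <- edgeR::cpm(counts)
  need <- ceiling(sample_fraction * ncol(counts))
  counts[rowSums(v >= cpm_min) >= need, , drop = FALSE]
}

#' Log2 RPKM transform
#'
#' `RPKM = count * 1e9 / (library_size * gene_length_bp)`; the returned
#' value is `log2(RPKM + pseudocount)`.
#'
#' @param counts integer matrix, genes x samples.
#' @param gene_lengths_bp named numeric vector of gene lengths in bp;
#'   must cover every gene in `counts`.
#' @param pseudocount added before the log (default 1).
#' @return Numeric matrix of log2 RPKM values.
#' @export
log_rpkm <- function(counts, gene_lengths_bp, pseudocount = 1) {
  stopifnot(is.matrix(counts))
  len <- gene_lengths_bp[rownames(counts)]
  if (anyNA(len))
    stop("missing gene length for: ",
         paste(head(rownames(counts)[is.na(len)], 5), collapse = ", "))
  if (any(len <= 0)) stop("gene lengths must be positive")
  lib <- colSums(counts)
  rpkm <- sweep(counts * 1e9 / len, 2, lib, "/")
  log2(rpkm + pseudocount)
}

#' Single-sample gene-set enrichment score (ssGSEA statistic)
#'
#' Genes are ranked by descending expression (ties broken by gene
#' identifier, so the score is fully deterministic); walking down the
#' ranked list, the in-set running sum increments by the gene's rank
#' weight `rank^weight_exponent` (normalized over the set) and the
#' out-of-set running sum by `1 / (n - |set|)`. The score is the sum of
#' the running differences divided by the number of genes; it is
#' invariant under any strictly monotone transform of the expression
#' values. When the set equals the whole universe the score is 0 by
#' convention.
#'
#' @param x named numeric vector: one sample's expression values.
#' @param gene_set character vector of gene ids.
#' @param weight_exponent rank weight exponent (default 0.25).
#' @return A single numeric score.
#' @export
ssgsea_score <- function(x, gene_set, weight_exponent = 0.25) {
  stopifnot(!is.null(names(x)))
  gene_set <- unique(gene_set)
  inset <- names(x) %in% gene_set
  k <- sum(inset)
  n <- length(x)
  if (k < 2) stop("fewer than 2 set genes present in the expression vector")
  if (k == n) return(0)
  ord <- order(-x, names(x))
  inset <- inset[ord]
  rank_val <- n - seq_len(n) + 1          # top gene gets weight n
  w <- rank_val^weight_exponent
  p_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  p_out <- cumsum(!inset) / (n - k)
  sum(p_in - p_out) / n
}

#' Score every signature (and the composite anti-TME set) per sample
#'
#' @param expr numeric matrix, genes x samples, log-normalized.
#' @param sigs a [signature_collection()].
#' @param weight_exponent passed to [ssgsea_score()].
#' @return Data.frame, samples x sets, with an `anti_TME` column scored
#'   on the exact union of the member sets.
#' @export
score_collection <- function(expr, sigs, weight_exponent = 0.25) {
  stopifnot(is.matrix(expr), inherits(sigs, "signature_collection"))
  all_sets <- c(sigs$sets, list(anti_TME = anti_tme_genes(sigs)))
  out <- sapply(all_sets, function(gs)
    apply(expr, 2, ssgsea_score, gene_set = gs,
          weight_exponent = weight_exponent))
  as.data.frame(out, row.names = colnames(expr))
}

#' K-means clustering of genes on z-scored expression profiles
#'
#' Genes are z-scored across samples first; constant genes are dropped
#' with a warning. Euclidean K-means with `restarts` random
#' initializations, deterministic given `seed`.
#'
#' @param expr numeric matrix, genes x samples.
#' @param k number of clusters (default 7).
#' @param seed integer seed.
#' @param restarts number of random starts (default 25).
#' @return Named integer vector of cluster assignments.
#' @export
kmeans_genes <- function(expr, k = 7, seed = 1, restarts = 25) {
  stopifnot(is.matrix(expr))
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene rows dropped")
    expr <- expr[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (k > nrow(expr)) stop("k exceeds the number of (non-constant) genes")
  z <- (expr - rowMeans(expr)) / sds
  fit <- withr::with_seed(seed,
    kmeans(z, centers = k, nstart = restarts, iter.max = 100))
  setNames(fit$cluster, rownames(z))
}

#' Hypergeometric over-representation test of two gene sets
#'
#' Upper-tail probability `P(X >= |A intersect B|)` with
#' `X ~ Hypergeometric(N = |universe|, K = |A|, n = |B|)`.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return The upper-tail p-value.
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  k <- length(intersect(setA, setB))
  phyper(k - 1, length(setA), length(universe) - length(setA),
         length(setB), lower.tail = FALSE)
}
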