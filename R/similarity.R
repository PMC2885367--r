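# Global similarity between expression datasets: correlation of
# correlations.  All pairwise Spearman correlations of genes (across
# tissues) or of tissues (across genes) are computed within each dataset,
# and the two vectors of pairwise coefficients are then Pearson-correlated
# between the datasets.  Significance is judged against the same statistic
# on row-randomized matrices.

# ranks per row over non-missing values, average ties
row_ranks <- function(m) t(apply(m, 1L, function(v)
  rank(v, ties.method = "average", na.last = "keep")))

# all pairwise Spearman correlations: ranks once per feature, Pearson with
# pairwise-complete observations (exact Spearman on complete data)
spearman_pairs <- function(m) {
  r <- row_ranks(m)
  suppressWarnings(stats::cor(t(r), use = "pairwise.complete.obs",
                              method = "pearson"))
}

#' Correlation of correlations between two datasets
#'
#' @param u,v expression matrices; rows are restricted to their common
#'   genes (for `mode = "tissues"` columns must be the common tissue
#'   classes).
#' @param mode `"genes"`: correlate all gene pairs across tissue columns;
#'   `"tissues"`: correlate all tissue-class pairs across genes.
#' @return a single Pearson correlation between the two vectors of pairwise
#'   Spearman coefficients; pairs undefined in either dataset (constant
#'   rows, insufficient overlap) are excluded pairwise.
#' @export
correlation_of_correlations <- function(u, v, mode = c("genes", "tissues")) {
  mode <- match.arg(mode)
  common <- intersect(rownames(u), rownames(v))
  if (length(common) < 2L) stop("need at least two common genes")
  u <- u[common, , drop = FALSE]
  v <- v[common, , drop = FALSE]
  if (mode == "tissues") {
    shared <- intersect(colnames(u), colnames(v))
    if (length(shared) < 2L) stop("need at least two common tissue classes")
    u <- t(u[, shared, drop = FALSE])
    v <- t(v[, shared, drop = FALSE])
  }
  cu <- spearman_pairs(u)
  cv <- spearman_pairs(v)
  a <- cu[upper.tri(cu)]
  b <- cv[upper.tri(cv)]
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3L) stop("fewer than 3 usable correlation pairs")
  stats::cor(a[keep], b[keep])
}

#' Randomized baseline for the correlation of correlations
#'
#' Independently permutes each gene's values across columns in both
#' datasets, recomputes the correlation of correlations, and averages over
#' `n_rand` draws.  The resulting baseline is the similarity expected when
#' all within-dataset co-expression structure is destroyed.
#'
#' @inheritParams correlation_of_correlations
#' @param n_rand number of randomization draws.
#' @param seed optional integer seed.
#' @return mean correlation of correlations over the randomized draws.
#' @export
randomized_baseline <- function(u, v, mode = c("genes", "tissues"),
                                n_rand = 10, seed = NULL) {
  mode <- match.arg(mode)
  if (n_rand < 1) stop("n_rand must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  shuffle_rows <- function(m) {
    t(apply(m, 1L, sample))
  }
  vals <- vapply(seq_len(n_rand), function(i) {
    ru <- shuffle_rows(u)
    rv <- shuffle_rows(v)
    dimnames(ru) <- dimnames(u)
    dimnames(rv) <- dimnames(v)
    correlation_of_correlations(ru, rv, mode)
  }, numeric(1))
  mean(vals)
}

#' Pairwise correlation-of-correlations matrix with randomized baseline
#'
#' @param datasets named list of >= 2 expression matrices on common genes.
#' @inheritParams randomized_baseline
#' @return list of class `"coc_matrix"`: `original` and `random` square
#'   matrices over dataset pairs and `n_genes_used`.
#' @export
coc_matrix <- function(datasets, mode = c("genes", "tissues"),
                       n_rand = 10, seed = NULL) {
  mode <- match.arg(mode)
  k <- length(datasets)
  if (k < 2L) stop("need at least two datasets")
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("dataset%d", seq_len(k))
  nm <- names(datasets)
  orig <- rand <- diag(1, k)
  dimnames(orig) <- dimnames(rand) <- list(nm, nm)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    orig[i, j] <- orig[j, i] <-
      correlation_of_correlations(datasets[[i]], datasets[[j]], mode)
    rand[i, j] <- rand[j, i] <-
      randomized_baseline(datasets[[i]], datasets[[j]], mode, n_rand)
  }
  structure(list(original = orig, random = rand,
                 n_genes_used = length(Reduce(intersect,
                                              lapply(datasets, rownames)))),
            class = "coc_matrix")
}

#' @export
print.coc_matrix <- function(x, ...) {
  cat(sprintf("Correlation of correlations over %d common genes\n",
              x$n_genes_used))
  cat("Original:\n"); print(round(x$original, 3))
  cat("Randomized baseline:\n"); print(signif(x$random, 2))
  invisible(x)
}

#' Hierarchical clustering of datasets from a correlation matrix
#'
#' Clusters datasets with Ward's minimum-variance method on the
#' dissimilarity `1 - r`, the standard view of which datasets share the
#' most co-expression structure.
#'
#' @param corr symmetric correlation matrix (e.g. `coc_matrix()$original`).
#' @return list with the `hclust` tree, the `order` of leaves and the
#'   reordered `heatmap` matrix.
#' @export
cluster_datasets <- function(corr) {
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "ward.D2")
  ord <- hc$labels[hc$order]
  list(hclust = hc, order = ord,
       heatmap = corr[ord, ord, drop = FALSE])
}

#' Gene-wise t statistics for one tissue class versus the rest
#'
#' Classical two-sample pooled-variance t statistic per gene on sample-level
#' data, signed positive when the target class's mean exceeds the rest.
#' Genes with fewer than two observations in either group, or zero pooled
#' variance, get a missing statistic.
#'
#' @param m sample-level expression matrix.
#' @param tc tissue-class map covering the columns of `m`; alternatively a
#'   logical vector per column marking the target group (for datasets
#'   without within-class replicates, where super-groups such as brain
#'   versus non-brain arrays are the test units).
#' @param target_class class name to contrast against all other samples
#'   (ignored when `tc` is logical).
#' @return named numeric vector of t statistics per gene.
#' @export
class_vs_rest_tscores <- function(m, tc, target_class = NULL) {
  validate_expression_matrix(m)
  if (is.logical(tc)) {
    grp <- tc
    if (length(grp) != ncol(m)) stop("logical group must match columns")
  } else {
    cl <- as.character(tc[colnames(m)])
    if (is.null(target_class) || !target_class %in% cl)
      stop("target class absent from the dataset")
    grp <- cl == target_class
  }
  x <- m[, grp, drop = FALSE]
  y <- m[, !grp, drop = FALSE]
  n1 <- rowSums(!is.na(x))
  n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE)
  m2 <- rowMeans(y, na.rm = TRUE)
  ss1 <- rowSums((x - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((y - m2)^2, na.rm = TRUE)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[n1 < 2 | n2 < 2 | !is.finite(t)] <- NA_real_
  stats::setNames(t, rownames(m))
}
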