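# Mean-rank consolidation of per-dataset MAX rankings, and its
# leave-one-out reliability assessment.  For one tissue, genes are ranked
# by descending MAX within every dataset (average ranks for ties, in
# particular the tied-at-zero mass of genes maximal elsewhere); the mean of
# the per-dataset ranks orders the consolidated list.

# MAX column for one tissue from a score_table or a plain score matrix
max_column <- function(x, tissue) {
  sc <- if (inherits(x, "score_table")) {
    if (x$kind != "max") stop("consolidation needs MAX score tables")
    x$scores
  } else x
  if (!tissue %in% colnames(sc))
    stop("tissue '", tissue, "' absent from a score table")
  sc[, tissue]
}

#' Consolidate per-dataset MAX scores into one tissue ranking
#'
#' @param score_tables list of >= 2 MAX `score_table` objects (or plain
#'   gene x tissue MAX matrices); genes are restricted to the common set.
#' @param tissue tissue-class name to rank for.
#' @param restrict_positive if `TRUE`, keep only genes with MAX > 0 in all
#'   datasets (the restriction used for the cross-validation); default
#'   ranks all common genes.
#' @return data frame of class `"consolidated_ranking"`, ordered by
#'   consolidated rank, with per-dataset MAX values and ranks, the mean
#'   rank, and `consolidated_rank` (ties in mean rank broken by gene id).
#' @export
consolidate_by_mean_rank <- function(score_tables, tissue,
                                     restrict_positive = FALSE) {
  if (length(score_tables) < 2L) stop("need at least two score tables")
  if (is.null(names(score_tables)))
    names(score_tables) <- sprintf("dataset%d", seq_along(score_tables))
  cols <- lapply(score_tables, max_column, tissue = tissue)
  common <- sort(Reduce(intersect, lapply(cols, names)))
  vals <- vapply(cols, function(v) v[common], numeric(length(common)))
  rownames(vals) <- common
  keep <- rowSums(is.na(vals)) == 0L
  if (restrict_positive) keep <- keep & rowSums(vals > 0) == ncol(vals)
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) < 1L) stop("no rankable genes for tissue '", tissue, "'")
  ranks <- apply(vals, 2L, function(v) rank(-v, ties.method = "average"))
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank, rownames(vals))
  out <- data.frame(gene = rownames(vals)[ord],
                    consolidated_rank = seq_along(ord),
                    mean_rank = mean_rank[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(vals) <- paste0("max.", colnames(vals))
  colnames(ranks) <- paste0("rank.", colnames(ranks))
  out <- cbind(out, vals[ord, , drop = FALSE], ranks[ord, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "tissue") <- tissue
  class(out) <- c("consolidated_ranking", "data.frame")
  out
}

#' @export
print.consolidated_ranking <- function(x, n = 10, ...) {
  cat(sprintf("Consolidated %s ranking: %d genes (top %d shown)\n",
              attr(x, "tissue"), nrow(x), min(n, nrow(x))))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' Leave-one-out cross-validation of consolidated rankings
#'
#' Restricts to genes with MAX > 0 for the tissue in all datasets; for each
#' held-out dataset, the remaining datasets are consolidated by mean rank,
#' and the held-out MAX scores are Spearman-correlated with (a) each
#' remaining dataset's MAX scores (averaged) and (b) the consolidated
#' scores (negated mean rank, so that larger = more specific).  A
#' consolidated correlation exceeding the mean pairwise correlation is the
#' signature that integration increases reliability.
#'
#' @param score_tables list of >= 3 MAX score tables or matrices.
#' @param tissue tissue-class name.
#' @return data frame with one row per held-out dataset: `held_out`,
#'   `mean_pairwise_spearman`, `consolidated_spearman` and `n_genes`.
#' @export
cross_validate <- function(score_tables, tissue) {
  if (length(score_tables) < 3L) stop("need at least three score tables")
  if (is.null(names(score_tables)))
    names(score_tables) <- sprintf("dataset%d", seq_along(score_tables))
  cols <- lapply(score_tables, max_column, tissue = tissue)
  common <- sort(Reduce(intersect, lapply(cols, names)))
  vals <- vapply(cols, function(v) v[common], numeric(length(common)))
  rownames(vals) <- common
  keep <- rowSums(is.na(vals)) == 0L & rowSums(vals > 0) == ncol(vals)
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) < 3L)
    stop("fewer than 3 genes with MAX > 0 in all datasets")
  sp <- function(a, b) stats::cor(a, b, method = "spearman")
  res <- lapply(seq_len(ncol(vals)), function(i) {
    held <- vals[, i]
    rest <- vals[, -i, drop = FALSE]
    pairwise <- mean(apply(rest, 2L, sp, a = held))
    cons <- -rowMeans(apply(rest, 2L,
                            function(v) rank(-v, ties.method = "average")))
    data.frame(held_out = colnames(vals)[i],
               mean_pairwise_spearman = pairwise,
               consolidated_spearman = sp(held, cons),
               n_genes = nrow(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
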