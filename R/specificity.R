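# Tissue-specificity scoring.
#
# PEM (preferential expression measure): for a class-averaged log2 matrix,
# PEM(g, t) = S(g, t) - A(g), where S is the gene's average expression in
# class t and A the unweighted mean of its K class averages; equivalently
# the log2 ratio of tissue expression to mean expression on the linear
# scale.  Positive = over-expressed, negative = under-expressed.
#
# MAX: difference between a gene's largest and second-largest class fold
# change (equivalently class average), assigned to the tissue of maximal
# expression; zero in all other tissues.  Measures uniqueness of
# over-expression.
#
# Significance: empirical FDR against N permutations of the sample-to-class
# assignment that preserve class sizes,
#   FDR(s) = [ (1/N) * #{ background >= s } ] / #{ observed >= s }
# (mirrored for the lower tail), capped at 1 and made monotone in the score.

#' Preferential expression measure (PEM)
#'
#' @param avg class-averaged log2 expression matrix (genes x tissue
#'   classes), e.g. from [average_by_class()].
#' @return matrix of PEM scores with the same dimnames; missing class cells
#'   are excluded from the gene's mean and stay missing in the result.
#' @export
pem_scores <- function(avg) {
  if (ncol(avg) < 2L) stop("PEM needs at least two tissue classes")
  a <- rowMeans(avg, na.rm = TRUE)
  a[!is.finite(a)] <- NA_real_
  avg - a
}

#' MAX uniqueness score
#'
#' Per gene, the difference between the largest and the second-largest
#' class value, assigned to the tissue with the largest expression; all
#' other tissues receive 0.  A tie at the top yields 0 (the gene is not
#' uniquely over-expressed anywhere).  Equal to the corresponding
#' difference of PEM fold changes, since the gene's mean cancels.
#'
#' @inheritParams pem_scores
#' @return matrix of MAX scores (>= 0); rows with fewer than two observed
#'   classes are all-missing.
#' @export
max_scores <- function(avg) {
  if (ncol(avg) < 2L) stop("MAX needs at least two tissue classes")
  n <- nrow(avg)
  x <- pem_scores(avg)
  nobs <- rowSums(!is.na(x))
  x0 <- x
  x0[is.na(x0)] <- -Inf
  j1 <- max.col(x0, ties.method = "first")
  top <- x0[cbind(seq_len(n), j1)]
  x0[cbind(seq_len(n), j1)] <- -Inf
  second <- x0[cbind(seq_len(n), max.col(x0, ties.method = "first"))]
  out <- matrix(0, n, ncol(avg), dimnames = dimnames(avg))
  ok <- nobs >= 2L
  out[cbind(which(ok), j1[ok])] <- (top - second)[ok]
  out[!ok, ] <- NA_real_
  out
}

#' Permutation background of tissue-specificity scores
#'
#' Repeatedly reassigns samples to tissue classes (a global shuffle that
#' preserves every class's size), recomputes class averages and scores, and
#' pools the resulting scores per tissue.  These backgrounds are what the
#' observed scores are compared against to obtain empirical FDRs.
#'
#' @param m sample-level log2 expression matrix (genes x samples).
#' @param tc tissue-class map covering every column of `m`.
#' @param score_kind `"pem"` or `"max"`.
#' @param n_perm number of permutations N.
#' @param seed optional integer seed.
#' @param perm_fun permutation function applied to the vector of class
#'   labels; defaults to a uniform shuffle.  Exposed so degenerate
#'   permutations (e.g. the identity) can be injected.
#' @return list of class `"perm_background"`: per-tissue matrices of
#'   background scores (genes x permutations) plus `n_perm`.
#' @export
permutation_background <- function(m, tc, score_kind = c("pem", "max"),
                                   n_perm = 100, seed = NULL,
                                   perm_fun = sample) {
  score_kind <- match.arg(score_kind)
  if (n_perm < 1) stop("n_perm must be >= 1")
  validate_expression_matrix(m)
  if (!is.null(seed)) set.seed(seed)
  cl <- as.character(tc[colnames(m)])
  if (anyNA(cl)) stop("samples without tissue-class assignment")
  lev <- intersect(class_levels(tc), cl)
  score_fun <- if (score_kind == "pem") pem_scores else max_scores
  bg <- lapply(lev, function(l) matrix(NA_real_, nrow(m), n_perm))
  names(bg) <- lev
  for (b in seq_len(n_perm)) {
    perm_cl <- perm_fun(cl)
    stopifnot(identical(sort(perm_cl), sort(cl)))  # class sizes conserved
    sc <- score_fun(class_average(m, perm_cl, lev))
    for (l in lev) bg[[l]][, b] <- sc[, l]
  }
  structure(list(scores = bg, n_perm = n_perm, score_kind = score_kind,
                 tissues = lev),
            class = "perm_background")
}

# #{v >= s} / #{v <= s} for a vector of thresholds, via sorted search
count_ge <- function(sorted_v, s) length(sorted_v) -
  findInterval(s, sorted_v, left.open = TRUE)
count_le <- function(sorted_v, s) findInterval(s, sorted_v)

#' Empirical false discovery rate from a permutation background
#'
#' For each observed score s the raw estimate is the expected number of
#' background scores per permutation at least as extreme as s, divided by
#' the number of observed scores at least as extreme.  Estimates are capped
#' at 1 and made monotone (non-increasing in score for the upper tail) by
#' assigning each gene the minimum raw estimate over all thresholds whose
#' list contains it.
#'
#' @param observed numeric vector of observed scores for one tissue
#'   (missing scores give missing FDRs).
#' @param background numeric vector (or matrix) of pooled background scores
#'   for the same tissue.
#' @param n_perm number of permutations the background pools.
#' @param tail `"upper"` for over-expression, `"lower"` for
#'   under-expression.
#' @return numeric vector of FDR values in `[0, 1]`, aligned with
#'   `observed`.
#' @export
empirical_fdr <- function(observed, background, n_perm,
                          tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  bg <- sort(as.numeric(background))  # drops NA
  if (length(bg) == 0L) stop("empty background")
  ok <- !is.na(observed)
  s <- observed[ok]
  so <- sort(s)
  if (tail == "upper") {
    raw <- (count_ge(bg, s) / n_perm) / count_ge(so, s)
  } else {
    raw <- (count_le(bg, s) / n_perm) / count_le(so, s)
  }
  raw <- pmin(raw, 1)
  # monotone: q(s) = min over thresholds t with s in the called list
  ord <- if (tail == "upper") order(s) else order(-s)
  q <- numeric(length(s))
  q[ord] <- cummin(raw[ord])
  out <- rep(NA_real_, length(observed))
  out[ok] <- q
  out
}

#' Tissue-specificity scores with permutation-based empirical FDR
#'
#' The package's central fitting routine: class-averages a sample-level
#' log2 expression matrix, computes PEM or MAX scores, generates a
#' permutation background that conserves class sizes, and converts observed
#' scores to empirical FDRs per tissue (upper tail; for PEM also the
#' mirrored lower tail for under-expression).
#'
#' @inheritParams permutation_background
#' @param kind score kind, `"pem"` or `"max"`.
#' @param keep_background keep the pooled background scores in the result
#'   (needed by [plot.score_table()]; off by default to save memory).
#' @return object of class `"score_table"` with components `scores`,
#'   `fdr` (upper tail), `fdr_lower` (PEM only), `kind`, `n_perm`,
#'   `tissues`, `class_sizes` and optionally `background`.
#' @export
specificity_scores <- function(m, tc, kind = c("pem", "max"),
                               n_perm = 100, seed = NULL,
                               keep_background = FALSE,
                               perm_fun = sample) {
  kind <- match.arg(kind)
  avg <- average_by_class(m, tc)
  scores <- if (kind == "pem") pem_scores(avg) else max_scores(avg)
  fdr <- fdr_lower <- NULL
  background <- NULL
  if (n_perm > 0) {
    bg <- permutation_background(m, tc, kind, n_perm = n_perm, seed = seed,
                                 perm_fun = perm_fun)
    fdr <- scores
    fdr[] <- NA_real_
    if (kind == "pem") fdr_lower <- fdr
    for (l in colnames(scores)) {
      fdr[, l] <- empirical_fdr(scores[, l], bg$scores[[l]], n_perm, "upper")
      if (kind == "pem")
        fdr_lower[, l] <- empirical_fdr(scores[, l], bg$scores[[l]],
                                        n_perm, "lower")
    }
    if (keep_background) background <- bg
  }
  cl <- as.character(tc[colnames(m)])
  structure(list(scores = scores, fdr = fdr, fdr_lower = fdr_lower,
                 kind = kind, n_perm = n_perm, tissues = colnames(scores),
                 class_sizes = table(cl)[colnames(scores)],
                 background = background),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Tissue-specificity score table (%s)\n", toupper(x$kind)))
  cat(sprintf("  %d genes x %d tissue classes; %d permutations\n",
              nrow(x$scores), ncol(x$scores), x$n_perm))
  if (!is.null(x$fdr)) {
    n <- colSums(x$scores > 0 & x$fdr < 0.25, na.rm = TRUE)
    cat("  genes with positive score at FDR < 0.25, per tissue:\n")
    print(n)
  }
  invisible(x)
}

#' @export
summary.score_table <- function(object, fdr_cutoff = 0.25, ...) {
  over <- colSums(object$scores > 0 & object$fdr < fdr_cutoff, na.rm = TRUE)
  res <- data.frame(tissue = object$tissues,
                    n_samples = as.integer(object$class_sizes),
                    n_over = as.integer(over))
  if (!is.null(object$fdr_lower))
    res$n_under <- as.integer(colSums(object$scores < 0 &
                                        object$fdr_lower < fdr_cutoff,
                                      na.rm = TRUE))
  rownames(res) <- NULL
  res
}

#' Plot observed versus background score distributions for one tissue
#'
#' Kernel-density view of the observed scores against the pooled
#' permutation background (the basis of the empirical FDR).  Requires a
#' table fitted with `keep_background = TRUE`.
#'
#' @param x a `score_table`.
#' @param tissue tissue-class name.
#' @param ... passed to [graphics::plot()].
#' @export
plot.score_table <- function(x, tissue = x$tissues[1], ...) {
  if (is.null(x$background))
    stop("refit with keep_background = TRUE to plot backgrounds")
  obs <- x$scores[, tissue]
  bg <- as.numeric(x$background$scores[[tissue]])
  dob <- stats::density(obs[!is.na(obs)])
  dbg <- stats::density(bg[!is.na(bg)])
  graphics::plot(dob, col = "red", main = sprintf("%s scores: %s",
                                                  toupper(x$kind), tissue),
                 xlab = "score", ylim = range(0, dob$y, dbg$y), ...)
  graphics::lines(dbg, col = "black")
  graphics::legend("topright", legend = c("observed", "background"),
                   col = c("red", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' Derive tissue-specific gene lists from a score table
#'
#' Over-expressed: positive score and upper-tail FDR below the cutoff.
#' Under-expressed: negative score and lower-tail FDR below the cutoff
#' (PEM tables only).  Uniquely over-expressed: positive MAX score and
#' upper-tail FDR below the cutoff (MAX tables only).
#'
#' @param st a `score_table` fitted with permutations.
#' @param fdr_cutoff FDR threshold (default 0.25).
#' @param direction `"over"`, `"under"` or `"unique_over"`.
#' @return named list of class `"gene_lists"`: tissue -> character vector
#'   of gene ids, with the threshold recorded in attributes.
#' @export
derive_gene_lists <- function(st, fdr_cutoff = 0.25,
                              direction = c("over", "under", "unique_over")) {
  direction <- match.arg(direction)
  if (is.null(st$fdr)) stop("score table has no FDRs; refit with n_perm > 0")
  sel <- switch(direction,
    over = st$scores > 0 & st$fdr < fdr_cutoff,
    under = {
      if (is.null(st$fdr_lower))
        stop("under-expression lists need a PEM table with lower-tail FDRs")
      st$scores < 0 & st$fdr_lower < fdr_cutoff
    },
    unique_over = {
      if (st$kind != "max")
        stop("uniquely over-expressed lists need a MAX score table")
      st$scores > 0 & st$fdr < fdr_cutoff
    })
  sel[is.na(sel)] <- FALSE
  lists <- lapply(st$tissues, function(l) rownames(st$scores)[sel[, l]])
  names(lists) <- st$tissues
  structure(lists, class = "gene_lists", direction = direction,
            fdr_cutoff = fdr_cutoff, score_kind = st$kind)
}

#' Cross-dataset overlap tally of tissue-specific gene lists
#'
#' Counts, over the union of all listed genes (per tissue, then pooled),
#' how many datasets support each gene, summarising list concordance
#' across platforms.
#'
#' @param lists list of `gene_lists` objects, one per dataset, sharing
#'   tissue names.
#' @return data frame with `n_datasets`, `n_genes` and `fraction` (of all
#'   detected gene-tissue pairs) supported by exactly that many datasets.
#' @export
list_overlap <- function(lists) {
  if (length(lists) < 2L) stop("need lists from at least two datasets")
  tissues <- Reduce(intersect, lapply(lists, names))
  support <- unlist(lapply(tissues, function(l) {
    tab <- table(unlist(lapply(lists, function(gl) unique(gl[[l]]))))
    as.integer(tab)
  }))
  tab <- table(factor(support, levels = seq_along(lists)))
  data.frame(n_datasets = as.integer(names(tab)),
             n_genes = as.integer(tab),
             fraction = as.numeric(tab) / max(1L, sum(tab)))
}
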