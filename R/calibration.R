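# Sample-size dependence of tissue-specific gene detection, and
# tissue-adjusted FDR thresholds.  The number of genes detected at a fixed
# FDR cutoff grows with the number of replicates in a class; to compare
# tissues with different sample counts, a reference class (typically brain,
# the largest) is subsampled to the target class's size and the FDR
# threshold is adjusted so that the reduced data recover the same number of
# significant genes as the full data.

# upper-tail PEM q-values for the reference tissue only (positive scores
# retain their q; non-positive scores get NA so they never count)
reference_qvalues <- function(m, tc, tissue, n_perm) {
  st <- specificity_scores(m, tc, kind = "pem", n_perm = n_perm)
  if (!tissue %in% st$tissues)
    stop("reference tissue '", tissue, "' absent")
  q <- st$fdr[, tissue]
  q[is.na(st$scores[, tissue]) | st$scores[, tissue] <= 0] <- NA_real_
  q
}

# drop all reference-class samples except `keep_samples`
reduce_reference <- function(m, tc, tissue, keep_samples) {
  cl <- as.character(tc[colnames(m)])
  drop <- colnames(m)[cl == tissue & !colnames(m) %in% keep_samples]
  m[, !colnames(m) %in% drop, drop = FALSE]
}

#' Detected-gene counts as a function of reference-class sample number
#'
#' Repeatedly subsamples the reference tissue class to each requested size
#' (all other classes are kept intact), recomputes PEM scores and empirical
#' FDRs, and counts genes significantly over-expressed in the reference
#' tissue.
#'
#' @param m sample-level log2 expression matrix.
#' @param tc tissue-class map.
#' @param reference_tissue class to subsample.
#' @param sizes integer vector of retained sample numbers.
#' @param n_reps subsampling repetitions per size.
#' @param fdr_cutoff significance cutoff (default 0.25).
#' @param n_perm permutations per FDR computation.
#' @param seed optional integer seed.
#' @return data frame with `size`, `mean_count` and `sd_count`; the per-rep
#'   count matrix is attached as attribute `"counts"`.
#' @export
subsample_detection_curve <- function(m, tc, reference_tissue, sizes,
                                      n_reps = 10, fdr_cutoff = 0.25,
                                      n_perm = 100, seed = NULL) {
  validate_expression_matrix(m)
  if (!is.null(seed)) set.seed(seed)
  ref_samples <- colnames(m)[as.character(tc[colnames(m)]) ==
                               reference_tissue]
  if (length(ref_samples) == 0L)
    stop("reference tissue '", reference_tissue, "' absent")
  if (any(sizes > length(ref_samples)))
    stop("requested size exceeds the ", length(ref_samples),
         " available reference samples")
  counts <- matrix(NA_real_, length(sizes), n_reps,
                   dimnames = list(as.character(sizes), NULL))
  for (i in seq_along(sizes)) for (r in seq_len(n_reps)) {
    keep <- sample(ref_samples, sizes[i])
    q <- reference_qvalues(reduce_reference(m, tc, reference_tissue, keep),
                           tc, reference_tissue, n_perm)
    counts[i, r] <- sum(q < fdr_cutoff, na.rm = TRUE)
  }
  data.frame(size = sizes,
             mean_count = rowMeans(counts),
             sd_count = apply(counts, 1L, stats::sd),
             row.names = NULL) -> out
  attr(out, "counts") <- counts
  out
}

#' Tissue-adjusted FDR threshold by reference-class subsampling
#'
#' Computes the number `N_ref` of genes significantly over-expressed in the
#' reference tissue at nominal threshold `alpha` on the full data, then
#' repeatedly subsamples the reference class to `s` samples and finds, per
#' repetition, the smallest achievable FDR cutoff `alpha'` at which the
#' reduced data still yield at least `N_ref` significant genes (1 when
#' unreachable).  The empirical-FDR estimator is a step function, so the
#' search runs over its achieved values: `alpha'` is the `N_ref`-th
#' smallest q-value among positively scored genes.  The 5th percentile of
#' the `alpha'` distribution is reported as the conservative adjusted
#' threshold.
#'
#' @inheritParams subsample_detection_curve
#' @param s subset size (samples retained in the reference class).
#' @param alpha nominal FDR threshold on the full data.
#' @return object of class `"fdr_calibration"`: a list with
#'   `reference_tissue`, `alpha`, `s`, `n_ref`, the `alpha_prime` vector
#'   and `adjusted_threshold` (5th percentile, linear interpolation).
#' @export
adjust_fdr_threshold <- function(m, tc, reference_tissue, s, alpha = 0.05,
                                 n_reps = 100, n_perm = 100, seed = NULL) {
  validate_expression_matrix(m)
  if (!is.null(seed)) set.seed(seed)
  ref_samples <- colnames(m)[as.character(tc[colnames(m)]) ==
                               reference_tissue]
  if (s > length(ref_samples))
    stop("s exceeds the ", length(ref_samples),
         " available reference samples")
  q_full <- reference_qvalues(m, tc, reference_tissue, n_perm)
  n_ref <- sum(q_full < alpha, na.rm = TRUE)
  if (n_ref == 0L) stop("no significant genes to calibrate against")
  alpha_prime <- vapply(seq_len(n_reps), function(r) {
    keep <- sample(ref_samples, s)
    q <- reference_qvalues(reduce_reference(m, tc, reference_tissue, keep),
                           tc, reference_tissue, n_perm)
    qs <- sort(q)  # drops NA
    if (length(qs) < n_ref) 1 else qs[n_ref]
  }, numeric(1))
  structure(list(reference_tissue = reference_tissue, alpha = alpha,
                 s = s, n_ref = n_ref, n_reps = n_reps,
                 alpha_prime = alpha_prime,
                 adjusted_threshold =
                   unname(stats::quantile(alpha_prime, 0.05, type = 7))),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat(sprintf(
    "FDR calibration: %s, alpha = %.3g, s = %d (N_ref = %d, %d reps)\n",
    x$reference_tissue, x$alpha, x$s, x$n_ref, x$n_reps))
  cat(sprintf("  adjusted threshold (5th percentile of alpha'): %.4g\n",
              x$adjusted_threshold))
  cat(sprintf("  alpha' quartiles: %s\n",
              paste(signif(stats::quantile(x$alpha_prime,
                                           c(.25, .5, .75)), 3),
                    collapse = " / ")))
  invisible(x)
}
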