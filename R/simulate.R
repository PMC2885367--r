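# Synthetic multi-platform compendium generator.  Values are simulated
# directly on the log2 scale: for gene g, platform p and a sample of tissue
# class t,
#   x = baseline(g) + bias(g, p) + effect(g, t) + N(0, noise_sd[p])
# with baseline(g) ~ N(8, 2), bias(g, p) ~ N(0, platform_offset_sd) and
# effect(g, t) = +/- effect size for planted (g, t) pairs, 0 otherwise.
# Entries are masked missing independently with a per-platform rate
# (cDNA-style dropouts).

#' Simulation configuration for a multi-platform tissue compendium
#'
#' The defaults emulate a compendium of four microarray platforms measuring
#' overlapping gene sets over 19 tissue classes with unequal replicate
#' counts, planted tissue-specifically expressed genes on the log2 scale,
#' gene-wise platform offsets, platform-specific noise, and missing values
#' on the last (cDNA-like) platform.
#'
#' @param n_genes total number of distinct genes in the universe.
#' @param n_platforms number of platforms (datasets).
#' @param gene_overlap_fraction fraction of genes measured by every
#'   platform; the remainder is split into disjoint platform-private sets.
#' @param tissue_classes named integer vector of samples per tissue class
#'   (recycled over platforms), or a list with one such vector per platform.
#' @param n_specific_genes number of planted tissue-specific genes, drawn
#'   from the shared core so every platform measures them.
#' @param effect_size_log2 planted effect on the log2 scale: a single value
#'   (all planted genes share it) or a length-2 range from which per-gene
#'   effects are drawn uniformly.
#' @param under_fraction fraction of planted genes that are
#'   under-expressed rather than over-expressed in their tissue.
#' @param noise_sd_log2 per-platform residual standard deviations
#'   (recycled to `n_platforms`).
#' @param platform_offset_sd standard deviation of the gene-by-platform
#'   additive bias (log2).
#' @param missing_rate per-platform probability that an entry is masked
#'   missing (recycled to `n_platforms`).
#' @param seed integer seed; the compendium is fully reproducible from it.
#' @return a list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_platforms = 4,
                              gene_overlap_fraction = 0.8,
                              tissue_classes = default_tissue_classes(),
                              n_specific_genes = 100,
                              effect_size_log2 = 3,
                              under_fraction = 0,
                              noise_sd_log2 = 0.7,
                              platform_offset_sd = 0.25,
                              missing_rate = c(rep(0, n_platforms - 1), 0.1),
                              seed = 1L) {
  tissue_classes <- normalize_classes(tissue_classes)
  if (!is.list(tissue_classes))
    tissue_classes <- rep(list(tissue_classes), n_platforms)
  if (length(tissue_classes) != n_platforms)
    stop("tissue_classes must have one entry per platform")
  tissue_classes <- lapply(tissue_classes, function(x) {
    storage.mode(x) <- "integer"
    x
  })
  noise_sd_log2 <- rep_len(noise_sd_log2, n_platforms)
  missing_rate <- rep_len(missing_rate, n_platforms)
  stopifnot(n_genes >= 1, n_platforms >= 1,
            gene_overlap_fraction >= 0, gene_overlap_fraction <= 1,
            n_specific_genes >= 0, all(noise_sd_log2 > 0),
            platform_offset_sd >= 0,
            all(missing_rate >= 0), all(missing_rate < 1),
            under_fraction >= 0, under_fraction <= 1,
            length(effect_size_log2) %in% c(1L, 2L),
            all(effect_size_log2 > 0))
  all_classes <- unique(unlist(lapply(tissue_classes, names)))
  if (is.null(all_classes) || any(!nzchar(all_classes)))
    stop("tissue_classes entries must be named integer vectors")
  totals <- vapply(all_classes, function(cl)
    sum(vapply(tissue_classes, function(x) sum(x[names(x) == cl]), 0)), 0)
  if (any(totals == 0))
    stop("tissue class with zero samples on all platforms: ",
         paste(all_classes[totals == 0], collapse = ", "))
  structure(list(n_genes = n_genes, n_platforms = n_platforms,
                 gene_overlap_fraction = gene_overlap_fraction,
                 tissue_classes = tissue_classes,
                 n_specific_genes = n_specific_genes,
                 effect_size_log2 = effect_size_log2,
                 under_fraction = under_fraction,
                 noise_sd_log2 = noise_sd_log2,
                 platform_offset_sd = platform_offset_sd,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default tissue-class layout: 19 classes, unequal replicate counts
#'
#' Mirrors the situation in merged human tissue compendia where a few
#' classes (brain, above all) accumulate many samples while several classes
#' are represented by a single array.
#'
#' @return named integer vector of samples per class.
#' @export
default_tissue_classes <- function() {
  c(brain = 10L, kidney = 5L, liver = 5L, lung = 4L, muscle = 3L,
    heart = 3L, testis = 3L, ovary = 2L, prostate = 2L, placenta = 2L,
    thymus = 2L, spleen = 2L, pancreas = 2L, adrenal = 1L, thyroid = 1L,
    salivary = 1L, uterus = 1L, skin = 1L, blood = 1L)
}

#' Simulate a multi-platform tissue-expression compendium
#'
#' @param cfg a [simulation_config()] object.
#' @return list with components `expression` (per-platform log2 matrices,
#'   genes x samples), `classes` (per-platform named character vectors
#'   sample -> tissue class) and `truth` (data frame with one row per
#'   planted gene: `gene`, `tissue`, `direction`, `effect_log2`).
#' @export
simulate_compendium <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(simulation_config, cfg)
  set.seed(cfg$seed)
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  n_core <- round(cfg$gene_overlap_fraction * cfg$n_genes)
  if (cfg$n_specific_genes > n_core)
    stop("n_specific_genes exceeds the shared gene core")
  core <- gene_ids[seq_len(n_core)]
  private <- split_private(setdiff(gene_ids, core), cfg$n_platforms)

  baseline <- stats::setNames(stats::rnorm(cfg$n_genes, 8, 2), gene_ids)
  all_classes <- unique(unlist(lapply(cfg$tissue_classes, names)))

  truth <- if (cfg$n_specific_genes > 0) {
    planted <- sample(core, cfg$n_specific_genes)
    tissues <- sample(rep_len(all_classes, cfg$n_specific_genes))
    n_under <- round(cfg$under_fraction * cfg$n_specific_genes)
    direction <- sample(rep(c("under", "over"),
                            c(n_under, cfg$n_specific_genes - n_under)))
    eff <- if (length(cfg$effect_size_log2) == 1L)
      rep(cfg$effect_size_log2, cfg$n_specific_genes)
    else stats::runif(cfg$n_specific_genes,
                      min(cfg$effect_size_log2), max(cfg$effect_size_log2))
    data.frame(gene = planted, tissue = tissues, direction = direction,
               effect_log2 = eff, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), tissue = character(),
               direction = character(), effect_log2 = numeric(),
               stringsAsFactors = FALSE)
  }

  expression <- vector("list", cfg$n_platforms)
  classes <- vector("list", cfg$n_platforms)
  for (p in seq_len(cfg$n_platforms)) {
    counts <- cfg$tissue_classes[[p]]
    counts <- counts[counts > 0]
    genes_p <- sort(c(core, private[[p]]))
    cl <- rep(names(counts), counts)
    samp <- sprintf("p%d_s%03d", p, seq_along(cl))
    tc <- stats::setNames(cl, samp)

    eff <- matrix(0, length(genes_p), length(cl),
                  dimnames = list(genes_p, samp))
    if (nrow(truth)) {
      signed <- ifelse(truth$direction == "over", 1, -1) * truth$effect_log2
      for (k in seq_len(nrow(truth))) {
        g <- truth$gene[k]
        hit <- cl == truth$tissue[k]
        if (g %in% genes_p && any(hit)) eff[g, hit] <- signed[k]
      }
    }
    bias <- stats::rnorm(length(genes_p), 0, cfg$platform_offset_sd)
    x <- baseline[genes_p] + bias + eff +
      matrix(stats::rnorm(length(eff), 0, cfg$noise_sd_log2[p]),
             nrow(eff), ncol(eff))
    if (cfg$missing_rate[p] > 0)
      x[matrix(stats::runif(length(x)) < cfg$missing_rate[p],
               nrow(x), ncol(x))] <- NA_real_
    dimnames(x) <- list(genes_p, samp)
    expression[[p]] <- x
    classes[[p]] <- tc
  }
  names(expression) <- names(classes) <-
    sprintf("platform%d", seq_len(cfg$n_platforms))
  list(expression = expression, classes = classes, truth = truth,
       config = cfg)
}

# Accepts YAML-style nested lists: a named list of scalar counts becomes a
# named integer vector (one layout for all platforms); a list of such
# lists/vectors stays per-platform.
normalize_classes <- function(x) {
  if (!is.list(x)) return(x)
  scalar <- vapply(x, function(e) is.atomic(e) && length(e) == 1L &&
                     is.null(names(e)), logical(1))
  if (all(scalar) && !is.null(names(x))) return(unlist(x))
  lapply(x, function(e) if (is.list(e)) unlist(e) else e)
}

# deterministic split of private genes into n roughly equal disjoint sets
split_private <- function(genes, n) {
  if (length(genes) == 0L) return(rep(list(character()), n))
  split(genes, rep_len(seq_len(n), length(genes)))
}
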