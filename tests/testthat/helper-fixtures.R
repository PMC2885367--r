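# Shared fixtures: small simulated compendia and hand-built matrices.

# small multi-platform compendium with planted signal
small_compendium <- function(seed = 11, n_genes = 300, n_platforms = 3,
                             classes = c(a = 3L, b = 3L, c = 3L, d = 3L),
                             n_specific = 20, effect = 3, noise = 0.5,
                             ...) {
  simulate_compendium(simulation_config(
    n_genes = n_genes, n_platforms = n_platforms,
    gene_overlap_fraction = 1, tissue_classes = classes,
    n_specific_genes = n_specific, effect_size_log2 = effect,
    noise_sd_log2 = noise, platform_offset_sd = 0.2,
    missing_rate = 0, seed = seed, ...))
}

# deterministic toy matrix with named dims
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# brute-force Spearman of two vectors (oracle)
spearman_bf <- function(a, b) {
  stats::cor(rank(a), rank(b), method = "pearson")
}

# brute-force correlation of correlations: explicit double loop over
# feature pairs (oracle, independent of the package implementation)
coc_bf <- function(u, v) {
  n <- nrow(u)
  a <- b <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- c(a, spearman_bf(u[i, ], u[j, ]))
    b <- c(b, spearman_bf(v[i, ], v[j, ]))
  }
  stats::cor(a, b)
}

# brute-force empirical FDR by direct counting (oracle)
fdr_bf <- function(observed, background, n_perm, tail = "upper") {
  raw <- vapply(observed, function(s) {
    if (tail == "upper") {
      min(1, (sum(background >= s) / n_perm) / sum(observed >= s))
    } else {
      min(1, (sum(background <= s) / n_perm) / sum(observed <= s))
    }
  }, numeric(1))
  # assign each score the minimum raw estimate over thresholds containing it
  vapply(seq_along(observed), function(k) {
    if (tail == "upper") min(raw[observed <= observed[k]])
    else min(raw[observed >= observed[k]])
  }, numeric(1))
}

# exact one-sided hypergeometric tail P(X >= a) via binomial coefficients
hyper_tail_bf <- function(a, set_size, cat_size, universe_size) {
  ks <- a:min(set_size, cat_size)
  sum(choose(cat_size, ks) * choose(universe_size - cat_size,
                                    set_size - ks)) /
    choose(universe_size, set_size)
}

toy_obo_path <- function() {
  system.file("extdata", "toy_ontology.obo", package = "tissuecons")
}
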