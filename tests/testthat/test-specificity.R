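test_that("PEM centers each gene row on its mean across tissues", {
  avg <- toy_matrix(c(4, 2, 2, 2,
                      5, 5, 5, 5), c("g1", "g2"),
                    c("t1", "t2", "t3", "t4"))
  pem <- pem_scores(avg)
  expect_equal(unname(pem["g1", ]), c(1.5, -0.5, -0.5, -0.5))  # A = 2.5
  expect_equal(unname(pem["g2", ]), rep(0, 4))
  # complete rows sum to zero; missing cells stay missing
  set.seed(5)
  r <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], LETTERS[1:5]))
  expect_equal(rowSums(pem_scores(r)), rep(0, 8), ignore_attr = TRUE)
  r[2, 3] <- NA
  p <- pem_scores(r)
  expect_true(is.na(p[2, 3]))
  expect_equal(p[2, 1], r[2, 1] - mean(r[2, -3]))
  expect_error(pem_scores(r[, 1, drop = FALSE]), "two tissue classes")
})

test_that("MAX is the gap between the two largest class values, at the argmax", {
  avg <- toy_matrix(c(3, 1, 0, -4,
                      2, 2, 2, 2,
                      1, 5, 5, 0), c("g1", "g2", "g3"),
                    c("t1", "t2", "t3", "t4"))
  mx <- max_scores(avg)
  expect_equal(unname(mx["g1", ]), c(2, 0, 0, 0))
  expect_equal(unname(mx["g2", ]), rep(0, 4))  # tie at the top
  expect_equal(unname(mx["g3", ]), rep(0, 4))  # two-way tie
  expect_true(all(mx >= 0))
  # a row with fewer than two observed classes has no MAX
  avg2 <- avg; avg2["g1", 2:4] <- NA
  expect_true(all(is.na(max_scores(avg2)["g1", ])))
})

test_that("PEM and MAX are invariant under gene-row shifts", {
  set.seed(8)
  avg <- matrix(rnorm(60), 10, 6,
                dimnames = list(sprintf("g%d", 1:10), letters[1:6]))
  shift <- avg + rnorm(10)  # different constant per row, recycled by column
  expect_equal(pem_scores(shift) - pem_scores(avg),
               matrix(0, 10, 6), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(max_scores(shift), max_scores(avg), tolerance = 1e-12)
})

test_that("permutation background conserves class sizes and seeds reproduce", {
  sim <- small_compendium(seed = 13, n_genes = 60)
  m <- sim$expression[[1]]; tc <- sim$classes[[1]]
  # the size check inside the loop would abort on any size-changing shuffle
  bg1 <- permutation_background(m, tc, "pem", n_perm = 5, seed = 31)
  bg2 <- permutation_background(m, tc, "pem", n_perm = 5, seed = 31)
  expect_identical(bg1$scores, bg2$scores)
  expect_identical(names(bg1$scores), c("a", "b", "c", "d"))
  expect_equal(dim(bg1$scores$a), c(60L, 5L))
  expect_error(permutation_background(m, tc, "pem", n_perm = 0), "n_perm")
})

test_that("the identity permutation reproduces the observed scores", {
  sim <- small_compendium(seed = 17, n_genes = 50)
  m <- sim$expression[[1]]; tc <- sim$classes[[1]]
  bg <- permutation_background(m, tc, "pem", n_perm = 1,
                               perm_fun = identity)
  obs <- pem_scores(average_by_class(m, tc))
  for (l in names(bg$scores))
    expect_equal(bg$scores[[l]][, 1], obs[, l], ignore_attr = TRUE)
})

test_that("background PEM is centred near zero on null data", {
  sim <- small_compendium(seed = 19, n_genes = 2000, n_platforms = 1,
                          n_specific = 0, noise = 0.7)
  bg <- permutation_background(sim$expression[[1]], sim$classes[[1]],
                               "pem", n_perm = 5, seed = 23)
  for (l in names(bg$scores))
    expect_lt(abs(mean(bg$scores[[l]])), 0.05)
})

test_that("empirical FDR matches direct counting, including monotonicity", {
  # hand case: one permutation, observed (3, 2, 1), background (1, 0, 0)
  expect_equal(empirical_fdr(c(3, 2, 1), c(1, 0, 0), n_perm = 1),
               c(0, 0, 1 / 3))
  # saturation: a score below everything gets FDR 1 with equal sizes
  expect_equal(empirical_fdr(c(5, 6, -10), c(0, 1, 2), n_perm = 1)[3], 1)
  # oracle equivalence on random instances with ties, both tails
  set.seed(99)
  for (rep in 1:20) {
    obs <- round(rnorm(sample(5:50, 1)), 1)
    bg <- round(rnorm(sample(10:120, 1)), 1)
    n_perm <- sample(1:4, 1)
    for (tail in c("upper", "lower")) {
      expect_equal(empirical_fdr(obs, bg, n_perm, tail),
                   fdr_bf(obs, bg, n_perm, tail))
    }
  }
})

test_that("FDR is monotone and NA-safe", {
  set.seed(12)
  obs <- rnorm(200); bg <- rnorm(1000)
  q <- empirical_fdr(obs, bg, n_perm = 5)
  ord <- order(obs)
  expect_true(all(diff(q[ord]) <= 1e-12))  # non-increasing in score
  expect_true(all(q >= 0 & q <= 1))
  obs[c(3, 7)] <- NA
  q2 <- empirical_fdr(obs, bg, n_perm = 5)
  expect_true(all(is.na(q2[c(3, 7)])))
  expect_error(empirical_fdr(obs, numeric(0), 1), "empty background")
})

test_that("gene lists respect score sign and FDR cutoff", {
  sim <- small_compendium(seed = 29, n_genes = 500, n_platforms = 1,
                          classes = stats::setNames(rep(3L, 8),
                                                    letters[1:8]),
                          n_specific = 24, effect = 3, noise = 0.5)
  st <- specificity_scores(sim$expression[[1]], sim$classes[[1]], "pem",
                           n_perm = 50, seed = 3)
  gl <- derive_gene_lists(st, 0.25, "over")
  for (l in names(gl)) {
    if (!length(gl[[l]])) next
    expect_true(all(st$scores[gl[[l]], l] > 0))
    expect_true(all(st$fdr[gl[[l]], l] < 0.25))
  }
  # every planted over-expressed gene is recovered in its own tissue
  over <- sim$truth[sim$truth$direction == "over", ]
  hit <- mapply(function(g, l) g %in% gl[[l]], over$gene, over$tissue)
  expect_true(all(hit))
  # an all-nonsignificant table yields empty lists
  st0 <- st; st0$fdr[] <- 1
  expect_true(all(lengths(derive_gene_lists(st0, 0.25, "over")) == 0))
  expect_error(derive_gene_lists(st, 0.25, "unique_over"), "MAX")
})

test_that("overlap tallies count cross-dataset support", {
  gl <- structure(list(t1 = c("a", "b"), t2 = "c"), class = "gene_lists")
  tally <- list_overlap(list(gl, gl, gl, gl))
  expect_equal(tally$n_genes, c(0L, 0L, 0L, 3L))  # all genes in all four
  gl2 <- structure(list(t1 = c("a", "z"), t2 = character()),
                   class = "gene_lists")
  tally2 <- list_overlap(list(gl, gl2))
  expect_equal(tally2$n_genes, c(3L, 1L))  # only "a" supported twice
})

test_that("observed PEM has a heavier upper tail than its background when signal is planted", {
  sim <- small_compendium(seed = 37, n_genes = 800, n_platforms = 1,
                          n_specific = 60, effect = 3, noise = 0.5)
  st <- specificity_scores(sim$expression[[1]], sim$classes[[1]], "pem",
                           n_perm = 20, seed = 5, keep_background = TRUE)
  pooled_obs <- as.numeric(st$scores)
  pooled_bg <- as.numeric(do.call(cbind, st$background$scores))
  ks <- suppressWarnings(
    stats::ks.test(pooled_obs, pooled_bg, alternative = "greater"))
  expect_lt(ks$p.value, 0.01)
})

test_that("score table methods report coherent summaries", {
  sim <- small_compendium(seed = 41, n_genes = 120)
  st <- specificity_scores(sim$expression[[1]], sim$classes[[1]], "max",
                           n_perm = 20, seed = 1, keep_background = TRUE)
  expect_output(print(st), "MAX")
  sm <- summary(st)
  expect_identical(sm$tissue, c("a", "b", "c", "d"))
  expect_true(all(sm$n_samples == 3L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(st, "a"))
})
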