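toy_ont <- function() read_obo(toy_obo_path())

# annotation table spreading genes over the toy DAG's leaves
toy_annotations <- function(n_per_leaf = 10) {
  leaves <- c("TOY:0000011", "TOY:0000012", "TOY:0000021", "TOY:0000022",
              "TOY:0000031", "TOY:0000040")
  data.frame(
    gene = sprintf("g%03d", seq_len(n_per_leaf * length(leaves))),
    term = rep(leaves, each = n_per_leaf), stringsAsFactors = FALSE)
}

test_that("OBO parsing extracts terms, names and is_a parents", {
  ont <- toy_ont()
  expect_s3_class(ont, "ontology")
  expect_true("TOY:0000021" %in% ont$id)
  expect_false("TOY:0000099" %in% ont$id)  # obsolete term skipped
  expect_identical(ont$parents[["TOY:0000021"]], "TOY:0000020")
  expect_identical(unname(ont$name["TOY:0000010"]), "metabolic process")
  expect_setequal(ont$ancestors[["TOY:0000021"]],
                  c("TOY:0000020", "TOY:0000001"))
  expect_identical(ont$ancestors[["TOY:0000001"]], character(0))
})

test_that("annotations propagate to all ancestors", {
  ont <- toy_ont()
  annot <- data.frame(gene = c("gA", "gB"),
                      term = c("TOY:0000021", "TOY:0000040"))
  tg <- propagate_annotations(annot, ont)
  expect_identical(tg[["TOY:0000021"]], "gA")
  expect_identical(tg[["TOY:0000020"]], "gA")
  expect_setequal(tg[["TOY:0000001"]], c("gA", "gB"))
  expect_length(tg[["TOY:0000011"]], 0)
})

test_that("informative categories obey the >threshold / children <threshold rule", {
  ont <- toy_ont()
  annot <- toy_annotations(10)
  universe <- unique(annot$gene)
  # counts: root 60; metabolism 20 (children 10, 10); neural 20; immune 10
  inf <- informative_categories(ont, propagate_annotations(annot, ont),
                                universe, threshold = 15)
  expect_setequal(inf, c("TOY:0000010", "TOY:0000020"))
  # root fails: its children metabolism/neural hold >= 15 genes
  # threshold above the largest count leaves nothing
  expect_length(informative_categories(
    ont, propagate_annotations(annot, ont), universe, threshold = 100), 0)
  # a 200-gene root with a 300 threshold is not informative
  expect_false("TOY:0000001" %in% informative_categories(
    ont, propagate_annotations(annot, ont), universe, threshold = 300))
  expect_error(informative_categories(
    ont, propagate_annotations(annot, ont), character(0)), "empty")
})

test_that("hand-built DAG: root(400) -> childA(350) -> grandchild(100), childB(50)", {
  dir <- withr::local_tempdir()
  obo <- file.path(dir, "mini.obo")
  writeLines(c("[Term]", "id: R", "name: root",
               "", "[Term]", "id: A", "name: childA", "is_a: R",
               "", "[Term]", "id: G", "name: grandchild", "is_a: A",
               "", "[Term]", "id: B", "name: childB", "is_a: R"), obo)
  ont <- read_obo(obo)
  genes <- sprintf("x%03d", 1:400)
  annot <- rbind(
    data.frame(gene = genes[1:100], term = "G"),
    data.frame(gene = genes[101:350], term = "A"),
    data.frame(gene = genes[351:400], term = "B"))
  tg <- propagate_annotations(annot, ont)
  expect_length(tg[["R"]], 400)
  expect_length(tg[["A"]], 350)
  inf <- informative_categories(ont, tg, genes, threshold = 300)
  expect_identical(inf, "A")  # root fails through childA >= 300
})

test_that("Fisher enrichment equals the exact hypergeometric tail", {
  universe <- sprintf("u%02d", 1:20)
  category <- universe[1:5]
  gene_set <- universe[c(1:4, 10)]  # overlap 4
  fe <- fisher_enrichment(gene_set, category, universe)
  expect_equal(fe$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(fe$p_value, hyper_tail_bf(4, 5, 5, 20), tolerance = 1e-12)
  expect_equal(unname(fe$table[1, 1]), 4)
  # zero overlap: the tail from 0 is the entire mass
  expect_equal(fisher_enrichment(universe[10:12], universe[1:3],
                                 universe)$p_value, 1)
  # oracle equivalence on random small tables
  set.seed(71)
  for (i in 1:25) {
    u <- sprintf("u%02d", 1:sample(10:50, 1))
    cat_g <- sample(u, sample(2:length(u), 1))
    set_g <- sample(u, sample(2:length(u), 1))
    a <- length(intersect(set_g, cat_g))
    expect_equal(fisher_enrichment(set_g, cat_g, u)$p_value,
                 hyper_tail_bf(a, length(set_g), length(cat_g),
                               length(u)),
                 tolerance = 1e-12)
  }
  # a larger null universe makes the same overlap more surprising
  u2 <- c(universe, sprintf("v%02d", 1:20))
  expect_lt(fisher_enrichment(gene_set, category, u2)$p_value,
            fe$p_value)
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.02, 0.02, 0.02)), c(0.02, 0.02, 0.02))
  expect_equal(bh_adjust(c(0.001, 0.5, 1)), c(0.003, 0.75, 1))
  p <- sort(runif(20))
  expect_true(all(diff(bh_adjust(p)) >= -1e-15))  # monotone on sorted p
  expect_error(bh_adjust(c(0.5, 2)), "0, 1")
})

test_that("planted annotation structure dominates the enrichment profile", {
  ont <- toy_ont()
  universe <- sprintf("g%04d", 1:2000)
  # liver-specific genes annotated to the metabolism subtree
  liver_genes <- universe[1:15]
  brain_genes <- universe[16:30]
  annot <- rbind(
    data.frame(gene = liver_genes, term = "TOY:0000011"),
    data.frame(gene = brain_genes, term = "TOY:0000021"),
    data.frame(gene = universe[31:60],
               term = rep(c("TOY:0000031", "TOY:0000040"), 15)))
  gene_sets <- list(liver = liver_genes, brain = brain_genes)
  prof <- profile_and_cluster(gene_sets, ont, annot, universe,
                              threshold = 10)
  expect_true(all(dim(prof$fdr) >= c(2, 1)))
  # the planted tissue-category pairs attain their rows' minima; with a
  # 10-gene threshold the informative level is the leaf holding the genes
  expect_identical(colnames(prof$fdr)[which.min(prof$fdr["liver", ])],
                   "TOY:0000011")
  expect_identical(colnames(prof$fdr)[which.min(prof$fdr["brain", ])],
                   "TOY:0000021")
  expect_true(all(prof$fdr >= 0 & prof$fdr <= 1))
  # identical gene sets give identical rows that merge at height 0
  prof2 <- profile_and_cluster(list(a = liver_genes, b = liver_genes),
                               ont, annot, universe, threshold = 10)
  expect_equal(unname(prof2$fdr["a", ]), unname(prof2$fdr["b", ]))
  expect_equal(prof2$row_hclust$height[1], 0)
  # shuffled labels destroy the enrichment signal
  set.seed(77)
  hits <- vapply(1:10, function(i) {
    shuffled <- lapply(gene_sets, function(g)
      sample(universe, length(g)))
    min(profile_and_cluster(shuffled, ont, annot, universe,
                            threshold = 10)$fdr)
  }, numeric(1))
  expect_gte(sum(hits > 0.25), 9)
  expect_error(profile_and_cluster(gene_sets, ont, annot, universe,
                                   threshold = 1000), "no informative")
})
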