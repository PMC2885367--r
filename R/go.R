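# Enrichment profiling of tissue-specific gene sets over "informative"
# ontology categories: categories with more than `threshold` annotated
# genes whose every child has fewer -- large enough for statistical power,
# small enough to stay functionally homogeneous.  Enrichment is a
# one-sided Fisher exact test, Benjamini-Hochberg adjusted, and the
# tissue x category FDR matrix is hierarchically clustered.

#' Read a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas for `id`, `name` and `is_a` parents (obsolete
#' terms are skipped).  Only `is_a` edges are used for ancestor
#' propagation.
#'
#' @param path OBO file path.
#' @return object of class `"ontology"`: list with `id`, `name` (named by
#'   id), `parents` and precomputed `ancestors` (named lists of ids).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  ids <- character()
  nms <- character()
  parents <- list()
  for (s in term_starts) {
    nxt <- starts[starts > s]
    block <- lines[(s + 1L):(if (length(nxt)) nxt[1L] - 1L
                             else length(lines))]
    get1 <- function(key) sub(paste0("^", key, ": *"), "",
                              grep(paste0("^", key, ": "), block,
                                   value = TRUE))
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- get1("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    nm <- get1("name")
    isa <- sub(" *!.*$", "", get1("is_a"))
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[1L] else id)
    parents[[id]] <- isa
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in OBO file")
  ont <- list(id = ids, name = stats::setNames(nms, ids),
              parents = parents)
  ont$ancestors <- compute_ancestors(ont)
  structure(ont, class = "ontology")
}

# transitive is_a closure; errors on cycles
compute_ancestors <- function(ont) {
  anc <- list()
  visit <- function(id, path = character()) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    if (id %in% path) stop("cycle in ontology at ", id)
    ps <- intersect(ont$parents[[id]], ont$id)
    res <- ps
    for (p in ps) res <- union(res, visit(p, c(path, id)))
    anc[[id]] <<- res
    res
  }
  for (id in ont$id) visit(id)
  anc[ont$id]
}

#' Read a two-column gene-to-term annotation table
#'
#' Accepts a plain two-column TSV (gene, term) or a GAF-style table, from
#' which columns 2 (gene) and 5 (term) are taken.
#'
#' @param path annotation file path.
#' @param gaf logical; `TRUE` for GAF-style column layout.
#' @return data frame with columns `gene` and `term`.
#' @export
read_gene_annotations <- function(path, gaf = FALSE) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  tab <- utils::read.delim(path, header = !gaf, sep = "\t",
                           colClasses = "character", comment.char = "!",
                           quote = "")
  if (gaf) {
    if (ncol(tab) < 5) stop("GAF table needs at least 5 columns")
    tab <- tab[, c(2L, 5L)]
  } else if (ncol(tab) < 2) {
    stop("annotation table needs two columns: gene, term")
  } else tab <- tab[, 1:2]
  colnames(tab) <- c("gene", "term")
  unique(tab)
}

#' Propagate gene annotations to ancestor categories
#'
#' @param annotations data frame with `gene` and `term` columns.
#' @param ont an [read_obo()] ontology.
#' @return named list term id -> character vector of annotated genes,
#'   closed under ancestry.
#' @export
propagate_annotations <- function(annotations, ont) {
  annotations <- annotations[annotations$term %in% ont$id, , drop = FALSE]
  ext <- lapply(seq_len(nrow(annotations)), function(i)
    data.frame(gene = annotations$gene[i],
               term = c(annotations$term[i],
                        ont$ancestors[[annotations$term[i]]]),
               stringsAsFactors = FALSE))
  all <- unique(do.call(rbind, c(list(annotations), ext)))
  lapply(split(all$gene, factor(all$term, levels = ont$id)), unique)
}

#' Informative ontology categories
#'
#' A category is informative when it annotates more than `threshold` genes
#' of the universe (after propagation) while each of its children
#' annotates fewer than `threshold`.
#'
#' @param ont ontology.
#' @param term_genes propagated annotation list from
#'   [propagate_annotations()].
#' @param universe character vector of genes forming the counting
#'   background.
#' @param threshold gene-count threshold (default 300).
#' @return character vector of informative category ids.
#' @export
informative_categories <- function(ont, term_genes, universe,
                                   threshold = 300) {
  if (length(universe) == 0L) stop("empty gene universe")
  counts <- vapply(term_genes, function(g)
    length(intersect(g, universe)), integer(1))
  children <- split(rep(ont$id, lengths(ont$parents)),
                    factor(unlist(ont$parents), levels = ont$id))
  ok <- vapply(ont$id, function(id) {
    counts[[id]] > threshold &&
      all(counts[children[[id]]] < threshold)
  }, logical(1))
  ont$id[ok]
}

#' One-sided Fisher exact enrichment test
#'
#' Tests whether `gene_set` accumulates genes of `category_genes` beyond
#' chance within `universe` (hypergeometric upper tail).
#'
#' @param gene_set genes of interest (subset of `universe`).
#' @param category_genes genes annotated to the category.
#' @param universe background gene set.
#' @return list with `p_value` and the 2x2 `table`.
#' @export
fisher_enrichment <- function(gene_set, category_genes, universe) {
  if (length(universe) == 0L) stop("empty gene universe")
  gene_set <- intersect(gene_set, universe)
  category_genes <- intersect(category_genes, universe)
  a <- length(intersect(gene_set, category_genes))
  b <- length(gene_set) - a
  c <- length(category_genes) - a
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), 2L,
                dimnames = list(set = c("in", "out"),
                                category = c("in", "out")))
  list(p_value = stats::fisher.test(tab, alternative = "greater")$p.value,
       table = tab)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (false discovery rates), via
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Strongly preferentially expressed gene sets per tissue
#'
#' The input sets for enrichment profiling: per tissue, the genes whose
#' PEM exceeds a fixed score threshold (default 0.8, i.e. about 1.74-fold
#' above their mean expression).
#'
#' @param st a PEM `score_table`.
#' @param threshold PEM cutoff.
#' @return named list tissue -> character vector of genes.
#' @export
pem_threshold_sets <- function(st, threshold = 0.8) {
  if (inherits(st, "score_table")) {
    if (st$kind != "pem") stop("need a PEM score table")
    sc <- st$scores
  } else sc <- st
  sets <- lapply(colnames(sc), function(l)
    rownames(sc)[!is.na(sc[, l]) & sc[, l] > threshold])
  stats::setNames(sets, colnames(sc))
}

#' Enrichment profile of tissue gene sets over informative categories
#'
#' Builds the tissue x category matrix of BH-adjusted Fisher enrichment
#' FDRs (adjustment across categories within each tissue) and clusters
#' rows and columns with Ward's method on Euclidean distances of
#' `-log10(FDR)`.
#'
#' @param gene_sets named list tissue -> genes (e.g.
#'   [pem_threshold_sets()]).
#' @param ont ontology.
#' @param annotations gene/term annotation data frame.
#' @param universe background gene set (typically all genes assayed).
#' @param threshold informative-category gene-count threshold.
#' @param categories optional explicit category ids, bypassing the
#'   informative-category selection.
#' @return object of class `"enrichment_profile"`: `fdr` matrix,
#'   `p_value` matrix, per-cell overlap `counts`, and `row_hclust` /
#'   `col_hclust` trees (NULL when a dimension has fewer than 3 entries).
#' @export
profile_and_cluster <- function(gene_sets, ont, annotations, universe,
                                threshold = 300, categories = NULL) {
  term_genes <- propagate_annotations(annotations, ont)
  if (is.null(categories))
    categories <- informative_categories(ont, term_genes, universe,
                                         threshold)
  if (length(categories) == 0L) stop("no informative categories")
  p <- matrix(NA_real_, length(gene_sets), length(categories),
              dimnames = list(names(gene_sets), categories))
  counts <- p
  for (i in seq_along(gene_sets)) for (j in seq_along(categories)) {
    fe <- fisher_enrichment(gene_sets[[i]], term_genes[[categories[j]]],
                            universe)
    p[i, j] <- fe$p_value
    counts[i, j] <- fe$table[1L, 1L]
  }
  fdr <- t(apply(p, 1L, bh_adjust))
  dimnames(fdr) <- dimnames(p)
  nl <- -log10(pmax(fdr, 1e-300))
  row_hc <- if (nrow(fdr) >= 2L)
    stats::hclust(stats::dist(nl), method = "ward.D2") else NULL
  col_hc <- if (ncol(fdr) >= 2L)
    stats::hclust(stats::dist(t(nl)), method = "ward.D2") else NULL
  structure(list(fdr = fdr, p_value = p, counts = counts,
                 row_hclust = row_hc, col_hclust = col_hc,
                 category_names = ont$name[categories]),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("Enrichment profile: %d tissues x %d categories\n",
              nrow(x$fdr), ncol(x$fdr)))
  best <- apply(x$fdr, 1L, function(v) colnames(x$fdr)[which.min(v)])
  cat("  most enriched category per tissue:\n")
  for (i in seq_len(nrow(x$fdr)))
    cat(sprintf("    %s: %s (FDR %.3g)\n", rownames(x$fdr)[i], best[i],
                min(x$fdr[i, ])))
  invisible(x)
}
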