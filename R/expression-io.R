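# Expression matrices are plain numeric matrices throughout the package:
# rows = features (probes before collapsing, genes after), columns = samples
# (or tissue classes after class averaging).  NA marks a missing measurement.
# Tissue-class maps are named character vectors: names(tc) = sample ids,
# values = tissue-class names; class order is the order of first appearance
# (or factor levels when a factor is supplied).

#' Validate an expression matrix
#'
#' Checks the structural invariants every stage of the pipeline relies on:
#' a numeric matrix with unique, non-empty row (feature) and column (sample)
#' names, and -- for linear-scale data -- strictly positive non-missing
#' values so that a log2 transform is defined.
#'
#' @param m numeric matrix, features x samples.
#' @param log_scale logical; `TRUE` when values are log2 units, `FALSE` for
#'   linear intensities.
#' @return `m`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(m, log_scale = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!log_scale && any(m[!is.na(m)] <= 0))
    stop("linear-scale expression values must be > 0 (needed for log2)")
  invisible(m)
}

#' Read a tab-delimited expression table
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers.  Empty cells and the tokens `"NA"`/`"NaN"` become missing
#' values; any other non-numeric cell is an error naming the offending row
#' and column.
#'
#' @param path file path of the TSV table.
#' @param missing_tokens character tokens treated as missing.
#' @return numeric matrix (features x samples) with NA for missing cells.
#' @export
read_expression_table <- function(path, missing_tokens = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  if (ncol(tab) < 2)
    stop("expression table needs a feature-id column plus >=1 sample column")
  features <- tab[[1L]]
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample names in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(features))
    stop("duplicate feature identifiers: ",
         paste(unique(features[duplicated(features)]), collapse = ", "))
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  miss <- cells %in% missing_tokens
  vals <- suppressWarnings(as.numeric(cells))
  bad <- is.na(vals) & !miss
  if (any(bad)) {
    idx <- which(bad)[1L]
    r <- (idx - 1L) %% nrow(cells) + 1L
    c <- (idx - 1L) %/% nrow(cells) + 1L
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 cells[idx], features[r], samples[c]))
  }
  vals[miss] <- NA_real_
  m <- matrix(vals, nrow = nrow(cells),
              dimnames = list(features, samples))
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as a tab-delimited table
#'
#' The inverse of [read_expression_table()].  Values are written with
#' `as.character()`, which round-trips doubles exactly through read/write
#' (15 significant digits); missing values are written as `NA`.
#'
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path output file path.
#' @param id_column header name of the feature-id column.
#' @export
write_expression_table <- function(m, path, id_column = "feature_id") {
  validate_expression_matrix(m)
  chr <- matrix(as.character(m), nrow = nrow(m))
  chr[is.na(m)] <- "NA"
  lines <- c(paste(c(id_column, colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column probe-to-gene mapping table
#'
#' @param path TSV with probe ids in column 1 and gene ids in column 2; a
#'   header line is detected and skipped if its first field is not reused as
#'   a probe id elsewhere is not attempted -- pass `header` explicitly.
#' @param header logical; whether the file has a header line.
#' @return named character vector, `names` = probe ids, values = gene ids.
#' @export
read_probe_map <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("probe map not found: ", path)
  tab <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("probe map needs two columns: probe, gene")
  map <- stats::setNames(tab[[2L]], tab[[1L]])
  if (anyDuplicated(names(map)))
    stop("probe mapped to more than one gene: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "))
  map
}

#' Read a two-column sample-to-tissue-class table
#'
#' @inheritParams read_probe_map
#' @return named character vector, `names` = sample ids, values = class names.
#' @export
read_class_map <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("class map not found: ", path)
  tab <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("class map needs two columns: sample, class")
  tc <- stats::setNames(tab[[2L]], tab[[1L]])
  if (anyDuplicated(names(tc)))
    stop("sample assigned to more than one class: ",
         paste(unique(names(tc)[duplicated(names(tc))]), collapse = ", "))
  tc
}

# class levels in declaration order (factor levels or first appearance)
class_levels <- function(tc) {
  if (is.factor(tc)) levels(tc) else unique(unname(as.character(tc)))
}

# Mean over columns grouped by a class assignment, ignoring NA.
# m: features x samples; cl: character vector of class labels per column;
# lev: class order.  Cells with no observation become NA.
class_average <- function(m, cl, lev = unique(cl)) {
  w <- vapply(lev, function(l) as.numeric(cl == l), numeric(length(cl)))
  if (length(cl) == 1L) w <- matrix(w, nrow = 1L, dimnames = list(NULL, lev))
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0
  sums <- m0 %*% w
  n <- obs %*% w
  avg <- sums / n
  avg[n == 0] <- NA_real_
  colnames(avg) <- lev
  avg
}

#' Collapse probe-level rows to gene-level rows
#'
#' Signals of probes mapped to the same gene are averaged per sample
#' (arithmetic mean on the stored scale, ignoring missing values); probes
#' absent from the map are dropped.  Output rows are sorted by gene id so
#' that collapsed matrices from different platforms align positionally
#' after [intersect_genes()].
#'
#' @param m probe-level expression matrix.
#' @param map named character vector probe id -> gene id
#'   (see [read_probe_map()]).
#' @return gene-level expression matrix, rows sorted by gene id.
#' @export
collapse_probes <- function(m, map) {
  validate_expression_matrix(m)
  mapped <- intersect(rownames(m), names(map))
  if (length(mapped) == 0L)
    stop("probe map covers none of the matrix's probes")
  sub <- m[mapped, , drop = FALSE]
  genes <- unname(map[mapped])
  obs <- !is.na(sub)
  sub0 <- sub
  sub0[!obs] <- 0
  sums <- rowsum(sub0, genes)
  n <- rowsum(obs + 0, genes)
  avg <- sums / n
  avg[n == 0] <- NA_real_
  avg[order(rownames(avg)), , drop = FALSE]
}

#' Average samples of the same tissue class
#'
#' Each output column is the per-gene arithmetic mean (on the stored scale,
#' ignoring missing values) over the samples assigned to one tissue class;
#' columns appear in class order.  Classes with no sample in `m` are absent.
#'
#' @param m expression matrix, features x samples.
#' @param tc tissue-class map: named character vector (or factor) mapping
#'   every column of `m` to a class.
#' @return expression matrix, features x tissue classes.
#' @export
average_by_class <- function(m, tc) {
  validate_expression_matrix(m)
  missing <- setdiff(colnames(m), names(tc))
  if (length(missing))
    stop("samples without tissue-class assignment: ",
         paste(missing, collapse = ", "))
  cl <- as.character(tc[colnames(m)])
  lev <- intersect(class_levels(tc), cl)
  class_average(m, cl, lev)
}

#' Restrict datasets to their common genes
#'
#' @param datasets list of >= 2 gene-level expression matrices.
#' @return list of matrices, all restricted to the sorted intersection of
#'   their gene ids, with identical row order.
#' @export
intersect_genes <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least two datasets")
  common <- sort(Reduce(intersect, lapply(datasets, rownames)))
  if (length(common) == 0L) stop("gene sets have an empty intersection")
  lapply(datasets, function(m) m[common, , drop = FALSE])
}

#' Quantile-normalize the columns of an expression matrix
#'
#' Makes every column's empirical distribution equal to the reference
#' distribution (the row-wise mean of the sorted columns) while preserving
#' within-column ranks.  Delegates to [limma::normalizeQuantiles()].
#'
#' @param m numeric matrix; columns are equalized.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("need a numeric matrix")
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na))
    stop("column(s) with all values missing: ",
         paste(colnames(m)[all_na], collapse = ", "))
  out <- limma::normalizeQuantiles(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2-transform a linear-scale expression matrix
#'
#' Values \eqn{\le 0} (possible in MAS5-style summaries) are set to missing
#' before the transform.
#'
#' @param m linear-scale expression matrix.
#' @return log2-scale matrix.
#' @export
log2_transform <- function(m) {
  m[!is.na(m) & m <= 0] <- NA_real_
  log2(m)
}
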