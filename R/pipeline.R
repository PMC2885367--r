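# End-to-end orchestration: simulate or ingest datasets, collapse probes,
# class-average, intersect to common genes, compare datasets, score
# specificity, derive gene lists, consolidate rankings, and (optionally)
# calibrate FDR thresholds.  Every intermediate table is written as TSV and
# recorded with its checksum in a JSON manifest; all randomness derives
# deterministically from one master seed.

# deterministic per-stage seed below 2^31
derive_seed <- function(master, stage) {
  (as.integer(master) %% 100000L) * 10007L +
    sum(utf8ToInt(stage)) %% 10007L
}

#' Write a score table as TSV (per-tissue score and FDR columns)
#'
#' Layout: gene id, one score column per tissue, then one FDR column per
#' tissue (`fdr.<tissue>`; for PEM additionally `fdr_lower.<tissue>`).
#'
#' @param st a `score_table`.
#' @param path output file path.
#' @export
write_score_table <- function(st, path) {
  out <- as.data.frame(st$scores)
  colnames(out) <- paste0(st$kind, ".", colnames(st$scores))
  if (!is.null(st$fdr)) {
    f <- as.data.frame(st$fdr)
    colnames(f) <- paste0("fdr.", colnames(st$fdr))
    out <- cbind(out, f)
  }
  if (!is.null(st$fdr_lower)) {
    f <- as.data.frame(st$fdr_lower)
    colnames(f) <- paste0("fdr_lower.", colnames(st$fdr_lower))
    out <- cbind(out, f)
  }
  out <- cbind(gene = rownames(st$scores), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full comparison-and-consolidation pipeline
#'
#' Stages, in dependency order: data (simulate a compendium, or read
#' per-dataset expression tables with optional probe collapsing), class
#' averaging, gene intersection, similarity (correlation of correlations
#' with randomized baseline and dataset clustering), specificity (PEM and
#' MAX score tables with permutation FDRs), gene lists and overlap tallies,
#' and mean-rank consolidation with cross-validation.  A failing stage
#' aborts with the stage named; every output TSV plus a JSON manifest with
#' parameters, derived seeds and file checksums lands in `out_dir`.
#'
#' @param config configuration list, or path of a YAML file holding one.
#'   Recognized fields: `simulate` (list of [simulation_config()]
#'   arguments) or `datasets` (list of entries with `path`, optional
#'   `probe_map`, `class_map`, `log_scale` = `"log2"`/`"linear"`);
#'   `n_perm` (default 100), `fdr_cutoff` (0.25), `n_rand` (10),
#'   `consolidate_tissues` (default: all), `calibration` (list with
#'   `reference_tissue`, `s`, `alpha`, `n_reps`), `seed` (master seed),
#'   `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  n_perm <- config$n_perm %||% 100L
  fdr_cutoff <- config$fdr_cutoff %||% 0.25
  n_rand <- config$n_rand %||% 10L
  manifest <- list(package = "tissuecons",
                   version = as.character(utils::packageVersion("tissuecons")),
                   seed = seed,
                   parameters = list(n_perm = n_perm,
                                     fdr_cutoff = fdr_cutoff,
                                     n_rand = n_rand),
                   files = list())
  record <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- data stage -----------------------------------------------------
  datasets <- stage("data", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% derive_seed(seed, "simulate")
      sim <- simulate_compendium(do.call(simulation_config, args))
      record(write_tsv(sim$truth, file.path(out_dir, "ground_truth.tsv")))
      Map(function(m, tc) list(expr = m, classes = tc),
          sim$expression, sim$classes)
    } else if (!is.null(config$datasets)) {
      res <- lapply(config$datasets, function(d) {
        m <- read_expression_table(d$path)
        if (!is.null(d$probe_map))
          m <- collapse_probes(m, read_probe_map(d$probe_map))
        if (identical(d$log_scale, "linear")) m <- log2_transform(m)
        tc <- read_class_map(d$class_map)
        list(expr = m, classes = tc)
      })
      names(res) <- vapply(config$datasets, function(d)
        d$name %||% basename(d$path), character(1))
      res
    } else stop("config needs either 'simulate' or 'datasets'")
  })

  # --- class averaging and intersection -------------------------------
  averaged <- stage("average", {
    avg <- lapply(datasets, function(d) average_by_class(d$expr, d$classes))
    avg <- intersect_genes(avg)
    for (nm in names(avg))
      record(write_expression_table(avg[[nm]],
        file.path(out_dir, paste0(nm, "_class_averaged.tsv")),
        id_column = "gene"))
    avg
  })

  # --- similarity ------------------------------------------------------
  stage("similarity", {
    cm <- coc_matrix(averaged, mode = "genes", n_rand = n_rand,
                     seed = derive_seed(seed, "similarity"))
    record(write_tsv(cbind(dataset = rownames(cm$original),
                           as.data.frame(cm$original)),
                     file.path(out_dir, "coc_original.tsv")))
    record(write_tsv(cbind(dataset = rownames(cm$random),
                           as.data.frame(cm$random)),
                     file.path(out_dir, "coc_random.tsv")))
    cl <- cluster_datasets(cm$original)
    leaf_path <- file.path(out_dir, "dataset_leaf_order.txt")
    writeLines(paste(cl$order, collapse = "\t"), leaf_path)
    record(leaf_path)
    cm
  })

  # --- specificity ------------------------------------------------------
  score_tables <- stage("specificity", {
    common <- rownames(averaged[[1L]])
    res <- list()
    for (nm in names(datasets)) {
      m <- datasets[[nm]]$expr[
        intersect(rownames(datasets[[nm]]$expr), common), , drop = FALSE]
      for (kind in c("pem", "max")) {
        st <- specificity_scores(m, datasets[[nm]]$classes, kind = kind,
                                 n_perm = n_perm,
                                 seed = derive_seed(seed,
                                                    paste0(kind, nm)))
        record(write_score_table(st,
          file.path(out_dir, sprintf("%s_%s_scores.tsv", nm, kind))))
        res[[kind]][[nm]] <- st
      }
    }
    res
  })

  # --- gene lists -------------------------------------------------------
  stage("gene_lists", {
    over <- lapply(score_tables$pem, derive_gene_lists,
                   fdr_cutoff = fdr_cutoff, direction = "over")
    unique_over <- lapply(score_tables$max, derive_gene_lists,
                          fdr_cutoff = fdr_cutoff,
                          direction = "unique_over")
    counts <- do.call(rbind, lapply(names(over), function(nm)
      data.frame(dataset = nm, tissue = names(over[[nm]]),
                 n_over = lengths(over[[nm]]),
                 n_unique_over = lengths(unique_over[[nm]]),
                 row.names = NULL)))
    record(write_tsv(counts, file.path(out_dir, "list_counts.tsv")))
    if (length(unique_over) >= 2L)
      record(write_tsv(list_overlap(unique_over),
                       file.path(out_dir, "list_overlap.tsv")))
  })

  # --- consolidation ----------------------------------------------------
  stage("consolidation", {
    tissues <- config$consolidate_tissues %||%
      score_tables$max[[1L]]$tissues
    for (l in tissues) {
      cons <- consolidate_by_mean_rank(score_tables$max, l)
      record(write_tsv(cons,
        file.path(out_dir, sprintf("consolidated_%s.tsv", l))))
    }
    if (length(score_tables$max) >= 3L) {
      cv <- tryCatch(cross_validate(score_tables$max, tissues[[1L]]),
                     error = function(e) NULL)
      if (!is.null(cv))
        record(write_tsv(cv, file.path(out_dir, "cross_validation.tsv")))
    }
  })

  # --- calibration (optional) ------------------------------------------
  if (!is.null(config$calibration)) stage("calibration", {
    cb <- config$calibration
    d1 <- datasets[[cb$dataset %||% 1L]]
    cal <- adjust_fdr_threshold(d1$expr, d1$classes,
                                cb$reference_tissue, s = cb$s,
                                alpha = cb$alpha %||% 0.05,
                                n_reps = cb$n_reps %||% 50L,
                                n_perm = n_perm,
                                seed = derive_seed(seed, "calibration"))
    record(write_tsv(data.frame(reference = cal$reference_tissue,
                                alpha = cal$alpha, s = cal$s,
                                n_ref = cal$n_ref,
                                adjusted_threshold =
                                  cal$adjusted_threshold),
                     file.path(out_dir, "fdr_calibration.tsv")))
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
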