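#' Assemble a run configuration
#'
#' One serializable object drives the whole pipeline; every run writes the
#' resolved configuration beside its outputs so results are reproducible from
#' that file alone.
#'
#' @param gff,etc_bed,chrom_sizes Annotation inputs ([load_annotation()]).
#' @param sample_sheet Path to a sample-sheet TSV, or a data.frame.
#' @param counts Optional path to a precomputed count TSV (skips counting).
#' @param simulate If `TRUE`, all inputs are generated by the simulator and
#'   the annotation paths are ignored.
#' @param dialect,uniqueness_policy,mapq_min Counting options.
#' @param partition A [partition_config()].
#' @param de A [de_config()].
#' @param classify A [classify_config()].
#' @param sim A [simulation_config()].
#' @param write_bedgraphs Export per-sample stranded coverage tracks (only
#'   when counting from alignments).
#' @return List of class `RunConfig`.
#' @export
run_config <- function(gff = NULL, etc_bed = NULL, chrom_sizes = NULL,
                       sample_sheet = NULL, counts = NULL, simulate = FALSE,
                       dialect = "reverse", uniqueness_policy = "auto",
                       mapq_min = 10L, partition = partition_config(),
                       de = de_config(), classify = classify_config(),
                       sim = simulation_config(),
                       write_bedgraphs = FALSE) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Write / read a run configuration as YAML
#' @param config A `RunConfig`.
#' @param path YAML path.
#' @return `write_run_config`: invisibly `path`; `read_run_config`: a
#'   `RunConfig`.
#' @export
write_run_config <- function(config, path) {
  ser <- lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(raw)) {
    if (nm %in% c("partition", "de", "classify", "sim") && is.list(raw[[nm]])) {
      fn <- switch(nm, partition = partition_config, de = de_config,
                   classify = classify_config, sim = simulation_config)
      cfg[[nm]] <- do.call(fn, raw[[nm]])
    } else if (!is.null(raw[[nm]])) {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

#' Write / read a count matrix TSV (region id, role, one column per sample)
#' @param counts Count matrix.
#' @param catalog Matching `RegionCatalog` (for the role column).
#' @param path TSV path.
#' @return `write_counts`: invisibly `path`; `read_counts`: integer matrix
#'   with region-id rownames.
#' @export
write_counts <- function(counts, catalog, path) {
  df <- data.frame(id = rownames(counts),
                   role = catalog$regions$role[
                     match(rownames(counts), catalog$regions$id)],
                   counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("id", "role")), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' Run the full analysis pipeline
#'
#' Executes annotate -> counting (or count/matrix loading or simulation) ->
#' differential expression -> classification -> summaries, writing TSV/BED
#' outputs plus the resolved configuration into `out_dir`. On failure the
#' partially written directory is marked with a `FAILED` file naming the
#' stage.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a named list of output paths (and, for simulated runs,
#'   the `RecoveryReport`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "configure"
  result <- tryCatch({
    write_run_config(config, file.path(out_dir, "config_resolved.yaml"))
    truth <- NULL; sim <- NULL
    stage <- "annotate"
    if (isTRUE(config$simulate)) {
      sim <- simulate_genome(config$sim)
      files <- write_simulated_genome(sim, file.path(out_dir, "sim"))
      ann <- list(genes = sim$genes, sites = sim$sites,
                  chrom_sizes = sim$chrom_sizes)
      truth <- sim$truth
    } else {
      if (is.null(config$gff) || is.null(config$chrom_sizes))
        stop("gff and chrom_sizes are required unless simulate = TRUE")
      ann <- load_annotation(config$gff, config$chrom_sizes, config$etc_bed)
    }
    catalog <- partition_genome(ann$genes, ann$chrom_sizes, config$partition)
    write_catalog(catalog, file.path(out_dir, "catalog.bed"),
                  file.path(out_dir, "catalog.tsv"))

    stage <- "counting"
    if (isTRUE(config$simulate)) {
      sc <- simulate_counts(sim, catalog)
      counts <- sc$counts
      sample_sheet <- sc$sample_sheet
    } else {
      sample_sheet <- if (is.data.frame(config$sample_sheet))
        validate_sample_sheet(config$sample_sheet)
      else read_sample_sheet(config$sample_sheet)
      if (!is.null(config$counts)) {
        counts <- read_counts(config$counts)
        counts <- counts[catalog$regions$id, , drop = FALSE]
      } else {
        counts <- build_count_matrix(sample_sheet, catalog,
                                     dialect = config$dialect,
                                     policy = config$uniqueness_policy,
                                     mapq_min = config$mapq_min)
        if (isTRUE(config$write_bedgraphs)) {
          for (i in seq_len(nrow(sample_sheet))) {
            fr <- filter_unique(
              read_alignments(sample_sheet$path[i], dialect = config$dialect),
              policy = config$uniqueness_policy, mapq_min = config$mapq_min)
            for (s in c("+", "-"))
              write_bedgraph(fr, file.path(out_dir, sprintf(
                "%s_%s.bedgraph", sample_sheet$sample[i],
                if (s == "+") "plus" else "minus")), strand = s,
                negate = (s == "-"))
          }
        }
      }
    }
    write_counts(counts, catalog, file.path(out_dir, "counts.tsv"))
    qc <- replicate_correlation(counts, sample_sheet)
    utils::write.table(
      data.frame(condition = names(qc), replicate_r = unname(qc)),
      file.path(out_dir, "qc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

    stage <- "diffexp"
    de <- run_de(counts, sample_sheet, catalog, config$de)
    write_de_table(de[de$scope == "genes", , drop = FALSE],
                   file.path(out_dir, "de_genes.tsv"))
    write_de_table(de[de$scope == "intergenic", , drop = FALSE],
                   file.path(out_dir, "de_intergenic.tsv"))

    stage <- "classify"
    classified <- classify_regions(de, catalog, ann$sites, config$classify)
    summary <- summarize_classification(classified, de, catalog, ann$sites,
                                        config$classify)
    write_classification(classified, summary,
                         file.path(out_dir, "classification.tsv"),
                         file.path(out_dir, "summary.tsv"))

    out <- list(dir = out_dir, de = de, classified = classified,
                summary = summary)
    if (!is.null(truth)) {
      stage <- "evaluate"
      recovery <- evaluate_recovery(classified, de, truth)
      utils::write.table(recovery$per_class,
                         file.path(out_dir, "recovery.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out$recovery <- recovery
    }
    out
  }, error = function(e) {
    writeLines(paste0("stage ", stage, ": ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
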