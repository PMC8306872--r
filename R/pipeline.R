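#' Assemble a validated pipeline configuration
#'
#' Either `expression` + `metadata` paths or a `generator` config must be
#' given. All analysis thresholds resolve through [contrast_params()]; the
#' resolved configuration is written beside every run's outputs for
#' provenance.
#'
#' @param expression,metadata paths to the input TSV pair (optional when
#'   `generator` is given).
#' @param annotation optional annotation TSV path.
#' @param generator optional [generator_config()] (or path to its YAML).
#' @param seed integer seed; required with a generator.
#' @param params analysis parameters from [contrast_params()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, metadata = NULL, annotation = NULL,
                            generator = NULL, seed = NULL,
                            params = contrast_params()) {
  if (is.null(generator) && (is.null(expression) || is.null(metadata))) {
    stop("either expression + metadata paths or a generator config is required")
  }
  if (!is.null(generator)) {
    if (is.character(generator)) generator <- read_generator_config(generator, seed = seed)
    stopifnot(inherits(generator, "generator_config"))
    if (!is.null(seed)) generator$seed <- as.integer(seed)
  }
  stopifnot(is.list(params))
  if (params$high <= params$low) stop("high threshold must exceed low threshold")
  if (params$background <= 0) stop("background must be > 0")
  if (params$ratio_threshold <= 1) stop("ratio_threshold must be > 1")
  if (params$q_threshold <= 0 || params$q_threshold > 1) stop("q_threshold must be in (0, 1]")
  structure(list(expression = expression, metadata = metadata,
                 annotation = annotation, generator = generator,
                 seed = seed, params = params),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `expression`, `metadata`, `annotation` (paths),
#' `generator` (inline generator config or a path), `seed`, and `params`
#' (any [contrast_params()] override).
#'
#' @param path YAML file.
#' @param seed overrides the file's seed.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  gen <- raw$generator
  if (!is.null(gen) && !is.character(gen)) {
    blocks <- if (is.null(gen$blocks)) default_blocks() else lapply(gen$blocks, function(b) {
      planted_block(b$label, b$n_genes, unlist(b$base_mean),
                    mean_spread = b$mean_spread %||% 0,
                    noise_scale = b$noise_scale %||% 1,
                    description = b$description %||% "")
    })
    gen <- generator_config(blocks = blocks,
                            replicates_per_condition = gen$replicates_per_condition %||% 3,
                            noise_sigma = gen$noise_sigma %||% 0.15,
                            seed = seed %||% gen$seed %||% raw$seed)
  }
  pipeline_config(expression = raw$expression, metadata = raw$metadata,
                  annotation = raw$annotation, generator = gen,
                  seed = seed %||% raw$seed,
                  params = do.call(contrast_params, raw$params %||% list()))
}

#' Run the pipeline end-to-end and write the report bundle
#'
#' Loads (or generates) the dataset, runs [nil_contrast()], and writes the
#' full report bundle to `out_dir`: one `hypothesis_<id>.tsv` per contrast
#' set, `deg_<contrast>.tsv` differential tables, `qc_correlations.tsv`,
#' `cluster_columns.txt`, `reference_candidates.tsv`,
#' `subset_profile.tsv`, `enrichment_<set>.tsv`, `summary.json` and the
#' resolved `config.yaml` (plus `truth.tsv` for generated data). Runs are
#' deterministic given inputs and seed; timestamps are confined to
#' `run.log`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if absent.
#' @param quiet suppress progress messages (default FALSE).
#' @return An object of class `nil_report`: `summary` (the counts written to
#'   `summary.json`), `analysis` (the [nil_contrast()] fit), `dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(sprintf("run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  stage <- "load"
  result <- tryCatch({
    truth <- NULL
    if (!is.null(config$generator)) {
      say("stage load: generating synthetic dataset (seed %d)", config$generator$seed)
      sim <- generate_dataset(config$generator)
      x <- sim$expression
      truth <- sim$truth
    } else {
      say("stage load: reading %s", config$expression)
      x <- read_expression_table(config$expression, config$metadata)
    }
    annotation <- if (!is.null(config$annotation)) {
      read_annotation_table(config$annotation)
    }
    p <- config$params
    say("stage analysis: thresholds %s",
        paste(names(p), vapply(p, function(v) paste(v, collapse = "/"), ""),
              sep = "=", collapse = " "))
    stage <- "analysis"
    fit <- nil_contrast(x, annotation = annotation, params = p)

    stage <- "write"
    say("stage write: %s", out_dir)
    if (!is.null(truth)) {
      write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    for (id in names(fit$sets)) {
      write_contrast_set(fit$sets[[id]], file.path(out_dir, paste0("hypothesis_", id, ".tsv")))
    }
    for (id in names(fit$differential)) {
      write.table(fit$differential[[id]], file.path(out_dir, paste0("deg_", id, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(fit$qc)) {
      write.table(fit$qc$pairs, file.path(out_dir, "qc_correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(fit$clustering)) {
      writeLines(fit$clustering$column_order, file.path(out_dir, "cluster_columns.txt"))
    }
    write.table(fit$reference, file.path(out_dir, "reference_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(fit$profiles)) {
      prof <- do.call(rbind, fit$profiles)
      prof <- cbind(set = names(fit$profiles), prof)
      write.table(prof, file.path(out_dir, "subset_profile.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (id in names(fit$enrichment)) {
      write.table(fit$enrichment[[id]], file.path(out_dir, paste0("enrichment_", id, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    s <- summary(fit)
    summary_counts <- list(
      n_contigs = s$n_contigs, n_samples = s$n_samples,
      expressed_count = s$expressed_count,
      set_sizes = as.list(s$set_sizes),
      deg_counts = as.list(s$deg_counts),
      reference_candidates = fit$reference$contig_id,
      qc = if (!is.null(fit$qc)) list(min_r = fit$qc$min_r, max_r = fit$qc$max_r)
    )
    jsonlite::write_json(summary_counts, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    resolved <- list(
      expression = config$expression, metadata = config$metadata,
      annotation = config$annotation, seed = config$seed,
      generator = if (!is.null(config$generator)) {
        g <- config$generator
        list(replicates_per_condition = g$replicates_per_condition,
             noise_sigma = g$noise_sigma, seed = g$seed,
             blocks = lapply(g$blocks, function(b) {
               list(label = b$label, n_genes = b$n_genes,
                    base_mean = as.numeric(b$base_mean),
                    mean_spread = b$mean_spread, noise_scale = b$noise_scale)
             }))
      },
      params = config$params
    )
    yaml::write_yaml(resolved, file.path(out_dir, "config.yaml"))
    structure(list(summary = summary_counts, analysis = fit, dir = out_dir),
              class = "nil_report")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  writeLines(log_lines, log_path)
  result
}

#' @export
print.nil_report <- function(x, ...) {
  cat("<nil_report> written to ", x$dir, "\n", sep = "")
  print(summary(x$analysis))
  invisible(x)
}

#' Re-read the summary of a written report bundle
#'
#' @param dir a directory written by [run_pipeline()].
#' @return the parsed `summary.json` list.
#' @export
read_report_summary <- function(dir) {
  path <- file.path(dir, "summary.json")
  if (!file.exists(path)) stop("no summary.json under ", dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
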