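BLOCK_LABELS <- c("exclusive_L", "exclusive_H", "induced_both_strongL",
                  "induced_L_only", "induced_H_only", "repressed_H_only",
                  "housekeeping", "null_background")

#' Define one planted gene block for the synthetic generator
#'
#' A block is a set of genes sharing the same four condition-level base means
#' (L/control, L/cadmium, H/control, H/cadmium, FPKM). Optional per-block
#' knobs: `mean_spread` draws one log-normal multiplier per gene (sdlog on the
#' natural-log scale) applied jointly to all four cell means, so fold changes
#' are preserved while between-gene abundance varies — this is what gives a
#' background block a realistic FPKM distribution; `noise_scale` rescales the
#' global replicate noise for the block (a housekeeping block is quieter than
#' the transcriptome at large). Both default to the plain behaviour
#' (identical means within a block, global noise).
#'
#' @param label one of `exclusive_L`, `exclusive_H`, `induced_both_strongL`,
#'   `induced_L_only`, `induced_H_only`, `repressed_H_only`, `housekeeping`,
#'   `null_background`.
#' @param n_genes number of genes planted under the label (>= 0).
#' @param base_mean numeric length-4 vector of FPKM base means, in the order
#'   L/control, L/cadmium, H/control, H/cadmium.
#' @param mean_spread sdlog of the per-gene abundance multiplier (default 0).
#' @param noise_scale per-block multiplier on the replicate noise (default 1).
#' @param description free text carried into reports.
#' @return A list of class `planted_block`.
#' @export
planted_block <- function(label, n_genes, base_mean, mean_spread = 0,
                          noise_scale = 1, description = "") {
  label <- match.arg(label, BLOCK_LABELS)
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 0) stop("n_genes must be >= 0")
  base_mean <- as.numeric(base_mean)
  if (length(base_mean) != 4 || any(!is.finite(base_mean)) || any(base_mean < 0)) {
    stop("base_mean must be four finite non-negative FPKM values ",
         "(L/control, L/cadmium, H/control, H/cadmium)")
  }
  names(base_mean) <- c("L.control", "L.cadmium", "H.control", "H.cadmium")
  if (mean_spread < 0) stop("mean_spread must be >= 0")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(label = label, n_genes = n_genes, base_mean = base_mean,
                 mean_spread = mean_spread, noise_scale = noise_scale,
                 description = description),
            class = "planted_block")
}

#' Default planted-block catalogue
#'
#' Ships the archetypes of the study design this package models, with base
#' means transcribed from its published condition-level FPKM tables:
#' genotype-exclusive panels (column means of the five L-exclusive and nine
#' H-exclusive contigs), a cadmium-induced block that responds in both
#' genotypes but far more strongly in L (the nicotianamine-synthase panel
#' means: 6.3 / 632.1 FPKM in L versus 34.4 / 245.0 in H, i.e. roughly
#' 100-fold versus 7-fold), genotype-specific induced and repressed blocks,
#' a quiet housekeeping block, and a log-normally spread null background.
#'
#' @param n_null number of null-background genes (default 2000).
#' @return list of [planted_block()] objects.
#' @export
default_blocks <- function(n_null = 2000) {
  list(
    planted_block("exclusive_L", 5, c(50.1, 36.3, 2.0, 1.3),
                  description = "constitutive in L, silent in H"),
    planted_block("exclusive_H", 9, c(1.30, 1.26, 73.5, 57.3),
                  description = "constitutive in H, silent in L"),
    planted_block("induced_both_strongL", 22, c(6.3, 632.1, 34.4, 245.0),
                  description = "cadmium-induced in both, strongly in L (NAS archetype)"),
    planted_block("induced_L_only", 40, c(8, 120, 8, 8),
                  description = "cadmium-induced only in L"),
    planted_block("induced_H_only", 25, c(8, 8, 8, 120),
                  description = "cadmium-induced only in H"),
    planted_block("repressed_H_only", 15, c(50, 50, 50, 5),
                  description = "cadmium-repressed only in H"),
    planted_block("housekeeping", 10, c(80, 80, 80, 80), noise_scale = 0.3,
                  description = "stable reference-gene candidates"),
    planted_block("null_background", n_null, c(20, 20, 20, 20), mean_spread = 1.3,
                  description = "log-normally spread unresponsive background")
  )
}

#' Treatment-dominant block catalogue for clustering QC
#'
#' A catalogue in which a broad cadmium response shared by both genotypes
#' dominates a modest genotype signature — the structure under which
#' unsupervised sample clustering separates control from cadmium-treated
#' samples at the top level, as the study's heatmap does. The shared
#' response block reuses the `induced_both_strongL` label (the catalogue's
#' shared-induction slot) with nearly symmetric fold changes.
#'
#' @param n_null number of null-background genes (default 500).
#' @return list of [planted_block()] objects.
#' @export
treatment_dominant_blocks <- function(n_null = 500) {
  list(
    planted_block("exclusive_L", 5, c(50.1, 36.3, 2.0, 1.3),
                  description = "constitutive in L, silent in H"),
    planted_block("exclusive_H", 9, c(1.30, 1.26, 73.5, 57.3),
                  description = "constitutive in H, silent in L"),
    planted_block("induced_both_strongL", 80, c(10, 300, 10, 250),
                  description = "broad cadmium induction shared by both genotypes"),
    planted_block("housekeeping", 10, c(80, 80, 80, 80), noise_scale = 0.3,
                  description = "stable reference-gene candidates"),
    planted_block("null_background", n_null, c(20, 20, 20, 20), mean_spread = 1.3,
                  description = "log-normally spread unresponsive background")
  )
}

#' Configure the synthetic FPKM generator
#'
#' @param blocks list of [planted_block()]s with unique labels
#'   (default [default_blocks()]).
#' @param replicates_per_condition biological replicates per genotype/treatment
#'   cell (default 3, the study design).
#' @param noise_sigma standard deviation of the natural-log-scale replicate
#'   noise (default 0.15; see the methods vignette for the calibration to the
#'   published replicate-correlation range).
#' @param seed integer RNG seed; mandatory so every dataset is reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(blocks = default_blocks(), replicates_per_condition = 3,
                             noise_sigma = 0.15, seed) {
  if (missing(seed) || is.null(seed)) stop("generator_config requires a seed")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (!length(blocks)) stop("at least one block is required")
  if (!all(vapply(blocks, inherits, logical(1), "planted_block"))) {
    stop("blocks must all be planted_block objects")
  }
  labels <- vapply(blocks, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate block label(s): ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  replicates_per_condition <- as.integer(replicates_per_condition)
  if (is.na(replicates_per_condition) || replicates_per_condition < 1) {
    stop("replicates_per_condition must be >= 1")
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(blocks = blocks,
                 replicates_per_condition = replicates_per_condition,
                 noise_sigma = noise_sigma, seed = seed),
            class = "generator_config")
}

#' Generate a replicate-level FPKM dataset with planted ground truth
#'
#' Emulates the 2 genotypes x 2 treatments x k replicates design. Every
#' replicate value is the gene's condition base mean times `exp(e)` with
#' `e ~ Normal(0, noise_sigma * noise_scale)` — multiplicative log-normal
#' noise, so values stay non-negative and a zero base mean stays exactly
#' zero. Deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @return list with elements `expression` (an [expression_set()]) and
#'   `truth` (data frame `contig_id`, `label` covering every generated contig
#'   exactly once).
#' @examples
#' sim <- generate_dataset(generator_config(seed = 1))
#' table(sim$truth$label)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  k <- config$replicates_per_condition
  cells <- paste(rep(GENOTYPES, each = 2), TREATMENTS, sep = ".")
  samples <- data.frame(
    sample_id = paste0(rep(c("L_ctrl", "L_cd", "H_ctrl", "H_cd"), each = k),
                       "_r", rep(seq_len(k), times = 4)),
    genotype  = rep(rep(GENOTYPES, each = 2), each = k),
    treatment = rep(rep(TREATMENTS, times = 2), each = k),
    replicate = rep(seq_len(k), times = 4),
    stringsAsFactors = FALSE
  )

  n_total <- sum(vapply(config$blocks, `[[`, integer(1), "n_genes"))
  values <- matrix(0, n_total, nrow(samples))
  truth <- character(n_total)
  row <- 0L
  for (block in config$blocks) {
    if (block$n_genes == 0L) next
    idx <- row + seq_len(block$n_genes)
    mult <- if (block$mean_spread > 0) {
      exp(rnorm(block$n_genes, 0, block$mean_spread))
    } else {
      rep(1, block$n_genes)
    }
    base <- outer(mult, block$base_mean)                      # genes x 4 cells
    colnames(base) <- cells
    sigma <- config$noise_sigma * block$noise_scale
    for (j in seq_len(nrow(samples))) {
      cell <- paste(samples$genotype[j], samples$treatment[j], sep = ".")
      eps <- if (sigma > 0) exp(rnorm(block$n_genes, 0, sigma)) else 1
      values[idx, j] <- base[, cell] * eps
    }
    truth[idx] <- block$label
    row <- row + block$n_genes
  }
  contig_ids <- sprintf("ctg%05d", seq_len(n_total))
  rownames(values) <- contig_ids
  colnames(values) <- samples$sample_id

  list(expression = expression_set(values, samples),
       truth = data.frame(contig_id = contig_ids, label = truth,
                          stringsAsFactors = FALSE))
}

#' Contigs planted under one truth label
#'
#' @param truth truth table from [generate_dataset()].
#' @param label a block label present in the truth table's config.
#' @return character vector of contig ids.
#' @export
truth_sets <- function(truth, label) {
  if (!label %in% BLOCK_LABELS) stop("unknown block label: ", label)
  truth$contig_id[truth$label == label]
}

#' Write a generated dataset as TSV files
#'
#' Writes `expression.tsv`, `metadata.tsv` and `truth.tsv` in the package's
#' TSV dialect.
#'
#' @param sim result of [generate_dataset()].
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_dataset <- function(sim, dir) {
  paths <- write_expression_table(sim$expression, dir)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, truth = truth_path))
}

#' Read a generator config from YAML
#'
#' The YAML mirrors [generator_config()]: top-level keys
#' `replicates_per_condition`, `noise_sigma`, `seed` (optional here; a seed
#' given to the caller overrides) and a `blocks` list whose entries carry
#' `label`, `n_genes`, `base_mean` (4 values) and optionally `mean_spread`,
#' `noise_scale`, `description`.
#'
#' @param path YAML file path.
#' @param seed overrides/supplies the seed.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  blocks <- if (is.null(raw$blocks)) default_blocks() else lapply(raw$blocks, function(b) {
    planted_block(b$label, b$n_genes, unlist(b$base_mean),
                  mean_spread = b$mean_spread %||% 0,
                  noise_scale = b$noise_scale %||% 1,
                  description = b$description %||% "")
  })
  generator_config(blocks = blocks,
                   replicates_per_condition = raw$replicates_per_condition %||% 3,
                   noise_sigma = raw$noise_sigma %||% 0.15,
                   seed = seed %||% raw$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
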