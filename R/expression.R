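#' @importFrom stats sd cor hclust dist as.dist cutree p.adjust pt phyper setNames rnorm
#' @importFrom utils read.delim write.table
NULL

GENOTYPES  <- c("L", "H")
TREATMENTS <- c("control", "cadmium")

#' Build a validated replicate-level FPKM expression set
#'
#' The container pairs a contigs-by-samples FPKM matrix with its sample
#' metadata (genotype, treatment, replicate). It is the sole primary input of
#' the analysis: every downstream stage (differential calling, hypothesis
#' filters, QC, reference-gene ranking) consumes this object.
#'
#' @param values numeric matrix of FPKM values, one row per contig and one
#'   column per sample. Row names are contig ids; column order must follow
#'   `samples$sample_id`.
#' @param samples data frame with columns `sample_id`, `genotype` (`"L"` or
#'   `"H"`), `treatment` (`"control"` or `"cadmium"`) and `replicate`
#'   (positive integer).
#' @return An object of class `expression_set`: a list with elements `values`
#'   and `samples`.
#' @examples
#' m <- matrix(c(10, 0, 12, 1), 2, 2, dimnames = list(c("c1", "c2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), genotype = "L",
#'                    treatment = c("control", "cadmium"), replicate = 1L)
#' expression_set(m, meta)
#' @export
expression_set <- function(values, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  required <- c("sample_id", "genotype", "treatment", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$genotype  <- as.character(samples$genotype)
  samples$treatment <- as.character(samples$treatment)
  samples$replicate <- as.integer(samples$replicate)

  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  bad_g <- setdiff(unique(samples$genotype), GENOTYPES)
  if (length(bad_g)) stop("unknown genotype value(s): ", paste(bad_g, collapse = ", "))
  bad_t <- setdiff(unique(samples$treatment), TREATMENTS)
  if (length(bad_t)) stop("unknown treatment value(s): ", paste(bad_t, collapse = ", "))
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1)) {
    stop("replicate must be a positive integer for every sample")
  }
  cells <- table(factor(samples$genotype, GENOTYPES), factor(samples$treatment, TREATMENTS))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("every genotype/treatment cell needs at least one sample; missing: ",
         paste(paste(GENOTYPES[empty[, 1]], TREATMENTS[empty[, 2]], sep = "/"),
               collapse = ", "))
  }

  if (nrow(values) > 0 && is.null(rownames(values))) {
    stop("expression matrix needs contig ids as row names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate contig id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (ncol(values) != nrow(samples)) {
    stop("expression matrix has ", ncol(values), " columns but metadata lists ",
         nrow(samples), " samples")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- samples$sample_id
  } else if (!identical(colnames(values), samples$sample_id)) {
    if (!setequal(colnames(values), samples$sample_id)) {
      stop("expression columns and metadata sample ids disagree")
    }
    values <- values[, samples$sample_id, drop = FALSE]  # metadata order wins
  }
  check_fpkm_values(values)

  structure(list(values = values, samples = samples), class = "expression_set")
}

check_fpkm_values <- function(values) {
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid FPKM value %s for contig '%s', sample '%s'",
                 format(values[bad[1, 1], bad[1, 2]]),
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  invisible(TRUE)
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$values), " contigs x ", ncol(x$values), " samples\n", sep = "")
  tab <- table(x$samples$genotype, x$samples$treatment)
  cat("replicates per genotype/treatment cell:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Read an FPKM expression table with its sample metadata
#'
#' Both files are tab-separated UTF-8 with a mandatory header and `.` decimal
#' separator. The expression table has the contig id in the first column and
#' one column per sample; the metadata table maps every sample id to genotype,
#' treatment and replicate. Column order of the returned matrix follows the
#' metadata row order, so the metadata file is the single source of design
#' information (no parsing of sample names).
#'
#' @param path path to the expression TSV (`contig_id` + one column per sample).
#' @param metadata_path path to the metadata TSV with columns
#'   `sample_id`, `genotype`, `treatment`, `replicate`.
#' @return An [expression_set()].
#' @export
read_expression_table <- function(path, metadata_path) {
  meta <- read_metadata_table(metadata_path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(tab) < 1) stop("expression table is empty: ", path)
  contig_ids <- as.character(tab[[1]])
  if (anyDuplicated(contig_ids)) {
    stop("duplicate contig id(s) in ", path, ": ",
         paste(unique(contig_ids[duplicated(contig_ids)]), collapse = ", "))
  }
  missing_samples <- setdiff(names(tab)[-1], meta$sample_id)
  if (length(missing_samples)) {
    stop("sample(s) absent from metadata: ", paste(missing_samples, collapse = ", "))
  }
  unseen <- setdiff(meta$sample_id, names(tab)[-1])
  if (length(unseen)) {
    stop("metadata sample(s) absent from expression table: ",
         paste(unseen, collapse = ", "))
  }
  values <- as.matrix(tab[, meta$sample_id, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- contig_ids
  expression_set(values, meta)
}

read_metadata_table <- function(path) {
  meta <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("sample_id", "genotype", "treatment", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata ", path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta[, required]
}

#' Write an expression set to the package's TSV dialect
#'
#' Writes `expression.tsv` (contig id + one column per sample) and
#' `metadata.tsv` next to each other; a read of the pair round-trips the
#' object bit-identically (values are serialised with full precision).
#'
#' @param x an [expression_set()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_expression_table <- function(x, dir) {
  stopifnot(inherits(x, "expression_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  df <- data.frame(contig_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = expr_path, metadata = meta_path))
}

#' Read a contig annotation table
#'
#' Tab-separated with columns `contig_id`, `description`, `agi_code` and
#' `terms` (category terms separated by `;`). Contigs absent from the table
#' are treated as unannotated by every consumer, never dropped.
#'
#' @param path path to the annotation TSV.
#' @return data frame with columns `contig_id`, `description`, `agi_code`,
#'   `terms` (`;`-joined character).
#' @export
read_annotation_table <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  required <- c("contig_id", "description")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols)) {
    stop("annotation ", path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ann$contig_id)) {
    stop("duplicate contig id(s) in annotation: ",
         paste(unique(ann$contig_id[duplicated(ann$contig_id)]), collapse = ", "))
  }
  if (is.null(ann$agi_code)) ann$agi_code <- NA_character_
  if (is.null(ann$terms)) ann$terms <- NA_character_
  ann[, c("contig_id", "description", "agi_code", "terms")]
}

annotation_terms <- function(annotation) {
  # contig_id -> character vector of category terms
  terms <- strsplit(ifelse(is.na(annotation$terms), "", annotation$terms), ";", fixed = TRUE)
  terms <- lapply(terms, function(t) unique(t[nzchar(t)]))
  names(terms) <- annotation$contig_id
  terms
}

#' Summarise replicate FPKM per contig and condition
#'
#' Computes, for every contig and every observed (genotype, treatment) cell,
#' the arithmetic mean, the sample standard deviation (n - 1 denominator,
#' zero when a cell holds a single replicate) and the replicate count. These
#' condition-level means are the quantities all hypothesis filters operate on.
#'
#' @param x an [expression_set()].
#' @return data frame with columns `contig_id`, `genotype`, `treatment`,
#'   `mean_fpkm`, `sd_fpkm`, `n`.
#' @export
condition_summary <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  cells <- unique(x$samples[, c("genotype", "treatment")])
  cells <- cells[order(match(cells$genotype, GENOTYPES),
                       match(cells$treatment, TREATMENTS)), , drop = FALSE]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    idx <- x$samples$genotype == cells$genotype[i] &
           x$samples$treatment == cells$treatment[i]
    sub <- x$values[, idx, drop = FALSE]
    n <- ncol(sub)
    n_contig <- nrow(x$values)
    out[[i]] <- data.frame(
      contig_id = if (n_contig) rownames(x$values) else character(0),
      genotype  = rep(cells$genotype[i], n_contig),
      treatment = rep(cells$treatment[i], n_contig),
      mean_fpkm = rowMeans(sub),
      sd_fpkm   = if (n > 1) apply(sub, 1, sd) else rep(0, n_contig),
      n         = rep(n, n_contig),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$contig_id, rownames(x$values)),
                   match(res$genotype, GENOTYPES),
                   match(res$treatment, TREATMENTS)), ]
  rownames(res) <- NULL
  res
}

# contigs x condition matrix of means, columns "L.control", "L.cadmium", ...
summary_matrix <- function(summaries) {
  key <- paste(summaries$genotype, summaries$treatment, sep = ".")
  contigs <- unique(summaries$contig_id)
  cols <- paste(rep(GENOTYPES, each = 2), TREATMENTS, sep = ".")
  cols <- intersect(cols, unique(key))
  m <- matrix(NA_real_, length(contigs), length(cols),
              dimnames = list(contigs, cols))
  m[cbind(match(summaries$contig_id, contigs), match(key, cols))] <- summaries$mean_fpkm
  m
}

condition_means <- function(x) summary_matrix(condition_summary(x))

# replicate columns of one genotype/treatment cell
cell_values <- function(x, genotype, treatment, contig = NULL) {
  genotype <- match.arg(genotype, GENOTYPES)
  treatment <- match.arg(treatment, TREATMENTS)
  idx <- x$samples$genotype == genotype & x$samples$treatment == treatment
  if (!any(idx)) stop("no samples for condition ", genotype, "/", treatment)
  v <- x$values[, idx, drop = FALSE]
  if (!is.null(contig)) v <- v[contig, , drop = FALSE]
  v
}
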