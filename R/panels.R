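PANELS <- c("exclusive_L", "exclusive_H", "nas", "naat_dmas")

#' Bundled worked-example gene panels
#'
#' Condition-level FPKM values (one value per genotype/treatment cell) for
#' four curated gene panels from the durum wheat NIL cadmium experiment this
#' package models: the five contigs constitutively expressed only in the
#' low-Cd line, the nine expressed only in the high-Cd line, the 22
#' nicotianamine-synthase contigs induced in both lines but far more
#' strongly in L, and the five NAAT/DMAS contigs of the mugineic-acid
#' pathway. The induction panels also carry the published per-genotype fold
#' changes (`fc_L`, `fc_H`), which derive from unrounded FPKM and therefore
#' differ slightly from ratios of the printed means.
#'
#' @param name one of `"exclusive_L"`, `"exclusive_H"`, `"nas"`,
#'   `"naat_dmas"`.
#' @return data frame with columns `contig_id`, `L_ctrl`, `L_cd`
#'   (+ `fc_L`), `H_ctrl`, `H_cd` (+ `fc_H`), `annotation`.
#' @examples
#' nas <- example_panel("nas")
#' round(mean(nas$fc_L), 1)  # 161.5
#' @export
example_panel <- function(name) {
  name <- match.arg(name, PANELS)
  path <- system.file("extdata", paste0(name, "_panel.tsv"), package = "nilcontrast",
                      mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Expression set built from condition-level panel values
#'
#' Assembles one or more panels into an [expression_set()] with a single
#' sample per genotype/treatment cell (the panels publish condition-level
#' values, read here as condition means). Suitable for the filters that
#' operate on condition means; replicate-based stages (Welch tests, QC)
#' need replicate-level input.
#'
#' @param names panels to stack (default: both genotype-exclusive panels).
#' @return an [expression_set()] with 4 columns.
#' @export
panel_expression_set <- function(names = c("exclusive_L", "exclusive_H")) {
  tabs <- lapply(names, example_panel)
  tab <- do.call(rbind, lapply(tabs, function(t) {
    t[, c("contig_id", "L_ctrl", "L_cd", "H_ctrl", "H_cd")]
  }))
  values <- as.matrix(tab[, -1])
  rownames(values) <- tab$contig_id
  colnames(values) <- c("L_ctrl", "L_cd", "H_ctrl", "H_cd")
  samples <- data.frame(
    sample_id = colnames(values),
    genotype  = c("L", "L", "H", "H"),
    treatment = c("control", "cadmium", "control", "cadmium"),
    replicate = 1L, stringsAsFactors = FALSE)
  expression_set(values, samples)
}

# published fold changes of an induction panel as named vectors
panel_fold_changes <- function(panel) {
  list(fc_L = setNames(panel$fc_L, panel$contig_id),
       fc_H = setNames(panel$fc_H, panel$contig_id))
}
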