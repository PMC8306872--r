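#' Construct a named contrast set
#'
#' A contrast set is the result of one hypothesis filter: a contig set plus
#' the exact parameters that produced it and a human-readable provenance
#' line. Members are kept sorted for stable output.
#'
#' @param id short identifier (e.g. `"H1"`, `"only_L_up"`).
#' @param members character vector of contig ids.
#' @param parameters named list of the thresholds used, recorded verbatim.
#' @param provenance one-line description of the filter.
#' @return list of class `contrast_set`.
#' @export
contrast_set <- function(id, members, parameters = list(), provenance = "") {
  structure(list(id = id, members = sort(unique(as.character(members))),
                 parameters = parameters, provenance = provenance),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("<contrast_set ", x$id, "> ", length(x$members), " contigs\n", sep = "")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  if (length(x$parameters)) {
    cat("  parameters: ",
        paste(names(x$parameters), unlist(lapply(x$parameters, paste, collapse = "/")),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.contrast_set <- function(x) length(x$members)

#' Genotype-exclusive constitutive expression filter (hypotheses 1 and 2)
#'
#' Retains contigs constitutively expressed in one genotype but silent in the
#' other: condition mean strictly above `high` FPKM in BOTH conditions
#' (control and cadmium) of `on_genotype`, and strictly below `low` FPKM in
#' both conditions of the other genotype. `on_genotype = "L"` is the search
#' for genes that could retain cadmium in the low-accumulating line (e.g. an
#' HMT1-like transporter); `"H"` mirrors it.
#'
#' @param summaries condition summary from [condition_summary()].
#' @param on_genotype `"L"` or `"H"`.
#' @param high constitutive-expression threshold, strict (default 25 FPKM).
#' @param low silence threshold for the other genotype, strict (default 5).
#' @return a [contrast_set()] (`H1` for L, `H2` for H).
#' @export
exclusive_set <- function(summaries, on_genotype, high = 25, low = 5) {
  on_genotype <- match.arg(on_genotype, GENOTYPES)
  if (high <= low) stop("high threshold must exceed low threshold")
  other <- setdiff(GENOTYPES, on_genotype)
  m <- summary_matrix(summaries)
  if (nrow(m) == 0) {
    return(contrast_set(if (on_genotype == "L") "H1" else "H2", character(0),
                        list(on_genotype = on_genotype, high = high, low = low),
                        "empty input"))
  }
  need <- paste(rep(GENOTYPES, each = 2), TREATMENTS, sep = ".")
  if (!all(need %in% colnames(m))) {
    stop("summaries must cover both genotypes and both treatments")
  }
  on_cols <- paste(on_genotype, TREATMENTS, sep = ".")
  off_cols <- paste(other, TREATMENTS, sep = ".")
  keep <- rowSums(m[, on_cols, drop = FALSE] > high) == 2 &
          rowSums(m[, off_cols, drop = FALSE] < low) == 2
  contrast_set(
    id = if (on_genotype == "L") "H1" else "H2",
    members = rownames(m)[keep],
    parameters = list(on_genotype = on_genotype, high = high, low = low),
    provenance = sprintf("constitutive in %s (> %g FPKM both conditions), silent in %s (< %g FPKM both conditions)",
                         on_genotype, high, other, low)
  )
}

#' Baseline-biased expression filter (hypotheses 3 and 4)
#'
#' Contigs more expressed in the control samples of one genotype than the
#' other: the favored genotype's control mean must reach `fold` times the
#' background expression level, and the contig must be called differentially
#' expressed between the two genotypes' control groups in the favored
#' direction (the Welch/BH/fold-change/abundance flag of
#' [call_differential()]).
#'
#' @param x an [expression_set()] with >= 2 control replicates per genotype.
#' @param favored_genotype `"L"` (H3) or `"H"` (H4).
#' @param background background expression level in FPKM (> 0, default 5).
#' @param fold multiple of background required (default 5, i.e. 25 FPKM).
#' @param ... DEG parameters passed to [call_differential()].
#' @return a [contrast_set()] with the per-contig DEG table attached as
#'   attribute `differential`.
#' @export
baseline_biased_set <- function(x, favored_genotype, background = 5, fold = 5, ...) {
  favored_genotype <- match.arg(favored_genotype, GENOTYPES)
  if (background <= 0) stop("background must be > 0")
  other <- setdiff(GENOTYPES, favored_genotype)
  de <- call_differential(x, ref = c(other, "control"),
                          alt = c(favored_genotype, "control"), ...)
  strong <- de$group_b_mean >= fold * background
  keep <- strong & de$is_deg & de$direction == "up"
  out <- contrast_set(
    id = if (favored_genotype == "L") "H3" else "H4",
    members = de$contig_id[keep],
    parameters = c(list(favored_genotype = favored_genotype,
                        background = background, fold = fold),
                   attr(de, "parameters")),
    provenance = sprintf("control-sample bias toward %s: mean >= %g x background and DEG vs %s control",
                         favored_genotype, fold, other)
  )
  attr(out, "differential") <- de
  out
}

#' Per-genotype cadmium response sets (hypotheses 5 and 6 primitive)
#'
#' Calls the cadmium-treated versus control contrast within one genotype and
#' partitions its DEGs by direction.
#'
#' @param x an [expression_set()].
#' @param genotype `"L"` or `"H"`.
#' @param ... DEG parameters passed to [call_differential()].
#' @return list with [contrast_set()]s `up` and `down` and the full
#'   `differential` table.
#' @export
response_sets <- function(x, genotype, ...) {
  genotype <- match.arg(genotype, GENOTYPES)
  de <- call_differential(x, ref = c(genotype, "control"),
                          alt = c(genotype, "cadmium"), ...)
  pars <- c(list(genotype = genotype), attr(de, "parameters"))
  list(
    up = contrast_set(paste0("up_", genotype),
                      de$contig_id[de$direction == "up"], pars,
                      sprintf("upregulated by cadmium in %s", genotype)),
    down = contrast_set(paste0("down_", genotype),
                        de$contig_id[de$direction == "down"], pars,
                        sprintf("downregulated by cadmium in %s", genotype)),
    differential = de
  )
}

#' Genotype-specific response sets (hypotheses 5 and 6)
#'
#' Set differences of the per-genotype response sets: contigs regulated by
#' cadmium in exactly one genotype.
#'
#' @param up_L,up_H,down_L,down_H [contrast_set()]s from [response_sets()]
#'   on the same dataset.
#' @return list of four [contrast_set()]s: `only_L_up`, `only_H_up`,
#'   `only_L_down`, `only_H_down`.
#' @export
specific_response_sets <- function(up_L, up_H, down_L, down_H) {
  mk <- function(id, a, b, what) {
    contrast_set(id, setdiff(a$members, b$members),
                 list(minuend = a$id, subtrahend = b$id),
                 sprintf("%s by cadmium only in %s", what,
                         if (grepl("L", id)) "L" else "H"))
  }
  list(only_L_up   = mk("only_L_up", up_L, up_H, "upregulated"),
       only_H_up   = mk("only_H_up", up_H, up_L, "upregulated"),
       only_L_down = mk("only_L_down", down_L, down_H, "downregulated"),
       only_H_down = mk("only_H_down", down_H, down_L, "downregulated"))
}

#' Shared response sets (hypothesis 7)
#'
#' Intersections of the per-genotype response sets: contigs commonly up- or
#' downregulated by cadmium in both genotypes.
#'
#' @inheritParams specific_response_sets
#' @return list of two [contrast_set()]s: `shared_up`, `shared_down`.
#' @export
shared_response_sets <- function(up_L, up_H, down_L, down_H) {
  list(
    shared_up = contrast_set("shared_up", intersect(up_L$members, up_H$members),
                             list(a = up_L$id, b = up_H$id),
                             "upregulated by cadmium in both genotypes"),
    shared_down = contrast_set("shared_down", intersect(down_L$members, down_H$members),
                               list(a = down_L$id, b = down_H$id),
                               "downregulated by cadmium in both genotypes")
  )
}

#' Strongly asymmetric induction subset (hypothesis 7 refinement)
#'
#' Among commonly regulated contigs, retains those whose fold change in L
#' exceeds the fold change in H by at least `ratio_threshold` — the
#' operational reading of "strongly upregulated only in the L-Cd NIL"
#' (the published NAS panel shows roughly 160-fold induction in L against
#' nine-fold in H).
#'
#' @param shared a [contrast_set()] (typically `shared_up`).
#' @param fc_L,fc_H named numeric vectors of per-genotype fold changes
#'   covering every member.
#' @param ratio_threshold minimum fc_L / fc_H ratio (> 1, default 10).
#' @return a [contrast_set()].
#' @export
strong_subset <- function(shared, fc_L, fc_H, ratio_threshold = 10) {
  stopifnot(inherits(shared, "contrast_set"))
  if (ratio_threshold <= 1) stop("ratio_threshold must be > 1")
  missing_fc <- setdiff(shared$members, intersect(names(fc_L), names(fc_H)))
  if (length(missing_fc)) {
    stop("fold changes missing for member(s): ", paste(missing_fc, collapse = ", "))
  }
  ratio <- fc_L[shared$members] / fc_H[shared$members]
  contrast_set(paste0(shared$id, "_strongL"),
               shared$members[ratio >= ratio_threshold],
               c(shared$parameters, list(ratio_threshold = ratio_threshold)),
               sprintf("members of %s with fc_L/fc_H >= %g", shared$id, ratio_threshold))
}

#' Column-mean profile of a contig set
#'
#' Arithmetic means, over the set members, of the four condition means and
#' the two per-genotype fold changes — the summary printed under a gene
#' panel. Values are kept at full precision; round only at report time.
#'
#' @param members character vector of contig ids (or a [contrast_set()]).
#' @param summaries condition summary covering every member.
#' @param fc_L,fc_H named per-genotype fold-change vectors covering every
#'   member.
#' @return one-row data frame: `n`, `mean_ctrl_L`, `mean_cd_L`, `mean_fc_L`,
#'   `mean_ctrl_H`, `mean_cd_H`, `mean_fc_H`.
#' @export
subset_profile <- function(members, summaries, fc_L, fc_H) {
  if (inherits(members, "contrast_set")) members <- members$members
  members <- as.character(members)
  m <- summary_matrix(summaries)
  miss <- union(setdiff(members, rownames(m)),
                setdiff(members, intersect(names(fc_L), names(fc_H))))
  if (length(miss)) stop("member(s) missing data: ", paste(miss, collapse = ", "))
  sub <- m[members, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- members[apply(sub, 1, anyNA)]
    stop("member(s) missing condition means: ", paste(bad, collapse = ", "))
  }
  data.frame(
    n = length(members),
    mean_ctrl_L = mean(sub[, "L.control"]),
    mean_cd_L   = mean(sub[, "L.cadmium"]),
    mean_fc_L   = mean(fc_L[members]),
    mean_ctrl_H = mean(sub[, "H.control"]),
    mean_cd_H   = mean(sub[, "H.cadmium"]),
    mean_fc_H   = mean(fc_H[members]),
    row.names = NULL
  )
}

#' Annotation-matched shared regulators (hypothesis 8 surface)
#'
#' The sequence-level comparison of shared regulators is out of scope for an
#' FPKM pipeline; its testable surface is the list of commonly upregulated
#' contigs whose annotation matches a user-supplied term list (e.g. `"bHLH"`
#' for the basic helix-loop-helix transcription factors).
#'
#' @param shared_up a [contrast_set()] of commonly upregulated contigs.
#' @param annotation annotation table from [read_annotation_table()].
#' @param patterns character patterns matched (fixed, case-insensitive)
#'   against description and category terms (default `"bHLH"`).
#' @return a [contrast_set()] with id `H8`.
#' @export
matched_regulator_set <- function(shared_up, annotation, patterns = "bHLH") {
  stopifnot(inherits(shared_up, "contrast_set"))
  idx <- match(shared_up$members, annotation$contig_id)
  text <- paste(ifelse(is.na(idx), "", annotation$description[idx]),
                ifelse(is.na(idx), "", ifelse(is.na(annotation$terms[idx]), "",
                                              annotation$terms[idx])))
  hit <- Reduce(`|`, lapply(patterns, function(p) {
    grepl(p, text, ignore.case = TRUE, fixed = FALSE)
  }), rep(FALSE, length(text)))
  contrast_set("H8", shared_up$members[hit],
               list(patterns = patterns, source = shared_up$id),
               sprintf("members of %s annotated as: %s", shared_up$id,
                       paste(patterns, collapse = ", ")))
}

#' Write a contrast set as TSV
#'
#' One contig per line, preceded by `#`-prefixed header lines echoing the
#' filter parameters.
#'
#' @param set a [contrast_set()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_contrast_set <- function(set, path) {
  stopifnot(inherits(set, "contrast_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contrast_set: %s", set$id), con)
  if (nzchar(set$provenance)) writeLines(sprintf("# %s", set$provenance), con)
  for (nm in names(set$parameters)) {
    writeLines(sprintf("# parameter %s = %s", nm,
                       paste(set$parameters[[nm]], collapse = ",")), con)
  }
  writeLines("contig_id", con)
  writeLines(set$members, con)
  invisible(path)
}
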