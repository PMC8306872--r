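#' Default analysis parameters
#'
#' All thresholds of the contrast-filtering analysis with their study
#' defaults: exclusive-expression cuts (`high` 25, `low` 5 FPKM), DEG flags
#' (`q_threshold` 0.001, `fc_threshold` 2, `min_fpkm` 5), expressed-gene
#' filter (`expressed_threshold` 5.0, strict), baseline bias (`background`
#' 5 FPKM, `background_fold` 5), strong-asymmetry ratio (`ratio_threshold`
#' 10), reference-gene screen (`cv_min_mean` 25, `cv_top_k` 3), enrichment
#' (`enrichment_alpha` 0.05), annotation patterns for the shared-regulator
#' set (`h8_patterns` `"bHLH"`), fold-change floor (`fc_floor` 0.01) and the
#' log2(FPKM + 1) test transform (`log_transform`).
#'
#' @param ... overrides for any of the defaults.
#' @return named list of parameters.
#' @export
contrast_params <- function(...) {
  defaults <- list(
    high = 25, low = 5,
    q_threshold = 0.001, fc_threshold = 2, min_fpkm = 5,
    min_fpkm_scope = "condition",
    expressed_threshold = 5.0,
    background = 5, background_fold = 5,
    ratio_threshold = 10,
    cv_min_mean = 25, cv_top_k = 3,
    enrichment_alpha = 0.05,
    h8_patterns = "bHLH",
    fc_floor = 0.01, log_transform = TRUE
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  defaults
}

#' Run the full NIL contrast-filtering analysis
#'
#' The package's central fitting-style function: takes a replicate-level
#' FPKM [expression_set()] and returns every stage of the analysis as one
#' classed object — condition summaries, the expressed-gene universe, the
#' eight hypothesis contrast sets, per-contrast differential tables,
#' replicate-correlation QC, column/row clustering, reference-gene
#' candidates and (with an annotation table) per-set category
#' over-representation.
#'
#' Stages that require biological replicates (Welch-test DEG calling and so
#' hypotheses 3–8, and replicate QC) are only run when every
#' genotype/treatment cell has at least two replicates; on condition-level
#' input (one sample per cell) the object still carries the
#' genotype-exclusive sets (H1/H2), the expressed universe, clustering and
#' reference ranking.
#'
#' @param x an [expression_set()].
#' @param annotation optional annotation table ([read_annotation_table()]).
#' @param params analysis parameters from [contrast_params()].
#' @return An object of class `nil_contrast`; see [summary.nil_contrast()].
#' @examples
#' sim <- generate_dataset(generator_config(seed = 1))
#' fit <- nil_contrast(sim$expression)
#' summary(fit)$set_sizes
#' @export
nil_contrast <- function(x, annotation = NULL, params = contrast_params()) {
  stopifnot(inherits(x, "expression_set"))
  p <- params
  summaries <- condition_summary(x)
  expressed <- expressed_contigs(x, threshold = p$expressed_threshold)

  cm <- summary_matrix(summaries)
  fc_L <- setNames(fold_change(cm[, "L.control"], cm[, "L.cadmium"], p$fc_floor),
                   rownames(cm))
  fc_H <- setNames(fold_change(cm[, "H.control"], cm[, "H.cadmium"], p$fc_floor),
                   rownames(cm))

  sets <- list(
    H1 = exclusive_set(summaries, "L", high = p$high, low = p$low),
    H2 = exclusive_set(summaries, "H", high = p$high, low = p$low)
  )
  differential <- list()
  qc <- NULL

  reps <- table(x$samples$genotype, x$samples$treatment)
  has_replicates <- all(reps >= 2)
  if (has_replicates) {
    qc <- replicate_correlation(x)
    deg_args <- list(q_threshold = p$q_threshold, fc_threshold = p$fc_threshold,
                     min_fpkm = p$min_fpkm, min_fpkm_scope = p$min_fpkm_scope,
                     fc_floor = p$fc_floor, log_transform = p$log_transform)

    h3 <- do.call(baseline_biased_set,
                  c(list(x, "L", background = p$background, fold = p$background_fold),
                    deg_args))
    h4 <- do.call(baseline_biased_set,
                  c(list(x, "H", background = p$background, fold = p$background_fold),
                    deg_args))
    resp_L <- do.call(response_sets, c(list(x, "L"), deg_args))
    resp_H <- do.call(response_sets, c(list(x, "H"), deg_args))
    specific <- specific_response_sets(resp_L$up, resp_H$up, resp_L$down, resp_H$down)
    shared <- shared_response_sets(resp_L$up, resp_H$up, resp_L$down, resp_H$down)
    strong <- strong_subset(shared$shared_up, fc_L, fc_H,
                            ratio_threshold = p$ratio_threshold)

    sets <- c(sets, list(H3 = h3, H4 = h4),
              setNames(list(resp_L$up, resp_L$down, resp_H$up, resp_H$down),
                       c("up_L", "down_L", "up_H", "down_H")),
              specific, shared, list(shared_up_strongL = strong))
    if (!is.null(annotation)) {
      sets$H8 <- matched_regulator_set(shared$shared_up, annotation,
                                       patterns = p$h8_patterns)
    }
    differential <- list(
      ctrl_H_vs_L = attr(h3, "differential"),
      ctrl_L_vs_H = attr(h4, "differential"),
      cadmium_vs_ctrl_L = resp_L$differential,
      cadmium_vs_ctrl_H = resp_H$differential
    )
  }

  reference <- rank_reference_candidates(x, min_mean = p$cv_min_mean,
                                         top_k = p$cv_top_k)
  any_varying <- nrow(x$values) > 0 && any(apply(x$values, 1, sd) > 0)
  clustering <- if (ncol(x$values) >= 2 && any_varying) cluster_heatmap(x) else NULL

  enrichment <- list()
  if (!is.null(annotation)) {
    for (id in names(sets)) {
      q <- intersect(sets[[id]]$members, expressed)
      if (length(q)) {
        enrichment[[id]] <- over_representation(q, annotation, expressed,
                                                alpha = p$enrichment_alpha)
      }
    }
  }

  profiles <- list()
  for (id in intersect(c("shared_up", "shared_up_strongL"), names(sets))) {
    if (length(sets[[id]]$members)) {
      profiles[[id]] <- subset_profile(sets[[id]], summaries, fc_L, fc_H)
    }
  }

  structure(list(
    expression = x, annotation = annotation, params = p,
    summaries = summaries, expressed = expressed,
    fold_changes = list(L = fc_L, H = fc_H),
    sets = sets, differential = differential, profiles = profiles,
    qc = qc, clustering = clustering, reference = reference,
    enrichment = enrichment, has_replicates = has_replicates
  ), class = "nil_contrast")
}

#' Summarise a contrast-filtering analysis
#'
#' @param object a `nil_contrast` object.
#' @param ... unused.
#' @return list of class `summary.nil_contrast`: `n_contigs`, `n_samples`,
#'   `expressed_count`, `set_sizes` (named integer vector), `deg_counts`
#'   (DEGs per contrast), `reference` (top candidates), `qc_range`
#'   (min/max replicate r, when computed).
#' @export
summary.nil_contrast <- function(object, ...) {
  out <- list(
    n_contigs = nrow(object$expression$values),
    n_samples = ncol(object$expression$values),
    expressed_count = length(object$expressed),
    set_sizes = vapply(object$sets, function(s) length(s$members), integer(1)),
    deg_counts = vapply(object$differential, function(d) sum(d$is_deg), integer(1)),
    reference = object$reference,
    qc_range = if (!is.null(object$qc)) c(min_r = object$qc$min_r,
                                          max_r = object$qc$max_r)
  )
  class(out) <- "summary.nil_contrast"
  out
}

#' @export
print.summary.nil_contrast <- function(x, ...) {
  cat("NIL contrast-filtering analysis\n")
  cat(sprintf("  %d contigs x %d samples; %d expressed (condition mean > threshold)\n",
              x$n_contigs, x$n_samples, x$expressed_count))
  if (!is.null(x$qc_range)) {
    cat(sprintf("  replicate Pearson r: %.3f - %.3f\n",
                x$qc_range[["min_r"]], x$qc_range[["max_r"]]))
  }
  cat("  contrast sets:\n")
  for (id in names(x$set_sizes)) {
    cat(sprintf("    %-18s %d\n", id, x$set_sizes[[id]]))
  }
  if (length(x$deg_counts)) {
    cat("  DEG counts per contrast:\n")
    for (id in names(x$deg_counts)) {
      cat(sprintf("    %-18s %d\n", id, x$deg_counts[[id]]))
    }
  }
  if (nrow(x$reference)) {
    cat("  reference-gene candidates:\n")
    for (i in seq_len(nrow(x$reference))) {
      cat(sprintf("    %d. %s (CV = %.3f)\n", x$reference$rank[i],
                  x$reference$contig_id[i], x$reference$cv[i]))
    }
  }
  invisible(x)
}

#' @export
print.nil_contrast <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
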