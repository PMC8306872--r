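#' Fold change between two condition means with a floored denominator
#'
#' `mean_alt / max(mean_ref, floor)`. The floor keeps fold changes finite for
#' silent reference conditions (condition tables legitimately contain 0.0
#' FPKM entries).
#'
#' @param mean_ref,mean_alt non-negative condition mean FPKM (vectorised).
#' @param floor denominator floor in FPKM (> 0, default 0.01).
#' @return positive fold change(s), alt over ref.
#' @examples
#' fold_change(10, 40)       # 4
#' fold_change(0, 50)        # 5000 via the floor
#' @export
fold_change <- function(mean_ref, mean_alt, floor = 0.01) {
  if (any(!is.finite(mean_ref)) || any(mean_ref < 0) ||
      any(!is.finite(mean_alt)) || any(mean_alt < 0)) {
    stop("condition means must be finite and non-negative")
  }
  if (!is.finite(floor) || floor <= 0) stop("floor must be > 0")
  mean_alt / pmax(mean_ref, floor)
}

#' Welch two-sample t-test for one contig
#'
#' Unequal-variance t-test with the Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. The t statistic is signed as mean(b) - mean(a).
#' Callers test log2(FPKM + 1)-transformed replicate values. When both groups
#' have zero variance: equal means give t = 0, p = 1 (no evidence of a
#' difference, by convention); unequal means give t = +-Inf, p = 0.
#'
#' @param group_a,group_b numeric vectors of replicate values (each >= 2).
#' @return list with `t_stat`, `df`, `p_value`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))  # |t| ~ 3.674, df = 4
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 replicate values")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    d <- mean(group_b) - mean(group_a)
    if (d == 0) return(list(t_stat = 0, df = length(group_a) + length(group_b) - 2,
                            p_value = 1))
    return(list(t_stat = sign(d) * Inf,
                df = length(group_a) + length(group_b) - 2, p_value = 0))
  }
  fit <- stats::t.test(group_b, group_a, var.equal = FALSE)
  list(t_stat = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns BH q-values in the input order; q is monotone in p and lies in
#' [0, 1].
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differential expression between two conditions
#'
#' For every contig: fold change of condition means ([fold_change()]), Welch
#' t-test on log2(FPKM + 1) replicate values (raw scale via
#' `log_transform = FALSE`), BH adjustment across all contigs of this
#' contrast, and the compound DEG flag: `q < q_threshold`, at least
#' `fc_threshold`-fold change in either direction, and a condition mean
#' (or, with `min_fpkm_scope = "sample"`, a single sample) of at least
#' `min_fpkm` FPKM. Direction is `up` when FC >= fc_threshold, `down` when
#' FC <= 1/fc_threshold, otherwise `none`.
#'
#' @param x an [expression_set()].
#' @param ref,alt conditions as `c(genotype, treatment)` (e.g.
#'   `c("L", "control")`); the fold change and t sign are alt over/minus ref.
#' @param q_threshold BH q cut (default 0.001).
#' @param fc_threshold fold-change cut, inclusive (default 2).
#' @param min_fpkm abundance cut in FPKM (default 5).
#' @param min_fpkm_scope `"condition"` (default): a condition mean of either
#'   group must reach `min_fpkm`; `"sample"`: any single replicate suffices.
#' @param fc_floor denominator floor for [fold_change()].
#' @param log_transform test log2(FPKM + 1) values (default) or raw FPKM.
#' @return data frame of class `differential_result` with columns
#'   `contig_id`, `group_a_mean`, `group_b_mean`, `fold_change`, `log2_fc`,
#'   `t_stat`, `df`, `p_value`, `q_value`, `is_deg`, `direction`.
#' @export
call_differential <- function(x, ref, alt, q_threshold = 0.001, fc_threshold = 2,
                              min_fpkm = 5, min_fpkm_scope = c("condition", "sample"),
                              fc_floor = 0.01, log_transform = TRUE) {
  stopifnot(inherits(x, "expression_set"))
  min_fpkm_scope <- match.arg(min_fpkm_scope)
  ref <- as.character(ref); alt <- as.character(alt)
  va <- cell_values(x, ref[1], ref[2])
  vb <- cell_values(x, alt[1], alt[2])
  if (ncol(va) < 2 || ncol(vb) < 2) {
    stop("both conditions need at least 2 replicates for the Welch test")
  }
  ta <- if (log_transform) log2(va + 1) else va
  tb <- if (log_transform) log2(vb + 1) else vb

  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  fc <- fold_change(mean_a, mean_b, floor = fc_floor)

  tests <- lapply(seq_len(nrow(x$values)), function(i) welch_t_test(ta[i, ], tb[i, ]))
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  q <- bh_adjust(p)

  abundant <- if (min_fpkm_scope == "condition") {
    pmax(mean_a, mean_b) >= min_fpkm
  } else {
    apply(cbind(va, vb), 1, max) >= min_fpkm
  }
  two_fold <- pmax(fc, 1 / fc) >= fc_threshold
  is_deg <- q < q_threshold & two_fold & abundant
  direction <- ifelse(!is_deg, "none",
                      ifelse(fc >= fc_threshold, "up",
                             ifelse(fc <= 1 / fc_threshold, "down", "none")))

  res <- data.frame(
    contig_id = rownames(x$values),
    group_a_mean = mean_a, group_b_mean = mean_b,
    fold_change = fc, log2_fc = log2(fc),
    t_stat = vapply(tests, `[[`, numeric(1), "t_stat"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p_value = p, q_value = q,
    is_deg = is_deg, direction = direction,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- list(ref = ref, alt = alt)
  attr(res, "parameters") <- list(q_threshold = q_threshold,
                                  fc_threshold = fc_threshold,
                                  min_fpkm = min_fpkm,
                                  min_fpkm_scope = min_fpkm_scope,
                                  fc_floor = fc_floor,
                                  log_transform = log_transform)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Contigs expressed in at least one condition
#'
#' A contig is expressed when its condition mean strictly exceeds `threshold`
#' FPKM in at least one genotype/treatment cell.
#'
#' @param x an [expression_set()].
#' @param threshold FPKM cut, strict (default 5.0).
#' @return character vector of contig ids.
#' @export
expressed_contigs <- function(x, threshold = 5.0) {
  m <- condition_means(x)
  rownames(m)[apply(m, 1, function(v) any(v > threshold, na.rm = TRUE))]
}
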