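#' Coefficient of variation of replicate FPKM values
#'
#' Sample standard deviation (n - 1 denominator) divided by the arithmetic
#' mean. Scale-invariant, so it ranks expression stability independently of
#' abundance.
#'
#' @param values numeric vector of >= 2 FPKM values with positive mean.
#' @return non-negative CV.
#' @examples
#' coefficient_of_variation(c(10, 12, 8, 10))  # 0.1633
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  sd(values) / m
}

#' Rank reference-gene candidates by expression stability
#'
#' Candidates for qRT-PCR normalisation: contigs whose overall mean FPKM
#' across ALL samples (both genotypes, both treatments — a reference gene
#' must be stable everywhere) exceeds `min_mean`, ranked by ascending
#' coefficient of variation. Ties are broken lexicographically by contig id.
#'
#' @param x an [expression_set()].
#' @param min_mean minimum overall mean FPKM, strict (default 25).
#' @param top_k number of candidates returned (default 3); `Inf` for all.
#' @return data frame with columns `contig_id`, `mean_fpkm`, `cv`, `rank`,
#'   sorted by rank; zero rows when nothing passes `min_mean`.
#' @export
rank_reference_candidates <- function(x, min_mean = 25, top_k = 3) {
  stopifnot(inherits(x, "expression_set"))
  means <- rowMeans(x$values)
  keep <- which(means > min_mean)
  if (!length(keep)) {
    return(data.frame(contig_id = character(0), mean_fpkm = numeric(0),
                      cv = numeric(0), rank = integer(0)))
  }
  cv <- apply(x$values[keep, , drop = FALSE], 1, sd) / means[keep]
  ord <- order(cv, rownames(x$values)[keep])
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(contig_id = rownames(x$values)[keep][ord],
             mean_fpkm = unname(means[keep][ord]),
             cv = unname(cv[ord]),
             rank = seq_along(ord),
             row.names = NULL, stringsAsFactors = FALSE)
}
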