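#' Hypergeometric over-representation of annotation categories
#'
#' Generic replacement for a web-service enrichment step: for every category
#' term attached to universe contigs, tests whether the query set overlaps
#' the term more than expected under hypergeometric sampling without
#' replacement. The upper-tail p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` with `N` the universe size, `K` the term
#' size within the universe, `n` the query size and `k` the observed
#' overlap; BH adjustment is applied across all tested terms. Terms absent
#' from the universe (`K = 0`) are skipped; unannotated contigs simply carry
#' no terms and still count toward `N` and `n`.
#'
#' @param query character vector of contig ids, a subset of `universe`.
#' @param annotation annotation table from [read_annotation_table()] (or a
#'   data frame with `contig_id` and `;`-joined `terms`).
#' @param universe character vector of background contig ids (typically
#'   [expressed_contigs()]).
#' @param alpha significance level recorded in the `significant` column
#'   (default 0.05).
#' @return data frame of class `enrichment_result`, sorted by p-value, with
#'   columns `term`, `k`, `K`, `n`, `N`, `p_value`, `q_value`, `significant`.
#' @examples
#' ann <- data.frame(contig_id = paste0("c", 1:20),
#'                   description = "x", agi_code = NA,
#'                   terms = rep(c("transport", ""), 10))
#' over_representation(paste0("c", c(1, 3, 5)), ann, paste0("c", 1:20))
#' @export
over_representation <- function(query, annotation, universe, alpha = 0.05) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query contig(s) outside the universe: ", paste(outside, collapse = ", "))
  }
  terms <- annotation_terms(annotation)
  terms <- terms[intersect(names(terms), universe)]
  term_members <- list()
  for (id in names(terms)) for (t in terms[[id]]) {
    term_members[[t]] <- c(term_members[[t]], id)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(term_members), function(t) {
    K <- length(term_members[[t]])
    k <- length(intersect(term_members[[t]], query))
    data.frame(term = t, k = k, K = K, n = n, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    res <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0))
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$term), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
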