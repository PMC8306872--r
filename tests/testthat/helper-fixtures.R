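# Shared fixture builders and independent oracles. Fixtures are built in code;
# nothing here touches the implementation paths it is used to check.

# expression_set from per-condition replicate lists:
# cells = list(L.control = matrix/vector, L.cadmium = ..., H.control, H.cadmium)
# vectors are one contig; matrices are contigs x replicates
make_expression <- function(cells, contig_ids = NULL) {
  cells <- lapply(cells, function(v) if (is.null(dim(v))) matrix(v, nrow = 1) else v)
  n_contig <- nrow(cells[[1]])
  if (is.null(contig_ids)) {
    contig_ids <- if (n_contig) paste0("c", seq_len(n_contig)) else character(0)
  }
  samples <- do.call(rbind, lapply(names(cells), function(key) {
    gt <- strsplit(key, ".", fixed = TRUE)[[1]]
    k <- ncol(cells[[key]])
    data.frame(sample_id = paste0(gsub("\\.", "_", key), "_r", seq_len(k)),
               genotype = gt[1], treatment = gt[2], replicate = seq_len(k),
               stringsAsFactors = FALSE)
  }))
  values <- do.call(cbind, cells)
  if (length(contig_ids)) rownames(values) <- contig_ids
  colnames(values) <- samples$sample_id
  expression_set(values, samples)
}

# four-cell design with k replicates per cell from a contigs x 4 base-mean
# matrix (columns L.control, L.cadmium, H.control, H.cadmium), exact values
make_flat_expression <- function(base, k = 3, contig_ids = NULL) {
  cells <- list(
    L.control = matrix(base[, 1], nrow(base), k),
    L.cadmium = matrix(base[, 2], nrow(base), k),
    H.control = matrix(base[, 3], nrow(base), k),
    H.cadmium = matrix(base[, 4], nrow(base), k)
  )
  make_expression(cells, contig_ids = contig_ids)
}

# the low-noise desk-scale condition used for exact truth recovery
recovery_config <- function(seed) {
  generator_config(blocks = default_blocks(n_null = 200),
                   noise_sigma = 0.01, seed = seed)
}

# --- independent oracles -----------------------------------------------------

# BH step-up from its definition: q_i = min over thresholds t >= p_i of
# m * t / #{p <= t}, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(m * ts / vapply(ts, function(t) sum(p <= t), numeric(1))))
  }, numeric(1))
}

# hypergeometric upper tail by direct combinatorial summation
hyper_tail_brute <- function(N, K, n, k) {
  if (k > min(K, n)) return(0)
  j <- seq(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# does a k=2 column cut separate control from cadmium samples exactly?
splits_by_treatment <- function(x) {
  cl <- column_clusters(cluster_heatmap(x), k = 2)
  treat <- x$samples$treatment[match(names(cl), x$samples$sample_id)]
  length(unique(cl[treat == "control"])) == 1 &&
    length(unique(cl[treat == "cadmium"])) == 1 &&
    cl[treat == "control"][1] != cl[treat == "cadmium"][1]
}
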