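# Pre-ranked gene-set enrichment analysis: weighted Kolmogorov-Smirnov
# running-sum enrichment score with a gene-set permutation null.

#' Rank features by a two-condition contrast
#'
#' Metric: `log2((mean CPM_B + 1) / (mean CPM_A + 1))`, sorted descending;
#' ties broken lexicographically by feature id so the order is
#' deterministic.
#'
#' @param cm A `count_matrix`.
#' @param cond_a,cond_b Condition labels (contrast is B vs A).
#' @return Data frame `feature_id`, `metric`, in ranked order.
#' @export
rank_by_contrast <- function(cm, cond_a, cond_b) {
  for (cond in c(cond_a, cond_b))
    if (!cond %in% cm$conditions) stop("condition label not in matrix: ", cond)
  cpm <- compute_cpm(cm)
  m_a <- rowMeans(cpm[, cm$conditions == cond_a, drop = FALSE])
  m_b <- rowMeans(cpm[, cm$conditions == cond_b, drop = FALSE])
  metric <- log2((m_b + 1) / (m_a + 1))
  ord <- order(-metric, rownames(cpm), method = "radix")
  data.frame(feature_id = rownames(cpm)[ord], metric = metric[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted KS enrichment score of a gene set in a ranked list
#'
#' The running sum increments by `|metric|^p / sum_hits |metric|^p` at set
#' members ("hits") and decrements by `1 / (N - N_hits)` elsewhere; the
#' enrichment score is the running-sum value of largest magnitude. With
#' `p_weight = 0` this is the classical Kolmogorov-Smirnov statistic. When
#' every hit metric is zero the hit increments fall back to equal weights.
#'
#' @param ranked Ranked list from [rank_by_contrast()] (or any data frame
#'   with `feature_id`, `metric` in descending-metric order).
#' @param gene_set Character vector of member ids (must intersect the
#'   list).
#' @param p_weight Metric weighting exponent (default 1).
#' @return List of class `gsea_result`: `es`, `running_sum`, `hit_index`,
#'   `leading_edge` (member ids up to / from the extremum).
#' @export
enrichment_score <- function(ranked, gene_set, p_weight = 1) {
  if (anyDuplicated(ranked$feature_id)) stop("duplicate ids in ranked list")
  is_hit <- ranked$feature_id %in% gene_set
  n <- nrow(ranked)
  n_hit <- sum(is_hit)
  if (n_hit == 0) stop("gene set has no overlap with the ranked list")
  w <- abs(ranked$metric)^p_weight
  w[!is_hit] <- 0
  if (sum(w) == 0) w[is_hit] <- 1
  inc <- w / sum(w)
  miss <- n - n_hit
  dec <- if (miss > 0) rep(1 / miss, n) else rep(0, n)
  dec[is_hit] <- 0
  rs <- cumsum(inc - dec)
  peak <- which.max(abs(rs))
  es <- rs[peak]
  le <- if (es >= 0) ranked$feature_id[seq_len(peak)][is_hit[seq_len(peak)]]
  else ranked$feature_id[peak:n][is_hit[peak:n]]
  structure(list(es = es, running_sum = rs, hit_index = which(is_hit),
                 leading_edge = le, set_size = n_hit),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES = %.4f (set size %d)", x$es, x$set_size))
  if (!is.null(x$p_value))
    cat(sprintf(", NES = %.3f, p = %.4g (%d permutations)", x$nes, x$p_value,
                x$n_perm))
  cat("\n")
  invisible(x)
}

#' Gene-set permutation null: nominal p and NES
#'
#' Resamples random sets of the same size from the ranked list's ids
#' (appropriate for pre-ranked mode). The nominal p is
#' `(1 + #{same-sign permutation ES with |ES| >= |ES_obs|}) /
#' (1 + #same-sign permutations)`; NES is `ES / mean |same-sign null ES|`.
#' Reproducible for a fixed seed.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return `gsea_result` augmented with `p_value`, `nes`, `null_es`,
#'   `n_perm`.
#' @export
permutation_null <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                             p_weight = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- enrichment_score(ranked, gene_set, p_weight)
  size <- obs$set_size
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm_set <- sample(ranked$feature_id, size)
    enrichment_score(ranked, perm_set, p_weight)$es
  }, numeric(1)))
  same <- null_es * sign(obs$es) >= 0
  obs$p_value <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + sum(same))
  denom <- mean(abs(null_es[same]))
  obs$nes <- if (sum(same) && denom > 0) obs$es / denom else NA_real_
  obs$null_es <- null_es
  obs$n_perm <- n_perm
  obs
}

#' Pre-ranked GSEA over a collection of gene sets
#'
#' @param cm A `count_matrix`.
#' @param cond_a,cond_b Contrast (B vs A).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]); members
#'   absent from the matrix are dropped.
#' @param n_perm,seed,p_weight See [permutation_null()].
#' @return Data frame `set`, `size`, `es`, `nes`, `p_value`,
#'   `leading_edge` (comma-separated).
#' @export
gsea_preranked <- function(cm, cond_a, cond_b, sets, n_perm = 1000, seed = 1,
                           p_weight = 1) {
  ranked <- rank_by_contrast(cm, cond_a, cond_b)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], ranked$feature_id)
    if (!length(members)) return(NULL)
    res <- permutation_null(ranked, members, n_perm, seed, p_weight)
    data.frame(set = nm, size = res$set_size, es = res$es, nes = res$nes,
               p_value = res$p_value,
               leading_edge = paste(res$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
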