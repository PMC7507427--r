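# TF-lncRNA co-expression: a weighted-correlation (soft-thresholded,
# topological-overlap) module pipeline and plain Pearson edge testing,
# intersected into the final network.

#' Pearson correlation edges between two feature sets
#'
#' Correlates every row of `expr_a` with every row of `expr_b` across
#' shared samples (columns). The p-value is the two-sided closed form from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Zero-variance features are excluded with a warning. Edges are
#' canonically ordered (`a < b` lexicographically) and deduplicated when
#' the two sets overlap.
#'
#' @param expr_a,expr_b Numeric matrices, features x samples, same columns.
#' @param alpha Keep edges with `p < alpha` (default 1 = keep all).
#' @return Data frame `a`, `b`, `r`, `p_value`.
#' @export
pearson_edges <- function(expr_a, expr_b, alpha = 1) {
  stopifnot(ncol(expr_a) == ncol(expr_b))
  n <- ncol(expr_a)
  if (n < 3) stop("need >= 3 shared samples")
  drop_flat <- function(m, lab) {
    v <- apply(m, 1, stats::var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance feature(s) excluded from ", lab)
      m <- m[v > 0, , drop = FALSE]
    }
    m
  }
  expr_a <- drop_flat(expr_a, "expr_a")
  expr_b <- drop_flat(expr_b, "expr_b")
  r <- stats::cor(t(expr_a), t(expr_b))
  df <- data.frame(a = rep(rownames(expr_a), times = ncol(r)),
                   b = rep(rownames(expr_b), each = nrow(r)),
                   r = as.vector(r), stringsAsFactors = FALSE)
  df <- df[df$a != df$b, , drop = FALSE]
  swap <- df$a > df$b
  tmp <- df$a[swap]; df$a[swap] <- df$b[swap]; df$b[swap] <- tmp
  df <- df[!duplicated(paste(df$a, df$b, sep = "\r")), , drop = FALSE]
  r2 <- pmin(df$r^2, 1 - 1e-15)
  t_stat <- df$r * sqrt((n - 2) / (1 - r2))
  df$p_value <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  df <- df[df$p_value < alpha, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta`, diagonal set to 0 (a node is not its own
#' neighbour for connectivity and shared-neighbour sums).
#'
#' @param expr Numeric matrix, features x samples.
#' @param beta Soft-threshold power (>= 1).
#' @return Symmetric adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(expr, beta) {
  stopifnot(beta >= 1)
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with shared
#' neighbourhood `l_ij = sum_u a_iu a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`; the diagonal is defined as 1.
#'
#' @param adj Symmetric adjacency with zero diagonal.
#' @return Symmetric TOM matrix in `[0, 1]`, unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) stop("adjacency not square")
  l <- adj %*% adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Scale-free topology fit of a soft-thresholded network
#'
#' Bins the connectivity distribution `k` into `n_bins` and regresses
#' `log10 p(k)` on `log10 mean(k)` per bin; the fit index is the signed
#' `R^2` (negated when the slope is positive, since scale-free networks
#' require a decreasing degree distribution).
#'
#' @param expr Numeric matrix, features x samples.
#' @param beta Candidate power.
#' @param n_bins Histogram bins (default 10).
#' @return Signed R-squared.
#' @export
scale_free_fit <- function(expr, beta, n_bins = 10) {
  k <- rowSums(adjacency_matrix(expr, beta))
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, brk, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & mk > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Pick the soft-threshold power by the scale-free criterion
#'
#' Returns the smallest candidate power whose signed scale-free fit reaches
#' `r2_min` (default 0.8); if none does, the power with the maximal fit.
#'
#' @param expr Numeric matrix, features x samples (>= 10 features).
#' @param candidate_powers Powers to try (default 1:10, 12, 14, 16).
#' @param r2_min Fit threshold.
#' @return List `beta`, `fit` (data frame of power and signed R^2).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12, 14, 16),
                                r2_min = 0.8) {
  if (nrow(expr) < 10) stop("need >= 10 features to assess scale-free fit")
  stopifnot(length(candidate_powers) > 0)
  r2 <- vapply(candidate_powers, function(b) scale_free_fit(expr, b),
               numeric(1))
  beta <- if (any(r2 >= r2_min)) candidate_powers[which(r2 >= r2_min)[1]]
  else candidate_powers[which.max(r2)]
  list(beta = beta,
       fit = data.frame(power = candidate_powers, r_squared = r2))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`
#' with a static tree cut at `cut_height`; clusters smaller than
#' `min_module_size` become unassigned (`grey`). Module labels are
#' colour-style strings ordered by descending module size. Deterministic
#' for a fixed input.
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size Smallest retained module (default 20).
#' @param cut_height Static cut height on `1 - TOM` (default 0.99 of the
#'   dendrogram's top merge height: absolute TOM dissimilarities depend
#'   strongly on the soft-threshold power, and distinct modules only join
#'   in the dendrogram's final merges, so a cut just below the top retains
#'   whole modules without fusing them).
#' @return Data frame `feature_id`, `module`.
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_height = NULL) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(hc$height)
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple")
  ord <- keep[order(-sizes[keep], as.integer(keep))]
  labels <- stats::setNames(rep("grey", length(sizes)), names(sizes))
  lab_pool <- c(palette, paste0("module", seq_len(max(0, length(ord) -
                                                        length(palette)))))
  labels[ord] <- lab_pool[seq_along(ord)]
  data.frame(feature_id = rownames(tom), module = unname(labels[as.character(cl)]),
             stringsAsFactors = FALSE)
}

#' Filter the TF-lncRNA network by weight and significance
#'
#' Keeps edges with one endpoint in `tf_ids` and the other in `lnc_ids`,
#' network weight above `weight_min` and Pearson p below `p_max`
#' (defaults 0.05 and 0.01).
#'
#' @param edges Edge data frame with `a`, `b`, `p_value`, `weight`.
#' @param tf_ids,lnc_ids Feature id vectors (tf_ids must be nonempty).
#' @param weight_min,p_max Thresholds.
#' @return Filtered edge data frame.
#' @export
build_tf_lnc_network <- function(edges, tf_ids, lnc_ids, weight_min = 0.05,
                                 p_max = 0.01) {
  if (!length(tf_ids)) stop("tf_ids is empty")
  cross <- (edges$a %in% tf_ids & edges$b %in% lnc_ids) |
    (edges$a %in% lnc_ids & edges$b %in% tf_ids)
  out <- edges[cross & edges$weight > weight_min & edges$p_value < p_max, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap between two edge sets
#'
#' @param pairs_a,pairs_b Data frames with canonical `a`, `b` columns.
#' @return List: `fraction` = |A intersect B| / |A|, and Venn counts
#'   `only_a`, `only_b`, `both`.
#' @export
network_overlap <- function(pairs_a, pairs_b) {
  key <- function(df) paste(df$a, df$b, sep = "\r")
  ka <- unique(key(pairs_a)); kb <- unique(key(pairs_b))
  both <- length(intersect(ka, kb))
  list(fraction = if (length(ka)) both / length(ka) else NA_real_,
       only_a = length(ka) - both, only_b = length(kb) - both, both = both)
}

#' Full co-expression network pipeline
#'
#' Expression input is `log2(CPM + 1)` restricted to the supplied feature
#' ids (typically DE lncRNAs plus DE protein-coding genes). Runs soft
#' threshold selection, adjacency, TOM, module detection, Pearson edge
#' testing, and attaches the TOM value of each Pearson edge as its network
#' weight.
#'
#' @param cm A `count_matrix`.
#' @param feature_ids Features to include.
#' @param tf_ids Subset of `feature_ids` that are TFs.
#' @param lnc_ids Subset that are lncRNAs.
#' @param beta Soft power, or `NULL` to pick by scale-free fit.
#' @param min_module_size,cut_height Module-detection parameters.
#' @param weight_min,p_max TF-lncRNA network thresholds.
#' @param weight_type `"tom"` (default) or `"adjacency"` as the exported
#'   edge weight.
#' @param conditions Optional subset of condition labels across which
#'   co-expression is measured (default: all samples).
#' @return List of class `coexpr_network`: `edges` (all Pearson edges with
#'   weights), `tf_lnc_edges` (filtered network), `modules`, `beta`,
#'   `soft_fit`.
#' @export
coexpression_network <- function(cm, feature_ids, tf_ids, lnc_ids,
                                 beta = NULL, min_module_size = 20,
                                 cut_height = NULL, weight_min = 0.05,
                                 p_max = 0.01, weight_type = c("tom",
                                                               "adjacency"),
                                 conditions = NULL) {
  weight_type <- match.arg(weight_type)
  expr <- log2(compute_cpm(cm)[feature_ids, , drop = FALSE] + 1)
  if (!is.null(conditions))
    expr <- expr[, cm$conditions %in% conditions, drop = FALSE]
  expr <- expr[apply(expr, 1, stats::var) > 0, , drop = FALSE]
  soft <- NULL
  if (is.null(beta)) {
    soft <- pick_soft_threshold(expr)
    beta <- soft$beta
  }
  adj <- adjacency_matrix(expr, beta)
  tom <- tom_similarity(adj)
  modules <- detect_modules(tom, min_module_size, cut_height)
  edges <- pearson_edges(expr, expr)
  w <- if (weight_type == "tom") tom else adj
  edges$weight <- w[cbind(match(edges$a, rownames(w)),
                          match(edges$b, rownames(w)))]
  tf_lnc <- build_tf_lnc_network(edges, tf_ids, lnc_ids, weight_min, p_max)
  structure(list(edges = edges, tf_lnc_edges = tf_lnc, modules = modules,
                 beta = beta, soft_fit = soft$fit, tom = tom),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("coexpr_network: beta =", x$beta, "\n")
  cat("  modules:", paste(names(table(x$modules$module)),
                          table(x$modules$module), sep = "=",
                          collapse = ", "), "\n")
  cat("  Pearson edges:", nrow(x$edges),
      "| TF-lncRNA edges passing filter:", nrow(x$tf_lnc_edges), "\n")
  invisible(x)
}
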