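# Differential expression of lncRNAs and protein-coding genes between two
# conditions. The engine is a negative-binomial Wald test on the difference
# of log mean CPM, with a method-of-moments dispersion estimate — a
# deliberately simple, fully specified stand-in for a full NB GLM framework.

#' Counts per million
#'
#' `cpm[f, s] = counts[f, s] / library_size[s] * 1e6` where the library size
#' is the column sum.
#'
#' @param counts Integer matrix, features x samples (or a `count_matrix`).
#' @return Numeric CPM matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Method-of-moments NB dispersion estimate
#'
#' For each feature and each condition with >= 2 replicates, the raw-count
#' moment estimator `(s^2 - xbar) / xbar^2` of the NB dispersion phi
#' (variance = mu + phi mu^2) is computed and pooled across conditions,
#' weighting by residual degrees of freedom; the pooled estimate is clamped
#' at 0, so Poisson data gives phi ~ 0.
#'
#' @param counts Integer matrix, features x samples.
#' @param conditions Condition label per column.
#' @return Numeric vector of per-feature dispersions `phi >= 0`.
#' @export
estimate_dispersion <- function(counts, conditions) {
  if (inherits(counts, "count_matrix")) {
    conditions <- counts$conditions
    counts <- counts$counts
  }
  stopifnot(ncol(counts) == length(conditions))
  reps <- table(conditions)
  usable <- names(reps)[reps >= 2]
  if (!length(usable))
    stop("dispersion estimation needs >= 2 replicates in some condition")
  num <- numeric(nrow(counts))
  den <- 0
  for (cond in usable) {
    sub <- counts[, conditions == cond, drop = FALSE]
    n <- ncol(sub)
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    phi_c <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + phi_c * (n - 1)
    den <- den + (n - 1)
  }
  stats::setNames(pmax(0, num / den), rownames(counts))
}

#' NB Wald test for differential expression between two conditions
#'
#' The log2 fold-change is `log2((mean_cpm_B + c) / (mean_cpm_A + c))` with
#' pseudocount `c` (default 1 CPM), so zero counts give bounded
#' fold-changes. The test statistic is the difference of `log2(mean + c)`
#' divided by its delta-method standard error under the NB variance
#' `mu + phi mu^2`, referred to a t distribution with `n_A + n_B - 2`
#' degrees of freedom (two-sided). A feature is called `up` when
#' `log2fc >= lfc_threshold` and `p < alpha`, `down` when
#' `log2fc <= -lfc_threshold` and `p < alpha`, else `not_de`.
#'
#' @param cm A `count_matrix` (or a bare counts matrix plus `conditions`).
#' @param cond_a,cond_b The two condition labels to contrast (B vs A).
#' @param alpha Significance threshold on the (raw) p-value, default 0.05.
#' @param lfc_threshold Absolute log2 fold-change threshold, default 1.
#' @param pseudocount CPM pseudocount in the fold-change, default 1.
#' @param fdr If TRUE, apply Benjamini-Hochberg correction and threshold the
#'   adjusted p-values instead (off by default: calls use raw p < alpha).
#' @param dispersion_prior_df Strength of the empirical-Bayes squeeze of
#'   per-feature dispersions toward their global mean (prior degrees of
#'   freedom, default 10; 0 disables). Per-feature moment estimates are far
#'   too noisy at typical replicate numbers to plug into a Wald test
#'   directly.
#' @param conditions Condition labels when `cm` is a bare matrix.
#' @return Data frame with columns `feature_id`, `biotype`, `mean_cpm_a`,
#'   `mean_cpm_b`, `log2fc`, `p_value`, `status`.
#' @export
de_test <- function(cm, cond_a, cond_b, alpha = 0.05, lfc_threshold = 1,
                    pseudocount = 1, fdr = FALSE, dispersion_prior_df = 10,
                    conditions = NULL) {
  if (inherits(cm, "count_matrix")) {
    counts <- cm$counts
    conditions <- cm$conditions
    biotype <- unname(cm$biotype)
  } else {
    counts <- cm
    if (is.null(conditions)) stop("conditions required for a bare matrix")
    biotype <- rep(NA_character_, nrow(counts))
  }
  for (cond in c(cond_a, cond_b))
    if (!cond %in% conditions)
      stop("condition label not in matrix: ", cond)
  sel <- conditions %in% c(cond_a, cond_b)
  counts <- counts[, sel, drop = FALSE]
  conditions <- conditions[sel]
  phi <- estimate_dispersion(counts, conditions)
  n_df <- ncol(counts) - 2
  if (dispersion_prior_df > 0)
    phi <- (n_df * phi + dispersion_prior_df * mean(phi)) /
      (n_df + dispersion_prior_df)
  cpm <- compute_cpm(counts)
  a <- conditions == cond_a
  b <- conditions == cond_b
  n_a <- sum(a); n_b <- sum(b)
  mean_a <- rowMeans(cpm[, a, drop = FALSE])
  mean_b <- rowMeans(cpm[, b, drop = FALSE])
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))

  # delta-method variance of log2(mean CPM + c): per-sample CPM variance is
  # (mu_cpm * 1e6 / libsize) + phi * mu_cpm^2 (Poisson part rescaled by the
  # CPM factor), averaged into the variance of the condition mean
  lib <- colSums(counts)
  var_mean <- function(mu, idx, n) {
    scale <- 1e6 / lib[idx]
    rowSums(outer(mu, scale) + phi * mu^2) / n^2
  }
  v_a <- var_mean(mean_a, which(a), n_a)
  v_b <- var_mean(mean_b, which(b), n_b)
  se <- sqrt(v_a / (mean_a + pseudocount)^2 + v_b / (mean_b + pseudocount)^2) /
    log(2)
  t_stat <- ifelse(se > 0, lfc / se, 0)
  # dispersion squeezing pools information across features, so the
  # reference t gains the prior degrees of freedom on top of the residual
  p <- 2 * stats::pt(-abs(t_stat),
                     df = n_a + n_b - 2 + dispersion_prior_df)
  p[se == 0 & lfc == 0] <- 1
  p_crit <- if (fdr) stats::p.adjust(p, "BH") else p
  status <- ifelse(p_crit < alpha & lfc >= lfc_threshold, "up",
                   ifelse(p_crit < alpha & lfc <= -lfc_threshold, "down",
                          "not_de"))
  data.frame(feature_id = rownames(counts), biotype = biotype,
             mean_cpm_a = mean_a, mean_cpm_b = mean_b,
             log2fc = lfc, p_value = p, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Drop features weakly expressed in both contrasted conditions
#'
#' A feature is kept iff its mean CPM is at least `cpm_min` in at least one
#' of the two conditions.
#'
#' @param de DE result data frame from [de_test()] (carries `mean_cpm_a`,
#'   `mean_cpm_b`).
#' @param cpm_min CPM floor, default 1.
#' @return The filtered DE data frame.
#' @export
filter_low_expression <- function(de, cpm_min = 1) {
  de[de$mean_cpm_a >= cpm_min | de$mean_cpm_b >= cpm_min, , drop = FALSE]
}
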