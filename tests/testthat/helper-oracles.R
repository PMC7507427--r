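# Independent oracles and shared fixtures for the test suite.

# memoized default synthetic study so several test files share one run
.study_cache <- new.env(parent = emptyenv())
default_study <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- simulate_study(sim_config(seed = seed))
  .study_cache[[key]]
}

# ---- per-base bitmap oracles on a single small chromosome -------------------

bitmap_from_intervals <- function(df, len) {
  bits <- logical(len)
  for (i in seq_len(nrow(df)))
    if (df$start[i] < df$end[i])
      bits[(df$start[i] + 1):df$end[i]] <- TRUE
  bits
}

intervals_from_bitmap <- function(bits, chrom = "chr1") {
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             strand = ".", stringsAsFactors = FALSE)
}

bitmap_dilate <- function(bits, flank) {
  n <- length(bits)
  out <- logical(n)
  idx <- which(bits)
  for (i in idx) out[max(1, i - flank):min(n, i + flank)] <- TRUE
  out
}

random_intervals <- function(n, len, max_width = 40, chrom = "chr1") {
  start <- sample.int(len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + width, len), strand = ".",
             stringsAsFactors = FALSE)
}

# ---- brute-force topological overlap ---------------------------------------

tom_bruteforce <- function(adj) {
  n <- nrow(adj)
  out <- matrix(0, n, n)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(adj[i, -i])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    out[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  dimnames(out) <- dimnames(adj)
  out
}

# ---- brute-force weighted KS enrichment score ------------------------------

es_bruteforce <- function(ids, metrics, set, p_weight = 1) {
  n <- length(ids)
  hit <- ids %in% set
  nr <- sum(abs(metrics[hit])^p_weight)
  rs <- numeric(n)
  run <- 0
  miss <- n - sum(hit)
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + (if (nr > 0) abs(metrics[i])^p_weight / nr
                    else 1 / sum(hit))
    } else run <- run - 1 / miss
    rs[i] <- run
  }
  rs[which.max(abs(rs))]
}

# ---- exact Mann-Whitney enumeration ----------------------------------------

# P(U >= u_obs) by enumerating all assignments of the pooled values
mw_exact_p_greater <- function(x, y) {
  pool <- c(x, y)
  n_x <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(length(pool), n_x)
  us <- apply(combs, 2, function(ix) u_stat(pool[ix], pool[-ix]))
  mean(us >= u_obs)
}

# ---- adjusted Rand index (independent of any clustering package) -----------

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
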