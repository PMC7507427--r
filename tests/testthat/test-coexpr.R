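# Correlation edges, soft threshold, TOM, modules, network filtering.

test_that("pearson edges recover exact correlations and closed-form p-values", {
  x <- matrix(seq_len(8), 1, 8, dimnames = list("x", NULL))
  y2 <- rbind(y = 2 * x[1, ] + 1, z = -x[1, ])
  colnames(x) <- colnames(y2) <- paste0("s", 1:8)
  e <- pearson_edges(x, y2)
  expect_equal(e$r[e$b == "y"], 1)
  expect_equal(e$r[e$b == "z"], -1)
  set.seed(123)
  a <- matrix(rnorm(5 * 6), 6, 5, dimnames = list(paste0("a", 1:6), NULL))
  b <- matrix(rnorm(5 * 6), 6, 5, dimnames = list(paste0("b", 1:6), NULL))
  colnames(a) <- colnames(b) <- paste0("s", 1:5)
  e2 <- pearson_edges(a, b)
  for (k in sample(nrow(e2), 10)) {
    ct <- stats::cor.test(a[e2$a[k], ], b[e2$b[k], ])
    expect_equal(e2$r[k], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(e2$p_value[k], ct$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_edges(a[, 1:2], b[, 1:2]), ">= 3")
  flat <- a; flat[1, ] <- 5
  expect_warning(pearson_edges(flat, b), "zero-variance")
})

test_that("pearson r is invariant to positive affine transforms", {
  set.seed(4)
  a <- matrix(rnorm(20), 2, 10, dimnames = list(c("p", "q"), paste0("s", 1:10)))
  e1 <- pearson_edges(a["p", , drop = FALSE], a["q", , drop = FALSE])
  a2 <- a; a2["p", ] <- 3 * a["p", ] + 7
  e2 <- pearson_edges(a2["p", , drop = FALSE], a2["q", , drop = FALSE])
  expect_equal(e1$r, e2$r, tolerance = 1e-12)
})

test_that("TOM matches hand values and the O(n^3) brute force", {
  adj2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(tom_similarity(adj2)[1, 2], 0.5)
  expect_equal(diag(tom_similarity(adj2)), c(1, 1))
  set.seed(66)
  for (n in c(5, 12, 30)) {
    r <- matrix(runif(n * n), n, n)
    adj <- (r + t(r)) / 2
    diag(adj) <- 0
    expect_equal(tom_similarity(adj), tom_bruteforce(adj), tolerance = 1e-12)
  }
  expect_error(tom_similarity(matrix(0, 2, 3)), "square")
})

test_that("identical expression collapses adjacency and TOM to 1", {
  expr <- matrix(rep(rnorm(8), each = 5), 5, 8,
                 dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
  adj <- adjacency_matrix(expr, 6)
  expect_true(all(adj[upper.tri(adj)] == 1))
  tom <- tom_similarity(adj)
  expect_equal(unname(tom), matrix(1, 5, 5))
  expect_equal(unique(detect_modules(tom, min_module_size = 2)$module),
               "turquoise")
})

test_that("soft-threshold selection takes the smallest power reaching the fit bar", {
  set.seed(12)
  study <- default_study()
  tr <- study$truth
  de_ids <- tr$feature_id[tr$de_status != "not_de"]
  expr <- log2(compute_cpm(study$cm)[de_ids[1:120], study$cm$conditions %in%
                                       sim_config()$satellite_conditions] + 1)
  powers <- c(2, 4, 6, 8)
  pick <- pick_soft_threshold(expr, powers)
  r2 <- vapply(powers, function(b) scale_free_fit(expr, b), numeric(1))
  want <- if (any(r2 >= 0.8)) powers[which(r2 >= 0.8)[1]]
  else powers[which.max(r2)]
  expect_equal(pick$beta, want)
  expect_equal(pick$fit$r_squared, r2)
  expect_error(pick_soft_threshold(expr[1:5, ], powers), "10 features")
})

test_that("planted correlation blocks are recovered as modules", {
  set.seed(90)
  n_per <- 30; n_mod <- 3; n_samp <- 30
  expr <- do.call(rbind, lapply(seq_len(n_mod), function(m) {
    z <- rnorm(n_samp)
    t(replicate(n_per, sqrt(0.8) * z + sqrt(0.2) * rnorm(n_samp)))
  }))
  rownames(expr) <- paste0("f", seq_len(nrow(expr)))
  colnames(expr) <- paste0("s", seq_len(n_samp))
  truth <- rep(seq_len(n_mod), each = n_per)
  tom <- tom_similarity(adjacency_matrix(expr, 6))
  mods <- detect_modules(tom, min_module_size = 10)
  expect_gte(adjusted_rand(mods$module, truth), 0.8)
  expect_equal(length(setdiff(unique(mods$module), "grey")), n_mod)
})

test_that("TF-lncRNA filtering respects thresholds, subsetting and monotonicity", {
  set.seed(17)
  edges <- data.frame(
    a = paste0("tf", sample(3, 50, TRUE)),
    b = paste0("lnc", sample(10, 50, TRUE)),
    r = runif(50, -1, 1), p_value = runif(50, 0, 0.05),
    weight = runif(50, 0, 0.2), stringsAsFactors = FALSE)
  tfs <- paste0("tf", 1:3); lncs <- paste0("lnc", 1:10)
  out <- build_tf_lnc_network(edges, tfs, lncs)
  manual <- edges[edges$weight > 0.05 & edges$p_value < 0.01, ]
  expect_setequal(paste(out$a, out$b, out$weight),
                  paste(manual$a, manual$b, manual$weight))
  expect_true(all(paste(out$a, out$b) %in% paste(edges$a, edges$b)))
  stricter <- build_tf_lnc_network(edges, tfs, lncs, weight_min = 0.1)
  expect_true(all(paste(stricter$a, stricter$b) %in% paste(out$a, out$b)))
  expect_equal(nrow(build_tf_lnc_network(
    data.frame(a = "tf1", b = "lnc1", r = 1, p_value = 0.005, weight = 0.04),
    tfs, lncs)), 0)
  expect_error(build_tf_lnc_network(edges, character(), lncs), "empty")
})

test_that("network overlap reports the set algebra", {
  pa <- data.frame(a = c("x", "y"), b = c("y", "z"))
  expect_equal(network_overlap(pa, pa)$fraction, 1)
  pb <- data.frame(a = "q", b = "r")
  expect_equal(network_overlap(pa, pb)$fraction, 0)
  set.seed(40)
  mk <- function(n) {
    d <- data.frame(a = paste0("g", sample(30, n, TRUE)),
                    b = paste0("g", sample(31:60, n, TRUE)))
    d[!duplicated(paste(d$a, d$b)), ]
  }
  A <- mk(40); B <- mk(40)
  ov <- network_overlap(A, B)
  ka <- paste(A$a, A$b); kb <- paste(B$a, B$b)
  expect_equal(ov$both, length(intersect(ka, kb)))
  expect_equal(ov$fraction, length(intersect(ka, kb)) / length(ka))
  expect_equal(ov$only_a + ov$both, length(ka))
  expect_equal(ov$only_b + ov$both, length(kb))
})
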