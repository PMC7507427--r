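# Chromatin-state classification, TF association, group comparisons.

test_that("category classification applies the H3K4me3 > H3K4me1 precedence", {
  len <- c(chr1 = 1e6)
  tx <- data.frame(transcript_id = paste0("t", 1:4), gene_id = paste0("t", 1:4),
                   biotype = "lncRNA", chrom = "chr1",
                   start = c(10000L, 40000L, 70000L, 100000L),
                   end = c(10000L, 40000L, 70000L, 100000L) + 400L,
                   strand = "+", stringsAsFactors = FALSE)
  w <- make_tss_windows(tx, 2500, 1500, len)
  atac <- gintervals("chr1", c(9800, 39800, 69800), c(10200, 40200, 70200))
  ext <- extend_peaks(atac, 1000, len)
  both_marks <- gintervals("chr1", 10300, 10700)       # near t1 only
  me1 <- rbind(both_marks, gintervals("chr1", 40300, 40700))
  me3 <- both_marks
  cats <- classify_category(w, ext, me1, me3)
  expect_equal(unname(cats),
               c("ATAC_H3K4me3",   # both marks present -> me3 wins
                 "ATAC_H3K4me1", "ATAC_only", "closed"))
  # invariant to input peak ordering
  shuf <- function(df) df[rev(seq_len(nrow(df))), , drop = FALSE]
  expect_equal(classify_category(w, ext, shuf(me1), shuf(me3)), cats)
})

test_that("TF association and co-localization fractions follow the window rule", {
  len <- c(chr1 = 1e6)
  tx <- data.frame(transcript_id = paste0("t", 1:3), gene_id = paste0("t", 1:3),
                   biotype = "lncRNA", chrom = "chr1",
                   start = c(10000L, 40000L, 70000L),
                   end = c(10400L, 40400L, 70400L),
                   strand = "+", stringsAsFactors = FALSE)
  w <- make_tss_windows(tx, 2500, 1500, len)
  atac <- gintervals("chr1", c(9800, 39800, 69800), c(10200, 40200, 70200))
  ext <- extend_peaks(atac, 1000, len)
  myod <- gintervals("chr1", c(9900, 39900), c(10100, 40100))
  bound <- associate_tfs(w, ext, list(MyoD = myod, MyoG = myod))
  expect_equal(bound$t1, c("MyoD", "MyoG"))
  expect_equal(bound$t3, character())
  expect_equal(colocalization_fraction(bound, "MyoD", "MyoG"), 1.0)
  none <- associate_tfs(w, ext, list(MyoD = gintervals("chr1", 1, 2),
                                     MyoG = gintervals("chr1", 5, 6)))
  expect_true(is.na(colocalization_fraction(none, "MyoD", "MyoG")))
})

test_that("non-DE control sampling is reproducible and exhaustive at n = pool", {
  pool <- paste0("l", 1:20)
  expect_setequal(sample_non_de_controls(pool, 20, 5), pool)
  expect_identical(sample_non_de_controls(pool, 7, 5),
                   sample_non_de_controls(pool, 7, 5))
  expect_error(sample_non_de_controls(pool, 21, 5), "pool")
  # inclusion frequency uniform across the pool
  draws <- table(unlist(lapply(1:2000, function(i)
    sample_non_de_controls(pool, 5, i))))
  expect_gt(stats::chisq.test(draws)$p.value, 0.001)
})

test_that("group comparison matches exact Mann-Whitney enumeration at small n", {
  up <- c(5, 6, 7); down <- c(-7, -6, -5)
  res <- compare_groups(up, down, c(-1, 0, 1))
  row <- res[res$group_a == "up" & res$group_b == "down", ]
  expect_equal(row$U, 9)
  expect_equal(mw_exact_p_greater(up, down), 0.05)  # 1/C(6,3) * 1
  # identical pooled values give p ~ 1 under the normal approximation
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_true(all(same$p_value > 0.9))
  expect_error(compare_groups(c(1, 2), down, down), ">= 3")
  # agreement with enumeration for random small samples (no ties)
  set.seed(55)
  for (rep in 1:20) {
    x <- sample(seq(0, 100, 0.5), sample(3:8, 1))
    y <- sample(seq(0.25, 100, 0.5), sample(3:8, 1))
    exact <- mw_exact_p_greater(x, y)
    wt <- stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(wt$p.value, exact, tolerance = 1e-12)
  }
})

test_that("annotation pipeline recovers planted categories and signal direction", {
  study <- default_study()
  de <- filter_low_expression(de_test(study$cm, "GM", "DM"))
  ann <- annotate_chromatin_state(
    de, study$transcripts, study$chromatin$atac_peaks,
    study$chromatin$atac_signal, study$chromatin$k4me1_peaks,
    study$chromatin$k4me3_peaks, mark_signal = study$chromatin$mark_signal,
    tf_peaks = study$chromatin$tf_peaks,
    chrom_lengths = study$chrom_lengths, seed = 1)
  a <- ann$annotation
  expect_setequal(unique(a$de_status), c("up", "down", "control"))
  expect_true(all(a$category %in% c("ATAC_H3K4me1", "ATAC_H3K4me3",
                                    "ATAC_only", "closed")))
  expect_true(all(xor(a$open_chromatin, a$category == "closed")))
  expect_true(all(is.na(a$mark_log2fc[!a$category %in%
                                        c("ATAC_H3K4me1", "ATAC_H3K4me3")])))
  # most planted MyoD/MyoG co-binding survives the pipeline
  coloc <- colocalization_fraction(ann$bound_tfs, "MyoD", "MyoG")
  expect_gt(coloc, 0.6)
})
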