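# Interval algebra, signal quantification and quantile normalization.

test_that("merge_peaks follows bedtools semantics at gap 0", {
  p <- gintervals("chr1", c(0, 10), c(10, 20))
  expect_equal(merge_peaks(p)[, c("start", "end")],
               data.frame(start = 0L, end = 20L))     # bookended join
  p2 <- gintervals("chr1", c(0, 11), c(10, 20))
  expect_equal(nrow(merge_peaks(p2)), 2)              # 1-bp gap kept
  expect_equal(nrow(merge_peaks(p2, gap = 1)), 1)     # joined at gap 1
})

test_that("extend_peaks grows, clamps and re-merges", {
  len <- c(chr1 = 100000L)
  expect_equal(extend_peaks(gintervals("chr1", 5000, 5100), 1000, len)[,
               c("start", "end")],
               data.frame(start = 4000L, end = 6100L))
  expect_equal(extend_peaks(gintervals("chr1", 100, 200), 1000, len)$start, 0L)
})

test_that("TSS windows are strand-aware and clamped", {
  len <- c(chr1 = 1e6)
  tx <- data.frame(transcript_id = c("a", "b", "c"), gene_id = c("a", "b", "c"),
                   biotype = "lncRNA", chrom = "chr1",
                   start = c(10000L, 8000L, 100L),
                   end = c(10400L, 10001L, 500L),
                   strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  w <- make_tss_windows(tx, 2500, 1500, len)
  expect_equal(w$start, c(7500L, 8501L, 0L))
  expect_equal(w$end, c(11500L, 12501L, 1600L))
})

test_that("overlap respects the half-open convention", {
  w <- gintervals("chr1", 0, 100)
  w$transcript_id <- "t1"
  expect_true(assign_open_chromatin(w, gintervals("chr1", 99, 200))[["t1"]])
  expect_false(assign_open_chromatin(w, gintervals("chr1", 100, 200))[["t1"]])
  expect_error(assign_open_chromatin(w, gintervals("chrX", 0, 10)),
               "naming mismatch")
})

test_that("merge/extend/overlap agree with a per-base bitmap oracle", {
  set.seed(202)
  for (rep in 1:200) {
    len <- sample(150:400, 1)
    peaks <- random_intervals(sample(2:12, 1), len)
    merged <- merge_peaks(peaks)
    bits <- bitmap_from_intervals(peaks, len)
    expect_identical(merged[, c("start", "end")],
                     intervals_from_bitmap(bits)[, c("start", "end")])
    flank <- sample(0:30, 1)
    ext <- extend_peaks(merged, flank, c(chr1 = len))
    expect_identical(ext[, c("start", "end")],
                     intervals_from_bitmap(bitmap_dilate(bits, flank))[,
                       c("start", "end")])
    other <- random_intervals(sample(1:8, 1), len)
    hits <- interval_overlaps(peaks, other)
    for (i in seq_len(nrow(peaks))) {
      bit_i <- bitmap_from_intervals(peaks[i, ], len)
      truth <- vapply(seq_len(nrow(other)), function(j)
        any(bit_i & bitmap_from_intervals(other[j, ], len)), logical(1))
      expect_setequal(hits$subject_idx[hits$query_idx == i], which(truth))
    }
  }
})

test_that("quantify_signal computes per-base means with implicit zeros", {
  reg <- gintervals("chr1", 100, 200)
  track <- data.frame(chrom = "chr1", start = 100L, end = 200L, value = 2)
  expect_equal(quantify_signal(track, reg), 2)
  half <- data.frame(chrom = "chr1", start = 100L, end = 150L, value = 4)
  expect_equal(quantify_signal(half, reg), 2)
  # random step tracks vs per-base summation
  set.seed(31)
  for (rep in 1:25) {
    len <- 300
    steps <- sort_intervals(random_intervals(5, len, max_width = 20))
    steps <- steps[c(TRUE, diff(steps$start) >= 21), , drop = FALSE]
    steps$value <- runif(nrow(steps), 0, 5)
    regs <- random_intervals(4, len)
    base_vals <- numeric(len)
    for (i in seq_len(nrow(steps)))
      base_vals[(steps$start[i] + 1):steps$end[i]] <- steps$value[i]
    want <- vapply(seq_len(nrow(regs)), function(j)
      mean(base_vals[(regs$start[j] + 1):regs$end[j]]), numeric(1))
    expect_equal(quantify_signal(steps, regs), want)
  }
})

test_that("quantile normalization matches the sorted-row-means definition", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
  m2 <- cbind(c(5, 1, 7), c(5, 1, 7))
  expect_equal(quantile_normalize(m2), m2)      # identical columns unchanged
  # ties get the mean of their tied reference values
  mt <- cbind(c(1, 1, 10), c(2, 4, 6))
  expect_equal(unname(quantile_normalize(mt)[, 1]),
               c(mean(c(1.5, 2.5)), mean(c(1.5, 2.5)), 8))
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(rnorm(40 * 4), 40, 4)
    out <- quantile_normalize(m)
    sorted <- apply(out, 2, sort)
    for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
    expect_equal(quantile_normalize(out), out)
    for (j in 1:4) expect_equal(order(out[, j]), order(m[, j]))  # rank-preserving
  }
})

test_that("signal log2 fold-change is anti-symmetric with a pseudocount", {
  expect_equal(signal_log2fc(c(3, 5), c(3, 5)), c(0, 0))
  expect_equal(signal_log2fc(3, 0), 2)
  set.seed(8)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(signal_log2fc(b, a), -signal_log2fc(a, b))
})
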