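# PWM parsing, log-odds scanning, Fisher enrichment.

test_that("the bundled PWM library parses into normalized matrices", {
  pwms <- default_pwms()
  expect_setequal(names(pwms), c("MyoD", "MyoG", "CTCF", "Runx", "AP-1",
                                 "ATF3"))
  for (p in pwms) {
    expect_equal(unname(colSums(p$prob)), rep(1, ncol(p$prob)),
                 tolerance = 1e-9)
    expect_true(all(p$prob > 0))
  }
  expect_equal(pwm_consensus(pwms$MyoD), "CAGCTG")
  expect_equal(pwm_consensus(pwms$`AP-1`), "TGACTCA")
})

test_that("consensus sequences score maximally and uniform PWMs score zero", {
  pwm <- default_pwms()$MyoG
  cons <- pwm_consensus(pwm)
  hits <- scan_pwm(cons, pwm)
  expect_true(any(hits$strand == "+" & hits$offset == 0))
  expect_equal(max(hits$score), pwm_max_score(pwm), tolerance = 1e-12)
  # a flat matrix equal to the background scores 0 everywhere
  flat <- pwm
  flat$prob <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"),
                                                  NULL))
  all_scores <- scan_pwm(random_dna(60), flat, threshold_bits = -Inf)
  expect_true(all(all_scores$score == 0))
})

test_that("scanning matches a direct per-window recomputation on both strands", {
  set.seed(444)
  pwm <- default_pwms()$MyoD
  lw <- log2(pwm$prob / 0.25)
  width <- ncol(pwm$prob)
  for (rep in 1:10) {
    s <- random_dna(150)
    got <- scan_pwm(s, pwm, threshold_bits = -Inf)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (strand in c("+", "-")) {
      seq_used <- if (strand == "+") s else rc
      chars <- strsplit(seq_used, "")[[1]]
      for (off0 in seq_len(nchar(s) - width + 1) - 1) {
        win <- chars[(off0 + 1):(off0 + width)]
        want <- sum(lw[cbind(match(win, rownames(lw)), seq_len(width))])
        fwd_off <- if (strand == "+") off0 else nchar(s) - width - off0
        hit <- got[got$strand == strand & got$offset == fwd_off, ]
        expect_equal(hit$score, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("hit counting is strand-symmetric under reverse complement", {
  set.seed(333)
  pwm <- default_pwms()$ATF3
  seqs <- vapply(1:30, function(i) random_dna(120), "")
  pos <- sample(30, 10)
  for (i in pos)   # plant some consensus instances
    substr(seqs[i], 20, 19 + ncol(pwm$prob)) <- pwm_consensus(pwm)
  counts <- vapply(seqs, function(s) nrow(scan_pwm(s, pwm)), integer(1))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  counts_rc <- vapply(rc, function(s) nrow(scan_pwm(s, pwm)), integer(1))
  expect_equal(unname(counts_rc), unname(counts))
})

test_that("windows containing N are skipped", {
  pwm <- default_pwms()$MyoD
  s <- paste0("AAAA", sub("G", "N", pwm_consensus(pwm)), "AAAA")
  expect_equal(nrow(scan_pwm(s, pwm, threshold_bits = -Inf)),
               2 * (nchar(s) - ncol(pwm$prob) + 1) - 2 * ncol(pwm$prob))
  wide <- default_pwms()$CTCF
  expect_equal(nrow(scan_pwm("ACGT", wide)), 0)  # PWM wider than sequence
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  # table (8,2,2,8): p = sum_{k>=8} C(10,k) C(10,10-k) / C(20,10)
  p_hyper <- sum(choose(10, 8:10) * choose(10, 10 - (8:10))) / choose(20, 10)
  genome <- c(chr1 = random_dna(4000))
  pwm <- default_pwms()$MyoG
  cons <- pwm_consensus(pwm)
  mk_regions <- function(n, offset) {
    data.frame(chrom = "chr1", start = offset + (0:(n - 1)) * 40L,
               end = offset + (0:(n - 1)) * 40L + 30L, strand = ".",
               stringsAsFactors = FALSE)
  }
  fg <- mk_regions(10, 0); bg <- mk_regions(10, 2000)
  set.seed(2)
  # force exactly 8 fg and 2 bg regions to contain the consensus, rest not
  blank <- paste(rep("A", 30), collapse = "")
  for (i in 1:10) {
    substr(genome["chr1"], fg$start[i] + 1, fg$start[i] + 30) <- blank
    substr(genome["chr1"], bg$start[i] + 1, bg$start[i] + 30) <- blank
  }
  for (i in 1:8)
    substr(genome["chr1"], fg$start[i] + 1, fg$start[i] + nchar(cons)) <- cons
  for (i in 1:2)
    substr(genome["chr1"], bg$start[i] + 1, bg$start[i] + nchar(cons)) <- cons
  enr <- motif_enrichment(fg, bg, genome, list(MyoG = pwm))
  expect_equal(enr$fg_hits, 8)
  expect_equal(enr$bg_hits, 2)
  expect_equal(enr$p_value, p_hyper, tolerance = 1e-12)
  expect_equal(enr$odds_ratio, (8 * 8) / (2 * 2))
})

test_that("equal hit rates give odds ratio 1 and a large one-sided p", {
  genome <- c(chr1 = random_dna(9000))
  pwm <- default_pwms()$MyoD
  cons <- pwm_consensus(pwm)
  blank <- paste(rep("A", 30), collapse = "")
  mk <- function(n, offset) data.frame(chrom = "chr1",
                                       start = offset + (0:(n - 1)) * 40L,
                                       end = offset + (0:(n - 1)) * 40L + 30L,
                                       stringsAsFactors = FALSE)
  fg <- mk(100, 0); bg <- mk(100, 4500)
  for (i in 1:100) {
    substr(genome["chr1"], fg$start[i] + 1, fg$start[i] + 30) <- blank
    substr(genome["chr1"], bg$start[i] + 1, bg$start[i] + 30) <- blank
  }
  for (i in 1:30) {
    substr(genome["chr1"], fg$start[i] + 1, fg$start[i] + nchar(cons)) <- cons
    substr(genome["chr1"], bg$start[i] + 1, bg$start[i] + nchar(cons)) <- cons
  }
  enr <- motif_enrichment(fg, bg, genome, list(MyoD = pwm))
  expect_equal(enr$odds_ratio, 1)
  expect_gt(enr$p_value, 0.5)
  # regions beyond the sequence bounds are an error
  expect_error(motif_enrichment(data.frame(chrom = "chr1", start = 8990L,
                                           end = 9020L), bg, genome,
                                list(MyoD = pwm)), "bounds")
})
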