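# Known-motif enrichment: log-odds PWM scanning on both strands and a
# one-sided Fisher test of foreground versus background hit frequencies.

#' Read a JASPAR-style PWM text file
#'
#' Format: `>motif_name` followed by four rows `A [ n n ... ]`,
#' `C [...]`, `G [...]`, `T [...]` of per-position counts (or
#' probabilities). Counts receive a pseudocount and are column-normalized
#' to probabilities.
#'
#' @param path Path to the motif file.
#' @param pseudocount Added to every cell before normalization (default
#'   0.5).
#' @param background Background base frequencies (default uniform).
#' @return Named list of `pwm` objects: `name`, `prob` (4 x width matrix,
#'   rows ACGT), `background`.
#' @export
read_jaspar <- function(path, pseudocount = 0.5,
                        background = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25)) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif records found in ", path)
  pwms <- lapply(seq_along(starts), function(i) {
    nm <- sub("^>\\s*", "", lines[starts[i]])
    nm <- strsplit(nm, "\\s+")[[1]][1]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[(starts[i] + 1):to]
    if (length(block) != 4) stop("motif ", nm, ": expected 4 base rows")
    rows <- lapply(block, function(l) {
      base <- sub("^([ACGT]).*", "\\1", l)
      stripped <- sub("^[ACGT]", "", l)
      nums <- regmatches(stripped, gregexpr("[0-9.]+", stripped))[[1]]
      list(base = base, counts = as.numeric(nums))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("motif ", nm, ": rows must be A, C, G, T")
    mat <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(mat) <- bases
    mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
    mat <- mat + pseudocount
    prob <- sweep(mat, 2, colSums(mat), "/")
    structure(list(name = nm, prob = prob, background = background),
              class = "pwm")
  })
  stats::setNames(pwms, vapply(pwms, `[[`, "", "name"))
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", x$name, "width", ncol(x$prob), "consensus",
      pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence and maximal score of a PWM
#'
#' @param pwm A `pwm` object.
#' @return `pwm_consensus`: the argmax base per column; `pwm_max_score`:
#'   the log-odds score (bits) of the consensus.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$prob)[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' @rdname pwm_consensus
#' @export
pwm_max_score <- function(pwm) {
  sum(log2(apply(pwm$prob, 2, max) / pwm$background[
    rownames(pwm$prob)[apply(pwm$prob, 2, which.max)]]))
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Scan a sequence with a PWM
#'
#' Slides the PWM over both strands scoring each window by
#' `sum_j log2(prob[base_j, j] / background[base_j])` (bits); windows
#' containing `N` are skipped. Offsets are 0-based on the forward strand.
#'
#' @param sequence A single DNA string over `A,C,G,T,N`.
#' @param pwm A `pwm` object.
#' @param threshold_bits Minimum reported score; default 60% of the PWM's
#'   maximal achievable score.
#' @return Data frame `offset`, `strand`, `score`.
#' @export
scan_pwm <- function(sequence, pwm, threshold_bits = 0.6 * pwm_max_score(pwm)) {
  width <- ncol(pwm$prob)
  n <- nchar(sequence)
  if (width > n)
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  score_strand <- function(seq_str) {
    chars <- strsplit(toupper(seq_str), "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    lw <- log2(pwm$prob / pwm$background[rownames(pwm$prob)])
    n_win <- n - width + 1
    scores <- numeric(n_win)
    valid <- rep(TRUE, n_win)
    for (j in seq_len(width)) {
      b <- idx[j:(j + n_win - 1)]
      valid <- valid & !is.na(b)
      contrib <- lw[cbind(b, j)]
      contrib[is.na(contrib)] <- 0
      scores <- scores + contrib
    }
    list(scores = scores, valid = valid)
  }
  fwd <- score_strand(sequence)
  rev <- score_strand(revcomp(sequence))
  hits_f <- which(fwd$valid & fwd$scores >= threshold_bits)
  hits_r <- which(rev$valid & rev$scores >= threshold_bits)
  out <- data.frame(
    offset = c(hits_f - 1L, n - width + 1L - hits_r),
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(fwd$scores[hits_f], rev$scores[hits_r]),
    stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Extract region sequences from a genome
#'
#' @param regions Interval data frame (0-based half-open).
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector of region sequences.
#' @export
region_sequences <- function(regions, genome) {
  if (!all(regions$chrom %in% names(genome)))
    stop("regions on chromosomes absent from the genome: ",
         paste(setdiff(regions$chrom, names(genome)), collapse = ", "))
  if (any(regions$end > nchar(genome[regions$chrom])))
    stop("region beyond sequence bounds")
  substr(genome[regions$chrom], regions$start + 1, regions$end)
}

#' Known-motif enrichment of foreground versus background regions
#'
#' For each PWM, counts regions with at least one hit in foreground and
#' background and tests the 2x2 table with a one-sided Fisher exact test
#' (alternative: foreground enriched). The odds ratio uses a Haldane
#' correction (+0.5 per cell) when any cell is zero.
#'
#' @param fg_regions,bg_regions Interval data frames.
#' @param genome Named character vector of chromosome sequences.
#' @param pwms Named list of `pwm` objects.
#' @param threshold_frac Hit threshold as a fraction of each PWM's maximal
#'   score (default 0.6).
#' @return Data frame `motif`, `fg_hits`, `fg_total`, `bg_hits`,
#'   `bg_total`, `odds_ratio`, `p_value`.
#' @export
motif_enrichment <- function(fg_regions, bg_regions, genome, pwms,
                             threshold_frac = 0.6) {
  fg_seq <- region_sequences(fg_regions, genome)
  bg_seq <- region_sequences(bg_regions, genome)
  rows <- lapply(pwms, function(pwm) {
    thr <- threshold_frac * pwm_max_score(pwm)
    hit <- function(seqs) vapply(seqs, function(s)
      nrow(scan_pwm(s, pwm, thr)) > 0, logical(1), USE.NAMES = FALSE)
    a <- sum(hit(fg_seq)); b <- length(fg_seq) - a
    c_ <- sum(hit(bg_seq)); d <- length(bg_seq) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    or <- if (any(c(a, b, c_, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.frame(motif = pwm$name, fg_hits = a, fg_total = length(fg_seq),
               bg_hits = c_, bg_total = length(bg_seq),
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled PWM library
#'
#' A small JASPAR-format library of consensus-derived matrices for the TFs
#' examined around myogenic lncRNA promoters (MyoD and MyoG E-boxes, CTCF,
#' Runx, AP-1, ATF3). These matrices are synthetic, built from published
#' consensus sequences, and ship as a plain-text fixture; substitute a real
#' JASPAR download for production use.
#'
#' @return Named list of `pwm` objects.
#' @export
default_pwms <- function() {
  read_jaspar(system.file("extdata", "pwms_synthetic_consensus.jaspar",
                          package = "lncstate", mustWork = TRUE))
}
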