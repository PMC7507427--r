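# Interval algebra for TSS windows, peak merging/extension and signal
# quantification. All arithmetic is done through GenomicRanges; coordinates
# at this surface are 0-based half-open.

#' Strand-aware TSS window of a transcript
#'
#' For a `+` strand transcript with TSS `t` the window is
#' `[t - upstream, t + downstream)`; for `-` strand it is mirrored so that
#' "upstream" remains 5' of transcription: `[t - downstream + 1,
#' t + upstream + 1)`. Windows are clamped to `[0, chrom_length)`.
#'
#' @param transcripts Transcript data frame (see [read_gtf()]).
#' @param upstream,downstream Window extent in bp (defaults 2500 and 1500).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return Interval data frame with a `transcript_id` column.
#' @export
make_tss_windows <- function(transcripts, upstream = 2500, downstream = 1500,
                             chrom_lengths) {
  if (!all(transcripts$chrom %in% names(chrom_lengths)))
    stop("chrom_lengths missing for: ",
         paste(setdiff(transcripts$chrom, names(chrom_lengths)), collapse = ", "))
  len <- chrom_lengths[transcripts$chrom]
  tss <- transcript_tss(transcripts)
  if (any(tss < 0 | tss >= len)) stop("TSS outside chromosome bounds")
  minus <- transcripts$strand == "-"
  start <- ifelse(minus, tss - downstream + 1L, tss - upstream)
  end <- ifelse(minus, tss + upstream + 1L, tss + downstream)
  df <- data.frame(chrom = transcripts$chrom,
                   start = pmax(0L, as.integer(start)),
                   end = pmin(as.integer(len), as.integer(end)),
                   strand = transcripts$strand,
                   transcript_id = transcripts$transcript_id,
                   stringsAsFactors = FALSE)
  validate_intervals(df, "TSS window")
  df
}

#' Merge overlapping or near-adjacent peaks
#'
#' Follows `bedtools merge` semantics: with `gap = 0` overlapping *and*
#' bookended intervals are joined; more generally intervals separated by at
#' most `gap` bases are joined. Strand is ignored (peaks carry `.`).
#'
#' @param peaks One interval data frame, or a list of them (concatenated
#'   before merging, e.g. per-condition ATAC peak sets).
#' @param gap Maximum separation joined across (default 0 = bookended).
#' @return Sorted, disjoint interval data frame.
#' @export
merge_peaks <- function(peaks, gap = 0) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  df <- do.call(rbind, lapply(peaks, function(p)
    p[, c("chrom", "start", "end"), drop = FALSE]))
  if (!nrow(df)) return(gintervals(character(), integer(), integer()))
  df$strand <- "."
  validate_intervals(df, "merge_peaks")
  gr <- GenomicRanges::reduce(as_granges(df), min.gapwidth = gap + 1L,
                              ignore.strand = TRUE)
  out <- granges_to_df(GenomicRanges::sort(gr, ignore.strand = TRUE))
  rownames(out) <- NULL
  out
}

#' Extend peaks by a flank and re-merge
#'
#' Each interval is grown by `flank` bp on both sides, clamped to
#' `[0, chrom_length)`, then merged at gap 0. This is the region used to
#' test histone-mark and TF co-localization with open chromatin.
#'
#' @param peaks Interval data frame.
#' @param flank Extension in bp (default 1000).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return Sorted, disjoint interval data frame.
#' @export
extend_peaks <- function(peaks, flank = 1000, chrom_lengths) {
  if (!all(peaks$chrom %in% names(chrom_lengths)))
    stop("chrom_lengths missing for: ",
         paste(setdiff(peaks$chrom, names(chrom_lengths)), collapse = ", "))
  df <- peaks
  df$start <- pmax(0L, as.integer(peaks$start - flank))
  df$end <- pmin(as.integer(chrom_lengths[peaks$chrom]),
                 as.integer(peaks$end + flank))
  merge_peaks(df)
}

#' Overlap query between two interval sets
#'
#' Returns the hit pairs with at least `min_overlap` shared bases; the
#' half-open convention means abutting intervals (`end == start`) do not
#' overlap. Strand is ignored.
#'
#' @param query,subject Interval data frames.
#' @param min_overlap Minimum shared bases (default 1).
#' @return Data frame of `query_idx`, `subject_idx` row indices.
#' @export
interval_overlaps <- function(query, subject, min_overlap = 1) {
  if (!nrow(query) || !nrow(subject))
    return(data.frame(query_idx = integer(), subject_idx = integer()))
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  data.frame(query_idx = S4Vectors::queryHits(hits),
             subject_idx = S4Vectors::subjectHits(hits))
}

#' Flag TSS windows overlapping open chromatin
#'
#' A lncRNA is open-chromatin-associated when its TSS window shares at least
#' one base with any ATAC peak. A zero intersection between the chromosome
#' names of windows and peaks almost always means a naming-convention
#' mismatch between input files and is reported as an error rather than
#' silently returning all-FALSE.
#'
#' @param windows TSS-window data frame with `transcript_id`.
#' @param atac_peaks Interval data frame of (merged) ATAC peaks.
#' @return Named logical vector over `windows$transcript_id`.
#' @export
assign_open_chromatin <- function(windows, atac_peaks) {
  stopifnot(nrow(windows) > 0, nrow(atac_peaks) > 0)
  if (!length(intersect(unique(windows$chrom), unique(atac_peaks$chrom))))
    stop("no chromosome names in common between windows and peaks ",
         "(naming mismatch?)")
  hits <- interval_overlaps(windows, atac_peaks)
  open <- rep(FALSE, nrow(windows))
  open[unique(hits$query_idx)] <- TRUE
  stats::setNames(open, windows$transcript_id)
}

#' Mean per-base signal over regions
#'
#' For each region, sums `value * covered_bases` over the track's disjoint
#' steps intersecting the region and divides by region width; bases covered
#' by no step contribute 0 (deeptools-style mean coverage).
#'
#' @param track bedGraph data frame (`chrom`, `start`, `end`, `value`).
#' @param regions Interval data frame.
#' @return Numeric vector, one mean per region row.
#' @export
quantify_signal <- function(track, regions) {
  validate_intervals(regions, "regions")
  out <- numeric(nrow(regions))
  if (!nrow(track)) return(out)
  hits <- interval_overlaps(regions, track)
  if (nrow(hits)) {
    ov <- pmin(regions$end[hits$query_idx], track$end[hits$subject_idx]) -
      pmax(regions$start[hits$query_idx], track$start[hits$subject_idx])
    contrib <- ov * track$value[hits$subject_idx]
    sums <- tapply(contrib, hits$query_idx, sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out / (regions$end - regions$start)
}

#' Quantile normalization of a signal matrix
#'
#' The classic microarray algorithm: sort each column, average across
#' columns to obtain a reference distribution, and map every value to the
#' reference value of its rank. Ties within a column receive the mean of
#' their tied reference values, so the procedure is deterministic and
#' idempotent; afterwards every column holds the identical sorted multiset.
#'
#' @param mat Numeric matrix (rows = regions/features, columns = samples),
#'   at least 2 columns, no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2, !anyNA(mat))
  ref <- rowMeans(apply(mat, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(mat, 2, function(col) {
    # tie group spanning ranks [r_min, r_max] gets the mean of its tied
    # reference values ref[r_min:r_max]
    r_min <- rank(col, ties.method = "min")
    r_max <- rank(col, ties.method = "max")
    (cs[r_max + 1] - cs[r_min]) / (r_max - r_min + 1)
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Log2 fold-change of signal vectors with a pseudocount
#'
#' @param values_b,values_a Equal-length non-negative numeric vectors
#'   (condition B over condition A).
#' @param pseudocount Added to both before the ratio (default 1).
#' @return `log2((B + c) / (A + c))`.
#' @export
signal_log2fc <- function(values_b, values_a, pseudocount = 1) {
  stopifnot(length(values_a) == length(values_b))
  log2((values_b + pseudocount) / (values_a + pseudocount))
}
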