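# Chromatin-state classification of DE lncRNA TSS windows and
# quantification of condition differences in ATAC / histone-mark signal and
# TF binding.

#' Classify TSS windows into chromatin-state categories
#'
#' Categories: `closed` when the TSS window overlaps no ATAC peak;
#' otherwise the extended ATAC regions overlapping the window are tested
#' against histone-mark peaks — `ATAC_H3K4me3` if any overlaps an H3K4me3
#' peak, else `ATAC_H3K4me1` if any overlaps an H3K4me1 peak, else
#' `ATAC_only`. The H3K4me3-over-H3K4me1 precedence makes the categories
#' exclusive when both marks are present. Mark co-occurrence is tested
#' against the extended (flanked and re-merged) ATAC regions, not the raw
#' TSS window.
#'
#' @param windows TSS-window data frame with `transcript_id`.
#' @param atac_ext Extended+merged ATAC peak data frame (see
#'   [extend_peaks()]).
#' @param k4me1_peaks,k4me3_peaks Histone-mark peak data frames.
#' @return Named character vector of categories over `transcript_id`.
#' @export
classify_category <- function(windows, atac_ext, k4me1_peaks, k4me3_peaks) {
  n <- nrow(windows)
  cat_out <- rep("closed", n)
  win_atac <- interval_overlaps(windows, atac_ext)
  if (nrow(win_atac)) {
    marked <- function(peaks) {
      if (!nrow(peaks)) return(integer())
      unique(interval_overlaps(atac_ext, peaks)$query_idx)
    }
    me3_regions <- marked(k4me3_peaks)
    me1_regions <- marked(k4me1_peaks)
    by_win <- split(win_atac$subject_idx, win_atac$query_idx)
    for (w in names(by_win)) {
      i <- as.integer(w)
      regions <- by_win[[w]]
      cat_out[i] <- if (any(regions %in% me3_regions)) "ATAC_H3K4me3"
      else if (any(regions %in% me1_regions)) "ATAC_H3K4me1"
      else "ATAC_only"
    }
  }
  stats::setNames(cat_out, windows$transcript_id)
}

#' TFs bound near each TSS window
#'
#' A TF is associated with a window when one of its peaks overlaps any
#' extended ATAC region that itself overlaps the window.
#'
#' @param windows TSS-window data frame.
#' @param atac_ext Extended+merged ATAC peaks.
#' @param tf_peaks Named list of per-TF peak data frames.
#' @return Named list (by `transcript_id`) of character vectors of TF names.
#' @export
associate_tfs <- function(windows, atac_ext, tf_peaks) {
  win_atac <- interval_overlaps(windows, atac_ext)
  by_win <- split(win_atac$subject_idx, win_atac$query_idx)
  tf_regions <- lapply(tf_peaks, function(p) {
    if (!nrow(p)) integer() else unique(interval_overlaps(atac_ext, p)$query_idx)
  })
  out <- rep(list(character()), nrow(windows))
  for (w in names(by_win)) {
    i <- as.integer(w)
    regions <- by_win[[w]]
    hit <- vapply(tf_regions, function(r) any(regions %in% r), logical(1))
    out[[i]] <- names(tf_peaks)[hit]
  }
  stats::setNames(out, windows$transcript_id)
}

#' Binding co-localization fraction of two TFs
#'
#' Jaccard-style fraction: windows bound by both TFs over windows bound by
#' either; `NA` when neither TF binds any window.
#'
#' @param bound_tfs Output of [associate_tfs()].
#' @param tf_a,tf_b TF names.
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
colocalization_fraction <- function(bound_tfs, tf_a, tf_b) {
  has_a <- vapply(bound_tfs, function(s) tf_a %in% s, logical(1))
  has_b <- vapply(bound_tfs, function(s) tf_b %in% s, logical(1))
  either <- sum(has_a | has_b)
  if (either == 0) return(NA_real_)
  sum(has_a & has_b) / either
}

#' Sample non-DE control lncRNAs
#'
#' Uniform sample without replacement, reproducible for a fixed seed. The
#' seed is applied to a private RNG stream so the caller's RNG state is
#' untouched.
#'
#' @param non_de_ids Pool of non-DE feature ids.
#' @param n Sample size (`n <= length(non_de_ids)`).
#' @param seed Integer seed.
#' @return Character vector of sampled ids.
#' @export
sample_non_de_controls <- function(non_de_ids, n, seed) {
  if (n > length(non_de_ids))
    stop("requested ", n, " controls from a pool of ", length(non_de_ids))
  with_seed(seed, sample(non_de_ids, n))
}

# run code under a local RNG seed without disturbing the global stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Mann-Whitney comparison of signal fold-changes across DE groups
#'
#' Two-sided Mann-Whitney U tests (normal approximation with tie
#' correction) for each pair among the up-regulated, down-regulated and
#' non-DE control groups.
#'
#' @param up_fc,down_fc,control_fc Numeric vectors of per-lncRNA signal
#'   log2 fold-changes (each of length >= 3).
#' @return Data frame with one row per pair: group labels, group medians,
#'   U statistic and p-value.
#' @export
compare_groups <- function(up_fc, down_fc, control_fc) {
  groups <- list(up = up_fc, down = down_fc, control = control_fc)
  if (any(lengths(groups) < 3)) stop("each group needs >= 3 values")
  pairs <- list(c("up", "control"), c("up", "down"), c("down", "control"))
  rows <- lapply(pairs, function(p) {
    ht <- stats::wilcox.test(groups[[p[1]]], groups[[p[2]]],
                             exact = FALSE, correct = TRUE)
    data.frame(group_a = p[1], group_b = p[2],
               median_a = stats::median(groups[[p[1]]]),
               median_b = stats::median(groups[[p[2]]]),
               U = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate DE lncRNAs with TSS chromatin state and signal fold-changes
#'
#' The full integration step. DE lncRNAs (plus an equally sized random
#' control drawn from non-DE lncRNAs) get a strand-aware TSS window
#' (default 2.5 kb upstream / 1.5 kb downstream); open-chromatin status is
#' tested against the merged union of both conditions' ATAC peaks; the
#' merged peaks are extended by `flank` (default 1 kb) and re-merged, and
#' each window's overlapping extended regions define where histone-mark
#' categories, TF binding, and per-condition mean signal are evaluated.
#' Signal matrices (one column per condition) are quantile-normalized
#' before the log2 fold-change.
#'
#' @param de DE results for lncRNAs (already CPM-filtered), from
#'   [de_test()] / [filter_low_expression()].
#' @param transcripts Transcript annotation data frame.
#' @param atac_peaks List of per-condition ATAC peak data frames (merged
#'   into the open-chromatin region set).
#' @param atac_signal Named list of two bedGraph data frames
#'   (`list(a = , b = )`, condition A and B signal).
#' @param k4me1_peaks,k4me3_peaks Histone-mark peak data frames.
#' @param mark_signal Optional named list
#'   `list(k4me1 = list(a=, b=), k4me3 = list(a=, b=))` of mark signal
#'   tracks; when supplied, `mark_log2fc` is computed for the two mark
#'   categories.
#' @param tf_peaks Named list of per-TF peak data frames.
#' @param chrom_lengths Named chromosome lengths.
#' @param upstream,downstream TSS window extents (bp).
#' @param flank ATAC extension (bp).
#' @param seed Seed for control sampling.
#' @return List of class `chromstate_annotation`: `annotation` data frame
#'   (transcript_id, de_status, open_chromatin, category, atac_log2fc,
#'   mark_log2fc, bound_tfs), `comparison` ([compare_groups()] table on
#'   atac_log2fc), `atac_regions` (the extended region set).
#' @export
annotate_chromatin_state <- function(de, transcripts, atac_peaks, atac_signal,
                                     k4me1_peaks, k4me3_peaks,
                                     mark_signal = NULL, tf_peaks = list(),
                                     chrom_lengths,
                                     upstream = 2500, downstream = 1500,
                                     flank = 1000, seed = 1) {
  lnc <- transcripts[transcripts$biotype == "lncRNA", , drop = FALSE]
  de_lnc <- de[de$status != "not_de" & de$feature_id %in% lnc$transcript_id, ]
  non_de_pool <- de$feature_id[de$status == "not_de" &
                                 de$feature_id %in% lnc$transcript_id]
  n_ctrl <- min(nrow(de_lnc), length(non_de_pool))
  ctrl_ids <- sample_non_de_controls(non_de_pool, n_ctrl, seed)

  ids <- c(de_lnc$feature_id, ctrl_ids)
  status <- c(de_lnc$status, rep("control", length(ctrl_ids)))
  tx <- lnc[match(ids, lnc$transcript_id), , drop = FALSE]
  if (anyNA(tx$transcript_id))
    stop("DE feature ids missing from annotation: ",
         paste(ids[is.na(tx$transcript_id)][1:3], collapse = ", "))

  windows <- make_tss_windows(tx, upstream, downstream, chrom_lengths)
  atac_merged <- merge_peaks(atac_peaks)
  open <- assign_open_chromatin(windows, atac_merged)
  atac_ext <- extend_peaks(atac_merged, flank, chrom_lengths)
  category <- classify_category(windows, atac_ext, k4me1_peaks, k4me3_peaks)
  bound <- associate_tfs(windows, atac_ext, tf_peaks)

  # per-window signal over its overlapping extended ATAC regions
  region_fc <- function(sig_a, sig_b) {
    m <- cbind(a = quantify_signal(sig_a, atac_ext),
               b = quantify_signal(sig_b, atac_ext))
    if (nrow(m) >= 2) m <- quantile_normalize(m)
    win_atac <- interval_overlaps(windows, atac_ext)
    by_win <- split(win_atac$subject_idx, win_atac$query_idx)
    va <- rep(NA_real_, nrow(windows)); vb <- va
    for (w in names(by_win)) {
      i <- as.integer(w)
      va[i] <- mean(m[by_win[[w]], "a"])
      vb[i] <- mean(m[by_win[[w]], "b"])
    }
    signal_log2fc(vb, va)
  }
  atac_fc <- region_fc(atac_signal$a, atac_signal$b)

  mark_fc <- rep(NA_real_, nrow(windows))
  if (!is.null(mark_signal)) {
    me1 <- region_fc(mark_signal$k4me1$a, mark_signal$k4me1$b)
    me3 <- region_fc(mark_signal$k4me3$a, mark_signal$k4me3$b)
    mark_fc[category == "ATAC_H3K4me1"] <- me1[category == "ATAC_H3K4me1"]
    mark_fc[category == "ATAC_H3K4me3"] <- me3[category == "ATAC_H3K4me3"]
  }

  ann <- data.frame(transcript_id = ids, de_status = status,
                    open_chromatin = unname(open),
                    category = unname(category),
                    atac_log2fc = atac_fc, mark_log2fc = mark_fc,
                    bound_tfs = vapply(bound, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)

  grp <- function(s) ann$atac_log2fc[ann$de_status == s & ann$open_chromatin &
                                       !is.na(ann$atac_log2fc)]
  comparison <- NULL
  if (all(vapply(c("up", "down", "control"), function(s) length(grp(s)) >= 3,
                 logical(1))))
    comparison <- compare_groups(grp("up"), grp("down"), grp("control"))

  structure(list(annotation = ann, comparison = comparison,
                 atac_regions = atac_ext, bound_tfs = bound),
            class = "chromstate_annotation")
}

#' @export
print.chromstate_annotation <- function(x, ...) {
  ann <- x$annotation
  cat("chromstate_annotation:", nrow(ann), "lncRNAs (",
      sum(ann$de_status != "control"), "DE +",
      sum(ann$de_status == "control"), "controls )\n")
  de <- ann[ann$de_status != "control", ]
  cat(sprintf("  open chromatin among DE: %d/%d (%.1f%%)\n",
              sum(de$open_chromatin), nrow(de),
              100 * mean(de$open_chromatin)))
  print(table(category = de$category))
  invisible(x)
}
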