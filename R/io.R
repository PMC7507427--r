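# Readers and writers for the on-disk formats the pipeline touches.
# One internal coordinate convention everywhere: 0-based half-open [start, end),
# BED-native. GTF (1-based inclusive) is converted at this boundary and
# nowhere else.

#' Construct a genomic interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand`, interpreted as 0-based half-open `[start, end)` coordinates.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, 0-based exclusive end; must satisfy `start < end`.
#' @param strand Strand characters in `+`, `-`, `.` (recycled).
#' @return A data frame of validated intervals.
#' @export
gintervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chromosome names must be non-empty")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(what, ": need 0 <= start < end (first offender row ", bad[1], ")")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'")
  invisible(df)
}

# Single conversion site to/from GRanges (1-based closed).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) sub("^\\.$", "*", df$strand) else "*")
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = sub("^\\*$", ".", as.character(GenomicRanges::strand(gr))),
             stringsAsFactors = FALSE)
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Transcription start site of a transcript
#'
#' The 5'-most transcribed base: `start` for `+` strand transcripts,
#' `end - 1` for `-` strand (0-based coordinates).
#'
#' @param transcripts Transcript data frame (see [read_gtf()]).
#' @return Integer vector of TSS positions.
#' @export
transcript_tss <- function(transcripts) {
  ifelse(transcripts$strand == "-", transcripts$end - 1L, transcripts$start)
}

#' Read transcript records from a GTF file
#'
#' Parses GTF2.2-style tab-separated annotation, keeping only `transcript`
#' feature rows. Coordinates are converted from GTF's 1-based inclusive
#' convention to the package's 0-based half-open convention. The biotype is
#' taken from the `gene_type` attribute if present, else `gene_biotype`
#' (GENCODE versus Ensembl dialects); records whose biotype is neither
#' `lncRNA` nor `protein_coding` are skipped with a warning.
#'
#' @param path Path to a GTF file.
#' @return Data frame with columns `transcript_id`, `gene_id`, `biotype`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("malformed GTF line ", idx[which(nf != 9)[1]], ": expected 9 fields, got ",
         nf[which(nf != 9)[1]])
  feat <- vapply(fields, `[[`, "", 3)
  fields <- fields[feat == "transcript"]
  if (!length(fields))
    return(data.frame(transcript_id = character(), gene_id = character(),
                      biotype = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  attr_of <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, ' "'), attrs))) > 0 &
             nchar(m) > 0,
           sub('"$', "", sub(paste0(key, ' "'), "", m)), NA_character_)
  }
  attrs <- vapply(fields, `[[`, "", 9)
  tid <- vapply(attrs, function(a) {
    m <- regmatches(a, regexpr('transcript_id "[^"]*"', a))
    if (length(m)) sub('"$', "", sub('transcript_id "', "", m)) else NA_character_
  }, "", USE.NAMES = FALSE)
  gid <- vapply(attrs, function(a) {
    m <- regmatches(a, regexpr('gene_id "[^"]*"', a))
    if (length(m)) sub('"$', "", sub('gene_id "', "", m)) else NA_character_
  }, "", USE.NAMES = FALSE)
  bt <- vapply(attrs, function(a) {
    for (key in c("gene_type", "gene_biotype")) {
      m <- regmatches(a, regexpr(paste0(key, ' "[^"]*"'), a))
      if (length(m)) return(sub('"$', "", sub(paste0(key, ' "'), "", m)))
    }
    NA_character_
  }, "", USE.NAMES = FALSE)
  df <- data.frame(
    transcript_id = tid,
    gene_id = gid,
    biotype = bt,
    chrom = vapply(fields, `[[`, "", 1),
    start = as.integer(vapply(fields, `[[`, "", 4)) - 1L,
    end = as.integer(vapply(fields, `[[`, "", 5)),
    strand = vapply(fields, `[[`, "", 7),
    stringsAsFactors = FALSE)
  known <- df$biotype %in% c("lncRNA", "protein_coding")
  if (any(!known)) {
    warning(sum(!known), " transcript record(s) with unknown biotype skipped (",
            paste(unique(df$biotype[!known]), collapse = ", "), ")")
    df <- df[known, , drop = FALSE]
  }
  validate_intervals(df, "GTF transcript")
  rownames(df) <- NULL
  df
}

#' Write transcripts back to GTF
#'
#' Inverse of [read_gtf()]: emits one `transcript` row per record with
#' 1-based inclusive coordinates and `gene_type` biotype attributes, so that
#' `read_gtf(write_gtf(x))` reproduces `x`.
#'
#' @param transcripts Transcript data frame.
#' @param path Output path.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- sprintf(
    '%s\tlncstate\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_type "%s";',
    transcripts$chrom, transcripts$start + 1L, transcripts$end,
    transcripts$strand, transcripts$gene_id, transcripts$transcript_id,
    transcripts$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED6 peak file
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Output is sorted by (chrom, start, end).
#'
#' @param path Path to a BED file.
#' @return Sorted interval data frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(gintervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1),
                   start = as.integer(vapply(fields, `[[`, "", 2)),
                   end = as.integer(vapply(fields, `[[`, "", 3)),
                   strand = vapply(fields, function(f)
                     if (length(f) >= 6) f[[6]] else ".", ""),
                   stringsAsFactors = FALSE)
  validate_intervals(df, "BED")
  df <- sort_intervals(df)
  rownames(df) <- NULL
  df
}

#' @rdname read_bed
#' @param intervals Interval data frame to write.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals, "BED")
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  if (all(strand == ".")) {
    writeLines(sprintf("%s\t%d\t%d", intervals$chrom, intervals$start,
                       intervals$end), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", intervals$chrom,
                       intervals$start, intervals$end, name, strand), path)
  }
  invisible(path)
}

#' Read / write a 4-column bedGraph signal track
#'
#' Steps must be non-overlapping within a chromosome and carry non-negative
#' values; violations are errors, not warnings, because downstream signal
#' quantification assumes disjoint coverage steps.
#'
#' @param path Path to a bedGraph file.
#' @return Data frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("malformed bedGraph line ", which(nf < 4)[1], ": expected 4 columns")
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1),
                   start = as.integer(vapply(fields, `[[`, "", 2)),
                   end = as.integer(vapply(fields, `[[`, "", 3)),
                   value = as.numeric(vapply(fields, `[[`, "", 4)),
                   stringsAsFactors = FALSE)
  validate_intervals(df, "bedGraph")
  if (any(df$value < 0)) stop("bedGraph: negative signal value")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  ov <- df$chrom[-1] == df$chrom[-nrow(df)] & df$start[-1] < df$end[-nrow(df)]
  if (nrow(df) > 1 && any(ov))
    stop("bedGraph: overlapping steps on ", df$chrom[-1][ov][1])
  rownames(df) <- NULL
  df
}

#' @rdname read_bedgraph
#' @param track Signal track data frame to write.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     format(track$value, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read / write a count matrix with sample metadata
#'
#' The TSV layout is `feature_id`, `biotype`, then one integer column per
#' sample. Sample names follow the `<condition>_<replicate>` convention
#' (e.g. `GM_1`, `DM60_3`, `W2_1`); condition labels are recovered by
#' stripping the final `_<replicate>` token.
#'
#' @param path Path to the counts TSV.
#' @return A `count_matrix` list: `counts` (integer matrix, features x
#'   samples), `biotype` (named character vector), `samples`, `conditions`.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("feature_id", "biotype") %in% names(df)))
    stop("counts file must have feature_id and biotype columns")
  mat <- as.matrix(df[, setdiff(names(df), c("feature_id", "biotype")),
                      drop = FALSE])
  if (any(mat < 0)) stop("counts must be non-negative")
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$feature_id
  count_matrix(mat, stats::setNames(df$biotype, df$feature_id))
}

#' @rdname read_counts
#' @param cm A `count_matrix` object.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts),
                   biotype = unname(cm$biotype[rownames(cm$counts)]),
                   cm$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a count matrix object
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param biotype Named character vector (`lncRNA` / `protein_coding`) over
#'   the features.
#' @param conditions Optional condition label per sample; defaults to sample
#'   names with their trailing `_<replicate>` removed.
#' @return A `count_matrix` list.
#' @export
count_matrix <- function(counts, biotype,
                         conditions = sub("_[^_]+$", "", colnames(counts))) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(rownames(counts) %in% names(biotype)))
    stop("every feature needs a biotype")
  structure(list(counts = counts,
                 biotype = biotype[rownames(counts)],
                 samples = colnames(counts),
                 conditions = stats::setNames(conditions, colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("  biotypes:", paste(names(table(x$biotype)), table(x$biotype),
                           sep = "=", collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$conditions), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("malformed GMT line ", which(lengths(fields) < 3)[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of member-id vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read / write FASTA sequence files
#'
#' Thin wrappers over Biostrings keeping the rest of the package free of
#' XStringSet handling.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
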