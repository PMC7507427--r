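# Synthetic study generator: a complete, deterministic input set with
# planted ground truth for every pipeline stage — NB counts with planted
# differential expression and co-expression modules, TSS chromatin
# categories with matching peaks and signal, TF binding with controlled
# co-localization, and motif instances embedded in foreground sequences.

#' Default simulation configuration
#'
#' Returns the study conditions emulated by the generator: 2 chromosomes of
#' 5 Mb; 300 lncRNAs and 1500 protein-coding genes (12 of them TFs); 3
#' replicates of a proliferation (GM) and a differentiation (DM) condition
#' plus 6 muscle-stem-cell developmental stages (W2-W12, 3 replicates
#' each); NB dispersion 0.1; 30% of features differentially expressed at
#' |log2FC| = 2; open/marked chromatin-category proportions mirroring the
#' observed composition of open-chromatin-associated lncRNA promoters
#' (roughly 64% open, of which ~83% carry H3K4me1 or H3K4me3); five
#' planted co-expression modules of 50 features at within-module
#' correlation 0.8; a 4-fold ATAC signal gain at up-regulated promoters;
#' and motif insertion at a 5-fold foreground/background rate ratio.
#'
#' @param seed Master seed; each stage derives its own stream from it.
#' @param ... Overrides for any listed field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_chrom = 2,
    chrom_length = 5e6,
    n_lnc = 300,
    n_pcg = 1500,
    n_tf = 12,
    replicates = 3,
    c2c12_conditions = c("GM", "DM"),
    satellite_conditions = c("W2", "W4", "W6", "W8", "W10", "W12"),
    phi = 0.1,
    de_fraction = 0.3,
    de_lfc = 2,
    category_props = c(ATAC_H3K4me1 = 0.26, ATAC_H3K4me3 = 0.27,
                       ATAC_only = 0.11, closed = 0.36),
    n_modules = 5,
    module_size = 50,
    module_r = 0.8,
    atac_gain = 4,
    chromatin_noise = 0,
    tf_bind_prob = 0.5,
    myod_myog_coloc = 0.8,
    motif_fg_rate = 0.5,
    motif_bg_rate = 0.1,
    upstream = 2500,
    downstream = 1500,
    flank = 1000)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (sum(cfg$category_props) > 1 + 1e-9)
    stop("category_props must sum to <= 1")
  structure(cfg, class = "sim_config")
}

stage_seed <- function(config, stage) (config$seed * 97L + stage) %% 2147483629L

#' Simulate transcript annotation and a genome
#'
#' Places single-isoform transcripts (width 200-500 bp, random strand) on
#' evenly spaced slots so that neighbouring transcripts are separated by at
#' least 5 kb and every TSS window fits without clamping. lncRNA and
#' protein-coding identities are interleaved at random; TF genes are a
#' designated subset of the protein-coding genes.
#'
#' @param config A `sim_config`.
#' @return List: `transcripts` (annotation data frame with `is_tf`),
#'   `genome` (named character vector), `chrom_lengths`.
#' @export
simulate_annotation <- function(config) {
  with_seed(stage_seed(config, 1L), {
    n_total <- config$n_lnc + config$n_pcg
    per_chrom <- ceiling(n_total / config$n_chrom)
    margin <- config$upstream + config$downstream + 1
    slot <- floor((config$chrom_length - 2 * margin) / per_chrom)
    max_width <- 500
    if (slot < max_width + 5000)
      stop("overcrowded chromosome: slot width ", slot,
           " cannot hold a transcript with >= 5 kb spacing")
    tf_names <- c("MyoD", "MyoG", "Mef2c", "Heyl",
                  paste0("TF", seq_len(max(0, config$n_tf - 4))))[
                    seq_len(config$n_tf)]
    ids <- c(sprintf("lnc_%04d", seq_len(config$n_lnc)),
             paste0("TF_", tf_names),
             sprintf("pcg_%04d", seq_len(config$n_pcg - config$n_tf)))
    biotype <- c(rep("lncRNA", config$n_lnc),
                 rep("protein_coding", config$n_pcg))
    ord <- sample(n_total)
    ids <- ids[ord]; biotype <- biotype[ord]
    chrom <- paste0("chr", rep(seq_len(config$n_chrom), each = per_chrom,
                               length.out = n_total))
    slot_idx <- unlist(lapply(table(factor(chrom,
                                           paste0("chr",
                                                  seq_len(config$n_chrom)))),
                              seq_len))
    width <- sample(200:max_width, n_total, replace = TRUE)
    offset <- sample(0:1000, n_total, replace = TRUE)
    start <- margin + (slot_idx - 1L) * slot + offset
    strand <- sample(c("+", "-"), n_total, replace = TRUE)
    tx <- data.frame(transcript_id = ids, gene_id = ids, biotype = biotype,
                     chrom = chrom, start = as.integer(start),
                     end = as.integer(start + width), strand = strand,
                     is_tf = grepl("^TF_", ids), stringsAsFactors = FALSE)
    genome <- vapply(seq_len(config$n_chrom), function(i)
      paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                   replace = TRUE), collapse = ""), "")
    names(genome) <- paste0("chr", seq_len(config$n_chrom))
    list(transcripts = tx, genome = genome,
         chrom_lengths = stats::setNames(rep(config$chrom_length,
                                             config$n_chrom), names(genome)))
  })
}

#' Plant per-feature ground truth
#'
#' Assigns DE status and effect size for the GM-vs-DM contrast, chromatin
#' categories (lncRNAs only; non-DE lncRNAs also get categories so the
#' control group has open-chromatin members), co-expression module
#' membership (drawn from DE features, each module seeded with TF hubs),
#' and the rise-then-fall developmental profile of the up-regulated lncRNA
#' set across W2-W12 (reversed for the down-regulated set).
#'
#' @param config A `sim_config`.
#' @param annotation Output of [simulate_annotation()].
#' @return Truth data frame, one row per feature.
#' @export
simulate_truth <- function(config, annotation) {
  tx <- annotation$transcripts
  with_seed(stage_seed(config, 2L), {
    n <- nrow(tx)
    truth <- data.frame(feature_id = tx$transcript_id, biotype = tx$biotype,
                        is_tf = tx$is_tf, de_status = "not_de",
                        true_lfc = 0, category = NA_character_,
                        module = "none", stringsAsFactors = FALSE)
    de_idx <- sample(n, round(config$de_fraction * n))
    up <- sample(c(TRUE, FALSE), length(de_idx), replace = TRUE)
    truth$de_status[de_idx] <- ifelse(up, "up", "down")
    truth$true_lfc[de_idx] <- ifelse(up, config$de_lfc, -config$de_lfc)
    # TFs are hub genes: force them DE so they enter the network stage
    tf_i <- which(truth$is_tf)
    need <- tf_i[truth$de_status[tf_i] == "not_de"]
    truth$de_status[need] <- sample(c("up", "down"), length(need),
                                    replace = TRUE)
    truth$true_lfc[need] <- ifelse(truth$de_status[need] == "up",
                                   config$de_lfc, -config$de_lfc)
    lnc_i <- which(truth$biotype == "lncRNA")
    props <- config$category_props
    truth$category[lnc_i] <- sample(names(props), length(lnc_i),
                                    replace = TRUE, prob = props)
    # modules drawn from DE features; each module seeded with TF hubs
    if (config$n_modules > 0) {
      de_pool <- which(truth$de_status != "not_de")
      tf_pool <- intersect(de_pool, tf_i)
      other_pool <- setdiff(de_pool, tf_i)
      tf_split <- split(sample(tf_pool),
                        rep_len(seq_len(config$n_modules), length(tf_pool)))
      for (m in seq_len(config$n_modules)) {
        hubs <- tf_split[[as.character(m)]]
        fill <- sample(other_pool, config$module_size - length(hubs))
        other_pool <- setdiff(other_pool, fill)
        truth$module[c(hubs, fill)] <- paste0("M", m)
      }
    }
    truth
  })
}

satellite_profile <- function(conditions, direction) {
  # log2 offsets planting a rise (W4-W6) then fall (W10-W12) for the "up"
  # set, mirrored for the "down" set
  prof <- c(W2 = 0, W4 = 0.75, W6 = 1, W8 = 0.5, W10 = 0, W12 = -0.75)
  direction * prof[conditions]
}

#' Simulate the count matrix
#'
#' NB(mu, phi) counts (Poisson when `phi = 0`) for GM/DM (x replicates) and
#' the six satellite-stage conditions. Baseline log2 means are uniform on
#' (3, 9); DE features shift their DM mean by the planted log2FC; module
#' members share a per-sample latent factor whose loading is calibrated
#' from the feature's NB noise so that within-module log-CPM correlation
#' matches `module_r`; the up/down lncRNA sets follow the rise-then-fall
#' satellite profile.
#'
#' @param config A `sim_config`.
#' @param truth Truth table from [simulate_truth()].
#' @return A `count_matrix`.
#' @export
simulate_counts <- function(config, truth) {
  with_seed(stage_seed(config, 3L), {
    conds <- c(rep(config$c2c12_conditions, each = config$replicates),
               rep(config$satellite_conditions, each = config$replicates))
    samples <- paste(conds, sequence(rep(config$replicates,
                                         length(unique(conds)))), sep = "_")
    n <- nrow(truth); s <- length(samples)
    mu0 <- stats::runif(n, 3, 9)
    logmu <- matrix(mu0, n, s)
    # the planted fold-change is split symmetrically across the two
    # conditions; with balanced up/down calls the expected library size is
    # then identical in GM and DM, so CPM fold-changes carry no
    # composition bias
    logmu[, conds == "GM"] <- logmu[, conds == "GM"] - truth$true_lfc / 2
    logmu[, conds == "DM"] <- logmu[, conds == "DM"] + truth$true_lfc / 2
    # planted developmental profile of the up/down lncRNA sets
    lnc_up <- truth$biotype == "lncRNA" & truth$de_status == "up"
    lnc_dn <- truth$biotype == "lncRNA" & truth$de_status == "down"
    w <- conds %in% config$satellite_conditions
    if (any(w) && any(lnc_up))
      logmu[lnc_up, w] <- logmu[lnc_up, w] +
        matrix(satellite_profile(conds[w], 1), sum(lnc_up), sum(w),
               byrow = TRUE)
    if (any(w) && any(lnc_dn))
      logmu[lnc_dn, w] <- logmu[lnc_dn, w] +
        matrix(satellite_profile(conds[w], -1), sum(lnc_dn), sum(w),
               byrow = TRUE)
    # latent module factors across the developmental series (the C2C12
    # GM/DM samples are left untouched so the planted differential
    # expression stays cleanly NB); the loading is calibrated from each
    # feature's NB noise and the active-sample fraction so within-module
    # log-CPM correlation hits the target
    active <- conds %in% config$satellite_conditions
    if (any(active)) {
      frac <- sum(active) / s
      for (m in unique(truth$module[truth$module != "none"])) {
        idx <- which(truth$module == m)
        z <- as.vector(scale(stats::rnorm(sum(active))))
        mu_lin <- 2^mu0[idx]
        sigma2 <- (1 / mu_lin + config$phi) / log(2)^2
        alpha <- sqrt(config$module_r / (1 - config$module_r) * sigma2 / frac)
        logmu[idx, active] <- logmu[idx, active] + outer(alpha, z)
      }
    }
    mu <- 2^logmu
    counts <- if (config$phi > 0)
      matrix(stats::rnbinom(n * s, mu = mu, size = 1 / config$phi), n, s)
    else matrix(stats::rpois(n * s, lambda = mu), n, s)
    dimnames(counts) <- list(truth$feature_id, samples)
    count_matrix(counts, stats::setNames(truth$biotype, truth$feature_id),
                 conditions = conds)
  })
}

#' Simulate chromatin peaks and signal tracks
#'
#' For every lncRNA with an open category, an ATAC peak (400 bp, centred on
#' the TSS) is written for both conditions, with bedGraph signal over the
#' peak's 1 kb-extended span: up-regulated lncRNAs gain `atac_gain`-fold
#' signal in DM, down-regulated ones lose it, others stay flat (up to
#' lognormal noise). H3K4me1/H3K4me3 peaks are planted inside the extended
#' ATAC span according to the truth category; TF peaks are placed there
#' with probability `tf_bind_prob`, MyoD and MyoG jointly at the configured
#' co-localization rate. With `chromatin_noise > 0`, each planted mark or
#' ATAC peak is independently dropped with that probability.
#'
#' @param config A `sim_config`.
#' @param truth Truth table (gains `bound_tfs` ground-truth column).
#' @param annotation Output of [simulate_annotation()].
#' @return List: `atac_peaks` (per condition), `atac_signal` (per
#'   condition), `k4me1_peaks`, `k4me3_peaks`, `mark_signal`, `tf_peaks`
#'   (named list), `truth` (updated).
#' @export
simulate_chromatin <- function(config, truth, annotation) {
  tx <- annotation$transcripts
  with_seed(stage_seed(config, 4L), {
    lnc <- tx[tx$biotype == "lncRNA", , drop = FALSE]
    tr <- truth[match(lnc$transcript_id, truth$feature_id), ]
    tss <- transcript_tss(lnc)
    open <- tr$category != "closed"
    if (config$chromatin_noise > 0)
      open <- open & stats::runif(nrow(lnc)) >= config$chromatin_noise

    peak <- data.frame(chrom = lnc$chrom, start = tss - 200L,
                       end = tss + 200L, strand = ".",
                       stringsAsFactors = FALSE)[open, ]
    span <- data.frame(chrom = lnc$chrom, start = tss - 1200L,
                       end = tss + 1200L, stringsAsFactors = FALSE)[open, ]

    g_gm <- stats::rlnorm(sum(open), log(10), 0.2)
    status_open <- tr$de_status[open]
    mult <- ifelse(status_open == "up", config$atac_gain,
                   ifelse(status_open == "down", 1 / config$atac_gain,
                          exp(stats::rnorm(sum(open), 0, 0.05))))
    sig <- function(vals) {
      df <- data.frame(chrom = span$chrom, start = span$start,
                       end = span$end, value = round(vals, 4),
                       stringsAsFactors = FALSE)
      df[order(df$chrom, df$start), ]
    }
    atac_signal <- list(a = sig(g_gm), b = sig(g_gm * mult))

    mark_peak <- function(which_cat) {
      keep <- open & tr$category == which_cat
      if (config$chromatin_noise > 0)
        keep <- keep & stats::runif(nrow(lnc)) >= config$chromatin_noise
      sort_intervals(data.frame(chrom = lnc$chrom[keep],
                                start = tss[keep] + 300L,
                                end = tss[keep] + 700L, strand = ".",
                                stringsAsFactors = FALSE))
    }
    k4me1 <- mark_peak("ATAC_H3K4me1")
    k4me3 <- mark_peak("ATAC_H3K4me3")
    mark_sig <- function(peaks) {
      v <- stats::rlnorm(nrow(peaks), log(8), 0.2)
      list(a = data.frame(chrom = peaks$chrom, start = peaks$start - 500L,
                          end = peaks$end + 500L, value = round(v, 4)),
           b = data.frame(chrom = peaks$chrom, start = peaks$start - 500L,
                          end = peaks$end + 500L,
                          value = round(v * exp(stats::rnorm(nrow(peaks), 0,
                                                             0.1)), 4)))
    }

    tf_names <- sub("^TF_", "", tx$transcript_id[tx$is_tf])
    marked <- open & tr$category %in% c("ATAC_H3K4me1", "ATAC_H3K4me3")
    bound <- matrix(FALSE, nrow(lnc), length(tf_names),
                    dimnames = list(lnc$transcript_id, tf_names))
    for (f in tf_names)
      bound[marked, f] <- stats::runif(sum(marked)) < config$tf_bind_prob
    if (all(c("MyoD", "MyoG") %in% tf_names)) {
      joint <- stats::runif(sum(marked)) < config$myod_myog_coloc
      bound[marked, "MyoG"] <- ifelse(joint, bound[marked, "MyoD"],
                                      bound[marked, "MyoG"])
    }
    tf_peaks <- lapply(stats::setNames(tf_names, tf_names), function(f) {
      keep <- bound[, f]
      sort_intervals(data.frame(chrom = lnc$chrom[keep],
                                start = tss[keep] - 100L,
                                end = tss[keep] + 100L, strand = ".",
                                stringsAsFactors = FALSE))
    })
    truth$bound_tfs <- ""
    truth$bound_tfs[match(lnc$transcript_id, truth$feature_id)] <-
      apply(bound, 1, function(r) paste(tf_names[r], collapse = ","))
    truth$open_planted <- FALSE
    truth$open_planted[match(lnc$transcript_id, truth$feature_id)] <- open

    list(atac_peaks = list(a = sort_intervals(peak), b = sort_intervals(peak)),
         atac_signal = atac_signal,
         k4me1_peaks = k4me1, k4me3_peaks = k4me3,
         mark_signal = list(k4me1 = mark_sig(k4me1), k4me3 = mark_sig(k4me3)),
         tf_peaks = tf_peaks, truth = truth)
  })
}

#' Simulate motif-enrichment inputs
#'
#' Foreground regions are the ATAC peaks of open DE lncRNAs; background
#' regions are those of open non-DE lncRNAs. MyoD/MyoG consensus sequences
#' are written into the genome at random offsets within each foreground
#' region with probability `motif_fg_rate` per region (per motif) and into
#' background regions at `motif_bg_rate`.
#'
#' @param config A `sim_config`.
#' @param truth Truth table with `open_planted`.
#' @param annotation Output of [simulate_annotation()] (genome is mutated).
#' @param pwms PWM list whose consensus sequences are inserted (default the
#'   bundled MyoD/MyoG matrices).
#' @return List: `fg`, `bg` (interval data frames), `genome` (mutated),
#'   `insertions` (log data frame).
#' @export
simulate_motif_regions <- function(config, truth, annotation,
                                   pwms = default_pwms()[c("MyoD", "MyoG")]) {
  tx <- annotation$transcripts
  genome <- annotation$genome
  with_seed(stage_seed(config, 5L), {
    lnc <- tx[tx$biotype == "lncRNA", , drop = FALSE]
    tr <- truth[match(lnc$transcript_id, truth$feature_id), ]
    tss <- transcript_tss(lnc)
    regions <- data.frame(chrom = lnc$chrom, start = tss - 200L,
                          end = tss + 200L, strand = ".",
                          name = lnc$transcript_id, stringsAsFactors = FALSE)
    is_fg <- tr$open_planted & tr$de_status != "not_de"
    is_bg <- tr$open_planted & tr$de_status == "not_de"
    fg <- regions[is_fg, ]; bg <- regions[is_bg, ]
    ins <- list()
    plant <- function(reg, rate) {
      for (i in seq_len(nrow(reg))) {
        for (pwm in pwms) {
          if (stats::runif(1) >= rate) next
          cons <- pwm_consensus(pwm)
          w <- nchar(cons)
          off <- sample.int(reg$end[i] - reg$start[i] - w + 1, 1) - 1L
          pos <- reg$start[i] + off
          substr(genome[[reg$chrom[i]]], pos + 1, pos + w) <<- cons
          ins[[length(ins) + 1]] <<- data.frame(
            region = reg$name[i], motif = pwm$name, offset = off,
            stringsAsFactors = FALSE)
        }
      }
    }
    plant(fg, config$motif_fg_rate)
    plant(bg, config$motif_bg_rate)
    list(fg = fg, bg = bg, genome = genome,
         insertions = if (length(ins)) do.call(rbind, ins)
         else data.frame(region = character(), motif = character(),
                         offset = integer()))
  })
}

#' Generate the full synthetic study in memory
#'
#' Runs annotation, truth planting, counts, chromatin and motif simulation
#' in order and returns every object plus the gene sets (up- and
#' down-regulated lncRNA sets) used for enrichment analysis. Fully
#' deterministic for a fixed config.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_study` with components `config`,
#'   `transcripts`, `chrom_lengths`, `genome`, `truth`, `cm`, `chromatin`,
#'   `motif`, `sets`.
#' @export
simulate_study <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  truth <- simulate_truth(config, ann)
  cm <- simulate_counts(config, truth)
  chrom <- simulate_chromatin(config, truth, ann)
  truth <- chrom$truth
  motif <- simulate_motif_regions(config, truth, ann)
  sets <- list(
    up_lncRNAs = truth$feature_id[truth$biotype == "lncRNA" &
                                    truth$de_status == "up"],
    down_lncRNAs = truth$feature_id[truth$biotype == "lncRNA" &
                                      truth$de_status == "down"])
  structure(list(config = config, transcripts = ann$transcripts,
                 chrom_lengths = ann$chrom_lengths, genome = motif$genome,
                 truth = truth, cm = cm,
                 chromatin = chrom[setdiff(names(chrom), "truth")],
                 motif = motif[c("fg", "bg", "insertions")], sets = sets),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study: seed", x$config$seed, "-", nrow(x$truth), "features on",
      x$config$n_chrom, "chromosomes\n")
  print(table(biotype = x$truth$biotype, de = x$truth$de_status))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits every pipeline input as plain text: `ann.gtf`, `genome.fa`,
#' `counts.tsv`, per-condition ATAC peak BEDs and signal bedGraphs,
#' histone-mark BEDs and bedGraphs, per-TF BEDs, `fg.bed`/`bg.bed`,
#' `sets.gmt`, and the ground truth under `truth_features.tsv`.
#'
#' @param study A `sim_study`.
#' @param outdir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  ch <- study$chromatin
  write_gtf(study$transcripts, p("ann.gtf"))
  write_fasta(study$genome, p("genome.fa"))
  write_counts(study$cm, p("counts.tsv"))
  write_bed(ch$atac_peaks$a, p("atac_gm.bed"))
  write_bed(ch$atac_peaks$b, p("atac_dm.bed"))
  write_bedgraph(ch$atac_signal$a, p("atac_gm.bedgraph"))
  write_bedgraph(ch$atac_signal$b, p("atac_dm.bedgraph"))
  write_bed(ch$k4me1_peaks, p("k4me1.bed"))
  write_bed(ch$k4me3_peaks, p("k4me3.bed"))
  write_bedgraph(ch$mark_signal$k4me1$a, p("k4me1_gm.bedgraph"))
  write_bedgraph(ch$mark_signal$k4me1$b, p("k4me1_dm.bedgraph"))
  write_bedgraph(ch$mark_signal$k4me3$a, p("k4me3_gm.bedgraph"))
  write_bedgraph(ch$mark_signal$k4me3$b, p("k4me3_dm.bedgraph"))
  for (tf in names(ch$tf_peaks))
    write_bed(ch$tf_peaks[[tf]], p(paste0("tf_", tf, ".bed")))
  write_bed(study$motif$fg, p("fg.bed"))
  write_bed(study$motif$bg, p("bg.bed"))
  write_gmt(study$sets, p("sets.gmt"))
  utils::write.table(study$truth, p("truth_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c("ann.gtf", "genome.fa", "counts.tsv", "atac_gm.bed",
             "atac_dm.bed", "atac_gm.bedgraph", "atac_dm.bedgraph",
             "k4me1.bed", "k4me3.bed", "fg.bed", "bg.bed", "sets.gmt",
             "truth_features.tsv",
             paste0("tf_", names(ch$tf_peaks), ".bed"))
  stats::setNames(file.path(outdir, files), files)
}

#' Cross-validate a study's truth table against its generated data
#'
#' Self-check run in tests: every lncRNA planted with an open category has
#' an ATAC peak overlapping its TSS window, closed lncRNAs have none;
#' planted mark categories have a matching mark peak overlapping the
#' extended ATAC span; every truth `bound_tfs` entry has a TF peak there.
#'
#' @param study A `sim_study`.
#' @return TRUE invisibly; stops with a message on any inconsistency.
#' @export
validate_truth <- function(study) {
  tx <- study$transcripts
  lnc <- tx[tx$biotype == "lncRNA", ]
  tr <- study$truth[match(lnc$transcript_id, study$truth$feature_id), ]
  windows <- make_tss_windows(lnc, study$config$upstream,
                              study$config$downstream, study$chrom_lengths)
  merged <- merge_peaks(study$chromatin$atac_peaks)
  open <- assign_open_chromatin(windows, merged)
  if (!identical(unname(open), tr$open_planted))
    stop("open-chromatin truth inconsistent with generated ATAC peaks")
  ext <- extend_peaks(merged, study$config$flank, study$chrom_lengths)
  cat_obs <- classify_category(windows, ext, study$chromatin$k4me1_peaks,
                               study$chromatin$k4me3_peaks)
  expected <- ifelse(tr$open_planted, tr$category, "closed")
  if (study$config$chromatin_noise == 0 &&
      !identical(unname(cat_obs), unname(expected)))
    stop("planted categories inconsistent with generated peaks")
  bound <- associate_tfs(windows, ext, study$chromatin$tf_peaks)
  obs <- vapply(bound, function(s) paste(sort(s), collapse = ","), "")
  want <- vapply(strsplit(tr$bound_tfs, ","), function(s)
    paste(sort(s[nzchar(s)]), collapse = ","), "")
  if (!identical(unname(obs), unname(want)))
    stop("planted TF binding inconsistent with generated TF peaks")
  invisible(TRUE)
}
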