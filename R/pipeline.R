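# End-to-end orchestration: a validated YAML config, stage functions over
# files, and a run manifest with input/output hashes.

pipeline_defaults <- function() {
  list(seed = 1,
       outdir = "lncstate_out",
       cond_a = "GM", cond_b = "DM",
       gsea_contrasts = list(c("W2", "W6"), c("W2", "W12")),
       alpha = 0.05, lfc = 1, cpm_min = 1,
       upstream = 2500, downstream = 1500, flank = 1000,
       weight_min = 0.05, p_max = 0.01,
       nperm = 1000,
       motif_threshold = 0.6,
       simulate = TRUE)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults for every absent key
#' (thresholds: TSS window 2500/1500 bp, ATAC flank 1000 bp, alpha 0.05,
#' |log2FC| 1, CPM floor 1, network weight 0.05 / p 0.01), and rejects
#' unknown keys and non-positive thresholds.
#'
#' @param path Path to a YAML config file, or a named list.
#' @return Validated `pipeline_config` list.
#' @export
validate_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (is.list(path)) path
  else {
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) list() else raw
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(user)] <- user
  num_keys <- c("alpha", "lfc", "cpm_min", "upstream", "downstream", "flank",
                "weight_min", "p_max", "nperm", "motif_threshold")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop("config key '", k, "' must be a positive number")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' @rdname validate_config
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths[file.exists(paths)])
  stats::setNames(unname(h), basename(names(h)))
}

#' Run the full pipeline
#'
#' Stages, in dependency order: simulate (optional) -> differential
#' expression -> chromatin-state annotation -> co-expression network ->
#' pre-ranked GSEA -> motif enrichment. Each stage writes TSV outputs under
#' `config$outdir` and records parameter snapshots plus MD5 hashes of its
#' outputs in the returned manifest; reruns with an identical config and
#' seed reproduce the hashes of every deterministic stage.
#'
#' @param config A `pipeline_config` (see [validate_config()]).
#' @return List of class `run_manifest`: `stages` (data frame of stage,
#'   status, seconds), `hashes` (per-stage named MD5 vectors), `params`,
#'   and the in-memory stage results under `results`.
#' @export
run_all <- function(config = validate_config()) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(); hashes <- list(); results <- list()
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages[[name]] <<- data.frame(
      stage = name, status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      stringsAsFactors = FALSE)
    res
  }

  study <- t_stage("simulate", function() {
    if (!isTRUE(config$simulate))
      stop("file-based input mode requires simulate: true in this release")
    study <- simulate_study(sim_config(seed = config$seed))
    files <- write_study(study, file.path(outdir, "data"))
    hashes[["simulate"]] <<- hash_files(files)
    study
  })
  results$study <- study

  de <- t_stage("de", function() {
    de <- de_test(study$cm, config$cond_a, config$cond_b,
                  alpha = config$alpha, lfc_threshold = config$lfc)
    de <- filter_low_expression(de, config$cpm_min)
    f <- file.path(outdir, "de.tsv")
    utils::write.table(de, f, sep = "\t", quote = FALSE, row.names = FALSE)
    hashes[["de"]] <<- hash_files(f)
    de
  })
  results$de <- de

  chromstate <- t_stage("chromstate", function() {
    ch <- study$chromatin
    ann <- annotate_chromatin_state(
      de, study$transcripts, ch$atac_peaks, ch$atac_signal,
      ch$k4me1_peaks, ch$k4me3_peaks, mark_signal = ch$mark_signal,
      tf_peaks = ch$tf_peaks, chrom_lengths = study$chrom_lengths,
      upstream = config$upstream, downstream = config$downstream,
      flank = config$flank, seed = config$seed)
    f <- file.path(outdir, "chromstate.tsv")
    utils::write.table(ann$annotation, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    hashes[["chromstate"]] <<- hash_files(f)
    ann
  })
  results$chromstate <- chromstate

  network <- t_stage("network", function() {
    de_ids <- de$feature_id[de$status != "not_de"]
    tf_ids <- intersect(de_ids,
                        study$truth$feature_id[study$truth$is_tf])
    lnc_ids <- intersect(de_ids,
                         study$truth$feature_id[study$truth$biotype ==
                                                  "lncRNA"])
    net <- coexpression_network(
      study$cm, de_ids, tf_ids, lnc_ids,
      weight_min = config$weight_min, p_max = config$p_max,
      conditions = sim_config()$satellite_conditions)
    f1 <- file.path(outdir, "edges.tsv")
    f2 <- file.path(outdir, "modules.tsv")
    utils::write.table(net$tf_lnc_edges, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(net$modules, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    hashes[["network"]] <<- hash_files(c(f1, f2))
    net
  })
  results$network <- network

  gsea <- t_stage("gsea", function() {
    rows <- lapply(config$gsea_contrasts, function(ct) {
      res <- gsea_preranked(study$cm, ct[1], ct[2], study$sets,
                            n_perm = config$nperm, seed = config$seed)
      res$contrast <- paste(ct[2], "vs", ct[1])
      res
    })
    out <- do.call(rbind, rows)
    f <- file.path(outdir, "gsea.tsv")
    utils::write.table(out[, c("contrast", setdiff(names(out), "contrast"))],
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    hashes[["gsea"]] <<- hash_files(f)
    out
  })
  results$gsea <- gsea

  motif <- t_stage("motif", function() {
    enr <- motif_enrichment(study$motif$fg, study$motif$bg, study$genome,
                            default_pwms(),
                            threshold_frac = config$motif_threshold)
    f <- file.path(outdir, "motif.tsv")
    utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    hashes[["motif"]] <<- hash_files(f)
    enr
  })
  results$motif <- motif

  manifest <- structure(list(stages = do.call(rbind, stages),
                             hashes = hashes,
                             params = unclass(config),
                             results = results),
                        class = "run_manifest")
  mf <- file.path(outdir, "manifest.tsv")
  man_df <- do.call(rbind, lapply(names(hashes), function(s)
    data.frame(stage = s, file = names(hashes[[s]]),
               md5 = unname(hashes[[s]]), stringsAsFactors = FALSE)))
  utils::write.table(man_df, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest: seed", x$params$seed, "\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
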