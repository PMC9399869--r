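# End-to-end orchestration: reads inputs, runs every analysis stage that
# its inputs allow, and writes all intermediate tables to a report
# directory.  Deterministic given (inputs, seed).

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) { col[is.na(col)] <- "."; col })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param transcripts path to the transcript FASTA (required).
#' @param genome optional path to a genomic contig FASTA.
#' @param counts optional path to a count TSV (`transcript_id`, sample
#'   columns, `effective_length`).
#' @param go optional path to an annotation TSV (`transcript_id`, `term`).
#' @param out_dir report directory (created if missing).
#' @param species SL system (`"psinerae"`, `"mnigrum"`, `"spi"`).
#' @param seed integer seed for the permutation stage.
#' @param window 5'-end motif search window (nt).
#' @param min_pid genome-scan exon identity threshold.
#' @param min_intron minimum SL-RNA intron length (nt).
#' @param polyt_window poly-T search window after the donor (nt).
#' @param consensus_threshold majority threshold for the consensus.
#' @param n_perm permutation samples for enrichment.
#' @param alpha enrichment significance threshold.
#' @param reference_sles optional named character vector of reference SL
#'   exons added to the parsimony analysis.
#' @return configuration list of class `sl_pipeline_config`.
#' @export
pipeline_config <- function(transcripts, genome = NULL, counts = NULL,
                            go = NULL, out_dir = "sl_report",
                            species = "psinerae", seed = 1L, window = 100L,
                            min_pid = 0.95, min_intron = 40L,
                            polyt_window = 120L, consensus_threshold = 0.6,
                            n_perm = 10000L, alpha = 0.05,
                            reference_sles = NULL) {
  structure(as.list(environment()), class = "sl_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return an `sl_pipeline_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Run the full SL analysis pipeline
#'
#' Stages (each skipped cleanly when its input is absent): SL detection and
#' classification; partition summary; consensus, position-frequency-matrix
#' and composition summaries; SL-RNA genome scan; TPM normalization and
#' pool abundance comparison; permutation GO enrichment; parsimony tree of
#' per-type SLe consensus sequences plus any reference SLes.  All
#' intermediate tables are written as TSV under `config$out_dir` and every
#' threshold used is logged to `run_log.txt`.
#'
#' @param config an [pipeline_config()] object.
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sl_pipeline_config"))
  if (is.null(config$transcripts) || !file.exists(config$transcripts))
    stop("config error: transcript FASTA missing (", config$transcripts, ")",
         call. = FALSE)
  for (f in c("genome", "counts", "go"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config error: ", f, " path does not exist: ", config[[f]],
           call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("sltrans pipeline | species=%s seed=%d", config$species, config$seed)
  logf("thresholds: window=%d min_pid=%.2f min_intron=%d polyt_window=%d consensus=%.2f n_perm=%d alpha=%.3f",
       config$window, config$min_pid, config$min_intron, config$polyt_window,
       config$consensus_threshold, config$n_perm, config$alpha)
  res <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sys <- generate_sl_system(config$species)
  transcripts <- run_stage("read", read_fasta(config$transcripts))
  calls <- run_stage("detect", detect_sl(transcripts, sys, config$window))
  res$calls <- calls
  write_tsv(calls[, c("transcript_id", "orientation", "motif_start",
                      "observed_extent", "sl_type", "complete",
                      "residual_len")],
            file.path(config$out_dir, "calls.tsv"))

  part <- run_stage("partition", partition_summary(calls))
  res$partition <- part
  write_partition_tsv(part, file.path(config$out_dir, "partition.tsv"))

  obs <- calls$observed_sle[calls$orientation != "none"]
  if (length(obs) > 0) {
    pfm <- run_stage("pfm", position_frequency_matrix(obs, sys$sle_length))
    res$pfm <- pfm
    pfm_df <- data.frame(position = seq_len(ncol(pfm$freq)),
                         t(pfm$freq), info_bits = pfm$info,
                         coverage = pfm$coverage)
    write_tsv(pfm_df, file.path(config$out_dir, "pfm.tsv"))
    cons <- character(0)
    for (type in setdiff(unique(calls$sl_type), c("none", "incomplete"))) {
      full <- calls$observed_sle[calls$sl_type == type &
                                   calls$observed_extent == sys$sle_length]
      if (length(full) > 0)
        cons[type] <- build_consensus(full, config$consensus_threshold)
    }
    res$consensus <- cons
    if (length(cons) > 0)
      write_fasta(cons, file.path(config$out_dir, "consensus.fasta"))
    comp <- t(vapply(
      stats::setNames(nm = names(cons)),
      function(t) nucleotide_composition(cons[[t]]), numeric(4)))
    if (length(cons) > 0)
      write_tsv(data.frame(sl_type = rownames(comp), comp),
                file.path(config$out_dir, "composition.tsv"))
    res$extent_distribution <- partial_length_distribution(calls)
    res$missed_sl_estimate <- estimate_missed_sl_fraction(
      calls$observed_extent[calls$orientation != "none"], sys$sle_length)
    logf("detected %d SL-bearing transcripts; missed-SL estimate %.4f",
         sum(calls$orientation != "none"), as.numeric(res$missed_sl_estimate))
  }

  if (!is.null(config$genome)) {
    contigs <- run_stage("scan", read_fasta(config$genome))
    scan <- run_stage("scan", scan_genome(sys, contigs, config$min_pid,
                                          config$min_intron,
                                          config$polyt_window))
    res$scan <- scan
    if (!is.null(scan$candidates) && nrow(scan$candidates) > 0) {
      write_tsv(scan$candidates[, setdiff(names(scan$candidates), "full_seq")],
                file.path(config$out_dir, "candidates.tsv"))
      write_candidates_gff3(scan$candidates,
                            file.path(config$out_dir, "candidates.gff3"))
    }
    logf("genome scan: %s",
         paste(names(scan$counts), scan$counts, sep = "=", collapse = " "))
  }

  if (!is.null(config$counts)) {
    cts <- run_stage("abundance",
                     read.table(config$counts, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
    ab <- run_stage("abundance", tpm_normalize(cts))
    res$abundance <- ab
    write_tsv(data.frame(transcript_id = ab$transcript_id, ab$tpm,
                         mean_tpm = ab$mean_tpm),
              file.path(config$out_dir, "tpm.tsv"))
    cmp <- run_stage("abundance", compare_sl_pools(ab, calls))
    res$pool_comparison <- cmp
    tests <- cmp$pairwise
    if (!is.null(cmp$kruskal_wallis))
      tests <- rbind(data.frame(pool_a = "all", pool_b = "all",
                                statistic = cmp$kruskal_wallis$statistic,
                                p_value = cmp$kruskal_wallis$p_value,
                                n_a = cmp$n_obs, n_b = NA, median_a = NA,
                                median_b = NA, stringsAsFactors = FALSE),
                     tests)
    write_tsv(tests, file.path(config$out_dir, "tests.tsv"))
  }

  if (!is.null(config$go)) {
    go <- run_stage("enrich",
                    read.table(config$go, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
    annot <- run_stage("enrich",
                       annotation_map(go, universe = calls$transcript_id))
    enr <- run_stage("enrich",
                     enrich_pools(calls, annot, alpha = config$alpha,
                                  n_perm = config$n_perm,
                                  seed = config$seed))
    res$enrichment <- enr
    write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
  }

  taxa <- c(res$consensus %||% character(0), config$reference_sles)
  if (length(taxa) >= 3L) {
    aln <- run_stage("phylo", align_sl_set(taxa))
    srch <- run_stage("phylo", exhaustive_parsimony_search(aln))
    res$parsimony <- srch
    ape::write.tree(srch$trees,
                    file.path(config$out_dir, "tree.nwk"))
    write_tsv(branch_changes(srch$trees[[1L]], aln),
              file.path(config$out_dir, "branch_changes.tsv"))
    logf("parsimony: %d taxa, best score %d over %d topologies",
         nrow(aln), srch$score, srch$n_topologies)
  }
  invisible(res)
}
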