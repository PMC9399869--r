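# Synthetic-data generator: transcriptomes, genomes, counts and GO
# annotations with known ground truth, emulating the statistical structure
# the SL analysis assumes (5'-truncation noise on SL exons, SL-RNA gene loci
# with donor + poly-T terminator, per-pool abundance shifts and planted
# enriched GO terms).

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# remove exact occurrences of the SL octamer (either strand) so that ground
# truth is never confounded by chance motif hits in simulated backgrounds
scrub_motif <- function(seqs, motif = SL_TAIL) {
  for (pat in c(motif, revcomp(motif))) {
    sub5 <- if (substr(pat, 5L, 5L) == "A") "C" else "A"
    repl <- paste0(substr(pat, 1L, 4L), sub5, substr(pat, 6L, nchar(pat)))
    has <- grepl(pat, seqs, fixed = TRUE)
    while (any(has)) {
      seqs[has] <- sub(pat, repl, seqs[has], fixed = TRUE)
      has <- grepl(pat, seqs, fixed = TRUE)
    }
  }
  seqs
}

# cap T-runs so simulated intron cores and decoys cannot carry an
# unintended poly-T terminator
scrub_polyt <- function(seqs) {
  while (any(grepl("TTTT", seqs, fixed = TRUE)))
    seqs <- sub("TTTT", "TTAT", seqs, fixed = TRUE)
  seqs
}

polyt_tract_seq <- function(pattern) {
  switch(pattern,
         perkinsozoa = "CTTTTTG",   # CT(4-6) G/C
         spi         = "CTTTTTA",   # CT(5) A
         dino        = "CTTTTTTTG", # CT(4-7) G/A
         stop("unknown poly-T pattern: ", pattern, call. = FALSE))
}

#' Generator configuration with study-condition defaults
#'
#' Central knobs of the synthetic bundle.  Defaults reflect the regime the
#' analysis is designed for: a fifth to a quarter of transcripts
#' SL-bearing, 5' truncation drawn from a rounded normal with mean 6 and sd
#' 4 nt (clipped to the exon), a 2-fold abundance shift on the first SL
#' pool, GO terms at 5% background frequency with one fourfold-enriched
#' term planted per SL pool, and a genome carrying three SL-RNA loci of the
#' first type and one of the second, plus donor/terminator-broken decoys.
#'
#' @param species `"psinerae"` (two SL types), `"mnigrum"` or `"spi"`
#'   (single type).
#' @param ... overrides for any default listed below.
#' @return a plain list of generator parameters.
#' @export
sl_generator_config <- function(species = "psinerae", ...) {
  multi <- species == "psinerae"
  cfg <- list(
    species = species,
    n_transcripts = 2000L,
    type_fractions = if (multi) c(type1 = 0.21, type2 = 0.06)
                     else c(single = 0.20),
    frac_pairs = 0.005,        # SL+/- isoform pairs (share one body)
    frac_cross = if (multi) 0.002 else 0,
    trunc_mean = 6, trunc_sd = 4,
    frac_residual = 0.05, residual_max = 20L,
    body_len_range = c(300L, 600L),
    n_samples = 3L,
    count_meanlog = 4, count_sdlog = 1.2, sample_noise_sdlog = 0.1,
    shift = 2.0,               # multiplicative abundance shift, first pool
    n_terms = 40L, go_background = 0.05, planted_fold = 4,
    n_contigs = 4L, contig_length = 10000L,
    loci_per_type = if (multi) c(type1 = 3L, type2 = 1L) else c(single = 3L),
    tandem_size = 1L, tandem_spacer = 100L,
    n_decoy_donor = 1L, n_decoy_polyt = 1L,
    n_genes = 4L, n_cis_genes = 1L, utr_length = 60L)
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(all(cfg$type_fractions >= 0), sum(cfg$type_fractions) <= 1,
            cfg$shift > 0, cfg$n_transcripts >= 1)
  cfg
}

#' Generate a synthetic transcriptome with ground truth
#'
#' SL-bearing transcripts carry a (possibly 5'-truncated) SL exon prepended
#' to a random body; truncation counts are drawn from the configured normal,
#' rounded and clipped to `[0, SLe length]`.  Full exon loss leaves the body
#' unmarked (recorded as `full_loss` in the truth; the transcript keeps its
#' true type for recovery statistics).  A small fraction of non-SL
#' transcripts reuse the body of an SL transcript (SL+/- isoform pairs), and
#' in two-type systems a small fraction of second-type transcripts reuse a
#' first-type body (cross-type species).  Counts are log-normal with the
#' multiplicative shift applied to the first SL pool; GO terms are assigned
#' i.i.d. at background frequency except the planted per-pool terms, whose
#' in-pool frequency is `planted_fold` times background.
#'
#' @param sl_system an [generate_sl_system()] definition.
#' @param config an [sl_generator_config()] list.
#' @param seed integer seed; the bundle is deterministic given (config, seed).
#' @return list with `transcripts` (named character), `counts` (data.frame:
#'   `transcript_id`, sample columns, `effective_length`), `go` (data.frame:
#'   `transcript_id`, `term`), `truth` (per-transcript data.frame) and
#'   `planted_terms` (data.frame: `pool`, `term`, `fold`).
#' @export
generate_transcriptome <- function(sl_system, config, seed = 1L) {
  set.seed(seed)
  n <- config$n_transcripts
  L <- sl_system$sle_length
  types <- names(sl_system$types)
  fr <- config$type_fractions
  if (!setequal(names(fr), types))
    stop("type_fractions names must match the SL system types", call. = FALSE)

  n_type <- stats::setNames(round(fr * n), names(fr))
  true_type <- rep("none", n)
  idx <- 1L
  for (t in names(n_type)) {
    if (n_type[[t]] > 0)
      true_type[idx:(idx + n_type[[t]] - 1L)] <- t
    idx <- idx + n_type[[t]]
  }
  true_type <- sample(true_type)          # shuffle pool membership

  body_len <- sample(config$body_len_range[1L]:config$body_len_range[2L],
                     n, replace = TRUE)
  bodies <- scrub_motif(random_dna(n, max(body_len)))
  bodies <- substr(bodies, 1L, body_len)

  is_sl <- true_type != "none"
  trunc <- integer(n)
  if (any(is_sl)) {
    raw <- round(rnorm(sum(is_sl), config$trunc_mean, config$trunc_sd))
    trunc[is_sl] <- pmin(pmax(raw, 0L), L)
  }

  # cross-type species: a second-type transcript reuses a first-type body
  n_cross <- round(config$frac_cross * n)
  cross_ids <- integer(0)
  if (n_cross > 0 && length(types) >= 2L) {
    a <- which(true_type == types[1L] & trunc == 0L)
    b <- which(true_type == types[2L] & trunc == 0L)
    n_cross <- min(n_cross, length(a), length(b))
    if (n_cross > 0) {
      a <- a[seq_len(n_cross)]; b <- b[seq_len(n_cross)]
      bodies[b] <- bodies[a]
      cross_ids <- b
    }
  }

  # SL+/- isoform pairs: a non-SL transcript reuses an SL transcript's body
  n_pairs <- round(config$frac_pairs * n)
  pair_ids <- integer(0)
  if (n_pairs > 0) {
    sl_ok <- setdiff(which(is_sl & trunc < L), cross_ids)
    no_ok <- which(!is_sl)
    n_pairs <- min(n_pairs, length(sl_ok), length(no_ok))
    if (n_pairs > 0) {
      donors <- sl_ok[seq_len(n_pairs)]
      pair_ids <- no_ok[seq_len(n_pairs)]
      bodies[pair_ids] <- bodies[donors]
    }
  }

  residual <- character(n)
  resid_idx <- which(is_sl & trunc == 0L &
                       runif(n) < config$frac_residual)
  if (length(resid_idx) > 0) {
    rl <- sample.int(config$residual_max, length(resid_idx), replace = TRUE)
    residual[resid_idx] <- substr(scrub_motif(random_dna(length(resid_idx),
                                                         config$residual_max)),
                                  1L, rl)
  }

  seqs <- bodies
  for (i in which(is_sl)) {
    sle <- sl_system$types[[true_type[i]]]
    remnant <- substr(sle, trunc[i] + 1L, L)
    seqs[i] <- paste0(residual[i], remnant, bodies[i])
  }
  ids <- sprintf("tx%04d", seq_len(n))
  names(seqs) <- ids

  # counts: log-normal base abundance, shift on the first SL pool,
  # mild per-sample multiplicative noise
  shifted_pool <- types[1L]
  base <- rlnorm(n, config$count_meanlog, config$count_sdlog)
  base[true_type == shifted_pool] <- base[true_type == shifted_pool] * config$shift
  counts <- sapply(seq_len(config$n_samples), function(s)
    base * rlnorm(n, 0, config$sample_noise_sdlog))
  colnames(counts) <- sprintf("S%d", seq_len(config$n_samples))
  counts_df <- data.frame(transcript_id = ids, counts,
                          effective_length = nchar(bodies),
                          stringsAsFactors = FALSE)

  # GO annotations with planted per-pool enriched terms
  terms <- sprintf("GO:%07d", seq_len(config$n_terms))
  planted <- data.frame(pool = types,
                        term = terms[seq_along(types)],
                        fold = config$planted_fold,
                        stringsAsFactors = FALSE)
  prob <- matrix(config$go_background, n, config$n_terms)
  for (k in seq_len(nrow(planted))) {
    in_pool <- true_type == planted$pool[k]
    prob[in_pool, match(planted$term[k], terms)] <-
      min(config$planted_fold * config$go_background, 1)
  }
  hits <- matrix(rbinom(n * config$n_terms, 1L, as.vector(prob)),
                 n, config$n_terms) == 1L
  wh <- which(hits, arr.ind = TRUE)
  go <- data.frame(transcript_id = ids[wh[, 1L]], term = terms[wh[, 2L]],
                   stringsAsFactors = FALSE)
  go <- go[order(go$transcript_id, go$term), , drop = FALSE]
  rownames(go) <- NULL

  truth <- data.frame(
    transcript_id = ids, true_type = true_type, truncation = trunc,
    full_loss = is_sl & trunc >= L,
    detectable = is_sl & trunc <= L - nchar(sl_system$motif),
    residual_len = nchar(residual),
    base_abundance = base,
    isoform_pair = seq_len(n) %in% pair_ids,
    cross_type = seq_len(n) %in% cross_ids,
    stringsAsFactors = FALSE)

  list(transcripts = seqs, counts = counts_df, go = go, truth = truth,
       planted_terms = planted)
}

#' Generate synthetic genomic contigs with planted SL-RNA loci
#'
#' Background contigs are i.i.d. uniform A/C/G/T.  Each planted SL-RNA locus
#' is the full SL exon followed by an intron that begins with the `GTA` of
#' the conserved exon/intron `GGTA` cleavage motif (so the splice donor is
#' `GT`) and ends in the system's poly-T terminator tract; every planted
#' locus satisfies the genome-scan validation rules by construction.
#' Optional decoys break exactly one rule each (donor `GT -> CT`, or poly-T
#' tract replaced by T-run-free sequence) and are labelled in the truth.
#' Optionally, gene loci are embedded whose 5' UTR lacks the SL exon and
#' ends in an acceptor `AG` immediately before the gene body (plus,
#' optionally, cis-encoded decoy genes whose UTR does contain the SLe).
#'
#' @param sl_system an [generate_sl_system()] definition.
#' @param config an [sl_generator_config()] list.
#' @param seed integer seed.
#' @param gene_bodies optional named character vector of mature transcript
#'   bodies to embed as gene loci (first `n_genes` used as trans-spliced
#'   genes, next `n_cis_genes` as cis-encoded decoys).
#' @return list with `contigs` (named character), `loci` (truth data.frame:
#'   contig, 1-based exon/locus intervals, type, kind) and `genes` (truth
#'   data.frame for embedded gene loci).
#' @export
generate_genome <- function(sl_system, config, seed = 1L, gene_bodies = NULL) {
  set.seed(seed + 1L)
  contigs <- scrub_motif(random_dna(config$n_contigs, config$contig_length))
  names(contigs) <- sprintf("contig%02d", seq_len(config$n_contigs))
  occupied <- lapply(contigs, function(x) cbind(start = integer(0), end = integer(0)))

  polyt <- polyt_tract_seq(sl_system$polyt_pattern)
  make_locus <- function(type, kind) {
    sle <- sl_system$types[[type]]
    core_len <- sl_system$intron_length - 3L - nchar(polyt)
    core <- scrub_polyt(scrub_motif(random_dna(1L, max(core_len, 0L))))
    tract <- if (kind == "decoy_polyt")
      scrub_polyt(random_dna(1L, nchar(polyt))) else polyt
    intron <- paste0("GTA", core, tract)
    if (kind == "decoy_donor") substr(intron, 1L, 1L) <- "C"
    paste0(sle, intron)
  }

  place <- function(insert, margin = 200L) {
    for (attempt in 1:200) {
      ci <- sample.int(length(contigs), 1L)
      maxs <- nchar(contigs[[ci]]) - nchar(insert) - margin
      if (maxs <= margin + 1L) next
      s <- sample(margin:maxs, 1L)
      e <- s + nchar(insert) - 1L
      occ <- occupied[[ci]]
      if (nrow(occ) > 0 &&
          any(s <= occ[, "end"] + margin & e >= occ[, "start"] - margin)) next
      substr(contigs[[ci]], s, e) <<- insert
      occupied[[ci]] <<- rbind(occ, cbind(start = s, end = e))
      return(list(contig = names(contigs)[ci], start = s, end = e))
    }
    stop("could not place locus: contigs too small for the requested layout",
         call. = FALSE)
  }

  loci <- NULL
  add_locus_row <- function(type, kind, pos, offset_exon) {
    L <- sl_system$sle_length
    loci <<- rbind(loci, data.frame(
      contig = pos$contig, type = type, kind = kind,
      exon_start = pos$start + offset_exon,
      exon_end = pos$start + offset_exon + L - 1L,
      locus_start = pos$start + offset_exon,
      locus_end = pos$start + offset_exon + L + sl_system$intron_length - 1L,
      stringsAsFactors = FALSE))
  }

  for (type in names(config$loci_per_type)) {
    for (r in seq_len(config$loci_per_type[[type]])) {
      k <- config$tandem_size
      # copies within one tandem array are identical, as for a recent repeat
      units <- rep(make_locus(type, "locus"), k)
      spacers <- if (k > 1L)
        scrub_polyt(scrub_motif(random_dna(k - 1L, config$tandem_spacer)))
      else character(0)
      block <- units[1L]
      offs <- 0L
      for (i in seq_len(k - 1L)) {
        block <- paste0(block, spacers[i], units[i + 1L])
        offs <- c(offs, nchar(block) - nchar(units[i + 1L]))
      }
      pos <- place(block)
      for (o in offs) add_locus_row(type, "locus", pos, o)
    }
  }
  decoy_type <- names(config$loci_per_type)[1L]
  for (r in seq_len(config$n_decoy_donor %||% 0L)) {
    pos <- place(make_locus(decoy_type, "decoy_donor"))
    add_locus_row(decoy_type, "decoy_donor", pos, 0L)
  }
  for (r in seq_len(config$n_decoy_polyt %||% 0L)) {
    pos <- place(make_locus(decoy_type, "decoy_polyt"))
    add_locus_row(decoy_type, "decoy_polyt", pos, 0L)
    # keep the terminator search window downstream of this decoy free of
    # chance T-runs, so its truth label (no poly-T) is exact
    wend <- min(pos$end + 150L, nchar(contigs[[pos$contig]]))
    substr(contigs[[pos$contig]], pos$start, wend) <-
      scrub_polyt(substr(contigs[[pos$contig]], pos$start, wend))
  }

  genes <- NULL
  if (!is.null(gene_bodies) && length(gene_bodies) > 0) {
    n_trans <- min(config$n_genes, length(gene_bodies))
    n_cis <- min(config$n_cis_genes,
                 max(length(gene_bodies) - n_trans, 0L))
    sle1 <- sl_system$types[[1L]]
    for (j in seq_len(n_trans + n_cis)) {
      cis <- j > n_trans
      utr <- scrub_motif(random_dna(1L, config$utr_length))
      if (cis)
        utr <- paste0(substr(utr, 1L, 20L), sle1,
                      substr(utr, 21L + nchar(sle1), config$utr_length))
      insert <- paste0(utr, "AG", gene_bodies[[j]])
      pos <- place(insert, margin = 250L)
      genes <- rbind(genes, data.frame(
        contig = pos$contig,
        transcript_id = names(gene_bodies)[j],
        body_start = pos$start + nchar(utr) + 2L,
        body_end = pos$end,
        cis_encoded = cis, stringsAsFactors = FALSE))
    }
  }

  list(contigs = contigs, loci = loci, genes = genes)
}

#' Generate a complete synthetic SL bundle
#'
#' Convenience wrapper producing a matched transcriptome and genome: the
#' genome embeds SL-RNA loci plus gene loci for a few of the generated
#' SL transcripts (and one cis-encoded decoy gene).  With a `dir`, writes
#' `transcripts.fasta`, `genome.fasta`, `counts.tsv`, `go.tsv` and
#' `truth.tsv`.
#'
#' @param config an [sl_generator_config()] list.
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return list with `sl_system`, `transcriptome`, `genome` and (if written)
#'   `dir`.
#' @export
simulate_sl_bundle <- function(config = sl_generator_config(), seed = 1L,
                               dir = NULL) {
  sys <- generate_sl_system(config$species)
  tr <- generate_transcriptome(sys, config, seed)
  usable <- with(tr$truth, which(detectable & !cross_type & !isoform_pair))
  usable <- head(usable, config$n_genes + config$n_cis_genes)
  bodies <- vapply(usable, function(i) {
    sle_seen <- sys$sle_length - tr$truth$truncation[i]
    substr(tr$transcripts[[i]],
           tr$truth$residual_len[i] + sle_seen + 1L,
           nchar(tr$transcripts[[i]]))
  }, "")
  names(bodies) <- names(tr$transcripts)[usable]
  gen <- generate_genome(sys, config, seed, gene_bodies = bodies)
  out <- list(sl_system = sys, transcriptome = tr, genome = gen)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(tr$transcripts, file.path(dir, "transcripts.fasta"))
    write_fasta(gen$contigs, file.path(dir, "genome.fasta"))
    write.table(tr$counts, file.path(dir, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(tr$go, file.path(dir, "go.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(tr$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$dir <- dir
  }
  out
}
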