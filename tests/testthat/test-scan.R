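# SL-RNA gene discovery: exon search, poly-T tracts, validation rules,
# deduplication, tandem context, Sm motifs, trans-splice verification.

test_that("short_match_search applies the identity threshold arithmetic", {
  sys <- generate_sl_system("psinerae")
  sle <- sys$types$type1                       # 28-mer
  set.seed(5)
  bg <- function(n) gsub("GGCTCAAG|CTTGAGCC", "GGGGGGGG", random_seq(n))
  exact <- paste0(bg(100), sle, bg(100))
  one_mm <- sle; substr(one_mm, 5, 5) <- "G"        # T -> G, one mismatch
  two_mm <- one_mm; substr(two_mm, 20, 20) <- "C"   # A -> C, second mismatch
  contigs <- c(c1 = exact,
               c2 = paste0(bg(50), one_mm, bg(50)),
               c3 = paste0(bg(50), two_mm, bg(50)))
  hits <- short_match_search(sle, contigs, min_pid = 0.95)
  expect_setequal(hits$contig, c("c1", "c2"))   # 27/28 kept, 26/28 rejected
  expect_equal(hits$pid[hits$contig == "c1"], 1.0)
  expect_equal(hits$pid[hits$contig == "c2"], 27 / 28)
  expect_equal(hits$start[hits$contig == "c1"], 101L)
  expect_error(short_match_search(sle, character(0)), "empty genome")
})

test_that("poly-T tract patterns match as specified", {
  spi <- find_polyt_tract("AAACTTTTTAGGG")
  expect_identical(spi$pattern, "spi")
  expect_null(find_polyt_tract("AAACTTTGAAA"))          # 3 Ts: below minimum
  dino <- find_polyt_tract("AAACTTTTTTTGAAA")           # 7 Ts then G
  expect_identical(dino$pattern, "dino")
  perk <- find_polyt_tract("GGCTTTTGCC")                # CT4G
  expect_identical(perk$pattern, "perkinsozoa")
  # leftmost wins and window is respected
  expect_equal(find_polyt_tract("AACTTTTGAACTTTTTC")$start, 3L)
  expect_null(find_polyt_tract(paste0(strrep("A", 130), "CTTTTTG"), window = 120))
})

test_that("validation accepts planted loci and rejects each broken rule", {
  sys <- generate_sl_system("psinerae")
  cfg <- sl_generator_config(n_transcripts = 40)
  gen <- generate_genome(sys, cfg, seed = 17)
  scan <- scan_genome(sys, gen$contigs)
  expect_true(all(scan$candidates$donor_ok))
  expect_true(all(scan$candidates$boundary_motif == "GGTA"))
  expect_true(all(scan$candidates$exon_pid >= 0.95))
  # every accepted candidate re-checked by direct string operations
  for (i in seq_len(nrow(scan$candidates))) {
    cd <- scan$candidates[i, ]
    ctg <- gen$contigs[[cd$contig]]
    ctx <- if (cd$strand == "+") ctg else rc_oracle(ctg)
    es <- if (cd$strand == "+") cd$exon_start else nchar(ctg) - cd$exon_end + 1L
    ee <- es + (cd$exon_end - cd$exon_start)
    expect_identical(substr(ctx, es, ee), sys$types[[cd$type]])
    expect_identical(substr(ctx, ee + 1, ee + 2), "GT")
    expect_gte(nchar(ctx) - ee, 40L)
    expect_true(grepl("CT{4,7}[GCA]", substr(ctx, ee + 1, ee + 120)))
    expect_equal(cd$total_length, nchar(cd$full_seq))
  }
  # decoys are rejected with the right reasons
  rej <- scan$rejected
  donor_decoy <- gen$loci[gen$loci$kind == "decoy_donor", ]
  expect_true(any(rej$reason == "donor" & rej$contig == donor_decoy$contig))
  polyt_decoy <- gen$loci[gen$loci$kind == "decoy_polyt", ]
  expect_true(any(rej$reason == "polyT" & rej$contig == polyt_decoy$contig))
  # no decoy slipped into the accepted set
  decoy_keys <- paste(gen$loci$contig, gen$loci$exon_start)[gen$loci$kind != "locus"]
  expect_false(any(paste(scan$candidates$contig, scan$candidates$exon_start)
                   %in% decoy_keys))
})

test_that("planted loci are fully recovered across seeds", {
  sys <- generate_sl_system("psinerae")
  cfg <- sl_generator_config(n_transcripts = 30)
  for (seed in 1:10) {
    gen <- generate_genome(sys, cfg, seed = seed)
    scan <- scan_genome(sys, gen$contigs)
    truth <- gen$loci[gen$loci$kind == "locus", ]
    expect_setequal(paste(scan$candidates$contig, scan$candidates$exon_start),
                    paste(truth$contig, truth$exon_start))
    expect_equal(sum(scan$counts), nrow(truth))
  }
})

test_that("identical copies deduplicate with multiplicity; variants stay", {
  base <- list(contig = "c", strand = "+", exon_start = 1L, exon_end = 28L,
               full_seq = "AAACCCGGG", type = "type1")
  df <- do.call(rbind, lapply(1:3, function(i)
    data.frame(base, stringsAsFactors = FALSE)))
  dd <- deduplicate_candidates(df)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$multiplicity, 3L)
  df2 <- df
  df2$full_seq[2] <- "AAACCCGGT"
  dd2 <- deduplicate_candidates(df2)
  expect_equal(sort(dd2$multiplicity), c(1L, 2L))
  empty <- df[0, ]
  expect_equal(nrow(deduplicate_candidates(empty)), 0L)
})

test_that("scanning is strand-invariant up to mirrored coordinates", {
  sys <- generate_sl_system("psinerae")
  gen <- generate_genome(sys, sl_generator_config(n_transcripts = 30), seed = 23)
  scan_f <- scan_genome(sys, gen$contigs)
  rc_contigs <- vapply(gen$contigs, rc_oracle, "")
  scan_r <- scan_genome(sys, rc_contigs)
  expect_equal(scan_r$counts, scan_f$counts)
  clen <- nchar(gen$contigs)
  mirrored <- clen[scan_f$candidates$contig] - scan_f$candidates$exon_end + 1L
  expect_setequal(paste(scan_r$candidates$contig, scan_r$candidates$exon_start),
                  paste(scan_f$candidates$contig, mirrored))
  expect_true(all(scan_r$candidates$strand !=
                    scan_f$candidates$strand[match(
                      paste(scan_r$candidates$contig, scan_r$candidates$exon_start),
                      paste(scan_f$candidates$contig, mirrored))]))
})

test_that("uniform random sequence yields no candidates (false-positive control)", {
  sys <- generate_sl_system("psinerae")
  n_cand <- 0L
  for (seed in 1:20) {
    set.seed(seed + 1000)
    contigs <- c(r = random_seq(100000))
    scan <- scan_genome(sys, contigs)
    n_cand <- n_cand + sum(scan$counts)
  }
  expect_equal(n_cand, 0L)
})

test_that("tandem arrays report counts, gaps and marker distance", {
  sys <- generate_sl_system("spi")
  cfg <- sl_generator_config("spi", n_transcripts = 30,
                             loci_per_type = c(single = 1L),
                             tandem_size = 3L, tandem_spacer = 100L,
                             n_decoy_donor = 0L, n_decoy_polyt = 0L)
  gen <- generate_genome(sys, cfg, seed = 3)
  scan <- scan_genome(sys, gen$contigs)
  # tandem copies have identical exon+intron -> collapse to multiplicity 3
  expect_equal(unname(scan$counts[["single"]]), 1L)
  expect_equal(scan$candidates$multiplicity, 3L)
  # context report on the pre-dedup truth layout
  raw <- data.frame(contig = gen$loci$contig, exon_start = gen$loci$exon_start,
                    polyt_end = gen$loci$locus_end, stringsAsFactors = FALSE)
  ctx <- tandem_context_report(raw, gen$contigs)
  expect_equal(ctx$arrays$n, 3L)
  gaps <- as.integer(strsplit(ctx$arrays$gaps, ",")[[1]])
  expect_equal(gaps, c(100L, 100L))
  # marker planted at a known distance downstream of the array
  marker <- paste(rep(c("A", "C", "G", "T"), 10), collapse = "")
  ct <- gen$loci$contig[1]
  arr_end <- max(gen$loci$locus_end)
  contigs2 <- gen$contigs
  substr(contigs2[[ct]], arr_end + 251L, arr_end + 250L + nchar(marker)) <- marker
  ctx2 <- tandem_context_report(raw, contigs2, marker = marker)
  expect_equal(ctx2$marker$nearest_distance[1], 250L)
})

test_that("Sm motif variants are found and labelled by region", {
  hits <- sm_motif_scan(paste0("GGG", "ATTTTGG", strrep("C", 20)), exon_length = 12L)
  expect_true(any(hits$pattern == "at4gg" & hits$region == "exon"))
  expect_equal(nrow(sm_motif_scan(strrep("AC", 30), exon_length = 10L)), 0L)
  rot <- sm_motif_scan(paste0(strrep("G", 25), "AATTCTGA"), exon_length = 10L)
  expect_true(any(rot$pattern == "aaytytga" & rot$region == "intron"))
})

test_that("trans-splice verification separates trans, cis and unmapped genes", {
  cfg <- sl_generator_config(n_transcripts = 150)
  b <- simulate_sl_bundle(cfg, seed = 11)
  calls <- detect_sl(b$transcriptome$transcripts, b$sl_system)
  genes <- b$genome$genes
  sle <- b$sl_system$types$type1
  for (i in seq_len(nrow(genes))) {
    mat <- calls$mature_seq[calls$transcript_id == genes$transcript_id[i]]
    v <- verify_trans_splicing(mat, b$genome$contigs, sle)
    if (genes$cis_encoded[i]) {
      expect_identical(v$status, "cis_encoded")
    } else {
      expect_identical(v$status, "confirmed")
      expect_equal(v$acceptor_position, -2L)
      expect_false(v$sle_in_genomic_5utr)
    }
  }
  set.seed(2)
  absent <- gsub("GGCTCAAG|CTTGAGCC", "GGGGGGGG", random_seq(400))
  v2 <- verify_trans_splicing(absent, b$genome$contigs, sle)
  expect_identical(v2$status, "unmapped")
})
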