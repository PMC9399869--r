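# SL detection, extent measurement, classification, trimming, and the
# consensus / PFM / composition summaries.

make_sys <- function() generate_sl_system("psinerae")

test_that("motif search finds sense hits in-window and respects the window", {
  sys <- make_sys()
  tx <- paste0("AAA", sys$types$type1, "ATGCCC")
  ev <- find_sl_evidence(tx)
  expect_identical(ev$orientation, "sense")
  expect_equal(ev$motif_start, 3L + 28L - 8L + 1L)  # octamer start, 1-based
  set.seed(1)
  scrub <- function(x) gsub("GGCTCAAG|CTTGAGCC", "GGGGGGGG", x)
  far <- paste0(scrub(random_seq(149)), "GGCTCAAG", scrub(random_seq(30)))
  expect_null(find_sl_evidence(far, window = 100L))
  expect_error(find_sl_evidence("ACGT"), "shorter")
})

test_that("antisense hits normalize to identical downstream calls", {
  sys <- make_sys()
  set.seed(21)
  for (i in 1:20) {
    body <- gsub("GGCTCAAG|CTTGAGCC", "GGGGGGGG", random_seq(300))
    trunc <- sample(0:20, 1)
    tx <- paste0(substr(sys$types$type1, trunc + 1, 28), body)
    calls_f <- detect_sl(c(t = tx), sys)
    calls_r <- detect_sl(c(t = rc_oracle(tx)), sys)
    expect_equal(calls_r$observed_extent, calls_f$observed_extent)
    expect_identical(calls_r$sl_type, calls_f$sl_type)
    expect_identical(calls_r$mature_seq, calls_f$mature_seq)
    expect_identical(calls_r$orientation, "antisense")
  }
})

test_that("extent measurement counts contiguous matching SLe suffix", {
  sys <- make_sys()
  sle <- sys$types$type1
  full <- paste0(sle, "ATGAAACCC")
  ev <- find_sl_evidence(full)
  m <- measure_sl_extent(ev$normalized, ev$motif_start, sle)
  expect_equal(m$extent, 28L)
  expect_identical(m$residual, "")

  part <- paste0(substr(sle, 15, 28), "ATGAAACCC")  # 14 nt visible
  ev2 <- find_sl_evidence(part)
  m2 <- measure_sl_extent(ev2$normalized, ev2$motif_start, sle)
  expect_equal(m2$extent, 14L)

  resid <- "GCGCG"
  ev3 <- find_sl_evidence(paste0(resid, sle, "ATG"))
  m3 <- measure_sl_extent(ev3$normalized, ev3$motif_start, sle)
  expect_equal(m3$extent, 28L)
  expect_identical(m3$residual, resid)
})

test_that("classification uses the discriminating positions and their coverage", {
  sys <- make_sys()
  t1_full <- detect_sl(c(x = paste0(sys$types$type1, "ATGCCCAAATTT")), sys)
  expect_identical(t1_full$sl_type, "type1")
  expect_true(t1_full$complete)

  t2_16 <- detect_sl(c(x = paste0(substr(sys$types$type2, 13, 28), "ATGCCCAAATTT")), sys)
  expect_identical(t2_16$sl_type, "type2")
  expect_equal(t2_16$observed_extent, 16L)

  inc_14 <- detect_sl(c(x = paste0(substr(sys$types$type1, 15, 28), "ATGCCCAAATTT")), sys)
  expect_identical(inc_14$sl_type, "incomplete")

  # single-type systems: any motif hit is SL-bearing
  mn <- generate_sl_system("mnigrum")
  short_hit <- detect_sl(c(x = paste0(substr(mn$types$single, 18, 25), "ATGCCCTTTAAA")), mn)
  expect_identical(short_hit$sl_type, "single")
})

test_that("trimming removes through the terminal AAG and is idempotent", {
  sys <- make_sys()
  body <- "ATGAAACCC"
  for (start in c(1L, 15L)) {           # full SLe and a partial one
    tx <- paste0(substr(sys$types$type1, start, 28), body)
    call <- detect_sl(setNames(tx, "t"), sys)
    expect_identical(call$mature_seq, body)
    again <- detect_sl(setNames(call$mature_seq, "t"), sys)
    expect_identical(again$mature_seq, body)   # no hit left; unchanged
  }
})

test_that("extent distribution histogram and threshold fractions", {
  calls <- data.frame(transcript_id = c("a", "b", "c", "d"),
                      orientation = c("sense", "sense", "sense", "none"),
                      observed_extent = c(8L, 12L, 20L, 0L))
  d <- partial_length_distribution(calls)
  expect_equal(sum(d$histogram), 3L)
  expect_equal(unname(d$fraction_at_least[["10"]]), 2 / 3)
  all28 <- data.frame(transcript_id = "a", orientation = "sense",
                      observed_extent = 28L)
  expect_equal(unname(partial_length_distribution(all28)$fraction_at_least[["10"]]), 1.0)
})

test_that("missed-SL estimate: zero for full exons, matches truth in the default regime, large when truncation is centred on the exon length", {
  sys <- make_sys()
  expect_warning(est0 <- estimate_missed_sl_fraction(rep(28L, 50), 28L), "degenerate")
  expect_equal(as.numeric(est0), 0)

  tr <- generate_transcriptome(sys, sl_generator_config(n_transcripts = 4000), seed = 6)
  calls <- detect_sl(tr$transcripts, sys)
  est <- estimate_missed_sl_fraction(
    calls$observed_extent[calls$orientation != "none"], 28L)
  true_p <- pnorm(28 - 0.5, 6, 4, lower.tail = FALSE)  # generator full-loss mass
  expect_lt(abs(as.numeric(est) - true_p), 0.05)

  # missing counts centred on the SLe length (deterministic quantized tail
  # of N(28, 6) over the observable range): roughly half the exons lost
  w <- dnorm(0:20, 28, 6)
  obs_m <- rep(0:20, times = round(2e4 * w / sum(w)))
  est2 <- estimate_missed_sl_fraction(28L - obs_m, 28L)
  expect_gt(as.numeric(est2), 0.4)
})

test_that("consensus follows the 60% majority / IUPAC >25% rule", {
  expect_identical(build_consensus(rep("ACGT", 3)), "ACGT")
  seqs <- c(rep("A", 7), rep("C", 3))
  expect_identical(build_consensus(seqs), "A")          # 0.7 >= 0.6
  expect_identical(build_consensus(c("A", "T")), "W")   # 0.5/0.5 -> IUPAC
  expect_identical(build_consensus(c("A", "C", "G", "T")), "N")
  expect_error(build_consensus(character(0)), "no sequences")
})

test_that("PFM columns sum to 1, use only covering observations, and track information", {
  obs_full <- rep("ACGTACGT", 5)
  pfm <- position_frequency_matrix(obs_full, 8L)
  expect_true(all(abs(colSums(pfm$freq) - 1) < 1e-9))
  expect_true(all(pfm$info == 2))
  expect_equal(pfm$coverage, rep(5L, 8))

  two <- c("ACGT", "ACTT")                 # differ at one position
  pfm2 <- position_frequency_matrix(two, 4L)
  expect_equal(unname(pfm2$info[3]), 1)
  expect_true(all(abs(colSums(pfm2$freq) - 1) < 1e-9))

  mixed <- c("TTTTT", "TTT", "TT")         # 3'-anchored suffixes of TTTTT
  pfm3 <- position_frequency_matrix(mixed, 5L)
  expect_equal(pfm3$coverage, c(1L, 1L, 2L, 3L, 3L))
  expect_true(all(abs(colSums(pfm3$freq) - 1) < 1e-9))
})

test_that("nucleotide composition sums to one and matches hand counts", {
  comp <- nucleotide_composition("ACCGTAGCCATCTTGGCTCAAG")
  expect_equal(unname(comp), c(5, 7, 5, 5) / 22)
  expect_equal(sum(comp), 1)
  expect_equal(unname(nucleotide_composition("AAAA")["A"]), 1.0)
  expect_equal(unname(nucleotide_composition("ACGT")), rep(0.25, 4))
  expect_warning(cn <- nucleotide_composition("ACGTN"), "excluded")
  expect_equal(sum(cn), 1)
})

test_that("partition percentages recompute from counts and categories always sum", {
  sys <- make_sys()
  tr <- generate_transcriptome(sys, sl_generator_config(n_transcripts = 600),
                               seed = 12)
  calls <- detect_sl(tr$transcripts, sys)
  p <- partition_summary(calls)
  expect_equal(unname(p$counts[["no_sl"]] + p$counts[["type1"]] +
                        p$counts[["type2"]] + p$counts[["incomplete"]]),
               unname(p$counts[["total"]]))
  expect_lte(abs(p$percentages[["sl_bearing_of_total"]] -
                   100 * p$counts[["sl_bearing"]] / p$counts[["total"]]),
             0.005 + 1e-9)

  all_none <- data.frame(transcript_id = c("a", "b"),
                         orientation = "none", sl_type = "none",
                         complete = FALSE, mature_seq = c("AA", "CC"))
  p0 <- partition_summary(all_none)
  expect_equal(unname(p0$percentages[["sl_bearing_of_total"]]), 0)
  expect_error(partition_summary(rbind(all_none, all_none)), "duplicate")
})

test_that("zero-truncation bundle partition equals the truth exactly", {
  sys <- make_sys()
  cfg <- sl_generator_config(n_transcripts = 800, trunc_mean = 0,
                             trunc_sd = 0, frac_residual = 0)
  tr <- generate_transcriptome(sys, cfg, seed = 31)
  calls <- detect_sl(tr$transcripts, sys)
  p <- partition_summary(calls)
  tt <- table(tr$truth$true_type)
  expect_equal(unname(p$counts[["type1"]]), unname(tt[["type1"]]))
  expect_equal(unname(p$counts[["type2"]]), unname(tt[["type2"]]))
  expect_equal(unname(p$counts[["no_sl"]]), unname(tt[["none"]]))
  expect_equal(unname(p$counts[["incomplete"]]), 0L)
  expect_equal(unname(p$counts[["sl_pairs"]]), sum(tr$truth$isoform_pair))
  expect_equal(unname(p$counts[["cross_type"]]), sum(tr$truth$cross_type))
})
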