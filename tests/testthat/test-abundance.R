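# TPM normalization, quartile filtering and the rank tests.

test_that("TPM follows the length-normalized formula and conserves 1e6", {
  tp <- tpm_normalize(data.frame(transcript_id = c("a", "b"),
                                 S1 = c(10, 10), effective_length = c(100, 100)))
  expect_equal(unname(tp$tpm[, 1]), c(5e5, 5e5))

  tp2 <- tpm_normalize(data.frame(transcript_id = c("a", "b"),
                                  S1 = c(10, 10), effective_length = c(100, 200)))
  expect_equal(unname(tp2$tpm[, 1]), c(2e6 / 3, 1e6 / 3))

  tp3 <- tpm_normalize(data.frame(transcript_id = "a", S1 = 7,
                                  effective_length = 123))
  expect_equal(unname(tp3$tpm[1, 1]), 1e6)

  set.seed(4)
  cts <- data.frame(transcript_id = paste0("t", 1:50),
                    S1 = rpois(50, 40), S2 = rpois(50, 40),
                    effective_length = sample(200:900, 50))
  tp4 <- tpm_normalize(cts)
  expect_true(all(abs(colSums(tp4$tpm) - 1e6) < 1e-3))
  expect_error(tpm_normalize(data.frame(transcript_id = "a", S1 = -1,
                                        effective_length = 10)), "negative")
  expect_error(tpm_normalize(data.frame(transcript_id = "a", S1 = 1,
                                        effective_length = 0)), "length")
})

test_that("quartile filter drops the interpolated lower quartile, keeps strict exceeders", {
  keep <- quartile_filter(1:8)                  # Q1 = 2.75
  expect_identical(which(keep), 3:8L)
  expect_warning(keep_deg <- quartile_filter(rep(5, 10)), "degenerate")
  expect_true(all(keep_deg))
  set.seed(8)
  x <- runif(100)
  expect_equal(sum(quartile_filter(x)), 75L)
  expect_error(quartile_filter(1:3), "at least 4")
})

test_that("Mann-Whitney exact p-values match full enumeration", {
  expect_equal(mann_whitney_test(1:10, 1:10)$p_value, 1.0)
  expect_equal(mann_whitney_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  set.seed(13)
  for (i in 1:10) {
    x <- round(runif(sample(3:8, 1)) * 20)
    y <- round(runif(sample(3:8, 1)) * 20)
    expect_equal(mann_whitney_test(x, y)$p_value, mw_p_oracle(x, y),
                 info = paste(c(x, "|", y), collapse = " "))
  }
  # tie-free small samples also agree with stats::wilcox.test exact p
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(9)
    expect_equal(mann_whitney_test(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("normal-approximation branch is close to the exact distribution", {
  set.seed(21)
  # sanity band: exact enumeration vs approximation at n = 10 vs 10
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    p_exact <- mw_p_oracle(x, y)
    p_norm <- sltrans:::mw_normal_p(x, y)
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
  # large-sample branch agrees with stats::wilcox.test (tie-corrected)
  for (i in 1:5) {
    x <- rnorm(60); y <- rnorm(55) + 0.3
    expect_equal(mann_whitney_test(x, y)$p_value,
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-8)
  }
})

test_that("Kruskal-Wallis H matches rank arithmetic and behaves under the null", {
  g <- list(a = c(1, 5, 9, 13), b = c(2, 6, 10, 14), c = c(3, 7, 11, 15))
  kt <- kruskal_wallis_test(g)
  expect_equal(kt$statistic, kw_h_oracle(g), tolerance = 1e-12)
  ident <- list(a = 1:5, b = 1:5, c = 1:5)
  expect_gt(kruskal_wallis_test(ident)$p_value, 0.95)
  expect_error(kruskal_wallis_test(list(1:3, 4:6)), ">= 3 groups")

  # type-I control: three groups cut from one permuted pool
  set.seed(31)
  rej <- mean(replicate(400, {
    pool <- rnorm(60)
    idx <- sample(rep(1:3, each = 20))
    kruskal_wallis_test(split(pool, idx))$p_value < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("KW with 2 groups relates to the squared standardized MW statistic", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(12) + 0.5
  # H (no tie correction, 2 groups) equals z^2 of the U statistic
  h2 <- kw_h_oracle(list(x, y))
  n1 <- length(x); n2 <- length(y)
  u <- sum(rank(c(x, y))[1:n1]) - n1 * (n1 + 1) / 2
  z2 <- (u - n1 * n2 / 2)^2 / (n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(h2, z2, tolerance = 1e-10)
})

test_that("planted 2x abundance shift is detected; no shift is controlled", {
  # power: shift = 2, n = 500 per group, alpha = 0.001
  set.seed(41)
  hits <- mean(replicate(100, {
    a <- rlnorm(500, 4, 1.2) * 2
    b <- rlnorm(500, 4, 1.2)
    mann_whitney_test(a, b)$p_value < 0.001
  }))
  expect_gte(hits, 0.95)
  # type-I: shift = 1, alpha = 0.05, rejection rate near nominal
  set.seed(42)
  fp <- mean(replicate(400, {
    a <- rlnorm(500, 4, 1.2)
    b <- rlnorm(500, 4, 1.2)
    mann_whitney_test(a, b)$p_value < 0.05
  }))
  expect_lte(fp, 0.07)
})

test_that("pool comparison mirrors the segregated-abundance design", {
  cfg <- sl_generator_config(n_transcripts = 1500, shift = 2.0)
  b <- simulate_sl_bundle(cfg, seed = 19)
  calls <- detect_sl(b$transcriptome$transcripts, b$sl_system)
  ab <- tpm_normalize(b$transcriptome$counts)
  cmp <- compare_sl_pools(ab, calls)
  expect_true(all(abs(colSums(ab$tpm) - 1e6) < 1e-3))
  expect_setequal(names(cmp$pools), c("none", "type1", "type2"))
  pw <- cmp$pairwise
  p_t1 <- pw$p_value[pw$pool_a == "none" & pw$pool_b == "type1"]
  p_t2 <- pw$p_value[pw$pool_a == "none" & pw$pool_b == "type2"]
  expect_lt(p_t1, 0.001)        # shifted pool clearly separated
  expect_gt(p_t2, 0.05)         # unshifted pool indistinguishable
  expect_lt(cmp$kruskal_wallis$p_value, 0.001)

  single <- calls[calls$sl_type %in% "none", ]
  ab_single <- tpm_normalize(b$transcriptome$counts[
    b$transcriptome$counts$transcript_id %in% single$transcript_id, ])
  expect_error(compare_sl_pools(ab_single, single), ">= 2 pools")
})
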