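# TPM normalization, low-coverage filtering and nonparametric comparison of
# transcript abundance between SL-defined pools.

#' TPM-normalize a count matrix
#'
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j(c_j / l_j)` per sample, so every
#' sample column sums to one million.
#'
#' @param counts data.frame with `transcript_id`, one numeric column per
#'   sample, and `effective_length` (or a plain numeric matrix plus
#'   `effective_length` argument).
#' @param effective_length optional numeric vector of per-transcript
#'   effective lengths (overrides the column).
#' @return object of class `abundance_matrix`: list with `transcript_id`,
#'   `samples`, `counts`, `effective_length`, `tpm` (matrix) and `mean_tpm`
#'   (per-transcript mean across samples).
#' @export
tpm_normalize <- function(counts, effective_length = NULL) {
  if (is.data.frame(counts)) {
    ids <- counts$transcript_id
    effective_length <- effective_length %||% counts$effective_length
    mat <- as.matrix(counts[, setdiff(names(counts),
                                      c("transcript_id", "effective_length")),
                            drop = FALSE])
  } else {
    mat <- as.matrix(counts)
    ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  if (is.null(effective_length)) stop("effective lengths required", call. = FALSE)
  if (any(effective_length <= 0)) stop("non-positive effective length", call. = FALSE)
  if (any(mat < 0)) stop("negative count", call. = FALSE)
  rate <- mat / effective_length
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("sample(s) with zero total count: ",
            paste(colnames(mat)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  structure(list(transcript_id = ids, samples = colnames(mat), counts = mat,
                 effective_length = effective_length, tpm = tpm,
                 mean_tpm = rowMeans(tpm)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance matrix: %d transcripts x %d samples (TPM)\n",
              length(x$transcript_id), length(x$samples)))
  invisible(x)
}

#' Drop the lowest quartile of transcripts by mean TPM
#'
#' Removes low-read-coverage transcripts before testing: transcripts whose
#' mean TPM is at or below the lower quartile (linear interpolation) are
#' dropped; values strictly above Q1 are kept.  When all values are tied
#' (degenerate), everything would be dropped, so the full set is kept with a
#' warning.
#'
#' @param mean_tpm numeric vector of per-transcript mean TPM (>= 4 values).
#' @return logical vector: `TRUE` for retained transcripts.
#' @export
quartile_filter <- function(mean_tpm) {
  if (length(mean_tpm) < 4L) stop("need at least 4 transcripts", call. = FALSE)
  q1 <- stats::quantile(mean_tpm, 0.25, names = FALSE)
  keep <- mean_tpm > q1
  if (!any(keep)) {
    warning("degenerate TPM distribution (all values <= Q1); keeping all")
    keep <- rep(TRUE, length(mean_tpm))
  }
  keep
}

mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

mw_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  sets <- utils::combn(n, n1)
  us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

mw_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)   # continuity-corrected
  min(1, 2 * pnorm(-abs(z)))
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum test.  For small problems (up to the size of a 10 vs
#' 10 comparison) the p-value comes from exhaustive enumeration of all group
#' assignments (symmetric definition: arrangements whose U is at least as
#' far from its null mean as observed); otherwise from the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return object of class `group_test`: `test`, `statistic` (U of `x`),
#'   `p_value`, `n_obs` (per group), `medians`.
#' @export
mann_whitney_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group", call. = FALSE)
  u <- mw_u_stat(x, y)
  enumerable <- choose(length(x) + length(y), min(length(x), length(y))) <=
    choose(20, 10)
  p <- if (enumerable) mw_exact_p(x, y) else mw_normal_p(x, y)
  structure(list(test = "mann_whitney", statistic = u, p_value = p,
                 n_obs = c(length(x), length(y)),
                 medians = c(stats::median(x), stats::median(y))),
            class = "group_test")
}

#' Kruskal-Wallis test across three or more groups
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups named list of numeric vectors (>= 3 groups, each
#'   non-empty).
#' @return a `group_test` object.
#' @export
kruskal_wallis_test <- function(groups) {
  if (length(groups) < 3L)
    stop("need >= 3 groups (use mann_whitney_test for 2)", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  structure(list(test = "kruskal_wallis",
                 statistic = unname(kt$statistic), p_value = kt$p.value,
                 n_obs = lengths(groups),
                 medians = vapply(groups, stats::median, 0)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %s)\n", x$test, x$statistic,
              x$p_value, paste(x$n_obs, collapse = "/")))
  invisible(x)
}

#' Compare transcript abundance between SL pools
#'
#' Averages replicate TPM per transcript, removes the lowest quartile
#' (low-coverage transcripts), partitions the remainder into SL pools
#' (classified SL types plus the non-SL pool; incomplete calls are
#' excluded), then tests: Kruskal-Wallis across pools when there are three
#' or more, plus a pairwise rank-sum (Wilcoxon / Mann-Whitney) matrix.
#'
#' @param abundance an [tpm_normalize()] object.
#' @param calls a [detect_sl()] table over the same transcripts.
#' @return list with `pools` (named list of TPM vectors after filtering),
#'   `medians`, `n_obs` (total observations tested), `kruskal_wallis` (a
#'   `group_test`, or NULL with two pools), `pairwise` (data.frame of
#'   pairwise Mann-Whitney results).
#' @export
compare_sl_pools <- function(abundance, calls) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  pool_of <- calls$sl_type[match(abundance$transcript_id, calls$transcript_id)]
  if (any(is.na(pool_of))) stop("calls missing for some transcripts", call. = FALSE)
  keep <- quartile_filter(abundance$mean_tpm) & pool_of != "incomplete"
  tpm <- abundance$mean_tpm[keep]
  pool_of <- pool_of[keep]
  pools <- split(tpm, pool_of)
  if (length(pools) < 2L) stop("need >= 2 pools with retained transcripts",
                               call. = FALSE)
  kw <- if (length(pools) >= 3L) kruskal_wallis_test(pools) else NULL
  pairs <- utils::combn(names(pools), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    t <- mann_whitney_test(pools[[a]], pools[[b]])
    data.frame(pool_a = a, pool_b = b, statistic = t$statistic,
               p_value = t$p_value, n_a = t$n_obs[1L], n_b = t$n_obs[2L],
               median_a = t$medians[1L], median_b = t$medians[2L],
               stringsAsFactors = FALSE)
  }))
  list(pools = pools,
       medians = vapply(pools, stats::median, 0),
       n_obs = length(tpm),
       kruskal_wallis = kw,
       pairwise = pw)
}
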