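# Permutation-based term enrichment of SL-defined transcript pools against
# the whole-transcriptome background.
#
# The sampling unit is the transcript: null samples are drawn from the
# universe without replacement, equal in size to the test set, and the
# empirical p-value uses the add-one estimator (1 + k) / (1 + N) so p is
# never exactly zero.  For small universes (choose(universe, test) within
# an exhaustive budget) the exact hypergeometric tail replaces sampling --
# identical contract, exact answer.

#' Build an annotation map from a long transcript-term table
#'
#' @param go data.frame with columns `transcript_id` and `term`.
#' @param universe optional character vector of all annotated transcripts
#'   (defaults to the transcripts present in `go`).
#' @return object of class `annotation_map`: list with `universe` and
#'   `terms` (named list: term -> character vector of member transcripts).
#' @export
annotation_map <- function(go, universe = NULL) {
  stopifnot(all(c("transcript_id", "term") %in% names(go)))
  universe <- universe %||% unique(go$transcript_id)
  if (!all(go$transcript_id %in% universe))
    stop("annotated transcripts missing from the universe", call. = FALSE)
  terms <- lapply(split(go$transcript_id, go$term), unique)
  structure(list(universe = universe, terms = terms),
            class = "annotation_map")
}

#' Observed, expected and fold enrichment per term
#'
#' Expected count is the universe frequency of the term scaled to the test
#' set size; fold enrichment is observed / expected (reported `NA` when the
#' term is absent from the universe).
#'
#' @param test_set character vector of test transcripts (subset of the
#'   universe).
#' @param annot an [annotation_map()].
#' @return data.frame: `term`, `observed`, `universe_count`, `expected`,
#'   `fold_enrichment`.
#' @export
term_counts <- function(test_set, annot) {
  if (length(test_set) == 0L) stop("empty test set", call. = FALSE)
  if (!all(test_set %in% annot$universe))
    stop("test set contains transcripts outside the universe", call. = FALSE)
  k <- length(test_set)
  u <- length(annot$universe)
  obs <- vapply(annot$terms, function(m) sum(test_set %in% m), 0L)
  ucount <- lengths(annot$terms)
  expected <- k * ucount / u
  data.frame(term = names(annot$terms), observed = unname(obs),
             universe_count = unname(ucount), expected = unname(expected),
             fold_enrichment = ifelse(expected > 0, obs / expected, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical permutation p-value for term enrichment
#'
#' One-sided (enrichment): the probability that a random transcript sample
#' of the test-set size, drawn from the universe without replacement,
#' contains at least the observed number of term members.  Estimated from
#' `n_perm` permutation samples with the add-one estimator, or computed
#' exactly from the hypergeometric tail when `choose(universe, test)` is
#' within the exhaustive budget (or `exhaustive = TRUE`).
#'
#' @param observed observed term count in the test set.
#' @param term term id.
#' @param annot an [annotation_map()].
#' @param test_size size of the test set.
#' @param n_perm number of permutation samples (default 100000).
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) the exact mode;
#'   default `NULL` chooses automatically (exact when
#'   `choose(universe, test) <= 1e6`).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, term, annot, test_size,
                               n_perm = 100000L, exhaustive = NULL) {
  u <- length(annot$universe)
  if (test_size > u) stop("test size exceeds universe size", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  members <- annot$terms[[term]]
  if (is.null(members)) stop("unknown term: ", term, call. = FALSE)
  K <- length(members)
  use_exact <- exhaustive %||% (choose(u, test_size) <= 1e6)
  if (use_exact)
    return(phyper(observed - 1L, K, u - K, test_size, lower.tail = FALSE))
  v <- annot$universe %in% members
  hits <- vapply(seq_len(n_perm), function(i)
    sum(v[sample.int(u, test_size)]), 0L)
  (1 + sum(hits >= observed)) / (1 + n_perm)
}

#' Permutation enrichment of every SL pool against the background
#'
#' For each SL pool (classified SL types; `incomplete` and `none` calls are
#' background-only), computes observed/expected/fold per term and an
#' empirical permutation p-value, sharing one set of permutation samples
#' across the terms of a pool.  Deterministic under a fixed seed.
#'
#' @param calls a [detect_sl()] table.
#' @param annot an [annotation_map()]; its universe should be the annotated
#'   transcriptome.
#' @param alpha significance threshold on the raw p-value (default 0.05; no
#'   multiple-testing correction, but see `adjust`).
#' @param n_perm permutation samples per pool (default 100000).
#' @param seed integer seed.
#' @param adjust optionally `"BH"` to add Benjamini-Hochberg adjusted
#'   p-values (flagging then uses the adjusted values).
#' @return data.frame: `pool`, `term`, `observed`, `expected`,
#'   `fold_enrichment`, `p_value`, (`p_adjusted`,) `significant`, for every
#'   (pool, term) with positive expected count.
#' @export
enrich_pools <- function(calls, annot, alpha = 0.05, n_perm = 100000L,
                         seed = 1L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  set.seed(seed)
  pools <- setdiff(unique(calls$sl_type), c("none", "incomplete"))
  if (length(pools) == 0L) stop("no classified SL pools in calls", call. = FALSE)
  u <- length(annot$universe)
  out <- NULL
  for (pool in sort(pools)) {
    test_set <- intersect(calls$transcript_id[calls$sl_type == pool],
                          annot$universe)
    if (length(test_set) == 0L) next
    k <- length(test_set)
    tc <- term_counts(test_set, annot)
    tc <- tc[tc$expected > 0, , drop = FALSE]
    use_exact <- choose(u, k) <= 1e6
    if (use_exact) {
      pv <- phyper(tc$observed - 1L, tc$universe_count,
                   u - tc$universe_count, k, lower.tail = FALSE)
    } else {
      memb <- matrix(FALSE, u, nrow(tc))
      for (j in seq_len(nrow(tc)))
        memb[, j] <- annot$universe %in% annot$terms[[tc$term[j]]]
      exceed <- integer(nrow(tc))
      for (i in seq_len(n_perm)) {
        idx <- sample.int(u, k)
        exceed <- exceed +
          (colSums(memb[idx, , drop = FALSE]) >= tc$observed)
      }
      pv <- (1 + exceed) / (1 + n_perm)
    }
    out <- rbind(out, data.frame(pool = pool, tc, p_value = pv,
                                 stringsAsFactors = FALSE))
  }
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  rownames(out) <- NULL
  out
}
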