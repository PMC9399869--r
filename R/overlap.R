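# Overlap between transcript sets (e.g. an SL-PCR amplified library versus
# the SL / non-SL pools of an RNA-seq assembly) under identity and
# alignment-length filters.

#' Overlap two transcript sets under identity/length filters
#'
#' A transcript of set A matches set B when some member of B yields a local
#' alignment with at least `min_len` aligned columns and identity at least
#' `min_pid` (identities / aligned columns, gap columns included).
#' Matching is by best hit and each transcript counts once regardless of
#' how many members it matches (deduplication by sequence id).
#'
#' @param set_a,set_b named character vectors of sequences.
#' @param min_pid minimum percent identity (default 0.98).
#' @param min_len minimum aligned length in nt (default 50).
#' @param label_a,label_b set labels for reporting.
#' @return object of class `overlap_result`: list with `labels`, `n_a`,
#'   `n_b`, `matched_a`, `matched_b` (counts), `frac_a`, `frac_b`,
#'   `best_hits` (per-A-transcript best hit: `id`, `best_match`, `pid`,
#'   `aligned_length`, `matched`).
#' @export
overlap_sets <- function(set_a, set_b, min_pid = 0.98, min_len = 50L,
                         label_a = "A", label_b = "B") {
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both sets must be non-empty", call. = FALSE)
  sm <- sub_matrix(1, -2)
  n_a <- length(set_a); n_b <- length(set_b)
  best_pid <- rep(0, n_a); best_len <- rep(0L, n_a)
  best_id <- rep(NA_character_, n_a)
  matched_b <- rep(FALSE, n_b)
  pat <- Biostrings::DNAStringSet(set_a)
  for (j in seq_len(n_b)) {
    pa <- Biostrings::pairwiseAlignment(pat, set_b[[j]], type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 0, gapExtension = 2)
    alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
    ident <- Biostrings::nmatch(pa)
    pid <- ifelse(alen > 0L, ident / alen, 0)
    ok <- alen >= min_len & pid >= min_pid
    matched_b[j] <- any(ok)
    take <- which(ok & (is.na(best_id) | pid > best_pid |
                          (pid == best_pid & alen > best_len)))
    best_pid[take] <- pid[take]
    best_len[take] <- alen[take]
    best_id[take] <- names(set_b)[j]
  }
  matched_a <- !is.na(best_id)
  structure(list(
    labels = c(label_a, label_b), n_a = n_a, n_b = n_b,
    matched_a = sum(matched_a), matched_b = sum(matched_b),
    frac_a = sum(matched_a) / n_a, frac_b = sum(matched_b) / n_b,
    best_hits = data.frame(id = names(set_a), best_match = best_id,
                           pid = best_pid, aligned_length = best_len,
                           matched = matched_a, stringsAsFactors = FALSE)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %s (n=%d) vs %s (n=%d): %d/%d matched (%.1f%%), %d/%d reverse (%.1f%%)\n",
              x$labels[1L], x$n_a, x$labels[2L], x$n_b,
              x$matched_a, x$n_a, 100 * x$frac_a,
              x$matched_b, x$n_b, 100 * x$frac_b))
  invisible(x)
}
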