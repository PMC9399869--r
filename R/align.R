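# Pairwise alignment utilities shared by the detection, genome-scan and
# library-overlap stages.  Both functions use exact dynamic programming via
# Biostrings::pairwiseAlignment with a linear gap penalty.
#
# Scoring convention (BLASTn-short-like, suited to short high-identity
# queries): match +1, mismatch -2, gap -2 per gapped position.  'N' never
# matches anything, which is conservative for the >=95/98% identity filters.
#
# Coordinates are 1-based inclusive throughout, following R convention.
# Percent identity (pid) is identities / aligned columns, gap columns
# included, so fixed identity cutoffs are reproducible.

sub_matrix <- function(match, mismatch) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(ab, ab))
  diag(m)[1:4] <- match
  m
}

align_result <- function(pa, query_id, subject_id, strand, query_len) {
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  alen <- nchar(ap)
  ident <- if (alen > 0L) Biostrings::nmatch(pa) else 0L
  qs <- Biostrings::start(Biostrings::pattern(pa))
  qe <- Biostrings::end(Biostrings::pattern(pa))
  if (strand == "-") {  # map back onto the original (forward) query
    tmp <- qs
    qs <- query_len - qe + 1L
    qe <- query_len - tmp + 1L
  }
  structure(list(
    query_id = query_id, subject_id = subject_id, strand = strand,
    query_start = qs, query_end = qe,
    subject_start = Biostrings::start(Biostrings::subject(pa)),
    subject_end = Biostrings::end(Biostrings::subject(pa)),
    aligned_length = alen, identities = ident,
    pid = if (alen > 0L) ident / alen else 0,
    score = Biostrings::score(pa),
    aligned_query = ap, aligned_subject = as_
  ), class = "local_alignment")
}

#' Optimal local alignment of two nucleotide sequences (both strands)
#'
#' Smith-Waterman local alignment under a simple linear-gap scheme.  The
#' query is aligned against the subject on both strands and the better-scoring
#' hit is returned; `strand = "-"` means the reverse complement of the query
#' matched the subject (query coordinates are reported on the original
#' query).  Percent identity is identities divided by aligned columns,
#' counting gap columns.
#'
#' @param query,subject sequences (single strings over A,C,G,T,N).
#' @param match,mismatch,gap scoring scheme; `match > 0 > mismatch, gap`.
#' @param query_id,subject_id optional labels carried into the result.
#' @return a `local_alignment` list: ids, strand, `query_start/end`,
#'   `subject_start/end` (1-based inclusive), `aligned_length`, `identities`,
#'   `pid`, `score` and the two gapped aligned strings.  A score of 0 with
#'   `aligned_length` 0 means no positive-scoring local alignment exists.
#' @export
smith_waterman_local <- function(query, subject, match = 1, mismatch = -2,
                                 gap = -2, query_id = "query",
                                 subject_id = "subject") {
  check_seq(query, "query"); check_seq(subject, "subject")
  stopifnot(match > 0, mismatch < 0, gap < 0)
  sm <- sub_matrix(match, mismatch)
  fwd <- Biostrings::pairwiseAlignment(query, subject, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = -gap)
  rev <- Biostrings::pairwiseAlignment(revcomp(query), subject, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = -gap)
  if (Biostrings::score(rev) > Biostrings::score(fwd)) {
    align_result(rev, query_id, subject_id, "-", nchar(query))
  } else {
    align_result(fwd, query_id, subject_id, "+", nchar(query))
  }
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment %s vs %s (%s): score %.1f, pid %.3f (%d/%d)\n",
              x$query_id, x$subject_id, x$strand, x$score, x$pid,
              x$identities, x$aligned_length))
  cat(sprintf("  query [%d,%d]  subject [%d,%d]\n",
              x$query_start, x$query_end, x$subject_start, x$subject_end))
  invisible(x)
}

#' Optimal global alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment under the same linear-gap scheme as
#' [smith_waterman_local()].  Gaps are written as `-`; removing them recovers
#' the input sequences.
#'
#' @inheritParams smith_waterman_local
#' @param a,b sequences to align.
#' @return list with elements `a`, `b` (equal-length aligned strings) and
#'   `score`.
#' @export
needleman_wunsch_global <- function(a, b, match = 1, mismatch = -2, gap = -2) {
  check_seq(a, "a"); check_seq(b, "b")
  sm <- sub_matrix(match, mismatch)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = -gap)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}
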