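# Consensus, position-frequency-matrix and composition summaries of the
# observed SL exon sequences.

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Majority-rule consensus of aligned sequences
#'
#' Per column: the base whose relative frequency reaches `threshold` is
#' emitted; otherwise the IUPAC ambiguity code covering every base with
#' frequency above 0.25; otherwise `N`.  Gap characters are ignored when
#' computing column frequencies; an all-gap column yields `-`.
#'
#' @param seqs character vector of equal-length aligned sequences over
#'   A,C,G,T and `-`.
#' @param threshold majority threshold (default 0.60).
#' @return consensus string.
#' @export
build_consensus <- function(seqs, threshold = 0.60) {
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must have equal aligned length", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  cons <- vapply(seq_len(w), function(j) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return("-")
    f <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    if (max(f) >= threshold) return(names(f)[which.max(f)])
    keep <- names(f)[f > 0.25]
    if (length(keep) == 0L) return("N")
    IUPAC_CODES[[paste(sort(keep), collapse = "")]]
  }, "")
  paste(cons, collapse = "")
}

#' Position frequency matrix of observed SL exon suffixes
#'
#' Observations are the 3'-anchored SLe suffixes recovered per transcript
#' (variable extent).  Column `j` of the matrix is computed only from
#' observations whose extent covers position `j`, so 5'-most columns may
#' rest on fewer observations; the per-column coverage is reported
#' alongside.  Columns with zero coverage are set to the uniform
#' distribution and flagged.
#'
#' @param observations character vector of observed SLe suffixes (each a
#'   suffix of the full SLe).
#' @param sle_length full SL exon length (number of columns).
#' @return object of class `pfm`: list with `freq` (4 x L matrix of
#'   relative frequencies, columns summing to 1), `info` (per-column
#'   information content in bits), `coverage` (observations per column) and
#'   `uncovered` (logical flag per column).
#' @export
position_frequency_matrix <- function(observations, sle_length) {
  observations <- observations[!is.na(observations)]
  if (length(observations) == 0L) stop("no observations", call. = FALSE)
  ext <- nchar(observations)
  freq <- matrix(0, 4L, sle_length,
                 dimnames = list(c("A", "C", "G", "T"), seq_len(sle_length)))
  coverage <- integer(sle_length)
  for (j in seq_len(sle_length)) {
    cover <- ext >= sle_length - j + 1L
    coverage[j] <- sum(cover)
    if (coverage[j] == 0L) { freq[, j] <- 0.25; next }
    idx <- j - (sle_length - ext[cover])     # position j within each suffix
    bases <- substr(observations[cover], idx, idx)
    f <- table(factor(bases, levels = c("A", "C", "G", "T")))
    freq[, j] <- as.numeric(f) / sum(f)
  }
  info <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  info[coverage == 0L] <- 0
  structure(list(freq = freq, info = info, coverage = coverage,
                 uncovered = coverage == 0L), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix over", ncol(x$freq), "columns\n")
  print(round(x$freq, 3))
  cat("information (bits):", paste(round(x$info, 2), collapse = " "), "\n")
  cat("coverage:", paste(x$coverage, collapse = " "), "\n")
  invisible(x)
}

#' Nucleotide composition
#'
#' @param seqs one or more nucleotide sequences.
#' @return named numeric vector of A, C, G, T fractions (summing to 1).
#'   Characters outside A,C,G,T are excluded from the denominator with a
#'   warning.
#' @export
nucleotide_composition <- function(seqs) {
  if (length(seqs) == 0L || all(!nzchar(seqs))) stop("no sequence", call. = FALSE)
  chars <- unlist(strsplit(paste(seqs, collapse = ""), ""))
  keep <- chars %in% c("A", "C", "G", "T")
  if (any(!keep))
    warning(sum(!keep), " non-ACGT character(s) excluded from composition")
  chars <- chars[keep]
  f <- as.numeric(table(factor(chars, levels = c("A", "C", "G", "T")))) / length(chars)
  stats::setNames(f, c("A", "C", "G", "T"))
}
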