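#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and RNA 'U' is converted to 'T' on read, so that
#' downstream code only ever sees the DNA alphabet A, C, G, T, N.  Record
#' order is preserved.  The sequence id is the first whitespace-delimited
#' token of the header; any remainder is kept as the description.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; names are the ids and the
#'   `"descriptions"` attribute holds the (possibly empty) description per id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path, call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence ", ids[bad][1L], " contains characters outside A,C,G,T,N/U",
         call. = FALSE)
  if (any(!nzchar(seqs))) stop("zero-length sequence in ", path, call. = FALSE)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences (optionally carrying a
#'   `"descriptions"` attribute, as returned by [read_fasta()]).
#' @param path output path.
#' @param wrap line width for the sequence lines (default 60 columns).
#' @return `path`, invisibly.  `read_fasta(write_fasta(x, p))` round-trips.
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  if (is.null(names(seqs)) && length(seqs) > 0L)
    stop("sequences must be named", call. = FALSE)
  desc <- attr(seqs, "descriptions")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    d <- if (!is.null(desc) && nzchar(desc[[id]] %||% "")) paste0(" ", desc[[id]]) else ""
    writeLines(paste0(">", id, d), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}
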