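# SL exon detection on transcript 5' ends.
#
# Detection anchors on the conserved 3' octamer of the SL exon (GGCTCAAG;
# its reverse complement CTTGAGCC is the literal the antisense strand is
# searched with).  Assembled transcripts have arbitrary strand, so both
# orientations are searched and antisense hits are reverse-complemented
# before all downstream steps.  The observed SLe extent is then measured by
# extending the octamer match upstream nucleotide-by-nucleotide with zero
# mismatches, and transcripts are classified into SL types from the bases at
# the type-discriminating positions (when the observed extent covers them).

#' Locate SL motif evidence on a transcript
#'
#' Searches for the conserved SLe 3' octamer within the first `window`
#' nucleotides of the transcript (sense) and, failing that, for its reverse
#' complement within the last `window` nucleotides (antisense).  Sense wins
#' when both orientations hit.
#'
#' @param transcript nucleotide string.
#' @param motif the SLe 3' octamer (default `GGCTCAAG`).
#' @param window search window from the relevant end, in nt (default 100).
#' @return `NULL` if no hit; otherwise a list with `orientation`
#'   (`"sense"`/`"antisense"`), `motif_start` (1-based start of the motif in
#'   the orientation-normalized transcript) and `normalized` (the transcript,
#'   reverse-complemented if the hit was antisense).
#' @export
find_sl_evidence <- function(transcript, motif = SL_TAIL, window = 100L) {
  check_seq(transcript)
  if (nchar(transcript) < nchar(motif))
    stop("transcript shorter than the search motif", call. = FALSE)
  if (window < nchar(motif)) stop("window must be >= motif length", call. = FALSE)
  hit <- function(x) {
    p <- regexpr(motif, substr(x, 1L, window + nchar(motif) - 1L), fixed = TRUE)
    if (p > 0L && p <= window) as.integer(p) else NA_integer_
  }
  p <- hit(transcript)
  if (!is.na(p))
    return(list(orientation = "sense", motif_start = p, normalized = transcript))
  rc <- revcomp(transcript)
  p <- hit(rc)
  if (!is.na(p))
    return(list(orientation = "antisense", motif_start = p, normalized = rc))
  NULL
}

#' Measure the observed SL exon extent
#'
#' Starting from a motif hit, measures the length of the longest SLe suffix
#' present on the transcript: the octamer itself plus contiguous upstream
#' nucleotides matching the full SLe with zero mismatches.  Anything further
#' upstream is the (unconserved) 5' residual.
#'
#' @param transcript orientation-normalized transcript.
#' @param motif_start 1-based start of the octamer hit.
#' @param sle the full SL exon sequence (must end with the octamer).
#' @param motif_len length of the anchoring octamer (default 8).
#' @return list with `extent` (nt of SLe observed, `motif_len`..`nchar(sle)`)
#'   and `residual` (transcript prefix upstream of the observed SLe).
#' @export
measure_sl_extent <- function(transcript, motif_start, sle, motif_len = 8L) {
  L <- nchar(sle)
  if (substr(sle, L - motif_len + 1L, L) !=
      substr(transcript, motif_start, motif_start + motif_len - 1L))
    stop("motif hit is inconsistent with the supplied SLe", call. = FALSE)
  k <- 0L
  max_up <- min(motif_start - 1L, L - motif_len)
  while (k < max_up &&
         substr(transcript, motif_start - 1L - k, motif_start - 1L - k) ==
         substr(sle, L - motif_len - k, L - motif_len - k)) {
    k <- k + 1L
  }
  list(extent = motif_len + k,
       residual = substr(transcript, 1L, motif_start - 1L - k))
}

#' Classify an SL call into an SL type
#'
#' For two-type systems the per-type observed extents decide: the assigned
#' type is the one whose SLe matched through every discriminating position;
#' when the observed extent covers none or only some discriminating
#' positions the call is `incomplete`.  Single-type systems label any motif
#' hit `single` (partial hits on single-SL species count as SL-bearing).
#'
#' @param extents named numeric vector of observed extent per SL type.
#' @param sl_system an [generate_sl_system()] definition.
#' @return one of the system's type names, or `"incomplete"`.
#' @export
classify_sl <- function(extents, sl_system) {
  if (!sl_system$multi_type) return(names(sl_system$types)[1L])
  need <- sl_system$sle_length - min(sl_system$disc_positions) + 1L
  covered <- extents >= need
  if (!any(covered)) return("incomplete")
  names(extents)[covered][which.max(extents[covered])]
}

#' Trim the SL exon (and any 5' residual) off a transcript
#'
#' Removes everything through the SLe terminal `AAG`, returning the mature
#' transcript body.  Transcripts without a motif hit are returned unchanged.
#' Trimming is idempotent.
#'
#' @param transcript orientation-normalized transcript.
#' @param motif_start 1-based start of the octamer hit, or `NA` for no hit.
#' @param motif_len length of the anchoring octamer (default 8).
#' @return the mature sequence (possibly empty).
#' @export
trim_sl <- function(transcript, motif_start, motif_len = 8L) {
  if (is.na(motif_start)) return(transcript)
  substr(transcript, motif_start + motif_len, nchar(transcript))
}

#' Detect and classify SL exons across a transcriptome
#'
#' Runs motif search, orientation normalization, extent measurement,
#' classification and trimming over a set of transcripts.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param sl_system an [generate_sl_system()] definition.
#' @param window 5'-end search window in nt (default 100).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `orientation` (`sense`/`antisense`/`none`), `motif_start`,
#'   `observed_extent`, `sl_type` (a type name, `incomplete`, or `none`),
#'   `complete` (observed extent equals the full SLe length), `residual_len`,
#'   `observed_sle` (the observed SLe suffix) and `mature_seq`.
#' @export
detect_sl <- function(transcripts, sl_system, window = 100L) {
  stopifnot(!is.null(names(transcripts)))
  n <- length(transcripts)
  L <- sl_system$sle_length
  out <- data.frame(
    transcript_id = names(transcripts),
    orientation = rep("none", n), motif_start = NA_integer_,
    observed_extent = 0L, sl_type = "none", complete = FALSE,
    residual_len = NA_integer_, observed_sle = NA_character_,
    mature_seq = unname(transcripts), stringsAsFactors = FALSE)
  # vectorized two-orientation motif search (same contract as
  # find_sl_evidence, batched: one reverse-complement pass for the set)
  motif <- sl_system$motif
  mlen <- nchar(motif)
  spos <- function(x) {
    p <- regexpr(motif, substr(x, 1L, window + mlen - 1L), fixed = TRUE)
    ifelse(p > 0L & p <= window, as.integer(p), NA_integer_)
  }
  sense_p <- spos(transcripts)
  rc <- rep(NA_character_, n)
  no_sense <- which(is.na(sense_p) & nchar(transcripts) >= mlen)
  rc[no_sense] <- revcomp(transcripts[no_sense])
  anti_p <- rep(NA_integer_, n)
  anti_p[no_sense] <- spos(rc[no_sense])

  for (i in seq_len(n)) {
    ev <- if (!is.na(sense_p[i])) {
      list(orientation = "sense", motif_start = sense_p[i],
           normalized = transcripts[[i]])
    } else if (!is.na(anti_p[i])) {
      list(orientation = "antisense", motif_start = anti_p[i],
           normalized = rc[i])
    } else NULL
    if (is.null(ev)) next
    meas <- lapply(sl_system$types, function(sle)
      measure_sl_extent(ev$normalized, ev$motif_start, sle))
    extents <- vapply(meas, `[[`, 0L, "extent")
    type <- classify_sl(extents, sl_system)
    best <- if (type %in% names(extents)) type else which.max(extents)
    ext <- meas[[best]]$extent
    out$orientation[i] <- ev$orientation
    out$motif_start[i] <- ev$motif_start
    out$observed_extent[i] <- ext
    out$sl_type[i] <- type
    out$complete[i] <- ext == L
    out$residual_len[i] <- nchar(meas[[best]]$residual)
    out$observed_sle[i] <- substr(ev$normalized,
                                  ev$motif_start + 8L - ext,
                                  ev$motif_start + 7L)
    out$mature_seq[i] <- trim_sl(ev$normalized, ev$motif_start)
  }
  out
}

#' Distribution of observed SL exon extents
#'
#' @param calls a [detect_sl()] table.
#' @param ks thresholds for cumulative fractions (default 10 and 15 nt).
#' @return list with `histogram` (named table of observed extents over
#'   hit-bearing calls) and `fraction_at_least` (fraction of hit-bearing
#'   calls with extent >= k, per k; `NA` when there are no hits).
#' @export
partial_length_distribution <- function(calls, ks = c(10L, 15L)) {
  ext <- calls$observed_extent[calls$orientation != "none"]
  if (length(ext) == 0L)
    return(list(histogram = table(integer(0)),
                fraction_at_least = stats::setNames(rep(NA_real_, length(ks)), ks)))
  list(histogram = table(ext),
       fraction_at_least = stats::setNames(
         vapply(ks, function(k) mean(ext >= k), 0), ks))
}

#' Estimate the fraction of SL transcripts whose SLe was entirely lost
#'
#' 5' truncation removes a variable number of leading SLe nucleotides; when
#' the whole exon (octamer included) is lost the transcript is undetectable
#' and counted as non-SL.  Treating the number of missing 5' nucleotides as
#' normally distributed, this fits a normal by maximum likelihood to the
#' observed missing counts (a sample truncated to the observable range,
#' i.e. missing <= SLe length - octamer length) and reports the fitted tail
#' mass at or beyond complete exon loss.
#'
#' @param extents observed extents of hit-bearing calls.
#' @param sle_length full SL exon length.
#' @param motif_len anchoring octamer length (default 8).
#' @return estimated fraction in \[0, 1\], with attributes `mu` and `sigma`
#'   (the fitted normal).
#' @export
estimate_missed_sl_fraction <- function(extents, sle_length, motif_len = 8L) {
  if (length(extents) == 0L) stop("no observed extents", call. = FALSE)
  m <- sle_length - extents                 # missing 5' nucleotides
  cmax <- sle_length - motif_len            # largest observable missing count
  if (length(unique(m)) == 1L) {
    warning("degenerate extent histogram (single value); estimate is a point-mass limit")
    est <- as.numeric(m[1L] >= cmax)        # all-full -> 0; all-at-edge -> 1
    return(structure(est, mu = m[1L], sigma = 0))
  }
  nll <- function(par) {
    mu <- par[1L]; sig <- exp(par[2L])
    denom <- pnorm(cmax + 0.5, mu, sig) - pnorm(-0.5, mu, sig)
    if (denom <= 0) return(1e10)
    -sum(dnorm(m, mu, sig, log = TRUE)) + length(m) * log(denom)
  }
  fit <- stats::optim(c(mean(m), log(stats::sd(m))), nll, method = "Nelder-Mead")
  mu <- fit$par[1L]; sig <- exp(fit$par[2L])
  est <- min(max(pnorm(sle_length - 0.5, mu, sig, lower.tail = FALSE), 0), 1)
  structure(est, mu = mu, sigma = sig)
}
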