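# SL-RNA gene discovery in genomic contigs.
#
# Candidate loci are exon hits (full-coverage, high-identity matches of an
# SL exon query, both strands) validated by the SL-RNA gene rules: the two
# nucleotides following the exon must be the splice donor GT, at least a
# minimum intron's worth of sequence must follow the exon, and a poly-T
# terminator tract must match within a window downstream of the donor.  The
# exon/intron boundary 4-mer (expected GGTA) is recorded but not required.

POLYT_PATTERNS <- c(perkinsozoa = "CT{4,6}[GC]",
                    spi = "CT{5}A",
                    dino = "CT{4,7}[GA]")

#' Search contigs for near-exact SL exon matches
#'
#' Finds all full-query-coverage matches of a short query in a set of
#' contigs, on both strands, at or above a minimum percent identity
#' (mismatches and indels both count against identity).
#'
#' @param query the SL exon sequence (>= 16 nt).
#' @param contigs named character vector of contig sequences.
#' @param min_pid minimum identity, identities / aligned columns (default
#'   0.95; use 0.90 for cross-species queries).
#' @return data.frame of hits sorted by contig then position: `contig`,
#'   `strand`, `start`, `end` (1-based, on the forward contig), `pid`.
#' @export
short_match_search <- function(query, contigs, min_pid = 0.95) {
  if (nchar(query) < 16L) stop("query must be >= 16 nt", call. = FALSE)
  if (length(contigs) == 0L) stop("empty genome", call. = FALSE)
  k <- floor(nchar(query) * (1 - min_pid))
  sm <- sub_matrix(1, -1)
  pid_of <- function(q, s) {
    pa <- Biostrings::pairwiseAlignment(q, s, type = "global",
                                        substitutionMatrix = sm,
                                        gapOpening = 0, gapExtension = 1)
    Biostrings::nmatch(pa) / nchar(as.character(Biostrings::alignedPattern(pa)))
  }
  res <- list()
  for (ci in seq_along(contigs)) {
    subj <- Biostrings::DNAString(contigs[[ci]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") query else revcomp(query)
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                    max.mismatch = k, with.indels = TRUE)
      if (length(m) == 0L) next
      st <- Biostrings::start(m); en <- Biostrings::end(m)
      pid <- vapply(seq_along(m), function(i)
        pid_of(pat, as.character(m[[i]])), 0)
      keep <- pid >= min_pid
      if (!any(keep)) next
      df <- data.frame(contig = names(contigs)[ci], strand = strand,
                       start = st[keep], end = en[keep], pid = pid[keep],
                       stringsAsFactors = FALSE)
      # drop overlapping duplicates of the same hit (indel-shifted views)
      df <- df[order(df$start, -df$pid), , drop = FALSE]
      if (nrow(df) > 1L) {
        sel <- rep(TRUE, nrow(df))
        last_end <- df$end[1L]
        for (i in 2:nrow(df)) {
          if (df$start[i] <= last_end) sel[i] <- FALSE
          else last_end <- df$end[i]
        }
        df <- df[sel, , drop = FALSE]
      }
      res[[length(res) + 1L]] <- df
    }
  }
  if (length(res) == 0L)
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0), pid = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(match(out$contig, names(contigs)), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find the first poly-T terminator tract in a sequence window
#'
#' Scans the leading `window` nucleotides for the poly-T tract patterns
#' (C, a run of 4-7 T, then a terminator base): `CT(4-6)G/C`
#' (Perkinsozoa), `CT(5)A` (SPI-like) and `CT(4-7)G/A` (dinoflagellate
#' style).  The leftmost match wins; ties go to the first pattern listed.
#'
#' @param seq sequence to scan.
#' @param window how far into `seq` a match may start (default 120 nt).
#' @param patterns named character vector of regular expressions
#'   (default [POLYT_PATTERNS]).
#' @return `NULL` if no match, else list with `start`, `end` (1-based within
#'   `seq`) and `pattern` (name).
#' @export
find_polyt_tract <- function(seq, window = 120L, patterns = POLYT_PATTERNS) {
  region <- substr(seq, 1L, window + 8L)
  best <- NULL
  for (nm in names(patterns)) {
    m <- regexpr(patterns[[nm]], region)
    if (m > 0L && m <= window && (is.null(best) || m < best$start)) {
      best <- list(start = as.integer(m),
                   end = as.integer(m) + attr(m, "match.length") - 1L,
                   pattern = nm)
    }
  }
  best
}

map_back <- function(strand, contig_len, s, e) {
  if (strand == "+") c(s, e) else c(contig_len - e + 1L, contig_len - s + 1L)
}

#' Validate an exon hit as an SL-RNA gene candidate
#'
#' Applies the SL-RNA gene selection rules to one [short_match_search()]
#' hit: (a) full exon coverage (guaranteed by the search), (b) the intron
#' must begin with the splice donor `GT`, (c) at least `min_intron` nt of
#' sequence must exist downstream of the exon, (d) a poly-T tract must match
#' within `polyt_window` nt after the donor.  The exon/intron boundary 4-mer
#' (exon-terminal base plus the next three; expected `GGTA`) is recorded but
#' not a selection rule.
#'
#' @param hit one row of a [short_match_search()] result.
#' @param contig the contig sequence the hit lies on.
#' @param min_intron minimum intron length in nt (default 40).
#' @param polyt_window poly-T search window after the donor (default 120 nt).
#' @return list: either `list(accepted = TRUE, candidate = <list>)` or
#'   `list(accepted = FALSE, reason = "donor"|"intron"|"polyT")`.  Candidate
#'   coordinates are 1-based on the forward contig.
#' @export
validate_candidate <- function(hit, contig, min_intron = 40L,
                               polyt_window = 120L) {
  clen <- nchar(contig)
  if (hit$start < 1L || hit$end > clen)
    stop("hit interval outside contig", call. = FALSE)
  # work in gene orientation
  ctx <- if (hit$strand == "+") contig else revcomp(contig)
  es <- if (hit$strand == "+") hit$start else clen - hit$end + 1L
  ee <- if (hit$strand == "+") hit$end else clen - hit$start + 1L
  donor <- substr(ctx, ee + 1L, ee + 2L)
  if (donor != "GT") return(list(accepted = FALSE, reason = "donor"))
  if (clen - ee < min_intron) return(list(accepted = FALSE, reason = "intron"))
  tract <- find_polyt_tract(substr(ctx, ee + 1L, clen), polyt_window)
  if (is.null(tract)) return(list(accepted = FALSE, reason = "polyT"))
  polyt_s <- ee + tract$start
  polyt_e <- ee + tract$end
  exon_fwd <- map_back(hit$strand, clen, es, ee)
  intron_fwd <- map_back(hit$strand, clen, ee + 1L, polyt_e)
  polyt_fwd <- map_back(hit$strand, clen, polyt_s, polyt_e)
  list(accepted = TRUE, candidate = list(
    contig = hit$contig, strand = hit$strand,
    exon_start = exon_fwd[1L], exon_end = exon_fwd[2L],
    intron_start = intron_fwd[1L], intron_end = intron_fwd[2L],
    polyt_start = polyt_fwd[1L], polyt_end = polyt_fwd[2L],
    donor_ok = TRUE,
    boundary_motif = substr(ctx, ee, ee + 3L),
    polyt_pattern = tract$pattern,
    total_length = polyt_e - es + 1L,
    exon_pid = hit$pid,
    full_seq = substr(ctx, es, polyt_e)))
}

#' Collapse identical SL-RNA candidates
#'
#' Candidates whose full sequence (exon + intron through the poly-T tract)
#' is identical collapse to one record with a multiplicity count; variants
#' differing anywhere are kept separate.
#'
#' @param candidates data.frame of validated candidates (rows as produced by
#'   [scan_genome()]).
#' @return the deduplicated data.frame with a `multiplicity` column.
#' @export
deduplicate_candidates <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(candidates)
  key <- candidates$full_seq
  first <- !duplicated(key)
  out <- candidates[first, , drop = FALSE]
  out$multiplicity <- as.integer(table(key)[out$full_seq])
  rownames(out) <- NULL
  out
}

#' Scan a genome for SL-RNA gene candidates
#'
#' For each SL exon type in the system: search (both strands), validate,
#' deduplicate.  Per-type counts are counts of distinct (deduplicated)
#' candidates.
#'
#' @param sl_system an [generate_sl_system()] definition.
#' @param contigs named character vector of contigs.
#' @param min_pid minimum exon identity (default 0.95).
#' @param min_intron,polyt_window validation thresholds, see
#'   [validate_candidate()].
#' @return list with `candidates` (deduplicated data.frame, one row per
#'   distinct candidate, with `type` and `multiplicity`), `counts` (named
#'   integer vector per type) and `rejected` (data.frame of rejected hits
#'   with reasons).
#' @export
scan_genome <- function(sl_system, contigs, min_pid = 0.95, min_intron = 40L,
                        polyt_window = 120L) {
  all_cand <- list(); all_rej <- list()
  for (type in names(sl_system$types)) {
    hits <- short_match_search(sl_system$types[[type]], contigs, min_pid)
    for (i in seq_len(nrow(hits))) {
      v <- validate_candidate(hits[i, ], contigs[[hits$contig[i]]],
                              min_intron, polyt_window)
      if (v$accepted) {
        all_cand[[length(all_cand) + 1L]] <-
          data.frame(type = type, v$candidate, stringsAsFactors = FALSE)
      } else {
        all_rej[[length(all_rej) + 1L]] <-
          data.frame(type = type, hits[i, ], reason = v$reason,
                     stringsAsFactors = FALSE)
      }
    }
  }
  cand <- if (length(all_cand) > 0) do.call(rbind, all_cand) else
    data.frame(type = character(0), contig = character(0),
               strand = character(0), exon_start = integer(0),
               exon_end = integer(0), full_seq = character(0),
               stringsAsFactors = FALSE)
  dedup <- if (nrow(cand) > 0) {
    do.call(rbind, lapply(split(cand, cand$type), deduplicate_candidates))
  } else cand
  if (!is.null(dedup) && nrow(dedup) > 0) rownames(dedup) <- NULL
  counts <- stats::setNames(integer(length(sl_system$types)),
                            names(sl_system$types))
  if (!is.null(dedup) && nrow(dedup) > 0) {
    tb <- table(dedup$type)
    counts[names(tb)] <- as.integer(tb)
  }
  list(candidates = dedup,
       counts = counts,
       rejected = if (length(all_rej) > 0) do.call(rbind, all_rej) else NULL)
}

#' Report tandem context of SL-RNA candidates
#'
#' For every contig carrying two or more candidates, reports the ordered
#' exon intervals and the gaps between consecutive candidates.  If a marker
#' sequence (e.g. a 5S rRNA gene) is supplied and found in a contig at
#' `min_marker_pid` identity, the distance from the marker to the nearest
#' candidate on that contig is reported.
#'
#' @param candidates a [scan_genome()] candidate data.frame (use the
#'   pre-deduplication rows if tandem copies are identical).
#' @param contigs named character vector of contigs.
#' @param marker optional marker sequence.
#' @param min_marker_pid identity threshold for the marker search.
#' @return list with `arrays` (data.frame: contig, n, ordered starts, gaps)
#'   and `marker` (data.frame of marker hits with nearest-candidate
#'   distance; `NULL` if no marker given or found).
#' @export
tandem_context_report <- function(candidates, contigs, marker = NULL,
                                  min_marker_pid = 0.95) {
  arrays <- NULL
  if (!is.null(candidates) && nrow(candidates) > 0) {
    for (ct in unique(candidates$contig)) {
      rows <- candidates[candidates$contig == ct, , drop = FALSE]
      if (nrow(rows) < 2L) next
      rows <- rows[order(rows$exon_start), , drop = FALSE]
      gaps <- rows$exon_start[-1L] - rows$polyt_end[-nrow(rows)] - 1L
      arrays <- rbind(arrays, data.frame(
        contig = ct, n = nrow(rows),
        starts = paste(rows$exon_start, collapse = ","),
        gaps = paste(gaps, collapse = ","), stringsAsFactors = FALSE))
    }
  }
  marker_df <- NULL
  if (!is.null(marker) && !is.null(candidates) && nrow(candidates) > 0) {
    hits <- short_match_search(marker, contigs, min_marker_pid)
    for (i in seq_len(nrow(hits))) {
      rows <- candidates[candidates$contig == hits$contig[i], , drop = FALSE]
      if (nrow(rows) == 0L) next
      d <- pmax(rows$exon_start - hits$end[i] - 1L,
                hits$start[i] - rows$polyt_end - 1L)
      marker_df <- rbind(marker_df, data.frame(
        contig = hits$contig[i], marker_start = hits$start[i],
        marker_end = hits$end[i], nearest_distance = max(min(d), 0L),
        stringsAsFactors = FALSE))
    }
  }
  list(arrays = arrays, marker = marker_df)
}

SM_MOTIF_PATTERNS <- c(at4gg = "ATTTTGG",
                       rat4_6gr = "[AG]AT{4,6}G[AG]",
                       at4cgg = "ATTTTCGG",
                       agct3gg = "AGCTTTGG",
                       aaytytga = "AA[CT]T[CT]TGA")

#' Scan an SL-RNA candidate for Sm-binding-site motif variants
#'
#' Searches the candidate sequence for known Sm-site motif variants
#' (`AT(4)GG`, `RAT(4-6)GR`, `AT(4)CGG`, `AGCT(3)GG`, `AAYTYTGA`) and
#' labels each match by the region it falls in.  An empty result is valid
#' (no classical Sm site is expected in Perkinsozoa SL-RNAs).
#'
#' @param seq candidate sequence (exon followed by intron).
#' @param exon_length number of leading nucleotides that are exon.
#' @return data.frame: `pattern`, `start`, `end` (1-based within `seq`),
#'   `region` (`exon`, `intron` or `boundary`).
#' @export
sm_motif_scan <- function(seq, exon_length) {
  out <- NULL
  for (nm in names(SM_MOTIF_PATTERNS)) {
    m <- gregexpr(SM_MOTIF_PATTERNS[[nm]], seq)[[1L]]
    if (m[1L] < 0L) next
    for (i in seq_along(m)) {
      s <- as.integer(m[i]); e <- s + attr(m, "match.length")[i] - 1L
      region <- if (e <= exon_length) "exon"
                else if (s > exon_length) "intron" else "boundary"
      out <- rbind(out, data.frame(pattern = nm, start = s, end = e,
                                   region = region, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(pattern = character(0), start = integer(0),
                      end = integer(0), region = character(0),
                      stringsAsFactors = FALSE)
  out
}

#' Verify trans-splicing by genomic absence of the SL exon upstream of a gene
#'
#' Locates the gene locus of an SL-trimmed (mature) transcript by local
#' alignment against the contigs, then tests whether the SL exon occurs in
#' the genomic window immediately upstream of the aligned gene start.  A
#' trans-spliced gene has no genomically encoded SLe upstream; finding one
#' means the leader is cis-encoded.  The nearest upstream `AG` acceptor
#' dinucleotide and the first downstream `ATG` are also reported.
#'
#' @param mature SL-trimmed transcript sequence.
#' @param contigs named character vector of contigs.
#' @param sle the full SL exon sequence.
#' @param min_pid minimum gene-locus alignment identity (default 0.95).
#' @param upstream_window genomic window upstream of the gene start searched
#'   for the SLe (default 200 nt).
#' @return list: `status` (`"confirmed"`, `"cis_encoded"` or `"unmapped"`),
#'   `contig`, `strand`, `pid`, `gene_start`, `gene_end` (forward-contig
#'   coordinates), `sle_in_genomic_5utr`, `acceptor_position` (start of the
#'   nearest upstream `AG`, relative to the gene start, e.g. -2 when
#'   immediately adjacent) and `atg_position` (1-based within the gene, NA
#'   if absent).
#' @export
verify_trans_splicing <- function(mature, contigs, sle, min_pid = 0.95,
                                  upstream_window = 200L) {
  best <- NULL
  for (ct in names(contigs)) {
    al <- smith_waterman_local(mature, contigs[[ct]], subject_id = ct)
    if (is.null(best) || al$score > best$score) best <- al
  }
  if (is.null(best) || best$aligned_length == 0L || best$pid < min_pid ||
      best$aligned_length < 0.9 * nchar(mature)) {
    return(list(status = "unmapped", contig = NA_character_,
                strand = NA_character_, pid = NA_real_,
                gene_start = NA_integer_, gene_end = NA_integer_,
                sle_in_genomic_5utr = NA, acceptor_position = NA_integer_,
                atg_position = NA_integer_))
  }
  contig <- contigs[[best$subject_id]]
  clen <- nchar(contig)
  ctx <- if (best$strand == "+") contig else revcomp(contig)
  gs <- if (best$strand == "+") best$subject_start else clen - best$subject_end + 1L
  ge <- if (best$strand == "+") best$subject_end else clen - best$subject_start + 1L
  ups <- substr(ctx, max(1L, gs - upstream_window), gs - 1L)
  k <- floor(nchar(sle) * 0.05)
  sle_hit <- length(Biostrings::matchPattern(
    Biostrings::DNAString(sle), Biostrings::DNAString(ups),
    max.mismatch = k, with.indels = TRUE)) > 0L
  ag <- gregexpr("AG", ups, fixed = TRUE)[[1L]]
  acceptor <- if (ag[1L] > 0L) max(ag) - nchar(ups) - 1L else NA_integer_
  atg <- regexpr("ATG", substr(ctx, gs, ge), fixed = TRUE)
  gene_fwd <- map_back(best$strand, clen, gs, ge)
  list(status = if (sle_hit) "cis_encoded" else "confirmed",
       contig = best$subject_id, strand = best$strand, pid = best$pid,
       gene_start = gene_fwd[1L], gene_end = gene_fwd[2L],
       sle_in_genomic_5utr = sle_hit,
       acceptor_position = acceptor,
       atg_position = if (atg > 0L) as.integer(atg) else NA_integer_)
}

#' Write SL-RNA candidates as GFF3
#'
#' Emits `SL_exon`, `SL_intron` and `polyT_tract` features per candidate,
#' grouped by a shared `Parent` attribute, with 1-based GFF coordinates.
#'
#' @param candidates a [scan_genome()] candidate data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_gff3 <- function(candidates, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(NROW(candidates))) {
    r <- candidates[i, ]
    id <- sprintf("slrna%03d", i)
    rows <- list(
      c(r$exon_start, r$exon_end, "SL_exon"),
      c(r$intron_start, r$intron_end, "SL_intron"),
      c(r$polyt_start, r$polyt_end, "polyT_tract"))
    for (f in rows) {
      writeLines(paste(r$contig, "sltrans", f[3L],
                       min(as.integer(f[1:2])), max(as.integer(f[1:2])),
                       ".", r$strand, ".",
                       sprintf("Parent=%s;sl_type=%s", id, r$type),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
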