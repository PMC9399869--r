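# Partition bookkeeping: how the transcriptome splits into non-SL, per-type
# SL, and incomplete-SL categories, plus SL+/- isoform pairs and cross-type
# shared transcript species.
#
# Percentage conventions: transcriptome-wide rows (SL-bearing, no-SL,
# isoform pairs, cross-type) are percentages of the total retained
# transcript count; within-SL rows (each type, incomplete, complete) are
# percentages of the SL-bearing count.  Percentages are rounded half-up to
# two decimals and recompute exactly from the counts.

#' Build a partition summary from category counts
#'
#' @param total total retained transcripts.
#' @param no_sl transcripts with no SL evidence.
#' @param type_counts named integer vector of classified SL transcripts per
#'   type (e.g. `c(type1 = ..., type2 = ...)` or `c(single = ...)`).
#' @param incomplete SL-bearing transcripts whose observed extent did not
#'   cover the type-discriminating positions.
#' @param complete SL-bearing transcripts carrying the full-length SLe
#'   (`NA` if not tracked).
#' @param sl_pairs transcript species with both an SL-bearing and a non-SL
#'   isoform.
#' @param cross_type transcript species carrying two distinct SL types.
#' @return object of class `sl_partition` with elements `counts` and
#'   `percentages`.  The SL-bearing count is `sum(type_counts) + incomplete`;
#'   if `no_sl + sl_bearing` differs from `total` the remainder is recorded
#'   as `unaccounted` with a warning (published category counts are not
#'   always internally consistent).
#' @export
partition_from_counts <- function(total, no_sl, type_counts, incomplete = 0L,
                                  complete = NA_integer_, sl_pairs = 0L,
                                  cross_type = 0L) {
  sl_bearing <- sum(type_counts) + incomplete
  unaccounted <- total - no_sl - sl_bearing
  if (unaccounted != 0L)
    warning("category counts leave ", unaccounted,
            " of ", total, " transcripts unaccounted")
  counts <- c(total = total, no_sl = no_sl, sl_bearing = sl_bearing,
              type_counts, incomplete = incomplete, complete = complete,
              sl_pairs = sl_pairs, cross_type = cross_type,
              unaccounted = unaccounted)
  pct_total <- function(x) round_half_up(100 * x / total, 2)
  pct_sl <- function(x) if (sl_bearing > 0) round_half_up(100 * x / sl_bearing, 2) else NA_real_
  percentages <- c(
    sl_bearing_of_total = pct_total(sl_bearing),
    no_sl_of_total = pct_total(no_sl),
    stats::setNames(pct_sl(type_counts), paste0(names(type_counts), "_of_sl")),
    incomplete_of_sl = pct_sl(incomplete),
    complete_of_sl = if (is.na(complete)) NA_real_ else pct_sl(complete),
    sl_pairs_of_total = pct_total(sl_pairs),
    cross_type_of_total = pct_total(cross_type))
  structure(list(counts = counts, percentages = percentages),
            class = "sl_partition")
}

#' Summarize the SL partition of a transcriptome
#'
#' Aggregates a [detect_sl()] call table into category counts and
#' percentages.  SL+/- isoform pairs are transcript species (groups of
#' transcripts with identical mature body sequence) containing both a
#' hit-bearing and a no-hit member; cross-type shared species are groups
#' containing two distinct classified SL types.
#'
#' @param calls a [detect_sl()] table.
#' @return an `sl_partition` object (see [partition_from_counts()]).
#' @export
partition_summary <- function(calls) {
  if (anyDuplicated(calls$transcript_id))
    stop("duplicate calls for a transcript", call. = FALSE)
  hit <- calls$orientation != "none"
  types <- setdiff(unique(calls$sl_type), c("none", "incomplete"))
  type_counts <- vapply(types, function(t) sum(calls$sl_type == t), 0L)
  # body-identical groups: mature body for SL calls, full sequence otherwise
  grp <- split(seq_len(nrow(calls)), calls$mature_seq)
  grp <- grp[lengths(grp) > 1L]
  sl_pairs <- sum(vapply(grp, function(i) any(hit[i]) && any(!hit[i]), TRUE))
  cross <- sum(vapply(grp, function(i)
    length(intersect(unique(calls$sl_type[i]), types)) >= 2L, TRUE))
  partition_from_counts(
    total = nrow(calls), no_sl = sum(!hit),
    type_counts = type_counts,
    incomplete = sum(calls$sl_type == "incomplete"),
    complete = sum(calls$complete),
    sl_pairs = sl_pairs, cross_type = cross)
}

#' @export
print.sl_partition <- function(x, ...) {
  cat("SL partition\n  counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-14s %s\n", nm, format(x$counts[[nm]])))
  cat("  percentages:\n")
  for (nm in names(x$percentages))
    cat(sprintf("    %-22s %s\n", nm, format(x$percentages[[nm]])))
  invisible(x)
}

#' Write a partition summary as a TSV table
#'
#' @param x an `sl_partition` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(x, path) {
  df <- data.frame(
    metric = c(paste0("count_", names(x$counts)),
               paste0("pct_", names(x$percentages))),
    value = c(unname(x$counts), unname(x$percentages)))
  df$value[is.na(df$value)] <- "."
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
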