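# SL system definitions.  An SL system describes, per species, the full SL
# exon (SLe) sequence of each SL type, which positions discriminate between
# types, and the geometry of the SL-RNA gene (intron template length and
# poly-T terminator pattern).
#
# All default SLe sequences share the Perkinsozoa 5' consensus decamer
# ACCGTAGCCA and the conserved 3' octamer GGCTCAAG (terminal triplet AAG);
# the spacer between the two is adenine-rich, reflecting the A-enriched
# insertions seen in the longer Perkinsozoa SL exons.

SL_HEAD <- "ACCGTAGCCA"  # conserved 5' decamer
SL_TAIL <- "GGCTCAAG"    # conserved 3' octamer; terminal triplet AAG

#' Construct a spliced-leader system definition
#'
#' Builds the SL exon definitions and SL-RNA gene geometry for one of three
#' default systems, or a custom one:
#' \describe{
#'   \item{`"psinerae"`}{two 28-nt SL exon types identical except at
#'     positions 13-14 (type 1 `TT`, type 2 `CA` by default); poly-T
#'     terminator pattern `CT(4-6)G/C`.}
#'   \item{`"mnigrum"`}{a single 25-nt SL exon; poly-T pattern `CT(4-6)G/C`.}
#'   \item{`"spi"`}{a single 22-nt SL exon; poly-T pattern `CT(5)A`.}
#' }
#' All exons start with `ACCGTAGCCA`, end with `GGCTCAAG`, and are padded
#' with an A-rich spacer to the requested length.  The discriminating
#' alleles of the two-type system are configurable, not biologically
#' asserted.
#'
#' @param species one of `"psinerae"`, `"mnigrum"`, `"spi"`.
#' @param sle_length SL exon length in nt (default per species: 28, 25, 22);
#'   must be at least 18 (decamer + octamer).
#' @param disc_positions integer positions (1-based within the SLe) that
#'   discriminate SL types; only used for two-type systems.
#' @param alleles named list of per-type allele strings at the
#'   discriminating positions (two-type systems only).
#' @param intron_length length of the SL intron template, donor through the
#'   end of the poly-T tract, in nt.  Defaults (40, 35, 44) give total
#'   exon+intron ORF lengths of 68, 60 and 66 nt respectively, matching the
#'   observed Perkinsozoa SL-RNA ORF length ranges.
#' @param polyt_pattern which terminator pattern the genome generator plants
#'   (`"perkinsozoa"` = CT(4-6)G/C, `"spi"` = CT(5)A, `"dino"` = CT(4-7)G/A).
#' @return an `sl_system` list with elements `species`, `types` (named list
#'   of full SLe strings), `sle_length`, `disc_positions`, `alleles`,
#'   `motif` (3' octamer), `intron_length`, `polyt_pattern`,
#'   `multi_type` flag.
#' @export
generate_sl_system <- function(species = c("psinerae", "mnigrum", "spi"),
                               sle_length = NULL,
                               disc_positions = c(13L, 14L),
                               alleles = list(type1 = "TT", type2 = "CA"),
                               intron_length = NULL,
                               polyt_pattern = NULL) {
  species <- match.arg(species)
  defaults <- list(
    psinerae = list(len = 28L, intron = 40L, polyt = "perkinsozoa"),
    mnigrum  = list(len = 25L, intron = 35L, polyt = "perkinsozoa"),
    spi      = list(len = 22L, intron = 44L, polyt = "spi"))
  d <- defaults[[species]]
  sle_length <- as.integer(sle_length %||% d$len)
  intron_length <- as.integer(intron_length %||% d$intron)
  polyt_pattern <- polyt_pattern %||% d$polyt
  if (sle_length < 18L)
    stop("sle_length must be >= 18 (5' decamer + 3' octamer)", call. = FALSE)

  spacer_len <- sle_length - nchar(SL_HEAD) - nchar(SL_TAIL)
  # deterministic A-rich spacer: TC then A-run (truncated/extended as needed)
  spacer <- substr(paste0("TC", strrep("A", max(spacer_len, 0L))), 1L, spacer_len)

  multi <- species == "psinerae"
  if (multi) {
    if (any(disc_positions <= nchar(SL_HEAD)) ||
        any(disc_positions > nchar(SL_HEAD) + spacer_len))
      stop("discriminating positions must lie in the SLe spacer region",
           call. = FALSE)
    types <- lapply(alleles, function(al) {
      if (nchar(al) != length(disc_positions))
        stop("allele string length must match number of discriminating positions",
             call. = FALSE)
      sp <- spacer
      for (i in seq_along(disc_positions)) {
        p <- disc_positions[i] - nchar(SL_HEAD)
        substr(sp, p, p) <- substr(al, i, i)
      }
      paste0(SL_HEAD, sp, SL_TAIL)
    })
  } else {
    types <- list(single = paste0(SL_HEAD, spacer, SL_TAIL))
    disc_positions <- integer(0)
    alleles <- list()
  }
  structure(list(species = species, types = types, sle_length = sle_length,
                 disc_positions = disc_positions, alleles = alleles,
                 motif = SL_TAIL, multi_type = multi,
                 intron_length = intron_length,
                 polyt_pattern = polyt_pattern),
            class = "sl_system")
}

#' @export
print.sl_system <- function(x, ...) {
  cat(sprintf("SL system '%s': %d type(s), SLe length %d nt\n",
              x$species, length(x$types), x$sle_length))
  for (nm in names(x$types)) cat(sprintf("  %-8s %s\n", nm, x$types[[nm]]))
  if (x$multi_type)
    cat("  discriminating positions:", paste(x$disc_positions, collapse = ","), "\n")
  cat(sprintf("  intron template %d nt, poly-T pattern '%s'\n",
              x$intron_length, x$polyt_pattern))
  invisible(x)
}
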