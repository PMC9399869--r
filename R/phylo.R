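# Parsimony analysis of aligned SL exon sequences with the gap character
# treated as a fifth state, with exhaustive unrooted-topology search for
# small taxon sets.

STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 16L)

#' Build a character alignment from aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   over A, C, G, T and `-` (>= 3 taxa).
#' @return character matrix (taxa x sites) with taxon rownames.
#' @export
character_alignment <- function(seqs) {
  if (length(seqs) < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  if (!all(mat %in% names(STATE_BITS)))
    stop("alignment characters must be A, C, G, T or '-'", call. = FALSE)
  mat
}

#' Fitch parsimony score of a topology (gaps as a fifth state)
#'
#' Per-site Fitch bottom-up pass over the five-state alphabet
#' \{A, C, G, T, -\}: at each internal node the child state sets are
#' intersected; an empty intersection costs one change and takes the union.
#' Multifurcations are folded pairwise (equivalent to an arbitrary binary
#' resolution, which does not affect the unrooted score).
#'
#' @param tree an `ape::phylo` tree whose tip labels match the alignment
#'   rownames (rooted or unrooted; the score is root-invariant).
#' @param alignment a [character_alignment()] matrix.
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, alignment) {
  if (!setequal(tree$tip.label, rownames(alignment)))
    stop("tree tips and alignment taxa differ", call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sites <- ncol(alignment)
  bits <- matrix(0L, ntip + nnode, sites)
  bits[seq_len(ntip), ] <-
    matrix(STATE_BITS[alignment[tree$tip.label, ]], ntip, sites)
  tr <- ape::reorder.phylo(tree, "postorder")
  score <- 0L
  edge <- tr$edge
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode))
  for (i in seq_len(nrow(edge))) {
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    if (!done[parent]) {            # first child initializes the parent set
      bits[parent, ] <- bits[child, ]
      done[parent] <- TRUE
    } else {
      inter <- bitwAnd(bits[parent, ], bits[child, ])
      empty <- inter == 0L
      score <- score + sum(empty)
      bits[parent, ] <- ifelse(empty,
                               bitwOr(bits[parent, ], bits[child, ]),
                               inter)
    }
  }
  as.integer(score)
}

#' Exhaustive maximum-parsimony search over unrooted topologies
#'
#' Enumerates all unrooted binary topologies on the alignment's taxa
#' (3*5*...*(2n-5) of them), scores each with [fitch_score()], and returns
#' every topology attaining the minimum.  Ties are all reported, in the
#' deterministic enumeration order.
#'
#' @param alignment a [character_alignment()] matrix with 3 to 8 taxa.
#' @return list with `trees` (`ape::multiPhylo` of best topologies),
#'   `score` (the minimum), `n_topologies` (number scored) and `scores`
#'   (all scores, in enumeration order).
#' @export
exhaustive_parsimony_search <- function(alignment) {
  n <- nrow(alignment)
  if (n < 3L || n > 8L) stop("taxon count must be between 3 and 8", call. = FALSE)
  topos <- phangorn::allTrees(n, rooted = FALSE,
                              tip.label = rownames(alignment))
  scores <- vapply(topos, fitch_score, 0L, alignment = alignment)
  best <- which(scores == min(scores))
  trees <- lapply(best, function(i) topos[[i]])  # expand compressed labels
  class(trees) <- "multiPhylo"
  list(trees = trees, score = min(scores),
       n_topologies = length(topos), scores = scores)
}

#' Per-branch character-change counts for one most-parsimonious assignment
#'
#' After the Fitch bottom-up pass, internal states are fixed top-down
#' (preferring the parent's state when compatible, otherwise the first
#' state in A,C,G,T,- order).  The assignment is one of possibly many
#' most-parsimonious labelings; counts on individual branches are therefore
#' not unique, though their total equals the Fitch score.
#'
#' @param tree an `ape::phylo` topology.
#' @param alignment a [character_alignment()] matrix.
#' @return data.frame: `parent`, `child` (node numbers), `changes`.
#' @export
branch_changes <- function(tree, alignment) {
  # the top-down refinement requires a rooted binary tree; resolve the
  # trifurcating root of an unrooted tree arbitrarily -- the unrooted score
  # is unchanged by the resolution
  tree <- ape::multi2di(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sites <- ncol(alignment)
  bits <- matrix(0L, ntip + nnode, sites)
  bits[seq_len(ntip), ] <-
    matrix(STATE_BITS[alignment[tree$tip.label, ]], ntip, sites)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode))
  for (i in seq_len(nrow(edge))) {
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    if (!done[parent]) { bits[parent, ] <- bits[child, ]; done[parent] <- TRUE }
    else {
      inter <- bitwAnd(bits[parent, ], bits[child, ])
      bits[parent, ] <- ifelse(inter == 0L,
                               bitwOr(bits[parent, ], bits[child, ]), inter)
    }
  }
  first_bit <- function(b) bitwAnd(b, bitwAnd(-b, b))  # lowest set bit
  state <- matrix(0L, ntip + nnode, sites)
  root <- edge[nrow(edge), 1L]
  state[root, ] <- first_bit(bits[root, ])
  for (i in rev(seq_len(nrow(edge)))) {              # preorder
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    keep <- bitwAnd(state[parent, ], bits[child, ]) != 0L
    state[child, ] <- ifelse(keep, state[parent, ], first_bit(bits[child, ]))
  }
  data.frame(parent = edge[, 1L], child = edge[, 2L],
             changes = vapply(seq_len(nrow(edge)), function(i)
               sum(state[edge[i, 1L], ] != state[edge[i, 2L], ]), 0L))
}

#' Align a set of SL exon sequences
#'
#' Pre-aligned input (equal lengths containing `-`) is passed through.
#' Otherwise a progressive center-star alignment anchored on the first
#' sequence (the fixed input-order guide) is built from pairwise
#' [needleman_wunsch_global()] alignments: each sequence is aligned to the
#' anchor and the per-pair gap patterns in the anchor are merged.
#'
#' @param seqs named character vector of >= 3 SL exon sequences.
#' @return a [character_alignment()] matrix.
#' @export
align_sl_set <- function(seqs) {
  if (length(seqs) < 3L) stop("need >= 3 sequences", call. = FALSE)
  if (any(grepl("-", seqs, fixed = TRUE)) || length(unique(nchar(seqs))) == 1L) {
    if (length(unique(nchar(seqs))) != 1L)
      stop("pre-aligned input must have equal lengths", call. = FALSE)
    return(character_alignment(seqs))
  }
  anchor <- seqs[[1L]]
  pws <- lapply(seqs[-1L], function(s) needleman_wunsch_global(anchor, s))
  # merged anchor coordinate system: for each anchor position, the maximum
  # number of inserted columns occurring before it in any pairwise alignment
  n_anchor <- nchar(anchor)
  ins_before <- matrix(0L, length(pws), n_anchor + 1L)
  for (j in seq_along(pws)) {
    a_chars <- strsplit(pws[[j]]$a, "")[[1L]]
    pos <- 0L
    for (ch in a_chars) {
      if (ch == "-") ins_before[j, pos + 1L] <- ins_before[j, pos + 1L] + 1L
      else pos <- pos + 1L
    }
  }
  max_ins <- apply(ins_before, 2L, max)
  width <- n_anchor + sum(max_ins)
  project <- function(a_aln, b_aln) {
    out <- character(width)
    oi <- 1L; pos <- 0L; pend <- 0L
    a_chars <- strsplit(a_aln, "")[[1L]]
    b_chars <- strsplit(b_aln, "")[[1L]]
    emit <- function(ch) { out[oi] <<- ch; oi <<- oi + 1L }
    flush_slot <- function(slot, used) {
      for (r in seq_len(max_ins[slot] - used)) emit("-")
    }
    used <- 0L
    for (i in seq_along(a_chars)) {
      if (a_chars[i] == "-") { emit(b_chars[i]); used <- used + 1L }
      else {
        flush_slot(pos + 1L, used); used <- 0L
        pos <- pos + 1L
        emit(b_chars[i])
      }
    }
    flush_slot(pos + 1L, used)
    paste(out, collapse = "")
  }
  rows <- c(
    stats::setNames(project(paste(rep("X", n_anchor), collapse = ""), anchor),
                    names(seqs)[1L]),
    stats::setNames(vapply(pws, function(p) project(p$a, p$b), ""),
                    names(seqs)[-1L]))
  character_alignment(rows)
}
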