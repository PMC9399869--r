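# Independent oracles used by the property-style tests.  These are written
# from first principles (plain dynamic programming / exhaustive enumeration)
# and share no code with the package implementations they check.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# plain Smith-Waterman DP, single strand: best local alignment score
sw_score_oracle_1strand <- function(a, b, match, mismatch, gap) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

sw_score_oracle <- function(a, b, match = 1, mismatch = -2, gap = -2) {
  max(sw_score_oracle_1strand(a, b, match, mismatch, gap),
      sw_score_oracle_1strand(rc_oracle(a), b, match, mismatch, gap))
}

# plain Needleman-Wunsch DP score
nw_score_oracle <- function(a, b, match = 1, mismatch = -2, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- (0:n) * gap; H[1, ] <- (0:m) * gap
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
    }
  }
  H[n + 1, m + 1]
}

# Fitch parsimony score by brute force: minimize, per site, the number of
# edge mismatches over all assignments of the five states to internal nodes
fitch_score_oracle <- function(tree, alignment) {
  states <- c("A", "C", "G", "T", "-")
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  internal <- sort(unique(edge[, 1]))
  total <- 0L
  for (site in seq_len(ncol(alignment))) {
    tip_state <- alignment[tree$tip.label, site]
    grids <- rep(list(states), length(internal))
    combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      assign_state <- function(node) {
        if (node <= ntip) tip_state[node]
        else combos[r, match(node, internal)]
      }
      cost <- sum(vapply(seq_len(nrow(edge)), function(e)
        assign_state(edge[e, 1]) != assign_state(edge[e, 2]), TRUE))
      best <- min(best, cost)
    }
    total <- total + best
  }
  as.integer(total)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_p_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  sets <- combn(n, n1)
  us <- apply(sets, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Kruskal-Wallis H from first-principles rank arithmetic (no tie correction;
# use on tie-free data only)
kw_h_oracle <- function(groups) {
  all_v <- unlist(groups)
  n <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
}

# exact hypergeometric enrichment tail by enumeration of all test sets
hyper_p_oracle <- function(universe_size, term_count, test_size, observed) {
  sets <- combn(universe_size, test_size)
  in_term <- seq_len(term_count)   # wlog the first term_count ids carry the term
  hits <- apply(sets, 2, function(ix) sum(ix %in% in_term))
  mean(hits >= observed)
}
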