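---
title: "Methods: detecting and analysing spliced-leader trans-splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing spliced-leader trans-splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sltrans)
```

## The biological problem

Spliced-leader trans-splicing (SLTS) transfers a short exon — the spliced
leader, SLe — from a small non-coding SL-RNA onto the 5' end of pre-mRNAs,
so that unrelated mature mRNAs share an identical 5' signature. In
Perkinsozoa parasites the SLe is 22–28 nt, begins with a conserved
`ACCGTAGCCA` decamer and ends with the octamer `GGCTCAAG` (terminal triplet
`AAG`); a species can carry more than one SLe variant in parallel, in which
case the transcriptome is effectively segregated into SL-defined pools.
This package detects SL evidence on assembled transcripts, recovers the
SL-RNA genes from genomic contigs, and asks two downstream questions of the
SL pools: do they differ in transcript abundance, and are they enriched for
particular functional (GO) categories?

## Detection model and its assumptions

Assembled transcripts frequently lack their outermost 5' nucleotides, so
detection cannot require the full SLe. Instead:

1. **Anchor.** The conserved SLe 3' octamer is searched within the first
   100 nt of the transcript (sense) and, failing that, its reverse
   complement within the last 100 nt (antisense); assembly strand is
   arbitrary, so antisense hits are reverse-complemented before all
   downstream steps. When both orientations hit, sense wins (a fixed,
   documented tie-break; both hits in one transcript are vanishingly rare).
2. **Extent.** The anchor is extended upstream base-by-base against the
   full SLe with *zero mismatches allowed*. Exact matching is conservative
   and reproducible; one sequencing error inside the observed SLe shortens
   the measured extent rather than producing a fuzzy call.
3. **Typing.** If the observed extent covers every type-discriminating
   position (positions 13–14 of the 28-nt two-type system — covered when
   the extent is at least 16 nt), the transcript takes the type whose
   alleles match; otherwise it is *incomplete*. In single-SL species any
   anchor hit counts as SL-bearing, however short.
4. **Trimming.** The mature body is everything after the SLe terminal
   `AAG`; the unconserved 5' residual upstream of the observed SLe is
   discarded with it. Trimming is idempotent because the body no longer
   carries the anchor in its 5' window.

The implied error model is one-sided: a transcript can lose SL evidence
(5' truncation) but essentially cannot gain it, since a chance octamer in a
5' window is rare and a chance *typed* extent rarer still.

## The missed-SL estimate

Transcripts whose truncation removed the whole SLe (or just the octamer)
are undetectable and sit in the non-SL pool. Treating the number of missing
5' nucleotides as normally distributed, the observed missing counts are a
sample truncated to the observable range (missing ≤ SLe length − 8). We fit
the normal by maximum likelihood with the truncation in the likelihood
(Nelder–Mead on (μ, log σ), initialized at the sample moments; a
single-valued histogram is degenerate and returns a warned point-mass
limit), then report the fitted mass at or beyond complete loss,
`P(X ≥ L − 0.5)` on the rounding-corrected scale. Under the default
truncation regime this estimate is far below the 10% level that matters for
interpretation. The estimator is honest but ill-conditioned when the
observable window covers only the far tail of the fitted normal: in that
regime (mean missing ≈ SLe length) its sampling variance is large, which is
why the tests exercise it there with a deterministic quantized-tail
histogram rather than random draws.

## SL-RNA gene discovery

Candidate loci are full-coverage matches of an SLe query in a contig
(both strands, mismatches and indels counted against identity, default
≥95%), validated by three rules: the two nucleotides following the exon are
the splice donor `GT`; at least 40 nt of sequence follows the exon (the
minimal intron); and a poly-T terminator tract matches within 120 nt after
the donor. The terminator patterns are `CT{4,6}[GC]`, `CT{5}A` and
`CT{4,7}[GA]` — a C, a run of 4–7 T, and a closing base — with the leftmost
match winning and ties going to the first pattern listed. The 4-mer at the
exon/intron boundary (expected `GGTA`: the exon-terminal G plus `GTA`) is
*recorded but not required*, since it is an observed feature of these genes
rather than a selection rule. The 120-nt poly-T window is deliberately
permissive: observed Perkinsozoa SL-RNA ORFs run 60–68 nt total, so a real
terminator sits well inside it. Identical candidates (exon through poly-T)
collapse to one record with a multiplicity count, which is how a tandem
array of identical copies is reported. The false-positive rate of the whole
chain on uniform random sequence is negligible — a ≥95%-identity, full
coverage 28-mer match alone is already below one expected hit per ~10^10
positions — and the test suite confirms zero candidates across 2 Mb of
random sequence.

Trans-splicing itself is verified per gene: the SL-trimmed transcript is
located in the genome by local alignment (≥95% identity over ≥90% of the
mature body), and the SLe is searched in the 200 nt upstream of the aligned
gene start. Absence upstream (with the acceptor `AG` reported, e.g. at
position −2) confirms the leader was added post-transcriptionally; presence
means it is cis-encoded. The 200-nt window is a design choice — 5' UTRs
here are short, and widening the window only makes the check stricter.

## Abundance comparison

Counts are TPM-normalized (`TPM_i = 10^6 (c_i/l_i)/Σ_j c_j/l_j`; each
sample column sums to one million by construction), replicate TPM is
averaged per transcript, and transcripts at or below the lower quartile of
mean TPM are removed as low-coverage — these are exactly the transcripts
whose 5' ends are most likely under-sampled. The quartile uses linear
interpolation and the filter keeps strict exceeders; an all-tied input
would drop everything, so that degenerate case keeps all with a warning.
Incomplete-SL calls are excluded from pools (they cannot be attributed to
a type). With three or more pools a tie-corrected Kruskal–Wallis test runs
alongside the pairwise Mann–Whitney matrix; with two pools the pairwise
test stands alone. The Mann–Whitney p-value is exact — full enumeration of
group assignments, two-sided by distance of U from its null mean — whenever
the enumeration is no larger than a 10-vs-10 problem, and otherwise uses
the tie-corrected normal approximation with continuity correction. All
tests are two-sided.

## Permutation enrichment

For each SL pool and term, the observed member count is compared with the
count distribution over random transcript samples of the pool's size drawn
from the annotated transcriptome without replacement (the transcript, not
the annotation, is the sampling unit). The p-value is one-sided for
enrichment with the add-one estimator `(1+k)/(1+N)`, so it is never zero
and never exceeds one; the default is 100 000 samples. When
`choose(universe, pool)` is at most 10^6 the exact hypergeometric tail
replaces sampling — same contract, exact answer. Raw p-values at α = 0.05
flag significance by default, matching common practice for these screens;
Benjamini–Hochberg adjustment is available behind a flag. Fold enrichment
is observed/expected with the expectation taken from the universe
frequency; note that a term planted *into* a pool also raises its universe
frequency, so realized fold is below the planted in-pool ratio — the
p-value, not the fold, is the detection criterion.

## Parsimony on SL exons

SL exon variants differ by substitutions *and* indels (the 21-nt vs 22-nt
leaders of *Perkinsus marinus* differ by one deleted T), so alignment gaps
are informative and are scored as a fifth character state. Fitch scoring
runs over the 5-letter alphabet {A,C,G,T,−} with bitmask set operations;
multifurcating (unrooted-style) roots are folded pairwise, which equals an
arbitrary binary resolution and leaves the unrooted score unchanged. For up
to 8 taxa every unrooted binary topology — (2n−5)!! of them — is scored and
all minimum-score topologies are returned in enumeration order; no
tie-break pretends the optimum is unique. Per-branch change counts come
from one most-parsimonious assignment (top-down refinement on a resolved
binary tree, preferring the parent state, otherwise the first state in
A,C,G,T,− order) and are documented as non-unique, though their sum always
equals the score. Input sets of equal length are treated as pre-aligned;
unequal-length sets are aligned by a center-star merge of pairwise global
alignments anchored on the first sequence. Alignment scoring is match +1,
mismatch −2, gap −2 per position (linear), a BLASTn-short-like scheme suited
to short, high-identity queries; `N` matches nothing, which is conservative
under the ≥95/98% identity cutoffs. Percent identity is identities over
aligned columns *including* gap columns. One caveat: when co-optimal local
alignments of different lengths exist, the reported pid depends on which
optimal traceback the aligner returns, so only the alignment score is
guaranteed symmetric under swapping query and subject.

## What the synthetic generator emulates — and what it does not

The generator produces the statistical structure the analysis assumes, with
defaults chosen once as the study conditions:

- **SL systems**: two 28-nt types differing at positions 13–14 (alleles
  `TT`/`CA` — configurable, since the true discriminating nucleotides are a
  free parameter), a single 25-nt type, and a single 22-nt type; all share
  the 5' decamer and 3' octamer, padded with an A-rich spacer.
- **Truncation**: missing 5' nucleotides ~ round(Normal(6, 4)), clipped to
  [0, SLe length]. This reproduces a regime where the extent histogram
  peaks at near-complete leaders, more than 90% of SL evidence retains at
  least the last 10 SLe nucleotides, and complete exon loss is far below
  10%.
- **Pools**: 21% type-1, 6% type-2 by default (roughly an SL-bearing
  quarter of the transcriptome split ~78/22 between types); 0.5% SL+/−
  isoform pairs sharing an identical body; 0.2% cross-type species.
- **Abundance**: per-transcript log-normal(meanlog 4, sdlog 1.2) with a
  2.0× multiplicative shift on the type-1 pool and mild per-sample noise;
  counts are generated directly, with no read-level simulation, because the
  analysis consumes quantified counts.
- **Annotation**: 40 terms at 5% background frequency, one term per pool
  planted at 4× background within its pool.
- **Genome**: uniform random contigs carrying 3 type-1 and 1 type-2 SL-RNA
  loci (intron templates of 40/35/44 nt give total ORF lengths of 68, 60
  and 66 nt for the three systems), donor-broken and terminator-free
  decoys, optional tandem arrays of identical copies, and embedded gene
  loci whose 5' UTR ends in `AG` and lacks the SLe (plus a cis-encoded
  decoy that contains it).

Two deliberate departures from pure randomness keep truth labels exact: the
SL octamer (either strand) is scrubbed from simulated backgrounds, bodies
and 5' residuals, so a chance anchor cannot contaminate the labels, and the
poly-T search window downstream of a terminator-free decoy is kept free of
chance T-runs so the decoy stays a decoy. Real data contain both
phenomena; on real data the corresponding events are rare but not
impossible, which is one reason passing tests on synthetic bundles bound
the pipeline's *algorithmic* correctness, not the sequencing error modes,
assembly chimerism, or contamination found in genuine libraries.

## Problem sizes used in validation

The shipped tests run at sizes chosen to exercise every code path at desk
scale: bundles of 2000 transcripts across 20 seeds for classification and
recovery sweeps, 100 random small alignments against the brute-force Fitch
oracle, 200 short pairs against the exhaustive alignment oracle, permutation
p-values against exact hypergeometric tails, and 100 kb random-genome
scans for false-positive control. The acceptance script reruns the main
computation on one default bundle per seed.

## Known limitations

- Extent measurement tolerates no mismatches; a single error inside the
  observed SLe shortens the call, slightly inflating the incomplete pool on
  noisy data.
- The missed-SL estimator assumes normal truncation; heavy-tailed
  degradation would bias it downward, and its variance grows sharply when
  only the far tail of the fitted distribution is observable.
- The quartile filter is global, not per-pool; the replicate summary fed to
  the rank tests is the mean TPM (the sum is retained in output tables).
- The center-star alignment is a guide-order heuristic, adequate for the
  short, highly similar SL exons it serves, not a general MSA.
- Enrichment treats terms independently: no GO-graph propagation, slimming
  or redundancy clustering — those live upstream/downstream of this
  package.
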