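---
title: "ngsdesk methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ngsdesk methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
method assumes, which parameters matter and why their defaults are what
they are, what the simulator does and does not emulate, and where the
design was genuinely open and a choice had to be made. It states no
empirical result that the test suite does not itself compute.

## Coordinate and sequence conventions

All internal coordinates are 0-based half-open; conversion to the
1-based conventions of SAM and the TSV outputs happens only at the I/O
boundary. Sequences are uppercased on input and restricted to
`{A,C,G,T,N}`; anything else is rejected with the offending record
named, rather than silently coerced. `N` is never counted as a match or
mismatch and is excluded from identity and frequency denominators. The
supported SAM dialect is the mandatory columns with CIGAR operations
`M/=/X/I/D/S`; BAM/CRAM and VCF are deliberately out of scope
(external converters exist, and committing to a variant-exchange format
is not needed for the toolkit's own TSV contracts).

## The simulator: a stated world

Every downstream method is exercised against data from the package's
own generator, so it is worth being precise about what that generator
is. Reads are single-end, fixed-length, forward-strand, with i.i.d.
per-base substitution errors (uniform over the three other bases) and
no indels. Genomes are i.i.d. base strings at a chosen GC content;
diverged taxa are produced by planting substitutions independently on a
shared ancestor at rate `divergence/2`, so expected pairwise divergence
is close to the nominal value; quasispecies haplotypes carry private,
evenly spaced substitutions on a shared backbone; recombinants splice
equal-length parents at given breakpoints.

What this does **not** emulate: quality-score structure, platform error
profiles, indels and structural variants, paired ends, strand effects,
coverage biases, and contamination. A green test therefore establishes
algorithmic correctness under a clean substitution-only model — it does
not establish robustness to real-platform artifacts. That boundary is
deliberate: the methods here are substitution-centric, and the
simulator gives them exact, seedable truth labels (source genome,
start, planted variants) at desk scale.

Two sizing choices in the simulated scenarios were open and were fixed
once: read length 150 bp (typical short-read scale) and a 1% per-base
error rate for mixture/recombination scenarios (0.1% where a scenario
states it). Variant-planting may be restricted to the reference
interior (`region` argument of `mutate_genome()`): with uniform read
starts the first and last read-length of a reference can never reach
the stated coverage, so scenarios that assert "variants at ≥ 30×" plant
them where 30× is actually attainable.

## Mapper

The mapper is a deterministic stand-in, not a contribution: exact
k-mer seeds (default `k = 11`) taken at every k-th read offset propose
candidate placements (`hit − offset`); each candidate is scored by
ungapped identity over the read/reference overlap; the best placement
wins if it reaches `min_identity` (default 0.8), with ties broken by
(reference id, position). Ungapped extension suffices because the
simulator is indel-free; gapped external alignments enter via SAM
import instead. There is no reverse-complement search (the simulator is
forward-only). `min_identity = 0.8` sits between the simulated error
rate (≤ a few percent) and the 10% divergence of wrong-reference
placements, so it rejects junk without rejecting true placements.

## Census

The estimator is deliberately simple: `B` independent iterations, each
sampling `n` reads uniformly *without replacement* and classifying them
by best hit. Means, SDs and 2.5/97.5 percentile intervals are taken
across iterations; an `unaligned` pseudo-taxon keeps every iteration on
the probability simplex. Choices that were open: with- vs
without-replacement sampling (without, so the exhaustive limit
`n ≥ |reads|` reproduces full-data classification exactly, which the
tests assert); the interval method (percentile across iterations — no
distributional assumption, honest at B = 20); and reference handling
(a user-supplied FASTA panel plus a flat `ref_id → taxon` TSV, instead
of a remote database and taxonomy service, keeping the tool
self-contained and offline). Taxonomy is flat; hierarchical roll-up is
out of scope.

## SNV profiler

Deletions are counted in depth but never yield calls and are excluded
from the non-reference frequency denominator
`(A+C+G+T − count(ref)) / (A+C+G+T)`. The latter keeps frequencies
comparable between samples with different deletion rates; the former
keeps depth an honest count of observations at the position. Default
thresholds `min_depth = 10`, `min_freq = 0.05` are conventional
low-coverage values; the stated scenarios use `min_freq = 0.2`, at
which a false call at 30× and 0.1% error would need six identical
errors at one position — vanishingly unlikely, which is why the
recall/precision criterion can demand exactness. Consensus ties break
toward the reference base, then alphabetically, so consensus extraction
is deterministic and conservative.

## Profile clustering

The pair-comparison rule distinguishes three states per position:
variant (frequency as observed), covered-but-reference (implicit 0),
and uncovered (position dropped for that pair, gated by `min_depth`).
Conflating the last two would manufacture similarity out of missing
coverage. The metric menu (Euclidean, Manhattan, Canberra, Pearson
`1 − r`) and linkage menu (single/complete/average, neighbor joining)
are representative choices — the platform this re-implements names no
specific functions. Pearson needs two conventions to stay total:
`r := 0` for constant unequal vectors and `r := 1` when the two vectors
are identical (so `d(P, P) = 0` holds for every metric). Agglomerative
node heights sit at half the merge distance, so branch lengths are
height differences and UPGMA output is ultrametric; NJ clamps negative
branch lengths to zero and splits the final join evenly. All ties break
on the lexicographically smallest label pair, which makes output
invariant to input order — a property the tests assert directly. The
CLI consumes the per-position profile TSVs (not the sparse SNV tables)
because the pair rule needs depth at every position.

## SNV phylogenetics and shrunk genomes

The variant key is (position, alternate allele): two samples with
different alternates at one site differ in *two* matrix columns. This
is the conservative reading — they share no allele at that site — and
it is stated prominently because the convention is invisible in the
output. Window merging affects the shrunk genomes only, not the tree
distance; whenever no two distinct variant positions share a window
column, the Hamming distance between two shrunk sequences equals the
symmetric difference of their variant keys (asserted on constructed
fixtures). Default `flank = 10` bp keeps windows informative but small.
No likelihood or parsimony search is bundled; the shrunk multi-FASTA is
the hand-off to external phylogenetics tools.

## Clone discovery

The support statistic `n11 / (n11 + n10 + n01)` is the Jaccard index
over alt-carrying reads. It was chosen over phi or chi-square because
it degrades gracefully at low coverage — the regime this tool is for —
and is directly interpretable as "of reads showing either variant, the
fraction showing both". Reads showing a third allele at either position
are skipped for that pair. Linkage closure is by connected components:
transitive, so two variants never co-spanned by one read still join a
clone through a shared partner. Clone frequency is the mean member
allele frequency; a constrained EM re-estimate would be sharper and is
a documented possible extension, not implemented. Raising
`min_support` can only remove edges, so the clone count is monotone
non-decreasing in it (asserted). Defaults `min_support = 0.8`,
`min_reads = 5`, `max_span = 500`.

## Recombination detection

References must be equal length: the mutual alignment is the identity
column map. For real unequal genomes the user supplies an externally
computed, gap-columned alignment FASTA — multiple alignment is a solved
external problem and re-implementing it would add nothing here. One
attribution rule deviates from a pure best-hit assignment: a read tied
at best identity across several references counts toward *all* of
them. Under strict deterministic tie-breaking, two identical references
would funnel every read to the lexicographically first one, which would
then "dominate" everywhere — a hallucinated recombination signal from
zero information. With tied attribution, indistinguishable references
produce identical coverage rows, ratio 1, no valid windows, and an
empty segment list; the negative-control test asserts exactly this.
Defaults `window = 200`, `min_ratio = 2`, `min_cov = 5` operationalize
"significant dominance"; the breakpoint resolution is window-level by
construction, so recovered breakpoints are asserted only to ±1 window.
Split-read detection within single reads is not attempted.

## CLI

The command-line layer replaces a web platform, so its contracts are
filesystem-flavored: atomic writes (temp file + rename), a config echo
alongside every run's outputs, logging to stderr only, and exit codes
0/2/1 for success/usage/runtime failure. `--config` files supply
`key=value` defaults; explicit flags override them (the conventional
precedence — a config file silently defeating a typed flag would be
surprising). Determinism is end-to-end: the same subcommand, config and
seed produce byte-identical outputs, asserted at file level.

## Known limitations

Single-end forward-strand model throughout; no base-quality use; no
indel or structural-variant calling; flat taxonomy; no statistical
significance attached to recombination breakpoints; clone frequency
estimates are means, not maximum-likelihood; the mapper is not a
general-purpose aligner and should not be used as one outside the
toolkit's scenarios.
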