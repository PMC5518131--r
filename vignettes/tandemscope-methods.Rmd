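---
title: "Measuring tandem-repeat capture in genome assemblies with tandemscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tandem-repeat capture in genome assemblies with tandemscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemscope)
```

## The problem

Tandemly arrayed sequence — several near-identical copies of a unit lying in
series on one DNA molecule — is the hardest content for genome assemblers.
Arrays collapse (several genomic copies co-assemble into fewer), fragment
across scaffolds, or vanish entirely, and tandem gene families (plant
disease-resistance NBS-LRR genes, cysteine-rich peptides, and the like) are
exactly where this matters biologically. tandemscope is a desk-scale toolkit
for quantifying how well an assembly represents tandem repeats: it calls
repeat pairs from a genome self-alignment, classifies how a second assembly
captures each pair, identifies tandem gene clusters from protein similarity,
validates copy number from read depth and qPCR, and provides the synthetic
long-range mate-pair scaffolding stages used by hybrid short-read/long-read
assembly pipelines. A synthetic-data generator plants arrays with exact
ground truth so every stage can be verified without any external download.

## Tandem repeat detection from self-alignments

The detector consumes a self-alignment table (PAF or nucmer show-coords
tabular; `read_alignments()`) and applies, in order:

1. keep only alignments of a sequence to itself;
2. orient each record so the earlier-starting interval is unit 1, drop the
   trivial full-length diagonal, and deduplicate — in particular each
   A-to-B record's B-to-A mirror;
3. keep identity ≥ `min_identity_pct` (default 95%);
4. discard records whose two units overlap;
5. keep midpoint separation ≤ `max_midpoint_sep` (default 1 Mbp), with
   integer midpoints `floor((start + end) / 2)` for determinism.

Each survivor is a repeat pair. Pairs are split into *long* and *short* at a
2 kb unit threshold; a pair counts as long only when the **shorter** of its
two units reaches the threshold, the conservative reading when the two units
differ in length. Inverted (reverse-strand) self-alignments are retained by
default because the filter list above does not mention strand; a flag
excludes them for users who want direct repeats only. When identical
interval pairs appear at several identities the highest is kept, making
deduplication deterministic.

Collection-level summaries (`repeat_collection_stats()`) compute N50 over
the multiset of all unit lengths, two per pair, with the usual
first-to-reach-half-total tie convention.

## Capture classification

Given repeat pairs on a reference and alignments of an assembly to that
reference, each pair is classified (`classify_capture()`):

* **one scaffold** — some single scaffold covers *more than* 50% of both
  units (union of its alignment intervals, clipped to each unit);
* **two scaffolds** — otherwise, two distinct scaffolds each cover more than
  50% of one unit apiece;
* **underrepresented** — otherwise.

Coverage at exactly the threshold does not count ("over 50%"). One-scaffold
takes precedence when both hold: it is the stronger capture claim. When
several scaffolds qualify, the largest summed coverage wins, ties broken
lexicographically, so output is deterministic. A `single_alignment` flag
records pairs where one alignment record alone exceeds the per-unit
threshold — positional agreement, not just content capture. Strand is
ignored in coverage; the classification is about sequence representation,
not orientation. `reciprocal_assessment()` swaps the roles (pairs detected
on assembly scaffolds, classified by reference-chromosome coverage); a
two-chromosome call there flags a likely false duplication in the assembly.

## Tandem gene clusters

The gene-cluster pipeline starts from tabular all-vs-all protein hits
(query, subject, E-value), not from a search engine: E-values of exactly 0
are replaced by the smallest non-zero E-value in the file (they carry no
resolvable magnitude), self-hits are dropped, and reciprocal hits merge
keeping the lower E-value. Edges are weighted `-log10(E)`; the upstream
search emits raw E-values and some transform is required for a weighted
clustering — the negative log is the conventional, order-preserving choice,
and a raw-score mode is available for users who prefer bit scores.

Markov clustering is run at inflation 2.0 (expansion 2, convergence
tolerance 1e-6, entries below 1e-9 pruned per iteration to keep the matrix
sparse). Self-loops take the node's maximum incident edge weight (1 for
isolated nodes). Clusters are read from attractor rows (diagonal mass above
1e-6 after convergence); the rare node reachable from several attractor
systems joins the lexicographically smallest one, so the result is always a
deterministic partition, singletons included. Because the transition matrix
is block-diagonal over connected components, MCL can only ever refine the
components — a property the test suite asserts.

Two co-clustered genes on one scaffold form a *tandem pair* when at most one
non-TE gene lies strictly between them in start order; annotated
transposable elements neither count as intervening nor form pairs. Tandem
clusters are the connected components of the pair graph, and the histogram
of cluster sizes is the standard summary. Where genes overlap, start
coordinates still give a total order (duplicate starts on one scaffold are
rejected).

## Copy number from depth and qPCR

Read-depth validation counts reads overlapping a region by ≥ 1 bp (half-open
intervals, so abutting reads do not count) and normalizes to RPM, defined
here as reads × 10⁶ / (library size × region length). The absolute RPM scale
is irrelevant: the copy-number estimate is the gene's RPM divided by the
mean RPM of single-copy control regions, so any common rescaling cancels —
an invariance the suite checks directly. Estimates are reported to one
decimal.

qPCR validation corrects for primer efficiency by multiplying each
reaction's CT by the signed OLS slope of CT on log2(dilution) from that
primer set's standard curve (serial dilution 1×–32×, replicates pooled);
copy number per plant is `2^(corrected reference CT − corrected target CT)`,
averaged over plants and primer combinations per genotype. The slope is
applied multiplicatively to CT, exactly as the protocol specifies, rather
than through the more common ΔΔCT efficiency form; with a perfect standard
curve (slope 1) the two coincide.

## Synthetic mate-pair scaffolding

Hybrid pipelines scaffold long-read contigs using connectivity sampled from
an existing short-read assembly: up to 200-fold coverage per insert class of
2 × 2000 bp innie pairs at 10, 40 and 160 kb inserts. The sampler draws
uniform start positions and normal insert jitter (sd = 10% of the insert,
the generator's own choice since the upstream simulator does not publish its
deviation), skips pairs that would overrun a scaffold end, and discards
reads over 50% N. "Up to 200X" is interpreted per insert class, matching the
per-class simulator invocations.

Reads are placed on contigs by unique exact match (leading k-mer anchor,
k = 31, full-length extension, both strands); ambiguous reads stay unmapped.
Pairs spanning two contigs are bundled into links keyed by the two facing
contig ends, with gap estimate the median over pairs of
`insert − d1 − d2` (each `d` the distance from a read's outer edge to its
contig's facing end) and support the pair count; links under 2 supporting
pairs are dropped.

Layout is a greedy end-occupancy scaffolder: links in decreasing support
(deterministic tie-breaks), accepted only when both ends are free and no
cycle would form (union-find). This stage is the package's largest
invention — the upstream pipeline delegates scaffolding to an assembler
whose algorithm is not published, so tandemscope specifies its own: inputs
(bundled mate links) and outputs (ordered, oriented contig paths with gap
estimates) match, the algorithm between them is ours. Rendered scaffolds
use N gaps of at least 20 bases so that contig re-extraction at the 20-N
rule inverts scaffolding exactly.

Quality control mirrors the published filter: scaffolds with fewer than 15
reads are removed (15 is retained), and positions with long-read coverage
below 2× are deleted, splitting the scaffold into maximal kept runs
(exactly 2× survives); pieces under 200 bp are dropped. Coverage is
computed by difference-array accumulation.

## The synthetic-data generator

`make_genome_with_arrays()` plants arrays of controlled unit length, copy
number, spacer and divergence in i.i.d. uniform background sequence.
Mutations are substitutions only, so pairwise identity between copies is
exactly computable by Hamming comparison — which is how
`emit_self_alignments()` produces an analytic self-alignment (diagonal,
every copy-vs-copy record, and all mirrors) without running an aligner,
keeping the tests hermetic. Divergence is capped at 5% per copy so that
detection-positive fixtures stay in the ≥ 95% identity regime.

Three corruption operators realize the three capture categories, and they
emit different alignment sets by design. A *collapsed* array keeps one copy
whose alignments are planted onto every original copy's reference interval —
that is precisely what the best available alignment for those positions
looks like when an assembly has collapsed a repeat, and it is why collapsed
arrays still classify as one-scaffold captures. *Fragmentation* cuts the
genome between copies and emits only the colinear segment alignments, and
*unit deletion* excises one copy, again with colinear alignments only, so
the deleted unit is genuinely uncovered. A single emission rule could not
realize all three categories at once; the per-operator rules are the point
of the operators.

What the generator does **not** emulate: sequencing error profiles, indels,
diploidy, segmental duplications between chromosomes, or the alignment
fragmentation real aligners produce around repeat boundaries. Passing tests
demonstrate that the *logic* of each stage is correct against exact truth;
they do not certify performance on real alignments, where pre-filtering
(e.g. best-per-position alignment selection) is the user's responsibility.

## Problem sizes and numerical choices

The randomized suites use 30 kb backgrounds with two planted arrays (units
0.2–2.5 kb, 2–5 copies), 50 truth sets for the classification grid, and 20
linear genomes of 5–20 contigs (4–9 kb) with 1–7 kb gaps at 10 kb inserts
and 25× mate coverage for scaffolding recovery — sizes chosen so the whole
suite exercises every code path in a few minutes on one core while keeping
every instance in the unambiguous regime (adjacent gaps well under the
insert size). Exhaustive checks are used where the space is small enough:
all multisets of up to 8 sequence lengths ≤ 10 for N50/NG50 and all TE-flag
configurations of up to 7 genes for the tandem-pair rule.

Determinism is treated as part of correctness: every sampler takes an
explicit seed and restores the caller's RNG state (`with_seed()`), ties are
always broken lexicographically, and identical inputs yield byte-identical
tables.

## Known limitations

* The detector is alignment-driven; it finds what the self-aligner reports
  and applies the stated filters, nothing more. It is not a sequence-level
  tandem-repeat finder.
* Whether published repeat censuses included inverted-orientation pairs, or
  deduplicated overlapping alignments of one repeat at different extents, is
  not stated upstream; both behaviours are exposed as options and the
  defaults reproduce the stated filters literally.
* The qPCR estimator implements the literal multiplicative slope correction;
  published per-accession qPCR copy numbers cannot be recomputed because the
  underlying raw CT values are not available.
* The greedy scaffolder is deliberately simple; it recovers unambiguous
  linear layouts and makes no attempt at repeat-aware path disambiguation.
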