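---
title: "Models and methods behind panplastome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panplastome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistics and algorithms the package
implements, the assumptions behind them, and the design choices made where
more than one reasonable definition exists. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` themselves compute.

## 1. The quadripartite model and its detection

A plastome is modelled as a circular molecule partitioned into four
intervals: LSC and SSC (single copy) and two inverted-repeat copies with
`sequence(IRb) = revcomp(sequence(IRa))`. Internally all coordinates are
0-based half-open; an interval with `end > n` wraps past the origin. GFF3
I/O converts to and from 1-based inclusive coordinates.

`detect_quadripartite()` searches for the maximal pair of non-overlapping
intervals that are exact reverse complements. Exact 32-mer matches between
the doubled sequence and its reverse complement are grouped by
anti-diagonal (the sum of the two start coordinates, which is constant
along an inverted-repeat pair); the longest run of consecutive seeds on
one anti-diagonal gives the repeat, and doubling the sequence makes the
search origin-aware. Seeds occurring more than 100 times are ignored as
low-complexity guards. Because every interior offset of a true repeat
carries a seed, the recovered interval is exactly maximal; the detection
therefore requires `min_ir_len >= 32` (default 500, well below real IR
lengths of 20–30 kb and above chance repeats, whose expected maximal
length in a random 150 kb molecule is ~17 bp). If no repeat reaches
`min_ir_len` the whole molecule is labelled LSC and a warning is raised.
Of the two single-copy arcs the longer is the LSC; IRa is the copy
immediately following it.

`detect_ir_by_coverage()` uses the orthogonal evidence that a collapsed
assembly shows doubled read depth over the IR: the single-copy baseline is
initialised with the median depth, doubled candidates are flagged, the
baseline is re-estimated from non-candidate positions, and the maximal
contiguous run with depth ratio in `[1.5, 2.5]` is returned. The band is
deliberately wide; at depth 100 with Gaussian noise of σ = 10 the 1.5×
boundary sits 5σ from both classes.

The SSC occurs in both orientations in living cells, so comparability
requires a convention: `normalize_orientation()` keeps the orientation in
which the SSC string is lexicographically smaller than its reverse
complement. Any fixed convention would do; the lexicographic one is
deterministic, sequence-only and idempotent. Features straddling an SSC
boundary cannot be remapped and raise an error naming the feature.

## 2. Regions from conserved microsynteny

Gene orders are circular, sorted by start coordinate, with IR-duplicated
genes collapsed to the IRa copy (the interpretation that each duplicated
gene enters the region table once). `conserved_adjacent_pairs()` is the
plain intersection of directed circular adjacency sets; adjacency ignores
strand, because the spacer between two genes exists regardless of their
orientations. Gene names pass through a small alias table at parse time
(psbN/pbf1 are two names for the same gene).

Extraction drops an intergenic pair globally when, in any sample, the two
genes overlap, the spacer has zero length, or the gap contains another
annotated feature. The third rule is an addition: IR-collapsed circular
orders make the last SSC gene adjacent to the first LSC gene, but their
"gap" spans the entire second IR copy; the contains-feature test rejects
exactly such junctions. Drops are logged, never silent, so the region
grid is always accounted for.

`harmonize_orientation()` mirrors an aligner's direction adjustment: each
sequence is kept or reverse-complemented to maximise the number of shared
11-mers with the first sample, with ties keeping the forward strand.
Plain (non-canonical) kmers are used here on purpose — canonical kmers are
strand-invariant and cannot distinguish orientations.

## 3. Alignment statistics

*Identity* is the fraction of columns in which all rows carry the same
non-gap nucleotide. A gap is not a nucleotide, so any gap makes a column
non-conserved. N is missing data: it is excluded from the unanimity check
when at least two non-gap, non-N residues remain; a column reduced below
that minimum (e.g. `{A, N}` in a two-row alignment) is neither conserved
nor a variant. A consequence worth knowing: with missing data, removing a
row can reduce identity, so the "adding an outgroup can only keep or
decrease identity" monotonicity holds exactly only for N-free columns.

*Events*: an SNV is a column with ≥ 2 distinct non-gap, non-N residues
(one event per column, regardless of allele count); an indel event is a
maximal run of gap characters within one row. Runs are counted per row,
without reconstructing ancestral events — the simplest definition that an
independent brute-force enumeration can verify, which the suite does
exactly on a 1000-alignment fuzz corpus. Counting per row rescales
densities compared to counting ancestral events once, but leaves mod-3
proportions unbiased, because a fanned-out event contributes the same
length to every row it touches. Densities divide the event count by
alignment length and by the number of rows.

The two headline contrasts are classical tests: a two-sided Wilcoxon
rank-sum on per-region identities (genic vs intergenic) and a two-sided
Fisher exact test on the 2×2 table class × (length ≡ 0 mod 3) of indel
lengths. Hotspot ranking sorts by density, descending, with ties keeping
plastome order (a stable sort).

## 4. Supermatrices, diagnostic markers, NJ

Trimming keeps a column when its non-gap fraction is ≥ 0.8 and the
majority-residue frequency among non-gap residues is ≥ 0.001 — the
gap-threshold/minimum-similarity semantics of common trimming tools, with
the similarity statistic simplified to the majority frequency.
Concatenation records a partition map and a summary (sites, distinct site
patterns, gap fraction, invariant fraction — a column with a single
distinct non-gap, non-N residue). Five matrix variants are built: genic,
intergenic, CDS with the first and last codon removed, codon positions
1+2, and position 3. Codon positions are assigned by alignment column
index, which is only meaningful when gaps preserve frame; a CDS alignment
whose length after terminal-codon removal is not a multiple of three is
excluded with a warning rather than silently mis-partitioned. For this
reason the file pipeline feeds the codon matrices from the complete
(untrimmed) alignments.

Diagnostic selection adds regions in ascending identity order (most
variable first) until every sample pair is separated by some column with
differing non-gap, non-N residues. Ascending order is the reading that
actually yields a small marker set; the selection is by construction a
prefix of the identity-sorted list, and the stopping step is minimal —
both properties are tested on 50 simulated datasets.

The NJ tree is a deliberate stand-in for full ML inference (out of
scope): p-distances over columns without gaps or N in either row, then
the standard neighbor-joining agglomeration from ape, rows in label order
for determinism. Its acceptance is recovery-based (Robinson–Foulds 0 to
the generating tree at the simulator's divergence levels), not
likelihood-based.

## 5. Kmer splits and the strict tree

Every canonical kmer (lexicographic minimum of the kmer and its reverse
complement) has a presence pattern — the set of samples containing it —
and every pattern is a candidate bipartition. Kmers whose total dataset
count is 1 are filtered as unsupported. Weights: `count` is the number of
distinct kmers per pattern; `geom` sums the geometric means of the
supporting counts; `geom2` additionally divides by one plus the mean
count outside the side. Because presence-defined patterns have zero
outside counts, geom2 coincides with geom here — matching the robustness
observation that motivates having both. `top = "10n"` keeps the
10·n-taxa heaviest splits, ties included. Singleton-side and full-set
patterns are trivial and discarded.

The strict tree is the greedy compatible subset: splits visited by
descending weight (ties: smaller side, then lexicographic), accepted iff
compatible with everything accepted. With all sides expressed relative to
a reference taxon, pairwise compatibility reduces to nested-or-disjoint,
so the accepted family is laminar and realizable as a tree, emitted with
branch lengths proportional to split weights. An independent brute-force
greedy oracle verifies the acceptance on 200 random split soups.

A caveat the tests encode: indels delete kmers, and kmer *loss* in one
lineage creates presence patterns that are genuine set differences, not
tree splits. On simulated data the true internal splits still dominate by
weight — the suite asserts the heaviest n−3 splits are exactly the true
ones and that the strict topology is identical at k = 21 and k = 31 —
but mid-weight conflicting splits are expected and are not a defect.

## 6. Split-set comparison

Split identity is by bipartition membership only; weights enter the
scores. Precision is the weight of correctly predicted splits over the
weight of all predicted splits, recall the mirror image with reference
weights, F1 their harmonic mean (0 when both are 0). The weighted
symmetric set distance sums each set's own weights over the symmetric
difference and is reported unnormalized, since no normalization is
standard. The Robinson–Foulds distance is the plain symmetric-difference
count; the tests check it against phangorn and verify the metric axioms
on random topologies. Trees are compared unrooted; trivial splits are
excluded.

## 7. The simulator: what it emulates, and what it does not

The generator is the package's ground-truth instrument, designed to
reproduce the *contrasts* a pan-plastome study reports — not any absolute
values, for which no generative model exists.

**Architecture.** Genes alternate with spacers; LSC and SSC start and end
with spacers while the IR starts and ends with genes, which makes the
circle alternate perfectly and puts IR boundaries on gene boundaries (as
in real plastomes, where the rRNA operon sits inside the IR — IR genes
are labelled rRNA accordingly). At least two IR genes are placed so the
internal spacer can absorb the IR length target. Defaults: 24 kb genome
(a deliberate ~6× scale-down of the real ~150 kb that preserves all
structural proportions), 20 genes, compartment fractions 0.56/0.12/0.16
(matching real LSC/SSC/IR proportions), gene lengths 300–900 bp snapped
to codon multiples, CDS sequences framed by ATG…TAA. The two single-copy
bases flanking the IRs are chosen to break chance complementarity, so the
annotated IR is exactly the maximal repeat and detection can be tested
for exact equality.

**Evolution.** Uniform-rate, equal-frequency substitutions (JC-like; the
GTR+G fitting of real analyses is out of scope and topology recovery only
needs model consistency), with per-site substitution probability
`1 − exp(−rate·t)` per branch. Indels are a Poisson process per region
class; lengths are geometric with mean 3, truncated at 12 bp, then
conditioned on being or not being a multiple of three with class
probability `p_frame` (defaults 0.45 genic / 0.30 intergenic, mirroring
the enrichment of frame-preserving indels in genes). Default substitution
rates 0.01/0.03 encode the genic-vs-intergenic conservation contrast at
1:3. Indels never cross a gene/spacer boundary, keeping event classes
clean; a deletion that would erase a gene entirely raises an error rather
than silently truncating. The IR evolves once and is mirrored into both
copies. True alignments are maintained exactly by inserting gap columns
into a growing node × column matrix during a preorder traversal; one
seeded generator drives the whole run (draw order: per preorder edge, per
unit in molecule order, substitutions then indels), so identical
configurations give byte-identical outputs.

**Guide trees.** When no tree is supplied, a seeded random topology is
scaled to mean root-to-tip depth 0.5 with a branch-length floor of 5 % of
the depth. The floor is a fixture-design decision: a random tree can
contain internal branches carrying less than one expected substitution
genome-wide, and recovery criteria are meant to test method correctness,
not the impossibility of resolving a zero-length branch.

**Coverage tracks** are emitted over the collapsed LSC+IR+SSC scaffold at
depth `coverage_depth`, doubled over the IR, with optional Gaussian noise
— the signature by which assemblies reveal the IR.

**Study conditions used by the acceptance checks** (sizes are the
package's own choices): the conservation/phylogeny block uses the default
8-taxon, 24 kb configuration (~40 regions, ~20 k sites). The
frame-recovery block uses a 3-taxon star tree at 30 kb with elevated
indel rates (~1000 called indels per class): on a star, each event
produces only one or two called gap runs, keeping the mod-3 proportion
estimator close to its binomial sampling bound, whereas events on deep
branches fan out into many correlated rows and dense gaps merge runs.
The structure block uses ten seeded ~8 kb architectures, each also tested
with the molecule rotated so an IR crosses the origin.

**Not emulated:** read-level sequencing (FASTQ) and error models,
recombination, gene gain/loss, rearrangements, mitogenomes, rate
heterogeneity across sites, and base-compositional bias. Passing tests
demonstrate correctness of the statistics and recovery under this clean
generative model; they do not certify performance on real data with
annotation errors, alignment artefacts or heterotachy.

## 8. Numerical and degeneracy conventions

Empty IRs (ir_frac = 0) give a two-part single-copy partition and a flat
coverage track. An empty conserved-pair intersection, a class with no
indels, and an inseparable sample pair all warn and return explicit
empty/NA results instead of failing. NJ raises an error when two rows
share no comparable column. NEXUS split weights are written with six
decimals and round-trip through the package's own reader. All tie-breaks
(hotspots, diagnostic order, split acceptance) are deterministic and
documented at the function level.
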