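# panplastome

Comparative pan-plastome analysis in R: from annotated chloroplast genomes
to conservation landscapes, diagnostic markers and phylogenies — with a
built-in plastome evolution simulator that provides ground truth for every
stage.

## The problem

Chloroplast genomes (plastomes) are ~150 kb circular molecules with a
conserved quadripartite architecture: a large and a small single-copy
region (LSC, SSC) separated by two inverted-repeat copies (IRa/IRb, exact
reverse complements). Within a genus, plastomes differ mostly by point
mutations and small indels concentrated in intergenic spacers, which makes
per-region conservation statistics and concatenated supermatrices the
workhorses of shallow-scale plant phylogenomics. This package implements
that comparative workflow end to end:

* **structure** — detect the quadripartite partition from sequence
  self-complementarity (maximal inverted-repeat pair, origin-aware) or
  from the doubled read coverage the collapsed IR shows in assemblies;
  normalize the SSC orientation, which co-occurs in both flips in vivo.
* **regions** — build IR-collapsed circular gene orders, intersect
  adjacencies across all samples (conserved microsynteny), and extract
  genic plus intergenic regions shared by every sample; pairs with
  overlapping genes or zero-length spacers are dropped globally and logged.
* **alignstats** — per-region alignment identity (fraction of columns in
  which all accessions carry the same non-gap nucleotide), SNV and indel
  event calling, length- and sample-normalized hotspot densities, the
  indel size spectrum, and two class contrasts: a rank-sum test on genic
  vs intergenic identities and a Fisher exact test on the proportion of
  frame-preserving (length ≡ 0 mod 3) indels.
* **supermatrix** — column trimming (gap threshold 0.8, minimum similarity
  0.001), concatenation with a partition map and summary (sites, site
  patterns, gap %, invariant %), the five standard matrix variants (genic,
  intergenic, CDS without start/stop codons, codon positions 1+2, codon
  position 3), greedy selection of a minimal diagnostic region set, and a
  neighbor-joining tree from p-distances.
* **ksplits** — alignment-free phylogeny: canonical kmer presence patterns
  across samples become weighted splits (count / geom / geom2 weights,
  `all` or `10n` output rule), a greedy compatibility pass extracts the
  strict tree, and splits export to SplitsTree-readable NEXUS.
* **treecmp** — weighted precision/recall/F1 between split sets, weighted
  symmetric set distance, Robinson–Foulds distance, all-vs-all matrices.
* **simulate** — a tree-conditioned plastome evolution simulator (JC-like
  substitutions, geometric indel lengths with class-specific mod-3 bias,
  lower rates in genes than spacers, IR evolved once and mirrored) that
  emits annotated FASTA/GFF3, true alignments, true indel records, true
  tree and coverage tracks.

## Worked example

```r
library(panplastome)

cfg <- sim_config(seed = 1, taxa = paste0("t", 1:8))   # ~24 kb, 20 genes
sim <- simulate_plastomes(cfg)

# conservation contrast on the true alignments (leaves only)
alns <- lapply(sim$truth$true_alignments,
               function(m) m[rownames(m) != "ancestor", , drop = FALSE])
ids <- identity_table(alns)
ct <- identity_contrast(ids$identity_all[ids$class == "genic"],
                        ids$identity_all[ids$class == "intergenic"])
round(c(genic = ct$mean_genic, intergenic = ct$mean_intergenic), 4)
#>      genic intergenic
#>     0.9717     0.9251
ct$p_value
#> [1] 1.450889e-11

# supermatrix and NJ tree
full <- concatenate(lapply(alns, trim_alignment))
full
#> <supermatrix> 8 samples x 19985 sites (40 regions); patterns 177; gaps 0.05%; invariant 96.56%
nj <- nj_tree(full)
compare_splits(splits_from_tree(nj), splits_from_tree(sim$tree))$rf_distance
#> [1] 0

# alignment-free phylogeny from 31-mers
sp <- infer_splits(build_profile(lapply(sim$samples, `[[`, "sequence"), k = 31),
                   weight_fn = "count", top = "10n")
st <- strict_tree(sp)
compare_splits(splits_from_tree(st$tree), splits_from_tree(sim$tree))$f1
#> [1] 1
```

Genes are clearly more conserved than spacers (97.2 % vs 92.5 % mean
identity, rank-sum p ≈ 1e-11), and both the supermatrix NJ tree and the
kmer-split strict tree reproduce the true 8-taxon topology exactly
(Robinson–Foulds distance 0, split F1 = 1).

File-based pipelines over the same stages are available as
`run_alignment_pipeline()` and `run_ksplit_pipeline()`; both write a
manifest with a config snapshot and per-artifact checksums.

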