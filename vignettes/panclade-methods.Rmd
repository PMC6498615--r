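---
title: "Methods: pangenome and clade-structure analysis with panclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome and clade-structure analysis with panclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

panclade reconstructs the population structure of a bacterial species from
genome assemblies and protein annotations, and then asks what gene content
separates the resulting clades. This vignette describes the models and
procedures, the parameters that matter, the synthetic data generator used to
validate every stage, and the numerical choices that make runs reproducible.

## The analysis in one paragraph

Given a set of assemblies (FASTA) with CDS annotations and protein
translations (GFF3 + protein FASTA), the pipeline (i) computes average
nucleotide identity between all genome pairs with two estimators — a
fragment-based one (ANIb style) that is robust between species, and a
maximal-exact-match one (ANIm style) that resolves close relatives — and
combines them into a hybrid distance matrix (ANIm within a species, ANIb
across species) from which a neighbor-joining tree is built and rooted on the
outgroup; (ii) clusters all proteins into gene families at >80% amino-acid
identity and >80% alignment coverage and summarises them as a ternary
genome-by-family matrix (absent / fragment-only / intact); (iii) selects the
single-copy core families with no pseudogenized member, aligns each family,
concatenates all SNP and indel columns (excluding any column containing `N`)
into a supermatrix, and builds a neighbor-joining tree from Kimura
2-parameter distances with column-bootstrap support; and (iv) profiles the
clades: clade-specific families, variable regions (runs of CDS absent from a
comparison group), amino-acid pathway completion, phosphotransferase-system
(PTS) component counts, and presence/fragmentation slices for arbitrary gene
sets.

## Average nucleotide identity

**ANIb.** The query genome is cut into consecutive non-overlapping fragments
of `fragment_length` (default 1020 bp; a terminal remainder is kept if it is
at least half a fragment). Each fragment is placed on the subject by shared
15-mer seeding: 15-mers that are unique within the subject are matched
against the fragment's 15-mers, and the modal diagonal positions a subject
window (`window_pad` = 48 bp of context). The fragment is aligned to this
window by banded local alignment (match +1, mismatch −1, gap open 4, extend
1; band half-width `window_pad + band_extra`). Fragments with identity
< 0.30 or aligned coverage < 0.70 are discarded — the conventional ANIb
retention rule — and ANI is the mean identity of retained fragments.
`aligned_fraction` is retained fragment bp over total fragment bp, so a
self-comparison reports exactly 1. A pair with no retained fragment yields a
*missing* ANI (never 0) and a warning.

**ANIm.** Maximal exact matches of at least `min_exact_match` (default 20)
bp, unique in both genomes, are found by k-mer matching and merged into
segments; segments are chained greedily in collinear order. Gaps between
consecutive chained matches up to `max_gap` (5 kb) on both genomes are closed
by global alignment; pure-indel gaps contribute gap columns only. Identity is
matches over matched (non-gap) columns, so indel-only differences do not
depress ANIm — a 1-kb deletion in an otherwise identical genome still gives
ANI 1.0. A chain with fewer than `min_chain_bp` (100) exact-match bp is
treated as chance k-mer seeding — two unrelated 20-kb sequences share a
20-mer at a rate of roughly L²/4²⁰ per pair, and an identity estimated from
a few dozen bases is meaningless — and is reported as missing.

**Hybrid distances.** The two directed values of each pair are averaged
(neighbor joining needs a symmetric matrix; the symmetrisation is the
arithmetic mean). The hybrid distance is `1 − ANIm` for same-species pairs
and `1 − ANIb` otherwise, with species labels supplied by the user. A missing
consulted cell is a hard error: the tree needs a complete matrix.

These estimators are self-contained reimplementations of the two ANI
flavours; they are not expected to match any external tool bit-for-bit.
Their calibration is tested directly: a copy with 5% of positions substituted
must score in [0.945, 0.955] with both estimators, and ANIb must respond
monotonically to substitution rates across 1–10%.

## Gene families and the ternary matrix

Two proteins are linked when their global affine-gap alignment (BLOSUM62,
gap open 11, extend 1) has identity **strictly greater** than 0.80 —
identical residues over aligned columns, terminal gaps excluded, internal
gap columns counted against identity — and coverage strictly greater than
0.80 **on both sequences** (aligned span over sequence length; the
both-sided reading is the conservative one). Families are connected
components of this graph (single linkage), deterministically labeled by
their smallest member id, so the partition is independent of input order.

All-versus-all alignment is avoided with a two-stage candidate filter:
(1) a provable length bound — both coverages > c at identity > t force
`min(len)/max(len) > t·c` = 0.64 — and (2) a shared 5-mer count screen.
A worst-case "shares at least one seed" guarantee at the 80% threshold only
exists for seeds of length ≤ 3 (pigeonhole on 20% mismatches), where the
filter would prune nothing; instead the screen requires a quarter of the
*expected* shared-5-mer count of a borderline pair, `t^k (c·min_len − k)`,
leaving a 4× margin. The filter's completeness is validated empirically: on
forty 50-protein random fixtures the filtered clustering equals brute-force
all-pairs clustering exactly.

The ternary matrix records, per genome and family, 2 if at least one intact
member is present, 1 if only fragments, 0 otherwise. Fragment-only presence
counts as presence for core/pan/rarefaction membership (the core genome
requires presence, not intactness); functional profiles (pathways, PTS)
count intact copies only by default. Note that a severely truncated fragment
can fail the coverage threshold against its own family's intact members and
land in a separate (usually singleton) family — an inherent property of
threshold clustering, visible in real annotation platforms too.

Partition: core = families present (state ≥ 1) in every genome; singleton =
families with exactly one member gene overall (this needs member counts, not
just the ternary states — `partition_pangenome` takes them as an argument);
variable = the rest. Rarefaction draws, for every subset size, a fixed
number of random strain subsets (default 10) and reports pangenome and
coregenome sizes. Group resampling statistics draw `sample_n = 5` strains
per group without replacement, 10,000 times, and report mean ± SD of unique
and per-strain-summed variable-family and singleton counts; a group of
exactly 5 strains is sampled exhaustively, so its SD is 0 by construction.
Sampling *with* replacement is available as an option; without replacement
is the default because it keeps a 5-strain group well defined at n = 5.

## The core-SNP supermatrix

Families enter the supermatrix only if they are intact in every genome, have
no fragment member anywhere, and are single-copy everywhere (the single-copy
rule makes the one-row-per-genome alignment well defined). Each family is
aligned by center-star MSA: the center minimises total pairwise edit
distance (ties: smallest genome label); all other sequences are aligned to
the center globally (match 1, mismatch −1, gap open −4, extend −1) and
merged under "once a gap, always a gap". Families whose members have equal
length and at most 15% pairwise Hamming divergence are stacked gaplessly —
for scattered substitutions the gapless alignment is optimal under this
scoring, and the shortcut keeps the stage ~10× faster at default scale.

A column is a variant column if it contains at least two distinct symbols
from `{A,C,G,T,-}` and no `N` in any row (the strictest reading of
"excluding Ns"); each gap column is an independent character. Variant
columns are concatenated in deterministic family-id order with per-column
provenance.

## Phylogenetics

**K2P.** With transition proportion P and transversion proportion Q over
pairwise-complete sites (gaps and Ns excluded pairwise),
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`. Saturation (`1 − 2P − Q ≤ 0` or
`1 − 2Q ≤ 0`) is a named error, not an NaN.

**Neighbor joining** uses the canonical Q-criterion with two determinism
rules: ties are broken by the lexicographically smallest label pair (a
cluster is labeled by its smallest descendant tip), and negative branch
lengths are clamped to zero. On additive matrices NJ reproduces the
generating topology and its path distances to 1e−9; this is tested against
200 random 4–6 leaf additive matrices and, for 4 leaves, against a
least-squares fit over all three enumerable topologies.

**Bootstrap.** Columns are resampled with replacement (default 100
replicates), distances and trees rebuilt, and each internal bipartition of
the point-estimate tree receives the percentage of replicates containing it.
Replicates that saturate the K2P correction are skipped with a warning; more
than 20% skipped aborts. Supports are invariant to column order because the
per-pair column classifications are precomputed once and only reweighted per
replicate.

**Rooting** places the root at the midpoint of the outgroup's pendant edge.
**Fitch parsimony** scores a character matrix by set operations in postorder
(polytomies are binarised with zero-length edges first); the score is
validated against exhaustive internal-state enumeration on 6-leaf instances.
**Complete-linkage dendrograms** of the ternary matrix (states as numeric
0/1/2, Euclidean distance) delegate to `stats::hclust` after sorting rows by
label, which makes the merge order independent of input row order.

## Clade profiles

A family is specific to clade c when present in ≥ 90% of c's genomes and
≤ 5% of the others (`min_in`, `max_out`; presence mode `any` by default —
existence questions count fragments, function questions do not). Variable
regions of a target genome against a comparison group are maximal runs of at
least `min_run = 5` CDS whose families are absent (state 0) from **every**
comparison genome, allowing `gap_tolerance = 0` interior exceptions; the
region span is last CDS end − first CDS start + 1. This is an operational,
content-based definition — composition-based signals of genomic-island
finders are intentionally out of scope — but it derives all the quantities
of interest (region count, bp, CDS). Pathway completion is the fraction of a
pathway's roles whose family is intact in a strain; PTS component counts are
integers in 0–4. Example definitions keyed to the synthetic generator's
truth families ship in `inst/extdata/` (`synthetic_pathways.tsv`,
`synthetic_pts.tsv`); real analyses supply their own tables.

## The synthetic data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with known truth for every stage:

* a star-like clade tree: 4 clades × 5 strains by default, stem branches at
  `inter_clade_divergence = 0.02` substitutions/site, tip branches at
  `intra_clade_divergence = 0.002`, plus one outgroup genome at 0.15 —
  divergences chosen to mirror a bacterial species with well-separated
  intra-species clades and a sister-genus outgroup;
* 300 ancestral gene families (uniform 300–1500 bp, terminal stop codons,
  50-bp intergenic spacers), evolved under a Kimura 2-parameter process with
  transition bias 4 — the same model family the K2P estimator assumes, so
  parameter recovery is a fair test; internal stop codons arising from
  random substitution are repaired (middle base → C), emulating purifying
  selection, so that premature stops appear only by pseudogenization;
* per-strain gene loss (p = 0.03) and pseudogenization (p = 0.02): a
  pseudogene keeps its genomic sequence but gains a premature stop at ≥ 30%
  of its length and is annotated as one truncated fragment or two split
  fragments;
* one planted 10-CDS operon block per clade, inserted at a clade-wide gene
  boundary and inherited by every member (blocks are exempt from loss and
  pseudogenization: they model clade-diagnostic operons, and the
  variable-region validation requires their exact recovery);
* genomes are emitted as single contigs (draft-like splitting at gene
  boundaries is available via `split_contigs` for I/O tests); strands are
  all `+` — strand is parsed and preserved by the readers but no downstream
  computation uses it.

Everything derives from one seed; two runs with the same configuration are
byte-identical on disk.

What the generator does **not** emulate: recombination and horizontal
transfer beyond the planted blocks, codon-usage and GC structure, rRNA
operons, plasmids, multi-copy paralogs, and assembly artifacts (chimeras,
Ns). Passing the validation suite therefore shows the pipeline's inferences
are correct when the data match its assumptions; on real data the clustering
thresholds and the content-based region definition remain heuristics whose
adequacy must be judged per dataset.

## Numerical and engineering choices

* All pairwise alignments run through one compiled affine-gap kernel
  (global / local / semiglobal, optional diagonal band). DP tie-breaks are
  fixed (diagonal > gap-in-b > gap-in-a; opening preferred over extension at
  equal score), so alignments are deterministic.
* Genome-scale seeding uses numeric k-mer codes (exact in a double for
  k ≤ 26) and R's hashed `match`.
* The default full pipeline (21 genomes × ~285 kb, ~6,400 proteins) runs in
  about 4–5 minutes on one CPU: ANIb dominates (~2.5 min), then ANIm
  (~1 min) and protein clustering (~40 s). These sizes were chosen as the
  package's default study conditions; larger sets scale quadratically in
  genome pairs.
* Randomised stages (simulation, rarefaction, resampling, bootstrap) take
  explicit seeds and restore the caller's RNG state.
* `write_newick` serialises with canonical child order (lexicographic by
  smallest descendant label) and 6 significant digits, so equal trees give
  byte-identical files.

## Known limitations

* ANI estimators are surrogates sharing the fragment/maximal-match character
  of the originals, not re-implementations of BLAST or MUMmer scoring.
* Center-star alignment is adequate for the near-identical core genes this
  pipeline consumes; it is not a general MSA replacement.
* The family graph uses single linkage: a chain of borderline pairs can
  bridge families; paralog splitting is out of scope.
* `detect_variable_regions` sees only family content; islands that differ by
  sequence but not by family membership are invisible to it.
* Maximum-likelihood tree search is deliberately absent; NJ + parsimony
  scoring cover the structure that can be validated against truth here.
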