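---
title: "Evaluating plastome-scale barcodes: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating plastome-scale barcodes: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Standard plant DNA barcodes (*matK*, *rbcL*, *trnH*-*psbA*, ITS) often fail
to separate closely related species because they carry too little
interspecific variation.  Whole plastomes and the complete nuclear
ribosomal cistron ("super-barcodes") promise far more signal, but their
discriminatory power has to be measured, not assumed — and failures have
biological causes of their own: chloroplast capture after hybridization
decouples the maternally inherited plastome from species boundaries, and
incomplete lineage sorting (ILS) lets two species share identical
haplotypes long after speciation.

`superbarcode` implements the full evaluation pipeline for such studies:
given species-labeled alignments of candidate barcoding datasets it
computes alignment feature statistics, locates divergence hotspots, runs
both of the field's species-discrimination methods (distance-based
barcoding gaps and tree-based monophyly), summarizes why datasets fail
(zero-distance statistics), and quantifies cytonuclear conflict between a
plastid and a nuclear phylogeny.  A synthetic-data module generates
datasets with known ground truth — including planted capture and
haplotype-sharing events — so every stage of the pipeline is testable
without sequence downloads.

## Data model

A `labeled_alignment` couples an aligned character matrix (rows = samples)
with a sample table (`sample_id`, `species`, optional `section` and
`provenance`).  Sequences are uppercase-normalized (`U`→`T`; `.` and `?`
→ `-`); IUPAC ambiguity codes are kept in the matrix and each statistic
declares its own treatment.  All column coordinates are 1-based inclusive,
in line with base R and the R phylogenetics ecosystem.  Trees are `ape`
`phylo` objects whose internal-node labels carry bootstrap supports on the
0–100 scale; `read_support_tree()` accepts both the `)87:` and `)0.87:`
newick dialects (a tree whose numeric labels are all ≤ 1 is interpreted as
proportions and rescaled).

## Alignment statistics

*Variable* and *parsimony-informative* (PI) sites are classified on
unambiguous bases only: a column is variable when at least two of
{A,C,G,T} occur among its rows, and PI when at least two bases each occur
in at least two rows.  A column whose variation involves only gaps or
ambiguity codes is not variable.  Haplotypes are counted after excluding
every column containing any gap or ambiguity in any row (the
"exclude sites with gaps" convention of the DnaSP lineage of tools).  GC
content is (#G + #C)/(#A + #C + #G + #T) pooled over rows, with gaps and
ambiguities excluded from both numerator and denominator.  These are
declared conventions: different programs differ in exactly these corners,
so the package fixes one self-consistent set rather than guessing another
tool's settings.

Percentages in feature and resolution tables use two-decimal **half-up**
rounding (`90.476 → 90.48`), applied uniformly.

## Nucleotide diversity and hotspots

Nucleotide diversity is the mean over all sample pairs of (differing
sites)/(comparable sites), where a site is comparable for a pair when both
rows carry an unambiguous base.  Per-pair denominators make the statistic
robust to gap-rich plastome spacers; pairs with no comparable sites in an
interval are skipped.  Note one consequence of the simple pair mean:
duplicating every sequence adds zero-distance pairs and therefore lowers
the mean slightly — the convention is documented rather than hidden.

`sliding_window()` profiles diversity in windows (defaults 600 bp window,
100 bp step, the conventional setting for plastome scans); windows start
at columns 1, 1+step, 2·step+1, … and a final truncated window is kept but
flagged `partial`.  `call_hotspots()` applies the hypervariable-region
rule: a named region qualifies when its peak ("crest") window diversity
exceeds `pi_threshold` (default 0.020) **and** its aligned length exceeds
`length_threshold` (default 600 bp).  The peak is the maximum diversity
over complete windows whose midpoint falls inside the region; partial
windows are excluded from peaks because their shorter denominators inflate
variance.  Output is sorted by peak diversity, descending.

## Distance-based discrimination

The Kimura 2-parameter distance separates transitions (A↔G, C↔T;
proportion $P$) from transversions (proportion $Q$) over the comparable
sites of each pair:

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Ambiguity codes are excluded from comparable sites entirely (no fractional
matching), which keeps the statistic deterministic.  Pairwise deletion is
the default (each pair uses its own comparable columns); complete deletion
is available by flag.  When $1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is
undefined (saturation) and the package raises an error naming the pair
rather than clamping to infinity — pathological inputs should surface, not
silently rank.  The raw-difference model counts differing comparable
columns as integers.

A species sampled with ≥ 2 individuals is **successfully identified** when
its minimum interspecific distance is strictly larger than its maximum
intraspecific distance (a tie is a failure, per the strict "larger than"
criterion).  Singleton species are not assessed but do serve as potential
nearest neighbors.  Three dataset-level summaries explain failures:

* `zero_k2p` — the number of assessed (multi-individual) species whose
  minimum interspecific K2P distance is exactly zero: these *cannot* show
  a gap, whatever their intraspecific diversity.
* `zero_k2p_all_pairs` — the number of unordered species pairs, over all
  species including singletons, whose minimum between-species distance is
  zero; a direct census of missing interspecific variation.
* AMID — for each assessed species, its minimum interspecific
  raw-difference count; the mean and range over species quantify how much
  absolute variation a dataset offers where it matters most.

`resolution_vs_zero_k2p()` regresses dataset resolution on the
`zero_k2p` count (OLS slope, Pearson r, two-sided p), the standard check
that lack of interspecific variation — not alignment length per se —
drives discrimination failure.

## Tree-based discrimination

Branches with bootstrap support below 50% are collapsed to polytomies
before testing (`collapse_low_support()`); edges without a support value
are treated as unsupported, with a warning.  Contracted edge lengths are
dropped, as in `ape::di2multi()`.  After collapsing, a species is
monophyletic when some edge of the (unrooted) tree separates exactly its
individuals from all other leaves — bipartition semantics, which are
stable whether or not the tree is rooted.  When an outgroup is supplied
its leaves are removed first, so the criterion applies to the ingroup
only.  The reported support is that of the edge adjacent to the species
clade; when polytomies leave several candidate edges the one directly
subtending the clade is used.  Because collapsing precedes testing, a
two-individual species whose connecting edge has support < 50 is scored
`N`, matching the "support ≥ 50%" clause of the criterion.

`compare_datasets()` reports species gained/lost between datasets and
pairs the supports of shared successes; `support_summary()` bins supports
into {100, [90,100), [65,90), <65}, the breakdown used when contrasting
super-barcodes with standard ones.

### Representative selection

For phylogenies built from one individual per species,
`select_representatives()` formalizes the usual manual rules, applied in
order: (1) singleton and monophyletic species keep their samples; (2)
own-provenance samples are preferred over downloaded ones; (3) for
non-monophyletic species, only individuals inside their section's dominant
clade are kept.  "Dominant clade" is defined as the largest clade whose
tips all belong to that section's samples (single tips count), with ties
broken by the smallest contained sample id — the minimal deterministic
formalization of "exclude the strays".  A species whose every individual
is a stray is flagged `unresolved` and keeps its first sample by id.  All
remaining ties break lexicographically.

### Two-tree (cytonuclear) comparison

`compare_trees()` contrasts two phylogenies at the sample, species or
section level.  At the group levels, a group collapses to a single leaf
only when it is monophyletic in that tree; a group torn apart in either
tree is excluded from the comparison in both, and reported — forcing a
placement for a non-monophyletic section would manufacture conflict.
Both trees are support-collapsed at the threshold (a tree carrying no
supports at all is taken as fully resolved), bipartition sets are compared
over the shared leaf set, and the comparison reports shared bipartitions,
the Robinson–Foulds distance (symmetric difference of the collapsed
bipartition sets) and the conflicting bipartitions: splits supported in
one tree that are incompatible (all four intersection cells non-empty)
with some supported split of the other.

## Neighbor joining with bootstrap

The package builds distance trees itself so the tree-based method runs
with no external phylogenetics tools; externally inferred ML trees remain
first-class inputs wherever a tree is accepted.  `neighbor_joining()` is
the classical Saitou–Nei agglomeration with the standard Q criterion.  A
negative branch length arising at a join is clamped to zero with the
remainder shifted to the sibling edge, preserving the pair's path length;
ties in Q break deterministically (first column-major minimum).  On
additive matrices the algorithm provably recovers the generating tree, and
the test suite checks exactly that, with `ape::nj` as an independent
implementation for cross-checks.

`bootstrap_tree()` is the Felsenstein nonparametric bootstrap: columns are
resampled with replacement, the NJ tree is rebuilt per replicate, and each
internal edge of the full-data tree receives the percentage of replicates
containing its bipartition (canonical, complement-invariant encoding, so
supports do not depend on sample order).  A replicate whose K2P distance
saturates for some pair falls back to raw differences for that replicate;
the count of fallbacks is recorded in the tree's metadata together with
the seed, replicate number and model.  Given a seed the whole procedure is
deterministic.

## The synthetic-data generator

`scenario_config()` defaults emulate a genus-scale barcoding study:

* 55 species, 83 samples — 21 species with 2–4 individuals (16×2, 3×3,
  2×4) and 34 singletons; sections are clusters of related species on the
  species tree (13 by default).
* three markers of very different lengths: a plastid "plastome" marker
  (4000 bp), a nuclear "nrDNA" marker (1000 bp) and a short nuclear
  "ITS" marker (300 bp).  Real plastomes are ~40× longer; lengths are
  scaled so the full pipeline (including bootstraps) runs in seconds while
  keeping the statistical regime — hundreds of interspecific differences
  on the long marker, a handful within species.
* `interspecific_scale = 0.05` expected substitutions/site per unit of
  species-tree path length and `intraspecific_scale = 0.002` expected
  pairwise divergence between conspecific individuals — a 25× separation,
  comfortably inside the "barcoding works" regime, so that failures in
  the clean default scenario indicate bugs, not biology.
* a two-rate-class (transition/transversion) substitution process with
  `ts_tv_ratio = 2` (total transition rate twice the total transversion
  rate).  The generator is deliberately the *generating counterpart of the
  K2P estimator*: estimator consistency becomes a clean, exact test.
  Sequences evolve by the closed-form K2P transition probabilities along
  each branch, seeded per marker, so every alignment is reproducible from
  the master seed.
* the species tree is a pure-birth (Yule) topology rescaled to unit root
  depth, with a fixed stem (`stem_length = 0.1`) appended to every
  terminal branch.  The stem models completed speciation: without it a
  Yule tree routinely contains species pairs whose divergence is far
  below the within-species diversity, and "100% resolution in the clean
  regime" would not be a property one could test.  Zero-divergence
  species pairs are still available — explicitly, via `ils_pairs`.
* chloroplast capture (`capture_events`) replaces the recipient sample's
  sequence on the captured (plastid) markers with a near-copy of a donor
  haplotype, perturbed at the intraspecific scale and seeded per event
  (hence idempotent).  Haplotype sharing (`ils_pairs`) plants *exact*
  copies of a donor haplotype in a fraction of the recipient species'
  individuals on plastid markers, creating species pairs at exactly zero
  distance.

What the generator does **not** emulate: indels and alignment error (the
matrices are gap-free), among-site rate heterogeneity, base-composition
bias (uniform by default; the `gc` knob shifts the root composition only),
coalescent ILS with explicit population sizes (sharing is planted, not
evolved), and the length and structural complexity of real plastomes.
Passing tests on synthetic data therefore demonstrate the correctness of
the statistics and the qualitative failure-mode logic, not performance on
real alignments with gaps, rate variation and sampling noise.

## Numerical choices

* Ties: a species whose minimum interspecific distance equals its maximum
  intraspecific distance fails; Q-criterion ties in NJ take the first
  column-major minimum; equal-size split sides canonicalize toward the
  side containing the alphabetically first leaf.
* K2P saturation is an error (with the pair named), never a clamp; the
  bootstrap's per-replicate fallback to raw differences is counted and
  reported.
* Degenerate inputs: alignments with < 2 rows refuse site statistics; a
  window longer than the alignment yields a single whole-alignment window
  with a warning; an all-gap/ambiguous alignment yields haplotype count 1
  with a warning; empty annotation lists yield empty hotspot calls rather
  than inferred regions.
* Reports round-trip: `read_report(write_report(r))` reproduces `r`
  (numbers serialized at 15 significant digits).

## Problem sizes in the test suite

The suite exercises the oracle checks on 100 random alignments of up to
12 × 300, NJ exactness on 50 random additive matrices of 5–12 taxa, and
the full 55-species/83-sample scenario across 20 seeds with 100 bootstrap
replicates for the parameter-recovery property — sizes chosen so the whole
suite completes in a few minutes while keeping every statistical check at
full strength.

## Known limitations

* Monophyly support is read from the single edge subtending the species
  clade; alternative conventions (e.g. the maximum support among defining
  edges under polytomies) would differ on heavily collapsed trees.
* The section-dominant-clade rule in representative selection is one
  deterministic formalization of "exclude strays"; curators may reasonably
  draw different lines when sections are deeply intermixed.
* `zero_k2p_all_pairs` compares species by their *minimum* pairwise
  distance, so one shared haplotype suffices — by design, since that is
  what breaks a barcoding gap.
* The pipeline evaluates discrimination given an alignment; alignment
  construction (MAFFT and manual curation) is upstream and out of scope.
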