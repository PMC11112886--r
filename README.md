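# superbarcode

Evaluation of plastome-scale ("super") DNA barcodes for species
discrimination.

Standard plant barcodes (*matK*, *rbcL*, *trnH*-*psbA*, ITS) frequently
fail in species-rich genera because they carry too little interspecific
variation.  Whole plastomes and the complete nuclear ribosomal cistron
offer far more signal — but their discriminatory power has to be measured,
and their failures diagnosed: chloroplast capture after hybridization and
incomplete lineage sorting can leave two species with identical plastid
haplotypes no matter how long the barcode.  `superbarcode` is an R
package for exactly this evaluation, aimed at researchers assessing
candidate barcoding datasets for a genus-scale study.

## What it computes

Given species-labeled alignments (FASTA + a sample map TSV), the package
provides:

* **Alignment features** — aligned length, variable and
  parsimony-informative sites, haplotype counts, GC content
  (`features_table()`).
* **Divergence hotspots** — sliding-window nucleotide diversity (default
  600 bp / 100 bp) and the hypervariable-region rule: peak π > 0.020 and
  aligned length > 600 bp (`sliding_window()`, `call_hotspots()`).
* **Distance-based discrimination** — Kimura 2-parameter distances
  (d = −½ ln(1−2P−Q) − ¼ ln(1−2Q), with P/Q the transition/transversion
  proportions over pairwise-comparable sites), barcoding gaps per species
  (minimum interspecific > maximum intraspecific, strictly), and the
  failure diagnostics: the number of species with zero minimum
  interspecific K2P distance, the number of species pairs at zero
  distance over all samples, and AMID, the average minimum interspecific
  raw-difference count (`evaluate_distance()`).
* **Tree-based discrimination** — support collapsing below 50%,
  bipartition-based monophyly per multi-individual species, resolution
  percentages, gained/lost species between datasets, and support
  histograms (`evaluate_tree()`, `compare_datasets()`,
  `support_summary()`).
* **Self-contained trees** — neighbor joining with a seedable
  nonparametric bootstrap, so the tree-based method needs no external
  phylogenetics tools (`bootstrap_tree()`); externally inferred ML trees
  in newick are accepted everywhere.
* **Cytonuclear conflict** — bipartition comparison of a plastid and a
  nuclear tree at sample/species/section level, with Robinson–Foulds
  distance and a list of supported, mutually incompatible splits
  (`compare_trees()`); one-representative-per-species selection with
  deterministic stray exclusion (`select_representatives()`).
* **Synthetic data** — a generator emulating a 55-species / 83-sample
  study with markers of very different lengths, controlled inter- and
  intraspecific divergence, and plantable chloroplast-capture and
  haplotype-sharing events with ground truth (`scenario_config()`,
  `make_scenario()`, `emit_scenario()`).
* **Orchestration** — `run_study()` evaluates a set of datasets end to
  end and writes feature, distance, tree and comparison tables plus a run
  log; `exec/superbarcode` is a thin command-line front end.

See `vignettes/superbarcode-methods.Rmd` for the statistical conventions
and design choices.

## Worked example

The package ships a published verdict table — the monophyly outcomes
(with bootstrap support) of 21 multi-individual *Acer* species under four
barcoding datasets — as a worked example:

```r
library(superbarcode)
v <- read_verdicts(system.file("extdata", "acer_monophyly_verdicts.tsv",
                               package = "superbarcode"))

resolution(v$plastome)                       # 90.48  (19/21 species)
resolution(v[["matK_rbcL_trnH-psbA"]])       # 61.9   (13/21 species)

compare_datasets(v$plastome, v[["matK_rbcL_trnH-psbA"]])$gained
# [1] "A. fabri"        "A. flabellatum"  "A. japonicum"    "A. maximowiczii"
# [5] "A. oblongum"     "A. tutcheri"

support_summary(v$plastome)$n_100            # 18
```

The whole plastome resolves 19 of 21 species (90.48%, printed as 90.47 in
the source table's truncation), six more than the three standard plastid
barcodes combined, and 18 of its 19 successes carry 100% bootstrap
support.

Running the pipeline on a synthetic clean-regime dataset:

```r
cfg <- scenario_config(seed = 1)      # 55 species, 83 samples, 3 markers
sc  <- make_scenario(cfg)
evaluate_distance(sc$alignments$plastome)
# discrimination_report 'plastome': 21 species
#   method: distance
#   resolution_pct: 100
#   n_assessed: 21
#   n_success: 21
#   zero_k2p: 0
#   zero_k2p_all_pairs: 0
#   amid_mean: 113.1905
#   amid_min: 41
#   amid_max: 255
```

All 21 assessed species show a barcoding gap, no species pair sits at
zero distance, and the average minimum interspecific difference is ~113
sites — the signature of a marker with ample interspecific variation.
Planting a capture event (`capture_events` in `scenario_config()`) makes
the recipient species fail on the plastid marker while remaining
identifiable on the nuclear one, reproducing the canonical failure mode.

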