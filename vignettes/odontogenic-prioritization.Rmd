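---
title: "Prioritizing candidate odontogenic loci from multimodal regulatory genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate odontogenic loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothprior)
```

## The problem

Tooth development is driven by transient structures — most prominently the
enamel knot of the cap-stage molar — whose regulatory landscape cannot be
read from adult tissue. Enhancers active in the developing tooth are
therefore the natural place to look for the common-variant basis of dental
phenotypes such as oligodontia or delayed eruption, but enhancer catalogues,
GWAS hits, single-cell marker genes, bulk differential expression and
co-expression modules each cover a different, noisy slice of the biology.
`toothprior` integrates those slices into a single auditable ranking of
candidate loci, keeping every intermediate quantity inspectable.

## The pipeline, stage by stage

### Coordinates and interval algebra

Everything is 0-based half-open (the BED convention); 1-based inputs
(GWAS-catalog positions) are converted once, at load. Interval merge,
subtraction and intersection are implemented on `GenomicRanges`; the test
suite checks them against an independent per-base boolean-mask oracle on
toy chromosomes, so the half-open conventions cannot drift. Chromosome
names are matched exactly — a naming mismatch between inputs should fail
loudly, not be silently "fixed".

### Enhancer extraction

In the 18-state chromatin model the strong-enhancer states are 8, 9 and 10
(`strong_states`, configurable). The strong set of a sample is the merged
union of those segments; adjacent strong segments fuse into one enhancer.
Tissue specificity is defined against background tissues, with two modes:

* `remove_whole` (default): a strong enhancer sharing at least `min_bp`
  (default 1) bases with any background strong enhancer is dropped whole.
  This matches counting discrete enhancers that either are or are not
  unique to the tissue, which is how tissue-specific enhancer tallies are
  usually reported.
* `trim`: base-wise subtraction, for sensitivity analysis.

Whether a published "unique to the tissue" subtraction removed whole
elements or trimmed bases is generally not recoverable from a methods
section; we ship both and default to whole-element removal because the
downstream score consumes enhancer *counts*, which are only well-defined
for discrete elements.

Cross-assembly projection (`apply_coordinate_map()`) deliberately accepts a
precomputed block map rather than computing alignments: sequence-level
conservation filtering belongs to specialized liftover tooling, and a
precomputed map keeps this package free of genome sequence handling.

### Gene association

`build_regulatory_domains()` implements the basal-plus-extension rule: a
basal window of 5 kb upstream / 1 kb downstream around the TSS
(strand-oriented; the window always contains the TSS base), extended on
each side up to 1 Mb beyond the basal edge or until the nearest other
gene's basal domain, whichever is closer, clipped to the chromosome. Two
genes with identical TSS do not truncate each other (the tie would
otherwise make domain shapes depend on row order), and a neighbouring basal
domain that already overlaps a gene's basal domain blocks extension on that
side without ever shrinking the basal domain. An enhancer is assigned to
every gene whose extended domain it overlaps by at least 1 bp; assignment
to several genes is intended, not an error.

Variant proximity ("gene within 500 kbp of a variant") is measured to the
gene *span*, boundary inclusive, with distance defined between closest
bases (adjacent bases are 1 apart). Measuring to the TSS instead is a
configuration switch (`variant_measure = "tss"`); the span reading is the
default because "genes located within" a distance most naturally refers to
the gene body. Validated-element proximity uses the same metric span-to-span
with a 1 Mb window.

Retention filters are read literally: GWAS variants kept at
`pvalue <= 5e-8` (inclusive) for the configured traits, with exact
`(variant_id, chrom, pos)` duplicates collapsed but multi-position rsIDs
kept; DEGs kept at `log2fc > 2` (strict) and `padj <= 0.05` (inclusive).

### Enrichment statistics

`permutation_set_enrichment()` draws `n_perm` uniform random subsets of the
gene universe of the query's size and compares overlaps with the target
set. The empirical p uses the +1 correction, `(1 + #extreme)/(1 + n_perm)`,
so the smallest reportable p is `1/(n_perm + 1)` — with the default
n = 10,000 that is just under 10⁻⁴. Both tails are computed; the reported
`p_empirical` follows the observed direction. The null mean converges to
the hypergeometric expectation `|query|·|target|/|universe|`, which the
test suite verifies to within three standard errors, together with an
under-null rejection-rate calibration. Sampling is uniform: no matching on
expression level, GC or domain length is attempted, so a strongly
structured universe can make the null optimistic — that is the main caveat
when interpreting module flags on real data.

Module flags (`module_enrichment_flags()`) run one permutation test per
module × category (enhancer-target genes, dental-phenotype ontology genes,
DEGs), BH-adjust across the whole family, and set a flag when `fold > 1`
and adjusted `p <= alpha` (default 0.05). The excluded (grey) module is not
tested, since its genes never reach the ranking.

`fisher_2x2()` authors the two-tailed Fisher exact p by probability
ordering — the sum of hypergeometric point probabilities not exceeding the
observed table's, with the standard `1 + 1e-7` relative tie tolerance —
and reports two effect sizes: the sample odds ratio `ad/bc` and the ratio
of group proportions `(a/(a+b))/(c/(c+d))`. The proportion ratio is the
"fold increase" a prevalence comparison reports; the two differ noticeably
for common outcomes, so both are returned.

### Scoring and ranking

The composite score is a sum of eight components (maximum 13): marker gene
(0/1), dental-cell-type marker (0/1; Enamel Knot, Epithelium, Mesenchyme,
Perivascular Cells), GWAS proximity (0/1), TSE-count bucket (0–4: 0 TSEs =
0, 1–2 = 1, 3–4 = 2, 5–6 = 3, 7+ = 4), module enrichment (0–3, one point
per flagged category), VISTA proximity (0/1), tooth-enhancer target (0/1),
DEG (0/1). Two readings of the module bonus are defensible — one point per
category or a lump point for any enrichment; we default to per-category
because it is the only reading under which the three categories are
individually meaningful, and provide `module_scoring = "lump"`. The
"enhancer target" point uses the strong set by default
(`te_target_kind`): it is the broader, better-powered notion of being under
tooth-enhancer control, with the tissue-specific variant available.

Ranking excludes the grey module (unassigned, low-expression genes), sorts
by total score, breaks ties by predicted targeting-TSE count (an STE-count
option exists, since either count is a defensible activity proxy), and
finally by gene id so output order is a pure function of the evidence.
Scoring involves no randomness at all.

## The synthetic world

`generate_world()` builds a deterministic toy genome for testing: two
chromosomes, 60 genes (alternating strand) spaced 2.5 Mb apart, one target
and three background segmentations, variants, validated elements and
marker/DE/module tables. The spacing is the load-bearing choice: with
basal-plus-extension domains capped at ~1 Mb, a 500 kbp variant window and
a 1 Mb element window, 2.5 Mb spacing guarantees that every planted
element, variant and enhancer is attributable to exactly one gene. Ground
truth — per-gene evidence and score — is therefore computable by arithmetic
at generation time, before any pipeline code runs, and the end-to-end test
demands exact recovery of the planted score decomposition and ranking over
a 20-seed sweep.

Planted structure follows module profiles: `red` genes carry 5–12
tissue-specific enhancers, dental markers, DEG status and an enriched
module on all three categories; `blue` carries enhancers only; `yellow`
DEG status only; `green` nothing; `grey` exercises the ranking exclusion.
Each non-grey module is deliberately either a subset of or disjoint from
each enrichment category, which makes every permutation-derived flag's
truth value deterministic by construction rather than borderline. Boundary
pins place one variant exactly at the 500 kbp window and one at one base
beyond (likewise for the 1 Mb element window), nailing the inclusive
boundary convention. DE edge rows pin the strict fold-change and inclusive
adjusted-p thresholds (log₂FC exactly 2.0 is excluded; padj exactly 0.05
is included).

What the world does *not* emulate: nucleotide sequence, linkage
disequilibrium among variants, realistic state-segment length
distributions, expression-correlated gene density, or assembly differences.
Passing the end-to-end tests therefore demonstrates that the pipeline's
logic and conventions are exactly right, not that the defaults are optimal
for any particular real dataset.

## Numerical and scale choices

* Permutation depth defaults to n = 10,000 (p floor ≈ 10⁻⁴). The test
  suite runs pipeline worlds at n = 2,000 and calibration fixtures at
  n = 499: the planted module structure is decided at fold ≫ 1, so the
  extra depth buys nothing there, while the statistical-property tests use
  depths matched to what they measure.
* Permutations use one locally seeded generator per call (the caller's RNG
  stream is saved and restored), and every result records its seed;
  family members in `module_enrichment_flags()` use `seed + test index`.
* Fisher p-values never exceed 1 by construction (the sum is clamped), and
  the `1e-7` relative tolerance in tie detection matches mainstream
  implementations, so enumeration cross-checks agree to 10⁻¹².
* Degenerate inputs are contracts, not surprises: an empty segmentation
  yields an empty enhancer set; an empty background list returns the
  re-tagged strong set with a warning; an empty enrichment category yields
  a `FALSE` flag; a query equal to the universe yields fold 1, p 1.

## Known limitations

* The permutation null is uniform over the universe; matched-control nulls
  (LD-aware variant shuffling, expression-matched gene draws) are out of
  scope, and enrichment on strongly structured real universes should be
  read accordingly.
* Regulatory-domain construction implements the basal-plus-extension rule
  only; curated species-specific domain exceptions that some annotation
  resources add are not modelled.
* Cross-assembly projection trusts its input map; no sequence-identity
  computation is performed.
* Genome-scale enhancer tallies from full multi-tissue compendia are not
  reproducible from the toy world — the package validates logic and
  conventions at desk scale and is applied to real inputs via the file
  interfaces.
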