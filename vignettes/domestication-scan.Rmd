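---
title: "Methods: candidate-gene domestication scans with domesticscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene domestication scans with domesticscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Crop domestication leaves a recognisable footprint on the genes it touched:
cultivated material (landraces) loses nucleotide diversity relative to the
wild and weedy gene pool, allele frequencies shift between the two pools, and
the site-frequency spectrum in the domesticated pool skews toward rare
variants. `domesticscan` implements a candidate-gene scan for this footprint
in a resequencing panel of inbred lines, split into a *wild/weedy* group and
a *landrace* group, with coding sequence (CDS) resolution. The motivating use
case is a panel of 25 sorghum genotypes screened over ~114 candidate genes
for seed size and weight, calibrated against ~159 neutral loci, but every
panel dimension is configurable.

# Estimators

All statistics operate on a per-gene `aln_matrix`: a haploid samples x SNPs
matrix over the CDS of one gene (inbred lines are represented by a single
haplotype; heterozygous calls are treated as missing, see below).

* **Nucleotide diversity** `theta_pi()`: the Nei–Li average pairwise
  difference per site. At each site the mismatch probability among pairs of
  non-missing alleles is `2 n1 n0 / (n (n-1))`; these are summed over sites
  and divided by the full CDS length, so monomorphic sites contribute zero
  and values are comparable across genes of different length. Whether to
  divide by CDS length or by total gene span is a genuine choice; we
  standardise on CDS length because the scan operates on CDS variants only.
* **Watterson's theta** `theta_w()`: segregating sites scaled by the
  harmonic number `a1 = sum(1/i), i < n`, per site.
* **Tajima's D** `tajima_d()`: `(k - S/a1) / sqrt(e1 S + e2 S (S-1))` with
  the constants of the 1989 derivation recomputed from the sample size at
  call time (`tajima_constants()`). `k` is the mean pairwise difference
  *count*. D is reported as `NA` (undefined), never zero, when `S = 0` or
  `n < 4`.
* **Hudson's Fst** `hudson_fst()`: `1 - Hw/Hb`, where `Hw` is the unweighted
  mean of the two within-group mean pairwise difference rates and `Hb` the
  mean between-group pairwise difference rate. Gene-level values aggregate
  per-site `Hw` and `Hb` as a ratio of sums, the standard multi-site form of
  this estimator. The two groups enter symmetrically and values may be
  negative; `Hb = 0` yields `NA`.
* **Reduction of diversity** `rod()`: the fold decrease
  `theta_pi(wild) / theta_pi(landrace)`. A gene invariant in the landraces
  but variable in the wild pool has `RoD = Inf`; a gene invariant everywhere
  has undefined RoD (`NA`).

Per-SNP statistics (`per_site_stats()`) use a 1-bp window: per-group site
diversity on the count scale, site-restricted Fst, the landrace group's
Tajima's D at that site (`S = 1`), and the per-site RoD ratio.

# The three-criterion selection classifier

`snp_selection_test()` flags a SNP as carrying a purifying-selection
signature when, jointly:

1. its per-site RoD exceeds the **neutral baseline** — the arithmetic mean
   of the finite gene-level RoD values across the neutral loci
   (`neutral_baseline()`); the comparison is evaluated in cross-multiplied
   form `pi_wild > mean_rod * pi_landrace`, so infinitely reduced sites need
   no division;
2. the per-site Fst is strictly positive;
3. the landrace group's Tajima's D at the site is defined and strictly
   negative.

Three interpretation points were open and are resolved as follows. The
group whose D enters criterion 3 is the landrace group: the skew of interest
is the excess of rare variants in the domesticated pool. "Positive Fst" and
"negative D" are read strictly (`> 0`, `< 0`). Sites where the landrace
group is monomorphic have *undefined* site D; they fail criterion 3 rather
than being dropped, a conservative composition — an infinite per-site RoD
alone cannot demonstrate a frequency skew that is undefined. Similarly,
infinite or undefined RoD values at *neutral* loci are excluded from the
baseline mean (and counted), since a mean over infinities is not usable as
a threshold.

A gene is *under selection* when at least one of its SNPs passes
(`gene_selection_calls()`); the nonsynonymous flag records whether any
passing SNP changes the encoded amino acid. Raising the baseline can only
shrink the selected set (monotonicity; property-tested). A genome-wide
gene-ranking screen is not implemented: it would require an external
genome-wide empirical distribution that a candidate-gene package cannot
recompute; an optional percentile screen over the supplied gene set can be
emulated by filtering the `gene_stats` table directly.

# Codon annotation

`classify_snp()` substitutes the alternate allele into the reference codon
and translates both with the standard nuclear genetic code
(`Biostrings::GENETIC_CODE`); stop gain/loss counts as nonsynonymous. Each
SNP is judged in the reference codon context only — no haplotype-aware
multi-SNP codons — matching the per-SNP design of the scan. Genes whose CDS
length is not a multiple of 3 are skipped with a warning. The classification
is symmetric in which allele is called reference.

# Seed-preferential expression and enrichment

`classify_seed_preferential()` compares the maximum FPKM over seed-tissue
samples to the maximum over non-seed samples; a strict fold difference > 2
defines seed-preferential expression. The non-seed maximum is floored at 1
FPKM: a floor avoids infinite fold changes at genes silent outside the seed
while still classifying genuinely seed-specific genes positive.
`enrichment_report()` crosses these classes with gene-level selection calls
into a 2x2 table, reports the percentage under selection in each class
(rounded to integers), and computes the **uncorrected Pearson chi-square**
(`pearson_chi2_2x2()`, with the chi-square(1) p-value). No Yates continuity
correction or likelihood-ratio variant is applied; the statistic is the
plain textbook formula, oracle-tested to 1e-10. For the classic worked
example of 17/22 seed-preferential versus 46/92 other genes under selection,
this formula gives 77% vs 50% and a statistic of 5.34 (p = 0.021).

# Ortholog merging

`bbh_pairs()` reads 12-column tabular protein-homology hit files and keeps
reciprocal best hits, with deterministic tie-breaking (bit score, then
e-value, then lexicographic subject id — published descriptions rarely state
a tie rule, so we fix one). `merge_evidence()` unions BBH and synteny pair
sets with a method label (`BBH`, `synteny`, `both`), `ortholog_tally()`
asserts the inclusion–exclusion identity per species and counts unique
targets overall (genes found from two or more source species count once),
and `add_external_candidates()` adds curated extras idempotently. Running
the protein alignment itself is out of scope; any aligner producing the
standard tabular format plugs in.

# Haplotype networks

`enumerate_haplotypes()` collapses complete-case allele strings over a
gene's SNPs into distinct haplotypes with per-group carrier counts; samples
with missing alleles are excluded per gene and counted. `build_network()`
links haplotypes by a minimum spanning tree over pairwise Hamming distances
(Kruskal, ties broken by distance then smallest index pair). An MST is used
instead of a statistical-parsimony network deliberately: it is
deterministic, cheaply testable against exhaustive enumeration, and
preserves the qualitative content of a haplotype map — distance-weighted
links between frequency-scaled, group-coloured nodes.

# The synthetic panel generator

`generate_dataset()` writes a complete, fully synthetic input bundle (FASTA,
haploid VCF v4.2, group/annotation/expression/tissue TSVs, and a
ground-truth table) so that every downstream stage is testable without any
external data. Genes are simulated independently under a two-population
coalescent: one ancestral population of constant size, a split `t_split`
coalescent units ago, and a landrace lineage whose effective size is
multiplied by `bottleneck_factor` after the split. Mutations follow the
infinite-sites model (Poisson on branches at `theta/2` per site, occupied
positions resampled, all sites biallelic). There is no recombination within
genes and no selfing model; multi-allelic sites and realistic chromosome
coordinates are out of scope.

## Emulating selection

Genes marked *selected* carry a partial sweep in the landrace lineage,
implemented purely by branch-length shrinkage in the coalescent: each
landrace lineage escapes the sweep with probability `1/selection_rod`;
non-escaped lineages coalesce before the split in a deme shrunk by a further
`1/selection_rod` (their branch lengths are literally compressed), escaped
lineages coalesce at the neutral landrace rate, and the two backgrounds do
not coalesce with each other before the split. Landrace-private branch
segments additionally carry `1/selection_rod` of the mutation load. The
escape mechanism matters: a sweep that removes landrace variation entirely
leaves nothing for a per-SNP test to see (criterion 3 is undefined at
landrace-monomorphic sites), whereas rare escaped haplotypes produce exactly
the detectable pattern — sites where the wild pool segregates at moderate
frequency while the landrace pool retains the variant at low frequency with
positive differentiation. The truth table records the *realized* per-gene
RoD, not the nominal `selection_rod`.

## Study conditions and their calibration

Defaults describe the intended panel: 12 wild/weedy + 13 landrace haploid
genotypes, 114 candidate + 159 neutral genes, CDS length 1404 bp,
`theta = 0.005` per site (`theta * L` about 7, placing wild-group diversity
in the observed range for such panels), `t_split = 0.15`,
`bottleneck_factor = 0.3`, `selection_rod = 10` at half of the candidates.

The bottleneck parameters are constrained by an identity worth recording.
With 12/13 samples, the per-site RoD is bounded: the largest possible
wild-group site diversity is 0.545 (6/6 split) and the smallest nonzero
landrace value is 0.154 (singleton), so no site can exceed an RoD of about
3.5. The neutral baseline is a mean over gene-level RoD values, whose
distribution is right-skewed under strong bottlenecks (small landrace
denominators); scenarios much stronger than the default push that mean above
the per-site ceiling and the scan cannot call anything, for any gene. The
default scenario keeps the neutral baseline near 2–3, inside the detectable
range, and corresponds to a landrace pool retaining roughly two thirds of
wild diversity at neutral loci — a moderate domestication bottleneck.

Expression tables emulate a compendium of 4 seed and 5 non-seed tissue
samples: per-gene log-normal baselines, log-normal sample noise, and a
seed-specific fold factor (>= 2.5) for seed-preferential genes, assigned
with probability 0.27 to selected and 0.10 to unselected candidates so the
enrichment stage has signal of the observed magnitude.

## What passing tests do and do not show

The generator shares the estimators' assumptions (haploid, biallelic,
infinite sites, free of recombination *within* genes, genes independent).
Tests against it therefore validate the statistical machinery and the
classifier's behaviour under a known demography; they do not probe
alignment or variant-calling artefacts, intragenic recombination (which
decorrelates sites and would, if anything, help the per-site scan), gene
flow between pools, or mis-assigned group labels in real panels.

# Numerical and degenerate-input conventions

* Undefined statistics are `NA` (serialized `"NA"`), infinite RoD is `Inf`
  (serialized `"Inf"`); neither is silently converted to zero.
* Internal coordinates are 0-based; conversion to and from 1-based VCF
  positions happens only at the I/O boundary. Minus-strand genes are
  reverse-complemented into coding orientation on read.
* Heterozygous or half-missing diploid genotype calls become missing
  (inbred-line panels are expected to be near-homozygous; no phasing rule is
  invented). Multi-allelic and indel records are dropped with a warning.
* Complete-case handling per site: a site with fewer than two usable
  alleles in a group contributes no within-group information there.
* All randomness flows from one integer seed; a fixed seed reproduces the
  generated files byte for byte and the pipeline outputs exactly.

# Problem sizes used by the test-suite

The packaged checks run at desk scale, chosen to finish in minutes while
keeping Monte-Carlo error well inside the asserted tolerances: estimator
oracle equivalence on 120 random matrices (tolerance 1e-10), exhaustive
codon enumeration (576 cases), neutral calibration on 200 simulated genes
against 400 replicates of an independent single-population coalescent
(3 standard errors), and parameter recovery on a 259-gene panel (159
neutral + 100 candidates, half selected at `selection_rod = 10`).

# Known limitations

* The scan is a deterministic filter, not a test with controlled error
  rates; no multiple-testing machinery is attached, and the neutral
  false-call rate depends on the demography (property-tested to stay below
  25% under the default scenario).
* Single-locus coalescent without recombination means all sites of a gene
  share one genealogy; per-site criteria within a gene are therefore highly
  correlated in the synthetic data.
* The maximum-likelihood polymorphism/divergence validation stage and any
  genome-wide ranking threshold are intentionally out of scope.
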