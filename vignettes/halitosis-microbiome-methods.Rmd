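---
title: "Methods: comparative oral-microbiome analysis of childhood halitosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative oral-microbiome analysis of childhood halitosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and design

`halimicro` implements the statistical core of a two-condition,
two-site oral-microbiome comparison: tongue-coating and saliva samples
from children with and without halitosis, characterized by 16S OTU
tables and by pooled shotgun-metagenome gene tables. The package is the
computational layer; thin numbered drivers under `analysis/` narrate a
full synthetic study. Everything upstream of an OTU or gene count table
(read QC, denoising, OTU clustering, taxonomy assignment, assembly, gene
prediction, annotation lookup) is out of scope; annotations are consumed
as input maps.

Because the original raw sequencing data are not required, a first-class
synthetic-data module generates cohorts with *planted*, recorded
effects. Every downstream detector is validated two ways: against
independent enumeration oracles on small inputs, and by recovery of the
planted truth at the study's own design size (10 subjects per condition,
two sites, one sample per subject and site).

## The synthetic cohort model

OTU intensities start from a log-normal rank-abundance spectrum
(`base_meanlog = 0`, `base_sdlog = 2`), drawn once, sorted in decreasing
order and assigned to `OTU001..OTUn` — so low-numbered ids are the
abundant taxa, which makes planted effects addressable by abundance
stratum. Each sample perturbs the spectrum with per-OTU log-normal noise
(`subject_sdlog = 0.7`, a dispersion that gives realistic subject-level
variability for oral communities) and is then drawn as
`multinomial(depth, composition)`; column sums therefore equal the
configured depth exactly. Defaults — 10 subjects per condition, depth
10,000 reads, 200 OTUs — mirror a small 454-scale amplicon cohort.

Planted effects:

- **Richness surplus**: `richness_delta` extra OTUs present only in
  halitosis tongue samples, each at a typical relative abundance of
  `richness_relab` (default 5·10⁻⁴, high enough to register at a
  7,180-read rarefaction depth without distorting the composition).
- **Fold effects**: an OTU's intensity is multiplied by `fold` in
  halitosis samples of one site.
- **Prevalence effects**: per-sample Bernoulli presence with separate
  probabilities per condition.
- **Correlated pairs**: the two members (possibly at different sites;
  members are subject-paired) share a per-subject standard-normal latent
  factor added to their log-intensities with loading λ.

The loading is calibrated *numerically*: a closed-form bivariate
log-normal inversion is exact for raw intensities, but the Pearson
correlation of **relative** abundances is attenuated by the shared
compositional denominator, so the calibration simulates the
normalization explicitly (4,000 pseudo-subjects) and solves r(λ) = ρ on
a grid. Two details matter:

- When compositional noise caps the reachable correlation below the
  target, the calibration is allowed to push the shared-factor variance
  *beyond* the baseline log-variance (the member's dispersion then
  inflates — a documented trade-off of planting strong correlations in
  compositional data). The calibration tolerance is |E[r] − ρ| ≤ 0.05;
  if the target is unreachable even so, the generator warns and plants
  the attenuated maximum.
- An OTU appearing in several pairs keeps its marginal log-variance by
  rescaling, so hub-like planted modules attenuate gracefully rather
  than exploding in variance.

Gene tables per site are Poisson: healthy counts with mean
`library_size × relative abundance`, halitosis counts with the abundance
multiplied by any planted fold (no renormalization, so unplanted genes
keep their abundance by construction). The first block of genes carries
the 17 H₂S pathway families (5 genes per family by default); KO
categories are assigned randomly (40 categories; ~10% of genes get a
second category, reflecting many-to-many KO maps).

What the generator deliberately does **not** emulate: sequencing error
and chimeras, overdispersion beyond log-normal × multinomial,
taxon–taxon ecological interactions other than the planted
correlations, site-specific baseline compositions, and realistic
phylogenetic signal (the tree is random with exponential branch
lengths, rate 10). Passing recovery tests therefore demonstrates that
the detectors work at the study's design size under a clean
compositional model — not that they are robust to every artefact of
real amplicon data.

## Diversity

Rarefaction draws a **single** subsample without replacement per sample
(default depth 7,180, the even-depth comparison point of the tongue
/saliva analysis); shallower samples are dropped with a warning.
Observed richness and bias-corrected Chao1
(S_obs + F₁(F₁−1)/(2(F₂+1)), the mothur-style default; always ≥ S_obs)
are compared between conditions with Welch's t-test — "independent
t-test" leaves the variance assumption open, and unequal variances are
the safer default at n = 10 per group.

Weighted UniFrac is implemented in its normalized form,
D = Σ l_b|A_b − B_b| / Σ l_b(A_b + B_b) ∈ [0, 1], via a single postorder
accumulation of descendant abundance fractions; a brute-force per-branch
oracle checks it in the tests. Missing branch lengths read from newick
default to zero with a warning — they then contribute nothing to the
distance, the conservative choice. AMOVA partitions the squared
distances into among- and within-group sums (Excoffier-style pseudo-F on
the distance matrix) and permutes sample labels; the p-value uses the
add-one estimator (1 + hits)/(n_perm + 1) so it can never be zero. The
diversity contrasts are run per site, matching the reported comparisons;
pooling sites would confound the strong tongue/saliva habitat difference
with condition.

## Differential OTUs

Relative abundances are compared with the Wilcoxon rank-sum test — the
exact null distribution when the smaller group has ≤ 10 values and the
pooled values are tie-free, otherwise the normal approximation with
midranks, tie-corrected variance and continuity correction. Prevalence
(count > 0, evaluated **after** rarefaction so detection is
depth-comparable) is compared with the two-sided Fisher exact test.
Flags use raw p < 0.05 on either test: with ~1,400 OTUs and no stated
correction this mirrors the analysis being reproduced, but both BH
q-values are always present in the output for stricter use. OTUs absent
from every sample of a site are excluded (and logged), not reported as
p = 1 rows.

## Co-occurrence networks

Nodes are (site, OTU) pairs within one condition; vectors are relative
abundances ordered by subject so tongue and saliva vectors of the same
child are positionally paired — the only pairing under which a
cross-site correlation is defined. All unordered node pairs are tested;
an edge requires |r| > 0.4 **and** permutation p < 0.01. Numerical
choices:

- The permutation null permutes one vector of the pair. When
  n! ≤ 10,000 (n ≤ 7) the full enumeration is used and the p-value is
  exact; otherwise `n_perm` (default 10,000, resolution 10⁻⁴ at the
  0.01 threshold) random permutations with the add-one estimator.
- Each pair's permutation stream is seeded by a stable 31-bit string
  hash of (global seed, ordered node ids), so the network is invariant
  to node input order and reproducible edge-by-edge.
- Zero-variance nodes are dropped (correlation undefined) with a
  message; the correlation magnitude is only thresholded, the sign
  labels the edge.

Edges are classed as inter-site or intra-site by their endpoints and by
sign; hub nodes are those with degree strictly greater than 30.
Exports: a Cytoscape-importable edge TSV and GraphML with node `site`
and `degree` attributes.

## Core microbiome

"Above 75%" is read strictly (> 0.75). Core OTUs exceed the threshold
in both tongue-coating groups; one-sided exceedance gives the
health-/halitosis-associated labels. Tier 1 requires prevalence 1.0 in
the relevant group(s) with mean relative abundance ≥ 1%, tier 2 is
prevalence 1.0 below 1%, tier 3 is prevalence in (0.75, 1.0). Two
points the tier legend leaves open are resolved symmetrically and
exposed as options: (a) a prevalence-1.0, ≥ 1% *associated* OTU gets
tier 1 within its own label; (b) a sub-100%-prevalence OTU keeps tier 3
regardless of abundance, since the outer tier is defined by prevalence.
The abundance denominator is all tongue samples for core OTUs and the
defining group's samples for associated OTUs by default
(`abundance_scope = "group"`); `"all"` switches to a common denominator.

## Gene function

The two pooled libraries have no replicates, so gene-level inference
uses the exact conditional binomial test: given n = k₁ + k₂, under equal
relative abundance k₁ ~ Binomial(n, N₁/(N₁+N₂)); the two-sided p sums
outcome probabilities ≤ the observed one. This replaces the original
MA-plot/random-sampling two-library method (DEGexp) with its standard
exact analogue; the decision rule — fold > 5 (pseudocount 0.5 on both
counts, guarding zeros) and p < 0.001 — is kept verbatim, applied to the
pseudocount-adjusted ratio. Library size means total mapped counts per
pooled library. KO enrichment is the upper-tail hypergeometric test
with the population defaulting to all KO-annotated genes; raw p < 0.05,
BH optional. The H₂S report sums member-gene counts per family and
site, and calls up/down/flat by the 2-fold rule (absent when a family
has no genes); tongue is conventionally printed outside and saliva
inside the brackets.

## Problem sizes and reproducibility

All stochastic functions take explicit seeds; one global integer seed
drives a simulation end to end, and identical seeds give bit-identical
tables, trees and summaries. The test and acceptance runs use sizes
chosen to make Monte-Carlo margins comfortable at interactive run
times: 40 null cohorts (~2,800 OTU tests) for Wilcoxon calibration, 500
null pairs for the edge test, 1,000 null genes for the two-library
test, 50 replicate cohorts each for differential-OTU sensitivity
(five 4-fold OTUs, n = 10/10) and for ρ = 0.9 edge recovery at
n = 50 subjects.

## Known limitations

- Compositionality is not corrected (no CLR/SparCC-style treatment);
  correlations and fold effects operate on relative abundances, as in
  the analysis being reproduced. Null calibration shows the tests hold
  their error rates, but compositional coupling inflates the variance
  of any aggregate false-positive count.
- CatchAll richness estimation is not implemented.
- The exact Wilcoxon branch requires tie-free data; heavily tied OTUs
  (many zeros) route to the corrected normal approximation, which is
  slightly conservative at n = 10.
- Permutation p-values are bounded below by 1/(n_perm + 1); edges whose
  true p sits near the 0.01 threshold can flicker between runs with
  different seeds at the default resolution.
- The core-microbiome tier extension for the cases the legend does not
  cover is a documented convention, not a reconstruction.
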