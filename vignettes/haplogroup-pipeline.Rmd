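---
title: "Methods: mtDNA haplogroup structure in array-typed birth cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA haplogroup structure in array-typed birth cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocline)
```

## The problem

Large neonatal-screening biobanks allow population-scale surveys of
mitochondrial DNA (mtDNA) haplogroups: maternally inherited SNP haplotypes
whose frequencies carry the signature of a population's migration history.
A typical survey genotypes a few hundred mtDNA loci on a SNP array, assigns
each sample to a haplogroup by matching defining SNPs against the PhyloTree
hierarchy, and then asks how haplogroup frequencies vary across regions and
birth years. The registry data behind such surveys are access-protected, so
`mitocline` pairs every analysis stage with a synthetic-cohort generator that
reproduces the statistical structure the analysis assumes — regional clines,
immigration-driven temporal trends, array-intensity noise — making the whole
pipeline testable end to end without any protected data.

## Genotype calling from array intensities

Arrays report, per sample and locus, a normalized intensity `r` (Norm R) and
an allele angle `theta` (Norm Theta) in [0, 1]. Haploid mtDNA should form two
clusters, near `theta = 0` (the A allele, treated as REF) and `theta = 1`
(the B allele, ALT). The caller applies three published thresholds:

* records with `r < 0.08` are unreliable and become MISSING;
* `theta <= theta_ref_max` is REF, `theta >= theta_alt_min` is ALT;
* the band in between is the heterozygous-looking AB cluster, which haploid
  mtDNA cannot legitimately occupy, so it is MISSING as well;
* samples with a call rate below 97% over the panel are removed entirely.

The original survey adjusted theta cluster boundaries manually per locus; a
fixed symmetric band is the reproducible surrogate. The defaults
`theta_ref_max = 0.25` and `theta_alt_min = 0.75` are our choice, not a
published fact, and are overridable in `caller_thresholds()`. Loci that end
up with no non-missing call are retained as uninformative columns so that
downstream matrix dimensions (notably for PCA) never shift silently.

## Hierarchical haplogroup classification

A `haplo_tree` is a rooted hierarchy of haplogroup nodes, each carrying
defining variants (rCRS position, derived allele) and a level tag
(macro / hg / sub-hg). Classification is a greedy root-to-leaf descent:
at each step every callable child is scored over its panel-covered defining
variants — `observed` non-missing calls, `matched` calls equal to the derived
allele — and the child maximizing `matched/observed` is accepted if
`observed >= 1` and the fraction reaches the level threshold. Ties break on
the higher matched count, then the lexicographically smaller name, so output
is deterministic.

The acceptance thresholds default to 1.0 at macro level and 0.5 below. The
rationale: a wrong macro assignment is unrecoverable (all deeper candidates
are in the wrong subtree), so the first split must be conflict-free, whereas
deeper nodes tolerate a minority of mismatches from genotyping error. These
defaults are a surrogate for the manual "unequivocal" matching of published
surveys, which is not algorithmically specified anywhere; they reproduce the
few-percent unassigned rates such surveys report, qualitatively not exactly.

Nodes whose defining variants are all off-panel are flagged *uncallable* and
made transparent: their callable children become candidates of the
grandparent. This mirrors how array surveys fold haplogroups they cannot
resolve (e.g. HV with no diagnostic SNPs on the array) into the parent
clade — samples route past the invisible node rather than stopping at it.

One property worth stating precisely: masking calls to MISSING can only
*remove* evidence at every node (`score_node` is monotone), and for
conflict-free genotypes masking can never create a new assignment. With
conflicting calls, however, masking the conflicting call legitimately raises
the match fraction and can rescue a previously rejected child — an inherent
feature of any fraction-based acceptance rule, not a defect. The test suite
asserts the monotone forms that actually hold.

## The synthetic cohort generator

`frequency_model()` fixes the study conditions: haplogroup proportions per
region at the first birth year, additive per-year trends, regional sampling
weights, and metropolitan fractions. Realized proportions for a year are
`base + trend * (year - first_year)`, floored at zero and renormalized; the
renormalization means realized trajectories sit slightly below the nominal
additive line once several haplogroups rise together (about 4% relative at
the final year under the defaults), which the tests account for by checking
against the realized — not nominal — proportions.

`default_frequency_model()` emulates a 1981–2005 Danish birth cohort: five
regions with sampling weights proportional to published regional sample
counts (6,818 / 3,550 / 5,660 / 4,957 / 2,632), hg-level base frequencies
from the published regional distribution, and trends
L +0.04, M +0.06, U +0.07 percentage points per year so the end-points match
the published rises (L 0.2% → ~1.2%, M 1.0% → ~2.4%, U 12.7% → ~14.3% between
the 1981–1986 and 2000–2005 period means). Trending haplogroups start at
their 1981 national level scaled by each region's relative level. The
metropolitan fractions per region are not derivable from published summary
tables; the defaults (0.75 Capital down to 0.15 Zealand) are plausible
census-shaped values and are a free configuration parameter.

Genotypes are tree-path constructs, not sequence evolution: each sample
carries the derived allele at every defining variant on its root-to-truth
path and the ancestral allele elsewhere, then independent private flips at a
per-locus rate (never at the sample's own path-defining positions, keeping
classification identifiable), then independent masking to MISSING. Intensity
simulation inverts the caller: REF draws theta from a clipped Gaussian
around 0.05, ALT around 0.95, with configurable fractions of AB-band and
low-intensity records. With zero noise the caller round-trips the generating
matrix exactly, which is the anchor for the end-to-end recovery tests.

What the generator deliberately does not emulate: recurrent mutation
(homoplasy), heteroplasmy, per-locus cluster geometry, linkage between
private variants, or coalescent genealogy within a haplogroup. Passing tests
therefore demonstrate the correctness of the pipeline's logic under the
stated noise model, not calling performance on real array data.

The bundled tree (`example_haplo_tree()`, shipped as
`extdata/haplotree_synthetic.tsv`) is a synthetic stand-in with the macro /
hg / sub-hg label set of published Danish tables and three invented defining
positions per node. Real PhyloTree branches vary widely in length; users with
a real defining-SNP table can load it with `load_tree()` unchanged.

## Median-joining networks

`build_mj()` implements median joining over binary haplotypes with unit site
weights, so the relaxation parameter epsilon is in mutation-count units and
the published "Epsilon 10" maps directly. Each iteration computes the
epsilon-relaxed minimum spanning network — all pairs whose Hamming distance
is within epsilon of the distance at which their components first connect
(computed as the bottleneck edge on a deterministic Kruskal MST; ties break
on sorted node labels) — then adds the quasi-median (majority state per
position) of every connected triplet as an inferred node when new, until
closure. Median vectors of degree ≤ 2 are then deleted iteratively: by the
triangle inequality a direct link between their neighbours never costs more,
so only degree-≥3 Steiner nodes are genuine. Preprocessing follows the
published pipeline: `frequency_filter()` (the "Frequency > 1" setting,
interpreted as dropping singleton haplotypes — the network software manual
does not define it beyond the parameter string) and `star_contraction()`,
which iteratively merges satellites within a Hamming radius onto their
unique nearest neighbour, summing multiplicities and logging every merge.

`mp_postprocess()` is the maximum-parsimony cleaning step: it deletes every
median node and edge that participates in no minimum-total-length spanning
subgraph connecting the observed haplotypes. Up to 12 network nodes the
search over median subsets is exhaustive and edge eligibility uses the
standard some-MST criterion (an edge is in some MST iff its endpoints are
disconnected under strictly lighter edges); above 12 nodes a greedy
remove-if-no-cost pruning runs instead and the output records
`mp_mode = "heuristic"`.

A caution from the analysis scripts: with the shallow synthetic tree (3
variants per branch) the radius-5 star contraction used for deep real clades
collapses the entire R clade onto its backbone. That is correct algorithm
behaviour, and the reason the network driver uses radius 1 on synthetic data.

## PCA structure summaries

`encode_binary()` maps REF/ALT to 0/1 and imputes missing calls to the locus
mean (an all-missing locus gets 0). `run_pca()` is a column-centered
decomposition without variance scaling — for binary loci, unit-variance
scaling would inflate rare variants; a `scale.` flag exists for users who
want it. Signs are fixed by making each component's largest-magnitude
loading positive, so output is bit-reproducible on fixed input and invariant
to sample order up to row permutation. Components requested beyond the
matrix rank are returned with zero variance and flagged. The quantitative
counterpart of "the macro-haplogroups separate on PC1/PC2" is
`cluster_separation_report()`: per-label centroids, RMS dispersions, and
pairwise centroid distances on PC1/PC2 and PC1/PC3. No formal
new-cluster test is defined for period comparisons because the source
analyses make that claim visually; we compute the same projections and leave
inference to the frequency tests.

## Frequency statistics

`crosstab()` counts samples per group (region, period, area, calendar year)
and haplogroup at a reporting level, with unassigned samples in a trailing
`"NA"` column and row percentages that sum to 100 — the layout of published
tables, including their convention of reporting each sample at the deepest
resolved level (a sample resolved only to macro R appears in the "R" row of
an hg-level table; `label_at_level()` implements the fallback).

`fisher_exact_2x2()` computes the two-sided exact p-value under the
point-probability convention: all hypergeometric tables no more probable
than the observed one are summed, with the same relative tolerance
(`1e-7`) standard implementations use. This convention reproduces the
published period-comparison p-values at printed precision (L: 1.14E-10,
M: 3.73E-08, H: 2.98E-03, J: 0.53), which is the package's evidence that it
matches the convention of the original analysis. For r×c tables,
`permutation_fisher()` uses the table point probability as statistic, draws
null tables with fixed margins via `stats::r2dtable()`, and reports the
add-one estimator `(1 + #{at most as probable}) / (n_perm + 1)` so p is
never zero; 2×2 input delegates to the exact routine. `bonferroni()`
defaults to m = 14 simultaneous comparisons (13 haplogroup rows plus the NA
row of the published tables).

`yearly_trend()` returns per-year proportions with Wilson 95% intervals
(the score interval, computed from its closed form), optionally with the
denominator restricted to one macro-haplogroup — the published U-within-R
analysis. `trend_slope()` fits ordinary least squares on the yearly series
for trend-recovery checks against the generator's configured slopes.

## Problem sizes and numerical choices

The bundled analyses and tests use cohorts of 2,000 (round-trip), 30,000
(full pipeline) and 50,000 (trend recovery) samples over the 418-locus
panel; these sizes give binomial standard errors small enough that 3-SE
recovery checks are meaningful for frequencies down to 0.2%. Statistical
recovery tests use 3-SE bands throughout; linear-algebra comparisons use
1e-8; exact-test comparisons use the printed precision of the reference
values. All randomness is seeded explicitly per operation; no global RNG
state is shared between stages.

## Known limitations

* The classifier's acceptance thresholds and the caller's theta band are
  reproducible surrogates for manual curation steps; unassigned rates match
  published ones qualitatively, not numerically.
* The generator's haplotypes are tree paths plus independent noise; any
  conclusion about homoplasy, heteroplasmy or real cluster geometry is out
  of reach of this test bed.
* The MP step is exact only up to 12 network nodes; beyond that the greedy
  mode may retain medians an exhaustive search would delete.
* Genomic (autosomal) ancestry estimation is out of scope entirely; mtDNA
  frequencies alone cannot separate immigration from drift, and the package
  makes no such claim.
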