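---
title: "Sex-specific linkage maps and recombination landscapes from full-sib coral crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific linkage maps and recombination landscapes from full-sib coral crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acromap)
```

## The problem

Reef-building corals such as the Atlantic acroporids are simultaneous
hermaphrodites: every colony produces both eggs and sperm. A controlled cross
between two colonies therefore yields a full-sib family in which one parent
acted as the egg donor (the *dam*, whose meioses define the "female" map) and
the other as the sperm donor (the *sire*, the "male" map). Genotyping the
parents and a set of offspring on a biallelic SNP array exposes the gametes
each parent transmitted, and from the co-segregation of marker pairs one can
build genetic linkage maps — separately per parental role. Corals show strong
*heterochiasmy*: female map lengths run 2–2.5 times the male lengths, a
pattern `acromap` is designed to estimate and to validate end to end on
simulated crosses with known truth.

The package covers the full workflow:

1. **Simulation** (`simulate_parents()`, `simulate_meiosis()`,
   `simulate_family()`, `simulate_cross()`) — crosses with known sex-specific
   recombination landscapes.
2. **Marker QC** (`qc_markers()` and friends) — informativeness
   classification, Mendelian-error masking, segregation-distortion and
   missingness filters, informativeness masks.
3. **Linkage analysis** (`pairwise_rf_lod()`, `pairwise_lod_matrix()`,
   `group_markers()`, `rescue_unassigned()`, `order_markers()`,
   `estimate_map_positions()`) — two-point recombination fractions and LOD
   scores, linkage-group formation, marker ordering under the Kosambi map
   function, and per-sex map positions.
4. **Refinement** (`trim_edges()`, `orient_map()`, `clean_marey()`,
   `loess_recomb()`) — edge cleaning, orientation, Marey-map outlier removal
   and local recombination rates in cM/Mb.
5. **Summaries** (`chromosome_summary()`, `genome_summary()`,
   `recovery_report()`) — per-chromosome and genome-wide rates,
   heterochiasmy ratios, marker spacing, and truth-recovery metrics.
6. **Divergence sidecar** (`split_alignments_at_genes()`, `iqr_outliers()`,
   `kimura_to_jc()`, `landscape_histogram()`,
   `windowed_repeat_content()`) — gene-level alignment identity with
   quartile-based outlier calling, and repeat-divergence landscapes.

`linkage_pipeline()` chains steps 2–5; `simulate_and_map()` wraps a complete
simulation-plus-recovery experiment.

## The genetic model

**Transmissions.** Offspring genotypes are biallelic dosages (0/1/2 of the B
allele). A marker reveals a parent's meiosis only where that parent is
heterozygous; `classify_informativeness()` encodes the standard codes
(1 = sire-only, 2 = dam-only, 3 = both, 0 = neither). For a heterozygous
parent, the transmitted allele follows from the offspring dosage and the
other parent's genotype — except at AB×AB markers, where a heterozygous
offspring is ambiguous (either parent could have contributed either allele).

**Two-point estimation.** For a marker pair, the recombination fraction *r*
per parent is estimated from the mismatch count among that parent's decodable
gametes, with the parental phase resolved to the likelihood-maximizing
assignment (recombinants = min(mismatches, matches)); a physical parent has a
single phase, so mismatch counts are pooled across families sharing that
parent before phase resolution. The LOD score is the base-10 log likelihood
ratio of linkage at the MLE against independence (*r* = 0.5). For pairs where
both markers are AB×AB in the same family, `pairwise_rf_lod()` uses the full
3×3 offspring-class likelihood, maximizing over the four parental phase
configurations and running EM over the ambiguous double heterozygotes
(start *r* = 0.25, stop when the log-likelihood changes by less than 1e-8 or
after 200 iterations).

**A conditioning subtlety.** For an AB×AB / AB×AB pair, a parent's gametes
are only directly observable in offspring homozygous at *both* markers.
That double conditioning is recombination-dependent: with coupling phases in
both parents it depletes recombinants (the observable subset is enriched for
double-non-recombinants), and with mixed phases it retains almost only
recombinants. Naively chaining such pairs produced map intervals of hundreds
of cM from three observable gametes. The package therefore excludes these
per-family contributions from all recombination-fraction estimates
(`pairwise_lod_matrix()` keeps them in the LOD matrix, where linked pairs
still yield valid positive evidence and unlinked pairs stay near zero) and
recovers the information exactly, where it matters per pair, through the EM
likelihood in `pairwise_rf_lod()`. Conditioning at a *single* marker of a
pair is harmless: the other parent's transmitted allele is an independent
fair coin, so the retained subset is unbiased.

**Mapping function.** Distances are Kosambi throughout,
d(cM) = 25·ln((1+2r)/(1−2r)), inverse r = tanh(d/50)/2; the two are mutually
inverse to 1e-10 across the domain.

## Grouping, ordering, and map distances

**Grouping** is single-linkage transitive closure over pairs with LOD at or
above the threshold; groups smaller than `min_size` (default 5) dissolve into
an unassigned pool, from which markers re-join iteratively when their best
group LOD reaches `rescue_lod` (2) and beats the runner-up group by
`rescue_diff` (2). Thresholds are data-dependent: 11 suits one ~100-offspring
family, while multi-family designs need either the denser marker sets of real
arrays or a slightly higher threshold than the nominal 5, because the null
distribution of a two-point LOD summed over many small phase-maximized
parent streams has a heavier tail than in a single large family.

**Ordering** (`order_markers()`) first collapses markers into bins by walking
the physical order and extending a bin while the candidate's recombination
fraction with *every* bin member stays below `identical_limit` (0.005).
Complete linkage over contiguous runs matters: single-linkage percolates
through sampling zeros (at 105 offspring roughly 40% of adjacent pairs show
zero recombinants) and produces huge, physically interleaved bins whose
expansion scrambles the map. Bin order is seeded from physical positions and
refined by permutation search — exhaustive for up to six bins, otherwise a
sliding window of four — minimizing the total Kosambi length over adjacent
bins *plus a physical-order prior* of `phys_penalty_cm` (default 5 cM) per
adjacent bin pair placed against the assembly orientation. The prior plays
the role of the small physical-anchoring weight used by array mapping
pipelines: at array densities the two-point distance noise between neighbors
exceeds their true separation, and an unpenalized minimum-length search
overfits that noise and degrades a correct physical seed. Distances missing
from the objective (pairs with no shared informative meioses, e.g. a
sire-only next to a dam-only marker) are filled by shortest paths through
markers linked to both; measured distances are never shortened.

**Map distances** (`estimate_map_positions()`) are chained per parental role
over markers informative for that role, linking each marker to the previous
*anchor* whenever the link rests on at least `min_meioses` (10) valid gametes
(validity excludes the double-conditioned AB×AB/AB×AB family contributions).
Markers that cannot be anchored are interpolated between anchored neighbors;
an interval with no information anywhere contributes 0 cM with a warning.
The sex-averaged map pools recombinant counts across both roles per adjacent
interval and falls back, where no role has valid shared meioses, to the mean
of the two sex-specific interval spans — a deliberate convention, since the
published consensus ("sex-averaged") lengths are close to, but not exactly,
the midpoint of the sex maps and their precise definition is not derivable
from the pipeline descriptions the field publishes.

## Refinement and rates

`trim_edges()` removes markers distal to any consecutive-marker gap strictly
exceeding 5% of the map span inside each terminal window of 10% of markers
(both ends by default; the rule is idempotent on its own output). The
pipeline re-orders and re-estimates after trimming. `orient_map()` flips a
group whose genetic map runs against the physical coordinates.
`clean_marey()` iteratively removes markers whose *leave-one-out* local-fit
residual exceeds 3 robust SDs (MAD); leave-one-out is essential because a
gross outlier otherwise anchors its own local fit and hides behind it, and an
absolute floor of 1e-8 of the track scale keeps floating-point noise on
numerically clean tracks from registering as aberrance. `loess_recomb()`
implements the smoothing directly as local weighted quadratic regression
(tricube weights over the `span` = 0.25 fraction of nearest markers,
evaluated on a 100-point grid plus the marker positions) because the local
recombination rate is taken as the *analytic first derivative* of each local
fit, scaled to cM/Mb and clamped at zero; the implementation reproduces any
global polynomial of degree ≤ 2 exactly.

## The simulator and what it does (not) emulate

`simulate_parents()` places markers uniformly at random along each
chromosome and assigns segregation configurations in fixed proportions
(default: equal thirds of sire-only, dam-only, and both-informative markers,
so that both parental meioses and both informativeness-mask conventions are
exercised). `simulate_meiosis()` draws crossover counts as Poisson with mean
map-length/100 — the Morgan definition, with no crossover interference (an
obligate-chiasma flag exists, off by default) — places them uniformly on the
genetic map, and converts to physical coordinates through the inverse Marey
profile. The default profile is a piecewise-linear sigmoid with the central
20% of the chromosome carrying half the average recombination density,
mimicking the metacentric centromeres both species' Marey maps display.
Noise is symmetric call swapping plus uniform missingness, applied after the
truth is recorded. All randomness flows from one seed; families receive
deterministic sub-seeds, and parents shared between families share
haplotypes, supporting half-sib designs.

The simulator does **not** emulate: array hybridization intensities or
cluster-QC artifacts (errors are exchangeable call swaps, not cluster-shaped
failures), segregating structural variation, genotyping batch effects,
crossover interference, or symbiont contamination. Passing recovery tests on
these simulations therefore demonstrates the correctness of the estimators
under the stated genetic model, not robustness to every artifact of real
array data.

**Study-scale validation.** The acceptance script
(`scripts/acceptance.R`) simulates one 105-offspring family across the 14
published *A. palmata* chromosomes (physical lengths and per-sex map lengths
taken from the published per-chromosome table shipped in `extdata`), 200
markers per chromosome and zero noise, runs the full pipeline at LOD 11, and
reports the genome-wide female:male rate-ratio averaged over five seeds. The
true ratio implied by the published table is 1460.68/583.19 ≈ 2.50. The
published tables themselves are also re-summarized directly
(`summarize_map_table()`), which reproduces every printed rate: genome-wide
female/male 5.49/2.19 cM/Mb (*A. palmata*) and 4.41/2.12 cM/Mb
(*A. cervicornis*), the per-chromosome extremes (7.00, 7.04, 1.55,
1.10 cM/Mb), and the marker spacings 0.48 and 0.19 cM. One bookkeeping note:
the published *A. cervicornis* consensus length (927.36 cM) exceeds the sum
of its own per-chromosome rows by exactly 1 cM; the package works from the
rows, so its assembly-denominator sex-averaged rate evaluates to 3.03 cM/Mb
against the published 3.04.

## Divergence sidecar

Gene-level identity uses pairwise whole-genome alignments in PAF: each
block's CIGAR is walked over target coordinates and `=`/`X` bases accrue to
every overlapping gene (0-based half-open intervals; gaps are excluded from
the identity denominator; plain-`M` CIGARs fall back to distributing the
`NM` substitution count proportionally, exact when a gene covers the whole
block). Outliers are genes strictly below Q1 − 3·IQR with type-7
(linear-interpolation) quartiles. Repeat divergence converts the
CpG-corrected Kimura substitution level to a Jukes–Cantor distance,
JC = −(3/4)·ln(1 − 4d/3) (natural log; saturating at d = 0.75), bins each
element's span into 0.01-wide divergence bins as percent of genome (with a
≤ 0.05 recent-insertion subset), and computes per-class repeat content in
500 kb / 5 kb sliding windows with same-class overlaps merged and the
trailing truncated window normalized by its actual width.

## Parameter reference

| Parameter | Default | Where | Why |
|---|---|---|---|
| segregation-type fractions | 1/3, 1/3, 1/3 | `simulate_parents()` | exercises both parents' meioses and both mask conventions |
| distortion p-value floor `alpha` | 1e-4 | `qc_markers()` | array-QC data tolerance convention |
| max missing per marker | 0.25 | `qc_markers()` | permissive; arrays drop most failures upstream |
| per-family Mendelian violation cap | 0.05 | `qc_markers()` | isolated miscalls are masked, systematic failure drops the marker |
| grouping LOD | 11 (single family) | `linkage_pipeline()` | clears the phase-maximized null by a wide margin at n≈105 |
| minimal group size | 5 markers | `group_markers()` | sub-threshold fragments carry no usable order |
| rescue LOD / difference | 2 / 2 | `rescue_unassigned()` | weak-but-unambiguous assignment |
| identical limit | 0.005 | `order_markers()` | collapses statistically indistinguishable neighbors |
| physical prior | 5 cM / discordant pair | `order_markers()` | two-point noise cannot resolve local order unaided |
| chain minimum meioses | 10 | `estimate_map_positions()` | keeps kosambi(k/n) off tiny denominators |
| edge window / gap | 10% / 5% of span | `trim_edges()` | published edge-cleaning rule |
| LOESS span / degree | 0.25 / 2 | `loess_recomb()` | published smoothing setting |
| Marey residual threshold | 3 robust SD, ≤ 10 iterations | `clean_marey()` | conventional outlier screen; criterion unpublished, configurable |

## Known limitations

- Two-point distances only: no multipoint HMM likelihood across whole
  chromosomes, and no genotype-likelihood (posterior) input mode. Local
  order inside bins is taken from the physical assembly.
- Per-sex lengths for regions covered *only* by AB×AB markers in a single
  family rest on interpolation between anchored markers; designs should
  include single-parent-informative markers throughout (arrays do).
- The sex-averaged map is a defined convention (pooled adjacent counts with
  midpoint fallback), not a likelihood-based consensus.
- Grouping LOD thresholds must account for the number of independent parent
  streams; the defaults are calibrated for the single-large-family design.
- The divergence sidecar consumes existing alignments and repeat calls; it
  performs no alignment or repeat discovery itself.
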