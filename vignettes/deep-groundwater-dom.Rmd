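---
title: "Methods: DOM molecular characterization and microbe-molecule networks"
author: "deepDOM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DOM molecular characterization and microbe-molecule networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepDOM)
```

# Scope

deepDOM implements the computational chain used to characterize dissolved
organic matter (DOM) in deep groundwater from ultrahigh-resolution mass
spectrometry (FT-ICR-MS), to relate it to hydrochemistry, and to associate
individual molecular formulas (MFs) with microbial amplicon sequence
variants (ASVs):

1. per-sample peak lists are aligned across samples at a fixed ppm
   tolerance;
2. aligned neutral masses receive CHNOSP molecular formulas under element
   bounds, isotopologue verification and contaminant removal;
3. intensities are normalized, detection limits harmonized, rare features
   removed, replicates averaged;
4. per-formula and per-sample molecular descriptors are computed (AI_mod,
   van Krevelen compound classes, MLB_w, intensity-weighted elemental
   ratios);
5. Bray-Curtis dissimilarity, NMDS, distance-based redundancy analysis
   (db-RDA) against hydrochemistry, and Procrustes congruence connect DOM,
   chemistry and community structure;
6. a compositional proportionality network links MFs to ASVs, with a
   permutation-FDR edge cutoff, fast-greedy modularity and z/P node roles;
7. radiocarbon and stable-isotope arithmetic convert bulk measurements into
   residence times and offsets.

Because the raw spectra and sequencing data behind such studies are large
external deposits, the package ships a synthetic-data generator with known
ground truth; every stage is validated against either closed forms,
exhaustive oracles, or planted structure.

# Formula assignment

## Masses and validity

Monoisotopic masses use C = 12 exactly, H = 1.00782503207, N = 14.0030740048,
O = 15.9949146196, S = 31.97207100, P = 30.97376163 Da. A candidate formula
is valid when element counts lie within C1-100, H1-100, O0-70, N0-4, S0-2,
P0-1, the double-bond equivalent DBE = 1 + C - H/2 + (N + P)/2 is a
non-negative integer, and (by default) O <= C + 2. The oxygen cap is not
part of the element bounds proper but excludes chemically implausible
oxygen-saturated candidates; it is standard practice in DOM assignment and
can be disabled (`assignmentParams(oxygenCap = FALSE)`).

## Ion convention

Negative-mode electrospray spectra of DOM are dominated by [M-H]⁻ ions, so
measured m/z are converted to neutral masses by adding a proton mass
(1.00727646 Da) before candidate search (`ionMode = "neg"`, the default).
Pre-neutralized input is accepted with `ionMode = "neutral"`. Assignment is
restricted to masses up to 1000 Da; heavier features are retained
unannotated.

## Search, filtering and tie-breaks

`enumerateCandidates()` solves for the hydrogen count per feasible
(C, N, O, S, P) combination, visiting only candidates that can match the
measured mass within the tolerance (default 0.5 ppm).
`bruteForceCandidates()` enumerates the full element grid instead; the two
must agree exactly, which the test suite asserts on a hundred synthetic
masses. The filtering chain then applies, in order: the heteroelement rule
(drop N+S+P > 3 unless the heteroatoms are nitrogen only, up to N4),
isotopologue verification, and selection of the surviving candidate with
the smallest |mass error|; remaining ties resolve to fewer heteroatoms,
then fewer total atoms (parsimony — the convention is ours, as no single
standard exists). Features whose assigned formula matches the four-entry
contaminant list (C16H32O2, C12H26O4S, C17H28O3S, C10H15NO2S, typical
tubing-derived surfactants) are removed as features, not merely
re-assigned.

## Isotopologue evidence

For each heavy isotope whose light element the candidate contains (13C
always; 15N and 34S when present), a companion feature is sought at the
parent mass plus 1.0033548, 0.9970349 or 1.9957959 Da respectively, within
the same ppm tolerance. The expected intensity ratio is linear in the atom
count (0.0107 per C, 0.00364 per N, 0.0442 per S — the one-heavy-atom
binomial term). A companion whose observed ratio deviates from expectation
by more than `isotopeIntensityTol` (default 0.5, i.e. 500 per mil) fails
the candidate; an absent companion only fails it when the expected
companion intensity exceeds the detection floor times the method detection
limit, so weak parents are never penalized for unobservable evidence.
A failing candidate is demoted (kept but flagged unverified) rather than
removed, because co-isolated features can corrupt ratio estimates;
`isotopeFailAction = "remove"` switches to strict removal. Features that
are themselves 13C companions of an assigned parent are flagged and
excluded from formula-level analyses, keeping the annotated set
monoisotopic.

# Peak alignment

Aligning sorted masses at a relative tolerance is single-linkage clustering
in one dimension, so the fast join sorts the pooled peaks and splits at
gaps above `tolPpm` (ppm computed against the smaller mass, which keeps the
relation symmetric in its tolerance regime and is documented for
reproducibility). Two safeguards shape the final features:

* **span cap.** Chained clusters can drift: peaks 0.4 ppm apart pairwise
  can span several ppm overall. Clusters whose total span exceeds
  2 x `tolPpm` are subdivided greedily from the left, bounding worst-case
  within-feature spread.
* **conflict rule.** When one sample contributes two peaks to a cluster,
  the more intense peak stays and the other is demoted to its own feature,
  preserving the one-peak-per-sample-per-feature property downstream
  statistics rely on.

Consensus masses are intensity-weighted means. `bruteForceJoin()` clusters
the complete pairwise ppm graph instead of the sorted gaps and must agree
exactly with the fast join; the suite checks this on ~500 peaks across 10
samples. Features detected only once in the whole dataset are removed
before assignment.

# Preprocessing

The canonical order is normalize, then harmonize detection limits, then
the occurrence filter — the steps do not commute and the order is part of
the contract (regression-tested):

* `normalizeToSum()` scales each sample to unit total intensity;
* `harmonizeDetectionLimit()` takes the *largest* per-sample minimum
  non-zero relative intensity as the common detection limit and zeroes
  entries strictly below it (entries exactly at the limit survive);
* `occurrenceFilter()` keeps features present in at least 3 samples;
* `averageReplicates()` averages columns per group (e.g. borehole) and
  renormalizes.

After zeroing and filtering the matrix is *not* renormalized: retained
relative intensities keep their original scale so samples remain
comparable; renormalization is available as an explicit extra
`normalizeToSum()` call. The harmonized detection limit is computed after
singleton removal (the matrix the caller passes is already singlet-free in
the standard pipeline); computing it before would only lower the threshold.

# Molecular descriptors

The modified aromaticity index is

$$AI_{mod} = \frac{1 + C - 0.5\,O - S - 0.5\,(H + N + P)}
                  {C - 0.5\,O - N - S - P},$$

with values clamped to 0 when the numerator is negative or the denominator
non-positive (the index is undefined there and the conventional reading is
"not aromatic"). Compound classes partition the van Krevelen plane into
seven regions (unsaturated oxygen-poor, unsaturated, amino sugar- and
carbohydrate-like, unsaturated hydrocarbon-like, condensed aromatics,
lignin-like, tannin-like) whose open/closed boundaries are encoded exactly
as published; points matching zero regions or more than one (the regions
overlap on some edges) are "unclassified".

Per-sample summaries weight formula-level quantities by relative
intensities renormalized over annotated, non-isotopologue features —
unassigned features carry no elemental information and would silently bias
the ratios if left in the denominator; a lab that prefers weights over all
features can renormalize externally. MLB_w sums the weights of formulas
with H/C strictly above 1.5 ("above the boundary" read as strict; the
boundary value itself is not labile). The AbioS contribution requires a
user-supplied list of sulfur-bearing reference formulas; the package ships
none because the reference list lives in external literature, and an empty
list yields 0%.

# Multivariate analysis

These are standard community-ecology computations and are delegated to
vegan behind the package's interface: Bray-Curtis via `vegdist`, NMDS via
`metaMDS` (k = 2, 20 random starts, convergence per monotone-regression
stress; seeded for reproducibility), db-RDA via `dbrda` with standardized
predictors, and Procrustes via `protest`. Package-level conventions:

* db-RDA explained variation is constrained inertia over the total of the
  *positive* eigenvalues; negative eigenvalues of the Bray-Curtis geometry
  are dropped (no correction), matching common practice. A Lingoes-style
  correction was considered and rejected as it changes the explained-
  variation scale; users needing it can pass a corrected distance matrix.
* Significance comes from free row permutation (`anova.cca`); the test
  suite verifies p-value uniformity under null predictors across 200
  replicate datasets (Kolmogorov-Smirnov).
* Procrustes uses symmetric scaling so m² is comparable regardless of
  which configuration is the target, and the permutation p-value is the
  PROTEST tail probability.

# The interdomain network

Both blocks are compositional (relative intensities, relative abundances),
so association is measured on the clr scale with the proportionality
coefficient
$$\rho(i,j) = 1 - \frac{\mathrm{var}(g_i - g_j)}
                        {\mathrm{var}(g_i) + \mathrm{var}(g_j)},$$
computed after: prevalence filtering (features in >= 5 samples; ASVs
additionally need a peak relative abundance >= 0.1%), per-feature zero
replacement by minimum/10 (zeros here are rounding artifacts, not
structural absences, and the replacement must not dominate the log-scale
spread), and clr transformation of each block *separately* before
stacking — transforming jointly would let the much larger MF block set the
geometric mean for the ASVs; the two choices demonstrably change rho and
the separate transform is regression-tested as the implemented one.

The |rho| edge cutoff is selected by permutation: sample labels of the ASV
block are shuffled (the MF block stays fixed, preserving within-block
covariance), between-block exceedance counts are compared with the
observed counts over a cutoff grid, and the smallest cutoff with estimated
FDR below the 5% target is chosen. Only between-block pairs enter the FDR
estimate because the permutation destroys exactly the between-block
dependence. Edges keep the sign of rho as an attribute; modularity runs on
the unweighted edge set (the cited fast-greedy agglomeration operates on
topology), with the merge tree cut at the community count maximizing Q and
ties resolved toward the coarsest partition, which makes results
deterministic. An Rcpp exhaustive-search oracle (restricted growth string
enumeration, feasible to ~13 nodes) validates the greedy optimum on
structured toy graphs.

Node roles use the canonical z/P scheme: within-module degree z-score
(z = 0 in modules with zero degree spread, including singletons) and
participation coefficient P = 1 - sum over modules of squared degree
fractions. Thresholds: peripheral (z <= 2.5, P <= 0.62), connector
(z <= 2.5, P > 0.62), module hub (z > 2.5, P <= 0.62), network hub
(z > 2.5, P > 0.62). A published variant that states module hubs as
P >= 0.62 overlaps the network-hub region and leaves low-P hubs unnamed;
it is available behind `nodeRoles(net, printedVariant = TRUE)`, with the
canonical scheme as the default.

# Isotope arithmetic

Radiocarbon residence time is age = tau ln(100 / pMC) with
tau = 5730 / ln 2 ~ 8266.6 yr. The 5730-year half-life is the default
because it reproduces reported groundwater residence times (pMC 60 ->
~4220 yr); the Libby 5568-year convention is available via
`convention = "libby"`. No calibration-curve correction is applied —
the quantities are uncalibrated mean residence times. pMC above 100
denotes modern (bomb-influenced) carbon and maps to age 0 with a flag
rather than a negative age. DON = TDN - (nitrate + nitrite + ammonium),
clamped at zero with a warning since measurement error can push the
difference slightly negative. Extraction efficiency is
100 x extracted DOC / DOC. Molar C/N uses DON when inorganic nitrogen is
supplied and TDN otherwise, with the denominator recorded per value, since
bulk surveys rarely tabulate DON completely.

The bundled `water_chemistry.csv` transcribes the published borehole
survey (2 Baltic Sea reference samples, 18 groundwater sampling
occasions) and backs the bulk-summary checks.

# The synthetic generator

`generateSamplePeakLists()` emulates the study design downstream
statistics assume: two endmembers — a lignin-dominated, fresher
surface-water pool and an aliphatic, saline deep pool — mixed along a
per-sample fraction; every formula present in both endmembers therefore
forms a shared core present in all samples. Observed intensities carry
multiplicative lognormal noise (relative spectra are positive and
heteroscedastic; the lognormal keeps the mean unbiased via a -sigma²/2
offset). Mass errors are Gaussian in ppm, truncated at three spreads
(default spread 0.25 ppm, within the 0.5 ppm instrument regime).
Hydrochemistry (Na, K, Ca, Mg, delta-18O, delta-2H, SO4, Cl) is affine in
the mixing fraction plus noise, with endmember values chosen at realistic
brackish-versus-brine magnitudes. Optional contaminant peaks appear in
every sample and 13C isotopologues accompany peaks at 0.0107 x C.

`generateAsvTable()` plants MF-ASV association modules: members of a
module share a standard-normal latent factor per sample, scaled by
`latentStrength`, on the log scale; at zero noise, member clr profiles
differ by constants and their rho is exactly 1, while non-members are
independent given closure. Module membership, link truth and latent
factors are returned for recovery scoring.

What the generator does **not** emulate: chromatographic or ionization
matrix effects, isotopic fine structure, multiply charged species,
sequencing error or compositional count noise in the ASV table, batch
effects, and more than two source waters. Passing tests on synthetic data
therefore demonstrate correctness of the computations under the stated
generative assumptions, not instrument-level fidelity.

# Problem sizes and numerical choices

Validation problem sizes were chosen so the whole suite runs comfortably
on a laptop: alignment oracle at ~500 peaks / 10 samples; assignment
oracle at 100 masses below 600 Da (the exhaustive grid grows roughly
cubically with mass); network recovery at 40 MFs, 20 ASVs, 10 planted
modules; FDR calibration over 100 replicate datasets at 10 samples (the
joint MF/ASV sample count a study of this design typically has); db-RDA
calibration over 200 null replicates of 15 samples with 199 permutations.
The zero-noise module-recovery check uses 20 samples: with only 10, two of
the ten random latent factors can be nearly collinear by chance, merging
planted modules for reasons unrelated to the method under test.

Other numerical conventions: candidate masses are compared at
tolerance + 1e-12 to absorb floating-point representation of exact hits;
consensus-mass ties created by conflict demotion are separated by a
1e-12 relative nudge so feature masses stay strictly increasing;
zero-variance clr features make rho undefined and are reported as 0 with a
flag; the FDR at cutoffs with zero observed exceedances is 0 when the
permuted count is also 0 and 1 otherwise; and all randomness flows through
explicit integer seeds with no hidden global state.

# Known limitations

* Formula assignment considers singly charged [M-H]⁻ ions only; adducts
  and multiply charged species are out of scope.
* Internal spectral recalibration is assumed done upstream; the package
  consumes calibrated peak lists.
* The isotopologue verification replaces quantile-based per-mass ratio
  tolerances used by some instrument pipelines with a single relative
  tolerance (default 500 per mil).
* The AbioS reference list must be supplied by the user.
* Fast-greedy modularity is a heuristic; the exhaustive oracle bounds its
  optimality gap only on small graphs.
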