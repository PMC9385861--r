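# deepDOM

Molecular characterization of dissolved organic matter (DOM) in deep
groundwater, and association networks between DOM molecules and microbial
communities.

Deep bedrock fracture waters carry a dilute, old DOM pool that feeds an
energy-limited microbial biosphere. Ultrahigh-resolution mass spectrometry
(FT-ICR-MS) resolves thousands of exact masses per water sample, each
assignable to a molecular formula (MF); 16S rRNA amplicon sequence
variants (ASVs) describe the resident microbes; hydrochemistry and carbon
isotopes constrain water origin and carbon age. deepDOM implements the
full computational chain connecting these data for geochemists and
microbial ecologists working on groundwater, porewater or other
low-energy aquatic systems:

* **Peak alignment** — per-sample peak lists joined across samples at a
  fixed relative tolerance (default 0.5 ppm); in one dimension the "fast
  join" is exactly single-linkage clustering at the gap threshold, with a
  2x-tolerance span cap and a per-sample uniqueness rule.
* **Formula assignment** — CHNOSP candidates within C1–100 H1–100 O0–70
  N0–4 S0–2 P0–1, integer DBE ≥ 0, |Δm| ≤ 0.5 ppm, with [M−H]⁻ → neutral
  conversion, a >3-heteroelement rule (N4 exempt), 13C/15N/34S
  isotopologue verification, and removal of four standard contaminant
  formulas.
* **Preprocessing** — per-sample sum normalization, harmonized detection
  limit (highest per-sample minimum), occurrence filter (≥3 samples),
  replicate averaging.
* **Molecular descriptors** — modified aromaticity index
  AI_mod = (1 + C − 0.5O − S − 0.5(H+N+P)) / (C − 0.5O − N − S − P),
  van Krevelen compound classes, intensity-weighted elemental ratios
  (H/C_MF, O/C_MF, N/C_MF, S/C_MF, P/C_MF), weighted mean mass, the
  molecular lability fraction MLB_w (weight above H/C = 1.5), and the
  AbioS sulfurization contribution.
* **Multivariate statistics** — Bray–Curtis dissimilarity, NMDS,
  distance-based redundancy analysis (db-RDA) of DOM on hydrochemistry
  with permutation inference, Procrustes/PROTEST congruence (vegan-backed).
* **Interdomain network** — centered log-ratio transform per data block,
  proportionality ρ(i,j) = 1 − var(gᵢ−gⱼ)/(var gᵢ + var gⱼ),
  permutation-FDR selection of the |ρ| cutoff, fast-greedy modularity, and
  z/P node roles (peripheral / connector / module hub / network hub).
* **Isotope arithmetic** — radiocarbon age τ·ln(100/pMC) with
  τ = 5730/ln 2, Δ¹³C(DIC−DOC), DON = TDN − inorganic N, solid-phase
  extraction efficiency; a transcribed groundwater survey table is
  bundled.
* **Synthetic data** — a two-endmember mixing generator (peak lists,
  hydrochemistry, ASV tables with planted MF–ASV modules) with known
  ground truth, so the whole pipeline is testable without external
  downloads.

## Worked example

Simulate a twelve-sample mixing series between a lignin-dominated
surface-like endmember and an aliphatic saline endmember, align, assign,
preprocess, and relate DOM composition to hydrochemistry:

```r
library(deepDOM)

lib <- generateFormulaLibrary(8, seed = 42)          # 56 formulas, 7 classes
wA <- ifelse(lib$class == "lignin-like", 3, 1)       # surface endmember
wB <- ifelse(lib$class %in% c("unsaturated oxygen-poor",
                              "unsaturated hydrocarbon-like"), 3, 1)
emA <- endmemberSpec("Baltic-like", lib, wA / sum(wA),
                     c(na = 1500, k = 60, ca = 90, mg = 220, d18o = -6,
                       d2h = -55, so4 = 470, cl = 3400), docMgL = 5.4)
emB <- endmemberSpec("Saline-like", lib, wB / sum(wB),
                     c(na = 3000, k = 12, ca = 5200, mg = 31, d18o = -12,
                       d2h = -95, so4 = 600, cl = 14500), docMgL = 0.9)
sim <- generateSamplePeakLists(list(emA, emB), seq(0, 1, length.out = 12),
                               massErrorPpm = 0.2, noiseCv = 0.05, seed = 1)

aligned <- removeSingletons(joinMassLists(sim$peakLists, tolPpm = 0.5))
ann <- assignFormulas(aligned, assignmentParams())
ann <- occurrenceFilter(harmonizeDetectionLimit(normalizeToSum(ann)), 3)
ann <- addFormulaMetrics(ann)
ann
#> AnnotatedMatrix with 56 features x 12 samples
#>   m/z range: 143.14415 - 941.28382
#>   assigned formulas: 56

summ <- weightedSampleSummary(ann)
round(summ[c(1, 12), c("hc_mf", "oc_mf", "mz_mf", "ai_mod_w", "mlb_w")], 3)
#>    hc_mf oc_mf   mz_mf ai_mod_w mlb_w
#> 1  1.622 0.160 347.989    0.194 0.563
#> 12 1.252 0.461 470.776    0.304 0.337

d <- brayCurtis(ann)
db <- runDbRDA(d, sim$chemistry[, c("na", "k", "ca", "mg", "d18o", "d2h",
                                    "so4", "cl")], nPerm = 999, seed = 1)
sprintf("explained = %.1f%%, pseudo-F = %.2f, p = %.3f",
        100 * db$explainedFraction, db$pseudoF, db$pValue)
#> "explained = 97.4%, pseudo-F = 14.28, p = 0.005"
```

Sample 1 is the pure saline endmember: aliphatic (H/C_MF 1.62), oxygen-poor
(O/C_MF 0.16), low aromaticity, high nominal lability (MLB_w 0.56).
Sample 12 is the pure surface endmember: more aromatic (AI_mod_w 0.30),
oxygen-richer, lignin-led. The eight hydrochemistry variables, affine in
the mixing fraction, explain 97% of Bray–Curtis DOM variability — mixing
dominates, which is exactly what the db-RDA is designed to quantify.

Radiocarbon arithmetic works directly on percent modern carbon:

```r
pmcToAge(c(60, 69))
#> [1] 4222.8 3067.5        # years (5730-yr half-life)
```

The end-to-end orchestration (`runPipeline()` with a YAML/JSON config, or
`inst/scripts/dompipe.R` from a shell) writes every stage output plus a
JSON run report with feature counts at each filter step.

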