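---
title: "Methods: targeted amniotic-fluid lipidomics for FLM prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted amniotic-fluid lipidomics for FLM prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amniolipids)
```

# The problem and the model

Fetal lung maturity (FLM) is assessed from the surfactant lipids that the
developing lungs shed into the amniotic fluid. Lecithin — diacyl
phosphatidylcholine, the dominant surfactant lipid — is synthesized from
about week 28 of gestation and rises sharply around week 36, while
sphingomyelin remains roughly constant through late pregnancy. The
lecithin/sphingomyelin (L/S) ratio therefore increases with lung
maturation, and a fluid with a low ratio predicts respiratory distress in
the newborn. This package implements the ratio as a high-resolution
mass-spectrometry quantity:

$$\mathrm{L/S} = \frac{\sum_{j \in \text{lecithin}} I_j}{\sum_{j \in \text{SM}} I_j}$$

summed over the 64 lecithin and 23 sphingomyelin species of a targeted
151-lipid catalogue, with the decision rule *premature* if L/S < 10.0.
The lamellar body count (LBC), a hematology-analyzer surrogate for the
same biology, uses the rule *premature* if LBC < 50 × 10⁹/L. Because the
ratio is a quotient of sums from one sample it is invariant to the
sample's overall signal level, which is what makes it robust across
injections.

## Which PCs count as lecithin

Targeted PC panels mix diacyl, ether-linked (O-, P-) and lyso species,
but "lecithin" denotes diacyl phosphatidylcholine specifically. The
package therefore flags `is_lecithin = TRUE` exactly for diacyl PCs, and
the bundled synthetic catalogue is constructed with 64 diacyl PCs among
its 88 PCs (12 ether-O, 6 ether-P, 6 lyso make up the rest), alongside
27 PEs, 23 SMs and 13 Cers. Every SM belongs to the ratio denominator.
The species *identities* in the generated catalogue are synthetic — only
its class structure mirrors a real targeted panel — and it is labeled as
such wherever it appears.

# Targeted extraction

Each sample is a peak list (m/z, RT, intensity). A library species with
neutral mass $M$ and adduct [M+H]⁺ / [M−H]⁻ has ion target
$M \pm 1.007276466$ Da, and a peak matches if

* $|(\text{obs} - \text{ref})/\text{ref} \times 10^6| \le$ `ppm_tol`
  (default 5 ppm, **inclusive**, so a peak exactly at the tolerance
  matches — strict inequality at a float boundary is a portability trap),
* $|\mathrm{RT} - \mathrm{RT}_{\text{expected}}| \le$ `rt_window`
  (default ± 0.2 min, a typical UPLC peak width; instruments vary, so it
  is a parameter).

When several peaks match, the default takes the **maximum-intensity**
candidate (robust to noise shoulders and deterministic for testing); a
`sum` option totals them instead. A species with no matching peak gets
intensity 0 — absence is data, not an error.

TIC normalization divides each sample row by its own total over the
library-matched species, so rows sum to 1. The denominator is the
*matched* total, not the raw full-scan ion current: the pipeline operates
downstream of targeted extraction and fixtures carry no unmatched ions.
Note that normalization introduces closure: when a large group of species
(the lecithins) genuinely rises, every other normalized value falls, so
fold changes of individual species are compressed relative to their raw
counterparts. The L/S ratio itself is unaffected, being scale-invariant.

# Quality control

Replicate injections of a pooled sample estimate precision as the
per-species coefficient of variation, $CV = sd/mean \times 100$ with the
$n-1$ standard deviation, averaged per lipid class; species with zero
mean are reported missing and excluded from averages. The PCA overview
(mean-centered, unit-variance scaled by default, matching the common
chemometrics-software default; center-only is available) shows run
stability: QC injections should form a tight cluster. All-zero species
columns are dropped before PCA with a warning, since they carry no
information and break unit-variance scaling.

# Diagnostic evaluation

Premature is the positive class — it is the condition being screened.
The bundled 33-sample clinical cohort contains seven 18-week
amniocentesis samples with no recorded newborn outcome; they are counted
as premature outcomes during evaluation, because an 18-week fetus cannot
have mature lungs and the cohort's stated composition (11 premature, 22
mature) requires it. Values exactly at a cutoff classify as mature,
mirroring the strict "< cutoff" definition of the premature call.
Sensitivity and specificity are reported as whole percents rounded
half-up (10/11 → 91%). Cutoffs are taken as given (10.0 and 50 × 10⁹/L
are literature values); ROC re-optimization is deliberately out of scope.

# Biomarker discovery

Group comparison uses Welch's unequal-variance t-test (two-sided) — the
robust default when group sizes differ — with **no multiple-testing
correction**, because the selection rule filters on raw p; this is a
documented caveat, not an oversight. Fold changes are ratios of
arithmetic group means of normalized intensities, unlogged, and a zero
premature mean is surfaced as an error rather than patched with a
pseudo-count.

The PLS-DA is a univariate-response NIPALS fit: X mean-centered and
unit-variance scaled, y the centered 0/1 class indicator; each
component's weight vector is $X^T y$ normalized to unit length, with X
and y deflated by the extracted score. Two components are fitted by
default (the convention for score plots); VIP is computed over all
fitted components as

$$VIP_j = \sqrt{p \cdot \frac{\sum_a SSY_a\,(w_{aj}/\lVert w_a\rVert)^2}{\sum_a SSY_a}}$$

which obeys $\sum_j VIP_j^2 = p$ exactly — the identity the tests assert
on random fits. The selection rule applies the strict inequalities
p < 0.05, VIP > 1.1, FC > 2 and ranks hits by fold change.

# Pathway analysis

Enrichment is one-sided hypergeometric over-representation (the standard
metabolite-set test), with Holm–Bonferroni step-down adjustment across
the tested pathways. The topology *impact* of a hit set is

$$\mathrm{impact} = \frac{\sum_{v \in \text{matched}} c(v)}{\sum_{v} c(v)}$$

where $c(v)$ is betweenness centrality normalized by $(n-1)(n-2)/2$.
Pathways with zero total centrality — complete graphs and graphs of one
or two nodes, where no node can sit between others — get impact 0 by
convention. The reported $-\log(p)$ uses the natural log by default
(base 10 is an option; the base convention differs between tools).
The packaged pathway graphs are synthetic toys with analytically known
centralities (a star, a path, a complete graph, and an 8-node tree whose
hand-computed centrality table ships in `extdata/`); real KEGG-derived
graphs can be supplied in the same JSON format but are never downloaded.
The enrichment background defaults to the library's compound universe.

# The synthetic-data generator

The generator produces what the pipeline needs and nothing more: peak
lists with the statistical structure of a targeted lipidomics study.

* **Intensities** are log-normal around per-species baselines, with
  $\sigma = \sqrt{\ln(1 + CV^2)}$ so the noise level is parameterized
  directly by a CV (default 30%, a realistic biological+technical spread).
* **The lecithin trajectory** is a logistic multiplier
  $1 + (m_{\max}-1)/(1 + e^{-k(\mathrm{GW}-g_0)})$ with midpoint
  $g_0 = 36$ weeks, steepness $k = 0.8$/week and ceiling
  $m_{\max} = 20×$, applied to lecithin species of **mature-outcome
  samples only** — premature lungs keep the immature baseline whatever
  the gestational week, which is precisely why the L/S ratio works as a
  maturity test rather than a calendar. These defaults place premature
  samples well below the 10.0 cutoff and term samples well above it,
  matching the clinical cohort's dynamic range (≈1.3–113).
* **The baseline L/S ratio** is set to 1.8 by scaling the lecithin
  baselines, inside the 1.3–2.3 spread of the cohort's 18-week controls.
* **Sphingomyelin** baselines never depend on gestational week; a
  regression test asserts the realized slope is within ±2%/week of flat.
* **Gestational weeks** are drawn per group: 18 (controls), 30–36
  (premature), 35–36 (preterm-mature) and 38–40 (term), the ranges
  observed in the clinical cohort.
* **LBC** is drawn normal around 2 × 10⁹/L for controls, 38 for
  premature and 58 for mature samples (sd 10 and 7), truncated at zero —
  roughly a 10% overlap across the 50 cutoff, which reproduces the
  fixture's misclassification pattern qualitatively.
* **QC replicates** use class CV targets of 3.8% (PC, also applied to PE
  and Cer) and 3.4% (SM), the precision of a well-behaved LC-HRMS run.
* Peak lists add m/z jitter (sd 1.2 ppm, clamped at ±4.5) and RT jitter
  (sd 0.03–0.05 min) plus ~100 uniform decoy peaks per sample, so the
  matcher is exercised, not bypassed.

Seeds are mandatory arguments everywhere; there is no hidden global
randomness, and every generator is bit-reproducible given (seed, spec,
library). What the generator does **not** emulate: chromatographic peak
shapes, isotope patterns, adduct interference, in-source fragmentation,
RT drift across batches, or blood/meconium contamination. Passing tests
on synthetic cohorts therefore validate the pipeline's logic and
statistics, not instrument-level robustness on real fluids.

## The recovery experiments

Two end-to-end checks define what "working" means here, at sizes chosen
to mirror a small clinical study while keeping the default test run
fast:

1. **Biomarker recovery** — 10 species planted at true fold change 4
   among 151, n = 10 vs 10. The cohort for this experiment uses a *flat*
   lecithin trajectory (`max_mult = 1`) so that the planted species are
   the only real group difference; otherwise all 64 lecithins would be
   genuinely differential and the notion of "false positive" would be
   meaningless. The selection rule is required to recover ≥ 8/10 planted
   species with ≤ 2 false positives. (TIC closure compresses the
   realized fold changes to ≈2.2–3.5, which the rule still clears.)
2. **Maturity recovery** — a premature vs mature cohort (n = 10 per
   group) pushed through extraction → normalization → L/S → the 10.0
   cutoff must reach ≥ 80% sensitivity and specificity. The marginal
   case is a 35-week mature sample, whose expected ratio (~12) sits
   closest to the cutoff.

# Numerical and design notes

* Proton mass fixed at 1.007276466 Da and recorded in saved library
  headers.
* Hyphen-like unicode glyphs in species names (O‐/P‐ prefixes) are
  normalized to ASCII, since printed tables mix dashes.
* Degenerate Welch inputs (both groups constant, equal means) return
  t = 0, p = 1 by convention rather than erroring mid-scan of a matrix.
* The orchestrator (`run_pipeline`) computes nothing itself: every
  reported number comes from one module function, stages with missing
  inputs are skipped with a recorded reason, and a fixed config + seed
  reproduces the serialized report byte for byte. It is deliberately a
  function, not a shell tool: the numbered scripts under `analysis/`
  are the command-line surface of this package.
* Standard statistics are delegated to base R (`t.test`, `phyper`,
  `p.adjust`, `prcomp`) and graph centrality to igraph; the tests check
  each against an independent oracle (textbook Welch formulas,
  exhaustive hypergeometric enumeration, hand-applied Holm step-down,
  SVD, hand-counted tree centralities). The PLS-DA/VIP machinery is
  implemented in the package and checked against closed forms.

# Known limitations

* Internal-standard (matrix-effect) correction is not modeled; the
  generator's QC replicates emulate post-correction precision directly.
* The numeric pathway-impact and biomarker fold-change/VIP values of any
  particular real study depend on its raw data and its pathway-graph
  version; this package reproduces the *procedures* and validates them
  structurally and on synthetic data.
* No peak picking from profile spectra, RT alignment, absolute
  quantification, mzML ingestion, OPLS variants, or cross-validated
  component selection.
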