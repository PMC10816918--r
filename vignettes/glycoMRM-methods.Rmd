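---
title: "glycoMRM: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glycoMRM: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMRM)
```

## The problem

Most glycosyltransferases (GTs) of the endoplasmic reticulum are
low-abundance polytopic membrane proteins, hard to quantify by shotgun
proteomics. A scheduled MRM (multiple reaction monitoring) assay solves
this by monitoring a fixed set of transitions — (precursor m/z, fragment
m/z) pairs — for proteotypic peptides of each target protein, with a
spike-in SILAC internal standard: a heavy-labeled membrane-protein
fraction added to every sample so that each light (endogenous) transition
has a co-eluting heavy partner. The light/heavy area ratio cancels
digestion, cleanup and instrument variability; normalizing each sample's
protein ratios to an ER reference protein (SEC63) additionally absorbs
differences in ER content and loading.

`glycoMRM` implements the computational side of this workflow end to end:
assay design, transition-level quality control, sum-then-ratio
quantification with SEC63 normalization, regression-based two-group
comparisons with Benjamini–Hochberg correction, and NanoString nCounter
transcript normalization — plus a synthetic-data generator with known
ground truth so every stage is testable without instrument data.

## Assay design

In silico design follows standard targeted-proteomics practice:

* **Digestion** — trypsin cleaves C-terminal to K/R unless the next
  residue is proline (Keil rule), zero missed cleavages. The digest tiles
  the protein; this is asserted as a test property.
* **Candidate filter** — peptides of 7–21 residues, no methionine
  (oxidation-prone), and exact full-sequence uniqueness within the
  caller-supplied background set. Uniqueness is *not* I/L-collapsed; if
  you need proteome-wide proteotypicity, supply the whole proteome digest
  as background.
* **Masses** — monoisotopic; proton 1.007276, water 18.010565,
  carbamidomethyl-Cys +57.021464, SILAC shifts +8.014199 (K) and
  +10.008269 (R). Heavy shifts apply to precursors and y-ions only
  (b-ions lack the C-terminal residue). Values were cross-checked against
  an independent residue-mass summation before being frozen into tests.
* **iRT calibration** — ordinary least squares of measured RT on
  reference iRT over the standard peptides; the fit is rejected below
  r² = 0.99 (configurable — the upstream software applies an internal fit
  without a published threshold, so we chose a strict default).
  Scheduling windows default to ±2.5 min, configurable; no window width
  is published for the original gradient.
* **Transition choice** — the 3–4 most intense fragments per precursor,
  ties broken by series/ordinal for determinism; candidate fragments
  default to y-ions of ordinal ≥ 3 (y1/y2 are rarely selective in QQQ
  practice).

## The synthetic-data generator

The generator is a stated world, not a tuning knob. For transition $t$,
sample $s$:

$$\mathrm{heavy}(t,s) = B_t \cdot \sigma_s \cdot 2^{\varepsilon}, \qquad
\mathrm{light}(t,s) = B_t \cdot \lambda_s \cdot \rho_{p(t)} \cdot
2^{\varepsilon'}$$

with $B_t$ the base intensity (log-uniform over two decades,
$10^4$–$10^6$), $\sigma_s$ the per-sample spike-in amount (log-normal,
CV = `spike_cv`), $\lambda_s$ a shared biological loading factor
($2^{N(0,\texttt{loading\_sigma})}$, carried by every light channel
including SEC63 so that SEC63 normalization cancels it exactly),
$\rho_p$ the true condition/control ratio of the peptide's protein
(control samples: 1; per-peptide overrides emulate heterozygous
variants), and $\varepsilon$ i.i.d. $N(0, \texttt{noise\_sigma})$ in
log2.

Artifacts: additive light-only interference (per light measurement with
probability `interference_rate`, magnitude `interference_scale` × true
area, half of the hits also losing the coelution flag), truncation flags,
and limit-of-detection censoring to *missing* (never zero, and never an
imputed floor — a protein whose light channel is fully censored is
reported as excluded with a reason, mirroring "at or below the detection
limit" findings).

Defaults — `noise_sigma = 0.15`, `spike_cv = 0.1`,
`loading_sigma = 0.2` — are invented but realistic for a well-behaved
scheduled MRM assay with a stable internal standard (ratio CVs around
10–15%); no quantitative noise model is published for the original data,
so these are surfaced in the ground-truth record and configurable. What
the generator does **not** emulate: chromatographic peak shapes (it works
at integrated-area level), inter-peptide digestion-efficiency
differences, heavy-channel interference, and RT drift. A green
parameter-recovery test therefore establishes correctness of the
*analysis*, not instrument robustness.

The named presets encode the study findings they stand in for: affected
protein at 10% (`alg1_cdg`), 20% (`alg11_loss`), below the detection
limit (`alg2_cdg`, ratio 0.001 with LOD 2500 so every condition light
area is censored), a single variant-bearing peptide at 35% with all
protein ratios at 1 (`alg11_variant`, pinned to the real tryptic peptide
INIPFDELK), and an all-null 3-vs-3 comparison
(`null_two_celltypes`). Patient/control sizes are 3 vs 4 as in the
source study; for the variant preset the three condition samples model
one patient's replicate injections treated as independent observations.

## Transition QC

The reference dot-product of a precursor in one sample is
$\mathrm{rdotp} = \langle \ell, h\rangle / (\|\ell\|\,\|h\|)$ over the
light and heavy fragment-area vectors; 1 means identical relative
fragment patterns. Missing areas count as zero — a fragment present in
only one channel is genuine pattern disagreement. The filter is
strict (`rdotp > 0.9`), applied per sample: a peptide failing in one
sample still contributes in samples where it passes. Flags collected per
fragment: `truncated`, `fwhm_degenerate`, and `not_coeluting` (either
channel flagged, or apex RTs differing by more than 0.1 min — the
tolerance is ours; the upstream software makes an internal call).

The original workflow marks interfered transitions non-quantitative by
manual inspection. We replace this with a deterministic, auditable
proposal rule: a transition is proposed when it is flagged in ≥ 50% of
samples, or when its peptide fails the across-sample median rdotp and
leave-one-out removal of the transition lifts the median above the
threshold. Proposals are written to a file and applied explicitly
(`apply_mask()`), never silently; masking is global — a masked
transition contributes to no sample, both labels.

At the default noise level every clean synthetic peptide passes the
filter. Note that for unbounded log-normal noise *some* peptide will
eventually dip below any threshold: at twice the default noise we
measure ≈ 99% passing, so the suite asserts 100% at the default and
≥ 98% at sigma 0.3 rather than an absolute claim.

## Quantification

Sum-then-ratio: all quantitative, QC-passed transition areas are summed
per sample × protein, and the log2 light/heavy ratio of the sums is the
protein ratio. A transition enters a sum only when **both** labels are
present (paired inclusion) — otherwise censoring of one channel would
bias the ratio. The literal all-peptide sum is used (not a
median-of-peptides); the peptide-level table is produced separately,
because a single-peptide effect (heterozygous variant) is diluted about
4-fold in the protein sum and only visible per peptide.
Normalization subtracts each sample's SEC63 log2 ratio; peptide tables
are normalized against the *protein-level* SEC63 ratio.

## Differential statistics

Per protein, ordinary least squares of the normalized log2 ratio on a
0/1 group indicator: the slope is the log2 fold change (identical to the
difference of group means), the slope's standard error gives a two-sided
p from the t distribution with n − 2 degrees of freedom and the 95% CI,
exponentiated to the linear scale for reporting. t-based rather than
normal quantiles because n is tiny (3 vs 4); a normal CI would be
anti-conservative. BH adjustment runs across the proteins of one
contrast; significance is `adj_p ≤ 0.05` (inclusive). SEC63 is excluded
(its normalized values are identically zero). Complete-case analysis,
no imputation; entities with fewer than one observation per group or
three total are excluded with a logged reason.

## nCounter normalization

Two steps, each a geometric-mean factor with the arithmetic mean of
per-sample geometric means as reference (the vendor convention): first
over the spiked positive-control probes, then over the housekeeping
genes C1orf43 and SNRPD3. After both steps the housekeeping geometric
mean is equal across lanes. Fold change is the ratio of group means on
the normalized linear scale; CI/p come from the same two-group
regression on log2 normalized counts, BH-adjusted across genes. One
subtlety: because the factor reference is itself data-dependent,
rescaling a single lane rescales the whole normalized matrix by one
global constant — every between-sample and between-gene *ratio* is
exactly invariant, and that is the property the tests assert. No
background (negative-control) subtraction is applied.

## Numerical and degenerate-input choices

* Ties in transition selection: series letter then ordinal, so results
  are reproducible across platforms.
* `rdotp` is capped at 1 against floating-point overshoot and undefined
  (NA) when either channel's norm is zero or fewer than two fragments
  exist.
* Zero-residual regressions return `se = 0` with p ∈ {0, 1}; df = 0
  returns the estimate with NA inference rather than an error.
* All generator randomness flows from a single scenario seed with a
  documented draw order (layout → sample factors → noise → artifacts);
  the generator restores the caller's RNG state.
* Below-LOD areas and their apex RTs are missing together (the report
  validator enforces `area missing ⇒ apex missing`).

## Known limitations

* The background set for peptide uniqueness defaults to the designed
  panel itself, not the human proteome; supply a proteome digest for
  production assay design.
* The QC flag triage consumes flags; it does not compute them from
  chromatograms (no peak picking).
* Only pairwise two-group contrasts — no batch covariates or mixed
  models, matching the original analysis script's scope.
* Replicate injections of one patient are treated as independent
  observations in the variant scenario; a mixed model would be more
  conservative.
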