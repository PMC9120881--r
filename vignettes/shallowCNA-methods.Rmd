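---
title: "Methods: tumour-fraction estimation and response monitoring from shallow cfDNA WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumour-fraction estimation and response monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and numerical decisions
behind shallowCNA, in the spirit of a methods supplement: what is assumed,
what is estimated, which defaults were open design choices, and what the
synthetic validation does and does not demonstrate.

## The mixture model

Plasma cfDNA from a cancer patient is modelled as a two-component mixture:
a tumour fraction $t \in [0, 1)$ of fragments from tumour cells with
locus-specific integer copy number $c$, and a fraction $1 - t$ from normal
diploid cells. After depth normalization, the expected log2 read-count
ratio of a bin with tumour copy number $c$ is

$$ m(c, t, \varphi) \;=\; \log_2 \frac{(1-t)\,2 + t\,c}{(1-t)\,2 + t\,\varphi}, $$

with $\varphi$ the tumour ploidy; dividing by the average copy content
makes $c = \varphi$ map to zero, so a profile re-centred at its median is
comparable across tumour fractions. All copy-number information is carried
by 1-Mb bins on the autosomes (hg19 frame, chr1–chr22); sex chromosomes are
excluded because their expected ratio depends on patient sex.

Assumptions worth stating explicitly: clonal events only (no subclonal
prevalence parameter — the estimator reports a single genome-wide $t$);
integer copy states up to a cap; events long relative to the 1-Mb bin
(arm-scale in the motivating application); and bin-level noise independent
across bins after normalization.

## Normalization

`correct_bias()` divides counts by a loess fit of count on GC fraction
(span 0.3, degree 2, *symmetric* family so that bins shifted by real
copy-number events are down-weighted and the trend is estimated from the
neutral mass), then by mappability, and rescales to median 1. Zero-count
bins are masked, not floored. `build_pon()` summarizes corrected control
samples into per-bin medians and MADs of log2 ratios and a blacklist
(GC outside [0.28, 0.65], mappability < 0.9, inter-normal MAD above the
99th percentile — all exposed, none sacred; they exist to drop bins whose
behaviour no per-sample correction can fix). `normalize_sample()` subtracts
the panel median and re-centres to median 0. The median re-centring is a
convention: in a heavily aneuploid genome it shifts the whole profile by a
fraction of the noise scale, which is why validation checks measure event
levels against the neutral level rather than against absolute zero.

## The HMM and its estimation

The observation sequence is the usable (unmasked) bins in genome order;
chromosomes are independent chains, and masked bins are skipped without
breaking adjacency. Hidden states are copy numbers $0..\mathrm{maxCN}$
(default 5). Three design choices depart from the most common textbook
setup, each forced by the operating regime:

* **Student-t emissions** (df = 4, scale $\sigma$, `df = Inf` recovers
  Gaussian). At shallow depth the log2 ratios of negative-binomial counts
  are heavy-tailed; with Gaussian emissions a spurious solution that packs
  many closely-spaced state means into the central noise mass wins the
  likelihood by shrinking $\sigma$ (a mixture-quadrature artefact). The
  t-EM uses the standard latent-scale weights, so monotonicity is
  preserved.
* **A diploid-concentrated state prior** $\pi_k \propto e^{-\lambda|k-2|}$
  (default $\lambda = 3$) entering the initial distribution and the
  off-diagonal transition mass (`trans(j,k) = e\,1[j{=}k] + (1-e)\pi_k`).
  Without it the model is *exactly* non-identifiable: a single-copy gain
  plus single-copy loss at tumour fraction $t$ produces identical emission
  means to a two-copy gain plus homozygous loss at $t/2$, and a
  ploidy-3 relabelling shifts every state by one. The prior resolves these
  aliases toward the parsimonious near-diploid interpretation.
* **A fixed emission scale.** $\sigma$ defaults to the bin-to-bin
  difference estimate $\mathrm{mad}(\Delta x)/\sqrt{2}$ (made
  MAD-consistent for the chosen df), which is insensitive to segment
  structure; re-estimating $\sigma$ inside EM (available via
  `estimate_sigma = TRUE`) lets degenerate solutions absorb genuine signal
  into the scale.

Self-transition probability $e$ defaults to 0.995. Larger values make
arm entry cost more log-likelihood than a subtle arm-level shift carries at
shallow depth (an arm at $t = 0.2$ carries roughly 13 nats here; at
$e = 1 - 10^{-6}$ entry costs ~29), while smaller values fragment segments;
0.995 balances the two at 1-Mb resolution.

**EM.** For each (ploidy, normal-fraction) initialization — defaults
$\varphi \in \{2, 3\}$, $n_0 \in \{0.5, 0.75, 0.9, 0.95, 0.99\}$ — the
E-step runs forward–backward (compiled); the M-step re-estimates $t$ by
bounded one-dimensional maximization of the expected complete-data
log-likelihood (state means are tied through $m(c,t,\varphi)$, so no closed
form exists; the candidate from `optimize()` is accepted only if it
improves the weighted score, alongside the current value and 0, making the
step a generalized-EM move and the likelihood monotone). Convergence is a
log-likelihood gain below $10^{-3}$ or 50 iterations. The winner is the
highest final likelihood; fits within 0.05 nats are treated as numerically
tied and resolved toward lower ploidy, then higher normal fraction — the
more conservative tumour call.

**Detection guard.** A flexible mixture extracts a small, scale-free
likelihood gain from any noisy profile (measured at 0–2 nats on
tumour-free synthetic profiles, versus 6–46 nats for real signal at
$t \ge 0.2$). The fitted model must therefore beat the $t = 0$ null by
`null_margin` (default 2.5 nats) or the fit collapses to the null — an
AIC-style parsimony rule that keeps specificity at the 0.016245
detectability cut-off above 90% without touching genuine detections.

**Two-pass rule.** If the first-pass estimate falls below 5%, the sample is
re-fitted with `hmm_params_low_tfx()`: normal-fraction initializations
0.95/0.99/0.995/0.999, initial ploidy fixed at 2, states capped at 3, no
subclonal modelling — the regime where only clonal single-copy events at a
low mixture fraction are identifiable — and the second-pass fit is
returned. The state cap matters beyond initialization: it removes the
$c \in \{4, 5\}$ aliases entirely, pinning $t$ to the single-copy
interpretation.

## Clinical thresholds

All defaults live in `response_thresholds()`:

| quantity | default | note |
|---|---|---|
| relative TFx change | 0.5 | strict `>`; boundary is stable |
| absolute TFx change | 0.03 | strict `>`; boundary is stable |
| detectability cut-off | 0.016245 | `>=` at the boundary |
| prognostic TFx split | 0.1 | `>=` is the high group |
| lipiodol deposition split | 0.5 | `>=` is the high group |
| arm-call coverage | 0.5 | fraction of arm length |
| AFP abnormality | 20 ng/mL | `>` is abnormal |

When the pre-treatment TFx is 0 the relative change is infinite and the
absolute threshold alone decides; 0 → 0 is stable. Both classifiers are
provided: the canonical dual-threshold decline/stable/increase rule and the
absolute-only decrease/stable/increase split
(`classify_tfx_change_abs()`). mRECIST thresholds (−30% / +20%) are
inclusive. No multiple-testing correction is applied anywhere in the
statistics layer — results are reported at nominal p-values, which is a
deliberate caveat, not an oversight.

## The synthetic cohort generator

The generator is the package's study stand-in, not a unit-test fixture. Its
defaults encode the monitored-cohort design: 89 non-cancer controls (32
"healthy" + 57 "cirrhosis"), 64 patients, an expected 45 reads per 1-Mb bin
with negative-binomial overdispersion 0.02 (`Var = mu + 0.02 mu^2`; the
depth is a desk-scale stand-in for ~3x coverage — see limitations),
a unimodal quadratic GC bias, a mappability track with a small minority of
poor bins, and a *shared* multiplicative per-bin artifact (log-sd 0.05)
applied to every sample but hidden from the bias corrector — the recurrent
technical structure a panel of normals exists to remove. Arm events follow
HCC-typical frequencies (gains 1q 0.50, 6p 0.35, 8q 0.55, 20p 0.25,
20q 0.30; losses 4q 0.45, 13q 0.40, 8p 0.40, 16q 0.35, 17p 0.40), chosen
once as representative cohort frequencies. True TFx trajectories are drawn
per change group (decline/stable/increase with probabilities 14/64, 43/64,
7/64 at the first session) so that group labels are consistent with the
classifier by construction; baseline TFx spans 0–0.65.

Outcomes are linked to truth by the simplest models that produce the
qualitative clinical contrasts with tunable effect sizes: exponential
survival with a proportional-hazards factor (PFS hazard ratio 3 for the
TFx-increase group on a 163-day baseline median; OS hazard ratio 2.6 for
baseline TFx ≥ 0.1 on a 630-day median; administrative censoring at
600/900 days), lesion-diameter multipliers per change group with
deliberate crossover so mRECIST and TFx agree imperfectly, AFP log-linear
in TFx with noise, and a lipiodol deposition rate that decreases
logistically in the true amplified-Mb burden (`plogis(1.2 − 0.008·Mb)`
plus noise). One master seed drives named substreams, so every table is
reproducible and carries its seed.

What the generator does **not** emulate: fragment-length and
nucleosome-footprint signal, replication-timing coverage waves, real GC
spectra, sub-arm and focal events (available but off by default),
subclonal heterogeneity, sex chromosomes, and sequencing error. Passing
tests therefore demonstrate correctness of the pipeline's logic and
calibration under the stated noise model — not clinical performance on
real plasma.

## Validation scale and measured limits

The test suite runs the estimator at the generator's defaults on the full
~2,880-bin autosomal frame: a recovery grid $t \in \{0, 0.05, 0.1, 0.2,
0.3, 0.5\}$ × 10 draws against an 89-control panel, 50 replicates of the
two-pass rule at $t = 0.02$, 500 replicates for the size of the log-rank
test at $n = 64$, 25 replicate cohorts for effect detection, and 200 truth
draws for the frequency profile; smaller three-chromosome fixtures at
higher depth isolate unit-level behaviour. Two honest limits are visible at
the default depth of 45 reads per bin, where the per-bin log2 noise is
~0.30: a whole arm at $t = 0.1$ carries only ~2–4 nats of likelihood
evidence (the same order as chance chromosome-scale wobbles on tumour-free
profiles), so recovery error below the detection threshold rises to the
0.05–0.09 range there; and at $t = 0.02$ the entire genome carries well
under one nat of evidence, so both passes collapse to the null and the
second pass ties rather than beats the first. At 10–20× more reads per bin
— the regime the method targets on real data — both limits recede; the
package reports what it measures rather than tuning the conditions.

## Known limitations

* No B-allele-frequency modelling: copy-neutral LOH is invisible.
* One genome-wide $t$: subclonal events bias the estimate downward.
* The ploidy candidate set {2, 3} with the parsimony prior resolves, but
  does not estimate, genome doubling; φ̂ is a label, not a measurement.
* Arm calls on acrocentric p-arms (13p, 14p, 15p, 21p, 22p) are reported
  but low-confidence: the hg19 frame assigns them few usable bins.
* The detectability cut-off 0.016245 is taken as a fixed clinical constant;
  its ROC provenance is not re-derived from synthetic data.
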