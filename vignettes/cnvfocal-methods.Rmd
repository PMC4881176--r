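---
title: "Separating focal from broad copy-number variation: methods and design"
author: "cnvfocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating focal from broad copy-number variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvfocal)
```

## The problem

Somatic copy-number profiles of tumors superimpose two kinds of events with
different biology and very different genomic extents. Broad CNVs (bCNV) span
large fractions of a chromosome arm and typically arise from mitotic
mis-segregation; focal CNVs (fCNV) span kilobases to a few megabases, arise
from DNA-repair errors, and — because selection acts on a small target — are
far more informative about driver genes. A focal gain sitting on top of a
broad loss (or vice versa) is invisible to methods that score the raw signal:
the two components cancel. `cnvfocal` treats a log-ratio profile as a
spectrum and separates its low-frequency (broad) and high-frequency (focal)
components before any cohort-level scoring.

## The decomposition model

Let $x$ be a sample's vector of $\log_2$ probe signals ordered along the
genome. The chain is:

1. **Mode normalization.** $x_{norm} = x - \mathrm{mode}(x)$, where the mode
   is the argmax of a Gaussian kernel density estimate of the signal values
   (Silverman's rule-of-thumb bandwidth, 512-point grid; grid ties resolve
   to the smaller value). The dominant copy state — diploid in most tumors —
   maps to zero regardless of normalization offsets upstream.
2. **Noise smoothing.** $x_{sm} = \mathrm{runmed}(x_{norm}, w)$ per
   chromosome, a running median with a small window of $w$ probes
   (default 51). The running median is the right smoother for
   piecewise-constant signals: it removes events narrower than $w/2$ probes
   as noise while preserving the location and height of genuine change
   points, which a linear filter would blur.
3. **Reduction.** Neighboring smoothed sites are nearly redundant, so the
   profile is retained only at indices $1, 1+s, 1+2s, \ldots$ with stride
   $s = \mathrm{round}(w/3)$ (round-half-to-even; $51 \to 17$), appending
   the final probe. This cuts the dimension ~17-fold with no loss at the
   smoothing scale.
4. **Broad/focal split.** $x_{bcnv} = \mathrm{runmed}(x_{red}, wb)$ with a
   long window of $wb$ reduced sites (default 641, roughly 32 Mb on a
   1M-probe whole-genome array), and $x_{fcnv} = x_{red} - x_{bcnv}$
   exactly. A segment spanning fewer than $wb/2$ reduced sites — about
   16 Mb — cannot move a window median, so it passes entirely into the
   focal track; anything longer is broad. The split is additive by
   construction: `fcnv` is stored as the exact floating-point difference.
5. **Noise estimate.** $\varepsilon = 1.4826 \cdot \mathrm{MAD}(x_{fcnv})$,
   per sample, over the genome-wide focal track. The scaled MAD is
   consistent for the Gaussian noise floor and ignores the rare, extreme
   true focal events that would inflate a standard deviation. We estimate
   per sample rather than per cohort because array quality varies
   sample-to-sample; the estimate is exposed on every decomposed profile.

Running-median boundaries use R's classic `endrule = "median"` (Tukey end
smoothing), so output length equals input length and boundary values stay
within the local data range. Smoothing, reduction and the broad split are
all per chromosome; nothing bleeds across a chromosome boundary, and the
reduction stride restarts on each chromosome.

### Calling and the cohort landscape

A reduced site is called a **gain** when $x_{fcnv} > k\varepsilon$, a
**loss** when $x_{fcnv} < -k\varepsilon$, neutral otherwise (strict
inequalities; default $k = 3$, for a per-site null call rate of
$2\Phi(-3) \approx 0.27\%$). Counting gain and loss calls per site across
the tumor cohort gives the frequency track, the landscape in which
recurrent focal regions appear as peaks.

## Peaks, confidence intervals, and the four criteria

Peaks are local maxima of the per-direction frequency track under a
41-site scanning window, discarding peaks below 8 samples. Plateaus of tied
qualifying sites collapse to their middle site, since a plateau has no
unique apex.

Peak **position uncertainty** comes from a case bootstrap: patients are
resampled with replacement (cohort size preserved) 500 times, the track and
peaks recomputed each time with identical parameters, and each original
peak matched to the nearest replicate peak on the same chromosome and
direction (ties toward the smaller position). The 95% interval is the
[2.5, 97.5] percentile range of the matched positions (type-1/inverse-ECDF
quantiles, so two resamples degenerate to [min, max]); it is clamped to the
probed range and always contains the original apex. Replicates with no peak
on the chromosome contribute nothing; if more than half contribute nothing
the interval is reported undefined.

A peak becomes a **selected focal region** when all four criteria hold:

1. height ≥ 8 samples;
2. 95% CI narrower than 1 Mb;
3. fewer than 4 retained normal-tissue samples with a gain-or-loss call
   inside the CI — this filters germline copy-number polymorphisms (CNPs);
   with no normals supplied the criterion passes vacuously and is reported
   as not evaluated;
4. gain and loss counts at the peak site significantly asymmetric
   (exact binomial sign test against 0.5, two-sided, α = 0.05).

The asymmetry test is two-sided for selection ("significantly different")
and one-sided (gain > loss) in the power simulation, where only
amplifications are planted. No multiplicity correction is applied across
peaks; the four criteria are conjunctive and already conservative.

Normal samples are screened first: each normal's CNP count is its number of
reduced sites with $|x_{fcnv}| > 5\varepsilon$, and normals above the upper
Tukey fence (Q3 + 3·IQR of the cohort's counts) are excluded as likely
tumor-contaminated or poor-quality before criterion 3 is evaluated. The
fence replaces a by-inspection removal, which cannot be reproduced as a
rule; the multiplier is configurable.

## Driver-gene association and expression effects

Genes overlapping a selected region's CI by at least 1 bp (1-based
inclusive intervals on both sides) are assigned to it. The association of
gains with oncogenes and losses with tumor-suppressor genes is tested by a
two-sided Fisher's exact test on the 2×2 table of distinct driver genes in
gain vs loss regions, with the effect reported as the fold between the two
oncogene:TSG ratios — numerically the sample odds ratio:

```{r fisher}
tab <- matrix(c(22, 2, 14, 11), 2,
              dimnames = list(c("gain", "loss"), c("oncogene", "TSG")))
driver_contingency_test(tab)[c("p_value", "ratio_fold")]
```

Expression effects per gene are mean $\log_2$ expression differences
between carrier and non-carrier tumors, oriented so that dosage-responsive
genes score positive in either direction (carrier − non-carrier for gains,
reversed for losses); a carrier is a sample with a call of the region's
direction anywhere inside the CI. Driver vs non-driver effect distributions
are compared by a two-sided Wilcoxon rank-sum test — the comparison is of
location, the groups are independent, and normality of per-gene effects is
not defensible, which is why a rank test rather than a t-test.

## The simulation harness

`sim_config()` / `simulate_cohort()` emulate the validation design the
method was assessed under: one synthetic chromosome of $L = 16{,}000$
equally spaced probes for $N = 500$ patients, each with a normal and a
tumor profile of iid Gaussian probe noise with unit standard deviation; a
fraction $f$ of patients carry a single amplicon of height $h$ $\log_2$
units over $n$ probes centered at probe $L/2$ of the tumor profile.
`evaluate_detection()` runs the decomposition and 3ε calling on every tumor
and classifies each patient at the reduced site nearest the amplicon
center; false/true positive/negative rates are computed against the planted
truth (per sample, among non-carriers/carriers respectively), and the locus-level
p-value is the one-sided exact binomial test that gains outnumber losses.

Design choices a user should know:

* **Probe spacing is 3 kb by default.** The harness needs physical
  coordinates only so that physical-unit parameters (the 1 Mb CI cap, broad
  windows stated in Mb) are exercisable; 3 kb per probe is typical of a
  ~1M-probe whole-genome array and makes the synthetic chromosome 48 Mb,
  with a reduced-grid step of 51 kb. Index-level behavior is unaffected by
  this constant.
* **The simulated chromosome carries no broad events**, so `wb` is clipped
  per chromosome to the largest odd window that fits the reduced grid
  (941 sites at the defaults). Clipping only matters when the chromosome is
  shorter than the requested window.
* **Coverage of a planted center is judged at grid resolution.** The true
  amplicon center generally falls between reduced-grid sites, and an exact
  two-site tie collapses to a single reported site, so a bootstrap CI is
  counted as covering the truth when the CI expanded by one reduced-grid
  step contains it. Positions simply do not exist at finer resolution after
  downsampling.
* **What the simulation does not emulate:** real probe spacing is irregular
  and platform-specific; real noise is heavy-tailed and locally correlated
  (GC waves); real tumors mix purity, ploidy shifts and many overlapping
  events; and amplicon boundaries are not crisp. Passing the harness shows
  the pipeline's statistical machinery behaves as designed under its own
  model, not that real-data performance will match the simulated rates.

At the defaults, detection power at the amplicon locus is driven by the
carrier count: with $f = 0.02$ and 500 patients, roughly 10 carriers are
called gain at the center against a ~0.1% per-sample false-positive rate,
and the one-sided binomial p-value falls below 0.05 in the median cohort —
the boundary at which a recurrent amplification is distinguishable from
noise in a cohort of this size.

## Numerical and degenerate-input behavior

* Windows must be odd; physical-span inputs are converted to the nearest
  odd probe count via the profile's median probe spacing, and counts win
  when both are given.
* Chromosomes shorter than a window are smoothed with the largest odd
  window that fits; chromosomes shorter than the reduction stride retain
  first and last probe.
* An all-constant focal track (ε = 0) is an error, not a silent pass:
  it indicates corrupt input.
* The mode estimator requires ≥ 10 finite values, ε ≥ 30; missing probe
  values are dropped at I/O with a logged count, never imputed.
* `bcnv + fcnv` re-added in floating point can differ from the reduced
  profile by one ulp; the stored `fcnv` is the exact difference.
* Internal coordinates are 1-based inclusive; BED export is 0-based
  half-open with `start_bed = start − 1` exactly. The Y chromosome is
  dropped on load by default (mixed-sex cohorts); X is retained.

## Problem sizes used in the package's own checks

The shipped tests exercise the full-scale simulation design (20 cohorts of
500 patients × 16,000 probes for the power boundary; 25 cohorts of 200
patients for bootstrap-CI coverage; 100 replicate cohorts for the
false-positive regime; broad windows equivalent to 30–40 Mb for stability),
with smaller profiles in unit tests where the property under test does not
depend on scale.

## Known limitations

* Calling is relative to each sample's own noise floor; no absolute
  copy-number, purity or ploidy inference is attempted.
* The peak height floor (8 samples) and CI cap (1 Mb) are cohort-size and
  platform dependent; cohorts much smaller than a few hundred samples will
  need a lower floor, at the cost of specificity.
* The first and last reduced sites of each chromosome are smoothed with
  shrinking windows, so their focal values are noisier than interior sites
  and call rates there are inflated. These end artifacts appear identically
  in matched normals and are symmetric in direction, so criterion 3 and the
  asymmetry test remove them; cohorts analyzed without normals should treat
  regions at chromosome termini with caution.
* Nearest-peak bootstrap matching can latch onto a neighboring stronger
  peak when two recurrent regions sit within a window of each other,
  widening the weaker peak's CI.
* Multi-platform cohorts should be processed per platform and the region
  tables compared; no cross-platform merging rule is provided.
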