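---
title: "Methods: quantitative CFTR theratyping with theratype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative CFTR theratyping with theratype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(theratype)
```

## Scope

`theratype` implements the quantitative analysis layer of a CFTR modulator
theratyping study: given molecular-dynamics trajectory output, allele-specific
qPCR CT values, Ussing-chamber short-circuit current recordings, time-lapse
ciliary imaging and Western blot densities from patient-derived airway
epithelial models, it produces the per-genotype summaries on which a
responder/non-responder call is based. It does not run simulations, design
primers, clamp voltages or segment gel images: each module starts from the
measurement its upstream instrument already exports.

This vignette records the models and the design decisions behind each module
— including the places where the underlying conventions were genuinely open
and a choice had to be made.

## Trajectory contact occupancy

CFTR gating requires ATP + Mg²⁺ bound at the NBD1/NBD2 interface. Two scalar
distances summarise binding-site integrity along a trajectory:

* **λ** — backbone amide nitrogen of residue 551 to the ATP γ-phosphate
  phosphorus; contact threshold 5 Å.
* **Σ** — α-carbon of residue 1291 to the Mg²⁺ ion; contact threshold 7 Å.

For a replicate $r$ with distances $d_{r,1}, \dots, d_{r,n_r}$, the occupancy
at threshold $\tau$ is $\frac{1}{n_r}\#\{i : d_{r,i} < \tau\}$, and the pooled
occupancy over replicates is frame-weighted,
$\sum_r \#\{d_{r,i} < \tau\} \big/ \sum_r n_r$ — the fraction *of the
simulation data* in contact, not the mean of per-replicate fractions. Both
are reported; the pooled value is canonical.

Decisions worth knowing:

* **Atom choices.** "Amide nitrogen of residue 551" is read as the backbone
  amide N (glycine at that position has no side-chain amide); the
  γ-phosphate is represented by its phosphorus atom; residue 1291 by its Cα.
  The Cα reading is used even though a side-chain atom would also be a
  defensible proxy for side-chain–ion contact: Cα is the only definition
  that stays well-defined across mutations at that position (Q/R/H side
  chains differ in length), at the cost of a ~2 Å offset from the
  coordinating atom. Users wanting a side-chain definition can supply their
  own `contact_metric()`.
* **Ties.** A frame exactly at the threshold is *not* in contact (strict
  `<`). With continuous distances this is measure-zero; it matters only for
  hand-built test data.
* **Mean ± SD.** `summarize_distances()` reports the mean and *sample* SD
  over all pooled frames; per-replicate means are also emitted because the
  pooled-frames and across-replicates conventions genuinely differ for
  unequal-length replicates, and published tables rarely say which they
  used. Neither convention is asserted against any published value.
* **Statistics are frame-based, not time-weighted**; when no frame times are
  given they default to 0, 1, 2, … ns. No frame interval is assumed beyond
  ordering.
* **Input formats.** Multi-model PDB (`MODEL`/`ENDMDL`, via bio3d) and plain
  tabular CSV (`time_ns, distance_angstrom, replicate_id, metric`). Binary
  trajectory formats are deliberately out of core: exporting distances or
  frames is a one-liner in any MD toolchain, and keeping the core tabular
  makes every statistic independently checkable.

## Allele-specific transcript quantification

Relative abundance follows the ΔΔCT convention with amplification
efficiency 2:

$$\Delta C_T = \overline{C_T}^{\text{target}} - \overline{C_T}^{\text{ref}},
\qquad
FC = 2^{-(\Delta C_T - \overline{\Delta C_T}^{\text{calibrators}})}$$

Per-allele percentages of total transcript are
$100 \cdot FC_i / (FC_a + FC_b)$. Assuming both alleles are transcribed
50:50, the fraction of the splicing-defective allele's transcript lost to
missplicing-driven degradation is estimated from the steady-state asymmetry:

$$\%\,\text{degradation} = \frac{Y - X}{Y} \times 100,$$

with $X$ the observed percent from the splicing-defective allele and $Y$ the
percent from the intact allele.

Decisions: technical replicates are combined by the arithmetic CT mean with
no outlier rejection; a non-detect replicate is dropped from the mean and a
fully non-detect target is an error, never an imputed CT of 40; calibrator
samples are named explicitly (they are a study design fact, not something to
infer from the data); amplification efficiency is configurable per assay but
defaults to perfect doubling; and negative degradation estimates ($X > Y$)
are returned as-is with a flag — they falsify the 50:50 transcription
assumption and hiding them by clamping would mask exactly the cases a user
must see.

## Ussing-chamber analysis

A recording is segmented by its compound-addition schedule (amiloride →
potentiator or vehicle → forskolin → CFTRinh-172 → ATP). For each addition,
the pre-addition plateau is the **median** Isc over a trailing window
(default 30 s) ending at the addition, and the post-response plateau is the
median over the window ending at the *next* addition — responses are read
as late as the protocol allows, because transition shape is not modelled.
The response is the signed plateau difference.

Total CFTR-activated current for a condition is cumulative:
$\Delta I_{sc}(\text{potentiator}) + \Delta I_{sc}(\text{forskolin})$ when
ivacaftor was added acutely, and the forskolin response alone for the
vehicle condition — which is also the definition of baseline activity
($\Delta I_{sc\text{-Fsk}}$). Fold change is total/baseline; the
above-baseline increment is total − baseline. The additive definition is
used even when the acute potentiator response is negative; whether a
published "cumulative" total should instead floor the potentiator term at
zero is not decidable from conventions alone, so the arithmetic one is
implemented and stated here.

The median was chosen over the mean as the plateau estimator because
acquisition glitches (solution changes, bubble artefacts) are spiky;
proprietary acquisition software does not document its own averaging, so no
claim of equivalence is made.

Drift: by default no detrending is applied (the protocol's 30-minute
stabilisation is the experimental control for drift). `segment_trace(...,
detrend = "linear")` estimates a linear baseline on the pre-stimulus
stabilisation segment and subtracts it; with a known additive drift this
removes a bias that accumulates across the inter-event interval (at
0.001 µA·cm⁻²·s⁻¹ over a 120 s interval, ~0.12 µA/cm², i.e. several percent
of a small CF-range forskolin response). The recovery test-suite enables it
for drifting traces; analyses of stable recordings need not.

TEER maturity uses the inclusive range 188–1250 Ω·cm² as a QC flag.
Reported folds and increments are rounded to 2 decimals; full precision is
kept internally.

## Ciliary beat frequency

Each pixel's intensity series is mean-detrended, Hann-windowed, zero-padded
to the next power of two and discrete-Fourier-transformed; the field
spectrum is the mean per-pixel power spectrum, and CBF is the frequency of
its highest peak within the search band. Averaging *power* after the
transform (rather than averaging pixels first) keeps the estimate robust to
phase differences between cilia — neighbouring cilia beat metachronously,
and pooling before the transform would let opposite phases cancel.
Near-static pixels (temporal variance below 10⁻¹² of the maximum) are
excluded as background. The default search band, 0.5–30 Hz, is deliberately
wider than the physiological plausibility range (3.0–11.1 Hz): the
physiological range is a QC *flag* applied at aggregation, not a hard
filter, so an implausible dominant peak is surfaced rather than silently
forced in-range. Zero-padding fixes the bin width at
`frame_rate / 2^⌈log₂ n⌉`, which is reported alongside every estimate;
the estimator is accurate to about one bin.

Aggregation is hierarchical: fields → culture mean → mean ± SEM across
cultures (and across participants per genotype in study reports), matching
the replicate structure of the experiment. SEM with $n = 1$ is reported as
`NA`, never 0.

## Blot densitometry

Mature CFTR (band C) is quantified as a ratio of ratios against the
wild-type lane:

$$\%\,\text{of WT} = 100 \cdot
\frac{C_{\text{sample}} / L_{\text{sample}}}
     {C_{\text{WT}} / L_{\text{WT}}}$$

with $C$ the band C density and $L$ the loading-control (calnexin) density.
This cancels per-lane exposure exactly, and cancels unequal protein loading
provided the control scales with loading — which is the property that
justifies loading different amounts per genotype to avoid saturation.
Loaded µg is therefore carried as metadata only; dividing it out *as well*
would double-correct. Technical blots are normalised per blot, then
averaged.

## Synthetic data: what it emulates, and what it does not

Every stage has a seeded generator that writes the same formats the readers
accept and returns a machine-readable truth record:

* **Trajectory** — a two-state (contact/disrupted) Markov switching process
  with Gaussian within-state distances. The default switching scale of 1
  frame makes successive frames independent draws at the stationary
  occupancy, so the empirical occupancy carries plain binomial error
  ($3\sqrt{p(1-p)/n}$ brackets the estimate); this is the regime in which
  occupancy recovery is tested. Real trajectories instead show long
  correlated episodes — disruption once and for all after hundreds of ns —
  which the `switch_scale` parameter can emulate, at the cost of an
  occupancy standard error inflated by the dwell length; recovering
  occupancy from such data to binomial precision is not possible and is not
  claimed.
* **qPCR** — CT = base − log₂(quantity) + Gaussian noise, triplicates per
  target, calibrators at an undegraded 50:50 mixture. The closed-form round
  trip (degradation $d$ in, $100d$ out at 50:50 transcription) is exact
  without noise.
* **Ussing** — piecewise plateaus joined by exponential transitions
  (τ = 10 s), 120 s between additions (≈12 τ, so responses settle well
  inside each interval), 2 Hz sampling, optional linear drift and Gaussian
  noise. Real traces additionally contain non-exponential transients,
  transient peaks that relax (notably after ATP) and mechanical artefacts,
  none of which are modelled — passing recovery tests shows the plateau
  logic is right, not that artefact robustness has been demonstrated.
* **CBF** — per-pixel sinusoids at one common frequency with random phases,
  static background pixels and additive Gaussian noise. Real fields contain
  multiple patches at different frequencies and broadband motion; the
  generator validates the single-dominant-peak estimator only.
* **Blot** — band density = level × load × exposure, control density =
  load × exposure × (1 + noise), which encodes exactly the
  proportional-control assumption the normalisation relies on.

Generators never touch the caller's RNG stream, and identical seed + config
gives byte-identical output.

## Problem sizes and numerical choices

The test-suites run at sizes chosen to make statistical tolerances
meaningful while keeping the whole suite fast on a laptop: occupancy
recovery at 10⁴–10⁵ frames, CT-table recovery over 100 seeds, forskolin
recovery over 50 seeded traces (~1 700 samples each), CBF recovery on
6 × 6 × 400-frame stacks over 120 runs, and the packaged demo study at
2 000 frames per trajectory replicate. Distances, currents and intensities
are plain doubles throughout; no tolerance tighter than the quantities'
reporting precision is asserted anywhere.

## Known limitations

* Atom selectors must resolve to exactly one atom per model; altLoc
  handling and heavy-atom heuristics are out of scope.
* The ΔΔCT layer assumes the configured amplification efficiency is right;
  no standard-curve fitting is provided.
* `cftr_activity()` needs an explicit baseline; it does not search a batch
  of traces for the vehicle condition.
* The CBF estimator reports one dominant frequency per field; multimodal
  fields are summarised by their strongest component.
* Inferential statistics (normality tests, ANOVA, multiple-comparison
  corrections) are deliberately left to standard tools downstream; the
  package reports descriptively (mean ± SEM).
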