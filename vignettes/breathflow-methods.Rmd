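---
title: "Methods: from raw breath traces to multilevel statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw breath traces to multilevel statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathflow)
```

breathflow implements the analysis chain of an online PTR-ToF-MS breath
campaign with repeated measures: 1 Hz instrument traces are segmented into
exhalations by a CO2 trigger, the end-tidal fraction of each breath is
averaged, ion counts are normalized and converted to concentrations, a
blank-based detection limit filters the ion panel, and repeated-measures
multivariate and univariate statistics quantify exercise- and
medication-related changes. This vignette documents the model, its
assumptions, the tunable parameters, and the design choices made where
more than one defensible implementation exists.

## End-tidal extraction

A breath sampler monitors the CO2 concentration of the exhaled air; the
late, alveolar ("end-tidal") fraction of an exhalation is the part that
best reflects blood-borne volatiles and is identified by CO2 >= 4%. The
trigger detector fires at the first tick at which CO2 crosses the
threshold from below and re-arms only after CO2 falls back under it, so a
noisy plateau cannot fire twice within one exhalation
(`detect_triggers()`).

Extraction (`extract_end_tidal()`) averages the ion signal over the window
starting `delay_s = 5` s after the trigger and lasting `window_s = 5` s.
At the instrument's one spectrum per second this is exactly five spectra
per breath sample. A window that runs past the end of the exhalation (CO2
drops below threshold inside it) or past the end of the recording is
flagged `short_exhalation` and excluded rather than shortened: every
retained sample must average the same fraction of the breath, otherwise
samples would not be comparable across participants. Exhalations last a
minimum of about 20 s in this protocol, so a 10 s delay-plus-window fits
comfortably.

Each participant gives two breath samples per session. `pair_duplicates()`
takes the first two unflagged samples as replicates 1 and 2; a session
with fewer usable samples is flagged `missing_replicate` (one sample) or
dropped (none). Downstream statistics use the mean of the duplicate
concentrations per participant-timepoint as the analysis unit — the
protocol does not prescribe how duplicates are merged, and the mean avoids
pseudo-replication while using both measurements.

Carryover QC (`flag_carryover()`): compounds such as ethanol and
monoterpenes linger in sampling lines. A sample is flagged when the
room-air signal of a watched ion just before its exhalation exceeds
`factor = 3` times the session's catalyzed-air background median *and*
exceeds it by at least `min_excess_cps = 5` counts. The absolute floor
exists because a x3 rule alone fires on Poisson counting fluctuations
around a ~2 cps background.

## Replicate agreement: Lin's concordance

Duplicate agreement is summarized by Lin's concordance correlation
coefficient,

$$ R_c = \frac{2 S_{YX}}{(\bar Y - \bar X)^2 + S_Y^2 + S_X^2}, $$

with covariance and variances computed with the population divisor $n$
(Lin's original definition; the coefficient is scale-consistent either way
provided one divisor is used throughout). $R_c$ penalizes both scatter and
location/scale shift, hence $|R_c| \le |r|$ (Pearson). Bands: excellent
above 0.9, satisfactory 0.6-0.9, unsatisfactory below 0.6.

`replicate_concordance()` computes $R_c$ per participant across the
stacked ion-concentration vectors of the duplicate pairs. Two choices are
deliberate and switchable: the comparison is per participant (not per
ion), which matches how a single below-threshold participant can be
reported, and it uses log concentrations so that the most abundant ions do
not dominate the agreement measure. Whether the original analysis used raw
counts, normalized counts or concentrations is not documented; log
concentrations are the package default (`log_scale = FALSE` reverts to
linear scale).

## Quantification

Product-ion counts are normalized to the primary-ion (H3O+) signal,
monitored through its oxygen-18 isotopologues at m/z 21.02 (x500) and
39.03 (x250):

$$ \mathrm{ncps} = \mathrm{cps} \times 10^6 / (500\,I_{21} + 250\,I_{39}), $$

i.e. counts per $10^6$ primary ions (the conventional normalization
target; only the isotope multipliers are instrument-specified).

Concentrations follow first-order proton-transfer kinetics: the VOC
number density is $I_{\mathrm{product}} / (I_{\mathrm{H_3O^+}}\, k\, t)$,
converted to ppbv with the drift-tube gas number density $N = p/(k_B T)$
at 2.6 mbar and 60 degC. The generic rate coefficient is
$k = 2\times10^{-9}$ cm$^3$/s, with experimentally known overrides for
methanol, acetone and isoprene in the default ion table. Two quantities
the instrument description omits are configuration inputs with defaults
chosen to be consistent with the printed operating point: the reaction
(residence) time `reaction_time_s = 1e-4` s, typical for this drift
geometry, and the drift length `drift_length_m = 0.0885` m, obtained by
inverting the definition of the reduced field so that 600 V / 2.6 mbar /
60 degC give E/N = 120 Td. `compute_reduced_field()` recomputes E/N from
the configuration and warns when it strays more than 5% from 120 Td, so
an inconsistent configuration is caught rather than silently propagated.

**Limit of detection.** The LoD is computed from catalyzed-air background
segments on the concentration scale as blank mean + 3 sd. Blank-based
guidelines admit 3 or 3.3 sigma-over-slope variants; with direct kinetic
quantification there is no calibration slope, so the plain 3-sigma form is
used and the multiplier is exposed (`k_sigma`). Values strictly below the
LoD are replaced by the LoD itself (keeping the matrix positive for the
log transform); values exactly at the LoD are untouched. An ion is
retained only if strictly more than 50% of samples exceed its LoD within
*each* study group separately — "more than" is read as a strict
inequality, and the filter is evaluated on all individual samples, not on
replicate means. Raising any LoD can only shrink the retained set
(monotonicity, tested).

## Ion identification

Formulas are assigned by accurate mass: `theoretical_mz()` computes the
monoisotopic mass of a protonated ion minus one electron mass, and
`match_formula()` ranks candidates by ppm error (default tolerance 200
ppm, matching a resolving power of 4000-5000). Related ions — fragments
and hydrate clusters — co-vary almost perfectly across samples;
`correlate_ions()` links two ions when their squared Pearson correlation
reaches 0.85 and reports connected components as clusters. Connected
components are the simplest reading of a correlation "cut-off"; complete
linkage at the same threshold would be stricter and can split genuine
fragment families. Correlation is computed on log concentrations across
all samples, consistent with the pipeline's transform (the original choice
of scale is undocumented). Exogenous channels (monoterpene, estragole)
carry an `exogenous` annotation; they remain in the quantification but can
be dropped from exercise models via `preprocess(drop_exogenous = TRUE)`.

## Multilevel models

With repeated measures per participant, most variance is between-subject
offset that is irrelevant to within-person change. `multilevel_split()`
decomposes the centered log matrix exactly into a between part (subject
mean rows) and a within part (deviations); each participant's baseline
acts as their own control. M-PCA (`mpca()`) is SVD-based PCA of the within
part. M-PLS-DA (`mplsda()`) fits PLS2 on the within part against the
column-centered one-hot class matrix using the iterative NIPALS sequence:

* initialization from the dummy column of maximal variance (deterministic),
* convergence tolerance 1e-12 on the weight vector, at most 1000
  iterations,
* X-only deflation (standard PLS2; Y deflation is algebraically inert for
  the scores because score vectors are mutually orthogonal, but deflation
  variants change VIP slightly, so the choice is fixed and documented).

Variable importance is
$\mathrm{VIP}_j = \sqrt{p \sum_a SS_a (w_{aj}/\|w_a\|)^2 / \sum_a SS_a}$
with $SS_a$ the Y-variance explained by component $a$; the mean square VIP
is 1 by construction, and ions with VIP > 1 are the model-selected
compounds. Score plots use 2 latent variables; VIP is reported at the
model's fitted number of components (selectable, at most 5 is sensible
here). The implementation reproduces the scores, VIP values and within
matrix of the reference mixOmics implementation to numerical precision
(verified in the test suite; mixOmics is used only as a cross-check, never
as the implementation).

**Cross-validation** (`cross_validate()`): 5-fold with 10 repetitions,
but folds partition *subjects*, never samples — all repeated measures of
one participant stay in one fold, otherwise the within-subject split leaks
the test subjects' means into training. Held-out subjects' within-parts
use their own subject means (computable because whole subjects are held
out), training column means are reapplied to the test block, and samples
are classified by the maximal predicted dummy response. The error metric
is the balanced error rate because the group sizes (24/17/21) are unequal.
A partition that leaves a class out of a training split is redrawn and
logged.

**Model selection rule.** Each study group gets its own
baseline-vs-post models, and the selected compound set is the union of
VIP > 1 ions over the per-group models (mirroring how per-group model
selections are combined in a Venn-style summary). The union matters:
inside the non-statin group the SCFA ions carry both the common exercise
response and the group-specific boost, and since VIP has mean square 1,
their dominance arithmetically pushes the remaining responsive ions just
below the VIP = 1 line in that one model; the statin-group models, where
effects are comparable across ions, select them reliably.

## Univariate follow-up

Normality is tested with the Lilliefors statistic (Kolmogorov-Smirnov
distance to a normal with estimated moments). Because the moments are
estimated, the null distribution is simulated: the p-value uses 10^4
Monte Carlo draws by default. The branch rule follows the pipeline:
normal data go to one-way ANOVA with Tukey's HSD, non-normal data to the
tie-corrected Kruskal-Wallis test. "Kruskal-Wallis followed by Tukey's
post hoc" is an unusual pairing in print; it is implemented the way common
statistical software behaves after a Kruskal-Wallis fit — Tukey-Kramer
comparisons on the group mean ranks against the studentized-range
distribution — with Dunn's z-tests plus Holm adjustment available as an
alternative (`method = "dunn-holm"`). An exact permutation p-value is
available for total n <= 10. Significance is at alpha = 0.05 per test
without multiplicity adjustment across ions, matching how raw p-values
are reported in this field. Group-difference tests can pool all
post-walking timepoints or run per timepoint — the original description is
ambiguous, so both modes are reachable by subsetting.

The SCFA cluster (acetic + propanoic + butanoic acid) is summarized as the
per-sample sum of the three parent ions, with group-by-timepoint mean and
standard error. The relative-change heat-map
(`relative_change_matrix()`) shows, per compound, cell medians centered on
the non-statin baseline cell and divided by the range of the centered
medians: every row has unit range and the reference cell sits at 0 (range
scaling to an anchored unit interval; the original figure states only
"range scaled").

## The synthetic study generator

No raw campaign data are deposited, so `simulate_study()` generates
sessions with the statistical structure the analysis assumes, plus ground
truth for recovery testing. Study conditions mirror the campaign: 62
participants (24 non-statin St0, 17 statin St1, 21 statin-with-complaints
St2), five timepoints (Day0 baseline, post-walking Day1/Day2/Day3,
pre-walking Day2am), duplicate samples.

* **Trace shape.** Each session opens with 30 s of catalyzed-air
  background, then one exhalation per replicate separated by 8 s room-air
  flushes. CO2 is trapezoidal: 2 s rise, 16 s plateau drawn uniformly
  from 4.5-5.4%, 2 s fall — so the plateau always holds the 5+5 s
  extraction window (a spec with a window longer than the plateau is
  rejected: the extraction rule would be undefined on such traces).
* **Signal model.** During the breath plateau each ion's expected cps is
  exactly the concentration divided by the configured ppbv-per-ncps
  factor (the quantification chain inverted), making
  generation-to-quantification an identity in the noiseless case — the
  basis of the round-trip tests. Room-air and background phases sit at the
  catalyzed-air level (~2 cps). Noise is multiplicative lognormal
  technical noise per replicate (`noise_cv = 0.10`) plus Poisson counting
  noise per one-second tick — counts stay non-negative and the log
  transform stays defined.
* **Effects (log scale).** Between-subject SD 0.4 (typical for breath
  VOC panels). All nine identified endogenous compounds rise +0.5 after
  the first walking day, relax to +0.1 by the next pre-walking morning
  and rise +0.4 after days 2 and 3 (equal by design, so those two days'
  profiles overlap); isoprene carries the mirrored pattern (its breath
  dynamics run opposite to the rest of the panel). SCFAs additionally
  get +0.5 post-walking in St0 and +0.2 at the pre-walking morning in the
  statin groups. Ethanol/monoterpene outliers (alcohol, food) hit ~5% of
  post-walking sessions at +2.5 log units.
* **Panel.** Fragments are generated in-instrument as fixed fractions of
  their parent's signal (so correlation clustering has real structure to
  find), and the panel includes 19 common non-responsive endogenous
  breath VOCs alongside the responsive nine: real untargeted retention
  keeps tens of ions that do not respond to the studied stimulus, and a
  VIP selection is only meaningful against such a background (with
  mean-square-1 VIPs, a panel where nearly every ion responds cannot
  place most of them above 1). One trace channel at m/z 131.07 is
  designed to sit below the LoD so the retention filter has designed
  structure: the default retained count is the designed above-LoD panel
  (34 ions).

Everything is deterministic given the design seed; identical seeds give
byte-identical fixture files.

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show: real breath humidity effects on primary-ion
chemistry, drift of instrument sensitivity over a field day, correlated
(panel-wide) between-subject physiology, diet-driven covariance between
compounds, exhalation-flow variability, and mass-spectral interferences
between nominally separated peaks. Recovery results demonstrate that the
pipeline's inference machinery finds designed effects of realistic size
under realistic counting statistics; they are not evidence about effect
sizes in real cohorts.

## Problem sizes and numerical choices

The test suite and recovery checks run the full 62-participant,
5-timepoint, duplicate design (310 sessions, ~28k spectra, 37 channels)
once, and replicate the group-contrast power check over 12 regenerated
studies of the same size; unit oracles use small matrices where hand
enumeration is possible. Monte Carlo sizes: 10^4 draws for Lilliefors
p-values in analyses (smaller in calibration loops, which average over
many repetitions), 10^4 replicates for the Kruskal-Wallis type-I check.
Degenerate inputs are handled explicitly rather than numerically:
constant replicate vectors make Lin's Rc undefined (error), constant ion
columns become singleton clusters (logged), a fully tied Kruskal-Wallis
sample reports H = 0 and p = 1, zero-variance within matrices abort
M-PCA, and zero-range rows of the relative-change matrix are flagged
rather than divided by zero. Ties in the NIPALS initialization (equal
dummy-column variances in a balanced two-class fit) resolve to the first
column, keeping fits reproducible.

## Known limitations

* Quantification accuracy is bounded by the generic k = 2e-9 assumption
  for most compounds — concentrations for those ions are best treated as
  relative; SCFAs in particular are quantified kinetically precisely
  because calibration standards are difficult at these volatilities.
* The kinetic conversion needs the reaction time and drift length, which
  are configuration inputs, not measured; E/N consistency is checked but
  absolute ppbv scales inherit any error in t.
* Per-participant Lin's Rc mixes ions across very different concentration
  scales even after the log transform; a participant with one discordant
  high-variance ion can still score well.
* VIP > 1 is a relative criterion: it identifies ions that contribute
  more than average to a given model and therefore depends on the whole
  retained panel, not only on the ion itself (see the model selection
  rule above).
* The univariate battery reports raw per-test p-values; with dozens of
  retained ions an FDR step would be appropriate for discovery-style use.
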