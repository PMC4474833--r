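---
title: "Measuring proteome turnover and tRNA dynamics with isoturn"
author: "isoturn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring proteome turnover and tRNA dynamics with isoturn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoturn)
```

## The kinetic model

When an exponentially growing bacterial culture is switched from light
(^14^N) to heavy (^15^N) medium at time $t_0$, every protein made after the
switch carries heavy nitrogen, while the pre-existing light pool decays as
it is diluted and degraded.  For a protein whose total abundance is at
steady state, degradation and synthesis rates coincide
($k_{deg} = k_{syn}$), and the light fraction decays exponentially:

$$N_{14}(t) = \left[N_{14}(t) + N_{15}(t)\right] e^{-k_{syn}(t - t_0)}.$$

Mass spectrometry measures the light/heavy ratio
$R = N_{14}/N_{15}$ per peptide, and the steady-state relation rearranges to

$$1 + \frac{1}{R} = e^{k_{syn}(t - t_0)}, \qquad
  Y \equiv \ln\!\left(1 + \frac{1}{R}\right) = k_{syn}\,(t - t_0).$$

$Y$ is linear in labeling time with slope $k_{syn}$, so an ordinary
least-squares fit of $Y$ on $t$ per protein yields the synthesis rate
constant, and the half-life of the pre-existing pool is
$T = \ln 2 / k_{syn}$.  This is exactly what `turnover_fit()` does,
returning a classed model object with the usual `coef`, `predict`,
`residuals`, `plot` and `simulate` methods.

Two deliberate deviations from the naive formulation:

* **Free intercept by default.**  The strict model passes through the
  origin, but a lag between the medium switch and full precursor-pool
  exchange shifts all $Y$ values by a constant.  A free intercept absorbs
  this without biasing the slope; `through_origin = TRUE` restores the
  strict form.
* **Censoring.**  A slope whose half-life exceeds 500 minutes, or whose
  correlation is not significant at $P \le 0.05$ (two-sided $t$-test of
  the Pearson correlation on $n - 2$ degrees of freedom), cannot be
  distinguished from "no turnover within the labeling window".  Such
  estimates are flagged `censored`, are excluded from mean half-life
  summaries by default, and are entered at the 500-minute cap in
  distribution comparisons and histograms.  Ratios reported as missing by
  quantification are dropped, never imputed.

The proteome-level trend (`proteome_trend()`) aggregates the per-protein
ratio at each timepoint with the median (robust to the long abundance
tail; switchable to the mean) and tests the aggregate against time.  Note
that $R(t)$ is convex, so even a perfect cohort has a linear correlation
somewhat above $-1$.

## Dual-isotope peptide chemistry

Quantifying $R$ requires knowing where both forms of a peptide appear in
MS1.  The chemistry layer provides:

* `digest()` — full tryptic specificity (cleavage after K/R, suppressed
  before proline by convention; the suppression is a switch because
  annotation practice varies), up to 2 missed cleavages.
* `composition_and_mass()` — residue-composition sums with fixed
  carbamidomethyl-C and variable oxidized-M, under both labels.  Every
  nitrogen contributes `n15_mass_shift()` = 0.9970349 Da extra under the
  heavy label, so the heavy-light mass gap counts nitrogens exactly.
* `isotope_envelope()` — the isotopologue distribution, computed by
  convolving per-element isotope abundance vectors.  C, H, O and S use
  natural abundances aggregated on the nominal-mass grid with
  intensity-weighted exact masses; nitrogen is kept separate, binomial in
  the number of heavy atoms: natural 0.364% under ^14^N, and the
  incorporation fraction (default 0.99, matching effectively complete
  metabolic labeling) under ^15^N.  Keeping nitrogen separate preserves
  the binomial fine structure a partially labeled peptide actually has.
  Peaks below a relative intensity of $10^{-3}$ are truncated (and not
  renormalized, so the retained area is visible); the pre-truncation
  distribution sums to 1 within $10^{-9}$.
* `build_dual_db()` / `candidate_lookup()` — a mass-sorted index over both
  labels supporting 10-ppm precursor windows, mirroring how a search
  engine selects candidates.  Charge states 1–4 are considered.
* `quantify_ratio()` — integrates the union of scan peaks matched by
  either envelope (within ±10 ppm per predicted peak, the same tolerance
  as the precursor window) across the retention window and reports
  $R = \mathrm{area}(^{14}\mathrm{N}) / \mathrm{area}(^{15}\mathrm{N})$.
  The union matters: fine-structure species closer than the tolerance
  must not be counted once per predicted peak.  When the heavy area falls
  below a floor the ratio is returned as missing with a reason; whether
  areas are summed over all scans or taken at the apex scan is
  configurable (`granularity`), since either convention is defensible for
  chromatogram-level areas.

Fragment-ion scoring and decoy-based FDR control are intentionally out of
scope: identification is assumed to arrive as a table, and this package
supplies the dual-isotope mass/envelope/ratio layer around it.

## tRNA sequencing

Mature tRNAs are heavily modified, and reverse transcription misreads
modified positions, so ordinary alignment undercounts exactly the species
the analysis cares about.  `align_read()` therefore runs a semi-global
dynamic-programming alignment — the read must be explained end to end,
both reference ends are free — in which reference positions listed in a
modification mask match any read base at zero cost.  All edit operations
cost one error; a read is accepted with at most 3 errors and at least 25
aligned bases.  Semi-global rather than strictly local alignment is
deliberate: a local aligner could evade the error cap by clipping
mismatches off the read ends, and the 3′ offset (bases of the reference
missing from the read's 3′ end) would be ill-defined.  A strictly local
mode remains available for comparison.  Ties between references are
broken deterministically: fewest errors, then longest alignment, then
lexicographically smallest species id.

Counting and normalization follow the spike-in design: a synthetic
CCA-ended RNA, at least 3 nt away from every cellular tRNA, is added in
known amount before library preparation and aligned like any reference.
Per-species counts divided by the spike-in count are comparable across
conditions; the per-species fold decrease is the ratio of normalized
counts, and the cohort mean is reported both as the mean of per-species
ratios and as the ratio of normalized totals (the two differ when
abundance shifts are not uniform, so both are shown).  3′-truncation
profiles histogram the 3′ offset (0–10) per species; for the few species
with tandem CCACCA ends, the offset-3 fraction isolates loss of one CCA
unit.

## Growth curves and qPCR

Optical density follows Beer–Lambert, $OD = \log_{10}(I_{blank}/I)$;
growth-rate constants are OLS slopes of $\ln OD$ versus time inside an
explicit window (or an automatic maximal-$R^2$ sliding window — a
convenience, since window choice is rarely reported), with a negative
constant read as net death.  Group comparisons use the two-tailed Student
$t$-test (pooled variance by default, Welch behind a flag), reporting
`NaN` with a reason on degenerate input.  The ΔΔCt convention here is
*reference minus target*, so larger ΔCt means more target and a negative
ΔΔCt means the target decreased under stress — the reverse of the most
common textbook convention; it is kept because spike-in-referenced ΔCt
tables are naturally read this way.  Fold change is $2^{\Delta\Delta Ct}$
and is invariant to any constant shift of all Ct values.

## What the generators emulate — and what they do not

Every analysis input can be synthesized with known truth
(`simulate_turnover()`, `simulate_ms1()`, `simulate_trna_reads()`,
`simulate_growth()`, `simulate_ct_table()`), and truth tables always
accompany the data so tests never re-derive ground truth.  The important
default choices, fixed once:

* **k~syn~ distribution**: log-normal, `meanlog = log(0.007)` per minute,
  `sdlog = 0.3` — a median half-life of ~99 minutes, the scale of an
  exponentially growing bacterial proteome.  Labeling timepoints default
  to 15/30/60/90 minutes; ratio noise is multiplicative log-normal with
  CV 0.1 and mean 1 (ratios are positive and MS ratio error is
  multiplicative, so this keeps $R > 0$ and leaves it unbiased).
* **Oxidative condition**: every k~syn~ is multiplied by 0.05, pushing
  nearly all half-lives beyond the 500-minute censoring cap — the
  qualitative regime of a stress that shuts down synthesis.
* **tRNA libraries**: 47 random tRNA-like references (74–93 nt, CCA ends,
  a few CCACCA), per-species abundances log-normal (`sdlog = 0.5`), reads
  3′-anchored because reverse transcription primes at the polyadenylated
  3′-CCA, truncations applied at the template 3′ end, substitution errors
  at 0.5% per base and 15% at modified positions (reverse-transcription
  misreading; the rate is configurable since no measured value exists).
  The spike-in (the published transcript sequence) is emitted at its
  expected depth — its input amount is known and equal across conditions,
  so at the scaled-down library sizes used for validation an extra
  Poisson draw on the normalizer would only inject common-mode noise that
  tests nothing about the pipeline; at realistic depths (millions of
  reads) the distinction is immaterial.  The spike-in fraction (5%) is a
  free experimental choice the protocol does not pin down.
* **MS1 scans**: Gaussian elution over 21 scans, label areas in the exact
  requested ratio, additive baseline-subtracted peak noise (left
  unclipped so integration stays unbiased) plus a few random background
  peaks.

What the generators deliberately do **not** emulate: chimeric and adapter
reads, position-dependent sequencing quality, RT fall-off gradients,
chromatographic co-elution and interference between different peptides,
ionization suppression, or protein-level summarization from multiple
peptides.  Passing the recovery suites therefore demonstrates that the
estimators invert the data-generating model they assume — including under
realistic counting and measurement noise — not that the model captures
every artifact of real instruments.

## Numerical choices

* Problem sizes in the validation suite: 500-protein cohorts for kinetics,
  1000 read/reference pairs for aligner/oracle equivalence, $10^5$-read
  libraries per condition for fold-change recovery — sizes at which the
  binomial/Poisson sampling error of each recovered quantity is several
  times smaller than the tolerance asserted on it.
* The aligner's batch driver orders references by a gapless upper bound on
  the error count and abandons a dynamic program as soon as a row minimum
  exceeds the best error count so far; this changes running time only,
  never results.
* Envelope convolution keeps at most 60 nominal isotopologue bins —
  binomial tails beyond that are below $10^{-40}$ for peptide-sized
  compositions — so the unit-sum invariant holds to $10^{-9}$.
* Ties in the alignment traceback prefer diagonal moves and the rightmost
  reference end, so equal-cost alignments resolve to the least-truncated
  interpretation reproducibly.
* `half_life_stats()` counts a protein as "below 100 min" only when
  uncensored, and censored proteins enter distribution comparisons at the
  cap, matching how censored values are plotted.

## Known limitations

* The steady-state assumption ($k_{deg} = k_{syn}$) is taken as given; no
  dilution-by-growth correction is applied, and non-steady-state
  proteomes are out of scope.
* Multi-mapped tRNA reads are assigned winner-takes-all; fractional
  assignment between near-identical isodecoders is not attempted, so
  counts for such pairs should be interpreted jointly.
* The constant-CV ratio noise model understates the error of very large
  ratios (heavy signal near the detection floor), where real measurements
  are dominated by the denominator's noise; censoring absorbs most of the
  consequence, but significance of near-zero slopes is optimistic in
  simulation compared with real data.
* PCR efficiency correction is not implemented; ΔΔCt assumes perfect
  doubling.
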