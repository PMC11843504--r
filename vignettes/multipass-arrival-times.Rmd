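---
title: "Multipass arrival times: model, extraction, correction and annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipass arrival times: model, extraction, correction and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclim)
```

## The multipass model

On a cyclic traveling-wave mobility device an ion's arrival time after
completing $n$ cycles is

$$t_n = t_0 + n\,t_p,$$

with $t_0$ the zero-pass arrival time (transit through the entry/exit optics
and the uncompleted part of the track, measured directly at a 0.01 ms
separation time, where no ion completes a cycle) and $t_p$ the periodic
drift time — the cycle time, characteristic of the ion's mobility. The model
is assumed exact for well-behaved ions; everything in this package either
exploits that linearity or quantifies departures from it.

Three experimental facts shape the design:

* $t_0$ is measured with much lower variance than $t_p$ (short travel
  distance), so the directly measured $t_0$ — not the fitted intercept — is
  the canonical value stored downstream. `fit_mobility()` reports both.
* The cycle time may differ slightly between the first pass and later
  passes, so $t_p$ is taken as the least-squares *slope* of $t_n$ against
  $n$ over at least 5 passes, never from a single pass difference.
* Between sessions (days, room temperatures, instruments, wave heights)
  $t_p$ and $t_0$ each drift along their own affine map; a linear
  correction fitted on co-measured calibrants aligns them.

## Pass assignment through wrap-around

At separation time $T$ the instrument ejects whatever is inside the
acquisition window, so the observed peaks mix pass numbers once faster ions
overtake slower ones ("wrap-around"). Given a compound's measured $t_0$,
`assign_pass_numbers()` infers the pass of each matched arrival $t$ as
$n = \operatorname{round}((t - t_0)/\hat t_p)$, iterating assignment and
line refit to a fixed point (at most 50 rounds; ties in rounding break
toward the lower pass, so an ion is never credited with a cycle it may not
have completed). Observations whose residual to the converged line exceeds
3 robust standard deviations (MAD) are flagged unassigned rather than
discarded silently.

The initial $\hat t_p$ deserves a note. Seeding with the lowest-separation
observation as "pass 1" fails in the common case where the first matched
peak at low separation times is the zero-pass peak itself ($t \approx t_0$).
The implementation instead seeds with the smallest gap $t - t_0$ exceeding
`min_tp` (default 2 ms, comfortably below the 5–30 ms range of plausible
single-pass drift times in this regime). The seed only needs to be within
~50% of the truth for the first rounding to be mostly right; the refit loop
does the rest. If the true pass-1 peak were never detected (e.g. a detection
threshold removing all low passes), the seed could lock onto a multiple of
$t_p$; the r² and residual diagnostics expose such fits, but the assignment
does not attempt to repair them.

Compounds with bimodal or asymmetrically broadened arrival distributions
(protomers, conformer tails) violate the single-line model and are not
deconvolved; a dispersion heuristic (within-pass relative spread > 1%, or
r² < 0.99) flags the fit `poor_fit`. Fits using fewer than 5 distinct
passes are flagged `low_pass_count`.

## Tolerances and defaults

| Parameter | Default | Where it acts | Rationale |
|---|---|---|---|
| `mz_ppm_match` | 10 ppm (inclusive) | matching peaks to reference compounds during extraction | standard-mixture matching window; most intense peak wins on multiple hits |
| `mz_ppm_annotate` | 20 ppm (inclusive) | database search of query features | wider, because query spectra come from a different (possibly uncalibrated) session |
| `mz_da_screen` | 0.005 Da (strict `<`) | screening feature lists against an m/z catalogue | absolute window used against structure-database m/z lists |
| `residual_threshold` | 0.7% (strict `>`) | class screening of post-correction residuals | features above it likely follow a different class's correction line |
| `window` | 26.4 ms | acquisition window (simulator; bin conversion) | instrument ejection-and-acquisition time |
| `n_bins` | 200 | drift bins spanning the window | bin width 26.4/200 = 0.132 ms |
| `zero_pass_time` | 0.01 ms | which acquisition yields $t_0$ | no ion completes a cycle in 0.01 ms |
| `n_max` | 10 | passes reconstructed in database entries | covers separation times up to ~150 ms for lipid-like cycle times |

ppm errors are computed relative to the *reference* (theoretical) m/z — the
usual database-search convention; at these tolerances the alternative
(observed-m/z denominator) differs by far less than the window granularity.
Relative arrival-time errors and MREs always use the *reference* value as
denominator. The m/z windows are inclusive ("within 10/20 ppm") while the
Da screen and the residual screen are strict, matching how the thresholds
are stated in their respective protocols.

## Correction lines

`fit_correction_line()` fits `reference = slope × measured + intercept` by
ordinary least squares — unweighted, because calibrant sets are small (5–6)
and plain linear fits with r² are the established practice. Separate lines
are fitted for $t_p$, $t_0$ and $t_n$; the three quantities are never
pooled. The direction convention (measured session → reference session /
database) makes annotation a single forward application of the line.

Lipids behave slightly differently under the traveling wave than other
compound classes, so correcting lipid analytes with nonlipid calibrants is
discouraged but not forbidden: the API warns when class tags show a
mismatch. After correction, features whose residual exceeds the screening
threshold are flagged out-of-class, and `group_self_correction()` fits a
fresh line within the flagged group — a much lower within-group MRE
supports the interpretation that those features follow their own class
line.

## The database and single-measurement annotation

A database entry stores species, adduct, m/z, corrected $t_0$ and $t_p$,
and the reconstructed $t_1 \dots t_{10}$, serialised as plain CSV with a
comment header (schema version, polarity, pass range) so it can be
exchanged between laboratories in transparent units. The defining invariant
$t_n = t_0 + n t_p$ is revalidated on every load (tolerance $10^{-9}$ ms).

Annotation of a query feature $(m/z, t)$ proceeds in two stages: entries
within the ppm window are candidates; within each candidate the pass is the
$n$ minimising the *absolute* distance $|t - t_n|$ (nearest reconstructed
arrival time, ties to the lower pass); candidates are then ranked by the
*relative* error $100\,|t - t_n|/t_n$. The two metrics are deliberate:
nearest-$t_n$ mirrors how a pass number is read off a database, while
percent error is the scale on which all arrival-time comparisons are
reported. Queries beyond the reconstructed pass range are refused rather
than extrapolated unless `extrapolate = TRUE` — the linear law would permit
it, but an explicit flag keeps silent extrapolation out of reports.

The single-measurement workflow (`run_annotate()`) corrects query arrival
times before the search: calibrant features co-measured with the queries
are located in the database, their pass numbers determined by nearest-$t_n$
search, a $t_n$ correction line fitted from measured to database values,
and all query times mapped through it. With a ~3% session drift this is the
difference between resolving isomers ~1 ms apart at pass 9 and
mis-annotating them.

For workflows built on three measurements instead of a database,
`three_point_tp()` implements $n = (t_n - t_0)/(t_1 - t_0)$ rounded to the
nearest integer and $t_p = (t_n - t_0)/n$, reporting $|n_{raw} - n|$ as a
consistency diagnostic.

## The simulator

`simulate_series()` is the ground-truth oracle for every other module. Its
acquisition model is a stated simplification: at separation time $T$ a
compound with session values $(t_0', t_p')$ emits one peak per pass $n$
with $0 \le (t_0' + n t_p') - T \le \text{window}$. The true ejection
geometry of a cyclic instrument (which passes are observable at a given
separation time) is more intricate; the window model reproduces the two
features the method actually depends on — wrap-around interleaving of pass
numbers and the multi-pass coverage of the separation-time schedule — and
nothing downstream uses more than that.

Design choices, each mirroring how variation is reported in practice:

* **Drift** acts as affine maps on $t_0$ and $t_p$ (not on raw $t_n$),
  because each quantity follows its own linear correction line between
  sessions. An optional class-specific second map emulates class-dependent
  behaviour for screening tests.
* **Noise** is multiplicative Gaussian on arrival times (variation is
  CV-like; intraday levels are ~0.1%).
* **Intensity** decays geometrically with pass number (default 0.7×/pass
  with a floor), so a detection threshold reproduces the loss of weak
  compounds at high passes.
* **Seeds** are mandatory arguments of every stochastic call; there is no
  hidden RNG state, and the caller's `.Random.seed` is restored afterwards.

The default compound generator draws cycle times uniform in 10–14 ms and
zero-pass times in 5–8 ms — the regime of protonated/sodiated lipid adducts
on a ~1 m cyclic track — with m/z spread over 436–786. The default
separation-time schedule is 0.01 ms plus the ladder 1–20 ms (step 1),
20–40 ms (step 2), 40–100 ms (step 5) and 100–150 ms (step 10): 48
acquisitions.

What passing simulator-based tests shows — and what it does not: the tests
demonstrate that extraction, correction and annotation are exact on data
that obey the linear model and degrade gracefully under the stated noise
and drift; they cannot certify behaviour on real spectra, whose peak
shapes, detector saturation, chimeric peaks and class-dependent wave
physics the simulator deliberately omits.

## Numerical choices

* Rounding ties in pass assignment and pass estimation break toward the
  lower pass, everywhere, so repeated runs cannot flip between passes on
  exact midpoints.
* Per-pass means enter the slope fit when a pass is observed at several
  separation times, so heavily re-observed passes do not dominate the
  least-squares fit.
* r² is computed directly from residual and total sums of squares (exact
  fits yield exactly 1, without the numerical-noise warnings of
  `summary.lm`).
* Series tables are serialised with 17 significant digits so a write/read
  cycle restores doubles bit-identically.
* Degenerate inputs fail loudly: fewer than 2 calibrant pairs, all-equal
  measured values, fewer than 2 distinct passes, empty catalogues, and
  zero-parsable-row files are errors; an empty annotation result is not.

## Validation problem sizes

The test suite validates extraction on series of 2–8 compounds over the
48-point schedule (200 replicates for the noise-recovery property),
correction on 12–20 compounds with 5 calibrants, and annotation against
randomized databases of up to 50 entries (100 instances against a
brute-force oracle). The two-session experiment reported by
`scripts/acceptance.R` uses 20 compounds, 5 calibrants and 15 analytes.

## Known limitations

* No deconvolution of bimodal or asymmetric arrival distributions; such
  compounds are flagged, not resolved.
* No collision-cross-section calibration: $t_p$ is the terminal quantity.
* Corrections are strictly affine; thermal or pressure excursions large
  enough to bend the relation would need a richer model.
* The simulator's window model is a simplification of the real ejection
  geometry (see above).
* Database versioning policy when entries are re-measured is left to the
  user; provenance fields record lineage but no merge logic is imposed.
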