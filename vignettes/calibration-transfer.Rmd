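---
title: "Stability-based wavelength selection for NIR calibration transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-based wavelength selection for NIR calibration transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A PLS calibration `y = Xb + e` built on one NIR spectrometer (the *master*)
usually predicts poorly from spectra of the same samples measured on a
second instrument or under a changed condition (the *slave*): baseline
drift, wavelength shift, gain differences and band-local peak-shape changes
move the slave spectra out of the master model's input distribution.
Calibration transfer repairs this either by mapping slave spectra into
master space (PDS, SST), by removing y-irrelevant structure before modeling
(OSC), or by linearly recalibrating the predictions themselves (SBC).

All of these work wavelength-by-wavelength or on the full spectrum, and all
inherit a weakness: wavelengths whose master/slave relationship is
*inconsistent* poison the mapping. The selection method at the heart of
this package scores each wavelength by the joint Monte-Carlo stability of
the two instruments' regression coefficients and keeps only wavelengths
that behave reproducibly on both sides.

## The stability index and its threshold

K paired subsamples of the calibration set are drawn (fraction `rate`,
without replacement; the *same* subset is applied to master and slave in
each draw, because the datasets are physically paired). Each draw yields a
master coefficient vector and a slave coefficient vector. For wavelength i,
with draws indexed by j,

\[
|c_i| \;=\;
\frac{\left|\bar a_i \cdot \bar b_i\right|}
     {\mathrm{sd}_j(a_{ij}) \cdot \mathrm{sd}_j(b_{ij})},
\]

standard deviations with denominator K−1. Both a large mean contribution
and a small sampling spread are required *on both instruments* for a large
index. Wavelengths with `|c_i| > T` are retained (strict inequality).
`sd = 0` with a nonzero mean product gives `+Inf` (always selected);
`sd = 0` with a zero mean gives 0.

The threshold T lives in `[min |c|, max |c|]`, extremes taken over the
finite values. A 20-bit chromosome decodes linearly onto that interval, and
a small elitist GA (population 50, 100 generations, one-point crossover
with probability 0.8, mutation probability 0.1, roulette selection with a
uniform fallback when a generation scores all zero) maximizes

\[ F = \frac{R^2}{1 + \mathrm{RMSEV}}, \]

where R² and RMSEV are measured by rebuilding the *entire* transfer path on
the candidate selection — master PLS with deterministic contiguous-block
cross-validation, the named transfer fitted on the calibration standards,
the slave validation set transferred and predicted. The threshold is
therefore transfer-specific: each transfer algorithm gets its own GA run
and its own `T_best`.

Two implementation notes. First, thresholds map many-to-one onto
selections (at most p+1 distinct selections exist), so fitness is cached on
the induced selection; this makes the full-size GA cheap without changing
its semantics. Second, mutation is per-chromosome (probability `p_mut` of
flipping one uniformly chosen bit); a per-bit mode is available
(`ga_config(mutation = "per-bit")`).

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `K` (MC iterations) | 1000 | Stable coefficient means/sds; tests use 100 (see below). |
| `rate` | 0.8 | Subsets of 80 % keep fits well-conditioned yet variable. |
| PLS latent-variable cap | 15 | Conventional ceiling for full NIR spectra; chosen count = argmin RMSECV, ties downward. |
| PDS `window` | 9 points | Local neighbourhoods wide enough for small shifts; local PLS with up to `min(3, window)` components, full-rank case computed as minimum-norm least squares via SVD. |
| SST `n_factors` | `"auto"` | Scans 1..min(15, rank), keeps the count minimizing validation RMSE. |
| OSC components | 1 | One y-orthogonal direction; more risks removing signal. |
| SBC | — | Pure slope/bias OLS on predicted standards. |
| Outlier screening | leverage > 3 × mean, \|studentized residual\| > t(0.975) | Conventional chemometrics cutoffs. |
| SNV | sample sd (n−1) | Stated because either convention appears in the wild. |
| Savitzky–Golay | window 21, order 2 | Order unstated in common practice descriptions; 2 is the usual choice, configurable. Edges use one-sided polynomial fits so no columns are trimmed and master/slave indices stay aligned (selection indices must be shareable). |
| GA | pop 50, 20 bits, 100 gens, pc 0.8, pm 0.1, elitist | Standard small-GA settings; a 20-generation stagnation stop is added (disable with `stagnation = Inf`). |

R² is the coefficient of determination on the evaluated set
(`1 − SSres/SStot`); squared Pearson correlation is available as a
sensitivity check (`r2_method = "pearson2"`). X is mean-centered only
before PLS — SNV already row-normalizes, and column autoscaling would
distort derivative spectra.

## The synthetic world

`synth_spec()`/`generate_pair()` emulate paired measurements: Gaussian-band
mixture spectra tied to a latent property through component concentrations,
an instrument-specific polynomial baseline, global wavelength shift (2 nm,
by linear interpolation onto the shared axis) and gain (1.05) on the slave,
white measurement noise on both instruments, and *unstable bands*. Default
components are plateau-like (three overlapping Gaussians each) so that
stability is roughly uniform inside a band and a threshold acts on whole
bands, as it does for real absorption bands.

The unstable bands deserve an explanation, because the obvious
implementation does nothing. A perturbation field added *identically to
every sample* is a constant column offset, and mean-centering inside PLS
removes it exactly: it can neither destabilize coefficients nor damage
transfer. What does reproduce the observed failure mode — a band that looks
trustworthy on the master but ruins transferred predictions — is a
*sample-dependent* distortion on the slave side only: each sample's slave
spectrum sees the band through its own random gain (sd 0.30 of unity),
plus a small fixed random profile modulated by per-sample amplitudes. No
fixed linear slave-to-master map can invert a per-sample gain, so PDS/SST
fitted on standards cannot learn the band away; meanwhile the slave model's
coefficients there fluctuate across Monte-Carlo draws, which is exactly
what the stability index detects. One default band sits on top of component
2's core (genuine signal, so the full-spectrum master model *wants* it —
its clean tails keep the chemical information recoverable after exclusion)
and one sits in empty baseline.

What the generator does **not** emulate: nonlinear detector response,
wavelength-dependent noise, scatter that SNV cannot remove, and any real
instrument pair's drift structure. A green planted-band test therefore
establishes that the algorithm rejects *this* kind of inconsistency, not
that it reproduces any particular instrument pair's numbers.

The planted-band acceptance test runs on raw generated spectra, not on SNV:
in this simple mixture world SNV's row-normalization turns flat baseline
stretches into surrogate carriers of total-intensity information and
inverts the stability ranking; real NIR spectra have no such empty regions.
That test's scales are: K = 100 (desk-scaled from 1000; the index is a
ratio of means to sds and stabilizes far earlier than 1000 draws),
latent-variable cap 8 for the 200-wavelength world, splits 60/30/30 of 120
samples (a 30-sample validation set gives the GA a resolvable objective),
GA at its full default settings. Selection-quality fractions are assessed
as means over the 20 replicates; the RMSEP comparison is counted per seed
(≥16/20). A per-seed coverage bound would over-ask: when a band is
redundant, a validation-optimal threshold legitimately keeps only a
spanning subset on some draws.

## Numerical choices

* **PLS** is SIMPLS (for one response identical to NIPALS PLS1, verified
  against an independent implementation to 1e−6), with a second
  orthogonalization pass against accumulated loadings to suppress drift,
  and explicit rank-collapse errors.
* **Contiguous-block CV** partitions samples in order into 10 blocks (sizes
  differing by at most one) and is bit-reproducible; the random scheme
  shuffles under a caller-supplied seed. `folds > n` is an error.
* **SPXY** ranks all samples by the Kennard–Stone rule on the joint
  distance `d_x/max d_x + d_y/max d_y`; calibration = first `n_cal` ranked,
  validation = restarted ranking on the remainder, prediction = the rest.
  Ties are broken by first index; on continuous data they have probability
  zero.
* **Degenerate inputs**: constant rows are an SNV error naming the row;
  constant reference values make R² an error rather than NaN; empty
  GA selections score fitness 0, and an empty final selection is an error.
* **Infinite stability values** sort above any threshold and are excluded
  from the decoding range, so they are always selected and never stretch
  the search interval.

## Limitations

* The GA fitness surface is a step function of T with at most p+1 levels;
  with small validation sets its maximizer can wobble between adjacent
  selections. Elitism plus the stagnation stop make runs reproducible under
  a fixed seed, not seed-free.
* SiPLS is exhaustive (`C(n_intervals, n_joint)` evaluations) and guarded
  by a combination cap rather than a heuristic search.
* The MAT container reader covers the public corn benchmark's layout
  (numeric arrays, zlib-compressed elements, struct/object `data` fields);
  it is not a general `.mat` implementation.
* Transfer standards default to the whole calibration set; subsampling
  standards (e.g. by SPXY) is left to the caller.
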