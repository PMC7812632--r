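---
title: "Inter-brain connectivity for two-person hyperscanning EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-brain connectivity for two-person hyperscanning EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperlink)
```

## The problem

Hyperscanning experiments record brain activity from two interacting people
simultaneously and ask whether, where and how their signals co-vary. The
analysis object is therefore not one channel-by-channel connectivity matrix
but a *joint* one: with N channels per participant, a (2N x 2N) matrix whose
two diagonal N x N blocks are the ordinary within-person (intra-brain)
connectivities and whose two off-diagonal blocks are the between-person
(inter-brain) connectivities. For non-directional metrics the two
inter-brain blocks are exact transposes of each other; for directed metrics
(partial directed coherence, transfer entropy) they differ, and that
difference is the point.

`hyperlink` implements this pipeline end to end: epoch containers with dyad
merge/split semantics, cross-participant artifact rejection, analytic-signal
band decomposition, ten connectivity metrics, non-parametric permutation
statistics with space-frequency cluster correction, topographic link
rendering, and a synthetic dyad generator with known ground truth used to
validate all of it.

## Signal model and band decomposition

All frequency-domain metrics are computed from the band-limited *analytic
signal* rather than from cross-spectral densities. Phase locking between two
people is intrinsically non-stationary — instantaneous frequency wanders —
and the Hilbert-transform phase representation does not assume stationarity
the way spectral-density phase estimates do.

`computeFreqBands()` decomposes each epoch into one complex series per
*integer* frequency f inside each requested band (closed interval; the
default table is Theta 4-7, Alpha_Low 7.5-11, Alpha_High 11.5-13, Beta
13.5-29.5, Gamma 30-48 Hz, so Alpha_Low yields the 8, 9, 10, 11 Hz bins).
Each bin applies a zero-phase band-pass of 1 Hz passband with 0.5 Hz
raised-cosine transitions. The filter and the Hilbert transform are applied
jointly in the frequency domain: the epoch is reflection-padded (half the
epoch length on each side), Fourier-transformed, multiplied by the band mask
with the negative-frequency half set to zero — which *is* the
analytic-signal construction — and transformed back. This is mathematically
a linear-phase FIR response; designing the same response as a time-domain
tap sequence would need a filter longer than a typical epoch (a 0.5 Hz
transition needs on the order of 6.6 x sfreq taps), which is why the
spectral form is used. Each epoch is processed on its own; there is no
cross-epoch concatenation.

Two practical consequences are worth knowing:

* The effective impulse response of a 1 Hz-wide filter spans about a second.
  With 2 s epochs a sizable fraction of each epoch carries edge response;
  phase metrics between *identically driven* channels are immune to this
  (the distortion is common), but a constant *lag* between the channels
  interacts with the reflection at the edges and attenuates recovered
  locking. Validation fixtures that assert near-perfect recovery use 16 s
  epochs for this reason.
* A narrow-band signal whose linewidth exceeds the 1 Hz bin bandwidth loses
  part of its phase dynamics to the filter. This attenuates, but never
  inverts, coupling estimates.

`welchPsd()` complements this with a standard Welch spectrum (Hann window,
50% overlap, per-segment mean detrend, one-sided V^2/Hz scaling). The
segment length should span at least four periods of the lowest frequency of
interest (`minSegmentLength()`); a shorter segment triggers a warning, not
an error.

## The metrics

For analytic series \(x(t) = a_x(t) e^{i\phi_x(t)}\) at one frequency bin:

* **plv** \(= |\langle e^{i(\phi_x - \phi_y)} \rangle_t|\): constancy of the
  phase relation, offset-invariant.
* **pli** \(= |\langle \mathrm{sign}\sin(\phi_x - \phi_y) \rangle_t|\):
  asymmetry of the relative-phase distribution; blind to zero-lag coupling.
* **ccorr**: circular correlation in the sine-deviation form
  \(\sum \sin(\phi_x - \bar\phi_x)\sin(\phi_y - \bar\phi_y) / \sqrt{\cdots}\)
  with circular means. A literal Pearson correlation on wrapped angles is
  available behind `ccorrMethod = "pearson"`, but it is discontinuous at
  \(\pm\pi\) and not the default.
* **coh** \(= |\langle x \bar y\rangle|^2 / (\langle|x|^2\rangle
  \langle|y|^2\rangle)\) and **imaginary_coh** \(= |\mathrm{Im}\,
  \langle x \bar y\rangle / \sqrt{\cdots}|\), which discards zero-lag
  (volume-conduction-like) dependence.
* **envelope_corr** / **pow_corr**: Pearson correlation of \(|x|\), \(|y|\)
  (or their squares) over time.
* **proj_pow_corr**: envelope correlation after per-sample orthogonalization
  \(y_\perp = \mathrm{Im}(y\,\bar x/|x|)\), removing the component of y
  parallel to x in the complex plane; the two orthogonalization directions
  are averaged because the one-sided value is direction-dependent.
* **pdc**: classic column-normalized partial directed coherence from a
  least-squares MVAR fit,
  \(\pi_{ij}(f) = |\bar A_{ij}(f)| / \sqrt{\sum_k |\bar A_{kj}(f)|^2}\);
  every column of squares sums to one.
* **transfer_entropy**: the Gaussian (linear) estimator, half the Granger
  log-ratio of restricted to full residual variances; non-negative by
  construction (nested least squares).

Epoch aggregation: phase metrics are computed over time within each epoch
and averaged across epochs (or kept per epoch with
`epochsAverage = FALSE`); coherency-family expectations run jointly over
samples and epochs; band values are unweighted means over the band's bins.
In directed matrices, cell (i, j) carries the influence of channel j on
channel i (column = source), matching the PDC normalization.

Directed metrics are fit on the band-limited *real* signal (the real part of
the summed per-bin analytic series). MVAR models fitted to very narrow-band
signals are ill-conditioned — the spectrum is nearly singular — so direction
recovery should use a broad band (e.g. 2-40 Hz) and a model order that can
absorb the filter's coloring; the validation suite uses order 6 on the
broadband fixture. The transfer-entropy lag defaults to 1 and should
likewise be raised (3-5) on filtered data, where the noise is strongly
autocorrelated.

## Standardization

The joint matrix is often reduced to one standardized block before
thresholding and display: `standardize()` zeroes the diagonal and then
z-scores all N^2 cells by the grand mean and grand (population) standard
deviation, zeroed diagonal included. The output has grand mean 0 and grand
SD 1 by construction, and is invariant under positive rescaling of the
input. It is *not* invariant under additive shifts: the zeroed diagonal
anchors the scale, so shifting the off-diagonal cells changes the result.
This matches the procedure as used in the field; treat the output as a
display/threshold scale, not as an effect-size estimate.

## Statistics

`permTtestFdr()` is the per-cell route: a one-sample t statistic (e.g. on
within-dyad condition differences) with sign-flip permutation p-values
(exact enumeration when 2^n does not exceed the requested permutation
count) and a Benjamini-Hochberg mask. Zero-variance cells are excluded from
the FDR family rather than silently producing NaN.

`statsCluster()` is the familywise route: independent/paired t or one-way F
per cell, a cluster-forming threshold equal to the parametric critical value
at alpha (overridable with a raw statistic value), connected components
under a supplied adjacency, cluster mass = sum of statistics, and a null
distribution of the maximum |mass| under label permutation (sign flips for
the paired test). P-values use the (1 + exceedances)/(1 + permutations)
convention, so they are never zero. With `tail = 0`, positive and negative
clusters form separately and are compared on |mass|. Multi-way ANOVA
clustering is declared out of scope and rejected explicitly.

Adjacency comes from `conMatrix()`: sensors are projected to 2-D by an
azimuthal equidistant projection and triangulated (Delaunay by the
empty-circumcircle property, computed by direct enumeration — sensor counts
are small enough that no geometry library is needed); a plain distance
threshold is available as an alternative rule. The channel graph is expanded
across F frequency bins so that (c, f) neighbors (c', f) for neighboring
channels and (c, f±1) for adjacent bins. For inter-brain matrices,
`interCellAdjacency()` implements the two-ends rule: cells (i, j) and
(k, l) are adjacent when each end is identical or a scalp neighbor on its
own head.

Dyad-level null hypotheses use `permuteDyads()`: epoch-order shuffling
within true pairs (destroys across-participant alignment, preserves each
participant's statistics), derangement-based fake pairs within a group, or
fake pairs across groups.

## Visualization

`render2dInter()` produces a deterministic figure description — two
projected head outlines, sensor points (crosses for bad channels), and one
arched 10th-order Bezier polyline per suprathreshold link, red colormap for
positive and blue for negative values, line width linear in |value| — that
`plot()` renders with ggplot2. Keeping the description as a first-class
object makes the rendering contract testable: the link count in the figure
equals the suprathreshold cell count by construction. The Bezier's interior
control points interpolate the endpoints and are displaced perpendicular to
the chord by a sine arch (peak a quarter of the chord length, canonical
upward side), so swapping the endpoints yields the same curve reversed.

## The synthetic dyad generator

`simulateCoupledDyad()` is the package's test bed and demo data. Its model:

* Phase: a wrapped-Gaussian random walk around the carrier,
  \(\phi(t+1) = \phi(t) + 2\pi f_c/f_s + \mathcal N(0, \sigma^2)\). The
  default \(\sigma = 0.3\) rad/sample gives a Lorentzian linewidth of about
  1 Hz at 128 Hz sampling — a realistic resting-alpha width, and wide
  enough that uncoupled phases decorrelate within a 2 s epoch.
* Coupling: participant 2's coupled channel blends participant 1's lagged
  phase against an independent walk by phasor interpolation,
  \(\phi_2 = \mathrm{Arg}\,[\kappa e^{i(\phi_1 + \mathrm{lag})} +
  (1-\kappa) e^{i\phi_{\mathrm{ind}}}]\); \(\kappa = 1\) reproduces the
  lagged phase exactly, \(\kappa = 0\) is fully independent, and the
  recovered PLV/ccorr/coherence are monotone in \(\kappa\).
* Envelope: exponentiated smoothed Gaussian modulation
  (\(e^{0.2 z}\), AR(0.97)-smoothed, unit variance), correlated across the
  dyad with coefficient `rhoEnv` at coupled pairs.
* Noise: white Gaussian at `noiseSd` times the clean RMS (default 0.1);
  amplitudes are on a 10 microvolt scale; the montage is a spiral layout on
  the upper head surface.
* Seeding: one master seed spawns a substream per (participant, epoch), so
  extending the epoch count leaves earlier epochs bit-identical.

`simulateDirectedDyad()` drives a resonant AR(2) oscillation at the carrier
through a one-sample-lagged linear coupling into the partner's target
channel, for exercising PDC and transfer entropy with a known direction.

What the generator does *not* emulate: volume conduction and shared
reference (which create zero-lag intra-brain dependence), 1/f background
(available as an option but off by default), eye/muscle artifacts, and
inter-individual montage differences. Passing the validation suite
therefore shows the estimators are correct on their own terms, not that
every real-data confound is handled; imaginary coherence and the projected
power correlation exist precisely because some of those confounds require
zero-lag-insensitive metrics.

## Numerical choices and validation sizes

Small denominators are guarded, never silently NaN: bounded ratios
(coherence family, PDC) use a 1e-300 floor that only prevents 0/0,
correlations on degenerate inputs raise errors in the scalar API and return
flagged zeros inside matrix assembly, and `projPowCorr()` returns 0 with a
`degenerate` attribute when orthogonalization removes everything.
Non-directional matrices are symmetrized exactly ((M + t(M))/2) to keep the
documented block identity bit-true against floating-point drift.

The validation suite's problem sizes were chosen to make Monte-Carlo
tolerances meaningful while keeping the whole suite around a minute: null
calibration of the cluster test uses 500 simulations of 10-cell maps at
1000 permutations (observed type-I error near 0.04 at nominal 0.05), power
fixtures use 30 seeded reruns, metric nulls use 200 replicates, and
simulate-and-recover fixtures use 1e4 samples. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch at any
seed.

## Known limitations

* No ICA and no learned per-channel rejection thresholds: artifact marking
  is a single global peak-to-peak rule (default 150 microvolts), and bad
  channels are dropped, not interpolated. The cross-participant
  *intersection* rule — keep only epochs and channels good for everyone —
  is the part this package treats as essential.
* FIF files are refused (no backend); EDF support is 16-bit and drops
  positions, bad-channel labels and the drop log. The columnar text dialect
  is the full-fidelity interchange format.
* Wavelet coherence, cross-frequency coupling, lagged connectivity, source
  reconstruction, groups larger than two, and multi-way ANOVA clustering
  are out of scope.
* Directed estimates on narrow single bins are unreliable by nature; use a
  broad band, as above.
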