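# hyperlink

Inter-brain connectivity analysis for two-person ("hyperscanning") EEG, in
R. Hyperscanning experiments record two interacting people at once; the
analysis object is the joint connectivity matrix over both participants'
channels. With N channels per person this is a (2N x 2N) matrix of four
N x N blocks — two intra-brain blocks on the diagonal, two inter-brain
blocks off it. Non-directional metrics make the inter-brain blocks exact
transposes of each other; directed metrics (partial directed coherence,
transfer entropy) make them differ, and that asymmetry carries the
direction of influence.

The package is aimed at social/cognitive neuroscientists who have epoched
two-participant EEG and want a validated, scriptable route from raw epochs
to thresholded inter-brain links:

* **Containers & I/O** — `EpochArray` / `HyperEpochArray` S4 classes,
  `mergeDyad()` / `splitDyad()` with `"_1"`/`"_2"` channel suffixes, a
  bit-exact columnar text format and minimal EDF support
  (`readEpochs()` / `writeEpochs()`).
* **Preprocessing** — peak-to-peak artifact marking
  (`markBadEpochsPtp()`) and the cross-participant intersection rule
  (`intersectGood()`): only epochs and channels good for *every*
  participant are kept.
* **Spectral** — Welch PSD (`welchPsd()`, with the four-periods segment
  rule `minSegmentLength()`) and analytic-signal decomposition into
  integer-Hz bins per band (`computeFreqBands()`), computed per epoch via
  zero-phase 1 Hz band masks with the negative frequencies removed.
* **Connectivity** — `computeSync()` assembles the joint matrix for ten
  metrics: `coh`, `imaginary_coh`, `plv`, `pli`, `ccorr` (circular
  correlation), `envelope_corr`, `pow_corr`, `proj_pow_corr`
  (orthogonalized), `pdc` and `transfer_entropy` (Gaussian estimator).
  `sliceBlocks()` yields the four blocks; `standardize()` applies the
  zero-diagonal grand z-score used for thresholding.
* **Statistics** — sign-flip permutation t-tests with FDR
  (`permTtestFdr()`), cluster-based permutation tests with
  space-frequency adjacency (`statsCluster()`, `conMatrix()`,
  `interCellAdjacency()`), and surrogate-dyad schemes
  (`permuteDyads()`: time shuffling, fake pairs within/between groups).
* **Visualization** — two-head topographic link plots with 10th-order
  Bezier links (`render2dInter()`, `plot()`), significant-sensor maps
  (`plotSignificantSensors()`).
* **Synthetic dyads** — `simulateCoupledDyad()` /
  `simulateDirectedDyad()` generate epoched narrow-band oscillations with
  controllable phase coupling strength, lag, envelope correlation and
  noise, reproducible from a single seed. They are first-class, tested
  code and the basis of the validation suite.

Key quantities, in the field's notation: the phase-locking value
`PLV = |<exp(i(phi_x - phi_y))>|`, the phase lag index
`PLI = |<sign sin(phi_x - phi_y)>|`, circular correlation on sine
deviations from circular means, coherence `|S_xy|^2 / (S_xx S_yy)` from
analytic cross-products, PDC `|A_ij(f)| / sqrt(sum_k |A_kj(f)|^2)` from a
least-squares MVAR fit, and Gaussian transfer entropy
`TE = 1/2 ln(Var(y_t | y_past) / Var(y_t | y_past, x_past))`.

## Worked example

Simulate a dyad with two planted inter-brain couplings (participant 1
channel 1 with participant 2 channel 2, and 3 with 5), then recover them:

```r
library(hyperlink)

cfg <- dyadSimConfig(nEpochs = 20, nChannels = 8, kappa = 0.9, lag = pi/4,
                     coupledPairs = rbind(c(1, 2), c(3, 5)), seed = 7)
dyad <- simulateCoupledDyad(cfg)
dyad[[1]]
#> EpochArray 'S1': 20 epochs x 8 channels x 256 samples @ 128 Hz

clean <- intersectGood(dyad)                       # cross-participant rule
analytic <- computeFreqBands(clean$epochs, list(Alpha_Low = c(7.5, 11)))
C <- computeSync(analytic, "plv")
C
#> ConnectivityMatrix 'plv': 1 x 16 x 16 (N = 8 per participant)
#>   bands: Alpha_Low

blocks <- sliceBlocks(C, band = "Alpha_Low")
round(blocks$inter12[1:4, 1:6], 2)
#>      [,1] [,2] [,3] [,4] [,5] [,6]
#> [1,] 0.49 0.82 0.52 0.48 0.46 0.50
#> [2,] 0.49 0.48 0.47 0.49 0.48 0.46
#> [3,] 0.42 0.46 0.51 0.51 0.83 0.51
#> [4,] 0.43 0.49 0.49 0.50 0.46 0.43

Z <- standardize(blocks$inter12)                   # zero diag, grand z-score
extractLinks(Z, threshold = 2)@links
#>   i j    value rendered
#> 1 1 2 2.291104     TRUE
#> 2 3 5 2.305497     TRUE

fig <- render2dInter(clean$epochs[[1]], clean$epochs[[2]], Z, threshold = 2)
fig
#> InterBrainFigure: 16 sensors, 2 link path(s)
plot(fig)   # draws the two heads and the two suprathreshold links
```

The PLV at the planted pairs (about 0.83 at coupling strength 0.9) stands
out of the background (about 0.48, the null level for 2 s epochs of 1
Hz-linewidth alpha), and exactly the two planted links cross the z = 2
threshold. Against uniform-phase nulls the background PLV would be near
zero; narrow-band signals in short epochs have an elevated null, which is
why thresholding operates on the standardized block and significance
testing uses surrogate dyads (`permuteDyads()`) or group permutation
(`statsCluster()`).

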