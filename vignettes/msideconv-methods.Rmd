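---
title: "Methods: per-pixel charge-state deconvolution for native protein MSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-pixel charge-state deconvolution for native protein MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MsiDeconv)
```

# The model

Native (non-denaturing) electrospray produces multiply charged protein
ions. A species of neutral mass $M$ observed at charge $z$ with a proton
adduct appears at

$$ m/z \;=\; \frac{M + z\,m_p}{z}, \qquad m_p = 1.00728\ \mathrm{Da}, $$

so one protein contributes a *series* of peaks, and peaks of different
proteins at different charges may overlap in $m/z$. Because native MSI is
typically acquired at resolving powers without isotopic resolution, charge
cannot be read from isotope spacing; it has to be *inferred* from the
consistency of the charge series. That inference, run independently on
every pixel of an imaging dataset with one shared parameter set, is what
this package implements.

## Charge assignment

For a preprocessed spectrum with axis $x_i$ and intensities $I_i$, every
data point is given a hypothesis mass per charge,
$M_{iz} = z\,(x_i - m_p)$ for $z \in [z_\min, z_\max]$, and a weight
matrix $W_{iz}$ — the probability that point $i$ belongs to charge $z$ —
initialised uniformly over the charges whose hypothesis mass falls inside
the configured output mass window (points with zero intensity keep zero
weight everywhere: no charge diffuses into the noise floor). Each of
`n_iter` iterations applies:

1. **Charge-smoothness filter.** A real species at mass $M_{iz}$ must also
   appear at neighbouring charges. For each $(i, z)$ the filter averages,
   over $z' \in [z - w, z + w]$ (clipped to the charge range), the
   intensity-weighted charge evidence $W_{\cdot z'} I_\cdot$ linearly
   interpolated at the position $\frac{M_{iz} + z' m_p}{z'}$ where that
   mass would sit at charge $z'$. The weights are multiplied by this
   smoothness score and renormalised per point (rows summing to zero stay
   zero). Because the interpolation positions depend only on the axis and
   the charge pair, the interpolation indices and weights are precomputed
   once — and reused across all pixels when the dataset shares one axis
   (continuous imzML), which is what makes a whole-image run cheap.

2. **Richardson–Lucy peak-width step** (when `peak_fwhm > 0`). The data
   are modelled as point intensities convolved with a known peak shape
   (Gaussian or Lorentzian of the configured FWHM). A per-point intensity
   estimate $B$ (initialised to $I$) is updated by the standard RL
   recursion $B \leftarrow B \cdot K^{T}\!\ast\!\big(I / (K \ast B)\big)$.
   The final mass-domain contribution of point $i$ at charge $z$ is
   $B_i W_{iz}$ — the same product an update that multiplied $W$ by the
   back-projected ratio would bin — but keeping the factor in $B$ leaves
   $W$ a proper per-point probability (rows sum to exactly 0 or 1), which
   is the invariant the `ChargeAssignment` class enforces.

3. **Binning.** $B_i W_{iz}$ is deposited at $M_{iz}$ onto the uniform
   grid `seq(mass_min, mass_max, by = mass_bin)`, split linearly between
   the two flanking bins. Linear splitting conserves intensity exactly:
   with `peak_fwhm = 0` ($B = I$) and a window covering all hypotheses,
   the mass-domain total equals the input total to machine precision
   (tested at 0.5%).

The engine contains no randomness: identical input and configuration give
bit-identical output, and pixels are processed independently, so permuting
input pixels permutes outputs identically (both properties are tested).

## Preprocessing

Per pixel: truncation to the analysis window `[mz_min, mz_max]` and, when
`background_width > 0`, subtraction of a centred rolling minimum of that
width (in Th), floored at zero. A rolling minimum removes a slowly varying
chemical background while clipping a peak apex by at most
(local slope) × (half window) — the sloped-baseline test asserts this
analytic bound. A window that excludes every point yields an *empty*
spectrum, which is a flagged, legal value that deconvolves to all-zero
output; it is not an error, because empty pixels are normal at tissue
edges.

# Parameters

| key | unit | default | rationale |
|---|---|---|---|
| `z_min`, `z_max` | — | 5, 30 | covers typical native protein charge states |
| `adduct_mass` | Da | 1.00728 | proton; all supported data are positive-mode cations |
| `mass_min`, `mass_max` | Da | 20,000–200,000 | intact proteins / small complexes |
| `mass_bin` | Da | 10 | matches ~10 Da reporting granularity of non-isotopic native MS |
| `n_iter` | — | 50 | charge assignment plateaus well before this on clean series |
| `charge_smooth_width` | charges | 1 | ±1 neighbour is the weakest filter that still kills harmonics |
| `peak_fwhm` | Th | 2 | set from the data in practice; 0 disables the RL step |
| `peak_shape` | — | gaussian | Orbitrap-like profiles; lorentzian available |
| `background_width` | Th | 0 (off) | background subtraction is data-dependent; opt-in |
| `mz_min`, `mz_max` | Th | 0–100,000 | no truncation unless asked |
| `mass_smooth_sigma` | Da | 0 (off) | cosmetic smoothing of the output grid |

One configuration applies to the *entire* dataset run — that is a design
constraint of the workflow, not a convenience: it keeps every pixel and
the dataset-summed spectrum on one grid, makes mass images comparable
across pixels, and is recorded into the HDF5 store with the results so
every image is traceable to one parameter set. The published
per-dataset settings of the original desktop tool are not reproduced here;
the defaults above are this package's own declared stand-ins, and every
one is exposed in the flat YAML config file.

# Image similarity and its caveat

Images are compared as flattened pixel vectors with cosine similarity,
reported in percent. The score is symmetric, scale-invariant, 100 exactly
for positive scalar multiples and 0 for disjoint support. By default *all*
pixels enter the comparison, zeros included, which reproduces a real
artefact: substrate ("empty slide") pixels are low-intensity and
near-identical at every m/z, so padding two genuinely different images
with more of them inflates the score toward 100% (a tested property).
The similarity report therefore prints the fraction of near-empty pixels
(total ion current below 1% of the maximum pixel), and an optional
`maskQuantile` argument excludes pixels below a total-intensity quantile
for the obvious mitigation. Whether to normalise or threshold images
before scoring is genuinely open; the default here is raw intensities with
no thresholding, with the mask as the single opt-in alternative. The
default flag cutoff for "same proteoform" is 80%, but — as the empty-slide
caveat shows — cutoffs should be established per experiment with positive
and negative control channels.

# The synthetic generator

`simulateMsiDataset()` emulates what the deconvolution needs to be tested
against: per pixel, each species contributes Gaussian m/z peaks at its
charge-state channels with areas proportional to a discretised, renormalised
Gaussian charge envelope (the standard bell shape of electrospray charge
distributions) times a spatial abundance pattern (uniform, half-plane,
disk, or gradient), plus additive Gaussian noise on a constant baseline,
floored at zero, under a mandatory seed. It does **not** simulate
desorption physics, ion transmission, detector response, Poisson counting
statistics, chemical background structure, or charge-reduction reaction
kinetics (`ptcrSeries()` models only the arithmetic of sequential proton
loss). Passing tests on synthetic data therefore demonstrate the
*algorithmic* properties — recovery, conservation, separation, image
closure — not robustness to every artefact of real tissue data, where
signal quality, not the algorithm, is the usual limiting factor.

# Numerical choices

- **Axis sampling in worked examples**: spectra are synthesised with at
  least ~8 points per peak FWHM (e.g. 0.05 Th steps for 1 Th peaks);
  coarser sampling aliases the binned mass peaks and biases refined
  apexes by a fraction of a bin.
- **Interpolation** in the smoothness filter is linear with zero outside
  the axis; at the self-charge ($z' = z$) it degenerates to the point's own
  evidence.
- **Apex refinement** in `peakPick()` is three-point parabolic; it is
  exact for a parabola and accurate to a small fraction of a bin for
  peaks a few bins wide. Ties between equal-height candidates resolve to
  the lower mass.
- **Convolution** uses direct short-kernel convolution (`stats::filter`)
  rather than FFT: kernels are tens of points, axes are thousands, and
  direct convolution is both faster and free of FFT length pathologies.
- **Kernels** are truncated at ±4σ (Gaussian) / ±8 FWHM (Lorentzian) and
  renormalised to unit sum.
- **Degenerate inputs**: all-zero spectra, empty analysis windows, and
  mass windows excluding every hypothesis all produce all-zero output
  (with a warning in the last case), never exceptions; truly contractual
  misuse (mass-domain input to the deconvolver, mismatched grids, empty
  datasets) raises classed errors that the CLI maps to exit codes.

# File-format decisions

- imzML is written with 64-bit axis values and 32-bit intensities: charge
  arithmetic is sensitive to axis precision, intensity is not.
- There is no controlled-vocabulary term for "this axis is mass, not
  m/z", so exported files carry an explicit `userParam` named
  `spectrum domain` on `<fileContent>`; files re-read here recover the
  tag, and third-party readers see an ordinary imzML file.
- A `permissive` parse flag downgrades UUID/SHA-1 mismatches between the
  XML and the binary companion to warnings, because converter-chain
  quirks of exactly this kind occur in the wild.
- Pixels absent from a file are absent from the dataset — images render
  them as zero, but no spectrum is fabricated, preserving the distinction
  between "no data" and "zero signal".
- The exact HDF5 schema of the desktop tool this workflow mirrors is not
  published; the store schema here (one zero-padded group per pixel with
  x/y/z attributes, documented in the README) is this package's own,
  compatible in spirit and fully specified so third parties can read it.

# Problem sizes

The test suite and examples run at desk scale by choice: single spectra of
2–35 thousand points for the worked examples, grids from 2×2 to 12×10 for
property tests, and one 32×32, two-species, 1500-point-axis full-pipeline
run (synthesis → import → deconvolve → export → images → similarity). The
engine's cost is linear in pixels and roughly linear in axis points ×
charges × iterations; the shared-axis geometry cache makes the per-pixel
cost tens of milliseconds at these sizes.

# Known limitations

- One parameter set per run: a pixel range needing a different mass or
  m/z window means re-running the whole dataset.
- Positive-mode proton adducts only (negative mode would need signed
  adduct handling).
- No isotope-resolved mode; the engine targets exactly the
  non-isotopically-resolved regime.
- Noise produces deconvolution artefacts and can yield false masses in
  low-signal data; similarity validation against component ion images is
  the intended guard, and manual review remains advisable.
- The similarity score inherits the empty-pixel inflation discussed
  above; report the near-empty fraction alongside any score.
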