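---
title: "Vibrational pseudo-spectra and the physical classification of odorants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibrational pseudo-spectra and the physical classification of odorants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdeva)
```

## The model

The vibration picture of olfaction holds that what a receptor senses
about an odorant is (at least partly) its vibrational spectrum; the
orthodox shape picture holds that it is the molecular geometry.  The two
meet in chemical graph theory: a molecule is a graph of atoms (masses
$m_i$, in amu) and bonds (harmonic stiffnesses $k_{ij}$, in N/m), and
the stiffness-weighted, mass-scaled Laplacian of that graph is the
dynamical matrix of its coupled-oscillator equations of motion,

$$D_{ij} = -\frac{k_{ij}}{\sqrt{m_i m_j}}, \qquad
  D_{ii} = \frac{1}{m_i}\sum_{j \sim i} k_{ij},$$

whose eigenvalues $\lambda = \omega^2$ give the vibrational wavenumbers
$\tilde\nu = \sqrt{\lambda}/(2\pi c)$.  `dynamical_matrix()` and
`vibrational_frequencies()` implement this as a *scalar* ball-and-spring
model: one displacement coordinate per atom, so an $N$-atom molecule has
$N$ modes and each connected component contributes exactly one
zero-frequency translation (a full Cartesian treatment would give $3N$
coordinates and six rigid-body modes).  The scalar model realizes the
Laplacian–dynamical-matrix correspondence exactly and is intended for
structure–spectrum intuition, not for reproducing density-functional
frequencies; production frequency lists are expected to be imported.

From a list of discrete mode wavenumbers $\lambda_i$ the EVA
pseudo-spectrum places a unit-area Gaussian on every mode and sums:

$$\mathrm{EVA}(x) \;=\; \sum_{i}
  \frac{1}{\sigma\sqrt{2\pi}}
  \exp\!\left(-\frac{(x-\lambda_i)^2}{2\sigma^2}\right).$$

All stems have equal magnitude; no infrared or Raman intensity weighting
is applied.  The broadening $\sigma$ sets the resolution scale: modes
closer than about $\sigma$ merge.  The default $\sigma = 100$ cm$^{-1}$
corresponds to room-temperature broadening of inelastic-tunneling
features ("300 K EVA").

The EVA curve is then simplified by *peak decomposition*
(`peak_decompose()`): a bounded Gaussian-sum least-squares fit with the
smallest number of components that reaches a relative RMS residual of
2 % of the curve maximum.  Each broad peak is identified with a
vibrational mode type by its position — the band table
(`mode_bands()`) spans low-frequency torsions (A, B), ring torsion and
C–H rocking (C, D), ring deformation / C–H wagging / C–C stretch (E, F),
C=C stretch (G), C=O stretch (H), S–H stretch (I) and C–H stretch (J).
The *centers* of the broad peaks, re-broadened with a smaller
$\sigma = 60$ cm$^{-1}$ and again with equal stem magnitudes, form the
Peak-Decomposed EVA (PD-EVA, `pd_eva()`), a descriptor that keeps the
mode-type structure while discarding the fine multiplicities.

Two pseudo-spectra are compared with the Hodgkin similarity index,

$$S(a, b) \;=\; \frac{2\sum_i a_i b_i}{\sum_i a_i^2 + \sum_i b_i^2}
  \;\in\; [0, 1],$$

with sums over grid points (the ratio is invariant to the grid step, so
this agrees with the continuum integral).  $S = 1$ exactly iff the
curves coincide.  For two single-mode spectra of equal $\sigma$ whose
centers differ by $\Delta$ the index has the closed form
$\exp(-\Delta^2/4\sigma^2)$, which the test suite uses as an oracle.

Clustering proceeds from the $n \times n$ similarity matrix: its
diagonal is zeroed to give an effective adjacency, the symmetric
normalized Laplacian $L = I - D^{-1/2} A D^{-1/2}$ is formed, molecules
are embedded as the (row-normalized) rows of the eigenvector matrix of
the $m$ smallest eigenvalues, and k-means with many restarts partitions
them — the Ng–Jordan–Weiss construction.  A random-walk variant
($D^{-1/2}$-rescaled embedding, no row normalization) is selectable;
both share the same eigenvalues.

## Choosing the number of clusters

No selection criterion is canonical for spectral clustering, and the
choice was genuinely open here.  `choose_m()` uses the eigengap
heuristic — the $m$ maximizing $\lambda_{m+1} - \lambda_m$ over the
candidate range, ties toward smaller $m$ — because it is the standard
diagnostic attached to the normalized Laplacian itself; the mean
silhouette width against the dissimilarity $1 - S$ is computed alongside
as an independent second opinion, and both are returned so the choice
can be audited.  On planted block-structured similarities both criteria
agree with the construction.

On the bundled 20-odorant set the two criteria also agree with each
other — and select a coarser structure than one might hope: the
eigengap over $m \in [2, 12]$ selects $m = 3$ (the silhouette peaks
there too), grouping the molecules into a musk-like, an
aromatic/ring-like and a fruity-like super-class, with 2 of the 6
perceptual classes spread over more than one cluster.  Finer
subdivisions are visible but sub-dominant: at a forced $m = 8$ the
garlic-class sulfur compounds of natural origin (Allicin, Diallyl
disulfide) separate cleanly from the synthetic ones, and the musk,
fruity, moth-ball and roasted-coffee classes each stay intact.  The
`summary()` method prints the full diagnostic table so users can weigh
these alternatives themselves; nothing in the package hard-codes a
preferred cluster count.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma` (EVA) | 100 | cm$^{-1}$ | thermal-broadening resolution scale |
| `sigma` (PD-EVA) | 60 | cm$^{-1}$ | finer re-broadening of peak centers |
| grid | 0–4000, step 1 | cm$^{-1}$ | covers all mid-IR fundamentals with $4\sigma$ headroom |
| `residual_tol` | 0.02 | – | relative RMS target of the peak fit |
| `width_bounds` | [30, 400] | cm$^{-1}$ | below: unidentifiable under broadening; above: merges bands |
| `max_components` | 8 | – | "a few broad peaks" ceiling |
| `m_range` | [2, 12] | – | candidate cluster counts |
| `nstart` | 50 | – | k-means restarts (best inertia kept) |

Band boundaries are a convention of this package: the mode-type *names*
carry the physics, but no standard fixes numeric cut points, so the
table is user-overridable (`read_bands()`), and every bundled odorant
mode falls inside its expected band under the defaults.

## Numerical choices

* **Zero modes.** Eigenvalues with $|\lambda| < 10^{-9}\max\lambda$ are
  treated as the null space; one per connected component is expected in
  the scalar model, and a negative eigenvalue beyond that tolerance is
  an internal error, never silently clipped.
* **Kernel truncation.** Kernels are evaluated over the full grid with
  no cutoff.  When a mode sits within $4\sigma$ of a grid edge the lost
  tail mass is real (a kernel centered at 0 keeps half its mass); the
  constructors warn rather than renormalize.
* **Peak-fit determinism.** Initialization is deterministic: centers at
  local maxima of the lightly smoothed curve; for each component count
  the fitter also tries augmenting the previous best fit with a
  component at its largest positive residual (which resolves two modes
  merged into one bump) and keeps the better solution.  There are no
  random restarts, so refits are bit-reproducible.
* **Clustering determinism and ties.** k-means is seeded explicitly;
  coincident embedding rows switch the algorithm to Lloyd (Hartigan–Wong
  stalls on exact duplicates), and a structureless similarity matrix
  (all off-diagonal entries equal) is flagged as arbitrary with ties
  broken by input order.
* **Degenerate inputs.** Empty spectra, all-zero curves, grid or kind
  mismatches between spectra, isolated vertices and out-of-band peak
  centers are errors naming the offender — never silent coercions.

## The synthetic generator

`synthetic_odorants()` emulates $K$ odour classes as per-class template
mode sets: each molecule inherits its class template with independent
Gaussian jitter (`jitter_sd`, default 15 cm$^{-1}$) and optional
per-mode dropout.  The default templates are an evenly staggered
lattice (within-class mode spacing 600 cm$^{-1}$, class-to-class offset
150 cm$^{-1}$), so that every pair of classes has the same minimum
inter-template mode gap.  That gap, 2.5 times the PD-EVA $\sigma$,
matters: class structure is only recoverable when templates differ at
the scale the broadened similarity can resolve, the same
$\gtrsim 2\sigma$ separation condition under which the peak fit can
recover mixture components.  Jitter alone being small relative to the
template gaps is *not* sufficient — templates whose modes interleave
within $\sim\sigma$ of another class's produce a hierarchical similarity
structure whose eigengap reads only the super-classes.

What the generator deliberately does not emulate: correlated jitter
across modes of one molecule, class-dependent mode counts, intensity
variation, or the long-tailed similarity structure of real chemical
families.  Passing recovery tests therefore demonstrates that the
pipeline machinery is correct under clean class structure, not that real
odorant families are this separable.

Problem sizes used throughout the test suite — 20-molecule reference
set, 4 planted classes of 5 molecules over 100 seeds, 50 random
Gaussian mixtures, random graphs up to 12 atoms — were chosen as the
smallest sizes at which each property is informative.

## Known limitations

* The scalar spring model gives one zero mode per component and makes
  no claim of quantitative agreement with DFT frequencies; its default
  bond-stiffness table (≈ 500/1000/1500 N/m by bond order) is
  illustrative.
* Only Gaussian line shapes are supported (no Lorentzian/Voigt), and
  stems are equal-magnitude by design.
* The bundled reference set is a 20-molecule proof of concept; cluster
  structure inferred from it should not be extrapolated to large
  odorant libraries.
* Similarity requires identical grids; resampling is the caller's
  explicit responsibility.
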