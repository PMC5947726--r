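---
title: "Models and methods for diffuse scattering map analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for diffuse scattering map analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diffusemap)
```

# The signal and the question

Bragg reflections measure the *average* electron density of a crystal;
everything the molecules do around that average — how their displacements
covary — is invisible to them. Correlated displacements scatter
incoherently into a continuous, anisotropic diffuse signal whose
structure in reciprocal space is the Fourier fingerprint of the
real-space correlations: short-ranged correlations spread intensity over
broad regions, correlations longer than a unit cell concentrate it into
speckles centered on reciprocal-lattice nodes. `diffusemap` reconstructs
three-dimensional diffuse maps from rotation-series images and asks
which parsimonious model of crystal disorder explains them.

# Map reconstruction

**Geometry.** Each pixel is mapped to the scattering vector
$\mathbf{q} = (2\pi/\lambda)(\hat{s} - \hat{s}_0)$, rotated into the
crystal-fixed frame at the frame's mid-oscillation spindle angle
(pixel values are *averaged* into voxels rather than integrated, which is
also why no Lorentz correction is applied — only the solid angle
subtended matters, not the arc a pixel sweeps). The convention is
$|\mathbf{q}| = 2\pi/d$; an amorphous-oil contaminant ring at a
$d$-spacing of about 4.8 Å therefore sits at $|\mathbf{q}| = 1.3$ Å⁻¹.
Intensities are divided by a Kahn-style polarization factor
(`polarization_fraction` defaults to 0.5, an unpolarized beam, because
beamline polarization is configuration, not physics) and by the
$\cos^3\psi$ flat-detector solid-angle ratio, then by per-image scale
factors.

**Bragg masking.** Reflections are predicted wherever a pixel's
fractional Miller index falls within `hkl_tolerance` (default 0.25) of
an integer along every axis at any of 5 sampled spindle angles across
the oscillation. Predicted pixels are masked when they exceed the mean
of the valid non-predicted pixels in a 30 × 30 window by more than 3
standard deviations (strict inequality; a window without any such
neighbor masks its pixel unconditionally). A second pass masks pixels
above the shell median plus 5 raw median absolute deviations (2.5 inside
a configured contaminated region). Masked pixels are dropped, never
replaced; both operations are idempotent because their statistics are
computed over the union of currently valid and previously
outlier-masked pixels.

**Backgrounds.** Per-frame radial profiles are fitted over
$0.63 < |\mathbf{q}| < 1.88$ Å⁻¹ to
$a|\mathbf{q}|^2 + b|\mathbf{q}| + c + m\,I_\mathrm{ref}(|\mathbf{q}| - q_0)$ —
linear least squares in $(a, b, c, m)$ with a golden-section search over
the shift $q_0 \in [-0.05, 0.05]$ Å⁻¹, whose best-so-far residual is
non-increasing by construction. The bundled reference
(`synthetic_reference_profile`) is a smooth synthetic stand-in peaked at
1.3 Å⁻¹; a measured oil profile can be supplied as a two-column table.
Only the scaled, shifted reference component is subtracted. Residual
frame-to-frame radial variance (solvent and beam fluctuations) is then
removed by mean-centered PCA of the radial profiles: each frame's
background is the reconstruction of its deviation from the mean profile
from the first $k$ components ($k$ = 2, 1 or 0 depending on the data
set), interpolated to pixel $|\mathbf{q}|$ and subtracted. Because every
correction is a function of $|\mathbf{q}|$ alone, anisotropy at fixed
resolution is untouched.

**Merging and symmetrization.** Corrected pixels are binned to the
nearest node of a grid oversampling the Miller indices 3× per axis
(odd oversampling keeps integral indices on nodes; exact half-distance
ties go to the lexicographically smaller node). Voxel intensity is the
mean, SNR the mean over the sample standard deviation (undefined below
two observations). Orbits under the Laue group (space-group rotations ×
Friedel inversion; operator tables for P1, P2₁2₁2₁, P4₂22, P6₃22) are
averaged with `n_obs` weights; the radial average, interpolated at each
voxel's $|\mathbf{q}|$ from 100 equal-width shells anchored at the
per-shell mean $|\mathbf{q}|$, is subtracted; a constant offset makes
all intensities positive (correlations are unaffected). Because the
radial estimate is interpolated rather than piecewise-constant, shell
means of the output vanish approximately (a few percent at toy-scale
voxel counts), exactly in the dense-map limit.

# Disorder models

All models share the molecular transform
$F(\mathbf{q}) = \sum_i o_i f_i(|\mathbf{q}|)\, e^{i \mathbf{q}\cdot\mathbf{r}_i}$
(tabulated four-Gaussian form factors; a constant-$f$ pseudo-element `"X"`
keeps toy oracles in closed form; no B-factor damping, since each model
supplies its own displacement statistics) and its incoherent orientation
sum $T_\mathrm{sym}(\mathbf{q}) = \sum_R |F(R\mathbf{q})|^2$, which makes
every prediction Laue- and Friedel-invariant by construction and
non-negative before radial subtraction.

* **Rigid-body translations** (`predict_rigid_translations`):
  $I_D = T_\mathrm{sym}(\mathbf{q})\,[1 - e^{-\sigma^2 q^2}]$, with
  $B = 8\pi^2\sigma^2$ (`wilson_b_to_sigma` converts back).
* **Rigid-body rotations** (`predict_rigid_rotations`): Monte-Carlo
  variance $\langle|F_k|^2\rangle - |\langle F_k\rangle|^2$ over
  rotations about the molecular centroid, axis uniform on the sphere,
  angle $\sim N(0, \sigma_\mathrm{rot}^2)$; default 2000 samples, seeded.
  The centroid (not the crystallographic origin) is used because a
  rotation center offset only adds a translation component already
  covered by the translational model.
* **Liquid-like motions** (`predict_llm`): correlations decay as
  $e^{-r/\gamma}$ with amplitude $\sigma$; in the one-phonon
  approximation
  $I_D = \sigma^2 q^2 e^{-\sigma^2 q^2} [I_\mathrm{basis} \circledast \Gamma_\gamma]$,
  where $\Gamma_\gamma(\delta q) = 8\pi\gamma^3/(1+\gamma^2\delta q^2)^2$
  is the 3D Fourier transform of the exponential decay, normalized so
  $(2\pi)^{-3}\!\int \Gamma_\gamma\, d^3q = 1$. The *confined* variant
  convolves $T_\mathrm{sym}$ (correlations limited to the asymmetric
  unit); the *extended* variant convolves the crystal transform, which
  is nonzero only at integral Miller indices — this is what produces
  speckles. Numerically, the kernel is sampled on the grid, truncated at
  $10^{-4}$ of its peak (capped at the grid span, with an error only
  when even the half-maximum is sub-voxel) and normalized to unit sum,
  so the large-$\gamma$ limit is exactly the unconvolved basis; the
  basis is evaluated on a grid enlarged by the kernel radius before the
  FFT convolution so edge voxels see true rather than zero-padded
  values.
* **Ensembles** (`predict_ensemble`): Guinier's weighted variance
  $\sum_s w_s |F_s|^2 - |\sum_s w_s F_s|^2$ for discrete
  probability-weighted states; two states reduce to
  $w_1 w_2 |F_1 - F_2|^2$.
* **Elastic network** (`build_enm_covariance`,
  `predict_gaussian_disorder`): a uniform-spring network on all atoms
  within a cutoff (default 10.5 Å), per-axis covariances from the
  pseudo-inverse of the network Laplacian, rescaled per atom so the
  implied B equals the refined B
  ($V_{ij} \leftarrow s_i s_j V_{ij}$,
  $s_i = [B_i / 8\pi^2 V_{ii}]^{1/2}$). This Cartesian isotropic network
  stands in for torsion-angle normal modes; the covariance blocks are
  scalar ($v_{ij} I_3$). The general Gaussian prediction
  $I_D = \sum_{ij} f_i f_j e^{-q^2(v_{ii}+v_{jj})/2}(e^{q^2 v_{ij}} - 1)\cos(\mathbf{q}\cdot\mathbf{r}_{ij})$
  also offers the linearized $e^x - 1 \to x$ option.

**Limits worth knowing.** The one-phonon LLM form converges to the
rigid-translation expression as $\gamma \to \infty$ only to first order
in $\sigma^2 q^2$ ($\sigma^2q^2e^{-\sigma^2q^2}$ versus
$1-e^{-\sigma^2q^2}$); the convergence check therefore uses
$\sigma = 0.1$ Å, where $\sigma^2 q^2 \le 0.03$ over the toy grid. At
larger displacements the two damping envelopes genuinely differ, which
is a property of the approximation, not of the implementation.

# Fitting

Agreement is the Pearson correlation over co-defined voxels with weights
$1/m$ (multiplicity $m$; $1/\sqrt{m}$ available), after subtracting the
radial average from the prediction as well. `scan_parameters` evaluates a
coarse grid (defaults bracket all published best-fit values:
$\sigma \in [0.05, 1.5]$ Å step 0.05; $\gamma \in [2, 150]$ Å, 20
log-spaced points; $\sigma_\mathrm{rot} \in [0.2°, 6°]$ step 0.2°), then
refines each axis once at a 10× finer step around the maximum,
coordinate-wise — a full fine outer product costs an order of magnitude
more kernel convolutions for identical recovery at the stated
tolerances. Ties break toward smaller parameters. Scale and platform are
a weighted least-squares afterthought that leaves the correlation
unchanged.

**Identifiability at desk scale.** $\sigma$ enters only through the
radial envelope; on a grid that reaches $\sigma^2 q^2 \sim 1$ it is well
constrained, but on a very large cell with a small grid extent
($q_\mathrm{max} \approx 0.4$ Å⁻¹, $\sigma^2q^2 \le 0.03$) it degenerates
into a pure scale factor that a correlation cannot see. $\gamma$ is
constrained by how strongly the kernel smooths resolvable transform
features (confined) or by the speckle weight profile (extended). The
recovery tests therefore assert $\sigma$ on fixtures with adequate
$q$-coverage and $\gamma$ on fixtures where the kernel acts on resolvable
features; all planted values are the published best-fit parameters.

# Speckle and autocorrelation diagnostics

`deltaq_profile` bins defined voxels by resolution shell (20 shells) and
by distance $\delta q$ to the nearest integral Miller index (bin width
one tenth of the smallest reciprocal-cell spacing, range to half that
spacing), records per-cell medians and normalizes each shell to its
$\delta q = 0$ bin. `fit_falloff` compares $a/\delta q^2 + c$
(single-phonon) with
$A\,8\pi\gamma^3/(1+\gamma^2\delta q^2)^2 + c$ (liquid-like motions) on
one shell. Both forms carry the same additive floor $c$: uncorrelated
disorder and the overlapping tails of neighboring nodes' kernels add a
near-constant per-shell level which otherwise biases the kernel width
about 30 % low and distorts the residual comparison; granting both
models the same extra degree of freedom keeps the comparison fair. The
$\delta q = 0$ bin anchors only the kernel fit (the phonon form diverges
there); residuals are compared on the shared $\delta q > 0$ bins. At toy
scale the literal lowest shell holds only a handful of lattice nodes, so
`first_usable_shell` selects the lowest shell with at least 4 defined
bins and 20 nodes; and because per-shell medians across nodes whose
amplitudes span orders of magnitude are noisy with so few nodes, the
γ-recovery fixture uses a one-scatterer-per-cell crystal whose flat
transform isolates the speckle shape.

`autocorrelation` Fourier-transforms the map (undefined voxels
zero-filled, fraction reported; any recorded positivity offset removed
first; if the origin sum is numerically zero, as for radial-subtracted
maps, normalization falls back to the maximum magnitude).
`lattice_peak_report` interpolates the six ±unit-cell translations and
flags peaks above the median of a surrounding shell (fractional radius
0.15–0.35 of a cell) by more than three raw MADs. Maps from extended
correlations show these peaks; asymmetric-unit-confined maps do not.

# The synthetic world

The generators state one world and the tests live in it:

* Toy crystals: ≤ 20 atoms placed with ≥ 1.5 Å separation inside one
  asymmetric unit of cells between 20 and 40 Å (fixtures that emulate the
  study's cells use its published dimensions); B factors 10–20 Ų.
* Detector: 128 × 128 pixels of 0.3 mm at 60 mm and λ = 1.0 Å — toy
  scale, but with Ewald curvature and solid-angle/polarization gradients
  comparable to the study's regime; 36 frames × 5° cover 180°.
* Photon scale: the diffuse level is normalized to a median of ~100
  counts per pixel; the isotropic background is a broad solvent-like bump
  (~150 counts, 40 % frame-to-frame fluctuation plus a ~50-count floor);
  the contaminant is the bundled reference with per-frame scale
  ~N(60, 18) and shift $q_0 \sim N(0.007, 0.003)$ Å⁻¹; per-frame scales
  are log-normal with 15 % spread; Bragg spots are 30× the diffuse scale
  with Gaussian footprints, recorded at the mid-oscillation orientation
  so that partiality decorrelates symmetry-equivalent reflections as in
  real rotation data; Poisson noise applies last, counts floored at 0.
* Map-space noise at "SNR 5" means multiplicative voxel noise
  $I(1 + \varepsilon/5)$, mirroring the per-voxel mean/σ definition of
  map SNR.
* The ensemble oracle draws explicit perturbed structures and takes the
  variance of their structure factors — the brute-force realization of
  each model's covariance (exponentially correlated Gaussian draws via
  Cholesky with $10^{-10}$ jitter for the liquid-like case; supercell
  replication for intermolecular correlations). With $2\times10^4$
  samples the oracle pins the analytic maps to CC > 0.98–0.999.

What a green test does *not* establish: behavior on detector-scale pixel
counts, parallax or point-spread effects, radiation damage, real
mosaicity, the accuracy of the one-phonon approximation at large
$\sigma^2q^2$, or σ-recovery on grids whose $q$-range cannot constrain a
Debye–Waller envelope. The pairwise symmetry correlation is also a
deliberately partial witness of map quality: Bragg contamination is
itself Laue-symmetric, so masking it *lowers* that statistic while
raising agreement with ground truth by a factor of three — the staged
validation therefore keeps masking on throughout its symmetry-based
chain and scores masking against ground truth directly.

# Numerical choices

* Nearest-node ties (exact half distances) go to the smaller index;
  measure-zero in practice, fixed for reproducibility.
* SNR uses the sample standard deviation (ddof 1); single-observation
  voxels carry undefined SNR.
* MAD is the raw median absolute deviation — no 1.4826 normality factor.
* PCA of radial profiles is mean-centered (standard); the alternative of
  projecting raw profiles would mix the mean profile into the removed
  components.
* Golden-section search for $q_0$; negative reference scales are clamped
  to a pure polynomial fit.
* Degenerate inputs error loudly: disconnected elastic networks (named
  component sizes), constant maps in correlations, fewer bins than
  parameters in fits, kernel half-maxima below grid resolution.
* All generators are bit-reproducible given their seed, and restore the
  caller's RNG state.

# Known limitations

Supported space groups are the study's four (P1, P2₁2₁2₁, P4₂22,
P6₃22) via an explicit operator table. Frame stacks and maps are
plain-text formats (CSV/JSON); binary HDF5/MRC containers are out of
scope here. Covariance blocks are isotropic. The extended-LLM sampled
oracle approximates an infinite crystal by a finite supercell and is not
used as an acceptance gate. Phonon lattice-dynamics forward models are
deliberately absent — there is no robust way to predict macromolecular
phonon diffuse scattering, which is precisely why the fall-off
diagnostic compares functional forms instead.
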