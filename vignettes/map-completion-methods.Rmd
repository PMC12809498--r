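---
title: "Synthetic fragment crystals and volumetric map completion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic fragment crystals and volumetric map completion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xtalfrag)
```

## The problem

X-ray diffraction measures structure-factor amplitudes but not phases, so
an electron-density map cannot be computed directly from an experiment.
The Patterson function sidesteps the phase problem — it is the Fourier
synthesis of the *squared* amplitudes with all phases set to zero, equal
to the autocorrelation of the density — but its peaks are interatomic
vectors, not atoms, and for a protein they blur into an uninterpretable
mass. This package builds the computational substrate for a
machine-learning attack on that problem: given (i) the Patterson map of a
small crystallised peptide and (ii) a density map computed from an
*incomplete, imperfect* predicted model of that peptide (a "partial
structure" with several terminal residues omitted), regress the complete
ground-truth density map. Everything needed to pose, train and score that
task on synthetic data is implemented here: crystal construction,
structure factors and map synthesis, the dataset-generation pipeline,
evaluation metrics, and a desk-scale hybrid 3D vision-transformer/CNN
with its training loop.

## Crystal model

A fragment is a tibble of heavy atoms (C/N/O/S, occupancy fixed at 1,
per-atom isotropic B factors). Cells are orthogonal-axis boxes in space
group P1 or P2~1~; a P2~1~ cell with all angles at 90 degrees is a valid
monoclinic setting, and the two-fold screw axis runs along axis 2 through
fractional (0, *y*, 0), the conventional origin.

Construction follows a fixed recipe:

1. **Reorientation** (`reorient()`): the coordinate axes are permuted so
   the extents satisfy e1 ≥ e3 ≥ e2 (first axis longest, second
   shortest). When the permutation is improper one axis is negated —
   amino acids are chiral, so a reflection is never applied.
2. **Contact-driven boxing** (`determine_cell()`): starting from the raw
   max–min extents, the axes implicated in the closest intermolecular
   contact (non-zero components of the offending lattice translation) are
   grown by 0.5 Å per iteration until the minimum atom–atom distance
   between the fragment and any lattice translate is at least 3.5 Å. The
   step size is a package choice; growing only the implicated axes keeps
   cells close to minimal. The centre of mass (mass-weighted over heavy
   atoms, C=12, N=14, O=16, S=32) sits at the exact cell centre, which
   pins the otherwise arbitrary origin of the translation-invariant
   Patterson map.
3. **P2~1~ conversion** (`to_p21()`): one ångström is added to every
   axis, axis 2 is multiplied by *u* ~ Uniform(1.7, 1.95), the fragment
   is re-centred (after all length changes), and the screw mate is
   generated by (x, y, z) → (−x, y + ½, −z) in fractional coordinates.
   Contacts are deliberately *not* re-checked: tight screw packing is
   tolerated, keeping the solvent fraction of the cells realistic.

`solvent_fraction()` reports the fraction of grid voxels farther than a
mask radius (default 2.2 Å, a van-der-Waals-scale value, configurable)
from every atom under periodic minimum-image distances.

## Reciprocal space

Structure factors are computed by direct summation over all atoms of all
symmetry copies,

$$F(hkl) = \sum_j f_j(s)\, e^{-B_j s^2/4}\, e^{2\pi i (h x_j + k y_j + l z_j)},$$

with fractional coordinates, $s = 1/d$, and for an orthogonal cell
$1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2$. Scattering factors use the
4-Gaussian Cromer–Mann parameterisation for C, N, O and S; a
`"constant-z"` mode (f = atomic number) is kept as a testing oracle.
Reflections are enumerated over the full sphere to the resolution limit
and stored as a Friedel hemisphere. Two symmetry checks follow from the
construction and are enforced in the test suite rather than assumed:
Friedel mates are complex conjugates, and the 2~1~ screw forces
F(0, k, 0) = 0 for odd k.

Density maps are synthesised by placing the hemisphere and its conjugate
mates into an FFT array; F(000) is omitted so maps are mean-zero (the
CCP4 FFT convention). The Patterson map is available by two routes that
are algebraically the same object and are cross-checked to relative
1e−6 on every fixture batch: the squared-amplitude synthesis, and
`patterson_via_autocorrelation()`, which computes
Re(IFFT(FFT(e) ⊙ FFT(ě))) from the inverse-shifted density ě.

**Numerics.** Grid shapes must satisfy n ≥ 2·h~max~+1 per axis or the
synthesis aborts (aliasing would silently fold reflections). Shapes are
rounded up to 2,3,5-smooth integers for FFT efficiency. The pipeline's
grid-sampling factors (2.29–2.7, below) always exceed 2, so the Shannon
condition holds by construction.

## Dataset pipeline

Chains are cut into 15-residue windows at stride 10, so consecutive
fragments overlap by at most 5 residues; a trailing window that would
need a larger overlap is dropped. Cleanup removes hydrogens, converts
selenomethionine to methionine (Se → S at atom SD), keeps original B
factors, and rejects fragments with non-standard residues, numbering
gaps, or heavy atoms missing relative to a bundled per-residue template
table — rejection is a signalled outcome (`NULL`), not an error.

Each ground-truth fragment receives up to J = 3 partial structures: per
draw the omission end is uniform over {start, end, both} and the omitted
count uniform over 3..7 of 15; "both" splits floor/ceil with a fair coin
deciding the larger side for odd counts. A draw that duplicates an
earlier omitted-residue set is discarded, not retried, so fewer than J
partials may result. Partial-structure atoms get a constant B = 20 Å²
and are placed in the *same* P2~1~ cell as their ground truth (same
Cartesian offset, same screw mate), so the Patterson, density and
template tensors of one example are voxel-aligned.

Examples are spread across 20 resolution bins by index modulo 20; bin i
interpolates d~min~ linearly over 1.75–2.3 Å and the grid-sampling
factor over 2.29–2.7. The pairing of the lowest d~min~ with the lowest
factor is a package choice (the association is otherwise unconstrained);
monotone pairing keeps voxel counts balanced across bins. The map shape
per axis is the smallest smooth integer ≥ length·factor/d~min~.

Normalisation maps each flavor to [−1, 1] by the *global* dataset
min/max — Patterson and density extremes computed separately, with
partial templates rescaled by the **density** extremes so templates and
targets share one scale (template values may therefore poke slightly past
±1; the stored `normalization_stats` invert the transform exactly).
Batching groups examples by identical shape, drops groups smaller than
6, cuts greedily into chunks of ≤ 11 and rebalances the last two chunks
so no batch falls below 6.

## Synthetic fixtures

`make_fragment()` grows an extended/coiled peptide backbone from ideal
internal coordinates (N–CA 1.46 Å, CA–C 1.52 Å, C–N 1.33 Å, trans
peptide bonds, φ/ψ drawn from broad β- and α-like regions), places the
carbonyl O and a C-β for non-glycine residues, and samples B factors
uniformly (default 10–40 Å²). Side chains are truncated at C-β: that is
enough to exercise every map and metric while keeping the heavy-atom
template table honest, so the default residue composition is an ALA/GLY
mixture (the two residues whose full heavy-atom complement the builder
produces) and fixtures pass `clean_fragment()` unchanged.
`make_prediction()` emulates an already-aligned structure prediction:
per-atom Gaussian displacements, optionally inflated at the termini, are
rescaled as a field so the realised C-α RMSD equals the target exactly,
and B is reset to the constant 20 Å² used for predicted templates. What
these fixtures deliberately do **not** model: real side-chain rotamers,
sequence-dependent conformational preferences, correlated prediction
error along the chain, bulk solvent, and experimental noise — so green
tests here demonstrate the machinery, not performance on PDB-derived
data.

## Metrics

* `pearson_cc()` — Pearson correlation over all voxels or over an
  in-model mask (voxels within 2.0 Å, periodic, of any ground-truth
  atom; radius configurable).
* `phase_error()` — per-reflection |Δφ| wrapped to [0, 180]°, with
  unweighted and FOM-weighted means and mean cosines (weighted means
  normalise by Σm). No origin-shift search is performed: all maps
  generated here share one origin by construction. This is a known
  fidelity gap relative to general-purpose phase-comparison tools, which
  search the allowed origin shifts of the space group.
* `normalized_amplitudes()` — E values over equal-count resolution
  shells (⟨E²⟩ = 1 per shell by construction).
* `estimate_sigma_a()` — a deterministic moment estimator built on the
  acentric identity corr(E~o~², E~c~²) = σ~A~⁴. The observed shell
  correlation r is shrunk linearly, (r − 3/√n)/(1 − 3/√n) floored at 0,
  before the fourth root. The shrinkage matters: the fourth root maps
  null sampling noise of order n^−1/2^ to σ~A~ values of 0.3–0.45, so an
  unshrunk estimator cannot distinguish an unrelated model from a weakly
  correlated one; the chosen form sends three null standard errors to
  zero while leaving a perfect correlation at one. A Rice-likelihood
  refinement (what production phasing programs do) is out of scope and
  documented as a fidelity gap.
* `fom()` — X = 2σ~A~E~o~E~c~/(1 − σ~A~²); acentric m = I₁(X)/I₀(X)
  (exponentially scaled Bessel functions, switching to the asymptote
  1 − 1/(2X) beyond X = 500 where `besselI` underflows), centric
  m = tanh(X/2); the P2~1~ centric zone is k = 0.
* `sigmaa_weighted_map()` — map coefficients (2m|F~o~| − D|F~c~|)e^iφc^
  acentric and m|F~o~|e^iφc^ centric, the standard partial-model
  reweighting.

## Model

The completion model stacks the Patterson map and one partial-structure
template as two channels of one volume (the fusion wiring is a package
choice exposed in `model_config()`). A 3×3×3 convolutional stem
(circular padding — the maps are periodic in the cell, so circular is
the physically correct boundary treatment and is used for divisibility
padding too) feeds a patch embedding (patch³ voxels per token), then
`n_layers` pre-norm transformer blocks with Nyström-approximate
attention. The token grid is downsampled 2× per axis by a strided
convolution after configurable blocks and upsampled by a transposed
convolution after later blocks (paired LIFO), then de-patchified to a
single-channel volume cropped to the input shape. Default geometry:
conv channels 10, patch 4, embed 512, 12 heads of dimension 64 (inner
dimension 768 with a linear projection back to 512 — the standard
resolution of that mismatch), MLP 2048, 12 layers, down after blocks 2
and 4, up after 8 and 10. `toy_model_config()` (patch 2, embed 64, 4
heads × 16, 4 layers, down after 2 / up after 3) fits a CPU.

Positional information is a fixed 3D sinusoidal encoding computed per
token-grid shape. A learned embedding would need one parameter set per
grid shape, and this dataset is deliberately shape-heterogeneous;
sinusoidal encodings are parameter-free and shape-adaptive.

Nyström attention uses contiguous-segment landmark means (default 64
landmarks; 16 in the toy preset) and 6 iterations of the cubic
Moore–Penrose pseudo-inverse scheme, falling back to exact attention
when the token count does not exceed the landmark count. The
approximation is accurate for token fields with smooth, low-rank
structure — which patch embeddings of band-limited crystallographic maps
are — and that is how the accuracy audit draws its token sets; on fully
iid Gaussian tokens the attention kernel is near full rank and *no*
landmark method approximates it well.

An optional scale-equivariant stem variant (off by default) applies the
same 3×3×3 kernel at dilations 1 and 2 with shared weights and takes the
elementwise maximum over scales.

**Loss.** L = MSE(ê, e) + w·(−r(ê, e)) with r the Pearson correlation
and w = 1 by default; w = 0 reduces the loss to plain MSE exactly. A
zero-variance target skips the correlation term with a warning.

**Training.** `train_toy()` runs an AdamW-style optimizer (decoupled
weight decay 3×10⁻², β = (0.9, 0.999)) under a one-cycle learning-rate
schedule whose three endpoints (initial 4.5×10⁻⁴, maximum 2.85×10⁻³,
final 8.57×10⁻⁴) are hit exactly, with gradient accumulation every two
batches. Everything is deterministic under the configured seed. The
engine underneath is a small reverse-mode autodiff tape written for this
package: nodes are environments (reference semantics; an intrusive
linked list forms the tape), and a single gather/scatter primitive with
precomputed scatter plans covers im2col convolution, patchify,
reshaping, padding and cropping. Every operation's gradient is validated
against central finite differences in the test suite.

**Problem sizes.** The memorisation audit trains the toy preset on 8
pipeline examples built from 3-residue fragments at d~min~ 2.5 Å (grids
of roughly 10–15 voxels per axis) for 150 optimizer steps of batch 4,
reaching in-model-region correlations above 0.99; the property tests use
2–3-residue fragments at 3 Å and the Monte-Carlo suites 50–100 seeded
15-residue fixtures. These sizes were chosen so the whole suite runs
comfortably on one CPU while still exercising every code path at
realistic cell geometry.

## Known limitations

* Orthogonal-axis cells and P1/P2~1~ only; no anomalous scattering,
  anisotropic B, occupancies < 1, bulk solvent or experimental noise.
* σ~A~/FOM weighting is a moment estimator, not a likelihood fit.
* Phase comparison assumes a shared origin (valid within this generator,
  not for externally phased maps).
* The fixture peptides are geometrically ideal and side-chain-truncated;
  conclusions about real experimentally derived structures and predicted
  models require real data.
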