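---
title: "Separating coexisting subunit conformations in helical assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating coexisting subunit conformations in helical assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Helical reconstruction of a decorated filament averages every asymmetric
unit of the lattice into one density. When the decorating subunits
populate more than one conformation — a kinesin motor domain that is
"open" on some tubulin sites and "closed" on others, or a two-heads-bound
dimer whose leading and trailing heads differ — the average map blurs the
states together. This package implements a desk-scale subunit refinement
and classification workflow (HASRC) that treats every asymmetric unit as
an independent particle, strips away the signal of its neighbours, sorts
the subunits into conformational classes, refines their local poses and
reconstructs each class from the original images. Everything is
validated on synthetic 15-start decorated-microtubule data generated by
the package's own simulator with per-subunit ground truth.

## Geometry and conventions

Volumes are cubic grids with the box centre at voxel `n/2` and the
helical axis along z. The screw operator `S_k` relating asymmetric units
is a rotation by `k * twist` about z plus a translation `k * rise` along
it; the defaults (rise 5.45 Å, twist 168.08°, 15 units per segment) are
the refined lattice values of a 15-protofilament microtubule. The
printed twist of such a lattice does not determine its hand, so the sign
of the applied twist is configurable (`handedness`), defaulting to
right-handed. Euler angles follow the intrinsic ZYZ single-particle
convention: a volume point `p` appears in the image at
`R p + s` with `R = Rz(psi) Ry(tilt) Rz(rot)`, and shifts `s` are stored
in Ångström so they survive resampling. Symmetry expansion composes each
segment pose with `S_k`, which reduces to `rot + k*twist` plus a rotated
axial translation whose in-plane part goes into the shifts and whose
beam-axis part is kept as a per-subunit defocus offset.

## The simulator

The phantom is a Gaussian pseudo-atom model of one asymmetric unit: a
tube-wall blob at radius 45 Å and a motor core at 72 Å shared by both
conformations; a mobile marker subdomain (w = 2.0, sd = 5.5 Å) at radius
82 Å whose centre moves 8 Å between the open and closed states — the
spatial scale of the KH0 subdomain shift, with the weight chosen so the
marker carries a realistic share of the motor density, since the real
open/closed transition repositions whole subdomains; a two-blob
neck-linker rod present only in the closed state; and, for dimer
lattices, a connecting density (two neck-linkers plus coiled coil)
joining each trailing subunit to its leading partner one dimer repeat
(15 subunits, 81.8 Å) up the protofilament.

Images are rendered analytically (a projected isotropic Gaussian is a
Gaussian, so segments are exact line integrals), multiplied by the CTF
in Fourier space at a defocus drawn uniformly from 1.0–1.9 μm (300 kV,
Cs 2.7 mm, amplitude contrast 0.07 — the first two printed, the last a
conventional value), and white Gaussian noise is added. The
signal-to-noise ratio is defined as the variance of the noiseless
segment image over the noise variance; `sigma_for_snr()` measures the
signal variance from a probe batch. Mixture mode draws independent
Bernoulli labels (default 70% open); dimer mode tiles each
protofilament deterministically with trailing(closed)/leading(open)
pairs, so the two dimer registrations are exactly equally populated by
construction. What the simulator does **not** emulate: coloured noise,
ice gradients, beam-induced motion, physically accurate scattering, or
the lattice seam of non-15-start microtubules — so a passing test shows
the algorithms behave correctly in this controlled regime, not that the
pipeline is production-ready for arbitrary real data.

## The pipeline

`run_hasrc()` executes, per dataset:

1. **Gold-standard split and consensus.** Whole filaments are assigned
   greedily to two halves; each half is backprojected (direct Fourier
   inversion with trilinear gridding on a 2× oversampled transform and
   sinc² de-apodization) and screw-averaged over the central 85% of the
   axial extent. No stage ever mixes the halves before the final FSC.
2. **Masks and symmetry expansion.** Two soft masks are rendered from
   pseudo-atom models: the *full* mask spans one decorated tubulin site
   (or the two-site dimer span plus linker) with flanking tubulin one
   dimer repeat up and down the protofilament; the *kinesin* mask holds
   only the motor parts. Mask construction low-passes the model density
   to 30 Å, binarizes at 5% of the maximum, dilates by 1 voxel and adds
   a 2-voxel raised-cosine edge — the printed recipe's pixel counts
   refer to ~1 Å grids, so the widths are scaled to the 4 Å grid (wide
   extensions were measured to pull lattice cross-talk into the focus
   footprint). Records are expanded 15-fold and the original images are
   re-centred on the projection of the full mask's centre of mass, with
   the centring folded into the record shifts so records stay consistent
   with volumes in the original frame.
3. **Partial signal subtraction.** Each image loses the CTF-modulated
   projection of `consensus × (1 − mask)` at its pose — first with the
   full mask (the input to pose refinement), then with the kinesin mask
   (the input to classification). A particle is only ever compared with
   its own half's consensus.
4. **Focused classification without alignment.** The kinesin-subtracted
   images are Fourier-crop resampled to 8 Å/px (the analogue of the
   resample-then-classify step; the printed 3.5 Å/px target lies below
   this package's 4 Å data sampling, and upsampling is excluded) and
   classified by the EM described below.
5. **Selection and subunit refinement.** Hard assignment by maximum
   responsibility; in dimer mode the class whose volume concentrates
   linker density at the full-mask centre of mass is flagged as the
   centred (leading/trailing) dimer. Selected classes are locally
   refined: a grid search over small Euler perturbations under a
   Gaussian prior of width `sigma_ang`, with shifts located by masked
   cross-correlation and parabolic sub-pixel interpolation within a
   3.5 Å radius.
6. **Final maps.** Each class and half-set is reconstructed from the
   re-centred **original** (never subtracted) images, screw-averaged in
   monomer mode, and the masked gold-standard FSC is read at the 0.143
   threshold (first crossing, linearly interpolated); the merged map is
   low-pass filtered at that resolution — a single global filter in
   place of local filtering/sharpening.

## The classification model

The E-step responsibility of class `c` for particle `i` is proportional
to `w_c * exp(-||(I_i - CTF_i Proj_i(V_c)) m_i||^2 / (2 sigma^2))`, with
`m_i` the particle's projected focus mask normalized to [0, 1] and a
single shared noise variance re-estimated from masked residuals. The
M-step rebuilds each class volume by responsibility-weighted,
CTF²-normalized direct Fourier inversion with a Wiener constant
`wiener_base / tau`; `tau` plays the role of the tau2_fudge
regularization multiplier (larger values trust the data more), with
`wiener_base = 1` calibrated so tau = 4 gives stable multi-class runs
on the default synthetic sets, and "padding 2" realised as the 2×
Fourier oversampling of projector and backprojector. Class volumes are
initialized from seeded random perturbations of uniform
responsibilities, so runs are deterministic given the seed.

Three stabilizers matter at realistic noise, and all were added after
watching unstabilized runs fail in characteristic ways:

* **Per-class Wiener scaling.** The Wiener constant scales with the
  class's effective particle fraction. With a fixed constant the
  heavier class's volume is systematically crisper, fits *every*
  particle better by a near-constant residual offset, and absorbs the
  run.
* **Deterministic annealing.** Log-likelihood differences are divided
  by a temperature decaying geometrically from 32 to 1 over 15
  iterations. Without it, per-particle log-likelihood gaps of order 30
  harden the responsibilities onto the random initialization within one
  iteration and the run strands in a seed-dependent local optimum.
* **Late weight updates and a patient stop.** Mixing weights stay
  uniform until a few iterations after annealing ends (early weight
  feedback collapses low-SNR mixtures), and the early stop requires
  three consecutive iterations with responsibility changes below 1e-5,
  because the moment annealing ends is a reliable false plateau.

Two honest limitations of this scheme are visible in the tests. The
M-step reconstructs from unmasked images — the stated single-`sigma`
simplification of the full per-frequency noise model — so the masked
log-likelihood can dip transiently by up to ~0.1% rather than being
exactly monotone. And hard assignments cannot be perfect even on
noiseless data: at views down the blob-alignment azimuths the
central-slice interpolation error exceeds the conformational signal, so
the separable-mixture check asserts an adjusted Rand index of at least
0.9 away from those views rather than exactly 1.

## Study conditions used by the tests and the acceptance script

* *Mixture recovery*: 200 segments × 15 subunits = 3000 subunits at
  variance-SNR 0.05, K = 2, 50 iterations; recovers the 70/30 split
  within a point and ARI ≈ 0.92–0.94.
* *Dimer parity*: 100 segments (1500 subunit anchors) at SNR 0.05,
  K = 2, 60 iterations; the two registration classes hold 50 ± 3% each
  because the axial sampling visits every tubulin site once per dimer.
  The per-subunit trailing/leading assignment is ~80% faithful at this
  noise level — the population parity is the robust observable.
* *Resolution gain*: 12 segments (180 subunits) at SNR 0.015 with 2 Å
  per-subunit lattice displacements. At milder noise the helically
  averaged route sits at the 8 Å Nyquist ceiling of the grid (screw
  averaging suppresses noise ~30-fold) and no difference is measurable;
  at SNR 0.01 the per-subunit shift refinement itself becomes
  noise-limited. Both routes are screw-averaged and use the same FSC
  mask, so the comparison isolates the per-subunit shift refinement;
  the acceptance script reports the median over seven replicate
  simulations because reading a noisy FSC at a hard threshold is
  shot-noise limited.

## Conformational descriptors and density quantification

The geometric classifier uses two nucleotide-binding-pocket Cα
distances (residues 488–604 for switch-1-to-P-loop, 406–647 for
KH0-to-switch-2) and the central β-sheet twist (angle between the Cα
475→480 and 527→531 strand vectors). The decision rule — closed below
17 Å on the KH0–switch-2 distance, otherwise semi-closed below 14 Å on
the switch-1–P-loop distance, otherwise open-like — places the cutoffs
at the midpoints between the published group means; `open*` is assigned
only from metadata (ATP-analogue nucleotide with an undocked
neck-linker) because the open and open* geometries overlap. Density
quantification follows the published formulas: open/closed relative
density as background-subtracted backbone means over the
non-overlapping KH0/KH1/KH2/KH3 regions (residues 403–412, 463–471,
501–515, 577–579), normalized by their sum — background is subtracted
in numerator and denominator, resolving an ambiguity in the printed
formula — and nucleotide relative density as base-atom mean over
P-loop (476–494) mean. Background probes are drawn in a 6–10 Å shell
around the selection, at least 3.5 Å from any model atom; those radii
are not printed anywhere and are logged with every run.

## Numerical choices and degenerate inputs

Projection is central-slice extraction from a 2× zero-padded transform
with trilinear interpolation; reconstruction is its exact adjoint with
sinc² de-apodization, so duplicated particle streams and doubled
weights give bit-identical maps. Fewer than three distinct views warn
about anisotropy. Fourier-crop resampling preserves the DC term.
`recenter` uses exact circular shifts for integer-pixel displacements
and Fourier phase ramps otherwise, and errors if the projected centre
leaves the croppable region. Defocus refinement is an exhaustive grid
search (step 50 Å, range ±1250 Å, u and v moved jointly with
astigmatism fixed) and returns the input when the range is smaller than
the step; the moving median over five contiguous particles truncates
its window at filament ends rather than inventing data, which is why
its idempotence on monotone series holds only where the full window
fits. Shift refinement is meaningful down to a quarter pixel thanks to
the parabolic peak interpolation; below that the shifts are held fixed.
Argmax ties in class selection go to the lowest class index and are
counted.

## Limitations

The noise model is white and scalar; the per-frequency spectral model
of production implementations is out of scope, as are pose
marginalization, Ewald-sphere correction, per-particle B-factors and
map-to-model validation. The deposited-model descriptor validation
requires coordinate downloads and is therefore exercised on synthetic
coordinates plus the printed descriptor table in the offline test
suite. Classification fidelity in dimer mode (~80% per-subunit) trails
the monomer case because the registration signal is spread over a
two-subunit span; the equally-populated-classes observable is robust.
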