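# hasrc

Subunit refinement and classification for helically symmetric cryo-EM
assemblies, at desk scale.

Helical reconstruction averages every asymmetric unit of a decorated
filament into one map. When the decorating subunits coexist in several
conformations — kinesin motor domains that are *open* on some tubulin
sites and *closed* on others, or a two-heads-bound dimer whose leading
and trailing heads differ — the helical average blurs the states
together. `hasrc` implements the HASRC workflow (helical assembly
subunit refinement and classification) that separates them:

1. **symmetry expansion** — replicate each segment's alignment record
   once per asymmetric unit, composing its pose with the screw operator
   `S_k : p ↦ R_z(k·168.08°) p + k·5.45 Å · ẑ` of the 15-start lattice;
2. **partial signal subtraction** — remove the CTF-modulated projection
   of `consensus × (1 − mask)` from every image, re-centred on the
   projected centre of mass *C*<sub>M</sub> of the mask;
3. **focused 3D classification without alignment** — regularized-
   likelihood EM over class assignments, responsibilities
   ∝ `w_c · exp(−‖(I − CTF·Proj V_c)·m‖² / 2σ²)` with `m` the projected
   focus mask, stabilized by deterministic annealing;
4. **local subunit refinement** — per-particle grid search over Euler
   perturbations under a Gaussian prior (`sigma_ang`) and sub-pixel
   shifts within 3.5 Å;
5. **reconstruction from the original (non-subtracted) images** per
   class and gold-standard half, real-space screw averaging, and masked
   FSC with resolution read at the 0.143 threshold.

A built-in simulator generates synthetic decorated-microtubule segments
(Gaussian pseudo-atom conformers on a 15R lattice, CTF at 1.0–1.9 μm
defocus, white noise, optional per-subunit lattice displacements) with
per-subunit ground-truth labels that only evaluation code may read. The
package also computes the motor-domain conformational descriptors — the
nucleotide-binding-pocket Cα distances K488–R604 (SW1–P-loop) and
R406–T647 (KH0–SW2), and the central β-sheet twist (∠ between Cα
475→480 and 527→531) — classifies conformations from them, and
quantifies open/closed and nucleotide relative densities in maps.

## Worked example

```r
library(hasrc)

spec <- phantom_spec()                        # 64^3 box at 4 A/px
sym  <- helical_symmetry()                    # rise 5.45 A, twist 168.08 deg
ctf  <- ctf_params(pixel_size = 4)

## 70/30 open/closed mixture, 3000 subunits at variance-SNR 0.05
sigma <- sigma_for_snr(spec, sym, snr = 0.05, ctf = ctf, seed = 11)
sim <- simulate_stack(spec, sym, n_segments = 200, n_filaments = 40,
                      mode = "mixture", fraction_open = 0.7,
                      noise_sigma = sigma, ctf = ctf, seed = 42)

mm  <- mask_models(spec, sym, "monomer")
run <- run_hasrc(sim$stack, sim$records, sym,
                 mask_full_model = mm$full, mask_kinesin_model = mm$kinesin,
                 ctf = ctf, mode = "monomer", K = 2, tau = 4,
                 iterations = 50, refine_selected = FALSE, seed = 7)
run
#> hasrc_run (monomer mode): 3000 expanded subunits, K = 2
#> class populations: 0.697 0.303
#>   class 1: 2092 particles, FSC_0.143 = 9.66 A
#>   class 2: 908 particles, FSC_0.143 = 10.71 A

evaluate_against_truth(run$records, sim$truth)[c("ari", "fraction_open")]
#> $ari
#> [1] 0.9262216
#> $fraction_open
#> [1] 0.6973333
```

The run recovers the simulated 70/30 conformational split to within a
fraction of a percentage point (the drawn ground truth here is 69.6%
open) and assigns individual subunits with an adjusted Rand index of
0.93 against the per-subunit truth. The printed populations are the two
class fractions after hard assignment; each populated class is
reconstructed from the original images per half-set, with its masked
gold-standard resolution reported.

The geometric classifier reproduces the published conformation groups
from the bundled descriptor table:

```r
ref <- kif14_reference_descriptors()
table(classify_conformation(ref),
      ifelse(ref$group %in% c("open", "open_star"), "open_like", ref$group))
#>               closed open_like semi_closed
#>   closed           8         0           0
#>   open_like        0        16           0
#>   semi_closed      0         0           1
```

A thin command-line front end over the same functions lives at
`inst/cli/helixsort.R` (`simulate`, `expand`, `run`, `fsc`, `geometry`,
`evaluate` subcommands; MRC/MRCS volumes, STAR-dialect tables, JSON
reports).

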