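# smdmtools

Tools for inferring the assembly state of intermediate-filament proteins
(vimentin, GFAP, keratins) from single-molecule diffusivity and from
sequence-based electrostatics.

The vimentin cytoskeleton — a homopolymer of a single ~54 kDa, ≈ −18-charged
protein — disassembles within minutes under low ionic strength and reassembles
within seconds when screening is restored. Two measurements quantify this:

* **Single-molecule displacement/diffusivity mapping (SMdM).** Transient
  (1 ms) displacements of ~10⁵ tagged molecules are binned spatially and each
  bin's magnitudes *r* are fit by maximum likelihood to
  `P(r|D) = (r/s²) exp(−r²/2s²)` with `s² = 2DΔt + 2σ_loc²` (optionally mixed
  with a uniform background), yielding a map of the local diffusion
  coefficient *D*. Filament-bound fusions show *D* ≈ 1.5 µm²/s, dispersed
  oligomers ~6–8 µm²/s; the cube-root mass scaling `D ∝ M^(−1/3)` converts the
  dispersed-state *D* into an average oligomer size.
* **Protein charge and screening.** Henderson–Hasselbalch titration of the
  sequence gives net charge vs pH and the isoelectric point; buffer recipes
  are speciated into ions to get ionic strength `I = ½Σcᵢzᵢ²`, Debye length
  `κ⁻¹ ∝ I^(−1/2)`, and osmolarity — separating the two variables hypotonic
  experiments usually confound.

The package contains a synthetic displacement generator (two-population
diffusivity fields with localization error), the per-bin MLE fitter and map,
the oligomer-size converter, the charge/pI calculator with bundled vimentin
and GFAP sequences, buffer presets for the relevant media, and an end-to-end
demo pipeline. No raw imaging data are required anywhere.

## Worked example

```r
library(smdmtools)

## simulate a filamentous cell and map its diffusivity
settings <- acquisition_settings(dt = 1e-3, sigma_loc = 0.02, seed = 7)
field <- make_filament_field(c(32, 32), n_filaments = 12, D_bound = 1.5,
                             D_free = 7, bound_fraction = 0.6, seed = 3)
sim <- simulate_displacements(field, settings, 2e5)
map <- map_diffusivity(sim$records, lattice_from_field(field), settings)
map
#> <diffusivity_map> 32 x 32 bins (0.4 um), 1024 unmasked, median D = 6.84 um^2/s

## dispersed-state D of 1/3 the free-FP reference -> average oligomer size
oligomer_size_from_D(D_measured = 1, D_reference = 3, mw_reference = 27,
                     mw_construct = 81, mw_vimentin = 54)
#> <oligomer_estimate> species mass 729.0 kDa -> 9.00 subunits (~10 filament proteins, 'all-fusions' assumption)

## sequence charge: vimentin is ~ -18 e at pH 7.3 with pI ~ 5
vim <- read_fasta(system.file("extdata", "vimentin_P08670_synthetic.fasta",
                              package = "smdmtools"))[[1]]
net_charge(vim, pH = 7.3, pka = "protcalc")
#> [1] -18.36972
charge_curve(vim)$pI
#> [1] 5.128001

## the low-ionic-strength / high-osmolarity medium vs DPBS
speciate("phosphate5_pH7.3_glucose350")
#> <ionic_state> phosphate5_pH7.3_glucose350 (pH 7.3): I = 0.01057 M, kappa^-1 = 2.96 nm, 363 mOsm/L
speciate("dpbs")
#> <ionic_state> dpbs (pH 7.3): I = 0.1637 M, kappa^-1 = 0.752 nm, 311 mOsm/L
```

The map's median D reads ~6.8 µm²/s here because free molecules populate every
bin while filaments cover a minority of them; per-region medians (on- vs
off-mask) separate cleanly into ~1.5 vs ~7. The oligomer estimate turns the
printed ratios (D ratio 3, 27 kDa reference, 3-fold-heavier fusion) into a
729 kDa species: 9 fusions, the "~10-mer" headline. The two buffers show the
decoupling that matters: the glucose-augmented phosphate medium is
*hyper*-osmotic relative to DPBS yet ~15-fold lower in ionic strength, so any
disassembly it causes after permeabilization is an ionic-strength effect, not
an osmotic one.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "smdmtools", package = "smdmtools"))')
Rscript $CLI simulate --out disp.csv --n 100000 --seed 1
Rscript $CLI fitmap --in disp.csv --out dmap
Rscript $CLI charge --fasta my.fasta --ph 7.3
Rscript $CLI buffer --preset dpbs
Rscript $CLI demo --out demo_run --seed 1
```

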