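---
title: "Inferring intermediate-filament assembly state from single-molecule diffusivity and protein charge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring intermediate-filament assembly state from single-molecule diffusivity and protein charge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdmtools)
```

## The scientific problem

Vimentin, the intermediate-filament protein of mesenchymal cells, self-assembles
hierarchically from a single ~54 kDa subunit without nucleators or energy input
— and in live cells its cytoskeleton can fully disassemble within minutes of
hypotonic stress, then reassemble within seconds of osmotic recovery. Two
quantitative handles make this behavior tractable at the desk:

1. **Diffusion.** Single-molecule displacement/diffusivity mapping (SMdM)
   collects the transient (~1 ms) displacements of ~10^5 individually localized
   tagged molecules between paired stroboscopic excitations, bins them
   spatially, and fits each bin's displacement distribution to yield a map of
   the local diffusion coefficient *D*. Filament-incorporated vimentin fusions
   show apparent *D* ≈ 1.5 µm²/s; after disassembly the dispersed species move
   at ~6–8 µm²/s, about 1/3 the rate of the free ~27 kDa fluorescent protein.
2. **Electrostatics.** The vimentin sequence carries ≈ −18 elementary charges
   at pH 7.3. Whether those mass-accumulated like charges are screened (high
   ionic strength, short Debye length) or intensified (high pH) predicts
   filament stability; the media used to probe this are all specifiable as
   buffer recipes.

`smdmtools` implements that full inference chain on synthetic data: a
displacement simulator, the per-bin maximum-likelihood fitter, the
diffusion-to-oligomer-size conversion, sequence charge curves, and buffer
ionics.

## The displacement model and its fitter

A molecule with local diffusion coefficient $D$ observed over pair interval
$\Delta t$ with per-axis localization precision $\sigma_{loc}$ (affecting both
paired localizations) has displacement components
$\Delta x, \Delta y \sim \mathcal{N}(0,\; 2D\Delta t + 2\sigma_{loc}^2)$, so
the magnitude $r$ is Rayleigh:

$$P(r \mid D) = \frac{r}{s^2}\, e^{-r^2 / 2s^2}, \qquad
  s^2 = 2D\Delta t + 2\sigma_{loc}^2 .$$

Optionally the model is mixed with a uniform-in-area background
$P_{bg}(r) = 2r/R_{cap}^2$ at weight $\varphi$, for bins contaminated by
mispaired localizations within the capture radius $R_{cap}$.
`fit_diffusivity()` maximizes the likelihood in $D$ (and $\varphi$ when
enabled): a bounded 1-D search started from the moment estimate, followed by a
Newton polish on the score, so that in the analytically solvable case
($\varphi = 0$, $\sigma_{loc} = 0$) the numeric optimum reproduces the closed
form $\hat D = \sum r_i^2 / (4N\Delta t)$ to better than 1e-9 relative error —
a dual-route check the test suite runs on 100 seeded instances. The joint
$(D, \varphi)$ fit uses multi-start L-BFGS-B because $\varphi$ often sits on
the boundary.

Numerical choices: the likelihood is given a large finite penalty (not `Inf`)
outside its support so L-BFGS-B never sees non-finite values; $\hat D$ is
floored at 0; bins with fewer than `n_min = 10` displacements are masked
rather than fitted (the acquisition literature does not fix this threshold;
10 keeps the estimator's relative error below ~25% where it is reported at
all); bin origins exactly on a boundary go to the higher-index bin (half-open
`[lo, hi)` convention).

## What the synthetic generator emulates — and what it does not

`make_filament_field()` rasterizes weakly-persistent random-walk polylines
onto a bin lattice: on-mask bins carry `D_bound` (default 1.5 µm²/s — the
filament state shows apparent motion, so bound molecules are slow, not
immobile), off-mask bins `D_free` (default 7 µm²/s, the middle of the
dispersed 6–8 range). `simulate_displacements()` places a stated fraction of
molecules on the mask, draws each displacement from the local $s^2$, and
discards (but counts) displacements beyond the capture radius, conserving
`n_molecules` exactly. Defaults follow the acquisition they emulate: 1 ms pair
interval, ~10^5 molecules per state, 0.4 µm bins. Values the source experiments
never state are set once at field-realistic levels and exposed in
configuration: $\sigma_{loc}$ = 0.02 µm (typical single-molecule localization
precision), $R_{cap}$ = 0.8 µm.

The generator does **not** simulate cameras, point-spread functions, photon
noise, localization algorithms, drift, molecular crossing between bins within
a step (1 ms steps are short relative to 0.4 µm bins), or dissociation
kinetics. A green recovery test therefore establishes that the *estimator
chain* is unbiased for data obeying the model's statistical structure — not
that the model captures every feature of real acquisitions.

## From diffusivity to oligomer size

For compact species, $D$ scales inversely with the cube root of molecular
weight with little shape dependence, so a measured $D$ against a monomeric
reference of mass $M_{ref}$ gives the species mass
$M = M_{ref}\,(D_{ref}/D)^3$. With the printed inputs — $D$ at 1/3 of the free
fluorescent protein, a 27 kDa reference, and a fusion ~3-fold heavier — the
species mass is $27 \times 3^3 = 729$ kDa; under the `all-fusions` assumption
(every subunit tagged) that is 9 subunits, reported alongside the
nearest-ten convenience figure of ~10. The alternative `one-tag` assumption
(one tagged construct among untagged 54 kDa subunits) is implemented and
labeled, giving 13 untagged subunits for the same inputs; `all-fusions` is the
default because the measured construct is the expressed fusion itself. The
absolute reference $D$ is a configurable input, never a constant: only the
ratio enters.

## Sequence charge, pI, and pKa presets

`net_charge()` sums Henderson–Hasselbalch fractional charges over D, E, C, Y
(acidic), K, R, H (basic) and the two termini; Cys and Tyr are included
because the calculators this reproduces include them (toggleable). Two pKa
presets ship: `"emboss"` and `"protcalc"` (the constants of the sequence-only
Protein Calculator tool: N-term 8.0, C-term 3.1, K 10.0, R 12.0, H 6.5,
D/E 4.4, C 8.5, Y 10.0). The `protcalc` preset is the default because it
reproduces the reference charge landmarks of this system — vimentin ≈ −18.4 e
at pH 7.3 with pI ≈ 5.13, GFAP ≈ −12.1 e — from the canonical human sequences.
The pI is found by bisection on the (strictly decreasing) charge function to
1e-4 pH units, independent of any plotting grid.

One property deserves a caveat: the textbook statement "at the pH extremes the
charge equals the ionizable-group counts" holds per group to ~0.01 e when all
pKas sit ≥ 2 units inside [0, 14], but not in aggregate for chains rich in
arginine (pKa 12): vimentin's 25 arginines retain ~0.25 e in total at pH 14.
The tests therefore check the aggregate bound on short sequences and a
per-group relative bound on full-length chains.

The bundled vimentin and GFAP FASTA files are offline reconstructions of the
canonical UniProt entries (P08670, P14136), labelled `_synthetic` because they
could not be fetched at build time; their computed molecular weights
(53.65 and 49.88 kDa) match the published values of those entries exactly,
and the charge landmarks above corroborate them.

## Buffer ionics

`speciate()` distributes each weak acid/base across protonation states at the
recipe pH (shipped constants: phosphate 2.15/7.20/12.35, acetate 4.76, CAPSO
9.6 — all configurable), adds strong-electrolyte ions, H⁺/OH⁻, and monovalent
counter-ions for exact electroneutrality, then reports
$I = \tfrac12 \sum c_i z_i^2$, the Debye length
$\kappa^{-1} = \sqrt{\varepsilon_r \varepsilon_0 k_B T / (2 N_A e^2 I \cdot 10^3)}$
(≈ 0.78 nm at 150 mM, 298 K), and ideal van 't Hoff osmolarity. Everything is
ideal-solution: no activity coefficients, ion pairing, or multivalent
correlations. Nonionic osmolytes (glucose, sorbitol) raise osmolarity without
touching $I$ — exactly the decoupling the 5 mM phosphate + 350 mM glucose
medium exploits: it is *hyper*-osmotic relative to DPBS (≈ 363 vs ≈ 311
mOsm/L here) yet ~15-fold lower in ionic strength (0.0106 vs 0.164 M).

The `repulsion_index()` — $Z^2 e^{-d/\kappa^{-1}}/d$ for subunit charge $Z$
at spacing $d$ — is an **interpretive** screened-Coulomb ranking tool, flagged
as such in every report it appears in. It is not a model stated by the source
experiments; it merely orders media and charge states the way the qualitative
stability model does (quadrupling with a doubled charge, shrinking with
screening).

Design choices where the sources are silent: the DPBS preset uses the
standard no-Ca/Mg formulation at pH 7.3 (the physiological pH quoted for the
system; nominal DPBS spans 7.0–7.3); detergents and permeabilizers are
treated as nonionic with negligible ionic contribution; the intracellular
ionic strength itself is never asserted — reports compare media only.

## Reproducibility machinery

Every stochastic operation draws from a locally seeded generator and restores
the caller's RNG state; sub-streams (timecourse steps, demo stages) derive
deterministically from one master seed, so a configuration plus seed
reproduces every CSV/JSON byte. Diffusivity grids travel as uncompressed
32-bit float TIFFs (written by a minimal internal writer, cross-validated in
the tests against an independent TIFF reader) with a JSON lattice sidecar as
the authoritative georeferencing.

## Known limitations

* Bound-state motion is modeled as slow free diffusion, not constrained
  motion along a filament; the apparent-D convention matches, the physics
  does not.
* The single-population fit is knowingly misspecified in bins containing both
  populations; it then reports a weighted apparent D (which is also what the
  real measurement reports).
* The charge model is sequence-only: no structural pKa shifts, no
  phosphorylation enumeration (a fixed −2 per phosphosite can be passed to
  `fusion_charge()`).
* Osmolarity is ideal and will overestimate high-concentration media.
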