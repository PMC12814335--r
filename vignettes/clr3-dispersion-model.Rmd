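---
title: "State-specific dispersion in polarizable QM/MM embeddings: the model behind clr3disp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-specific dispersion in polarizable QM/MM embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clr3disp)
```

## The problem

The absorption energy of a chromophore embedded in a protein or solvent is
shifted by its environment. Polarizable QM/MM (MMPol) embeddings capture the
electrostatic and induction parts of that shift well, but London dispersion —
the correlated-fluctuation attraction between the chromophore and its
surroundings — changes upon electronic excitation too, because the molecular
polarizability of the excited state differs from that of the ground state. A
pigment whose excited state is *less* polarizable than its ground state loses
dispersion stabilization upon excitation and its transition shifts to the
blue; a more polarizable excited state shifts it to the red. For
light-harvesting pigments this state-specific dispersion term is of the same
order as the excitonic couplings that shape the energy funnel, so neglecting
it biases site energies.

`clr3disp` implements the dispersion side of the cLR³ decomposition of the
excitation energy in a polarizable atomistic environment,

$$\Delta E_{\mathrm{cLR^3}} \;=\; \Delta E_{\mathrm{GS\text{-}pol}}
  + R_{\mathrm{SS\text{-}pol}} + R_{\mathrm{LR\text{-}disp}}
  + R_{\mathrm{SS\text{-}disp}},$$

where $\Delta E_{\mathrm{GS\text{-}pol}}$ is the excitation energy with the
environment polarization frozen to the ground state, $R_{\mathrm{SS\text{-}pol}}$
the state-specific polarization response, $R_{\mathrm{LR\text{-}disp}}$ the
linear-response (transition-density) dispersion term, and
$R_{\mathrm{SS\text{-}disp}}$ the state-specific dispersion difference. The
first three come out of a polarizable-embedding response solver and are
consumed here as plain tables; the fourth is what this package computes:

$$R_{\mathrm{SS\text{-}disp}} = R^{\mathrm{ExS}}_{\mathrm{disp}}
  - R^{\mathrm{GS}}_{\mathrm{disp}}, \qquad
R^{\mathrm{state}}_{\mathrm{disp}} = -\sum_{A}^{\mathrm{QM}}\sum_{B}^{\mathrm{MM}}
  f_{AB}\, C_{6,AB}\, R_{AB}^{-6}.$$

Only QM–MM pairs enter the sum: intramolecular (QM–QM) dispersion is part of
the electronic-structure calculation, and MM–MM dispersion cancels in the
excitation-energy difference.

## Volume ratios: density-dependent C6 coefficients

Following the Tkatchenko–Scheffler (TS) scheme, atomic polarizabilities are
taken proportional to atomic volumes. The in-molecule volume of atom $A$ is
obtained by Hirshfeld (stockholder) partitioning of the molecular electron
density $\rho$ delivered on a Gaussian cube grid,

$$\gamma_A[\rho] = \frac{V_A[\rho]}{V_A^{\mathrm{free}}}
 = \frac{\int r^3\, w_A(\mathbf r)\, \rho(\mathbf r)\, d^3 r}
        {\int r^3\, \rho_A^{\mathrm{free}}(r)\, d^3 r},\qquad
  w_A(\mathbf r) = \frac{\rho_A^{\mathrm{free}}(|\mathbf r - \mathbf R_A|)}
        {\sum_B \rho_B^{\mathrm{free}}(|\mathbf r - \mathbf R_B|)},$$

with $r$ measured from the nucleus of $A$ in both integrals (the standard TS
convention; the numerator's weight field and the denominator share the same
free-atom reference). From the ratios,

$$\alpha_A^{\mathrm{eff}} = \gamma_A\, \alpha_A^{\mathrm{free}}, \qquad
  C_{6,AA}^{\mathrm{eff}} = \gamma_A^2\, C_{6,AA}^{\mathrm{free}},$$

and heteronuclear coefficients follow the standard combination rule

$$C_{6,AB} = \frac{2\, C_{6,AA} C_{6,BB}}
 {\frac{\alpha_B}{\alpha_A} C_{6,AA} + \frac{\alpha_A}{\alpha_B} C_{6,BB}},$$

which is symmetric and exact in the homonuclear limit. MM atoms have no
density; their ratios are estimated directly from the force field's atomic
polarizabilities, $\gamma_B = \alpha_B^{\mathrm{MM}} / \alpha_B^{\mathrm{free}}$,
and are treated as state-independent — the environment stays in its
electronic ground state.

## Excited-state rescaling

The polarizability–volume proportionality is a ground-state argument. An
electronically excited molecule acquires negative-frequency transition terms
in its polarizability; the imaginary-frequency polarizability can shrink or
even turn negative, which no non-negative volume can represent. Applying the
Hirshfeld machinery to the excited-state density alone therefore misses part
of the polarizability change.

The correction adopted here rescales each excited-state volume ratio so that
the scaled TS atomic polarizabilities reproduce the excited/ground ratio of a
distributed-polarizability decomposition (Heid–Hunt–Schröder style, HHS),
whose atomic contributions sum to the molecular polarizability:

$$\beta_A = \frac{\gamma_A^{\mathrm{GS}}}{\gamma_A^{\mathrm{ExS}}}\cdot
            \frac{\alpha_A^{\mathrm{HHS,ExS}}}{\alpha_A^{\mathrm{HHS,GS}}},
  \qquad \tilde\gamma_A^{\mathrm{ExS}} = \gamma_A[\rho^{\mathrm{ExS}}]\,\beta_A.$$

By construction $\tilde\alpha_A^{\mathrm{ExS}} / \alpha_A^{\mathrm{GS}} =
\alpha_A^{\mathrm{HHS,ExS}} / \alpha_A^{\mathrm{HHS,GS}}$ atom by atom — the
defining identity, asserted to 1e-12 in the test suite — and the scaled
molecular sum $\sum_A \tilde\gamma_A \alpha_A^{\mathrm{free}}$ inherits the
HHS molecular ratio. The default mode keeps the full density dependence
(excited-state ratios from the excited-state density, then rescaled); the
documented alternative `mode = "hhs_only"` neglects the volume-ratio change
and uses the bare HHS ratio. HHS tables are consumed as per-atom scalars;
anisotropic tensors are reduced to their isotropic mean (trace/3) on input.
Per-configuration (embedded) HHS sets may be averaged arithmetically with
`average_hhs_sets()` before the ratio is formed.

A negative excited-state HHS atomic polarizability is a hard error, not a
clamp: it signals a repulsive-dispersion regime that the volume-ratio model
cannot represent, and silently flooring it would fabricate an attraction.

## Damping and its parameters

The $R^{-6}$ sum diverges at short range; a Fermi switch suppresses it:

$$f_{AB}(R) = \left[1 + \exp\!\left(-d\left(\frac{R}{s_r (R^0_A + R^0_B)}
  - 1\right)\right)\right]^{-1}.$$

| parameter | meaning | default | units |
|---|---|---|---|
| `d` | steepness of the switch | 20 | — |
| `s_r` | scaling of the vdW-radius sum | 0.97 | — |
| `radius_mode` | effective radii $R^0 = \gamma^{1/3} R^0_{\mathrm{free}}$ (`"scaled"`) or free radii (`"free"`) | `"scaled"` | — |
| `cutoff` | pair-distance cutoff | none (all pairs) | bohr |

The damping family and its two parameters are a modeling choice this package
makes explicitly: the Fermi form with $d = 20$ is the TS convention, and
$s_r = 0.97$ sits in the narrow range used across TS parametrizations. Both
are exposed in `damping_spec()` and recorded in every result's metadata,
because short-range pair energies are sensitive to them — results that hinge
on near-contact pairs should be checked against a second parametrization.
For excited states the scaled $\tilde\gamma$ enters the radius scaling too,
keeping the damping consistent with the density dependence of the C6 side.
No cutoff is applied by default; a finite cutoff is a user choice and is
validated against the fingerprint when ground- and excited-state results are
differenced. Note one deliberate consequence of `radius_mode = "scaled"`:
a larger $\gamma$ grows $C_6$ *and* pushes the damping radius outward, so
for near-contact pairs the two effects can partially offset; the strict
"larger volume, deeper attraction" monotonicity holds at fixed radii.

## Free-atom reference data

Free-atom polarizabilities, homonuclear $C_6$ coefficients and vdW radii are
packaged from the standard Chu–Dalgarno-derived reference set used by TS
implementations (H, C, N, O, F, Na, Mg, P, S, Cl; atomic units throughout).
Elements outside the table are a hard error rather than a silent default —
$C_6$ errors are quadratic in $\gamma$. Users can override any element via
`load_element_params(path)`.

The packaged free-atom *densities* are deliberately simple single-exponential
Slater models $\rho(r) = n_e \zeta^3/(8\pi)\, e^{-\zeta r}$ with valence-like
exponents, normalized exactly to the electron count. They make the whole
pipeline self-contained and analytically checkable (the hydrogen model's
$r^3$-weighted volume is exactly $60/\zeta^3 \cdot n_e = 7.5$ bohr³·e), but
they are not Hartree–Fock atomic densities: for production partitioning,
tabulated radial densities can be substituted per element
(`free_atom_density(element, table = ...)`).

## Numerical choices

- **Units.** Atomic units internally (bohr, hartree); cm⁻¹ only in reported
  results, with 219474.6313632 cm⁻¹/hartree; coordinates read from XYZ/PDB
  are converted at 1.8897259886 bohr/Å.
- **Quadrature.** Volume integrals are plain Riemann sums on the delivered
  cube grid — the grid *is* the data; accuracy is governed by its spacing
  and checked by a refinement property (halving the spacing moves γ by less
  than 5e-3 on bonded-distance fixtures). Tabulated radial densities are
  integrated by composite trapezoid on their own grid; the analytic Slater
  models use closed forms.
- **Promolecule floor.** Grid points where the promolecule density falls
  below ε = 1e-12 e/bohr³ are excluded from all integrals (weights set to
  zero), avoiding 0/0 far from the molecule. On retained points the weights
  sum to 1 to machine precision.
- **Degenerate inputs.** Coincident atoms, QM–MM pairs closer than 0.1 bohr,
  non-positive γ, empty QM selections, unit-label mismatches in component
  tables, and already-scaled γ sets passed to the scaler are all hard
  errors. Tiny negative cube values (correlated densities) are tolerated up
  to a configurable magnitude (default 1e-4).
- **Fingerprints.** Dispersion results carry a geometry/damping/cutoff
  fingerprint; differencing two results with different fingerprints is
  refused rather than silently producing a meaningless shift.

## The site-energy assembly

`assemble_clr3()` is the exact arithmetic sum of the four components;
`site_energy_table()` averages frames per pigment label first (averaging and
assembling commute by linearity). `site_energy_range()` reports the spread
of site energies across environments and attributes it per component as
(component range)/(total range) — components co-vary, so the attributions
need not sum to 100% and are reported unrenormalized.

Published tables print components rounded to integer cm⁻¹ *after* averaging,
so a recomputed total can differ from a printed total by up to ±2 cm⁻¹ (four
half-unit roundings) and a recomputed range by a couple of cm⁻¹; the
packaged LH2 example table therefore carries the published assembled totals
in a clearly marked extra column for cross-checking, and comparisons against
printed integers use a ±2 cm⁻¹ tolerance rather than forcing agreement.

## What the synthetic fixtures do and do not show

`make_model_density()` superposes scaled free-atom model densities, so the
target γ values are known by construction (exactly equal to the scales for
non-overlapping atoms, recovered to ≤1e-2 at 0.25 bohr spacing on the
fixtures used in the tests, which run on grids of ~3×10⁵ points).
`make_toy_system()` generates seeded random QM/MM geometries (minimum
separation 4.5 bohr in a 15–25 bohr box — roughly the closest nonbonded
H···H approach, so environment atoms sit at or outside van der Waals
contact with the chromophore rather than inside the damping wall),
γ/HHS/component tables with recorded ground truth, and writes every file
the CLI consumes plus a JSON manifest. Note that the blue/red sign rule for
the state-specific shift is a statement about dispersion-bound geometries:
for pairs squeezed far inside the damping midpoint, the γ-dependence of the
damping radius dominates the γ-dependence of C₆ and individual pair
contributions can invert, which is the same feedback discussed in the
damping section. "Excitation" as per-atom density rescaling yields analytically
known targets, which is its purpose; it does not emulate charge transfer,
nodal structure of real excited-state densities, or anisotropic
polarizability changes. Passing tests therefore demonstrate that the
*machinery* — partitioning, scaling algebra, pairwise summation, assembly —
is correct, not that the physical model is accurate for any particular
chromophore; the latter depends on the quality of the supplied densities,
HHS tables and MM polarizabilities.

## Known limitations

- Pairwise-additive $C_6/R^6$ only: no many-body dispersion, no $C_8/C_{10}$
  terms, no exchange–repulsion, no analytic gradients.
- The response quantities ($\Delta E_{\mathrm{GS\text{-}pol}}$,
  $R_{\mathrm{SS\text{-}pol}}$, $R_{\mathrm{LR\text{-}disp}}$) and the HHS
  decomposition itself are inputs; this package neither runs TD-DFT nor
  solves the polarizable-embedding response equations.
- Hirshfeld partitioning is the classic stockholder scheme; iterative
  (Hirshfeld-I) refinements are out of scope.
- The packaged free-atom densities are model exponentials (see above).

## A worked example

```{r example, eval = FALSE}
library(clr3disp)

# seeded toy system: geometry + gamma/HHS/component tables + manifest
sys <- make_toy_system(seed = 42, n_qm = 5, n_mm = 20, box = 25)

# excited-state rescaling from the HHS tables
beta <- compute_beta(sys$gamma_qm_gs, sys$gamma_qm_exs_unscaled,
                     sys$hhs_gs, sys$hhs_exs)
gamma_es <- scaled_volume_ratios(sys$gamma_qm_exs_unscaled, beta)

# ground- and excited-state dispersion, and the state-specific shift
gs <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm)
es <- dispersion_energy(sys$geometry, gamma_es, sys$gamma_mm)
state_specific_dispersion(es, gs)

# assembling published MD-averaged components for the LH2 antenna
lh2 <- read_component_table(system.file("extdata",
  "lh2_qy_components_cm1.tsv", package = "clr3disp"))
tab <- site_energy_table(lh2)
tab$total                      # 13721, 13817, 13965 cm^-1
site_energy_range(tab)         # spread and per-component attribution
```
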