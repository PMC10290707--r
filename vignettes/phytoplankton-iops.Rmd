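---
title: "Modelling chlorophyll-specific phytoplankton optics with coated spheres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chlorophyll-specific phytoplankton optics with coated spheres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoiop)
```

## The model

`phytoiop` simulates hyperspectral inherent optical properties (IOPs) of
phytoplankton assemblages — Chl-*a*-specific absorption $a^*_\phi$, scatter
$b^*_\phi$ and backscatter $b^*_{b\phi}$ (m$^2$ mg$^{-1}$), together with
volume scattering functions, phase functions and backscatter probabilities —
from a small set of biophysical parameters.  Each cell is a concentric
two-layer sphere: for eukaryotes a weakly absorbing cytoplasm core
(volume fraction $V_c = 1 - V_v$) surrounded by a pigmented chloroplast
shell (volume fraction $V_v$); for vacuolate cyanobacteria a low-refractive-
index vacuole-like core surrounded by a shell holding the thylakoids and
cytoplasm.  The electromagnetic problem is solved exactly (stratified-sphere
Mie theory), so the pigment package effect, the interference structure of
scattering, and the angular distribution of scattered light all emerge from
the physics rather than from parameterisations.

The chain from biology to optics is:

1. **Imaginary refractive index of the shell.**  A pigment absorption shape
   (a measured mean *in vivo* spectrum, or a synthetic sum of Gaussian
   pigment bands) fixes the spectral form of the shell's imaginary
   refractive index $n'(\lambda)$.  Its magnitude is anchored at 675 nm,
   where Chl *a* dominates and the core is assumed non-absorbing: the shell
   material absorption is equated with that of unpackaged pigment at the
   intracellular density, $a_{675} = (c_i / V_v)\, a^*_{sol}(675)$ with
   $a^*_{sol}(675) = 0.027$ m$^2$ mg$^{-1}$, and converted through the
   standard relation $n' = a \lambda_{med} / 4\pi$ (with
   $\lambda_{med} = \lambda / n_{media}$, $n_{media} = 1.334$).  This makes
   the imaginary index — and through it every IOP — an explicit function of
   the intracellular Chl-*a* density $c_i$.
2. **Real refractive index by causality.**  The real part must be consistent
   with the imaginary part through the Kramers–Kronig relations; its
   dispersion shape is computed as the discrete Hilbert conjugate of
   $n'(\lambda)$ and anchored so its 400–850 nm spectral mean equals a
   literature magnitude: 1.10 for the chloroplast shell, 1.02 for the
   cytoplasm core (all refractive indices relative to water).
3. **Per-particle optics.**  The complex indices $m = n - i\,n'$ of core and
   shell enter the stratified-sphere engine, which returns efficiency
   factors $Q_a$, $Q_b$, $Q_{bb}$, cross sections, the unpolarised angular
   intensity on 1800 angles, the phase function and the backscatter
   probability for each diameter and wavelength.
4. **Assemblage integration.**  Per-particle cross sections are summed over
   a size distribution characterised by its effective diameter $D_{eff}$ and
   effective variance $v_{eff}$, normalised so the assemblage holds exactly
   1 mg Chl *a* m$^{-3}$; the resulting coefficients are therefore
   numerically Chl-specific.  Intracellular carbon density $C_i$ (by
   default tied to the homogenised real index at 660 nm through the
   empirical relation $C_i = 3441.055\,n(660) - 3404.99$) yields the
   carbon-to-Chl ratio of the same assemblage.

The packaged library spans 16 eukaryote groups plus a *Microcystis*-like
vacuolate prokaryote, each over 4–5 effective diameters and
$c_i \in \{2, 5, 8\}$ kg m$^{-3}$ (`pg_groups()`), written in the published
per-group CSV layout by `build_pg_dataset()`.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `c_i` | kg m$^{-3}$ | — | whole-cell intracellular Chl-*a* density; healthy cultures span ~0.5–6, the library extends to 8 to cover photoacclimation |
| `V_v` | — | 0.2 | chloroplast (shell) volume fraction of eukaryote cells |
| `a_sol_675` | m$^2$ mg$^{-1}$ | 0.027 | unpackaged Chl-*a*-specific absorption at 675 nm (the anchor) |
| shell / core real-RI magnitude | — | 1.10 / 1.02 | spectral-mean anchors of the Hilbert-derived real indices |
| core `amp400`, `slope` | —, nm$^{-1}$ | $10^{-4}$, 0.01 | exponential imaginary index of the cytoplasm; negligible at 675 nm by construction |
| `D_eff`, `v_eff` | µm, — | —, 0.6 | Hansen–Travis moments of the size distribution; 0.6 is the monospecific-culture width used for the library |
| `n_bins` | — | 50 | diameter bins of the discretised distribution |
| vacuole `core_real_ri`, `core_fraction` | —, — | 0.75, 0.15 | relative index (gas ≈ 1.0 absolute) and volume fraction of the prokaryote vacuole core — configurable stand-ins |
| `n_media` | — | 1.334 | real refractive index of the aqueous medium |

## Numerical choices

**Discrete Hilbert transform.**  The dispersion shape is computed with the
half-sample discrete Hilbert kernel $2/\pi(i-j)$ over odd index offsets,
after removing the straight line through the two endpoints of the input.
This combination is spectrally accurate for resolved absorption bands
(verified against the analytic Lorentzian conjugate pair to better than 1%
of the dispersion amplitude on interior wavelengths) and maps constants to
exactly zero, so band-free spectra acquire no spurious structure.  Because
any finite-window transform is unreliable near its edges, indices are built
on 380–900 nm and IOPs reported only on 400–850 nm; shapes whose measured
support ends at 385/800 nm should first be extended with
`extrapolate_edges()` (straight-line extrapolation, clamped at zero).

**Stratified-sphere recursion.**  Two-layer Mie coefficients are evaluated
with logarithmic derivatives of the Riccati–Bessel functions (downward
recurrence for $D^{(1)}$, upward for $D^{(3)}$ via the $\psi\zeta$ product)
combined through the bounded ratio
$Q_n = [\psi_n(z_1)/\xi_n(z_1)]\,/\,[\psi_n(z_2)/\xi_n(z_2)]$, so only
O(1) quantities are ever formed and absorbing layers remain stable to size
parameters of several hundred (series length
$N = \lceil x + 4.05x^{1/3} + 2\rceil$, with an explicit error — never a
silent truncation — beyond a configurable cap).  The engine was validated
against the closed-form Rayleigh polarizability of a coated sphere, a
from-first-principles boundary-condition solve with independently computed
Bessel functions, and an arbitrary-precision homogeneous reference; absolute
accuracy is ~$10^{-10}$ relative at $x \lesssim 100$, degrading gracefully
to ~$10^{-4}$ at $x \sim 500$ for nearly conservative particles (the
classical upward Riccati–Bessel recurrence past the turning point).

**Angular grid and quadrature.**  Scattering angles sit at the 1800 uniform
midpoints 0.05°, 0.15°, …, 179.95°; excluding the exact forward direction
keeps quadrature of the forward diffraction lobe well behaved.  Integrals
over angle use composite-midpoint weights ($\sin\theta\,\Delta\theta$),
which on this grid are symmetric about 90° (fore–aft symmetric patterns give
a backscatter probability of exactly one half).  For assemblage work the
backscatter probability divides the backward-hemisphere quadrature by the
exact series identity $\int_0^\pi S_{11}\sin\theta\,d\theta = x^2 Q_b/2$
rather than by a forward-lobe quadrature, which stays accurate when the lobe
of large particles is sharper than 0.1°.  For the same reason the VSF of
assemblages dominated by particles with $x \gtrsim 10^3$ under-resolves the
forward peak; its solid-angle integral is verified against $b^*$ to
$10^{-3}$ for the micron-scale fixtures used in the tests.

**Size distribution.**  The monospecific generator uses the two-parameter
standard distribution of size-distribution optics,
$n(d) \propto d^{(1-3b)/b} e^{-d/ab}$, on a fixed uniform bin grid, with
$(a, b)$ solved by damped Newton iteration so the *discrete* binned moments
reproduce the requested $(D_{eff}, v_{eff})$ to $10^{-6}$; an infeasible
request (for instance a span too narrow to carry the requested variance)
raises an explicit error.  A Gaussian bell cannot carry an effective
variance of 0.6 — truncated to positive diameters its Hansen–Travis
effective variance is bounded near 0.21, with the exponential limit of the
family capping at 1/3 — so the gamma-shaped standard family, which realises
the library's $v_{eff} = 0.6$ exactly and reduces to a narrow quasi-normal
bell at small $v_{eff}$, is used for all distributions.  Cross sections are
evaluated at bin centres; doubling the default 50 bins changes $a^*$ by
less than 0.1%.  Requests with $v_{eff} < 10^{-8}$ return a single delta
bin.  The default bin span reaches $D_{eff}(1 + 2\sqrt{v} + 4v)$
(≈ 4.9 $D_{eff}$ at $v_{eff} = 0.6$); the moments are re-solved on the
truncated support, so reported moments are exact by construction.

**Problem sizes.**  The test-suite builds the full 17-group, 451-wavelength
library grid at 5 diameter bins, which reproduces the schema and the
qualitative physics at a few percent of the cost of the 50-bin production
build; physics checks that need converged values (package effect, closure,
limits) run at single wavelengths with 15–30 bins.

## The synthetic pigment library

Measured mean *in vivo* absorption shapes for the 17 groups are not shipped;
`synthetic_invivo_means()` substitutes deterministic sums of Gaussian
pigment bands — a Soret band at 438 nm and the Chl-*a* red peak at 675 nm
for every group, plus diagnostic bands per group (phycocyanin 620 nm for
blue-mode cyanobacteria and *Microcystis*, phycoerythrin ~565 nm for
red-mode cyanobacteria and *Synechococcus*, Chl *b* 480/650 nm for green
algae, fucoxanthin/carotenoid shoulders for diatoms, dinoflagellates and
relatives).  These stand-ins preserve what the model actually consumes — a
positive spectral shape with a 675 nm anchor and group-distinctive band
structure — so tests exercised on them demonstrate the machinery
(anchoring, dispersion, package effect, schema), not fidelity to any
particular culture: spectral details of real assemblages (band fine
structure, measured band ratios, shoulder asymmetries) are not represented,
and the library's numerical values will differ from those derived from
measured means.  Users with measured shapes load them with
`read_invivo_means()` and obtain measurement-driven libraries through the
same pipeline.

## Design choices in open territory

- **Units of the 675 nm anchor.**  The anchoring relation is implemented
  dimensionally, as the standard absorption-to-imaginary-index conversion
  $n' = a\,\lambda_{med}/4\pi$ applied to the chloroplast-local absorption
  $(c_i/V_v)\,a^*_{sol}$, with $c_i$ in mg m$^{-3}$ and $\lambda_{med}$ in
  metres.
- **Real-RI anchoring.**  "Scaled to 1.10/1.02" is interpreted as the
  400–850 nm spectral mean because the Hilbert dispersion shape is
  mean-free by construction; anchoring the peak instead would make the
  magnitude depend on band structure.
- **Whole-cell vs compartment densities.**  The empirical
  $c_i(n'_{675})$ relation does not state whether it refers to the
  pigmented compartment or the whole cell (the two differ by $V_v$); the
  function documents the ambiguity and applies no hidden correction.
- **Vacuole configuration.**  The prokaryote core uses a flat relative
  index of 0.75 (a gas inclusion) with volume fraction 0.15, inside the
  documented range of gas-vesicle volume fractions; both are configurable
  stand-ins.  With them, the vacuolate configuration scatters and
  backscatters more at 550 nm than the eukaryote configuration of the same
  size and pigmentation, as expected for buoyant bloom-forming
  cyanobacteria.  Replacing only the core at fixed geometry elevates the
  backward-hemisphere scattering robustly, but *reduces* total scatter at
  the 3–6 µm *Microcystis* sizes: the low-index core cancels part of the
  shell's phase advance near the interference maximum of $Q_b$.  Total-b
  elevation under same-geometry replacement therefore holds only for cells
  below a couple of microns and is not asserted in general.
- **Divinyl-Chl groups.**  *Prochlorococcus* lacks monovinyl Chl *a*; the
  same 675 nm anchor is nevertheless applied to its divinyl-dominated
  shape, which overstates the certainty of its absolute magnitude — a
  documented caveat rather than a correction.

## Known limitations

- **Rayleigh-limit anchor deficit.**  The 675 nm anchor equates shell
  *material* absorption with unpackaged pigment absorption; for
  vanishingly small cells electromagnetic absorption additionally carries
  the internal-field (Lorentz) factor of the coated particle, whose exact
  electrostatic value for the default indices gives
  $a^*(675) \to 0.977 \times 0.027$ instead of 0.027.  Finite-size
  corrections cancel the deficit near $D_{eff} \approx 0.2$ µm and
  overshoot to +3% around 1 µm, so $a^*(675)$ is not monotone in
  $D_{eff}$ below ~1 µm; the package effect proper (monotone decline) sets
  in from about 1 µm upward.
- Spheres only: no shape, aggregation or internal-structure complexity
  beyond the two concentric layers, and no polarised (Mueller-matrix)
  output.
- Single-population assemblages: mixed multi-group or power-law open-ocean
  assemblages are composable from per-group outputs but not packaged.
- The model demonstrates signal causality (how pigment, size and density
  drive optics); it is not a species-accurate reproduction of measured
  IOPs, and absolute values inherit the uncertainty of $c_i$, $V_v$ and
  the real-RI magnitudes.
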