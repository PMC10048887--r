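---
title: "Multistate reaction energetics of pinene hydroxylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate reaction energetics of pinene hydroxylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinetics)
```

## The problem

Cytochrome P450 (CYP) monooxygenases hydroxylate hydrocarbons through a
two-step radical mechanism: the iron(IV)-oxo species abstracts a hydrogen atom
from the substrate (the rate-limiting step), and the resulting carbon radical
rebounds onto the Fe-bound hydroxyl to give the alcohol. For a substrate like
alpha- or beta-pinene the outcome is decided by a competition across many
close-lying states: eight candidate abstraction sites on the bicyclic
scaffold, two diastereotopic allylic hydrogens (a *cis* and a *trans*
stereopath) at the key allylic site, and three spin surfaces of the
iron-porphyrin system (doublet, quartet, sextet) that are near-degenerate and
can interconvert. Predicting the dominant product therefore is not a single
barrier calculation but an ensemble analysis: relative free energies of all
competing stationary points, equilibrium (Boltzmann) populations of the
conformers at each reaction-coordinate stage, and transition-state-theory
rates for the competing abstraction paths.

`pinetics` implements that analysis as a reusable post-processing layer. It
deliberately does **not** perform electronic-structure calculations: the DFT
energies, the D4 dispersion and geometric-counterpoise (BSSE) corrections and
the PCM solvent term are inputs, accepted as pre-computed additive terms. The
package's job is everything downstream of them.

## Model and conventions

**Energies.** All energies are carried internally in hartree (Eh) and
converted to kcal/mol only at reporting boundaries, with a fixed factor of
627.5095 kcal/mol per Eh. That factor, applied to the packaged reference
tables, recovers the published relative-energy cells at their printed
precision, which is why it is the default rather than a higher-precision
CODATA value; it is configurable in `pin_constants()`.

**Corrected free energy.** The working quantity is
$G_\mathrm{cor} = G_\mathrm{DFT} + E_\mathrm{disp} + E_\mathrm{gCP} +
\Delta G_\mathrm{qh} (+ E_\mathrm{solv})$, a plain sum of finite additive
terms (`correction_set()`, `total_free_energy()`). Additivity and
commutativity are asserted, nothing more: the package validates and sums,
it never re-derives a correction.

**Relative energies.** `relative_energies()` follows the convention of the
published tables: the most stable structure of a set defines the zero, so the
minimum maps to exactly 0 and all other entries are non-negative. Ties are
broken by first occurrence in input order, which makes the reference
deterministic for any fixed input ordering.

**Boltzmann populations.** For an ensemble of conformers at one
reaction-coordinate stage,
$p_i = \exp(-(G_i - G_{\min})/k_BT) \big/ \sum_j \exp(-(G_j - G_{\min})/k_BT)$
with $k_B = 3.166811563\times10^{-6}$ Eh/K applied directly to hartree
energies — no molar conversion is involved, and subtracting the minimum
before exponentiation makes the computation overflow-safe for arbitrarily
deep absolute energies (the reference tables sit near $-1976$ Eh). Each
conformer counts as a single state: no degeneracy factors are applied,
matching how the published distributions treat the conformers.

**Eyring kinetics.** $k = \kappa\,(k_BT/h)\,e^{-\Delta G^\ddagger/RT}$ with
the barrier in kcal/mol and $R = 1.98720425864\times10^{-3}$ kcal/(mol K).
The transmission coefficient defaults to 1 (no tunnelling correction — the
source analysis is silent on tunnelling). `rate_ratio()` exposes the
prefactor-free ratio $e^{(\Delta G^\ddagger_2-\Delta G^\ddagger_1)/RT}$.

**Temperature.** The default is 298.15 K at 1 atm. The source analysis never
states its temperature explicitly; 298.15 K reproduces the published
populations to the printed digit, so it is adopted as the package default and
exposed in `run_config()`.

## Quasi-harmonic thermochemistry

`thermochemistry()` builds ideal-gas thermal corrections from a harmonic
frequency list: Sackur–Tetrode translational entropy at (T, P), classical
rigid-rotor rotational entropy with a symmetry number, electronic entropy
$k_B\ln g$, harmonic ZPE and vibrational thermal energy. Two vibrational
entropy treatments are available:

* **RRHO** — the textbook harmonic-oscillator mode entropy
  $S_\nu = k_B\left[\frac{x}{e^{x}-1} - \ln(1-e^{-x})\right]$,
  $x = hc\nu/k_BT$, which diverges as $\nu \to 0$;
* **quasi-RRHO** (default) — the Grimme interpolation: each mode is also
  assigned a free-rotor entropy through an effective moment
  $\mu = h/(8\pi^2c\nu)$, reduced against an average molecular moment
  $B_\mathrm{av}$ as $\mu' = \mu B_\mathrm{av}/(\mu+B_\mathrm{av})$, and the
  two are mixed with the damping weight $w(\nu) = 1/(1+(\nu_0/\nu)^\alpha)$:
  $S = w\,S_\mathrm{RRHO} + (1-w)\,S_\mathrm{FR}$.

Defaults $\nu_0 = 100\ \mathrm{cm^{-1}}$, $\alpha = 4$,
$B_\mathrm{av} = 10^{-44}\ \mathrm{kg\,m^2}$ are the canonical parameters of
that scheme; all are configurable. Design points worth stating explicitly:

* only the entropy is interpolated — ZPE and thermal energy stay harmonic,
  so RRHO and quasi-RRHO results differ in `s_vib` alone;
* frequencies are used unscaled (no empirical scaling factor is applied);
* imaginary modes (negative wavenumbers) are dropped with a warning, not
  projected — the common post-processing convention; appending an imaginary
  mode to any input leaves every component unchanged;
* no hindered-rotor scans and no anharmonic (VPT2) treatment: the
  quasi-harmonic free-rotor interpolation is the only low-mode treatment
  implemented, because it is the only one the source methodology specifies
  operationally.

Because no frequency lists are published for this system, the thermochemistry
module is validated entirely by closed-form oracles (independently coded
formula evaluations in the test helpers) and by properties: mode-wise
envelope between the RRHO and free-rotor values, the exact midpoint
$w(\nu_0)=\tfrac12$, the high-frequency collapse onto RRHO, and monotonic
temperature dependence over 100–1000 K.

## Reaction paths and profiles

A `reaction_path` maps stages I (reactant complex) → II (abstraction TS) →
III (radical + Fe–OH) → IV (hydroxylated product) for one
site/spin/stereopath. Two conventions come straight from the chemistry:

* **The rebound step is barrierless.** No rebound TS could be located at the
  underlying level of theory, so the schema has no stage for it: III → IV is
  a first-class barrierless segment, never an error. A missing abstraction TS
  (stage II) is likewise a flagged state, usable for sensitivity checks.
* **Descriptors are stage differences.** Reaction quantities are
  (III − I), barriers are (II − I), and the hydroxylation free energy
  $^\mathrm{Hyd}\Delta_rG_\mathrm{cor}$ is (IV − I), each in the matching
  energy column (electronic, enthalpy, Gibbs, corrected Gibbs), reported in
  kcal/mol with negative meaning released.

`profile_report()` emits one row per path with all nine descriptors, ordered
site → spin ascending → *cis* before *trans* (the layout of the published
descriptor tables), and checks transition-state betweenness (TS above both I
and III in corrected G). The check warns rather than fails because the
published set itself contains one endergonic path (the beta-pinene
alpha-site doublet) whose barrier lies below its reaction free energy.

`render_diagram()` anchors every profile at the single global reference —
the most stable stage-I structure across all paths — and emits stage-wise
relative energies with uniform stage spacing, as CSV, aligned text, or a
minimal deterministic SVG (identical numeric series across formats; the SVG
is static, byte-stable, and suitable for snapshot testing). For the packaged
beta-pinene set the reference resolves to the alpha-site doublet reactant
complex; for alpha-pinene, to the gamma-site doublet — both as published.

### Reconstructed stages

Only stage-I absolute free energies are published for the enzyme-bound
system; the stage II–IV absolute values live in an appendix that is not
distributed with the tables. The published coordinate-I and coordinate-III G
columns are, moreover, not on a common footing: stage III minus stage I from
those columns does not reproduce the printed reaction free energies.
`reference_paths()` therefore reconstructs stages II, III and IV as stage-I
G plus the corresponding printed descriptor, flags the paths
`reconstructed`, and carries the corrected-minus-uncorrected gap as a lumped
correction term. The coordinate-III ensemble table is used only for what it
is internally consistent for — Boltzmann populations. This split mirrors how
the source analysis itself uses the two tables.

## Synthetic ensembles and the oracle design

`generate_ensemble()` emulates the object of study — a multi-conformer,
multi-spin ensemble at one reaction-coordinate stage — by prescribing
free-energy gaps above a base structure: uniform or exponential gap draws, or
explicit gap lists, at a realistic absolute anchor (−1976 Eh, the scale of
the enzyme-bound system). A fixed seed fully determines the output, and the
RNG state of the session is left untouched. The generator returns the
analytically known populations alongside the ensemble, computed by a second,
deliberately simpler implementation: direct closed-form weights relative to
the first member, with no overflow-guarding minimum subtraction, evaluated on
the gaps the ensemble actually realized in double precision. Engine and
oracle share no code path, and the closed-loop test demands agreement to
1e-10 over 100 random specifications.

Two numerical facts shaped this design. First, the hartree-scale Boltzmann
constant and the kcal-scale molar gas constant are independently rounded
published values; routing the same gap through the two constants differs at
~4e-8 relative, so an oracle defined in kcal/mol can never agree with the
hartree-space engine to 1e-10. Second, at an absolute anchor of −1976 Eh the
spacing of double-precision numbers is ~2.3e-13 Eh, so "the gap as
prescribed" and "the gap as stored" differ enough to move populations at the
~5e-10 level. The oracle therefore takes the realized gaps as ground truth;
a separate test documents the kcal-route agreement at its attainable ~1e-6
level. What the synthetic ensembles do **not** emulate: real conformer
searches (no geometry, no redundancy, no basin structure), correlated
spin-state energetics, or DFT-level noise. Passing the closed loop
demonstrates the statistics are exact, not that the energies of any real
system are right.

`generate_spectrum()` provides harmonic-mode stand-ins (sorted positive
wavenumbers, optionally one leading imaginary mode for a TS) for exercising
the thermochemistry; the mode positions are uniform draws, not fitted to any
molecule.

## Reference data and known inconsistencies

Nine published tables ship as CSV under `inst/extdata/` with a JSON manifest
(source table number, row counts, notes). Printed kcal/mol and percentage
columns are stored as character strings so their printed precision is
recoverable; minus signs are ASCII. Three cells of the beta-pinene
bare-system table are reproduced at one unit in the last printed digit
rather than at exact half-up rounding (20.9 vs computed 20.955, 19.4 vs
19.450, 4.63 vs 4.635) — evidently truncated at source; the table-wide test
asserts the one-ulp bound, while the headline cells match exact rounding.

One row of the alpha-pinene coordinate-I ensemble is internally
inconsistent: the alpha-quartet G value implies a negligible Boltzmann
weight, yet a 20.9% population is printed. The row ships verbatim, tagged
`suspect = TRUE`, and `compare_populations()` reports all comparisons as
pairwise population ratios against the most stable non-suspect row — a
statistic immune to the normalisation error one bad row introduces. All
non-suspect rows agree with recomputation within 0.4% relative.

One narrative claim is deliberately not reproduced: the stated "two and
three times faster" comparison between the delta-trans-doublet path and the
delta-cis doublet/quartet paths. The Eyring ratio from the printed barriers
(10.8 vs 12.4 and 13.6 kcal/mol) gives 14.9× and 112.8× at 298.15 K under
any transmission coefficient; the procedure behind the printed factors is
not recoverable, so the package surfaces the computed ratios instead.

## Degenerate inputs, tie-breaks, tolerances

* Empty ensembles, non-finite free energies, non-positive temperatures,
  frequencies or moments are rejected with explicit messages.
* All-imaginary spectra are an error; a single imaginary mode is at most a
  warning (and is excluded everywhere).
* Auto-reference ties: first occurrence wins.
* `g_corr = h_corr − T·ΣS` is maintained to 1e-10 Eh by construction and
  asserted in tests.
* Machine-readable outputs are written at full precision; rounding happens
  only in human-readable report rendering (`output_precision`, default 3
  significant digits).

## Problem sizes

Everything here is desk-scale by design: the ensembles have 8–10 members,
the property suites run 100-ensemble closed loops and 1000-point conversion
round-trips, and synthetic spectra use 10–15 modes. The entire test suite
and the full two-molecule analysis complete in seconds on one CPU.

## Limitations

* No electronic-structure content: energies and corrections are trusted
  inputs; no checkpoint/log-file parsing beyond the documented CSV/JSON and
  frequency-list formats.
* No spin-crossover (MECP) location and no microkinetic time-course: spin
  interconversion feasibility is treated qualitatively, as in the source
  analysis.
* No concentration standard-state corrections (ideal gas at 1 atm only).
* The sextet stage-III structures of the real system are non-classical
  (no rebounded product); the schema carries this as a free-text note, not a
  distinct type.
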