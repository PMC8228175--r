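---
title: "Modelling 2D-material ISFET biosensors with an LC frequency readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 2D-material ISFET biosensors with an LC frequency readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isfetsim)
```

# Scope and assumptions

`isfetsim` models a label-free DNA biosensor as a chain of closed-form
stages: sequence comparison, proton release, surface-charge transduction,
Dirac-channel quantum capacitance, a four-capacitor equivalent circuit, and
an LC resonant readout.  Every stage is a deterministic algebraic map; there
are no differential equations, no Poisson–Boltzmann electrostatics, and no
hybridization thermodynamics.  The package's purpose is to make the coupled
parameter dependencies of such a device — how carrier density, geometry,
oxide thickness and inductance interact — explorable and testable, not to
predict absolute signal levels for a fabricated device.

The structural assumptions, in the order the chain applies them:

* **Ideal Dirac dispersion.** The channel density of states is linear in
  energy with a single Fermi velocity, so
  $E_F = \mathrm{sign}(n)\,\hbar v_F \sqrt{\pi |n|}$ and the finite-$T$
  quantum capacitance per unit area is
  $C_Q'' = \frac{2 e^2 k T}{\pi (\hbar v_F)^2}
  \ln\!\big[2(1+\cosh\tfrac{E_F}{kT})\big]$.
  Band gaps, spin–orbit structure and defect states are outside the model;
  the silicene/graphene presets differ only through $v_F$, mobility,
  geometry and residual density.
* **Lumped interface electrostatics.** The Stern, diffuse and bulk layers
  of the solid–liquid interface are represented by constant capacitors, not
  by a spatial potential profile.  $C_{semi}$ and $C_{elec}$ are
  user-supplied constants with large defaults (1 µF) so that
  $C_{ISFET} = \mathrm{series}(C_{semi}, C_{OX}) +
  \mathrm{series}(C_{elec}, C_Q)$ is dominated by the quantum capacitance,
  the regime the device concept relies on.
* **Square-law transistor.** The drain current is the textbook triode
  expression, clamped at its vertex beyond pinch-off and zero below
  threshold.  No subthreshold conduction, velocity saturation or contact
  resistance.
* **Linear ion-release chemistry.** Every matched base releases a fixed
  number of protons into a fixed volume; the carrier-density response to
  the concentration change is a single linear gain.  Amplification cycles,
  buffer chemistry and melting thermodynamics are not modelled.

# Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `fermi_velocity` | m/s | 5.21e5 (silicene), 1.1e6 (graphene) | sets the $C_Q$ magnitude; the material presets' defining constants |
| `gate_length`, finger width, finger count | µm, µm, – | 1 (sil.) / 0.2 (gra.), 10, 200 | active area $A = LWN$; scales every capacitance |
| `eot_nm` | nm | 0.6 (sil.), 0.5 (gra.) | oxide capacitance $C_{OX} = 3.9\,\varepsilon_0 A / \mathrm{EOT}$; sweepable 1–8 nm |
| `residual_carrier_density` | cm⁻² | 1e9 (sil.), 1e10 (gra.) | floor density at charge neutrality; see below |
| `inductance` | H | 250e-9 | tank inductor; sets the frequency scale $f = 1/(2\pi\sqrt{LC_Q})$ |
| `ions_per_match`, `solution_volume`, `charge_to_density_gain` | –, L, (m⁻²)/(mol/L) | 1, 1e-6, 1e19 | the ion-release model; illustrative values, not measurements |
| `planck_convention` | – | `"reduced"` | which Planck constant enters the Dirac formulas |

Geometry note: the tabulated gate lengths and finger widths are read as
micrometres, the only physically plausible unit for a multi-finger FET gate
(a metre-scale gate would give farad-scale oxide capacitances).  Both are
overridable.

**Planck convention.** Some device-modelling sources typeset the Dirac
formulas with the bare Planck constant $h$ where the derivation from the
linear dispersion requires $\hbar$.  The package defaults to $\hbar$
(`planck_convention = "reduced"`), which is the physically standard choice;
`"bare"` substitutes $h$ literally so the typeset variant can be reproduced
and cross-checked.  The two differ by exact factors of $2\pi$, which the
test suite pins.

**Residual density floor.** The ideal Dirac $C_Q$ vanishes at $n = 0$,
which would make the LC frequency diverge.  Real samples retain an
electron–hole puddle density at nominal neutrality, so the sweep floors the
effective density at the material's residual density.  The presets use the
clean-sample lower bounds of the tabulated ranges, 1e9 cm⁻² for silicene
and 1e10 cm⁻² for graphene: this preserves the silicene-below-graphene
ordering of charge density, and it keeps the floor below the default sweep
resolution (1e11 cm⁻² per grid step) so the frequency curve is strictly
monotone in $|n|$ everywhere except the single regularized
charge-neutrality row.  A floor at or above the grid step would instead
flatten the first step of the curve — an artifact of regularization, not of
the physics.

# The DNA front end

Sequences are 2-bit encoded with A→00, C→01, G→10, T→11.  This particular
code is chosen because it makes Watson–Crick complementarity a bitwise
identity: two bases pair exactly when their codes XOR to 11, so the
complement-mode Match-Score is computable in Boolean algebra, and the
identity-mode score (XOR = 00) falls out of the same comparison.  Both
modes are exposed because "similarity" of a probe/target pair can
reasonably mean either; complement mode is the hybridization-relevant
default.  Comparison is positionwise over the shorter sequence; an optional
`reverse_target` flag reverses the target first, which is what antiparallel
hybridization against a reverse-complement target requires.

The downstream mapping — protons per match, reaction volume, and the
charge-to-density gain — has no canonical parameterization; the defaults
(one proton per matched base, 1 µL, 1e19 (m⁻²)/(mol/L)) are documented as
illustrative and chosen only to keep every stage's output finite, positive
and monotone.  Conclusions about absolute pH or frequency shifts should not
be drawn from them; relative and monotonicity statements (more matches ⇒
more protons ⇒ lower pH ⇒ larger frequency shift) are the meaningful
outputs, and those are what the test suite asserts.

# Synthetic fixtures: what they emulate and what they do not

`make_fixture_pairs(n_pairs, length, mismatch_frac, seed)` draws uniform
random probes and builds each target as the positionwise complement with
exactly `round(mismatch_frac * length)` planted non-complementary
positions.  The complement-mode Match-Score of each pair is therefore known
*by construction*, which is what makes the fixtures a ground truth for the
scoring algorithm: the planted score is recovered exactly, and a
character-level brute-force comparison must agree with the bitwise
implementation pair by pair.

What the generator does **not** emulate: real probe/target panels are not
uniform random (GC content, repeats, secondary structure), mismatches are
not uniformly placed, hybridization is not all-or-nothing per position, and
real measurements add noise at every stage.  Passing the fixture suite
therefore demonstrates the correctness of the scoring and transduction
algebra, not sensor performance on real assays.

# Numerical choices

* `log(2(1 + cosh x))` is evaluated as `log(4) + 2 log(cosh(x/2))` with an
  overflow-safe `log(cosh)`, so the thermal capacitance is finite for
  arbitrarily degenerate $E_F$ (naive `cosh` overflows near $x = 710$).
* Signed densities enter square roots as $|n|$, with the sign retained only
  on $E_F$; evenness of $C_Q$ is then exact in floating point, not
  approximate.
* The drain current is continuous at both boundaries: zero below threshold
  and clamped at the triode vertex beyond pinch-off.
* The staged sensitivity holds the capacitor network fixed at the operating
  point; the feedback of the perturbation on $C_Q$ itself is second order
  and excluded by the stage definitions.  The suite checks the staged
  product against the composed pipeline at $dn = 10^{-6} n_0$.
* Reference values in the device literature are printed at two significant
  figures; `round_sig()` reproduces that convention with
  round-half-away-from-zero at ties (unlike `signif()`).
* Series composition returns 0 when either capacitor is 0 and drops an
  infinite capacitor exactly, so the dominant-capacitor limits used in the
  analysis are identities rather than approximations.

# Problem sizes

The default sweeps use 601 grid points over ±3×10¹³ cm⁻² and 8 EOT points
over 1–8 nm — fine enough that monotonicity and evenness are checked at the
resolution a practitioner would plot, while the whole suite (including
1,000 scored fixture pairs of length 120 and the five-step detection
ladder) runs in well under a minute.

# Known limitations

* Absolute capacitance magnitudes depend on the geometry reading and the
  rounded physical constants; the package treats printed peak-capacitance
  values from the device literature as *inputs* to the readout stage (e.g.
  `resonant_frequency(lc_readout(), 5.5e-12)`), not as outputs the model
  must reproduce, because they are not derivable from the stated equations
  and geometry under any single unit convention.
* The tuning ratio has no canonical definition in the source literature;
  the package pins $\mathrm{TR} = 1 - \sqrt{C_{Q,\min}/C_Q}$, the relative
  downward frequency shift from the sweep's minimum-capacitance point —
  dimensionless, zero-anchored, monotone in $C_Q$.  Comparisons with other
  definitions require recomputation.
* pH is computed as $-\log_{10}[\mathrm{H}^+]$, the chemical definition
  (sources occasionally typeset it without the sign).
* No noise model: every reported shift is a noiseless model output.
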