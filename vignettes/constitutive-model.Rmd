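---
title: "Stress softening and residual strains by the rule of mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress softening and residual strains by the rule of mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mullins)
```

## The model

Soft biological tissues and biocompatible polymers loaded cyclically in
uniaxial tension or compression show two conspicuous inelastic effects: the
stress on reloading falls below the virgin (first-loading) curve up to the
previously attained maximum strain (the Mullins effect), and a nonzero
stretch remains at zero stress after unloading (permanent set). This package
implements a constitutive family that captures both on top of a
rule-of-mixtures hyperelastic backbone, together with a cycle simulator,
packaged literature parameter sets, a synthetic-data generator, and
calibration tools.

### Kinematics

All states are incompressible and handled in the principal frame: a state is
the stretch triple $(\lambda_1,\lambda_2,\lambda_3)$ with invariants
$I_1,I_2,I_3$ of the right Cauchy–Green tensor and the strain intensity
$m=\sqrt{\operatorname{tr}B^2}=\sqrt{I_1^2-2I_2}$, which equals $\sqrt3$ at
the identity and grows on both the tensile and compressive side. Uniaxial
states have $\lambda_2=\lambda_3=\lambda^{-1/2}$ and
$m=\sqrt{\lambda^4+2\lambda^{-2}}$. Full tensors are never materialised:
every downstream equation depends only on stretches and invariants, and the
uniaxial scope makes the general machinery untestable dead weight.

### Energy: rule of mixtures

The total strain energy density blends a matrix and a fiber contribution,

$$W_T=(1-f)\,W_{iso}(I_1)+f\,W_{aniso}(I_1,I_3),$$

where $f\in[0,1]$ is the equivalent anisotropic volumetric fraction. The
matrix part is the amended non-Gaussian eight-chain energy

$$W_{iso}=\mu\left[N\Big(\beta\lambda_r+\ln\frac{\beta}{\sinh\beta}\Big)
-\frac{\sqrt N}{8}\ln\frac{\beta}{\lambda_r}\right]+c,
\qquad \lambda_r=\sqrt{\frac{I_1}{3N}},\quad
\beta=\mathcal L^{-1}(\lambda_r),$$

with $\mathcal L(\beta)=\coth\beta-1/\beta$ the Langevin function, $\mu$ the
shear modulus, $N$ the number of rigid links per chain (locking stretch
$\sqrt N$) and $c$ an additive energy constant. The fiber part is the
eight-chain anisotropic energy *isotropized* over the diagonal direction set
$(\pm1,\pm1,1)/\sqrt3$,

$$W_{aniso}=\frac{A_1}{3}(I_1-3)+\frac{A_2}{9}(I_1-3)^2
-\frac{2A_1}{3}\ln I_3 .$$

The grouping of the amendment term in $W_{iso}$ is not typographically
unambiguous in the printed sources this model family descends from. We fixed
it by requiring *exact* analytic consistency with the response function

$$\aleph=2\frac{\partial W_{iso}}{\partial I_1}
=\frac{\mu}{3\lambda_r}\left[\beta+\frac{1}{8\sqrt N}
\Big(\frac1{\lambda_r}-\frac{1}{\beta(1-\lambda_r^2-2\lambda_r/\beta)}\Big)\right],$$

which is the unique reading under which the stress is the energy gradient;
the test suite verifies $\sigma=\mathrm dW_T/\mathrm d\lambda$ by central
differences to $10^{-6}$ relative over random parameter draws, and the
Gaussian limit $\aleph\to\mu$ as $N\to\infty$ recovers the neo-Hookean
model.

### Virgin stress and the direction-cosine question

Eliminating the hydrostatic pressure against traction-free lateral faces
gives the virgin uniaxial engineering stress

$$\sigma(\lambda)=\Big[(1-f)\aleph+\tfrac{2f}{3}\big(A_1+\tfrac{2A_2}{3}(I_1-3)\big)\Big]
\frac{\lambda^2-\lambda^{-1}}{\lambda}.$$

A literal transcription of the stress-difference equations carries a factor
$\{x_{ji}^2-x_{ki}^2\}$ of fiber direction cosines which is identically zero
for the eight-chain set (all $x^2=1/3$) — it would annihilate every fitted
fiber constant. The implemented default uses the derivative of the
isotropized energy above (the only reading consistent with
$\sigma=\mathrm dW_T/\mathrm d\lambda$ and with nonzero published $A_2$
fits); the literal variant is retained behind
`fiber_term = "literal"` for audit.

### Stress softening with permanent set

Once the material has been loaded to a maximum strain intensity $M$ (with
per-axis stretch maxima $\lambda_{max,a}$), states below the primary path
follow

$$\tau_j-\tau_k=\Big[(T_j-T_k)+\frac{\mu C}{2}
(\lambda_j f_j-\lambda_k f_k)\Big]\,e^{-b(M-m)(m/M)},
\qquad
f_k=-2n\lambda_k^{n-1}\big(\lambda_{max,k}^n-\lambda_k^n\big).$$

The exponential kernel equals 1 on the primary path, so loading, unloading
and reloading meet without stress discontinuities; $b\ge0$ controls the
depth of softening and $C\ge0$ the permanent set. The kernel's printed form
has also lost typography in the sources; the package treats it as a
selectable strategy (`kernel = "literal"`, the default above, or
`kernel = "sqrt"` for $e^{-b(\sqrt M-\sqrt m)\sqrt{m/M}}$). Every package
property relies only on the kernel contract (unity at $m=M$, positive,
decreasing away from the primary path), so both variants fit and simulate
identically in structure. The residual exponent $n$ defaults to 1, the value
used in practice. With $C>0$ the unloading branch crosses zero at a residual
stretch $\lambda_{res}>1$, located by bracketed bisection
(`residual_stretch()`, residual below $10^{-9}$); the bracket is confined to
the history-consistent region $m\le M$, since $m$ grows again in
compression.

Histories update on *any* primary-path excursion, including compression:
$m$ measures intensity regardless of strain sign, so a compressive leg
extends $M$ exactly as a tensile one. This is the behaviour needed for
tension–compression brain protocols.

### Pseudo-elastic unloading

As an alternative inelastic law the package implements a modified
Dorfmann–Ogden pseudo-elastic model,

$$\tau_j-\tau_k=\Big[(T_j-T_k)+(1-\eta_2)\big(\nu_1\lambda_j^2-\nu_2\lambda_k^2\big)\Big]\eta_1,$$

with softening variables driven by the total energy relative to its value at
reversal, $W_{max}=W_T(\lambda_{max})$:

$$\eta_1=1-\frac1{r_1}\tanh\frac{W_{max}-W_T}{\mu m_1},\qquad
\eta_2=\frac{1}{r_1\tanh1}\tanh\big[(W_T/W_{max})^\alpha\big],$$
$$\nu_1=\nu_2\Big(1-\frac1{r_2}\tanh[10(\lambda_{max}-1)]\Big),\qquad
\nu_2=\gamma\mu,\qquad
\alpha=\frac1{10}\Big(3+\frac{8W_{max}}{5\mu}\Big).$$

The groupings (division bars are lost in the printed sources) are the only
dimensionless readings giving $\eta_1=1$ and $\eta_2=1/r_1$ at the reversal
point, so the gap to the virgin curve at reversal is proportional to
$1-1/r_1$ and vanishes as $r_1\to1$ — consistent with published fits using
$r_1\approx1$. $\eta_1$ multiplies the whole bracket. The constant $c$
enters $W_T$ and $W_{max}$ consistently; the difference $W_{max}-W_T$ is
invariant to it, the ratio $W_T/W_{max}$ is not, which is why the sign and
size of $c$ matter only to $\eta_2$.

## Parameters, units and fixtures

Stress-valued parameters ($\mu$, $A_1$, $A_2$, the printed residual constant,
$\nu_2$) live in one working pressure unit per material (MPa or kPa — the
unit of $\mu$). The packaged fixtures store every published number verbatim
with its printed unit and convert on load:

* tracheal fiber constants are printed in MPa against a kPa $\mu$ and are
  rescaled $\times10^3$;
* the energy constant $c$ is printed in J/m³ (= Pa) and is rescaled to the
  working unit;
* fiber fractions are printed in percent and divided by 100 (for the vaginal
  sets, whose printed 0.2 is ambiguous between 0.2% and a 0.2 fraction, the
  percent reading is the default and `f_as_fraction = TRUE` exposes the
  other);
* the printed residual-strain column carries stress units while the model
  constant $C$ is dimensionless entering as $\mu C$; the printed number is
  read as the product $\mu C$, i.e. `soft$C = printed / mu`.

Each fixture also records a protocol stretch $\lambda_{max}$ — the largest
(or, for compression sets, smallest) stretch its loading curve is exercised
to in tests. These were chosen once from the deformation ranges the
materials are reported to sustain and from the locking stretches implied by
$N$ (the tracheal sets stay inside the observed 1.048–1.215 window; the
mucosa/submucosa membranes lock near $\lambda\approx1.19$, the adventitial
membranes near 1.23).

## Numerical choices

* **Inverse Langevin.** Defined by root finding, not by a fixed approximant:
  a Padé-seeded, bracket-safeguarded Newton iteration converged to residual
  $10^{-13}$, vectorised. This keeps approximation error out of the
  stress–energy consistency checks. Locking ($\lambda_r\ge1$) raises a typed
  error naming the offending stretch and $N$, never returns infinity.
* **Stable special functions.** $\ln(\beta/\sinh\beta)$ and
  $\mathcal L(\beta)$ switch to series below $\beta=10^{-2}$ and to
  asymptotic forms for large $\beta$ to avoid cancellation and overflow.
* **Cycle simulation.** A sample lies on the primary path iff its strain
  intensity reaches the running maximum within $10^{-12}$ relative; below
  it, the inelastic law is evaluated with frozen history. Phases are
  labelled per sample (`loading` on the primary path; otherwise `unloading`
  or `reloading` by the sign of $\Delta m$), so legs crossing $\lambda=1$
  label correctly under compression.
* **Calibration.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
  branch-weighted residuals, with a seeded multi-start (default 8) because
  the objective is multimodal in $(N,b)$. $N$'s lower bound is derived from
  the data's maximum stretch so trial evaluations can never lock; trials
  that fail anyway (non-finite model stress) return a large penalty residual
  rather than crashing. Identical inputs give bitwise-identical results: all
  randomness flows through the configured seed and the global RNG state is
  restored.

## What the synthetic-data generator emulates — and what it does not

`generate_cycle_data()` produces idealised cyclic uniaxial protocols:
piecewise-linear stretch programs, exact model kinematics, additive
homoscedastic Gaussian stress noise. Real tissue data additionally carry
rate effects (viscoelasticity is deliberately outside this model family),
preconditioning drift across nominally identical cycles, heteroscedastic
transducer noise, and stretch-measurement error. Passing recovery tests on
synthetic data therefore demonstrates the correctness and identifiability of
the implementation under the model's own assumptions, not that the model is
an adequate description of any particular tissue.

## Identifiability and the design of the recovery experiments

Two structural facts shape the parameter-recovery studies:

* The isotropized mixture is **not identifiable in $f$** from uniaxial
  stress data: only the products $(1-f)\mu$, $fA_1$, $fA_2$ (and $\mu C$)
  enter the stress. Noiseless fits reach RSS $\sim10^{-15}$ at displaced
  parameter values along this ridge. Recovery experiments therefore hold
  $f$ at its known value — mirroring practice, where the anisotropic energy
  fraction is measured (e.g. by X-ray diffraction during loading), not
  fitted. $A_1$ is additionally near-collinear with $\mu$ over modest
  stretch windows and is held at its known value (zero for the mouse-skin
  truth set) in the noisy experiment.
* For the pseudo-elastic law, a linearized power analysis at the truth
  (Jacobian-based standard errors) shows that with 2%-of-peak noise the
  $\gamma$ estimator has an intrinsic sd of ~15% on a two-cycle suture
  protocol; no optimiser can beat that. The $\gamma$-recovery experiment is
  therefore designed at 0.5% peak noise, where the linearized sd is ~4%.

Problem sizes used throughout the tests and the acceptance script — 100
samples per branch, one or two cycles, 8 multi-starts — are the smallest at
which these experiments are comfortably identified; they run in seconds.

## Known limitations

* Uniaxial scope only: no biaxial or shear response, no full stress tensors,
  no compressibility.
* One scalar history: per-axis maxima are slaved to the axial maximum, as
  appropriate for uniaxial reversal points; independent multi-axis damage is
  out of scope.
* The softening kernel's exact printed typography is unresolved at the
  source; both defensible readings are implemented and selectable, and no
  package result depends on the choice.
* No uncertainty quantification on fitted parameters (the power analysis
  above is used for experiment design, not reported inference).
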