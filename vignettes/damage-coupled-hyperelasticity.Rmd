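---
title: "Layer-specific damage-coupled hyperelasticity for biaxially tested intestinal wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-specific damage-coupled hyperelasticity for biaxially tested intestinal wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(biaxdamage)
```

## The model

The large-intestine wall is modeled as an incompressible fiber-reinforced
composite: an isotropic extracellular matrix plus four collagen fiber
families — one in the longitudinal muscular layer (`a01`, along e1), one in
the circumferential muscular layer (`a02`, along e2), and a crosswise
submucosal pair (`a03`, `a04`) at ±α to the longitudinal axis (α = 30° by
default, from histology; configurable). Mucosa and serosa contribute no
appreciable in-plane stiffness and are not modeled.

With the isochoric–volumetric split \(F = (J^{1/3} I)\,\bar F\),
\(\bar C = J^{-2/3} C\), \(\bar I_1 = \operatorname{tr}\bar C\) and
\(\bar I_{4,i} = a_{0i}\cdot\bar C\,a_{0i}\), the strain-energy function is

\[
\psi \;=\; \underbrace{\tfrac{\kappa_0}{2}(J-1)^2}_{\text{volumetric}}
\;+\; \underbrace{\tfrac{\mu_0}{2}(\bar I_1 - 3)}_{\text{matrix}}
\;+\; \sum_{i=1}^{2} \tfrac{k_{1,mus}}{2k_{2,mus}}
      \big(e^{k_{2,mus}(\bar I_{4,i}-1)^2}-1\big)
\;+\; \sum_{j=3}^{4} \tfrac{k_{1,sm}}{2k_{2,sm}}
      \big(e^{k_{2,sm}(\bar I_{4,j}-1)^2}-1\big),
\]

with every fiber term switched off when \(\bar I_4 < 1\) (collagen carries no
compression). The two muscular families share one constant pair
\((k_{1,mus}, k_{2,mus})\); the two submucosal fibers share
\((k_{1,sm}, k_{2,sm})\) and, assuming no fiber interaction, their pooled
energy is simply the sum of two independent single-fiber terms. Units are
MPa–mm–N throughout; stretches are dimensionless.

The analytic Cauchy stress is the push-forward

\[
\sigma = p I + \frac{\mu_0}{J}\Big(\bar B - \frac{\bar I_1}{3} I\Big)
 + \sum_i \frac{2}{J}\,\bar\psi'(\bar I_{4,i})
   \Big(\bar A_i - \frac{\bar I_{4,i}}{3} I\Big),
\qquad
\bar\psi'(\bar I_4) = k_1 (\bar I_4 - 1)\, e^{k_2 (\bar I_4-1)^2},
\]

with \(\bar A_i\) the isochoric spatial structural tensor of family *i*. In
penalty mode \(p = \kappa_0 (J-1)\); in incompressible mode (the default for
all curve-level work, because the rig's force-to-true-stress conversion
\(\sigma = P\lambda/(LT)\) itself assumes \(J = 1\)) the constraint pressure
is fixed by the plane-stress condition \(\sigma_{zz} = 0\). `cauchy_stress()`
is verified against central finite differences of `strain_energy()` — the
two routes are implemented independently and agree to better than 1e-5
relative on random deformations with principal stretches in [0.85, 1.6]
(see `test-acceptance.R`).

## Per-layer damage

Only the collagenous layers damage; matrix and volumetric terms never do
(the non-collagenous matrix fails far below the loading range of interest,
so its degradation is not modeled). Each layer k ∈ {lm, cm, sm} carries a
scalar \(D_k \in [0,1]\) applied as a Kachanov reduction \((1-D_k)\) to its
undamaged energy and stress. The two muscular layers are damaged
independently; the two submucosal fibers share a single scalar and a pooled
energy — this asymmetry is intentional and mirrored throughout the API.

Damage is driven by the equivalent strain
\(\tau_k = \sqrt{2\bar\psi_k}\) (units MPa^1/2) of the *undamaged* layer
energy. (The source text typesets the norm without the root, but the
printed parameter units MPa^1/2 identify the intended square root; it is
implemented as such.) With threshold \(\tau_0\) and fracture energy per
unit volume \(g_f\),

\[
D(\tau) = 1 - \frac{\tau_0}{\tau}\,
  \exp\!\Big(A\big(1 - \tfrac{\tau}{\tau_0}\big)\Big)
  \;\;(\tau > \tau_0), \qquad
A = \Big(\frac{g_f}{\tau_0^2} - \frac12\Big)^{-1},
\]

so \(D(\tau_0) = 0\), \(D \to 1\) as \(\tau \to \infty\), and
well-posedness requires \(g_f > \tau_0^2/2\) (enforced at construction,
with a 1e-9 relative guard so a float-boundary pair is still rejected).
Irreversibility is handled by the history maximum: `update_damage_state()`
evolves \(D\) only when \(\tau\) exceeds the largest value seen, so
unloading and elastic reloading freeze the state and the incremental
dissipation \(\sum_k \dot D_k \bar\psi_k\) is non-negative on every update.
Because the law is a closed form of the running maximum, whole loading
paths are evaluated vectorized (`run_path()`), and path-grid refinement
changes nothing but the reporting resolution.

Two numerical conventions: `damage_value()` returns the exact evolution
function (its endpoints are analytic statements and are tested as such),
while the state-update path used by solvers caps \(D\) at \(1 - 10^{-12}\)
so a fully failed layer keeps an infinitesimal stiffness and the
plane-stress root solve cannot degenerate.

## Protocol solvers

`equibiaxial_stress()` evaluates the closed-form in-plane stresses for a
diagonal incompressible state \(F = \mathrm{diag}(\lambda_L, \lambda_C,
1/\lambda_L\lambda_C)\): all four families lie in the plane, the ±α
submucosal off-diagonal terms cancel pairwise, and
\(\sigma_{ii} = \sigma^{dev}_{ii} - \sigma^{dev}_{zz}\). Shear components
are ignored on this path (measured shear strains are roughly two orders of
magnitude below the normal strains); the tensor engine still accepts full
deformation gradients.

`simulate_brick()` reproduces a displacement-controlled biaxial test on a
1 mm cube treated as a single homogeneous material point (one element ≡ one
constitutive evaluation; no dynamics, no hourglass control). Displacements
ramp proportionally; at each increment \(\lambda_z\) solves
\(\sigma_{zz} = 0\) — exactly \(1/\lambda_x\lambda_y\) in incompressible
mode, by bracketed root-finding (`stats::uniroot`, bracket initialized at
[0.2, 1.2] times the incompressible guess and expanded geometrically) in
penalty mode. The damage update and the root solve are iterated to a fixed
point within each increment. The accepted plane-stress residual is below
1e-9 MPa.

κ₀ is not identifiable from planar data and is not printed with the
published parameters; the penalty default is \(10^4 \max(\mu_0, k_{1,mus},
k_{1,sm})\), exposed in the interface. Under in-plane tension the
deviatoric \(\sigma_{zz}\) is negative, so the penalty pressure is positive
and \(J \ge 1\): penalty-mode DZ converges to the incompressible value
\(1/(\lambda_x \lambda_y) - 1\) *from above* as κ₀ grows (at DX = 0.31 mm,
DY = 0.38 mm that limit is −0.4468 mm). A static plane-stress solve of this
model therefore cannot contract more than the incompressible limit, and
the much larger contraction reported for the original explicit-dynamics
single-element run is not reproducible without the unprinted bulk modulus
and solver settings; the solver reports DZ for any user-chosen κ₀ instead
of targeting that figure.

```{r brick}
s1 <- specimen_parameters("S1")
mat <- as_material_params(s1)
dmg <- as_damage_params(s1)
brick <- simulate_brick(0.31, 0.38, mat, dmg, mode = "incompressible",
                        steps = 10)
brick[nrow(brick), c("DX", "DY", "DZ", "J", "D_lm", "D_cm", "D_sm")]
```

## Synthetic rig data

`generate_curve()` emulates the study's equibiaxial protocol: 40 mm × 40 mm
specimens, crosshead speed 10 mm/min per axis sampled at 1 Hz (stretch
increment 1/240 per frame), thickness either fixed at the reported mean
1.188 mm or drawn per specimen from the reported range 0.68–2.15 mm (a
uniform draw — a documented stand-in, the true distribution is unreported).
The noise-free stresses come from `run_path()`; forces are back-computed as
\(P = \sigma L T / \lambda\); multiplicative Gaussian noise (default 2%
relative — an assumption, no noise statistics are reported) plus an
optional additive sensor floor (default 0.01 N) are applied to the forces,
and the noisy true stresses re-derived, so all channels stay mutually
consistent. Rupture is emulated by truncating the record at the first
frame where any layer's damage exceeds a cap (default 0.99).

What the generator does *not* emulate: preconditioning cycles (the model
is rate-independent and the damage history makes sub-threshold cycles
redundant), needle-fixation tearing (excluded from the original analysis),
heterogeneous strain fields, and viscoelasticity. Passing recovery tests
on these data therefore demonstrate correctness of the estimation
machinery under the model's own assumptions — not robustness to the model
errors real records contain.

```{r synth, fig.alt = "Synthetic S1 stress-stretch curves"}
curve <- generate_curve(mat, dmg, rig_protocol(), seed = 1)
plot_biaxial_curve(curve)
plot_damage_trajectory(attr(curve, "truth"))
```

## Parameter identification

`fit_biaxial()` estimates the four fiber constants and six damage
parameters jointly from both directions (a single parameter set must
explain both records, as in the published per-specimen rows), with μ₀ held
at its 1e-4 MPa floor — every published specimen sits on that value,
indicating a fit bound, so releasing it is optional. Three design choices
matter and were genuinely open:

* **Search geometry.** `k1`, `k2`, `tau0` are searched in log space
  (`k2` within [1e-3, 1e2] for conditioning of the exponential model);
  fracture energies through \(g_f = \tau_0^2/2\,(1+e^u)\), which makes the
  feasibility constraint \(g_f > \tau_0^2/2\) structural rather than a
  rejection rule.
* **Objective weighting.** The default residual scaling
  \(1/\sqrt{\sigma^2 + (0.02\,\sigma_{max})^2}\) matches the multiplicative
  sensor noise (a plain unweighted objective is available as
  `weighting = "absolute"`). This is not cosmetic: absolute weighting
  drowns the toe region, where the early-crossing circumferential layer
  carries its information, and measurably degrades the attainable
  precision of `gf_cm` even for an estimator started at the truth.
* **Optimizer.** The damage evolution law makes the least-squares
  landscape piecewise-smooth (threshold switches plus a running-maximum
  history), and a pure Levenberg–Marquardt multi-start stalls on the kinks.
  The shipped procedure is staged: (1) a linearized regression of the toe
  region — where \(\sigma_{LL} - \sigma_{CC}\) isolates the submucosal
  response and \(\log(\bar\psi'/x) = \log k_1 + k_2 x^2\) is linear —
  seeds the fiber constants; (2) 16 seeded Nelder–Mead starts over the six
  damage parameters with thresholds spread across 0.15–1.6× the observed
  equivalent-strain range (starts above the range let a layer come out
  undamaged); (3) the three best candidates are refined jointly over all
  ten parameters, with a bounded Levenberg–Marquardt polish kept only when
  it improves the objective. The whole search is deterministic given the
  seed.

Quality control mirrors the experimental selection rules: records must be
J-shaped over their leading 80%, and (for experimental records) must
soften concurrently in both directions — without concurrent softening the
damage parameters of all layers are not identifiable. The softening rule
is off by default because rupture-truncated synthetic records can end
before the second direction visibly softens even though all layers damage.

### What is identifiable, and from what

On an equibiaxial path all in-plane fibers see the same \(\bar I_4 =
\lambda^2\), so a layer's damage parameters influence the record only if
its threshold is crossed before rupture. Solving the forward model for the
published rows: S1 and S3 cross all three thresholds within their records;
S2's and S4's circumferential thresholds lie beyond any reachable stretch
(S4's would require λ ≈ 2.0 against a ramp ending at 1.56), so their
`tau0_cm`/`gf_cm` have exactly zero influence on the data and no estimator
can recover them. Recovery tests assert machine-precision recovery of the
identifiable set and that the fitted model correctly reports the
circumferential layer undamaged on those records.

Under 2% multiplicative noise a second, statistical limit appears: for S1,
\(A_{cm} = 0.0072\) makes the circumferential softening shape nearly flat
in `gf_cm`, and even fits started at the true parameters leave a ~30–40%
median error in that one coordinate. S3 (\(A_{cm} = 0.019\)) is the row
with all three layers active *and* sensitive, so the shipped noisy
recovery study (10 seeded replicates, `test-acceptance.R`) runs on S3,
where the fitted medians for all ten parameters stay within the claimed
bounds. Problem sizes throughout the suite — records of 60–140 frames, 16
multi-starts, 10 noisy replicates — are the defaults of the generator and
fitter; they are the package's chosen study scale.

```{r fit, eval = FALSE}
clean <- generate_curve(mat, dmg, rig_protocol(noise_rel = 0,
                                               force_floor = 0),
                        noise = FALSE)
fit <- fit_biaxial(clean, fit_config(seed = 1))
glance(fit)   # r2_L = r2_C = 1 at machine precision
tidy(fit)     # recovers the generating row
autoplot(fit)
```

## Known limitations

* Fiber dispersion, the coupling invariants I5/I7/I8, active muscle tone,
  viscoelasticity and rate effects are out of scope by design.
* Damage is local; no nonlocal averaging or phase-field regularization, so
  the model is meant for material-point and single-element use, not for
  mesh-based softening simulations.
* The equibiaxial identifiability analysis above is specific to
  proportional paths; unequal biaxial ratios would separate the muscular
  families differently and could activate layers the equibiaxial protocol
  cannot.
* The generator's noise model and thickness distribution are assumptions
  standing in for unreported rig statistics.
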