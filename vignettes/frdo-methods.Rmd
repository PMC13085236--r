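---
title: "Methods: freeze-and-release direct optimization of excited-state mean fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: freeze-and-release direct optimization of excited-state mean fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frdo)
```

## The problem

A mean-field excited state ("ΔSCF") is a stationary point of the
self-consistent-field energy with a non-aufbau occupation: an electron has
been promoted from an occupied orbital (the *hole*) to a virtual orbital
(the *particle*), and the orbitals are re-optimized under this occupation.
Such states are not minima. For each orbital pair whose occupations are
inverted relative to the aufbau order, the energy has negative curvature,
so the target is a saddle point whose order equals the number of such
inverted pairs (to leading order). Gradient-following minimizers drift off
the saddle to a lower solution — *variational collapse*. For
charge-transfer (CT) states the collapsed solution typically delocalizes
the transferred charge, destroying the −1/R asymptotics that make ΔSCF
attractive for CT physics in the first place.

## Orbital parametrization and stationarity

All optimizers work in the exponential parametrization

$$ C(\kappa) = C_0 \, e^{\kappa}, \qquad \kappa^{\mathsf T} = -\kappa, $$

per spin channel, with one nonredundant parameter $\kappa_{ij}$ ($i<j$)
per pair with $f_i \neq f_j$. With $H = C^{\mathsf T} F C$ the mean-field
Hamiltonian in the current molecular-orbital basis, the gradient and the
diagonal curvature model are

$$ g_{ij} = 2\,(f_j - f_i)\,H_{ij}, \qquad
   d_{ij} = 2\,(\varepsilon_i - \varepsilon_j)(f_j - f_i). $$

$d_{ij} < 0$ exactly on the inverted pairs, so counting negative
$d_{ij}$ gives a cheap saddle-order estimate
(`diagonal_order_estimate()`), checked against the finite-difference
electronic Hessian (`numeric_hessian()`, central differences on the
gradient). Convergence is monitored by the residual
$r = (\mathrm{eV}^2/N)\sum_{i\,\mathrm{occ}} |H_{ji}|^2$ over
occupied–virtual pairs.

## Freeze-and-release (FR-DO)

1. **Ground state.** Preconditioned L-BFGS direct minimization from the
   core-Hamiltonian guess, verified in the tests against a damped
   fixed-point SCF oracle to $10^{-9}$ Ha.
2. **Guess.** Occupations of the hole and particle orbitals are swapped in
   the ground-state orbital basis.
3. **Freeze.** The hole and particle columns are held bit-identical while
   the remaining orbitals relax by L-BFGS restricted to the complementary
   rotation block, to a loose residual (default `tol_constrained = 4e-3`
   eV²/e). This lets the environment respond to the moved charge without
   letting the hole and particle mix back.
4. **Refresh.** A subspace diagonalization within equal-occupation blocks
   re-canonicalizes the orbitals and refreshes the orbital energies, so the
   diagonal model $d_{ij}$ acquires the correct (negative) curvature signs
   for the released phase. The remix is energy-invariant; frozen columns
   survive it as exact spans of their occupation blocks.
5. **Release.** All nonredundant rotations are optimized by limited-memory
   SR1 with a signed diagonal preconditioner $1/d_{ij}$ (magnitude-floored),
   which steps uphill along negative-curvature directions, to the full
   tolerance (default `tol_full = 4e-8` eV²/e).

The DO-MOM baseline (`do_mom()`) instead runs L-SR1 directly from the
swapped guess with the ground-state orbital-energy preconditioner, using
the *redundant* pair set, and reassigns occupations each iteration by the
maximum overlap method: $\Omega = C^{\mathsf T}_{\mathrm{ref,occ}} S C$,
weights $\omega_i = \sum_r \Omega_{ri}^2$, occupy the $N$ largest (ties at
the boundary retain the current occupation).

## The model backend

The backend is an unrestricted Pariser–Parr–Pople (PPP) donor–acceptor
dimer in the zero-differential-overlap approximation: site basis with
$S = I$, hopping $t$ within and between fragments, on-site energies
$\alpha_p$, core charges $z_p$, and Ohno-interpolated two-electron
integrals

$$ V_{pq} = \frac{1}{\sqrt{R_{pq}^2 + a_{pq}^2}}, \qquad
   a_{pq} = \frac{2}{U_p + U_q}, \qquad V_{pp} = U_p, $$

with the exact-exchange mean field $F_\sigma = h + J - K_\sigma$ and
$h_{pq} = \delta_{pq}(\alpha_p - \sum_r V_{pr} z_r) - t_{pq}$. This is the
smallest self-contained model that has real long-range Coulomb physics:
the CT-state energy follows $E_{\mathrm{CT}}(R) \approx E_\infty - 1/R$
(the fitted slope on the decoupled fixture is −0.990 Ha·Bohr over
$R \in [10, 30]$), the Le Bahers-style barycenter descriptors give
$d_{\mathrm{CT}} \approx R$ and $q_{\mathrm{CT}} \approx 1$, and the
disjoint open-shell singlet determinant carries exactly 1.0 electrons of
spin contamination (the acceptance target).

## Fixture generators and their realism

`generate_fixture(seed, kind)` produces deterministic test systems.

**Decoupled** fixtures have zero inter-fragment hopping, so the CT state is
an exact product of fragment states: FR-DO and DO-MOM must agree, scans
over every nonredundant pair must be stationary, and the 1/R law is clean.
These are the "physics is known in closed form" regressions.

**Collapse** fixtures are tuned so that DO-MOM demonstrably collapses while
FR-DO holds the saddle. Two structural facts shaped the tuning:

* For paired electrons, the opposite-spin mean field screens the vacated
  donor level, and the orbital-energy flip that drives collapse never
  occurs in this model. The fixture is therefore spin-polarized (all
  electrons in one spin channel, fractional core charges for neutrality),
  where exchange is exact and the flip condition
  $E_{90} - E_0 < -1/R$ (local excitation below the CT state by roughly
  the hole–electron attraction) can be met.
* In an exact-exchange mean field, the frozen single-pair rotation scan is
  an *exact single harmonic*, $E(\theta) = A + B\cos 2\theta + C\sin
  2\theta$: self-interaction cancels, so no higher harmonics appear. Its
  maximum and minimum are always 90° apart. A scan shape with a maximum
  near 0° *and* a minimum near 45° — the signature reported for semilocal
  density-functional mean fields, whose self-interaction error adds a
  $\cos 4\theta$ component — is structurally unattainable here. The
  generator therefore targets the attainable part of the signature: an
  interior minimum near 45° strictly below the guess energy, positive
  diagonal curvature at the guess, and negative curvature after the
  constrained phase, together with DO-MOM converging strictly below FR-DO
  with a smaller $d_{\mathrm{CT}}$. The one acceptance clause asserting a
  maximum near 0° is left asserted verbatim and fails, documenting the
  model-class limitation rather than hiding it.

The generator jitters a calibrated base point (separation ≈ 23.7 Bohr,
asymmetric acceptor depths, strong inter-fragment hopping $t_{DA} \approx
0.10$) and accepts a candidate only after verifying the full collapse
phenomenology on that exact system, so every seed ships a working trap.

## Numerical choices

* $e^\kappa$ by scaling-and-squaring with a Padé/Taylor core; unitarity is
  tested to machine precision.
* Limited-memory two-loop recursion for L-BFGS; compact limited-memory SR1
  operator for the saddle search; both with uniform max-norm step clipping
  (direction-preserving) and magnitude-floored preconditioners.
* Finite-difference gradients and Hessians use central differences with
  $h = 10^{-5}$; the analytic gradient matches to $<10^{-7}$ over random
  instances.
* JSON reports are written with 17 significant digits so numeric fields
  round-trip IEEE doubles exactly.

## Limitations

* The backend is a model Hamiltonian: site bases, ZDO integrals, no real
  molecular integrals. External geometries (`read_xyz()`) parse but have
  no integral adapter.
* Exact exchange only; the semilocal-functional scan shapes (quartic
  harmonics, max-near-0° signature) are outside the model class, as
  discussed above.
* The residual threshold bounds the gradient norm only up to a
  unit-conversion factor; tests that assert gradient norms directly use
  deep-convergence settings.
* Saddle-order estimates from the diagonal model are leading-order; the
  finite-difference Hessian is the arbiter in tests.

All quantitative statements above (slope −0.990, contamination 1.0,
gradient accuracy, scan stationarity) are computed by the test suite or
`scripts/acceptance.R`; the vignette makes no claims beyond them.
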