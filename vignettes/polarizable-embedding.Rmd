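---
title: "Polarizable embedding with induced point dipoles: model, conventions, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarizable embedding with induced point dipoles: model, conventions, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polembed)
```

## The physical model

`polembed` implements the classical half of a polarizable-embedding QM/MM
scheme of the AMOEBA family, together with everything needed to couple it to
a quantum-mechanical description of an embedded subsystem. Each classical
site carries

* fixed multipoles up to quadrupole: charge $q_k$ (e), dipole $\mu_k$
  (e·bohr), traceless Cartesian quadrupole $\Theta_k$ (e·bohr²);
* an isotropic polarizability $\alpha_k$ (bohr³) — a site with
  $\alpha_k = 0$ simply does not appear among the polarization unknowns;
* a Thole damping factor $a_k$ (dimensionless, default 0.39);
* a polarization-group label, by default the connected component of the bond
  graph the site belongs to.

All internal quantities are in Hartree atomic units; files on disk use
angstrom, and excitation energies are converted to eV only at the output
boundary. This removes every physical constant from the working equations:
all interactions are pure Coulomb forms.

The total energy is assembled from a variational functional with five
pieces: the QM internal energy, the permanent-multipole self-energy, the
QM–MM electrostatic energy, the polarization energy, and a Lagrangian
coupling term $\tfrac12\langle\mu^p,\,T\mu^d - E^{QM} - E^d(M)\rangle$ that
vanishes at the solution of the dipole equations. Two induced-dipole sets
appear because the force field prescribes *different screening rules* for
the field that polarizes the environment ("direct", $s^d$) and the field
that enters the energy ("polarization", $s^p$); both sets share the one
coupling matrix $T$ with blocks
$T_{kl} = \alpha_k^{-1}\delta_{kl} - (1-\delta_{kl})\,s^p_{kl}\,T^{11}_{kl}$.

## Interaction tensors and the quadrupole convention

The generalized Coulomb kernel is the tensor of mixed derivatives of
$1/|r_k - r_l|$, taken $L$ times with respect to $r_k$ and $L'$ times with
respect to $r_l$, applied literally in that order; this fixes every sign in
the package once, and the test suite pins the convention with
finite-difference checks (multipole sign conventions being a classic source
of silent drift). Energies contract multipoles with these tensors at *full
derivative weight*: no extra $1/3$ (or $1/2$) factor is applied to the
quadrupole contraction. Because published force-field conventions differ
here, the choice is documented rather than discoverable: a quadrupole in a
`polembed` parameter file is interpreted such that its potential at distance
$R$ is $\Theta : \nabla\nabla(1/r)$, and all fixture generators emit
quadrupoles in the same convention. Quadrupoles are stored traceless (the
constructor enforces $|\mathrm{tr}\,\Theta| \le 10^{-10}$ and
`traceless_quadrupole()` projects arbitrary symmetric input), so the
invisible trace component can never leak into an energy.

## Thole damping

Mutual polarization with point dipoles diverges when two polarizable sites
approach closer than $(4\alpha_k\alpha_l)^{1/6}$; the standard cure is to
smear the interacting dipole over an exponential charge cloud. With
$u = r/(\alpha_k\alpha_l)^{1/6}$, $t = a u^3$ and the pair factor $a$ the
*minimum* of the two site factors, the field-level damping is
$\lambda_3 = 1 - e^{-t}$ with companions $\lambda_5, \lambda_7, \lambda_9$
generated by the recursion $\lambda_{n+2} = \lambda_n - (r/n)\,
\mathrm{d}\lambda_n/\mathrm{d}r$, each multiplying the corresponding radial
power in the tensors. The scalar kernel consistent with this chain is needed
so the damped tensors can be validated against finite differences of an
actual function; it evaluates in closed form to
$\lambda_1 = 1 - e^{-t} + t^{1/3}\,\Gamma(2/3, t)$ (upper incomplete gamma,
computed via `pgamma`). Two deliberate properties:

* a Thole factor of 0 (or a non-polarizable partner) switches damping off
  *exactly*, recovering the undamped kernel bit-for-bit;
* damping applies only to polarization-related kernels — the source fields
  that drive the dipoles and the dipole–dipole blocks of $T$. The permanent
  self-energy and all QM–MM interactions are undamped, and QM sources are
  likewise undamped by default (a flag on `qm_field()` enables site-side
  damping for experimentation), since the QM–MM coupling terms of the model
  carry no damping function.

Note that $\lambda_7$ and $\lambda_9$ are slightly *negative* at small $t$;
this is a genuine property of the exponential-smearing derivative chain, not
a bug, and the finite-difference tests cover the regime.

## Screening defaults

The screening factors are configuration, not physics baked into the code.
The defaults follow common AMOEBA practice: $s^m = (0, 0, 0.4, 0.8)$ for
bonded neighbor orders 1-2 through 1-5, $s^d = (0, 0, 1, 1)$, and $s^p$
decided by polarization-group membership (0 within a group, 1 across
groups). All of them can be overridden in the parameter file, including
switching $s^p$ to bond-order lookup. Pairs more than four bonds apart (or
in disconnected fragments) always interact at full strength.

## The coupling loop and the model QM

A *density provider* abstracts the quantum side: given the environment
potential (values, fields and field gradients at its declared density
sites) it returns a point-charge density and an internal energy, per state
label. The self-consistent loop alternates (i) environment potential at the
QM sites — permanent multipoles plus the potential of the *averaged* dipole
set $(\mu^d + \mu^p)/2$, the same average that enters the gradient
expression, (ii) density from the provider, (iii) QM field at the
polarizable sites, (iv) the two dipole solves. Convergence requires both
the total-energy change (default $10^{-9}$ hartree) and the max-norm
dipole/charge changes (default $10^{-7}$) to fall below tolerance; plain
fixed-point iteration with optional linear mixing (default 1.0; 0.5 is
useful for stiff response matrices) and a hard cap of 100 cycles.

The built-in model QM responds linearly: $q = q^0 + K V$ with $K$ symmetric,
negative semidefinite, and row-sum zero, so total charge is conserved by
construction. Its internal energy $E_0 - \tfrac12 V^\top K V$ is exactly the
Legendre-consistent energy of that response, which makes the coupled fixed
point variational: the total energy is stationary in both the dipoles and
the density charges. Two consequences are tested rather than assumed — the
fixed point coincides with a monolithic dense solve of the joint
dipole+charge linear system, and explicit-only geometrical gradients agree
with finite differences of the fully re-converged energy. The default
response is a chain-graph Laplacian scaled by 0.05 e²/hartree, small enough
that the plain fixed-point iteration is contractive on all shipped fixtures.

## Gradients and the frozen-environment optimizer

At stationarity the gradient of every embedding term reduces to explicit
derivatives: each QM point charge times the gradient of the static MM
potential (electrostatic term) plus the gradient of the averaged
induced-dipole potential (polarization term). Density charges ride rigidly
with a declared host atom; in a real electronic-structure coupling the
analogous derivative of the one-electron integrals is the provider's
responsibility. MM-side gradients of the self-energy and the QM–MM term are
implemented too — not for optimization (the environment is always frozen)
but to make momentum-conservation checks possible: translations must see
zero total force and, for orientation-free sites, zero total torque.

The optimizer is a conservative BFGS: inverse-Hessian update with a
curvature guard, Armijo backtracking (so accepted steps never raise the
energy), convergence at max $|g| \le 4.5\times10^{-4}$ hartree/bohr over the
free coordinates, and an optional restraint hook for e.g. dihedral
penalties. Cartesian coordinates only; the intended fixtures are small
enough that robustness beats sophistication.

## Linear solvers

The dipole systems are solved by dense Cholesky factorization below 600
unknowns and by Jacobi-preconditioned conjugate gradient above (relative
residual $10^{-8}$, 200 iterations cap; both thresholds configurable, and
the SCF passes the previous cycle's dipoles as the CG starting guess). The
assembly validates $T$: a minimum eigenvalue below $10^{-10}$ raises a
conditioning error naming the closest polarizable pair, which is the
diagnosable symptom of an undamped close contact.

## What the fixtures emulate — and what they do not

The seeded generators produce: a polarizable dimer scan (damping
monotonicity), random multipolar clusters with short bonded fragments
(several polarization groups, so intra-group screening and inter-group
coupling both occur), water-like clusters with AMOEBA-magnitude parameters
(charges −0.42/+0.21 e, polarizabilities 5.65/3.35 bohr³, Thole 0.39, rigid
monomer geometry), and a coupled model-QM case: a diatomic with four density
sites, a ground-like and a charge-transfer-like state density plus their
equal-weight average — the state average is the arithmetic mean with equal
weights throughout. All geometries respect a 1.5 bohr minimum separation.
Problem sizes are deliberately small (clusters of 5–50 sites, two to six
water-like molecules): every property checked here — tensor consistency,
stationarity, solver agreement, gradient exactness — is size-independent
algebra, so desk scale loses no generality. What passing tests do *not*
show: that the force-field parameters are realistic for any particular
protein environment, that the point-charge model density behaves like a real
correlated density, or that the fixed-point iteration converges for strongly
coupled (high-$K$) quantum regions — the model QM is a linear stand-in, and
real applications inherit the convergence behavior of the electronic
structure code behind the provider contract.

## Degenerate inputs and tie-breaks

Coincident unscreened point pairs raise singularity errors naming the pair;
coincident *damped* pairs are legal and use the analytic $r \to 0$ limits of
the damped tensors. A QM evaluation point may not coincide with an MM site.
The density-site-to-atom map is required as soon as gradients touch density
charges; it is never guessed from distances except in the model QM
constructor, where the nearest nucleus is an explicit, documented default.
The state-specific correction computes both the electrostatic and the
polarization pieces of its energy difference even though the electrostatic
piece cancels identically for fixed point-charge densities — keeping the
implementation aligned with the defining expression rather than its
simplification.

## Known limitations

Open boundary conditions only — no periodic images, no Ewald summation, no
cutoffs (all pair loops are $O(N^2)$). No bonded or van-der-Waals MM terms,
no link atoms: this package is the electrostatic/polarization core, not a
complete force field. The CLI reads JSON parameter files only; importing
native force-field parameter dialects is out of scope.
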