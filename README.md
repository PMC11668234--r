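# polembed

Polarizable-embedding QM/MM machinery in the induced-point-dipole (AMOEBA)
formulation, for method developers who need the classical half of a
QM/polarizable-MM coupling — multipole electrostatics, mutual polarization,
analytical gradients — as a small, fully testable R library with a pluggable
quantum-mechanical side.

## The model

The environment is a set of classical sites `k` carrying fixed multipoles
`M_k^L` (charge, dipole, traceless Cartesian quadrupole; `L = 0, 1, 2`), an
isotropic polarizability `alpha_k` and a Thole damping factor. The total
energy of the coupled system is assembled from a variational functional

```
L = E_QM + E_self(M) + E_ele(QM, M) + E_pol(QM, M)
      + 1/2 < mu_p, T mu_d - E(QM) - E_d(M) >
```

with

* `E_self = 1/2 sum_{k != l} s^m_kl  M_k^L T^{LL'}_kl M_l^L'`, the permanent
  multipole self-energy, where `T^{LL'}` is the tensor of mixed derivatives of
  `1/|r_k - r_l|` and `s^m` the bonded screening factors;
* `E_ele`, every MM multipole interacting with the QM charge distribution
  (point nuclei plus weighted density charges), unscreened and undamped;
* two induced-dipole sets solving `T mu_d = E(QM) + E_d(M)` and
  `T mu_p = E(QM) + E_p(M)`, which differ only through the screening of their
  permanent-multipole source fields; the matrix `T` has `alpha_k^-1 I` on the
  diagonal and Thole-damped dipole-field blocks off the diagonal;
* `E_pol = -1/2 < mu_d, E(QM) + E_p(M) >`;
* a state-specific correction for excitation energies: after a state-averaged
  calculation the dipoles are re-relaxed against each individual state density
  and `dE_SS = dE_SA + (E_corr^F - E_corr^I)`.

Thole damping uses the exponential smearing `lambda_3 = 1 - exp(-a u^3)` with
`u = r/(alpha_k alpha_l)^(1/6)` and derivative-consistent companions, which
keeps every tensor finite at short range (no polarization catastrophe).

The QM side is a *contract*: any density provider that returns a point-charge
density and an internal energy for a given external potential plugs in. A
built-in linear-response model QM (`q = q0 + K V` with a symmetric
negative-semidefinite, row-sum-zero `K`) gives a genuine coupled fixed point
so every equation is exercisable at desk scale, including analytical
geometrical gradients: at the converged fixed point only explicit derivatives
are needed, and the package verifies this against finite differences of the
fully re-converged energy.

## Worked example

```r
library(polembed)

case <- model_qm_case(n_mm = 2, seed = 3)   # water-like MM + model QM diatomic
print(case$system)
st <- pe_scf(case$system, case$provider, "SA")
print(st)
g <- embedding_gradient(st, validate = TRUE)
print(g)
```

prints

```
mm_system: 6 sites, 4 bonds, 6 polarizable, 2 polarization group(s)
  total charge: 0 e; p screening: group-based
pe_state [SA] converged in 2 iteration(s)
  E_self          -0.0000388080
  E_ele           -0.0000033484
  E_pol           -0.0000177502
  E_qm            -1.0249999999
  E_total         -1.0250599065  hartree
gradient_report: 2 QM atom(s); max |g| = 3.056554e-05 hartree/bohr; FD max deviation = 1.309187e-12
```

The energy breakdown is the per-term decomposition of the functional above
(hartree); the gradient report confirms that the analytic forces on the QM
atoms agree with finite differences of the re-converged total energy to
~1e-12 hartree/bohr. A state-specific excitation correction on the same
fixture:

```r
corr <- state_specific_correction(case$system, case$densities$S0,
                                  case$densities$S1, case$densities$SA)
corrected_excitation(3.50, hartree_to_ev(corr$de_corr))
```

returns the state-averaged excitation shifted by the (here tiny, ~1e-7 eV)
re-polarization of the weakly coupled environment.

A command-line front end covering `energy`, `polarize`, `gradient
[--check-fd]`, `optimize`, `excite` and `fixture` is installed at
`system.file("cli/polembed", package = "polembed")`.

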