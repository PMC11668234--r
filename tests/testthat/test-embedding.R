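test_that("QM-MM electrostatic energy reproduces point-charge closed forms", {
  mmq <- mm_system(matrix(0, 1, 3), charges = 1)
  bare <- qm_density(matrix(c(2, 0, 0), 1, 3), 1)
  expect_equal(electrostatic_energy(mmq, bare), 0.5, tolerance = 1e-14)

  neutral <- qm_density(matrix(c(2, 0, 0), 1, 3), 1,
                        matrix(c(2, 0, 0), 1, 3), -1, density_atoms = 1)
  expect_equal(electrostatic_energy(mmq, neutral), 0, tolerance = 1e-14)

  mmd <- mm_system(matrix(0, 1, 3), dipoles = matrix(c(0, 0, 1), 1, 3))
  zdens <- qm_density(matrix(c(0, 0, 2), 1, 3), 1)
  expect_equal(electrostatic_energy(mmd, zdens), 0.25, tolerance = 1e-14)
})

test_that("action-reaction symmetry: both evaluation routes give the same interaction energy", {
  sys <- random_cluster(6, seed = 40, charged = TRUE)
  nuc <- apply(sys$positions, 2, max) + c(3, 1, 2)
  dens <- qm_density(rbind(nuc, nuc + c(1.5, 0, 0)), c(1, 1),
                     rbind(nuc + c(0.5, 0, 0), nuc + c(1.0, 0, 0)),
                     c(-1, -1), density_atoms = c(1, 2))
  e_via_qm_points <- electrostatic_energy(sys, dens)
  # reverse route: each MM multipole in the potential of the QM point charges
  pc_pot <- function(p) {
    s <- 0
    pts <- rbind(dens$nuclei_positions, dens$density_positions)
    chg <- c(dens$nuclear_charges, dens$density_charges)
    for (j in seq_along(chg)) s <- s + chg[j] / sqrt(sum((p - pts[j, ])^2))
    s
  }
  e_rev <- 0
  h <- 1e-4
  for (k in seq_len(nrow(sys$positions))) {
    p <- sys$positions[k, ]
    grad <- numeric(3); hess <- matrix(0, 3, 3)
    for (a in 1:3) {
      ea <- numeric(3); ea[a] <- h
      grad[a] <- (pc_pot(p + ea) - pc_pot(p - ea)) / (2 * h)
      for (b in 1:3) {
        eb <- numeric(3); eb[b] <- h
        hess[a, b] <- (pc_pot(p + ea + eb) - pc_pot(p + ea - eb) -
                         pc_pot(p - ea + eb) + pc_pot(p - ea - eb)) / (4 * h^2)
      }
    }
    e_rev <- e_rev + sys$charges[k] * pc_pot(p) +
      sum(sys$dipoles[k, ] * grad) +
      sum(quad_unpack(sys$quadrupoles[k, ]) * hess)
  }
  expect_equal(e_via_qm_points, e_rev, tolerance = 1e-6)
})

test_that("QM field at polarizable sites matches a naive Coulomb sum", {
  one <- mm_system(rbind(c(10, 0, 0)), polarizabilities = 1)
  lone <- qm_density(matrix(0, 1, 3), 1)
  expect_equal(unclass(qm_field(lone, one)), matrix(c(0.01, 0, 0), 1, 3),
               ignore_attr = TRUE, tolerance = 1e-15)

  pair <- qm_density(matrix(0, 1, 3), 1, matrix(0, 1, 3), -1,
                     density_atoms = 1)
  # co-located +1 nucleus and -1 electron cloud: field cancels
  expect_lt(max(abs(unclass(qm_field(pair, one)))), 1e-12)

  sys <- random_cluster(6, seed = 2)
  nuc <- apply(sys$positions, 2, min) - c(3, 3, 3)
  dens <- qm_density(matrix(nuc, 1, 3), 2, matrix(nuc + c(1, 0, 0), 1, 3), -2,
                     density_atoms = 1)
  E <- unclass(qm_field(dens, sys))
  pol <- polarizable_sites(sys)
  for (i in seq_along(pol)) {
    S1 <- sys$positions[pol[i], ] - nuc
    S2 <- sys$positions[pol[i], ] - (nuc + c(1, 0, 0))
    ref <- 2 * S1 / sum(S1^2)^1.5 - 2 * S2 / sum(S2^2)^1.5
    expect_close(E[i, ], ref, 1e-12)
  }
})

test_that("the SCF loop terminates immediately for rigid problems", {
  # non-polarizable MM + fixed density: one iteration, additive energies
  sys <- mm_system(rbind(c(0, 0, 0), c(3, 0, 0)), charges = c(0.3, -0.3))
  dens <- qm_density(matrix(c(10, 0, 0), 1, 3), 1, label = "S0")
  pr <- fixed_density_provider(dens, c(S0 = -0.7))
  st <- pe_scf(sys, pr, "S0")
  expect_true(st$converged)
  expect_equal(st$iterations, 1L)
  expect_equal(st$energies$total,
               st$energies$qm_internal + st$energies$self + st$energies$electrostatic,
               tolerance = 1e-14)
  expect_equal(st$energies$polarization, 0)
  expect_equal(total_energy(st), st$energies$total)

  # model QM without response: density frozen, at most two sweeps
  case <- model_qm_case(2, seed = 6, response_strength = 0)
  st2 <- pe_scf(case$system, case$provider, "SA")
  expect_true(st2$converged)
  expect_lte(st2$iterations, 2L)
})

test_that("the coupled fixed point matches a monolithic dense solve and forgets its start", {
  case <- model_qm_case(2, seed = 3)
  st <- pe_scf(case$system, case$provider, "SA", tol_e = 1e-13, tol_mu = 1e-11)
  mono <- oracle_monolithic(case$system, case$provider, "SA")
  expect_lt(abs(st$energies$total - mono$total), 1e-8)
  expect_close(st$density$density_charges, mono$q, 1e-8)
  expect_close(st$dipoles$mu_d, mono$mu_d, 1e-8)
  expect_close(st$dipoles$mu_p, mono$mu_p, 1e-8)

  # independence of the initial density guess, and of the mixing path
  st_alt <- pe_scf(case$system, case$provider, "SA", tol_e = 1e-13,
                   tol_mu = 1e-11, initial_density = case$densities$S1)
  expect_lt(abs(st_alt$energies$total - st$energies$total), 1e-8)
  st_mix <- pe_scf(case$system, case$provider, "SA", tol_e = 1e-13,
                   tol_mu = 1e-11, mixing = 0.5)
  expect_lt(abs(st_mix$energies$total - st$energies$total), 1e-8)

  # energy decomposition is exhaustive and the penalty is dead
  expect_equal(st$energies$total,
               with(st$energies, self + electrostatic + polarization + qm_internal),
               tolerance = 1e-14)
  expect_lt(abs(st$penalty), 1e-10)
})

test_that("provider contract violations are detected", {
  sys <- mm_system(rbind(c(0, 0, 0)), charges = 0.1)
  bad <- fixed_density_provider(qm_density(matrix(c(5, 0, 0), 1, 3), 1,
                                           label = "S0"))
  bad$density <- function(potential, label) {
    d <- qm_density(matrix(c(5, 0, 0), 1, 3), 1, label = "S0")
    d$charge <- 3 # lie about the declared charge
    d
  }
  expect_error(pe_scf(sys, bad, "S0"), "charge conservation")
  expect_error(pe_scf(sys, fixed_density_provider(
    qm_density(matrix(c(5, 0, 0), 1, 3), 1, label = "S0")), "S9"),
    "does not know")
})

test_that("state-specific correction vanishes for identical densities and matches a dense oracle", {
  case <- model_qm_case(2, seed = 5)
  d <- case$densities

  same <- state_specific_correction(case$system, d$SA, d$SA, d$SA)
  expect_identical(same$de_corr, 0)
  expect_identical(same$e_corr_i, 0)

  # non-polarizable environment: no dipoles, no correction
  rigid <- case$system
  rigid$polarizabilities[] <- 0
  none <- state_specific_correction(rigid, d$S0, d$S1, d$SA)
  expect_identical(none$de_corr, 0)

  # SA really is the equal-weight average of the state densities
  expect_equal(d$SA$density_charges,
               (d$S0$density_charges + d$S1$density_charges) / 2)

  # dense oracle: explicit T^-1 solves with oracle-assembled matrix and fields
  T <- oracle_polarization_matrix(case$system)
  pol <- polarizable_sites(case$system)
  field_of <- function(dens) {
    E <- numeric(3 * length(pol))
    pts <- rbind(dens$nuclei_positions, dens$density_positions)
    chg <- c(dens$nuclear_charges, dens$density_charges)
    for (i in seq_along(pol)) {
      for (j in seq_along(chg)) {
        S <- case$system$positions[pol[i], ] - pts[j, ]
        E[3 * i - 2:0] <- E[3 * i - 2:0] + chg[j] * S / sum(S^2)^1.5
      }
    }
    E
  }
  Emm_d <- as.numeric(t(unclass(multipole_field(case$system, "d"))))
  Emm_p <- as.numeric(t(unclass(multipole_field(case$system, "p"))))
  mu_of <- function(dens, kindfield) solve(T, field_of(dens) + kindfield)
  elepol <- function(dens, mu_d) {
    electrostatic_energy(case$system, dens) -
      0.5 * sum(mu_d * (field_of(dens) + Emm_p))
  }
  oracle_corr <- function(dens, sa) {
    elepol(dens, mu_of(dens, Emm_d)) - elepol(dens, mu_of(sa, Emm_d))
  }
  got <- state_specific_correction(case$system, d$S0, d$S1, d$SA)
  expect_lt(abs(got$e_corr_i - oracle_corr(d$S0, d$SA)), 1e-10)
  expect_lt(abs(got$e_corr_f - oracle_corr(d$S1, d$SA)), 1e-10)
  expect_lt(abs(got$de_corr -
                  (oracle_corr(d$S1, d$SA) - oracle_corr(d$S0, d$SA))), 1e-10)

  expect_error(state_specific_correction(case$system, d$S0, d$S1,
                                         qm_density(matrix(0, 1, 3), 1)),
               "layout")
})

test_that("excitation-energy correction is plain additive arithmetic in eV", {
  expect_equal(corrected_excitation(3.50, 0.08), 3.58)
  expect_equal(corrected_excitation(3.63, 0.02), 3.65)
  expect_equal(corrected_excitation(4.2, 0), 4.2)
  expect_equal(hartree_to_ev(ev_to_hartree(1.7)), 1.7)
})
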