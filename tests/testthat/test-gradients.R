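test_that("electrostatic gradient matches finite differences and closed forms", {
  mmq <- mm_system(matrix(0, 1, 3), charges = 1)
  dens <- qm_density(matrix(c(2, 0, 0), 1, 3), 1)
  g <- grad_electrostatic(mmq, dens)
  # E = 1/r along x: dE/dx = -1/r^2 at r = 2 (sign fixed by the FD oracle)
  efun <- function(pos) electrostatic_energy(mmq, qm_density(pos, 1))
  fd <- validate_fd(efun, dens$nuclei_positions, gradient = g, step = 1e-4)
  expect_lt(fd$max_deviation, 1e-8)
  expect_equal(g[1, ], c(-0.25, 0, 0), tolerance = 1e-9)

  # neutral co-located nucleus + density charge: zero gradient
  neut <- qm_density(matrix(c(2, 0, 0), 1, 3), 1, matrix(c(2, 0, 0), 1, 3),
                     -1, density_atoms = 1)
  expect_equal(max(abs(grad_electrostatic(mmq, neut))), 0)
})

test_that("force sums vanish under translation and torque under rotation", {
  sys <- random_cluster(6, seed = 40, charged = TRUE)
  nuc <- apply(sys$positions, 2, max) + c(3, 1, 2)
  dens <- qm_density(rbind(nuc, nuc + c(1.5, 0, 0)), c(1, 1),
                     rbind(nuc + c(0.5, 0, 0), nuc + c(1, 0, 0)), c(-1, -1),
                     density_atoms = c(1, 2))
  # translation: QM-side + MM-side electrostatic forces cancel (full multipoles)
  tsum <- colSums(grad_electrostatic(sys, dens)) +
    colSums(grad_electrostatic_mm(sys, dens))
  expect_lt(max(abs(tsum)), 1e-9)
  # translation: MM self-energy forces cancel among themselves
  expect_lt(max(abs(colSums(grad_self_mm(sys)))), 1e-9)

  # rotation: with charges only (no oriented multipoles) the total torque of
  # all forces about the origin vanishes
  qsys <- random_cluster(6, seed = 41, charged = TRUE)
  qsys$dipoles[] <- 0
  qsys$quadrupoles[] <- 0
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  torque <- numeric(3)
  gs <- grad_self_mm(qsys)
  for (k in seq_len(nrow(qsys$positions))) {
    torque <- torque + cross(qsys$positions[k, ], -gs[k, ])
  }
  expect_lt(max(abs(torque)), 1e-9)

  # QM-MM term: per-point forces (charge times local field) so each force acts
  # at its true application point
  gm <- grad_electrostatic_mm(qsys, dens)
  torque2 <- numeric(3)
  for (k in seq_len(nrow(qsys$positions))) {
    torque2 <- torque2 + cross(qsys$positions[k, ], -gm[k, ])
  }
  pts <- rbind(dens$nuclei_positions, dens$density_positions)
  chg <- c(dens$nuclear_charges, dens$density_charges)
  Eat <- potential_at_points(qsys, pts)$field
  for (j in seq_along(chg)) {
    torque2 <- torque2 + cross(pts[j, ], chg[j] * Eat[j, ])
  }
  expect_lt(max(abs(torque2)), 1e-9)
})

test_that("polarization gradient obeys the single-site closed form and the alpha = 0 limit", {
  # alpha = 0 everywhere: no dipoles, no gradient
  rigid <- mm_system(rbind(c(0, 0, 0), c(3, 0, 0)), charges = c(0.2, -0.2))
  dens <- qm_density(matrix(c(8, 0, 0), 1, 3), 1, label = "S0")
  st <- pe_scf(rigid, fixed_density_provider(dens), "S0")
  expect_equal(max(abs(grad_polarization(rigid, st))), 0)

  # one polarizable site + one QM charge: E_pol = -alpha q^2 / (2 r^4),
  # d/dr = 2 alpha q^2 / r^5
  alpha <- 1.3; q <- 1; r <- 4
  one <- mm_system(matrix(0, 1, 3), polarizabilities = alpha)
  d1 <- qm_density(matrix(c(r, 0, 0), 1, 3), q, label = "S0")
  st1 <- pe_scf(one, fixed_density_provider(d1), "S0",
                tol_e = 1e-14, tol_mu = 1e-12)
  g <- grad_polarization(one, st1)
  expect_equal(g[1, 1], 2 * alpha * q^2 / r^5, tolerance = 1e-10)
  expect_equal(st1$energies$polarization, -alpha * q^2 / (2 * r^4),
               tolerance = 1e-12)

  # unconverged state is refused
  st1$converged <- FALSE
  expect_error(grad_polarization(one, st1), "converged")
})

test_that("the explicit-only total gradient matches finite differences of the re-converged energy", {
  case <- model_qm_case(2, seed = 3)
  st <- pe_scf(case$system, case$provider, "SA", tol_e = 1e-13, tol_mu = 1e-11)
  rep <- embedding_gradient(st, validate = TRUE, fd_step = 1e-3)
  expect_lt(rep$fd_max_deviation, 1e-6)
  expect_equal(rep$total, rep$electrostatic + rep$polarization + rep$qm_internal,
               tolerance = 1e-15)
})

test_that("the finite-difference validator is exact on quadratics and second-order accurate", {
  quadratic <- function(pos) sum(pos^2) + sum(pos[, 1] * pos[, 2])
  set.seed(3)
  coords <- matrix(rnorm(9, sd = 2), 3, 3)
  grad <- 2 * coords
  grad[, 1] <- grad[, 1] + coords[, 2]
  grad[, 2] <- grad[, 2] + coords[, 1]
  out <- validate_fd(quadratic, coords, gradient = grad, step = 1e-3)
  expect_lt(out$max_deviation, 1e-11)

  # MM self-energy: FD error scales as step^2
  sys <- random_cluster(5, seed = 27)
  efun <- function(pos) { s <- sys; s$positions <- pos; self_energy(s) }
  g <- grad_self_mm(sys)
  d1 <- validate_fd(efun, sys$positions, gradient = g, step = 2e-3)$max_deviation
  d2 <- validate_fd(efun, sys$positions, gradient = g, step = 1e-3)$max_deviation
  expect_lt(d2, 1e-6)
  expect_gt(d1 / d2, 2.5) # ~4 for clean second-order behavior
  expect_error(validate_fd(function(pos) NaN, coords), "non-finite")
})

test_that("frozen-environment optimizer finds the midpoint of a symmetric charge trap", {
  sys <- mm_system(rbind(c(0, 0, 0), c(10, 0, 0)), charges = c(1, 1))
  pr <- fixed_density_provider(qm_density(matrix(c(3, 0, 0), 1, 3), 1,
                                          label = "S0"))
  traj <- optimize_qm(sys, pr, tol_g = 1e-7)
  expect_true(traj$converged)
  xs <- traj$positions[[length(traj$positions)]]
  expect_equal(xs[1, 1], 5, tolerance = 1e-5)
  expect_true(all(diff(traj$energies) <= 1e-14))

  # starting at the minimum: zero steps
  pr0 <- fixed_density_provider(qm_density(matrix(c(5, 0, 0), 1, 3), 1,
                                           label = "S0"))
  traj0 <- optimize_qm(sys, pr0, tol_g = 1e-7)
  expect_equal(traj0$steps, 0L)

  # frozen coordinates stay put
  case <- model_qm_case(1, seed = 9)
  tr <- optimize_qm(case$system, case$provider, "SA",
                    frozen = c(FALSE, TRUE), max_steps = 3L, tol_g = 1e-3)
  first <- tr$positions[[1]]
  last <- tr$positions[[length(tr$positions)]]
  expect_equal(last[2, ], first[2, ])
})
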