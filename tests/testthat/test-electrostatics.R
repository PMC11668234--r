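test_that("self-energy reproduces closed-form pair energies", {
  sys <- mm_system(rbind(c(0, 0, 0), c(2, 0, 0)), charges = c(1, -1))
  expect_equal(self_energy(sys), -0.5, tolerance = 1e-14)

  # bonded 1-2 pair is fully screened under the default rules
  bonded <- mm_system(rbind(c(0, 0, 0), c(2, 0, 0)), charges = c(1, -1),
                      bonds = rbind(c(1, 2)))
  expect_identical(self_energy(bonded), 0)

  # collinear head-to-tail unit dipoles at r = 3: -2 mu^2 / r^3
  dd <- mm_system(rbind(c(0, 0, 0), c(0, 0, 3)),
                  dipoles = rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(self_energy(dd), -2 / 27, tolerance = 1e-14)

  expect_error(self_energy(mm_system(rbind(c(0, 0, 0), c(0, 0, 0)),
                                     charges = c(1, 1))), "coincident")
})

test_that("self-energy is invariant under rigid rotation and translation", {
  sys <- random_cluster(7, seed = 21)
  e0 <- self_energy(sys)
  # random proper rotation
  set.seed(5)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rot <- sys
  rot$positions <- sys$positions %*% t(R)
  rot$dipoles <- sys$dipoles %*% t(R)
  rot$quadrupoles <- t(apply(sys$quadrupoles, 1, function(p) {
    quad_pack <- function(m) c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
    quad_pack(R %*% matrix(c(p[1], p[2], p[3], p[2], p[4], p[5], p[3], p[5], p[6]),
                           3, 3) %*% t(R))
  }))
  expect_equal(self_energy(rot), e0, tolerance = 1e-10)

  sh <- sys
  sh$positions <- sweep(sys$positions, 2, c(13.7, -4.2, 8.9), "+")
  expect_equal(self_energy(sh), e0, tolerance = 1e-10)
})

test_that("multipole source fields match the closed-form oracle site by site", {
  # trivial cases first
  one <- mm_system(rbind(c(0, 0, 0), c(10, 0, 0)), charges = c(1, 0),
                   polarizabilities = c(0, 1), thole = c(0, 0))
  E <- multipole_field(one, "d")
  expect_equal(unclass(E)[1, ], c(0.01, 0, 0), tolerance = 1e-14)

  zero <- mm_system(rbind(c(0, 0, 0), c(10, 0, 0)), charges = c(1, 0),
                    polarizabilities = c(0, 1),
                    rules = screening_rules(d = c(0, 0, 0, 0),
                                            group_based_p = FALSE),
                    bonds = rbind(c(1, 2)))
  expect_equal(max(abs(unclass(multipole_field(zero, "d")))), 0)

  # random 8-site cluster vs independent closed-form loop
  sys <- random_cluster(8, seed = 14)
  pol <- polarizable_sites(sys)
  for (kind in c("d", "p")) {
    E <- unclass(multipole_field(sys, kind))
    for (i in seq_along(pol)) {
      k <- pol[i]
      ref <- numeric(3)
      for (l in seq_len(nrow(sys$positions))) {
        if (l == k) next
        s <- screening_factor(sys, k, l, kind)
        if (s == 0) next
        a <- min(sys$thole[k], sys$thole[l])
        ref <- ref + s * oracle_damped_field(
          sys$charges[l], sys$dipoles[l, ], quad_unpack(sys$quadrupoles[l, ]),
          sys$positions[l, ], sys$positions[k, ],
          sys$polarizabilities[k], sys$polarizabilities[l], a)
      }
      expect_close(E[i, ], ref, 1e-10)
    }
  }
})

test_that("potentials and fields at external points are mutually consistent", {
  # printed examples
  s2 <- mm_system(matrix(0, 1, 3), charges = 2)
  expect_equal(potential_at_points(s2, matrix(c(4, 0, 0), 1, 3))$potential, 0.5)
  s3 <- mm_system(matrix(0, 1, 3), dipoles = matrix(c(0, 0, 1), 1, 3))
  expect_equal(potential_at_points(s3, matrix(c(0, 0, 2), 1, 3))$potential, 0.25)
  expect_error(potential_at_points(s2, matrix(0, 1, 3)), "coincides")

  # potential equals the line integral of the field from infinity
  sys <- random_cluster(5, seed = 33, charged = TRUE)
  P <- apply(sys$positions, 2, max) + c(3, 2, 4)
  u <- c(1, 1, 1) / sqrt(3)
  along <- function(s) {
    vapply(s, function(si) {
      sum(potential_at_points(sys, matrix(P + si * u, 1, 3))$field * u)
    }, numeric(1))
  }
  quad <- stats::integrate(along, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-10)
  expect_equal(quad$value,
               potential_at_points(sys, matrix(P, 1, 3))$potential,
               tolerance = 1e-6)

  # field and field gradient are numerical derivatives of the potential
  phi <- function(p) potential_at_points(sys, matrix(p, 1, 3))$potential
  out <- potential_at_points(sys, matrix(P, 1, 3))
  h <- 1e-4
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    expect_equal(out$field[1, j], -(phi(P + e) - phi(P - e)) / (2 * h),
                 tolerance = 1e-8)
    fcol <- (potential_at_points(sys, matrix(P + e, 1, 3))$field -
               potential_at_points(sys, matrix(P - e, 1, 3))$field) / (2 * h)
    expect_close(out$field_gradient[, j, 1], as.numeric(fcol), 1e-7)
  }
})
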