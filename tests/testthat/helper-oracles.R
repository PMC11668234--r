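# Independent oracles used across the suite.  Everything here is written from
# closed-form textbook expressions or naive numerics, independent of the
# package's tensor machinery.

# electrostatic potential of one multipolar site at point P (closed forms;
# S = r_site - P, consistent with the package's contraction convention)
oracle_site_potential <- function(q, mu, Th, r_site, P) {
  S <- r_site - P
  r <- sqrt(sum(S^2))
  q / r + sum(mu * (P - r_site)) / r^3 + 3 * drop(S %*% Th %*% S) / r^5
}

# field as a Richardson-extrapolated numerical gradient of the oracle potential
oracle_site_field <- function(q, mu, Th, r_site, P, h = 1e-3) {
  g <- numeric(3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- 1
    d1 <- (oracle_site_potential(q, mu, Th, r_site, P + h * e) -
             oracle_site_potential(q, mu, Th, r_site, P - h * e)) / (2 * h)
    d2 <- (oracle_site_potential(q, mu, Th, r_site, P + h / 2 * e) -
             oracle_site_potential(q, mu, Th, r_site, P - h / 2 * e)) / h
    g[j] <- (4 * d2 - d1) / 3
  }
  -g
}

# Thole damping scalars, independently coded from the standard expressions
oracle_lambdas <- function(r, alpha_k, alpha_l, a) {
  u <- r / (alpha_k * alpha_l)^(1 / 6)
  t <- a * u^3
  list(l3 = 1 - exp(-t),
       l5 = 1 - (1 + t) * exp(-t),
       l7 = 1 - (1 + t + 3 * t^2 / 5) * exp(-t))
}

# damped field of one multipolar site at an observation point (closed forms)
oracle_damped_field <- function(q, mu, Th, r_site, P, alpha_k, alpha_l, a) {
  S <- P - r_site
  r <- sqrt(sum(S^2))
  lam <- oracle_lambdas(r, alpha_k, alpha_l, a)
  Eq <- lam$l3 * q * S / r^3
  Ed <- 3 * lam$l5 * sum(mu * S) * S / r^5 - lam$l3 * mu / r^3
  Eth <- 15 * lam$l7 * drop(S %*% Th %*% S) * S / r^7 - 6 * lam$l5 * drop(Th %*% S) / r^5
  Eq + Ed + Eth
}

# naive per-pair assembly of the dipole-dipole coupling matrix
oracle_polarization_matrix <- function(system) {
  pol <- polarizable_sites(system)
  n <- length(pol)
  T <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    k <- pol[i]
    T[3 * i - 2:0, 3 * i - 2:0] <- diag(3) / system$polarizabilities[k]
    for (j in seq_len(n)) {
      if (i == j) next
      l <- pol[j]
      sp <- screening_factor(system, k, l, "p")
      if (sp == 0) next
      S <- system$positions[k, ] - system$positions[l, ]
      r <- sqrt(sum(S^2))
      a <- min(system$thole[k], system$thole[l])
      lam <- if (a > 0) oracle_lambdas(r, system$polarizabilities[k],
                                       system$polarizabilities[l], a)
      else list(l3 = 1, l5 = 1)
      blk <- -(3 * lam$l5 * tcrossprod(S) / r^5 - lam$l3 * diag(3) / r^3)
      T[3 * i - 2:0, 3 * j - 2:0] <- sp * blk
    }
  }
  T
}

# direct dense solution of the fully coupled dipole+charge linear system for a
# model-QM provider; returns energies and unknowns
oracle_monolithic <- function(system, provider, label) {
  pol <- polarizable_sites(system)
  n <- length(pol)
  P <- provider$density_points(label)
  p <- nrow(P)
  T <- oracle_polarization_matrix(system)
  Emm_d <- as.numeric(t(unclass(multipole_field(system, "d"))))
  Emm_p <- as.numeric(t(unclass(multipole_field(system, "p"))))
  Enuc <- numeric(3 * n)
  for (i in seq_len(n)) {
    for (a in seq_along(provider$nuclear_charges)) {
      S <- system$positions[pol[i], ] - provider$nuclei_positions[a, ]
      Enuc[3 * i - 2:0] <- Enuc[3 * i - 2:0] +
        provider$nuclear_charges[a] * S / sum(S^2)^1.5
    }
  }
  F <- matrix(0, 3 * n, p)
  for (j in seq_len(p)) {
    for (i in seq_len(n)) {
      S <- system$positions[pol[i], ] - P[j, ]
      F[3 * i - 2:0, j] <- S / sum(S^2)^1.5
    }
  }
  Vmm <- potential_at_points(system, P)$potential
  K <- provider$response
  q0 <- provider$density(list(potential = numeric(p)), label)$density_charges
  A <- rbind(cbind(T, matrix(0, 3 * n, 3 * n), -F),
             cbind(matrix(0, 3 * n, 3 * n), T, -F),
             cbind(K %*% t(F) / 2, K %*% t(F) / 2, diag(p)))
  b <- c(Enuc + Emm_d, Enuc + Emm_p, q0 + drop(K %*% Vmm))
  x <- solve(A, b)
  mud <- x[1:(3 * n)]
  mup <- x[(3 * n + 1):(6 * n)]
  q <- x[(6 * n + 1):(6 * n + p)]
  V <- Vmm - drop(t(F) %*% (mud + mup)) / 2
  dens <- qm_density(provider$nuclei_positions, provider$nuclear_charges, P, q,
                     label = label)
  e_int <- provider$internal_energy(list(potential = V), label)
  e_ele <- electrostatic_energy(system, dens)
  e_pol <- -0.5 * sum(mud * (Enuc + drop(F %*% q) + Emm_p))
  list(total = e_int + self_energy(system) + e_ele + e_pol,
       q = q,
       mu_d = matrix(mud, n, 3, byrow = TRUE),
       mu_p = matrix(mup, n, 3, byrow = TRUE))
}

# small helpers
rand_unit_sep <- function(min_r = 0.5, max_r = 6) {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2)) * stats::runif(1, min_r, max_r)
}

expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
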