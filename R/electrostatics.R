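#' Multipole electrostatics of the classical environment
#'
#' Pair energies, source fields and potentials built from the generalized
#' Coulomb tensors.  Permanent-multipole interactions (the self-energy and all
#' QM-MM statics) are undamped; only the fields that drive the induced dipoles
#' and the dipole-dipole coupling use the Thole-damped kernels.
#'
#' @name electrostatics
#' @keywords internal
NULL

## multipole list for site k: q scalar, mu 3-vector, Th full 3x3
site_multipole <- function(system, k) {
  list(q = system$charges[k],
       mu = system$dipoles[k, ],
       Th = quad_unpack(system$quadrupoles[k, ]))
}

## Full multipole-multipole pair interaction energy, M_k (x) T^{LL'} (x) M_l
## summed over L, L' = 0..2, with D^n evaluated at R = r_k - r_l (optionally
## damped).  Symmetric under k <-> l exchange.
pair_energy <- function(Mk, Ml, R, lam = rep(1, 6)) {
  d <- d_tensors(R, 4, lam)
  e <- Mk$q * Ml$q * d[[1]]
  e <- e + sum(Mk$mu * d[[2]]) * Ml$q - Mk$q * sum(Ml$mu * d[[2]])
  e <- e - drop(Mk$mu %*% d[[3]] %*% Ml$mu)
  e <- e + Ml$q * sum(Mk$Th * d[[3]]) + Mk$q * sum(Ml$Th * d[[3]])
  e <- e + contract_v_m3(d[[4]], Mk$mu, Ml$Th) - contract_v_m3(d[[4]], Ml$mu, Mk$Th)
  e + contract_m_m4(d[[5]], Mk$Th, Ml$Th)
}

#' Permanent-multipole self-energy of the MM environment
#'
#' `E_self = 1/2 * sum_{k != l} s^m_kl * sum_{LL'} M^L_k T^{LL'} M^L'_l`,
#' with undamped kernels and m-kind screening.
#'
#' @param system an [mm_system()].
#' @param breakdown if `TRUE`, also return the per-pair energy matrix.
#' @return scalar energy in hartree, or a list `(energy, pairs)` when
#'   `breakdown = TRUE`.
#' @export
#' @examples
#' sys <- mm_system(rbind(c(0, 0, 0), c(2, 0, 0)), charges = c(1, -1))
#' self_energy(sys)  # q1*q2/r = -0.5
self_energy <- function(system, breakdown = FALSE) {
  n <- nrow(system$positions)
  sm <- screening_matrix(system, "m")
  pairs <- matrix(0, n, n)
  e <- 0
  for (k in seq_len(n)) {
    Mk <- site_multipole(system, k)
    for (l in seq_len(n)) {
      if (l <= k || sm[k, l] == 0) next
      R <- system$positions[k, ] - system$positions[l, ]
      if (sum(R * R) == 0) {
        stop("coincident unscreened MM sites ", k, " and ", l, call. = FALSE)
      }
      ekl <- sm[k, l] * pair_energy(Mk, site_multipole(system, l), R)
      pairs[k, l] <- pairs[l, k] <- ekl
      e <- e + ekl
    }
  }
  if (breakdown) list(energy = e, pairs = pairs) else e
}

#' Source field of the permanent multipoles at the polarizable sites
#'
#' `E_k = -sum_l s_kl * sum_L T^{1L}_kl M^L_l` evaluated at every polarizable
#' site, with Thole-damped kernels (these fields drive the induced dipoles)
#' and either d-kind ("direct") or p-kind ("polarization") screening.  The two
#' induced-dipole sets differ only through this screening choice.
#'
#' @param system an [mm_system()].
#' @param kind `"d"` or `"p"`.
#' @return object of class `field_set`: matrix `n_pol x 3` (hartree/(e*bohr))
#'   with attributes `sites` (indices) and `kind`.
#' @export
multipole_field <- function(system, kind = c("d", "p")) {
  kind <- match.arg(kind)
  pol <- polarizable_sites(system)
  s <- screening_matrix(system, kind)
  E <- matrix(0, length(pol), 3)
  for (i in seq_along(pol)) {
    k <- pol[i]
    for (l in seq_len(nrow(system$positions))) {
      if (l == k || s[k, l] == 0) next
      R <- system$positions[k, ] - system$positions[l, ]
      damp <- pair_damping(system$polarizabilities[k], system$polarizabilities[l],
                           system$thole[k], system$thole[l])
      if (is.null(damp) && sum(R * R) == 0) {
        stop("coincident undamped sites ", k, " and ", l, call. = FALSE)
      }
      Ml <- site_multipole(system, l)
      E[i, ] <- E[i, ] + s[k, l] * point_field(Ml, R, damp)
    }
  }
  field_set(E, pol, kind)
}

## field at displacement R = r_obs - r_src from multipole M (optionally damped):
## E = -D1 q + D2 mu - D3 : Theta
point_field <- function(M, R, damp = NULL) {
  r <- sqrt(sum(R * R))
  if (r == 0) {
    if (is.null(damp)) stop("coincident points in field evaluation", call. = FALSE)
    return(drop(damped_origin_tensor(2, damp) %*% M$mu)) # odd terms vanish
  }
  lam <- lambda_vector(r, damp)
  d <- d_tensors(R, 3, lam)
  -M$q * d[[2]] + drop(d[[3]] %*% M$mu) - contract_m3_m(d[[4]], M$Th)
}

field_set <- function(E, sites, kind) {
  stopifnot(all(is.finite(E)))
  structure(E, sites = sites, kind = kind, class = c("field_set", "matrix"))
}

#' @export
print.field_set <- function(x, ...) {
  cat("field_set [", attr(x, "kind"), "] at ", nrow(x),
      " polarizable site(s); max |E| = ",
      format(if (nrow(x)) max(sqrt(rowSums(x^2))) else 0), " a.u.\n", sep = "")
  invisible(x)
}

#' Electrostatic potential, field and field gradient at arbitrary points
#'
#' Evaluates the potential of the permanent MM multipoles (and, optionally, of
#' a set of induced dipoles) at points that do not coincide with any MM site.
#' This is the quantity a QM density provider needs to build its one-electron
#' embedding operator: QM-MM interactions carry no screening and no damping.
#'
#' @param system an [mm_system()].
#' @param points m x 3 matrix, bohr.
#' @param dipoles optional `n_pol x 3` matrix of induced dipoles (e*bohr) on
#'   the polarizable sites, added to the sources.
#' @return list with `potential` (length m), `field` (m x 3) and
#'   `field_gradient` (3 x 3 x m), atomic units.
#' @export
potential_at_points <- function(system, points, dipoles = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  m <- nrow(points)
  n <- nrow(system$positions)
  pol <- polarizable_sites(system)
  if (!is.null(dipoles)) {
    dipoles <- as.matrix(dipoles)
    stopifnot(nrow(dipoles) == length(pol))
  }
  V <- numeric(m)
  E <- matrix(0, m, 3)
  G <- array(0, c(3, 3, m))
  for (j in seq_len(m)) {
    P <- points[j, ]
    for (k in seq_len(n)) {
      R <- system$positions[k, ] - P
      if (sum(R * R) == 0) {
        stop("evaluation point ", j, " coincides with MM site ", k, call. = FALSE)
      }
      M <- site_multipole(system, k)
      if (!is.null(dipoles)) {
        i <- match(k, pol)
        if (!is.na(i)) M$mu <- M$mu + dipoles[i, ]
      }
      d <- d_tensors(R, 4)
      ## potential phi(P) = q D0 + mu . D1(R) + Theta : D2(R), R = r_k - P
      V[j] <- V[j] + M$q * d[[1]] + sum(M$mu * d[[2]]) + sum(M$Th * d[[3]])
      ## E = -grad_P phi; each d/dP brings -D^(n+1)
      E[j, ] <- E[j, ] + M$q * d[[2]] + drop(d[[3]] %*% M$mu) +
        contract_m3_m(d[[4]], M$Th)
      G[, , j] <- G[, , j] - M$q * d[[3]] - contract_m3_v_last(d[[4]], M$mu) -
        contract_m4_m_last(d[[5]], M$Th)
    }
  }
  list(potential = V, field = E, field_gradient = G)
}
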