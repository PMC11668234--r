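#' QM-MM coupling and the self-consistent polarization loop
#'
#' The embedding energy splits into the permanent-multipole self-energy, the
#' QM-MM electrostatic interaction, the polarization energy of the induced
#' dipoles, and the QM internal energy.  Mutual polarization is converged by
#' alternating between the density provider (which sees the MM potential plus
#' the potential of the averaged induced dipoles) and the dipole linear
#' systems (which see the field of the current QM density).
#'
#' @name embedding
#' @keywords internal
NULL

#' QM-MM electrostatic interaction energy
#'
#' `E_ele = sum_k sum_L M^L_k [ sum_a T^L0_ka Z_a + sum_j T^L0_kj q_j ]`:
#' every MM multipole interacting with every QM point charge (nuclei and
#' density charges), unscreened and undamped.
#'
#' @param system an [mm_system()].
#' @param density a [qm_density()].
#' @return scalar energy, hartree.
#' @export
electrostatic_energy <- function(system, density) {
  pc <- qm_point_charges(density)
  if (length(pc$charges) == 0L) return(0)
  phi <- potential_at_points(system, pc$points)$potential
  sum(pc$charges * phi)
}

#' Electric field of the QM density at the polarizable MM sites
#'
#' Plain Coulomb field of the QM nuclei and density charges, undamped by
#' default (QM sources carry no Thole smearing).
#'
#' @param density a [qm_density()].
#' @param system an [mm_system()].
#' @param damped apply Thole damping using each MM site's own parameters
#'   (off by default).
#' @return `field_set` of kind `"qm"` (`n_pol x 3`, hartree/(e*bohr)).
#' @export
qm_field <- function(density, system, damped = FALSE) {
  pol <- polarizable_sites(system)
  pc <- qm_point_charges(density)
  E <- matrix(0, length(pol), 3)
  for (i in seq_along(pol)) {
    k <- pol[i]
    for (j in seq_along(pc$charges)) {
      R <- system$positions[k, ] - pc$points[j, ]
      damp <- if (damped) {
        pair_damping(system$polarizabilities[k], system$polarizabilities[k],
                     system$thole[k], system$thole[k])
      } else NULL
      if (is.null(damp) && sum(R * R) == 0) {
        stop("QM point ", j, " coincides with MM site ", k, call. = FALSE)
      }
      E[i, ] <- E[i, ] + point_field(list(q = pc$charges[j], mu = numeric(3),
                                          Th = matrix(0, 3, 3)), R, damp)
    }
  }
  field_set(E, pol, "qm")
}

## potential/field/field-gradient spec handed to the density provider:
## MM permanent multipoles plus (optionally) induced dipoles, at given points
embedding_potential <- function(system, points, dipoles_avg = NULL) {
  if (nrow(points) == 0L) {
    return(list(potential = numeric(0), field = matrix(0, 0, 3),
                field_gradient = array(0, c(3, 3, 0))))
  }
  potential_at_points(system, points, dipoles_avg)
}

#' Self-consistent polarizable-embedding calculation
#'
#' Iterates the mutual polarization between the MM induced dipoles and a
#' density provider until the total energy and the dipole/charge changes fall
#' below tolerance.  Each cycle: (i) evaluate the environment potential
#' (permanent multipoles + averaged induced dipoles `(mu_d + mu_p)/2`) at the
#' provider's density sites, (ii) obtain the state density, (iii) recompute
#' the QM field at the polarizable sites, (iv) re-solve the two dipole
#' systems.
#'
#' @param system an [mm_system()].
#' @param provider a `density_provider`.
#' @param label state label to converge (default: provider's first).
#' @param tol_e energy convergence threshold, hartree.
#' @param tol_mu max-norm threshold on dipole and density-charge changes.
#' @param max_iter iteration cap.
#' @param mixing linear mixing factor on the density charges (1 = plain
#'   fixed-point; use 0.5 for stiff response matrices).
#' @param solver,cg_tol passed to [solve_dipoles()].
#' @param initial_density optional [qm_density()] used as the starting guess
#'   in place of the provider's unpolarized density (the converged fixed
#'   point does not depend on this choice; the option exists to demonstrate
#'   exactly that).
#' @return object of class `pe_state`: energies by term, converged dipoles,
#'   density, per-iteration trace, convergence flag.
#' @export
pe_scf <- function(system, provider, label = provider$labels[1],
                   tol_e = 1e-9, tol_mu = 1e-7, max_iter = 100L,
                   mixing = 1, solver = "auto", cg_tol = 1e-10,
                   initial_density = NULL) {
  stopifnot(inherits(provider, "density_provider"))
  if (!label %in% provider$labels) {
    stop("provider does not know state '", label, "'", call. = FALSE)
  }
  pol <- polarizable_sites(system)
  npol <- length(pol)
  dpoints <- provider$density_points(label)
  e_self <- self_energy(system)

  ## iteration 0: provider sees the static MM potential only, no dipoles
  pot <- embedding_potential(system, dpoints)
  dens <- if (is.null(initial_density)) provider$density(pot, label) else initial_density
  check_provider_density(dens)
  dip <- structure(list(mu_d = matrix(0, npol, 3), mu_p = matrix(0, npol, 3),
                        residual_norms = c(0, 0), iterations = c(0L, 0L),
                        sites = pol), class = "induced_dipoles")
  e_int <- provider$internal_energy(pot, label)
  e_ele <- electrostatic_energy(system, dens)
  total <- e_int + e_self + e_ele
  trace <- data.frame(iter = 0L, dE = NA_real_, dmu = NA_real_, dq = NA_real_,
                      total = total)

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## (iii)+(iv): dipoles from the current density
    Eqm <- if (npol > 0) qm_field(dens, system) else NULL
    new_dip <- if (npol > 0) {
      solve_dipoles(system, Eqm, solver = solver, cg_tol = cg_tol, guess = dip)
    } else dip
    ## (i)+(ii): density from the updated embedding potential
    mu_avg <- if (npol > 0) (new_dip$mu_d + new_dip$mu_p) / 2 else NULL
    pot <- embedding_potential(system, dpoints, mu_avg)
    new_dens <- provider$density(pot, label)
    check_provider_density(new_dens, reference = dens)
    if (mixing != 1 && length(new_dens$density_charges)) {
      qmix <- mixing * new_dens$density_charges +
        (1 - mixing) * dens$density_charges
      new_dens <- qm_density(new_dens$nuclei_positions, new_dens$nuclear_charges,
                             new_dens$density_positions, qmix,
                             label = new_dens$label,
                             density_atoms = new_dens$density_atoms)
    }
    e_int <- provider$internal_energy(pot, label)
    e_ele <- electrostatic_energy(system, new_dens)
    e_pol <- if (npol > 0) polarization_energy(system, new_dip, Eqm) else 0
    new_total <- e_int + e_self + e_ele + e_pol

    dmu <- max(abs(new_dip$mu_d - dip$mu_d), abs(new_dip$mu_p - dip$mu_p), 0)
    dq <- if (length(new_dens$density_charges)) {
      max(abs(new_dens$density_charges - dens$density_charges))
    } else 0
    dE <- abs(new_total - total)
    trace <- rbind(trace, data.frame(iter = it, dE = dE, dmu = dmu, dq = dq,
                                     total = new_total))
    dens <- new_dens; dip <- new_dip; total <- new_total
    if (dE <= tol_e && max(dmu, dq) <= tol_mu) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("polarization SCF did not converge in ", max_iter,
         " iterations (last dE = ", format(tail_value(trace$dE)),
         ", dmu = ", format(tail_value(trace$dmu)), ")", call. = FALSE)
  }
  Eqm <- if (npol > 0) qm_field(dens, system) else NULL
  e_pol <- if (npol > 0) polarization_energy(system, dip, Eqm) else 0
  penalty <- if (npol > 0) lagrangian_penalty(system, dip, Eqm) else 0
  structure(list(
    energies = list(self = e_self, electrostatic = e_ele,
                    polarization = e_pol, qm_internal = e_int,
                    total = e_int + e_self + e_ele + e_pol),
    dipoles = dip, density = dens, qm_field = Eqm, penalty = penalty,
    trace = trace, converged = converged, iterations = max(trace$iter),
    system = system, provider = provider, label = label,
    tol = c(tol_e = tol_e, tol_mu = tol_mu)), class = "pe_state")
}

check_provider_density <- function(dens, reference = NULL) {
  if (!inherits(dens, "qm_density")) {
    stop("provider returned an object that is not a qm_density", call. = FALSE)
  }
  tot <- sum(dens$nuclear_charges) + sum(dens$density_charges)
  if (abs(tot - dens$charge) > 1e-8) {
    stop("provider violated charge conservation: total ", format(tot),
         " vs declared ", format(dens$charge), call. = FALSE)
  }
  if (!is.null(reference) && abs(dens$charge - reference$charge) > 1e-8) {
    stop("provider changed the total QM charge between calls", call. = FALSE)
  }
  invisible(dens)
}

#' Total embedding energy of a converged state
#'
#' Sum of the QM internal, self, electrostatic and polarization terms.  The
#' Lagrangian penalty is verified to vanish (it is a stationarity check, not
#' an energy contribution) and excluded.
#'
#' @param state a `pe_state` from [pe_scf()].
#' @param penalty_tol bound the penalty term must satisfy.
#' @return scalar energy, hartree.
#' @export
total_energy <- function(state, penalty_tol = 1e-8) {
  if (!isTRUE(state$converged)) {
    stop("total energy requested for an unconverged state", call. = FALSE)
  }
  if (abs(state$penalty) > penalty_tol) {
    stop("Lagrangian penalty ", format(state$penalty),
         " exceeds tolerance; dipoles are not stationary", call. = FALSE)
  }
  with(state$energies, qm_internal + self + electrostatic + polarization)
}

#' @export
print.pe_state <- function(x, ...) {
  cat("pe_state [", x$label, "] ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iteration(s)\n", sep = "")
  e <- x$energies
  cat(sprintf("  E_self     %18.10f\n  E_ele      %18.10f\n  E_pol      %18.10f\n  E_qm       %18.10f\n  E_total    %18.10f  hartree\n",
              e$self, e$electrostatic, e$polarization, e$qm_internal, e$total))
  invisible(x)
}

#' @export
summary.pe_state <- function(object, ...) {
  print(object)
  cat("  penalty term:", format(object$penalty),
      " max |mu_d|:", format(if (nrow(object$dipoles$mu_d)) max(abs(object$dipoles$mu_d)) else 0), "\n")
  invisible(object)
}

#' @export
coef.pe_state <- function(object, ...) {
  list(mu_d = object$dipoles$mu_d, mu_p = object$dipoles$mu_p,
       density_charges = object$density$density_charges)
}

#' @export
residuals.pe_state <- function(object, ...) object$trace

#' @export
plot.pe_state <- function(x, ...) {
  tr <- x$trace[-1, ]
  graphics::plot(tr$iter, pmax(tr$dE, 1e-16), log = "y", type = "b",
                 xlab = "SCF iteration", ylab = "|dE| (hartree)",
                 main = "Polarization SCF convergence", ...)
  invisible(x)
}

#' State-specific correction to the embedding energy
#'
#' After a state-averaged calculation, the environment dipoles are relaxed
#' for each individual state density and the electrostatic + polarization
#' energy is recomputed: `E_corr^X = E_elepol(gamma^X, mu(gamma^X)) -
#' E_elepol(gamma^X, mu(gamma_avg))` for each state `X`, and the excitation
#' correction is the final-minus-initial difference.
#'
#' @param system an [mm_system()].
#' @param density_i,density_f [qm_density()] objects for the initial and
#'   final states.
#' @param density_sa the state-averaged density on the same site layout.
#' @param solver passed to [solve_dipoles()].
#' @return list with `e_corr_i`, `e_corr_f`, `de_corr` (hartree) and the
#'   per-state energy pieces.
#' @export
state_specific_correction <- function(system, density_i, density_f, density_sa,
                                      solver = "auto") {
  layouts_match <- function(a, b) {
    nrow(a$density_positions) == nrow(b$density_positions) &&
      nrow(a$nuclei_positions) == nrow(b$nuclei_positions) &&
      max(abs(a$density_positions - b$density_positions), 0) < 1e-12 &&
      max(abs(a$nuclei_positions - b$nuclei_positions)) < 1e-12
  }
  if (!layouts_match(density_i, density_sa) || !layouts_match(density_f, density_sa)) {
    stop("state densities must share the site layout of the averaged density",
         call. = FALSE)
  }
  npol <- length(polarizable_sites(system))
  elepol <- function(dens_energy, dipoles, field_of_dens) {
    electrostatic_energy(system, dens_energy) +
      if (npol > 0) polarization_energy(system, dipoles, field_of_dens) else 0
  }
  if (npol == 0L) {
    ## no induced dipoles: the electrostatic term cancels identically
    return(list(e_corr_i = 0, e_corr_f = 0, de_corr = 0))
  }
  E_sa <- qm_field(density_sa, system)
  mu_sa <- solve_dipoles(system, E_sa, solver = solver)
  corr <- function(dens) {
    E_x <- qm_field(dens, system)
    mu_x <- solve_dipoles(system, E_x, solver = solver)
    ## both evaluations use the state density gamma^X; only the dipoles differ
    elepol(dens, mu_x, E_x) - elepol(dens, mu_sa, E_x)
  }
  e_i <- corr(density_i)
  e_f <- corr(density_f)
  list(e_corr_i = e_i, e_corr_f = e_f, de_corr = e_f - e_i)
}

#' State-specific corrected excitation energy
#'
#' Adds the state-specific polarization correction to a state-averaged
#' excitation energy: `dE_SS = dE_SA + dE_corr`.  Both inputs and the result
#' are in eV (use [hartree_to_ev()] at the boundary).
#'
#' @param de_sa state-averaged excitation energy, eV.
#' @param de_corr excitation correction (final minus initial state), eV.
#' @return corrected excitation energy, eV.
#' @export
#' @examples
#' corrected_excitation(3.50, 0.08)  # 3.58
corrected_excitation <- function(de_sa, de_corr) {
  stopifnot(is.finite(de_sa), is.finite(de_corr))
  de_sa + de_corr
}
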