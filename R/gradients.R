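#' Analytical geometrical gradients of the embedding terms
#'
#' At the converged fixed point the embedding energy is stationary with
#' respect to the induced dipoles and the model-QM density charges, so only
#' explicit derivatives are needed: the gradient of the QM-MM electrostatic
#' term is each QM point charge times the gradient of the static MM potential,
#' and the polarization gradient is `-1/2 sum_k (mu_d + mu_p)_k . dE_k/dr`,
#' i.e. each QM charge times the gradient of the averaged induced-dipole
#' potential.  MM-side gradients of the self-energy and the QM-MM term are
#' provided to support force-conservation checks even though geometry
#' optimization freezes the MM atoms.
#'
#' @name gradients
#' @keywords internal
NULL

## field at points from induced dipoles alone (mu: n_pol x 3)
dipole_field_at_points <- function(system, mu, points) {
  pol <- polarizable_sites(system)
  points <- matrix(as.numeric(points), ncol = 3)
  E <- matrix(0, nrow(points), 3)
  for (j in seq_len(nrow(points))) {
    for (i in seq_along(pol)) {
      R <- system$positions[pol[i], ] - points[j, ]
      d <- d_tensors(R, 2)
      E[j, ] <- E[j, ] + drop(d[[3]] %*% mu[i, ])
    }
  }
  E
}

## accumulate per-carrier gradients onto their host atoms
fold_to_atoms <- function(g_sites, atoms, n_atoms) {
  g <- matrix(0, n_atoms, 3)
  for (s in seq_len(nrow(g_sites))) {
    a <- atoms[s]
    if (is.na(a)) {
      stop("density site without a site-to-atom map; cannot assign gradient",
           call. = FALSE)
    }
    g[a, ] <- g[a, ] + g_sites[s, ]
  }
  g
}

#' Gradient of the QM-MM electrostatic energy with respect to QM atoms
#'
#' Nuclei contribute directly; density charges ride rigidly with their mapped
#' host atom.
#'
#' @param system an [mm_system()].
#' @param density a [qm_density()] (with `density_atoms` set if density
#'   charges are present).
#' @return `n_atoms x 3` matrix, hartree/bohr.
#' @export
grad_electrostatic <- function(system, density) {
  pc <- qm_point_charges(density)
  n_at <- nrow(density$nuclei_positions)
  if (length(pc$charges) == 0L) return(matrix(0, n_at, 3))
  E <- potential_at_points(system, pc$points)$field
  fold_to_atoms(-pc$charges * E, pc$atoms, n_at) # dE/dr = q * grad(phi) = -q * E
}

#' Gradient of the polarization energy with respect to QM atoms
#'
#' Explicit derivative only, valid at dipole stationarity:
#' `-1/2 sum_k (mu_d + mu_p)_k . dE_k(QM)/dr_a`, which equals each QM point
#' charge times the gradient of the averaged induced-dipole potential.
#'
#' @param system an [mm_system()].
#' @param state a converged `pe_state`, or a list with `dipoles` and
#'   `density`.
#' @return `n_atoms x 3` matrix, hartree/bohr.
#' @export
grad_polarization <- function(system, state) {
  if (inherits(state, "pe_state") && !isTRUE(state$converged)) {
    stop("polarization gradient requires converged dipoles", call. = FALSE)
  }
  dipoles <- state$dipoles
  density <- state$density
  n_at <- nrow(density$nuclei_positions)
  if (length(dipoles$sites) == 0L) return(matrix(0, n_at, 3))
  pc <- qm_point_charges(density)
  mu_avg <- (dipoles$mu_d + dipoles$mu_p) / 2
  E_ind <- dipole_field_at_points(system, mu_avg, pc$points)
  fold_to_atoms(-pc$charges * E_ind, pc$atoms, n_at)
}

## gradient of the full pair energy with respect to R = r_k - r_l
pair_energy_grad <- function(Mk, Ml, R) {
  d <- d_tensors(R, 5)
  D1 <- d[[2]]; D2 <- d[[3]]; D3 <- d[[4]]; D4 <- d[[5]]; D5 <- d[[6]]
  c3_vv <- function(D, a, b) {
    v <- numeric(3)
    for (i in 1:3) v[i] <- drop(a %*% D[, , i] %*% b)
    v
  }
  c3_m <- function(D, M) vapply(1:3, function(i) sum(D[, , i] * M), numeric(1))
  c4_vm <- function(D, v, M) {
    out <- numeric(3)
    for (i in 1:3) out[i] <- sum(vapply(1:3, function(a) v[a] * sum(D[a, , , i] * M), numeric(1)))
    out
  }
  c5_mm <- function(D, A, B) {
    out <- numeric(3)
    for (i in 1:3) {
      s <- 0
      for (a in 1:3) for (b in 1:3) s <- s + A[a, b] * sum(D[a, b, , , i] * B)
      out[i] <- s
    }
    out
  }
  g <- Mk$q * Ml$q * D1
  g <- g + Ml$q * drop(D2 %*% Mk$mu) - Mk$q * drop(D2 %*% Ml$mu)
  g <- g - c3_vv(D3, Mk$mu, Ml$mu)
  g <- g + Ml$q * c3_m(D3, Mk$Th) + Mk$q * c3_m(D3, Ml$Th)
  g <- g + c4_vm(D4, Mk$mu, Ml$Th) - c4_vm(D4, Ml$mu, Mk$Th)
  g + c5_mm(D5, Mk$Th, Ml$Th)
}

#' MM-site gradients of the permanent-multipole self-energy
#'
#' @param system an [mm_system()].
#' @return `n x 3` matrix, hartree/bohr.
#' @export
grad_self_mm <- function(system) {
  n <- nrow(system$positions)
  sm <- screening_matrix(system, "m")
  g <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    Mk <- site_multipole(system, k)
    for (l in seq_len(n)) {
      if (l <= k || sm[k, l] == 0) next
      R <- system$positions[k, ] - system$positions[l, ]
      gk <- sm[k, l] * pair_energy_grad(Mk, site_multipole(system, l), R)
      g[k, ] <- g[k, ] + gk
      g[l, ] <- g[l, ] - gk
    }
  }
  g
}

#' MM-site gradients of the QM-MM electrostatic energy
#'
#' @param system an [mm_system()].
#' @param density a [qm_density()].
#' @return `n x 3` matrix, hartree/bohr.
#' @export
grad_electrostatic_mm <- function(system, density) {
  pc <- qm_point_charges(density)
  n <- nrow(system$positions)
  g <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    M <- site_multipole(system, k)
    for (j in seq_along(pc$charges)) {
      R <- system$positions[k, ] - pc$points[j, ]
      d <- d_tensors(R, 3)
      g[k, ] <- g[k, ] + pc$charges[j] *
        (M$q * d[[2]] + drop(d[[3]] %*% M$mu) + contract_m3_m(d[[4]], M$Th))
    }
  }
  g
}

#' Per-term gradient report for a converged embedding state
#'
#' @param state a converged `pe_state`.
#' @param validate if `TRUE`, finite-difference the fully re-converged total
#'   energy and report the worst deviation.
#' @param fd_step central-difference step, bohr.
#' @return object of class `gradient_report`: per-QM-atom matrices
#'   `electrostatic`, `polarization`, `qm_internal`, `total` (hartree/bohr),
#'   plus `fd_max_deviation` when validation was requested.
#' @export
embedding_gradient <- function(state, validate = FALSE, fd_step = 1e-4) {
  stopifnot(inherits(state, "pe_state"))
  sys <- state$system
  g_ele <- grad_electrostatic(sys, state$density)
  g_pol <- grad_polarization(sys, state)
  g_int <- matrix(0, nrow(g_ele), 3) # model QM internal energy is geometry-free
  rep <- structure(list(electrostatic = g_ele, polarization = g_pol,
                        qm_internal = g_int, total = g_ele + g_pol + g_int,
                        fd_max_deviation = NA_real_), class = "gradient_report")
  if (validate) {
    efun <- scf_energy_function(sys, state$provider, state$label,
                                tol_e = min(1e-12, state$tol["tol_e"]),
                                tol_mu = min(1e-10, state$tol["tol_mu"]))
    rep$fd_max_deviation <- validate_fd(efun, state$provider$nuclei_positions,
                                        gradient = rep$total, step = fd_step)$max_deviation
  }
  rep
}

#' @export
print.gradient_report <- function(x, ...) {
  cat("gradient_report:", nrow(x$total), "QM atom(s); max |g| =",
      format(max(abs(x$total))), "hartree/bohr")
  if (is.finite(x$fd_max_deviation)) {
    cat("; FD max deviation =", format(x$fd_max_deviation))
  }
  cat("\n")
  invisible(x)
}

## total energy as a function of the QM nuclear coordinates (re-converged SCF)
scf_energy_function <- function(system, provider, label, tol_e = 1e-12,
                                tol_mu = 1e-10) {
  function(positions) {
    pr <- provider$relocate(matrix(positions, ncol = 3))
    total_energy(pe_scf(system, pr, label, tol_e = tol_e, tol_mu = tol_mu))
  }
}

#' Finite-difference gradient validator
#'
#' Central differences (second order by default, optional Richardson
#' extrapolation) of a deterministic energy function over every coordinate.
#'
#' @param energy_fn function taking an `n x 3` coordinate matrix and
#'   returning a scalar energy.
#' @param coords `n x 3` matrix of evaluation coordinates, bohr.
#' @param gradient optional analytic `n x 3` gradient to compare against.
#' @param step central-difference step, bohr.
#' @param order 2 (plain central) or 4 (Richardson-extrapolated).
#' @return list with `fd_gradient` and, when `gradient` was supplied,
#'   `max_deviation` (worst absolute component difference).
#' @export
validate_fd <- function(energy_fn, coords, gradient = NULL, step = 1e-4,
                        order = 2) {
  stopifnot(order %in% c(2, 4))
  coords <- matrix(as.numeric(coords), ncol = 3)
  fd <- matrix(0, nrow(coords), 3)
  central <- function(h, i, j) {
    cp <- coords; cm <- coords
    cp[i, j] <- cp[i, j] + h
    cm[i, j] <- cm[i, j] - h
    ep <- energy_fn(cp); em <- energy_fn(cm)
    if (!is.finite(ep) || !is.finite(em)) {
      stop("non-finite energy at displacement of coordinate (", i, ",", j,
           ") by ", h, call. = FALSE)
    }
    (ep - em) / (2 * h)
  }
  for (i in seq_len(nrow(coords))) {
    for (j in 1:3) {
      fd[i, j] <- if (order == 2) {
        central(step, i, j)
      } else {
        (4 * central(step / 2, i, j) - central(step, i, j)) / 3
      }
    }
  }
  out <- list(fd_gradient = fd)
  if (!is.null(gradient)) out$max_deviation <- max(abs(fd - as.matrix(gradient)))
  out
}

#' Frozen-environment geometry optimization of the QM region
#'
#' Quasi-Newton (BFGS with Armijo backtracking line search) minimization of
#' the fully re-converged embedding energy over the unfrozen QM coordinates.
#' All MM sites are always frozen.  Accepted steps never increase the energy;
#' convergence is declared when the largest gradient component over the free
#' coordinates drops below `tol_g`.
#'
#' @param system an [mm_system()].
#' @param provider a `density_provider`.
#' @param label state label to follow.
#' @param frozen logical `n_atoms` vector (or `n x 3` matrix) of frozen QM
#'   coordinates; default none.
#' @param tol_g convergence threshold on max |gradient|, hartree/bohr.
#' @param max_steps step cap.
#' @param tol_e,tol_mu SCF tolerances used at each geometry.
#' @param restraint optional list `(energy = function(pos), gradient =
#'   function(pos))` adding a penalty term (e.g. a dihedral restraint).
#' @return object of class `pe_trajectory`: per-step `positions` (list of
#'   matrices), `energies`, `grad_norms`, `converged`, `steps`.
#' @export
optimize_qm <- function(system, provider, label = provider$labels[1],
                        frozen = NULL, tol_g = 4.5e-4, max_steps = 100L,
                        tol_e = 1e-11, tol_mu = 1e-9, restraint = NULL) {
  pos <- provider$nuclei_positions
  n_at <- nrow(pos)
  free <- if (is.null(frozen)) {
    matrix(TRUE, n_at, 3)
  } else if (is.matrix(frozen)) {
    !frozen
  } else {
    matrix(rep(!as.logical(frozen), 3), n_at, 3)
  }
  fmask <- as.vector(t(free)) # row-major flatten matches x layout below

  eval_point <- function(p) {
    pr <- provider$relocate(p)
    st <- pe_scf(system, pr, label, tol_e = tol_e, tol_mu = tol_mu)
    e <- total_energy(st)
    g <- embedding_gradient(st)$total
    if (!is.null(restraint)) {
      e <- e + restraint$energy(p)
      g <- g + restraint$gradient(p)
    }
    list(e = e, g = as.vector(t(g)))
  }

  x <- as.vector(t(pos))
  cur <- eval_point(pos)
  H <- diag(sum(fmask)) # inverse-Hessian estimate over free coordinates
  traj_pos <- list(pos)
  energies <- cur$e
  gnorms <- max(abs(cur$g[fmask]))
  steps <- 0L
  converged <- gnorms <= tol_g

  while (!converged && steps < max_steps) {
    gf <- cur$g[fmask]
    p <- -drop(H %*% gf)
    if (sum(p * gf) > 0) p <- -gf # reset to steepest descent if not a descent direction
    ## Armijo backtracking
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      xn <- x
      xn[fmask] <- x[fmask] + alpha * p
      cand <- eval_point(matrix(xn, ncol = 3, byrow = TRUE))
      if (cand$e <= cur$e + 1e-4 * alpha * sum(gf * p)) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      stop("line search failed; last accepted geometry at step ", steps,
           " with energy ", format(cur$e), call. = FALSE)
    }
    s <- alpha * p
    y <- cand$g[fmask] - gf
    sy <- sum(s * y)
    if (sy > 1e-12) { # BFGS inverse update with curvature guard
      rho <- 1 / sy
      I <- diag(length(s))
      V <- I - rho * outer(s, y)
      H <- V %*% H %*% t(V) + rho * outer(s, s)
    }
    x <- xn
    cur <- cand
    steps <- steps + 1L
    traj_pos[[steps + 1L]] <- matrix(x, ncol = 3, byrow = TRUE)
    energies <- c(energies, cur$e)
    gnorms <- c(gnorms, max(abs(cur$g[fmask])))
    converged <- tail_value(gnorms) <= tol_g
  }
  structure(list(positions = traj_pos, energies = energies,
                 grad_norms = gnorms, converged = converged, steps = steps,
                 tol_g = tol_g), class = "pe_trajectory")
}

#' @export
print.pe_trajectory <- function(x, ...) {
  cat("pe_trajectory:", x$steps, "step(s);",
      if (x$converged) "converged" else "not converged",
      "(max |g| =", format(tail_value(x$grad_norms)), "hartree/bohr)\n")
  cat("  energy:", format(x$energies[1], digits = 10), "->",
      format(tail_value(x$energies), digits = 10), "hartree\n")
  invisible(x)
}
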