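#' Mutual polarization of the induced point dipoles
#'
#' The induced dipoles solve two linear systems sharing one coupling matrix:
#' `T mu_d = E_qm + E_direct(M)` and `T mu_p = E_qm + E_pol(M)`, where the
#' kl-block of `T` is `alpha_k^-1 I` on the diagonal and the (Thole-damped,
#' p-screened) dipole-field tensor off the diagonal.  The two sets differ only
#' through the screening of their permanent-multipole source fields.
#'
#' @name polarization
#' @keywords internal
NULL

#' Assemble the polarization coupling matrix
#'
#' Builds the symmetric positive-definite `3n x 3n` matrix over the
#' polarizable sites: diagonal blocks `alpha_k^-1 I`, off-diagonal blocks the
#' negated damped dipole-field tensor scaled by the p-kind screening factor.
#'
#' @param system an [mm_system()] with at least one polarizable site.
#' @return symmetric matrix of size `3 n_pol`, with attribute `sites`.
#' @export
polarization_matrix <- function(system) {
  pol <- polarizable_sites(system)
  n <- length(pol)
  if (n == 0L) stop("no polarizable sites in system", call. = FALSE)
  sp <- screening_matrix(system, "p")
  T <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    k <- pol[i]
    T[3 * i - 2:0, 3 * i - 2:0] <- diag(3) / system$polarizabilities[k]
    for (j in seq_len(n)) {
      if (j <= i) next
      l <- pol[j]
      if (sp[k, l] == 0) next
      R <- system$positions[k, ] - system$positions[l, ]
      damp <- pair_damping(system$polarizabilities[k], system$polarizabilities[l],
                           system$thole[k], system$thole[l])
      ## T^11 block = -D2(damped); symmetric and even in R
      blk <- if (is.null(damp)) {
        if (sum(R * R) == 0) {
          stop("coincident undamped polarizable sites ", k, " and ", l, call. = FALSE)
        }
        -sp[k, l] * d_tensors(R, 2)[[3]]
      } else if (sum(R * R) == 0) {
        -sp[k, l] * damped_origin_tensor(2, damp)
      } else {
        -sp[k, l] * d_tensors(R, 2, lambda_vector(sqrt(sum(R * R)), damp))[[3]]
      }
      T[3 * i - 2:0, 3 * j - 2:0] <- blk
      T[3 * j - 2:0, 3 * i - 2:0] <- t(blk)
    }
  }
  ev_min <- min(eigen(T, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10) {
    d <- as.matrix(stats::dist(system$positions[pol, , drop = FALSE]))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    stop("polarization matrix is near-singular (min eigenvalue ",
         format(ev_min), "); closest polarizable pair: sites ",
         pol[ij[1]], " and ", pol[ij[2]], call. = FALSE)
  }
  attr(T, "sites") <- pol
  T
}

## Jacobi-preconditioned conjugate gradient; returns solution + residual trace
pcg_solve <- function(A, b, x0 = NULL, tol = 1e-8, max_iter = 200L) {
  x <- if (is.null(x0)) numeric(length(b)) else x0
  Minv <- 1 / diag(A)
  r <- b - drop(A %*% x)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) bnorm <- 1
  trace <- sqrt(sum(r * r)) / bnorm
  it <- 0L
  while (tail_value(trace) > tol && it < max_iter) {
    it <- it + 1L
    Ap <- drop(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    trace <- c(trace, sqrt(sum(r * r)) / bnorm)
  }
  if (tail_value(trace) > tol) {
    stop("conjugate gradient did not converge in ", max_iter,
         " iterations; relative residual trace: ",
         paste(format(trace, digits = 3), collapse = " "), call. = FALSE)
  }
  list(x = x, iterations = it, residual = tail_value(trace))
}

tail_value <- function(v) v[length(v)]

#' Solve for the direct and polarization induced-dipole sets
#'
#' @param system an [mm_system()].
#' @param qm_field `n_pol x 3` matrix (or [multipole_field()]-style object) of
#'   the QM electric field at the polarizable sites; zero if `NULL`.
#' @param solver `"auto"` (dense below 600 unknowns, CG above), `"dense"`
#'   (Cholesky factorization) or `"cg"` (Jacobi-preconditioned conjugate
#'   gradient).
#' @param cg_tol relative-residual tolerance for CG.
#' @param max_iter CG iteration cap.
#' @param guess optional `induced_dipoles` object used as CG starting guess.
#' @return object of class `induced_dipoles`: list with `mu_d`, `mu_p`
#'   (`n_pol x 3`, e*bohr), `residual_norms`, `iterations`, `sites`.
#' @export
solve_dipoles <- function(system, qm_field = NULL, solver = c("auto", "dense", "cg"),
                          cg_tol = 1e-8, max_iter = 200L, guess = NULL) {
  solver <- match.arg(solver)
  pol <- polarizable_sites(system)
  n <- length(pol)
  if (n == 0L) {
    return(structure(list(mu_d = matrix(0, 0, 3), mu_p = matrix(0, 0, 3),
                          residual_norms = c(0, 0), iterations = c(0L, 0L),
                          sites = integer(0)), class = "induced_dipoles"))
  }
  Eqm <- if (is.null(qm_field)) matrix(0, n, 3) else unclass(qm_field)[, , drop = FALSE]
  stopifnot(nrow(Eqm) == n, all(is.finite(Eqm)))
  T <- polarization_matrix(system)
  bd <- as.numeric(t(Eqm + unclass(multipole_field(system, "d"))))
  bp <- as.numeric(t(Eqm + unclass(multipole_field(system, "p"))))
  if (solver == "auto") solver <- if (3 * n < 600) "dense" else "cg"
  if (solver == "dense") {
    ch <- chol(T)
    xd <- backsolve(ch, forwardsolve(t(ch), bd))
    xp <- backsolve(ch, forwardsolve(t(ch), bp))
    res <- c(vec_norm(bd - drop(T %*% xd)) / max(vec_norm(bd), 1e-300),
             vec_norm(bp - drop(T %*% xp)) / max(vec_norm(bp), 1e-300))
    its <- c(1L, 1L)
  } else {
    g_d <- if (!is.null(guess)) as.numeric(t(guess$mu_d)) else NULL
    g_p <- if (!is.null(guess)) as.numeric(t(guess$mu_p)) else NULL
    sd <- pcg_solve(T, bd, g_d, tol = cg_tol, max_iter = max_iter)
    sp <- pcg_solve(T, bp, g_p, tol = cg_tol, max_iter = max_iter)
    xd <- sd$x; xp <- sp$x
    res <- c(sd$residual, sp$residual)
    its <- c(sd$iterations, sp$iterations)
  }
  structure(list(mu_d = matrix(xd, n, 3, byrow = TRUE),
                 mu_p = matrix(xp, n, 3, byrow = TRUE),
                 residual_norms = res, iterations = its, sites = pol),
            class = "induced_dipoles")
}

vec_norm <- function(v) sqrt(sum(v * v))

#' @export
print.induced_dipoles <- function(x, ...) {
  cat("induced_dipoles on", nrow(x$mu_d), "site(s):",
      "max |mu_d| =", format(if (nrow(x$mu_d)) max(sqrt(rowSums(x$mu_d^2))) else 0),
      " max |mu_p| =", format(if (nrow(x$mu_p)) max(sqrt(rowSums(x$mu_p^2))) else 0),
      "\n  residuals:", format(x$residual_norms, digits = 3),
      " iterations:", x$iterations, "\n")
  invisible(x)
}

#' Polarization energy
#'
#' `E_pol = -1/2 <mu_d, E_qm + E_pol(M)>`: the direct dipoles contracted with
#' the sum of the QM field and the p-screened permanent-multipole field.
#'
#' @param system an [mm_system()].
#' @param dipoles an `induced_dipoles` object.
#' @param qm_field QM field at polarizable sites (`n_pol x 3`) or `NULL`.
#' @return scalar energy, hartree.
#' @export
polarization_energy <- function(system, dipoles, qm_field = NULL) {
  n <- length(dipoles$sites)
  if (n == 0L) return(0)
  Eqm <- if (is.null(qm_field)) matrix(0, n, 3) else unclass(qm_field)[, , drop = FALSE]
  if (!all(dim(Eqm) == dim(dipoles$mu_d))) {
    stop("field/dipole shape mismatch", call. = FALSE)
  }
  Ep <- unclass(multipole_field(system, "p"))
  -0.5 * sum(dipoles$mu_d * (Eqm + Ep))
}

#' Lagrangian polarization penalty
#'
#' The coupling term `1/2 <mu_p, T mu_d - E_qm - E_direct(M)>` of the
#' variational energy functional.  It vanishes (to solver tolerance) when
#' `mu_d` solves its linear system, which is the stationarity condition that
#' makes explicit-only gradients exact.
#'
#' @inheritParams polarization_energy
#' @return scalar, hartree.
#' @export
lagrangian_penalty <- function(system, dipoles, qm_field = NULL) {
  n <- length(dipoles$sites)
  if (n == 0L) return(0)
  Eqm <- if (is.null(qm_field)) matrix(0, n, 3) else unclass(qm_field)[, , drop = FALSE]
  T <- polarization_matrix(system)
  bd <- as.numeric(t(Eqm + unclass(multipole_field(system, "d"))))
  md <- as.numeric(t(dipoles$mu_d))
  mp <- as.numeric(t(dipoles$mu_p))
  0.5 * sum(mp * (drop(T %*% md) - bd))
}
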