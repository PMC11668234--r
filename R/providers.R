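#' Density providers: the QM side of the embedding contract
#'
#' A density provider is the package's abstraction of an electronic-structure
#' code.  Given the external one-electron potential (potentials, fields and
#' field gradients of the environment at its density sites) it must return a
#' [qm_density()] and the QM internal energy of the requested state under that
#' embedding.  Providers must be deterministic and charge-conserving.  Two
#' implementations ship with the package: a frozen-density provider and a
#' linear-response "model QM" whose charges respond to the embedding
#' potential, giving a genuine coupled fixed point without any wavefunction
#' machinery.
#'
#' @name density-providers
#' @keywords internal
NULL

new_provider <- function(fields) structure(fields, class = "density_provider")

#' @export
print.density_provider <- function(x, ...) {
  cat("density_provider [", x$type, "]: states ",
      paste(x$labels, collapse = ", "), "; ",
      nrow(x$nuclei_positions), " nuclei\n", sep = "")
  invisible(x)
}

#' Frozen-density provider
#'
#' Wraps one or more fixed [qm_density()] objects: the density does not
#' respond to the embedding potential (the internal energies are constants).
#'
#' @param densities a single `qm_density` or a list of them (state labels are
#'   taken from each object).
#' @param energies named numeric vector of internal energies (hartree) per
#'   label; defaults to 0.
#' @return a `density_provider`.
#' @export
fixed_density_provider <- function(densities, energies = NULL) {
  if (inherits(densities, "qm_density")) densities <- list(densities)
  labels <- vapply(densities, function(d) d$label, character(1))
  names(densities) <- labels
  if (is.null(energies)) energies <- stats::setNames(numeric(length(labels)), labels)
  new_provider(list(
    type = "fixed",
    labels = labels,
    nuclei_positions = densities[[1]]$nuclei_positions,
    nuclear_charges = densities[[1]]$nuclear_charges,
    density = function(potential, label) densities[[label]],
    internal_energy = function(potential, label) unname(energies[label]),
    density_points = function(label) densities[[label]]$density_positions,
    relocate = function(positions) {
      moved <- lapply(densities, relocate_density, positions = positions)
      fixed_density_provider(moved, energies)
    }))
}

## move nuclei to new positions; density sites ride rigidly with their host atom
relocate_density <- function(d, positions) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  stopifnot(nrow(positions) == nrow(d$nuclei_positions))
  dp <- d$density_positions
  if (nrow(dp) > 0L) {
    if (is.null(d$density_atoms)) {
      stop("density sites present but no site-to-atom map; cannot relocate",
           call. = FALSE)
    }
    shift <- positions[d$density_atoms, , drop = FALSE] -
      d$nuclei_positions[d$density_atoms, , drop = FALSE]
    dp <- dp + shift
  }
  qm_density(positions, d$nuclear_charges, dp, d$density_charges,
             charge = d$charge, label = d$label, density_atoms = d$density_atoms)
}

#' Linear-response model QM
#'
#' A desk-scale stand-in for a polarizable quantum region: point nuclei plus
#' density charges `q = q0 + K V`, where `V` is the external potential at the
#' density sites and `K` is a symmetric negative-semidefinite response matrix
#' with zero row sums (so the total charge is conserved exactly).  The
#' internal energy consistent with this response is
#' `E_int = E0 - 1/2 V' K V`, which makes the coupled QM + polarization fixed
#' point variational: explicit-only geometrical gradients are then exact.
#'
#' @param nuclei_positions m x 3 matrix, bohr.
#' @param nuclear_charges numeric length m, e.
#' @param density_positions p x 3 matrix of density sites, bohr.
#' @param base_charges numeric length p: unperturbed density charges `q0`, e.
#' @param response p x p response matrix `K` (e^2/hartree); symmetric NSD with
#'   zero row sums.  `NULL` means no response (frozen density).
#' @param density_atoms integer length p: host nucleus of each density site.
#' @param E0 unperturbed internal energy per state, named by label.
#' @param labels state labels; the model supports per-state base charges via a
#'   list in `base_charges` (named by label).
#' @return a `density_provider`.
#' @export
model_qm <- function(nuclei_positions, nuclear_charges,
                     density_positions, base_charges,
                     response = NULL, density_atoms = NULL,
                     E0 = NULL, labels = NULL) {
  nuclei_positions <- matrix(as.numeric(nuclei_positions), ncol = 3)
  density_positions <- matrix(as.numeric(density_positions), ncol = 3)
  p <- nrow(density_positions)
  if (!is.list(base_charges)) base_charges <- list(SA = as.numeric(base_charges))
  if (is.null(labels)) labels <- names(base_charges)
  stopifnot(all(vapply(base_charges, length, integer(1)) == p))
  if (is.null(density_atoms)) {
    density_atoms <- nearest_atom_map(density_positions, nuclei_positions)
  }
  if (!is.null(response)) {
    response <- as.matrix(response)
    stopifnot(all(dim(response) == c(p, p)))
    if (max(abs(response - t(response))) > 1e-12) {
      stop("response matrix must be symmetric", call. = FALSE)
    }
    if (max(abs(rowSums(response))) > 1e-12) {
      stop("response matrix rows must sum to zero (charge conservation)",
           call. = FALSE)
    }
    if (max(eigen(response, symmetric = TRUE, only.values = TRUE)$values) > 1e-10) {
      stop("response matrix must be negative semidefinite", call. = FALSE)
    }
  }
  if (is.null(E0)) E0 <- stats::setNames(numeric(length(labels)), labels)

  make <- function(nuc_pos, dens_pos) {
    new_provider(list(
      type = "model_qm",
      labels = labels,
      nuclei_positions = nuc_pos,
      nuclear_charges = nuclear_charges,
      response = response,
      density_points = function(label) dens_pos,
      density = function(potential, label) {
        q0 <- base_charges[[label]]
        q <- if (is.null(response)) q0 else q0 + drop(response %*% potential$potential)
        qm_density(nuc_pos, nuclear_charges, dens_pos, q,
                   label = label, density_atoms = density_atoms)
      },
      internal_energy = function(potential, label) {
        e <- unname(E0[label])
        if (!is.null(response)) {
          V <- potential$potential
          e <- e - 0.5 * drop(V %*% response %*% V)
        }
        e
      },
      relocate = function(positions) {
        positions <- matrix(as.numeric(positions), ncol = 3)
        shift <- positions[density_atoms, , drop = FALSE] -
          nuc_pos[density_atoms, , drop = FALSE]
        make(positions, dens_pos + shift)
      }))
  }
  make(nuclei_positions, density_positions)
}

nearest_atom_map <- function(points, atoms) {
  vapply(seq_len(nrow(points)), function(j) {
    which.min(colSums((t(atoms) - points[j, ])^2))
  }, integer(1))
}

#' Graph-Laplacian response matrix for the model QM
#'
#' Builds a symmetric negative-semidefinite matrix with zero row sums from a
#' chain graph over the density sites, scaled by `strength` (e^2/hartree).
#' Small strengths keep the coupled QM/MM fixed-point iteration contractive.
#'
#' @param p number of density sites.
#' @param strength positive scale of the response.
#' @return p x p matrix.
#' @export
chain_response_matrix <- function(p, strength = 0.05) {
  if (p < 2) return(matrix(0, p, p))
  L <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    L[i, i] <- L[i, i] + 1
    L[i + 1, i + 1] <- L[i + 1, i + 1] + 1
    L[i, i + 1] <- L[i, i + 1] - 1
    L[i + 1, i] <- L[i + 1, i] - 1
  }
  -strength * L
}
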