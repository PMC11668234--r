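#' Screening rules for intramolecular interactions
#'
#' Per-pair scale factors that remove or attenuate short-range intramolecular
#' interactions in an induced-point-dipole force field.  Three independent sets
#' exist: `m` scales the permanent-multipole self-energy, `d` scales the
#' "direct" field that polarizes the environment, and `p` scales the
#' "polarization" field entering the polarization energy and the dipole-dipole
#' coupling.  Each set holds four factors for bonded neighbor orders 1-2, 1-3,
#' 1-4 and 1-5 (graph distances 1..4); pairs further apart always interact at
#' full strength.  When `group_based_p` is `TRUE` the `p` factor is decided by
#' polarization-group membership instead: 0 within a group, 1 across groups.
#'
#' Defaults follow common AMOEBA practice: `m = (0, 0, 0.4, 0.8)`,
#' `d = (0, 0, 1, 1)`, group-based `p`.
#'
#' @param m,d,p numeric length-4 vectors in `[0, 1]` (orders 1-2, 1-3, 1-4, 1-5).
#' @param group_based_p logical; decide `p` by polarization group membership.
#' @return object of class `screening_rules`.
#' @export
screening_rules <- function(m = c(0, 0, 0.4, 0.8),
                            d = c(0, 0, 1, 1),
                            p = c(0, 0, 1, 1),
                            group_based_p = TRUE) {
  for (v in list(m = m, d = d, p = p)) {
    if (length(v) != 4L || !is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1)) {
      stop("screening factor sets must be numeric length-4 vectors in [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(m = as.numeric(m), d = as.numeric(d), p = as.numeric(p),
                 group_based_p = isTRUE(group_based_p)),
            class = "screening_rules")
}

#' Build a classical multipolar environment
#'
#' Assembles and validates the MM side of a polarizable-embedding calculation:
#' one site per classical atom carrying a fixed charge, dipole and traceless
#' quadrupole, an isotropic polarizability, a Thole damping factor and a
#' polarization-group label, plus the bond topology from which neighbor orders
#' (and hence screening factors) are derived.  Open boundary conditions only;
#' there is no minimum-image convention.
#'
#' @param positions n x 3 numeric matrix, bohr.
#' @param charges numeric length n, e.  Default 0.
#' @param dipoles n x 3 numeric matrix, e*bohr.  Default 0.
#' @param quadrupoles n x 6 matrix of packed traceless Cartesian components
#'   (xx, xy, xz, yy, yz, zz), e*bohr^2.  Default 0.  Validated traceless.
#' @param polarizabilities numeric length n, bohr^3, each >= 0.  Sites with 0
#'   are excluded from the polarization unknowns.  Default 0.
#' @param thole numeric length n, dimensionless damping width; 0 disables
#'   damping for pairs involving the site.  Default 0.39.
#' @param groups integer length n of polarization-group labels; default the
#'   connected components of the bond graph.
#' @param bonds m x 2 integer matrix of 1-based site indices (may have 0 rows).
#' @param rules a [screening_rules()] object.
#' @param elements optional character length n (element symbols, for IO).
#' @return object of class `mm_system` with a precomputed neighbor-order table.
#' @export
mm_system <- function(positions,
                      charges = NULL,
                      dipoles = NULL,
                      quadrupoles = NULL,
                      polarizabilities = NULL,
                      thole = NULL,
                      groups = NULL,
                      bonds = NULL,
                      rules = screening_rules(),
                      elements = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !is.numeric(positions) || anyNA(positions)) {
    stop("positions must be a numeric n x 3 matrix", call. = FALSE)
  }
  n <- nrow(positions)
  if (n < 1L) stop("at least one MM site is required", call. = FALSE)

  charges <- if (is.null(charges)) numeric(n) else as.numeric(charges)
  if (length(charges) != n) stop("charges must have one entry per site", call. = FALSE)
  dipoles <- if (is.null(dipoles)) matrix(0, n, 3) else as.matrix(dipoles)
  if (!all(dim(dipoles) == c(n, 3L))) stop("dipoles must be n x 3", call. = FALSE)
  quadrupoles <- if (is.null(quadrupoles)) matrix(0, n, 6) else as.matrix(quadrupoles)
  if (!all(dim(quadrupoles) == c(n, 6L))) stop("quadrupoles must be n x 6 (packed)", call. = FALSE)
  for (k in seq_len(n)) {
    tr <- quadrupoles[k, 1] + quadrupoles[k, 4] + quadrupoles[k, 6]
    if (abs(tr) > 1e-10) {
      stop("quadrupole of site ", k, " is not traceless (|trace| = ",
           format(abs(tr)), "); use traceless_quadrupole()", call. = FALSE)
    }
  }
  polarizabilities <- if (is.null(polarizabilities)) numeric(n) else as.numeric(polarizabilities)
  if (length(polarizabilities) != n || any(polarizabilities < 0)) {
    stop("polarizabilities must be length n and >= 0", call. = FALSE)
  }
  thole <- if (is.null(thole)) rep(0.39, n) else as.numeric(thole)
  if (length(thole) != n || any(thole < 0)) {
    stop("thole factors must be length n and >= 0", call. = FALSE)
  }

  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(0), 0, 2)
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
  }
  if (nrow(bonds) > 0L) {
    if (any(bonds < 1L) || any(bonds > n)) {
      stop("bond references a missing site (indices are 1-based)", call. = FALSE)
    }
    if (any(bonds[, 1] == bonds[, 2])) stop("bond graph has a self-loop", call. = FALSE)
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bond in topology", call. = FALSE)
  }
  if (!inherits(rules, "screening_rules")) {
    stop("rules must be a screening_rules object", call. = FALSE)
  }

  orders <- neighbor_order_table(n, bonds)
  if (is.null(groups)) {
    groups <- bond_components(n, bonds)
  } else {
    groups <- as.integer(groups)
    if (length(groups) != n) stop("groups must have one label per site", call. = FALSE)
  }
  if (!is.null(elements) && length(elements) != n) {
    stop("elements must have one symbol per site", call. = FALSE)
  }

  structure(list(positions = positions,
                 charges = charges,
                 dipoles = dipoles,
                 quadrupoles = quadrupoles,
                 polarizabilities = polarizabilities,
                 thole = thole,
                 groups = groups,
                 bonds = bonds,
                 rules = rules,
                 orders = orders,
                 elements = elements),
            class = "mm_system")
}

#' @export
print.mm_system <- function(x, ...) {
  n <- nrow(x$positions)
  npol <- sum(x$polarizabilities > 0)
  cat("mm_system:", n, "sites,", nrow(x$bonds), "bonds,",
      npol, "polarizable,", length(unique(x$groups)), "polarization group(s)\n")
  cat("  total charge:", format(sum(x$charges)), "e;",
      "p screening:", if (x$rules$group_based_p) "group-based" else "bond-order", "\n")
  invisible(x)
}

#' @export
summary.mm_system <- function(object, ...) {
  print(object)
  cat("  multipole norms: |q| <=", format(max(abs(object$charges))),
      " |mu| <=", format(max(sqrt(rowSums(object$dipoles^2)))),
      " |Theta| <=", format(max(abs(object$quadrupoles))), "\n")
  invisible(object)
}

## Breadth-first search distances on the bond graph, capped at 4 (orders beyond
## the 1-5 neighbor class behave identically, so the cap loses nothing).
neighbor_order_table <- function(n, bonds) {
  orders <- matrix(Inf, n, n)
  diag(orders) <- 0
  if (nrow(bonds) == 0L) return(orders)
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0L && d < 4) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    orders[s, ] <- dist
  }
  orders
}

## connected components of the bond graph (default polarization groups)
bond_components <- function(n, bonds) {
  comp <- seq_len(n)
  if (nrow(bonds) > 0L) {
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(bonds))) {
        a <- bonds[i, 1]; b <- bonds[i, 2]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[comp == comp[a] | comp == comp[b]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(comp, sort(unique(comp)))
}

#' Bonded neighbor order of a site pair
#'
#' @param system an [mm_system()].
#' @param k,l 1-based site indices.
#' @return integer graph distance 1..4, or `Inf` beyond 4 bonds / disconnected.
#' @export
neighbor_order <- function(system, k, l) {
  system$orders[k, l]
}

#' Screening factor for a site pair
#'
#' Looks up the scale factor of the requested kind (`"m"` multipole
#' self-energy, `"d"` direct field, `"p"` polarization field / dipole-dipole
#' coupling) for the pair's bonded neighbor order; for `"p"` under group-based
#' rules the factor is 0 within a polarization group and 1 across groups.
#'
#' @param system an [mm_system()].
#' @param k,l distinct 1-based site indices.
#' @param kind one of `"m"`, `"d"`, `"p"`.
#' @return scalar factor in `[0, 1]`.
#' @export
screening_factor <- function(system, k, l, kind = c("m", "d", "p")) {
  kind <- match.arg(kind)
  if (k == l) stop("screening factor undefined for a site with itself", call. = FALSE)
  if (kind == "p" && system$rules$group_based_p) {
    return(if (system$groups[k] == system$groups[l]) 0 else 1)
  }
  ord <- system$orders[k, l]
  if (!is.finite(ord) || ord > 4) return(1)
  system$rules[[kind]][ord]
}

## full n x n screening matrix for one kind (diagonal zero, never used)
screening_matrix <- function(system, kind) {
  n <- nrow(system$positions)
  s <- matrix(1, n, n)
  if (kind == "p" && system$rules$group_based_p) {
    same <- outer(system$groups, system$groups, "==")
    s[same] <- 0
  } else {
    fac <- system$rules[[kind]]
    for (ord in 1:4) s[system$orders == ord] <- fac[ord]
  }
  diag(s) <- 0
  s
}

#' Indices of polarizable sites
#' @param system an [mm_system()].
#' @return integer vector of sites with polarizability > 0.
#' @export
polarizable_sites <- function(system) {
  which(system$polarizabilities > 0)
}

#' Quantum-region charge distribution
#'
#' A discretized stand-in for a QM one-particle density: point nuclei plus
#' weighted density charges (negative for electrons) placed at density sites.
#' One object per electronic state (or per state average).  The total charge
#' must equal the declared QM charge.
#'
#' @param nuclei_positions m x 3 matrix, bohr.
#' @param nuclear_charges numeric length m, e.
#' @param density_positions p x 3 matrix, bohr (may be 0-row).
#' @param density_charges numeric length p, e (electrons negative).
#' @param charge declared total QM charge, e.  Default: the actual sum.
#' @param label state identifier, e.g. `"SA"`, `"S0"`, `"S1"`.
#' @param density_atoms optional integer length p mapping each density site to
#'   the nucleus it rides with under geometry changes (needed for gradients).
#' @return object of class `qm_density`.
#' @export
qm_density <- function(nuclei_positions, nuclear_charges,
                       density_positions = matrix(0, 0, 3),
                       density_charges = numeric(0),
                       charge = NULL, label = "SA",
                       density_atoms = NULL) {
  nuclei_positions <- matrix(as.numeric(nuclei_positions), ncol = 3)
  density_positions <- matrix(as.numeric(density_positions), ncol = 3)
  nuclear_charges <- as.numeric(nuclear_charges)
  density_charges <- as.numeric(density_charges)
  if (nrow(nuclei_positions) != length(nuclear_charges)) {
    stop("one nuclear charge per nucleus required", call. = FALSE)
  }
  if (nrow(density_positions) != length(density_charges)) {
    stop("one weight per density site required", call. = FALSE)
  }
  tot <- sum(nuclear_charges) + sum(density_charges)
  if (is.null(charge)) charge <- tot
  if (abs(tot - charge) > 1e-10) {
    stop("total charge ", format(tot), " differs from declared QM charge ",
         format(charge), call. = FALSE)
  }
  if (!is.null(density_atoms)) {
    density_atoms <- as.integer(density_atoms)
    if (length(density_atoms) != length(density_charges) ||
        any(density_atoms < 1L) || any(density_atoms > nrow(nuclei_positions))) {
      stop("density_atoms must map each density site to an existing nucleus",
           call. = FALSE)
    }
  }
  structure(list(nuclei_positions = nuclei_positions,
                 nuclear_charges = nuclear_charges,
                 density_positions = density_positions,
                 density_charges = density_charges,
                 charge = charge, label = label,
                 density_atoms = density_atoms),
            class = "qm_density")
}

#' @export
print.qm_density <- function(x, ...) {
  cat("qm_density [", x$label, "]: ", length(x$nuclear_charges), " nuclei, ",
      length(x$density_charges), " density sites, total charge ",
      format(x$charge), " e\n", sep = "")
  invisible(x)
}

## all QM charge carriers as flat points/charges (+ host atom of each carrier)
qm_point_charges <- function(density) {
  pts <- rbind(density$nuclei_positions, density$density_positions)
  chg <- c(density$nuclear_charges, density$density_charges)
  atoms <- c(seq_along(density$nuclear_charges),
             if (length(density$density_charges)) {
               if (is.null(density$density_atoms)) rep(NA_integer_, length(density$density_charges))
               else density$density_atoms
             })
  list(points = pts, charges = chg, atoms = atoms)
}
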