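#' File formats
#'
#' Geometries travel as standard XYZ (angstrom on disk, bohr in memory);
#' parameters/topology and the QM-region specification are versioned JSON
#' documents.  Readers validate and reject rather than silently coerce.
#'
#' @name io
#' @keywords internal
NULL

PARAMS_SCHEMA_VERSION <- 1L

#' Read a standard XYZ geometry file
#'
#' @param path file path.
#' @return list with `elements` (character), `coordinates` (n x 3, bohr) and
#'   `comment`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error at line 1: empty file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line 1: invalid atom count", call. = FALSE)
  }
  if (length(lines) < n + 2L) {
    stop("XYZ parse error: expected ", n, " atoms, file has ",
         length(lines) - 2L, " atom line(s)", call. = FALSE)
  }
  elements <- character(n)
  coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop("XYZ parse error at line ", ln, ": need element + 3 coordinates",
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate",
           call. = FALSE)
    }
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  list(elements = elements, coordinates = ang_to_bohr(coords),
       comment = lines[2])
}

#' Write a standard XYZ geometry file
#'
#' @param elements character vector of element symbols.
#' @param coordinates n x 3 matrix, bohr (written in angstrom).
#' @param path output path.
#' @param comment comment line.
#' @param append append as an extra frame (multi-frame XYZ).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(elements, coordinates, path, comment = "", append = FALSE) {
  coords <- bohr_to_ang(matrix(as.numeric(coordinates), ncol = 3))
  lines <- c(as.character(length(elements)), comment,
             sprintf("%-3s %18.12f %18.12f %18.12f",
                     elements, coords[, 1], coords[, 2], coords[, 3]))
  if (append) {
    cat(lines, file = path, sep = "\n", append = TRUE)
    cat("\n", file = path, append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an MM parameter/topology JSON file
#'
#' Expected document: `schema_version`, `sites` (list of objects with
#' `charge`, `dipole` (3), `quadrupole` (6, packed traceless, e*bohr^2),
#' `polarizability`, `thole`, `group`), `bonds` (pairs of 1-based indices)
#' and `screening` (`m`, `d`, `p`, `group_based_p`).  Unknown keys are
#' rejected.  Positions come from the companion XYZ file; combine both with
#' [mm_system()] via the returned pieces.
#'
#' @param path file path.
#' @return list with `sites` (data pieces), `bonds`, `rules`.
#' @export
read_params <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  allowed <- c("schema_version", "sites", "bonds", "screening")
  extra <- setdiff(names(doc), allowed)
  if (length(extra)) {
    stop("parameter file /", extra[1], ": unknown key", call. = FALSE)
  }
  if (is.null(doc$schema_version) || doc$schema_version != PARAMS_SCHEMA_VERSION) {
    stop("parameter file /schema_version: expected ", PARAMS_SCHEMA_VERSION,
         call. = FALSE)
  }
  if (is.null(doc$sites) || length(doc$sites) == 0L) {
    stop("parameter file /sites: at least one site required", call. = FALSE)
  }
  n <- length(doc$sites)
  site_allowed <- c("charge", "dipole", "quadrupole", "polarizability",
                    "thole", "group")
  charges <- numeric(n); pols <- numeric(n); thole <- rep(0.39, n)
  groups <- rep(NA_integer_, n)
  dipoles <- matrix(0, n, 3); quads <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    s <- doc$sites[[i]]
    bad <- setdiff(names(s), site_allowed)
    if (length(bad)) {
      stop("parameter file /sites/", i, "/", bad[1], ": unknown key",
           call. = FALSE)
    }
    if (!is.null(s$charge)) charges[i] <- as.numeric(s$charge)
    if (!is.null(s$dipole)) {
      if (length(s$dipole) != 3L) {
        stop("parameter file /sites/", i, "/dipole: need 3 components",
             call. = FALSE)
      }
      dipoles[i, ] <- as.numeric(unlist(s$dipole))
    }
    if (!is.null(s$quadrupole)) {
      if (length(s$quadrupole) != 6L) {
        stop("parameter file /sites/", i,
             "/quadrupole: need 6 packed components", call. = FALSE)
      }
      quads[i, ] <- as.numeric(unlist(s$quadrupole))
    }
    if (!is.null(s$polarizability)) {
      pols[i] <- as.numeric(s$polarizability)
      if (is.na(pols[i]) || pols[i] < 0) {
        stop("parameter file /sites/", i,
             "/polarizability: must be >= 0", call. = FALSE)
      }
    }
    if (!is.null(s$thole)) thole[i] <- as.numeric(s$thole)
    if (!is.null(s$group)) groups[i] <- as.integer(s$group)
  }
  bonds <- if (is.null(doc$bonds) || length(doc$bonds) == 0L) {
    matrix(integer(0), 0, 2)
  } else {
    do.call(rbind, lapply(doc$bonds, function(b) {
      if (length(b) != 2L) stop("parameter file /bonds: pairs required", call. = FALSE)
      as.integer(unlist(b))
    }))
  }
  rules <- if (is.null(doc$screening)) {
    screening_rules()
  } else {
    sc <- doc$screening
    screening_rules(m = as.numeric(unlist(sc$m %||% c(0, 0, 0.4, 0.8))),
                    d = as.numeric(unlist(sc$d %||% c(0, 0, 1, 1))),
                    p = as.numeric(unlist(sc$p %||% c(0, 0, 1, 1))),
                    group_based_p = sc$group_based_p %||% TRUE)
  }
  list(sites = list(charges = charges, dipoles = dipoles, quadrupoles = quads,
                    polarizabilities = pols, thole = thole,
                    groups = if (all(is.na(groups))) NULL else groups),
       bonds = bonds, rules = rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an MM parameter/topology JSON file
#'
#' @param system an [mm_system()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(system, path) {
  n <- nrow(system$positions)
  sites <- lapply(seq_len(n), function(i) {
    list(charge = system$charges[i],
         dipole = system$dipoles[i, ],
         quadrupole = system$quadrupoles[i, ],
         polarizability = system$polarizabilities[i],
         thole = system$thole[i],
         group = system$groups[i])
  })
  doc <- list(schema_version = PARAMS_SCHEMA_VERSION,
              sites = sites,
              bonds = if (nrow(system$bonds)) {
                lapply(seq_len(nrow(system$bonds)), function(i) system$bonds[i, ])
              } else list(),
              screening = list(m = system$rules$m, d = system$rules$d,
                               p = system$rules$p,
                               group_based_p = system$rules$group_based_p))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Combine a geometry and a parameter set into an mm_system
#'
#' @param xyz_path XYZ geometry (angstrom).
#' @param params_path JSON parameters.
#' @return an [mm_system()].
#' @export
load_mm_system <- function(xyz_path, params_path) {
  geo <- read_xyz(xyz_path)
  par <- read_params(params_path)
  if (length(geo$elements) != length(par$sites$charges)) {
    stop("geometry has ", length(geo$elements), " atoms but parameter file has ",
         length(par$sites$charges), " sites", call. = FALSE)
  }
  mm_system(geo$coordinates,
            charges = par$sites$charges, dipoles = par$sites$dipoles,
            quadrupoles = par$sites$quadrupoles,
            polarizabilities = par$sites$polarizabilities,
            thole = par$sites$thole, groups = par$sites$groups,
            bonds = par$bonds, rules = par$rules, elements = geo$elements)
}

#' Read a QM-region specification (JSON)
#'
#' Document: `charge`, `nuclei` (objects with `Z`, `position` in angstrom),
#' `states` (objects with `label`, `energy` (hartree, optional) and
#' `density_sites`: `position` (angstrom), `charge`, `atom` 1-based), and
#' optional `response` (row-major response matrix enabling the built-in
#' linear-response model QM).
#'
#' @param path file path.
#' @return a `density_provider` (fixed-density, or model QM when a response
#'   matrix is present).
#' @export
read_qm_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$nuclei) || length(doc$nuclei) == 0L) {
    stop("QM spec /nuclei: at least one nucleus required", call. = FALSE)
  }
  Z <- vapply(doc$nuclei, function(x) as.numeric(x$Z), numeric(1))
  nuc <- do.call(rbind, lapply(doc$nuclei, function(x) as.numeric(unlist(x$position))))
  nuc <- ang_to_bohr(nuc)
  if (is.null(doc$states) || length(doc$states) == 0L) {
    stop("QM spec /states: at least one state required", call. = FALSE)
  }
  labels <- vapply(doc$states, function(s) as.character(s$label), character(1))
  parse_state <- function(s) {
    ds <- s$density_sites %||% list()
    pos <- if (length(ds)) {
      ang_to_bohr(do.call(rbind, lapply(ds, function(x) as.numeric(unlist(x$position)))))
    } else matrix(0, 0, 3)
    list(positions = pos,
         charges = vapply(ds, function(x) as.numeric(x$charge), numeric(1)),
         atoms = vapply(ds, function(x) as.integer(x$atom %||% NA_integer_), integer(1)),
         energy = as.numeric(s$energy %||% 0))
  }
  states <- lapply(doc$states, parse_state)
  names(states) <- labels
  energies <- stats::setNames(vapply(states, `[[`, numeric(1), "energy"), labels)
  if (!is.null(doc$response)) {
    K <- do.call(rbind, lapply(doc$response, function(r) as.numeric(unlist(r))))
    base <- lapply(states, `[[`, "charges")
    model_qm(nuc, Z, states[[1]]$positions, base, response = K,
             density_atoms = states[[1]]$atoms, E0 = energies, labels = labels)
  } else {
    dens <- lapply(labels, function(lb) {
      st <- states[[lb]]
      qm_density(nuc, Z, st$positions, st$charges, label = lb,
                 density_atoms = if (anyNA(st$atoms)) NULL else st$atoms)
    })
    fixed_density_provider(dens, energies)
  }
}
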