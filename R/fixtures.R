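#' Deterministic fixture generation
#'
#' Seeded generators for the desk-scale systems used throughout the test
#' suite and the worked examples: a polarizable dimer scan, random multipolar
#' clusters, water-like clusters with AMOEBA-magnitude parameters, and a
#' coupled model-QM case with two state densities and their average.  All
#' geometries respect a minimum inter-site separation of 1.5 bohr.
#'
#' @name fixtures
#' @keywords internal
NULL

## rejection-sampled points with minimum pairwise separation (bohr)
packed_points <- function(n, min_sep = 1.5, box = NULL, max_tries = 20000L) {
  if (is.null(box)) box <- max(4, 2.2 * n^(1 / 3) * min_sep)
  pts <- matrix(0, 0, 3)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("unsatisfiable packing: ", n, " points with separation ", min_sep,
           " in box ", box, call. = FALSE)
    }
    cand <- stats::runif(3, 0, box)
    if (nrow(pts) == 0L || min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep) {
      pts <- rbind(pts, cand)
    }
  }
  unname(pts)
}

## small random traceless quadrupole (packed)
random_quadrupole <- function(scale = 0.1) {
  m <- matrix(stats::rnorm(9, sd = scale), 3, 3)
  traceless_quadrupole((m + t(m)) / 2)
}

#' Random multipolar cluster
#'
#' `n` sites with random charges (net-zero-ish), dipoles, traceless
#' quadrupoles and polarizabilities in `[0.3, 1.5]` bohr^3; a near-neighbor
#' chain of bonds exercises the screening table.
#'
#' @param n number of sites.
#' @param seed RNG seed.
#' @param charged include monopoles (default `TRUE`).
#' @param polarizable_fraction fraction of sites with nonzero polarizability.
#' @return an [mm_system()].
#' @export
random_cluster <- function(n, seed = 1L, charged = TRUE,
                           polarizable_fraction = 1) {
  set.seed(seed)
  pos <- packed_points(n, 1.5)
  q <- if (charged) stats::rnorm(n, sd = 0.3) else numeric(n)
  if (charged) q <- q - mean(q) # keep the cluster near-neutral
  mu <- matrix(stats::rnorm(3 * n, sd = 0.2), n, 3)
  quad <- t(vapply(seq_len(n), function(i) random_quadrupole(0.08), numeric(6)))
  alpha <- stats::runif(n, 0.3, 1.5)
  if (polarizable_fraction < 1) {
    off <- sample(n, round((1 - polarizable_fraction) * n))
    alpha[off] <- 0
  }
  ## short bonded fragments (three sites each): several polarization groups,
  ## so both intra-group screening and inter-group dipole coupling occur
  keep <- which(seq_len(max(n - 1, 0)) %% 3 != 0)
  bonds <- if (n >= 2 && length(keep)) cbind(keep, keep + 1) else NULL
  mm_system(pos, charges = q, dipoles = mu, quadrupoles = quad,
            polarizabilities = alpha, thole = rep(0.39, n), bonds = bonds,
            elements = rep("X", n))
}

#' Water-like cluster with AMOEBA-magnitude parameters
#'
#' `n` rigid three-site molecules (O, H, H; r(OH) = 0.9572 angstrom, angle
#' 104.52 degrees) with charges (-0.42, +0.21, +0.21) e, a small fixed dipole
#' on the oxygen, AMOEBA-magnitude polarizabilities (O 5.65, H 3.35 bohr^3)
#' and Thole factor 0.39.  Molecules are packed with at least 1.5 bohr
#' between any two sites; each molecule is one polarization group.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @return an [mm_system()].
#' @export
water_cluster <- function(n, seed = 1L) {
  set.seed(seed)
  roh <- ang_to_bohr(0.9572)
  ang <- 104.52 * pi / 180
  template <- rbind(c(0, 0, 0),
                    c(roh, 0, 0),
                    c(roh * cos(ang), roh * sin(ang), 0))
  centers <- packed_points(n, 5.5, box = max(8, 4.5 * n^(1 / 3)))
  pos <- NULL
  for (i in seq_len(n)) {
    ## random proper rotation from QR of a gaussian matrix
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Rm <- qr.Q(qr_)
    if (det(Rm) < 0) Rm[, 1] <- -Rm[, 1]
    pos <- rbind(pos, sweep(template %*% t(Rm), 2, centers[i, ], "+"))
  }
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (min(d) < 1.5) {
    stop("unsatisfiable packing of water-like molecules", call. = FALSE)
  }
  idx <- function(i) 3 * (i - 1)
  bonds <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(c(idx(i) + 1, idx(i) + 2), c(idx(i) + 1, idx(i) + 3))
  }))
  n3 <- 3 * n
  charges <- rep(c(-0.42, 0.21, 0.21), n)
  dipoles <- matrix(0, n3, 3)
  dipoles[seq(1, n3, by = 3), 3] <- 0.14 # small fixed dipole on each oxygen
  mm_system(pos, charges = charges, dipoles = dipoles,
            polarizabilities = rep(c(5.65, 3.35, 3.35), n),
            thole = rep(0.39, n3), bonds = bonds,
            elements = rep(c("O", "H", "H"), n))
}

#' Coupled model-QM test case
#'
#' A water-like MM cluster plus a diatomic model QM region: two unit nuclei,
#' four density sites along the bond axis carrying a net -2 e electron cloud,
#' and a chain-Laplacian response matrix.  Two state densities (ground-like
#' and charge-transfer-like) are generated together with their equal-weight
#' average, for exercising the state-specific correction.
#'
#' @param n_mm number of MM molecules.
#' @param seed RNG seed.
#' @param response_strength scale of the model response matrix, e^2/hartree.
#' @return list with `system`, `provider` (model QM with states S0, S1, SA),
#'   `densities` (fixed S0/S1/SA at the unperturbed charges).
#' @export
model_qm_case <- function(n_mm = 2L, seed = 1L, response_strength = 0.05) {
  system <- water_cluster(n_mm, seed = seed)
  ## place the QM diatomic outside the MM cluster
  lo <- apply(system$positions, 2, min)
  nuc <- rbind(lo - c(4, 4, 4), lo - c(4, 4, 4) + c(2.0, 0, 0))
  Z <- c(1, 1)
  ds <- rbind(nuc[1, ], nuc[1, ] + c(0.7, 0, 0),
              nuc[2, ] - c(0.7, 0, 0), nuc[2, ])
  atoms <- c(1L, 1L, 2L, 2L)
  q0_s0 <- c(-0.7, -0.3, -0.3, -0.7)
  q0_s1 <- c(-0.5, -0.3, -0.3, -0.9) # charge-transfer-like excited state
  q0_sa <- (q0_s0 + q0_s1) / 2
  K <- chain_response_matrix(4, response_strength)
  provider <- model_qm(nuc, Z, ds,
                       base_charges = list(S0 = q0_s0, S1 = q0_s1, SA = q0_sa),
                       response = K, density_atoms = atoms,
                       E0 = c(S0 = -1.1, S1 = -0.95, SA = -1.025))
  densities <- list(
    S0 = qm_density(nuc, Z, ds, q0_s0, label = "S0", density_atoms = atoms),
    S1 = qm_density(nuc, Z, ds, q0_s1, label = "S1", density_atoms = atoms),
    SA = qm_density(nuc, Z, ds, q0_sa, label = "SA", density_atoms = atoms))
  list(system = system, provider = provider, densities = densities)
}

#' Write fixture files to disk
#'
#' Generates one of the canonical fixtures and writes its geometry (XYZ),
#' parameters (JSON) and, for `model_qm_case`, the QM specification with the
#' two state densities and their equal-weight average.  Byte-identical output
#' for identical `(kind, n, seed)`.
#'
#' @param kind one of `"dimer_scan"`, `"random_cluster"`,
#'   `"water_like_cluster"`, `"model_qm_case"`.
#' @param n size parameter (sites, molecules, or scan frames).
#' @param seed RNG seed, recorded in every file header.
#' @param dir output directory (created if missing).
#' @return named character vector of the files written (invisibly the
#'   generated objects as attribute `objects`).
#' @export
generate_fixture <- function(kind = c("dimer_scan", "random_cluster",
                                      "water_like_cluster", "model_qm_case"),
                             n = 8L, seed = 1L, dir = ".") {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- paste0(kind, " n=", n, " seed=", seed)
  files <- character(0)
  objects <- NULL
  if (kind == "dimer_scan") {
    ## two polarizable charged sites scanned over r in [0.5, 10] bohr
    rs <- seq(0.5, 10, length.out = max(n, 2))
    path <- file.path(dir, "dimer_scan.xyz")
    if (file.exists(path)) file.remove(path)
    for (r in rs) {
      write_xyz(c("X", "X"), rbind(c(0, 0, 0), c(r, 0, 0)), path,
                comment = paste(stamp, "r_bohr=", format(r)), append = TRUE)
    }
    sys <- mm_system(rbind(c(0, 0, 0), c(rs[1], 0, 0)), charges = c(1, -1),
                     polarizabilities = c(1, 1), elements = c("X", "X"))
    pfile <- file.path(dir, "dimer_scan_params.json")
    write_params(sys, pfile)
    files <- c(geometry = path, params = pfile)
    objects <- list(system = sys, distances = rs)
  } else if (kind %in% c("random_cluster", "water_like_cluster")) {
    sys <- if (kind == "random_cluster") random_cluster(n, seed) else water_cluster(n, seed)
    gfile <- file.path(dir, paste0(kind, ".xyz"))
    pfile <- file.path(dir, paste0(kind, "_params.json"))
    write_xyz(sys$elements, sys$positions, gfile, comment = stamp)
    write_params(sys, pfile)
    files <- c(geometry = gfile, params = pfile)
    objects <- list(system = sys)
  } else {
    case <- model_qm_case(n_mm = n, seed = seed)
    sys <- case$system
    gfile <- file.path(dir, "model_qm_case.xyz")
    pfile <- file.path(dir, "model_qm_case_params.json")
    qfile <- file.path(dir, "model_qm_case_qm.json")
    write_xyz(sys$elements, sys$positions, gfile, comment = stamp)
    write_params(sys, pfile)
    pr <- case$provider
    state_doc <- function(lb) {
      d <- case$densities[[lb]]
      list(label = lb, energy = 0,
           density_sites = lapply(seq_along(d$density_charges), function(j) {
             list(position = bohr_to_ang(d$density_positions[j, ]),
                  charge = d$density_charges[j],
                  atom = d$density_atoms[j])
           }))
    }
    doc <- list(charge = 0,
                nuclei = lapply(seq_along(pr$nuclear_charges), function(i) {
                  list(Z = pr$nuclear_charges[i],
                       position = bohr_to_ang(pr$nuclei_positions[i, ]))
                }),
                states = lapply(c("S0", "S1", "SA"), state_doc),
                response = lapply(seq_len(nrow(pr$response)), function(i) pr$response[i, ]))
    jsonlite::write_json(doc, qfile, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(geometry = gfile, params = pfile, qm = qfile)
    objects <- case
  }
  attr(files, "objects") <- objects
  invisible(files)
}
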