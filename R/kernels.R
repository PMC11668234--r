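#' Interaction tensors for multipole electrostatics
#'
#' The generalized Coulomb kernel is the tensor of mixed derivatives of
#' `1/|r_k - r_l|`, taken `L` times with respect to `r_k` and `L'` times with
#' respect to `r_l`.  Writing `R = r_k - r_l`, each derivative with respect to
#' `r_l` contributes a sign flip relative to a derivative with respect to `R`,
#' so the kernel equals `(-1)^L' * D^(L+L')(R)` where `D^n` is the n-th
#' gradient of `1/r`.  The same structure carries the Thole-damped variant:
#' every radial power `r^-(2m+1)` is scaled by a damping function
#' `lambda_(2m+1)(u)` that tends to 1 at long range and regularizes the tensor
#' at short range.
#'
#' @name kernels
#' @keywords internal
NULL

## ---- Thole damping functions -------------------------------------------
## Exponential Thole smearing.  t = a*u^3 with u = r/(alpha_k*alpha_l)^(1/6).
## lambda3 = 1 - exp(-t) is the classic field damping; lambda5/7/9 follow from
## the recursion lambda_{n+2} = lambda_n - (r/n) dlambda_n/dr.  lambda1 (the
## scalar damped potential weight) is obtained in closed form from
## lambda1/r = Int_r^Inf lambda3(s)/s^2 ds, which evaluates to
## lambda1 = 1 - exp(-t) + t^(1/3) Gamma(2/3, t)  (upper incomplete gamma).
thole_lambdas <- function(t) {
  et <- exp(-t)
  l3 <- -expm1(-t)
  if (t < 1e-4) {
    ## leading series; note l7 and l9 are (correctly) negative at small t
    l5 <- t^2 / 2 - t^3 / 3 + t^4 / 8
    l7 <- -t^2 / 10 + t^3 * (4 / 15) - t^4 * (7 / 40)
    l9 <- -t^2 / 70 - t^3 * (8 / 105) + t^4 / 8
  } else {
    l5 <- 1 - (1 + t) * et
    l7 <- 1 - (1 + t + 0.6 * t^2) * et
    l9 <- 1 - (1 + t + (18 / 35) * t^2 + (9 / 35) * t^3) * et
  }
  ## upper incomplete gamma Gamma(2/3, t) via pgamma
  g23 <- gamma(2 / 3) * stats::pgamma(t, 2 / 3, lower.tail = FALSE)
  l1 <- l3 + t^(1 / 3) * g23
  c(l1 = l1, l3 = l3, l5 = l5, l7 = l7, l9 = l9, l11 = 1)
}

## damping parameters for a site pair; returns NULL when damping is off
pair_damping <- function(alpha_k, alpha_l, thole_k, thole_l) {
  a <- min(thole_k, thole_l)
  if (a <= 0 || alpha_k <= 0 || alpha_l <= 0) return(NULL)
  list(a = a, w = (alpha_k * alpha_l)^(1 / 6))
}

## lambda vector (l1,l3,l5,l7,l9,l11) for distance r under `damp`; all ones
## when damp is NULL
lambda_vector <- function(r, damp) {
  if (is.null(damp)) return(rep(1, 6))
  u <- r / damp$w
  thole_lambdas(damp$a * u^3)
}

## ---- gradient tensors of 1/r -------------------------------------------
## D^n(R): rank-n symmetric tensors; lam = c(l1,l3,l5,l7,l9,l11) scales the
## radial powers 1/r, 1/r^3, ..., 1/r^11 term by term.
d_tensors <- function(R, nmax, lam = rep(1, 6)) {
  r2 <- sum(R * R)
  r <- sqrt(r2)
  if (r == 0) stop("coincident points in interaction tensor", call. = FALSE)
  out <- vector("list", nmax + 1L)
  out[[1]] <- lam[1] / r
  if (nmax >= 1) out[[2]] <- -lam[2] * R / r^3
  if (nmax >= 2) {
    out[[3]] <- 3 * lam[3] * tcrossprod(R) / r^5 - lam[2] * diag(3) / r^3
  }
  if (nmax >= 3) {
    D3 <- array(0, c(3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
      D3[i, j, k] <- -15 * lam[4] * R[i] * R[j] * R[k] / r^7 +
        3 * lam[3] * ((i == j) * R[k] + (i == k) * R[j] + (j == k) * R[i]) / r^5
    }
    out[[4]] <- D3
  }
  if (nmax >= 4) {
    D4 <- array(0, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      sRR <- (i == j) * R[k] * R[l] + (i == k) * R[j] * R[l] +
        (i == l) * R[j] * R[k] + (j == k) * R[i] * R[l] +
        (j == l) * R[i] * R[k] + (k == l) * R[i] * R[j]
      sdd <- (i == j) * (k == l) + (i == k) * (j == l) + (i == l) * (j == k)
      D4[i, j, k, l] <- 105 * lam[5] * R[i] * R[j] * R[k] * R[l] / r^9 -
        15 * lam[4] * sRR / r^7 + 3 * lam[3] * sdd / r^5
    }
    out[[5]] <- D4
  }
  if (nmax >= 5) {
    D5 <- array(0, c(3, 3, 3, 3, 3))
    idx <- as.matrix(expand.grid(1:3, 1:3, 1:3, 1:3, 1:3))
    for (row in seq_len(nrow(idx))) {
      ii <- idx[row, ]
      sRRR <- 0 # sum over 10 ways to pick one delta pair
      sddR <- 0 # sum over 15 ways to pick two delta pairs
      pairs <- utils::combn(5, 2)
      for (cpair in seq_len(ncol(pairs))) {
        p <- pairs[, cpair]
        rest <- setdiff(1:5, p)
        if (ii[p[1]] == ii[p[2]]) {
          sRRR <- sRRR + prod(R[ii[rest]])
          rp <- utils::combn(rest, 2)
          for (c2 in seq_len(ncol(rp))) {
            q <- rp[, c2]
            if (q[1] < p[1]) next # count each {pair,pair} partition once
            last <- setdiff(rest, q)
            if (ii[q[1]] == ii[q[2]]) sddR <- sddR + R[ii[last]]
          }
        }
      }
      D5[matrix(ii, 1)] <- -945 * lam[6] * prod(R[ii]) / r^11 +
        105 * lam[5] * sRRR / r^9 - 15 * lam[4] * sddR / r^7
    }
    out[[6]] <- D5
  }
  out
}

#' Generalized Coulomb interaction tensor
#'
#' Returns the rank `L + L'` Cartesian tensor of derivatives of
#' `1/|r_k - r_l|`: `L` derivatives with respect to `r_k` followed by `L'`
#' with respect to `r_l` (derivative order applied literally, which fixes the
#' sign convention used throughout the package).
#'
#' @param r_k,r_l numeric 3-vectors, bohr.
#' @param L,Lp multipole ranks in `{0, 1, 2}` (charge, dipole, quadrupole).
#' @return scalar (`L + L' = 0`), 3-vector, or dense array of rank `L + L'`.
#' @export
#' @examples
#' coulomb_kernel(c(0, 0, 0), c(2, 0, 0), 0, 0)  # 1/r = 0.5
coulomb_kernel <- function(r_k, r_l, L, Lp) {
  stopifnot(L %in% 0:2, Lp %in% 0:2)
  n <- L + Lp
  d <- d_tensors(as.numeric(r_k) - as.numeric(r_l), n)
  (-1)^Lp * d[[n + 1L]]
}

#' Thole-damped Coulomb interaction tensor
#'
#' Same derivative structure as [coulomb_kernel()], but built from the damped
#' scalar kernel `lambda(r)/r` (exponential Thole smearing).  The damping
#' width is set by `u = r / (alpha_k * alpha_l)^(1/6)` and the pair factor
#' `a = min(thole_k, thole_l)`; all tensor elements stay finite as `r -> 0`,
#' which is what prevents the polarization catastrophe.  A Thole factor of 0
#' (or a non-polarizable partner) switches damping off exactly, recovering the
#' undamped kernel.
#'
#' @inheritParams coulomb_kernel
#' @param alpha_k,alpha_l site polarizabilities, bohr^3.
#' @param thole pair damping factor `a` (use the smaller of the two site
#'   factors); 0 disables damping.
#' @return tensor of rank `L + L'`.
#' @export
damped_kernel <- function(r_k, r_l, L, Lp, alpha_k, alpha_l, thole = 0.39) {
  stopifnot(L %in% 0:2, Lp %in% 0:2)
  n <- L + Lp
  R <- as.numeric(r_k) - as.numeric(r_l)
  damp <- pair_damping(alpha_k, alpha_l, thole, thole)
  r <- sqrt(sum(R * R))
  if (is.null(damp)) {
    if (r == 0) stop("coincident points in undamped interaction tensor", call. = FALSE)
    return((-1)^Lp * d_tensors(R, n)[[n + 1L]])
  }
  if (r == 0) return((-1)^Lp * damped_origin_tensor(n, damp))
  lam <- lambda_vector(r, damp)
  (-1)^Lp * d_tensors(R, n, lam)[[n + 1L]]
}

## r -> 0 limits of the damped D^n tensors.  Odd ranks vanish by symmetry;
## D0 -> a^(1/3) Gamma(2/3)/w, D2 -> -(a/w^3) I (from lambda3/r^3 -> a/w^3);
## D4: lambda5/r^5 -> 0 like r, lambda7,9 terms vanish faster -> 0.
damped_origin_tensor <- function(n, damp) {
  switch(as.character(n),
         "0" = damp$a^(1 / 3) * gamma(2 / 3) / damp$w,
         "1" = numeric(3),
         "2" = -(damp$a / damp$w^3) * diag(3),
         "3" = array(0, c(3, 3, 3)),
         "4" = array(0, c(3, 3, 3, 3)),
         stop("unsupported rank at coincident points", call. = FALSE))
}

## ---- contraction helpers ------------------------------------------------
contract_v_m3 <- function(D3, v, M) {
  ## sum_abc v_a M_bc D3[a,b,c]
  s <- 0
  for (a in 1:3) s <- s + v[a] * sum(D3[a, , ] * M)
  s
}

contract_m_m4 <- function(D4, A, B) {
  ## sum_abcd A_ab B_cd D4[a,b,c,d]
  s <- 0
  for (a in 1:3) for (b in 1:3) s <- s + A[a, b] * sum(D4[a, b, , ] * B)
  s
}

contract_m3_m <- function(D3, M) {
  ## vector over first index: sum_bc D3[i,b,c] M_bc
  vapply(1:3, function(i) sum(D3[i, , ] * M), numeric(1))
}

contract_m3_v_last <- function(D3, v) {
  ## matrix over first two indices: sum_c D3[i,j,c] v_c
  apply(D3, c(1, 2), function(x) sum(x * v))
}

contract_m4_m_last <- function(D4, M) {
  ## matrix over first two indices: sum_cd D4[i,j,c,d] M_cd
  apply(D4, c(1, 2), function(x) sum(x * M))
}
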