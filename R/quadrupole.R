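#' Enforce the traceless Cartesian quadrupole convention
#'
#' Subtracts one third of the trace from the diagonal of a symmetric 3x3
#' Cartesian quadrupole and packs the six independent components in the order
#' (xx, xy, xz, yy, yz, zz).  Quadrupoles enter every energy expression through
#' a full double contraction with the rank-2/3/4 interaction tensors, with no
#' additional 1/3 weight; the traceless form is what makes that contraction
#' independent of the (physically invisible) trace.
#'
#' @param raw symmetric 3x3 numeric matrix, e*bohr^2.
#' @param tol symmetry tolerance for validation.
#' @return packed numeric 6-vector (xx, xy, xz, yy, yz, zz), traceless.
#' @export
#' @examples
#' traceless_quadrupole(diag(c(3, 0, 0)))  # -> diag(2, -1, -1) packed
traceless_quadrupole <- function(raw, tol = 1e-8) {
  raw <- as.matrix(raw)
  if (!all(dim(raw) == c(3L, 3L)) || !is.numeric(raw)) {
    stop("quadrupole must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (max(abs(raw - t(raw))) > tol) {
    stop("quadrupole matrix is not symmetric within tolerance ", tol, call. = FALSE)
  }
  sym <- (raw + t(raw)) / 2
  tl <- sym - diag(3) * sum(diag(sym)) / 3
  quad_pack(tl)
}

## pack/unpack between the 6-component storage and the full 3x3 matrix
quad_pack <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

quad_unpack <- function(p) {
  matrix(c(p[1], p[2], p[3],
           p[2], p[4], p[5],
           p[3], p[5], p[6]), 3, 3, byrow = TRUE)
}
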