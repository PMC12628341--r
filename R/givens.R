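# Exact decomposition of a complex unitary orbital-rotation matrix into
# adjacent generalized Givens rotations plus a final phase layer.
#
# A generalized rotation r(p, theta, phi) is the identity except for the
# 2x2 block
#     [ cos(theta)              -e^{+i phi} sin(theta) ]
#     [ e^{-i phi} sin(theta)    cos(theta)            ]
# at adjacent rows/columns (p, p+1).  Applying a sequence of such rotations
# from the left reduces any unitary u to a diagonal of unit-modulus phases;
# the rotations and phases reproduce u exactly (no Trotterization).

#' Generalized Givens rotation matrix
#'
#' @param p first of the two adjacent modes (1-based; acts on p, p+1)
#' @param theta rotation angle (radians)
#' @param phi relative phase angle (radians)
#' @param M matrix dimension
#' @export
rotation_matrix <- function(p, theta, phi, M) {
  if (p < 1 || p + 1 > M) stop("rotation index out of range")
  r <- diag(M) + 0i
  ct <- cos(theta); st <- sin(theta)
  r[p, p] <- ct
  r[p + 1, p + 1] <- ct
  r[p, p + 1] <- -exp(1i * phi) * st
  r[p + 1, p] <- exp(-1i * phi) * st
  r
}

#' Number of rotations needed for an M-mode unitary
#' @param M number of modes
#' @export
rotation_count <- function(M) as.integer(M * (M - 1) / 2)

#' Decompose a complex unitary into adjacent generalized Givens rotations
#'
#' Column-major elimination of sub-diagonal entries with adjacent-row
#' rotations only; entries already below `tol` skip their rotation.  A
#' degenerate pivot (the entry above an entry to be zeroed vanishing) uses
#' the deterministic tie-break theta = pi/2, phi = 0.
#'
#' @param u unitary matrix
#' @param tol unitarity check / pruning tolerance
#' @return list with `rotations` (list of `list(p, theta, phi)` in the
#'   order they are applied to u) and `phases` (numeric vector, the residual
#'   diagonal arguments), satisfying
#'   `u = dagger(r_1) ... dagger(r_K) diag(exp(1i*phases))`.
#' @export
complex_givens_decompose <- function(u, tol = 1e-10) {
  M <- nrow(u)
  if (max(abs(u %*% Conj(t(u)) - diag(M))) > tol) {
    stop("input matrix is not unitary")
  }
  w <- u + 0i
  rotations <- list()
  if (M > 1) {
    for (cc in 1:(M - 1)) {
      for (r in M:(cc + 1)) {
        b <- w[r, cc]
        if (Mod(b) < 1e-12) next
        a <- w[r - 1, cc]
        if (Mod(a) < 1e-12) {
          theta <- pi / 2; phi <- 0
        } else {
          z <- -b / a
          theta <- atan(Mod(z))
          phi <- -Arg(z)
        }
        rot <- list(p = r - 1L, theta = theta, phi = phi)
        rotations[[length(rotations) + 1L]] <- rot
        ct <- cos(theta); st <- sin(theta); ph <- exp(1i * phi)
        rp <- w[r - 1, ]; rq <- w[r, ]
        w[r - 1, ] <- ct * rp - ph * st * rq
        w[r, ] <- Conj(ph) * st * rp + ct * rq
        w[r, cc] <- 0
      }
    }
  }
  phases <- Arg(diag(w))
  list(rotations = rotations, phases = phases)
}

#' Rebuild a unitary from its Givens decomposition
#' @param decomp output of [complex_givens_decompose()]
#' @param M matrix dimension
#' @export
givens_reconstruct <- function(decomp, M) {
  u <- diag(exp(1i * decomp$phases), M)
  for (rot in rev(decomp$rotations)) {
    u <- Conj(t(rotation_matrix(rot$p, rot$theta, rot$phi, M))) %*% u
  }
  u
}
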