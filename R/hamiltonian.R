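# Second-quantized Hamiltonian, Jordan-Wigner qubit image, sector
# diagonalization and Slater-Condon determinant energies.
#
# Spin-orbital indexing is spin-blocked: qubits 0..M-1 carry the alpha
# spatial orbitals in ascending order, qubits M..2M-1 the beta orbitals.
# Spatial-orbital indices in the R interface are 1-based.

#' Qubit index of a spin orbital
#' @param p spatial orbital (1-based)
#' @param spin "a" or "b"
#' @param M number of spatial orbitals
#' @export
spin_orbital_qubit <- function(p, spin, M) {
  stopifnot(p >= 1, p <= M)
  as.integer(p - 1L + if (spin == "b") M else 0L)
}

#' Reference determinant
#' @param occ_alpha,occ_beta 1-based occupied spatial-orbital indices
#' @param kind reference label ("RHF", "UHF" or "custom")
#' @export
reference_determinant <- function(occ_alpha, occ_beta, kind = "RHF") {
  occ_alpha <- sort(unique(as.integer(occ_alpha)))
  occ_beta <- sort(unique(as.integer(occ_beta)))
  structure(list(occ_alpha = occ_alpha, occ_beta = occ_beta, kind = kind),
            class = "ref_det")
}

#' Basis integer of a reference determinant
#' @param ref a `ref_det`
#' @param M number of spatial orbitals
#' @export
determinant_index <- function(ref, M) {
  b <- 0L
  for (p in ref$occ_alpha) b <- bitwOr(b, bitwShiftL(1L, p - 1L))
  for (p in ref$occ_beta) b <- bitwOr(b, bitwShiftL(1L, M + p - 1L))
  b
}

#' Jordan-Wigner qubit Hamiltonian from active-space integrals
#'
#' Builds H = E_core + sum h_pq a+_ps a_qs
#'          + 1/2 sum (pq|rs) a+_ps a+_rt a_st a_qs
#' (chemists' notation for the two-body tensor) and maps it to a Hermitian
#' Pauli sum over 2M qubits.
#'
#' @param ints an `asints` object
#' @param tol integral entries below `tol` in modulus are skipped
#' @return a collected `pauli_sum`
#' @export
build_qubit_hamiltonian <- function(ints, tol = 1e-13) {
  M <- ints$n_spatial
  N <- 2L * M
  words <- character(); coeffs <- complex(0)
  push <- function(ps) {
    words <<- c(words, ps$words)
    coeffs <<- c(coeffs, ps$coeffs)
  }
  push(pauli_sum(strrep("I", N), ints$core_energy + 0i, N, collect = FALSE))
  cre <- lapply(0:(N - 1), jw_creation, n_qubits = N)
  ann <- lapply(0:(N - 1), jw_annihilation, n_qubits = N)
  for (p in 1:M) for (q in 1:M) {
    hpq <- ints$one_body[p, q]
    if (abs(hpq) < tol) next
    for (off in c(0L, M)) {
      push(ps_scale(pauli_multiply(cre[[p + off]], ann[[q + off]]), hpq))
    }
  }
  for (p in 1:M) for (q in 1:M) for (r in 1:M) for (s in 1:M) {
    gpqrs <- ints$two_body[p, q, r, s]
    if (abs(gpqrs) < tol) next
    for (off1 in c(0L, M)) for (off2 in c(0L, M)) {
      op <- pauli_multiply(
        pauli_multiply(cre[[p + off1]], cre[[r + off2]]),
        pauli_multiply(ann[[s + off2]], ann[[q + off1]]))
      push(ps_scale(op, 0.5 * gpqrs))
    }
  }
  pauli_sum(words, coeffs, N)
}

#' Particle-number sector basis
#'
#' @param M number of spatial orbitals
#' @param n_alpha,n_beta per-spin occupation numbers
#' @return integer vector of basis indices (bit p = occupation of qubit p)
#' @export
sector_basis <- function(M, n_alpha, n_beta) {
  N <- 2L * M
  all_idx <- 0:(2^N - 1L)
  amask <- bitwShiftL(1L, M) - 1L
  na <- .popcount(bitwAnd(all_idx, amask))
  nb <- .popcount(bitwShiftR(all_idx, M))
  idx <- all_idx[na == n_alpha & nb == n_beta]
  if (!length(idx)) stop("empty particle-number sector")
  idx
}

#' Matrix of a Pauli sum restricted to a set of basis states
#'
#' Matrix elements connecting to states outside the set are discarded, so
#' for symmetry-preserving operators this is the exact sector block.
#'
#' @param ps a `pauli_sum`
#' @param basis integer vector of basis indices
#' @export
pauli_sector_matrix <- function(ps, basis) {
  d <- length(basis)
  m <- matrix(0i, d, d)
  lookup <- integer(2^ps$n_qubits)
  lookup[basis + 1L] <- seq_len(d)
  for (i in seq_along(ps$words)) {
    im <- pauli_word_apply(ps$words[i], basis)
    rows <- lookup[im$basis + 1L]
    keep <- rows > 0L
    m[cbind(rows[keep], seq_len(d)[keep])] <-
      m[cbind(rows[keep], seq_len(d)[keep])] + ps$coeffs[i] * im$phase[keep]
  }
  m
}

#' Exact (FCI-equivalent) ground state in a particle-number sector
#'
#' Dense diagonalization of the qubit Hamiltonian restricted to the
#' bitstrings with the requested per-spin occupations.
#'
#' @param H a Hermitian `pauli_sum` over 2M qubits
#' @param n_alpha,n_beta electron counts
#' @param n_states number of lowest eigenpairs to return
#' @return list with `energy` (lowest eigenvalue), `state` (a
#'   `sparse_state`), and `values` (the `n_states` lowest eigenvalues)
#' @export
exact_ground_state <- function(H, n_alpha, n_beta, n_states = 1L) {
  M <- H$n_qubits %/% 2L
  basis <- sector_basis(M, n_alpha, n_beta)
  hs <- pauli_sector_matrix(H, basis)
  ee <- eigen((hs + Conj(t(hs))) / 2)
  ord <- order(Re(ee$values))
  v <- ee$vectors[, ord[1]]
  v <- v / sqrt(sum(Mod(v)^2))
  list(energy = Re(ee$values[ord[1]]),
       state = sparse_state(basis, v, H$n_qubits),
       values = Re(ee$values[ord[seq_len(min(n_states, length(ord)))]]))
}

#' Slater-Condon energy of a determinant
#'
#' @param ints an `asints` object
#' @param ref a `ref_det` whose occupation counts match the integrals sector
#' @export
reference_energy <- function(ints, ref) {
  if (length(ref$occ_alpha) != ints$n_alpha ||
      length(ref$occ_beta) != ints$n_beta) {
    stop("determinant occupation does not match the integrals sector")
  }
  h <- ints$one_body; g <- ints$two_body
  oa <- ref$occ_alpha; ob <- ref$occ_beta
  e <- ints$core_energy + sum(Re(diag(h))[c(oa, ob)])
  coul <- function(i, j) g[i, i, j, j]
  exch <- function(i, j) g[i, j, j, i]
  for (i in oa) for (j in oa) e <- e + 0.5 * (coul(i, j) - exch(i, j))
  for (i in ob) for (j in ob) e <- e + 0.5 * (coul(i, j) - exch(i, j))
  for (i in oa) for (j in ob) e <- e + coul(i, j)
  e
}
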