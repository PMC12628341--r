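# Spin-adapted configuration-state-function analysis for the two-electron,
# two-spatial-orbital sector, and S^2 expectation values.

.pkg_cache <- new.env(parent = emptyenv())

#' Jordan-Wigner image of the total-spin operator S^2
#'
#' S^2 = S- S+ + Sz (Sz + 1) with S+ = sum_p a+_{p alpha} a_{p beta},
#' cached per orbital count.
#'
#' @param M number of spatial orbitals
#' @return a Hermitian `pauli_sum` over 2M qubits
#' @export
s_squared_pauli <- function(M) {
  key <- paste0("s2_", M)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  N <- 2L * M
  splus_terms <- lapply(seq_len(M) - 1L, function(p) {
    pauli_multiply(jw_creation(p, N), jw_annihilation(p + M, N))
  })
  splus <- do.call(ps_add, splus_terms)
  sminus <- ps_dagger(splus)
  sz_terms <- lapply(seq_len(M) - 1L, function(p) {
    ps_add(ps_scale(jw_number_operator(p, N), 0.5),
           ps_scale(jw_number_operator(p + M, N), -0.5))
  })
  sz <- do.call(ps_add, sz_terms)
  ident <- pauli_sum(strrep("I", N), 1 + 0i, N, collect = FALSE)
  s2 <- ps_add(pauli_multiply(sminus, splus),
               pauli_multiply(sz, ps_add(sz, ident)))
  .pkg_cache[[key]] <- ps_collect(s2)
  .pkg_cache[[key]]
}

#' Expectation of S^2 in a state
#' @param state a `sparse_state` over 2M qubits
#' @param M number of spatial orbitals
#' @export
s_squared_expectation <- function(state, M) {
  expectation(s_squared_pauli(M), state)
}

.fix_phase <- function(s) {
  i <- which(Mod(s$amp) > 1e-10)[1]
  sparse_state(s$basis, s$amp * Conj(s$amp[i]) / Mod(s$amp[i]), s$n_qubits)
}

#' Configuration-state-function basis of the (2e, 2o) singlet/triplet sector
#'
#' Four orthonormal S^2 eigenstates spanning the (1 alpha, 1 beta) sector of
#' two spatial orbitals: the closed-shell ground (gerade) singlet, the
#' doubly excited (gerade) singlet, the open-shell (ungerade) singlet, and
#' the Ms = 0 (ungerade) triplet.
#'
#' @param M number of spatial orbitals; must be 2
#' @return named list of `sparse_state` vectors with attribute `s2` (the
#'   S^2 eigenvalue of each member)
#' @export
build_csf_basis <- function(M = 2L) {
  if (M != 2L) stop("the CSF basis is constructed for the (2e, 2o) sector")
  N <- 4L
  det_idx <- function(pa, pb) {
    bitwOr(bitwShiftL(1L, pa - 1L), bitwShiftL(1L, M + pb - 1L))
  }
  hf <- basis_state(det_idx(1, 1), N)
  de <- basis_state(det_idx(2, 2), N)
  # open-shell combinations: diagonalize S^2 in the two-determinant span
  d12 <- det_idx(1, 2)
  d21 <- det_idx(2, 1)
  s2m <- pauli_sector_matrix(s_squared_pauli(M), c(d12, d21))
  ee <- eigen((s2m + Conj(t(s2m))) / 2)
  vals <- Re(ee$values)
  mk <- function(col) .fix_phase(sparse_state(c(d12, d21), ee$vectors[, col], N))
  osl <- mk(which.min(vals))   # S^2 = 0
  trip <- mk(which.max(vals))  # S^2 = 2
  out <- list(hf_singlet_g = hf, doubly_excited_singlet_g = de,
              open_shell_singlet_u = osl, triplet_ms0_u = trip)
  attr(out, "s2") <- c(hf_singlet_g = 0, doubly_excited_singlet_g = 0,
                       open_shell_singlet_u = 0, triplet_ms0_u = 2)
  out
}

#' CSF decomposition of a state
#'
#' Squared overlap weights onto a CSF basis, the residual outside the basis
#' span, and the S^2 expectation of the state.
#'
#' @param state a `sparse_state` in the sector of the basis
#' @param basis output of [build_csf_basis()]
#' @export
csf_decompose <- function(state, basis = build_csf_basis()) {
  weights <- vapply(basis, function(v) Mod(overlap(v, state))^2, numeric(1))
  nrm <- sum(Mod(state$amp)^2)
  M <- state$n_qubits %/% 2L
  list(weights = weights, residual = nrm - sum(weights),
       s_squared = s_squared_expectation(state, M))
}
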