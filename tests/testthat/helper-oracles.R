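# Independent dense oracles built directly from first principles (kron
# chains of 2x2 matrices), used to cross-check the package's Pauli and
# Jordan-Wigner machinery.

oracle_kron_chain <- function(ops) {
  m <- matrix(1 + 0i, 1, 1)
  for (o in ops) m <- o %x% m  # qubit 0 least significant
  m
}

# dense JW creation operator a+_p on n qubits
oracle_creation <- function(p, n) {
  I2 <- diag(2) + 0i
  Z2 <- diag(c(1, -1)) + 0i
  cr <- matrix(c(0, 1, 0, 0), 2, 2)  # |1><0| in (|0>, |1>) basis
  ops <- c(rep(list(Z2), p), list(cr), rep(list(I2), n - p - 1))
  oracle_kron_chain(ops)
}

oracle_annihilation <- function(p, n) Conj(t(oracle_creation(p, n)))

# dense matrix exponential via eigendecomposition (general square matrix)
oracle_expm <- function(A) {
  ee <- eigen(A)
  ee$vectors %*% diag(exp(ee$values), nrow(A)) %*% solve(ee$vectors)
}

# dense vector of a sparse state
oracle_dense_state <- function(s) {
  v <- complex(2^s$n_qubits)
  v[s$basis + 1L] <- s$amp
  v
}
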