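test_that("one-mode Hamiltonian has independent-mode spectrum {0, e, e, 2e}", {
  eps <- -0.8
  ints <- active_space_integrals(0, matrix(eps, 1, 1), array(0, rep(1, 4)), 1, 1)
  H <- build_qubit_hamiltonian(ints)
  vals <- sort(Re(eigen(pauli_matrix(H))$values))
  expect_equal(vals, sort(c(0, eps, eps, 2 * eps)), tolerance = 1e-12)
})

test_that("diagonal one-body integrals give an I/Z-only Pauli sum", {
  ints <- active_space_integrals(0.3, diag(c(-1, -0.5)), array(0, rep(2, 4)), 1, 1)
  H <- build_qubit_hamiltonian(ints)
  expect_true(all(grepl("^[IZ]+$", H$words)))
})

test_that("the qubit Hamiltonian matches the dense ladder-operator oracle", {
  ints <- make_synthetic_integrals(2, 1, 1, seed = 21)
  H <- pauli_matrix(build_qubit_hamiltonian(ints))
  M <- 2; N <- 4
  cre <- lapply(0:(N - 1), oracle_creation, n = N)
  ann <- lapply(cre, function(m) Conj(t(m)))
  Ho <- ints$core_energy * diag(2^N)
  for (p in 1:M) for (q in 1:M) for (off in c(0, M)) {
    Ho <- Ho + ints$one_body[p, q] * cre[[p + off]] %*% ann[[q + off]]
  }
  for (p in 1:M) for (q in 1:M) for (r in 1:M) for (s in 1:M) {
    for (o1 in c(0, M)) for (o2 in c(0, M)) {
      Ho <- Ho + 0.5 * ints$two_body[p, q, r, s] *
        cre[[p + o1]] %*% cre[[r + o2]] %*% ann[[s + o2]] %*% ann[[q + o1]]
    }
  }
  expect_lt(max(abs(H - Ho)), 1e-10)
})

test_that("the Hamiltonian commutes with the per-spin number operators", {
  for (M in 2:3) {
    ints <- make_synthetic_integrals(M, 1, 1, seed = M + 30)
    H <- pauli_matrix(build_qubit_hamiltonian(ints))
    N <- 2 * M
    for (block in list(1:M, (M + 1):N)) {
      Nop <- Reduce(`+`, lapply(block - 1, function(p) {
        pauli_matrix(jw_number_operator(p, N))
      }))
      expect_lt(max(abs(H %*% Nop - Nop %*% H)), 1e-10)
    }
  }
})

test_that("sector diagonalization matches the filtered full diagonalization", {
  ints <- make_synthetic_integrals(3, 1, 1, seed = 5)
  H <- build_qubit_hamiltonian(ints)
  eg <- exact_ground_state(H, 1, 1)
  Hd <- pauli_matrix(H)
  idx <- sector_basis(3, 1, 1)
  vals <- eigen((Hd[idx + 1, idx + 1] +
                   Conj(t(Hd[idx + 1, idx + 1]))) / 2)$values
  expect_equal(eg$energy, min(Re(vals)), tolerance = 1e-10)
  expect_equal(sum(Mod(eg$state$amp)^2), 1, tolerance = 1e-12)
  expect_error(exact_ground_state(H, 4, 0), "sector")
})

test_that("a diagonal number Hamiltonian fills the lowest levels", {
  ints <- active_space_integrals(0, diag(c(-2, -1, 1)), array(0, rep(3, 4)), 1, 1)
  eg <- exact_ground_state(build_qubit_hamiltonian(ints), 1, 1)
  expect_equal(eg$energy, -4)
  expect_equal(eg$state$basis, determinant_index(reference_determinant(1, 1), 3))
})

test_that("Slater-Condon energies equal the simulator expectation", {
  expect_equal(reference_energy(active_space_integrals(
    0.7, matrix(0, 1, 1), array(0, rep(1, 4)), 0, 0),
    reference_determinant(integer(0), integer(0))), 0.7)
  set.seed(8)
  for (trial in 1:4) {
    M <- 3
    na <- sample(0:2, 1); nb <- sample(1:2, 1)
    ints <- make_synthetic_integrals(M, na, nb, seed = trial + 50)
    occ_a <- sort(sample(1:M, na)); occ_b <- sort(sample(1:M, nb))
    ref <- reference_determinant(occ_a, occ_b)
    H <- build_qubit_hamiltonian(ints)
    expect_equal(reference_energy(ints, ref),
                 expectation(H, determinant_state(ref, M)),
                 tolerance = 1e-10)
  }
  ints <- make_synthetic_integrals(2, 1, 1, seed = 1)
  expect_error(reference_energy(ints, reference_determinant(1:2, 1)), "match")
})

test_that("the exact ground state lies below every determinant of its sector", {
  for (M in 2:3) {
    ints <- make_synthetic_integrals(M, 1, 1, seed = M + 70)
    H <- build_qubit_hamiltonian(ints)
    eg <- exact_ground_state(H, 1, 1)
    for (a in 1:M) for (b in 1:M) {
      expect_lte(eg$energy,
                 reference_energy(ints, reference_determinant(a, b)) + 1e-10)
    }
  }
})
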