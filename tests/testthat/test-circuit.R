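test_that("the zero-parameter circuit prepares the reference determinant", {
  for (variant in c("re", "im", "g")) {
    jt <- enumerate_j_terms(3, 1, 1)
    prm <- ucj_params(variant, 3)
    ref <- reference_determinant(2, 1)
    st <- apply_circuit(build_exact_ucj_circuit(prm, ref))
    expect_equal(st$basis, determinant_index(ref, 3))
    expect_equal(Mod(st$amp), 1, tolerance = 1e-12)
  }
})

test_that("exact circuits reproduce the dense operator product e^K e^J e^-K", {
  set.seed(18)
  for (variant in c("re", "im", "g")) {
    for (M in 2:3) {
      jt <- enumerate_j_terms(M, 1, 1)
      prm <- random_ucj_params(variant, M, jt, sd = 0.4,
                               seed = M * 10 + match(variant, UCJ_VARIANTS))
      ref <- reference_determinant(1, 1)
      circ <- build_exact_ucj_circuit(prm, ref)
      st <- apply_circuit(circ)
      ops <- build_operators(prm)
      refv <- complex(4^M)
      refv[determinant_index(ref, M) + 1] <- 1
      target <- oracle_expm(pauli_matrix(ops$K)) %*%
        (oracle_expm(pauli_matrix(ops$J)) %*%
           (oracle_expm(-pauli_matrix(ops$K)) %*% refv))
      fid <- Mod(sum(Conj(target) * oracle_dense_state(st)))
      expect_gte(fid, 1 - 1e-10)
      # norm preservation and adjacency of every Givens gate
      expect_equal(sum(Mod(st$amp)^2), 1, tolerance = 1e-12)
      for (g in circ$gates) {
        if (g$kind == "givens") expect_equal(diff(g$qubits), 1L)
      }
    }
  }
})

test_that("CNOT counts equal the closed-form formula across shapes", {
  set.seed(19)
  for (M in 2:5) for (sector in list(c(1, 1), c(2, 2), c(2, 1))) {
    na <- min(sector[1], M); nb <- min(sector[2], M)
    jt <- enumerate_j_terms(M, na, nb)
    ref <- reference_determinant(seq_len(na), seq_len(nb))
    counts <- vapply(c("re", "im", "g"), function(v) {
      prm <- random_ucj_params(v, M, jt, sd = 0.3, seed = M)
      count_cnots(build_exact_ucj_circuit(prm, ref))
    }, integer(1))
    expect_true(all(counts == cnot_count_formula(M, na, nb)))
  }
})

test_that("Trotterizing the commuting Jastrow factor is exact", {
  jt <- enumerate_j_terms(2, 1, 1)
  prm <- random_ucj_params("g", 2, jt, sd = 0.6, seed = 23)
  ops <- build_operators(prm)
  circ <- build_trotter_circuit(ops$J)
  ref <- reference_determinant(1, 2)
  st0 <- determinant_state(ref, 2)
  st <- apply_circuit(circ, st0)
  target <- oracle_expm(pauli_matrix(ops$J)) %*% oracle_dense_state(st0)
  expect_lt(max(abs(oracle_dense_state(st) - target)), 1e-12)
  expect_error(build_trotter_circuit(build_qubit_hamiltonian(
    make_synthetic_integrals(2, seed = 1))), "anti-Hermitian")
})

test_that("Trotterized uCJ converges quadratically to the exact circuit", {
  jt <- enumerate_j_terms(2, 1, 1)
  ref <- reference_determinant(1, 1)
  base <- random_ucj_params("g", 2, jt, sd = 1, seed = 29)
  x0 <- ucj_pack(base, jt)
  scales <- c(0.4, 0.2, 0.1, 0.05, 0.025)
  infid <- vapply(scales, function(s) {
    prm <- ucj_unpack(s * x0, "g", 2, jt)
    exact <- apply_circuit(build_exact_ucj_circuit(prm, ref))
    ops <- build_operators(prm)
    tro <- qcircuit(4, c(build_exact_ucj_circuit(ucj_params("g", 2), ref)$gates,
                         build_trotter_circuit(ops$K)$gates,
                         build_trotter_circuit(ops$J)$gates,
                         build_trotter_circuit(ps_scale(ops$K, -1))$gates))
    st <- apply_circuit(tro)
    max(1 - Mod(overlap(exact, st)), 1e-16)
  }, numeric(1))
  # infidelity should fall at least ~quadratically with the parameter scale
  slopes <- diff(log(infid)) / diff(log(scales))
  expect_gt(mean(slopes), 1.7)
})

test_that("Pauli evolution gates follow the staircase CNOT rule", {
  circ <- qcircuit(4, list(gate_pauli_evol("XZYI", 0.3),
                           gate_pauli_evol("IZII", 0.2),
                           gate_pauli_evol("XXXX", 0.1)))
  expect_equal(count_cnots(circ), 2 * (3 - 1) + 0 + 2 * (4 - 1))
})

test_that("T-gate estimates follow the printed synthesis formula", {
  empty <- qcircuit(2, list(gate_prep_x(0L)))
  expect_equal(estimate_t_gates(empty, 0.5), 0)
  one_rot <- qcircuit(2, list(gate_nphase(0L, 0.3)))
  expect_equal(estimate_t_gates(one_rot, 1), 9.2)
  ten <- qcircuit(4, replicate(10, gate_nnphase(0L, 1L, 0.1), simplify = FALSE))
  expect_equal(estimate_t_gates(ten, 2^-10), 10 * (1.15 * 10 + 9.2))
  expect_equal(count_cnots(ten), 20L)
  expect_error(estimate_t_gates(ten, 0), "eps")
})

test_that("UCCSD generators are anti-Hermitian and number conserving", {
  ref <- reference_determinant(1, 1)
  gen <- uccsd_generator(2, ref)
  expect_true(ps_is_antihermitian(gen, tol = 1e-12))
  m <- pauli_matrix(gen)
  for (block in list(1:2, 3:4)) {
    Nop <- Reduce(`+`, lapply(block - 1, function(p) {
      pauli_matrix(jw_number_operator(p, 4))
    }))
    expect_lt(max(abs(m %*% Nop - Nop %*% m)), 1e-10)
  }
  tro <- build_trotter_circuit(gen)
  expect_gt(count_cnots(tro), 0)
})
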