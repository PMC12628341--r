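test_that("state prep and basic gates act as expected", {
  st <- apply_circuit(qcircuit(3, list(gate_prep_x(c(0L, 2L)))))
  expect_equal(st$basis, 5L)
  expect_equal(st$amp, 1 + 0i)
  # full givens rotation moves the particle between adjacent modes
  circ <- qcircuit(2, list(gate_prep_x(0L), gate_givens(0L, pi / 2, 0)))
  st <- apply_circuit(circ)
  expect_equal(st$basis, 2L)
  expect_equal(Mod(st$amp), 1, tolerance = 1e-12)
})

test_that("random circuits match the dense unitary oracle", {
  set.seed(31)
  n <- 4
  for (trial in 1:6) {
    gates <- list(gate_prep_x(sample(0:(n - 1), 2)))
    U <- diag(2^n) + 0i
    mat_of <- function(g) {
      switch(g$kind,
        prep_x = {
          m <- diag(2^n) + 0i
          im <- pauli_word_apply(paste(ifelse(0:(n - 1) %in% g$qubits, "X", "I"),
                                       collapse = ""), 0:(2^n - 1))
          m2 <- matrix(0i, 2^n, 2^n)
          m2[cbind(im$basis + 1, 1:2^n)] <- im$phase
          m2
        },
        givens = {
          gen <- jw_hop(g$qubits[1], g$qubits[2],
                        -g$theta * exp(1i * g$phi), n)
          oracle_expm(pauli_matrix(gen))
        },
        nphase = oracle_expm(1i * g$angle *
                               pauli_matrix(jw_number_operator(g$qubits[1], n))),
        nnphase = oracle_expm(1i * g$angle * pauli_matrix(pauli_multiply(
          jw_number_operator(g$qubits[1], n),
          jw_number_operator(g$qubits[2], n)))),
        pauli_evol = oracle_expm(1i * g$angle * pauli_matrix(g$word, n)))
    }
    for (i in 1:5) {
      kind <- sample(c("givens", "nphase", "nnphase", "pauli_evol"), 1)
      g <- switch(kind,
        givens = gate_givens(sample(0:(n - 2), 1), runif(1, -2, 2), runif(1, -3, 3)),
        nphase = gate_nphase(sample(0:(n - 1), 1), runif(1, -3, 3)),
        nnphase = {q <- sample(0:(n - 1), 2); gate_nnphase(q[1], q[2], runif(1, -3, 3))},
        pauli_evol = gate_pauli_evol(paste(sample(c("I", "X", "Y", "Z"), n, TRUE),
                                           collapse = ""), runif(1, -1, 1)))
      gates[[length(gates) + 1]] <- g
    }
    for (g in gates) U <- mat_of(g) %*% U
    st <- apply_circuit(qcircuit(n, gates))
    v0 <- complex(2^n); v0[1] <- 1
    expect_lt(max(abs(oracle_dense_state(st) - U %*% v0)), 1e-10)
    expect_equal(sum(Mod(st$amp)^2), 1, tolerance = 1e-12)
  }
})

test_that("expectation values follow the sign conventions and linearity", {
  vac <- vacuum_state(2)
  expect_equal(expectation(pauli_sum("ZI", 1), vac), 1)  # |0> is unoccupied
  one <- basis_state(1L, 2)
  expect_equal(expectation(pauli_sum("ZI", 1), one), -1)
  sys <- h2_sto3g_sys()
  eg <- exact_ground_state(sys$H, 1, 1)
  expect_equal(expectation(sys$H, eg$state), eg$energy, tolerance = 1e-10)
  expect_warning(expectation(pauli_sum("XI", 1i), vac), "Hermitian")
})

test_that("overlap is the inner product with unit bound", {
  set.seed(32)
  a <- sparse_state(0:3, complex(real = rnorm(4), imaginary = rnorm(4)), 2)
  a <- sparse_state(a$basis, a$amp / sqrt(sum(Mod(a$amp)^2)), 2)
  b <- sparse_state(0:3, complex(real = rnorm(4), imaginary = rnorm(4)), 2)
  b <- sparse_state(b$basis, b$amp / sqrt(sum(Mod(b$amp)^2)), 2)
  expect_equal(overlap(a, a), 1 + 0i, tolerance = 1e-12)
  expect_lte(Mod(overlap(a, b)), 1 + 1e-12)
  expect_equal(overlap(a, b),
               sum(Conj(oracle_dense_state(a)) * oracle_dense_state(b)),
               tolerance = 1e-12)
  expect_equal(overlap(basis_state(1L, 2), basis_state(2L, 2)), 0 + 0i)
})

test_that("sampling a diagonal Hamiltonian in a basis state has zero variance", {
  H <- pauli_sum(c("ZZ", "IZ", "II"), c(0.5, -0.25, 0.125))
  st <- basis_state(3L, 2)
  se <- sampled_expectation(H, st, shots_per_group = 10, n_trials = 3, seed = 1)
  expect_equal(se$mean, expectation(H, st), tolerance = 1e-12)
  expect_equal(sd(se$trial_means), 0, tolerance = 1e-14)
})

test_that("sampled expectations are seeded-reproducible and unbiased", {
  sys <- h2_sto3g_sys()
  eg <- exact_ground_state(sys$H, 1, 1)
  a <- sampled_expectation(sys$H, eg$state, 500, n_trials = 4, seed = 9)
  b <- sampled_expectation(sys$H, eg$state, 500, n_trials = 4, seed = 9)
  expect_identical(a$trial_means, b$trial_means)
  c <- sampled_expectation(sys$H, eg$state, 2000, n_trials = 30, seed = 10)
  # trial mean within 5 sigma of the exact value
  expect_lt(abs(c$mean - eg$energy), 5 * max(c$stderr, 1e-6))
})

test_that("shot-noise standard error scales as one over sqrt(shots)", {
  sys <- h2_sto3g_sys()
  jt <- sys$jterms
  x <- ucj_pack(random_ucj_params("im", 2, jt, sd = 0.3, seed = 3), jt)
  st <- ucj_state(x, sys, "im")
  shots <- c(100, 1000, 10000)
  sds <- vapply(shots, function(s) {
    se <- sampled_expectation(sys$H, st, s, n_trials = 40, seed = 21)
    sd(se$trial_means)
  }, numeric(1))
  slope <- diff(log(sds)) / diff(log(shots))
  expect_lt(abs(mean(slope) + 0.5), 0.12)
})

test_that("uCJ states conserve particle number exactly", {
  for (variant in c("re", "im", "g")) {
    sys <- synthetic_sys(3, seed = 40)
    x <- ucj_pack(random_ucj_params(variant, 3, sys$jterms, sd = 0.5,
                                    seed = 44), sys$jterms)
    st <- ucj_state(x, sys, variant)
    expect_true(all(st$basis %in% sector_basis(3, 1, 1)))
    # and through the circuit path as well
    prm <- ucj_unpack(x, variant, 3, sys$jterms)
    st2 <- apply_circuit(build_exact_ucj_circuit(prm, sys$ref))
    expect_true(all(st2$basis %in% sector_basis(3, 1, 1)))
    expect_gte(Mod(overlap(st, st2)), 1 - 1e-10)
  }
})
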