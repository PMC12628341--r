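test_that("K parameter counts follow the variant restrictions", {
  jt_s <- enumerate_j_terms(2, 1, 1, screen = TRUE)
  jt_u <- enumerate_j_terms(2, 1, 1, screen = FALSE)
  # M = 2: general complex K has 4 free reals, restricted variants 2
  expect_equal(n_ucj_params("g", 2, jt_s) - nrow(jt_s), 4L)
  expect_equal(n_ucj_params("re", 2, jt_s) - nrow(jt_s), 2L)
  expect_equal(n_ucj_params("im", 2, jt_s) - nrow(jt_s), 2L)
  # two-electron singlet screening: 4 J parameters, 6 without
  expect_equal(nrow(jt_s), 4L)
  expect_equal(nrow(jt_u), 6L)
})

test_that("J term enumeration matches the combinatorial counts", {
  expect_equal(nrow(enumerate_j_terms(4, 2, 2)), 28L)   # all C(8,2)
  expect_equal(nrow(enumerate_j_terms(3, 1, 1)), 9L)    # M^2 opposite-spin
  expect_equal(nrow(enumerate_j_terms(4, 1, 1)), 16L)
  jt <- enumerate_j_terms(2, 1, 1)
  expect_true(all(jt$p < jt$q))
  expect_false(any(jt$same_spin))
})

test_that("pack/unpack is the identity for all variants and k <= 2", {
  set.seed(4)
  for (variant in c("re", "im", "g")) for (k in 1:2) {
    M <- 3
    jt <- enumerate_j_terms(M, 1, 1)
    x <- rnorm(n_ucj_params(variant, M, jt, k))
    prm <- ucj_unpack(x, variant, M, jt, k)
    expect_true(validate_ucj_params(prm))
    expect_equal(ucj_pack(prm, jt), x, tolerance = 1e-14)
  }
  jt <- enumerate_j_terms(2, 1, 1)
  expect_error(ucj_unpack(rnorm(3), "re", 2, jt), "length")
})

test_that("k_to_unitary is the closed-form rotation for a real 2x2 generator", {
  th <- 0.37
  K <- matrix(c(0, th, -th, 0), 2, 2)
  expect_lt(max(abs(k_to_unitary(K) -
                      matrix(c(cos(th), -sin(th), sin(th), cos(th)),
                             2, 2, byrow = TRUE))), 1e-13)
  expect_equal(k_to_unitary(matrix(0, 3, 3)), diag(3) + 0i)
  set.seed(6)
  for (M in 2:6) {
    S <- matrix(rnorm(M * M) + 1i * rnorm(M * M), M, M)
    u <- k_to_unitary(S - Conj(t(S)))
    expect_lt(max(abs(u %*% Conj(t(u)) - diag(M))), 1e-12)
  }
  expect_error(k_to_unitary(diag(2)), "anti-Hermitian")
})

test_that("build_operators yields a diagonal J and an anti-Hermitian K", {
  jt <- enumerate_j_terms(2, 1, 1)
  prm <- random_ucj_params("g", 2, jt, sd = 0.5, seed = 12)
  ops <- build_operators(prm)
  expect_true(all(grepl("^[IZ]+$", ops$J$words)))
  expect_true(ps_is_antihermitian(ops$K, tol = 1e-12))
  expect_true(ps_is_antihermitian(ops$J, tol = 1e-12))
  # commuting family: exp of the sum equals the product of term exponentials
  Jm <- pauli_matrix(ops$J)
  prod_m <- diag(16) + 0i
  jterms_all <- which(upper.tri(prm$replicas[[1]]$J_real) &
                        prm$replicas[[1]]$J_real != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(jterms_all))) {
    p <- jterms_all[i, 1] - 1L; q <- jterms_all[i, 2] - 1L
    nn <- pauli_multiply(jw_number_operator(p, 4), jw_number_operator(q, 4))
    term <- ps_scale(nn, 2i * prm$replicas[[1]]$J_real[p + 1, q + 1])
    prod_m <- prod_m %*% oracle_expm(pauli_matrix(term))
  }
  expect_lt(max(abs(oracle_expm(Jm) - prod_m)), 1e-11)
})

test_that("im-uCJ K maps to the XX/YY Pauli pattern of adjacent hops", {
  jt <- enumerate_j_terms(2, 1, 1)
  prm <- random_ucj_params("im", 2, jt, sd = 0.5, seed = 2)
  K <- ps_collect(build_operators(prm)$K)
  # imaginary amplitudes on same-spin adjacent modes: only XX/YY-type words
  expect_true(all(vapply(strsplit(K$words, ""), function(l) {
    lets <- l[l != "I" & l != "Z"]
    length(unique(lets)) == 1
  }, logical(1))))
})

test_that("screened J terms annihilate every state of the declared sector", {
  for (M in 2:3) {
    jt_all <- enumerate_j_terms(M, 1, 1, screen = FALSE)
    screened_away <- jt_all[jt_all$same_spin, ]
    basis <- sector_basis(M, 1, 1)
    for (i in seq_len(nrow(screened_away))) {
      nn <- pauli_multiply(jw_number_operator(screened_away$p[i], 2 * M),
                           jw_number_operator(screened_away$q[i], 2 * M))
      m <- pauli_sector_matrix(nn, basis)
      expect_lt(max(abs(m)), 1e-13)
    }
  }
})

test_that("restricted variants embed exactly into the general variant", {
  sys <- synthetic_sys(2, seed = 33)
  jt <- sys$jterms
  for (variant in c("re", "im")) {
    prm <- random_ucj_params(variant, 2, jt, sd = 0.3, seed = 5)
    # re-tag as general: same matrices, general packing
    gprm <- ucj_params("g", 2, 1, prm$replicas)
    e1 <- ucj_energy(ucj_pack(prm, jt), sys, variant)
    e2 <- ucj_energy(ucj_pack(gprm, jt), sys, "g")
    expect_equal(e1, e2, tolerance = 1e-12)
  }
})

test_that("parameter constraint violations are rejected", {
  expect_error(ucj_params("re", 2, 1, list(list(
    K_alpha = matrix(c(0, 1i, 1i, 0), 2, 2), K_beta = matrix(0i, 2, 2),
    J_real = matrix(0, 4, 4)))))
  expect_error(ucj_params("g", 2, 1, list(list(
    K_alpha = matrix(0i, 2, 2), K_beta = matrix(0i, 2, 2),
    J_real = diag(4)))))
})
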