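test_that("single-qubit Pauli products follow the multiplication table", {
  zz <- pauli_word_multiply("Z", "Z")
  expect_equal(zz$word, "I")
  expect_equal(zz$phase, 1 + 0i)
  xy <- pauli_word_multiply("X", "Y")
  expect_equal(xy$word, "Z")
  expect_equal(xy$phase, 1i)
})

test_that("pauli_multiply matches the dense matrix product on random sums", {
  set.seed(11)
  for (trial in 1:5) {
    n <- sample(2:4, 1)
    rand_ps <- function() {
      words <- replicate(3, paste(sample(c("I", "X", "Y", "Z"), n, TRUE),
                                  collapse = ""))
      pauli_sum(words, complex(real = rnorm(3), imaginary = rnorm(3)), n)
    }
    a <- rand_ps(); b <- rand_ps()
    expect_lt(max(abs(pauli_matrix(pauli_multiply(a, b)) -
                        pauli_matrix(a) %*% pauli_matrix(b))), 1e-12)
  }
})

test_that("collection merges duplicate words and drops zeros", {
  ps <- pauli_sum(c("XZ", "XZ", "YY"), c(1, -1, 2i))
  expect_equal(sort(ps$words), "YY")
  expect_equal(ps$coeffs, 2i)
})

test_that("jw number operator is diag(0, 1) and idempotent", {
  np <- jw_number_operator(0, 1)
  expect_equal(pauli_matrix(np), diag(c(0, 1)) + 0i)
  sq <- pauli_multiply(np, np)
  expect_equal(pauli_matrix(sq), pauli_matrix(np))
  expect_error(jw_number_operator(3, 2), "range")
})

test_that("jw ladder operators match the first-principles kron construction", {
  for (n in 2:4) for (p in 0:(n - 1)) {
    expect_lt(max(abs(pauli_matrix(jw_creation(p, n)) - oracle_creation(p, n))),
              1e-13)
  }
})

test_that("jw_hop reproduces the dense anti-Hermitian hopping generator", {
  set.seed(3)
  for (trial in 1:6) {
    n <- 4
    pq <- sample(0:(n - 1), 2)
    c0 <- complex(real = rnorm(1), imaginary = rnorm(1))
    hop <- jw_hop(pq[1], pq[2], c0, n)
    target <- c0 * oracle_creation(pq[1], n) %*% oracle_annihilation(pq[2], n) -
      Conj(c0) * oracle_creation(pq[2], n) %*% oracle_annihilation(pq[1], n)
    expect_lt(max(abs(pauli_matrix(hop) - target)), 1e-12)
    expect_true(ps_is_antihermitian(hop))
  }
  # real amplitude on adjacent modes: XY/YX pattern, two weight-2 words
  h <- jw_hop(0, 1, 0.4 + 0i, 2)
  expect_setequal(h$words, c("XY", "YX"))
  # imaginary amplitude: XX/YY pattern
  h2 <- jw_hop(0, 1, 0.4i, 2)
  expect_setequal(h2$words, c("XX", "YY"))
  # non-adjacent modes carry the parity string
  h3 <- jw_hop(0, 2, 1 + 2i, 4)
  expect_true(all(substr(h3$words, 2, 2) == "Z"))
  expect_error(jw_hop(1, 1, 1, 4), "differ")
})

test_that("pauli_word_apply agrees with dense matrix columns", {
  set.seed(5)
  for (trial in 1:5) {
    n <- 3
    w <- paste(sample(c("I", "X", "Y", "Z"), n, TRUE), collapse = "")
    m <- pauli_matrix(w, n)
    im <- pauli_word_apply(w, 0:(2^n - 1L))
    for (b in 0:(2^n - 1L)) {
      col <- complex(2^n)
      col[im$basis[b + 1] + 1] <- im$phase[b + 1]
      expect_equal(col, m[, b + 1])
    }
  }
})

test_that("restricted K operators use half as many Pauli words as general K", {
  set.seed(9)
  for (M in 2:4) {
    jt <- enumerate_j_terms(M, 1, 1)
    n_words <- function(variant) {
      prm <- random_ucj_params(variant, M, jt, sd = 0.3, seed = M)
      length(ps_collect(build_operators(prm)$K)$words)
    }
    expect_equal(2L * n_words("re"), n_words("g"))
    expect_equal(2L * n_words("im"), n_words("g"))
  }
})

test_that("qwc grouping is a partition of qubit-wise commuting terms", {
  sys <- h2_sto3g_sys()
  groups <- qwc_group(sys$H)
  # partition: together the groups hold every collected term exactly once
  all_words <- unlist(lapply(groups, `[[`, "words"))
  expect_setequal(all_words, ps_collect(sys$H)$words)
  expect_equal(length(all_words), length(ps_collect(sys$H)$words))
  # exhaustive pairwise letter scan within each group
  for (gr in groups) {
    lw <- strsplit(gr$words, "")
    if (length(lw) < 2) next
    for (i in seq_along(lw)) for (j in seq_len(i - 1)) {
      clash <- lw[[i]] != "I" & lw[[j]] != "I" & lw[[i]] != lw[[j]]
      expect_false(any(clash))
    }
  }
  # diagonal sums need a single group, clashing terms split
  expect_length(qwc_group(pauli_sum(c("ZZ", "ZI", "IZ"), c(1, 2, 3))), 1L)
  expect_length(qwc_group(pauli_sum(c("XI", "ZI"), c(1, 1))), 2L)
})
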