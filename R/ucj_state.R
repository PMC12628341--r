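# Sector-space evaluation of uCJ states.
#
# Within a fixed (n_alpha, n_beta) sector the ansatz factorizes: the
# orbital-rotation exponential e^{K} acts on alpha and beta occupation
# strings through the compound (minor-determinant) matrix of the M x M
# unitary exp(K_sigma), and e^{J} is a diagonal phase.  This evaluator is
# algebraically identical to simulating the exact Givens circuit (verified
# against it in the test suite) and is the fast path used by the
# variational optimizer.

# all n_el-subsets of M orbitals as bit masks (ascending integer order)
.spin_strings <- function(M, n_el) {
  if (n_el == 0) return(0L)
  combos <- utils::combn(seq_len(M) - 1L, n_el, simplify = FALSE)
  masks <- vapply(combos, function(s) sum(bitwShiftL(1L, s)), numeric(1))
  sort(as.integer(masks))
}

# index tables for the compound matrix: for strings I, J of n_el orbitals,
# entry (I, J) = det(u[orbs(I), orbs(J)])
.compound_tables <- function(M, n_el, strings) {
  d <- length(strings)
  orbs <- lapply(strings, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(M - 1))) > 0))
  if (n_el == 0) return(list(dim = d, n_el = 0))
  perms <- .permutations(n_el)
  signs <- vapply(perms, .perm_sign, numeric(1))
  # linear index tables, one matrix (d x d) per (permutation, position)
  tabs <- lapply(seq_along(perms), function(k) {
    lapply(seq_len(n_el), function(pos) {
      rowidx <- vapply(orbs, function(o) o[perms[[k]][pos]], numeric(1))
      colidx <- vapply(orbs, function(o) o[pos], numeric(1))
      outer(rowidx, colidx, function(r, cc) (cc - 1) * M + r)
    })
  })
  list(dim = d, n_el = n_el, tabs = tabs, signs = signs)
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in .permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

.perm_sign <- function(p) {
  n <- length(p)
  inv <- 0L
  for (i in seq_len(n - 1)) inv <- inv + sum(p[(i + 1):n] < p[i])
  (-1)^inv
}

.compound_matrix <- function(u, ct) {
  if (ct$n_el == 0) return(matrix(1 + 0i, 1, 1))
  uv <- as.vector(u)
  acc <- matrix(0i, ct$dim, ct$dim)
  for (k in seq_along(ct$tabs)) {
    prod_k <- uv[ct$tabs[[k]][[1]]]
    if (ct$n_el > 1) {
      for (pos in 2:ct$n_el) prod_k <- prod_k * uv[ct$tabs[[k]][[pos]]]
    }
    acc <- acc + ct$signs[k] * matrix(prod_k, ct$dim, ct$dim)
  }
  acc
}

#' uCJ variational system context
#'
#' Precomputes everything needed for fast repeated energy evaluation:
#' the qubit Hamiltonian restricted to the particle-number sector, the
#' sector string spaces, the screened Jastrow term list and its occupancy
#' table, and the reference determinant.
#'
#' @param ints an `asints` object
#' @param ref optional `ref_det` (defaults to the aufbau determinant)
#' @param screen apply occupancy-based J screening
#' @param H optional precomputed qubit Hamiltonian `pauli_sum`
#' @export
ucj_system <- function(ints, ref = NULL, screen = TRUE, H = NULL) {
  M <- ints$n_spatial
  na <- ints$n_alpha; nb <- ints$n_beta
  if (is.null(ref)) ref <- reference_determinant(seq_len(na), seq_len(nb))
  if (is.null(H)) H <- build_qubit_hamiltonian(ints)
  astr <- .spin_strings(M, na)
  bstr <- .spin_strings(M, nb)
  basis <- as.integer(outer(astr, bitwShiftL(bstr, M), `+`))  # alpha fastest
  Hs <- pauli_sector_matrix(H, basis)
  Hs <- (Hs + Conj(t(Hs))) / 2
  jterms <- enumerate_j_terms(M, na, nb, screen = screen)
  # occupancy indicator per basis state and J term
  jocc <- matrix(0, length(basis), nrow(jterms))
  for (t in seq_len(nrow(jterms))) {
    m <- bitwOr(bitwShiftL(1L, jterms$p[t]), bitwShiftL(1L, jterms$q[t]))
    jocc[, t] <- as.numeric(bitwAnd(basis, m) == m)
  }
  refidx <- match(determinant_index(ref, M), basis)
  if (is.na(refidx)) stop("reference determinant outside the sector")
  pairs <- .k_pairs(M)
  list(ints = ints, H = H, ref = ref, M = M, n_alpha = na, n_beta = nb,
       basis = basis, Hs = Hs, jterms = jterms, jocc = jocc,
       refidx = refidx, na_dim = length(astr), nb_dim = length(bstr),
       ct_a = .compound_tables(M, na, astr),
       ct_b = .compound_tables(M, nb, bstr),
       kidx_up = (pairs[, 2] - 1L) * M + pairs[, 1],
       kidx_lo = (pairs[, 1] - 1L) * M + pairs[, 2])
}

.expm_antiherm <- function(K) {
  ee <- eigen(1i * K, symmetric = TRUE)
  ee$vectors %*% (exp(-1i * ee$values) * Conj(t(ee$vectors)))
}

# state vector over the sector basis from a packed parameter vector.
# Lean unpacking (layout identical to ucj_pack/ucj_unpack, which are the
# reference implementation tested against this path).
.ucj_sector_vector <- function(x, system, variant, k = 1L) {
  M <- system$M
  up <- system$kidx_up; lo <- system$kidx_lo
  npairs <- length(up)
  nj <- nrow(system$jterms)
  per <- if (variant == "g") 2L else 1L
  v <- complex(length(system$basis))
  v[system$refidx] <- 1 + 0i
  pos <- 0L
  blocks <- vector("list", 2L * k)
  lams <- vector("list", k)
  for (r in seq_len(k)) {
    for (blk in 1:2) {
      vals <- if (npairs == 0) complex(0) else switch(variant,
        re = x[pos + seq_len(npairs)] + 0i,
        im = 1i * x[pos + seq_len(npairs)],
        g = {
          xv <- x[pos + seq_len(2L * npairs)]
          complex(real = xv[c(TRUE, FALSE)], imaginary = xv[c(FALSE, TRUE)])
        })
      pos <- pos + per * npairs
      K <- complex(M * M)
      K[up] <- vals
      K[lo] <- -Conj(vals)
      dim(K) <- c(M, M)
      blocks[[(r - 1L) * 2L + blk]] <- .expm_antiherm(K)
    }
    lams[[r]] <- 2 * x[pos + seq_len(nj)]
    pos <- pos + nj
  }
  if (pos != length(x)) stop("parameter vector length mismatch")
  for (r in rev(seq_len(k))) {
    Ua <- .compound_matrix(blocks[[(r - 1L) * 2L + 1L]], system$ct_a)
    Ub <- .compound_matrix(blocks[[(r - 1L) * 2L + 2L]], system$ct_b)
    V <- matrix(v, system$na_dim, system$nb_dim)
    V <- Conj(t(Ua)) %*% V %*% Conj(Ub)          # e^{-K}
    v <- as.vector(V) * exp(1i * as.vector(system$jocc %*% lams[[r]]))  # e^{J}
    V <- Ua %*% matrix(v, system$na_dim, system$nb_dim) %*% t(Ub)  # e^{K}
    v <- as.vector(V)
  }
  v
}

#' uCJ state over the sector basis
#'
#' @param x packed real parameter vector (see [ucj_pack()])
#' @param system a [ucj_system()] context
#' @param variant uCJ variant tag
#' @param k number of replicas
#' @return a `sparse_state`
#' @export
ucj_state <- function(x, system, variant, k = 1L) {
  v <- .ucj_sector_vector(x, system, variant, k)
  sparse_state(system$basis, v, 2L * system$M)
}

#' uCJ energy expectation
#' @inheritParams ucj_state
#' @export
ucj_energy <- function(x, system, variant, k = 1L) {
  v <- .ucj_sector_vector(x, system, variant, k)
  Re(sum(Conj(v) * (system$Hs %*% v)))
}
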