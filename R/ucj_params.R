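# Parameterization of the three unitary cluster Jastrow variants.
#
# A k-fold uCJ state is  prod_i e^{K_i} e^{J_i} e^{-K_i} |ref>,  where each
# K_i is a one-body orbital-rotation generator restricted to same-spin
# rotations (an anti-Hermitian M x M block per spin) and each J_i is a
# purely imaginary symmetric two-body density-density correlator over spin
# orbitals.  The variants restrict K: Re-uCJ (real antisymmetric), Im-uCJ
# (purely imaginary), g-uCJ (general complex anti-Hermitian).

UCJ_VARIANTS <- c("re", "im", "g")

#' uCJ parameter container
#'
#' @param variant one of "re", "im", "g"
#' @param M number of spatial orbitals
#' @param k number of cluster Jastrow replicas
#' @param replicas optional list of length k, each a list with complex M x M
#'   anti-Hermitian `K_alpha`, `K_beta` and a real symmetric zero-diagonal
#'   2M x 2M matrix `J_real` (the correlator is J = i * J_real)
#' @export
ucj_params <- function(variant, M, k = 1L, replicas = NULL) {
  variant <- match.arg(variant, UCJ_VARIANTS)
  N <- 2L * M
  if (is.null(replicas)) {
    replicas <- replicate(k, list(K_alpha = matrix(0i, M, M),
                                  K_beta = matrix(0i, M, M),
                                  J_real = matrix(0, N, N)),
                          simplify = FALSE)
  }
  obj <- structure(list(variant = variant, M = as.integer(M),
                        k = as.integer(k), replicas = replicas),
                   class = "ucj_params")
  validate_ucj_params(obj)
  obj
}

#' Validate uCJ parameter constraints
#' @param params a `ucj_params`
#' @param tol numeric tolerance
#' @export
validate_ucj_params <- function(params, tol = 1e-12) {
  for (rep in params$replicas) {
    for (K in list(rep$K_alpha, rep$K_beta)) {
      if (max(abs(K + Conj(t(K)))) > tol) stop("K block is not anti-Hermitian")
      if (params$variant == "re" && max(abs(Im(K))) > tol) {
        stop("Re-uCJ requires a real K block")
      }
      if (params$variant == "im" && max(abs(Re(K))) > tol) {
        stop("Im-uCJ requires a purely imaginary K block")
      }
    }
    J <- rep$J_real
    if (max(abs(J - t(J))) > tol) stop("J_real must be symmetric")
    if (max(abs(diag(J))) > tol) stop("J_real must have zero diagonal")
  }
  invisible(TRUE)
}

#' @export
print.ucj_params <- function(x, ...) {
  cat(sprintf("<ucj_params> %s-uCJ, M = %d, k = %d\n", x$variant, x$M, x$k))
  invisible(x)
}

#' Enumerate Jastrow number-pair terms with sector screening
#'
#' All unordered distinct spin-orbital pairs; with `screen = TRUE`, same-spin
#' pairs are dropped for any spin sector holding at most one electron (such
#' n n products annihilate every state of the sector).
#'
#' @param M number of spatial orbitals
#' @param n_alpha,n_beta electron counts of the target sector
#' @param screen apply occupancy-based screening
#' @return data.frame with 0-based qubit columns `p`, `q` (p < q) and a
#'   logical `same_spin`
#' @export
enumerate_j_terms <- function(M, n_alpha, n_beta, screen = TRUE) {
  N <- 2L * M
  pq <- t(utils::combn(0:(N - 1L), 2L))
  same_spin <- (pq[, 1] < M) == (pq[, 2] < M)
  keep <- rep(TRUE, nrow(pq))
  if (screen) {
    alpha_pair <- same_spin & pq[, 1] < M
    beta_pair <- same_spin & pq[, 1] >= M
    if (n_alpha <= 1) keep[alpha_pair] <- FALSE
    if (n_beta <= 1) keep[beta_pair] <- FALSE
  }
  data.frame(p = pq[keep, 1], q = pq[keep, 2], same_spin = same_spin[keep])
}

# number of real K parameters per replica
.n_k_params <- function(variant, M) {
  npairs <- M * (M - 1) / 2
  per_block <- if (variant == "g") 2 * npairs else npairs
  as.integer(2 * per_block)
}

#' Number of free real parameters of a uCJ ansatz
#' @param variant uCJ variant tag
#' @param M number of spatial orbitals
#' @param jterms output of [enumerate_j_terms()]
#' @param k number of replicas
#' @export
n_ucj_params <- function(variant, M, jterms, k = 1L) {
  as.integer(k * (.n_k_params(variant, M) + nrow(jterms)))
}

# upper-triangle pair index list for K blocks
.k_pairs <- function(M) {
  if (M < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(seq_len(M), 2L))
}

#' Pack uCJ parameters into a minimal real coordinate vector
#'
#' Per replica: the free real coordinates of `K_alpha` then `K_beta`
#' (Re-uCJ: the real upper triangle; Im-uCJ: the imaginary upper triangle;
#' g-uCJ: interleaved real, imaginary), then one real per surviving J term.
#'
#' @param params a `ucj_params`
#' @param jterms output of [enumerate_j_terms()] defining the J coordinates
#' @export
ucj_pack <- function(params, jterms) {
  out <- numeric(0)
  pairs <- .k_pairs(params$M)
  for (rep in params$replicas) {
    for (K in list(rep$K_alpha, rep$K_beta)) {
      vals <- K[pairs]
      out <- c(out, switch(params$variant,
                           re = Re(vals),
                           im = Im(vals),
                           g = as.vector(rbind(Re(vals), Im(vals)))))
    }
    out <- c(out, rep$J_real[cbind(jterms$p + 1L, jterms$q + 1L)])
  }
  out
}

#' @rdname ucj_pack
#' @param x real parameter vector
#' @param variant,M,k ansatz shape
#' @export
ucj_unpack <- function(x, variant, M, jterms, k = 1L) {
  variant <- match.arg(variant, UCJ_VARIANTS)
  pairs <- .k_pairs(M)
  npairs <- nrow(pairs)
  N <- 2L * M
  pos <- 0L
  take <- function(n) {
    v <- x[(pos + 1L):(pos + n)]
    pos <<- pos + n
    v
  }
  replicas <- vector("list", k)
  for (r in seq_len(k)) {
    Ks <- list()
    for (blk in 1:2) {
      K <- matrix(0i, M, M)
      if (npairs > 0) {
        vals <- switch(variant,
                       re = take(npairs) + 0i,
                       im = 1i * take(npairs),
                       g = {
                         v <- take(2L * npairs)
                         complex(real = v[c(TRUE, FALSE)],
                                 imaginary = v[c(FALSE, TRUE)])
                       })
        K[pairs] <- vals
        K[pairs[, c(2, 1), drop = FALSE]] <- -Conj(vals)
      }
      Ks[[blk]] <- K
    }
    J <- matrix(0, N, N)
    if (nrow(jterms) > 0) {
      jv <- take(nrow(jterms))
      J[cbind(jterms$p + 1L, jterms$q + 1L)] <- jv
      J[cbind(jterms$q + 1L, jterms$p + 1L)] <- jv
    }
    replicas[[r]] <- list(K_alpha = Ks[[1]], K_beta = Ks[[2]], J_real = J)
  }
  if (pos != length(x)) stop("parameter vector length mismatch")
  ucj_params(variant, M, k, replicas)
}

#' Random uCJ parameters (for tests and multi-start initialization)
#' @param variant,M,k ansatz shape
#' @param jterms output of [enumerate_j_terms()]
#' @param sd normal scale of the coordinates
#' @param seed integer seed
#' @export
random_ucj_params <- function(variant, M, jterms, k = 1L, sd = 0.1, seed = 1L) {
  n <- n_ucj_params(variant, M, jterms, k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  ucj_unpack(stats::rnorm(n, sd = sd), variant, M, jterms, k)
}

#' Matrix exponential of an anti-Hermitian matrix
#'
#' Computed through the eigendecomposition of the Hermitian matrix iK, so
#' the result is unitary to machine precision.
#'
#' @param K anti-Hermitian matrix
#' @export
k_to_unitary <- function(K) {
  if (max(abs(K + Conj(t(K)))) > 1e-10) stop("K is not anti-Hermitian")
  if (nrow(K) == 1) return(matrix(exp(K[1, 1]), 1, 1))
  ee <- eigen(1i * K, symmetric = TRUE)
  ee$vectors %*% diag(exp(-1i * ee$values)) %*% Conj(t(ee$vectors))
}

#' Jordan-Wigner operators of a uCJ replica
#'
#' @param params a `ucj_params`
#' @param replica replica index
#' @return list with `K` (anti-Hermitian `pauli_sum`) and `J`
#'   (anti-Hermitian `pauli_sum` containing only I/Z letters)
#' @export
build_operators <- function(params, replica = 1L) {
  M <- params$M
  N <- 2L * M
  rep <- params$replicas[[replica]]
  kps <- pauli_sum(strrep("I", N), 0i, N, collect = FALSE)
  pairs <- .k_pairs(M)
  terms <- list(kps)
  for (blk in 1:2) {
    K <- if (blk == 1) rep$K_alpha else rep$K_beta
    off <- if (blk == 1) 0L else M
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, 1]; q <- pairs[i, 2]
      if (Mod(K[p, q]) == 0) next
      terms[[length(terms) + 1L]] <-
        jw_hop(p - 1L + off, q - 1L + off, K[p, q], N)
    }
  }
  Khat <- do.call(ps_add, terms)
  jterms_all <- which(upper.tri(rep$J_real) & rep$J_real != 0, arr.ind = TRUE)
  jparts <- list(pauli_sum(strrep("I", N), 0i, N, collect = FALSE))
  for (i in seq_len(nrow(jterms_all))) {
    p <- jterms_all[i, 1] - 1L; q <- jterms_all[i, 2] - 1L
    nn <- pauli_multiply(jw_number_operator(p, N), jw_number_operator(q, N))
    jparts[[length(jparts) + 1L]] <-
      ps_scale(nn, 2i * rep$J_real[p + 1L, q + 1L])
  }
  Jhat <- do.call(ps_add, jparts)
  list(K = Khat, J = Jhat)
}
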