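# Minimal self-consistent-field backend for hydrogen-cluster benchmarks.
#
# All benchmark systems treated numerically in this package (H2, H3+, square
# H4) contain only hydrogen atoms, so the AO basis is built exclusively from
# contracted s-type Gaussians, for which overlap, kinetic, nuclear-attraction
# and repulsion integrals have closed forms involving only the zeroth Boys
# function.  Restricted and unrestricted Hartree-Fock follow, and the MO
# integrals are exported as an active-space container over all orbitals.

BOHR_PER_ANGSTROM <- 1 / 0.52917721092

# contracted s shells: exponents and coefficients (for normalized primitives)
.h_basis_sets <- list(
  "sto-3g" = list(list(exps = c(3.42525091, 0.62391373, 0.16885540),
                       coef = c(0.15432897, 0.53532814, 0.44463454))),
  "6-31g" = list(list(exps = c(18.7311370, 2.8253937, 0.6401217),
                      coef = c(0.03349460, 0.23472695, 0.81375733)),
                 list(exps = 0.1612778, coef = 1.0)),
  "6-311g" = list(list(exps = c(33.86500, 5.094790, 1.158790),
                       coef = c(0.0254938, 0.190687, 0.852162)),
                  list(exps = 0.325840, coef = 1.0),
                  list(exps = 0.102741, coef = 1.0)))

.boys0 <- function(t) {
  ifelse(t < 1e-12, 1 - t / 3,
         0.5 * sqrt(pi / pmax(t, 1e-300)) * (2 * stats::pnorm(sqrt(2 * pmax(t, 0))) - 1))
}

# build normalized contracted shells at nuclear coordinates (bohr)
.build_shells <- function(coords_bohr, basis) {
  bs <- .h_basis_sets[[tolower(basis)]]
  if (is.null(bs)) stop("unsupported hydrogen basis: ", basis)
  shells <- list()
  for (a in seq_len(nrow(coords_bohr))) {
    for (sh in bs) {
      cc <- sh$coef * (2 * sh$exps / pi)^0.75
      s <- 0
      for (i in seq_along(sh$exps)) for (j in seq_along(sh$exps)) {
        s <- s + cc[i] * cc[j] * (pi / (sh$exps[i] + sh$exps[j]))^1.5
      }
      shells[[length(shells) + 1L]] <-
        list(center = coords_bohr[a, ], exps = sh$exps, coef = cc / sqrt(s))
    }
  }
  shells
}

#' Atomic-orbital integrals for a hydrogen cluster
#'
#' @param coords_ang matrix of Cartesian coordinates (angstrom), one H atom
#'   per row
#' @param basis one of "sto-3g", "6-31g", "6-311g"
#' @return list with overlap `S`, core Hamiltonian `hcore`, repulsion tensor
#'   `eri` (chemists' notation) and nuclear energy `e_nuc`
#' @export
hydrogen_ao_integrals <- function(coords_ang, basis = "sto-3g") {
  coords <- as.matrix(coords_ang) * BOHR_PER_ANGSTROM
  shells <- .build_shells(coords, basis)
  n <- length(shells)
  S <- matrix(0, n, n); Tm <- matrix(0, n, n); V <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A <- shells[[i]]$center; B <- shells[[j]]$center
    ab2 <- sum((A - B)^2)
    for (ii in seq_along(shells[[i]]$exps)) for (jj in seq_along(shells[[j]]$exps)) {
      al <- shells[[i]]$exps[ii]; be <- shells[[j]]$exps[jj]
      cc <- shells[[i]]$coef[ii] * shells[[j]]$coef[jj]
      p <- al + be
      pre <- cc * exp(-al * be / p * ab2)
      S[i, j] <- S[i, j] + pre * (pi / p)^1.5
      Tm[i, j] <- Tm[i, j] +
        pre * al * be / p * (3 - 2 * al * be / p * ab2) * (pi / p)^1.5
      P <- (al * A + be * B) / p
      for (a in seq_len(nrow(coords))) {
        pc2 <- sum((P - coords[a, ])^2)
        V[i, j] <- V[i, j] - pre * 2 * pi / p * .boys0(p * pc2)
      }
    }
  }
  eri <- array(0, rep(n, 4))
  for (i in 1:n) for (j in 1:i) {
    A <- shells[[i]]$center; B <- shells[[j]]$center
    ab2 <- sum((A - B)^2)
    for (k in 1:i) {
      lmax <- if (k == i) j else k
      for (l in 1:lmax) {
        C <- shells[[k]]$center; D <- shells[[l]]$center
        cd2 <- sum((C - D)^2)
        val <- 0
        for (ii in seq_along(shells[[i]]$exps)) for (jj in seq_along(shells[[j]]$exps)) {
          al <- shells[[i]]$exps[ii]; be <- shells[[j]]$exps[jj]
          p <- al + be
          P <- (al * A + be * B) / p
          kab <- exp(-al * be / p * ab2) * shells[[i]]$coef[ii] * shells[[j]]$coef[jj]
          for (kk in seq_along(shells[[k]]$exps)) for (ll in seq_along(shells[[l]]$exps)) {
            ga <- shells[[k]]$exps[kk]; de <- shells[[l]]$exps[ll]
            q <- ga + de
            Q <- (ga * C + de * D) / q
            kcd <- exp(-ga * de / q * cd2) * shells[[k]]$coef[kk] * shells[[l]]$coef[ll]
            pq2 <- sum((P - Q)^2)
            val <- val + kab * kcd * 2 * pi^2.5 / (p * q * sqrt(p + q)) *
              .boys0(p * q / (p + q) * pq2)
          }
        }
        for (idx in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                         c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                         c(k, l, j, i), c(l, k, j, i))) {
          eri[idx[1], idx[2], idx[3], idx[4]] <- val
        }
      }
    }
  }
  e_nuc <- 0
  na <- nrow(coords)
  if (na > 1) {
    for (i in 1:(na - 1)) for (j in (i + 1):na) {
      e_nuc <- e_nuc + 1 / sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  list(S = S, hcore = Tm + V, eri = eri, e_nuc = e_nuc, n_ao = n)
}

.coulomb_exchange <- function(eri, D) {
  n <- nrow(D)
  J <- matrix(0, n, n); K <- matrix(0, n, n)
  for (p in 1:n) for (q in 1:n) {
    J[p, q] <- sum(eri[p, q, , ] * D)
    K[p, q] <- sum(eri[p, , q, ] * D)
  }
  list(J = J, K = K)
}

.lowdin <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(e$values^-0.5, nrow(S)) %*% t(e$vectors)
}

#' Restricted Hartree-Fock for a hydrogen cluster
#'
#' Roothaan iterations with aufbau occupation.  `occ_subspace` optionally
#' restricts the occupied orbitals to the span of the given AO-coefficient
#' columns, which selects a symmetry-adapted SCF stationary point when the
#' aufbau solution is ambiguous (degenerate frontier shell); the virtual
#' orbitals outside the subspace are appended after convergence.
#'
#' @param ao output of [hydrogen_ao_integrals()]
#' @param n_occ number of doubly occupied orbitals
#' @param occ_subspace optional n_ao x m matrix of AO coefficients
#' @param maxit,tol iteration controls
#' @return list with `energy`, MO coefficients `C`, orbital energies `eps`
#' @export
scf_rhf <- function(ao, n_occ, occ_subspace = NULL, maxit = 500, tol = 1e-13) {
  S <- ao$S; h <- ao$hcore; eri <- ao$eri
  n <- nrow(S)
  P <- occ_subspace
  if (is.null(P)) P <- diag(n)
  blocks <- list(P)
  if (ncol(P) < n) {
    # S-orthogonal complement of the subspace
    V <- diag(n) - P %*% solve(t(P) %*% S %*% P, t(P) %*% S)
    ev <- eigen(t(V) %*% S %*% V, symmetric = TRUE)
    keep <- ev$values > 1e-10
    blocks[[2]] <- V %*% ev$vectors[, keep, drop = FALSE] %*%
      diag(ev$values[keep]^-0.5, sum(keep))
  }
  Xs <- lapply(blocks, function(B) .lowdin(t(B) %*% S %*% B))
  diag_blocks <- function(F) {
    # diagonalize the Fock operator separately in each symmetry block
    C <- NULL; eps <- NULL; blk <- NULL
    for (bi in seq_along(blocks)) {
      B <- blocks[[bi]]; X <- Xs[[bi]]
      ee <- eigen(t(X) %*% (t(B) %*% F %*% B) %*% X, symmetric = TRUE)
      ord <- order(ee$values)
      C <- cbind(C, B %*% (X %*% ee$vectors[, ord, drop = FALSE]))
      eps <- c(eps, ee$values[ord])
      blk <- c(blk, rep(bi, length(ord)))
    }
    list(C = C, eps = eps, blk = blk)
  }
  # occupied orbitals are always drawn from the subspace block
  db <- diag_blocks(h)
  occ_cols <- which(db$blk == 1L)[seq_len(n_occ)]
  C <- db$C[, occ_cols, drop = FALSE]
  e_old <- Inf; energy <- NA_real_; Ffull <- h
  for (it in seq_len(maxit)) {
    D <- 2 * C %*% t(C)
    jk <- .coulomb_exchange(eri, D)
    Ffull <- h + jk$J - 0.5 * jk$K
    energy <- sum(D * h) + 0.5 * sum(D * (jk$J - 0.5 * jk$K)) + ao$e_nuc
    db <- diag_blocks(Ffull)
    occ_cols <- which(db$blk == 1L)[seq_len(n_occ)]
    C <- db$C[, occ_cols, drop = FALSE]
    if (abs(energy - e_old) < tol && it > 5) break
    e_old <- energy
  }
  # final MO set: occupied from the subspace block, then all remaining
  # orbitals ordered by orbital energy
  rest <- setdiff(seq_len(n), occ_cols)
  rest <- rest[order(db$eps[rest])]
  ord <- c(occ_cols, rest)
  list(energy = energy, C = db$C[, ord], eps = db$eps[ord], n_occ = n_occ)
}

#' Unrestricted Hartree-Fock with broken-symmetry multi-start
#'
#' Runs Roothaan UHF from a HOMO-LUMO spin-mixed guess plus seeded random
#' orbital-rotation guesses and returns the lowest converged solution
#' (a cheap stand-in for analytic stability following).
#'
#' @param ao output of [hydrogen_ao_integrals()]
#' @param n_alpha,n_beta electron counts
#' @param C0 initial MO coefficients (e.g. from [scf_rhf()])
#' @param n_starts number of seeded random restarts
#' @param seed integer seed
#' @param maxit,tol iteration controls
#' @export
scf_uhf <- function(ao, n_alpha, n_beta, C0, n_starts = 6, seed = 1,
                    maxit = 2000, tol = 1e-13) {
  S <- ao$S; h <- ao$hcore; eri <- ao$eri
  X <- .lowdin(S)
  n <- nrow(S)
  run <- function(Ca, Cb) {
    e_old <- Inf; energy <- NA_real_
    for (it in seq_len(maxit)) {
      Da <- Ca[, seq_len(n_alpha), drop = FALSE] %*% t(Ca[, seq_len(n_alpha), drop = FALSE])
      Db <- Cb[, seq_len(n_beta), drop = FALSE] %*% t(Cb[, seq_len(n_beta), drop = FALSE])
      jkt <- .coulomb_exchange(eri, Da + Db)
      jka <- .coulomb_exchange(eri, Da)
      jkb <- .coulomb_exchange(eri, Db)
      Fa <- h + jkt$J - jka$K
      Fb <- h + jkt$J - jkb$K
      energy <- sum(Da * h) + sum(Db * h) +
        0.5 * sum(Da * (jkt$J - jka$K)) + 0.5 * sum(Db * (jkt$J - jkb$K)) + ao$e_nuc
      if (abs(energy - e_old) < tol && it > 6) break
      e_old <- energy
      ea <- eigen(t(X) %*% Fa %*% X, symmetric = TRUE)
      Ca <- X %*% ea$vectors[, order(ea$values)]
      eb <- eigen(t(X) %*% Fb %*% X, symmetric = TRUE)
      Cb <- X %*% eb$vectors[, order(eb$values)]
    }
    energy
  }
  best <- Inf
  # HOMO-LUMO mixing guess
  if (n_alpha < n && n_alpha >= 1) {
    th <- pi / 4
    Ca <- C0; Cb <- C0
    i <- n_alpha; j <- n_alpha + 1L
    Ca[, i] <- cos(th) * C0[, i] + sin(th) * C0[, j]
    Ca[, j] <- -sin(th) * C0[, i] + cos(th) * C0[, j]
    Cb[, i] <- cos(th) * C0[, i] - sin(th) * C0[, j]
    Cb[, j] <- sin(th) * C0[, i] + cos(th) * C0[, j]
    best <- min(best, run(Ca, Cb))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (s in seq_len(n_starts)) {
    Qa <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    Qb <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    best <- min(best, run(C0 %*% Qa, C0 %*% Qb))
  }
  list(energy = best)
}

#' Transform AO integrals to an MO active-space container
#'
#' @param ao output of [hydrogen_ao_integrals()]
#' @param C MO coefficient matrix (all orbitals active)
#' @param n_alpha,n_beta electron counts
#' @return an `asints` object (core energy = nuclear repulsion)
#' @export
mo_active_space <- function(ao, C, n_alpha, n_beta) {
  n <- ncol(C)
  nao <- nrow(C)
  hmo <- t(C) %*% ao$hcore %*% C
  # pair-index transform: (pq|rs) viewed as a matrix over (pq), (rs) pairs
  G <- ao$eri
  dim(G) <- c(nao * nao, nao * nao)
  K <- kronecker(C, C)  # maps MO pair (i fast, j slow) to AO pair (p fast, q slow)
  Gmo <- t(K) %*% G %*% K
  dim(Gmo) <- rep(n, 4)
  active_space_integrals(ao$e_nuc, (hmo + t(hmo)) / 2, symmetrize_two_body(Gmo),
                         n_alpha, n_beta)
}

# ---------------------------------------------------------------------------
# Benchmark geometries

#' Benchmark hydrogen-cluster geometries
#'
#' `h2_geometry(r)` is the diatomic at bond length `r`; `h3plus_geometry(r)`
#' the linear symmetric trimer cation with nearest-neighbour distance `r`;
#' `h4_square_geometry(side)` the square with the given side length.  All
#' lengths in angstrom.
#'
#' @param r,side internuclear distance (angstrom)
#' @return coordinate matrix, one atom per row
#' @export
h2_geometry <- function(r) matrix(c(0, 0, 0, 0, 0, r), 2, 3, byrow = TRUE)

#' @rdname h2_geometry
#' @export
h3plus_geometry <- function(r) {
  matrix(c(0, 0, -r, 0, 0, 0, 0, 0, r), 3, 3, byrow = TRUE)
}

#' @rdname h2_geometry
#' @export
h4_square_geometry <- function(side) {
  matrix(c(0, 0, 0, side, 0, 0, 0, side, 0, side, side, 0), 4, 3, byrow = TRUE)
}

#' Restricted Hartree-Fock reference for a hydrogen cluster
#'
#' Convenience wrapper producing the RHF solution, MO-basis active-space
#' integrals and the reference determinant.  For the square H4 cluster the
#' closed-shell aufbau problem is ambiguous because the frontier orbital
#' shell is doubly degenerate; `homo_orientation = "diagonal"` selects the
#' stationary point whose occupied frontier orbital is symmetric under the
#' diagonal reflection (the symmetry-adapted reference used for the
#' correlation-energy benchmarks), while "edge" gives the lower-energy
#' broken-orientation aufbau solution.
#'
#' @param coords_ang coordinate matrix (angstrom)
#' @param basis hydrogen basis set name
#' @param charge total molecular charge
#' @param homo_orientation "aufbau" or "diagonal" (square H4/STO-3G only)
#' @return list with `ao`, `scf`, `ints` (asints), `e_rhf`, `n_occ`
#' @export
hydrogen_reference <- function(coords_ang, basis = "sto-3g", charge = 0,
                               homo_orientation = c("aufbau", "diagonal")) {
  homo_orientation <- match.arg(homo_orientation)
  ao <- hydrogen_ao_integrals(coords_ang, basis)
  nelec <- nrow(as.matrix(coords_ang)) - charge
  if (nelec %% 2 != 0) stop("open-shell references are not supported")
  n_occ <- nelec %/% 2
  occ_subspace <- NULL
  if (homo_orientation == "diagonal") {
    if (nrow(as.matrix(coords_ang)) != 4 || ao$n_ao != 4) {
      stop("homo_orientation = 'diagonal' is defined for square H4/STO-3G")
    }
    # AO combinations even under the reflection swapping atoms 2 and 3
    occ_subspace <- cbind(c(1, 0, 0, 0), c(0, 0, 0, 1),
                          c(0, 1, 1, 0) / sqrt(2))
  }
  scf <- scf_rhf(ao, n_occ, occ_subspace = occ_subspace)
  ints <- mo_active_space(ao, scf$C, n_occ, n_occ)
  list(ao = ao, scf = scf, ints = ints, e_rhf = scf$energy, n_occ = n_occ)
}
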