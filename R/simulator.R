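# Statevector simulation: sparse states, circuit application, exact and
# shot-sampled expectation values.

#' Sparse statevector
#'
#' A map from occupation bitstrings (stored as basis integers, bit p =
#' occupation of qubit p) to complex amplitudes.
#'
#' @param basis integer vector of basis indices
#' @param amp complex amplitude vector
#' @param n_qubits number of qubits
#' @param prune amplitudes with modulus below this are dropped
#' @export
sparse_state <- function(basis, amp, n_qubits, prune = 1e-14) {
  keep <- Mod(amp) > prune
  ord <- order(basis[keep])
  structure(list(basis = as.integer(basis[keep][ord]),
                 amp = as.complex(amp[keep][ord]),
                 n_qubits = as.integer(n_qubits)),
            class = "sparse_state")
}

#' @export
print.sparse_state <- function(x, ...) {
  cat("<sparse_state> ", length(x$basis), " amplitudes on ", x$n_qubits,
      " qubits\n", sep = "")
  n <- min(length(x$basis), 8L)
  for (i in seq_len(n)) {
    bits <- paste(rev(as.integer(intToBits(x$basis[i]))[seq_len(x$n_qubits)]),
                  collapse = "")
    cat(sprintf("  |%s>  %s\n", bits, format(x$amp[i], digits = 5)))
  }
  if (length(x$basis) > n) cat("  ...\n")
  invisible(x)
}

#' Basis-state constructors
#' @param n_qubits number of qubits
#' @export
vacuum_state <- function(n_qubits) sparse_state(0L, 1 + 0i, n_qubits)

#' @rdname vacuum_state
#' @param index basis integer
#' @export
basis_state <- function(index, n_qubits) sparse_state(index, 1 + 0i, n_qubits)

#' Reference-determinant state
#' @param ref a `ref_det`
#' @param M number of spatial orbitals
#' @export
determinant_state <- function(ref, M) {
  basis_state(determinant_index(ref, M), 2L * M)
}

.state_norm <- function(s) sqrt(sum(Mod(s$amp)^2))

#' Inner product of two sparse states
#' @param a,b `sparse_state` objects
#' @export
overlap <- function(a, b) {
  if (a$n_qubits != b$n_qubits) stop("qubit counts differ")
  pos <- match(a$basis, b$basis)
  keep <- !is.na(pos)
  sum(Conj(a$amp[keep]) * b$amp[pos[keep]])
}

.to_dense <- function(s) {
  v <- complex(2^s$n_qubits)
  v[s$basis + 1L] <- s$amp
  v
}

.from_dense <- function(v, n_qubits, prune = 1e-14) {
  nz <- which(Mod(v) > prune)
  sparse_state(nz - 1L, v[nz], n_qubits, prune = prune)
}

#' Apply a circuit to a sparse state
#'
#' Gate semantics (see [gate()]): `prep_x` flips qubits; `givens` is the
#' two-qubit generalized fermionic rotation on adjacent modes (identity on
#' the 00 and 11 subspaces); `nphase`/`nnphase` multiply occupation-
#' conditional phases; `gphase` is a global phase; `pauli_evol` is
#' exp(i angle * word).
#'
#' @param circuit a `qcircuit`
#' @param state a `sparse_state` (defaults to the vacuum)
#' @export
apply_circuit <- function(circuit, state = NULL) {
  n <- circuit$n_qubits
  if (is.null(state)) state <- vacuum_state(n)
  if (state$n_qubits != n) stop("qubit counts differ")
  L <- 2^n
  idx <- 0:(L - 1L)
  v <- .to_dense(state)
  for (g in circuit$gates) {
    v <- .apply_gate_dense(g, v, idx, n)
  }
  .from_dense(v, n)
}

.apply_gate_dense <- function(g, v, idx, n) {
  switch(g$kind,
    prep_x = {
      m <- 0L
      for (q in g$qubits) m <- bitwOr(m, bitwShiftL(1L, q))
      v[bitwXor(idx, m) + 1L]
    },
    givens = {
      p <- g$qubits[1]; q <- g$qubits[2]
      bp <- bitwShiftL(1L, p); bq <- bitwShiftL(1L, q)
      i10 <- idx[bitwAnd(idx, bp) > 0 & bitwAnd(idx, bq) == 0]
      i01 <- i10 - bp + bq
      a <- v[i10 + 1L]; b <- v[i01 + 1L]
      ct <- cos(g$theta); st <- sin(g$theta); ph <- exp(1i * g$phi)
      # single-particle block [[cos, -e^{i phi} sin], [e^{-i phi} sin, cos]]
      # acting on (amplitude at p, amplitude at q)
      v[i10 + 1L] <- ct * a - ph * st * b
      v[i01 + 1L] <- Conj(ph) * st * a + ct * b
      v
    },
    nphase = {
      b <- bitwShiftL(1L, g$qubits[1])
      sel <- bitwAnd(idx, b) > 0
      v[sel] <- v[sel] * exp(1i * g$angle)
      v
    },
    nnphase = {
      m <- bitwOr(bitwShiftL(1L, g$qubits[1]), bitwShiftL(1L, g$qubits[2]))
      sel <- bitwAnd(idx, m) == m
      v[sel] <- v[sel] * exp(1i * g$angle)
      v
    },
    gphase = v * exp(1i * g$angle),
    pauli_evol = {
      im <- pauli_word_apply(g$word, idx)
      w <- complex(length(v))
      w[im$basis + 1L] <- im$phase * v
      cos(g$angle) * v + 1i * sin(g$angle) * w
    },
    stop("unknown gate kind: ", g$kind))
}

#' Exact expectation value of a Pauli sum in a sparse state
#' @param H a `pauli_sum` (Hermitian for a real result)
#' @param state a `sparse_state`
#' @param check_hermitian warn when H is not Hermitian
#' @export
expectation <- function(H, state, check_hermitian = TRUE) {
  if (H$n_qubits != state$n_qubits) stop("qubit counts differ")
  if (check_hermitian && !ps_is_hermitian(H)) {
    warning("expectation of a non-Hermitian operator; returning real part")
  }
  total <- 0i
  for (i in seq_along(H$words)) {
    im <- pauli_word_apply(H$words[i], state$basis)
    pos <- match(im$basis, state$basis)
    keep <- !is.na(pos)
    total <- total + H$coeffs[i] *
      sum(Conj(state$amp[pos[keep]]) * im$phase[keep] * state$amp[keep])
  }
  Re(total)
}

# ---------------------------------------------------------------------------
# Shot-sampled expectation values over qubit-wise commuting groups

# rotate a dense state into the measurement basis of a QWC group mask:
# X -> H, Y -> H S^dagger so that the letter becomes Z
.rotate_for_mask <- function(v, mask, idx) {
  letters <- strsplit(mask, "", fixed = TRUE)[[1]]
  for (p in seq_along(letters)) {
    l <- letters[p]
    if (l == "I" || l == "Z") next
    b <- bitwShiftL(1L, p - 1L)
    i1 <- idx[bitwAnd(idx, b) > 0]
    i0 <- i1 - b
    a0 <- v[i0 + 1L]; a1 <- v[i1 + 1L]
    if (l == "Y") a1 <- -1i * a1    # S^dagger
    v[i0 + 1L] <- (a0 + a1) / sqrt(2)
    v[i1 + 1L] <- (a0 - a1) / sqrt(2)
  }
  v
}

#' Shot-sampled expectation value of a Hamiltonian
#'
#' Partitions the Hamiltonian into qubit-wise commuting groups (unless a
#' precomputed grouping is supplied), rotates the state into each group's
#' shared measurement basis, and draws multinomial shot counts from the
#' exact outcome distribution.  The estimator is unbiased; no circuit noise
#' is modelled.
#'
#' @param H a Hermitian `pauli_sum`
#' @param state a `sparse_state`
#' @param shots_per_group shots drawn for every group
#' @param n_trials number of independent repetitions
#' @param seed integer seed (one master seed; trials consume the stream)
#' @param groups optional precomputed output of [qwc_group()]
#' @return list with `mean` (grand mean over trials), `stderr` (standard
#'   error of the trial mean: sd of trial means / sqrt(n_trials) when
#'   n_trials > 1, else the propagated single-trial shot error),
#'   `trial_means`, and `shot_stderr` (propagated per-trial error)
#' @export
sampled_expectation <- function(H, state, shots_per_group = 10000L,
                                n_trials = 1L, seed = 1L, groups = NULL) {
  stopifnot(shots_per_group >= 1, n_trials >= 1)
  if (is.null(groups)) groups <- qwc_group(H)
  n <- state$n_qubits
  idx <- 0:(2^n - 1L)
  v0 <- .to_dense(state)
  # precompute per-group outcome distributions and term eigenvalue tables
  prep <- lapply(groups, function(gr) {
    vr <- .rotate_for_mask(v0, gr$mask, idx)
    probs <- Mod(vr)^2
    keep <- probs > 1e-15
    outcomes <- idx[keep]
    probs <- probs[keep] / sum(probs[keep])
    gvals <- numeric(length(outcomes))  # group energy per outcome
    const <- 0
    for (t in seq_along(gr$words)) {
      lw <- strsplit(gr$words[t], "", fixed = TRUE)[[1]]
      m <- 0L
      for (p in which(lw != "I")) m <- bitwOr(m, bitwShiftL(1L, p - 1L))
      c_t <- Re(gr$coeffs[t])
      if (m == 0L) const <- const + c_t
      else gvals <- gvals + c_t * (-1)^(.popcount(bitwAnd(outcomes, m)))
    }
    list(probs = probs, gvals = gvals, const = const)
  })
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  trial_means <- numeric(n_trials)
  shot_var <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    e <- 0; var_acc <- 0
    for (pg in prep) {
      counts <- as.vector(stats::rmultinom(1, shots_per_group, pg$probs))
      f <- counts / shots_per_group
      est <- sum(f * pg$gvals)
      e <- e + est + pg$const
      var_acc <- var_acc +
        max(sum(f * pg$gvals^2) - est^2, 0) / shots_per_group
    }
    trial_means[tr] <- e
    shot_var[tr] <- var_acc
  }
  grand <- mean(trial_means)
  stderr <- if (n_trials > 1) {
    stats::sd(trial_means) / sqrt(n_trials)
  } else {
    sqrt(shot_var[1])
  }
  list(mean = grand, stderr = stderr, trial_means = trial_means,
       shot_stderr = sqrt(shot_var))
}
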