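# Circuit synthesis for uCJ ansatz states and Trotterized comparators,
# with native two-qubit (CNOT) gate accounting.
#
# Gate kinds and their compiled CNOT / Rz-rotation costs:
#   prep_x(qubits)          X layer for the reference determinant; 0 CNOT
#   givens(p, theta, phi)   generalized fermionic rotation on adjacent
#                           qubits (p, p+1); 3 CNOT, 4 Rz-class rotations
#   nphase(q, angle)        e^{i angle n_q}; 0 CNOT, 1 rotation
#   nnphase(p, q, angle)    e^{i angle n_p n_q}; 2 CNOT, 1 rotation
#                           (the ZZ rotation; local phases merge into the
#                           neighbouring phase layer)
#   gphase(angle)           global phase; free
#   pauli_evol(word, angle) e^{i angle P} by a CNOT staircase;
#                           2(weight-1) CNOT, 1 rotation

#' Gate constructors
#'
#' @param qubits integer vector of 0-based qubit indices
#' @param p,q qubit indices
#' @param theta,phi,angle angles in radians
#' @param word Pauli word
#' @return a gate object (plain list with a `kind` tag)
#' @export
gate_prep_x <- function(qubits) list(kind = "prep_x", qubits = as.integer(qubits))

#' @rdname gate_prep_x
#' @export
gate_givens <- function(p, theta, phi = 0) {
  list(kind = "givens", qubits = c(as.integer(p), as.integer(p) + 1L),
       theta = theta, phi = phi)
}

#' @rdname gate_prep_x
#' @export
gate_nphase <- function(q, angle) {
  list(kind = "nphase", qubits = as.integer(q), angle = angle)
}

#' @rdname gate_prep_x
#' @export
gate_nnphase <- function(p, q, angle) {
  list(kind = "nnphase", qubits = c(as.integer(p), as.integer(q)), angle = angle)
}

#' @rdname gate_prep_x
#' @export
gate_gphase <- function(angle) list(kind = "gphase", qubits = integer(0), angle = angle)

#' @rdname gate_prep_x
#' @export
gate_pauli_evol <- function(word, angle) {
  list(kind = "pauli_evol", qubits = which(strsplit(word, "")[[1]] != "I") - 1L,
       word = word, angle = angle)
}

#' Quantum circuit container
#' @param n_qubits number of qubits
#' @param gates ordered list of gates (first gate acts first)
#' @param metadata free-form list
#' @export
qcircuit <- function(n_qubits, gates = list(), metadata = list()) {
  for (g in gates) {
    if (length(g$qubits) && (min(g$qubits) < 0 || max(g$qubits) >= n_qubits)) {
      stop("gate qubit index out of range")
    }
    if (g$kind == "givens" && diff(g$qubits) != 1L) {
      stop("givens gates must act on adjacent qubits")
    }
  }
  structure(list(n_qubits = as.integer(n_qubits), gates = gates,
                 metadata = metadata),
            class = "qcircuit")
}

#' @export
print.qcircuit <- function(x, ...) {
  cat(sprintf("<qcircuit> %d qubits, %d gates, %d CNOTs\n",
              x$n_qubits, length(x$gates), count_cnots(x)))
  invisible(x)
}

# gates implementing U(u) for one spin block: phase layer then inverted
# rotation sequence (the rotations that triangularize u, daggered, in
# reverse order)
.orbital_rotation_gates <- function(u, qubit_offset) {
  M <- nrow(u)
  dec <- complex_givens_decompose(u)
  gates <- list()
  for (p in seq_len(M)) {
    if (abs(dec$phases[p]) > 1e-14) {
      gates[[length(gates) + 1L]] <- gate_nphase(qubit_offset + p - 1L,
                                                 dec$phases[p])
    }
  }
  for (rot in rev(dec$rotations)) {
    gates[[length(gates) + 1L]] <-
      gate_givens(qubit_offset + rot$p - 1L, -rot$theta, rot$phi)
  }
  gates
}

#' Exact (Trotter-free) uCJ circuit
#'
#' Prepares the reference determinant with an X layer, then per replica
#' applies e^{-K} (adjacent Givens networks, one per spin block), the
#' commuting e^{J} phase factors, and e^{K}.  The circuit action equals the
#' dense operator product exp(K) exp(J) exp(-K) on the reference state.
#'
#' @param params a `ucj_params`
#' @param ref a `ref_det`
#' @param prune_rotations drop Givens rotations with |theta| below this
#'   (counting uses the un-pruned structural network; see
#'   [cnot_count_formula()])
#' @export
build_exact_ucj_circuit <- function(params, ref, prune_rotations = 0) {
  M <- params$M
  N <- 2L * M
  occ <- c(ref$occ_alpha - 1L, M + ref$occ_beta - 1L)
  gates <- list(gate_prep_x(occ))
  for (r in seq_len(params$k)) {
    rp <- params$replicas[[r]]
    for (sgn in c(-1, 1)) {
      blk_gates <- list()
      for (blk in 1:2) {
        K <- if (blk == 1) rp$K_alpha else rp$K_beta
        u <- k_to_unitary(sgn * K)
        blk_gates <- c(blk_gates,
                       .orbital_rotation_gates(u, if (blk == 1) 0L else M))
      }
      if (sgn < 0) {
        gates <- c(gates, blk_gates)
        # e^J between e^{-K} and e^{K}
        jt <- which(upper.tri(rp$J_real) & rp$J_real != 0, arr.ind = TRUE)
        for (i in seq_len(nrow(jt))) {
          p <- jt[i, 1] - 1L; q <- jt[i, 2] - 1L
          gates[[length(gates) + 1L]] <-
            gate_nnphase(p, q, 2 * rp$J_real[p + 1L, q + 1L])
        }
      } else {
        gates <- c(gates, blk_gates)
      }
    }
  }
  if (prune_rotations > 0) {
    gates <- Filter(function(g) {
      !(g$kind == "givens" && abs(g$theta) < prune_rotations)
    }, gates)
  }
  qcircuit(N, gates, metadata = list(variant = params$variant, M = M,
                                     k = params$k,
                                     n_alpha = length(ref$occ_alpha),
                                     n_beta = length(ref$occ_beta)))
}

#' CNOT count of a compiled circuit
#'
#' X preparations and single-qubit phases are free; each generalized Givens
#' rotation compiles to 3 CNOTs, each number-pair phase factor to 2 CNOTs,
#' and a weight-w Pauli evolution to a 2(w-1) CNOT staircase.
#'
#' @param circuit a `qcircuit`
#' @export
count_cnots <- function(circuit) {
  total <- 0L
  for (g in circuit$gates) {
    total <- total + switch(g$kind,
      givens = 3L,
      nnphase = 2L,
      pauli_evol = 2L * max(length(g$qubits) - 1L, 0L),
      0L)
  }
  total
}

#' Closed-form CNOT count of the exact k-fold uCJ circuit
#'
#' Each of e^{K} and e^{-K} costs 3 CNOTs per Givens rotation with
#' C(M,2) rotations per spin block; e^{J} costs 2 CNOTs per surviving
#' number-pair term.
#'
#' @param M number of spatial orbitals
#' @param n_alpha,n_beta electron counts (used for J-term screening)
#' @param k number of replicas
#' @param screen apply occupancy-based J screening
#' @export
cnot_count_formula <- function(M, n_alpha, n_beta, k = 1L, screen = TRUE) {
  njt <- nrow(enumerate_j_terms(M, n_alpha, n_beta, screen = screen))
  as.integer(k * (2L * 3L * 2L * rotation_count(M) + 2L * njt))
}

#' Count of Rz-class rotations in a circuit
#' @param circuit a `qcircuit`
#' @export
count_rotations <- function(circuit) {
  total <- 0L
  for (g in circuit$gates) {
    total <- total + switch(g$kind,
      givens = 4L,
      nnphase = 1L,
      nphase = 1L,
      pauli_evol = 1L,
      0L)
  }
  total
}

#' T-gate estimate for fault-tolerant synthesis of the rotations
#'
#' Every Rz-class rotation is synthesized to accuracy `eps_syn` with
#' 1.15 log2(1/eps_syn) + 9.2 T gates.
#'
#' @param circuit a `qcircuit`
#' @param eps_syn synthesis error in (0, 1]
#' @export
estimate_t_gates <- function(circuit, eps_syn) {
  if (eps_syn <= 0 || eps_syn > 1) stop("eps_syn must be in (0, 1]")
  count_rotations(circuit) * (1.15 * log2(1 / eps_syn) + 9.2)
}

#' Single-Trotter-step circuit of an anti-Hermitian Pauli-sum generator
#'
#' One Pauli evolution per surviving word after collection, in lexicographic
#' word order.  For mutually commuting generators (such as the Jastrow
#' correlator) the circuit equals the exact exponential.
#'
#' @param op an anti-Hermitian `pauli_sum` (i times a real combination)
#' @export
build_trotter_circuit <- function(op) {
  op <- ps_collect(op)
  if (!ps_is_antihermitian(op, tol = 1e-10)) {
    stop("Trotter generator must be anti-Hermitian")
  }
  gates <- list()
  for (i in order(op$words)) {
    ang <- Im(op$coeffs[i])
    if (all(strsplit(op$words[i], "")[[1]] == "I")) {
      gates[[length(gates) + 1L]] <- gate_gphase(ang)
    } else {
      gates[[length(gates) + 1L]] <- gate_pauli_evol(op$words[i], ang)
    }
  }
  qcircuit(op$n_qubits, gates)
}

#' UCCSD excitation generator (for structural gate counting)
#'
#' Builds the anti-Hermitian T - T^dagger over all spin-conserving single
#' and double excitations from the reference determinant, with placeholder
#' amplitudes, for Trotterized gate-count comparisons only.
#'
#' @param M number of spatial orbitals
#' @param ref a `ref_det`
#' @param amplitude scalar placeholder amplitude for every excitation
#' @export
uccsd_generator <- function(M, ref, amplitude = 0.01) {
  N <- 2L * M
  occ <- c(ref$occ_alpha - 1L, M + ref$occ_beta - 1L)
  vir <- setdiff(0:(N - 1L), occ)
  same_spin <- function(p, q) (p < M) == (q < M)
  terms <- list(pauli_sum(strrep("I", N), 0i, N, collect = FALSE))
  for (i in occ) for (a in vir) {
    if (!same_spin(i, a)) next
    terms[[length(terms) + 1L]] <- jw_hop(a, i, amplitude + 0i, N)
  }
  docc <- expand.grid(i = occ, j = occ)
  dvir <- expand.grid(a = vir, b = vir)
  docc <- docc[docc$i < docc$j, , drop = FALSE]
  dvir <- dvir[dvir$a < dvir$b, , drop = FALSE]
  for (r1 in seq_len(nrow(docc))) for (r2 in seq_len(nrow(dvir))) {
    i <- docc$i[r1]; j <- docc$j[r1]; a <- dvir$a[r2]; b <- dvir$b[r2]
    # conserve per-spin particle number
    na_change <- sum(c(a, b) < M) - sum(c(i, j) < M)
    if (na_change != 0) next
    N4 <- N
    ex <- pauli_multiply(
      pauli_multiply(jw_creation(a, N4), jw_creation(b, N4)),
      pauli_multiply(jw_annihilation(j, N4), jw_annihilation(i, N4)))
    terms[[length(terms) + 1L]] <-
      ps_add(ps_scale(ex, amplitude), ps_scale(ps_dagger(ex), -amplitude))
  }
  ps_collect(do.call(ps_add, terms))
}
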