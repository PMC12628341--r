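# Pauli-word algebra over n qubits.
#
# A Pauli sum is stored as a character vector of words over {I,X,Y,Z}
# (position p+1 of the string is the letter on qubit p) together with a
# complex coefficient vector.  Qubit 0 indexes the least significant bit of
# a computational-basis integer.

PAULI_LETTERS <- c("I", "X", "Y", "Z")

# single-qubit product tables: result letter and phase for a*b
.pauli_prod_letter <- matrix(c(
  "I", "X", "Y", "Z",
  "X", "I", "Z", "Y",
  "Y", "Z", "I", "X",
  "Z", "Y", "X", "I"), 4, 4, byrow = TRUE,
  dimnames = list(PAULI_LETTERS, PAULI_LETTERS))

.pauli_prod_phase <- matrix(c(
  1,   1,    1,    1,
  1,   1,    1i,  -1i,
  1,  -1i,   1,    1i,
  1,   1i,  -1i,   1), 4, 4, byrow = TRUE,
  dimnames = list(PAULI_LETTERS, PAULI_LETTERS))

#' Construct a Pauli sum
#'
#' @param words character vector of Pauli words, e.g. `c("IZ", "XX")`.
#' @param coeffs complex (or numeric) coefficient vector, recycled to
#'   `length(words)`.
#' @param n_qubits number of qubits; defaults to the word length.
#' @param collect collect duplicate words and drop zero coefficients.
#' @return an object of class `pauli_sum`.
#' @export
pauli_sum <- function(words = character(), coeffs = complex(0),
                      n_qubits = NULL, collect = TRUE) {
  words <- as.character(words)
  coeffs <- rep_len(as.complex(coeffs), length(words))
  if (is.null(n_qubits)) {
    n_qubits <- if (length(words)) nchar(words[[1]]) else 0L
  }
  if (length(words) && any(nchar(words) != n_qubits)) {
    stop("all Pauli words must have length n_qubits = ", n_qubits)
  }
  ps <- structure(list(words = words, coeffs = coeffs,
                       n_qubits = as.integer(n_qubits)),
                  class = "pauli_sum")
  if (collect) ps_collect(ps) else ps
}

#' @export
print.pauli_sum <- function(x, ...) {
  cat("<pauli_sum> ", length(x$words), " terms on ", x$n_qubits, " qubits\n",
      sep = "")
  n <- min(length(x$words), 12L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s  %s\n", x$words[i], format(x$coeffs[i], digits = 6)))
  }
  if (length(x$words) > n) cat("  ...\n")
  invisible(x)
}

#' Collect duplicate words and drop numerically zero terms
#' @param ps a `pauli_sum`
#' @param tol coefficients with modulus below `tol` are dropped
#' @export
ps_collect <- function(ps, tol = 1e-14) {
  if (!length(ps$words)) return(ps)
  agg <- rowsum(cbind(Re(ps$coeffs), Im(ps$coeffs)), group = ps$words)
  words <- rownames(agg)
  coeffs <- complex(real = agg[, 1], imaginary = agg[, 2])
  keep <- Mod(coeffs) > tol
  pauli_sum(words[keep], coeffs[keep], ps$n_qubits, collect = FALSE)
}

#' Add Pauli sums
#' @param ... `pauli_sum` objects on the same number of qubits
#' @export
ps_add <- function(...) {
  parts <- list(...)
  nq <- unique(vapply(parts, function(p) p$n_qubits, integer(1)))
  if (length(nq) != 1) stop("qubit counts differ")
  pauli_sum(unlist(lapply(parts, `[[`, "words")),
            unlist(lapply(parts, `[[`, "coeffs")), nq)
}

#' Scale a Pauli sum by a complex factor
#' @param ps a `pauli_sum`
#' @param z complex scalar
#' @export
ps_scale <- function(ps, z) {
  pauli_sum(ps$words, ps$coeffs * as.complex(z), ps$n_qubits, collect = FALSE)
}

#' Multiply two Pauli words
#'
#' @param w1,w2 Pauli words of equal length
#' @return list with elements `word` and `phase`
#' @export
pauli_word_multiply <- function(w1, w2) {
  if (nchar(w1) != nchar(w2)) stop("word length mismatch")
  a <- strsplit(w1, "", fixed = TRUE)[[1]]
  b <- strsplit(w2, "", fixed = TRUE)[[1]]
  idx <- cbind(match(a, PAULI_LETTERS), match(b, PAULI_LETTERS))
  list(word = paste(.pauli_prod_letter[idx], collapse = ""),
       phase = prod(.pauli_prod_phase[idx]))
}

#' Multiply two Pauli sums
#' @param a,b `pauli_sum` objects on the same qubits
#' @export
pauli_multiply <- function(a, b) {
  if (a$n_qubits != b$n_qubits) stop("qubit counts differ")
  if (!length(a$words) || !length(b$words)) {
    return(pauli_sum(character(), complex(0), a$n_qubits))
  }
  words <- character(length(a$words) * length(b$words))
  coeffs <- complex(length(words))
  k <- 0L
  for (i in seq_along(a$words)) {
    for (j in seq_along(b$words)) {
      k <- k + 1L
      pr <- pauli_word_multiply(a$words[i], b$words[j])
      words[k] <- pr$word
      coeffs[k] <- a$coeffs[i] * b$coeffs[j] * pr$phase
    }
  }
  pauli_sum(words, coeffs, a$n_qubits)
}

#' Hermitian conjugate of a Pauli sum
#' @param ps a `pauli_sum`
#' @export
ps_dagger <- function(ps) {
  pauli_sum(ps$words, Conj(ps$coeffs), ps$n_qubits, collect = FALSE)
}

#' Test Hermiticity / anti-Hermiticity of a Pauli sum
#' @param ps a `pauli_sum`
#' @param tol numeric tolerance
#' @export
ps_is_hermitian <- function(ps, tol = 1e-12) {
  all(abs(Im(ps_collect(ps)$coeffs)) < tol)
}

#' @rdname ps_is_hermitian
#' @export
ps_is_antihermitian <- function(ps, tol = 1e-12) {
  all(abs(Re(ps_collect(ps)$coeffs)) < tol)
}

# ---------------------------------------------------------------------------
# Jordan-Wigner images of ladder operators

.jw_ladder <- function(p, n_qubits, dagger) {
  if (p < 0 || p >= n_qubits) stop("index out of range")
  zs <- strrep("Z", p)
  rest <- strrep("I", n_qubits - p - 1L)
  wx <- paste0(zs, "X", rest)
  wy <- paste0(zs, "Y", rest)
  sgn <- if (dagger) -1i else 1i
  pauli_sum(c(wx, wy), c(0.5 + 0i, 0.5 * sgn), n_qubits, collect = FALSE)
}

#' Jordan-Wigner creation / annihilation operators
#'
#' Convention: qubit state |0> is unoccupied, the number operator maps to
#' (I - Z)/2, and the parity string acts on qubits 0..p-1.
#'
#' @param p spin-orbital (= qubit) index, 0-based
#' @param n_qubits total number of qubits
#' @export
jw_creation <- function(p, n_qubits) .jw_ladder(p, n_qubits, dagger = TRUE)

#' @rdname jw_creation
#' @export
jw_annihilation <- function(p, n_qubits) .jw_ladder(p, n_qubits, dagger = FALSE)

#' Jordan-Wigner number operator (I - Z_p)/2
#' @param p qubit index, 0-based
#' @param n_qubits total number of qubits
#' @export
jw_number_operator <- function(p, n_qubits) {
  if (p < 0 || p >= n_qubits) stop("index out of range")
  wi <- strrep("I", n_qubits)
  wz <- paste0(strrep("I", p), "Z", strrep("I", n_qubits - p - 1L))
  pauli_sum(c(wi, wz), c(0.5 + 0i, -0.5 + 0i), n_qubits, collect = FALSE)
}

#' Jordan-Wigner anti-Hermitian hopping generator
#'
#' Returns the qubit image of c a\eqn{^\dagger}_p a_q - c* a\eqn{^\dagger}_q a_p,
#' including the parity Z string between the two modes.
#'
#' @param p,q distinct spin-orbital indices (0-based)
#' @param c complex amplitude
#' @param n_qubits total number of qubits
#' @export
jw_hop <- function(p, q, c, n_qubits) {
  if (p == q) stop("p and q must differ")
  t1 <- pauli_multiply(jw_creation(p, n_qubits), jw_annihilation(q, n_qubits))
  t2 <- pauli_multiply(jw_creation(q, n_qubits), jw_annihilation(p, n_qubits))
  ps_add(ps_scale(t1, c), ps_scale(t2, -Conj(c)))
}

# ---------------------------------------------------------------------------
# Dense matrices (oracle scale, n <= ~12)

.pauli_1q <- list(
  I = diag(2) + 0i,
  X = matrix(c(0, 1, 1, 0), 2, 2) + 0i,
  Y = matrix(c(0, 1i, -1i, 0), 2, 2),
  Z = diag(c(1, -1)) + 0i)

#' Dense matrix of a Pauli word or Pauli sum
#'
#' Qubit 0 is the least significant bit of the basis index, so the word
#' "XI" (X on qubit 0) maps to I (x) X in Kronecker order.
#'
#' @param x a Pauli word (string) or a `pauli_sum`
#' @param n_qubits required when `x` is a word
#' @export
pauli_matrix <- function(x, n_qubits = NULL) {
  if (inherits(x, "pauli_sum")) {
    dim <- 2^x$n_qubits
    m <- matrix(0i, dim, dim)
    for (i in seq_along(x$words)) {
      m <- m + x$coeffs[i] * pauli_matrix(x$words[i], x$n_qubits)
    }
    return(m)
  }
  letters <- strsplit(x, "", fixed = TRUE)[[1]]
  m <- matrix(1 + 0i, 1, 1)
  for (l in letters) m <- .pauli_1q[[l]] %x% m  # qubit 0 least significant
  m
}

# ---------------------------------------------------------------------------
# Matrix-free action of Pauli words on basis integers

.popcount <- local({
  tab <- NULL
  function(x) {
    if (is.null(tab)) {
      t0 <- integer(65536L)
      for (b in 0:15) {
        hit <- bitwAnd(0:65535, bitwShiftL(1L, b)) > 0
        t0[hit] <- t0[hit] + 1L
      }
      tab <<- t0
    }
    tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
  }
})

#' Apply a Pauli word to computational-basis states
#'
#' @param word Pauli word
#' @param basis integer vector of basis indices (bit p = occupation of qubit p)
#' @return list with integer vector `basis` (image indices) and complex
#'   vector `phase` such that word|b> = phase |basis>
#' @export
pauli_word_apply <- function(word, basis) {
  letters <- strsplit(word, "", fixed = TRUE)[[1]]
  flip <- 0L; zmask <- 0L; ny <- 0L
  for (p in seq_along(letters)) {
    l <- letters[p]
    bit <- bitwShiftL(1L, p - 1L)
    if (l == "X" || l == "Y") flip <- bitwOr(flip, bit)
    if (l == "Z" || l == "Y") zmask <- bitwOr(zmask, bit)
    if (l == "Y") ny <- ny + 1L
  }
  phase <- (1i)^ny * (-1)^(.popcount(bitwAnd(basis, zmask)))
  list(basis = bitwXor(basis, flip), phase = phase)
}

# ---------------------------------------------------------------------------
# Qubit-wise commuting grouping

#' Partition a Pauli sum into qubit-wise commuting groups
#'
#' Greedy first-fit assignment in order of decreasing coefficient magnitude:
#' a term joins the first group in which, at every qubit, its letter agrees
#' with the group letter or one of the two is the identity.
#'
#' @param ps a collected `pauli_sum`
#' @return list of groups; each group is a list with `words`, `coeffs` and
#'   the group measurement `mask` (a word with the non-identity letters).
#' @export
qwc_group <- function(ps) {
  ps <- ps_collect(ps)
  ord <- order(-Mod(ps$coeffs))
  groups <- list()
  masks <- list()  # character vectors of per-qubit letters
  for (i in ord) {
    lw <- strsplit(ps$words[i], "", fixed = TRUE)[[1]]
    placed <- FALSE
    for (gi in seq_along(groups)) {
      m <- masks[[gi]]
      ok <- all(lw == "I" | m == "I" | lw == m)
      if (ok) {
        masks[[gi]] <- ifelse(m == "I", lw, m)
        groups[[gi]]$words <- c(groups[[gi]]$words, ps$words[i])
        groups[[gi]]$coeffs <- c(groups[[gi]]$coeffs, ps$coeffs[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      masks[[length(groups) + 1L]] <- ifelse(lw == "I", "I", lw)
      groups[[length(groups) + 1L]] <-
        list(words = ps$words[i], coeffs = ps$coeffs[i])
    }
  }
  for (gi in seq_along(groups)) {
    groups[[gi]]$mask <- paste(masks[[gi]], collapse = "")
    groups[[gi]]$n_qubits <- ps$n_qubits
  }
  groups
}
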