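# Active-space integrals and FCIDUMP interchange (Molpro-style dialect).

#' Active-space integrals container
#'
#' Holds the core (frozen + nuclear) energy, the one-body matrix and the
#' two-body tensor in chemists' notation (pq|rs) over M spatial orbitals,
#' together with the electron counts of the target sector.  All energies are
#' in hartree.
#'
#' @param core_energy scalar core energy
#' @param one_body M x M Hermitian matrix
#' @param two_body M x M x M x M tensor with full 8-fold permutation symmetry
#' @param n_alpha,n_beta electron counts
#' @param validate check invariants (Hermiticity, 8-fold symmetry)
#' @return object of class `asints`
#' @export
active_space_integrals <- function(core_energy, one_body, two_body,
                                   n_alpha, n_beta, validate = TRUE) {
  M <- nrow(one_body)
  obj <- structure(list(core_energy = as.numeric(core_energy),
                        one_body = one_body,
                        two_body = two_body,
                        n_spatial = as.integer(M),
                        n_alpha = as.integer(n_alpha),
                        n_beta = as.integer(n_beta)),
                   class = "asints")
  if (validate) validate_integrals(obj)
  obj
}

#' @export
print.asints <- function(x, ...) {
  cat(sprintf("<asints> M = %d spatial orbitals, (%d alpha, %d beta) electrons, core = %.8f\n",
              x$n_spatial, x$n_alpha, x$n_beta, x$core_energy))
  invisible(x)
}

#' Validate active-space integral invariants
#' @param ints an `asints` object
#' @param tol numeric tolerance
#' @export
validate_integrals <- function(ints, tol = 1e-12) {
  h <- ints$one_body
  if (max(abs(h - Conj(t(h)))) > tol) stop("one_body is not Hermitian")
  g <- ints$two_body
  M <- ints$n_spatial
  perms <- list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  for (pm in perms) {
    if (max(abs(g - aperm(g, pm))) > tol) {
      stop("two_body violates 8-fold permutation symmetry")
    }
  }
  if (ints$n_alpha + ints$n_beta > 2L * M) stop("too many electrons")
  invisible(TRUE)
}

#' Symmetrize a two-body tensor to full 8-fold permutation symmetry
#' @param g M^4 tensor
#' @export
symmetrize_two_body <- function(g) {
  perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  out <- 0
  for (pm in perms) out <- out + aperm(g, pm)
  out / 8
}

#' Synthetic reproducible active-space integrals
#'
#' Generates pseudo-random integrals satisfying all container invariants:
#' a real symmetric one-body matrix with a spread diagonal (so the mean-field
#' determinant is generically non-degenerate) plus weaker symmetric two-body
#' couplings.
#'
#' @param M number of spatial orbitals
#' @param n_alpha,n_beta electron counts
#' @param seed integer seed
#' @param two_body_scale magnitude of the two-electron couplings
#' @export
make_synthetic_integrals <- function(M, n_alpha = 1L, n_beta = 1L, seed = 1L,
                                     two_body_scale = 0.2) {
  stopifnot(M >= 1)
  rs <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    h <- matrix(stats::rnorm(M * M, sd = 0.15), M, M)
    h <- (h + t(h)) / 2
    diag(h) <- seq(-1, 1, length.out = M) + stats::rnorm(M, sd = 0.05) - 1
    g <- array(stats::rnorm(M^4, sd = two_body_scale), rep(M, 4))
    list(h = h, g = symmetrize_two_body(g), core = stats::rnorm(1, sd = 0.5))
  })
  active_space_integrals(rs$core, rs$h, rs$g, n_alpha, n_beta)
}

# ---------------------------------------------------------------------------
# FCIDUMP (Molpro namelist dialect, 1-based indices, real orbitals)

#' Read an FCIDUMP file
#'
#' Expects a Molpro-style namelist header declaring NORB, NELEC and MS2,
#' followed by `value i j k l` records: two-electron entries (ij|kl) in
#' chemists' notation, one-electron entries with k = l = 0, and the core
#' energy with all indices 0.  Stored unique entries are expanded to the
#' full 8-fold symmetric tensor.
#'
#' @param path file path
#' @return an `asints` object
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr_end <- grep("&END|/\\s*$|^\\s*/", lines)[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP header: no &END terminator")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  getkey <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), hdr))
    if (!length(m)) stop("malformed FCIDUMP header: missing ", key)
    as.integer(sub(paste0(key, "\\s*=\\s*"), "", m))
  }
  norb <- getkey("NORB")
  nelec <- getkey("NELEC")
  ms2 <- getkey("MS2")
  n_alpha <- (nelec + ms2) %/% 2L
  n_beta <- nelec - n_alpha

  h <- matrix(0, norb, norb)
  g <- array(0, rep(norb, 4))
  core <- 0
  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  for (ln in body) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    val <- as.numeric(tok[1])
    ij <- as.integer(tok[2:5])
    if (any(ij < 0 | ij > norb)) stop("FCIDUMP index out of range: ", ln)
    i <- ij[1]; j <- ij[2]; k <- ij[3]; l <- ij[4]
    if (i == 0 && j == 0 && k == 0 && l == 0) {
      core <- val
    } else if (k == 0 && l == 0) {
      h[i, j] <- val; h[j, i] <- val
    } else {
      for (idx in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                       c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                       c(k, l, j, i), c(l, k, j, i))) {
        g[idx[1], idx[2], idx[3], idx[4]] <- val
      }
    }
  }
  active_space_integrals(core, h, g, n_alpha, n_beta)
}

#' Write an FCIDUMP file
#'
#' Only the canonical unique entries (i >= j, k >= l, (ij) >= (kl)) of the
#' two-body tensor are stored.
#'
#' @param ints an `asints` object
#' @param path output file path
#' @param tol entries with modulus below `tol` are omitted
#' @export
write_fcidump <- function(ints, path, tol = 1e-14) {
  M <- ints$n_spatial
  nelec <- ints$n_alpha + ints$n_beta
  ms2 <- ints$n_alpha - ints$n_beta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", M, nelec, ms2), con)
  writeLines(sprintf("  ORBSYM=%s", paste(rep("1,", M), collapse = "")), con)
  writeLines("  ISYM=1,", con)
  writeLines(" &END", con)
  fmt <- function(v, i, j, k, l) sprintf(" %23.16E %3d %3d %3d %3d", v, i, j, k, l)
  out <- character()
  for (i in 1:M) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      v <- ints$two_body[i, j, k, l]
      if (abs(v) > tol) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in 1:M) for (j in 1:i) {
    v <- Re(ints$one_body[i, j])
    if (abs(v) > tol) out <- c(out, fmt(v, i, j, 0, 0))
  }
  out <- c(out, fmt(ints$core_energy, 0, 0, 0, 0))
  writeLines(out, con)
  invisible(path)
}
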