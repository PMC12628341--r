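# Reproducible benchmark workflows: gate-count tables, energy scans and
# fixture generation.  These functions are the programmatic backend of the
# command-line workbench in inst/cli/.

#' Benchmark system catalogue for gate counting
#'
#' The active-space shapes (spatial orbitals and electron counts) of the
#' benchmark molecules; gate counts depend only on these.
#'
#' @return data.frame with columns `system`, `n_elec`, `n_qubit`, `M`,
#'   `n_alpha`, `n_beta`
#' @export
benchmark_catalogue <- function() {
  df <- data.frame(
    system = c("H2 (STO-3G)", "Be2 (STO-3G, (2e,2o))", "C2H6 (STO-3G, (2e,2o))",
               "H3+ (STO-3G)", "H2 (6-31G)", "H4 (STO-3G)",
               "C2H4 (STO-3G, (4e,4o))", "C6H6 (STO-3G, (4e,4o))",
               "H2 (6-311G)"),
    M = c(2L, 2L, 2L, 3L, 4L, 4L, 4L, 4L, 6L),
    n_alpha = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 1L),
    n_beta = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 1L))
  df$n_elec <- df$n_alpha + df$n_beta
  df$n_qubit <- 2L * df$M
  df[, c("system", "n_elec", "n_qubit", "M", "n_alpha", "n_beta")]
}

#' Exact-circuit CNOT count table
#'
#' Builds, for every catalogue row and uCJ variant, the exact k=1 circuit
#' with generic (seeded random) parameters and counts CNOTs, alongside the
#' closed-form count.
#'
#' @param catalogue data.frame as from [benchmark_catalogue()]
#' @param seed seed for the generic circuit parameters
#' @return data.frame with per-variant CNOT counts and the formula count
#' @export
cmd_counts <- function(catalogue = benchmark_catalogue(), seed = 1L) {
  rows <- NULL
  for (i in seq_len(nrow(catalogue))) {
    M <- catalogue$M[i]
    na <- catalogue$n_alpha[i]; nb <- catalogue$n_beta[i]
    jt <- enumerate_j_terms(M, na, nb, screen = TRUE)
    ref <- reference_determinant(seq_len(na), seq_len(nb))
    counts <- vapply(UCJ_VARIANTS, function(v) {
      prm <- random_ucj_params(v, M, jt, sd = 0.3, seed = seed)
      count_cnots(build_exact_ucj_circuit(prm, ref))
    }, integer(1))
    rows <- rbind(rows, data.frame(
      system = catalogue$system[i], n_elec = catalogue$n_elec[i],
      n_qubit = catalogue$n_qubit[i],
      cnot_g = counts[["g"]], cnot_re = counts[["re"]],
      cnot_im = counts[["im"]],
      cnot_formula = cnot_count_formula(M, na, nb)))
  }
  rows
}

#' Assemble a variational system for a hydrogen-cluster benchmark
#'
#' Runs the RHF backend, transforms the integrals and builds the
#' [ucj_system()] context.
#'
#' @param coords_ang geometry matrix (angstrom)
#' @param basis hydrogen basis set
#' @param charge total charge
#' @param homo_orientation see [hydrogen_reference()]
#' @return a [ucj_system()] context with extra fields `e_rhf` and `backend`
#' @export
hydrogen_ucj_system <- function(coords_ang, basis = "sto-3g", charge = 0,
                                homo_orientation = "aufbau") {
  hr <- hydrogen_reference(coords_ang, basis, charge, homo_orientation)
  sys <- ucj_system(hr$ints)
  sys$e_rhf <- hr$e_rhf
  sys$backend <- hr
  sys
}

#' Bond scan for H2
#'
#' Continuation scan (association or dissociation) over a distance grid.
#'
#' @param distances bond lengths in angstrom, any order; they are sorted
#'   ascending for "dissociation" and descending for "association"
#' @param basis hydrogen basis set
#' @param variant uCJ variant tag
#' @param direction "dissociation" or "association"
#' @param seed integer seed
#' @param ... passed to [continuation_scan()]
#' @export
cmd_scan <- function(distances, basis = "sto-3g", variant = "g",
                     direction = c("dissociation", "association"),
                     seed = 1L, ...) {
  direction <- match.arg(direction)
  distances <- sort(distances, decreasing = direction == "association")
  systems <- lapply(distances, function(r) {
    hydrogen_ucj_system(h2_geometry(r), basis)
  })
  sc <- continuation_scan(systems, distances, variant, seed = seed, ...)
  sc$table$branch <- direction
  sc
}

#' Write FCIDUMP fixtures
#'
#' Writes synthetic fixtures and (for hydrogen clusters) RHF-basis
#' benchmark FCIDUMPs to a directory.
#'
#' @param dir output directory
#' @param seed seed for the synthetic instances
#' @return invisible character vector of written paths
#' @export
cmd_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (M in 2:3) {
    ints <- make_synthetic_integrals(M, 1L, 1L, seed = seed + M)
    p <- file.path(dir, sprintf("synthetic_M%d.fcidump", M))
    write_fcidump(ints, p)
    paths <- c(paths, p)
  }
  for (r in c(0.7, 1.2, 1.7)) {
    hr <- hydrogen_reference(h2_geometry(r), "sto-3g")
    p <- file.path(dir, sprintf("h2_sto3g_r%0.2f.fcidump", r))
    write_fcidump(hr$ints, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
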