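# Classical variational optimization of uCJ parameters: multi-start local
# minimization with central-difference gradients, staged perfect-pairing
# warm starts for larger active spaces, continuation scans along bond
# coordinates, and shot-noise (derivative-free) optimization.

#' Fraction of correlation energy recovered
#'
#' 100 (E_ref - E) / (E_ref - E_exact), the percentage of the mean-field to
#' exact energy gap recovered by an intermediate energy E.
#'
#' @param E energy to score (hartree)
#' @param E_ref mean-field reference energy
#' @param E_exact exact (FCI/CASCI) energy
#' @export
correlation_fraction <- function(E, E_ref, E_exact) {
  denom <- E_ref - E_exact
  if (abs(denom) < 1e-12) stop("degenerate correlation denominator")
  100 * (E_ref - E) / denom
}

.central_gradient <- function(fn, x, step = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + step
    xm[i] <- xm[i] - step
    g[i] <- (fn(xp) - fn(xm)) / (2 * step)
  }
  g
}

# one local minimization; counts evaluations and records the history of
# accepted (monotone best-so-far) energies
.local_minimize <- function(fn, x0, maxit = 400, reltol = 1e-11,
                            grad_step = 1e-6) {
  n_evals <- 0L
  best <- Inf
  history <- numeric(0)
  wrapped <- function(x) {
    n_evals <<- n_evals + 1L
    e <- fn(x)
    if (e < best) {
      best <<- e
      history <<- c(history, e)
    }
    e
  }
  res <- stats::optim(x0, wrapped,
                      gr = function(x) .central_gradient(wrapped, x, grad_step),
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  list(x = res$par, value = res$value, converged = res$convergence == 0L,
       n_evals = n_evals, history = history)
}

#' Variational optimization of a uCJ ansatz
#'
#' Multi-start BFGS with central-difference gradients on the exact
#' (noiseless) energy.  The first start is the zero vector (or `init` when
#' given); the remaining starts add seeded normal perturbations of scale
#' `perturb_sd`.  The minimum-energy solution is returned.
#'
#' @param system a [ucj_system()] context
#' @param variant uCJ variant tag ("re", "im", "g")
#' @param init optional initial packed parameter vector (continuation)
#' @param k number of replicas
#' @param n_starts number of starts (>= 1)
#' @param seed integer seed for the perturbations
#' @param perturb_sd normal scale of the start perturbations
#' @param maxit,reltol,grad_step optimizer controls
#' @return a `vqe_result` list: `energy`, `x` (packed parameters), `params`
#'   (a `ucj_params`), `converged`, `n_evals`, `history`, `seed`
#' @export
ucj_optimize <- function(system, variant, init = NULL, k = 1L, n_starts = 8L,
                         seed = 1L, perturb_sd = 0.1, maxit = 400,
                         reltol = 1e-11, grad_step = 1e-6) {
  variant <- match.arg(variant, UCJ_VARIANTS)
  nprm <- n_ucj_params(variant, system$M, system$jterms, k)
  base <- if (is.null(init)) numeric(nprm) else init
  if (length(base) != nprm) stop("init has the wrong length")
  fn <- function(x) ucj_energy(x, system, variant, k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  starts <- list(base)
  if (n_starts > 1) {
    for (s in 2:n_starts) {
      starts[[s]] <- base + stats::rnorm(nprm, sd = perturb_sd)
    }
  }
  best <- NULL
  total_evals <- 0L
  for (x0 in starts) {
    r <- .local_minimize(fn, x0, maxit = maxit, reltol = reltol,
                         grad_step = grad_step)
    total_evals <- total_evals + r$n_evals
    if (is.null(best) || r$value < best$value) best <- r
  }
  structure(list(energy = best$value, x = best$x,
                 params = ucj_unpack(best$x, variant, system$M,
                                     system$jterms, k),
                 converged = best$converged, n_evals = total_evals,
                 history = best$history, seed = seed, variant = variant),
            class = "vqe_result")
}

#' @export
print.vqe_result <- function(x, ...) {
  cat(sprintf("<vqe_result> %s-uCJ  E = %.9f hartree  (%d evaluations%s)\n",
              x$variant, x$energy, x$n_evals,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

# free-parameter mask for a stage: K pairs in `kpairs_free` (list of sorted
# spatial index pairs), J terms whose two spatial orbitals are both inside
# one of the allowed groups
.stage_mask <- function(system, variant, k, allowed_orbs, kpairs_free = NULL) {
  M <- system$M
  pairs <- .k_pairs(M)
  per <- if (variant == "g") 2L else 1L
  jt <- system$jterms
  mask <- logical(0)
  for (r in seq_len(k)) {
    for (blk in 1:2) {
      for (i in seq_len(nrow(pairs))) {
        ok <- if (is.null(kpairs_free)) {
          pairs[i, 1] %in% allowed_orbs && pairs[i, 2] %in% allowed_orbs
        } else {
          any(vapply(kpairs_free, function(pp) all(pairs[i, ] == pp), logical(1)))
        }
        mask <- c(mask, rep(ok, per))
      }
    }
    spat <- function(q) (q %% M) + 1L
    for (t in seq_len(nrow(jt))) {
      ps <- spat(jt$p[t]); qs <- spat(jt$q[t])
      ok <- if (is.null(kpairs_free)) {
        ps %in% allowed_orbs && qs %in% allowed_orbs
      } else {
        ps == qs || any(vapply(kpairs_free,
                               function(pp) all(sort(c(ps, qs)) == pp) ||
                                 (ps == qs && ps %in% pp), logical(1)))
      }
      mask <- c(mask, ok)
    }
  }
  mask
}

#' Staged perfect-pairing warm start
#'
#' Stage 1 optimizes only the parameters coupling each occupied orbital to
#' its antibonding partner (default pairing: occupied i with virtual
#' 2 n_occ + 1 - i).  Subsequent stages gradually extend the freed orbital
#' connectivity one orbital at a time until fully connected, each stage
#' warm-started from the previous optimum with small seeded perturbations
#' for the newly freed coordinates.
#'
#' @param system a [ucj_system()] context
#' @param variant uCJ variant tag
#' @param k number of replicas
#' @param pairing named integer vector mapping occupied to virtual spatial
#'   orbitals (1-based); default is the standard bonding/antibonding map
#' @param n_restarts repetitions of the whole staged pipeline with
#'   different seeds; the minimum-energy result is returned
#' @param seed master seed
#' @param new_param_sd perturbation scale for newly freed coordinates
#' @param maxit,reltol,grad_step optimizer controls
#' @return a `vqe_result` with an extra `stage_energies` field (of the best
#'   restart); stage energies are monotone non-increasing
#' @export
perfect_pairing_warmstart <- function(system, variant, k = 1L, pairing = NULL,
                                      n_restarts = 3L, seed = 1L,
                                      new_param_sd = 0.1, maxit = 400,
                                      reltol = 1e-11, grad_step = 1e-6) {
  variant <- match.arg(variant, UCJ_VARIANTS)
  M <- system$M
  n_occ <- max(system$n_alpha, system$n_beta)
  if (M < 2 || n_occ < 1) stop("perfect pairing needs M >= 2 and electrons")
  if (is.null(pairing)) {
    virts <- pmin(2L * n_occ + 1L - seq_len(n_occ), M)
    pairing <- stats::setNames(virts, seq_len(n_occ))
  }
  pp_pairs <- lapply(seq_along(pairing), function(i) {
    sort(c(as.integer(names(pairing)[i]), pairing[[i]]))
  })
  pp_orbs <- sort(unique(unlist(pp_pairs)))
  stage_masks <- list(.stage_mask(system, variant, k, NULL, pp_pairs))
  if (length(pp_orbs) < M) {
    grow <- pp_orbs
    for (m in setdiff(seq_len(M), pp_orbs)) {
      grow <- sort(c(grow, m))
      stage_masks[[length(stage_masks) + 1L]] <-
        .stage_mask(system, variant, k, grow)
    }
  } else {
    stage_masks[[2]] <- rep(TRUE, n_ucj_params(variant, M, system$jterms, k))
  }
  nprm <- n_ucj_params(variant, M, system$jterms, k)
  fn <- function(x) ucj_energy(x, system, variant, k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  restart_seeds <- sample.int(2^30, n_restarts)
  best <- NULL
  total_evals <- 0L
  for (rs in restart_seeds) {
    set.seed(rs)
    x <- numeric(nprm)
    inited <- logical(nprm)
    stage_e <- numeric(0)
    r <- NULL
    for (mask in stage_masks) {
      newly <- mask & !inited
      x[newly] <- stats::rnorm(sum(newly), sd = new_param_sd)
      inited <- inited | mask
      obj <- function(xf) {
        xx <- x
        xx[mask] <- xf
        fn(xx)
      }
      r <- .local_minimize(obj, x[mask], maxit = maxit, reltol = reltol,
                           grad_step = grad_step)
      x[mask] <- r$x
      stage_e <- c(stage_e, r$value)
      total_evals <- total_evals + r$n_evals
    }
    if (is.null(best) || r$value < best$value) {
      best <- list(value = r$value, x = x, converged = r$converged,
                   stage_energies = stage_e, history = r$history)
    }
  }
  structure(list(energy = best$value, x = best$x,
                 params = ucj_unpack(best$x, variant, system$M,
                                     system$jterms, k),
                 converged = best$converged, n_evals = total_evals,
                 history = best$history, seed = seed, variant = variant,
                 stage_energies = best$stage_energies),
            class = "vqe_result")
}

#' Continuation scan along a bond coordinate
#'
#' Optimizes a list of systems in order, warm-starting every point from the
#' previous optimum (the association/dissociation protocol, depending on
#' whether the supplied distances decrease or increase).
#'
#' @param systems list of [ucj_system()] contexts, ordered along the scan
#' @param distances numeric vector of scan coordinates (must be strictly
#'   monotone), same length as `systems`
#' @param variant uCJ variant tag
#' @param k number of replicas
#' @param n_starts starts for the first point (subsequent points use the
#'   warm start plus one perturbed start)
#' @param seed integer seed
#' @param ... further arguments passed to [ucj_optimize()]
#' @return list with `table` (data.frame: distance, energy, e_exact, error,
#'   corr_percent) and `results` (list of `vqe_result`)
#' @export
continuation_scan <- function(systems, distances, variant, k = 1L,
                              n_starts = 8L, seed = 1L, ...) {
  stopifnot(length(systems) == length(distances))
  if (length(distances) > 1 && !(all(diff(distances) > 0) ||
                                 all(diff(distances) < 0))) {
    stop("scan distances must be strictly monotone")
  }
  results <- list()
  init <- NULL
  rows <- NULL
  for (i in seq_along(systems)) {
    sys <- systems[[i]]
    res <- ucj_optimize(sys, variant, init = init, k = k,
                        n_starts = if (i == 1) n_starts else 2L,
                        seed = seed + i - 1L, ...)
    results[[i]] <- res
    eg <- exact_ground_state(sys$H, sys$n_alpha, sys$n_beta)
    e_ref <- reference_energy(sys$ints, sys$ref)
    rows <- rbind(rows, data.frame(
      distance = distances[i], variant = variant, energy = res$energy,
      e_exact = eg$energy, e_ref = e_ref, error = res$energy - eg$energy,
      corr_percent = correlation_fraction(res$energy, e_ref, eg$energy)))
    init <- res$x
  }
  list(table = rows, results = results)
}

# Powell-style direction-set minimization with a three-point parabolic
# line search.  The wide-bracket parabola fit averages the shot noise over
# the step, which keeps line minimizations informative where simplex
# methods collapse; the step is annealed down to `s_min` and the direction
# set is periodically reset.
.powell_minimize <- function(fn, x0, n_sweeps = 100L, step0 = 0.4,
                             shrink = 0.85, s_min = 0.12, reset_every = 12L) {
  n <- length(x0)
  x <- x0
  dirs <- diag(n)
  s <- step0
  fx <- fn(x)
  for (sw in seq_len(n_sweeps)) {
    if (sw %% reset_every == 0L) dirs <- diag(n)
    x_start <- x
    for (di in seq_len(n)) {
      d <- dirs[, di]
      tm <- c(-s, 0, s)
      fm <- c(fn(x - s * d), fx, fn(x + s * d))
      rep_c <- 0L
      while (which.min(fm) != 2L && rep_c < 5L) {
        if (which.min(fm) == 1L) {
          tm <- c(tm[1] - 2 * s, tm[1:2])
          fm <- c(fn(x + tm[1] * d), fm[1:2])
        } else {
          tm <- c(tm[2:3], tm[3] + 2 * s)
          fm <- c(fm[2:3], fn(x + tm[3] * d))
        }
        rep_c <- rep_c + 1L
      }
      denom <- (tm[1] - tm[2]) * (tm[1] - tm[3]) * (tm[2] - tm[3])
      A <- (tm[3] * (fm[2] - fm[1]) + tm[2] * (fm[1] - fm[3]) +
              tm[1] * (fm[3] - fm[2])) / denom
      B <- (tm[3]^2 * (fm[1] - fm[2]) + tm[2]^2 * (fm[3] - fm[1]) +
              tm[1]^2 * (fm[2] - fm[3])) / denom
      tstar <- if (A > 1e-12) -B / (2 * A) else tm[which.min(fm)]
      tstar <- max(min(tstar, max(tm)), min(tm))
      fstar <- fn(x + tstar * d)
      if (fstar <= min(fm)) {
        x <- x + tstar * d
        fx <- fstar
      } else {
        x <- x + tm[which.min(fm)] * d
        fx <- min(fm)
      }
    }
    dnew <- x - x_start
    nrm <- sqrt(sum(dnew^2))
    if (nrm > 1e-10) dirs <- cbind(dirs[, -1, drop = FALSE], dnew / nrm)
    s <- max(s * shrink, s_min)
  }
  list(par = x, value = fx)
}

#' Shot-noise uCJ optimization (derivative-free)
#'
#' Optimizes the sampled energy with a Powell-style direction-set search
#' (parabolic line minimizations over wide brackets, which tolerate the
#' shot noise), every energy evaluation drawing fresh multinomial shots
#' over the qubit-wise-commuting groups.  Several seeded random starts are
#' run; the candidate with the best averaged sampled score is selected and
#' re-evaluated over independent trials.
#'
#' @param system a [ucj_system()] context
#' @param variant uCJ variant tag
#' @param shots_per_group shots per QWC group per energy evaluation
#' @param n_trials independent evaluation trials of the final parameters
#' @param seed master seed
#' @param n_starts random starts (normal scale `start_sd`; the optimizer
#'   cannot leave the zero saddle of the mean-field point, so starts are
#'   drawn away from it)
#' @param start_sd scale of the random starts
#' @param n_sweeps Powell sweeps per start
#' @param score_evals sampled evaluations averaged to rank the starts
#' @param k number of replicas
#' @return list with `mean`, `stderr` (standard error of the trial mean),
#'   `trial_means`, `x` (selected parameters), `n_evals`
#' @export
ucj_optimize_sampled <- function(system, variant, shots_per_group = 10000L,
                                 n_trials = 20L, seed = 1L, n_starts = 6L,
                                 start_sd = 0.3, n_sweeps = 150L,
                                 score_evals = 10L, k = 1L) {
  variant <- match.arg(variant, UCJ_VARIANTS)
  nprm <- n_ucj_params(variant, system$M, system$jterms, k)
  groups <- qwc_group(system$H)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  n_evals <- 0L
  eval_seed <- sample.int(2^30, 1L)
  noisy_fn <- function(x) {
    n_evals <<- n_evals + 1L
    st <- ucj_state(x, system, variant, k)
    sampled_expectation(system$H, st, shots_per_group = shots_per_group,
                        n_trials = 1L, seed = eval_seed + n_evals,
                        groups = groups)$mean
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    x0 <- stats::rnorm(nprm, sd = start_sd)
    res <- .powell_minimize(noisy_fn, x0, n_sweeps = n_sweeps)
    score <- mean(vapply(seq_len(score_evals),
                         function(i) noisy_fn(res$par), numeric(1)))
    if (is.null(best) || score < best$score) {
      best <- list(par = res$par, score = score)
    }
  }
  st <- ucj_state(best$par, system, variant, k)
  fin <- sampled_expectation(system$H, st, shots_per_group = shots_per_group,
                             n_trials = n_trials,
                             seed = eval_seed + n_evals + 1L, groups = groups)
  list(mean = fin$mean, stderr = fin$stderr, trial_means = fin$trial_means,
       x = best$par, n_evals = n_evals)
}
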