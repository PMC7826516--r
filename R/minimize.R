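#' Minimizer configuration
#'
#' Fletcher-Reeves conjugate gradients with Armijo backtracking.  The stopping
#' rule is the study's: RMS Cartesian gradient over the free atoms below
#' `rms_gradient_tol` (default 0.1 kcal/(mol A)).
#'
#' @param rms_gradient_tol convergence threshold, kcal/(mol A).
#' @param max_iterations iteration cap.
#' @param initial_step initial line-search step, A per unit gradient.
#' @param backtrack step-shrink factor of the backtracking line search.
#' @param c_armijo sufficient-decrease constant.
#' @param restart_every reset the search direction to steepest descent every
#'   this many iterations (`NULL`: every 3 x free-coordinate count).
#' @param max_step cap on the largest single-atom displacement per step, A.
#' @return a `MinimizerConfig` list.
#' @export
minimizer_config <- function(rms_gradient_tol = 0.1, max_iterations = 500L,
                             initial_step = 0.01, backtrack = 0.5,
                             c_armijo = 1e-4, restart_every = NULL,
                             max_step = 0.5) {
  stopifnot(rms_gradient_tol > 0, max_iterations >= 1L, initial_step > 0,
            backtrack > 0, backtrack < 1, c_armijo > 0, max_step > 0)
  out <- list(rms_gradient_tol = rms_gradient_tol,
              max_iterations = as.integer(max_iterations),
              initial_step = initial_step, backtrack = backtrack,
              c_armijo = c_armijo, restart_every = restart_every,
              max_step = max_step)
  class(out) <- "MinimizerConfig"
  out
}

#' RMS gradient over free atoms
#'
#' Square root of the mean squared Cartesian gradient component, free atoms
#' only; the relaxation stopping criterion.
#'
#' @param forces n x 3 matrix of forces (or gradients; only magnitudes enter).
#' @param free_mask logical vector; `TRUE` marks free atoms.
#' @return kcal/(mol A).
#' @export
rms_gradient <- function(forces, free_mask = rep(TRUE, nrow(forces))) {
  if (!any(free_mask)) stop("all atoms are frozen; RMS gradient undefined")
  g <- forces[free_mask, , drop = FALSE]
  sqrt(mean(g^2))
}

#' Relax a structure by Fletcher-Reeves conjugate gradients
#'
#' Direction update beta = |g_new|^2 / |g_old|^2, restricted to free atoms
#' (frozen atoms never move; their input coordinates are preserved exactly).
#' An Armijo backtracking line search guarantees that the energy trace over
#' accepted iterations is non-increasing.  The direction is reset to steepest
#' descent on restart intervals and whenever it is not a descent direction.
#'
#' @param s a `Structure`; its `frozen` flags are honored.
#' @param params an `FFParams` object.
#' @param config a [minimizer_config()].
#' @param topo optional precomputed [ff_topology()] (avoids re-deriving it).
#' @param verbose print per-iteration progress?
#' @return a `MinimizationResult`: `structure`, `energy`, `iterations`,
#'   `rms_gradient`, `converged`, `trace` (accepted-step energies).
#' @export
minimize <- function(s, params = default_ffparams(),
                     config = minimizer_config(), topo = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(s, "Structure"))
  if (is.null(topo)) topo <- ff_topology(s, params)
  free <- !s$frozen
  if (!any(free)) stop("all atoms are frozen; nothing to minimize")
  x <- s$positions
  nfree3 <- 3L * sum(free)
  restart_every <- if (is.null(config$restart_every)) nfree3 else
    as.integer(config$restart_every)
  ev <- ff_eval(topo, x, gradient = TRUE)
  if (!is.finite(ev$total)) stop("non-finite energy at start of minimization")
  g <- ev$gradient
  g[!free, ] <- 0
  e <- ev$total
  trace <- e
  gg <- sum(g * g)
  d <- -g
  iters <- 0L
  rms <- sqrt(gg / nfree3)
  alpha_prev <- config$initial_step
  while (rms > config$rms_gradient_tol && iters < config$max_iterations) {
    iters <- iters + 1L
    gd <- sum(g * d)
    if (gd >= 0 || iters %% restart_every == 0L) {  # not a descent direction
      d <- -g
      gd <- -gg
    }
    dmax <- max(abs(d))
    # warm-started trial step: grow from the last accepted step, capped so no
    # atom moves more than max_step in one trial
    alpha <- min(2 * alpha_prev, config$max_step / dmax)
    accepted <- FALSE
    for (bt in 1:40) {
      xn <- x
      xn[free, ] <- x[free, ] + alpha * d[free, ]
      en <- ff_eval(topo, xn, gradient = FALSE)$total
      if (is.finite(en) && en <= e + config$c_armijo * alpha * gd) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * config$backtrack
    }
    if (!accepted) {
      if (all(d == -g)) break          # line search failed along steepest descent
      d <- -g                          # retry once along steepest descent
      next
    }
    alpha_prev <- alpha
    x <- xn
    ev <- ff_eval(topo, x, gradient = TRUE)
    gn <- ev$gradient
    gn[!free, ] <- 0
    e <- ev$total
    trace <- c(trace, e)
    ggn <- sum(gn * gn)
    beta <- ggn / max(gg, 1e-300)
    d <- -gn + beta * d
    g <- gn
    gg <- ggn
    rms <- sqrt(gg / nfree3)
    if (verbose)
      message(sprintf("  iter %4d  E = %.6f  RMS grad = %.5f", iters, e, rms))
  }
  s$positions <- x
  out <- list(structure = s, energy = e, iterations = iters,
              rms_gradient = rms, converged = rms <= config$rms_gradient_tol,
              trace = trace)
  class(out) <- "MinimizationResult"
  out
}

#' @export
print.MinimizationResult <- function(x, ...) {
  cat(sprintf("MinimizationResult: E = %.4f kcal/mol after %d iterations (RMS grad %.4g, %s)\n",
              x$energy, x$iterations, x$rms_gradient,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
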