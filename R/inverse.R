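# Inverse design: relocate an azeotrope to a prescribed composition by
# tuning the bond energy of selected patch pairs.

#' Set the bond energy of selected patch pairs
#'
#' @param design A [mixture_design()].
#' @param pairs List of length-2 integer vectors of global patch types (a
#'   self-complementary patch is `c(a, a)`). Each pair must already be a
#'   bonding edge of the design.
#' @param eps New bond energy (> 0) applied to every pair.
#' @return The modified design.
#' @export
set_bond_energy <- function(design, pairs, eps) {
  stopifnot(eps > 0)
  em <- design$energy_matrix
  for (p in pairs) {
    p <- as.integer(p)
    if (length(p) != 2L || any(p < 1L) || any(p > design$n_types))
      stop("each pair must be two valid patch types", call. = FALSE)
    if (em[p[1], p[2]] == 0)
      stop(sprintf("patch pair %d-%d is not a bonding edge of the design",
                   p[1], p[2]), call. = FALSE)
    em[p[1], p[2]] <- em[p[2], p[1]] <- eps
  }
  mixture_design(design$species, em, design$kf)
}

#' Self-complementary bonding pairs of a design
#'
#' @param design A [mixture_design()].
#' @return List of `c(a, a)` pairs (diagonal bonding edges).
#' @export
self_complementary_pairs <- function(design) {
  dg <- which(diag(design$energy_matrix) > 0)
  lapply(dg, function(a) c(a, a))
}

#' Shift an azeotrope to a target composition by tuning bond energies
#'
#' Iteratively adjusts a single scalar bond energy `eps'` applied to the
#' `tunable_pairs` until the azeotropic composition at temperature `T`
#' reaches `target_x`. Each iteration re-solves the full azeotrope location
#' (pressure bisection until the vapor-liquid composition gap collapses, see
#' [find_azeotrope()]) for the perturbed design and updates `eps'` by a
#' secant step on `x_azeo(eps')`; the first perturbation is `+0.1`.
#'
#' @param design A binary [mixture_design()] with a known azeotrope at `T`.
#' @param target_x Desired azeotropic molar fraction of species 1 (in (0, 1)).
#' @param T Temperature at which the azeotrope is tracked (the azeotropic
#'   line spans a range of temperatures; the design loop holds `T` fixed).
#' @param tunable_pairs Patch pairs carrying the tunable energy; defaults to
#'   all self-complementary pairs of species 1.
#' @param start Optional [find_azeotrope()] result for the starting design
#'   (recomputed if omitted).
#' @param tol Composition tolerance for convergence.
#' @param max_iter Maximum number of energy updates.
#' @param step0 Initial perturbation of `eps'`.
#' @param ghs Pair-correlation treatment, see [compute_delta()].
#' @return An object of class `design_trace`: list with `iterations` (a
#'   data.frame of `eps_prime`, `T_azeo`, `P_azeo`, `x_azeo`), `converged`,
#'   `target_x`, and `design` (the final tuned design).
#' @export
shift_azeotrope <- function(design, target_x, T, tunable_pairs = NULL,
                            start = NULL, tol = 0.01, max_iter = 12,
                            step0 = 0.1, ghs = "shell") {
  stopifnot(target_x > 0, target_x < 1)
  if (is.null(tunable_pairs)) {
    sc <- self_complementary_pairs(design)
    own1 <- vapply(sc, function(p) design$owner[p[1]] == 1L, TRUE)
    tunable_pairs <- sc[own1]
    if (length(tunable_pairs) == 0L) tunable_pairs <- sc
  }
  if (length(tunable_pairs) == 0L)
    stop("no tunable pairs given and the design has no self-complementary pairs",
         call. = FALSE)
  e0 <- unique(vapply(tunable_pairs, function(p)
    design$energy_matrix[p[1], p[2]], 0))
  if (length(e0) != 1L)
    stop("tunable pairs must share one bond energy", call. = FALSE)

  if (is.null(start)) start <- find_azeotrope(design, T, ghs = ghs)
  it <- data.frame(eps_prime = e0, T_azeo = start$T, P_azeo = start$P,
                   x_azeo = start$x_azeo)
  if (abs(start$x_azeo - target_x) < tol) {
    return(structure(list(iterations = it, converged = TRUE,
                          target_x = target_x, design = design),
                     class = "design_trace"))
  }

  eps_cur <- e0
  x_cur <- start$x_azeo
  # first perturbation: step toward the target
  eps_new <- e0 + sign(target_x - x_cur) * step0 * sign(step0)
  eps_prev <- eps_cur; x_prev <- x_cur
  converged <- FALSE
  final_design <- design
  for (k in seq_len(max_iter)) {
    if (eps_new <= 0.05) eps_new <- 0.05
    d_new <- set_bond_energy(design, tunable_pairs, eps_new)
    az <- find_azeotrope(d_new, T, ghs = ghs)
    it <- rbind(it, data.frame(eps_prime = eps_new, T_azeo = az$T,
                               P_azeo = az$P, x_azeo = az$x_azeo))
    final_design <- d_new
    if (abs(az$x_azeo - target_x) < tol) { converged <- TRUE; break }
    # secant update on x_azeo(eps')
    dx <- az$x_azeo - x_prev
    de <- eps_new - eps_prev
    eps_prev <- eps_new; x_prev_old <- x_prev; x_prev <- az$x_azeo
    if (abs(dx) < 1e-12) {
      eps_new <- eps_new + sign(target_x - az$x_azeo) * step0
    } else {
      eps_next <- eps_new + (target_x - az$x_azeo) * de / dx
      # guard wild extrapolation
      if (!is.finite(eps_next) || abs(eps_next - eps_new) > 0.5)
        eps_next <- eps_new + 0.5 * sign(eps_next - eps_new)
      eps_new <- eps_next
    }
  }
  if (!converged)
    warning(sprintf("shift_azeotrope did not reach |x - %.3g| < %.3g in %d iterations",
                    target_x, tol, max_iter))
  structure(list(iterations = it, converged = converged, target_x = target_x,
                 design = final_design),
            class = "design_trace")
}

#' @export
print.design_trace <- function(x, ...) {
  cat(sprintf("Azeotrope-shifting trace (target x = %g, %s)\n", x$target_x,
              if (x$converged) "converged" else "NOT converged"))
  print(x$iterations, row.names = FALSE)
  invisible(x)
}
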