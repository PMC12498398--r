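# Two-branch Gibbs free-energy construction, common-tangent coexistence and
# azeotrope location for binary mixtures.

# Vectorized density roots of P(rho; x) = P at fixed T. `xmat` has one
# composition row per requested point. Returns a list of vectors (NA where a
# branch does not exist): rho_vapor (lowest root), rho_liquid (highest root),
# and n_roots. Middle roots of a van der Waals loop are mechanically unstable
# and discarded.
branch_roots <- function(design, T, P, xmat, ghs = "shell",
                         phi_max = 0.58, n_grid = 140) {
  Vs <- v_sphere(design$kf$sigma)
  rg <- exp(seq(log(1e-12), log(phi_max / Vs), length.out = n_grid))
  nx <- nrow(xmat)
  rho_all <- rep(rg, times = nx)
  x_all <- xmat[rep(seq_len(nx), each = n_grid), , drop = FALSE]
  Pm <- matrix(wz_eval(design, T, rho_all, x_all, ghs)$P, nrow = n_grid)
  s <- sign(Pm - P)
  lo <- hi <- xi <- c()
  which_root <- c()   # 1 = vapor, 2 = liquid
  n_roots <- integer(nx)
  for (j in seq_len(nx)) {
    idx <- which(diff(s[, j]) != 0 & s[-1, j] != 0)
    n_roots[j] <- length(idx)
    if (length(idx) == 0L) next
    pick <- unique(c(idx[1], idx[length(idx)]))
    for (k in seq_along(pick)) {
      lo <- c(lo, rg[pick[k]]); hi <- c(hi, rg[pick[k] + 1]); xi <- c(xi, j)
      which_root <- c(which_root, if (length(pick) == 1L) 1L else k)
    }
  }
  rho_v <- rho_l <- rep(NA_real_, nx)
  if (length(lo)) {
    s_lo <- sign(matrix(wz_eval(design, T, lo, xmat[xi, , drop = FALSE],
                                ghs)$P, ncol = 1) - P)
    for (k in 1:48) {
      mid <- sqrt(lo * hi)
      Ps <- wz_eval(design, T, mid, xmat[xi, , drop = FALSE], ghs)$P
      left <- sign(Ps - P) == s_lo
      lo[left] <- mid[left]
      hi[!left] <- mid[!left]
    }
    root <- sqrt(lo * hi)
    for (k in seq_along(root)) {
      if (which_root[k] == 1L) rho_v[xi[k]] <- root[k] else rho_l[xi[k]] <- root[k]
    }
  }
  list(rho_vapor = rho_v, rho_liquid = rho_l, n_roots = n_roots)
}

# Branch thermodynamics on a composition grid: g and chemical potentials on
# the vapor and liquid branches, plus their difference d = g_v - g_l.
branch_grid <- function(design, T, P, xs, ghs = "shell") {
  xmat <- cbind(xs, 1 - xs)
  br <- branch_roots(design, T, P, xmat, ghs)
  ev <- function(rho) {
    ok <- !is.na(rho)
    out <- list(g = rep(NA_real_, length(xs)),
                mu = matrix(NA_real_, length(xs), 2))
    if (any(ok)) {
      e <- wz_eval(design, T, rho[ok], xmat[ok, , drop = FALSE], ghs)
      out$g[ok] <- e$g
      out$mu[ok, ] <- e$mu
    }
    out
  }
  v <- ev(br$rho_vapor); l <- ev(br$rho_liquid)
  list(x = xs, rho_vapor = br$rho_vapor, rho_liquid = br$rho_liquid,
       g_vapor = v$g, g_liquid = l$g, mu_vapor = v$mu, mu_liquid = l$mu,
       d = v$g - l$g)
}

#' Two-branch Gibbs free-energy curve
#'
#' For each composition on `x_grid`, finds all density roots of
#' `P(rho; x, T) = P`, assigns the lowest-density root to the vapor branch and
#' the highest to the liquid branch (discarding mechanically unstable middle
#' roots), and evaluates the Gibbs free energy per particle
#' `g = f + P/rho` (in k_B T) on each branch. Where the pressure equation has
#' a single root the two branches coincide (single fluid phase).
#'
#' @param design A binary [mixture_design()].
#' @param T Temperature.
#' @param P Pressure (`beta * P`, reduced units).
#' @param x_grid Compositions of species 1 (default 101 points in (0, 1)).
#' @param ghs Pair-correlation treatment, see [compute_delta()].
#' @return An object of class `gibbs_curve` with the grid, per-branch
#'   densities and `g` values, and per-branch chemical potentials.
#' @export
gibbs_curve <- function(design, T, P, x_grid = seq(0.005, 0.995, length.out = 101),
                        ghs = "shell") {
  if (length(design$species) != 2L)
    stop("gibbs_curve requires a binary design", call. = FALSE)
  bg <- branch_grid(design, T, P, x_grid, ghs)
  if (all(is.na(bg$rho_vapor)) && all(is.na(bg$rho_liquid)))
    stop(sprintf("no density root of P(rho) = %g found at T = %g for any x",
                 P, T), call. = FALSE)
  two <- !is.na(bg$d)
  structure(c(bg, list(T = T, P = P, ghs = ghs, two_phase_window = two)),
            class = "gibbs_curve")
}

#' @export
print.gibbs_curve <- function(x, ...) {
  cat(sprintf("Gibbs free-energy curve at T = %g, P = %g\n", x$T, x$P))
  nb <- sum(!is.na(x$d))
  cat(sprintf("  %d grid points, %d with two branches\n", length(x$x), nb))
  invisible(x)
}

#' @export
plot.gibbs_curve <- function(x, ...) {
  rng <- range(c(x$g_vapor, x$g_liquid), na.rm = TRUE)
  graphics::plot(x$x, x$g_vapor, type = "l", col = "red3", ylim = rng,
                 xlab = "x (species 1)", ylab = "g / kT",
                 main = sprintf("T = %g, P = %g", x$T, x$P), ...)
  graphics::lines(x$x, x$g_liquid, col = "blue3")
  graphics::legend("topright", c("vapor", "liquid"), lty = 1,
                   col = c("red3", "blue3"), bty = "n")
  invisible(x)
}

# scalar branch evaluation used by the Newton iterations
branch_point <- function(design, T, P, x1, branch, ghs = "shell") {
  bg <- branch_grid(design, T, P, x1, ghs)
  rho <- if (branch == "vapor") bg$rho_vapor else bg$rho_liquid
  mu <- if (branch == "vapor") bg$mu_vapor else bg$mu_liquid
  g <- if (branch == "vapor") bg$g_vapor else bg$g_liquid
  list(rho = rho[1], mu = mu[1, ], g = g[1])
}

# lower convex hull common-tangent estimate on a grid (fallback seeding)
hull_tangent <- function(xs, gmin, label) {
  ok <- which(!is.na(gmin))
  if (length(ok) < 3) return(NULL)
  pts_x <- xs[ok]; pts_g <- gmin[ok]; pts_lab <- label[ok]
  hull <- c(1L)
  for (i in 2:length(pts_x)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      cross <- (pts_x[b] - pts_x[a]) * (pts_g[i] - pts_g[a]) -
               (pts_g[b] - pts_g[a]) * (pts_x[i] - pts_x[a])
      if (cross < 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  # tangent segment = hull edge whose endpoints lie on different branches
  for (k in seq_len(length(hull) - 1)) {
    a <- hull[k]; b <- hull[k + 1]
    if (pts_lab[a] != pts_lab[b])
      return(list(x_vapor = if (pts_lab[a] == "vapor") pts_x[a] else pts_x[b],
                  x_liquid = if (pts_lab[a] == "liquid") pts_x[a] else pts_x[b]))
  }
  NULL
}

#' Coexistence point by common tangent
#'
#' Locates the compositions of coexisting vapor and liquid phases at fixed
#' `(T, P)`: a 2x2 Newton iteration on `(x_vapor, x_liquid)` drives the
#' chemical-potential differences of both species across the branches to
#' zero (the common-tangent condition), seeded from the crossing of the two
#' Gibbs free-energy branches; when the Newton iteration stalls, a
#' convex-hull common-tangent construction on a fine grid supplies the
#' result.
#'
#' @inheritParams gibbs_curve
#' @param x_near Preferred region: when the two-phase region splits into
#'   several lobes, the crossing closest to `x_near` is solved.
#' @param tol Convergence tolerance on the chemical-potential residuals.
#' @return An object of class `coexistence_point`: list with `T`, `P`,
#'   `x_vapor`, `x_liquid`, `rho_vapor`, `rho_liquid`, `mu_residual`.
#' @export
coexistence <- function(design, T, P, x_near = 0.5, ghs = "shell",
                        tol = 1e-9) {
  xs <- seq(0.005, 0.995, length.out = 201)
  bg <- branch_grid(design, T, P, xs, ghs)
  d <- bg$d
  cross <- which(diff(sign(d)) != 0 & !is.na(d[-1]) & !is.na(d[-length(d)]))
  if (length(cross) == 0L)
    stop(sprintf("no two-phase coexistence found at T = %g, P = %g", T, P),
         call. = FALSE)
  ic <- cross[which.min(abs(xs[cross] - x_near))]
  # vapor phase lives where d < 0
  h <- xs[2] - xs[1]
  if (d[ic] < 0) { xv <- xs[ic] - h; xl <- xs[ic + 1] + h }
  else { xv <- xs[ic + 1] + h; xl <- xs[ic] - h }
  xv <- min(max(xv, 1e-4), 1 - 1e-4); xl <- min(max(xl, 1e-4), 1 - 1e-4)

  resfun <- function(p) {
    v <- branch_point(design, T, P, p[1], "vapor", ghs)
    l <- branch_point(design, T, P, p[2], "liquid", ghs)
    if (is.na(v$rho) || is.na(l$rho)) return(NULL)
    list(r = v$mu - l$mu, v = v, l = l)
  }
  p <- c(xv, xl)
  ok <- FALSE
  for (it in 1:40) {
    f0 <- resfun(p)
    if (is.null(f0)) break
    if (max(abs(f0$r)) < tol) { ok <- TRUE; break }
    J <- matrix(0, 2, 2)
    hstep <- 1e-6
    for (j in 1:2) {
      ph <- p; ph[j] <- ph[j] + hstep
      fh <- resfun(ph)
      if (is.null(fh)) { J <- NULL; break }
      J[, j] <- (fh$r - f0$r) / hstep
    }
    if (is.null(J) || any(!is.finite(J))) break
    step <- tryCatch(solve(J, f0$r), error = function(e) NULL)
    if (is.null(step)) break
    # damp: stay inside (0,1) and limit step length
    lim <- 0.1
    step <- pmin(pmax(step, -lim), lim)
    pn <- p - step
    pn <- pmin(pmax(pn, 1e-4), 1 - 1e-4)
    if (max(abs(pn - p)) < 1e-14) { f0 <- resfun(p); ok <- max(abs(f0$r)) < 1e-6; break }
    p <- pn
  }
  if (!ok) {
    # convex-hull fallback on a fine grid
    gmin <- pmin(bg$g_vapor, bg$g_liquid, na.rm = TRUE)
    lab <- ifelse(!is.na(bg$d) & bg$d > 0, "liquid",
                  ifelse(!is.na(bg$d), "vapor",
                         ifelse(is.na(bg$g_liquid), "vapor", "liquid")))
    ht <- hull_tangent(xs, gmin, lab)
    if (is.null(ht))
      stop(sprintf("coexistence solver failed at T = %g, P = %g", T, P),
           call. = FALSE)
    p <- c(ht$x_vapor, ht$x_liquid)
    f0 <- resfun(p)
  }
  v <- f0$v; l <- f0$l
  structure(list(T = T, P = P, x_vapor = p[1], x_liquid = p[2],
                 rho_vapor = v$rho, rho_liquid = l$rho,
                 mu_residual = max(abs(f0$r))),
            class = "coexistence_point")
}

#' @export
print.coexistence_point <- function(x, ...) {
  cat(sprintf(paste0("Coexistence at T = %g, P = %g\n",
                     "  vapor:  x = %.6f, rho = %.6g\n",
                     "  liquid: x = %.6f, rho = %.6g\n",
                     "  |mu residual| = %.2e\n"),
              x$T, x$P, x$x_vapor, x$rho_vapor, x$x_liquid, x$rho_liquid,
              x$mu_residual))
  invisible(x)
}

# classify the phase structure at (T, P): "none" (no two-branch window),
# "vapor"/"liquid" (one phase globally stable), or "two" (branch crossing).
# Returns the crossings of d(x) refined locally so that near-collapsed pairs
# are resolved well below the global grid spacing.
phase_classify <- function(design, T, P, xlim, ghs, n = 81) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  bg <- branch_grid(design, T, P, xs, ghs)
  d <- bg$d
  ok <- which(!is.na(d))
  if (length(ok) < 2) return(list(class = "none", crossings = numeric()))
  cr <- ok[which(diff(sign(d[ok])) != 0 &
                 diff(ok) == 1L)]  # sign changes between adjacent valid pts
  if (length(cr) == 0L) {
    cls <- if (all(d[ok] < 0)) "vapor" else if (all(d[ok] > 0)) "liquid" else "none"
    return(list(class = cls, crossings = numeric(),
                dmax = max(d[ok]), dmin = min(d[ok]),
                x_at_dmax = xs[ok][which.max(d[ok])],
                x_at_dmin = xs[ok][which.min(d[ok])]))
  }
  # crossing positions by linear interpolation of d
  crx <- vapply(cr, function(i)
    xs[i] - d[i] * (xs[i + 1] - xs[i]) / (d[i + 1] - d[i]), 0)
  list(class = "two", crossings = crx, spacing = xs[2] - xs[1],
       dmax = max(d[ok]), dmin = min(d[ok]),
       x_at_dmax = xs[ok][which.max(d[ok])], x_at_dmin = xs[ok][which.min(d[ok])])
}

# re-measure a close pair of branch crossings on a zoomed-in grid
zoom_pair <- function(design, T, P, pair, pad, ghs, n = 81) {
  lo <- max(pair[1] - pad, 1e-4); hi <- min(pair[2] + pad, 1 - 1e-4)
  xs <- seq(lo, hi, length.out = n)
  d <- branch_grid(design, T, P, xs, ghs)$d
  ok <- which(!is.na(d))
  if (length(ok) < 2) return(NULL)
  cr <- ok[which(diff(sign(d[ok])) != 0 & diff(ok) == 1L)]
  if (length(cr) < 2) return(NULL)
  vapply(cr, function(i)
    xs[i] - d[i] * (xs[i + 1] - xs[i]) / (d[i + 1] - d[i]), 0)
}

#' Locate an azeotrope at fixed temperature
#'
#' Scans pressure (geometrically) for the two-phase band at temperature `T`,
#' then bisects in `ln P` toward the band edge at which the vapor-liquid
#' coexistence gap collapses at an interior composition: the azeotropic
#' point, where the two Gibbs free-energy branches become tangent at a single
#' concentration. The bisection terminates once the residual composition gap
#' between the bracketing branch crossings falls below `tol`.
#'
#' @inheritParams gibbs_curve
#' @param P_range Pressure range scanned for the two-phase band.
#' @param xlim Interior composition window searched.
#' @param tol Detection tolerance on the residual coexistence gap.
#' @param n_scan Number of points of the initial geometric pressure scan.
#' @return An object of class `azeotrope_point`: list with `T`, `P`,
#'   `x_azeo` and `width_at_detection` (residual gap).
#' @export
find_azeotrope <- function(design, T, P_range = c(1e-8, 0.2),
                           xlim = c(0.02, 0.98), tol = 1e-3, n_scan = 25,
                           ghs = "shell") {
  if (length(design$species) != 2L)
    stop("find_azeotrope requires a binary design", call. = FALSE)
  Ps <- exp(seq(log(P_range[1]), log(P_range[2]), length.out = n_scan))
  cls <- character(n_scan)
  info <- vector("list", n_scan)
  for (i in seq_len(n_scan)) {
    info[[i]] <- phase_classify(design, T, Ps[i], xlim, ghs)
    cls[i] <- info[[i]]$class
  }
  two <- which(cls == "two")
  if (length(two) == 0L)
    stop(sprintf("no two-phase region found at T = %g in the scanned pressure range", T),
         call. = FALSE)
  # candidate band edges: transitions between "two" and a single-phase class
  cands <- list()
  for (i in two) {
    for (j in c(i - 1L, i + 1L)) {
      if (j >= 1 && j <= n_scan && cls[j] %in% c("vapor", "liquid"))
        cands[[length(cands) + 1L]] <- list(P_two = Ps[i], P_one = Ps[j],
                                            one_class = cls[j])
    }
  }
  if (length(cands) == 0L)
    stop("two-phase band does not close within the scanned pressure range; widen `P_range`",
         call. = FALSE)

  min_diff_pair <- function(pc) {
    cr <- sort(pc$crossings)
    if (length(cr) < 2) return(NULL)
    prs <- which.min(diff(cr))
    cr[c(prs, prs + 1)]
  }

  # Bisect in ln P between a two-phase and a single-phase pressure, shrinking
  # the classification window onto the collapsing crossing pair so that the
  # composition resolution always tracks the residual gap.
  bisect_edge <- function(cand) {
    P_two <- cand$P_two; P_one <- cand$P_one
    win <- xlim
    last <- phase_classify(design, T, P_two, win, ghs)
    pair <- min_diff_pair(last)
    for (k in 1:70) {
      gap <- if (!is.null(pair)) diff(pair) else Inf
      if (gap < tol) break
      if (!is.null(pair) && is.finite(gap)) {
        # zoom the window once the pair is well inside it
        w_new <- c(max(xlim[1], pair[1] - 6 * gap), min(xlim[2], pair[2] + 6 * gap))
        if (diff(w_new) < diff(win)) win <- w_new
      }
      Pm <- exp((log(P_two) + log(P_one)) / 2)
      pc <- phase_classify(design, T, Pm, win, ghs)
      if (pc$class == "two") {
        P_two <- Pm
        pm <- min_diff_pair(pc)
        if (!is.null(pm)) { last <- pc; pair <- pm }
      } else P_one <- Pm
      if (abs(log(P_two) - log(P_one)) < 5e-14) break
    }
    if (!is.null(pair)) {
      list(P = P_two, x = mean(pair), width = diff(pair),
           interior = mean(pair) > xlim[1] + 0.01 && mean(pair) < xlim[2] - 0.01)
    } else {
      list(P = P_two, x = NA_real_, width = Inf, interior = FALSE)
    }
  }

  results <- lapply(cands, bisect_edge)
  good <- Filter(function(r) r$interior && r$width < tol, results)
  if (length(good) == 0L)
    stop(sprintf("no azeotrope bracketed at T = %g: coexistence gap does not collapse at an interior composition", T),
         call. = FALSE)
  best <- good[[which.min(vapply(good, `[[`, 0, "width"))]]
  structure(list(T = T, P = best$P, x_azeo = best$x,
                 width_at_detection = best$width),
            class = "azeotrope_point")
}

#' Vapor-liquid binodal point at fixed composition
#'
#' Solves the equal-pressure, equal-Gibbs-energy condition between the vapor
#' and liquid branches of the equation of state at a fixed composition
#' (Maxwell construction in density). For azeotropic states this gives the
#' coexistence densities directly; off-azeotrope it is the pseudo-binodal of
#' the composition-constrained system.
#'
#' @inheritParams gibbs_curve
#' @param x Molar fraction of species 1.
#' @param P_range Pressure bracket scanned for the transition.
#' @return List with `T`, `x`, `P`, `rho_vapor`, `rho_liquid`.
#' @export
binodal_point <- function(design, T, x, P_range = c(1e-10, 0.5),
                          ghs = "shell") {
  ns <- length(design$species)
  xm <- if (ns == 1L) matrix(1, 1, 1) else matrix(c(x, 1 - x), nrow = 1)
  dfun <- function(P) {
    br <- branch_roots(design, T, P, xm, ghs)
    if (is.na(br$rho_vapor[1]) || is.na(br$rho_liquid[1])) return(NULL)
    e <- wz_eval(design, T, c(br$rho_vapor[1], br$rho_liquid[1]),
                 rbind(xm, xm), ghs)
    list(d = e$g[1] - e$g[2], rv = br$rho_vapor[1], rl = br$rho_liquid[1])
  }
  # scan for a sign change of g_v - g_l over the pressure range
  Ps <- exp(seq(log(P_range[1]), log(P_range[2]), length.out = 41))
  vals <- lapply(Ps, dfun)
  okI <- which(!vapply(vals, is.null, TRUE))
  if (length(okI) < 2)
    stop(sprintf("no two-branch region found at T = %g, x = %g", T, x),
         call. = FALSE)
  ds <- vapply(vals[okI], `[[`, 0, "d")
  sc <- which(diff(sign(ds)) != 0)
  if (length(sc) == 0L)
    stop(sprintf("no vapor-liquid transition bracketed at T = %g, x = %g", T, x),
         call. = FALSE)
  lo <- Ps[okI[sc[1]]]; hi <- Ps[okI[sc[1] + 1]]; slo <- sign(ds[sc[1]])
  best <- NULL
  for (k in 1:60) {
    mid <- sqrt(lo * hi)
    vm <- dfun(mid)
    if (is.null(vm)) break
    best <- vm
    if (sign(vm$d) == slo) lo <- mid else hi <- mid
    if (abs(vm$d) < 1e-12) break
  }
  P <- sqrt(lo * hi)
  list(T = T, x = x, P = P, rho_vapor = best$rv, rho_liquid = best$rl)
}

#' @export
print.azeotrope_point <- function(x, ...) {
  cat(sprintf("Azeotrope at T = %g: x_azeo = %.4f (P = %.6g, residual gap %.2g)\n",
              x$T, x$x_azeo, x$P, x$width_at_detection))
  invisible(x)
}
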