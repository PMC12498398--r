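# Hard-sphere pair correlation treatments for the bond-strength integral
# Delta = (1/Vs) * Int g_HS(r) (e^{beta eps} - 1) dr over the bonding shell.
#
# Three treatments are supported:
#   "unit"    g_HS = 1 (low-density form)
#   "contact" g_HS = Carnahan-Starling contact value, constant over the shell
#   "shell"   full Percus-Yevick g_HS(r) integrated across the shell (default)

#' Percus-Yevick hard-sphere pair correlation, first shell
#'
#' Analytic (Wertheim-Thiele) solution of the Percus-Yevick equation for
#' hard spheres, valid on the first coordination shell `sigma <= r < 2 sigma`
#' (distances in units of the diameter).
#'
#' @param r Distances in units of the hard-sphere diameter (`1 <= r < 2`).
#' @param eta Packing fraction.
#' @return `g(r)` values.
#' @export
py_g_hs <- function(r, eta) {
  if (eta < 1e-8) return(rep(1, length(r)))
  # S(t) = (1-eta)^2 t^3 + 6 eta (1-eta) t^2 + 18 eta^2 t - 12 eta (1+2 eta)
  troots <- polyroot(c(-12 * eta * (1 + 2 * eta), 18 * eta^2,
                       6 * eta * (1 - eta), (1 - eta)^2))
  L <- 12 * eta * ((1 + eta / 2) * troots + (1 + 2 * eta))
  Sp <- 3 * (1 - eta)^2 * troots^2 + 12 * eta * (1 - eta) * troots + 18 * eta^2
  vapply(r, function(ri) {
    Re(sum(troots * L * exp(troots * (ri - 1)) / Sp)) / (12 * eta * ri)
  }, 0)
}

# Shell-averaged correlation factor: Int_sigma^{sigma+delta} g(r) r^2 dr
# normalized by the same integral with g = 1, so the factor is 1 at eta = 0.
shell_g_factor <- function(phi, sigma, delta) {
  lo <- 1; hi <- (sigma + delta) / sigma
  norm <- (hi^3 - lo^3) / 3
  vapply(phi, function(p) {
    if (p < 1e-8) return(1)
    stats::integrate(function(r) py_g_hs(r, p) * r^2, lo, hi,
                     rel.tol = 1e-10)$value / norm
  }, 0)
}

.ghs_cache <- new.env(parent = emptyenv())

# Polynomial fit (ascending coefficients) of ln(shell factor) vs phi on
# [0, 0.6]; used by the C++ equation of state so that the density derivative
# of the bond strength stays analytic.
shell_poly_coefs <- function(sigma, delta, degree = 10) {
  key <- sprintf("%.12g_%.12g_%d", sigma, delta, degree)
  if (!is.null(.ghs_cache[[key]])) return(.ghs_cache[[key]])
  phis <- seq(0, 0.6, length.out = 121)
  y <- log(shell_g_factor(phis, sigma, delta))
  X <- outer(phis, seq_len(degree), `^`)
  fit <- stats::lm.fit(X, y)   # no intercept: ln factor = 0 at phi = 0
  cf <- c(0, fit$coefficients)
  .ghs_cache[[key]] <- cf
  cf
}

ghs_mode_code <- function(ghs) {
  switch(ghs, unit = 0L, contact = 1L, shell = 2L,
         stop("`ghs` must be one of \"shell\", \"contact\", \"unit\"",
              call. = FALSE))
}
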