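# Monte Carlo simulation surface: configurations, schedules, and the
# NVT / NPT / Gibbs-ensemble / grand-canonical drivers.

# design in the flat form consumed by the C++ engine
design_clist <- function(design) {
  pv <- do.call(rbind, lapply(design$species, `[[`, "patch_vectors"))
  cnt <- vapply(design$species, function(s) length(s$patch_type_ids), 0L)
  off <- cumsum(c(0L, cnt))[seq_along(cnt)]
  ptype <- unlist(lapply(design$species, `[[`, "patch_type_ids")) - 1L
  list(eps = design$energy_matrix, patch_count = as.integer(cnt),
       patch_offset = as.integer(off), patch_type = as.integer(ptype),
       patch_vectors = pv, sigma = design$kf$sigma, delta = design$kf$delta,
       cos_theta_max = design$kf$cos_theta_max)
}

#' Kern-Frenkel pair energy
#'
#' Energy of one particle pair: `+Inf` on hard-core overlap
#' (`r < sigma`), minus the bond energy summed over patch pairs whose cones
#' mutually contain the center-center axis while `sigma <= r < sigma +
#' delta`, and 0 otherwise. Positions are taken in a periodic cubic box of
#' edge `L` (minimum image).
#'
#' @param r_i,r_j Length-3 position vectors.
#' @param q_i,q_j Unit quaternions (w, x, y, z) giving the orientations.
#' @param s_i,s_j Species indices (1-based).
#' @param design A [mixture_design()].
#' @param L Box edge (default large: effectively unbounded).
#' @return Numeric scalar energy in reduced units.
#' @export
pair_energy <- function(r_i, r_j, q_i, q_j, s_i, s_j, design, L = 1e6) {
  kf_pair_energy_cpp(as.numeric(r_i), as.numeric(q_i), as.integer(s_i),
                     as.numeric(r_j), as.numeric(q_j), as.integer(s_j),
                     L, design_clist(design))
}

#' Total potential energy of a configuration
#'
#' @param state A `sim_state` (see [make_initial_config()]).
#' @param design A [mixture_design()].
#' @return Total Kern-Frenkel energy (possibly `Inf` for overlapping states).
#' @export
total_energy <- function(state, design) {
  kf_total_energy_cpp(unclass(state), design_clist(design))
}

#' Monte Carlo move schedule
#'
#' Per-move attempt probabilities (normalized internally) and move
#' amplitudes. Defaults give displacement-dominated sampling with a modest
#' fraction of AVB moves; ensembles ignore probabilities for moves they do
#' not own (e.g. `p_volume` in NVT).
#'
#' @param p_translate,p_rotate,p_avb,p_volume,p_transfer Attempt weights.
#' @param dmax Maximum displacement (reduced units).
#' @param rot_max Maximum rotation angle (radians).
#' @param dlnv Maximum log-volume step.
#' @param transfer_bias Probability that a transfer/insertion is placed,
#'   orientationally biased, into the bonding shell of a random target
#'   particle rather than uniformly (the generation densities of both
#'   channels enter the acceptance rule, so any value in [0, 1) is valid).
#' @return An object of class `move_schedule`.
#' @export
move_schedule <- function(p_translate = 0.4, p_rotate = 0.4, p_avb = 0.1,
                          p_volume = 0.01, p_transfer = 0.09, dmax = 0.15,
                          rot_max = 0.6, dlnv = 0.02, transfer_bias = 0.3) {
  p <- c(p_translate, p_rotate, p_avb, p_volume, p_transfer)
  if (any(p < 0) || sum(p) <= 0)
    stop("move probabilities must be >= 0 and not all zero", call. = FALSE)
  p <- p / sum(p)
  structure(list(p_translate = p[1], p_rotate = p[2], p_avb = p[3],
                 p_volume = p[4], p_transfer = p[5], dmax = dmax,
                 rot_max = rot_max, dlnv = dlnv,
                 transfer_bias = transfer_bias),
            class = "move_schedule")
}

random_quats <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2), sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3), sqrt(u1) * cos(2 * pi * u3))
}

#' Random overlap-free initial configuration
#'
#' Places `n_per_species[i]` particles of each species at random positions
#' (sequential insertion with hard-core rejection) and random orientations
#' in a cubic periodic box sized to give total number density `rho`.
#'
#' @param n_per_species Integer vector of particle counts per species.
#' @param rho Total number density (`sigma^-3`); the packing fraction
#'   `rho * pi / 6` must stay below 0.45 for random insertion to succeed.
#' @param design A [mixture_design()].
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param max_attempts Insertion attempts per particle before giving up.
#' @return An object of class `sim_state`: list with `L`, `positions`
#'   (N x 3), `orientations` (N x 4 quaternions), `species`, `energy`.
#' @export
make_initial_config <- function(n_per_species, rho, design, seed = NULL,
                                max_attempts = 1e4) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- design$kf$sigma
  phi <- rho * v_sphere(sigma)
  if (phi >= 0.45)
    stop(sprintf("packing fraction %.3f too high for random insertion (< 0.45)",
                 phi), call. = FALSE)
  N <- sum(n_per_species)
  if (N < 1) stop("need at least one particle", call. = FALSE)
  L <- (N / rho)^(1 / 3)
  pos <- matrix(NA_real_, N, 3)
  placed <- 0L
  for (i in seq_len(N)) {
    for (att in seq_len(max_attempts)) {
      cand <- stats::runif(3, 0, L)
      if (placed > 0L) {
        d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
        d <- d - L * round(d / L)
        if (min(rowSums(d^2)) < sigma^2) next
      }
      pos[i, ] <- cand
      placed <- placed + 1L
      break
    }
    if (is.na(pos[i, 1]))
      stop("random insertion failed; density too high", call. = FALSE)
  }
  species <- rep(seq_along(n_per_species), times = n_per_species)
  structure(list(L = L, positions = pos, orientations = random_quats(N),
                 species = as.integer(species), energy = NA_real_),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("Configuration: N = %d in cubic box L = %.4f (rho = %.4f)\n",
              length(x$species), x$L, length(x$species) / x$L^3))
  cat("  species counts:", paste(table(x$species), collapse = " / "), "\n")
  invisible(x)
}

#' Two-box Gibbs-ensemble state
#'
#' @param box_a,box_b Two `sim_state` objects (see [make_initial_config()]).
#' @return An object of class `gibbs_state`.
#' @export
gibbs_state <- function(box_a, box_b) {
  stopifnot(inherits(box_a, "sim_state"), inherits(box_b, "sim_state"))
  structure(list(box_a = box_a, box_b = box_b), class = "gibbs_state")
}

mc_run_result <- function(raw, ensemble, T, design, extra = list()) {
  obs <- as.data.frame(raw$observables)
  st <- structure(raw$state, class = "sim_state")
  out <- c(list(ensemble = ensemble, T = T, observables = obs,
                state = st, frames = raw$frames,
                acceptance = raw$acceptance,
                max_energy_drift = raw$max_energy_drift,
                design = design),
           extra)
  if (!is.null(raw$state_b))
    out$state_b <- structure(raw$state_b, class = "sim_state")
  structure(out, class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("%s Monte Carlo run at T = %g: %d observable rows\n",
              toupper(x$ensemble), x$T, nrow(x$observables)))
  acc <- vapply(x$acceptance, function(a) if (a[1] > 0) a[2] / a[1] else NA_real_, 0)
  ok <- !is.na(acc) & vapply(x$acceptance, `[`, 0, 1) > 0
  if (any(ok))
    cat("  acceptance:", paste(sprintf("%s %.2f", names(acc)[ok], acc[ok]),
                               collapse = ", "), "\n")
  cat(sprintf("  max energy drift: %.3g\n", x$max_energy_drift))
  invisible(x)
}

#' @export
plot.mc_run <- function(x, quantity = "rho", ...) {
  ob <- x$observables
  graphics::plot(ob$sweep[ob$box == 1], ob[[quantity]][ob$box == 1], type = "l",
                 xlab = "sweep", ylab = quantity,
                 ylim = range(ob[[quantity]], na.rm = TRUE), ...)
  if (any(ob$box == 2))
    graphics::lines(ob$sweep[ob$box == 2], ob[[quantity]][ob$box == 2],
                    col = "red3")
  invisible(x)
}

run_mc <- function(state, design, ensemble, T, P = 0, mu = 0, schedule,
                   sweeps, obs_stride, frame_stride, audit_stride, state_b) {
  if (length(design$species) > 0 && T <= 0) stop("T must be positive")
  raw <- kf_mc_run_cpp(unclass(state), design_clist(design), ensemble, T, P,
                       rep_len(as.numeric(mu), length(design$species)),
                       unclass(schedule), as.integer(sweeps),
                       as.integer(obs_stride), as.integer(frame_stride),
                       as.integer(audit_stride),
                       if (is.null(state_b)) NULL else unclass(state_b))
  raw
}

#' Canonical (NVT) Monte Carlo
#'
#' @param state A `sim_state` starting configuration.
#' @param design A [mixture_design()].
#' @param T Temperature.
#' @param schedule A [move_schedule()]; volume/transfer weights are ignored.
#' @param sweeps Number of sweeps (N attempted moves each).
#' @param obs_stride Sweeps between observable rows.
#' @param frame_stride Sweeps between stored frames (0 = none).
#' @param audit_stride Sweeps between full-energy audits of the running
#'   energy (0 = none); the maximum drift is reported in the result.
#' @return An object of class `mc_run` with the observable series
#'   (sweep, box, N, N1, V, rho, x1, E), final state, stored frames,
#'   acceptance rates and the maximum energy drift.
#' @export
run_nvt <- function(state, design, T, schedule = move_schedule(p_volume = 0,
                      p_transfer = 0), sweeps = 1000, obs_stride = 10,
                    frame_stride = 0, audit_stride = 1000) {
  raw <- run_mc(state, design, "nvt", T, schedule = schedule, sweeps = sweeps,
                obs_stride = obs_stride, frame_stride = frame_stride,
                audit_stride = audit_stride, state_b = NULL)
  mc_run_result(raw, "nvt", T, design)
}

#' Isothermal-isobaric (NPT) Monte Carlo
#'
#' Adds log-volume moves to the NVT move set.
#'
#' @inheritParams run_nvt
#' @param P Pressure in energy units (`epsilon / sigma^3`); the acceptance
#'   rule uses `beta P = P / T`. Note the theory-side functions report
#'   `beta * P` instead.
#' @return An `mc_run` object.
#' @export
run_npt <- function(state, design, T, P, schedule = move_schedule(p_transfer = 0),
                    sweeps = 1000, obs_stride = 10, frame_stride = 0,
                    audit_stride = 1000) {
  raw <- run_mc(state, design, "npt", T, P = P, schedule = schedule,
                sweeps = sweeps, obs_stride = obs_stride,
                frame_stride = frame_stride, audit_stride = audit_stride,
                state_b = NULL)
  mc_run_result(raw, "npt", T, design, extra = list(P = P))
}

#' Gibbs-ensemble Monte Carlo
#'
#' Two-box sampling of phase coexistence: single-particle moves in both
#' boxes, paired log-volume exchanges conserving the total volume, and
#' particle transfers conserving the total particle count.
#'
#' @inheritParams run_nvt
#' @param gstate A [gibbs_state()].
#' @return An `mc_run` object; `observables` carries one row per box per
#'   stride and `state`, `state_b` the two final boxes.
#' @export
run_gibbs <- function(gstate, design, T, schedule = move_schedule(),
                      sweeps = 1000, obs_stride = 10, frame_stride = 0,
                      audit_stride = 1000) {
  stopifnot(inherits(gstate, "gibbs_state"))
  raw <- run_mc(gstate$box_a, design, "gibbs", T, schedule = schedule,
                sweeps = sweeps, obs_stride = obs_stride,
                frame_stride = frame_stride, audit_stride = audit_stride,
                state_b = gstate$box_b)
  mc_run_result(raw, "gibbs", T, design)
}

#' Grand-canonical Monte Carlo
#'
#' Insertion/deletion sampling at fixed chemical potential(s); insertions
#' use the same mixed uniform/shell-biased channel as Gibbs transfers.
#'
#' @inheritParams run_nvt
#' @param mu Chemical potential, one value per species (recycled).
#' @return An `mc_run` object.
#' @export
run_gcmc <- function(state, design, T, mu, schedule = move_schedule(
                       p_volume = 0, p_transfer = 0.2), sweeps = 1000,
                     obs_stride = 10, frame_stride = 0, audit_stride = 1000) {
  raw <- run_mc(state, design, "gcmc", T, mu = mu, schedule = schedule,
                sweeps = sweeps, obs_stride = obs_stride,
                frame_stride = frame_stride, audit_stride = audit_stride,
                state_b = NULL)
  mc_run_result(raw, "gcmc", T, design, extra = list(mu = mu))
}

#' Block-averaged mean and standard error
#'
#' @param x Numeric series (e.g. an observable column after equilibration).
#' @param nblocks Number of blocks (>= 2).
#' @return List with `mean`, `se` (standard error over block means) and
#'   `nblocks`.
#' @export
block_average <- function(x, nblocks = 10) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < nblocks) stop("series shorter than the number of blocks", call. = FALSE)
  bl <- split(x, cut(seq_len(n), nblocks, labels = FALSE))
  bm <- vapply(bl, mean, 0)
  list(mean = mean(bm), se = stats::sd(bm) / sqrt(nblocks), nblocks = nblocks)
}
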