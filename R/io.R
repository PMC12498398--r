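# Trajectory / table output, fixtures, and run configuration records.

pkg_version <- function() as.character(utils::packageVersion("azeopatch"))

# small polynomial hash of a deparsed object, for tagging outputs with
# their config (stays in exact double-integer range)
config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = " ")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write configurations as extended XYZ
#'
#' One block per frame: particle count, a comment line carrying the box
#' edge, package version and config hash, then one row per particle with
#' species label, position and orientation quaternion.
#'
#' @param frames A single `sim_state` or a list of them.
#' @param path Output file.
#' @param tag Optional config hash to embed (defaults to a hash of the
#'   first frame's dimensions).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, tag = NULL) {
  if (inherits(frames, "sim_state")) frames <- list(frames)
  if (is.null(tag)) tag <- config_hash(list(length(frames),
                                            frames[[1]]$L,
                                            length(frames[[1]]$species)))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- length(fr$species)
    writeLines(as.character(n), con)
    writeLines(sprintf("L=%.12g azeopatch=%s config=%s", fr$L, pkg_version(),
                       tag), con)
    rows <- sprintf("S%d %.10g %.10g %.10g %.10g %.10g %.10g %.10g",
                    fr$species,
                    fr$positions[, 1], fr$positions[, 2], fr$positions[, 3],
                    fr$orientations[, 1], fr$orientations[, 2],
                    fr$orientations[, 3], fr$orientations[, 4])
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory written by [write_xyz()]
#'
#' @param path File path.
#' @return List of `sim_state` objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    L <- as.numeric(sub("^L=([^ ]+).*", "\\1", lines[i + 1]))
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(block, " ", fixed = TRUE))
    out[[length(out) + 1L]] <- structure(list(
      L = L,
      positions = matrix(as.numeric(parts[, 2:4]), n, 3),
      orientations = matrix(as.numeric(parts[, 5:8]), n, 4),
      species = as.integer(sub("^S", "", parts[, 1])),
      energy = NA_real_), class = "sim_state")
    i <- i + 2L + n
  }
  out
}

#' Write an observables table as CSV
#'
#' Adds a comment header embedding the package version and config hash.
#'
#' @param df Data frame (e.g. `mc_run$observables`).
#' @param path Output file.
#' @param tag Config hash; defaults to a hash of the table dimensions.
#' @return `path`, invisibly.
#' @export
write_observables <- function(df, path, tag = NULL) {
  if (is.null(tag)) tag <- config_hash(dim(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# azeopatch=%s config=%s", pkg_version(), tag), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' A bonded two-particle (dimer) configuration
#'
#' Builds a configuration of one particle of each given species with exactly
#' one Kern-Frenkel bond: particle 2 sits at distance `sigma + delta/2`
#' along the first patch direction of particle 1, oriented so that its first
#' patch points straight back. When the two patches' types are complementary
#' the pair energy equals minus their bond energy.
#'
#' @param design A [mixture_design()].
#' @param species Length-2 species indices.
#' @param patches Which patch (index within each particle) to align.
#' @param L Box edge.
#' @return A `sim_state` of two particles.
#' @export
make_dimer <- function(design, species = c(1L, 2L), patches = c(1L, 1L),
                       L = 20) {
  s1 <- design$species[[species[1]]]; s2 <- design$species[[species[2]]]
  v1 <- s1$patch_vectors[patches[1], ]
  v2 <- s2$patch_vectors[patches[2], ]
  r <- design$kf$sigma + design$kf$delta / 2
  # orientation of particle 2: rotate v2 onto -v1
  c2 <- sum(v2 * -v1)
  if (c2 > 1 - 1e-12) q2 <- c(1, 0, 0, 0)
  else {
    ax <- c(v2[2] * -v1[3] - v2[3] * -v1[2],
            v2[3] * -v1[1] - v2[1] * -v1[3],
            v2[1] * -v1[2] - v2[2] * -v1[1])
    if (sum(ax^2) < 1e-20) ax <- if (abs(v2[1]) < 0.9) c(0, -v2[3], v2[2]) else
      c(-v2[2], v2[1], 0)
    ax <- ax / sqrt(sum(ax^2))
    ang <- acos(max(-1, min(1, c2)))
    q2 <- c(cos(ang / 2), sin(ang / 2) * ax)
  }
  ctr <- rep(L / 2, 3)
  structure(list(L = L,
                 positions = rbind(ctr, ctr + r * v1),
                 orientations = rbind(c(1, 0, 0, 0), q2),
                 species = as.integer(species), energy = NA_real_),
            class = "sim_state")
}

#' Generate a reproducible test fixture
#'
#' Writes, depending on `kind`: a bonded two-particle configuration with
#' exactly one Kern-Frenkel bond (`"dimer"`, XYZ), an overlap-free random
#' gas at given counts and density (`"random-gas"`, XYZ), a synthetic
#' structure-factor table drawn from the Ornstein-Zernike form with known
#' parameters (`"oz-curve"`, CSV with columns k, S), or a factory design
#' file (`"design"`, JSON).
#'
#' @param kind One of `"dimer"`, `"random-gas"`, `"oz-curve"`, `"design"`.
#' @param path Output file path.
#' @param params List of kind-specific parameters: `design` (object or name
#'   `"n2c8"` / `"ideal"`), `n_per_species`, `rho`, `S0`, `xi2`, `k_max`,
#'   `noise_sd`, `eps_prime`, `eps`.
#' @param seed Integer seed; fixtures are reproducible from
#'   `(kind, params, seed)`.
#' @return The written path, invisibly; the generated object as attribute
#'   `"object"`.
#' @export
generate_fixture <- function(kind = c("dimer", "random-gas", "oz-curve",
                                      "design"),
                             path, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  get_design <- function() {
    d <- params$design
    if (is.null(d)) d <- "n2c8"
    if (inherits(d, "mixture_design")) return(d)
    switch(d,
           n2c8 = build_n2c8(params$eps_prime %||% 1, params$eps %||% 1),
           ideal = build_ideal_azeotrope_binary(),
           stop("unknown factory design `", d, "`", call. = FALSE))
  }
  obj <- switch(kind,
    dimer = {
      st <- make_dimer(get_design())
      write_xyz(st, path, tag = config_hash(list(kind, params, seed)))
      st
    },
    `random-gas` = {
      st <- make_initial_config(params$n_per_species %||% c(32, 32),
                                params$rho %||% 0.2, get_design())
      write_xyz(st, path, tag = config_hash(list(kind, params, seed)))
      st
    },
    `oz-curve` = {
      k <- seq(0.2, params$k_max %||% 2, length.out = params$n_k %||% 24)
      S0 <- params$S0 %||% 0.7
      xi2 <- params$xi2 %||% 2.25
      S <- S0 / (1 + k^2 * xi2)
      if (!is.null(params$noise_sd))
        S <- S + stats::rnorm(length(k), 0, params$noise_sd)
      df <- data.frame(k = k, S = S)
      write_observables(df, path, tag = config_hash(list(kind, params, seed)))
      df
    },
    design = {
      d <- get_design()
      write_design(d, path)
      d
    })
  out <- path
  attr(out, "object") <- obj
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
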