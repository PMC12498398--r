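#' Kern-Frenkel interaction geometry
#'
#' Bundles the three geometric parameters of the Kern-Frenkel pair potential:
#' the hard-core diameter `sigma`, the square-well (bonding shell) width
#' `delta`, and the cosine of the patch angular half-width `cos_theta_max`.
#' Two particles bond when their centers lie within `[sigma, sigma + delta)`
#' and a complementary patch on each particle points at the other within the
#' cone `cos(theta) > cos_theta_max`. All lengths are in units of `sigma`,
#' energies in units of the reference bond energy, and temperatures in units
#' of that energy over Boltzmann's constant.
#'
#' @param sigma Hard-core diameter (default 1, reduced units).
#' @param delta Bonding-shell width (default 0.2).
#' @param cos_theta_max Cosine of the angular half-width (default 0.98).
#' @return An object of class `kern_frenkel_params`.
#' @export
kern_frenkel_params <- function(sigma = 1, delta = 0.2, cos_theta_max = 0.98) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (!(is.numeric(delta) && length(delta) == 1L && delta > 0 && delta < sigma))
    stop("`delta` must satisfy 0 < delta < sigma", call. = FALSE)
  if (!(is.numeric(cos_theta_max) && length(cos_theta_max) == 1L &&
        cos_theta_max > 0 && cos_theta_max < 1))
    stop("`cos_theta_max` must lie in (0, 1)", call. = FALSE)
  structure(list(sigma = sigma, delta = delta, cos_theta_max = cos_theta_max),
            class = "kern_frenkel_params")
}

#' Specify one patchy-particle species
#'
#' @param species_id Integer species label.
#' @param patch_type_ids Integer vector of global patch-type identifiers,
#'   one per patch. Patch types are global: no two species may share one.
#' @param patch_vectors Numeric matrix with one row per patch giving the
#'   patch direction as a unit vector in the particle body frame.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(species_id, patch_type_ids, patch_vectors) {
  patch_type_ids <- as.integer(patch_type_ids)
  patch_vectors <- as.matrix(patch_vectors)
  if (nrow(patch_vectors) != length(patch_type_ids) || ncol(patch_vectors) != 3L)
    stop("`patch_vectors` must be a |patch_type_ids| x 3 matrix", call. = FALSE)
  norms <- sqrt(rowSums(patch_vectors^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("`patch_vectors` rows must be unit vectors", call. = FALSE)
  if (anyDuplicated(patch_type_ids))
    stop("`patch_type_ids` must be distinct within a species", call. = FALSE)
  structure(list(species_id = as.integer(species_id),
                 patch_type_ids = patch_type_ids,
                 patch_vectors = patch_vectors),
            class = "species_spec")
}

#' Construct a mixture design (species/patch interaction graph)
#'
#' A mixture design is the central object of the package: a list of species,
#' each carrying patches of globally unique types, plus a symmetric matrix of
#' bonding energies `eps[alpha, gamma]` over all global patch types. A zero
#' entry means the pair never bonds; diagonal entries encode self-complementary
#' patches (self-loops of the interaction graph).
#'
#' @param species List of [species_spec()] objects. Their patch types must
#'   jointly enumerate `1..n_types` with no repeats.
#' @param energy_matrix Symmetric non-negative `n_types x n_types` matrix of
#'   bonding energies in reduced units.
#' @param kf A [kern_frenkel_params()] object.
#' @return An object of class `mixture_design`.
#' @export
mixture_design <- function(species, energy_matrix, kf = kern_frenkel_params()) {
  stopifnot(is.list(species), length(species) >= 1L)
  if (!all(vapply(species, inherits, logical(1), "species_spec")))
    stop("`species` must be a list of species_spec objects", call. = FALSE)
  ids <- unlist(lapply(species, `[[`, "patch_type_ids"))
  n_types <- length(ids)
  if (anyDuplicated(ids))
    stop("patch types must be globally unique across species", call. = FALSE)
  if (!setequal(ids, seq_len(n_types)))
    stop("patch types must enumerate 1..n_types", call. = FALSE)
  energy_matrix <- as.matrix(energy_matrix)
  if (!all(dim(energy_matrix) == c(n_types, n_types)))
    stop("`energy_matrix` must be ", n_types, " x ", n_types, call. = FALSE)
  if (any(energy_matrix < 0))
    stop("`energy_matrix` entries must be >= 0", call. = FALSE)
  if (max(abs(energy_matrix - t(energy_matrix))) > 1e-12)
    stop("`energy_matrix` must be symmetric", call. = FALSE)
  if (!inherits(kf, "kern_frenkel_params"))
    stop("`kf` must be a kern_frenkel_params object", call. = FALSE)
  # owner[alpha]: index into `species` of the species carrying patch type alpha
  owner <- integer(n_types)
  for (i in seq_along(species)) owner[species[[i]]$patch_type_ids] <- i
  structure(list(species = species,
                 energy_matrix = unname(energy_matrix),
                 kf = kf,
                 n_types = n_types,
                 owner = owner),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  ns <- length(x$species)
  cat("Mixture design:", ns, "species,", x$n_types, "global patch types\n")
  for (sp in x$species)
    cat("  species", sp$species_id, "- patches:",
        paste(sp$patch_type_ids, collapse = " "), "\n")
  ed <- bonding_edges(x)
  cat("  bonding edges (alpha-gamma: eps):\n")
  for (k in seq_len(nrow(ed)))
    cat(sprintf("    %d-%d: %g\n", ed$alpha[k], ed$gamma[k], ed$eps[k]))
  cat(sprintf("  Kern-Frenkel: sigma = %g, delta = %g, cos(theta_max) = %g\n",
              x$kf$sigma, x$kf$delta, x$kf$cos_theta_max))
  invisible(x)
}

#' Bonding edges of a design
#'
#' @param design A [mixture_design()].
#' @return A data.frame with columns `alpha`, `gamma` (`alpha <= gamma`) and
#'   `eps`, one row per bonding pair (nonzero energy-matrix entry).
#' @export
bonding_edges <- function(design) {
  em <- design$energy_matrix
  idx <- which(em > 0 & upper.tri(em, diag = TRUE), arr.ind = TRUE)
  data.frame(alpha = idx[, 1], gamma = idx[, 2], eps = em[idx])
}

tetrahedral_vectors <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v / sqrt(3)
}

#' The N2c8 binary design
#'
#' Two species with four tetrahedral patches each and eight global patch
#' types (1-4 on species 1, 5-8 on species 2). The bond-exclusive pairing
#' used here is: cross-species edges 1-5 and 4-8, self-complementary patches
#' 2-2 and 3-3 on species 1 and 6-6 and 7-7 on species 2. The two species-1
#' self-loops carry the tunable energy `eps_prime`; every other bonding edge
#' carries `eps`. With `eps_prime == eps` the design is symmetric under
#' species exchange.
#'
#' @param eps_prime Bond energy of the self-complementary pairs 2-2 and 3-3.
#' @param eps Bond energy of all other bonding pairs.
#' @param kf Kern-Frenkel geometry.
#' @return A [mixture_design()].
#' @export
build_n2c8 <- function(eps_prime = 1, eps = 1, kf = kern_frenkel_params()) {
  if (!(eps > 0 && eps_prime > 0))
    stop("bond energies must be positive", call. = FALSE)
  tet <- tetrahedral_vectors()
  sp <- list(species_spec(1L, 1:4, tet), species_spec(2L, 5:8, tet))
  em <- matrix(0, 8, 8)
  em[1, 5] <- em[5, 1] <- eps
  em[4, 8] <- em[8, 4] <- eps
  em[6, 6] <- em[7, 7] <- eps
  em[2, 2] <- em[3, 3] <- eps_prime
  mixture_design(sp, em, kf)
}

#' The ideal-azeotropic binary design
#'
#' Two species with four tetrahedral patches each; every patch type has
#' exactly two complementary patch types, one on each species, and all
#' bonding energies equal 1. Intra-species edges: 1-2, 3-4 (species 1) and
#' 5-6, 7-8 (species 2); cross-species edges: 1-5, 2-6, 3-7, 4-8. With this
#' topology the mass-action bonding probabilities are independent of
#' composition and the mixture is azeotropic at every concentration.
#'
#' @param kf Kern-Frenkel geometry.
#' @return A [mixture_design()].
#' @export
build_ideal_azeotrope_binary <- function(kf = kern_frenkel_params()) {
  tet <- tetrahedral_vectors()
  sp <- list(species_spec(1L, 1:4, tet), species_spec(2L, 5:8, tet))
  em <- matrix(0, 8, 8)
  pair <- function(a, b) em[a, b] <<- em[b, a] <<- 1
  pair(1, 2); pair(3, 4); pair(5, 6); pair(7, 8)
  pair(1, 5); pair(2, 6); pair(3, 7); pair(4, 8)
  mixture_design(sp, em, kf)
}

#' Bond exclusivity test
#'
#' A design is bond-exclusive when every patch type has exactly one bonding
#' partner among all patch types of all species (a self-complementary patch
#' counts as its own single partner). Bond-exclusive designs with uniform
#' bond energies exhibit an azeotrope at equimolar composition.
#'
#' @param design A [mixture_design()].
#' @return Logical scalar.
#' @export
is_bond_exclusive <- function(design) {
  adj <- design$energy_matrix > 0
  all(rowSums(adj) == 1L)
}

#' Ideal azeotropy test
#'
#' A design is ideal-azeotropic when every patch type has exactly one bonding
#' partner on each species and all nonzero bond energies are equal. Such
#' mixtures are azeotropic at every composition: the mass-action bonding
#' probabilities lose their dependence on the molar fractions.
#'
#' @param design A [mixture_design()].
#' @return Logical scalar.
#' @export
is_ideal_azeotropic <- function(design) {
  em <- design$energy_matrix
  adj <- em > 0
  for (sp in design$species) {
    # each patch type must have exactly one partner among this species' patches
    cnt <- rowSums(adj[, sp$patch_type_ids, drop = FALSE])
    if (any(cnt != 1L)) return(FALSE)
  }
  eps <- em[em > 0]
  length(eps) > 0 && max(eps) - min(eps) <= 1e-12
}

#' Write a mixture design to JSON
#'
#' The file stores the Kern-Frenkel geometry, the species with their patch
#' types and body-frame patch vectors, and the energy matrix in sparse
#' `"alpha-gamma": value` form (upper triangle; symmetric completion is
#' applied on load).
#'
#' @param design A [mixture_design()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  ed <- bonding_edges(design)
  em <- as.list(ed$eps)
  names(em) <- sprintf("%d-%d", ed$alpha, ed$gamma)
  obj <- list(
    kern_frenkel = list(sigma = design$kf$sigma, delta = design$kf$delta,
                        cos_theta_max = design$kf$cos_theta_max),
    species = lapply(design$species, function(sp)
      list(id = sp$species_id, patch_types = sp$patch_type_ids,
           patch_vectors = sp$patch_vectors)),
    energy_matrix = em
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a mixture design from JSON
#'
#' @param path File path written by [write_design()] (or hand-authored with
#'   the same schema). Validation errors name the offending field.
#' @return A [mixture_design()].
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("kern_frenkel", "species", "energy_matrix"))
    if (is.null(obj[[field]]))
      stop("design file missing field `", field, "`", call. = FALSE)
  kfo <- obj$kern_frenkel
  kf <- kern_frenkel_params(kfo$sigma, kfo$delta, kfo$cos_theta_max)
  spl <- obj$species
  if (is.data.frame(spl)) {
    spl <- lapply(seq_len(nrow(spl)), function(i)
      list(id = spl$id[i], patch_types = spl$patch_types[[i]],
           patch_vectors = spl$patch_vectors[[i]]))
  }
  species <- lapply(spl, function(sp) {
    pv <- sp$patch_vectors
    if (is.list(pv)) pv <- do.call(rbind, pv)
    pv <- as.matrix(pv)
    if (nrow(pv) != length(sp$patch_types))
      stop("species ", sp$id, ": `patch_vectors` has ", nrow(pv),
           " rows but `patch_types` has ", length(sp$patch_types),
           " entries", call. = FALSE)
    species_spec(sp$id, sp$patch_types, pv)
  })
  n_types <- sum(vapply(species, function(s) length(s$patch_type_ids), 0L))
  em <- matrix(0, n_types, n_types)
  entries <- obj$energy_matrix
  for (key in names(entries)) {
    ag <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    if (length(ag) != 2L || anyNA(ag) || any(ag < 1L) || any(ag > n_types))
      stop("`energy_matrix` key `", key, "` is not a valid patch-type pair",
           call. = FALSE)
    val <- as.numeric(entries[[key]])
    cur <- em[ag[1], ag[2]]
    if (cur != 0 && abs(cur - val) > 1e-12)
      stop("`energy_matrix` entries for pair ", ag[1], "-", ag[2],
           " are asymmetric", call. = FALSE)
    em[ag[1], ag[2]] <- em[ag[2], ag[1]] <- val
  }
  mixture_design(species, em, kf)
}
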