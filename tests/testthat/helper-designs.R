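# shared fixtures: designs and small geometric helpers

tet_vectors <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

# single species, 4 tetrahedral patches, every patch bonds every patch;
# eps = 0 gives pure hard spheres
one_species_design <- function(eps = 1, kf = kern_frenkel_params()) {
  mixture_design(list(species_spec(1L, 1:4, tet_vectors())),
                 matrix(eps, 4, 4), kf)
}

# three species, two patches each, bond-exclusive pairing 1-3, 2-5, 4-6
three_species_exclusive <- function(eps = 1) {
  pv <- rbind(c(0, 0, 1), c(0, 0, -1))
  sp <- list(species_spec(1L, 1:2, pv), species_spec(2L, 3:4, pv),
             species_spec(3L, 5:6, pv))
  em <- matrix(0, 6, 6)
  em[1, 3] <- em[3, 1] <- eps
  em[2, 5] <- em[5, 2] <- eps
  em[4, 6] <- em[6, 4] <- eps
  mixture_design(sp, em)
}

# a wider-patch, quickly equilibrating test fluid for engine validation
wide_patch_fluid <- function() {
  mixture_design(list(species_spec(1L, 1:4, tet_vectors())),
                 matrix(1, 4, 4), kern_frenkel_params(1, 0.2, 0.90))
}

# quaternion rotating body vector v onto lab direction u
quat_align <- function(v, u) {
  cth <- sum(v * u)
  if (cth > 1 - 1e-12) return(c(1, 0, 0, 0))
  ax <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
          v[1] * u[2] - v[2] * u[1])
  if (sum(ax^2) < 1e-20) ax <- if (abs(v[1]) < 0.9) c(0, -v[3], v[2]) else
    c(-v[2], v[1], 0)
  ax <- ax / sqrt(sum(ax^2))
  ang <- acos(max(-1, min(1, cth)))
  c(cos(ang / 2), sin(ang / 2) * ax)
}
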