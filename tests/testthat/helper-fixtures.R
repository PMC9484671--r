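# Composite fixtures shared by pipeline and acceptance tests.

# A lysine-bearing mini-helix at the bottom of an open-topped
# cylindrical well of pseudo-atoms: its amine sites are well exposed to
# a small probe but unreachable once the inflated wall spheres seal the
# mouth, driving the class flip to non-reacting at large probe radii.
make_crevice_protein <- function(wall_radius = 14, z_top = 16) {
  h <- build_ideal_helix(4, "KAAA")
  ha <- h$atoms
  ctr <- colMeans(ha[, c("x", "y", "z")])
  ha$x <- ha$x - ctr[1]; ha$y <- ha$y - ctr[2]; ha$z <- ha$z - ctr[3]
  ang <- seq(0, 2 * pi, length.out = 29)[-29]
  wall <- NULL
  for (z in seq(-8, z_top, by = 2.5))
    wall <- rbind(wall, cbind(wall_radius * cos(ang),
                              wall_radius * sin(ang), z))
  fl <- rbind(c(0, 0, -8),
              cbind(4 * cos(ang), 4 * sin(ang), -8),
              cbind(8 * cos(ang), 8 * sin(ang), -8),
              cbind(11.5 * cos(ang), 11.5 * sin(ang), -8))
  sph <- rbind(wall, fl)
  sa <- data.frame(serial = seq_len(nrow(sph)), name = "X", elem = "C",
                   resname = "SPH", chain = "W",
                   resno = seq_len(nrow(sph)), insert = "",
                   x = sph[, 1], y = sph[, 2], z = sph[, 3],
                   het = FALSE, radius = 1.8, stringsAsFactors = FALSE)
  ha$radius <- NA_real_
  m <- rbind(ha, sa)
  m$serial <- seq_len(nrow(m))
  aminereact:::new_structure(m, provenance = list(
    source = "fixture:crevice_protein"))
}

# Random small sphere clusters for oracle-equivalence checks.
random_cluster <- function(seed, n_max = 6) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  build_sphere_cluster(matrix(rnorm(3 * n, sd = 2), ncol = 3),
                       radii = runif(n, 1.2, 2.2))
}
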