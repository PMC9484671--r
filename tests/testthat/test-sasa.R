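# Exposed surface area: closed forms, oracle equivalence, probe-size
# behaviour and geometric invariances.

test_that("isolated sphere matches the closed form on both algorithms", {
  m <- build_sphere_cluster(matrix(c(3, -2, 7), 1, 3), radii = 1.8)
  exact <- 4 * pi * (1.8 + 1.4)^2
  expect_equal(atom_sasa(m, 1.4), exact, tolerance = 0.005)
  expect_equal(atom_sasa(m, 1.4, algorithm = "shrake-rupley",
                         resolution = 500), exact, tolerance = 0.005)
  # large probe
  exact2 <- 4 * pi * (1.8 + 4.2)^2
  expect_equal(atom_sasa(m, 4.2), exact2, tolerance = 0.005)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  R <- 1.8 + 1.4
  for (offset in list(c(0, 0, 2), c(2, 0, 0), c(1.2, 1.2, 0.8))) {
    m <- build_sphere_cluster(rbind(c(0, 0, 0), offset), radii = 1.8)
    d <- sqrt(sum(offset^2))
    expect_equal(sum(atom_sasa(m, 1.4)), two_sphere_area(R, d),
                 tolerance = 0.01)
  }
})

test_that("Monte-Carlo oracle converges on the closed form and matches Lee-Richards", {
  m <- build_sphere_cluster(matrix(0, 1, 3), radii = 1.8)
  mc <- mc_atom_sasa(m, 1.4, n_points = 1e5, seed = 11)
  expect_equal(mc$area, 4 * pi * 3.2^2, tolerance = 0.01)
  worst <- 0
  for (k in 1:20) {
    cl <- random_cluster(seed = 100 + k)
    lr <- atom_sasa(cl, 1.4, resolution = 200)
    mc <- mc_atom_sasa(cl, 1.4, n_points = 1e4, seed = k)
    expect_true(all(abs(lr - mc$area) <= 3 * mc$se + 0.005 * lr + 0.05),
                info = sprintf("cluster %d", k))
  }
})

test_that("a shell-enclosed atom is fully buried in both implementations", {
  m <- build_buried_fixture()
  expect_equal(atom_sasa(m, 1.4)[1], 0)
  expect_equal(mc_atom_sasa(m, 1.4, n_points = 1e4, seed = 3)$area[1], 0)
})

test_that("areas respect the isolated-sphere bound and totals are positive", {
  for (k in 1:5) {
    cl <- random_cluster(seed = 200 + k)
    r <- cl$atoms$radius
    a <- atom_sasa(cl, 1.4)
    expect_true(all(a >= 0))
    expect_true(all(a <= 4 * pi * (r + 1.4)^2 + 1e-6))
    expect_gt(sum(a), 0)
  }
})

test_that("areas are invariant under rigid motion (translation exact, rotation to discretisation error)", {
  m <- build_ideal_helix(6, "AAKAAA")
  a0 <- atom_sasa(m, 4.2)
  shifted <- rotate_structure(m, angles = c(0, 0, 0),
                              shift = c(13.7, -6.1, 42))
  expect_equal(atom_sasa(shifted, 4.2), a0, tolerance = 1e-6)
  rot <- rotate_structure(m, angles = c(0.4, -1.2, 2.2))
  expect_equal(sum(atom_sasa(rot, 4.2)), sum(a0), tolerance = 0.01)
})

test_that("probe-size behaviour: monotone growth on a convex site, collapse to zero in a crevice", {
  sph <- build_sphere_cluster(rbind(c(0, 0, 0), c(3.5, 0, 0)), radii = 1.8)
  areas <- vapply(c(1, 5, 10), function(rp) atom_sasa(sph, rp)[1],
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  cr <- build_crevice_fixture()
  expect_gt(atom_sasa(cr, 1.4)[1], 0)
  expect_equal(atom_sasa(cr, 4.2)[1], 0)
})

test_that("coincident centres are treated as occluding duplicates with a warning", {
  m <- build_sphere_cluster(rbind(c(0, 0, 0), c(0, 0, 0)), radii = 1.8)
  expect_warning(a <- atom_sasa(m, 1.4), "coincident")
  expect_equal(a, c(0, 0))
})

test_that("residue ESA sums atom areas per residue and errors on unknown residues", {
  m <- build_ideal_helix(6, "KAAAAA")
  areas <- atom_sasa(m, 4.2)
  s <- amine_sites(m)
  esa <- residue_esa(m, areas, s)
  k1 <- sum(areas[m$atoms$resno == 1])
  expect_equal(esa[s$site_id == "A:1:epsilon"], k1)
  expect_equal(esa[s$site_id == "A:1:alpha"], k1)   # same residue
  bogus <- s[1, ]; bogus$resno <- 99L; bogus$site_id <- "A:99:alpha"
  expect_error(residue_esa(m, areas, bogus), "not found")
  # all-zero residue sums to zero
  expect_equal(residue_esa(m, areas * 0, s), rep(0, nrow(s)))
})
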