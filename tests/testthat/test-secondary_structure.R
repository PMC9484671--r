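# Kabsch-Sander hydrogen bonds and 8-state assignment.

# two complete residues with controlled donor/acceptor geometry; the
# expected energy is recomputed in the test from raw distances
make_two_residue <- function(acceptor_shift) {
  n1 <- rbind(N = c(0, 0, 0), CA = c(1.45, 0, 0), C = c(2.0, 1.3, 0),
              O = c(3.2, 1.5, 0), H = c(-0.6, 0.8, 0))
  n2 <- sweep(n1, 2, acceptor_shift, "+")
  a <- rbind(
    data.frame(name = rownames(n1), elem = c("N", "C", "C", "O", "H"),
               resname = "ALA", chain = "A", resno = 1L, insert = "",
               x = n1[, 1], y = n1[, 2], z = n1[, 3], het = FALSE),
    data.frame(name = rownames(n2), elem = c("N", "C", "C", "O", "H"),
               resname = "ALA", chain = "A", resno = 2L, insert = "",
               x = n2[, 1], y = n2[, 2], z = n2[, 3], het = FALSE))
  a$serial <- seq_len(nrow(a))
  aminereact:::new_structure(a)
}

ks_energy_byhand <- function(model, donor_res, acceptor_res) {
  # donor_res / acceptor_res are residue numbers (resno), not indices
  a <- model$atoms
  g <- function(rn, nm) unlist(a[a$resno == rn & a$name == nm,
                                 c("x", "y", "z")])
  d <- function(p, q) sqrt(sum((p - q)^2))
  0.084 * 332 * (1 / d(g(acceptor_res, "O"), g(donor_res, "N")) +
                   1 / d(g(acceptor_res, "C"), g(donor_res, "H")) -
                   1 / d(g(acceptor_res, "O"), g(donor_res, "H")) -
                   1 / d(g(acceptor_res, "C"), g(donor_res, "N")))
}

test_that("hydrogen-bond energy matches the hand-computed formula and the -0.5 threshold", {
  # residue 2 placed so its O sits 1.9 A beyond H along the N-H axis
  m <- make_two_residue(c(-4.94, 0.82, 0))
  ks <- ks_hbonds(m)
  expect_gt(nrow(ks$bonds), 0)
  resno_of <- vapply(ks$residues, `[[`, 0L, "resno")
  for (r in seq_len(nrow(ks$bonds))) {
    e_hand <- ks_energy_byhand(m, resno_of[ks$bonds$donor[r]],
                               resno_of[ks$bonds$acceptor[r]])
    expect_equal(ks$bonds$energy[r], e_hand)
    expect_lt(ks$bonds$energy[r], -0.5)
  }
  # far apart: no bonds at all
  far <- make_two_residue(c(50, 0, 0))
  expect_equal(nrow(ks_hbonds(far)$bonds), 0L)
})

test_that("at most the two lowest-energy acceptors are kept per donor", {
  # one donor residue surrounded by three acceptor-only residues at
  # staggered distances
  don <- data.frame(name = c("N", "CA", "C", "O", "H"),
                    elem = c("N", "C", "C", "O", "H"),
                    resname = "ALA", chain = "A", resno = 1L, insert = "",
                    x = c(0, 1.45, 2.0, 3.1, -0.6),
                    y = c(0, 0, 1.3, 1.4, 0.81),
                    z = 0, het = FALSE)
  acc <- NULL
  for (k in 1:3) {
    dy <- 2.35 + 0.15 * k
    acc <- rbind(acc, data.frame(
      name = c("N", "CA", "C", "O"), elem = c("N", "C", "C", "O"),
      resname = "ALA", chain = "A", resno = 10L + k, insert = "",
      x = c(-2.6, -2.0, -1.3, -0.6) + 0.1 * k,
      y = c(dy + 1.3, dy + 2, dy + 0.6, dy), z = 0, het = FALSE))
  }
  a <- rbind(don, acc)
  a$serial <- seq_len(nrow(a))
  m <- aminereact:::new_structure(a)
  ks <- ks_hbonds(m)
  b1 <- ks$bonds[ks$bonds$donor == 1, ]
  expect_equal(nrow(b1), 2L)
  # all three candidates are sub-threshold bonds; only the two lowest kept
  all_e <- vapply(11:13, function(rn) ks_energy_byhand(m, 1, rn), numeric(1))
  expect_true(all(all_e < -0.5))
  expect_equal(sort(b1$energy), sort(all_e)[1:2])
})

test_that("an ideal alpha helix shows the i -> i-4 bond pattern and interior H", {
  m <- build_ideal_helix(12)
  ks <- ks_hbonds(m)
  has44 <- vapply(5:12, function(i)
    any(ks$bonds$donor == i & ks$bonds$acceptor == i - 4), logical(1))
  expect_true(all(has44))
  ss <- assign_ss(m)
  expect_true(all(ss$ss8[3:10] == "H"))
  expect_true(all(ss$ss3[3:10] == "helix"))
})

test_that("an antiparallel hairpin assigns strand to the paired residues", {
  m <- build_beta_hairpin()
  ss <- assign_ss(m)
  expect_true(all(ss$ss8[c(2:4, 9:11)] == "E"))
  expect_true(all(ss$ss3[c(2:4, 9:11)] == "strand"))
  # the connector never reads as helix or strand
  expect_true(all(ss$ss3[6:7] == "coil"))
})

test_that("short or extended chains come out coil, and ss3 is total", {
  di <- make_two_residue(c(6, 2, 1))
  ss <- assign_ss(di)
  expect_true(all(ss$ss3 == "coil"))
  ext <- build_ideal_helix(6, phi = -139, psi = 135)   # lone strand
  ss2 <- assign_ss(ext)
  expect_true(all(ss2$ss3 %in% c("helix", "strand", "coil")))
  expect_true(all(ss2$ss8 %in% c("H", "G", "I", "E", "B", "T", "S", "-")))
  # single extended strand has no partner: no E without a ladder
  expect_false(any(ss2$ss8 == "E"))
})

test_that("assignments are invariant under rigid motion", {
  for (m in list(build_ideal_helix(10, "AAKAAAAAAA"),
                 build_beta_hairpin())) {
    ss0 <- assign_ss(m)$ss8
    mr <- rotate_structure(m, angles = c(1.0, -0.5, 0.8),
                           shift = c(5, -3, 11))
    expect_equal(assign_ss(mr)$ss8, ss0)
  }
})
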