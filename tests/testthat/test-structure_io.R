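# PDB/PQR parsing, cleaning, assembly selection, amine enumeration and
# geometric protonation.

pdb_line <- function(rec, serial, name, alt, resname, chain, resno, xyz,
                     occ = 1, elem = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, substr(nm, 1, 4), alt, resname, chain, resno, " ",
          xyz[1], xyz[2], xyz[3], occ, 0, elem)
}

test_that("PDB round-trip preserves atoms, names, chains and coordinates", {
  m <- build_ideal_helix(8, "AAKAAAKA")
  f <- tempfile(fileext = ".pdb")
  write_pdb_file(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$name, m$atoms$name)
  expect_equal(m2$chains, m$chains)
  expect_equal(m2$atoms$resno, m$atoms$resno)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_equal(m2$atoms$y, m$atoms$y, tolerance = 1e-3)
  expect_equal(m2$atoms$z, m$atoms$z, tolerance = 1e-3)
})

test_that("altloc resolution keeps the highest occupancy, ties prefer A", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("ATOM", 1, "N", "A", "ALA", "A", 1, c(0, 0, 0), occ = 0.4),
    pdb_line("ATOM", 2, "N", "B", "ALA", "A", 1, c(1, 0, 0), occ = 0.6),
    pdb_line("ATOM", 3, "CA", "A", "ALA", "A", 1, c(2, 0, 0), occ = 0.5),
    pdb_line("ATOM", 4, "CA", "B", "ALA", "A", 1, c(3, 0, 0), occ = 0.5),
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$name == "N"], 1)    # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 2)   # tie -> altloc A
})

test_that("cleaning removes waters always, hetero optionally, and a water-only file is empty", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("ATOM", 1, "N", " ", "ALA", "A", 1, c(0, 0, 0)),
    pdb_line("ATOM", 2, "CA", " ", "ALA", "A", 1, c(1.4, 0, 0)),
    pdb_line("HETATM", 3, "O", " ", "HOH", "A", 90, c(9, 9, 9)),
    pdb_line("HETATM", 4, "FE", " ", "HEM", "A", 91, c(5, 5, 5), elem = "FE"),
    "END"), f)
  m <- read_structure(f)
  c1 <- clean_structure(m, keep_hetero = FALSE, quiet = TRUE)
  expect_equal(nrow(c1$atoms), 2L)
  expect_false(any(c1$atoms$resname %in% c("HOH", "HEM")))
  c2 <- clean_structure(m, keep_hetero = TRUE, quiet = TRUE)
  expect_true("HEM" %in% c2$atoms$resname)
  expect_false("HOH" %in% c2$atoms$resname)
  # idempotence on a water-free model
  expect_equal(nrow(clean_structure(c1, quiet = TRUE)$atoms), nrow(c1$atoms))
  fw <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line("HETATM", 1, "O", " ", "HOH", "A", 1, c(0, 0, 0)),
               "END"), fw)
  mw <- suppressWarnings(read_structure(fw))
  expect_error(clean_structure(mw, quiet = TRUE), "empty structure")
})

test_that("amine enumeration: one epsilon per lysine, one alpha per chain, N-terminal lysine gives both", {
  m <- build_ideal_helix(6, "KAAAAK")
  s <- amine_sites(m)
  expect_equal(nrow(s), 3L)
  expect_equal(s$site_id, c("A:1:alpha", "A:1:epsilon", "A:6:epsilon"))
  expect_true(all(s$resname[s$kind == "epsilon"] == "LYS"))
  # alpha site on a non-lysine first residue
  s2 <- amine_sites(build_ideal_helix(5, "AAKAA"))
  expect_equal(s2$site_id, c("A:1:alpha", "A:3:epsilon"))
})

test_that("site enumeration is invariant to atom order within residues and commutes with chain selection", {
  m <- build_ideal_helix(6, "KAAAKA")
  set.seed(7)
  a <- m$atoms
  key <- paste(a$chain, a$resno)
  groups <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  perm <- unlist(lapply(groups, function(i) i[sample(length(i))]))
  shuffled <- aminereact:::new_structure(a[perm, , drop = FALSE])
  expect_equal(amine_sites(shuffled)$site_id, amine_sites(m)$site_id)
  dim2 <- build_homodimer(m, c(60, 0, 0))
  s_then_e <- amine_sites(select_chains(dim2, "B"))$site_id
  e_then_s <- amine_sites(dim2)
  e_then_s <- e_then_s$site_id[e_then_s$chain == "B"]
  expect_equal(sort(s_then_e), sort(e_then_s))
})

test_that("chain selection validates ids and preserves identity on full selection", {
  m <- build_ideal_helix(5, "KAAAA")
  d <- build_homodimer(m, c(50, 0, 0))
  expect_error(select_chains(d, "Q"), "available: A, B")
  full <- select_chains(d, c("A", "B"))
  expect_equal(full$atoms[, c("name", "x", "y", "z")],
               d$atoms[, c("name", "x", "y", "z")])
  half <- select_chains(d, "A")
  expect_equal(nrow(half$atoms), nrow(d$atoms) / 2)
})

test_that("geometric protonation: amide H at 1.01 A, prolines skipped, idempotent", {
  m <- build_ideal_helix(6, "AAPAKA")
  p <- add_hydrogens(m)
  a <- p$atoms
  for (rn in c(2, 4, 6)) {
    N <- unlist(a[a$resno == rn & a$name == "N", c("x", "y", "z")])
    H <- unlist(a[a$resno == rn & a$name == "H", c("x", "y", "z")])
    expect_equal(sqrt(sum((N - H)^2)), 1.01, tolerance = 1e-3)
  }
  expect_equal(sum(a$resno == 3 & a$name == "H"), 0L)  # proline
  # lysine NZ and N-terminal amines get three tetrahedral hydrogens
  expect_equal(sum(a$resno == 5 & a$name %in% c("HZ1", "HZ2", "HZ3")), 3L)
  NZ <- unlist(a[a$resno == 5 & a$name == "NZ", c("x", "y", "z")])
  for (hz in c("HZ1", "HZ2", "HZ3")) {
    H <- unlist(a[a$resno == 5 & a$name == hz, c("x", "y", "z")])
    expect_equal(sqrt(sum((NZ - H)^2)), 1.01, tolerance = 1e-3)
  }
  expect_equal(sum(a$resno == 1 & a$name %in% c("H1", "H2", "H3")), 3L)
  # idempotence
  expect_equal(nrow(add_hydrogens(p)$atoms), nrow(p$atoms))
})

test_that("PQR parsing: field mapping, chain-less default, charge conservation, line errors", {
  f <- tempfile(fileext = ".pqr")
  writeLines("ATOM 1 N LYS A 1 0.0 0.0 0.0 -0.3000 1.8240", f)
  q <- suppressMessages(read_pqr(f))
  expect_equal(q$charge, -0.30)
  expect_equal(q$radius, 1.824)
  expect_equal(q$chain, "A")
  writeLines(c("ATOM 1 NZ LYS 1 0.0 0.0 0.0 1.0 1.5",
               "ATOM 2 NZ LYS 2 3.0 0.0 0.0 1.0 1.5"), f)
  q2 <- suppressMessages(read_pqr(f))
  expect_equal(unique(q2$chain), "A")   # chain column absent
  expect_equal(sum(q2$charge), 2.0)
  writeLines("ATOM 1 N LYS A 1 0.0 0.0 0.0 oops 1.8", f)
  expect_error(suppressMessages(read_pqr(f)), "line 1")
  # round-trip through the writer
  writeLines(c("ATOM 1 NZ LYS 1 0.5 -0.25 4.0 1.0 1.5"), f)
  q3 <- suppressMessages(read_pqr(f))
  f2 <- tempfile(fileext = ".pqr")
  write_pqr_file(q3, f2)
  q4 <- suppressMessages(read_pqr(f2))
  expect_equal(q4$charge, q3$charge)
  expect_equal(q4$x, q3$x)
})
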