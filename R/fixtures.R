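# Synthetic structure generators with known analytic properties.  Every
# algorithm in the package is testable offline against these: ideal
# helices for secondary structure, sphere clusters with closed-form
# areas for SASA, calibrated point-charge systems for the Coulomb sum,
# and constructed donor/acceptor geometries for hydrogen bonds.

AA_321 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# NeRF internal-to-Cartesian placement: position D bonded to C with
# bond length r, angle B-C-D = theta, dihedral A-B-C-D = chi (degrees).
place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ch <- -chi * pi / 180
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  C + d[1] * bc + d[2] * m + d[3] * n
}

dihedral_angle <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

atoms_frame <- function(name, elem, resname, chain, resno, xyz,
                        het = FALSE, radius = NULL) {
  df <- data.frame(serial = seq_along(name), name = name, elem = elem,
                   resname = resname, chain = chain,
                   resno = as.integer(resno),
                   insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   het = het, stringsAsFactors = FALSE)
  if (!is.null(radius)) df$radius <- radius
  df
}

#' Build an ideal polypeptide helix (or any fixed-dihedral backbone)
#'
#' Constructs a chain with standard bond lengths and angles at the given
#' backbone dihedrals (defaults are the ideal alpha-helix, phi = -57,
#' psi = -47, omega = 180 degrees).  Lysines get an extended side chain
#' through NZ; other residues get a CB (except glycine).  Construction
#' is fully deterministic; an optional seeded Gaussian jitter (sigma up
#' to 0.05 Angstrom) is available for robustness tests.
#'
#' @param n Number of residues (at least 4).
#' @param sequence One-letter sequence of length `n` (default poly-Ala).
#' @param phi,psi,omega Backbone dihedrals in degrees.
#' @param chain Chain identifier.
#' @param jitter Standard deviation of optional coordinate noise
#'   (Angstrom, at most 0.05); 0 disables it.
#' @param seed Seed for the jitter.
#' @return An `"amine_structure"`.
#' @examples
#' h <- build_ideal_helix(12, "AAAAAKAAAAAA")
#' nrow(amine_sites(h))   # one alpha + one epsilon site
#' @export
build_ideal_helix <- function(n, sequence = strrep("A", n),
                              phi = -57, psi = -47, omega = 180,
                              chain = "A", jitter = 0, seed = 1) {
  if (n < 4) stop("n must be at least 4")
  seq1 <- strsplit(sequence, "")[[1]]
  if (length(seq1) != n) stop("sequence length must equal n")
  if (!all(seq1 %in% names(AA_321)))
    stop("invalid residue letter(s): ",
         paste(unique(seq1[!seq1 %in% names(AA_321)]), collapse = ","))
  if (jitter < 0 || jitter > 0.05) stop("jitter must be in [0, 0.05]")

  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8

  N <- CA <- CC <- O <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(b_NCA, 0, 0)
  th <- a_NCAC * pi / 180
  CC[[1]] <- CA[[1]] + b_CAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], CC[[i]], b_CN, a_CACN, psi)
    CA[[i + 1]] <- place_atom(CA[[i]], CC[[i]], N[[i + 1]], b_NCA,
                              a_CNCA, omega)
    CC[[i + 1]] <- place_atom(CC[[i]], N[[i + 1]], CA[[i + 1]], b_CAC,
                              a_NCAC, phi)
    O[[i]] <- place_atom(N[[i + 1]], CA[[i]], CC[[i]], b_CO, a_CACO, 180)
  }
  O[[n]] <- place_atom(N[[n]], CA[[n]], CC[[n]], b_CO, a_CACO, psi + 180)

  rows <- list()
  for (i in seq_len(n)) {
    rn <- AA_321[[seq1[i]]]
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(N[[i]], CA[[i]], CC[[i]], O[[i]])
    el <- c("N", "C", "C", "O")
    if (rn != "GLY") {
      CB <- place_atom(CC[[i]], N[[i]], CA[[i]], 1.53, 110.5, 122.5)
      nm <- c(nm, "CB"); el <- c(el, "C"); xyz <- rbind(xyz, CB)
      if (rn == "LYS") {
        CG <- place_atom(N[[i]], CA[[i]], CB, 1.52, 114.0, 180)
        CD <- place_atom(CA[[i]], CB, CG, 1.52, 111.3, 180)
        CE <- place_atom(CB, CG, CD, 1.52, 111.3, 180)
        NZ <- place_atom(CG, CD, CE, 1.489, 111.9, 180)
        nm <- c(nm, "CG", "CD", "CE", "NZ")
        el <- c(el, "C", "C", "C", "N")
        xyz <- rbind(xyz, CG, CD, CE, NZ)
      }
    }
    rows[[i]] <- atoms_frame(nm, el, rn, chain, i, xyz)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  if (jitter > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
  }
  new_structure(atoms, provenance = list(
    source = sprintf("fixture:ideal_helix(n=%d,phi=%g,psi=%g)", n, phi, psi)))
}

#' Build a synthetic antiparallel beta hairpin
#'
#' Two antiparallel strands joined by a two-residue connector, built
#' directly in hydrogen-bond space: paired strand residues carry
#' mutually ideal N-H...O=C geometries (H...O about 1.9 Angstrom,
#' collinear), which is what the Kabsch-Sander bridge and ladder rules
#' consume.  Hydrogens are placed explicitly by the generator.
#'
#' @param n_strand Residues per strand (at least 4); residues
#'   `2..(n_strand-1)` of each strand are H-bond paired.
#' @param chain Chain identifier.
#' @return An `"amine_structure"` of `2 * n_strand + 2` alanine
#'   residues.
#' @export
build_beta_hairpin <- function(n_strand = 5, chain = "A") {
  if (n_strand < 4) stop("n_strand must be at least 4")
  n_total <- 2 * n_strand + 2
  rows <- list()
  add_res <- function(resno, N, CA, C, O, H = NULL) {
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    xyz <- rbind(N, CA, C, O)
    if (!is.null(H)) { nm <- c(nm, "H"); el <- c(el, "H"); xyz <- rbind(xyz, H) }
    rows[[length(rows) + 1]] <<- atoms_frame(nm, el, "ALA", chain, resno, xyz)
  }
  # strand A runs +x at y = 0; strand B antiparallel at y = 4.13
  for (i in seq_len(n_strand)) {
    x <- 3.5 * i
    add_res(i,
            N = c(x, 0, 0), CA = c(x + 1.0, -0.8, 0.3),
            C = c(x + 2.0, 0, 0), O = c(x + 2.0, 1.23, 0),
            H = c(x, 1.01, 0))
  }
  # connector: out of plane, hydrogens pointing away (+z)
  xc <- 3.5 * n_strand + 4
  add_res(n_strand + 1, N = c(xc, 0.8, 2.0), CA = c(xc + 0.8, 1.6, 2.4),
          C = c(xc + 0.4, 2.6, 2.0), O = c(xc + 0.4, 2.6, 0.77),
          H = c(xc, 0.8, 3.01))
  add_res(n_strand + 2, N = c(xc + 0.2, 3.4, 2.2), CA = c(xc - 0.6, 4.0, 2.6),
          C = c(xc - 1.4, 4.6, 2.0), O = c(xc - 1.4, 4.6, 0.77),
          H = c(xc + 0.2, 3.4, 3.21))
  # strand B: residue j pairs with strand-A residue i = n_total + 1 - j
  for (j in (n_strand + 3):n_total) {
    i <- n_total + 1 - j
    x <- 3.5 * i
    add_res(j,
            N = c(x + 2.0, 4.13, 0), CA = c(x + 1.0, 4.93, 0.3),
            C = c(x, 4.13, 0), O = c(x, 2.9, 0),
            H = c(x + 2.0, 3.12, 0))
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, provenance = list(
    source = sprintf("fixture:beta_hairpin(n_strand=%d)", n_strand)))
}

#' Build a cluster of pseudo-atoms with explicit radii
#'
#' Pseudo-atom systems for closed-form SASA tests: isolated spheres,
#' overlapping pairs, buried shells and crevices.  Each atom is its own
#' residue (resname "SPH") and carries an explicit `radius` column that
#' [atom_sasa()] uses instead of the chemical radius table.
#'
#' @param positions Numeric matrix (n x 3) of centres in Angstrom.
#' @param radii Radii in Angstrom (recycled to n).
#' @param chain Chain identifier.
#' @return An `"amine_structure"` with a `radius` atom column.
#' @export
build_sphere_cluster <- function(positions, radii = 1.8, chain = "A") {
  positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  if (n < 1) stop("at least one atom required")
  radii <- rep_len(radii, n)
  atoms <- atoms_frame(rep("X", n), rep("C", n), rep("SPH", n), chain,
                       seq_len(n), positions, radius = radii)
  new_structure(atoms, provenance = list(
    source = sprintf("fixture:sphere_cluster(n=%d)", n)))
}

# Twelve icosahedron vertex directions (unit vectors).
icosahedron_vertices <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, g), c(0, -1, g), c(0, 1, -g), c(0, -1, -g),
             c(1, g, 0), c(-1, g, 0), c(1, -g, 0), c(-1, -g, 0),
             c(g, 0, 1), c(g, 0, -1), c(-g, 0, 1), c(-g, 0, -1))
  v / sqrt(1 + g^2)
}

#' Fully buried atom inside an icosahedral shell
#'
#' A small central atom surrounded by twelve shell atoms on icosahedron
#' vertices, sized so that every point of the central atom's inflated
#' sphere lies inside at least one shell sphere: its SASA is exactly 0.
#'
#' @param probe_radius Probe radius the burial is guaranteed for.
#' @return An `"amine_structure"`; the buried atom is row 1.
#' @export
build_buried_fixture <- function(probe_radius = 1.4) {
  v <- icosahedron_vertices()
  pos <- rbind(c(0, 0, 0), 2.0 * v)
  build_sphere_cluster(pos, radii = c(0.5, rep(2.5, 12)))
}

#' Deep-crevice fixture
#'
#' A target atom at the bottom of a narrow cylindrical well.  A small
#' probe reaches it through the mouth; beyond a finite probe radius the
#' inflated wall spheres seal the well and the target's area drops to
#' exactly 0 ("fewer spaces in the interior and crevices to fit").
#'
#' @param wall_radius Cylinder radius of the well wall (Angstrom).
#' @param depth Number of wall rings (1.5 Angstrom apart).
#' @return An `"amine_structure"`; the crevice atom is row 1.
#' @export
build_crevice_fixture <- function(wall_radius = 4.5, depth = 8) {
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  pos <- c(0, 0, 0)
  for (z in seq(0, by = 1.5, length.out = depth))
    pos <- rbind(pos, cbind(wall_radius * cos(ang),
                            wall_radius * sin(ang), z))
  # floor below the target
  pos <- rbind(pos, c(0, 0, -3),
               cbind(3 * cos(ang), 3 * sin(ang), -3),
               cbind(6 * cos(ang), 6 * sin(ang), -2.5))
  build_sphere_cluster(pos, radii = 1.8)
}

#' Build a point-charge system as a PQR-style table
#'
#' Charged pseudo-atoms for Coulomb-energy tests, one residue per atom
#' unless `resno` is given.  Includes helpers for the calibration pair
#' (two unit charges 3.320637 Angstrom apart give exactly 100 kcal/mol
#' at dielectric 1) via [build_calibration_pair()].
#'
#' @param positions Numeric matrix (n x 3) of positions.
#' @param charges Partial charges in elementary-charge units.
#' @param radii Atom radii (Angstrom, recycled).
#' @param resno Residue numbers (default: each atom its own residue).
#' @param chain Chain identifier.
#' @return A charged-atom data frame in the layout of [read_pqr()].
#' @export
build_charge_system <- function(positions, charges, radii = 1.5,
                                resno = NULL, chain = "A") {
  positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  if (n < 1) stop("at least one charge required")
  stopifnot(length(charges) == n)
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(serial = seq_len(n), name = "Q", resname = "CHG",
             chain = chain, resno = resno, insert = "",
             x = positions[, 1], y = positions[, 2], z = positions[, 3],
             charge = charges, radius = rep_len(radii, n),
             stringsAsFactors = FALSE)
}

#' @rdname build_charge_system
#' @export
build_calibration_pair <- function() {
  build_charge_system(rbind(c(0, 0, 0), c(3.320637, 0, 0)),
                      charges = c(1, 1))
}

#' Duplicate a structure into a homodimer
#'
#' Appends a rigidly displaced copy of the model on a fresh chain.  A
#' large displacement gives two non-interacting copies (every atom area
#' equals its monomer value); a small one buries the interface.
#'
#' @param model An `"amine_structure"` (single chain).
#' @param displacement 3-vector in Angstrom applied to the copy.
#' @param new_chain Chain identifier for the copy.
#' @return An `"amine_structure"` with both copies.
#' @export
build_homodimer <- function(model, displacement, new_chain = "B") {
  stopifnot(inherits(model, "amine_structure"))
  if (new_chain %in% model$chains)
    stop("chain id collision: ", new_chain, " already present")
  b <- model$atoms
  b$chain <- new_chain
  b$x <- b$x + displacement[1]
  b$y <- b$y + displacement[2]
  b$z <- b$z + displacement[3]
  a <- rbind(model$atoms, b)
  a$serial <- seq_len(nrow(a))
  new_structure(a, provenance = list(
    source = paste0(model$provenance$source, "+homodimer")))
}

#' Minimal donor/acceptor geometry for hydrogen-bond tests
#'
#' One donor residue (backbone N with its H) and one acceptor residue
#' (carbonyl O) placed at an exact donor--acceptor distance and
#' donor-H-acceptor angle.
#'
#' @param d_a Donor--acceptor N...O distance (Angstrom).
#' @param angle Donor-H-acceptor angle (degrees).
#' @return An `"amine_structure"` with two residues.
#' @export
build_hbond_geometry <- function(d_a = 2.9, angle = 180) {
  N <- c(0, 0, 0)
  H <- c(1.01, 0, 0)
  # acceptor at distance d_a from N such that angle N-H-A is `angle`
  th <- angle * pi / 180
  # law of cosines on triangle N-H-A: |NA| = d_a, |NH| = 1.01
  # solve |HA| from d_a^2 = 1.01^2 + |HA|^2 - 2*1.01*|HA|*cos(theta)
  qb <- -2 * 1.01 * cos(th)
  qc <- 1.01^2 - d_a^2
  ha <- (-qb + sqrt(qb^2 - 4 * qc)) / 2
  A <- H + ha * c(-cos(th), sin(th), 0)
  atoms <- rbind(
    atoms_frame(c("N", "H", "CA"), c("N", "H", "C"), "ALA", "A", 1,
                rbind(N, H, c(-0.5, -1.2, 0))),
    atoms_frame(c("O", "C"), c("O", "C"), "ALA", "A", 2,
                rbind(A, A + c(0.9, 0.9, 0))))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, provenance = list(
    source = sprintf("fixture:hbond(d_a=%g,angle=%g)", d_a, angle)))
}
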