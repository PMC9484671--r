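# Exposed-surface-area (ESA) calculation with a configurable probe
# radius.  The default algorithm is Lee-Richards slicing: each atom
# sphere is inflated by the probe radius, cut into thin z-slabs, and the
# accessible arc length of each slab circle is integrated against all
# neighbouring inflated spheres.  Hydrogens carry radius 0 and are
# excluded both as surface atoms and as occluders (areas are computed on
# crystallographic heavy atoms).

# ProtOr-style group radii (Angstrom), keyed by atom class.
SP2_CARBONS <- list(
  ASP = c("CG"), ASN = c("CG"), GLU = c("CD"), GLN = c("CD"),
  ARG = c("CZ"),
  HIS = c("CG", "CD2", "CE1"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

#' Van der Waals radii for SASA
#'
#' Assigns a ProtOr-style class radius to every atom: carbonyl and other
#' sp2 carbons 1.61/1.76, aliphatic carbons 1.88, nitrogen 1.64, oxygen
#' 1.42, sulfur 1.77; hydrogens 0 (excluded from the area calculation);
#' unknown elements fall back to 1.80.  An explicit `radius` column on
#' the atom table overrides the lookup (used by pseudo-atom fixtures).
#'
#' @param atoms An atom data frame from an `"amine_structure"`.
#' @return Numeric vector of radii, one per atom row.
#' @export
atom_radii <- function(atoms) {
  r <- rep(1.80, nrow(atoms))
  e <- atoms$elem
  r[e == "C"] <- 1.88
  r[e == "N"] <- 1.64
  r[e == "O"] <- 1.42
  r[e == "S"] <- 1.77
  r[e == "P"] <- 1.80
  r[e == "H"] <- 0
  r[atoms$name == "C" & e == "C"] <- 1.61
  for (rn in names(SP2_CARBONS))
    r[atoms$resname == rn & atoms$name %in% SP2_CARBONS[[rn]]] <- 1.76
  if (!is.null(atoms$radius)) {
    expl <- !is.na(atoms$radius)
    r[expl] <- atoms$radius[expl]
  }
  r
}

# Neighbour lists via a uniform spatial grid with cell edge equal to the
# largest inflated diameter, so any overlapping pair sits in adjacent
# cells.  Returns, for each atom, the indices of atoms whose inflated
# spheres intersect its own.
neighbor_list <- function(xyz, R) {
  n <- nrow(xyz)
  if (n <= 1) return(rep(list(integer()), n))
  cell <- max(2 * R)
  ix <- floor(xyz / cell)
  key <- paste(ix[, 1], ix[, 2], ix[, 3], sep = ",")
  cells <- split(seq_len(n), key)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- paste(ix[i, 1] + off[, 1], ix[i, 2] + off[, 2],
                ix[i, 3] + off[, 3], sep = ",")
    cand <- unlist(cells[ks], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      cand <- cand[d2 < (R[cand] + R[i])^2]
    }
    out[[i]] <- cand
  }
  out
}

# Merge angular occlusion intervals on a circle and return the total
# occluded angle.  Intervals are rows (start, end) with start < end,
# possibly extending beyond [0, 2pi) before normalisation.
occluded_angle <- function(starts, ends) {
  # normalise and split wrap-around intervals
  w <- 2 * pi
  s <- starts %% w
  e <- s + (ends - starts)
  wrap <- e > w
  if (any(wrap)) {
    s <- c(s[!wrap], s[wrap], rep(0, sum(wrap)))
    e <- c(e[!wrap], rep(w, sum(wrap)), e[wrap] - w)
  }
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0
  cur_s <- s[1]; cur_e <- e[1]
  if (length(s) > 1) for (k in 2:length(s)) {
    if (s[k] <= cur_e) cur_e <- max(cur_e, e[k])
    else { tot <- tot + (cur_e - cur_s); cur_s <- s[k]; cur_e <- e[k] }
  }
  min(tot + (cur_e - cur_s), w)
}

lee_richards_atom <- function(i, xyz, R, nb, n_slices) {
  Ri <- R[i]
  dz <- 2 * Ri / n_slices
  zk <- xyz[i, 3] - Ri + (seq_len(n_slices) - 0.5) * dz
  rho_i <- sqrt(pmax(Ri^2 - (zk - xyz[i, 3])^2, 0))
  fully <- rep(FALSE, n_slices)
  iv <- vector("list", n_slices)    # occlusion intervals per slice
  for (j in nb) {
    dx <- xyz[j, 1] - xyz[i, 1]; dy <- xyz[j, 2] - xyz[i, 2]
    d <- sqrt(dx^2 + dy^2)
    u <- zk - xyz[j, 3]
    act <- which(abs(u) < R[j] & !fully)
    if (!length(act)) next
    rho_j <- sqrt(R[j]^2 - u[act]^2)
    if (d < 1e-9) {
      # coincident in-plane centres: the larger slab circle buries the
      # smaller one completely
      full <- rho_j >= rho_i[act]
      fully[act[full]] <- TRUE
      next
    }
    buried <- d + rho_i[act] <= rho_j
    fully[act[buried]] <- TRUE
    part <- !buried & (d < rho_i[act] + rho_j) & (d + rho_j > rho_i[act]) &
      rho_i[act] > 0
    if (any(part)) {
      pa <- act[part]
      cosa <- (d^2 + rho_i[pa]^2 - rho_j[part]^2) / (2 * d * rho_i[pa])
      alpha <- acos(pmin(pmax(cosa, -1), 1))
      phi <- atan2(dy, dx)
      for (m in seq_along(pa)) {
        k <- pa[m]
        iv[[k]] <- c(iv[[k]], phi - alpha[m], phi + alpha[m])
      }
    }
  }
  frac <- numeric(n_slices)
  for (k in seq_len(n_slices)) {
    if (fully[k]) next
    if (is.null(iv[[k]])) { frac[k] <- 1; next }
    v <- matrix(iv[[k]], ncol = 2, byrow = TRUE)
    frac[k] <- 1 - occluded_angle(v[, 1], v[, 2]) / (2 * pi)
  }
  sum(frac) * 2 * pi * Ri * dz
}

# Deterministic quasi-uniform sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

point_accessible_fraction <- function(i, pts, xyz, R, nb) {
  p <- sweep(pts * R[i], 2, xyz[i, ], "+")
  ok <- rep(TRUE, nrow(p))
  for (j in nb) {
    d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
      (p[, 3] - xyz[j, 3])^2
    ok <- ok & d2 > R[j]^2
    if (!any(ok)) break
  }
  mean(ok)
}

#' Per-atom exposed surface area
#'
#' Computes the solvent-excluded surface area of every atom at probe
#' radius `probe_radius`, by Lee-Richards slab integration (default) or
#' Shrake-Rupley point sampling.  Hydrogens get area 0 and do not
#' occlude.
#'
#' @param model An `"amine_structure"` (cleaned).
#' @param probe_radius Probe radius in Angstrom (default 4.2, the ATRP
#'   initiator).
#' @param algorithm `"lee-richards"` or `"shrake-rupley"`.
#' @param resolution Slices per atom (Lee-Richards) or points per sphere
#'   (Shrake-Rupley).
#' @param radii Optional explicit per-atom radii overriding
#'   [atom_radii()].
#' @return Numeric vector of areas in Angstrom^2, one per atom row of
#'   `model$atoms`.
#' @examples
#' sph <- build_sphere_cluster(matrix(0, 1, 3), radii = 1.8)
#' atom_sasa(sph, probe_radius = 1.4)   # 4*pi*3.2^2
#' @export
atom_sasa <- function(model, probe_radius = 4.2,
                      algorithm = c("lee-richards", "shrake-rupley"),
                      resolution = 100, radii = NULL) {
  stopifnot(inherits(model, "amine_structure"))
  algorithm <- match.arg(algorithm)
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (resolution < 20) stop("resolution must be at least 20")
  a <- model$atoms
  r <- if (is.null(radii)) atom_radii(a) else radii
  stopifnot(length(r) == nrow(a))
  heavy <- which(r > 0)
  areas <- numeric(nrow(a))
  if (!length(heavy)) return(areas)
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  R <- r[heavy] + probe_radius
  # coincident heavy-atom centres fully occlude their duplicates
  if (anyDuplicated(round(xyz, 6)))
    warning("coincident atom centres treated as fully occluding duplicates")
  nb <- neighbor_list(xyz, R)
  if (algorithm == "lee-richards") {
    for (m in seq_along(heavy))
      areas[heavy[m]] <- lee_richards_atom(m, xyz, R, nb[[m]], resolution)
  } else {
    pts <- sphere_points(resolution)
    for (m in seq_along(heavy))
      areas[heavy[m]] <- 4 * pi * R[m]^2 *
        point_accessible_fraction(m, pts, xyz, R, nb[[m]])
  }
  areas
}

#' Monte-Carlo SASA oracle
#'
#' Independent stochastic estimate of the same quantity as
#' [atom_sasa()]: for each atom, the fraction of uniformly random points
#' on its inflated sphere lying outside all neighbouring inflated
#' spheres, times the isolated-sphere area.  Intended as a test oracle;
#' seeded and reproducible.
#'
#' @inheritParams atom_sasa
#' @param n_points Random points per atom (at least 10^4).
#' @param seed Integer RNG seed.
#' @return List with `area` (numeric vector, Angstrom^2) and `se`
#'   (binomial standard error of each estimate, Angstrom^2).
#' @export
mc_atom_sasa <- function(model, probe_radius = 4.2, n_points = 1e4,
                         seed = 1, radii = NULL) {
  stopifnot(inherits(model, "amine_structure"))
  if (n_points < 1e4) stop("n_points must be at least 10^4")
  a <- model$atoms
  r <- if (is.null(radii)) atom_radii(a) else radii
  heavy <- which(r > 0)
  area <- se <- numeric(nrow(a))
  if (!length(heavy)) return(list(area = area, se = se))
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  R <- r[heavy] + probe_radius
  nb <- neighbor_list(xyz, R)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (m in seq_along(heavy)) {
    g <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    pts <- g / sqrt(rowSums(g^2))
    f <- point_accessible_fraction(m, pts, xyz, R, nb[[m]])
    area[heavy[m]] <- 4 * pi * R[m]^2 * f
    se[heavy[m]] <- 4 * pi * R[m]^2 * sqrt(f * (1 - f) / n_points)
  }
  list(area = area, se = se)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Residue-level exposed surface area for amine sites
#'
#' The ESA of a site is the sum of the atom areas of its residue (for
#' alpha sites on a non-lysine first residue, that residue's atoms).
#'
#' @param model The `"amine_structure"` the areas were computed on.
#' @param areas Per-atom areas from [atom_sasa()].
#' @param sites Site table from [amine_sites()].
#' @return Numeric vector of residue ESA values, one per site row.
#' @export
residue_esa <- function(model, areas, sites) {
  a <- model$atoms
  stopifnot(length(areas) == nrow(a))
  key <- residue_key(a$chain, a$resno, a$insert)
  out <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    k <- residue_key(sites$chain[i], sites$resno[i], sites$insert[i])
    sel <- key == k
    if (!any(sel)) stop("site residue not found in model: ", sites$site_id[i])
    out[i] <- sum(areas[sel])
  }
  out
}
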