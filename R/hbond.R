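# Geometric hydrogen-bond detection in the style of Baker-Hubbard,
# using the donor--acceptor distance convention: a bond is any
# (donor N/O, covalent H, acceptor N/O/S) triple with D-A distance at
# most the cutoff and D-H-A angle at least the cutoff, donor and
# acceptor in different residues.

#' Detect hydrogen bonds by geometric criteria
#'
#' Donors are nitrogen or oxygen atoms with a covalently attached
#' hydrogen (D-H at most 1.2 Angstrom); acceptors are N, O or S.  A
#' triple qualifies when the heavy-atom D-A distance is at most
#' `d_a_cutoff` and the D-H-A angle is at least `angle_cutoff`.
#' Intra-residue pairs are excluded; salt bridges count if the geometry
#' qualifies.
#'
#' @param model A protonated `"amine_structure"` (see
#'   [add_hydrogens()]).
#' @param d_a_cutoff Maximum donor--acceptor distance (Angstrom).
#' @param angle_cutoff Minimum donor-H-acceptor angle (degrees).
#' @return Data frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor` (atom row indices), `distance` (Angstrom), `angle`
#'   (degrees).
#' @examples
#' g <- build_hbond_geometry(d_a = 2.9, angle = 180)
#' detect_hbonds(g)
#' @export
detect_hbonds <- function(model, d_a_cutoff = 3.0, angle_cutoff = 150) {
  stopifnot(inherits(model, "amine_structure"))
  a <- model$atoms
  h_idx <- which(a$elem == "H")
  if (!length(h_idx))
    stop("no hydrogens in model; run add_hydrogens() first")
  heavy_d <- which(a$elem %in% c("N", "O"))
  heavy_a <- which(a$elem %in% c("N", "O", "S"))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rkey <- residue_key(a$chain, a$resno, a$insert)
  out <- list()
  for (h in h_idx) {
    dd <- sqrt(colSums((t(xyz[heavy_d, , drop = FALSE]) - xyz[h, ])^2))
    don <- heavy_d[dd <= 1.2]
    if (!length(don)) next
    don <- don[which.min(dd[dd <= 1.2])]
    da <- sqrt(colSums((t(xyz[heavy_a, , drop = FALSE]) - xyz[don, ])^2))
    cand <- heavy_a[da <= d_a_cutoff & heavy_a != don &
                      rkey[heavy_a] != rkey[don]]
    for (acc in cand) {
      v1 <- xyz[don, ] - xyz[h, ]
      v2 <- xyz[acc, ] - xyz[h, ]
      ang <- acos(pmin(pmax(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)),
                            -1), 1)) * 180 / pi
      if (ang >= angle_cutoff)
        out[[length(out) + 1]] <- data.frame(
          donor = don, hydrogen = h, acceptor = acc,
          distance = sqrt(sum((xyz[acc, ] - xyz[don, ])^2)),
          angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Is an amine site a hydrogen-bond donor?
#'
#' True when the site's amine nitrogen (backbone N for alpha sites, NZ
#' for epsilon sites) appears as the donor heavy atom of at least one
#' detected bond.  Acting only as an acceptor does not count.
#'
#' @param site One row of the [amine_sites()] table.
#' @param bonds Bond table from [detect_hbonds()] computed on the same
#'   model.
#' @return Logical.
#' @export
is_amine_donor <- function(site, bonds) {
  stopifnot(nrow(site) == 1)
  site$n_idx %in% bonds$donor
}
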