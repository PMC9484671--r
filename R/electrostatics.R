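# Local Coulomb electrostatics from PQR partial charges.  The energy at
# an amine nitrogen is the full pairwise sum k q_i q_j / (eps r_ij)
# over all charges outside the amine's own residue; no distance cutoff
# is applied.  Energies above 100 kcal/mol (strictly) flag an area of
# low positive charge.

COULOMB_K <- 332.0637   # kcal * Angstrom / (mol * e^2)

#' Coulomb electrostatic energy at one charged atom
#'
#' \deqn{E_i = \sum_{j} k\, q_i q_j / (\epsilon\, r_{ij})} with
#' k = 332.0637 kcal A / (mol e^2), summed over every other charged
#' atom; atoms of the target's own residue are excluded when
#' `exclude_same_residue` (local-environment semantics).  Pairs closer
#' than 0.5 Angstrom are skipped with a warning.
#'
#' @param charged Charged-atom data frame (see [read_pqr()]).
#' @param target Row index of the target atom in `charged`.
#' @param dielectric Relative dielectric constant (> 0).
#' @param exclude_same_residue Drop the target residue's own charges.
#' @return Energy in kcal/mol.
#' @examples
#' atom_coulomb_energy(build_calibration_pair(), 1)   # 100 kcal/mol
#' @export
atom_coulomb_energy <- function(charged, target, dielectric = 1,
                                exclude_same_residue = TRUE) {
  if (dielectric <= 0) stop("dielectric must be positive")
  n <- nrow(charged)
  if (length(target) != 1 || is.na(target) || target < 1 || target > n)
    stop("target atom not found in charge list")
  dx <- charged$x - charged$x[target]
  dy <- charged$y - charged$y[target]
  dz <- charged$z - charged$z[target]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  sel <- seq_len(n) != target
  if (exclude_same_residue) {
    key <- residue_key(charged$chain, charged$resno, charged$insert)
    sel <- sel & key != key[target]
  }
  close <- sel & r < 0.5
  if (any(close)) {
    warning(sum(close), " pair(s) closer than 0.5 Angstrom skipped")
    sel <- sel & !close
  }
  if (!any(sel)) return(0)
  sum(COULOMB_K * charged$charge[target] * charged$charge[sel] /
        (dielectric * r[sel]))
}

#' Coulomb energy and low-positive-charge flag for an amine site
#'
#' Evaluates the energy at the site's amine nitrogen (NZ for epsilon
#' sites, backbone N for alpha sites) as found in the PQR charge set,
#' and flags the site when the energy strictly exceeds the threshold
#' ("greater than" is strict: exactly 100 kcal/mol does not flag).
#'
#' @param charged Charged-atom data frame (see [read_pqr()]).
#' @param site One row of the [amine_sites()] table.
#' @param config A [react_config()].
#' @return List with `energy` (kcal/mol) and `low_positive_charge`
#'   (logical).
#' @export
site_charge_flag <- function(charged, site, config = react_config()) {
  stopifnot(nrow(site) == 1)
  want <- if (site$kind == "epsilon") "NZ" else "N"
  hit <- which(charged$chain == site$chain &
                 charged$resno == site$resno &
                 charged$insert == site$insert &
                 charged$name == want)
  if (length(hit) != 1)
    stop("atom ", want, " for site ", site$site_id,
         " not found in PQR charge set")
  e <- atom_coulomb_energy(charged, hit, dielectric = config$dielectric,
                           exclude_same_residue = config$exclude_same_residue)
  list(energy = e, low_positive_charge = e > config$charge_threshold)
}
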