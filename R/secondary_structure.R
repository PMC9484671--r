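# Kabsch-Sander secondary-structure assignment from atomic coordinates.
# Backbone hydrogen bonds are scored with the classic electrostatic
# energy model E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)
# kcal/mol; a bond exists below -0.5 kcal/mol.  n-turns, the minimal-
# helix rule, bridge/ladder detection, turns and bends then yield the
# 8-state alphabet {H,G,I,E,B,T,S,-}, collapsed to helix/strand/coil by
# the standard convention {H,G,I} / {E,B} / {T,S,-}.

KS_Q <- 0.084 * 332          # kcal/mol * Angstrom
KS_EMIN <- -0.5              # bond threshold
KS_ECLIP <- -9.9             # clamp for near-contact geometries

# Per-residue backbone coordinate table.  The amide H is the placed
# hydrogen when present, otherwise the classic DSSP estimate
# N + (unit(N - C_prev) + unit(N - O_prev)) normalised to 1.01 A.
backbone_table <- function(model) {
  a <- model$atoms
  std <- !a$het & a$resname %in% STANDARD_AA
  res <- residue_index(a[std, , drop = FALSE])
  sub <- a[std, , drop = FALSE]
  n <- length(res)
  get <- function(idx, nm) {
    i <- idx[sub$name[idx] == nm]
    if (length(i)) c(sub$x[i[1]], sub$y[i[1]], sub$z[i[1]]) else NULL
  }
  out <- vector("list", n)
  for (ri in seq_len(n)) {
    idx <- res[[ri]]
    out[[ri]] <- list(
      chain = sub$chain[idx[1]], resno = sub$resno[idx[1]],
      insert = sub$insert[idx[1]], resname = sub$resname[idx[1]],
      N = get(idx, "N"), CA = get(idx, "CA"),
      C = get(idx, "C"), O = get(idx, "O"), H = get(idx, "H"))
  }
  # estimate missing amide hydrogens from the preceding carbonyl
  for (ri in seq_len(n)) {
    r <- out[[ri]]
    if (!is.null(r$H) || is.null(r$N) || r$resname == "PRO") next
    if (ri == 1 || out[[ri - 1]]$chain != r$chain) next
    p <- out[[ri - 1]]
    if (is.null(p$C) || is.null(p$O)) next
    d <- unitv(unitv(r$N - p$C) + unitv(r$N - p$O))
    out[[ri]]$H <- r$N + 1.01 * d
  }
  out
}

#' Kabsch-Sander backbone hydrogen bonds
#'
#' Scores every donor (backbone N-H) against candidate acceptors
#' (backbone C=O) with the Kabsch-Sander electrostatic energy and keeps
#' bonds with energy below -0.5 kcal/mol, at most the two lowest-energy
#' acceptors per donor.  Prolines and chain-initial residues cannot
#' donate; self-bonds are excluded, sequence-adjacent pairs are allowed.
#'
#' @param model An `"amine_structure"` with backbone N, CA, C, O (amide
#'   H placed or estimated internally).
#' @return A list with `bonds` (data frame: `donor`, `acceptor` as
#'   residue indices, `energy` kcal/mol) and `residues` (the residue
#'   table the indices refer to).
#' @export
ks_hbonds <- function(model) {
  bt <- backbone_table(model)
  n <- length(bt)
  ca <- t(vapply(bt, function(r) if (is.null(r$CA)) c(NA, NA, NA) else r$CA,
                 numeric(3)))
  don <- which(vapply(bt, function(r)
    !is.null(r$N) && !is.null(r$H) && r$resname != "PRO", logical(1)))
  acc <- which(vapply(bt, function(r)
    !is.null(r$C) && !is.null(r$O), logical(1)))
  skipped <- setdiff(seq_len(n), union(don, acc))
  if (length(skipped))
    warning("residues with incomplete backbone skipped: ",
            length(skipped))
  bonds <- list()
  for (i in don) {
    if (anyNA(ca[i, ])) next
    # CA-CA prefilter at 9 A, the classic neighbourhood bound
    cand <- acc[acc != i]
    d2 <- (ca[cand, 1] - ca[i, 1])^2 + (ca[cand, 2] - ca[i, 2])^2 +
      (ca[cand, 3] - ca[i, 3])^2
    cand <- cand[!is.na(d2) & d2 < 81]
    if (!length(cand)) next
    e <- vapply(cand, function(j) {
      r <- bt[[j]]
      rON <- vnorm(r$O - bt[[i]]$N); rCH <- vnorm(r$C - bt[[i]]$H)
      rOH <- vnorm(r$O - bt[[i]]$H); rCN <- vnorm(r$C - bt[[i]]$N)
      if (min(rON, rCH, rOH, rCN) < 0.5) return(KS_ECLIP)
      KS_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }, numeric(1))
    keep <- which(e < KS_EMIN)
    if (!length(keep)) next
    keep <- keep[order(e[keep])][seq_len(min(2, length(keep)))]
    bonds[[length(bonds) + 1]] <-
      data.frame(donor = i, acceptor = cand[keep], energy = e[keep])
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds)
  else data.frame(donor = integer(), acceptor = integer(),
                  energy = numeric())
  rownames(bonds) <- NULL
  list(bonds = bonds, residues = bt)
}

#' Assign 8-state secondary structure and its 3-state collapse
#'
#' Applies the Kabsch-Sander rules to the backbone hydrogen-bond set:
#' n-turn detection (bonds CO(i) <- NH(i+n), n = 3, 4, 5), the minimal
#' helix rule (two consecutive n-turns) for G/H/I, bridge and ladder
#' detection for B/E, hydrogen-bonded turns T, and bends S (CA direction
#' change above 70 degrees).  Conflicts resolve by the fixed priority
#' H > E > G > I > B > T > S > '-'.
#'
#' @param model An `"amine_structure"`.
#' @return A data frame with one row per standard residue: `chain`,
#'   `resno`, `insert`, `resname`, `ss8`, `ss3`.
#' @examples
#' h <- build_ideal_helix(12)
#' table(assign_ss(h)$ss3)
#' @export
assign_ss <- function(model) {
  ks <- ks_hbonds(model)
  bt <- ks$residues
  n <- length(bt)
  hb <- matrix(FALSE, n, n)   # hb[acceptor, donor]
  if (nrow(ks$bonds)) hb[cbind(ks$bonds$acceptor, ks$bonds$donor)] <- TRUE
  same_chain_run <- function(i, j) {
    # residues i..j consecutive rows of one chain
    j <= n && i >= 1 &&
      all(vapply((i:j)[-1], function(k)
        bt[[k]]$chain == bt[[i]]$chain, logical(1)))
  }
  turn <- list()
  for (nn in 3:5) {
    t_ <- rep(FALSE, n)
    if (n > nn) for (i in seq_len(n - nn))
      if (same_chain_run(i, i + nn) && hb[i, i + nn]) t_[i] <- TRUE
    turn[[as.character(nn)]] <- t_
  }
  ss <- rep("-", n)
  set_if_lower <- function(idx, code) {
    pri <- c(H = 7, E = 6, G = 5, I = 4, B = 3, T = 2, S = 1, "-" = 0)
    for (k in idx) if (pri[[code]] > pri[[ss[k]]]) ss[k] <<- code
  }
  # bends first (lowest priority)
  if (n >= 5) for (i in 3:(n - 2)) {
    if (!same_chain_run(i - 2, i + 2)) next
    u <- bt[[i]]$CA - bt[[i - 2]]$CA
    v <- bt[[i + 2]]$CA - bt[[i]]$CA
    if (is.null(u) || is.null(v)) next
    ang <- acos(pmin(pmax(sum(u * v) / (vnorm(u) * vnorm(v)), -1), 1)) *
      180 / pi
    if (ang > 70) set_if_lower(i, "S")
  }
  # hydrogen-bonded turns
  for (nn in 3:5) {
    t_ <- turn[[as.character(nn)]]
    for (i in which(t_)) set_if_lower((i + 1):(i + nn - 1), "T")
  }
  # bridges and ladders
  bridge <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) <= 2 && bt[[i]]$chain == bt[[j]]$chain) next
    if (i >= j) next
    par <- (i > 1 && j < n && hb[i - 1, j] && hb[j, i + 1]) ||
      (j > 1 && i < n && j < n && hb[j - 1, i] && hb[i, j + 1])
    anti <- (hb[i, j] && hb[j, i]) ||
      (i > 1 && j < n && i < n && j > 1 &&
         hb[i - 1, j + 1] && hb[j - 1, i + 1])
    if (par || anti)
      bridge <- rbind(bridge, c(i, j))
  }
  if (!is.null(bridge)) {
    in_ladder <- rep(FALSE, nrow(bridge))
    for (b in seq_len(nrow(bridge))) {
      i <- bridge[b, 1]; j <- bridge[b, 2]
      others <- bridge[-b, , drop = FALSE]
      if (nrow(others) &&
          any(abs(others[, 1] - i) == 1 & abs(others[, 2] - j) == 1))
        in_ladder[b] <- TRUE
    }
    for (b in seq_len(nrow(bridge)))
      set_if_lower(bridge[b, ], if (in_ladder[b]) "E" else "B")
  }
  # helices: two consecutive n-turns
  helix_mark <- function(t_, len, code) {
    for (i in which(t_))
      if (i > 1 && t_[i - 1]) set_if_lower(i:(i + len - 1), code)
  }
  helix_mark(turn[["5"]], 5, "I")
  helix_mark(turn[["3"]], 3, "G")
  helix_mark(turn[["4"]], 4, "H")
  ss3 <- ifelse(ss %in% c("H", "G", "I"), "helix",
                ifelse(ss %in% c("E", "B"), "strand", "coil"))
  data.frame(
    chain = vapply(bt, `[[`, "", "chain"),
    resno = vapply(bt, `[[`, 0L, "resno"),
    insert = vapply(bt, `[[`, "", "insert"),
    resname = vapply(bt, `[[`, "", "resname"),
    ss8 = ss, ss3 = ss3, stringsAsFactors = FALSE)
}
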