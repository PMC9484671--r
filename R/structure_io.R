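#' @importFrom stats ave setNames
#' @importFrom utils head read.table write.csv
NULL

# Twenty standard amino-acid three-letter codes; everything else is
# treated as hetero unless whitelisted.
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

new_structure <- function(atoms, provenance = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "elem", "resname", "chain", "resno",
            "insert", "x", "y", "z", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  atoms$name <- trimws(atoms$name)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 chains = unique(atoms$chain),
                 provenance = provenance),
            class = "amine_structure")
}

#' Read a protein structure from a PDB file
#'
#' Parses the fixed-column PDB format into an atom table.  Only the
#' first MODEL of a multi-model file is kept; for alternate locations
#' the highest-occupancy conformer wins, with ties resolved in favour of
#' altloc "A".  ANISOU and TER records are ignored.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @return An object of class `"amine_structure"`: a list with an
#'   `atoms` data frame (serial, name, elem, resname, chain, resno,
#'   insert, x, y, z, het), the chain list, and provenance.
#' @examples
#' helix <- build_ideal_helix(8, "AAAAKAAA")
#' pdb <- tempfile(fileext = ".pdb")
#' write_pdb_file(helix, pdb)
#' m <- read_structure(pdb)
#' nrow(m$atoms)
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("empty structure: no ATOM records in ", path)
  elem <- trimws(a$elesy)
  guess <- toupper(substr(gsub("[0-9'\"]", "", trimws(a$elety)), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    alt = ifelse(is.na(a$alt), "", a$alt),
    elem = toupper(elem),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  atoms$alt <- atoms$occ <- NULL
  if (!any(!atoms$het))
    warning("structure contains only HETATM records")
  new_structure(atoms, provenance = list(source = path))
}

# Highest occupancy wins within each (chain, resno, insert, name) group;
# exact occupancy tie prefers altloc "A", then file order.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name,
               atoms$resname, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$alt != "A", seq_len(nrow(atoms)))
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]
}

#' Remove waters (and optionally all hetero groups) from a structure
#'
#' Water molecules are always removed.  Other HETATM groups (cofactors,
#' ligands, modified residues such as MSE) are removed unless
#' `keep_hetero = TRUE`.
#'
#' @param model An `"amine_structure"`.
#' @param keep_hetero Retain non-water hetero atoms.
#' @param quiet Suppress the removal-count message.
#' @return The cleaned `"amine_structure"`.
#' @export
clean_structure <- function(model, keep_hetero = FALSE, quiet = FALSE) {
  stopifnot(inherits(model, "amine_structure"))
  a <- model$atoms
  is_water <- a$resname %in% WATER_NAMES
  drop <- is_water
  if (!keep_hetero) drop <- drop | (a$het & !is_water)
  if (!quiet)
    message(sprintf("clean_structure: removed %d water and %d other hetero atoms",
                    sum(is_water), sum(drop) - sum(is_water)))
  a <- a[!drop, , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure: nothing left after cleaning")
  prov <- model$provenance
  prov$cleaned <- TRUE
  prov$keep_hetero <- keep_hetero
  new_structure(a, prov)
}

#' Restrict a structure to a chain subset (assembly selection)
#'
#' Used to score one biological unit of a crystallographic oligomer,
#' e.g. a single monomer of a dimer.  All downstream parameters must be
#' recomputed on the subset; nothing is cached across subsets.
#'
#' @param model An `"amine_structure"`.
#' @param chains Character vector of chain identifiers to keep.
#' @return The restricted `"amine_structure"`.
#' @export
select_chains <- function(model, chains) {
  stopifnot(inherits(model, "amine_structure"))
  unknown <- setdiff(chains, model$chains)
  if (length(unknown))
    stop("unknown chain(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(model$chains, collapse = ", "))
  a <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  prov <- model$provenance
  prov$chains <- chains
  new_structure(a, prov)
}

#' Enumerate the primary-amine sites of a structure
#'
#' One epsilon site per lysine (its NZ nitrogen) and one alpha site per
#' chain at the chain's first standard residue (its backbone N).  An
#' N-terminal lysine therefore contributes two sites.  Order is
#' deterministic: by chain, then residue number, alpha before epsilon.
#'
#' @param model A cleaned `"amine_structure"`.
#' @return A data frame with columns `site_id`
#'   (`"<chain>:<resno><icode>:<alpha|epsilon>"`), `chain`, `resno`,
#'   `insert`, `resname`, `kind`, and `n_idx` (row index of the amine
#'   nitrogen in `model$atoms`).
#' @export
amine_sites <- function(model) {
  stopifnot(inherits(model, "amine_structure"))
  a <- model$atoms
  out <- list()
  for (ch in model$chains) {
    ai <- which(a$chain == ch & !a$het & a$resname %in% STANDARD_AA)
    if (!length(ai)) {
      warning("chain ", ch, " has no standard residues; skipped")
      next
    }
    sub <- a[ai, , drop = FALSE]
    # alpha site: backbone N of the first standard residue in the chain
    first <- ai[1]
    fr <- a[first, ]
    n_idx <- ai[sub$resno == fr$resno & sub$insert == fr$insert &
                  sub$name == "N"]
    if (length(n_idx) == 1) {
      out[[length(out) + 1]] <- data.frame(
        site_id = sprintf("%s:%d%s:alpha", ch, fr$resno, fr$insert),
        chain = ch, resno = fr$resno, insert = fr$insert,
        resname = fr$resname, kind = "alpha", n_idx = n_idx,
        stringsAsFactors = FALSE)
    } else {
      warning("chain ", ch, " first residue lacks a backbone N; ",
              "alpha site skipped")
    }
    # epsilon sites: NZ of every lysine
    nz <- ai[sub$resname == "LYS" & sub$name == "NZ"]
    for (i in nz) {
      r <- a[i, ]
      out[[length(out) + 1]] <- data.frame(
        site_id = sprintf("%s:%d%s:epsilon", r$chain, r$resno, r$insert),
        chain = r$chain, resno = r$resno, insert = r$insert,
        resname = r$resname, kind = "epsilon", n_idx = i,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(site_id = character(), chain = character(),
                      resno = integer(), insert = character(),
                      resname = character(), kind = character(),
                      n_idx = integer(), stringsAsFactors = FALSE))
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$chain, sites$resno, sites$insert,
                       sites$kind != "alpha"), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# Residue-level split helper: list of atom-row indices keyed by
# "chain|resno|insert", in structure order.
residue_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
}

residue_key <- function(chain, resno, insert) {
  paste(chain, resno, insert, sep = "|")
}

#' Add missing amide and amine hydrogens by geometric placement
#'
#' Deterministic geometric protonation sufficient for hydrogen-bond
#' analysis: a backbone amide H is placed 1.01 Angstrom from N along the
#' bisector of the N-C(prev) and N-O(prev) directions (anti to the
#' preceding carbonyl); a lysine NZ and a chain-terminal alpha-amino N
#' each receive three tetrahedral hydrogens at 1.01 Angstrom.  Residues
#' that already carry the hydrogen are left untouched, and prolines get
#' no amide H.
#'
#' @param model A cleaned `"amine_structure"`.
#' @return The protonated `"amine_structure"`.
#' @export
add_hydrogens <- function(model) {
  stopifnot(inherits(model, "amine_structure"))
  a <- model$atoms
  res <- residue_index(a)
  keys <- names(res)
  new_rows <- list()
  serial0 <- max(a$serial)
  get_atom <- function(idx, nm) {
    i <- idx[a$name[idx] == nm]
    if (length(i)) as.numeric(a[i[1], c("x", "y", "z")]) else NULL
  }
  mk <- function(template_idx, nm, xyz) {
    r <- a[template_idx, , drop = FALSE]
    r$serial <- serial0 + length(new_rows) + 1L
    r$name <- nm; r$elem <- "H"
    r$x <- xyz[1]; r$y <- xyz[2]; r$z <- xyz[3]
    r
  }
  tetra_h <- function(n_pos, heavy_pos, ref_pos, names) {
    # three H on a cone at 109.47 deg from the heavy->N axis, staggered
    # relative to the reference substituent of the heavy atom
    axis <- unitv(n_pos - heavy_pos)
    r0 <- ref_pos - heavy_pos
    perp <- r0 - sum(r0 * axis) * axis
    perp <- if (vnorm(perp) < 1e-6) {
      b <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      unitv(b - sum(b * axis) * axis)
    } else unitv(perp)
    perp2 <- c(axis[2] * perp[3] - axis[3] * perp[2],
               axis[3] * perp[1] - axis[1] * perp[3],
               axis[1] * perp[2] - axis[2] * perp[1])
    ang <- (109.47 / 180) * pi
    out <- list()
    for (k in 0:2) {
      # staggered: offset 60 deg from the reference, then 120 deg apart
      phi <- pi + (pi / 3) + k * (2 * pi / 3)
      d <- cos(pi - ang) * axis +
        sin(pi - ang) * (cos(phi) * perp + sin(phi) * perp2)
      out[[k + 1]] <- n_pos + 1.01 * unitv(d)
    }
    setNames(out, names)
  }

  chain_first <- tapply(seq_along(keys), sub("\\|.*", "", keys), min)
  for (ri in seq_along(res)) {
    idx <- res[[ri]]
    rn <- a$resname[idx[1]]
    if (!(rn %in% STANDARD_AA)) next
    ch <- a$chain[idx[1]]
    is_first <- ri == chain_first[[ch]]
    N <- get_atom(idx, "N"); CA <- get_atom(idx, "CA")
    # backbone amide H (not for proline, not for the chain's first residue)
    if (!is_first && rn != "PRO" && !is.null(N) &&
        !any(a$name[idx] == "H")) {
      prev <- res[[ri - 1]]
      same_chain <- a$chain[prev[1]] == ch
      Cp <- if (same_chain) get_atom(prev, "C") else NULL
      Op <- if (same_chain) get_atom(prev, "O") else NULL
      if (is.null(Cp) || is.null(Op)) {
        warning("amide H skipped for ", rn, " ", a$resno[idx[1]],
                ": preceding residue atoms missing")
      } else {
        d <- unitv(unitv(N - Cp) + unitv(N - Op))
        new_rows[[length(new_rows) + 1]] <- mk(idx[1], "H", N + 1.01 * d)
      }
    }
    # alpha-amino hydrogens on the chain's first standard residue
    if (is_first && rn != "PRO" && !is.null(N) && !is.null(CA) &&
        !any(a$name[idx] %in% c("H1", "H2", "H3"))) {
      Cx <- get_atom(idx, "C")
      ref <- if (is.null(Cx)) CA + c(1, 0, 0) else Cx
      hs <- tetra_h(N, CA, ref, c("H1", "H2", "H3"))
      for (nm in names(hs))
        new_rows[[length(new_rows) + 1]] <- mk(idx[1], nm, hs[[nm]])
    }
    # lysine zeta hydrogens
    if (rn == "LYS" && !any(a$name[idx] %in% c("HZ1", "HZ2", "HZ3"))) {
      NZ <- get_atom(idx, "NZ"); CE <- get_atom(idx, "CE")
      CD <- get_atom(idx, "CD")
      if (!is.null(NZ) && !is.null(CE)) {
        ref <- if (is.null(CD)) CE + c(0, 0, 1) else CD
        hs <- tetra_h(NZ, CE, ref, c("HZ1", "HZ2", "HZ3"))
        for (nm in names(hs))
          new_rows[[length(new_rows) + 1]] <- mk(idx[1], nm, hs[[nm]])
      }
    }
  }
  if (!length(new_rows)) return(model)
  a2 <- rbind(a, do.call(rbind, new_rows))
  prov <- model$provenance
  prov$protonated <- TRUE
  new_structure(a2, prov)
}

#' Write an atom table to a fixed-column PDB file
#'
#' @param model An `"amine_structure"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(model, path) {
  stopifnot(inherits(model, "amine_structure"))
  a <- model$atoms
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  nm <- vapply(a$name, function(s)
    if (nchar(s) < 4) sprintf(" %-3s", s) else sprintf("%-4s", s), "")
  lines <- sprintf("%s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000L, nm, a$resname,
                   substr(paste0(a$chain, " "), 1, 1), a$resno,
                   substr(paste0(a$insert, " "), 1, 1),
                   a$x, a$y, a$z, 1, 0, a$elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PQR file of partial charges and radii
#'
#' Parses the whitespace-delimited PQR dialect written by PDB2PQR:
#' `record serial name resname [chain] resnum x y z charge radius`.
#' The chain column may be absent, in which case all atoms are assigned
#' chain "A".
#'
#' @param path Path to a PQR file.
#' @return A data frame of charged atoms: `serial`, `name`, `resname`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `charge` (elementary
#'   charges) and `radius` (Angstrom).
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM|HETATM)", lines)
  if (!any(sel)) stop("no ATOM records in PQR file ", path)
  rows <- vector("list", sum(sel))
  k <- 0
  for (li in which(sel)) {
    tok <- strsplit(trimws(lines[li]), "\\s+")[[1]]
    has_chain <- length(tok) >= 11 && is.na(suppressWarnings(as.numeric(tok[5])))
    if (length(tok) < if (has_chain) 11 else 10)
      stop("PQR parse error at line ", li, ": too few fields")
    o <- if (has_chain) 1L else 0L
    chain <- if (has_chain) tok[5] else "A"
    resfield <- tok[5 + o]
    insert <- sub("^-?[0-9]+", "", resfield)
    resno <- suppressWarnings(as.integer(sub("([0-9])[A-Za-z]$", "\\1",
                                             resfield)))
    num <- suppressWarnings(as.numeric(tok[(6 + o):(10 + o)]))
    if (any(is.na(num)) || is.na(resno))
      stop("PQR parse error at line ", li, ": non-numeric field")
    k <- k + 1
    rows[[k]] <- data.frame(
      serial = suppressWarnings(as.integer(tok[2])),
      name = tok[3], resname = tok[4], chain = chain,
      resno = resno, insert = insert,
      x = num[1], y = num[2], z = num[3],
      charge = num[4], radius = num[5], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (any(out$radius <= 0))
    stop("PQR file contains non-positive radii")
  tot <- tapply(out$charge, out$chain, sum)
  message("read_pqr: per-chain charge sums ",
          paste(sprintf("%s=%.3f", names(tot), tot), collapse = ", "))
  out
}

#' Write a PQR file
#'
#' @param charged A data frame as returned by [read_pqr()].
#' @param path Output file path.
#' @param chain_column Include the chain identifier column.
#' @return `path`, invisibly.
#' @export
write_pqr_file <- function(charged, path, chain_column = TRUE) {
  fmt <- if (chain_column)
    sprintf("ATOM %6d %-4s %-4s %s %4d %11.4f %11.4f %11.4f %8.4f %7.4f",
            charged$serial, charged$name, charged$resname, charged$chain,
            charged$resno, charged$x, charged$y, charged$z,
            charged$charge, charged$radius)
  else
    sprintf("ATOM %6d %-4s %-4s %4d %11.4f %11.4f %11.4f %8.4f %7.4f",
            charged$serial, charged$name, charged$resname,
            charged$resno, charged$x, charged$y, charged$z,
            charged$charge, charged$radius)
  writeLines(fmt, path)
  invisible(path)
}

#' @export
print.amine_structure <- function(x, ...) {
  a <- x$atoms
  nres <- length(residue_index(a[!a$het, , drop = FALSE]))
  cat(sprintf("amine_structure: %d atoms, %d residues, chains %s\n",
              nrow(a), nres, paste(x$chains, collapse = ",")))
  if (!is.null(x$provenance$source))
    cat("  source:", x$provenance$source, "\n")
  invisible(x)
}
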