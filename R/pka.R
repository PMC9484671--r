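# Empirical amine pKa estimation.  The builtin backend is a transparent
# two-term heuristic: an unperturbed model pKa (10.5 for a lysine
# epsilon-amine, 8.0 for an alpha-amino terminus) shifted by a burial
# (desolvation) term and a distance-weighted charge-charge term.  Its
# only role in the pipeline is the pKa <= 10.3 branch of the decision
# tree; a PROPKA-compatible predictor can be registered as the
# "external" backend for higher-fidelity values.

pka_backends <- new.env(parent = emptyenv())

#' Register or retrieve a pKa backend
#'
#' A backend is a function `(model, site, config) -> list(pka, terms)`.
#' The `"builtin"` backend is always available; `"external"` must be
#' registered by the user (e.g. a wrapper around a PROPKA-compatible
#' predictor) and requesting it unregistered is a configuration error,
#' so a run fails before any scoring rather than silently degrading.
#'
#' @param name `"builtin"` or `"external"`.
#' @param fun When supplied, registers `fun` as the backend `name`.
#' @return The backend function, invisibly when registering.
#' @export
pka_backend <- function(name, fun = NULL) {
  if (!is.null(fun)) {
    if (!name %in% c("builtin", "external"))
      stop("unknown backend name '", name, "'; available: builtin, external")
    assign(name, fun, envir = pka_backends)
    return(invisible(fun))
  }
  if (name == "builtin") return(builtin_pka)
  if (name == "external") {
    if (!exists("external", envir = pka_backends))
      stop("configuration error: external pKa backend requested but none ",
           "registered; see ?pka_backend")
    return(get("external", envir = pka_backends))
  }
  stop("unknown backend name '", name, "'; available: builtin, external")
}

# Cationic and anionic charged-group atoms considered by the charge term.
charged_group_atoms <- function(atoms, sites = NULL) {
  anion <- (atoms$resname == "ASP" & atoms$name %in% c("OD1", "OD2")) |
    (atoms$resname == "GLU" & atoms$name %in% c("OE1", "OE2"))
  cation <- (atoms$resname == "ARG" & atoms$name == "CZ") |
    (atoms$resname == "LYS" & atoms$name == "NZ")
  # chain N-termini count as cationic groups
  if (!is.null(sites)) {
    alpha <- sites[sites$kind == "alpha", , drop = FALSE]
    if (nrow(alpha)) cation[alpha$n_idx] <- TRUE
  }
  list(anion = which(anion), cation = which(cation))
}

builtin_pka <- function(model, site, config = react_config()) {
  a <- model$atoms
  i <- site$n_idx
  n_pos <- c(a$x[i], a$y[i], a$z[i])
  model_pka <- if (site$kind == "epsilon") 10.5 else 8.0
  heavy <- a$elem != "H"
  d <- sqrt((a$x - n_pos[1])^2 + (a$y - n_pos[2])^2 + (a$z - n_pos[3])^2)
  # burial term: heavy-atom neighbour count above the baseline
  n_near <- sum(heavy & d <= config$pka_burial_radius) - 1  # exclude self
  desolv <- config$pka_burial_per_atom *
    max(0, n_near - config$pka_burial_baseline)
  # charge-charge term: anions raise, cations lower; the site's own
  # residue is excluded (it is the titrating group, not its environment)
  sites_all <- amine_sites(model)
  grp <- charged_group_atoms(a, sites_all)
  own <- residue_key(a$chain, a$resno, a$insert) ==
    residue_key(site$chain, site$resno, site$insert)
  shift_from <- function(idx, sign) {
    idx <- idx[!own[idx]]
    dd <- d[idx]
    idx <- idx[dd <= config$pka_charge_radius]
    dd <- dd[dd <= config$pka_charge_radius]
    if (!length(idx)) return(0)
    sum(sign * config$pka_charge_max * (1 - dd / config$pka_charge_radius))
  }
  chg <- shift_from(grp$anion, +1) + shift_from(grp$cation, -1)
  pka <- model_pka + desolv + chg
  list(pka = pka,
       terms = c(model = model_pka, desolvation = desolv, charge = chg))
}

#' Predict the pKa of one amine site
#'
#' Dispatches to the configured backend and validates the result.  The
#' builtin heuristic is documented in the methods vignette; its terms
#' are additive by construction (`pka = model + desolvation + charge`).
#' pH does not enter the predicted value; it is carried in the run
#' configuration for downstream interpretation only.
#'
#' @param model A cleaned `"amine_structure"`.
#' @param site One row of the [amine_sites()] table.
#' @param config A [react_config()].
#' @return A list with `pka`, the named `terms` breakdown, and
#'   `backend`.
#' @examples
#' h <- build_ideal_helix(6, "AAKAAA")
#' s <- amine_sites(h)
#' predict_pka(h, s[s$kind == "epsilon", ], react_config())$pka
#' @export
predict_pka <- function(model, site, config = react_config()) {
  stopifnot(inherits(model, "amine_structure"), nrow(site) == 1)
  i <- site$n_idx
  if (is.na(i) || i < 1 || i > nrow(model$atoms))
    stop("amine nitrogen missing for site ", site$site_id)
  expected <- if (site$kind == "epsilon") "NZ" else "N"
  if (model$atoms$name[i] != expected)
    stop("amine nitrogen missing for site ", site$site_id,
         " (expected atom ", expected, ")")
  fun <- pka_backend(config$pka_backend)
  res <- fun(model, site, config)
  if (!is.finite(res$pka) || res$pka <= 0 || res$pka >= 16)
    stop("backend returned an implausible pKa (", res$pka, ") for site ",
         site$site_id)
  res$backend <- config$pka_backend
  res
}
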