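# Orchestration: one call runs cleaning, assembly selection,
# protonation, the five predictor computations and the decision tree,
# and returns a classed result object with one row per amine site.

#' Predict the NHS-ester reactivity of every amine site in a protein
#'
#' The main entry point.  Takes a structure (PDB path or parsed
#' `"amine_structure"`) and a matching charge set (PQR path or parsed
#' table), computes for every lysine epsilon-amine and chain N-terminus
#' the exposed surface area at the configured probe radius, an
#' empirical pKa, the secondary-structure class, hydrogen-bond-donor
#' status and the local Coulomb energy, and classifies each site as
#' fast-, slow- or non-reacting.
#'
#' @param pdb Path to a PDB file, or an `"amine_structure"`.
#' @param pqr Path to a PQR file, or a charged-atom data frame from
#'   [read_pqr()].
#' @param config A [react_config()]; its `chains` field restricts the
#'   analysis to an assembly subset, in which case every parameter is
#'   recomputed on the subset.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `"amine_reactivity"`: a list with
#'   `table` (the per-site results, see Details), `config`, `sites`,
#'   `model` (the cleaned, protonated structure) and `provenance`.
#'
#' @details The result table has one row per amine site, ordered by
#' chain, residue number, alpha before epsilon, with columns `site_id`,
#' `residue_name`, `amine_kind`, `esa`, `pka`, `ss8`, `ss3`, `h_donor`,
#' `coulomb_energy`, `low_positive_charge`, `reactivity_class` and
#' `rule_path`.
#'
#' @examples
#' helix <- build_ideal_helix(12, "AAKAAAAKAAAA")
#' pqr <- helix_charge_set(helix)
#' fit <- amine_reactivity(helix, pqr, verbose = FALSE)
#' fit
#' @export
amine_reactivity <- function(pdb, pqr, config = react_config(),
                             verbose = TRUE) {
  stopifnot(inherits(config, "react_config"))
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  t0 <- proc.time()[["elapsed"]]
  model <- if (inherits(pdb, "amine_structure")) pdb else read_structure(pdb)
  charged <- if (is.data.frame(pqr)) pqr
  else suppressMessages(read_pqr(pqr))
  model <- clean_structure(model, keep_hetero = config$keep_hetero,
                           quiet = !verbose)
  if (!is.null(config$chains)) {
    model <- select_chains(model, config$chains)
    charged <- charged[charged$chain %in% config$chains, , drop = FALSE]
    if (!nrow(charged))
      stop("no PQR atoms on selected chain(s) ",
           paste(config$chains, collapse = ","))
  }
  # chain-less PQR dialect against a single-chain model: align labels
  if (length(model$chains) == 1 &&
      identical(unique(charged$chain), "A") &&
      model$chains != "A")
    charged$chain <- model$chains
  model <- add_hydrogens(model)
  sites <- amine_sites(model)
  if (!nrow(sites)) stop("no amine sites found after cleaning")
  say("sites", "%d amine sites (%d epsilon, %d alpha)", nrow(sites),
      sum(sites$kind == "epsilon"), sum(sites$kind == "alpha"))

  # PQR <-> PDB reconciliation: every site nitrogen must resolve
  miss <- character()
  for (i in seq_len(nrow(sites))) {
    want <- if (sites$kind[i] == "epsilon") "NZ" else "N"
    ok <- any(charged$chain == sites$chain[i] &
                charged$resno == sites$resno[i] &
                charged$insert == sites$insert[i] &
                charged$name == want)
    if (!ok) miss <- c(miss, sites$site_id[i])
  }
  if (length(miss))
    stop("PQR reconciliation failed; unmatched site nitrogens: ",
         paste(miss, collapse = ", "))

  areas <- atom_sasa(model, probe_radius = config$probe_radius,
                     algorithm = config$sasa_algorithm,
                     resolution = config$sasa_resolution)
  esa <- residue_esa(model, areas, sites)
  say("sasa", "probe %.2f A, total area %.1f A^2", config$probe_radius,
      sum(areas))

  pka <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites)))
    pka[i] <- predict_pka(model, sites[i, ], config)$pka
  say("pka", "backend %s, range %.2f-%.2f", config$pka_backend,
      min(pka), max(pka))

  ss <- assign_ss(model)
  ss_key <- residue_key(ss$chain, ss$resno, ss$insert)
  site_key <- residue_key(sites$chain, sites$resno, sites$insert)
  m <- match(site_key, ss_key)
  ss8 <- ifelse(is.na(m), "-", ss$ss8[m])
  ss3 <- ifelse(is.na(m), "coil", ss$ss3[m])
  say("ss", "%d helix, %d strand, %d coil residues",
      sum(ss$ss3 == "helix"), sum(ss$ss3 == "strand"),
      sum(ss$ss3 == "coil"))

  bonds <- detect_hbonds(model, d_a_cutoff = config$hbond_distance,
                         angle_cutoff = config$hbond_angle)
  h_donor <- vapply(seq_len(nrow(sites)), function(i)
    is_amine_donor(sites[i, ], bonds), logical(1))
  say("hbond", "%d bonds; %d amine donors", nrow(bonds), sum(h_donor))

  energy <- numeric(nrow(sites))
  lowq <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    el <- site_charge_flag(charged, sites[i, ], config)
    energy[i] <- el$energy
    lowq[i] <- el$low_positive_charge
  }

  cls <- character(nrow(sites))
  rule_path <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    r <- classify_site(list(esa = esa[i], pka = pka[i], ss3 = ss3[i],
                            h_donor = h_donor[i],
                            low_positive_charge = lowq[i]), config)
    cls[i] <- as.character(r$class)
    rule_path[i] <- r$rule_path
  }
  tab <- data.frame(
    site_id = sites$site_id, residue_name = sites$resname,
    amine_kind = sites$kind, chain = sites$chain, resno = sites$resno,
    esa = esa, pka = pka, ss8 = ss8, ss3 = ss3, h_donor = h_donor,
    coulomb_energy = energy, low_positive_charge = lowq,
    reactivity_class = factor(cls, levels = REACTIVITY_LEVELS),
    rule_path = rule_path, stringsAsFactors = FALSE)
  say("done", "%.2f s; %d fast, %d slow, %d non-reacting",
      proc.time()[["elapsed"]] - t0,
      sum(cls == "fast_reacting"), sum(cls == "slow_reacting"),
      sum(cls == "non_reacting"))
  structure(list(table = tab, config = config, sites = sites,
                 model = model,
                 provenance = model$provenance),
            class = "amine_reactivity")
}

#' Probe-radius scan
#'
#' Reruns the full analysis at each probe radius (only the probe radius
#' varies) and reports the sites whose reactivity class flips between
#' consecutive radii.  Larger probes emulate bulkier reagents (RAFT
#' CTAs, PEGs); deep or crevice sites collapse to zero area and flip to
#' non-reacting once the probe no longer fits.
#'
#' @inheritParams amine_reactivity
#' @param radii Numeric vector of distinct positive probe radii.
#' @return An object of class `"probe_scan"`: `radii`, `runs` (one
#'   `"amine_reactivity"` per radius) and `flips` (data frame of class
#'   changes between consecutive radii).
#' @export
probe_scan <- function(pdb, pqr, radii, config = react_config(),
                       verbose = FALSE) {
  if (any(radii <= 0) || anyDuplicated(radii))
    stop("radii must be positive and distinct")
  runs <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    cfg <- config
    cfg$probe_radius <- radii[k]
    runs[[k]] <- tryCatch(
      amine_reactivity(pdb, pqr, cfg, verbose = verbose),
      error = function(e) stop("probe radius ", radii[k], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  flips <- NULL
  if (length(radii) > 1) for (k in seq_len(length(radii) - 1)) {
    a <- runs[[k]]$table; b <- runs[[k + 1]]$table
    ch <- which(as.character(a$reactivity_class) !=
                  as.character(b$reactivity_class))
    if (length(ch))
      flips <- rbind(flips, data.frame(
        site_id = a$site_id[ch],
        from_radius = radii[k], to_radius = radii[k + 1],
        from_class = as.character(a$reactivity_class[ch]),
        to_class = as.character(b$reactivity_class[ch]),
        stringsAsFactors = FALSE))
  }
  if (is.null(flips))
    flips <- data.frame(site_id = character(), from_radius = numeric(),
                        to_radius = numeric(), from_class = character(),
                        to_class = character(), stringsAsFactors = FALSE)
  structure(list(radii = radii, runs = runs, flips = flips),
            class = "probe_scan")
}

#' Write the per-site results table
#'
#' Writes a human-readable CSV (areas, energies and pKa rounded to two
#' decimals) and a machine-precision long-format TSV alongside it
#' (17 significant digits; re-reading reproduces the values
#' bit-exactly).
#'
#' @param x An `"amine_reactivity"` object or its `table`.
#' @param path Output CSV path; the long format goes to the same path
#'   with extension `.long.tsv`.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  tab <- if (inherits(x, "amine_reactivity")) x$table else x
  if (!is.data.frame(tab) || !nrow(tab)) stop("empty table refused")
  disp <- tab
  for (cc in c("esa", "pka", "coulomb_energy"))
    disp[[cc]] <- sprintf("%.2f", tab[[cc]])
  utils::write.csv(disp, path, row.names = FALSE, quote = FALSE)
  longp <- paste0(sub("\\.csv$", "", path), ".long.tsv")
  longt <- tab
  for (cc in c("esa", "pka", "coulomb_energy"))
    longt[[cc]] <- sprintf("%.17g", tab[[cc]])
  utils::write.table(longt, longp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read back a machine-precision long-format table
#'
#' @param path Path to a `.long.tsv` written by [write_site_table()].
#' @return The site table with numeric columns restored bit-exactly.
#' @export
read_site_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (cc in c("esa", "pka", "coulomb_energy"))
    tab[[cc]] <- as.numeric(tab[[cc]])
  tab$resno <- as.integer(tab$resno)
  tab$h_donor <- as.logical(tab$h_donor)
  tab$low_positive_charge <- as.logical(tab$low_positive_charge)
  tab$reactivity_class <- factor(tab$reactivity_class,
                                 levels = REACTIVITY_LEVELS)
  tab
}

#' @export
print.amine_reactivity <- function(x, ...) {
  tb <- x$table
  cat(sprintf("Amine reactivity prediction: %d sites (probe %.2f A, pH %.1f)\n",
              nrow(tb), x$config$probe_radius, x$config$ph))
  cnt <- table(tb$reactivity_class)
  cat(sprintf("  fast-reacting: %d   slow-reacting: %d   non-reacting: %d\n",
              cnt[["fast_reacting"]], cnt[["slow_reacting"]],
              cnt[["non_reacting"]]))
  show <- tb[, c("site_id", "residue_name", "esa", "pka", "ss3",
                 "h_donor", "coulomb_energy", "reactivity_class")]
  show$esa <- round(show$esa, 2)
  show$pka <- round(show$pka, 2)
  show$coulomb_energy <- round(show$coulomb_energy, 2)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.amine_reactivity <- function(object, ...) {
  tb <- object$table
  out <- list(
    n_sites = nrow(tb),
    n_fast = sum(tb$reactivity_class == "fast_reacting"),
    n_slow = sum(tb$reactivity_class == "slow_reacting"),
    n_non = sum(tb$reactivity_class == "non_reacting"),
    probe_radius = object$config$probe_radius,
    ph = object$config$ph,
    esa_range = range(tb$esa),
    pka_range = range(tb$pka))
  out$n_reactive <- out$n_fast + out$n_slow
  class(out) <- "summary.amine_reactivity"
  out
}

#' @export
print.summary.amine_reactivity <- function(x, ...) {
  cat(sprintf("%d amine sites at probe radius %.2f A (pH %.1f)\n",
              x$n_sites, x$probe_radius, x$ph))
  cat(sprintf("  reactive: %d (%d fast + %d slow); non-reacting: %d\n",
              x$n_reactive, x$n_fast, x$n_slow, x$n_non))
  cat(sprintf("  ESA %.2f-%.2f A^2; pKa %.2f-%.2f\n",
              x$esa_range[1], x$esa_range[2],
              x$pka_range[1], x$pka_range[2]))
  invisible(x)
}

#' @export
as.data.frame.amine_reactivity <- function(x, ...) x$table

#' @export
plot.amine_reactivity <- function(x, ...) {
  tb <- x$table
  cols <- c(non_reacting = "firebrick", slow_reacting = "goldenrod",
            fast_reacting = "forestgreen")
  op <- graphics::par(mar = c(6, 4, 3, 1)); on.exit(graphics::par(op))
  graphics::barplot(tb$esa, names.arg = tb$site_id, las = 2,
                    col = cols[as.character(tb$reactivity_class)],
                    ylab = "residue ESA (A^2)",
                    main = sprintf("Amine reactivity (probe %.1f A)",
                                   x$config$probe_radius), ...)
  graphics::abline(h = x$config$esa_reactive, lty = 2)
  graphics::legend("topright", legend = names(cols), fill = cols,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
print.probe_scan <- function(x, ...) {
  cat(sprintf("Probe-radius scan over {%s} A\n",
              paste(format(x$radii), collapse = ", ")))
  for (k in seq_along(x$radii)) {
    cnt <- table(x$runs[[k]]$table$reactivity_class)
    cat(sprintf("  r = %5.1f A: %d fast, %d slow, %d non-reacting\n",
                x$radii[k], cnt[["fast_reacting"]],
                cnt[["slow_reacting"]], cnt[["non_reacting"]]))
  }
  if (nrow(x$flips)) {
    cat("class flips between consecutive radii:\n")
    print(x$flips, row.names = FALSE)
  } else cat("no class flips\n")
  invisible(x)
}

#' @export
plot.probe_scan <- function(x, ...) {
  esa <- sapply(x$runs, function(r) r$table$esa)
  if (is.null(dim(esa))) esa <- matrix(esa, nrow = 1)
  graphics::matplot(x$radii, t(esa), type = "b", pch = 16,
                    xlab = "probe radius (A)",
                    ylab = "residue ESA (A^2)", ...)
  graphics::legend("topleft", legend = x$runs[[1]]$table$site_id,
                   col = seq_len(nrow(esa)), lty = seq_len(nrow(esa)),
                   bty = "n", cex = 0.7)
  invisible(x)
}

#' Synthetic charge set matching a structure
#'
#' Builds a PQR-style charged-atom table for a synthetic structure with
#' simple formal-charge assignments: +1 on lysine NZ and chain-terminal
#' N, -0.5 on each Asp/Glu carboxylate oxygen, -0.3/+0.3 on backbone
#' O/N, 0 elsewhere.  Intended for fixtures and demonstrations where no
#' force-field PQR exists; real analyses should use a PDB2PQR file.
#'
#' @param model An `"amine_structure"`.
#' @return A charged-atom data frame in the layout of [read_pqr()].
#' @export
helix_charge_set <- function(model) {
  a <- model$atoms[model$atoms$elem != "H", , drop = FALSE]
  q <- rep(0, nrow(a))
  q[a$name == "NZ" & a$resname == "LYS"] <- 1
  q[a$resname == "ASP" & a$name %in% c("OD1", "OD2")] <- -0.5
  q[a$resname == "GLU" & a$name %in% c("OE1", "OE2")] <- -0.5
  q[a$name == "O"] <- -0.3
  q[a$name == "N"] <- 0.3
  first <- !duplicated(a$chain)
  # chain-terminal amine carries a full formal charge
  for (ch in unique(a$chain)) {
    sel <- which(a$chain == ch & a$name == "N")
    if (length(sel)) q[sel[1]] <- 1
  }
  data.frame(serial = seq_len(nrow(a)), name = a$name,
             resname = a$resname, chain = a$chain, resno = a$resno,
             insert = a$insert, x = a$x, y = a$y, z = a$z,
             charge = q, radius = pmax(atom_radii(a), 1),
             stringsAsFactors = FALSE)
}
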