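# Rules-based reactivity classification.  The tree is evaluated in
# order; the first matching condition decides the class:
#   1. esa < esa_reactive          -> non_reacting   (buried amine)
#   2. pka > pka_branch            -> slow_reacting  (protonated at
#                                     reaction pH, poor nucleophile)
#   3. helix                       -> slow_reacting  (ordered, less
#                                     accessible fold)
#   4. hydrogen-bond donor         -> slow_reacting  (amine sequestered)
#   5. low positive charge         -> fast_reacting, else slow_reacting
# Boundary semantics are fixed: esa exactly at the threshold is
# reactive (the test is strict '<'); pka exactly at the branch point
# passes it (the test is strict '>'); the charge flag is strict '>'.
# The rule set is data, not code: it can be serialised to a plain-text
# file and swapped without touching the classifier.

REACTIVITY_LEVELS <- c("non_reacting", "slow_reacting", "fast_reacting")

#' Construct a classifier rule set
#'
#' A rule set is an ordered table of `condition -> outcome` pairs plus
#' a default outcome.  Conditions are R expressions over the predictor
#' variables `esa`, `pka`, `ss3`, `h_donor`, `low_positive_charge` and
#' the threshold variables `esa_reactive` and `pka_branch`.
#'
#' @param conditions Character vector of condition expressions.
#' @param outcomes Character vector of outcomes (one of `non_reacting`,
#'   `slow_reacting`, `fast_reacting`), same length.
#' @param default Outcome when no condition fires.
#' @return A `"classifier_rules"` object.
#' @export
classifier_rules <- function(conditions = NULL, outcomes = NULL,
                             default = "slow_reacting") {
  if (is.null(conditions)) {
    conditions <- c("esa < esa_reactive", "pka > pka_branch",
                    "ss3 == \"helix\"", "h_donor", "low_positive_charge")
    outcomes <- c("non_reacting", "slow_reacting", "slow_reacting",
                  "slow_reacting", "fast_reacting")
  }
  stopifnot(length(conditions) == length(outcomes),
            all(c(outcomes, default) %in% REACTIVITY_LEVELS))
  structure(list(conditions = conditions, outcomes = outcomes,
                 default = default), class = "classifier_rules")
}

#' Read / write a rule set as plain text
#'
#' Each line is `condition -> outcome`; a line with condition `default`
#' sets the fall-through outcome.  Lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param rules A `"classifier_rules"` object (for writing).
#' @return `read_rules()` returns a `"classifier_rules"` object;
#'   `write_rules()` returns `path` invisibly.
#' @export
read_rules <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "->", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed rule line(s): ",
                     paste(lines[bad], collapse = "; "))
  cond <- trimws(vapply(parts, `[`, "", 1))
  out <- trimws(vapply(parts, `[`, "", 2))
  is_def <- cond == "default"
  classifier_rules(cond[!is_def], out[!is_def],
                   default = if (any(is_def)) out[is_def][1]
                   else "slow_reacting")
}

#' @rdname read_rules
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "classifier_rules"))
  writeLines(c(paste(rules$conditions, "->", rules$outcomes),
               paste("default ->", rules$default)), path)
  invisible(path)
}

#' Classify one amine site from its five predictors
#'
#' Evaluates the decision tree on a complete predictor set and returns
#' the reactivity class together with the full audit trail of branch
#' decisions taken.
#'
#' @param params A list or one-row data frame with `esa` (Angstrom^2),
#'   `pka`, `ss3` (`"helix"`/`"strand"`/`"coil"`), `h_donor` (logical)
#'   and `low_positive_charge` (logical).
#' @param config A [react_config()] supplying the thresholds and,
#'   optionally, an overriding rule set.
#' @return List with `class` (factor over non/slow/fast) and
#'   `rule_path` (character, `;`-separated record of each test).
#' @examples
#' classify_site(list(esa = 26.37, pka = 10.1, ss3 = "coil",
#'                    h_donor = FALSE, low_positive_charge = FALSE))$class
#' @export
classify_site <- function(params, config = react_config()) {
  need <- c("esa", "pka", "ss3", "h_donor", "low_positive_charge")
  for (f in need) {
    v <- params[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      stop("classification error: parameter '", f, "' missing")
  }
  if (params$esa < 0) stop("classification error: negative esa")
  if (!params$ss3 %in% c("helix", "strand", "coil"))
    stop("classification error: ss3 must be helix/strand/coil")
  rules <- if (is.null(config$rules)) classifier_rules() else config$rules
  env <- list2env(list(
    esa = params$esa, pka = params$pka, ss3 = params$ss3,
    h_donor = isTRUE(params$h_donor),
    low_positive_charge = isTRUE(params$low_positive_charge),
    esa_reactive = config$esa_reactive, pka_branch = config$pka_branch))
  path <- character()
  cls <- NULL
  for (k in seq_along(rules$conditions)) {
    hit <- isTRUE(eval(parse(text = rules$conditions[k]), envir = env))
    path <- c(path, sprintf("[%s]=%s", rules$conditions[k],
                            if (hit) "yes" else "no"))
    if (hit) { cls <- rules$outcomes[k]; break }
  }
  if (is.null(cls)) {
    cls <- rules$default
    path <- c(path, sprintf("default=%s", cls))
  }
  list(class = factor(cls, levels = REACTIVITY_LEVELS),
       rule_path = paste(path, collapse = "; "))
}
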