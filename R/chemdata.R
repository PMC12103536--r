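# Data model for compounds, reactions and reaction databases, with element
# and charge balance checking and TSV/JSON input-output.

#' Parse a molecular formula string
#'
#' Converts e.g. `"C6H12O6"` into a named integer vector
#' `c(C = 6, H = 12, O = 6)`.  Multi-letter elements (`Mg`, `Fe`, ...) are
#' supported; an omitted count means 1.
#'
#' @param x formula string.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(toks)) != nchar(x)) stop("cannot parse formula: ", x)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Format an element-count vector back into a formula string
#' @param f named integer vector.
#' @return formula string (Hill-ish order: C, H, then alphabetical).
#' @export
format_formula <- function(f) {
  f <- f[f != 0]
  if (!length(f)) return("")
  ord <- c(intersect(c("C", "H"), names(f)), sort(setdiff(names(f), c("C", "H"))))
  paste0(ord, ifelse(f[ord] == 1, "", f[ord]), collapse = "")
}

#' Create a compound
#'
#' @param id compound identifier.
#' @param formula formula string or named element-count vector (H included).
#' @param charge integer formal charge.
#' @param structure_key first block of a hashed 2D-structure identifier
#'   (InChIKey connectivity layer); empty when the structure is undefined.
#'   Compounds with an empty key cannot be mapped onto host metabolites.
#' @param smiles optional SMILES string (used for substructure and maximum
#'   common substructure operations).
#' @param dfg0_prime,dfg0_error optional standard transformed Gibbs energy of
#'   formation and its estimation error, kJ/mol.
#' @param excluded logical; species such as metal cofactors and unconnected
#'   gases that are never treated as boundary metabolites.
#' @return object of class `"pw_compound"`.
#' @export
compound <- function(id, formula = "", charge = 0L, structure_key = "",
                     smiles = NA_character_, dfg0_prime = NA_real_,
                     dfg0_error = NA_real_, excluded = FALSE) {
  f <- if (is.character(formula)) parse_formula(formula) else {
    stopifnot(!is.null(names(formula)))
    stats::setNames(as.integer(formula), names(formula))
  }
  structure(list(
    id = as.character(id), formula = f, charge = as.integer(charge),
    structure_key = as.character(structure_key), smiles = smiles,
    dfg0_prime = as.numeric(dfg0_prime), dfg0_error = as.numeric(dfg0_error),
    excluded = isTRUE(excluded)
  ), class = "pw_compound")
}

#' Number of carbon atoms in a compound
#' @param x a `pw_compound`.
#' @return integer carbon count (0 when the formula has no carbon).
#' @export
n_carbon <- function(x) {
  nc <- x$formula["C"]
  if (is.na(nc)) 0L else as.integer(nc)
}

#' Create a reaction
#'
#' @param id reaction identifier.
#' @param stoich named numeric vector of signed stoichiometric coefficients
#'   over compound ids (negative = substrate, positive = product).  Zero
#'   coefficients are not allowed.
#' @param reversible logical.
#' @param provenance `"known"` or `"predicted"`.
#' @param bridgit_score optional enzyme-assignment score in \[0, 1\].
#' @param ec_hint optional EC number hint.
#' @return object of class `"pw_reaction"`.
#' @export
reaction <- function(id, stoich, reversible = FALSE, provenance = "known",
                     bridgit_score = NA_real_, ec_hint = NA_character_) {
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  if (any(stoich == 0)) stop("reaction ", id, ": zero stoichiometric coefficients are not stored")
  if (!any(stoich < 0) || !any(stoich > 0))
    stop("reaction ", id, ": needs at least one substrate and one product")
  provenance <- match.arg(provenance, c("known", "predicted"))
  structure(list(
    id = as.character(id), stoich = stoich, reversible = isTRUE(reversible),
    provenance = provenance, bridgit_score = as.numeric(bridgit_score),
    ec_hint = ec_hint
  ), class = "pw_reaction")
}

#' Check element and charge balance of a reaction
#'
#' A reaction is balanced when, summed with signed stoichiometry over all
#' participants, every element count and the total charge are zero.
#' Unbalanced reactions are excluded from the search space because they can
#' create chemicals without consuming resources.
#'
#' @param rxn a `pw_reaction`.
#' @param compounds named list of `pw_compound` covering all participants.
#' @param charge_strict if `FALSE`, a nonzero charge residual (elements
#'   balanced) is downgraded to a warning.
#' @return list with `element_residual` (named numeric), `charge_residual`,
#'   and `balanced` (logical).
#' @export
check_balance <- function(rxn, compounds, charge_strict = TRUE) {
  els <- character(0)
  for (cid in names(rxn$stoich)) {
    cp <- compounds[[cid]]
    if (is.null(cp)) stop("reaction ", rxn$id, ": unknown compound ", cid)
    if (!length(cp$formula)) stop("compound ", cid, " has no formula; cannot check balance")
    els <- union(els, names(cp$formula))
  }
  res <- stats::setNames(numeric(length(els)), els)
  qres <- 0
  for (cid in names(rxn$stoich)) {
    cp <- compounds[[cid]]
    n <- rxn$stoich[[cid]]
    res[names(cp$formula)] <- res[names(cp$formula)] + n * cp$formula
    qres <- qres + n * cp$charge
  }
  ok_el <- all(abs(res) < 1e-9)
  ok <- ok_el && (abs(qres) < 1e-9 || !charge_strict)
  if (ok_el && abs(qres) >= 1e-9 && !charge_strict)
    warning("reaction ", rxn$id, ": charge residual ", qres, " ignored (charge_strict = FALSE)")
  list(element_residual = res, charge_residual = qres, balanced = ok)
}

#' Parse a reaction equation string
#'
#' Accepts the `"2 A + B <=> C"` convention; `<=>` marks a reversible
#' reaction, `=>` (or `->`) an irreversible one.
#'
#' @param eq equation string.
#' @return list with `stoich` (named numeric) and `reversible`.
#' @export
parse_equation <- function(eq) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, "<=>|=>|->")[[1]]
  if (length(sides) != 2L) stop("cannot parse equation: ", eq)
  take <- function(side, sign) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 2L && grepl("^[0-9.]+$", parts[1])) {
        out[parts[2]] <- sign * as.numeric(parts[1]) + (if (is.na(out[parts[2]])) 0 else out[parts[2]])
      } else if (length(parts) == 1L) {
        out[parts[1]] <- sign * 1 + (if (is.na(out[parts[1]])) 0 else out[parts[1]])
      } else stop("cannot parse term '", tm, "' in equation: ", eq)
    }
    out
  }
  lhs <- take(sides[1], -1)
  rhs <- take(sides[2], +1)
  stoich <- lhs
  for (cid in names(rhs)) stoich[cid] <- (if (is.na(stoich[cid])) 0 else stoich[cid]) + rhs[cid]
  stoich <- stoich[stoich != 0]
  list(stoich = stoich, reversible = rev)
}

#' Format a stoichiometry vector as an equation string
#' @param stoich named signed numeric vector.
#' @param reversible logical.
#' @return equation string.
#' @export
format_equation <- function(stoich, reversible = FALSE) {
  side <- function(v) paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))), collapse = " + ")
  lhs <- stoich[stoich < 0]; rhs <- stoich[stoich > 0]
  paste(side(lhs), if (reversible) "<=>" else "=>", side(rhs))
}

#' Assemble and validate a reaction database
#'
#' @param compounds named list of `pw_compound`.
#' @param reactions named list of `pw_reaction`.
#' @param rp_pairs data frame with columns `source`, `target`, `car`
#'   (conserved atom ratio in \[0, 1\]) and `reactions` (semicolon-separated
#'   reaction ids); one row per reactant-product pair.
#' @param validate run referential-integrity checks.
#' @return object of class `"reaction_db"`.
#' @export
reaction_database <- function(compounds = list(), reactions = list(),
                              rp_pairs = NULL, validate = TRUE) {
  if (is.null(names(compounds)) && length(compounds))
    names(compounds) <- vapply(compounds, `[[`, "", "id")
  if (is.null(names(reactions)) && length(reactions))
    names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (is.null(rp_pairs))
    rp_pairs <- data.frame(source = character(0), target = character(0),
                           car = numeric(0), reactions = character(0),
                           stringsAsFactors = FALSE)
  db <- structure(list(compounds = compounds, reactions = reactions,
                       rp_pairs = rp_pairs), class = "reaction_db")
  if (validate) validate_database(db)
  db
}

#' Validate referential integrity of a reaction database
#'
#' Checks that every compound referenced by a reaction or RP-pair exists,
#' that RP-pair reaction ids exist, and that each such reaction actually
#' consumes the pair's source and produces its target (or the reverse, for a
#' reversible reaction).
#'
#' @param db a `reaction_db`.
#' @return the database, invisibly; errors on violation.
#' @export
validate_database <- function(db) {
  cids <- names(db$compounds)
  for (r in db$reactions) {
    miss <- setdiff(names(r$stoich), cids)
    if (length(miss))
      stop("reaction ", r$id, " references unknown compounds: ", paste(miss, collapse = ", "))
  }
  rp <- db$rp_pairs
  if (nrow(rp)) {
    miss <- setdiff(unique(c(rp$source, rp$target)), cids)
    if (length(miss)) stop("rp_pairs reference unknown compounds: ", paste(miss, collapse = ", "))
    if (any(rp$car < 0 | rp$car > 1)) stop("conserved atom ratios must lie in [0, 1]")
    for (i in seq_len(nrow(rp))) {
      rids <- strsplit(rp$reactions[i], ";", fixed = TRUE)[[1]]
      for (rid in rids) {
        r <- db$reactions[[rid]]
        if (is.null(r)) stop("rp_pair ", rp$source[i], "->", rp$target[i],
                             " references unknown reaction ", rid)
        fwd <- !is.na(r$stoich[rp$source[i]]) && r$stoich[rp$source[i]] < 0 &&
               !is.na(r$stoich[rp$target[i]]) && r$stoich[rp$target[i]] > 0
        bwd <- r$reversible &&
               !is.na(r$stoich[rp$source[i]]) && r$stoich[rp$source[i]] > 0 &&
               !is.na(r$stoich[rp$target[i]]) && r$stoich[rp$target[i]] < 0
        if (!fwd && !bwd)
          stop("rp_pair ", rp$source[i], "->", rp$target[i], ": reaction ", rid,
               " does not consume the source and produce the target")
      }
    }
  }
  invisible(db)
}

#' Default excluded species
#'
#' Species never connected to the host when encountered as cosubstrates:
#' metal cofactors and certain gases.  Shipped as an editable TSV in
#' `inst/extdata/excluded_species.tsv`.
#'
#' @return character vector of compound ids.
#' @export
default_excluded_species <- function() {
  path <- system.file("extdata", "excluded_species.tsv", package = "pathweaver")
  if (!nzchar(path)) return(character(0))
  utils::read.delim(path, stringsAsFactors = FALSE)$id
}

#' Load a reaction database
#'
#' TSV format expects a directory holding `compounds.tsv` (id, structure_key,
#' formula, charge, smiles, dfg0_prime, dfg0_error), `reactions.tsv`
#' (reaction_id, equation, provenance, bridgit_score) and `rp_pairs.tsv`
#' (source, target, car, reactions).  JSON format expects the single document
#' written by [save_database()].  Reactions failing element/charge balance
#' are rejected; the rejection report is attached as attribute `"rejected"`.
#'
#' @param path directory (tsv) or file (json).
#' @param format `"tsv"` or `"json"`.
#' @param excluded ids treated as excluded species.
#' @param charge_strict passed to [check_balance()].
#' @return validated `reaction_db` with attribute `"rejected"` (data frame of
#'   id/reason for excluded reaction rows).
#' @export
load_database <- function(path, format = c("tsv", "json"),
                          excluded = default_excluded_species(),
                          charge_strict = TRUE) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    comps <- lapply(doc$compounds, function(cp) compound(
      id = cp$id, formula = cp$formula, charge = cp$charge %||% 0L,
      structure_key = cp$structure_key %||% "", smiles = cp$smiles %||% NA_character_,
      dfg0_prime = cp$dfg0_prime %||% NA_real_, dfg0_error = cp$dfg0_error %||% NA_real_,
      excluded = isTRUE(cp$excluded)))
    names(comps) <- vapply(comps, `[[`, "", "id")
    rx <- data.frame(
      reaction_id = vapply(doc$reactions, `[[`, "", "id"),
      equation = vapply(doc$reactions, `[[`, "", "equation"),
      provenance = vapply(doc$reactions, function(r) r$provenance %||% "known", ""),
      bridgit_score = vapply(doc$reactions, function(r) as.numeric(r$bridgit_score %||% NA_real_), 0),
      stringsAsFactors = FALSE)
    rp <- if (length(doc$rp_pairs)) data.frame(
      source = vapply(doc$rp_pairs, `[[`, "", "source"),
      target = vapply(doc$rp_pairs, `[[`, "", "target"),
      car = vapply(doc$rp_pairs, function(p) as.numeric(p$car), 0),
      reactions = vapply(doc$rp_pairs, `[[`, "", "reactions"),
      stringsAsFactors = FALSE) else NULL
  } else {
    need <- file.path(path, c("compounds.tsv", "reactions.tsv", "rp_pairs.tsv"))
    for (f in need[1:2]) if (!file.exists(f)) stop("missing database file: ", f)
    ctab <- utils::read.delim(need[1], stringsAsFactors = FALSE, colClasses = "character")
    req <- c("id", "formula", "charge")
    if (!all(req %in% names(ctab)))
      stop("compounds.tsv must have columns: ", paste(req, collapse = ", "))
    comps <- lapply(seq_len(nrow(ctab)), function(i) compound(
      id = ctab$id[i], formula = ctab$formula[i], charge = as.integer(ctab$charge[i]),
      structure_key = if ("structure_key" %in% names(ctab)) ctab$structure_key[i] else "",
      smiles = if ("smiles" %in% names(ctab) && nzchar(ctab$smiles[i])) ctab$smiles[i] else NA_character_,
      dfg0_prime = if ("dfg0_prime" %in% names(ctab) && nzchar(ctab$dfg0_prime[i]))
        as.numeric(ctab$dfg0_prime[i]) else NA_real_,
      dfg0_error = if ("dfg0_error" %in% names(ctab) && nzchar(ctab$dfg0_error[i]))
        as.numeric(ctab$dfg0_error[i]) else NA_real_))
    names(comps) <- ctab$id
    rx <- utils::read.delim(need[2], stringsAsFactors = FALSE)
    req <- c("reaction_id", "equation")
    if (!all(req %in% names(rx)))
      stop("reactions.tsv must have columns: ", paste(req, collapse = ", "))
    if (!"provenance" %in% names(rx)) rx$provenance <- "known"
    if (!"bridgit_score" %in% names(rx)) rx$bridgit_score <- NA_real_
    rp <- if (file.exists(need[3]))
      utils::read.delim(need[3], stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric", "character")) else NULL
  }
  for (cp in comps) if (cp$id %in% excluded) comps[[cp$id]]$excluded <- TRUE

  rxns <- list(); rejected <- data.frame(id = character(0), reason = character(0))
  for (i in seq_len(nrow(rx))) {
    pe <- tryCatch(parse_equation(rx$equation[i]), error = function(e)
      stop("reactions row ", i, " (", rx$reaction_id[i], "): ", conditionMessage(e)))
    miss <- setdiff(names(pe$stoich), names(comps))
    if (length(miss))
      stop("reactions row ", i, " (", rx$reaction_id[i],
           "): dangling compound reference: ", paste(miss, collapse = ", "))
    r <- reaction(rx$reaction_id[i], pe$stoich, reversible = pe$reversible,
                  provenance = rx$provenance[i], bridgit_score = rx$bridgit_score[i])
    bal <- check_balance(r, comps, charge_strict = charge_strict)
    if (!bal$balanced) {
      bad <- bal$element_residual[abs(bal$element_residual) > 1e-9]
      reason <- if (length(bad)) paste0("element residual: ",
        paste(names(bad), round(bad, 6), sep = "=", collapse = ", "))
        else paste0("charge residual: ", bal$charge_residual)
      rejected <- rbind(rejected, data.frame(id = r$id, reason = reason))
      next
    }
    rxns[[r$id]] <- r
  }
  if (!is.null(rp) && nrow(rp)) {
    keep <- vapply(seq_len(nrow(rp)), function(i)
      any(strsplit(rp$reactions[i], ";", fixed = TRUE)[[1]] %in% names(rxns)), TRUE)
    rp <- rp[keep, , drop = FALSE]
    rp$reactions <- vapply(rp$reactions, function(s)
      paste(intersect(strsplit(s, ";", fixed = TRUE)[[1]], names(rxns)), collapse = ";"), "")
    rownames(rp) <- NULL
  }
  db <- reaction_database(comps, rxns, rp)
  attr(db, "rejected") <- rejected
  db
}

#' Save a reaction database
#'
#' Inverse of [load_database()]; `load_database(save_database(db))` is the
#' identity on the validated portion of a database.
#'
#' @param db a `reaction_db`.
#' @param path directory (tsv) or file (json).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  comps <- if (length(db$compounds)) db$compounds[order(names(db$compounds))] else list()
  rxns <- if (length(db$reactions)) db$reactions[order(names(db$reactions))] else list()
  if (format == "json") {
    doc <- list(
      compounds = lapply(unname(comps), function(cp) list(
        id = cp$id, formula = format_formula(cp$formula), charge = cp$charge,
        structure_key = cp$structure_key, smiles = cp$smiles,
        dfg0_prime = cp$dfg0_prime, dfg0_error = cp$dfg0_error,
        excluded = cp$excluded)),
      reactions = lapply(unname(rxns), function(r) list(
        id = r$id, equation = format_equation(r$stoich, r$reversible),
        provenance = r$provenance, bridgit_score = r$bridgit_score)),
      rp_pairs = if (nrow(db$rp_pairs)) lapply(seq_len(nrow(db$rp_pairs)), function(i)
        as.list(db$rp_pairs[i, c("source", "target", "car", "reactions")])) else list())
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    ctab <- data.frame(
      id = vapply(comps, `[[`, "", "id"),
      structure_key = vapply(comps, `[[`, "", "structure_key"),
      formula = vapply(comps, function(cp) format_formula(cp$formula), ""),
      charge = vapply(comps, `[[`, 0L, "charge"),
      smiles = vapply(comps, function(cp) if (is.na(cp$smiles)) "" else cp$smiles, ""),
      dfg0_prime = vapply(comps, function(cp) if (is.na(cp$dfg0_prime)) "" else
        format(cp$dfg0_prime, digits = 15), ""),
      dfg0_error = vapply(comps, function(cp) if (is.na(cp$dfg0_error)) "" else
        format(cp$dfg0_error, digits = 15), ""))
    rtab <- data.frame(
      reaction_id = vapply(rxns, `[[`, "", "id"),
      equation = vapply(rxns, function(r) format_equation(r$stoich, r$reversible), ""),
      provenance = vapply(rxns, `[[`, "", "provenance"),
      bridgit_score = vapply(rxns, function(r) if (is.na(r$bridgit_score)) "" else
        format(r$bridgit_score, digits = 15), ""))
    utils::write.table(ctab, file.path(path, "compounds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rtab, file.path(path, "reactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(db$rp_pairs, file.path(path, "rp_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.reaction_db <- function(x, ...) {
  cat("Reaction database:", length(x$compounds), "compounds,",
      length(x$reactions), "reactions,", nrow(x$rp_pairs), "RP-pairs\n")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej)) cat("  rejected (unbalanced):", nrow(rej), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
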