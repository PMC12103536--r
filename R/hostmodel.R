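# Host genome-scale model input-output, structure-key metabolite mapping,
# and integration of an extracted subnetwork with a target demand reaction.

#' Construct a host model
#'
#' @param id model identifier.
#' @param metabolites data frame with columns `id`, `compartment`,
#'   `structure_key` (empty string when the structure is undefined).
#' @param reactions named list; each element a list with `id`, `stoich`
#'   (named numeric over metabolite ids), `lb`, `ub` (mmol/gDW/h).
#' @param substrate_exchange id of the carbon-source exchange reaction
#'   (e.g. glucose uptake), or `NA`.
#' @return object of class `"host_model"`.  Exchange reactions (single
#'   metabolite) are detected automatically.
#' @export
host_model <- function(id, metabolites, reactions, substrate_exchange = NA_character_) {
  stopifnot(all(c("id", "compartment", "structure_key") %in% names(metabolites)))
  if (is.null(names(reactions))) names(reactions) <- vapply(reactions, `[[`, "", "id")
  for (r in reactions) {
    miss <- setdiff(names(r$stoich), metabolites$id)
    if (length(miss)) stop("host reaction ", r$id, " references unknown metabolites: ",
                           paste(miss, collapse = ", "))
  }
  exchanges <- names(reactions)[vapply(reactions, function(r) length(r$stoich) == 1L, TRUE)]
  if (!length(exchanges) && is.na(substrate_exchange))
    warning("host model has no exchange reactions; substrate_exchange unset")
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 exchanges = exchanges, substrate_exchange = substrate_exchange),
            class = "host_model")
}

#' @export
print.host_model <- function(x, ...) {
  cat("Host model", x$id, ":", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,", length(x$exchanges), "exchanges\n")
  invisible(x)
}

#' Load a host model
#'
#' Reads COBRA-JSON or SBML Level 3 (with the flux-bounds subset of the FBC
#' extension).  Structure keys are taken from a metabolite's
#' `annotation$structure_key`, or from the first block of
#' `annotation$inchi_key` when present.  Missing bounds default to +/-1000
#' with a warning.
#'
#' @param path model file.
#' @param format `"cobra-json"` or `"sbml"`.
#' @param substrate_exchange optional exchange reaction id for the carbon
#'   source.
#' @return a `host_model`.
#' @export
load_host <- function(path, format = c("cobra-json", "sbml"),
                      substrate_exchange = NA_character_) {
  format <- match.arg(format)
  if (format == "cobra-json") .load_host_json(path, substrate_exchange)
  else .load_host_sbml(path, substrate_exchange)
}

.load_host_json <- function(path, substrate_exchange) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- data.frame(
    id = vapply(doc$metabolites, `[[`, "", "id"),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "c", ""),
    structure_key = vapply(doc$metabolites, function(m) {
      sk <- m$annotation$structure_key
      if (is.null(sk)) {
        ik <- m$annotation$inchi_key
        sk <- if (is.null(ik)) "" else strsplit(ik[[1]], "-", fixed = TRUE)[[1]][1]
      }
      as.character(sk)
    }, ""), stringsAsFactors = FALSE)
  warned <- FALSE
  reactions <- lapply(doc$reactions, function(r) {
    lb <- r$lower_bound; ub <- r$upper_bound
    if (is.null(lb) || is.null(ub)) {
      if (!warned) { warning("missing bounds in ", path, "; defaulting to +/-1000"); warned <<- TRUE }
      lb <- lb %||% -1000; ub <- ub %||% 1000
    }
    st <- unlist(r$metabolites)
    list(id = r$id, stoich = stats::setNames(as.numeric(st), names(st)),
         lb = as.numeric(lb), ub = as.numeric(ub),
         non_native = isTRUE(r$annotation$non_native))
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  host_model(doc$id %||% basename(path), mets, reactions, substrate_exchange)
}

.load_host_sbml <- function(path, substrate_exchange) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    compartment = xml2::xml_attr(species, "compartment"),
    structure_key = {
      sk <- xml2::xml_attr(species, "name")
      key <- vapply(species, function(sp) {
        n <- xml2::xml_find_first(sp, ".//s:notes", ns)
        if (inherits(n, "xml_missing")) "" else {
          txt <- xml2::xml_text(n)
          m <- regmatches(txt, regexpr("structure_key: *[A-Z0-9]+", txt))
          if (length(m)) sub("structure_key: *", "", m) else ""
        }
      }, "")
      key
    }, stringsAsFactors = FALSE)
  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  warned <- FALSE
  reactions <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    take <- function(xp, sign) {
      refs <- xml2::xml_find_all(rn, xp, ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    stoich <- c(take(".//s:listOfReactants/s:speciesReference", -1),
                take(".//s:listOfProducts/s:speciesReference", +1))
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else NA_real_
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else NA_real_
    if (is.na(lb) || is.na(ub)) {
      rv <- xml2::xml_attr(rn, "reversible")
      if (is.na(lb)) lb <- if (identical(rv, "true")) -1000 else 0
      if (is.na(ub)) ub <- 1000
      if (!warned) { warning("missing FBC bounds in ", path, "; defaulting"); warned <<- TRUE }
    }
    list(id = id, stoich = stoich, lb = lb, ub = ub, non_native = FALSE)
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  host_model(xml2::xml_attr(model, "id"), mets, reactions, substrate_exchange)
}

#' Write a host or integrated model as COBRA-JSON
#'
#' Produces a document following the COBRA-JSON schema (metabolites,
#' reactions with bounds, genes empty).  Non-native reactions carry
#' `annotation: {non_native: true}`.
#'
#' @param model a `host_model` or `integrated_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  nn <- if (inherits(model, "integrated_model")) model$non_native else character(0)
  doc <- list(
    id = model$id %||% "model",
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$id, compartment = m$compartment,
           annotation = list(structure_key = m$structure_key))
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      out <- list(id = r$id, name = r$id, metabolites = as.list(r$stoich),
                  lower_bound = r$lb, upper_bound = r$ub,
                  gene_reaction_rule = "")
      if (r$id %in% nn) out$annotation <- list(non_native = TRUE)
      out
    }),
    genes = list(), compartments = as.list(stats::setNames(
      unique(model$metabolites$compartment), unique(model$metabolites$compartment))),
    version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a host model as SBML Level 3 with FBC flux bounds
#'
#' @param model a `host_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  bvals <- sort(unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub)))))
  bid <- function(v) sprintf("b_%s", gsub("[^0-9a-zA-Z]", "_", format(v, trim = TRUE)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">',
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', unique(model$metabolites$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    vapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      sprintf('      <species id="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>structure_key: %s</p></body></notes></species>',
              esc(m$id), esc(m$compartment), esc(m$structure_key))
    }, ""),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="%s" value="%s" constant="true"/>', bid(bvals),
            format(bvals, trim = TRUE)),
    '    </listOfParameters>',
    '    <listOfReactions>',
    unlist(lapply(unname(model$reactions), function(r) {
      refs <- function(v, tag) {
        if (!length(v)) return(character(0))
        c(sprintf('        <%s>', tag),
          sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  esc(names(v)), format(abs(v), trim = TRUE)),
          sprintf('        </%s>', tag))
      }
      c(sprintf('      <reaction id="%s" reversible="%s" fast="false" lowerFluxBound="%s" upperFluxBound="%s">',
                esc(r$id), tolower(r$lb < 0), bid(r$lb), bid(r$ub)),
        refs(r$stoich[r$stoich < 0], "listOfReactants"),
        refs(r$stoich[r$stoich > 0], "listOfProducts"),
        '      </reaction>')
    })),
    '    </listOfReactions>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Map host metabolites to database compounds by 2D structure key
#'
#' A host metabolite maps to a database compound if and only if their
#' structure keys match; compartments are ignored, so several compartmental
#' copies of a metabolite map to the same compound.  Metabolites without a
#' defined structure are excluded from the mapping.
#'
#' @param host a `host_model`.
#' @param db a `reaction_db`.
#' @return list with `mapping` (named character, host metabolite id ->
#'   compound id), `host_set` (compound ids with a host counterpart; these
#'   act as native precursors in the graph search), `met_for_compound`
#'   (compound id -> preferred host metabolite, cytosolic copy first),
#'   `coverage` (mapped/total), and `unmapped` metabolite ids.
#' @export
map_metabolites <- function(host, db) {
  keys <- vapply(db$compounds, `[[`, "", "structure_key")
  keys <- keys[nzchar(keys)]
  lookup <- split(names(keys), keys)
  collisions <- lookup[lengths(lookup) > 1L]
  if (length(collisions))
    warning("structure-key collisions in database: ",
            paste(names(collisions), collapse = ", "), "; using first id")
  lookup <- vapply(lookup, function(ids) sort(ids)[1], "")

  mets <- host$metabolites
  has_key <- nzchar(mets$structure_key)
  hit <- has_key & mets$structure_key %in% names(lookup)
  mapping <- stats::setNames(unname(lookup[mets$structure_key[hit]]), mets$id[hit])
  met_for_compound <- character(0)
  for (cid in unique(mapping)) {
    cand <- mets[mets$id %in% names(mapping)[mapping == cid], ]
    cand <- cand[order(cand$compartment != "c", cand$id), ]
    met_for_compound[cid] <- cand$id[1]
  }
  list(mapping = mapping,
       host_set = sort(unique(unname(mapping))),
       met_for_compound = met_for_compound,
       coverage = c(mapped = sum(hit), total = nrow(mets)),
       unmapped = mets$id[!hit])
}

#' Integrate a converged subnetwork into the host model
#'
#' Subnetwork reactions are added to the host in the cytosol with fresh ids
#' (`NN_` prefix) and marked non-native; compounds shared with the host are
#' unified through the structure-key mapping; a demand reaction draining the
#' target from the cytosol is added.  Native stoichiometry and bounds are
#' never altered.  Excluded species (metal cofactors, listed gases) without a
#' host counterpart receive a free exchange reaction, since they are assumed
#' available without an explicit production route.
#'
#' @param host a `host_model`.
#' @param subnetwork a converged `subnetwork` (or a character vector of
#'   reaction ids from `db`).
#' @param db the `reaction_db` the subnetwork was extracted from.
#' @param target target compound id.
#' @param mapping optional result of [map_metabolites()]; computed when
#'   missing.
#' @param demand_lb,demand_ub demand reaction bounds; enumeration later
#'   tightens the effective lower bound through the production fraction
#'   theta.
#' @param big_bound flux bound magnitude for added reactions.
#' @return object of class `"integrated_model"`.
#' @export
integrate_subnetwork <- function(host, subnetwork, db, target, mapping = NULL,
                                 demand_lb = 0, demand_ub = 1000, big_bound = 1000) {
  rids <- if (inherits(subnetwork, "subnetwork")) subnetwork$reactions else as.character(subnetwork)
  if (is.null(mapping)) mapping <- map_metabolites(host, db)
  mets <- host$metabolites
  reactions <- host$reactions
  met_of <- mapping$met_for_compound

  ensure_met <- function(cid) {
    if (cid %in% names(met_of)) return(met_of[[cid]])
    mid <- paste0(cid, "_nn")
    if (!mid %in% mets$id) {
      cp <- db$compounds[[cid]]
      mets <<- rbind(mets, data.frame(id = mid, compartment = "c",
                                      structure_key = cp$structure_key,
                                      stringsAsFactors = FALSE))
      if (cp$excluded) {
        exid <- paste0("EX_", cid, "_nn")
        reactions[[exid]] <<- list(id = exid, stoich = stats::setNames(-1, mid),
                                   lb = -big_bound, ub = big_bound)
      }
    }
    met_of[cid] <<- mid
    mid
  }

  non_native <- character(0)
  for (rid in sort(rids)) {
    r <- db$reactions[[rid]]
    if (is.null(r)) stop("subnetwork reaction ", rid, " not in database")
    new_id <- paste0("NN_", rid)
    if (new_id %in% names(reactions)) stop("reaction id clash: ", new_id)
    stoich <- stats::setNames(unname(r$stoich),
                              vapply(names(r$stoich), ensure_met, ""))
    reactions[[new_id]] <- list(id = new_id, stoich = stoich,
                                lb = if (r$reversible) -big_bound else 0, ub = big_bound)
    non_native <- c(non_native, new_id)
  }

  if (!target %in% names(met_of)) {
    if (is.null(db$compounds[[target]])) stop("target ", target, " not found in database")
    if (!length(rids)) stop("target ", target, " is unmapped and the subnetwork is empty")
    stop("target ", target, " neither mapped to the host nor produced by the subnetwork")
  }
  demand_id <- paste0("DM_", target)
  reactions[[demand_id]] <- list(id = demand_id,
                                 stoich = stats::setNames(-1, met_of[[target]]),
                                 lb = demand_lb, ub = demand_ub)
  structure(list(
    id = paste0(host$id, "+", length(non_native), "nn"),
    metabolites = mets, reactions = reactions,
    exchanges = host$exchanges, substrate_exchange = host$substrate_exchange,
    non_native = non_native, demand_reaction = demand_id,
    mapping = mapping, target = target,
    db_reaction_ids = if (length(rids))
      stats::setNames(sort(rids), paste0("NN_", sort(rids))) else
      stats::setNames(character(0), character(0))
  ), class = c("integrated_model", "host_model"))
}

#' @export
print.integrated_model <- function(x, ...) {
  cat("Integrated model:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions (", length(x$non_native), "non-native ),",
      "demand:", x$demand_reaction, "\n")
  invisible(x)
}
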