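# Subnetwork orchestration: core pathway search, iterative expansion until
# every cosubstrate and byproduct is connected to the host metabolism (or
# omitted), convergence pruning to a closed reaction set, topology reporting
# and Gephi GDF export.

#' Construct a subnetwork object
#' @param reactions,compounds character id sets.
#' @param core_pathways list of `linear_pathway`.
#' @param edges data frame of the RP-edges the subnetwork was built from.
#' @param target target compound id.
#' @param host_set database compound ids with a host counterpart.
#' @return object of class `"subnetwork"`.
#' @export
subnetwork <- function(reactions = character(0), compounds = character(0),
                       core_pathways = list(), edges = NULL,
                       target = NA_character_, host_set = character(0)) {
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        reactions = character(0), stringsAsFactors = FALSE)
  structure(list(reactions = sort(unique(reactions)),
                 compounds = sort(unique(compounds)),
                 core_pathways = core_pathways, edges = edges,
                 boundary = character(0), omitted = character(0),
                 rounds = integer(0), target = target, host_set = host_set,
                 status = "initial"),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Subnetwork [", x$status, "]:", length(x$reactions), "reactions,",
      length(x$compounds), "compounds,", length(x$core_pathways), "core pathways")
  if (length(x$omitted)) cat(",", length(x$omitted), "omitted")
  cat("\n")
  invisible(x)
}

# all reactions attached to a pathway's edges, plus the participants
.pathway_payload <- function(graph, db, pathway) {
  idx <- match(pathway$edge_keys, .edge_key(graph$edges$source, graph$edges$target))
  rids <- unique(unlist(strsplit(graph$edges$reactions[idx], ";", fixed = TRUE)))
  comps <- unique(c(pathway$nodes, unlist(lapply(db$reactions[rids], function(r) names(r$stoich)))))
  list(reactions = rids, compounds = comps, edges = graph$edges[idx, c("source", "target", "reactions")])
}

#' Extract the core pathway set
#'
#' Union of the k-shortest loopless pathways from each precursor to the
#' target, deduplicated, together with all reactions attached to the
#' traversed RP-edges (cosubstrates included).
#'
#' @param graph an `rp_graph`.
#' @param db the originating `reaction_db`.
#' @param target target compound id (must be in the graph).
#' @param precursors precursor compound ids (host-mapped natives or a
#'   user-defined list).
#' @param host_set database compound ids mapped to the host.
#' @param k pathways per precursor.
#' @param max_len maximum pathway length in steps.
#' @return a `subnetwork` holding the core pathways.
#' @export
extract_core <- function(graph, db, target, precursors, host_set = precursors,
                         k = 5L, max_len = 10L) {
  if (!target %in% graph$nodes) stop("target not in graph: ", target)
  if (target %in% precursors) stop("degenerate search: target is a precursor")
  paths <- list(); seen <- character(0)
  for (p in sort(precursors)) {
    if (!p %in% graph$nodes) next
    for (pw in k_shortest_paths(graph, p, target, k = k, max_len = max_len)) {
      key <- paste(pw$nodes, collapse = "|")
      if (!key %in% seen) { seen <- c(seen, key); paths[[length(paths) + 1L]] <- pw }
    }
  }
  sn <- subnetwork(target = target, host_set = host_set)
  for (pw in paths) {
    pay <- .pathway_payload(graph, db, pw)
    sn$reactions <- union(sn$reactions, pay$reactions)
    sn$compounds <- union(sn$compounds, pay$compounds)
    sn$edges <- unique(rbind(sn$edges, pay$edges))
  }
  sn$core_pathways <- paths
  sn$reactions <- sort(sn$reactions); sn$compounds <- sort(sn$compounds)
  sn$status <- if (length(paths)) "core" else "empty_core"
  sn
}

# boundary metabolites: non-host, non-excluded compounds that appear as a
# substrate with no producing reaction in the subnetwork (production needed)
# or as a product with no consuming reaction (consumption needed).
.boundary_needs <- function(sn, db) {
  rxns <- db$reactions[sn$reactions]
  consumed <- produced <- character(0)
  for (r in rxns) {
    s <- names(r$stoich)[r$stoich < 0]; p <- names(r$stoich)[r$stoich > 0]
    if (r$reversible) { s <- names(r$stoich); p <- names(r$stoich) }
    consumed <- union(consumed, s); produced <- union(produced, p)
  }
  skip <- function(ids) {
    ids <- setdiff(ids, c(sn$host_set, sn$target, sn$omitted))
    ids[!vapply(db$compounds[ids], `[[`, TRUE, "excluded")]
  }
  need_prod <- skip(setdiff(consumed, produced))
  need_cons <- skip(setdiff(produced, consumed))
  list(production = sort(need_prod), consumption = sort(need_cons))
}

#' Iteratively expand a subnetwork to connect boundary metabolites
#'
#' Each round collects the boundary metabolites (non-host substrates that
#' need a production route; non-host byproducts that need a consumption
#' route), searches linear pathways between the host-mapped compounds and
#' each boundary with length at most `shortest + extra_steps`, preferring
#' connection pathways that introduce the fewest non-host cosubstrates, and
#' appends up to `k_cosub` of them.  Boundaries with no connection are marked
#' omitted.  Excluded species (metal cofactors, listed gases) are never
#' treated as boundaries.  The per-round boundary counts are recorded in
#' `$rounds`; the trace always terminates at 0.
#'
#' @param sn a `subnetwork` containing core pathways.
#' @param graph the `rp_graph` to search.
#' @param db the originating `reaction_db`.
#' @param extra_steps X: admissible extra length beyond the shortest
#'   connection found.
#' @param k_cosub connection pathways kept per boundary metabolite.
#' @param max_len hard cap on connection pathway length.
#' @return expanded `subnetwork`.
#' @export
expand_subnetwork <- function(sn, graph, db, extra_steps = 0L, k_cosub = 3L,
                              max_len = 10L) {
  hosts <- sort(intersect(sn$host_set, graph$nodes))
  repeat {
    needs <- .boundary_needs(sn, db)
    bnd <- union(needs$production, needs$consumption)
    sn$rounds <- c(sn$rounds, length(bnd))
    if (!length(bnd)) break
    progress <- FALSE
    for (b in sort(bnd)) {
      for (dir in c("production", "consumption")) {
        if (!b %in% needs[[dir]]) next
        cands <- list()
        if (b %in% graph$nodes) {
          ends <- if (dir == "production") cbind(hosts, b) else cbind(b, hosts)
          for (i in seq_len(nrow(ends)))
            cands <- c(cands, all_loopless_paths(graph, ends[i, 1], ends[i, 2], max_len = max_len))
        }
        if (!length(cands)) { sn$omitted <- union(sn$omitted, b); next }
        lens <- vapply(cands, `[[`, 0L, "length")
        cands <- cands[lens <= min(lens) + extra_steps]
        # prefer connections introducing the fewest non-host cosubstrates
        new_cos <- vapply(cands, function(pw) {
          pay <- .pathway_payload(graph, db, pw)
          fresh <- setdiff(pay$compounds, c(sn$compounds, sn$host_set))
          fresh <- fresh[!vapply(db$compounds[fresh], `[[`, TRUE, "excluded")]
          length(fresh)
        }, 0L)
        ws <- vapply(cands, `[[`, 0, "total_weight")
        keys <- vapply(cands, function(pw) paste(pw$nodes, collapse = "|"), "")
        cands <- cands[order(new_cos, ws, keys)]
        cands <- cands[!duplicated(vapply(cands, function(pw) paste(pw$nodes, collapse = "|"), ""))]
        for (pw in cands[seq_len(min(k_cosub, length(cands)))]) {
          pay <- .pathway_payload(graph, db, pw)
          sn$reactions <- sort(union(sn$reactions, pay$reactions))
          sn$compounds <- sort(union(sn$compounds, pay$compounds))
          sn$edges <- unique(rbind(sn$edges, pay$edges))
          progress <- TRUE
        }
      }
    }
    if (!progress) {
      needs2 <- .boundary_needs(sn, db)
      sn$rounds <- c(sn$rounds, length(union(needs2$production, needs2$consumption)))
      break
    }
  }
  sn$boundary <- character(0)
  sn$status <- "expanded"
  sn
}

#' Converge a subnetwork to a closed reaction set
#'
#' Removes all reactions that reference an omitted compound or a compound
#' with no production (when consumed) or no consumption (when produced)
#' inside the subnetwork, cascading until a fixed point: afterwards every
#' non-host, non-excluded compound has at least one producing and one
#' consuming retained reaction, or is the target.  `converge` is idempotent
#' and only forced removals occur.  If the cascade disconnects the target
#' entirely the status is set to `"failed"`.
#'
#' @param sn an expanded `subnetwork`.
#' @param db the originating `reaction_db`.
#' @return converged `subnetwork` (status `"converged"` or `"failed"`).
#' @export
converge_subnetwork <- function(sn, db) {
  rids <- sn$reactions
  repeat {
    rxns <- db$reactions[rids]
    produced <- consumed <- character(0)
    for (r in rxns) {
      s <- names(r$stoich)[r$stoich < 0]; p <- names(r$stoich)[r$stoich > 0]
      if (r$reversible) { s <- names(r$stoich); p <- names(r$stoich) }
      consumed <- union(consumed, s); produced <- union(produced, p)
    }
    ok_compound <- function(cid, role) {
      if (cid %in% sn$omitted) return(FALSE)
      if (cid %in% sn$host_set) return(TRUE)
      cp <- db$compounds[[cid]]
      if (cp$excluded) return(TRUE)
      if (identical(cid, sn$target)) return(role == "product" || cid %in% produced)
      if (role == "substrate") cid %in% produced else cid %in% consumed
    }
    bad <- vapply(rxns, function(r) {
      s <- names(r$stoich)[r$stoich < 0]; p <- names(r$stoich)[r$stoich > 0]
      if (r$reversible) { s <- names(r$stoich); p <- names(r$stoich) }
      any(!vapply(s, ok_compound, TRUE, role = "substrate")) ||
        any(!vapply(p, ok_compound, TRUE, role = "product"))
    }, TRUE)
    if (!any(bad)) break
    rids <- rids[!bad]
  }
  sn$reactions <- sort(rids)
  sn$compounds <- sort(unique(unlist(lapply(db$reactions[rids], function(r) names(r$stoich)))))
  edge_rids <- strsplit(sn$edges$reactions, ";", fixed = TRUE)
  keep_edge <- vapply(edge_rids, function(rr) any(rr %in% rids), TRUE)
  sn$edges <- sn$edges[keep_edge, , drop = FALSE]
  sn$edges$reactions <- vapply(edge_rids[keep_edge], function(rr)
    paste(intersect(rr, rids), collapse = ";"), "")
  target_produced <- any(vapply(db$reactions[rids], function(r)
    !is.na(r$stoich[sn$target]) && (r$stoich[sn$target] > 0 || r$reversible), TRUE))
  sn$core_pathways <- Filter(function(pw) {
    all(pw$edge_keys %in% .edge_key(sn$edges$source, sn$edges$target))
  }, sn$core_pathways)
  sn$status <- if (target_produced) "converged" else "failed"
  sn
}

#' Topology report of a converged subnetwork
#'
#' Components are computed on the undirected compound graph in which two
#' compounds are adjacent when they participate in the same retained
#' reaction; the main component is the largest by compound count.
#'
#' @param sn a `subnetwork`.
#' @param db the originating `reaction_db`.
#' @return list with `n_compounds`, `n_reactions`, `n_edges`,
#'   `n_isolated_components`, `pct_main_component` (percent of compounds in
#'   the main component) and `target_in_main`.
#' @export
subnetwork_topology <- function(sn, db) {
  if (!length(sn$compounds))
    return(list(n_compounds = 0L, n_reactions = 0L, n_edges = 0L,
                n_isolated_components = 0L, pct_main_component = 0,
                target_in_main = FALSE))
  pairs <- unique(do.call(rbind, lapply(db$reactions[sn$reactions], function(r) {
    ids <- names(r$stoich)
    if (length(ids) < 2) return(NULL)
    t(utils::combn(sort(ids), 2))
  })))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(sn$compounds), name = sn$compounds)
  if (!is.null(pairs) && nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_main <- names(comp$membership)[comp$membership == main]
  list(n_compounds = length(sn$compounds),
       n_reactions = length(sn$reactions),
       n_edges = if (is.null(pairs)) 0L else nrow(pairs),
       n_isolated_components = comp$no,
       pct_main_component = 100 * max(comp$csize) / length(sn$compounds),
       target_in_main = sn$target %in% in_main)
}

.gdf_quote <- function(x) {
  needs <- grepl("[,'\"]", x)
  x[needs] <- paste0("'", gsub("'", "’", x[needs]), "'")
  x
}

#' Write a network in Gephi GDF format
#'
#' Node table: id, host flag, boundary flag.  Edge table: source, target,
#' attached reaction ids.  Fields containing commas are quoted.
#'
#' @param x an `rp_graph` or `subnetwork`.
#' @param path output file.
#' @param host_set,boundary node flag sets (for `rp_graph` input; a
#'   `subnetwork` carries its own).
#' @return `path`, invisibly.
#' @export
write_gdf <- function(x, path, host_set = character(0), boundary = character(0)) {
  if (inherits(x, "subnetwork")) {
    nodes <- x$compounds; edges <- x$edges
    host_set <- x$host_set; boundary <- union(x$boundary, x$omitted)
  } else if (inherits(x, "rp_graph")) {
    nodes <- x$nodes
    edges <- x$edges[c("source", "target", "reactions")]
  } else stop("write_gdf: unsupported object")
  lines <- c(
    "nodedef>name VARCHAR,host BOOLEAN,boundary BOOLEAN",
    if (length(nodes)) paste(.gdf_quote(nodes),
                             tolower(nodes %in% host_set),
                             tolower(nodes %in% boundary), sep = ","),
    "edgedef>node1 VARCHAR,node2 VARCHAR,reactions VARCHAR",
    if (nrow(edges)) paste(.gdf_quote(edges$source), .gdf_quote(edges$target),
                           .gdf_quote(edges$reactions), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GDF file back into node and edge tables
#' @param path GDF file written by [write_gdf()].
#' @return list with data frames `nodes` and `edges`.
#' @export
read_gdf <- function(path) {
  lines <- readLines(path)
  ed <- grep("^edgedef>", lines)
  split_row <- function(row) {
    out <- character(0); buf <- ""; inq <- FALSE
    for (ch in strsplit(row, "")[[1]]) {
      if (ch == "'") inq <- !inq
      else if (ch == "," && !inq) { out <- c(out, buf); buf <- "" }
      else buf <- paste0(buf, ch)
    }
    c(out, buf)
  }
  parse_block <- function(rows, cols) {
    if (!length(rows)) {
      df <- as.data.frame(stats::setNames(replicate(length(cols), character(0), simplify = FALSE), cols))
      return(df)
    }
    m <- do.call(rbind, lapply(rows, split_row))
    stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), cols)
  }
  ncols <- sub("^nodedef>", "", lines[1])
  ncols <- vapply(strsplit(ncols, ",")[[1]], function(s) strsplit(trimws(s), " ")[[1]][1], "")
  ecols <- sub("^edgedef>", "", lines[ed])
  ecols <- vapply(strsplit(ecols, ",")[[1]], function(s) strsplit(trimws(s), " ")[[1]][1], "")
  nodes <- parse_block(lines[setdiff(seq_len(ed - 1L), 1L)], ncols)
  erows <- if (ed < length(lines)) lines[(ed + 1L):length(lines)] else character(0)
  list(nodes = nodes, edges = parse_block(erows, ecols))
}

#' Serialize a subnetwork to JSON
#' @param sn a `subnetwork`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_subnetwork_json <- function(sn, path) {
  doc <- list(
    status = sn$status, target = sn$target,
    reactions = as.list(sn$reactions), compounds = as.list(sn$compounds),
    core_pathways = lapply(sn$core_pathways, function(pw)
      list(nodes = as.list(pw$nodes), total_weight = pw$total_weight, length = pw$length)),
    omitted = as.list(sn$omitted), rounds = as.list(sn$rounds),
    host_set = as.list(sn$host_set))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
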