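# Reactant-product-pair graph construction and weighted k-shortest loopless
# path search.  Compounds are nodes; each retained RP-pair is a directed edge
# that carries its conserved atom ratio (CAR), the attached reactions and
# their cosubstrates, so that hypergraph information survives inside a simple
# graph.

#' Edge weight from atom conservation and reaction provenance
#'
#' `weight = beta^known * car^(-lambda)`.  With `lambda = 0, beta = 1` every
#' edge has unit weight and the search reduces to plain hop counting; larger
#' `lambda` penalizes steps that lose atoms, and `beta < 1` expresses a
#' preference for edges backed by at least one known reaction.
#'
#' @param car conserved atom ratio in (0, 1].
#' @param has_known does any attached reaction have provenance "known"?
#' @param lambda exponent (>= 0) of the inverse-CAR transformation.
#' @param beta known-reaction preference factor in (0, 1].
#' @return positive edge weight.
#' @export
edge_weight <- function(car, has_known = FALSE, lambda = 1, beta = 1) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  if (any(car <= 0)) stop("edge with car = 0 should have been filtered out")
  ifelse(has_known, beta, 1) * car^(-lambda)
}

#' Build the explorable RP-pair graph from a reaction database
#'
#' One directed edge per retained reactant-product pair.  Pairs whose
#' conserved atom ratio falls below `car_threshold` are removed ("the
#' threshold for the conserved atom ratio per pathway step"); excluded
#' compounds, and any compounds listed in `drop_compounds`, are removed with
#' their incident edges; pairs whose attached reactions are all reversible
#' are traversable in both directions.
#'
#' @param db a `reaction_db`.
#' @param car_threshold minimum conserved atom ratio in \[0, 1\].
#' @param lambda,beta weighting parameters, see [edge_weight()].
#' @param drop_compounds compound ids to remove from the graph.
#' @return object of class `"rp_graph"`: list with `nodes`, `edges` (data
#'   frame: source, target, car, reactions, has_known, weight) and `igraph`
#'   (the directed igraph used for searches).
#' @export
build_graph <- function(db, car_threshold = 0, lambda = 1, beta = 1,
                        drop_compounds = character(0)) {
  if (car_threshold < 0 || car_threshold > 1)
    stop("car_threshold must lie in [0, 1]")
  excl <- names(db$compounds)[vapply(db$compounds, `[[`, TRUE, "excluded")]
  drop <- union(excl, drop_compounds)
  nodes <- setdiff(names(db$compounds), drop)
  rp <- db$rp_pairs
  keep <- rp$car >= car_threshold & rp$car > 0 &
    !(rp$source %in% drop) & !(rp$target %in% drop)
  rp <- rp[keep, , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(rp))) {
    rids <- strsplit(rp$reactions[i], ";", fixed = TRUE)[[1]]
    rxns <- db$reactions[rids]
    has_known <- any(vapply(rxns, `[[`, "", "provenance") == "known")
    rows[[length(rows) + 1L]] <- data.frame(
      source = rp$source[i], target = rp$target[i], car = rp$car[i],
      reactions = rp$reactions[i], has_known = has_known, stringsAsFactors = FALSE)
    if (any(vapply(rxns, `[[`, TRUE, "reversible")))
      rows[[length(rows) + 1L]] <- data.frame(
        source = rp$target[i], target = rp$source[i], car = rp$car[i],
        reactions = rp$reactions[i], has_known = has_known, stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0), car = numeric(0),
               reactions = character(0), has_known = logical(0))
  edges <- edges[!duplicated(edges[c("source", "target")]), , drop = FALSE]
  edges$weight <- if (nrow(edges))
    edge_weight(edges$car, edges$has_known, lambda, beta) else numeric(0)
  rownames(edges) <- NULL

  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$source, edges$target),
                           weight = edges$weight)
  structure(list(nodes = nodes, edges = edges, igraph = g, db_ref = NULL),
            class = "rp_graph")
}

#' @export
print.rp_graph <- function(x, ...) {
  cat("RP-pair graph:", length(x$nodes), "compounds,", nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Cosubstrates and byproducts of a reaction relative to a pathway step
#'
#' @param rxn a `pw_reaction`.
#' @param source,target the main substrate and product of the step.
#' @return list with `substrates` (participants consumed other than
#'   `source`) and `products` (participants produced other than `target`).
#' @export
step_cosubstrates <- function(rxn, source, target) {
  subs <- names(rxn$stoich)[rxn$stoich < 0]
  prods <- names(rxn$stoich)[rxn$stoich > 0]
  if (rxn$reversible && !(source %in% subs) && source %in% prods) {
    tmp <- subs; subs <- prods; prods <- tmp   # traversed in reverse
  }
  list(substrates = setdiff(subs, source), products = setdiff(prods, target))
}

# internal: weights/edge lookup from the edges table
.edge_key <- function(s, t) paste(s, t, sep = ">")

#' k-shortest loopless paths between two compounds
#'
#' Yen's algorithm on the weighted RP-pair graph.  Paths longer than
#' `max_len` edges are skipped but enumeration continues, so the result is
#' exhaustive up to `k` within the length bound.  Ties in total weight are
#' broken by length (shorter first), then lexicographically on the edge-id
#' sequence, making the output deterministic.
#'
#' @param graph an `rp_graph`.
#' @param source,target compound ids (must differ).
#' @param k maximum number of paths.
#' @param max_len maximum number of edges per path.
#' @return list of pathways, each of class `"linear_pathway"`: list with
#'   `nodes` (ordered compound ids), `edge_keys`, `total_weight`, `length`.
#'   Empty list when no path exists.
#' @export
k_shortest_paths <- function(graph, source, target, k = 5L, max_len = 10L) {
  if (identical(source, target)) stop("source and target must differ")
  if (!source %in% graph$nodes) stop("source compound not in graph: ", source)
  if (!target %in% graph$nodes) stop("target compound not in graph: ", target)
  if (k < 1) stop("k must be >= 1")
  g <- graph$igraph
  wkey <- stats::setNames(graph$edges$weight, .edge_key(graph$edges$source, graph$edges$target))

  path_weight <- function(nodes) {
    if (length(nodes) < 2) return(0)
    sum(wkey[.edge_key(nodes[-length(nodes)], nodes[-1])])
  }
  sp <- function(gg, from, to) {
    res <- suppressWarnings(igraph::shortest_paths(gg, from, to, weights = igraph::E(gg)$weight,
                                                   output = "vpath"))
    vp <- res$vpath[[1]]
    if (!length(vp)) return(NULL)
    names(vp)
  }

  found <- list()       # accepted shortest paths in enumeration order
  cand <- list()        # candidate pool (unique by node sequence)
  seen <- character(0)
  p0 <- sp(g, source, target)
  if (is.null(p0)) return(list())
  cand[[1]] <- p0; seen <- paste(p0, collapse = "|")
  kept <- list()        # paths within max_len
  max_iter <- 100000L
  it <- 0L
  while (length(cand) && it < max_iter) {
    it <- it + 1L
    ws <- vapply(cand, path_weight, 0)
    lens <- lengths(cand) - 1L
    keys <- vapply(cand, paste, "", collapse = "|")
    ord <- order(ws, lens, keys)
    best <- cand[[ord[1]]]
    cand <- cand[-ord[1]]
    found[[length(found) + 1L]] <- best
    if (length(best) - 1L <= max_len) kept[[length(kept) + 1L]] <- best
    if (length(kept) >= k) {
      # continue only while ties with the k-th kept weight remain possible
      kth <- path_weight(kept[[k]])
      if (!length(cand) || min(vapply(cand, path_weight, 0)) > kth + 1e-12) break
    }
    # spur paths off the last accepted path
    for (i in seq_len(length(best) - 1L)) {
      root <- best[seq_len(i)]
      gg <- g
      # remove edges used by previous paths sharing this root
      for (p in found) {
        if (length(p) > i && identical(p[seq_len(i)], root)) {
          eid <- tryCatch(igraph::get_edge_ids(gg, c(p[i], p[i + 1L])), error = function(e) 0)
          eid <- eid[eid > 0]
          if (length(eid)) gg <- igraph::delete_edges(gg, eid)
        }
      }
      # remove root nodes except the spur node
      if (i > 1L) gg <- igraph::delete_vertices(gg, root[seq_len(i - 1L)])
      spur <- sp(gg, root[i], target)
      if (is.null(spur)) next
      full <- c(root[seq_len(i - 1L)], spur)
      key <- paste(full, collapse = "|")
      if (!key %in% seen) { seen <- c(seen, key); cand[[length(cand) + 1L]] <- full }
    }
  }
  kept <- kept[lengths(kept) - 1L <= max_len]
  if (!length(kept)) return(list())
  ws <- vapply(kept, path_weight, 0)
  lens <- lengths(kept) - 1L
  ekeys <- vapply(kept, function(p) paste(.edge_key(p[-length(p)], p[-1]), collapse = ","), "")
  ord <- order(ws, lens, ekeys)
  kept <- kept[ord][seq_len(min(k, length(kept)))]
  lapply(kept, function(p) linear_pathway(p, path_weight(p)))
}

#' Construct a linear pathway object
#' @param nodes ordered compound ids (precursor ... target).
#' @param total_weight sum of edge weights.
#' @return object of class `"linear_pathway"`.
#' @export
linear_pathway <- function(nodes, total_weight) {
  if (anyDuplicated(nodes)) stop("linear pathways are loopless: repeated node")
  structure(list(nodes = nodes,
                 edge_keys = if (length(nodes) > 1)
                   .edge_key(nodes[-length(nodes)], nodes[-1]) else character(0),
                 total_weight = total_weight,
                 length = length(nodes) - 1L),
            class = "linear_pathway")
}

#' @export
print.linear_pathway <- function(x, ...) {
  cat(paste(x$nodes, collapse = " -> "), sprintf(" [%d steps, w=%.4g]\n", x$length, x$total_weight))
  invisible(x)
}

#' Enumerate all loopless paths by depth-first search
#'
#' Exhaustive enumeration used as the brute-force counterpart of
#' [k_shortest_paths()] and inside subnetwork expansion on the small graphs
#' this package targets.
#'
#' @inheritParams k_shortest_paths
#' @return list of `linear_pathway`, sorted by (weight, length, edge keys).
#' @export
all_loopless_paths <- function(graph, source, target, max_len = 10L) {
  adj <- split(graph$edges$target, graph$edges$source)
  wkey <- stats::setNames(graph$edges$weight, .edge_key(graph$edges$source, graph$edges$target))
  out <- list()
  rec <- function(path, w) {
    last <- path[length(path)]
    if (last == target) { out[[length(out) + 1L]] <<- list(nodes = path, w = w); return() }
    if (length(path) - 1L >= max_len) return()
    for (nb in adj[[last]]) if (!nb %in% path)
      rec(c(path, nb), w + wkey[[.edge_key(last, nb)]])
  }
  if (source %in% graph$nodes && target %in% graph$nodes) rec(source, 0)
  if (!length(out)) return(list())
  ws <- vapply(out, `[[`, 0, "w")
  lens <- lengths(lapply(out, `[[`, "nodes")) - 1L
  ekeys <- vapply(out, function(p) paste(.edge_key(p$nodes[-length(p$nodes)], p$nodes[-1]),
                                         collapse = ","), "")
  out <- out[order(ws, lens, ekeys)]
  lapply(out, function(p) linear_pathway(p$nodes, p$w))
}
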