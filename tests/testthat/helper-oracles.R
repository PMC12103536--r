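# Independent brute-force oracles, deliberately implemented without reusing
# the package's search code paths.

# exhaustive loopless path enumeration over an edge table (source, target,
# weight); returns list of list(nodes, w), sorted by (w, length, edge keys)
oracle_paths <- function(edges, source, target, max_len = 10L) {
  out <- list()
  wmap <- new.env()
  for (i in seq_len(nrow(edges)))
    assign(paste(edges$source[i], edges$target[i]), edges$weight[i], envir = wmap)
  succ <- split(edges$target, edges$source)
  walk <- function(path) {
    last <- path[length(path)]
    if (last == target) {
      w <- 0
      if (length(path) > 1)
        for (j in seq_len(length(path) - 1L))
          w <- w + get(paste(path[j], path[j + 1L]), envir = wmap)
      out[[length(out) + 1L]] <<- list(nodes = path, w = w)
      return()
    }
    if (length(path) - 1L >= max_len) return()
    for (nxt in succ[[last]]) if (!nxt %in% path) walk(c(path, nxt))
  }
  walk(source)
  if (!length(out)) return(out)
  key <- vapply(out, function(p) paste(paste(p$nodes[-length(p$nodes)], p$nodes[-1], sep = ">"),
                                       collapse = ","), "")
  out[order(vapply(out, `[[`, 0, "w"), lengths(lapply(out, `[[`, "nodes")) - 1L, key)]
}

# LP feasibility of a given open non-native set at a production requirement
support_feasible <- function(model, open, requirement, uptake = 10) {
  fp <- pathweaver:::.flux_problem(model, uptake)
  closed <- setdiff(model$non_native, open)
  fp$lb[closed] <- 0
  fp$ub[closed] <- 0
  obj <- as.numeric(fp$rids == model$demand_reaction)
  res <- solve_lp(obj, A = fp$S, b = rep(0, nrow(fp$S)), lb = fp$lb, ub = fp$ub,
                  maximize = TRUE)
  res$status == "optimal" && res$objval >= requirement - 1e-6
}

# all inclusion-minimal feasible non-native supports, by subset enumeration
# in ascending cardinality with superset pruning (feasibility is monotone in
# the open set)
oracle_minimal_supports <- function(model, theta, uptake = 10, vmax = NULL) {
  if (is.null(vmax)) vmax <- max_production(model, uptake)$vmax
  if (vmax <= 1e-9) return(list())
  req <- theta * vmax - 1e-7
  nn <- model$non_native
  minimal <- list()
  for (size in 0:length(nn)) {
    combos <- if (size == 0) list(character(0)) else
      utils::combn(nn, size, simplify = FALSE)
    for (s in combos) {
      if (any(vapply(minimal, function(m) all(m %in% s), TRUE))) next
      if (support_feasible(model, s, req, uptake))
        minimal[[length(minimal) + 1L]] <- s
    }
  }
  minimal
}

support_key <- function(s) paste(sort(s), collapse = "+")

# toy model helpers used across tests
fixture_model <- function(fixture, target, precursors = "P1",
                          lambda = 1, k = 5, extra_steps = 0) {
  host <- make_fixture("H1")
  db <- make_fixture(fixture)
  map <- map_metabolites(host, db)
  graph <- build_graph(db, lambda = lambda)
  sn <- extract_core(graph, db, target, precursors, host_set = map$host_set, k = k)
  sn <- expand_subnetwork(sn, graph, db, extra_steps = extra_steps)
  sn <- converge_subnetwork(sn, db)
  model <- integrate_subnetwork(host, sn, db, target, mapping = map)
  list(host = host, db = db, map = map, graph = graph, sn = sn, model = model)
}

fixture_targets <- c(F1 = "T1", F2 = "T2", F3 = "T3", F4 = "T4", F5 = "T5")

# random weighted digraph as an edge table + rp_graph, for search oracles
random_digraph <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
  if (!nrow(pairs)) pairs <- data.frame(source = nodes[1], target = nodes[2])
  pairs$car <- round(runif(nrow(pairs), 0.2, 1), 3)
  pairs$reactions <- sprintf("RX%03d", seq_len(nrow(pairs)))
  comps <- lapply(nodes, function(n) compound(n, "C2H4O2", structure_key = paste0("K", n)))
  names(comps) <- nodes
  rxns <- lapply(seq_len(nrow(pairs)), function(i)
    reaction(pairs$reactions[i],
             stats::setNames(c(-1, 1), c(pairs$source[i], pairs$target[i]))))
  db <- reaction_database(comps, rxns, pairs[c("source", "target", "car", "reactions")])
  build_graph(db, lambda = 1)
}
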