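# Precursor candidate selection: carbon-count and substructure filtering,
# then ranking by maximum common substructure (MCS) with the target.
#
# Structures come in as SMILES and are parsed through ChemmineR/ChemmineOB.
# The MCS is computed on heavy atoms as a maximum clique of the modular
# product of the two molecular graphs; when a structure cannot be resolved
# (or the clique search exceeds its budget) the ranking falls back to a
# common-element-count heuristic.

.have_chemmine <- function() {
  requireNamespace("ChemmineR", quietly = TRUE) &&
    requireNamespace("ChemmineOB", quietly = TRUE)
}

# heavy-atom molecular graph from a SMILES string:
# list(elements, bonds = data.frame(a, b, order)) or NULL
.mol_graph <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles) || !.have_chemmine()) return(NULL)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(NULL)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  el <- sub("_.*$", "", rownames(ab))
  heavy <- which(el != "H")
  idx <- match(seq_along(el), heavy)   # old -> new index
  bonds <- data.frame(a = idx[bb[, 1]], b = idx[bb[, 2]], order = as.integer(bb[, 3]))
  bonds <- bonds[!is.na(bonds$a) & !is.na(bonds$b), , drop = FALSE]
  list(elements = el[heavy], bonds = bonds)
}

# maximum common (induced) substructure size in atoms, via maximum clique on
# the modular product graph; -1 on failure
.mcs_atoms <- function(g1, g2, max_nodes = 4000L) {
  if (is.null(g1) || is.null(g2)) return(-1L)
  n1 <- length(g1$elements); n2 <- length(g2$elements)
  pairs <- which(outer(g1$elements, g2$elements, "=="), arr.ind = TRUE)
  if (!nrow(pairs)) return(0L)
  if (nrow(pairs) > max_nodes) return(-1L)
  bmat <- function(g, n) {
    m <- matrix(0L, n, n)
    if (nrow(g$bonds)) {
      m[cbind(g$bonds$a, g$bonds$b)] <- g$bonds$order
      m[cbind(g$bonds$b, g$bonds$a)] <- g$bonds$order
    }
    m
  }
  b1 <- bmat(g1, n1); b2 <- bmat(g2, n2)
  np <- nrow(pairs)
  adj <- matrix(FALSE, np, np)
  for (u in seq_len(np - 1L)) {
    i <- pairs[u, 1]; j <- pairs[u, 2]
    vs <- (u + 1L):np
    ok <- pairs[vs, 1] != i & pairs[vs, 2] != j &
      b1[i, pairs[vs, 1]] == b2[j, pairs[vs, 2]]
    adj[u, vs[ok]] <- TRUE
    adj[vs[ok], u] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::clique_num(g))
}

# fallback similarity: atoms of each heavy element shared between formulas
.common_heavy_atoms <- function(f1, f2) {
  els <- setdiff(intersect(names(f1), names(f2)), "H")
  if (!length(els)) return(0L)
  sum(pmin(f1[els], f2[els]))
}

#' Filter precursor candidates by carbon count and substructure
#'
#' Candidates with more carbon atoms than the target are removed (they
#' cannot be fully incorporated without carbon loss).  When a substructure
#' pattern is given (SMARTS string), only candidates containing it are
#' retained.
#'
#' @param target a `pw_compound`.
#' @param candidates list of `pw_compound`.
#' @param substructure optional SMARTS pattern.
#' @return filtered list of `pw_compound`.
#' @export
filter_candidates <- function(target, candidates, substructure = NULL) {
  keep <- vapply(candidates, function(cp) n_carbon(cp) <= n_carbon(target), TRUE)
  candidates <- candidates[keep]
  if (!is.null(substructure) && length(candidates)) {
    if (!.have_chemmine())
      stop("substructure filtering needs ChemmineR/ChemmineOB")
    smiles <- vapply(candidates, function(cp) if (is.na(cp$smiles)) "" else cp$smiles, "")
    has_struct <- nzchar(smiles)
    if (any(!has_struct))
      warning("candidates without SMILES skipped by substructure filter: ",
              paste(vapply(candidates[!has_struct], `[[`, "", "id"), collapse = ", "))
    hits <- logical(length(candidates))
    if (any(has_struct)) {
      sdf <- ChemmineR::smiles2sdf(smiles[has_struct])
      counts <- tryCatch(ChemmineR::smartsSearchOB(sdf, substructure, uniqueMatches = FALSE),
                         error = function(e) stop("unparsable substructure pattern: ", substructure))
      hits[has_struct] <- counts > 0
    }
    candidates <- candidates[hits]
  }
  candidates
}

#' Rank precursor candidates by maximum common substructure with the target
#'
#' Candidates are scored by the number of heavy atoms in their MCS with the
#' target and the `n` best are returned; ties are broken by candidate id, so
#' the result is invariant to input order.  Candidates whose structure
#' cannot be resolved are scored by the common-element-count heuristic and a
#' warning is raised.
#'
#' @param target a `pw_compound` with a SMILES structure.
#' @param candidates list of `pw_compound`.
#' @param n how many to keep.
#' @return list of up to `n` `pw_compound`, best first, with the scores in
#'   attribute `"mcs_atoms"`.
#' @export
rank_by_mcs <- function(target, candidates, n = 5L) {
  if (!length(candidates)) return(list())
  gt <- .mol_graph(target$smiles)
  scores <- vapply(candidates, function(cp) {
    sc <- .mcs_atoms(gt, .mol_graph(cp$smiles))
    if (sc < 0) {
      warning("structure unresolved for ", cp$id, "; using element-count heuristic")
      sc <- .common_heavy_atoms(target$formula, cp$formula)
    }
    sc
  }, 0L)
  ids <- vapply(candidates, `[[`, "", "id")
  ord <- order(-scores, ids)
  out <- candidates[ord][seq_len(min(n, length(candidates)))]
  attr(out, "mcs_atoms") <- scores[ord][seq_len(min(n, length(candidates)))]
  out
}

#' Select precursors for a target from a candidate pool
#'
#' Convenience wrapper: carbon/substructure filtering followed by MCS
#' ranking.  The default pool is the host-mapped metabolite set.
#'
#' @param target a `pw_compound`.
#' @param db a `reaction_db`.
#' @param pool candidate compound ids (default: all db compounds with a
#'   structure key, typically restricted by the caller to host-mapped ones).
#' @param n number of precursors to select.
#' @param substructure optional SMARTS pattern.
#' @return character vector of selected precursor compound ids.
#' @export
select_precursors <- function(target, db, pool, n = 5L, substructure = NULL) {
  cands <- db$compounds[intersect(pool, names(db$compounds))]
  cands <- filter_candidates(target, unname(cands), substructure)
  if (!length(cands)) return(character(0))
  ranked <- rank_by_mcs(target, cands, n)
  vapply(ranked, `[[`, "", "id")
}
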