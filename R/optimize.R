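# Flux balance analysis and mixed-integer enumeration of minimal feasible
# production pathways.  The MILP is
#
#   min sum(w_j y_j)   over v, y
#   s.t. S v = 0
#        LB_j <= v_j <= UB_j                   (native)
#        y_j LB_j <= v_j <= y_j UB_j           (non-native, y_j binary)
#        theta * Vmax_product <= v_product
#        integer cuts excluding previously found active sets
#
# where each binary y_j switches a non-native reaction on or off.  A single
# binary controls both directions of a reversible non-native reaction.

.flux_problem <- function(model, uptake = NULL) {
  rids <- names(model$reactions)
  mids <- model$metabolites$id
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  lb <- ub <- stats::setNames(numeric(length(rids)), rids)
  for (r in model$reactions) {
    S[names(r$stoich), r$id] <- r$stoich
    lb[r$id] <- r$lb; ub[r$id] <- r$ub
  }
  if (!is.null(uptake)) {
    sx <- model$substrate_exchange
    if (is.na(sx) || !sx %in% rids) stop("substrate exchange reaction not identified")
    lb[sx] <- -abs(uptake)
  }
  list(S = S, lb = lb, ub = ub, rids = rids)
}

#' Maximum production rate of the target
#'
#' Solves the FBA linear program maximizing the demand-reaction flux with the
#' substrate uptake bounded at `uptake` (default 10 mmol/gDW/h).  An optimum
#' of 0 means no feasible production pathway exists in the model; an
#' infeasible LP (inconsistent bounds) raises an error instead.
#'
#' @param model an `integrated_model` (or any `host_model` with a demand).
#' @param uptake substrate uptake bound, mmol/gDW/h.
#' @param objective_reaction reaction whose flux is maximized; defaults to
#'   the model's demand reaction.
#' @return list with `vmax` (optimal demand flux) and `fluxes`.
#' @export
max_production <- function(model, uptake = 10, objective_reaction = NULL) {
  obj_id <- objective_reaction %||% model$demand_reaction
  if (is.null(obj_id) || !obj_id %in% names(model$reactions))
    stop("model has no demand reaction")
  fp <- .flux_problem(model, uptake)
  obj <- as.numeric(fp$rids == obj_id)
  res <- solve_lp(obj, A = fp$S, b = rep(0, nrow(fp$S)), lb = fp$lb, ub = fp$ub,
                  maximize = TRUE)
  if (res$status != "optimal") stop("FBA infeasible: inconsistent model bounds")
  list(vmax = res$objval, fluxes = stats::setNames(res$x, fp$rids))
}

#' Molar and carbon yield of a production flux
#'
#' Molar yield: moles of product per mole of substrate consumed.  Carbon
#' yield: fraction of substrate carbon atoms ending up in the product (1.0 =
#' 100% g-C, all carbon conserved).
#'
#' @param v_product production flux.
#' @param substrate_flux substrate uptake flux (> 0).
#' @param n_c_target,n_c_substrate carbon counts of target and substrate.
#' @return named numeric: `molar_yield`, `carbon_yield`.
#' @export
yields <- function(v_product, substrate_flux, n_c_target, n_c_substrate) {
  if (substrate_flux <= 0) stop("substrate flux must be positive")
  molar <- v_product / substrate_flux
  c(molar_yield = molar, carbon_yield = molar * n_c_target / n_c_substrate)
}

#' Enzyme-assignment weights from BridgIT scores
#'
#' `w_j = W - s_j`; a reaction without a score gets the worst case
#' `w_j = W`.  Higher `W` favours smaller pathways, lower `W` favours
#' reactions with better enzyme assignments; `W` must not fall below any
#' score, or weights would go non-positive.
#'
#' @param reactions named list of `pw_reaction` (or numeric scores).
#' @param W offset; commonly 1.1 or 2.
#' @return named numeric weights.
#' @export
bridgit_weights <- function(reactions, W = 2) {
  s <- if (is.numeric(reactions)) reactions else
    vapply(reactions, `[[`, 0, "bridgit_score")
  if (any(!is.na(s) & s > W)) stop("W must be >= every BridgIT score")
  w <- W - s
  w[is.na(w)] <- W
  w
}

#' Enumerate minimal feasible production pathways by MILP with integer cuts
#'
#' Repeatedly solves the enumeration MILP; after each optimum with active set
#' `A`, the integer cut `sum(j in A) (1 - y_j) >= 1` is added, excluding that
#' active set and all of its supersets, and the MILP is re-solved until `K`
#' pathways are found, the objective exceeds the first optimum by more than
#' `slack`, or the program becomes infeasible.  Every returned pathway is
#' re-verified by an independent LP in which only its active non-native
#' reactions are open.
#'
#' @param model an `integrated_model`.
#' @param theta fraction of the maximum production rate enforced as a lower
#'   bound on the demand flux.
#' @param objective `"size"` (`w_j = 1`) or `"weight"` (BridgIT weights).
#' @param W offset for [bridgit_weights()] in weight mode.
#' @param weights optional explicit named weights over non-native reaction
#'   ids (overrides `objective`).
#' @param K maximum number of alternatives.
#' @param slack stop once the objective exceeds the minimum by more than
#'   this (Inf = enumerate to K).
#' @param uptake substrate uptake bound.
#' @param vmax precomputed maximum production (computed when NULL).
#' @param db optional `reaction_db` for carbon-yield computation.
#' @return list of pathways, each of class `"feasible_pathway"`: fields
#'   `active_non_native`, `size`, `weight`, `v_product`, `molar_yield`,
#'   `carbon_yield`, `thermo_feasible` (NA until checked).  Attribute
#'   `"status"` is `"ok"` or `"infeasible"` (empty list).
#' @export
enumerate_pathways <- function(model, theta = 0.5, objective = c("size", "weight"),
                               W = 2, weights = NULL, K = 100L, slack = Inf,
                               uptake = 10, vmax = NULL, db = NULL) {
  objective <- match.arg(objective)
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (is.null(vmax)) vmax <- max_production(model, uptake)$vmax
  out <- list()
  if (vmax <= 1e-9) { attr(out, "status") <- "no_production"; return(out) }
  fp <- .flux_problem(model, uptake)
  nr <- length(fp$rids)
  nn <- model$non_native
  ni <- match(nn, fp$rids)
  nb <- length(nn)
  if (is.null(weights)) {
    weights <- if (objective == "size") stats::setNames(rep(1, nb), nn) else {
      if (is.null(db)) stop("weight objective needs db for BridgIT scores")
      dbr <- model$db_reaction_ids[nn]
      stats::setNames(unname(bridgit_weights(db$reactions[dbr], W)), nn)
    }
  }
  w <- stats::setNames(rep(0, nr + nb), c(fp$rids, paste0("y_", nn)))
  w[nr + seq_len(nb)] <- unname(weights[nn])

  Aeq <- cbind(fp$S, matrix(0, nrow(fp$S), nb))
  beq <- rep(0, nrow(fp$S))
  # coupling rows: v_j - UB_j y_j <= 0 ; -v_j + LB_j y_j <= 0
  G <- matrix(0, 2L * nb + 1L, nr + nb)
  h <- numeric(2L * nb + 1L)
  for (t in seq_len(nb)) {
    j <- ni[t]
    G[2 * t - 1L, j] <- 1;  G[2 * t - 1L, nr + t] <- -fp$ub[j]
    G[2 * t, j] <- -1;      G[2 * t, nr + t] <- fp$lb[j]
  }
  di <- match(model$demand_reaction, fp$rids)
  G[2L * nb + 1L, di] <- -1
  # at theta = 0 still require (tiny) positive production, so the empty
  # active set is only returned when the host alone already makes the target;
  # the floor is scaled to vmax so relaxation y-values stay clearly fractional
  prod_floor <- if (theta > 0) theta * vmax - 1e-7 else 1e-3 * vmax
  h[2L * nb + 1L] <- -prod_floor
  lb <- c(fp$lb, rep(0, nb)); ub <- c(fp$ub, rep(1, nb))
  # with y_j = 0 the coupling rows close the reaction, so widen v bounds there
  lb[ni] <- pmin(fp$lb[ni], 0); ub[ni] <- pmax(fp$ub[ni], 0)

  tgt_nc <- sub_nc <- NA_integer_
  if (!is.null(db)) {
    tgt_nc <- n_carbon(db$compounds[[model$target]])
    sx_met <- names(model$reactions[[model$substrate_exchange]]$stoich)
    sx_key <- model$metabolites$structure_key[model$metabolites$id == sx_met]
    cand <- names(db$compounds)[vapply(db$compounds, `[[`, "", "structure_key") == sx_key]
    if (length(cand)) sub_nc <- n_carbon(db$compounds[[sort(cand)[1]]])
  }

  min_obj <- NA_real_
  while (length(out) < K) {
    res <- solve_milp(w, A = Aeq, b = beq, G = G, h = h, lb = lb, ub = ub,
                      bin_idx = nr + seq_len(nb))
    if (res$status != "optimal") break
    yv <- round(res$x[nr + seq_len(nb)])
    active <- nn[yv > 0.5]
    if (is.na(min_obj)) min_obj <- res$objval
    if (res$objval > min_obj + slack + 1e-9) break
    # independent LP verification with only the active non-natives open
    vlb <- fp$lb; vub <- fp$ub
    closed <- setdiff(nn, active)
    vlb[closed] <- 0; vub[closed] <- 0
    ver <- solve_lp(as.numeric(fp$rids == model$demand_reaction),
                    A = fp$S, b = beq, lb = vlb, ub = vub, maximize = TRUE)
    v_prod <- if (ver$status == "optimal") ver$objval else 0
    verified <- v_prod >= prod_floor - 1e-7
    if (verified) {
      yl <- if (!is.na(tgt_nc) && !is.na(sub_nc))
        yields(v_prod, uptake, tgt_nc, sub_nc) else
        c(molar_yield = v_prod / uptake, carbon_yield = NA_real_)
      pw <- structure(list(
        active_non_native = active, size = length(active),
        weight = sum(weights[active]), v_product = v_prod,
        molar_yield = unname(yl["molar_yield"]),
        carbon_yield = unname(yl["carbon_yield"]),
        fluxes = stats::setNames(ver$x, fp$rids),
        thermo_feasible = NA), class = "feasible_pathway")
      out[[length(out) + 1L]] <- pw
    }
    if (!length(active)) break   # size-0 solution: host alone makes the target
    cut <- numeric(nr + nb)
    cut[nr + match(active, nn)] <- 1
    G <- rbind(G, cut)                  # sum(y_j, j in active) <= |active| - 1
    h <- c(h, length(active) - 1)
  }
  attr(out, "status") <- if (length(out)) "ok" else "infeasible"
  out
}

#' @export
print.feasible_pathway <- function(x, ...) {
  cat("Pathway {", paste(x$active_non_native, collapse = ", "), "} size", x$size,
      "weight", format(x$weight), "v_product", format(x$v_product),
      "molar yield", format(x$molar_yield), "\n")
  invisible(x)
}

#' Minimum pathway size across production fractions (Pareto staircase)
#'
#' For each theta, the smallest number of non-native reactions able to carry
#' at least `theta * Vmax` production; optionally requiring thermodynamic
#' feasibility of the accepted pathway.  Higher production fractions can
#' only demand larger (or equal) pathways, so the staircase is
#' non-decreasing.
#'
#' @param model an `integrated_model`.
#' @param thetas production fractions to sweep (default the
#'   25/50/75/100% grid).
#' @param with_thermo require TFA feasibility (needs `db` and `ctx`).
#' @param db `reaction_db` (for thermodynamic data and yields).
#' @param ctx a [thermo_context()].
#' @param K_thermo how many alternatives to try per theta in thermo mode.
#' @param uptake substrate uptake bound.
#' @return data frame with columns `theta`, `min_size` (NA when infeasible),
#'   `thermo_constrained`.
#' @export
pareto_sweep <- function(model, thetas = c(0.25, 0.5, 0.75, 1.0),
                         with_thermo = FALSE, db = NULL, ctx = NULL,
                         K_thermo = 20L, uptake = 10) {
  if (any(thetas < 0 | thetas > 1)) stop("thetas must lie in [0, 1]")
  vmax <- max_production(model, uptake)$vmax
  rows <- lapply(thetas, function(th) {
    pws <- enumerate_pathways(model, theta = th, K = if (with_thermo) K_thermo else 1L,
                              uptake = uptake, vmax = vmax, db = db)
    size <- NA_integer_
    for (pw in pws) {
      if (with_thermo) {
        ok <- tfa_check(model, pw, db = db, ctx = ctx, theta = th, vmax = vmax,
                        uptake = uptake)$feasible
        if (!ok) next
      }
      size <- pw$size
      break
    }
    data.frame(theta = th, min_size = size, thermo_constrained = with_thermo)
  })
  do.call(rbind, rows)
}

#' Rank feasible pathways
#'
#' Stable multi-key sort over the ranking criteria: thermodynamic
#' feasibility (feasible first), product yield (higher first), pathway size
#' (smaller first), weight (smaller first).
#'
#' @param pathways list of `feasible_pathway`.
#' @param keys ordering criteria, a subset of
#'   `c("thermo", "yield", "size", "weight")`.
#' @return data frame, one row per pathway, ranked.
#' @export
rank_report <- function(pathways, keys = c("thermo", "yield", "size")) {
  if (!length(pathways))
    return(data.frame(rank = integer(0), reactions = character(0), size = integer(0),
                      weight = numeric(0), v_product = numeric(0),
                      molar_yield = numeric(0), carbon_yield = numeric(0),
                      thermo_feasible = logical(0)))
  df <- data.frame(
    reactions = vapply(pathways, function(p) paste(p$active_non_native, collapse = ";"), ""),
    size = vapply(pathways, `[[`, 0L, "size"),
    weight = vapply(pathways, `[[`, 0, "weight"),
    v_product = vapply(pathways, `[[`, 0, "v_product"),
    molar_yield = vapply(pathways, `[[`, 0, "molar_yield"),
    carbon_yield = vapply(pathways, function(p) as.numeric(p$carbon_yield), 0),
    thermo_feasible = vapply(pathways, function(p) as.logical(p$thermo_feasible), TRUE),
    stringsAsFactors = FALSE)
  cols <- list(
    thermo = -xtfrm(!is.na(df$thermo_feasible) & df$thermo_feasible),
    yield = -df$molar_yield, size = df$size, weight = df$weight)
  ord <- do.call(order, cols[intersect(keys, names(cols))])
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Net elemental exchange of a flux distribution
#'
#' Sums `flux * formula` over all boundary (single-metabolite) reactions.
#' For a steady-state solution of an elementally balanced model every entry
#' is zero: whatever enters through exchanges leaves through the demand.
#'
#' @param model an `integrated_model`.
#' @param fluxes named flux vector.
#' @param db `reaction_db` for formulas of non-native metabolites.
#' @return named numeric vector of net element export.
#' @export
element_exchange_balance <- function(model, fluxes, db) {
  key2formula <- list()
  for (cp in db$compounds) if (nzchar(cp$structure_key))
    key2formula[[cp$structure_key]] <- cp$formula
  formula_of <- function(mid) {
    key <- model$metabolites$structure_key[model$metabolites$id == mid]
    if (length(key) && nzchar(key) && !is.null(key2formula[[key]])) return(key2formula[[key]])
    cid <- sub("_nn$", "", mid)
    if (!is.null(db$compounds[[cid]])) return(db$compounds[[cid]]$formula)
    stop("no formula known for metabolite ", mid)
  }
  net <- numeric(0)
  for (r in model$reactions) {
    if (length(r$stoich) != 1L) next
    v <- fluxes[[r$id]]
    if (is.null(v) || is.na(v) || abs(v) < 1e-12) next
    f <- formula_of(names(r$stoich))
    contrib <- -unname(r$stoich) * v * f     # export positive
    for (el in names(contrib))
      net[el] <- (if (el %in% names(net)) net[[el]] else 0) + contrib[[el]]
  }
  net
}
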