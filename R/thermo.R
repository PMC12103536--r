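# Reaction Gibbs energies and thermodynamics-based flux analysis (TFA).
#
# The Gibbs energy of a reaction with participants j is
#
#   DrG' = sum_j n_j DfG'0_j + R T ln( prod_j x_j^n_j )
#
# with R = 8.31e-3 kJ/K/mol and T = 298 K.  In TFA the concentrations x_j
# become bounded variables and a binary direction indicator per reaction
# couples the flux sign to the sign of DrG' through big-M constraints.

#' Thermodynamic context
#'
#' @param temperature K.
#' @param pH cytosolic pH used by the Debye-Hueckel adjustment.
#' @param ionic_strength mol/L.
#' @param conc_intracellular,conc_extracellular concentration bounds
#'   (mol/L): intracellular metabolites between 11 and 50 mM, extracellular
#'   between 10 nM and 100 mM.
#' @param dfg_error_policy `"relax"` widens the directionality constraint by
#'   the propagated estimation error (favouring feasibility when uncertain);
#'   `"ignore"` uses point estimates.
#' @return object of class `"thermo_context"`.
#' @export
thermo_context <- function(temperature = 298, pH = 7, ionic_strength = 0.15,
                           conc_intracellular = c(0.011, 0.050),
                           conc_extracellular = c(1e-8, 0.1),
                           dfg_error_policy = c("relax", "ignore")) {
  stopifnot(conc_intracellular[1] > 0, conc_intracellular[1] < conc_intracellular[2],
            conc_extracellular[1] > 0, conc_extracellular[1] < conc_extracellular[2])
  structure(list(R = 8.31e-3, T = temperature, pH = pH,
                 ionic_strength = ionic_strength,
                 conc_bounds = list(intracellular = conc_intracellular,
                                    extracellular = conc_extracellular),
                 dfg_error_policy = match.arg(dfg_error_policy)),
            class = "thermo_context")
}

#' Adjust a formation energy for pH and ionic strength
#'
#' Extended Debye-Hueckel / Legendre transform of a standard formation
#' energy to the transformed scale at the context's pH and ionic strength:
#'
#'   DfG'0 = DfG0 + N_H R T ln(10) pH - A (z^2 - N_H) sqrt(I) / (1 + B sqrt(I))
#'
#' with A = 2.91482 kJ/mol/M^0.5 and B = 1.6 M^-0.5 (standard
#' biothermodynamics constants at 298 K).  At zero ionic strength only the
#' pH (proton chemical potential) term remains.  Energies flagged as already
#' transformed pass through unchanged.
#'
#' @param cp a `pw_compound` with `dfg0_prime`, a formula containing the
#'   hydrogen count, and a charge.
#' @param ctx a [thermo_context()].
#' @param pre_transformed input energies are already on the transformed
#'   scale; return them unchanged.
#' @return adjusted formation energy, kJ/mol.
#' @export
adjust_formation_energy <- function(cp, ctx = thermo_context(), pre_transformed = FALSE) {
  if (is.na(cp$dfg0_prime)) stop("compound ", cp$id, " has no formation energy")
  if (pre_transformed) return(cp$dfg0_prime)
  if (!length(cp$formula)) stop("compound ", cp$id, " needs a formula (H count) for adjustment")
  nh <- if ("H" %in% names(cp$formula)) cp$formula[["H"]] else 0
  z <- cp$charge
  rt <- ctx$R * ctx$T
  sq <- sqrt(ctx$ionic_strength)
  dh <- 2.91482 * (z^2 - nh) * sq / (1 + 1.6 * sq)
  cp$dfg0_prime + nh * rt * log(10) * ctx$pH - dh
}

#' Gibbs energy of a reaction
#'
#' Evaluates the reaction Gibbs energy from transformed formation energies
#' and metabolite concentrations; the standard-state range is widened by the
#' root-sum-square of the participants' estimation errors.
#'
#' @param rxn a `pw_reaction`.
#' @param energies named formation energies (kJ/mol) covering all
#'   participants (defaults to the compounds' `dfg0_prime`).
#' @param errors named estimation errors (kJ/mol); missing entries are 0.
#' @param concentrations named concentrations (mol/L); missing entries are
#'   1 M, i.e. they contribute nothing to the log term.
#' @param ctx a [thermo_context()].
#' @return list with `drg0` (standard transformed reaction energy),
#'   `drg_prime` (including the concentration term), `error` (propagated),
#'   and `range` (`drg0 +/- error`).
#' @export
reaction_gibbs <- function(rxn, energies, errors = NULL, concentrations = NULL,
                           ctx = thermo_context()) {
  ids <- names(rxn$stoich)
  miss <- ids[!ids %in% names(energies) | is.na(energies[ids])]
  if (length(miss))
    stop("missing formation energies for: ", paste(miss, collapse = ", "))
  n <- unname(rxn$stoich)
  drg0 <- sum(n * energies[ids])
  err <- if (is.null(errors)) 0 else {
    e <- errors[ids]; e[is.na(e)] <- 0
    sqrt(sum((n * e)^2))
  }
  logterm <- 0
  if (!is.null(concentrations)) {
    x <- concentrations[ids]
    x[is.na(x)] <- 1
    logterm <- ctx$R * ctx$T * sum(n * log(x))
  }
  list(drg0 = drg0, drg_prime = drg0 + logterm, error = err,
       range = c(drg0 - err, drg0 + err))
}

# formation energies/errors for the db compounds participating in the model's
# non-native reactions; reactions with any missing energy are unconstrained
.thermo_data <- function(model, db) {
  constrained <- list()
  for (nnid in model$non_native) {
    rid <- model$db_reaction_ids[[nnid]]
    r <- db$reactions[[rid]]
    en <- vapply(names(r$stoich), function(cid) db$compounds[[cid]]$dfg0_prime, 0)
    if (any(is.na(en))) next
    er <- vapply(names(r$stoich), function(cid) {
      e <- db$compounds[[cid]]$dfg0_error
      if (is.na(e)) 0 else e
    }, 0)
    constrained[[nnid]] <- list(rxn = r, energies = en, errors = er)
  }
  constrained
}

#' Thermodynamic feasibility check of a feasible pathway
#'
#' Builds the directionality-constrained MILP for the model restricted to
#' the pathway's active non-native reactions: per thermo-constrained
#' reaction a binary direction indicator forces flux forward only when
#' DrG' <= 0 (relaxed by the propagated estimation error) and backward only
#' when DrG' >= 0, with log-concentration variables bounded by the context's
#' concentration ranges.  The pathway is TFA-feasible when an assignment
#' exists that still reaches `theta * vmax` production.  Transport, exchange
#' and demand reactions, and reactions with missing energies, carry no
#' thermodynamic constraint.
#'
#' @param model an `integrated_model`.
#' @param pathway a `feasible_pathway` (or character vector of active
#'   non-native reaction ids).
#' @param db the originating `reaction_db` (formation energies).
#' @param ctx a [thermo_context()].
#' @param theta,vmax production requirement (vmax computed when NULL).
#' @param uptake substrate uptake bound.
#' @param flag_threshold kJ/mol; steps with a standard reaction energy above
#'   this are flagged in the diagnostics as highly unfavourable.
#' @return list with `feasible` (logical), `v_product`, and `diagnostics`
#'   (data frame: reaction, drg0, error, constrained, flagged).
#' @export
tfa_check <- function(model, pathway, db, ctx = thermo_context(),
                      theta = 0.5, vmax = NULL, uptake = 10,
                      flag_threshold = 50) {
  active <- if (inherits(pathway, "feasible_pathway")) pathway$active_non_native
            else as.character(pathway)
  if (is.null(ctx)) ctx <- thermo_context()
  if (is.null(vmax)) vmax <- max_production(model, uptake)$vmax
  fp <- .flux_problem(model, uptake)
  closed <- setdiff(model$non_native, active)
  fp$lb[closed] <- 0; fp$ub[closed] <- 0

  td <- .thermo_data(model, db)
  td <- td[names(td) %in% active]
  rt <- ctx$R * ctx$T

  comp_ids <- sort(unique(unlist(lapply(td, function(x) names(x$rxn$stoich)))))
  lnb <- vapply(comp_ids, function(cid) {
    cls <- "intracellular"   # subnetwork reactions live in the cytosol
    log(ctx$conc_bounds[[cls]])
  }, numeric(2))
  nr <- length(fp$rids); nc <- length(comp_ids); nz <- length(td)
  # variables: v (nr), ln x (nc), z (nz binary direction indicators)
  ntot <- nr + nc + nz
  obj <- numeric(ntot); obj[match(model$demand_reaction, fp$rids)] <- 1
  Aeq <- cbind(fp$S, matrix(0, nrow(fp$S), nc + nz))
  beq <- rep(0, nrow(fp$S))
  G <- matrix(0, 0, ntot); h <- numeric(0)
  add <- function(row, rhs) { G <<- rbind(G, row); h <<- c(h, rhs) }

  diag_rows <- list()
  for (t in seq_along(td)) {
    nnid <- names(td)[t]
    info <- td[[t]]
    j <- match(nnid, fp$rids)
    zi <- nr + nc + t
    n <- info$rxn$stoich
    drg0 <- sum(unname(n) * info$energies[names(n)])
    err <- if (ctx$dfg_error_policy == "relax") sqrt(sum((unname(n) * info$errors[names(n)])^2)) else 0
    ci <- nr + match(names(n), comp_ids)
    span <- sum(abs(unname(n)) * apply(abs(lnb[, names(n), drop = FALSE]), 2, max)) * rt
    M <- abs(drg0) + err + span + 10
    # flux coupling: z = 1 -> 0 <= v <= UB ; z = 0 -> LB <= v <= 0
    row <- numeric(ntot); row[j] <- 1; row[zi] <- -fp$ub[j]; add(row, 0)
    row <- numeric(ntot); row[j] <- -1; row[zi] <- -fp$lb[j]; add(row, -fp$lb[j])
    # direction: z = 1 -> DrG' - err <= 0 ; z = 0 -> DrG' + err >= 0
    row <- numeric(ntot); row[ci] <- rt * unname(n); row[zi] <- M; add(row, M - drg0 + err)
    row <- numeric(ntot); row[ci] <- -rt * unname(n); row[zi] <- -M; add(row, drg0 + err)
    diag_rows[[nnid]] <- data.frame(reaction = nnid, drg0 = drg0, error = err,
                                    constrained = TRUE, flagged = drg0 > flag_threshold)
  }
  for (nnid in setdiff(active, names(td)))
    diag_rows[[nnid]] <- data.frame(reaction = nnid, drg0 = NA_real_, error = NA_real_,
                                    constrained = FALSE, flagged = FALSE)
  # production requirement
  row <- numeric(ntot); row[match(model$demand_reaction, fp$rids)] <- -1
  add(row, -(theta * vmax - 1e-6))

  lb <- c(fp$lb, if (nc) lnb[1, ] else numeric(0), rep(0, nz))
  ub <- c(fp$ub, if (nc) lnb[2, ] else numeric(0), rep(1, nz))
  res <- solve_milp(obj, A = Aeq, b = beq, G = G, h = h, lb = lb, ub = ub,
                    bin_idx = if (nz) nr + nc + seq_len(nz) else integer(0),
                    maximize = TRUE)
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(reaction = character(0), drg0 = numeric(0), error = numeric(0),
               constrained = logical(0), flagged = logical(0))
  rownames(diagnostics) <- NULL
  if (res$status != "optimal")
    return(list(feasible = FALSE, v_product = 0, diagnostics = diagnostics))
  list(feasible = res$objval >= theta * vmax - 1e-5,
       v_product = res$objval, diagnostics = diagnostics)
}
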