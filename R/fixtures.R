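# Deterministic synthetic fixtures: a toy host model and five reaction
# databases, each exercising one behaviour of the pipeline; plus a random
# balanced-network generator for property-based oracle tests.
#
# Shared chemistry: the toy host imports glucose G (C6H12O6), splits it into
# P1 (C4H8O4) and P2 (C2H4O2), can condense 2 P2 -> P1, and can secrete the
# byproduct W (C2H4O2) and excess P2.  All fixture compounds are built from
# CH2O units so that every generated reaction is elementally balanced by
# construction.

.fixture_base_compounds <- function() {
  list(
    G  = compound("G",  "C6H12O6", structure_key = "KEYGLC", smiles = "OCC1OC(O)C(O)C(O)C1O"),
    P1 = compound("P1", "C4H8O4",  structure_key = "KEYP1",  smiles = "OCC(O)C(O)C=O"),
    P2 = compound("P2", "C2H4O2",  structure_key = "KEYP2",  smiles = "OCC=O"),
    W  = compound("W",  "C2H4O2",  structure_key = "KEYW",   smiles = "CC(=O)O")
  )
}

#' Construct a named synthetic fixture
#'
#' Deterministic generators for the test systems used throughout the package:
#' \describe{
#'   \item{H1}{Toy host model: 6 metabolites, 7 reactions; glucose exchange
#'     (uptake bound 10 mmol/gDW/h), glucose split `G -> P1 + P2`,
#'     condensation `2 P2 -> P1`, secretion of W and P2.}
#'   \item{F1}{Diverging routes to a C4 target T1: a 2-step route
#'     `P1 -> A -> T1` and a 3-step route `P1 -> B -> C -> T1`; minimal
#'     enumeration support is `{R1, R2}`.}
#'   \item{F2}{Carbon loss vs conservation: a linear route `2 P1 -> T2 + W`
#'     that wastes 2 of 8 carbons against a branched route
#'     `P1 + P2 -> I2 -> T2` that conserves all carbon.}
#'   \item{F3}{Two-branch target: `A3 + B3 -> T3` condensation where A3 comes
#'     from P1 and B3 from P2 via a 2-step chain; no single-precursor linear
#'     pathway covers all of the target's atoms.}
#'   \item{F4}{Orphan cofactor: the route `P1 -> N4 -> T4` requires cofactor
#'     X4 with no production route, triggering a two-round convergence
#'     cascade; the alternative `P1 -> M4 -> T4` survives.  The Mg2+ and H2
#'     participants are excluded species and never become boundaries.}
#'   \item{F5}{Thermodynamic block: two single-reaction routes to T5; the
#'     direct one carries a step at +95.2 kJ/mol (the kcal-scale value 22.75
#'     converted), the coupled one `P1 + P2 -> T5 + W` is exergonic.}
#' }
#'
#' @param name one of `"H1"`, `"F1"`..`"F5"`.
#' @param seed integer; fixtures are fully deterministic, the seed is part of
#'   the interface for symmetry with [random_network()].
#' @return `H1`: a `host_model`; `F1`..`F5`: a `reaction_db`.
#' @export
make_fixture <- function(name = c("H1", "F1", "F2", "F3", "F4", "F5"), seed = 1L) {
  name <- match.arg(name)
  if (name == "H1") return(.fixture_h1())
  base <- .fixture_base_compounds()
  rp <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(source = m[, 1], target = m[, 2], car = as.numeric(m[, 3]),
               reactions = m[, 4], stringsAsFactors = FALSE)
  }
  db <- switch(name,
    F1 = {
      comps <- c(base, list(
        A  = compound("A",  "C4H8O4", structure_key = "KEYA"),
        B  = compound("B",  "C4H8O4", structure_key = "KEYB"),
        C  = compound("C",  "C4H8O4", structure_key = "KEYC"),
        T1 = compound("T1", "C4H8O4", structure_key = "KEYT1")))
      rxns <- list(
        reaction("R1", c(P1 = -1, A = 1),  provenance = "known",     bridgit_score = 0.9),
        reaction("R2", c(A = -1, T1 = 1),  provenance = "predicted", bridgit_score = 0.6),
        reaction("R3", c(P1 = -1, B = 1),  provenance = "known",     bridgit_score = 0.8),
        reaction("R4", c(B = -1, C = 1),   provenance = "known",     bridgit_score = 0.8),
        reaction("R5", c(C = -1, T1 = 1),  provenance = "predicted", bridgit_score = 0.5))
      reaction_database(comps, rxns, rp(
        "P1", "A",  0.6, "R1",
        "A",  "T1", 0.6, "R2",
        "P1", "B",  0.9, "R3",
        "B",  "C",  0.9, "R4",
        "C",  "T1", 0.9, "R5"))
    },
    F2 = {
      comps <- c(base, list(
        I2 = compound("I2", "C6H12O6", structure_key = "KEYI2"),
        T2 = compound("T2", "C6H12O6", structure_key = "KEYT2")))
      rxns <- list(
        reaction("F2L",  c(P1 = -2, T2 = 1, W = 1),  provenance = "known", bridgit_score = 0.9),
        reaction("F2B1", c(P1 = -1, P2 = -1, I2 = 1), provenance = "predicted", bridgit_score = 0.7),
        reaction("F2B2", c(I2 = -1, T2 = 1),          provenance = "predicted", bridgit_score = 0.8))
      reaction_database(comps, rxns, rp(
        "P1", "T2", 0.75, "F2L",
        "P1", "W",  0.25, "F2L",
        "P1", "I2", 0.67, "F2B1",
        "P2", "I2", 0.33, "F2B1",
        "I2", "T2", 1.0,  "F2B2"))
    },
    F3 = {
      comps <- c(base, list(
        A3 = compound("A3", "C4H8O4", structure_key = "KEYA3"),
        B0 = compound("B0", "C2H4O2", structure_key = "KEYB0"),
        B3 = compound("B3", "C2H4O2", structure_key = "KEYB3"),
        T3 = compound("T3", "C6H12O6", structure_key = "KEYT3")))
      rxns <- list(
        reaction("R31",  c(P1 = -1, A3 = 1), provenance = "known", bridgit_score = 0.9),
        reaction("R32a", c(P2 = -1, B0 = 1), provenance = "known", bridgit_score = 0.9),
        reaction("R32b", c(B0 = -1, B3 = 1), provenance = "predicted", bridgit_score = 0.7),
        reaction("R33",  c(A3 = -1, B3 = -1, T3 = 1), provenance = "predicted", bridgit_score = 0.6))
      reaction_database(comps, rxns, rp(
        "P1", "A3", 1.0,  "R31",
        "P2", "B0", 1.0,  "R32a",
        "B0", "B3", 1.0,  "R32b",
        "A3", "T3", 0.67, "R33",
        "B3", "T3", 0.33, "R33"))
    },
    F4 = {
      comps <- c(base, list(
        M4 = compound("M4", "C4H8O4",  structure_key = "KEYM4"),
        X4 = compound("X4", "CH4O",    structure_key = "KEYX4"),
        N4 = compound("N4", "C4H10O4", structure_key = "KEYN4"),
        Y4 = compound("Y4", "CH2O",    structure_key = "KEYY4"),
        MG = compound("MG", "Mg", charge = 2L, excluded = TRUE),
        H2 = compound("H2", "H2", excluded = TRUE),
        T4 = compound("T4", "C4H8O4Mg", charge = 2L, structure_key = "KEYT4")))
      rxns <- list(
        reaction("R41", c(P1 = -1, M4 = 1), provenance = "known", bridgit_score = 0.9),
        reaction("R42", c(P1 = -1, X4 = -1, N4 = 1, Y4 = 1), provenance = "predicted", bridgit_score = 0.5),
        reaction("R43", c(N4 = -1, MG = -1, T4 = 1, H2 = 1), provenance = "predicted", bridgit_score = 0.5),
        reaction("R44", c(M4 = -1, MG = -1, T4 = 1), provenance = "known", bridgit_score = 0.8))
      reaction_database(comps, rxns, rp(
        "P1", "M4", 1.0, "R41",
        "P1", "N4", 0.8, "R42",
        "N4", "T4", 0.9, "R43",
        "M4", "T4", 0.9, "R44"))
    },
    F5 = {
      comps <- base
      comps$P1$dfg0_prime <- 0;      comps$P1$dfg0_error <- 0.05
      comps$P2$dfg0_prime <- 0;      comps$P2$dfg0_error <- 0.05
      comps$W$dfg0_prime  <- -115.2; comps$W$dfg0_error  <- 0.05
      comps$T5 <- compound("T5", "C4H8O4", structure_key = "KEYT5",
                           dfg0_prime = 95.2, dfg0_error = 0.05)
      rxns <- list(
        reaction("R51", c(P1 = -1, T5 = 1), provenance = "predicted", bridgit_score = 0.9),
        reaction("R52", c(P1 = -1, P2 = -1, T5 = 1, W = 1), provenance = "known", bridgit_score = 0.7))
      reaction_database(comps, rxns, rp(
        "P1", "T5", 1.0,  "R51;R52",
        "P2", "W",  0.5,  "R52"))
    })
  db
}

.fixture_h1 <- function() {
  mets <- data.frame(
    id = c("glc_e", "glc_c", "p1_c", "p2_c", "w_c", "w_e"),
    compartment = c("e", "c", "c", "c", "c", "e"),
    structure_key = c("KEYGLC", "KEYGLC", "KEYP1", "KEYP2", "KEYW", "KEYW"),
    stringsAsFactors = FALSE)
  rxn <- function(id, stoich, lb = 0, ub = 1000)
    list(id = id, stoich = stoich, lb = lb, ub = ub)
  reactions <- list(
    EX_glc   = rxn("EX_glc",   c(glc_e = -1), lb = -10),
    GLCt     = rxn("GLCt",     c(glc_e = -1, glc_c = 1)),
    GLCSPLIT = rxn("GLCSPLIT", c(glc_c = -1, p1_c = 1, p2_c = 1)),
    P2COND   = rxn("P2COND",   c(p2_c = -2, p1_c = 1)),
    WT       = rxn("WT",       c(w_c = -1, w_e = 1)),
    EX_w     = rxn("EX_w",     c(w_e = -1)),
    SK_p2    = rxn("SK_p2",    c(p2_c = -1)))
  host_model(id = "H1", metabolites = mets, reactions = reactions,
             substrate_exchange = "EX_glc")
}

#' Generate a random balanced reaction database
#'
#' Compounds are chains of `CH2O` units (1-6 units), so any reaction that
#' conserves the total unit count is automatically element- and
#' charge-balanced.  The generator guarantees at least one route from the
#' host-mappable precursor `P1` to the designated target `TGT`, then adds
#' random unit-conserving reactions.  Deterministic for a given
#' `(parameters, seed)`.
#'
#' @param n_compounds number of random intermediate compounds (besides the
#'   host-mappable base set and the target).
#' @param n_reactions total number of reactions to aim for.
#' @param seed integer seed.
#' @param max_chain length of the guaranteed `P1 -> ... -> TGT` route.
#' @param plant_orphan add an orphan-cofactor reaction (a reaction on a side
#'   route requiring a compound with no production route), exercising the
#'   convergence cascade.
#' @return a `reaction_db`; the target compound id is `"TGT"`.
#' @export
random_network <- function(n_compounds = 10, n_reactions = 12, seed = 1L,
                           max_chain = 3L, plant_orphan = FALSE) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)

  comps <- .fixture_base_compounds()
  units <- c(G = 6L, P1 = 4L, P2 = 2L, W = 2L)
  for (i in seq_len(n_compounds)) {
    id <- sprintf("RC%02d", i)
    u <- sample(1:6, 1)
    comps[[id]] <- compound(id, sprintf("C%dH%dO%d", u, 2 * u, u),
                            structure_key = paste0("KEY", id))
    units[id] <- u
  }
  u_t <- sample(2:6, 1)
  comps$TGT <- compound("TGT", sprintf("C%dH%dO%d", u_t, 2 * u_t, u_t),
                        structure_key = "KEYTGT")
  units["TGT"] <- u_t

  rxns <- list(); rps <- NULL
  add_rxn <- function(subs, prods, id) {
    # subs/prods: named coefficient vectors (positive counts)
    stoich <- c(-subs, prods)
    r <- reaction(id, stoich, provenance = sample(c("known", "predicted"), 1),
                  bridgit_score = round(stats::runif(1, 0.3, 1), 2))
    rxns[[id]] <<- r
    for (s in names(subs)) for (p in names(prods)) {
      car <- round(min(units[s], units[p]) / max(units[s], units[p]), 3)
      key <- paste(s, p)
      if (is.null(rps[[key]])) rps[[key]] <<- list(source = s, target = p, car = car, rxns = id)
      else rps[[key]]$rxns <<- paste(rps[[key]]$rxns, id, sep = ";")
    }
  }
  balance_products <- function(u, pool) {
    # pick product multiset from pool summing to u units
    prods <- integer(0)
    while (u > 0) {
      cand <- names(pool)[pool <= u]
      if (!length(cand)) return(NULL)
      p <- sample(cand, 1)
      prods[p] <- (if (is.na(prods[p])) 0L else prods[p]) + 1L
      u <- u - pool[[p]]
    }
    prods
  }

  inter <- setdiff(names(comps), c("G", "W", "TGT"))
  # guaranteed chain P1 -> ... -> TGT
  chain <- c("P1", if (max_chain > 1) sample(setdiff(inter, "P1"), max_chain - 1L), "TGT")
  k <- 0L
  for (i in seq_len(length(chain) - 1L)) {
    s <- chain[i]; p <- chain[i + 1L]
    k <- k + 1L
    us <- units[[s]]; up <- units[[p]]
    l <- .lcm(us, up)
    subs <- stats::setNames(l / us, s)
    prods <- stats::setNames(l / up, p)
    if (s == p) next
    add_rxn(subs, prods, sprintf("RR%02d", k))
  }
  pool_all <- units[setdiff(names(units), "G")]
  while (length(rxns) < n_reactions && k < 5L * n_reactions) {
    k <- k + 1L
    ns <- sample(1:2, 1)
    subs_ids <- sample(setdiff(names(pool_all), "TGT"), ns)
    subs <- stats::setNames(rep(1L, ns), subs_ids)
    u <- sum(units[subs_ids])
    prods <- balance_products(u, pool_all[setdiff(names(pool_all), subs_ids)])
    if (is.null(prods)) next
    id <- sprintf("RR%02d", k)
    add_rxn(subs, prods, id)
  }
  if (plant_orphan) {
    # side route off the chain: consumes an orphan cofactor with no production
    # route; the matching byproduct keeps the reaction balanced by construction
    mid <- chain[length(chain) - 1L]
    comps$ORPH <- compound("ORPH", "CH2O", structure_key = "")
    units["ORPH"] <- 1L
    ob <- units[[mid]] + 1L
    comps$ORPHB <- compound("ORPHB", sprintf("C%dH%dO%d", ob, 2 * ob, ob),
                            structure_key = "KEYORPHB")
    units["ORPHB"] <- ob
    add_rxn(stats::setNames(c(1L, 1L), c(mid, "ORPH")),
            stats::setNames(1L, "ORPHB"), "RORPH")
  }
  rp <- do.call(rbind, lapply(rps, function(p)
    data.frame(source = p$source, target = p$target, car = max(p$car, 0.01),
               reactions = p$rxns, stringsAsFactors = FALSE)))
  rownames(rp) <- NULL
  reaction_database(comps, rxns, rp)
}

.lcm <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a * b / g(a, b)
}
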