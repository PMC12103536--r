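test_that("thermo context carries the standard constants and bounds", {
  ctx <- thermo_context()
  expect_equal(ctx$R, 8.31e-3)
  expect_equal(ctx$T, 298)
  expect_equal(ctx$conc_bounds$intracellular, c(0.011, 0.050))
  expect_equal(ctx$conc_bounds$extracellular, c(1e-8, 0.1))
  expect_error(thermo_context(conc_intracellular = c(0.05, 0.011)))
  expect_error(thermo_context(conc_intracellular = c(0, 0.05)))
})

test_that("formation-energy adjustment: identity when pre-transformed, pH term at I = 0", {
  cp <- compound("x", "C3H7O2", charge = -1L, dfg0_prime = -300)
  ctx <- thermo_context(pH = 7, ionic_strength = 0)
  expect_equal(adjust_formation_energy(cp, ctx, pre_transformed = TRUE), -300)
  # at zero ionic strength only the proton chemical-potential term remains
  rt <- 8.31e-3 * 298
  expect_equal(adjust_formation_energy(cp, ctx), -300 + 7 * rt * log(10) * 7)
  # the Debye-Hueckel term scales with z^2 - N_H
  ctx2 <- thermo_context(pH = 7, ionic_strength = 0.25)
  sq <- 0.5
  dh <- 2.91482 * ((-1)^2 - 7) * sq / (1 + 1.6 * sq)
  expect_equal(adjust_formation_energy(cp, ctx2),
               -300 + 7 * rt * log(10) * 7 - dh)
  expect_error(adjust_formation_energy(compound("y", dfg0_prime = 1), ctx), "formula")
  expect_error(adjust_formation_energy(compound("z", "CH2O"), ctx), "formation energy")
})

test_that("reaction Gibbs energy evaluates the closed form", {
  rxn <- reaction("r", c(A = -1, B = 1))
  en <- c(A = -10, B = -12)
  # equal concentrations cancel in the log term
  g <- reaction_gibbs(rxn, en, concentrations = c(A = 0.02, B = 0.02))
  expect_equal(g$drg_prime, -2.0, tolerance = 1e-12)
  expect_equal(g$drg0, -2.0)
  # a concentration ratio of e adds exactly RT
  g <- reaction_gibbs(rxn, en, concentrations = c(A = 0.01, B = 0.01 * exp(1)))
  expect_equal(g$drg_prime, -2.0 + 8.31e-3 * 298, tolerance = 1e-9)
  # stoichiometric exponents: 2A -> B at unit concentrations
  rxn2 <- reaction("r2", c(A = -2, B = 1))
  g <- reaction_gibbs(rxn2, c(A = -10, B = -12), concentrations = c(A = 1, B = 1))
  expect_equal(g$drg_prime, -12 - 2 * (-10))
  expect_equal(g$drg_prime, g$drg0)
  # errors propagate as root-sum-square weighted by stoichiometry
  g <- reaction_gibbs(rxn2, c(A = -10, B = -12), errors = c(A = 0.3, B = 0.4))
  expect_equal(g$error, sqrt((2 * 0.3)^2 + 0.4^2))
  expect_equal(g$range, c(g$drg0 - g$error, g$drg0 + g$error))
  expect_error(reaction_gibbs(rxn, c(A = -10)), "missing formation")
})

test_that("reaction Gibbs energy is linear in formation energies and additive", {
  set.seed(5)
  rxn <- reaction("r", c(A = -2, B = -1, C = 1, D = 2))
  e1 <- c(A = runif(1), B = runif(1), C = runif(1), D = runif(1))
  e2 <- c(A = runif(1), B = runif(1), C = runif(1), D = runif(1))
  a <- 2.5; b <- -1.5
  g <- reaction_gibbs(rxn, a * e1 + b * e2)
  expect_equal(g$drg0, a * reaction_gibbs(rxn, e1)$drg0 + b * reaction_gibbs(rxn, e2)$drg0,
               tolerance = 1e-12)
})

test_that("the +95.2 kJ/mol step is TFA-infeasible, the coupled route is feasible", {
  fm <- fixture_model("F5", "T5")
  vmax <- max_production(fm$model)$vmax
  pws <- enumerate_pathways(fm$model, theta = 0.5, db = fm$db, K = 10)
  sup <- vapply(pws, function(p) support_key(p$active_non_native), "")
  direct <- pws[[which(sup == "NN_R51")]]
  coupled <- pws[[which(sup == "NN_R52")]]
  ctx <- thermo_context()
  td <- tfa_check(fm$model, direct, db = fm$db, ctx = ctx, theta = 0.5, vmax = vmax)
  tc <- tfa_check(fm$model, coupled, db = fm$db, ctx = ctx, theta = 0.5, vmax = vmax)
  expect_false(td$feasible)
  expect_true(tc$feasible)
  # the diagnostic flags the highly unfavourable step with its energy
  expect_equal(td$diagnostics$drg0, 95.2)
  expect_true(td$diagnostics$flagged)
  expect_equal(tc$diagnostics$drg0, -20, tolerance = 1e-9)
  # the concentration bounds give at most ~3.75 kJ/mol of leeway per unit
  # stoichiometry, far below 95.2: widening them cannot rescue a step this bad,
  # but a wildly wide range can (monotonicity)
  wide <- thermo_context(conc_intracellular = c(1e-18, 1e18))
  tw <- tfa_check(fm$model, direct, db = fm$db, ctx = wide, theta = 0.5, vmax = vmax)
  expect_true(tw$feasible)
})

test_that("with all standard energies at zero TFA reduces to FBA", {
  fm <- fixture_model("F5", "T5")
  for (cid in names(fm$db$compounds)) {
    if (!is.na(fm$db$compounds[[cid]]$dfg0_prime)) fm$db$compounds[[cid]]$dfg0_prime <- 0
  }
  vmax <- max_production(fm$model)$vmax
  pws <- enumerate_pathways(fm$model, theta = 0.5, db = fm$db, K = 10)
  for (p in pws) {
    tf <- tfa_check(fm$model, p, db = fm$db, theta = 0.5, vmax = vmax)
    expect_true(tf$feasible)
    expect_equal(tf$v_product, p$v_product, tolerance = 1e-6)
  }
})

test_that("pathways with only unconstrained reactions are feasible iff FBA-feasible", {
  fm <- fixture_model("F1", "T1")     # no formation energies anywhere
  pws <- enumerate_pathways(fm$model, theta = 0.5, db = fm$db)
  for (p in pws) {
    tf <- tfa_check(fm$model, p, db = fm$db, theta = 0.5)
    expect_true(tf$feasible)
    expect_false(any(tf$diagnostics$constrained))
  }
})

test_that("TFA-feasible pathways are a subset of FBA-feasible pathways", {
  for (fx in c("F1", "F2", "F5")) {
    fm <- fixture_model(fx, fixture_targets[[fx]])
    vmax <- max_production(fm$model)$vmax
    pws <- enumerate_pathways(fm$model, theta = 0.5, db = fm$db, K = 10)
    n_tfa <- sum(vapply(pws, function(p)
      tfa_check(fm$model, p, db = fm$db, theta = 0.5, vmax = vmax)$feasible, TRUE))
    expect_lte(n_tfa, length(pws))
    expect_gte(n_tfa, 0L)
  }
})

test_that("thermo-constrained Pareto sweep drops the blocked high-yield step (F5)", {
  fm <- fixture_model("F5", "T5")
  plain <- pareto_sweep(fm$model, db = fm$db)
  constrained <- pareto_sweep(fm$model, with_thermo = TRUE, db = fm$db,
                              ctx = thermo_context())
  expect_equal(plain$min_size, rep(1L, 4))
  # at 25/50% the exergonic coupled route suffices; above that only the
  # +95.2 kJ/mol step reaches the required production and TFA rejects it
  expect_equal(constrained$min_size[constrained$theta <= 0.5], c(1L, 1L))
  expect_true(all(is.na(constrained$min_size[constrained$theta > 0.5])))
})
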