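test_that("toy host round-trips through COBRA-JSON and SBML identically", {
  h1 <- make_fixture("H1")
  jf <- withr::local_tempfile(fileext = ".json")
  sf <- withr::local_tempfile(fileext = ".xml")
  write_model_json(h1, jf)
  write_model_sbml(h1, sf)
  hj <- load_host(jf, "cobra-json", substrate_exchange = "EX_glc")
  hs <- load_host(sf, "sbml", substrate_exchange = "EX_glc")
  for (h2 in list(hj, hs)) {
    expect_equal(h2$metabolites, h1$metabolites)
    expect_setequal(names(h2$reactions), names(h1$reactions))
    for (rid in names(h1$reactions)) {
      expect_equal(sort(h2$reactions[[rid]]$stoich), sort(h1$reactions[[rid]]$stoich))
      expect_equal(h2$reactions[[rid]]$lb, h1$reactions[[rid]]$lb)
      expect_equal(h2$reactions[[rid]]$ub, h1$reactions[[rid]]$ub)
    }
    expect_setequal(h2$exchanges, h1$exchanges)
  }
  # the two encodings load identically
  expect_equal(hj$metabolites, hs$metabolites)
  expect_equal(hj$reactions[order(names(hj$reactions))],
               hs$reactions[order(names(hs$reactions))])
})

test_that("missing bounds default to +/-1000 with a warning", {
  doc <- jsonlite::read_json(local({
    f <- tempfile(fileext = ".json"); write_model_json(make_fixture("H1"), f); f
  }), simplifyVector = FALSE)
  doc$reactions[[1]]$lower_bound <- NULL
  doc$reactions[[1]]$upper_bound <- NULL
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_warning(h <- load_host(f, "cobra-json"), "1000")
  rid <- doc$reactions[[1]]$id
  expect_equal(h$reactions[[rid]]$lb, -1000)
  expect_equal(h$reactions[[rid]]$ub, 1000)
})

test_that("a model without exchanges warns and leaves substrate_exchange unset", {
  mets <- data.frame(id = c("a", "b"), compartment = "c", structure_key = c("KA", "KB"))
  rxns <- list(list(id = "r", stoich = c(a = -1, b = 1), lb = 0, ub = 10))
  expect_warning(h <- host_model("noex", mets, rxns), "no exchange")
  expect_true(is.na(h$substrate_exchange))
  expect_length(h$exchanges, 0)
})

test_that("metabolite mapping matches on structure keys, ignoring compartments", {
  h1 <- make_fixture("H1")
  db <- make_fixture("F1")
  m <- map_metabolites(h1, db)
  # glc_e and glc_c share a key and collapse onto one compound
  expect_equal(unname(m$mapping[c("glc_e", "glc_c")]), c("G", "G"))
  expect_equal(unname(m$met_for_compound["G"]), "glc_c")  # cytosolic copy preferred
  expect_equal(unname(m$coverage), c(6L, 6L))
  expect_setequal(m$host_set, c("G", "P1", "P2", "W"))
  # a metabolite without a structure key is excluded from the mapping
  h1$metabolites$structure_key[h1$metabolites$id == "w_e"] <- ""
  m2 <- map_metabolites(h1, db)
  expect_equal(unname(m2$coverage), c(5L, 6L))
  expect_true("w_e" %in% m2$unmapped)
})

test_that("mapping warns on structure-key collisions and stays a function", {
  h1 <- make_fixture("H1")
  db <- make_fixture("F1")
  db$compounds$Gdup <- compound("Gdup", "C6H12O6", structure_key = "KEYGLC")
  expect_warning(m <- map_metabolites(h1, db), "collision")
  expect_equal(unname(m$mapping[["glc_c"]]), "G")   # first id by sort order
  expect_lte(max(table(names(m$mapping))), 1L)       # each metabolite maps once
})

test_that("integration adds non-natives, demand, and never touches native content", {
  fm <- fixture_model("F1", "T1")
  h1 <- fm$host; model <- fm$model
  for (rid in names(h1$reactions)) {
    expect_equal(model$reactions[[rid]]$stoich, h1$reactions[[rid]]$stoich)
    expect_equal(model$reactions[[rid]]$lb, h1$reactions[[rid]]$lb)
    expect_equal(model$reactions[[rid]]$ub, h1$reactions[[rid]]$ub)
  }
  expect_length(intersect(model$non_native, names(h1$reactions)), 0)
  expect_equal(model$demand_reaction, "DM_T1")
  dem <- model$reactions$DM_T1
  expect_equal(names(dem$stoich), "T1_nn")
  expect_equal(unname(dem$stoich), -1)
  expect_equal(dem$lb, 0)
  # non-native copies live in the cytosol
  added <- setdiff(model$metabolites$id, h1$metabolites$id)
  expect_true(all(model$metabolites$compartment[model$metabolites$id %in% added] == "c"))
})

test_that("excluded species receive a free exchange on integration", {
  fm <- fixture_model("F4", "T4")
  model <- fm$model
  expect_true("EX_MG_nn" %in% names(model$reactions))
  expect_equal(model$reactions$EX_MG_nn$lb, -1000)
  # and production through the cofactor-requiring route is possible
  expect_gt(max_production(model)$vmax, 0)
})

test_that("a duplicate of a native reaction is still added as distinct non-native", {
  h1 <- make_fixture("H1")
  db <- make_fixture("F1")
  db$compounds$GLC2 <- compound("GLC2", "C6H12O6", structure_key = "KEYGLC")
  db$reactions$RDUP <- reaction("RDUP", c(GLC2 = -1, P1 = 1, P2 = 1))
  # the duplicate glucose key makes the mapping warn about the collision
  model <- suppressWarnings(integrate_subnetwork(h1, c("R1", "R2", "RDUP"), db, "T1"))
  expect_true("NN_RDUP" %in% model$non_native)
  expect_true("GLCSPLIT" %in% names(model$reactions))   # native copy untouched
})

test_that("integrating an empty subnetwork fails for an unmapped target", {
  h1 <- make_fixture("H1")
  db <- make_fixture("F1")
  expect_error(integrate_subnetwork(h1, character(0), db, "T1"), "empty")
  # mapped target works: host + demand only, no production route
  model <- integrate_subnetwork(h1, character(0), db, "P1")
  expect_length(model$non_native, 0)
  # P1 is natively producible: 10 glucose (60 C) -> 15 C4 units
  expect_equal(max_production(model)$vmax, 15)
})

test_that("integrated models round-trip through COBRA-JSON with annotations", {
  fm <- fixture_model("F1", "T1")
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(fm$model, f)
  doc <- jsonlite::read_json(f, simplifyVector = FALSE)
  ids <- vapply(doc$reactions, `[[`, "", "id")
  nn <- ids[vapply(doc$reactions, function(r) isTRUE(r$annotation$non_native), TRUE)]
  expect_setequal(nn, fm$model$non_native)
  h2 <- load_host(f, "cobra-json", substrate_exchange = "EX_glc")
  expect_equal(sort(h2$reactions$DM_T1$stoich), sort(fm$model$reactions$DM_T1$stoich))
  expect_equal(h2$reactions$DM_T1$lb, fm$model$reactions$DM_T1$lb)
  expect_equal(h2$reactions$DM_T1$ub, fm$model$reactions$DM_T1$ub)
})
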