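test_that("core extraction finds both F1 routes and fails gracefully", {
  db <- make_fixture("F1")
  g <- build_graph(db)
  sn <- extract_core(g, db, "T1", "P1")
  expect_length(sn$core_pathways, 2)
  expect_setequal(sn$reactions, c("R1", "R2", "R3", "R4", "R5"))
  expect_error(extract_core(g, db, "T1", "T1"), "degenerate")
  # unreachable target: empty core reported, not an error
  sn2 <- extract_core(g, db, "P1", "T1")
  expect_equal(sn2$status, "empty_core")
})

test_that("F3 core from one precursor leaves the condensation cosubstrate unconnected", {
  db <- make_fixture("F3")
  g <- build_graph(db)
  sn <- extract_core(g, db, "T3", "P1", host_set = c("G", "P1", "P2", "W"))
  expect_length(sn$core_pathways, 1)
  expect_true("R33" %in% sn$reactions)          # condensation edge reached
  needs <- pathweaver:::.boundary_needs(sn, db)
  expect_equal(needs$production, "B3")          # cosubstrate branch missing
  sn <- expand_subnetwork(sn, g, db)
  expect_setequal(sn$reactions, c("R31", "R32a", "R32b", "R33"))
  expect_equal(sn$rounds, c(1L, 0L))            # strictly reaches 0
})

test_that("excluded species never enter the boundary set", {
  db <- make_fixture("F4")
  g <- build_graph(db)
  sn <- extract_core(g, db, "T4", "P1", host_set = c("G", "P1", "P2", "W"))
  needs <- pathweaver:::.boundary_needs(sn, db)
  expect_false(any(c("MG", "H2") %in% unlist(needs)))
  sn <- expand_subnetwork(sn, g, db)
  expect_setequal(sn$omitted, c("X4", "Y4"))
  expect_false(any(c("MG", "H2") %in% sn$omitted))
  expect_equal(sn$rounds[length(sn$rounds)], 0L)
})

test_that("convergence removes exactly the F4 cascade and is idempotent", {
  db <- make_fixture("F4")
  g <- build_graph(db)
  sn <- expand_subnetwork(extract_core(g, db, "T4", "P1",
                                       host_set = c("G", "P1", "P2", "W")), g, db)
  expect_setequal(sn$reactions, c("R41", "R42", "R43", "R44"))
  cv <- converge_subnetwork(sn, db)
  # R42 uses the orphan cofactor X4; its removal orphans N4, which kills R43
  expect_setequal(cv$reactions, c("R41", "R44"))
  expect_equal(cv$status, "converged")
  cv2 <- converge_subnetwork(cv, db)
  expect_equal(cv2$reactions, cv$reactions)
  expect_equal(cv2$compounds, cv$compounds)
  # already-closed subnetwork passes through unchanged
  f1 <- fixture_model("F1", "T1")
  cc <- converge_subnetwork(f1$sn, f1$db)
  expect_equal(cc$reactions, f1$sn$reactions)
})

test_that("convergence reports failure when every route needs an omitted cofactor", {
  db <- make_fixture("F4")
  db$reactions$R44 <- NULL                     # drop the clean route
  db$rp_pairs <- db$rp_pairs[db$rp_pairs$reactions != "R44", ]
  g <- build_graph(db)
  sn <- expand_subnetwork(extract_core(g, db, "T4", "P1",
                                       host_set = c("G", "P1", "P2", "W")), g, db)
  cv <- converge_subnetwork(sn, db)
  expect_equal(cv$status, "failed")
  expect_length(cv$reactions, 0)
})

test_that("after convergence every inner compound has a producer and a consumer", {
  for (fx in c("F1", "F2", "F3", "F4", "F5")) {
    fm <- fixture_model(fx, fixture_targets[[fx]])
    db <- fm$db; sn <- fm$sn
    expect_equal(sn$status, "converged")
    for (cid in sn$compounds) {
      if (cid %in% sn$host_set || db$compounds[[cid]]$excluded) next
      prod <- any(vapply(db$reactions[sn$reactions], function(r)
        !is.na(r$stoich[cid]) && (r$stoich[cid] > 0 || r$reversible), TRUE))
      cons <- any(vapply(db$reactions[sn$reactions], function(r)
        !is.na(r$stoich[cid]) && (r$stoich[cid] < 0 || r$reversible), TRUE))
      expect_true(prod, label = paste(fx, cid, "produced"))
      expect_true(cons || identical(cid, sn$target),
                  label = paste(fx, cid, "consumed or target"))
    }
  }
})

test_that("expansion with extra steps X yields supersets (monotonicity in X)", {
  for (seed in 1:10) {
    db <- random_network(8, 10, seed = 300 + seed)
    g <- build_graph(db)
    sn0 <- extract_core(g, db, "TGT", "P1", host_set = c("G", "P1", "P2", "W"), k = 3)
    if (sn0$status != "core") next
    e0 <- expand_subnetwork(sn0, g, db, extra_steps = 0L)
    e2 <- expand_subnetwork(sn0, g, db, extra_steps = 2L)
    expect_true(all(e0$reactions %in% e2$reactions),
                label = paste("seed", seed, "X-monotone"))
    expect_equal(e0$rounds[length(e0$rounds)], 0L)
  }
})

test_that("topology report counts components and locates the target", {
  fm <- fixture_model("F1", "T1")
  topo <- subnetwork_topology(fm$sn, fm$db)
  expect_equal(topo$n_compounds, 5L)
  expect_equal(topo$n_reactions, 5L)
  expect_equal(topo$n_isolated_components, 1L)
  expect_equal(topo$pct_main_component, 100)
  expect_true(topo$target_in_main)
  # single reaction A -> B
  db <- reaction_database(list(a = compound("a", "CH2O"), b = compound("b", "CH2O")),
                          list(reaction("r", c(a = -1, b = 1))))
  sn <- subnetwork(reactions = "r", compounds = c("a", "b"), target = "b")
  topo <- subnetwork_topology(sn, db)
  expect_equal(topo$n_compounds, 2L)
  expect_equal(topo$n_reactions, 1L)
  expect_true(topo$target_in_main)
  # two disjoint planted nets
  db2 <- reaction_database(
    lapply(stats::setNames(nm = c("a", "b", "c", "d", "e")), compound, formula = "CH2O"),
    list(reaction("r1", c(a = -1, b = 1)), reaction("r2", c(c = -1, d = 1)),
         reaction("r3", c(d = -1, e = 1))))
  sn2 <- subnetwork(reactions = c("r1", "r2", "r3"), compounds = c("a", "b", "c", "d", "e"),
                    target = "b")
  topo2 <- subnetwork_topology(sn2, db2)
  expect_equal(topo2$n_isolated_components, 2L)
  expect_equal(topo2$pct_main_component, 60)    # the 3-compound chain
  expect_false(topo2$target_in_main)
  # empty subnetwork: all-zero report
  topo0 <- subnetwork_topology(subnetwork(target = "x"), db2)
  expect_equal(topo0$n_compounds, 0L)
  expect_false(topo0$target_in_main)
})

test_that("GDF export round-trips through the parser, quoting awkward ids", {
  g <- build_graph(make_fixture("F1"))
  f <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(g, f, host_set = c("G", "P1", "P2", "W"))
  gdf <- read_gdf(f)
  expect_equal(nrow(gdf$nodes), 8L)             # all F1 compounds
  expect_equal(nrow(gdf$edges), 5L)
  expect_setequal(gdf$nodes$name, g$nodes)
  expect_equal(gdf$nodes$host[gdf$nodes$name == "P1"], "true")
  # subnetwork flavour carries host/boundary flags
  fm <- fixture_model("F4", "T4")
  write_gdf(fm$sn, f)
  gdf <- read_gdf(f)
  expect_setequal(gdf$nodes$name, fm$sn$compounds)
  # ids containing commas are quoted and recovered
  dbq <- reaction_database(
    list(`a,1` = compound("a,1", "CH2O"), b = compound("b", "CH2O")),
    list(reaction("r", stats::setNames(c(-1, 1), c("a,1", "b")))),
    data.frame(source = "a,1", target = "b", car = 1, reactions = "r"))
  gq <- build_graph(dbq)
  write_gdf(gq, f)
  gdf <- read_gdf(f)
  expect_true("a,1" %in% gdf$nodes$name)
  expect_equal(gdf$edges$node1, "a,1")
  # empty network: header-only file
  write_gdf(subnetwork(target = "x"), f)
  expect_length(read_gdf(f)$nodes$name, 0)
})
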