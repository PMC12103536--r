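test_that("formula parsing handles counts, multi-letter elements and round trips", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_formula("C4H8O4Mg")[["Mg"]], 1L)
  expect_equal(parse_formula("H2"), c(H = 2L))
  expect_length(parse_formula(""), 0)
  expect_error(parse_formula("C6?"), "parse")
  f <- parse_formula("C7H6O2")
  expect_equal(parse_formula(format_formula(f)), f)
})

test_that("balance check: fermentation balances, oxygen-off-by-one does not", {
  comps <- list(
    glc = compound("glc", "C6H12O6"),
    eth = compound("eth", "C2H6O"),
    co2 = compound("co2", "CO2"),
    A = compound("A", "C2H4O"),
    B = compound("B", "C2H4O2"))
  ferm <- reaction("ferm", c(glc = -1, eth = 2, co2 = 2))
  bal <- check_balance(ferm, comps)
  expect_true(bal$balanced)
  expect_true(all(bal$element_residual == 0))
  ox <- reaction("ox", c(A = -1, B = 1))
  bal <- check_balance(ox, comps)
  expect_false(bal$balanced)
  expect_equal(unname(bal$element_residual["O"]), 1)  # product side has one O extra
})

test_that("balance residuals negate under reaction reversal, verdict unchanged", {
  comps <- list(a = compound("a", "C3H6O2", charge = -1L),
                b = compound("b", "C3H7O2", charge = 0L))
  fwd <- reaction("f", c(a = -1, b = 1))
  rev <- reaction("r", c(a = 1, b = -1))
  bf <- check_balance(fwd, comps, charge_strict = TRUE)
  br <- check_balance(rev, comps, charge_strict = TRUE)
  expect_equal(bf$element_residual, -br$element_residual)
  expect_equal(bf$charge_residual, -br$charge_residual)
  expect_equal(bf$balanced, br$balanced)
})

test_that("charge-only imbalance is rejected by default, warned when relaxed", {
  comps <- list(a = compound("a", "C2H4O2", charge = 0L),
                b = compound("b", "C2H4O2", charge = -1L))
  r <- reaction("r", c(a = -1, b = 1))
  expect_false(check_balance(r, comps)$balanced)
  expect_warning(bal <- check_balance(r, comps, charge_strict = FALSE), "charge")
  expect_true(bal$balanced)
})

test_that("equation parsing reads coefficients and reversibility", {
  pe <- parse_equation("2 A + B <=> C")
  expect_true(pe$reversible)
  expect_equal(pe$stoich[c("A", "B", "C")], c(A = -2, B = -1, C = 1))
  pe <- parse_equation("P1 => T1")
  expect_false(pe$reversible)
  eq <- format_equation(c(P1 = -2, T2 = 1, W = 1))
  expect_equal(parse_equation(eq)$stoich[c("P1", "T2", "W")], c(P1 = -2, T2 = 1, W = 1))
})

test_that("reaction constructor enforces signed, nonzero stoichiometry", {
  expect_error(reaction("r", c(A = -1)), "substrate and one product")
  expect_error(reaction("r", c(A = -1, B = 0, C = 1)), "zero")
})

test_that("database load rejects unbalanced rows and reports them", {
  db <- make_fixture("F1")
  dir <- withr::local_tempdir()
  save_database(db, dir, "tsv")
  # plant an unbalanced row: C4 compound turned into a C6 target
  rt <- read.delim(file.path(dir, "reactions.tsv"))
  rt <- rbind(rt, data.frame(reaction_id = "RBAD", equation = "A => G",
                             provenance = "predicted", bridgit_score = ""))
  write.table(rt, file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  db2 <- load_database(dir, "tsv")
  expect_equal(length(db2$reactions), 5L)
  rej <- attr(db2, "rejected")
  expect_equal(rej$id, "RBAD")
  expect_match(rej$reason, "C=")
})

test_that("database load fails with the offending ids on dangling references", {
  dir <- withr::local_tempdir()
  save_database(make_fixture("F1"), dir, "tsv")
  rt <- read.delim(file.path(dir, "reactions.tsv"))
  rt$equation[1] <- "P1 => GHOST"
  write.table(rt, file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_database(dir, "tsv"), "GHOST")
})

test_that("empty reaction table loads as an empty database", {
  dir <- withr::local_tempdir()
  db <- reaction_database(list(a = compound("a", "CH2O")), list())
  save_database(db, dir, "tsv")
  db2 <- load_database(dir, "tsv")
  expect_length(db2$reactions, 0)
  expect_equal(nrow(attr(db2, "rejected")), 0L)
})

test_that("load after save is the identity on the validated database (both formats)", {
  for (fx in c("F1", "F4", "F5")) {
    db <- make_fixture(fx)
    dir <- withr::local_tempdir()
    save_database(db, dir, "tsv")
    db2 <- load_database(dir, "tsv")
    jf <- file.path(dir, "db.json")
    save_database(db, jf, "json")
    db3 <- load_database(jf, "json")
    for (other in list(db2, db3)) {
      expect_setequal(names(other$reactions), names(db$reactions))
      expect_setequal(names(other$compounds), names(db$compounds))
      for (rid in names(db$reactions)) {
        expect_equal(sort(other$reactions[[rid]]$stoich), sort(db$reactions[[rid]]$stoich))
        expect_equal(other$reactions[[rid]]$provenance, db$reactions[[rid]]$provenance)
      }
      for (cid in names(db$compounds)) {
        expect_equal(other$compounds[[cid]]$formula, db$compounds[[cid]]$formula)
        expect_equal(other$compounds[[cid]]$charge, db$compounds[[cid]]$charge)
        expect_equal(other$compounds[[cid]]$dfg0_prime, db$compounds[[cid]]$dfg0_prime)
      }
      expect_equal(nrow(other$rp_pairs), nrow(db$rp_pairs))
    }
  }
})

test_that("excluded-species list flags compounds by id", {
  excl <- default_excluded_species()
  expect_true(all(c("MG", "H2", "N2") %in% excl))
  db <- make_fixture("F4")
  expect_true(db$compounds$MG$excluded)
  expect_true(db$compounds$H2$excluded)
  expect_false(db$compounds$P1$excluded)
})

test_that("validation catches rp-pairs inconsistent with their reactions", {
  comps <- list(a = compound("a", "CH2O"), b = compound("b", "CH2O"))
  rxns <- list(reaction("r1", c(a = -1, b = 1)))
  bad_rp <- data.frame(source = "b", target = "a", car = 1, reactions = "r1")
  expect_error(reaction_database(comps, rxns, bad_rp), "consume the source")
  # reversible reactions support the reverse pair
  rxns <- list(reaction("r1", c(a = -1, b = 1), reversible = TRUE))
  expect_s3_class(reaction_database(comps, rxns, bad_rp), "reaction_db")
})
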