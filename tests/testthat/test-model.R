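# Model construction, reaction classification, medium application, and the
# two reader dialects.

test_that("reaction classification follows the single-entry boundary rule", {
  t1 <- make_toy("chain")
  expect_identical(unname(t1$reaction_class),
                   c("exchange", "internal", "growth"))
  t2 <- make_toy("branched")
  expect_identical(sum(t2$reaction_class == "internal"), 4L)
  # classification is a partition of the reaction set
  for (m in list(t1, t2, make_toy("two_substrate"), random_network(3, 1))) {
    tab <- table(m$reaction_class)
    expect_identical(sum(tab), length(m$reaction_ids))
    expect_identical(sum(m$reaction_class == "growth"), 1L)
  }
  # a sink/demand (single metabolite, no biomass role) classes as exchange
  snk <- metabolic_model(c("A"), c("EX_A", "DM_A", "GRO"),
                         matrix(c(1, -1, -1), 1, 3),
                         c(0, 0, 0), c(10, 5, 10), "GRO")
  expect_identical(unname(snk$reaction_class["DM_A"]), "exchange")
  expect_error(classify_reactions(t1, "nope"), "not in the model")
})

test_that("invalid bounds and ambiguous objectives are rejected at read", {
  bad <- bigg_json_text(list(
    list(id = "EX_A", metabolites = list(A = -1),
         lower_bound = 5, upper_bound = -5, objective_coefficient = 1)),
    c("A"))
  expect_error(read_model(write_fixture_json(bad)), "lower bound exceeds")
  two_obj <- bigg_json_text(list(
    list(id = "EX_A", metabolites = list(A = -1),
         lower_bound = -10, upper_bound = 0, objective_coefficient = 1),
    list(id = "GRO", metabolites = list(A = 1),
         lower_bound = 0, upper_bound = 10, objective_coefficient = 1)),
    c("A"))
  expect_error(read_model(write_fixture_json(two_obj)),
               "ambiguous objective.*EX_A.*GRO")
  no_obj <- bigg_json_text(list(
    list(id = "EX_A", metabolites = list(A = -1),
         lower_bound = -10, upper_bound = 0, objective_coefficient = 0)),
    c("A"))
  expect_error(read_model(write_fixture_json(no_obj)), "no objective")
  expect_error(read_model("does_not_exist.json"), "not found")
})

test_that("BiGG-signed exchanges get uptake as a negative lower bound", {
  m <- read_model(bigg_chain_path())
  expect_identical(unname(m$reaction_class["EX_A"]), "exchange")
  med <- medium(c(EX_A = 10))
  cond <- apply_medium(m, med)
  expect_equal(cond$lower_bounds[["EX_A"]], -10)
  expect_equal(cond$upper_bounds[["EX_A"]], Inf)
  # anaerobic-style closure: limit 0 closes the uptake direction
  closed <- apply_medium(m, medium(c(EX_A = 0)))
  expect_equal(closed$lower_bounds[["EX_A"]], 0)
  # positive uptake magnitudes everywhere user-facing
  sol <- solve_fba(cond)
  expect_equal(unname(uptake_rates(cond, sol$flux, "EX_A")), 10)
  expect_equal(sol$value, 10)
})

test_that("apply_medium validates ids, is idempotent, closes unlisted exchanges", {
  t3 <- make_toy("two_substrate")
  expect_error(apply_medium(t3, medium(c(TC = 1))), "non-exchange")
  expect_error(medium(c(EX_C = -1)), "non-negative")
  med <- medium(c(EX_C = 4, EX_N = 6))
  a <- apply_medium(t3, med)
  b <- apply_medium(a, med)
  expect_identical(a$lower_bounds, b$lower_bounds)
  expect_identical(a$upper_bounds, b$upper_bounds)
  # EX_W unlisted: closed for uptake, free for secretion
  expect_equal(a$upper_bounds[["EX_W"]], Inf)   # secretion direction (W ->)
  expect_equal(a$lower_bounds[["EX_W"]], 0)     # no uptake of waste
  expect_equal(a$upper_bounds[["EX_C"]], 4)
})

test_that("JSON round trip preserves stoichiometry, bounds and classes", {
  for (preset in c("chain", "branched", "two_substrate")) {
    m <- make_toy(preset)
    path <- tempfile(fileext = ".json")
    write_model_json(m, path)
    m2 <- read_model(path)
    expect_equal(as.matrix(m$stoichiometry), as.matrix(m2$stoichiometry))
    expect_identical(m$reaction_class, m2$reaction_class)
    expect_equal(unname(pmax(pmin(m$upper_bounds, 1e6), -1e6)),
                 unname(m2$upper_bounds))
    expect_identical(m$biomass, m2$biomass)
  }
})

test_that("SBML L3+FBC models load with boundary species dropped", {
  m <- read_model(sbml_fixture_path(), "sbml-fbc")
  expect_identical(m$metabolite_ids, c("A", "B"))   # A_e (boundary) dropped
  expect_identical(unname(m$reaction_class),
                   c("exchange", "internal", "growth"))
  expect_equal(m$upper_bounds[["EX_A"]], 10)
  expect_equal(solve_fba(m)$value, 10)
})

test_that("medium YAML reader handles scalars, pairs and .inf", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("exchanges:",
               "  EX_C: 4",
               "  EX_N: {uptake: .inf, secretion: 2}"), p)
  med <- read_medium(p)
  expect_equal(med$uptake[["EX_C"]], 4)
  expect_equal(med$uptake[["EX_N"]], Inf)
  expect_equal(med$secretion[["EX_N"]], 2)
  cond <- apply_medium(make_toy("two_substrate"), med)
  expect_equal(cond$lower_bounds[["EX_N"]], -2)     # secretion cap
})
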