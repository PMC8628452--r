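test_that("uptake constraints set the exchange sign convention", {
  m <- generate_toy_model(seed = 1)
  m2 <- apply_uptake_constraints(m, c(EX_A = 7))
  i <- match("EX_A", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i], -7)
  expect_equal(m2$reactions$upper_bound[i], 1000)
  # zero uptake makes the nutrient unavailable
  m3 <- apply_uptake_constraints(m, c(EX_A = 0))
  expect_equal(m3$reactions$lower_bound[match("EX_A", m3$reactions$id)], 0)
  # internal reactions are rejected
  expect_error(apply_uptake_constraints(m, c(T_A = 5)), "exchange")
  expect_error(apply_uptake_constraints(m, c(EX_A = -2)), "non-negative")
  # measured secretion forbids uptake
  mb <- generate_toy_model(branches = list(c(1, 1)), seed = 1)
  mb$reactions$lower_bound[match("EX_P1", mb$reactions$id)] <- -5
  mb2 <- apply_uptake_constraints(mb, secretions = "EX_P1")
  expect_equal(mb2$reactions$lower_bound[match("EX_P1", mb2$reactions$id)], 0)
})

test_that("FBA on the toy chain reproduces the hand-computed optimum", {
  m <- generate_toy_model(seed = 1)  # uptake 10
  prof <- expression_profile(c(gT = 100, g1 = 50))
  # expression bounds T_A = 10, R1 = 5: growth limited by the weakest step
  cm <- apply_eflux_bounds(m, compute_reaction_scores(m, scale_expression(prof, 10)))
  fba <- solve_fba(cm)
  expect_equal(fba$status, "optimal")
  expect_equal(fba$objective_value, 5, tolerance = 1e-9)
  # with all expression bounds above the uptake, growth is uptake-limited
  cm2 <- apply_eflux_bounds(m, compute_reaction_scores(m, scale_expression(prof, 100)))
  expect_equal(solve_fba(cm2)$objective_value, 10, tolerance = 1e-9)
  # blocked chain with a positive maintenance demand is infeasible
  mm <- generate_toy_model(maintenance_flux = 0.5, seed = 1)
  cm3 <- apply_eflux_bounds(mm, compute_reaction_scores(mm, scale_expression(prof, 0)))
  r3 <- solve_fba(cm3)
  expect_equal(r3$status, "infeasible")
  expect_null(r3$fluxes)
})

test_that("FBA matches the brute-force vertex-enumeration oracle", {
  for (seed in 1:12) {
    m <- random_fixture_model(seed)
    prof <- generate_synthetic_expression(m, seed = seed)
    delta <- runif(1, 2, 80)
    cm <- apply_eflux_bounds(m, compute_reaction_scores(m, scale_expression(prof, delta)))
    fba <- solve_fba(cm)
    oracle <- vertex_fba_oracle(cm)
    if (fba$status == "optimal") {
      expect_equal(fba$objective_value, oracle, tolerance = 1e-9,
                   label = paste("seed", seed))
      # returned fluxes satisfy mass balance and bounds
      S <- stoichiometric_matrix(cm)
      expect_lt(max(abs(S %*% fba$fluxes)), 1e-6)
      expect_true(all(fba$fluxes >= cm$reactions$lower_bound - 1e-9))
      expect_true(all(fba$fluxes <= cm$reactions$upper_bound + 1e-9))
    } else {
      expect_false(is.finite(oracle))
    }
  }
})

test_that("the optimum responds monotonically to bound relaxation", {
  m <- generate_toy_model(seed = 1)
  prof <- expression_profile(c(gT = 100, g1 = 50))
  cm <- apply_eflux_bounds(m, compute_reaction_scores(m, scale_expression(prof, 10)))
  base <- solve_fba(cm)$objective_value
  relaxed <- set_bounds(cm, "R1", upper = 8)
  expect_gte(solve_fba(relaxed)$objective_value, base)
  tightened <- set_bounds(cm, "R1", upper = 2)
  expect_lte(solve_fba(tightened)$objective_value, base)
})

test_that("flux vectors export as TSV", {
  m <- generate_toy_model(seed = 1)
  fba <- solve_fba(m)
  p <- tempfile(fileext = ".tsv")
  write_flux_tsv(fba, p)
  tab <- read.delim(p)
  expect_equal(tab$reaction, m$reactions$id)
  expect_equal(tab$flux[tab$reaction == "BIOMASS"], 10)
})
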