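toy_profile <- function() {
  expression_profile(c(gT = 100, g1 = 50, g2 = 80), condition = "toy")
}

test_that("reaction scores follow the GPR semantics on scaled values", {
  m <- generate_toy_model(seed = 1)  # T_A: gT, R1: g1
  sc <- scale_expression(toy_profile(), 10)  # g_max = 100
  act <- compute_reaction_scores(m, sc)
  expect_equal(act$scores[["T_A"]], 10)   # 100/100 * 10
  expect_equal(act$scores[["R1"]], 5)     # 50/100 * 10
  expect_true(is.na(act$scores[["EX_A"]]))     # no GPR -> absent
  expect_true(is.na(act$scores[["BIOMASS"]]))
  expect_equal(act$delta, 10)

  # an AND pair takes the minimum of the scaled values
  m2 <- generate_toy_model(gpr_pattern = "and-pair", seed = 1)
  prof2 <- expression_profile(c(gT = 100, g1a = 50, g1b = 80))
  act2 <- compute_reaction_scores(m2, scale_expression(prof2, 100))
  expect_equal(act2$scores[["R1"]], 50)

  # GPR errors carry the reaction id
  m3 <- m
  m3$reactions$gpr[2] <- "gT and ("
  m3$genes <- "g1"  # keep validation out of the way
  expect_error(compute_reaction_scores(m3, sc), "T_A")
})

test_that("bound imposition follows the irreversible/reversible rule", {
  set.seed(5)
  for (trial in 1:10) {
    m <- random_fixture_model(trial + 100)
    prof <- generate_synthetic_expression(m, seed = trial)
    delta <- runif(1, 1, 50)
    act <- compute_reaction_scores(m, scale_expression(prof, delta))
    rev <- is_reversible_reaction(m)
    exch <- is_exchange_reaction(m)
    out <- apply_eflux_bounds(m, act)
    for (i in seq_along(act$scores)) {
      b <- act$scores[[i]]
      rid <- m$reactions$id[i]
      if (is.na(b) || exch[i] || rid == m$objective_reaction_id) {
        expect_equal(out$reactions$lower_bound[i],
                     m$reactions$lower_bound[i])
        expect_equal(out$reactions$upper_bound[i],
                     m$reactions$upper_bound[i])
      } else if (rev[i]) {
        expect_equal(out$reactions$lower_bound[i], -b)
        expect_equal(out$reactions$upper_bound[i], b)
      } else {
        expect_equal(out$reactions$lower_bound[i], 0)
        expect_equal(out$reactions$upper_bound[i], b)
      }
    }
    # idempotence for fixed activity
    expect_equal(apply_eflux_bounds(out, act)$reactions, out$reactions)
  }
})

test_that("a zero score blocks a reaction and exchanges stay exempt", {
  m <- generate_toy_model(seed = 1)
  prof <- expression_profile(c(gT = 100, g1 = 50))
  act <- compute_reaction_scores(m, scale_expression(prof, 0))
  out <- apply_eflux_bounds(m, act)
  expect_equal(out$reactions$upper_bound[out$reactions$id == "T_A"], 0)
  expect_equal(out$reactions$lower_bound[out$reactions$id == "EX_A"], -10)
})

test_that("scores below a positive maintenance bound tighten with warning", {
  m <- generate_toy_model(seed = 1)
  m <- set_bounds(m, "R1", lower = 2)  # forced minimum conversion flux
  prof <- expression_profile(c(gT = 100, g1 = 50))
  act <- compute_reaction_scores(m, scale_expression(prof, 1))  # R1 score 0.5
  expect_warning(out <- apply_eflux_bounds(m, act), "below positive lower")
  i <- match("R1", out$reactions$id)
  expect_equal(out$reactions$lower_bound[i], out$reactions$upper_bound[i])
  expect_lte(out$reactions$lower_bound[i], out$reactions$upper_bound[i])
})

test_that("bounds report tabulates old and new bounds with scores", {
  m <- generate_toy_model(seed = 1)
  act <- compute_reaction_scores(m, scale_expression(toy_profile(), 10))
  out <- apply_eflux_bounds(m, act)
  rep <- bounds_report(m, out, act)
  expect_equal(names(rep),
               c("reaction", "old_lb", "old_ub", "new_lb", "new_ub", "score"))
  expect_equal(rep$new_ub[rep$reaction == "R1"], 5)
  expect_equal(rep$old_ub[rep$reaction == "R1"], 1000)
})
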