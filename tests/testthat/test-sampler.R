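segment <- function() flux_polytope(matrix(c(1, 1), 1, 2), 5,
                                    c(0, 0), c(5, 5),
                                    reaction_ids = c("v1", "v2"))

test_that("fixing the objective pins biomass near its optimum", {
  m <- generate_toy_model(seed = 1)
  prof <- expression_profile(c(gT = 100, g1 = 50))
  cm <- apply_eflux_bounds(m, compute_reaction_scores(m, scale_expression(prof, 8)))
  fx <- fix_objective_at_optimum(cm, fraction = 1.0)
  i <- match("BIOMASS", fx$reactions$id)
  expect_equal(fx$reactions$lower_bound[i], 4, tolerance = 1e-6)
  fx9 <- fix_objective_at_optimum(cm, fraction = 0.9)
  expect_equal(fx9$reactions$lower_bound[match("BIOMASS", fx9$reactions$id)],
               3.6, tolerance = 1e-6)
  # infeasible input propagates
  mm <- generate_toy_model(maintenance_flux = 20, seed = 1)
  expect_error(fix_objective_at_optimum(mm), "infeasible")
  expect_error(fix_objective_at_optimum(cm, fraction = 0), "in \\(0, 1\\]")
})

test_that("warm-up points are feasible, spanning and deterministic", {
  st <- generate_warmup(segment(), n_warmup = 12, seed = 42)
  W <- st$warmup
  expect_equal(dim(W), c(2, 12))
  expect_lt(max(abs(colSums(W) - 5)), 1e-9)          # on the segment
  expect_true(all(W >= -1e-9 & W <= 5 + 1e-9))       # inside the bounds
  expect_gt(diff(range(W[1, ])), 4)                  # spans the segment
  expect_equal(st$center, rowMeans(W))
  st2 <- generate_warmup(segment(), n_warmup = 12, seed = 42)
  expect_identical(st$warmup, st2$warmup)
  expect_error(generate_warmup(segment(), n_warmup = 1), "at least 2")
})

test_that("ACHR samples stay feasible and centre on the segment midpoint", {
  st <- generate_warmup(segment(), n_warmup = 10, seed = 42)
  sam <- achr_sample(st, n_points = 3000, thinning = 5)
  pts <- sam$points
  expect_equal(dim(pts), c(3000, 2))
  expect_lt(max(abs(rowSums(pts) - 5)), 1e-6)
  expect_true(all(pts >= -1e-6 & pts <= 5 + 1e-6))
  se <- sd(pts[, 1]) / sqrt(nrow(pts))
  expect_lt(abs(mean(pts[, 1]) - 2.5), 3 * se + 0.15)
  # a single requested point is a single feasible point
  one <- achr_sample(generate_warmup(segment(), n_warmup = 10, seed = 1),
                     n_points = 1, thinning = 3)
  expect_equal(nrow(one$points), 1)
  expect_equal(sum(one$points), 5, tolerance = 1e-9)
})

test_that("a fully determined polytope warns and returns its single point", {
  point <- flux_polytope(matrix(c(1, 0, 0, 1), 2, 2), c(2, 3),
                         c(0, 0), c(5, 5))
  expect_warning(st <- generate_warmup(point, n_warmup = 4, seed = 1),
                 "degenerate")
  sam <- achr_sample(st, n_points = 10, thinning = 2)
  expect_true(all(abs(sam$points[, 1] - 2) < 1e-9))
  expect_true(all(abs(sam$points[, 2] - 3) < 1e-9))
})

test_that("summaries report mean and sd per reaction", {
  st <- generate_warmup(segment(), n_warmup = 10, seed = 42)
  sam <- achr_sample(st, n_points = 2000, thinning = 5)
  summ <- summarize_samples(sam)
  expect_equal(summ$reaction, c("v1", "v2"))
  expect_equal(summ$mean[1], mean(sam$points[, "v1"]))
  expect_equal(summ$sd[1], sd(sam$points[, "v1"]))
  expect_error(summarize_samples(sam, "nope"), "unknown reaction")
  # constant column has sd zero
  csam <- structure(list(points = matrix(4, 5, 1, dimnames = list(NULL, "c")),
                         settings = list()), class = "flux_sample_set")
  s2 <- summarize_samples(csam)
  expect_equal(s2$mean, 4)
  expect_equal(s2$sd, 0)
})

test_that("head-to-head comparison counts wins and ties by hand", {
  pa <- data.frame(reaction = c("r1", "r2", "r3"), mean = c(1.0, 2.0, 6.0))
  pb <- data.frame(reaction = c("r1", "r2", "r3"), mean = c(3.0, 2.0, 5.0))
  measured <- c(r1 = 1.5, r2 = 7, r3 = 4.5)
  res <- compare_to_measured(pa, pb, measured)
  expect_equal(res$count_a_closer, 1)  # r1: |1-1.5| < |3-1.5|
  expect_equal(res$count_b_closer, 1)  # r3: |5-4.5| < |6-4.5|
  expect_equal(res$ties, 1)            # r2 equal means
  expect_equal(nrow(res$detail), 3)
  expect_error(compare_to_measured(pa, pb, numeric(0)), "non-empty")
  expect_error(compare_to_measured(pa, pb, c(zz = 1)), "missing")
})

test_that("sampling a constrained toy model keeps mass balance", {
  m <- generate_toy_model(n_chain = 3, branches = list(c(1, 1)), seed = 5)
  prof <- generate_synthetic_expression(m, seed = 5)
  cm <- apply_eflux_bounds(m, compute_reaction_scores(m, scale_expression(prof, 40)))
  fx <- fix_objective_at_optimum(cm, fraction = 0.99)
  st <- generate_warmup(fx, seed = 9)
  sam <- achr_sample(st, n_points = 500, thinning = 10)
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% t(sam$points))), 1e-6)
  lb <- fx$reactions$lower_bound; ub <- fx$reactions$upper_bound
  expect_true(all(t(sam$points) >= lb - 1e-6 & t(sam$points) <= ub + 1e-6))
})
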