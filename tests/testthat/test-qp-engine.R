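test_that("objective is zero at baseline and counts standardized deviations", {
  # one category alone in its group, sd 10 at both levels
  s <- tiny_survey(100, sds = 10, group_sd = 10)
  w <- category_weights(s)  # degenerate single-member group: w = (1.5, 1.5)
  base <- stats::setNames(100, "c1")
  expect_equal(objective_value(base, s, w), 0)
  # +1 SD at both category and group level: w_plus * 1 + z * 1
  up <- stats::setNames(110, "c1")
  expect_equal(objective_value(up, s, w), 1.5 + 2)
  down <- stats::setNames(90, "c1")
  expect_equal(objective_value(down, s, w), 1.5 + 2)
  # directional pick of the weights
  w$category$w_plus <- 1.2
  w$category$w_minus <- 1.8
  expect_equal(objective_value(up, s, w), 1.2 + 2)
  expect_equal(objective_value(down, s, w), 1.8 + 2)
  expect_true(objective_value(up, s, w) > 0)
})

test_that("a feasible baseline is the unconstrained minimizer", {
  s <- fixture_survey()
  w <- category_weights(s)
  cs <- build_constraints(s, make_feasible_spec(s))
  res <- solve_qp(s, w, cs)
  expect_identical(res$status, "optimal")
  expect_equal(unname(res$quantities),
               s$categories$baseline_intake, tolerance = 1e-6)
  expect_lt(res$objective, 1e-10)
})

test_that("two equally weighted categories share a forced group shift", {
  # single equality q1 + q2 = Q0 + delta with equal weights and SDs:
  # the Lagrange conditions give dq1 = dq2 = delta / 2
  delta <- 30
  s <- tiny_survey(c(100, 100), sds = c(10, 10), group_sd = 20,
                   p95 = c(400, 400),
                   energy_target = 0.01 * 500 * (200 + delta))
  w <- unit_weights(s)
  cs <- build_constraints(s, NULL, fix_group_totals = c(g1 = 200 + delta),
                          mass_band = 0.5)
  res <- solve_qp(s, w, cs)
  expect_identical(res$status, "optimal")
  expect_equal(unname(res$quantities), c(115, 115), tolerance = 1e-6)
  # closed form: 2 * w * (15/10)^2 + z * (30/20)^2
  expect_equal(res$objective, 2 * 1 * 1.5^2 + 2 * 1.5^2, tolerance = 1e-6)
})

test_that("inconsistent boxes are reported infeasible", {
  s <- tiny_survey(c(100, 100), p5 = c(150, 20), p95 = c(120, 200))
  s$categories$p5[1] <- 150  # p5 > p95 for c1
  w <- unit_weights(s)
  cs <- build_constraints(s, NULL)
  res <- solve_qp(s, w, cs)
  expect_identical(res$status, "infeasible")
  expect_null(res$quantities)
})

test_that("solver agrees with a generic-minimizer oracle on small instances", {
  skip_if_not_installed("nloptr")
  n_agree <- 0
  for (seed in 1:40) {
    s <- generate_survey(n_categories = sample(4:6, 1), m_groups = 2,
                         seed = seed, zero_p95_frac = 0)
    w <- category_weights(s)
    nut <- sample(c("protein", "iron", "fiber"), 1)
    spec <- make_binding_spec(s, nut, push = runif(1, 0.02, 0.15))
    cs <- build_constraints(s, spec)
    res <- solve_qp(s, w, cs)
    if (res$status != "optimal") next
    orc <- qp_oracle(s, w, cs, start = res$quantities +
                       runif(length(res$quantities), -1, 1))
    expect_equal(res$objective, orc$value,
                 tolerance = 1e-4, label = paste("seed", seed))
    n_agree <- n_agree + 1
  }
  expect_gte(n_agree, 30)
})

test_that("tightening a constraint never decreases the optimum", {
  s <- fixture_survey(seed = 11)
  w <- category_weights(s)
  objs <- vapply(c(0.05, 0.10, 0.15, 0.20), function(push) {
    spec <- make_binding_spec(s, "protein", push = push)
    res <- solve_qp(s, w, build_constraints(s, spec))
    expect_identical(res$status, "optimal")
    res$objective
  }, numeric(1))
  expect_true(all(diff(objs) >= -1e-8))
})

test_that("the audit passes optima and flags corrupted solutions", {
  s <- fixture_survey()
  w <- category_weights(s)
  spec <- make_binding_spec(s, "protein", push = 0.1)
  cs <- build_constraints(s, spec)
  res <- solve_qp(s, w, cs)
  expect_identical(res$status, "optimal")
  expect_identical(nrow(audit_solution(res, s, w, cs)), 0L)

  # push one category outside its box
  bad <- res
  i <- which(!s$categories$is_fixed & !s$categories$is_new_food)[1]
  bad$quantities[i] <- s$categories$p95[i] + 5
  rep <- audit_solution(bad, s, w, cs)
  expect_true(any(rep$check == "feasibility"))
  expect_true(any(grepl(s$categories$id[i], rep$problem)))

  # objective mismatch is flagged
  bad2 <- res
  bad2$solver_objective <- res$solver_objective * 1.5 + 1
  expect_true(any(audit_solution(bad2, s, w, cs)$check == "objective"))

  expect_error(audit_solution(list(status = "infeasible"), s, w, cs),
               "optimal")
})

test_that("split variables are complementary at the optimum", {
  for (seed in c(7, 8)) {
    s <- fixture_survey(seed = seed)
    w <- category_weights(s)
    spec <- make_binding_spec(s, "iron", push = 0.2)
    cs <- build_constraints(s, spec)
    res <- solve_qp(s, w, cs)
    expect_identical(res$status, "optimal")
    up <- res$split$q_plus - s$categories$baseline_intake
    down <- s$categories$baseline_intake - res$split$q_minus
    expect_true(all(pmin(up, down) <= 1e-6 * pmax(1, s$categories$intake_sd)))
  }
})
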