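test_that("the simplex core solves, detects infeasibility and unboundedness", {
  # min -x1 - 2 x2 s.t. x1 + x2 <= 4, x1 <= 3 -> (3, 1), value -5
  r <- dietshift:::simplex_solve(c(-1, -2), rbind(c(1, 1), c(1, 0)),
                                 c("<=", "<="), c(4, 3))
  expect_identical(r$status, "optimal")
  expect_equal(r$value, -8)  # vertex (0, 4)
  expect_equal(r$x, c(0, 4))

  # equality + lower bound: min x1 + 2 x2, x1 + x2 = 1, x1 <= 0.4
  r2 <- dietshift:::simplex_solve(c(1, 2), rbind(c(1, 1), c(1, 0)),
                                  c("=", "<="), c(1, 0.4))
  expect_identical(r2$status, "optimal")
  expect_equal(r2$x, c(0.4, 0.6))

  r3 <- dietshift:::simplex_solve(c(1, 1), rbind(c(1, 1), c(1, 1)),
                                  c("=", "="), c(1, 2))
  expect_identical(r3$status, "infeasible")

  r4 <- dietshift:::simplex_solve(c(-1, 0), rbind(c(0, 1)), "<=", 1)
  expect_identical(r4$status, "unbounded")
})

test_that("simplex matches brute-force vertex enumeration on random LPs", {
  set.seed(99)
  for (rep in 1:60) {
    nv <- sample(2:3, 1)
    nr <- sample(2:4, 1)
    A <- matrix(round(runif(nr * nv, -2, 3), 2), nr)
    b <- round(runif(nr, 1, 6), 2)
    dir <- sample(c("<=", ">="), nr, replace = TRUE, prob = c(0.8, 0.2))
    cc <- round(runif(nv, 0.1, 2), 2)  # positive cost keeps the LP bounded
    r <- dietshift:::simplex_solve(cc, A, dir, b)
    # oracle: enumerate all basic points from rows + axes
    planes_A <- rbind(A, diag(nv))
    planes_b <- c(b, numeric(nv))
    best <- Inf
    feas <- function(x) {
      all(x >= -1e-9) &&
        all((A %*% x <= b + 1e-9)[dir == "<="]) &&
        all((A %*% x >= b - 1e-9)[dir == ">="])
    }
    if (feas(numeric(nv))) best <- 0
    for (combo in utils::combn(nrow(planes_A), nv, simplify = FALSE)) {
      M <- planes_A[combo, , drop = FALSE]
      if (abs(det(M)) < 1e-9) next
      x <- solve(M, planes_b[combo])
      if (feas(x)) best <- min(best, sum(cc * x))
    }
    if (is.infinite(best)) {
      expect_identical(r$status, "infeasible")
    } else {
      expect_identical(r$status, "optimal")
      expect_equal(r$value, best, tolerance = 1e-7,
                   label = paste("rep", rep))
    }
  }
})

test_that("the linear objective measures relative deviations", {
  s <- tiny_survey(c(100, 50), sds = c(10, 5))
  w <- unit_weights(s)
  cs <- build_constraints(s, NULL)
  model <- build_lp(s, w, cs, group_terms = FALSE)
  base <- stats::setNames(c(100, 50), c("c1", "c2"))
  expect_equal(lp_objective_value(base, model), 0)
  # one category up by 10% of baseline contributes 0.1
  up <- stats::setNames(c(110, 50), c("c1", "c2"))
  expect_equal(lp_objective_value(up, model), 0.1)
})

test_that("zero-baseline categories fall back to the SD denominator", {
  s <- tiny_survey(c(0, 100), sds = c(25, 10),
                   is_new_food = c(TRUE, FALSE))
  w <- unit_weights(s)
  cs <- build_constraints(s, NULL)
  model <- build_lp(s, w, cs, group_terms = FALSE)
  # new food at q = sd contributes exactly 1
  q <- stats::setNames(c(25, 100), c("c1", "c2"))
  expect_equal(lp_objective_value(q, model), 1)
  model2 <- build_lp(s, w, cs, group_terms = FALSE, zero_denominator = 50)
  expect_equal(lp_objective_value(q, model2), 0.5)
  expect_error(build_lp(s, w, cs, zero_denominator = -3), "positive")
})

test_that("a feasible baseline solves to zero objective", {
  s <- fixture_survey()
  w <- category_weights(s)
  cs <- build_constraints(s, make_feasible_spec(s))
  res <- solve_lp(build_lp(s, w, cs))
  expect_identical(res$status, "optimal")
  expect_equal(unname(res$quantities), s$categories$baseline_intake,
               tolerance = 1e-7)
  expect_lt(res$objective, 1e-9)
})

test_that("infeasible boxes are reported infeasible by the LP", {
  s <- tiny_survey(c(100, 100))
  s$categories$p5[1] <- 150
  s$categories$p95[1] <- 120
  w <- unit_weights(s)
  res <- solve_lp(build_lp(s, w, build_constraints(s, NULL)))
  expect_identical(res$status, "infeasible")
})

test_that("LP optima match exhaustive arrangement-vertex enumeration", {
  for (seed in 1:25) {
    s <- generate_survey(n_categories = 3, m_groups = 1, seed = seed,
                         zero_p95_frac = 0, host_group = 1)
    w <- category_weights(s)
    nut <- sample(c("protein", "iron"), 1)
    spec <- make_binding_spec(s, nut, push = runif(1, 0.02, 0.1))
    cs <- build_constraints(s, spec)
    res <- solve_lp(build_lp(s, w, cs))
    orc <- lp_oracle(s, w, cs)
    if (res$status != "optimal") {
      expect_true(is.infinite(orc$value), label = paste("seed", seed))
    } else {
      expect_equal(res$objective, orc$value, tolerance = 1e-6,
                   label = paste("seed", seed))
    }
  }
})

test_that("up and down deviations are never simultaneously positive", {
  s <- fixture_survey(seed = 5)
  w <- category_weights(s)
  spec <- make_binding_spec(s, "protein", push = 0.12)
  cs <- build_constraints(s, spec)
  res <- solve_lp(build_lp(s, w, cs))
  expect_identical(res$status, "optimal")
  expect_true(all(res$deviations$up * res$deviations$down <= 1e-8))
  expect_identical(nrow(audit_solution(res, s, w, cs)), 0L)
})

test_that("LP and QP agree when constraints force a unique point", {
  s <- tiny_survey(c(50, 80), p5 = c(60, 90), p95 = c(60, 90),
                   energy_target = 0.01 * 500 * 150)
  w <- category_weights(s)
  cs <- build_constraints(s, NULL, mass_band = 0.5)
  lp <- solve_lp(build_lp(s, w, cs))
  qp <- solve_qp(s, w, cs)
  expect_identical(lp$status, "optimal")
  expect_identical(qp$status, "optimal")
  expect_equal(lp$quantities, qp$quantities, tolerance = 1e-7)
  expect_equal(unname(lp$quantities), c(60, 90), tolerance = 1e-7)
})
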