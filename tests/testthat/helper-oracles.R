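# Independent oracles the solver tests compare against. These never call the
# package's own solve paths.

# Generic-minimizer oracle for the quadratic model: minimizes the piecewise
# quadratic acceptability objective directly in q-space with nloptr::slsqp.
qp_oracle <- function(survey, weights, constraints, start = NULL) {
  cats <- survey$categories
  grps <- survey$groups
  n <- nrow(cats)
  w <- weights$category[match(cats$id, weights$category$id), ]
  z <- weights$group$z[match(grps$id, weights$group$id)]
  gmat <- outer(grps$id, cats$group_id, "==") * 1  # m x n membership

  fn <- function(q) {
    delta <- q - cats$baseline_intake
    wdir <- ifelse(delta >= 0, w$w_plus, w$w_minus)
    dQ <- as.numeric(gmat %*% q) - grps$baseline_total
    sum(wdir * (delta / cats$intake_sd)^2) + sum(z * (dQ / grps$group_sd)^2)
  }
  gr <- function(q) {
    delta <- q - cats$baseline_intake
    wdir <- ifelse(delta >= 0, w$w_plus, w$w_minus)
    dQ <- as.numeric(gmat %*% q) - grps$baseline_total
    2 * wdir * delta / cats$intake_sd^2 +
      as.numeric(crossprod(gmat, 2 * z * dQ / grps$group_sd^2))
  }
  eq <- constraints$dir == "="
  le <- constraints$dir == "<="
  ge <- constraints$dir == ">="
  heq <- function(q) as.numeric(constraints$A[eq, , drop = FALSE] %*% q) -
    constraints$rhs[eq]
  hin <- function(q) {  # <= 0 when feasible
    c(as.numeric(constraints$A[le, , drop = FALSE] %*% q) -
        constraints$rhs[le],
      constraints$rhs[ge] -
        as.numeric(constraints$A[ge, , drop = FALSE] %*% q))
  }
  if (is.null(start)) start <- cats$baseline_intake
  sol <- nloptr::slsqp(start, fn = fn, gr = gr, hin = hin, heq = heq,
                       control = list(xtol_rel = 1e-12, maxeval = 5000),
                       deprecatedBehavior = FALSE)
  list(par = sol$par, value = fn(sol$par), convergence = sol$convergence)
}

# Exhaustive arrangement-vertex oracle for the piecewise-linear model: the
# optimum lies at an intersection of n active hyperplanes drawn from the
# constraint rows and the kink planes q_i = q_i^0. Enumerates them all.
lp_oracle <- function(survey, weights, constraints, lp_options = list()) {
  model <- do.call(build_lp, c(list(survey = survey, weights = weights,
                                    constraints = constraints), lp_options))
  n <- ncol(constraints$A)
  planes_A <- rbind(constraints$A, diag(n))
  planes_b <- c(constraints$rhs, survey$categories$baseline_intake)
  np <- nrow(planes_A)
  best <- Inf
  best_q <- NULL
  scale <- pmax(1, sqrt(rowSums(constraints$A^2)))
  feasible <- function(q) all(constraint_violations(constraints, q) <=
                                1e-7 * scale)
  for (combo in utils::combn(np, n, simplify = FALSE)) {
    A <- planes_A[combo, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    q <- tryCatch(solve(A, planes_b[combo]), error = function(e) NULL)
    if (is.null(q) || !feasible(q)) next
    val <- lp_objective_value(stats::setNames(q, survey$categories$id), model)
    if (val < best - 1e-12) {
      best <- val
      best_q <- q
    }
  }
  list(value = best, par = best_q)
}

# Dense grid search for the maximal feasible GHGE reduction.
max_reduction_grid_oracle <- function(survey, nutrients, nutr_result,
                                      resolution = 0.01, engine = "qp") {
  grid <- seq(0, 1 - resolution, by = resolution)
  feasible <- vapply(grid, function(x) {
    if (x == 0) return(TRUE)
    res <- run_ghge_ladder(survey, nutrients, nutr_result, reductions = x,
                           engine = engine)
    res[[1]]$status == "optimal"
  }, logical(1))
  max(grid[feasible])
}
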