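# Quadratic goal-programming engine.
#
# Decision variables follow the split formulation: for each category i an
# above-baseline level q_i^+ >= q_i^0 and a below-baseline level q_i^- with
# 0 <= q_i^- <= q_i^0, linked by q_i = q_i^+ + q_i^- - q_i^0, and likewise
# Q_j^+ / Q_j^- per group. The objective
#   sum_i w_i^+ ((q_i^+ - q_i^0)/sigma_i)^2 + w_i^- ((q_i^- - q_i^0)/sigma_i)^2
#   + sum_j z_j ((Q_j^+ - Q_j^0)/sigma_j)^2 + z_j ((Q_j^- - Q_j^0)/sigma_j)^2
# is strictly convex, so at the optimum deviations are one-sided (a property
# the audit asserts rather than assumes). The QP is handed to
# quadprog::solve.QP in this split-variable space.

#' Acceptability objective of a diet vector
#'
#' Popularity-weighted, SD-standardized squared deviation of a diet from the
#' baseline, summed over categories and groups. Increases are weighted by
#' `w_plus`, decreases by `w_minus`, group deviations by `z`.
#'
#' @param quantities named numeric vector of g/day intakes per category.
#' @param survey a `diet_survey`.
#' @param weights a `penalty_weights` object (see [category_weights()]).
#' @return Non-negative scalar; 0 iff the diet equals the baseline.
#' @export
objective_value <- function(quantities, survey, weights) {
  cats <- survey$categories
  q <- quantities[cats$id]
  if (any(is.na(q))) stop("quantities must cover every survey category")
  if (any(cats$intake_sd <= 0)) stop("all category SDs must be positive")
  if (any(survey$groups$group_sd <= 0)) stop("all group SDs must be positive")
  w <- weights$category[match(cats$id, weights$category$id), ]
  delta <- q - cats$baseline_intake
  wdir <- ifelse(delta >= 0, w$w_plus, w$w_minus)
  cat_term <- sum(wdir * (delta / cats$intake_sd)^2)
  Q <- group_totals(survey, q)
  g <- survey$groups
  z <- weights$group$z[match(g$id, weights$group$id)]
  grp_term <- sum(z * ((Q[g$id] - g$baseline_total) / g$group_sd)^2)
  cat_term + grp_term
}

# Index layout of the split-variable space.
split_layout <- function(n, m) {
  list(qp = seq_len(n), qm = n + seq_len(n),
       Qp = 2 * n + seq_len(m), Qm = 2 * n + m + seq_len(m),
       N = 2 * n + 2 * m)
}

# Map a q-space constraint row to split-variable space:
# a'q = a'(qp + qm) - a'q0.
lift_row <- function(a, layout) {
  row <- numeric(layout$N)
  row[layout$qp] <- a
  row[layout$qm] <- a
  row
}

#' Solve the acceptability-weighted quadratic program
#'
#' @param survey a `diet_survey`.
#' @param weights a `penalty_weights` object.
#' @param constraints a `constraint_system` from [build_constraints()].
#' @param label scenario label attached to the result.
#' @return A `scenario_result`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"error"`), `quantities` (named g/day vector),
#'   `objective` (recomputed from the diet), `solver_objective`, `totals`
#'   (energy/mass/ghge/cost), `split` (the optimal split variables), `binding`
#'   (data.frame of near-active constraints) and `engine = "qp"`.
#' @export
solve_qp <- function(survey, weights, constraints, label = "scenario") {
  cats <- survey$categories
  grps <- survey$groups
  n <- nrow(cats)
  m <- nrow(grps)
  lay <- split_layout(n, m)
  q0 <- cats$baseline_intake
  Q0 <- grps$baseline_total
  w <- weights$category[match(cats$id, weights$category$id), ]
  z <- weights$group$z[match(grps$id, weights$group$id)]
  if (any(cats$intake_sd <= 0) || any(grps$group_sd <= 0)) {
    stop("all SDs must be positive")
  }
  if (any(c(w$w_plus, w$w_minus, z) <= 0)) stop("all weights must be positive")

  dcoef <- c(w$w_plus / cats$intake_sd^2, w$w_minus / cats$intake_sd^2,
             z / grps$group_sd^2, z / grps$group_sd^2)
  centers <- c(q0, q0, Q0, Q0)
  Dmat <- diag(2 * dcoef, lay$N)
  dvec <- 2 * dcoef * centers
  const0 <- sum(dcoef * centers^2)  # completes the square in the objective

  # Equality rows first (quadprog's meq convention): group linking, then the
  # system's own equality rows.
  Aeq <- matrix(0, nrow = m, ncol = lay$N)
  beq <- numeric(m)
  for (j in seq_len(m)) {
    sel <- cats$group_id == grps$id[j]
    Aeq[j, lay$qp[sel]] <- 1
    Aeq[j, lay$qm[sel]] <- 1
    Aeq[j, lay$Qp[j]] <- -1
    Aeq[j, lay$Qm[j]] <- -1
    beq[j] <- sum(q0[sel]) - Q0[j]
  }
  eq <- which(constraints$dir == "=")
  for (r in eq) {
    Aeq <- rbind(Aeq, lift_row(constraints$A[r, ], lay))
    beq <- c(beq, constraints$rhs[r] + sum(constraints$A[r, ] * q0))
  }

  # Inequalities, all as >= rows.
  rows <- list()
  rhs <- numeric(0)
  push <- function(a, b) {
    rows[[length(rows) + 1L]] <<- a
    rhs <<- c(rhs, b)
  }
  for (r in which(constraints$dir != "=")) {
    a <- lift_row(constraints$A[r, ], lay)
    b <- constraints$rhs[r] + sum(constraints$A[r, ] * q0)
    if (constraints$dir[r] == "<=") push(-a, -b) else push(a, b)
  }
  for (i in seq_len(n)) {  # split-variable sign bounds
    e <- numeric(lay$N); e[lay$qp[i]] <- 1; push(e, q0[i])        # qp >= q0
    if (q0[i] > 0) {
      e <- numeric(lay$N); e[lay$qm[i]] <- -1; push(e, -q0[i])    # qm <= q0
      e <- numeric(lay$N); e[lay$qm[i]] <- 1; push(e, 0)          # qm >= 0
    } else {
      # zero baseline collapses the qm interval to a point; an equality row
      # avoids a degenerate opposing inequality pair
      e <- numeric(lay$N); e[lay$qm[i]] <- 1
      Aeq <- rbind(Aeq, e); beq <- c(beq, 0)
    }
  }
  for (j in seq_len(m)) {
    e <- numeric(lay$N); e[lay$Qp[j]] <- 1; push(e, Q0[j])        # Qp >= Q0
    e <- numeric(lay$N); e[lay$Qm[j]] <- -1; push(e, -Q0[j])      # Qm <= Q0
    e <- numeric(lay$N); e[lay$Qm[j]] <- 1; push(e, 0)            # Qm >= 0
  }
  Amat <- t(rbind(Aeq, do.call(rbind, rows)))
  bvec <- c(beq, rhs)

  # precondition: solve in SD units (x = scl * y) with unit-norm constraint
  # rows, which keeps the Goldfarb-Idnani iterations well-scaled
  scl <- c(cats$intake_sd, cats$intake_sd, grps$group_sd, grps$group_sd)
  Dmat_s <- Dmat * outer(scl, scl)
  dvec_s <- dvec * scl
  Amat_s <- Amat * scl
  rnorm <- sqrt(colSums(Amat_s^2))
  rnorm[rnorm == 0] <- 1
  Amat_s <- sweep(Amat_s, 2, rnorm, "/")
  bvec_s <- bvec / rnorm

  sol <- tryCatch(
    quadprog::solve.QP(Dmat_s, dvec_s, Amat_s, bvec_s, meq = nrow(Aeq)),
    error = function(e) e)
  if (inherits(sol, "error")) {
    status <- if (grepl("inconsistent|no solution", conditionMessage(sol))) {
      "infeasible"
    } else "error"
    return(structure(list(label = label, engine = "qp", status = status,
                          message = conditionMessage(sol),
                          quantities = NULL, objective = NA_real_,
                          totals = NULL, split = NULL, binding = NULL),
                     class = "scenario_result"))
  }
  x <- scl * sol$solution
  q <- x[lay$qp] + x[lay$qm] - q0
  names(q) <- cats$id
  split <- list(q_plus = stats::setNames(x[lay$qp], cats$id),
                q_minus = stats::setNames(x[lay$qm], cats$id),
                Q_plus = stats::setNames(x[lay$Qp], grps$id),
                Q_minus = stats::setNames(x[lay$Qm], grps$id))
  structure(list(label = label, engine = "qp", status = "optimal",
                 message = NULL,
                 quantities = q,
                 objective = objective_value(q, survey, weights),
                 solver_objective = sol$value + const0,
                 totals = diet_totals(survey, q),
                 split = split,
                 binding = binding_constraints(constraints, q),
                 degenerate = FALSE),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario '", x$label, "' [", x$engine, "]: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat(sprintf("  objective %.6g | energy %.1f kJ | mass %.1f g | GHGE %.3f kg CO2e | cost %.2f EUR\n",
                x$objective, x$totals$energy, x$totals$mass, x$totals$ghge,
                x$totals$cost))
    cat("  binding constraints:", nrow(x$binding), "\n")
  } else if (!is.null(x$message)) cat("  ", x$message, "\n")
  invisible(x)
}

# Constraints whose slack at q is below tolerance (scaled by row norm).
binding_constraints <- function(constraints, q, tol = 1e-6) {
  viol <- constraint_violations(constraints, q)
  scale <- pmax(1, sqrt(rowSums(constraints$A^2)))
  sel <- viol >= -tol * scale
  data.frame(name = constraints$name[sel], family = constraints$family[sel],
             slack = -viol[sel], stringsAsFactors = FALSE)
}

#' Independently audit an optimal scenario result
#'
#' Re-checks, without consulting the solver, that every constraint row holds
#' at the reported diet, that deviations are one-sided (split-variable
#' complementarity), and that the objective recomputed from the diet vector
#' agrees with the solver's objective.
#'
#' @param result an optimal `scenario_result`.
#' @param survey,weights,constraints the inputs the scenario was solved with.
#' @param tol absolute feasibility tolerance on g/day rows, scaled by each
#'   row's coefficient norm; also the relative tolerance for the objective
#'   comparison.
#' @return A data.frame with columns `check` and `problem`; zero rows when the
#'   solution passes the audit.
#' @export
audit_solution <- function(result, survey, weights, constraints, tol = 1e-6) {
  if (result$status != "optimal") stop("can only audit an optimal result")
  issues <- list()
  note <- function(check, problem) issues[[length(issues) + 1L]] <<-
    data.frame(check = check, problem = problem, stringsAsFactors = FALSE)
  q <- result$quantities[survey$categories$id]

  viol <- constraint_violations(constraints, q)
  scale <- pmax(1, sqrt(rowSums(constraints$A^2)))
  bad <- which(viol > tol * scale)
  for (r in bad) {
    note("feasibility", sprintf("constraint '%s' violated by %.3g",
                                constraints$name[r], viol[r]))
  }
  if (!is.null(result$split)) {
    cats <- survey$categories
    up <- result$split$q_plus[cats$id] - cats$baseline_intake
    down <- cats$baseline_intake - result$split$q_minus[cats$id]
    both <- pmin(up, down) > tol * pmax(1, cats$intake_sd)
    for (i in which(both)) {
      note("complementarity",
           sprintf("category '%s' has two-sided deviation (up %.3g, down %.3g)",
                   cats$id[i], up[i], down[i]))
    }
  }
  obj <- if (identical(result$engine, "lp")) {
    model <- do.call(build_lp, c(list(survey = survey, weights = weights,
                                      constraints = constraints),
                                 result$lp_options))
    lp_objective_value(q, model)
  } else {
    objective_value(q, survey, weights)
  }
  ref <- if (!is.null(result$solver_objective)) result$solver_objective else
    result$objective
  if (abs(obj - ref) > tol * max(1, abs(obj))) {
    note("objective", sprintf(
      "recomputed objective %.8g disagrees with solver objective %.8g",
      obj, ref))
  }
  if (length(issues) == 0) {
    return(data.frame(check = character(), problem = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
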