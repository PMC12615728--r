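# Relative piecewise-linear comparator model.
#
# Deviations are measured relative to the baseline: |q_i - q_i^0| / q_i^0,
# split into up (u_i) and down (d_i) parts so the absolute value becomes
# linear. A zero baseline makes the relative deviation undefined, so
# zero-baseline categories (the novel food) use their imputed intake SD as
# the denominator, keeping the term dimensionless and comparable to the
# SD-standardized quadratic model. Directional category weights and
# group-level terms (weights z, denominators Q_j^0) mirror the quadratic
# objective's structure in linear form; both are toggleable.

#' Build the piecewise-linear deviation model
#'
#' @param survey a `diet_survey`.
#' @param weights a `penalty_weights` object.
#' @param constraints a `constraint_system`.
#' @param use_weights apply the directional category weights (`w_plus` on up,
#'   `w_minus` on down deviations)? Default `TRUE`.
#' @param group_terms include group-level deviation terms (weight `z`,
#'   denominator the group baseline)? Default `TRUE`.
#' @param zero_denominator denominator rule for zero-baseline categories:
#'   `"sd"` (imputed intake SD, default) or a positive number used verbatim.
#' @return An object of class `lp_model` describing the LP in the deviation
#'   variables, to be solved with [solve_lp()].
#' @export
build_lp <- function(survey, weights, constraints, use_weights = TRUE,
                     group_terms = TRUE, zero_denominator = "sd") {
  cats <- survey$categories
  grps <- survey$groups
  n <- nrow(cats)
  m <- nrow(grps)
  q0 <- cats$baseline_intake
  denom <- q0
  zero <- q0 <= 0
  if (identical(zero_denominator, "sd")) {
    denom[zero] <- cats$intake_sd[zero]
  } else {
    if (!is.numeric(zero_denominator) || zero_denominator <= 0) {
      stop("zero_denominator must be \"sd\" or a positive number")
    }
    denom[zero] <- zero_denominator
  }
  if (any(denom <= 0)) stop("all denominators must be positive")

  w <- weights$category[match(cats$id, weights$category$id), ]
  cu <- (if (use_weights) w$w_plus else rep(1, n)) / denom
  cd <- (if (use_weights) w$w_minus else rep(1, n)) / denom

  # variables: u (n), d (n), then group U (m), D (m) when group terms are on
  nv <- 2 * n + if (group_terms) 2 * m else 0
  c_obj <- c(cu, cd, if (group_terms) {
    z <- weights$group$z[match(grps$id, weights$group$id)]
    if (any(grps$baseline_total <= 0)) {
      stop("group terms need positive group baseline totals")
    }
    rep(z / grps$baseline_total, 2)
  })

  # q-space rows: a'q (dir) r  ->  a'(u - d) (dir) r - a'q0
  A <- matrix(0, nrow(constraints$A), nv)
  A[, seq_len(n)] <- constraints$A
  A[, n + seq_len(n)] <- -constraints$A
  rhs <- constraints$rhs - as.numeric(constraints$A %*% q0)
  dir <- constraints$dir
  nm <- constraints$name

  # d_i <= q0_i keeps q non-negative through the deviation bound
  bound <- matrix(0, n, nv)
  bound[cbind(seq_len(n), n + seq_len(n))] <- 1
  A <- rbind(A, bound)
  rhs <- c(rhs, q0)
  dir <- c(dir, rep("<=", n))
  nm <- c(nm, paste0(cats$id, " down-deviation bound"))

  if (group_terms) {
    # U_j - D_j = sum_{i in S_j} (u_i - d_i)
    link <- matrix(0, m, nv)
    for (j in seq_len(m)) {
      sel <- cats$group_id == grps$id[j]
      link[j, seq_len(n)][sel] <- 1
      link[j, n + seq_len(n)][sel] <- -1
      link[j, 2 * n + j] <- -1
      link[j, 2 * n + m + j] <- 1
    }
    A <- rbind(A, link)
    rhs <- c(rhs, numeric(m))
    dir <- c(dir, rep("=", m))
    nm <- c(nm, paste0("group ", grps$id, " deviation link"))
  }

  structure(list(survey = survey, weights = weights,
                 constraints = constraints,
                 c_obj = c_obj, A = A, dir = dir, rhs = rhs, row_names = nm,
                 n = n, m = m, group_terms = group_terms, denom = denom,
                 options = list(use_weights = use_weights,
                                group_terms = group_terms,
                                zero_denominator = zero_denominator)),
            class = "lp_model")
}

#' Solve the piecewise-linear deviation model
#'
#' @param model an `lp_model` from [build_lp()].
#' @param label scenario label attached to the result.
#' @return A `scenario_result` (see [solve_qp()]) with `engine = "lp"`; the
#'   `degenerate` flag is `TRUE` when zero reduced costs indicate alternative
#'   optimal vertices.
#' @export
solve_lp <- function(model, label = "scenario") {
  sol <- simplex_solve(model$c_obj, model$A, model$dir, model$rhs)
  survey <- model$survey
  cats <- survey$categories
  if (sol$status != "optimal") {
    status <- if (sol$status == "infeasible") "infeasible" else "error"
    return(structure(list(label = label, engine = "lp", status = status,
                          message = paste("simplex:", sol$status),
                          quantities = NULL, objective = NA_real_,
                          totals = NULL, split = NULL, binding = NULL),
                     class = "scenario_result"))
  }
  n <- model$n
  u <- sol$x[seq_len(n)]
  d <- sol$x[n + seq_len(n)]
  q <- cats$baseline_intake + u - d
  names(q) <- cats$id
  structure(list(label = label, engine = "lp", status = "optimal",
                 message = NULL, quantities = q,
                 objective = sol$value,
                 solver_objective = sol$value,
                 totals = diet_totals(survey, q),
                 split = list(q_plus = stats::setNames(
                                cats$baseline_intake + u, cats$id),
                              q_minus = stats::setNames(
                                cats$baseline_intake - d, cats$id)),
                 deviations = list(up = stats::setNames(u, cats$id),
                                   down = stats::setNames(d, cats$id)),
                 binding = binding_constraints(model$constraints, q),
                 lp_options = model$options,
                 degenerate = isTRUE(sol$degenerate)),
            class = "scenario_result")
}

#' Piecewise-linear objective of a diet vector
#'
#' The value [solve_lp()] minimizes, recomputed directly from a diet vector
#' (used by audits and tests).
#'
#' @param quantities named numeric g/day vector.
#' @param model an `lp_model`.
#' @return Non-negative scalar; 0 iff the diet equals the baseline.
#' @export
lp_objective_value <- function(quantities, model) {
  cats <- model$survey$categories
  q <- quantities[cats$id]
  delta <- q - cats$baseline_intake
  u <- pmax(delta, 0)
  d <- pmax(-delta, 0)
  val <- sum(model$c_obj[seq_len(model$n)] * u) +
    sum(model$c_obj[model$n + seq_len(model$n)] * d)
  if (model$group_terms) {
    Q <- group_totals(model$survey, q)
    g <- model$survey$groups
    z <- model$weights$group$z[match(g$id, model$weights$group$id)]
    val <- val + sum(z * abs(Q[g$id] - g$baseline_total) / g$baseline_total)
  }
  val
}
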