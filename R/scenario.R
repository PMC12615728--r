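# Optimization strategy: the nutritionally adequate diet ("NUTR"), then a
# stepwise ladder of greenhouse-gas reduction scenarios ("NUTR+GHGE-X%") with
# the novel food's host-group total held at its NUTR level.

solve_with_engine <- function(survey, weights, constraints, engine, label,
                              lp_options = list()) {
  if (engine == "qp") {
    solve_qp(survey, weights, constraints, label = label)
  } else if (engine == "lp") {
    model <- do.call(build_lp, c(list(survey = survey, weights = weights,
                                      constraints = constraints), lp_options))
    solve_lp(model, label = label)
  } else stop("unknown engine '", engine, "' (use \"qp\" or \"lp\")")
}

#' Optimize the nutritionally adequate (NUTR) diet
#'
#' Solves the model under nutritional, energy, feasible-range, group-cap,
#' fixed-category and total-mass constraints, with no greenhouse-gas cap.
#'
#' @param survey a `diet_survey`.
#' @param nutrients a `nutrient_spec`.
#' @param engine `"qp"` (default) or `"lp"`.
#' @param weights penalty weights; computed from the survey when `NULL`.
#' @param lp_options list passed to [build_lp()] when `engine = "lp"`.
#' @return A `scenario_result` labelled `"NUTR"`.
#' @export
run_nutr <- function(survey, nutrients, engine = "qp", weights = NULL,
                     lp_options = list()) {
  if (is.null(weights)) weights <- category_weights(survey)
  cs <- build_constraints(survey, nutrients)
  solve_with_engine(survey, weights, cs, engine, "NUTR", lp_options)
}

#' Run the stepwise GHGE-reduction scenario ladder
#'
#' For each reduction fraction `x`, re-optimizes with (i) dietary GHGE capped
#' at `(1 - x)` times the GHGE of the NUTR diet and (ii) the novel food's
#' host-group total pinned at its NUTR value, so the novel food must absorb
#' within-group substitution. Stops after the first infeasible step.
#'
#' @param survey a `diet_survey`.
#' @param nutrients a `nutrient_spec`.
#' @param nutr_result the optimal `scenario_result` of [run_nutr()].
#' @param reductions increasing fractions in `[0, 1)`, default 5\% steps up
#'   to 60\%.
#' @param engine `"qp"` or `"lp"`.
#' @param fix_group id of the group whose total is pinned; defaults to the
#'   new food's host group.
#' @param weights penalty weights; computed from the survey when `NULL`.
#' @param lp_options list passed to [build_lp()] when `engine = "lp"`.
#' @return List of `scenario_result`s labelled `"NUTR+GHGE-X%"`, in order,
#'   truncated at the first infeasible step (which is included, with status).
#' @export
run_ghge_ladder <- function(survey, nutrients, nutr_result,
                            reductions = seq(0.05, 0.60, by = 0.05),
                            engine = "qp", fix_group = NULL, weights = NULL,
                            lp_options = list()) {
  if (nutr_result$status != "optimal") {
    stop("the NUTR result must be optimal before running the ladder")
  }
  if (any(reductions < 0 | reductions >= 1) ||
      any(diff(reductions) <= 0)) {
    stop("reductions must be strictly increasing fractions in [0, 1)")
  }
  if (is.null(weights)) weights <- category_weights(survey)
  if (is.null(fix_group)) {
    nf <- survey$categories[survey$categories$is_new_food, , drop = FALSE]
    if (nrow(nf) == 0) stop("no new food in survey; name fix_group explicitly")
    fix_group <- nf$group_id[1]
  }
  ghge_base <- nutr_result$totals$ghge
  group_total <- group_totals(survey, nutr_result$quantities)[fix_group]
  results <- list()
  for (x in reductions) {
    label <- sprintf("NUTR+GHGE-%g%%", 100 * x)
    cap <- (1 - x) * ghge_base
    cs <- build_constraints(survey, nutrients, ghge_cap = cap,
                            fix_group_totals = stats::setNames(group_total,
                                                               fix_group))
    res <- solve_with_engine(survey, weights, cs, engine, label, lp_options)
    res$reduction <- x
    res$ghge_cap <- cap
    res$ghge_reference <- ghge_base  # NUTR-diet GHGE the cap is relative to
    results[[label]] <- res
    if (res$status != "optimal") break
  }
  results
}

#' Largest feasible GHGE reduction
#'
#' Bisects on the reduction fraction to find, within `resolution`, the
#' largest `x` for which the capped model remains feasible.
#'
#' @inheritParams run_ghge_ladder
#' @param resolution bisection stopping width on the fraction scale.
#' @return The largest feasible fraction found (0 if even tiny reductions are
#'   infeasible).
#' @export
max_feasible_reduction <- function(survey, nutrients, nutr_result,
                                   engine = "qp", resolution = 0.01,
                                   fix_group = NULL, weights = NULL) {
  if (nutr_result$status != "optimal") stop("NUTR result must be optimal")
  probe <- function(x) {
    res <- run_ghge_ladder(survey, nutrients, nutr_result, reductions = x,
                           engine = engine, fix_group = fix_group,
                           weights = weights)
    res[[1]]$status == "optimal"
  }
  lo <- 0
  hi <- 1 - 1e-9
  if (probe(hi)) return(hi)
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (probe(mid)) lo <- mid else hi <- mid
  }
  lo
}
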