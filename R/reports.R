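# Reporting layer: group shares of diet metrics, group-by-nutrient
# contribution tables and within-group category breakdowns, all as tidy
# data.frames with shares stored as fractions.

metric_per_category <- function(survey, quantities, metric) {
  q <- quantities[survey$categories$id]
  switch(metric,
         mass = q,
         energy = UNIT_PER100G * q *
           survey$nutrients[, survey$energy_nutrient],
         ghge = UNIT_PER100G * q * survey$categories$ghge,
         cost = UNIT_PER100G * q * survey$categories$price,
         stop("unknown metric '", metric,
              "' (use mass, energy, ghge or cost)"))
}

#' Food-group shares of a diet metric
#'
#' @param result an optimal `scenario_result`.
#' @param survey the `diet_survey` it was solved on.
#' @param metric one of `"mass"`, `"energy"`, `"ghge"`, `"cost"`.
#' @return Named numeric vector of per-group shares summing to 1.
#' @export
group_shares <- function(result, survey, metric = "mass") {
  if (result$status != "optimal") stop("result must be optimal")
  vals <- metric_per_category(survey, result$quantities, metric)
  total <- sum(vals)
  if (total <= 0) stop("diet total for metric '", metric, "' is zero")
  shares <- vapply(survey$groups$id, function(g) {
    sum(vals[survey$categories$group_id == g])
  }, numeric(1)) / total
  names(shares) <- survey$groups$id
  shares
}

#' Group contributions to nutrient intakes
#'
#' For each nutrient, the share of its total daily intake supplied by each
#' food group, with a flag where a group's share reaches the threshold
#' (nutrients for which a group is a major source).
#'
#' @param result an optimal `scenario_result`.
#' @param survey the `diet_survey`.
#' @param threshold flag shares at or above this fraction (default 0.20).
#' @return Tidy data.frame with columns `group_id`, `nutrient`, `share` and
#'   `flagged`. A nutrient with zero total intake gets `NA` shares.
#' @export
nutrient_contributions <- function(result, survey, threshold = 0.20) {
  if (result$status != "optimal") stop("result must be optimal")
  q <- result$quantities[survey$categories$id]
  intake <- UNIT_PER100G * q * survey$nutrients  # category x nutrient
  totals <- colSums(intake)
  rows <- list()
  for (g in survey$groups$id) {
    gsum <- colSums(intake[survey$categories$group_id == g, , drop = FALSE])
    share <- ifelse(totals > 0, gsum / totals, NA_real_)
    rows[[g]] <- data.frame(group_id = g, nutrient = colnames(intake),
                            share = as.numeric(share),
                            flagged = !is.na(share) & share >= threshold,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Category breakdown within one food group
#'
#' @param result an optimal `scenario_result`.
#' @param survey the `diet_survey`.
#' @param group_id the group to break down.
#' @return List with `table` (per-category mass/energy/ghge/cost and
#'   within-group shares of each), `group_totals`, and `new_food_share` (the
#'   novel food's share of group mass, `NA` if the group hosts none).
#' @export
category_breakdown <- function(result, survey, group_id) {
  if (result$status != "optimal") stop("result must be optimal")
  if (!group_id %in% survey$groups$id) stop("unknown group: ", group_id)
  sel <- survey$categories$group_id == group_id
  ids <- survey$categories$id[sel]
  tab <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (metric in c("mass", "energy", "ghge", "cost")) {
    vals <- metric_per_category(survey, result$quantities, metric)[sel]
    tab[[metric]] <- as.numeric(vals)
    total <- sum(vals)
    tab[[paste0(metric, "_share")]] <-
      if (total > 0) as.numeric(vals) / total else NA_real_
  }
  gt <- as.list(colSums(tab[, c("mass", "energy", "ghge", "cost")]))
  nf <- survey$categories$is_new_food[sel]
  nf_share <- if (any(nf) && gt$mass > 0) sum(tab$mass[nf]) / gt$mass else
    NA_real_
  list(table = tab, group_totals = gt, new_food_share = nf_share)
}

#' Tidy long table of scenario results
#'
#' One row per scenario and category with the optimized quantity, baseline
#' and per-category metric values — the delimited output of the scenario
#' commands.
#'
#' @param results list of `scenario_result`s (e.g. `c(list(nutr), ladder)`).
#' @param survey the `diet_survey`.
#' @return A tidy data.frame.
#' @export
results_table <- function(results, survey) {
  rows <- lapply(results, function(r) {
    if (r$status != "optimal") return(NULL)
    data.frame(scenario = r$label,
               id = survey$categories$id,
               group_id = survey$categories$group_id,
               baseline = survey$categories$baseline_intake,
               quantity = as.numeric(r$quantities[survey$categories$id]),
               energy = as.numeric(metric_per_category(
                 survey, r$quantities, "energy")),
               ghge = as.numeric(metric_per_category(
                 survey, r$quantities, "ghge")),
               cost = as.numeric(metric_per_category(
                 survey, r$quantities, "cost")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' JSON-ready summary of one scenario
#'
#' @param result a `scenario_result`.
#' @return A list (status, objective, totals, binding constraint names)
#'   suitable for [jsonlite::write_json()].
#' @export
scenario_summary <- function(result) {
  list(label = result$label, engine = result$engine, status = result$status,
       objective = result$objective,
       totals = result$totals,
       binding = if (!is.null(result$binding)) result$binding$name else
         character(0),
       degenerate = isTRUE(result$degenerate))
}
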