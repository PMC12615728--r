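# Survey data model and data-preparation transforms.
#
# A diet survey describes one population stratum: n food categories nested in
# m food groups, each category with an observed mean daily intake (g/day), the
# population SD of that intake, 5th/95th percentile bounds, per-100 g nutrient,
# greenhouse-gas and price coefficients, and flags for the novel food (zero
# baseline) and fixed categories (e.g. water).

# All per-100 g coefficients meet g/day quantities through this single factor.
UNIT_PER100G <- 0.01

#' Construct a diet survey object
#'
#' Bundles the category table, nutrient coefficient matrix and group table for
#' one population stratum into a validated `diet_survey` object.
#'
#' @param categories data.frame with columns `id`, `name`, `group_id`,
#'   `baseline_intake` (g/day), `intake_sd` (g/day), `p5`, `p95` (g/day),
#'   `is_new_food`, `is_fixed` (logical), `ghge` (kg CO2e per 100 g) and
#'   `price` (EUR per 100 g).
#' @param nutrients numeric matrix, one row per category (rownames = category
#'   ids), one column per nutrient, amounts per 100 g. Must contain the
#'   `energy_nutrient` column (kJ per 100 g).
#' @param groups data.frame with columns `id`, `name`, `group_sd` (g/day),
#'   `group_weight` (dimensionless) and optionally `p95` (g/day, the 95th
#'   percentile of total group consumption; when absent the sum of member
#'   category p95 values is used where a group-level cap is required).
#' @param stratum label for the population stratum (e.g. `"male 18-64"`).
#' @param energy_target total dietary energy (kJ/day) held constant during
#'   optimization; defaults to the energy content of the baseline diet.
#' @param energy_nutrient name of the nutrient column holding energy (kJ/100 g).
#' @return An object of class `diet_survey`.
#' @export
diet_survey <- function(categories, nutrients, groups, stratum = "unspecified",
                        energy_target = NULL, energy_nutrient = "energy_kj") {
  stopifnot(is.data.frame(categories), is.data.frame(groups))
  nutrients <- as.matrix(nutrients)
  if (is.null(rownames(nutrients))) rownames(nutrients) <- categories$id
  if (!energy_nutrient %in% colnames(nutrients)) {
    stop("nutrient matrix lacks the designated energy column '",
         energy_nutrient, "'")
  }
  categories$is_new_food <- as.logical(categories$is_new_food)
  categories$is_fixed <- as.logical(categories$is_fixed)
  if (!"baseline_total" %in% names(groups)) {
    groups$baseline_total <- vapply(groups$id, function(g) {
      sum(categories$baseline_intake[categories$group_id == g])
    }, numeric(1))
  }
  if (!"p95" %in% names(groups)) groups$p95 <- NA_real_
  survey <- structure(
    list(stratum = stratum,
         categories = categories,
         nutrients = nutrients[categories$id, , drop = FALSE],
         groups = groups,
         energy_nutrient = energy_nutrient,
         energy_target = NA_real_),
    class = "diet_survey")
  if (is.null(energy_target)) {
    energy_target <- sum(UNIT_PER100G * categories$baseline_intake *
                           nutrients[categories$id, energy_nutrient])
  }
  survey$energy_target <- energy_target
  survey
}

#' @export
print.diet_survey <- function(x, ...) {
  cat("Diet survey (", x$stratum, "): ", nrow(x$categories), " categories in ",
      nrow(x$groups), " groups, ", ncol(x$nutrients), " nutrients\n", sep = "")
  cat("  energy target:", format(x$energy_target, digits = 6), "kJ/day\n")
  nf <- x$categories$id[x$categories$is_new_food]
  if (length(nf)) cat("  new food:", paste(nf, collapse = ", "), "\n")
  invisible(x)
}

#' Number of categories / groups in a survey
#' @param survey a `diet_survey`.
#' @return Integer count.
#' @export
n_categories <- function(survey) nrow(survey$categories)

#' @rdname n_categories
#' @export
n_groups <- function(survey) nrow(survey$groups)

#' Member category ids of a group
#' @param survey a `diet_survey`.
#' @param group_id a group id.
#' @return Character vector of category ids.
#' @export
group_members <- function(survey, group_id) {
  survey$categories$id[survey$categories$group_id == group_id]
}

#' Convert raw to as-consumed mass with a yield factor
#'
#' Survey intakes recorded as purchased/raw mass are converted to as-consumed
#' form (raw-to-cooked meat, dried-to-cooked legumes) by multiplication with a
#' yield factor.
#'
#' @param raw_quantity mass in grams, non-negative.
#' @param factor positive dimensionless yield factor.
#' @param id optional category name used in error messages.
#' @return `raw_quantity * factor`.
#' @export
apply_yield_factor <- function(raw_quantity, factor, id = NULL) {
  if (any(!is.finite(factor)) || any(factor <= 0)) {
    stop("yield factor must be positive",
         if (!is.null(id)) paste0(" (category '", id, "')"))
  }
  if (any(raw_quantity < 0)) stop("raw quantity must be non-negative")
  raw_quantity * factor
}

#' Intake-weighted nutrient profile of a food category
#'
#' Aggregates item-level per-100 g nutrient profiles into a category profile,
#' weighting each item by its current intake.
#'
#' @param item_intakes numeric vector of item intakes (g/day).
#' @param item_profiles list of named numeric vectors (per-100 g amounts), one
#'   per item, all sharing the same nutrient names.
#' @return Named numeric vector: the intake-weighted mean profile.
#' @export
aggregate_category_profile <- function(item_intakes, item_profiles) {
  if (length(item_intakes) != length(item_profiles)) {
    stop("item_intakes and item_profiles must have equal length")
  }
  total <- sum(item_intakes)
  if (total <= 0) {
    stop("total intake is zero: cannot form intake-weighted nutrient profile")
  }
  keys <- names(item_profiles[[1]])
  for (k in seq_along(item_profiles)) {
    missing <- setdiff(keys, names(item_profiles[[k]]))
    extra <- setdiff(names(item_profiles[[k]]), keys)
    if (length(missing) || length(extra)) {
      stop("item ", k, " has mismatched nutrient keys: ",
           paste(c(missing, extra), collapse = ", "))
    }
  }
  mat <- do.call(rbind, lapply(item_profiles, function(p) p[keys]))
  out <- colSums(mat * item_intakes) / total
  names(out) <- keys
  out
}

#' Rescale a GHGE coefficient to a different electricity mix
#'
#' The life-cycle emission coefficient of an industrially produced food splits
#' into an electricity share and a remainder; moving production to a grid with
#' a different global-warming potential rescales only the electricity part.
#'
#' @param coef emission coefficient, kg CO2e per 100 g.
#' @param elec_share fraction of the coefficient attributable to electricity,
#'   in `[0, 1]` (0.6 for mycoprotein).
#' @param gwp_old,gwp_new global-warming potential of the old and new
#'   electricity mixes (kg CO2e/kWh); `gwp_old` must be positive.
#' @return Rescaled coefficient, kg CO2e per 100 g.
#' @export
rescale_ghge_electricity <- function(coef, elec_share, gwp_old, gwp_new) {
  if (elec_share < 0 || elec_share > 1) stop("elec_share must lie in [0, 1]")
  if (gwp_old <= 0) stop("gwp_old must be positive")
  coef * (1 - elec_share) + coef * elec_share * (gwp_new / gwp_old)
}

#' Impute the intake SD of a zero-baseline novel food
#'
#' A food absent from the survey has no observed intake SD; it is estimated as
#' the arithmetic mean of the SDs of reference categories (for mycoprotein, the
#' common meat categories of its host group).
#'
#' @param survey a `diet_survey`.
#' @param reference_ids category ids whose SDs are averaged. When `NULL`, the
#'   default reference set is the five largest-baseline non-novel categories of
#'   the new food's host group.
#' @return The imputed SD (g/day). Use [set_new_food_sd()] to write it back.
#' @export
impute_new_food_sd <- function(survey, reference_ids = NULL) {
  cats <- survey$categories
  if (is.null(reference_ids)) {
    nf <- cats[cats$is_new_food, , drop = FALSE]
    if (nrow(nf) == 0) stop("survey has no new-food category")
    host <- cats[cats$group_id == nf$group_id[1] & !cats$is_new_food, ,
                 drop = FALSE]
    host <- host[order(-host$baseline_intake), , drop = FALSE]
    reference_ids <- utils::head(host$id, 5L)
  }
  if (length(reference_ids) == 0) stop("reference id list is empty")
  unknown <- setdiff(reference_ids, cats$id)
  if (length(unknown)) {
    stop("unknown reference category id(s): ", paste(unknown, collapse = ", "))
  }
  sds <- cats$intake_sd[match(reference_ids, cats$id)]
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("all reference categories must have positive intake SD")
  }
  mean(sds)
}

#' @rdname impute_new_food_sd
#' @export
set_new_food_sd <- function(survey, reference_ids = NULL) {
  sd <- impute_new_food_sd(survey, reference_ids)
  survey$categories$intake_sd[survey$categories$is_new_food] <- sd
  survey
}

#' Derive a per-100 g price from expenditure and quantity
#'
#' Household-budget surveys report average expenditure and quantity purchased
#' per period; their ratio gives the price, converted to EUR per 100 g.
#'
#' @param expenditure EUR per period.
#' @param quantity kg per period; must be positive.
#' @return Price in EUR per 100 g.
#' @export
derive_price <- function(expenditure, quantity) {
  if (any(quantity <= 0)) stop("quantity purchased must be positive")
  (expenditure / quantity) / 10  # EUR/kg -> EUR/100 g
}

#' Validate a diet survey against its structural invariants
#'
#' Checks every type invariant of the data model: positive SDs, ordered
#' percentile bounds, non-negative intakes and coefficients, zero baseline for
#' the new food, pinned bounds for fixed categories, group membership
#' consistency and group baseline totals.
#'
#' @param survey a `diet_survey`.
#' @return A data.frame with columns `object` and `problem`, one row per
#'   violation; zero rows iff the survey is well-formed.
#' @export
validate_survey <- function(survey) {
  v <- list()
  note <- function(object, problem) v[[length(v) + 1L]] <<- data.frame(
    object = object, problem = problem, stringsAsFactors = FALSE)
  cats <- survey$categories
  grps <- survey$groups

  if (anyDuplicated(cats$id)) note("categories", "duplicate category ids")
  if (anyDuplicated(grps$id)) note("groups", "duplicate group ids")
  for (i in seq_len(nrow(cats))) {
    cid <- cats$id[i]
    if (!is.finite(cats$intake_sd[i]) || cats$intake_sd[i] <= 0) {
      note(cid, "intake_sd must be positive (impute for a new food)")
    }
    if (cats$p5[i] < 0 || cats$p5[i] > cats$p95[i]) {
      note(cid, "percentile bounds must satisfy 0 <= p5 <= p95")
    }
    if (cats$baseline_intake[i] < 0) note(cid, "baseline_intake is negative")
    if (cats$ghge[i] < 0) note(cid, "ghge coefficient is negative")
    if (cats$price[i] < 0) note(cid, "price coefficient is negative")
    if (cats$is_new_food[i] && cats$baseline_intake[i] != 0) {
      note(cid, "a new food must have baseline_intake = 0")
    }
    if (cats$is_fixed[i] &&
        !(isTRUE(all.equal(cats$p5[i], cats$baseline_intake[i])) &&
          isTRUE(all.equal(cats$p95[i], cats$baseline_intake[i])))) {
      note(cid, "a fixed category must have p5 = p95 = baseline_intake")
    }
    if (!cats$group_id[i] %in% grps$id) {
      note(cid, paste0("unknown group id '", cats$group_id[i], "'"))
    }
  }
  if (any(survey$nutrients < 0)) {
    bad <- rownames(survey$nutrients)[apply(survey$nutrients < 0, 1, any)]
    for (cid in bad) note(cid, "negative nutrient coefficient")
  }
  for (j in seq_len(nrow(grps))) {
    gid <- grps$id[j]
    members <- cats$baseline_intake[cats$group_id == gid]
    if (length(members) == 0) {
      note(gid, "group has no member categories")
      next
    }
    tot <- sum(members)
    if (abs(grps$baseline_total[j] - tot) >
        1e-9 * max(1, abs(tot))) {
      note(gid, "baseline_total does not equal the sum of member baselines")
    }
    if (!is.finite(grps$group_sd[j]) || grps$group_sd[j] <= 0) {
      note(gid, "group_sd must be positive")
    }
    if (grps$group_weight[j] < 1) note(gid, "group_weight must be >= 1")
  }
  if (!is.finite(survey$energy_target) || survey$energy_target <= 0) {
    note("survey", "energy_target must be positive")
  }
  if (length(v) == 0) {
    return(data.frame(object = character(), problem = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Read / write diet surveys as delimited text
#'
#' The survey file has one row per category with columns `id`, `name`,
#' `group_id`, `baseline_intake`, `intake_sd`, `p5`, `p95`, `is_new_food`,
#' `is_fixed`, `ghge`, `price`, followed by one column per nutrient. The group
#' file has columns `id`, `name`, `group_sd`, `group_weight` and optionally
#' `p95`.
#'
#' @param survey_file,group_file paths to comma-separated files.
#' @param stratum,energy_target,energy_nutrient passed to [diet_survey()].
#' @return [read_survey()] returns a `diet_survey`; [write_survey()] writes the
#'   two files and returns the paths invisibly.
#' @export
read_survey <- function(survey_file, group_file, stratum = "unspecified",
                        energy_target = NULL, energy_nutrient = "energy_kj") {
  if (!file.exists(survey_file)) stop("survey file not found: ", survey_file)
  if (!file.exists(group_file)) stop("group file not found: ", group_file)
  tab <- utils::read.csv(survey_file, stringsAsFactors = FALSE)
  grp <- utils::read.csv(group_file, stringsAsFactors = FALSE)
  fixed_cols <- c("id", "name", "group_id", "baseline_intake", "intake_sd",
                  "p5", "p95", "is_new_food", "is_fixed", "ghge", "price")
  missing <- setdiff(fixed_cols, names(tab))
  if (length(missing)) {
    stop("survey file lacks column(s): ", paste(missing, collapse = ", "))
  }
  nutr_cols <- setdiff(names(tab), fixed_cols)
  nutrients <- as.matrix(tab[, nutr_cols, drop = FALSE])
  rownames(nutrients) <- tab$id
  diet_survey(tab[, fixed_cols], nutrients, grp, stratum = stratum,
              energy_target = energy_target, energy_nutrient = energy_nutrient)
}

#' @rdname read_survey
#' @param survey a `diet_survey` to write.
#' @export
write_survey <- function(survey, survey_file, group_file) {
  tab <- cbind(survey$categories,
               as.data.frame(survey$nutrients, stringsAsFactors = FALSE))
  utils::write.csv(tab, survey_file, row.names = FALSE, quote = FALSE)
  grp <- survey$groups
  utils::write.csv(grp[, setdiff(names(grp), "baseline_total")], group_file,
                   row.names = FALSE, quote = FALSE)
  invisible(c(survey_file, group_file))
}

# Totals of a diet vector: the one place per-100 g coefficients meet g/day.
#' Energy, mass, GHGE and cost totals of a diet
#'
#' @param survey a `diet_survey`.
#' @param quantities named numeric vector of g/day intakes covering every
#'   category of the survey.
#' @return List with elements `energy` (kJ), `mass` (g), `ghge` (kg CO2e) and
#'   `cost` (EUR), all per day.
#' @export
diet_totals <- function(survey, quantities) {
  q <- quantities[survey$categories$id]
  if (any(is.na(q))) stop("quantities must cover every survey category")
  list(
    energy = sum(UNIT_PER100G * q *
                   survey$nutrients[, survey$energy_nutrient]),
    mass = sum(q),
    ghge = sum(UNIT_PER100G * q * survey$categories$ghge),
    cost = sum(UNIT_PER100G * q * survey$categories$price))
}

#' Group totals of a diet vector
#'
#' @param survey a `diet_survey`.
#' @param quantities named numeric vector of g/day intakes.
#' @return Named numeric vector of group totals `Q_j` (g/day).
#' @export
group_totals <- function(survey, quantities) {
  q <- quantities[survey$categories$id]
  out <- vapply(survey$groups$id, function(g) {
    sum(q[survey$categories$group_id == g])
  }, numeric(1))
  names(out) <- survey$groups$id
  out
}
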