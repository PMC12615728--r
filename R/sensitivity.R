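# Sensitivity-analysis variants: each changes exactly one declared input of
# the base configuration and re-runs the NUTR + ladder scenarios.

#' Base configuration for scenario and sensitivity runs
#'
#' @param survey a `diet_survey`.
#' @param nutrients a `nutrient_spec`.
#' @param reductions ladder of GHGE reduction fractions.
#' @param engine `"qp"` or `"lp"`.
#' @param lp_options options passed to [build_lp()] for the LP engine.
#' @return A list of class `diet_config`.
#' @export
diet_config <- function(survey, nutrients,
                        reductions = seq(0.05, 0.60, by = 0.05),
                        engine = "qp", lp_options = list()) {
  structure(list(survey = survey, nutrients = nutrients,
                 reductions = reductions, engine = engine,
                 lp_options = lp_options),
            class = "diet_config")
}

run_config <- function(config, weights = NULL) {
  nutr <- run_nutr(config$survey, config$nutrients, engine = config$engine,
                   weights = weights, lp_options = config$lp_options)
  ladder <- if (nutr$status == "optimal") {
    run_ghge_ladder(config$survey, config$nutrients, nutr,
                    reductions = config$reductions, engine = config$engine,
                    weights = weights, lp_options = config$lp_options)
  } else list()
  list(nutr = nutr, ladder = ladder)
}

#' Run one sensitivity variant
#'
#' Variants mirror the four robustness checks of the modelling framework:
#' `profile_override` swaps the novel food's nutrient profile (e.g. a
#' market-product profile instead of the pure ingredient);
#' `no_category_weights` sets every directional category weight to 1, leaving
#' group weights untouched; `ghge_scale` multiplies only the novel food's
#' GHGE coefficient (e.g. 0.5 / 1.5 for +/-50\%); `engine_swap` re-runs the
#' identical configuration with the piecewise-linear engine. Everything else
#' is held fixed.
#'
#' @param base_config a `diet_config`.
#' @param variant one of `"base"`, `"profile_override"`,
#'   `"no_category_weights"`, `"ghge_scale"`, `"engine_swap"`.
#' @param params variant parameters: `profile` (complete named per-100 g
#'   vector) for `profile_override`; `scale` (positive number) for
#'   `ghge_scale`.
#' @return List with the variant `label`, the effective `config` after the
#'   variant's change, and `results` (`nutr` plus `ladder`).
#' @export
run_variant <- function(base_config, variant = "base", params = list()) {
  config <- base_config
  weights <- NULL
  label <- variant
  survey <- config$survey
  nf_idx <- which(survey$categories$is_new_food)
  if (variant %in% c("profile_override", "ghge_scale") && !length(nf_idx)) {
    stop("survey has no new-food category")
  }
  if (variant == "base") {
    # unchanged
  } else if (variant == "profile_override") {
    profile <- unlist(params$profile)
    missing <- setdiff(colnames(survey$nutrients), names(profile))
    if (length(missing)) {
      stop("override profile lacks nutrient(s): ",
           paste(missing, collapse = ", "))
    }
    survey$nutrients[nf_idx, ] <- profile[colnames(survey$nutrients)]
    config$survey <- survey
  } else if (variant == "no_category_weights") {
    weights <- category_weights(survey, no_category_weights = TRUE)
  } else if (variant == "ghge_scale") {
    scale <- params$scale
    if (is.null(scale) || scale <= 0) stop("ghge_scale needs a positive scale")
    survey$categories$ghge[nf_idx] <- scale * survey$categories$ghge[nf_idx]
    config$survey <- survey
    label <- sprintf("ghge_scale_%g", scale)
  } else if (variant == "engine_swap") {
    config$engine <- "lp"
  } else stop("unknown variant '", variant, "'")
  list(label = label, config = config, results = run_config(config, weights))
}

#' Run a declarative grid of sensitivity variants
#'
#' @param base_config a `diet_config`.
#' @param grid list of variant specs, each a list with `variant` and optional
#'   `params` (the JSON grid file format, after [jsonlite::fromJSON] with
#'   `simplifyVector = FALSE`).
#' @return Named list of [run_variant()] outputs.
#' @export
run_sensitivity_grid <- function(base_config, grid) {
  out <- list()
  for (g in grid) {
    res <- run_variant(base_config, g$variant,
                       if (is.null(g$params)) list() else g$params)
    out[[res$label]] <- res
  }
  out
}

scenario_quantity_table <- function(results) {
  all_res <- c(list(results$nutr), unname(results$ladder))
  rows <- lapply(all_res, function(r) {
    if (r$status != "optimal") return(NULL)
    data.frame(scenario = r$label, id = names(r$quantities),
               quantity = as.numeric(r$quantities), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two scenario runs
#'
#' @param results_a,results_b outputs of [run_variant()] (or any list with
#'   `results$nutr` / `results$ladder`) over the same survey and grid.
#' @return List with `differences` (per scenario and category: quantity under
#'   a, under b, and b minus a) and `new_food_share` (per scenario: the novel
#'   food's share of its host group's mass under each run).
#' @export
compare_runs <- function(results_a, results_b) {
  ta <- scenario_quantity_table(results_a$results)
  tb <- scenario_quantity_table(results_b$results)
  shared <- intersect(unique(ta$scenario), unique(tb$scenario))
  if (!setequal(unique(ta$scenario), unique(tb$scenario))) {
    warning("scenario grids differ; comparing ", length(shared),
            " shared scenarios")
  }
  if (!length(shared)) stop("no shared scenarios between the two runs")
  ta <- ta[ta$scenario %in% shared, ]
  tb <- tb[tb$scenario %in% shared, ]
  key <- function(t) paste(t$scenario, t$id)
  if (!setequal(key(ta), key(tb))) stop("mismatched scenario/category grids")
  tb <- tb[match(key(ta), key(tb)), ]
  diffs <- data.frame(scenario = ta$scenario, id = ta$id,
                      quantity_a = ta$quantity, quantity_b = tb$quantity,
                      difference = tb$quantity - ta$quantity,
                      stringsAsFactors = FALSE)

  survey <- results_a$config$survey
  cats <- survey$categories
  nf <- cats$id[cats$is_new_food][1]
  share <- NULL
  if (!is.na(nf)) {
    host <- cats$id[cats$group_id == cats$group_id[cats$id == nf]]
    share <- do.call(rbind, lapply(shared, function(s) {
      qa <- ta$quantity[ta$scenario == s]
      names(qa) <- ta$id[ta$scenario == s]
      qb <- tb$quantity[tb$scenario == s]
      names(qb) <- tb$id[tb$scenario == s]
      data.frame(scenario = s,
                 share_a = qa[nf] / sum(qa[host]),
                 share_b = qb[nf] / sum(qb[host]),
                 stringsAsFactors = FALSE)
    }))
    rownames(share) <- NULL
  }
  list(differences = diffs, new_food_share = share)
}
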