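# Small surveys built in code for unit tests.

# A hand-sized survey: `baselines` per category, `group_of` assigns groups.
# One nutrient ("energy_kj") unless a nutrient matrix is supplied.
tiny_survey <- function(baselines, group_of = rep("g1", length(baselines)),
                        sds = NULL, p5 = NULL, p95 = NULL,
                        nutrients = NULL, ghge = NULL, price = NULL,
                        group_sd = NULL, is_new_food = NULL, is_fixed = NULL,
                        group_p95 = NULL, energy_target = NULL) {
  n <- length(baselines)
  ids <- sprintf("c%d", seq_len(n))
  if (is.null(sds)) sds <- pmax(0.5 * baselines, 1)
  if (is.null(p5)) p5 <- 0.2 * baselines
  if (is.null(p95)) p95 <- pmax(2 * baselines, 1)
  if (is.null(is_new_food)) is_new_food <- rep(FALSE, n)
  if (is.null(is_fixed)) is_fixed <- rep(FALSE, n)
  p5[is_fixed] <- baselines[is_fixed]
  p95[is_fixed] <- baselines[is_fixed]
  p5[is_new_food] <- 0
  p95[is_new_food] <- 0
  if (is.null(ghge)) ghge <- rep(0.2, n)
  if (is.null(price)) price <- rep(0.5, n)
  if (is.null(nutrients)) {
    nutrients <- matrix(500, n, 1, dimnames = list(ids, "energy_kj"))
  }
  cats <- data.frame(id = ids, name = ids, group_id = group_of,
                     baseline_intake = baselines, intake_sd = sds,
                     p5 = p5, p95 = p95, is_new_food = is_new_food,
                     is_fixed = is_fixed, ghge = ghge, price = price,
                     stringsAsFactors = FALSE)
  gids <- unique(group_of)
  if (is.null(group_sd)) {
    group_sd <- vapply(gids, function(g) {
      max(1, 0.5 * sum(baselines[group_of == g]))
    }, numeric(1))
  }
  grps <- data.frame(id = gids, name = gids, group_sd = group_sd,
                     group_weight = 2,
                     p95 = if (is.null(group_p95)) NA_real_ else group_p95,
                     stringsAsFactors = FALSE)
  diet_survey(cats, nutrients, grps, stratum = "tiny",
              energy_target = energy_target)
}

# The package's standard seeded fixture for regression-style tests.
fixture_survey <- function(seed = 7, ...) generate_survey(seed = seed, ...)

unit_weights <- function(survey) {
  category_weights(survey, no_category_weights = TRUE)
}
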