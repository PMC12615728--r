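# Synthetic dietary-survey generator.
#
# Emulates the structure of a national dietary survey: n categories in m
# groups with right-skewed positive baseline intakes, SDs proportional to
# intake, percentile bounds bracketing the mean, positive nutrient / GHGE /
# price coefficients, one fixed water category and one zero-baseline novel
# food inside a designated host (meat-like) group. Magnitudes are generic and
# deliberately do not imitate any particular country's intake data.

SYNTH_NUTRIENTS <- c("energy_kj", "protein", "fat", "carbohydrate", "fiber",
                     "iron", "zinc", "vitamin_b12", "sodium")

#' Generate a synthetic diet survey
#'
#' @param n_categories number of food categories (default 79).
#' @param m_groups number of food groups (default 13).
#' @param seed integer seed; the same seed reproduces the same survey.
#' @param host_group index of the group hosting the novel food (default 2).
#' @param cv coefficient of variation linking intake SDs to baselines.
#' @param zero_p95_frac fraction of ordinary categories given a zero 95th
#'   percentile (rarely-consumed foods whose cap is later replaced by the
#'   mean observed intake).
#' @param new_food_ghge_factor the novel food's GHGE coefficient as a multiple
#'   of its host group's mean (default 0.5: half the group mean, mirroring a
#'   low-emission meat alternative).
#' @return A valid `diet_survey` with stratum `"synthetic"`.
#' @export
generate_survey <- function(n_categories = 79, m_groups = 13, seed = 1,
                            host_group = 2, cv = 0.9, zero_p95_frac = 0.05,
                            new_food_ghge_factor = 0.5) {
  if (n_categories < m_groups || m_groups < 1) {
    stop("need n_categories >= m_groups >= 1")
  }
  if (cv <= 0) stop("cv must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- n_categories
  m <- m_groups
  host_group <- ((host_group - 1) %% m) + 1
  group_ids <- sprintf("g%02d", seq_len(m))
  # every group gets at least 2 members where possible
  base_sizes <- rep(floor(n / m), m)
  extra <- n - sum(base_sizes)
  if (extra > 0) base_sizes[seq_len(extra)] <- base_sizes[seq_len(extra)] + 1
  group_of <- rep(group_ids, base_sizes)

  id <- sprintf("c%02d", seq_len(n))
  # right-skewed baselines, group-specific scale
  group_scale <- stats::rlnorm(m, meanlog = log(15), sdlog = 0.6)
  baseline <- stats::rlnorm(n, meanlog = log(group_scale[match(
    group_of, group_ids)]), sdlog = 0.8)
  sdv <- pmax(cv * baseline, 1)
  p5 <- baseline * stats::runif(n, 0.05, 0.5)
  p95 <- baseline * stats::runif(n, 1.8, 3.5)

  # rarely-consumed categories: zero 5th AND 95th percentile, positive mean
  n_zero <- floor(zero_p95_frac * n)
  if (n_zero > 0) {
    # smallest baselines, skipping the first member of each group so the
    # water / new-food placements below stay untouched
    cand <- setdiff(order(baseline), match(group_ids, group_of))
    zsel <- utils::head(cand, n_zero)
    p5[zsel] <- 0
    p95[zsel] <- 0
  }

  ghge <- stats::rlnorm(n, meanlog = log(0.15), sdlog = 0.9)
  # the host group is meat-like: markedly more emission-intensive than the
  # rest of the diet, which is what makes the novel food a relevant
  # substitution lever under greenhouse-gas caps
  ghge[group_of == group_ids[host_group]] <-
    ghge[group_of == group_ids[host_group]] * 6
  price <- stats::rlnorm(n, meanlog = log(0.5), sdlog = 0.6)

  nutrients <- matrix(0, n, length(SYNTH_NUTRIENTS),
                      dimnames = list(id, SYNTH_NUTRIENTS))
  nutrients[, "energy_kj"] <- stats::rlnorm(n, meanlog = log(350), sdlog = 0.7)
  nutrients[, "protein"] <- stats::runif(n, 0.5, 25)
  nutrients[, "fat"] <- stats::runif(n, 0.2, 20)
  nutrients[, "carbohydrate"] <- stats::runif(n, 0.5, 60)
  nutrients[, "fiber"] <- stats::runif(n, 0, 8)
  nutrients[, "iron"] <- stats::runif(n, 0.05, 4)
  nutrients[, "zinc"] <- stats::runif(n, 0.05, 5)
  nutrients[, "vitamin_b12"] <- stats::runif(n, 0, 3)
  nutrients[, "sodium"] <- stats::runif(n, 5, 600)

  is_new <- rep(FALSE, n)
  is_fixed <- rep(FALSE, n)

  nf <- match(group_ids[host_group], group_of)  # novel food: first host member

  # water: fixed at a large intake, placed in a non-host group (the last
  # group, or the first when the host group is last); never the novel food
  water_group <- if (host_group == m && m > 1) 1 else m
  water <- setdiff(which(group_of == group_ids[water_group]), nf)[1]
  if (is.na(water)) stop("survey too small to place both water and a new food")
  is_fixed[water] <- TRUE
  baseline[water] <- 1200
  sdv[water] <- 400
  p5[water] <- baseline[water]
  p95[water] <- baseline[water]
  nutrients[water, ] <- 0
  ghge[water] <- 0.001
  price[water] <- 0.001

  # novel food: zero baseline, protein-rich, low-GHGE, priced near the top
  # of its host group
  is_new[nf] <- TRUE
  baseline[nf] <- 0
  p5[nf] <- 0
  p95[nf] <- 0
  host <- group_of == group_ids[host_group]
  ghge[nf] <- new_food_ghge_factor * mean(ghge[host & !is_new])
  price[nf] <- 0.95 * max(price[host & !is_new])
  nutrients[nf, "energy_kj"] <- 356
  nutrients[nf, "protein"] <- 11
  nutrients[nf, "fat"] <- 2.9
  nutrients[nf, "carbohydrate"] <- 3
  nutrients[nf, "fiber"] <- 6
  nutrients[nf, "iron"] <- 0.5
  nutrients[nf, "zinc"] <- 6.7
  nutrients[nf, "vitamin_b12"] <- 0.1
  nutrients[nf, "sodium"] <- 5

  categories <- data.frame(
    id = id, name = paste("food", id), group_id = group_of,
    baseline_intake = baseline, intake_sd = sdv, p5 = p5, p95 = p95,
    is_new_food = is_new, is_fixed = is_fixed, ghge = ghge, price = price,
    stringsAsFactors = FALSE)

  groups <- data.frame(
    id = group_ids, name = paste("group", group_ids),
    group_sd = NA_real_, group_weight = 2, p95 = NA_real_,
    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    tot <- sum(baseline[group_of == group_ids[j]])
    groups$group_sd[j] <- max(0.5 * tot, 1) * stats::runif(1, 0.8, 1.2)
    groups$p95[j] <- tot * stats::runif(1, 1.25, 1.5)
  }

  survey <- diet_survey(categories, nutrients, groups, stratum = "synthetic")
  set_new_food_sd(survey)
}

#' Nutrient bounds that keep the baseline diet feasible
#'
#' Builds a constraint spec whose bounds are `(1 - slack)` and `(1 + slack)`
#' times the baseline intake of each nutrient, so the observed diet always
#' satisfies it — a guaranteed-feasible starting point for tests.
#'
#' @param survey a `diet_survey`.
#' @param slack non-negative relative slack (0 gives degenerate equalities,
#'   still feasible at baseline).
#' @return A `nutrient_spec` with one row per survey nutrient.
#' @export
make_feasible_spec <- function(survey, slack = 0.3) {
  if (slack < 0) stop("slack must be non-negative")
  base_q <- survey$categories$baseline_intake
  totals <- as.numeric(UNIT_PER100G * base_q %*% survey$nutrients)
  names(totals) <- colnames(survey$nutrients)
  nut <- setdiff(colnames(survey$nutrients), survey$energy_nutrient)
  nutrient_spec(nutrient_id = nut,
                lower = (1 - slack) * totals[nut],
                upper = (1 + slack) * totals[nut],
                basis = "absolute")
}

#' Nutrient bounds forcing a binding constraint
#'
#' Starts from [make_feasible_spec()] and raises the lower bound of one
#' nutrient to `(1 + push)` times its baseline intake (dropping its upper
#' bound), so that nutrient must bind and drive substitutions.
#'
#' @param survey a `diet_survey`.
#' @param nutrient_id nutrient to push.
#' @param push positive fraction by which the lower bound exceeds baseline.
#' @param slack slack used for the remaining nutrients.
#' @return A `nutrient_spec`.
#' @export
make_binding_spec <- function(survey, nutrient_id, push = 0.1, slack = 0.5) {
  if (!nutrient_id %in% colnames(survey$nutrients)) {
    stop("unknown nutrient id: ", nutrient_id)
  }
  if (push < 0) stop("push must be non-negative")
  spec <- make_feasible_spec(survey, slack = slack)
  base_q <- survey$categories$baseline_intake
  total <- sum(UNIT_PER100G * base_q * survey$nutrients[, nutrient_id])
  r <- spec$nutrient_id == nutrient_id
  spec$lower[r] <- (1 + push) * total
  spec$upper[r] <- NA_real_
  spec
}
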