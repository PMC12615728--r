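# Popularity-based directional penalty weights.
#
# Within each food group, a category's baseline intake is min-max normalized
# to [0,1] as a popularity proxy p. Increasing an unpopular food is penalized
# more (w_plus = 2 - p), decreasing a popular food is penalized more
# (w_minus = 1 + p); both lie in [1,2] and sum to 3. A zero-baseline novel
# food sits at its group minimum and therefore gets w_plus = 2, w_minus = 1.
# Group-level deviations carry a single weight z per group, default 2.

#' Min-max normalized popularity of a baseline intake within its group
#'
#' @param q_obs baseline intake of the category (g/day).
#' @param group_values baseline intakes of all categories in the same group.
#' @return Fraction in `[0, 1]`; a degenerate group (all baselines equal)
#'   returns the neutral value 0.5.
#' @export
normalized_popularity <- function(q_obs, group_values) {
  if (length(group_values) == 0) stop("group_values must be non-empty")
  lo <- min(group_values)
  hi <- max(group_values)
  if (q_obs < lo - 1e-9 || q_obs > hi + 1e-9) {
    stop("q_obs must lie within the range of its group's baselines")
  }
  if (hi - lo <= 0) return(0.5)
  (q_obs - lo) / (hi - lo)
}

#' Directional category penalty weights for a survey
#'
#' Computes, for every category, the increase weight `w_plus = 2 - p` and the
#' decrease weight `w_minus = 1 + p`, where `p` is the within-group min-max
#' normalized baseline intake, plus the group weights `z`.
#'
#' @param survey a `diet_survey`.
#' @param z_override optional named list/vector replacing the default group
#'   weight of 2 for specific groups; values must be positive.
#' @param no_category_weights when `TRUE`, every category weight is set to 1
#'   (the "no penalty weights" sensitivity variant); group weights are kept.
#' @return An object of class `penalty_weights`: list with data.frames
#'   `category` (`id`, `w_plus`, `w_minus`) and `group` (`id`, `z`).
#' @export
category_weights <- function(survey, z_override = NULL,
                             no_category_weights = FALSE) {
  cats <- survey$categories
  p <- numeric(nrow(cats))
  for (g in survey$groups$id) {
    idx <- which(cats$group_id == g)
    vals <- cats$baseline_intake[idx]
    p[idx] <- vapply(vals, normalized_popularity, numeric(1),
                     group_values = vals)
  }
  if (no_category_weights) {
    w_plus <- rep(1, nrow(cats))
    w_minus <- rep(1, nrow(cats))
  } else {
    w_plus <- 2 - p
    w_minus <- 1 + p
  }
  structure(
    list(category = data.frame(id = cats$id, w_plus = w_plus,
                               w_minus = w_minus, stringsAsFactors = FALSE),
         group = data.frame(id = survey$groups$id,
                            z = group_weights(survey, z_override),
                            stringsAsFactors = FALSE)),
    class = "penalty_weights")
}

#' Group-level penalty weights
#'
#' @param survey a `diet_survey`.
#' @param override optional named list/vector of positive replacements.
#' @return Named numeric vector of `z` weights, default 2 per group.
#' @export
group_weights <- function(survey, override = NULL) {
  z <- rep(2, nrow(survey$groups))
  names(z) <- survey$groups$id
  if (!is.null(override)) {
    override <- unlist(override)
    unknown <- setdiff(names(override), names(z))
    if (length(unknown)) {
      stop("unknown group id(s) in override: ", paste(unknown, collapse = ", "))
    }
    if (any(override <= 0)) stop("group weight overrides must be positive")
    z[names(override)] <- override
  }
  z
}

#' @export
print.penalty_weights <- function(x, ...) {
  cat("Penalty weights:", nrow(x$category), "categories,",
      nrow(x$group), "groups\n")
  cat("  w_plus range:", paste(round(range(x$category$w_plus), 3),
                               collapse = " .. "), "\n")
  cat("  w_minus range:", paste(round(range(x$category$w_minus), 3),
                                collapse = " .. "), "\n")
  invisible(x)
}

#' Export penalty weights as a delimited table
#'
#' @param weights a `penalty_weights` object.
#' @param file path of the comma-separated file to write.
#' @return The path, invisibly.
#' @export
write_weights <- function(weights, file) {
  utils::write.csv(weights$category, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
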