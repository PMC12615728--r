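# Linear constraint system over the diet vector q (g/day per category).
#
# Rows live in q-space; the QP and LP engines translate them into their own
# decision-variable spaces. Each row carries a family tag so scenario and
# audit code can reason about constraint provenance:
#   nutrition   - lower/upper bounds on daily nutrient intake
#   energy      - dietary energy pinned at its observed level
#   feasible-range - per-category box between the 5th and 95th percentile
#   group-cap   - host-group total capped at the group 95th percentile
#   fixed       - categories pinned at baseline (e.g. water)
#   mass        - total food mass within a band around baseline
#   ghge        - cap on dietary greenhouse-gas emissions
#   group-total - a group total pinned (the scenario ladder's meat fix)
#   nonneg      - q >= 0

CONSTRAINT_FAMILIES <- c("nutrition", "energy", "feasible-range", "group-cap",
                         "fixed", "mass", "ghge", "group-total", "nonneg")

#' Nutrient constraint specification
#'
#' @param nutrient_id character vector of nutrient ids (columns of the
#'   survey's nutrient matrix).
#' @param lower,upper numeric bounds; `NA` for absent. On the `absolute`
#'   basis these are amounts per day; on the `percent_energy` basis they are
#'   percent of total dietary energy supplied by the nutrient.
#' @param basis `"absolute"` or `"percent_energy"` per row.
#' @param energy_per_g kJ per gram of the nutrient, required for
#'   `percent_energy` rows (e.g. 37 for fat, 17 for protein and carbohydrate).
#' @return A data.frame of class `nutrient_spec`.
#' @export
nutrient_spec <- function(nutrient_id, lower = NA_real_, upper = NA_real_,
                          basis = "absolute", energy_per_g = NA_real_) {
  spec <- data.frame(nutrient_id = nutrient_id, lower = lower, upper = upper,
                     basis = basis, energy_per_g = energy_per_g,
                     stringsAsFactors = FALSE)
  bad <- !spec$basis %in% c("absolute", "percent_energy")
  if (any(bad)) stop("basis must be 'absolute' or 'percent_energy'")
  both <- !is.na(spec$lower) & !is.na(spec$upper)
  if (any(both & spec$lower > spec$upper)) {
    stop("lower bound exceeds upper bound for: ",
         paste(spec$nutrient_id[both & spec$lower > spec$upper],
               collapse = ", "))
  }
  pe <- spec$basis == "percent_energy"
  if (any(pe & (is.na(spec$energy_per_g) | spec$energy_per_g <= 0))) {
    stop("percent_energy rows need a positive energy_per_g")
  }
  pct <- c(spec$lower[pe], spec$upper[pe])
  if (any(!is.na(pct) & (pct < 0 | pct > 100))) {
    stop("percent_energy bounds must lie in [0, 100]")
  }
  class(spec) <- c("nutrient_spec", "data.frame")
  spec
}

#' Read / write nutrient constraint specifications
#'
#' Delimited text with columns `nutrient_id`, `lower`, `upper`, `basis` and
#' optionally `energy_per_g`.
#'
#' @param file path to a comma-separated file.
#' @return A `nutrient_spec`.
#' @export
read_nutrient_spec <- function(file) {
  if (!file.exists(file)) stop("constraint spec file not found: ", file)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"energy_per_g" %in% names(tab)) tab$energy_per_g <- NA_real_
  nutrient_spec(tab$nutrient_id, tab$lower, tab$upper, tab$basis,
                tab$energy_per_g)
}

#' @rdname read_nutrient_spec
#' @param spec a `nutrient_spec` to write.
#' @export
write_nutrient_spec <- function(spec, file) {
  utils::write.csv(as.data.frame(spec), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

new_constraint_system <- function(n, ids) {
  structure(list(A = matrix(numeric(0), nrow = 0, ncol = n,
                            dimnames = list(NULL, ids)),
                 dir = character(0), rhs = numeric(0),
                 family = character(0), name = character(0)),
            class = "constraint_system")
}

add_row <- function(cs, coeffs, dir, rhs, family, name) {
  if (any(!is.finite(coeffs)) || !is.finite(rhs)) {
    stop("constraint row '", name, "' has non-finite coefficients")
  }
  stopifnot(family %in% CONSTRAINT_FAMILIES, dir %in% c("<=", ">=", "="))
  cs$A <- rbind(cs$A, coeffs)
  cs$dir <- c(cs$dir, dir)
  cs$rhs <- c(cs$rhs, rhs)
  cs$family <- c(cs$family, family)
  cs$name <- c(cs$name, name)
  cs
}

#' @export
print.constraint_system <- function(x, ...) {
  cat("Constraint system:", nrow(x$A), "rows over", ncol(x$A), "categories\n")
  print(table(x$family))
  invisible(x)
}

#' Assemble the constraint system for a survey
#'
#' Builds the full linear constraint system over the diet vector: nutrient
#' bounds, the energy equality, per-category feasible consumption boxes
#' (5th-95th percentile, with a zero 95th percentile replaced by the mean
#' observed intake), the host-group cap for the novel food, fixed categories,
#' the total-mass band, non-negativity, and optionally a greenhouse-gas cap
#' and pinned group totals.
#'
#' @param survey a `diet_survey`.
#' @param nutrients a `nutrient_spec`, or `NULL` for no nutrient rows.
#' @param ghge_cap optional positive cap on dietary GHGE (kg CO2e/day).
#' @param fix_group_totals optional named numeric vector pinning the totals of
#'   the named groups (g/day).
#' @param mass_band half-width of the relative total-mass band (default 0.2,
#'   i.e. total mass within +/-20\% of baseline).
#' @return A `constraint_system`.
#' @export
build_constraints <- function(survey, nutrients = NULL, ghge_cap = NULL,
                              fix_group_totals = NULL, mass_band = 0.2) {
  cats <- survey$categories
  n <- nrow(cats)
  cs <- new_constraint_system(n, cats$id)
  unit <- UNIT_PER100G

  # (a) nutrient bounds
  if (!is.null(nutrients)) {
    unknown <- setdiff(nutrients$nutrient_id, colnames(survey$nutrients))
    if (length(unknown)) {
      stop("unknown nutrient id(s) in constraint spec: ",
           paste(unknown, collapse = ", "))
    }
    for (r in seq_len(nrow(nutrients))) {
      nid <- nutrients$nutrient_id[r]
      coeffs <- unit * survey$nutrients[, nid]
      lo <- nutrients$lower[r]
      hi <- nutrients$upper[r]
      if (nutrients$basis[r] == "percent_energy") {
        # percent of dietary energy -> grams/day via the nutrient's kJ/g,
        # valid because energy is pinned at energy_target by an equality row
        conv <- survey$energy_target / (100 * nutrients$energy_per_g[r])
        lo <- lo * conv
        hi <- hi * conv
      }
      if (!is.na(lo) && !is.na(hi) && hi - lo <= 1e-12 * max(1, abs(hi))) {
        # coincident bounds: one exact equality row, numerically sturdier
        # than an inequality pair
        cs <- add_row(cs, coeffs, "=", lo, "nutrition",
                      paste0("nutrient ", nid, " pinned"))
      } else {
        if (!is.na(lo)) {
          cs <- add_row(cs, coeffs, ">=", lo, "nutrition",
                        paste0("nutrient ", nid, " lower"))
        }
        if (!is.na(hi)) {
          cs <- add_row(cs, coeffs, "<=", hi, "nutrition",
                        paste0("nutrient ", nid, " upper"))
        }
      }
    }
  }

  # (b) energy pinned at its observed level
  cs <- add_row(cs, unit * survey$nutrients[, survey$energy_nutrient], "=",
                survey$energy_target, "energy", "dietary energy")

  # (c) feasible consumption boxes; novel foods are capped at group level
  # instead, fixed categories are pinned in (e)
  for (i in seq_len(n)) {
    if (cats$is_new_food[i] || cats$is_fixed[i]) next
    e <- numeric(n)
    e[i] <- 1
    ub <- cats$p95[i]
    if (ub <= 0) ub <- cats$baseline_intake[i]  # mean replaces a zero p95
    cs <- add_row(cs, e, ">=", cats$p5[i], "feasible-range",
                  paste0(cats$id[i], " >= p5"))
    cs <- add_row(cs, e, "<=", ub, "feasible-range",
                  paste0(cats$id[i], " <= p95"))
  }

  # (d) host-group cap for each novel food; when the same group's total is
  # pinned below the cap by (h), the cap row is implied and omitted
  for (i in which(cats$is_new_food)) {
    g <- cats$group_id[i]
    e <- as.numeric(cats$group_id == g)
    gp95 <- survey$groups$p95[survey$groups$id == g]
    if (is.na(gp95)) gp95 <- sum(cats$p95[cats$group_id == g])
    pinned <- fix_group_totals[[g]]
    if (!is.null(pinned) && pinned <= gp95) next
    cs <- add_row(cs, e, "<=", gp95, "group-cap",
                  paste0("group ", g, " total <= group p95"))
  }

  # (e) fixed categories
  for (i in which(cats$is_fixed)) {
    e <- numeric(n)
    e[i] <- 1
    cs <- add_row(cs, e, "=", cats$baseline_intake[i], "fixed",
                  paste0(cats$id[i], " fixed at baseline"))
  }

  # (f) total mass band around baseline (fixed categories included)
  m0 <- sum(cats$baseline_intake)
  cs <- add_row(cs, rep(1, n), ">=", (1 - mass_band) * m0, "mass",
                "total mass lower")
  cs <- add_row(cs, rep(1, n), "<=", (1 + mass_band) * m0, "mass",
                "total mass upper")

  # (g) greenhouse-gas cap
  if (!is.null(ghge_cap)) {
    if (ghge_cap <= 0) stop("ghge_cap must be positive")
    cs <- add_row(cs, unit * cats$ghge, "<=", ghge_cap, "ghge",
                  "dietary GHGE cap")
  }

  # (h) pinned group totals (scenario ladder)
  if (!is.null(fix_group_totals)) {
    for (g in names(fix_group_totals)) {
      if (!g %in% survey$groups$id) stop("unknown group id: ", g)
      e <- as.numeric(cats$group_id == g)
      cs <- add_row(cs, e, "=", fix_group_totals[[g]], "group-total",
                    paste0("group ", g, " total pinned"))
    }
  }

  # non-negativity (omitted only where an identical p5 = 0 box row exists)
  for (i in seq_len(n)) {
    boxed <- !cats$is_new_food[i] && !cats$is_fixed[i]
    if (boxed && cats$p5[i] == 0) next
    e <- numeric(n)
    e[i] <- 1
    cs <- add_row(cs, e, ">=", 0, "nonneg", paste0(cats$id[i], " >= 0"))
  }
  cs
}

# Signed violation of each row at q: positive numbers violate.
constraint_violations <- function(cs, q) {
  lhs <- as.numeric(cs$A %*% q)
  viol <- numeric(length(lhs))
  viol[cs$dir == "<="] <- lhs[cs$dir == "<="] - cs$rhs[cs$dir == "<="]
  viol[cs$dir == ">="] <- cs$rhs[cs$dir == ">="] - lhs[cs$dir == ">="]
  viol[cs$dir == "="] <- abs(lhs[cs$dir == "="] - cs$rhs[cs$dir == "="])
  viol
}
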