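test_that("nutrient specs validate bounds and bases", {
  spec <- nutrient_spec(c("protein", "fat"), lower = c(50, NA),
                        upper = c(NA, 30), basis = c("absolute", "absolute"))
  expect_s3_class(spec, "nutrient_spec")
  expect_error(nutrient_spec("a", lower = 10, upper = 5), "exceeds")
  expect_error(nutrient_spec("a", lower = 1, basis = "weekly"), "basis")
  expect_error(nutrient_spec("a", lower = 10, basis = "percent_energy"),
               "energy_per_g")
  expect_error(nutrient_spec("a", lower = 120, basis = "percent_energy",
                             energy_per_g = 37), "0, 100")
})

test_that("constraint specs round-trip through delimited files", {
  spec <- nutrient_spec(c("protein", "fat"), lower = c(50, 10),
                        upper = c(150, NA),
                        basis = c("absolute", "percent_energy"),
                        energy_per_g = c(NA, 37))
  f <- tempfile(fileext = ".csv")
  write_nutrient_spec(spec, f)
  spec2 <- read_nutrient_spec(f)
  expect_equal(as.data.frame(spec2), as.data.frame(spec))
})

test_that("the packaged example constraint spec loads and applies", {
  f <- system.file("extdata", "example_nutrient_spec.csv",
                   package = "dietshift")
  spec <- read_nutrient_spec(f)
  expect_s3_class(spec, "nutrient_spec")
  expect_true(all(spec$basis %in% c("absolute", "percent_energy")))
  s <- fixture_survey()
  cs <- build_constraints(s, spec)
  expect_gt(sum(cs$family == "nutrition"), 0)
})

test_that("the synthetic market-product profile drives the override variant", {
  f <- system.file("extdata", "mycoprotein_product_profile_synthetic.csv",
                   package = "dietshift")
  prof_tab <- read.csv(f)
  profile <- stats::setNames(prof_tab$per_100g, prof_tab$nutrient)
  s <- fixture_survey()
  config <- diet_config(s, make_feasible_spec(s), reductions = c(0.1))
  over <- run_variant(config, "profile_override", list(profile = profile))
  nf <- which(s$categories$is_new_food)
  expect_equal(unname(over$config$survey$nutrients[nf, names(profile)]),
               unname(profile))
})

test_that("constraint families and row counts follow the survey structure", {
  s <- tiny_survey(c(0, 100, 200, 50, 1200),
                   group_of = c("meat", "meat", "meat", "veg", "drink"),
                   is_new_food = c(TRUE, rep(FALSE, 4)),
                   is_fixed = c(rep(FALSE, 4), TRUE),
                   nutrients = cbind(energy_kj = rep(400, 5),
                                     protein = c(11, 20, 15, 3, 0),
                                     iron = c(0.5, 2, 1, 1, 0)))
  spec <- nutrient_spec(c("protein", "iron"), lower = c(40, 5),
                        upper = c(200, 20))
  cs <- build_constraints(s, spec)
  fam <- table(cs$family)
  expect_equal(unname(fam["nutrition"]), 4L)      # 2 nutrients, both sides
  expect_equal(unname(fam["energy"]), 1L)
  expect_equal(unname(fam["feasible-range"]), 6L) # 3 boxed categories
  expect_equal(unname(fam["group-cap"]), 1L)      # one new food
  expect_equal(unname(fam["fixed"]), 1L)          # water
  expect_equal(unname(fam["mass"]), 2L)
  expect_equal(unname(fam["nonneg"]), 5L)
  expect_false("ghge" %in% names(fam))

  cs2 <- build_constraints(s, spec, ghge_cap = 1,
                           fix_group_totals = c(meat = 300))
  expect_equal(sum(cs2$family == "ghge"), 1L)
  expect_equal(sum(cs2$family == "group-total"), 1L)
})

test_that("a fixed category is pinned at its baseline", {
  s <- tiny_survey(c(100, 1200), is_fixed = c(FALSE, TRUE))
  cs <- build_constraints(s, NULL)
  r <- which(cs$family == "fixed")
  expect_identical(length(r), 1L)
  expect_identical(cs$dir[r], "=")
  expect_equal(unname(cs$rhs[r]), 1200)
  expect_equal(unname(cs$A[r, ]), c(0, 1))
})

test_that("a zero 95th percentile is replaced by the mean observed intake", {
  s <- tiny_survey(c(4, 100), p5 = c(0, 20), p95 = c(0, 200))
  cs <- build_constraints(s, NULL)
  up <- which(cs$family == "feasible-range" & grepl("c1 <= p95", cs$name))
  expect_equal(unname(cs$rhs[up]), 4)
})

test_that("the new-food cap binds the host-group total at the group p95", {
  s <- tiny_survey(c(0, 100, 200), is_new_food = c(TRUE, FALSE, FALSE),
                   group_p95 = 380)
  cs <- build_constraints(s, NULL)
  r <- which(cs$family == "group-cap")
  expect_equal(unname(cs$A[r, ]), c(1, 1, 1))
  expect_equal(unname(cs$rhs[r]), 380)
  # fallback: sum of member p95 when the group value is absent
  s2 <- tiny_survey(c(0, 100, 200), is_new_food = c(TRUE, FALSE, FALSE))
  cs2 <- build_constraints(s2, NULL)
  r2 <- which(cs2$family == "group-cap")
  expect_equal(unname(cs2$rhs[r2]), sum(s2$categories$p95))
})

test_that("percent-of-energy bounds linearize against the energy target", {
  s <- tiny_survey(c(100, 100),
                   nutrients = cbind(energy_kj = c(400, 600),
                                     fat = c(10, 5)))
  # fat between 20% and 35% of energy, 37 kJ/g
  spec <- nutrient_spec("fat", lower = 20, upper = 35,
                        basis = "percent_energy", energy_per_g = 37)
  cs <- build_constraints(s, spec)
  rows <- which(cs$family == "nutrition")
  lo <- cs$rhs[rows[cs$dir[rows] == ">="]]
  hi <- cs$rhs[rows[cs$dir[rows] == "<="]]
  expect_equal(unname(lo), 0.20 * s$energy_target / 37)
  expect_equal(unname(hi), 0.35 * s$energy_target / 37)
})

test_that("assembly rejects bad inputs by name", {
  s <- tiny_survey(c(100, 200))
  expect_error(build_constraints(s, nutrient_spec("selenium", lower = 1)),
               "selenium")
  expect_error(build_constraints(s, NULL, ghge_cap = -2), "positive")
  expect_error(build_constraints(s, NULL, fix_group_totals = c(nope = 10)),
               "nope")
})

test_that("the mass band spans the baseline including fixed categories", {
  s <- tiny_survey(c(100, 1200), is_fixed = c(FALSE, TRUE))
  cs <- build_constraints(s, NULL, mass_band = 0.2)
  rows <- which(cs$family == "mass")
  expect_equal(sort(unname(cs$rhs[rows])), c(0.8, 1.2) * 1300)
  expect_true(all(cs$A[rows, ] == 1))
})
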