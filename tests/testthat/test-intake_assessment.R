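test_that("EDI multiplies concentration by intake and normalizes by weight", {
  e <- edi(0.078, 24.2, 13.87)
  expect_equal(e$edi_total, 1.888, tolerance = 1e-3)
  expect_equal(edi(0.3, 0, 10)$edi_total, 0)
  expect_equal(edi(1, 13.87, 13.87)$edi_bw, 1)
  expect_error(edi(0.1, 10, 0), "positive")
  # dimensional consistency on random inputs
  set.seed(501)
  conc <- stats::runif(100, 0, 1); ir <- stats::runif(100, 0, 300)
  bw <- stats::runif(100, 5, 30)
  e <- edi(conc, ir, bw)
  expect_equal(e$edi_bw * bw, e$edi_total, tolerance = 1e-12)
})

test_that("AI percentages reproduce the published compliance values", {
  expect_equal(ai_percent(3.24, 20), 16.20)
  expect_equal(ai_percent(0.71, 20), 3.55)
  expect_equal(ai_percent(20, 20), 100)
  expect_error(ai_percent(5, 0), "positive")
})

test_that("net selenium subtracts mercury mass (or its molar equivalent)", {
  expect_equal(net_se(17.37, 0.56), 16.81)
  expect_equal(net_se(4.2, 0), 4.2)
  expect_equal(net_se(0.24, 0.75), -0.51)
  cfg <- study_config()
  expect_equal(net_se(10, 2, molar_equivalent = TRUE, config = cfg),
               10 - 2 * 78.971 / 200.59)
  # linearity through the AI percentage
  a <- c(17.37, 9.41, 0.24); b <- c(0.56, 1.89, 0.75)
  expect_equal(ai_percent(net_se(a, b), 20),
               ai_percent(a, 20) - ai_percent(b, 20), tolerance = 1e-12)
})

test_that("hazard quotient flags only strict exceedance", {
  hq <- hazard_quotient(0.23, 0.23)
  expect_equal(hq$hq, 1)
  expect_false(hq$risk)
  expect_equal(hazard_quotient(0.1361, 0.23)$hq, 0.5917, tolerance = 1e-3)
  expect_equal(hazard_quotient(0, 0.23)$hq, 0)
  expect_true(hazard_quotient(0.3, 0.23)$risk)
  expect_error(hazard_quotient(0.1, 0), "positive")
})

test_that("daily and monthly consumption limits match hand values", {
  expect_equal(cr_lim(0.0001, 13.87, 0.093), 14.91, tolerance = 0.005)
  expect_equal(cr_lim(0.0001, 13.87, 0.044), 31.52, tolerance = 0.005)
  expect_equal(cr_lim(0, 13.87, 0.1), 0)
  expect_error(cr_lim(0.0001, 13.87, 0), "unbounded")

  expect_equal(cr_mm(14.91, 30.44, 65), 6.98, tolerance = 0.005)
  expect_equal(cr_mm(31.52, 30.44, 65), 14.76, tolerance = 0.005)
  expect_equal(cr_mm(10, 30, 10 * 30), 1)  # unit-portion identity
  expect_error(cr_mm(10, 30, 0), "positive")

  # inverse linearity in portion size and concentration
  expect_equal(cr_mm(10, 30.44, 130), cr_mm(10, 30.44, 65) / 2)
  expect_equal(cr_lim(0.0001, 13.87, 0.2), cr_lim(0.0001, 13.87, 0.1) / 2)
})

test_that("eating exactly CR_lim of a food gives HQ 1 against the same RfD", {
  # EPA mercury RfD 0.0001 mg/kg/day = 0.1 ug/kg-BW/day
  set.seed(502)
  conc <- stats::runif(50, 0.001, 0.5)
  bw <- stats::runif(50, 8, 25)
  lim <- cr_lim(0.0001, bw, conc)
  hq <- hazard_quotient(edi(conc, lim, bw)$edi_bw, 0.1)
  expect_equal(hq$hq, rep(1, 50), tolerance = 1e-12)
})

test_that("servings to meet the selenium AI match the dietary guidance", {
  expect_equal(servings_to_meet_ai(20, 0.309, 35), 1.85, tolerance = 0.005)
  expect_equal(servings_to_meet_ai(20, 0.452, 35), 1.26, tolerance = 0.005)
  expect_equal(servings_to_meet_ai(20, 0.521, 60), 0.64, tolerance = 0.005)
  expect_equal(servings_to_meet_ai(20, 0.521, 60, whole_units = TRUE), 1)
  expect_error(servings_to_meet_ai(20, 0, 35), "positive")
})

test_that("nutrient profiles scale linearly with servings", {
  expect_equal(nutrient_profile_at_ai(2, c(protein = 7)), c(protein = 14))
  expect_equal(nutrient_profile_at_ai(0, c(dha = 100, epa = 50)),
               c(dha = 0, epa = 0))
  expect_equal(nutrient_profile_at_ai(1.85, c(dha = 100)), c(dha = 185))
  expect_error(nutrient_profile_at_ai(1, c(dha = -1)), "nonnegative")
})

test_that("population assessment reproduces published-style intake tables", {
  cfg <- study_config()
  # category "concentrations" and intakes back-solved from the published
  # population selenium intakes: the pipeline must return those intakes
  # and their AI percentages
  specs <- default_food_specs()
  summaries <- data.frame(category = names(default_intake_means()))
  summaries$se_mass_mean <- vapply(summaries$category, function(cc) {
    r <- specs[specs$category == cc, ]
    sum(r$se_mean * r$n_samples) / sum(r$n_samples)
  }, numeric(1))
  summaries$hg_mass_mean <- vapply(summaries$category, function(cc) {
    r <- specs[specs$category == cc, ]
    sum(r$hg_mean * r$n_samples) / sum(r$n_samples)
  }, numeric(1))
  ir <- default_intake_means()
  intakes <- data.frame(child_id = "population", category = names(ir),
                        intake_rate = unname(ir))
  res <- assess_population_intake(summaries, intakes, cfg)

  published_ai_pct <- c("Eggs" = 86.86, "Fish" = 47.06, "Fruits" = 1.19,
                        "Grains and related products" = 78.96,
                        "Leafy vegetables" = 3.55,
                        "Legumes and related products" = 16.29,
                        "Meat and meat products" = 63.17,
                        "Milk and dairy products" = 89.98,
                        "Non-leafy vegetables" = 9.32, "Rice" = 6.86,
                        "Shellfish" = 16.20)
  got <- res$ai_pct[match(names(published_ai_pct), res$category)]
  # 0.05 pp bound: the published inputs are printed to 2 decimals of
  # ug/day, i.e. up to 0.025 pp of rounding each way on the AI scale
  expect_true(all(abs(got - published_ai_pct) <= 0.05))
  # rows whose printed inputs are self-consistent agree to 0.02 pp
  consistent <- c("Eggs", "Fish", "Leafy vegetables", "Shellfish", "Rice")
  expect_true(all(abs(got[match(consistent, names(published_ai_pct))] -
                      published_ai_pct[consistent]) <= 0.02))
  # invariant columns
  expect_equal(res$ai_pct, 100 * res$edi_se_total / cfg$ai_se)
  expect_equal(res$net_se, res$edi_se_total - res$edi_hg_total)
  expect_true(all(res$hq_hg >= 0))
})

test_that("per-child and population modes agree for a uniform cohort", {
  cfg <- study_config()
  summaries <- data.frame(category = c("Eggs", "Fish"),
                          se_mass_mean = c(0.521, 0.408),
                          hg_mass_mean = c(0.014, 0.078))
  intakes <- expand.grid(child_id = c("C1", "C2", "C3"),
                         category = c("Eggs", "Fish"),
                         stringsAsFactors = FALSE)
  intakes$intake_rate <- 30
  pop <- assess_population_intake(summaries, intakes, cfg)
  per <- assess_population_intake(summaries, intakes, cfg,
                                  mode = "per_child")
  expect_equal(pop$edi_se_total, per$edi_se_total, tolerance = 1e-12)
  expect_equal(pop$hq_hg, per$hq_hg, tolerance = 1e-12)
})

test_that("consumption limits table reproduces the monthly serving limits", {
  cfg <- study_config()
  summaries <- data.frame(
    category = c("Marine fish", "Freshwater fish", "Eggs"),
    se_mass_mean = c(0.452, 0.309, 0.521),
    hg_mass_mean = c(0.093, 0.044, 0.014))
  lim <- consumption_limits(summaries, cfg)
  pick <- function(cat, el, col)
    lim[lim$category == cat & lim$element == el, col]
  # US EPA 65-g fish meals per month
  expect_equal(pick("Marine fish", "Hg", "cr_mm_meals"), 7, tolerance = 0.05)
  expect_equal(pick("Freshwater fish", "Hg", "cr_mm_meals"), 14.8,
               tolerance = 0.05)
  # Taiwan exchange servings per month
  expect_equal(pick("Marine fish", "Hg", "cr_mm_servings"), 13,
               tolerance = 0.05)
  expect_equal(pick("Freshwater fish", "Hg", "cr_mm_servings"), 27.4,
               tolerance = 0.05)
  expect_equal(pick("Eggs", "Se", "cr_mm_servings"), 67.5, tolerance = 0.05)
  expect_true(is.na(pick("Eggs", "Hg", "cr_mm_meals")))
})
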