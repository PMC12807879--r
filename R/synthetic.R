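# Seed-deterministic generators for food panels, cohorts, intakes and
# growth outcomes with known ground truth. Defaults are calibrated to the
# study conditions: category concentration means/SDs of the analyzed food
# panel, a hair-Hg distribution of mean 1.11 and SD 1.15 ug/g, cohort
# demographics (n = 349, mean age 2.9 y, 54% male), and intake rates
# back-solved from the published population selenium intakes.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Lognormal parameters from a target mean and SD
#'
#' Moment matching on the natural scale:
#' `mu = ln(mean^2 / sqrt(sd^2 + mean^2))`,
#' `sigma = sqrt(ln(1 + sd^2 / mean^2))`. A zero SD degenerates to a point
#' mass at `mean` (`sigma = 0`).
#'
#' @param mean Target arithmetic mean (> 0).
#' @param sd Target arithmetic SD (>= 0).
#' @return `list(mu, sigma)` on the log scale.
#' @export
#' @examples
#' lognormal_params_from_moments(1.11, 1.15)
lognormal_params_from_moments <- function(mean, sd) {
  if (any(mean <= 0)) stop("mean must be positive.", call. = FALSE)
  if (any(sd < 0)) stop("sd must be nonnegative.", call. = FALSE)
  list(mu = log(mean^2 / sqrt(sd^2 + mean^2)),
       sigma = sqrt(log(1 + sd^2 / mean^2)))
}

rlnorm_moments <- function(n, mean, sd) {
  p <- lognormal_params_from_moments(mean, sd)
  if (p$sigma == 0) rep(mean, n) else stats::rlnorm(n, p$mu, p$sigma)
}

#' Default food-panel distribution specs
#'
#' One row per category (fish split into its marine and freshwater
#' subpanels), with the sample counts and the Se and Hg concentration
#' means/SDs (mg/kg wet weight) of the analyzed 108-sample panel as
#' lognormal calibration targets.
#'
#' @return `data.frame(category, subcategory, n_samples, se_mean, se_sd,
#'   hg_mean, hg_sd)`.
#' @export
default_food_specs <- function() {
  specs <- rbind(
    c("Eggs", NA, 6, 0.521, 0.045, 0.014, 0.004),
    c("Fish", "marine", 9, 0.452, 0.199, 0.093, 0.081),
    c("Fish", "freshwater", 4, 0.309, 0.149, 0.044, 0.033),
    c("Fruits", NA, 13, 0.002, 0.002, 0.005, 0.001),
    c("Grains and related products", NA, 10, 0.158, 0.186, 0.015, 0.010),
    c("Leafy vegetables", NA, 9, 0.006, 0.005, 0.005, 0.005),
    c("Legumes and related products", NA, 7, 0.086, 0.063, 0.009, 0.006),
    c("Meat and meat products", NA, 18, 0.255, 0.099, 0.011, 0.003),
    c("Milk and dairy products", NA, 10, 0.063, 0.055, 0.007, 0.004),
    c("Non-leafy vegetables", NA, 13, 0.028, 0.069, 0.004, 0.003),
    c("Rice", NA, 4, 0.036, 0.039, 0.025, 0.012),
    c("Shellfish", NA, 5, 0.306, 0.113, 0.022, 0.023))
  out <- data.frame(category = specs[, 1], subcategory = specs[, 2],
                    stringsAsFactors = FALSE)
  for (i in 3:7) out[[c("x", "x", "n_samples", "se_mean", "se_sd",
                        "hg_mean", "hg_sd")[i]]] <- as.numeric(specs[, i])
  out
}

#' Default population intake rates (g/day)
#'
#' Per-category mean daily intake rates back-solved from the published
#' population selenium intakes divided by the category mean Se
#' concentrations (only intakes combined with concentrations, not the raw
#' food-frequency rates, are published).
#'
#' @return Named numeric vector, g/day per category.
#' @export
default_intake_means <- function() {
  edi_se <- c("Eggs" = 17.37, "Fish" = 9.41, "Fruits" = 0.24,
              "Grains and related products" = 15.79,
              "Leafy vegetables" = 0.71,
              "Legumes and related products" = 3.26,
              "Meat and meat products" = 12.63,
              "Milk and dairy products" = 17.99,
              "Non-leafy vegetables" = 1.86, "Rice" = 1.37,
              "Shellfish" = 3.24)
  specs <- default_food_specs()
  se_mean <- vapply(names(edi_se), function(cc) {
    rows <- specs[specs$category == cc, ]
    sum(rows$se_mean * rows$n_samples) / sum(rows$n_samples)
  }, numeric(1))
  edi_se / se_mean
}

#' Generate a synthetic food panel
#'
#' Per spec row, `n_samples` independent lognormal draws for Se and Hg
#' (optionally log-scale correlated), moment-matched to the spec mean/SD.
#' Deterministic under a fixed seed.
#'
#' @param specs Spec table as from [default_food_specs()].
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @param log_correlation Correlation between log-Se and log-Hg within a
#'   category (0 = independent, the default; the real dependence is
#'   unknown, so it is exposed only for sensitivity analyses).
#' @return Food-sample `data.frame` as from [read_food_samples()].
#' @export
gen_food_panel <- function(specs = default_food_specs(), seed = NULL,
                           log_correlation = 0) {
  stopifnot(abs(log_correlation) <= 1)
  local_seed(seed, {
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      sp <- specs[i, ]
      n <- sp$n_samples
      pse <- lognormal_params_from_moments(sp$se_mean, sp$se_sd)
      phg <- lognormal_params_from_moments(sp$hg_mean, sp$hg_sd)
      z1 <- stats::rnorm(n)
      z2 <- log_correlation * z1 +
        sqrt(1 - log_correlation^2) * stats::rnorm(n)
      data.frame(category = sp$category, subcategory = sp$subcategory,
                 se_conc = exp(pse$mu + pse$sigma * z1),
                 hg_conc = exp(phg$mu + phg$sigma * z2),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(out))), out)
    out$se_nondetect <- FALSE
    out$hg_nondetect <- FALSE
    out
  })
}

#' Synthetic LMS growth-reference table
#'
#' Smooth L, M, S curves over 0-72 months for both sexes and both measures,
#' shaped like a child growth standard (median weight ~14 kg and height
#' ~92 cm near age 3): weight medians follow `a + b * sqrt(months)` with a
#' mildly negative Box-Cox power and CV ~0.12; height medians follow a
#' power curve with `L = 1` and CV ~0.04. Synthetic: it supports testing
#' without reference-table downloads, and a real WHO table in the same
#' layout drops in unchanged.
#'
#' @param age_months Grid of tabulated ages.
#' @return LMS `data.frame` as from [read_lms_table()].
#' @export
synthetic_lms_table <- function(age_months = 0:72) {
  a <- age_months
  rows <- list()
  for (sx in c("male", "female")) {
    w0 <- if (sx == "male") 3.3 else 3.2
    wb <- if (sx == "male") 1.85 else 1.78
    h0 <- if (sx == "male") 50.0 else 49.3
    hb <- if (sx == "male") 6.2 else 6.1
    rows[[paste0(sx, "_w")]] <- data.frame(
      sex = sx, age_months = a, measure = "weight",
      L = 0.35 - 0.5 * a / 72,
      M = w0 + wb * sqrt(a),
      S = 0.11 + 0.02 * a / 72, stringsAsFactors = FALSE)
    rows[[paste0(sx, "_h")]] <- data.frame(
      sex = sx, age_months = a, measure = "height",
      L = 1,
      M = h0 + hb * a^0.55,
      S = 0.035 + 0.005 * a / 72, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic child cohort with intakes
#'
#' Children: ages uniform over `age_range` (default centred on a 2.9-year
#' mean), sex Bernoulli (54 percent male), hair mercury lognormal
#' moment-matched to (1.11, 1.15) ug/g, income band and maternal parity
#' drawn from the cohort's observed proportions. Each child carries latent
#' standard-normal weight and height scores; weight and height are produced
#' by inverting the LMS reference at the child's age, so the z-score stage
#' recovers the latent scores exactly. Intakes: per category, gamma draws
#' with the given CV around the mean rates. Deterministic under a fixed
#' seed.
#'
#' @param n_children Cohort size.
#' @param seed Integer seed (or `NULL`).
#' @param lms_table LMS reference used to realize weights and heights.
#' @param hair_hg_mean,hair_hg_sd Hair-Hg moments, ug/g.
#' @param intake_means Named vector of mean intake rates, g/day.
#' @param intake_cv Coefficient of variation of the gamma intake draws.
#' @param age_range Age range in years (uniform draw).
#' @param p_male Probability of male sex.
#' @return `list(children, intakes, truth)`; `truth` records the latent
#'   z-scores and every generating parameter.
#' @export
gen_cohort <- function(n_children = 349, seed = NULL,
                       lms_table = synthetic_lms_table(),
                       hair_hg_mean = 1.11, hair_hg_sd = 1.15,
                       intake_means = default_intake_means(),
                       intake_cv = 0.5,
                       age_range = c(0.3, 5.5), p_male = 0.54) {
  stopifnot(n_children >= 1, intake_cv >= 0)
  rng <- range(lms_table$age_months) / 12
  if (age_range[1] < rng[1] || age_range[2] > rng[2])
    stop("LMS table range narrower than requested ages.", call. = FALSE)
  local_seed(seed, {
    id <- sprintf("C%04d", seq_len(n_children))
    age <- stats::runif(n_children, age_range[1], age_range[2])
    sex <- ifelse(stats::runif(n_children) < p_male, "male", "female")
    hair <- rlnorm_moments(n_children, hair_hg_mean, hair_hg_sd)
    income <- sample(c("<2300", "2300-3300", ">3300"), n_children,
                     replace = TRUE, prob = c(0.289, 0.289, 0.422))
    parity <- sample(c(1L, 2L, 3L), n_children, replace = TRUE,
                     prob = c(0.605, 0.345, 0.05))
    z_w <- stats::rnorm(n_children)
    z_h <- stats::rnorm(n_children)
    months <- age * 12
    weight <- height <- numeric(n_children)
    for (sx in c("male", "female")) {
      sel <- sex == sx
      if (!any(sel)) next
      w <- interpolate_lms(lms_table, sx, "weight", months[sel])
      h <- interpolate_lms(lms_table, sx, "height", months[sel])
      weight[sel] <- lms_invert(z_w[sel], w$L, w$M, w$S)
      height[sel] <- lms_invert(z_h[sel], h$L, h$M, h$S)
    }
    children <- data.frame(
      child_id = id, sex = sex, age = age, weight = weight, height = height,
      hair_hg = hair, income_band = income, parity = parity,
      age_at_measurement = age, stringsAsFactors = FALSE)
    shape <- if (intake_cv > 0) 1 / intake_cv^2 else Inf
    intakes <- do.call(rbind, lapply(names(intake_means), function(cc) {
      m <- intake_means[[cc]]
      rate <- if (intake_cv == 0 || m == 0) rep(m, n_children)
              else stats::rgamma(n_children, shape = shape,
                                 scale = m / shape)
      data.frame(child_id = id, category = cc, intake_rate = rate,
                 stringsAsFactors = FALSE)
    }))
    truth <- list(seed = seed, n_children = n_children,
                  hair_hg_mean = hair_hg_mean, hair_hg_sd = hair_hg_sd,
                  intake_means = as.list(intake_means),
                  intake_cv = intake_cv, age_range = age_range,
                  p_male = p_male, latent_waz = z_w, latent_haz = z_h)
    list(children = children, intakes = intakes, truth = truth)
  })
}

#' Generate growth outcomes with known regression truth
#'
#' `outcome = intercept + sum_c beta_c * net_ai_c + covariate effects +
#' N(0, noise_sd)`, where the `net_ai_*` exposure columns must already be
#' present on `children` (see [net_ai_exposures()]). Default truth betas
#' carry the published effect scale (0.01 outcome units per net-AI
#' percentage point for fish and eggs, -0.41 for fruits). All generating
#' coefficients are returned as the truth record.
#'
#' @param children Child table with exposure columns.
#' @param true_betas Named vector: `net_ai_*` column name -> slope.
#' @param covariate_effects Named list of additive effects: `hg_high`
#'   (added when hair Hg exceeds `hair_cutoff`), `male`, `age` (per year).
#' @param intercept Outcome intercept.
#' @param noise_sd Residual SD (>= 0), outcome units.
#' @param outcome Name of the generated column.
#' @param hair_cutoff Hair-Hg cutoff used for the `hg_high` effect, ug/g.
#' @param seed Integer seed (or `NULL`).
#' @return `list(children, truth)` with the outcome column added.
#' @export
gen_outcomes <- function(children,
                         true_betas = c(net_ai_fish = 0.01,
                                        net_ai_eggs = 0.01,
                                        net_ai_fruits = -0.41),
                         covariate_effects = list(hg_high = -0.1,
                                                  male = 0.05, age = 0),
                         intercept = 0, noise_sd = 0.5,
                         outcome = "haz_outcome",
                         hair_cutoff = 1.0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  missing_cols <- setdiff(names(true_betas), names(children))
  if (length(missing_cols) > 0)
    stop("Exposure column(s) absent from children: ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  local_seed(seed, {
    y <- rep(intercept, nrow(children))
    for (cc in names(true_betas)) y <- y + true_betas[[cc]] * children[[cc]]
    if (!is.null(covariate_effects$hg_high))
      y <- y + covariate_effects$hg_high * (children$hair_hg > hair_cutoff)
    if (!is.null(covariate_effects$male))
      y <- y + covariate_effects$male * (children$sex == "male")
    if (!is.null(covariate_effects$age))
      y <- y + covariate_effects$age * children$age
    y <- y + stats::rnorm(nrow(children), 0, noise_sd)
    children[[outcome]] <- y
    truth <- list(true_betas = as.list(true_betas),
                  covariate_effects = covariate_effects,
                  intercept = intercept, noise_sd = noise_sd,
                  outcome = outcome, seed = seed)
    list(children = children, truth = truth)
  })
}

#' Simulate a full synthetic study to disk
#'
#' Generates a food panel, LMS reference, cohort with intakes, exposure
#' columns and growth outcomes, and writes `foods.csv`, `children.csv`,
#' `intakes.csv`, `lms.csv` and `truth.json` to `out_dir`. Byte-identical
#' output under a fixed seed.
#'
#' @param n_children Cohort size.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if absent).
#' @param config A [study_config()].
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(n_children = 349, seed = 1,
                           out_dir = ".", config = study_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  foods <- gen_food_panel(seed = seed)
  lms <- synthetic_lms_table()
  cohort <- gen_cohort(n_children = n_children, seed = seed + 1,
                       lms_table = lms)
  summaries <- summarize_food_panel(foods, config)
  children <- net_ai_exposures(cohort$children, cohort$intakes, summaries,
                               config)
  out <- gen_outcomes(children, seed = seed + 2)
  truth <- c(cohort$truth["seed" != names(cohort$truth)],
             list(cohort_seed = seed + 1, panel_seed = seed,
                  outcome_seed = seed + 2), out$truth)
  truth$latent_waz <- NULL; truth$latent_haz <- NULL
  utils::write.csv(foods, file.path(out_dir, "foods.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(out$children, file.path(out_dir, "children.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(cohort$intakes, file.path(out_dir, "intakes.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(lms, file.path(out_dir, "lms.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(foods = foods, lms = lms, children = out$children,
                 intakes = cohort$intakes, summaries = summaries,
                 truth = truth))
}
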