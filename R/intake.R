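#' Estimated daily intake of an element through one food
#'
#' `EDI = C_i * IR_i / BW`. With the concentration in mg/kg and the intake
#' rate in g/day, `C_i * IR_i` is in ug/day, so the body-weight-normalized
#' value comes out in ug/kg-BW/day directly.
#'
#' @param conc Element concentration in the food, mg/kg wet weight.
#' @param intake_rate Daily intake rate, g/day.
#' @param bw Body weight, kg (> 0).
#' @return `data.frame(edi_total, edi_bw)`: ug/day and ug/kg-BW/day.
#' @export
#' @examples
#' edi(0.078, 24.2, 13.87)
edi <- function(conc, intake_rate, bw) {
  if (any(bw <= 0)) stop("Body weight must be positive.", call. = FALSE)
  if (any(conc < 0) || any(intake_rate < 0))
    stop("conc and intake_rate must be nonnegative.", call. = FALSE)
  total <- conc * intake_rate
  data.frame(edi_total = total, edi_bw = total / bw)
}

#' Percentage of the selenium adequate intake
#'
#' `100 * edi_se_total / ai`. Also applied to the net (Hg-corrected)
#' selenium intake, where it can be negative.
#'
#' @param edi_se_total Selenium intake, ug/day (may be negative when net).
#' @param ai Adequate intake, ug/day (> 0).
#' @return Percentage of the AI.
#' @export
#' @examples
#' ai_percent(3.24, 20)  # 16.2
ai_percent <- function(edi_se_total, ai) {
  if (any(ai <= 0)) stop("Adequate intake must be positive.", call. = FALSE)
  100 * edi_se_total / ai
}

#' Net selenium intake after mercury
#'
#' Mass-based difference `edi_se - edi_hg` (ug/day), the exposure variable
#' of the growth models. An optional molar-equivalent mode instead subtracts
#' the selenium mass stoichiometrically bound by the ingested mercury,
#' `edi_hg * (M_Se / M_Hg)`; the published tables are mass-based, so this is
#' off by default.
#'
#' @param edi_se_total,edi_hg_total Elemental intakes, ug/day (>= 0).
#' @param molar_equivalent Subtract the Se mass equivalent of the Hg moles
#'   rather than the Hg mass itself.
#' @param config A [study_config()] (molar masses, used only in
#'   molar-equivalent mode).
#' @return Net selenium, ug/day; may be negative.
#' @export
net_se <- function(edi_se_total, edi_hg_total, molar_equivalent = FALSE,
                   config = study_config()) {
  if (any(edi_se_total < 0) || any(edi_hg_total < 0))
    stop("Intakes must be nonnegative.", call. = FALSE)
  hg_term <- if (molar_equivalent)
    edi_hg_total * config$molar_mass_se / config$molar_mass_hg
  else edi_hg_total
  edi_se_total - hg_term
}

#' Hazard quotient
#'
#' `HQ = EDI / RfD` on body-weight-normalized intakes; values strictly
#' above 1 flag a potential non-carcinogenic risk.
#'
#' @param edi_bw Intake, ug/kg-BW/day.
#' @param rfd Reference dose, ug/kg-BW/day (> 0); the JECFA dietary Hg RfD
#'   is 0.23 ug/kg-BW/day ([study_config()] key `rfd_hg_jecfa`).
#' @return `data.frame(hq, risk)` with `risk = hq > 1`.
#' @export
#' @examples
#' hazard_quotient(0.1361, 0.23)
hazard_quotient <- function(edi_bw, rfd) {
  if (any(rfd <= 0)) stop("Reference dose must be positive.", call. = FALSE)
  if (any(edi_bw < 0)) stop("EDI must be nonnegative.", call. = FALSE)
  hq <- edi_bw / rfd
  data.frame(hq = hq, risk = hq > 1)
}

#' Maximum safe daily intake of a food (CR_lim)
#'
#' `CR_lim = RfD * BW / C_i`, converted to g/day. Uses the US EPA reference
#' doses in mg/kg/day (Hg 0.0001, Se 0.005), never the JECFA
#' hazard-quotient dose.
#'
#' @param rfd Reference dose, mg/kg/day (>= 0).
#' @param bw Body weight, kg.
#' @param conc Element concentration in the food, mg/kg (> 0).
#' @return Safe daily intake, g/day.
#' @export
#' @examples
#' cr_lim(0.0001, 13.87, 0.093)  # ~14.9 g/day of marine fish
cr_lim <- function(rfd, bw, conc) {
  if (any(conc <= 0))
    stop("Concentration must be positive (limit unbounded otherwise).",
         call. = FALSE)
  if (any(rfd < 0) || any(bw <= 0))
    stop("rfd must be nonnegative and bw positive.", call. = FALSE)
  rfd * bw / conc * 1000
}

#' Monthly safe consumption limit in portions (CR_mm)
#'
#' `CR_mm = CR_lim * T / MS`: the daily limit accumulated over the
#' averaging period T (days/month) and divided by the portion size.
#' Portions are either Taiwan exchange servings (g/serving) or the US EPA
#' child fish meal (65 g/meal).
#'
#' @param cr_lim Daily limit, g/day.
#' @param days Averaging period, days/month.
#' @param portion Portion size, g (> 0).
#' @return Portions per month.
#' @export
#' @examples
#' cr_mm(31.52, 30.44, 65)  # ~14.8 freshwater-fish meals/month
cr_mm <- function(cr_lim, days, portion) {
  if (any(portion <= 0)) stop("Portion size must be positive.", call. = FALSE)
  if (any(cr_lim < 0) || any(days <= 0))
    stop("cr_lim must be nonnegative and days positive.", call. = FALSE)
  cr_lim * days / portion
}

#' Daily servings of a food needed to meet the selenium adequate intake
#'
#' `AI / (C * serving)` with the concentration in mg/kg (= ug/g) and the
#' serving in g. For foods eaten in whole practical units (an egg), set
#' `whole_units = TRUE` to apply a ceiling to the exact value.
#'
#' @param ai Adequate intake, ug/day.
#' @param conc Selenium concentration, mg/kg (> 0).
#' @param serving Serving size, g (> 0).
#' @param whole_units Round up to whole servings for presentation.
#' @return Servings per day (exact real number unless `whole_units`).
#' @export
#' @examples
#' servings_to_meet_ai(20, 0.309, 35)          # ~1.8 freshwater-fish servings
#' servings_to_meet_ai(20, 0.521, 60, TRUE)    # one egg
servings_to_meet_ai <- function(ai, conc, serving, whole_units = FALSE) {
  if (any(ai <= 0)) stop("ai must be positive.", call. = FALSE)
  if (any(conc <= 0) || any(serving <= 0))
    stop("conc and serving must be positive.", call. = FALSE)
  s <- ai / (conc * serving)
  if (whole_units) ceiling(s) else s
}

#' Scale a per-serving nutrient profile to the servings meeting the Se AI
#'
#' Pure elementwise scaling of per-serving nutrient amounts by the number of
#' servings; no recomposition or interaction between nutrients.
#'
#' @param servings Servings per day (>= 0).
#' @param nutrient_table Named numeric vector or one-row `data.frame` of
#'   per-serving amounts (>= 0).
#' @return Scaled amounts per day, same shape and names.
#' @export
#' @examples
#' nutrient_profile_at_ai(1.85, c(protein_g = 7, dha_mg = 100))
nutrient_profile_at_ai <- function(servings, nutrient_table) {
  vals <- unlist(nutrient_table)
  if (any(vals < 0)) stop("Nutrient amounts must be nonnegative.",
                          call. = FALSE)
  if (any(servings < 0)) stop("servings must be nonnegative.", call. = FALSE)
  out <- vals * servings
  if (is.data.frame(nutrient_table))
    as.data.frame(as.list(out), optional = TRUE)
  else out
}

# Population mean intake rate per category from the long intake table.
# Children without a row for a category are counted as zero intake.
population_intake_means <- function(intakes) {
  children <- unique(intakes$child_id)
  agg <- stats::aggregate(intake_rate ~ category, data = intakes, FUN = sum)
  agg$intake_rate <- agg$intake_rate / length(children)
  agg
}

#' Population-level intake assessment per food category
#'
#' The published-table computation: per category, the selenium and mercury
#' EDIs (ug/day and ug/kg-BW/day), the percentage of the selenium AI met,
#' the net selenium after mercury with its AI percentage, and the mercury
#' hazard quotient against the JECFA reference dose.
#'
#' Two aggregation modes are exposed because cohort tables can be built
#' either way: `"population"` (default) multiplies the category mean
#' concentration by the population mean intake rate; `"per_child"` computes
#' each child's EDI first (with per-child body weight if a `children` table
#' is given) and averages across children.
#'
#' @param summaries Category summaries from [summarize_food_panel()].
#' @param intakes Long intake table (see [read_intake_records()]).
#' @param config A [study_config()].
#' @param mode `"population"` or `"per_child"`.
#' @param children Optional child table supplying per-child body weights in
#'   `"per_child"` mode; otherwise `config$default_bw` is used throughout.
#' @return `data.frame` with one row per category: `edi_se_total`,
#'   `ai_pct`, `edi_hg_total`, `net_se`, `net_ai_pct`, `edi_se_bw`,
#'   `edi_hg_bw`, `hq_hg`, `hq_risk`.
#' @export
assess_population_intake <- function(summaries, intakes,
                                     config = study_config(),
                                     mode = c("population", "per_child"),
                                     children = NULL) {
  mode <- match.arg(mode)
  cats <- intersect(summaries$category, unique(intakes$category))
  conc <- summaries[match(cats, summaries$category), ]
  if (mode == "population") {
    means <- population_intake_means(intakes)
    ir <- means$intake_rate[match(cats, means$category)]
    ir[is.na(ir)] <- 0
    e_se <- edi(conc$se_mass_mean, ir, config$default_bw)
    e_hg <- edi(conc$hg_mass_mean, ir, config$default_bw)
    edi_se_total <- e_se$edi_total; edi_se_bw <- e_se$edi_bw
    edi_hg_total <- e_hg$edi_total; edi_hg_bw <- e_hg$edi_bw
  } else {
    ids <- unique(intakes$child_id)
    bw <- rep(config$default_bw, length(ids))
    if (!is.null(children)) {
      m <- match(ids, children$child_id)
      if (anyNA(m)) stop("Intake table has child_id absent from the child ",
                         "table.", call. = FALSE)
      bw <- children$weight[m]
    }
    per_cat <- function(cc) {
      rows <- intakes[intakes$category == cc, ]
      ir <- rows$intake_rate[match(ids, rows$child_id)]
      ir[is.na(ir)] <- 0
      i <- match(cc, conc$category)
      e_se <- edi(conc$se_mass_mean[i], ir, bw)
      e_hg <- edi(conc$hg_mass_mean[i], ir, bw)
      c(mean(e_se$edi_total), mean(e_se$edi_bw),
        mean(e_hg$edi_total), mean(e_hg$edi_bw))
    }
    m <- vapply(cats, per_cat, numeric(4))
    edi_se_total <- m[1, ]; edi_se_bw <- m[2, ]
    edi_hg_total <- m[3, ]; edi_hg_bw <- m[4, ]
  }
  net <- net_se(edi_se_total, edi_hg_total, config = config)
  hq <- hazard_quotient(edi_hg_bw, config$rfd_hg_jecfa)
  data.frame(category = cats,
             edi_se_total = edi_se_total,
             ai_pct = ai_percent(edi_se_total, config$ai_se),
             edi_hg_total = edi_hg_total,
             net_se = net,
             net_ai_pct = 100 * net / config$ai_se,
             edi_se_bw = edi_se_bw, edi_hg_bw = edi_hg_bw,
             hq_hg = hq$hq, hq_risk = hq$risk,
             stringsAsFactors = FALSE)
}

#' Safe consumption limits per category and element
#'
#' For each category summary and each element (Hg against the US EPA
#' mercury reference dose, Se against the selenium one): the daily limit
#' CR_lim (g/day), its translation into exchange servings per month, and --
#' for fish rows only -- into US EPA 65-g fish meals per month.
#'
#' @param summaries Category summaries from [summarize_food_panel()]
#'   (mean concentrations are the `C_i` of the limit formula).
#' @param config A [study_config()].
#' @param bw Body weight, kg; defaults to `config$default_bw`.
#' @return `data.frame(category, element, conc, cr_lim, serving_g,
#'   cr_mm_servings, cr_mm_meals)`; `cr_mm_meals` is `NA` for non-fish rows.
#' @export
consumption_limits <- function(summaries, config = study_config(),
                               bw = config$default_bw) {
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    if (identical(s$category, "Total")) return(NULL)
    is_fish <- s$category %in%
      c("Fish", "Marine fish", "Freshwater fish")
    serving <- config$serving_sizes[[s$category]]
    if (is.null(serving)) serving <- config$serving_sizes[["Fish"]]
    one <- function(element, rfd, conc) {
      if (conc <= 0) return(NULL)
      lim <- cr_lim(rfd, bw, conc)
      data.frame(category = s$category, element = element, conc = conc,
                 cr_lim = lim, serving_g = serving,
                 cr_mm_servings = cr_mm(lim, config$days_per_month, serving),
                 cr_mm_meals = if (is_fish)
                   cr_mm(lim, config$days_per_month,
                         config$epa_meal_size * 1000) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    rbind(one("Hg", config$rfd_hg_epa, s$hg_mass_mean),
          one("Se", config$rfd_se_epa, s$se_mass_mean))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
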