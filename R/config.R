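#' Controlled vocabulary of food categories
#'
#' The eleven food-category labels used throughout the package, matching the
#' grouping of the underlying food survey. Fish may additionally carry a
#' `marine` / `freshwater` subcategory (see [read_food_samples()]).
#'
#' @return Character vector of the eleven category labels.
#' @export
#' @examples
#' food_categories()
food_categories <- function() {
  c("Eggs", "Fish", "Fruits", "Grains and related products",
    "Leafy vegetables", "Legumes and related products",
    "Meat and meat products", "Milk and dairy products",
    "Non-leafy vegetables", "Rice", "Shellfish")
}

#' @rdname food_categories
#' @export
fish_subcategories <- function() c("marine", "freshwater")

# Case-insensitive category matcher. Accepts the 11 canonical labels plus
# "Marine fish" / "Freshwater fish", which map to Fish with the subcategory
# filled in. Returns a data.frame(category, subcategory).
match_category <- function(x) {
  canon <- food_categories()
  x_trim <- trimws(x)
  key <- tolower(x_trim)
  idx <- match(key, tolower(canon))
  sub <- rep(NA_character_, length(x))
  fish_alias <- match(key, c("marine fish", "freshwater fish"))
  idx[!is.na(fish_alias)] <- match("Fish", canon)
  sub[!is.na(fish_alias)] <- fish_subcategories()[fish_alias[!is.na(fish_alias)]]
  if (anyNA(idx)) {
    bad <- unique(x_trim[is.na(idx)])
    stop("Unknown food category: ", paste(sQuote(bad), collapse = ", "),
         ". Valid labels are: ", paste(canon, collapse = ", "),
         " (plus 'Marine fish'/'Freshwater fish').", call. = FALSE)
  }
  data.frame(category = canon[idx], subcategory = sub,
             stringsAsFactors = FALSE)
}

#' Default exchange serving sizes (g/serving)
#'
#' Ministry-of-Health-and-Welfare-style exchange portions used to translate a
#' daily safe intake (g/day) into servings per month. Fish and egg values
#' (35 g and 60 g) are anchored to the published monthly-limit figures; the
#' remaining categories carry conventional exchange portions and are
#' user-overridable through the config.
#'
#' @return Named numeric vector, g/serving, one entry per category plus the
#'   marine/freshwater fish sub-labels.
#' @export
default_serving_sizes <- function() {
  c("Eggs" = 60, "Fish" = 35, "Marine fish" = 35, "Freshwater fish" = 35,
    "Shellfish" = 35, "Meat and meat products" = 35,
    "Milk and dairy products" = 240, "Leafy vegetables" = 100,
    "Non-leafy vegetables" = 100, "Fruits" = 100,
    "Grains and related products" = 20,
    "Legumes and related products" = 20, "Rice" = 40)
}

#' Assessment constants
#'
#' Builds the configuration object carrying every constant of the
#' assessment: atomic molar masses, the EFSA adequate selenium intake for
#' preschool children, the two mercury reference doses (the JECFA dose used
#' for hazard quotients and the US-EPA dose used for consumption limits; the
#' two are never interchangeable), the US-EPA selenium reference dose,
#' portion-size conventions, the default child body weight, the hair-mercury
#' exposure cutoff, and nondetect-substitution rules.
#'
#' @param molar_mass_se Selenium molar mass, g/mol.
#' @param molar_mass_hg Mercury molar mass, g/mol.
#' @param ai_se EFSA adequate intake of Se for preschool children, ug/day.
#' @param rfd_hg_jecfa JECFA dietary Hg reference dose, ug/kg-BW/day
#'   (hazard-quotient denominator).
#' @param rfd_hg_epa US EPA Hg reference dose, mg/kg/day (consumption-limit
#'   numerator).
#' @param rfd_se_epa US EPA Se reference dose, mg/kg/day.
#' @param days_per_month Averaging period T, days/month.
#' @param epa_meal_size US EPA child fish meal size, kg/meal.
#' @param default_bw Default child body weight, kg.
#' @param hair_cutoff Hair-Hg high/low exposure cutoff, ug/g.
#' @param nondetect_factor Fraction of the detection limit substituted for
#'   below-detection concentrations (default 1/2).
#' @param mdl_se,mdl_hg Method detection limits for Se and Hg in food,
#'   mg/kg wet weight, used when a cell reads `<MDL`.
#' @param serving_sizes Named numeric vector of exchange serving sizes,
#'   g/serving; entries override [default_serving_sizes()] per category.
#'
#' @return A validated list of class `study_config`.
#' @seealso [load_config()] to read overrides from a YAML/JSON file.
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$ai_se
study_config <- function(molar_mass_se = 78.971,
                         molar_mass_hg = 200.59,
                         ai_se = 20,
                         rfd_hg_jecfa = 0.23,
                         rfd_hg_epa = 0.0001,
                         rfd_se_epa = 0.005,
                         days_per_month = 30.44,
                         epa_meal_size = 0.065,
                         default_bw = 13.87,
                         hair_cutoff = 1.0,
                         nondetect_factor = 0.5,
                         mdl_se = 3e-5,
                         mdl_hg = 9e-6,
                         serving_sizes = NULL) {
  sizes <- default_serving_sizes()
  if (!is.null(serving_sizes)) {
    serving_sizes <- unlist(serving_sizes)
    sizes[names(serving_sizes)] <- serving_sizes
  }
  cfg <- structure(list(
    molar_mass_se = molar_mass_se, molar_mass_hg = molar_mass_hg,
    ai_se = ai_se, rfd_hg_jecfa = rfd_hg_jecfa, rfd_hg_epa = rfd_hg_epa,
    rfd_se_epa = rfd_se_epa, days_per_month = days_per_month,
    epa_meal_size = epa_meal_size, default_bw = default_bw,
    hair_cutoff = hair_cutoff, nondetect_factor = nondetect_factor,
    mdl_se = mdl_se, mdl_hg = mdl_hg, serving_sizes = sizes),
    class = "study_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  positive <- c("molar_mass_se", "molar_mass_hg", "ai_se", "rfd_hg_jecfa",
                "rfd_hg_epa", "rfd_se_epa", "days_per_month",
                "epa_meal_size", "default_bw", "mdl_se", "mdl_hg")
  for (key in positive) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("Config key ", sQuote(key), " must be a single positive number, got ",
           deparse(v), call. = FALSE)
  }
  if (!is.numeric(cfg$hair_cutoff) || cfg$hair_cutoff < 0)
    stop("Config key 'hair_cutoff' must be nonnegative.", call. = FALSE)
  if (!is.numeric(cfg$nondetect_factor) || cfg$nondetect_factor < 0 ||
      cfg$nondetect_factor > 1)
    stop("Config key 'nondetect_factor' must lie in [0, 1].", call. = FALSE)
  if (cfg$days_per_month <= 28 || cfg$days_per_month >= 32)
    stop("Config key 'days_per_month' must lie in (28, 32).", call. = FALSE)
  if (any(!is.finite(cfg$serving_sizes)) || any(cfg$serving_sizes < 0))
    stop("Config key 'serving_sizes' entries must be nonnegative numbers.",
         call. = FALSE)
  cfg
}

#' Read assessment constants from a YAML or JSON file
#'
#' Keys absent from the file keep their [study_config()] defaults; an empty
#' file yields the full default configuration. `serving_sizes` entries merge
#' per category. Unknown keys and invalid values fail with a message naming
#' the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` key-value file.
#' @return A validated `study_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("Config file must parse to a key-value mapping.",
                          call. = FALSE)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("Unknown config key(s): ", paste(sQuote(unknown), collapse = ", "),
         call. = FALSE)
  do.call(study_config, raw)
}

# Serving size lookup honouring the marine/freshwater sub-labels.
serving_size_for <- function(cfg, category, subcategory = NA_character_) {
  key <- category
  if (identical(category, "Fish") && !is.na(subcategory)) {
    key <- paste0(toupper(substring(subcategory, 1, 1)),
                  substring(subcategory, 2), " fish")
  }
  s <- cfg$serving_sizes[[key]]
  if (is.null(s) || is.na(s)) s <- cfg$serving_sizes[[category]]
  if (is.null(s) || is.na(s))
    stop("No serving size configured for category ", sQuote(key), call. = FALSE)
  s
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  scalars <- x[setdiff(names(x), "serving_sizes")]
  for (k in names(scalars)) cat(sprintf("  %-17s %s\n", k, format(scalars[[k]])))
  cat("  serving sizes (g):",
      paste(sprintf("%s=%g", names(x$serving_sizes), x$serving_sizes),
            collapse = ", "), "\n")
  invisible(x)
}
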