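# Readers and writers for the pipeline's CSV tables. All tables are UTF-8,
# comma-separated with a header row and decimal points (comma decimals are
# rejected as malformed numbers).

# Strict numeric parser: NA for anything that is not a plain decimal number.
parse_number_strict <- function(x) {
  x <- trimws(x)
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  out <- rep(NA_real_, length(x))
  out[ok] <- as.numeric(x[ok])
  out
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(what, " is missing required column(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  invisible(df)
}

# Parse one concentration column, handling nondetects written as "<MDL" or
# "<0.05". Returns list(value, nondetect); nondetects are substituted by
# nondetect_factor * limit but keep their flag for auditability.
parse_concentration <- function(x, mdl, factor, column) {
  x <- trimws(as.character(x))
  nondetect <- grepl("^<", x)
  value <- rep(NA_real_, length(x))
  value[!nondetect] <- parse_number_strict(x[!nondetect])
  if (any(nondetect)) {
    lim_txt <- sub("^<\\s*", "", x[nondetect])
    lim <- ifelse(toupper(lim_txt) == "MDL", mdl, parse_number_strict(lim_txt))
    value[nondetect] <- factor * lim
  }
  bad <- which(is.na(value))
  if (length(bad) > 0)
    stop("Malformed number in column ", sQuote(column), ", row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(sQuote(x[bad]), collapse = ", "), call. = FALSE)
  if (any(value < 0))
    stop("Negative concentration in column ", sQuote(column), call. = FALSE)
  list(value = value, nondetect = nondetect)
}

#' Read a food-sample table
#'
#' Expects columns `sample_id`, `category`, `se_conc`, `hg_conc`
#' (concentrations in mg/kg wet weight) and optionally `subcategory`
#' (`marine`/`freshwater`, fish only) and `feeding_habit`. Categories are
#' matched case-insensitively against [food_categories()]; an unknown label
#' fails with the list of valid ones. Concentration cells may read `<MDL`
#' or `<limit`; these are flagged as nondetects and substituted by
#' `nondetect_factor` times the limit (config `mdl_se`/`mdl_hg` when the
#' cell says `MDL`).
#'
#' @param path CSV file path.
#' @param config A [study_config()] (controls nondetect substitution).
#' @return `data.frame` with columns `sample_id`, `category`, `subcategory`,
#'   `se_conc`, `hg_conc`, `se_nondetect`, `hg_nondetect`.
#' @export
read_food_samples <- function(path, config = study_config()) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  require_columns(df, c("sample_id", "category", "se_conc", "hg_conc"),
                  "Food-sample table")
  if (anyDuplicated(df$sample_id))
    stop("Duplicate sample_id: ",
         paste(sQuote(unique(df$sample_id[duplicated(df$sample_id)])),
               collapse = ", "), call. = FALSE)
  cat_match <- match_category(df$category)
  sub <- cat_match$subcategory
  if ("subcategory" %in% names(df)) {
    explicit <- tolower(trimws(df$subcategory))
    explicit[explicit %in% c("", "na")] <- NA_character_
    bad <- !is.na(explicit) & !explicit %in% fish_subcategories()
    if (any(bad))
      stop("Invalid subcategory (use 'marine' or 'freshwater'): ",
           paste(sQuote(unique(df$subcategory[bad])), collapse = ", "),
           call. = FALSE)
    sub <- ifelse(is.na(explicit), sub, explicit)
  }
  se <- parse_concentration(df$se_conc, config$mdl_se,
                            config$nondetect_factor, "se_conc")
  hg <- parse_concentration(df$hg_conc, config$mdl_hg,
                            config$nondetect_factor, "hg_conc")
  out <- data.frame(sample_id = df$sample_id,
                    category = cat_match$category,
                    subcategory = sub,
                    se_conc = se$value, hg_conc = hg$value,
                    se_nondetect = se$nondetect, hg_nondetect = hg$nondetect,
                    stringsAsFactors = FALSE)
  if ("feeding_habit" %in% names(df)) out$feeding_habit <- df$feeding_habit
  out
}

#' Read per-child daily intake rates
#'
#' Expects columns `child_id`, `category`, `intake_rate` (g/day). The
#' (`child_id`, `category`) pair must be unique and rates nonnegative.
#'
#' @param path CSV file path.
#' @return `data.frame(child_id, category, intake_rate)`.
#' @export
read_intake_records <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  require_columns(df, c("child_id", "category", "intake_rate"),
                  "Intake table")
  cat_match <- match_category(df$category)
  rate <- parse_number_strict(df$intake_rate)
  if (anyNA(rate))
    stop("Malformed intake_rate in row(s) ",
         paste(which(is.na(rate)), collapse = ", "), call. = FALSE)
  if (any(rate < 0)) stop("intake_rate must be nonnegative.", call. = FALSE)
  key <- paste(df$child_id, cat_match$category, sep = "\r")
  if (anyDuplicated(key))
    stop("Duplicate (child_id, category) pair(s) in intake table.",
         call. = FALSE)
  data.frame(child_id = df$child_id, category = cat_match$category,
             intake_rate = rate, stringsAsFactors = FALSE)
}

#' Read child records
#'
#' Expects columns `child_id`, `sex` (`male`/`female`), `age` (years),
#' `weight` (kg), `height` (cm), `hair_hg` (ug/g), and optionally
#' `income_band`, `parity`, `age_at_measurement` (defaults to `age`).
#' Ages must lie in \[0, 7), weight/height/hair positive, parity >= 1.
#'
#' @param path CSV file path.
#' @return Validated `data.frame` of child records.
#' @export
read_child_records <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  require_columns(df, c("child_id", "sex", "age", "weight", "height",
                        "hair_hg"), "Child table")
  df$sex <- tolower(trimws(df$sex))
  if (!all(df$sex %in% c("male", "female")))
    stop("Column 'sex' must be 'male' or 'female'.", call. = FALSE)
  for (col in c("age", "weight", "height", "hair_hg"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$age < 0 | df$age >= 7))
    stop("Child age must lie in [0, 7) years.", call. = FALSE)
  if (any(df$weight <= 0 | df$height <= 0 | df$hair_hg <= 0))
    stop("weight, height and hair_hg must be positive.", call. = FALSE)
  if (!"age_at_measurement" %in% names(df)) df$age_at_measurement <- df$age
  if ("parity" %in% names(df)) {
    df$parity <- as.integer(df$parity)
    if (any(df$parity < 1)) stop("parity must be >= 1.", call. = FALSE)
  }
  if (anyDuplicated(df$child_id))
    stop("Duplicate child_id in child table.", call. = FALSE)
  df
}

#' Read an LMS growth-reference table
#'
#' Expects columns `sex` (`male`/`female`), `age_months`, `measure`
#' (`weight` or `height`), `L`, `M`, `S`. Rows are sorted by age within
#' each sex-by-measure stratum; M and S must be positive. WHO Child Growth
#' Standards tables restructured to this layout drop in unchanged.
#'
#' @param path CSV file path.
#' @return Validated `data.frame` usable by [zscore_for_child()].
#' @export
read_lms_table <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  require_columns(df, c("sex", "age_months", "measure", "L", "M", "S"),
                  "LMS table")
  df$sex <- tolower(trimws(df$sex))
  df$measure <- tolower(trimws(df$measure))
  if (!all(df$sex %in% c("male", "female")))
    stop("LMS 'sex' must be 'male' or 'female'.", call. = FALSE)
  if (!all(df$measure %in% c("weight", "height")))
    stop("LMS 'measure' must be 'weight' or 'height'.", call. = FALSE)
  if (any(df$M <= 0) || any(df$S <= 0))
    stop("LMS M and S must be positive.", call. = FALSE)
  df[order(df$measure, df$sex, df$age_months), , drop = FALSE]
}

fmt_mean_sd <- function(mean, sd, digits) {
  paste0(formatC(mean, format = "f", digits = digits), " ± ",
         formatC(sd, format = "f", digits = digits))
}

#' Write a category concentration report
#'
#' Formats [summarize_food_panel()] output into the published table layout:
#' per category, n, Se and Hg in mass (mg/kg) and molar (umol/kg) units as
#' mean +/- SD (3 decimals), the Se:Hg molar ratio and HBV_Se (2 decimals).
#' An infinite ratio (category with no detectable Hg) is written as `Inf`.
#'
#' @param summaries Output of [summarize_food_panel()].
#' @param path Output CSV path.
#' @return Invisibly, the formatted `data.frame` written to `path`.
#' @export
write_category_report <- function(summaries, path) {
  cols <- c("category", "n", "se_mg_kg", "se_umol_kg", "hg_mg_kg",
            "hg_umol_kg", "ratio_se_hg", "hbv_se")
  if (nrow(summaries) == 0) {
    out <- stats::setNames(
      as.data.frame(matrix(character(0), 0, length(cols)),
                    stringsAsFactors = FALSE), cols)
  } else {
    out <- data.frame(
      category = summaries$category,
      n = summaries$n,
      se_mg_kg = fmt_mean_sd(summaries$se_mass_mean, summaries$se_mass_sd, 3),
      se_umol_kg = fmt_mean_sd(summaries$se_molar_mean, summaries$se_molar_sd, 3),
      hg_mg_kg = fmt_mean_sd(summaries$hg_mass_mean, summaries$hg_mass_sd, 3),
      hg_umol_kg = fmt_mean_sd(summaries$hg_molar_mean, summaries$hg_molar_sd, 3),
      ratio_se_hg = ifelse(is.finite(summaries$ratio_se_hg),
                           formatC(summaries$ratio_se_hg, format = "f",
                                   digits = 2), "Inf"),
      hbv_se = formatC(summaries$hbv_se, format = "f", digits = 2),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}

#' Write the intake-assessment and consumption-limit reports
#'
#' `write_intake_report()` writes [assess_population_intake()] output
#' (EDI_Se, AI percentage, net Se, net AI percentage, HQ); numeric columns
#' are written unrounded so the table round-trips. `write_limits_report()`
#' writes [consumption_limits()] output.
#'
#' @param x Result `data.frame`.
#' @param path Output CSV path.
#' @return Invisibly, `x`.
#' @export
write_intake_report <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(x)
}

#' @rdname write_intake_report
#' @export
write_limits_report <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(x)
}
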