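#' Convert a mass concentration to a molar concentration
#'
#' mg/kg wet weight to umol/kg: `conc * 1000 / molar_mass`. The conversion is
#' linear, so the molar mean of a sample set equals the converted mass mean.
#'
#' @param conc Concentration(s), mg/kg (>= 0).
#' @param molar_mass Molar mass, g/mol (> 0).
#' @return Molar concentration(s), umol/kg.
#' @export
#' @examples
#' to_molar(0.078, 200.59)  # mercury, ~0.389 umol/kg
to_molar <- function(conc, molar_mass) {
  if (!is.numeric(molar_mass) || any(molar_mass <= 0))
    stop("molar_mass must be positive.", call. = FALSE)
  if (any(conc < 0)) stop("conc must be nonnegative.", call. = FALSE)
  conc * 1000 / molar_mass
}

#' Selenium-to-mercury molar ratio
#'
#' `se_molar / hg_molar`, both in umol/kg. A ratio above 1 indicates molar
#' selenium in excess of mercury, i.e. capacity to offset Hg binding.
#'
#' @param se_molar,hg_molar Molar concentrations, umol/kg.
#' @param allow_infinite If `TRUE`, a zero mercury concentration yields
#'   `Inf` (the formula's limit, used in category summaries); otherwise it
#'   is an error, since the ratio is undefined without mercury.
#' @return Dimensionless ratio(s).
#' @export
#' @examples
#' se_hg_ratio(5.170, 0.389)  # ~13.29
se_hg_ratio <- function(se_molar, hg_molar, allow_infinite = FALSE) {
  if (any(se_molar < 0) || any(hg_molar < 0))
    stop("Molar concentrations must be nonnegative.", call. = FALSE)
  if (!allow_infinite && any(hg_molar == 0))
    stop("Se:Hg ratio undefined (no Hg); set allow_infinite = TRUE for an ",
         "Inf sentinel.", call. = FALSE)
  se_molar / hg_molar
}

#' Health benefit value of selenium (HBV_Se)
#'
#' `(Se - Hg) / Se * (Se + Hg)` on molar concentrations (umol/kg), which
#' simplifies to `Se - Hg^2 / Se`. Positive values indicate a net selenium
#' surplus after accounting for mercury sequestration; the index is bounded
#' above by the selenium concentration itself (equality when Hg = 0) and,
#' unlike the plain ratio, stays moderate for foods whose mercury content is
#' nearly zero.
#'
#' @param se_molar,hg_molar Molar concentrations, umol/kg; `se_molar` > 0.
#' @return HBV_Se index value(s), on the umol/kg scale.
#' @export
#' @examples
#' hbv_se(6.486, 0.069)  # eggs, ~6.49
#' hbv_se(0.020, 0.023)  # fruits, slightly negative
hbv_se <- function(se_molar, hg_molar) {
  if (any(hg_molar < 0)) stop("hg_molar must be nonnegative.", call. = FALSE)
  if (any(se_molar <= 0))
    stop("HBV_Se undefined (no Se): se_molar must be positive.",
         call. = FALSE)
  (se_molar - hg_molar) / se_molar * (se_molar + hg_molar)
}

#' Summarize one food category
#'
#' Mass mean and sample SD (n - 1 denominator) of Se and Hg over the
#' samples, their molar counterparts, and the Se:Hg ratio and HBV_Se
#' computed from the unrounded molar means (never from printed, rounded
#' values). A category with zero mean mercury reports `Inf` for the ratio
#' and HBV_Se equal to the molar selenium mean.
#'
#' @param samples `data.frame` of food samples (see [read_food_samples()]);
#'   all rows must share one category.
#' @param config A [study_config()] supplying the molar masses.
#' @param label Optional label overriding the category name in the output
#'   (used for marine/freshwater splits and the pooled total).
#' @return One-row `data.frame` with mass/molar means and SDs, `ratio_se_hg`
#'   and `hbv_se`.
#' @export
summarize_category <- function(samples, config = study_config(),
                               label = NULL) {
  if (nrow(samples) == 0) stop("No samples to summarize.", call. = FALSE)
  cats <- unique(samples$category)
  if (is.null(label) && length(cats) > 1)
    stop("Mixed categories in one summary: ",
         paste(sQuote(cats), collapse = ", "), call. = FALSE)
  n <- nrow(samples)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  se_mass_mean <- mean(samples$se_conc)
  hg_mass_mean <- mean(samples$hg_conc)
  se_molar_mean <- to_molar(se_mass_mean, config$molar_mass_se)
  hg_molar_mean <- to_molar(hg_mass_mean, config$molar_mass_hg)
  data.frame(
    category = if (is.null(label)) cats else label,
    n = n,
    se_mass_mean = se_mass_mean, se_mass_sd = sd0(samples$se_conc),
    se_molar_mean = se_molar_mean,
    se_molar_sd = to_molar(sd0(samples$se_conc), config$molar_mass_se),
    hg_mass_mean = hg_mass_mean, hg_mass_sd = sd0(samples$hg_conc),
    hg_molar_mean = hg_molar_mean,
    hg_molar_sd = to_molar(sd0(samples$hg_conc), config$molar_mass_hg),
    ratio_se_hg = se_hg_ratio(se_molar_mean, hg_molar_mean,
                              allow_infinite = TRUE),
    hbv_se = if (se_molar_mean > 0) hbv_se(se_molar_mean, hg_molar_mean)
             else NA_real_,
    stringsAsFactors = FALSE)
}

#' Summarize a whole food panel
#'
#' One [summarize_category()] row per category present, optionally followed
#' by marine/freshwater fish sub-rows and a pooled `Total` row over all
#' samples. Categories are ordered alphabetically, with fish sub-rows
#' directly after the fish row.
#'
#' @param samples Food-sample `data.frame`.
#' @param config A [study_config()].
#' @param split_fish Add `Marine fish` / `Freshwater fish` rows when the
#'   subcategory column is informative.
#' @param total Append a pooled all-sample `Total` row.
#' @return `data.frame` of category summaries.
#' @export
summarize_food_panel <- function(samples, config = study_config(),
                                 split_fish = TRUE, total = TRUE) {
  cats <- sort(unique(samples$category))
  rows <- lapply(cats, function(cc) {
    block <- summarize_category(samples[samples$category == cc, , drop = FALSE],
                                config)
    if (split_fish && cc == "Fish") {
      fish <- samples[samples$category == "Fish", , drop = FALSE]
      for (sub in fish_subcategories()) {
        part <- fish[!is.na(fish$subcategory) & fish$subcategory == sub, ,
                     drop = FALSE]
        if (nrow(part) > 0) {
          lbl <- paste0(toupper(substring(sub, 1, 1)), substring(sub, 2),
                        " fish")
          block <- rbind(block, summarize_category(part, config, label = lbl))
        }
      }
    }
    block
  })
  out <- do.call(rbind, rows)
  if (total && nrow(samples) > 0)
    out <- rbind(out, summarize_category(samples, config, label = "Total"))
  rownames(out) <- NULL
  out
}
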