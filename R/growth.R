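#' LMS (Box-Cox) z-score
#'
#' `z = ((x/M)^L - 1) / (L*S)` for `L != 0` and `ln(x/M)/S` for `L = 0`.
#' With `adjust_tails = TRUE` the restricted-tail rule used by growth
#' standards for weight-based indices is applied: beyond |z| > 3 the score
#' is re-expressed on a linear scale anchored at the +/-2 and +/-3 SD
#' curves, `z* = 3 + (x - SD3) / (SD3 - SD2)` above and symmetrically
#' below, which keeps extreme measurements from exploding under the
#' Box-Cox transform.
#'
#' @param x Measurement (> 0), same units as M.
#' @param L Box-Cox power.
#' @param M Median (> 0).
#' @param S Coefficient of variation (> 0).
#' @param adjust_tails Apply the restricted-tail adjustment beyond |z| > 3.
#' @return z-score(s).
#' @seealso [lms_invert()] for the exact inverse of the unadjusted score.
#' @export
#' @examples
#' lms_zscore(20, L = -1.6, M = 16.0, S = 0.14)
lms_zscore <- function(x, L, M, S, adjust_tails = FALSE) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0))
    stop("x, M and S must be positive.", call. = FALSE)
  z <- ifelse(L != 0, ((x / M)^L - 1) / (L * S), log(x / M) / S)
  if (adjust_tails) {
    hi <- z > 3
    if (any(hi)) {
      sd3 <- lms_invert(3, L, M, S); sd2 <- lms_invert(2, L, M, S)
      z[hi] <- (3 + (x - sd3) / (sd3 - sd2))[hi]
    }
    lo <- z < -3
    if (any(lo)) {
      sd3n <- lms_invert(-3, L, M, S); sd2n <- lms_invert(-2, L, M, S)
      z[lo] <- (-3 + (x - sd3n) / (sd3n - sd2n))[lo]
    }
  }
  z
}

#' Invert the LMS transform
#'
#' Measurement at a given (unadjusted) z-score:
#' `x = M * (1 + L*S*z)^(1/L)` for `L != 0`, `M * exp(S*z)` for `L = 0`.
#' Used by the synthetic cohort generator to produce weights and heights
#' from latent growth scores.
#'
#' @param z z-score(s).
#' @inheritParams lms_zscore
#' @return Measurement(s) in the units of M.
#' @export
lms_invert <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) stop("M and S must be positive.",
                                       call. = FALSE)
  ifelse(L != 0, M * (1 + L * S * z)^(1 / L), M * exp(S * z))
}

# Linear interpolation of L, M, S at given ages within one sex x measure
# stratum of an LMS table.
interpolate_lms <- function(lms_table, sex, measure, age_months) {
  stratum <- lms_table[lms_table$sex == sex & lms_table$measure == measure, ]
  if (nrow(stratum) == 0)
    stop("LMS table has no rows for sex=", sQuote(sex), ", measure=",
         sQuote(measure), ".", call. = FALSE)
  rng <- range(stratum$age_months)
  if (any(age_months < rng[1] | age_months > rng[2]))
    stop("Age ", paste(round(age_months[age_months < rng[1] |
                                        age_months > rng[2]], 1),
                       collapse = ", "),
         " months outside LMS table range [", rng[1], ", ", rng[2], "].",
         call. = FALSE)
  ip <- function(col) stats::approx(stratum$age_months, stratum[[col]],
                                    xout = age_months, ties = "ordered")$y
  data.frame(L = ip("L"), M = ip("M"), S = ip("S"))
}

#' Weight- and height-for-age z-scores for children
#'
#' Interpolates L, M, S linearly to each child's age in months within the
#' matching sex stratum and applies [lms_zscore()] to weight (kg) and
#' height (cm). The restricted-tail adjustment is applied to the
#' weight-for-age score only (growth-standard convention; switchable).
#'
#' @param children Child table (see [read_child_records()]); ages in years.
#' @param lms_table LMS reference (see [read_lms_table()]).
#' @param adjust_weight_tails Apply the restricted-tail rule to WAZ.
#' @return `children` with `age_months`, `waz` and `haz` columns added.
#' @export
zscore_for_child <- function(children, lms_table,
                             adjust_weight_tails = TRUE) {
  months <- children$age * 12
  waz <- numeric(nrow(children)); haz <- numeric(nrow(children))
  for (sx in unique(children$sex)) {
    sel <- children$sex == sx
    w <- interpolate_lms(lms_table, sx, "weight", months[sel])
    h <- interpolate_lms(lms_table, sx, "height", months[sel])
    waz[sel] <- lms_zscore(children$weight[sel], w$L, w$M, w$S,
                           adjust_tails = adjust_weight_tails)
    haz[sel] <- lms_zscore(children$height[sel], h$L, h$M, h$S)
  }
  children$age_months <- months
  children$waz <- waz
  children$haz <- haz
  children
}

#' Dichotomize hair-mercury exposure
#'
#' High exposure is a hair Hg concentration strictly above the cutoff
#' (default 1 ug/g, the US EPA reference level); exactly 1 ug/g is low,
#' matching the `<= 1 ug/g` bin convention.
#'
#' @param hair_hg Hair mercury, ug/g (>= 0).
#' @param cutoff Cutoff, ug/g.
#' @return Factor with levels `low`, `high` (low first, the reference
#'   level in regression models).
#' @export
#' @examples
#' classify_hg_exposure(c(0.4, 1.0, 1.11))
classify_hg_exposure <- function(hair_hg, cutoff = 1.0) {
  if (any(hair_hg < 0)) stop("hair_hg must be nonnegative.", call. = FALSE)
  factor(ifelse(hair_hg > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Univariate covariate screening
#'
#' Fits `outcome ~ candidate` separately for each candidate and keeps those
#' whose overall regression F-test has p below the threshold (0.2 by
#' convention for pre-selection into a multivariable model). Categorical
#' candidates are expanded to indicators and judged by the joint F-test.
#' Candidates with no variation are excluded with a warning. Input order is
#' preserved.
#'
#' @param data `data.frame` holding outcome and candidates.
#' @param outcome Name of the numeric outcome column.
#' @param candidates Character vector of candidate column names.
#' @param threshold Screening p-value threshold.
#' @return Character vector of selected candidates, with a `p_values`
#'   attribute (named, one per screened candidate).
#' @export
screen_covariates <- function(data, outcome, candidates, threshold = 0.2) {
  if (!outcome %in% names(data))
    stop("Outcome column ", sQuote(outcome), " not found.", call. = FALSE)
  p_values <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    if (!cand %in% names(data))
      stop("Candidate column ", sQuote(cand), " not found.", call. = FALSE)
    v <- data[[cand]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("Candidate ", sQuote(cand), " is constant; excluded from ",
              "screening.", call. = FALSE)
      next
    }
    fit <- stats::lm(stats::reformulate(cand, response = outcome),
                     data = data)
    fstat <- summary(fit)$fstatistic
    p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    p_values[i] <- p
    keep[i] <- p < threshold
  }
  structure(candidates[keep], p_values = p_values)
}

#' Fit the adjusted growth-association model
#'
#' Ordinary least squares of a growth outcome (WAZ, HAZ, weight or height)
#' on the net selenium adequacy percentage from one food category, adjusted
#' for the supplied covariates (conventionally: high/low hair-Hg exposure,
#' sex, income band, parity, age at measurement). Returns the full
#' coefficient table with t-based 95 percent Wald intervals; rows with
#' missing values are dropped listwise with a message.
#'
#' @param data `data.frame` holding outcome, exposure and covariates.
#' @param outcome Name of the outcome column.
#' @param exposure Name of the exposure column (net AI_Se percentage).
#' @param covariates Character vector of adjustment columns (may be empty).
#' @param conf_level Confidence level for the Wald intervals.
#' @return `data.frame` of class `growth_model_result`: one row per model
#'   term with `outcome`, `term`, `beta`, `ci_low`, `ci_high`, `p_value`,
#'   `n`, `is_exposure`; attributes `covariates_included` and `fit` (the
#'   underlying `lm` object).
#' @export
fit_growth_model <- function(data, outcome, exposure,
                             covariates = character(0),
                             conf_level = 0.95) {
  vars <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0)
    stop("Column(s) not found: ", paste(sQuote(missing_cols), collapse = ", "),
         call. = FALSE)
  complete <- stats::complete.cases(data[, vars, drop = FALSE])
  if (!all(complete))
    message(sum(!complete), " row(s) dropped by listwise deletion.")
  d <- data[complete, vars, drop = FALSE]
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::lm(form, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("Rank-deficient design; collinear term(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  n <- nrow(d)
  if (n < length(stats::coef(fit)) + 1)
    stop("Too few observations (n = ", n, ") for ",
         length(stats::coef(fit)), " model terms.", call. = FALSE)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  out <- data.frame(outcome = outcome,
                    term = rownames(sm),
                    beta = sm[, "Estimate"],
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    p_value = sm[, "Pr(>|t|)"],
                    n = n,
                    is_exposure = startsWith(rownames(sm), exposure),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, covariates_included = covariates, fit = fit,
            class = c("growth_model_result", "data.frame"))
}

#' Per-child net selenium adequacy exposures
#'
#' Builds the exposure columns of the growth models: for each child and
#' food category, the net selenium intake (category mean concentrations
#' times the child's intake rate) as a percentage of the selenium AI.
#' Column names are `net_ai_<category slug>`.
#'
#' @param children Child table.
#' @param intakes Long intake table.
#' @param summaries Category summaries (mean concentrations).
#' @param config A [study_config()].
#' @return `children` with one `net_ai_*` column per category in
#'   `summaries` (excluding sub- and total rows absent from the intakes).
#' @export
net_ai_exposures <- function(children, intakes, summaries,
                             config = study_config()) {
  cats <- intersect(summaries$category, unique(intakes$category))
  for (cc in cats) {
    s <- summaries[summaries$category == cc, ]
    rows <- intakes[intakes$category == cc, ]
    ir <- rows$intake_rate[match(children$child_id, rows$child_id)]
    ir[is.na(ir)] <- 0
    net <- net_se(s$se_mass_mean * ir, s$hg_mass_mean * ir, config = config)
    children[[paste0("net_ai_", category_slug(cc))]] <-
      ai_percent(net, config$ai_se)
  }
  children
}

# "Meat and meat products" -> "meat_and_meat_products"
category_slug <- function(x) {
  gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", tolower(x)))
}

#' Forest plot of growth-model exposure coefficients
#'
#' Point estimates and confidence intervals of the exposure term across a
#' list of fitted models, one row per food category. Requires ggplot2.
#'
#' @param results List of [fit_growth_model()] results.
#' @param labels Optional row labels (defaults to the exposure term names).
#' @return A ggplot object.
#' @export
plot_growth_forest <- function(results, labels = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting.", call. = FALSE)
  rows <- do.call(rbind, lapply(results, function(r) r[r$is_exposure, ]))
  rows$label <- if (is.null(labels)) rows$term else labels
  ggplot2::ggplot(rows, ggplot2::aes(x = beta, y = label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Coefficient (95% CI)", y = NULL)
}
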