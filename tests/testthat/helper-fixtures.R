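# Shared fixtures, built in code.

# Published category molar means (umol/kg) and the values printed alongside
# them; inputs for the desk-scale reproduction checks.
printed_molar_means <- function() {
  data.frame(
    category = c("Eggs", "Fish", "Freshwater fish", "Fruits"),
    se_molar = c(6.486, 5.170, 3.920, 0.020),
    hg_molar = c(0.069, 0.389, 0.219, 0.023),
    printed_hbv = c(6.48, 5.14, 3.91, -0.01),
    stringsAsFactors = FALSE)
}

# Write a small food CSV and return its path.
write_food_csv <- function(lines) {
  path <- tempfile("foods", fileext = ".csv")
  writeLines(c("sample_id,category,se_conc,hg_conc", lines), path)
  path
}

# Two-sample egg panel whose unrounded molar means are consistent with the
# published eggs row (Se 6.486 umol/kg, ratio 94.27, HBV 6.48).
eggs_fixture <- function(cfg = study_config()) {
  se_molar <- 6.4856
  hg_molar <- se_molar / 94.27
  d_se <- 0.2       # symmetric spread, keeps the means exact
  d_hg <- 0.002
  data.frame(
    sample_id = c("E1", "E2"), category = "Eggs",
    subcategory = NA_character_,
    se_conc = (se_molar + c(-d_se, d_se)) * cfg$molar_mass_se / 1000,
    hg_conc = (hg_molar + c(-d_hg, d_hg)) * cfg$molar_mass_hg / 1000,
    se_nondetect = FALSE, hg_nondetect = FALSE,
    stringsAsFactors = FALSE)
}

# Brute-force category summary used as the independent oracle.
brute_summary <- function(samples, cfg) {
  n <- nrow(samples)
  mean_loop <- function(x) { s <- 0; for (v in x) s <- s + v; s / n }
  sd_loop <- function(x) {
    if (n < 2) return(0)
    m <- mean_loop(x); s <- 0
    for (v in x) s <- s + (v - m)^2
    sqrt(s / (n - 1))
  }
  se_m <- mean_loop(samples$se_conc) * 1000 / cfg$molar_mass_se
  hg_m <- mean_loop(samples$hg_conc) * 1000 / cfg$molar_mass_hg
  list(se_mass_mean = mean_loop(samples$se_conc),
       se_mass_sd = sd_loop(samples$se_conc),
       hg_mass_mean = mean_loop(samples$hg_conc),
       hg_mass_sd = sd_loop(samples$hg_conc),
       se_molar_mean = se_m, hg_molar_mean = hg_m,
       ratio = se_m / hg_m,
       hbv = (se_m - hg_m) / se_m * (se_m + hg_m))
}
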