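# Reference distributions of the 17 physiological and clinical chemistry
# markers, per gender: published baseline mean (SD), a distribution family
# (right-skewed markers as moment-matched lognormal, the rest truncated
# normal), and the per-marker missingness implied by the published ns
# (male sample n = 118, female n = 110).

#' Reference table of the 17 health markers
#'
#' One row per marker and gender with the calibrated mean, SD, generating
#' family, missingness rate and unit. `flip` marks markers where *higher*
#' values indicate better health (vitamin B12), which reverses the
#' healthy/risky median-split direction.
#'
#' @return data.frame with columns `marker`, `unit`, `gender`, `n_obs`,
#'   `mean`, `sd`, `family`, `miss_rate`, `flip`.
#' @export
marker_reference <- function() {
  def <- function(marker, unit, family, flip,
                  n_m, mean_m, sd_m, n_f, mean_f, sd_f) {
    data.frame(
      marker = marker, unit = unit,
      gender = c("male", "female"),
      n_obs = c(n_m, n_f),
      mean = c(mean_m, mean_f), sd = c(sd_m, sd_f),
      family = family,
      miss_rate = c(1 - n_m / 118, 1 - n_f / 110),
      flip = flip, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    def("albumin",         "g/dl",    "normal",    FALSE, 115, 4.20, 0.31, 107, 4.16, 0.31),
    def("alt",             "U/l",     "lognormal", FALSE, 115, 22.52, 8.62, 107, 18.46, 5.90),
    def("ast",             "U/l",     "lognormal", FALSE, 112, 24.10, 5.75, 107, 23.31, 5.40),
    def("bilirubin_total", "mg/dl",   "lognormal", FALSE, 115, 0.61, 0.30, 107, 0.46, 0.20),
    def("sbp",             "mmHg",    "normal",    FALSE, 118, 134.9, 17.21, 110, 134.1, 16.69),
    def("dbp",             "mmHg",    "normal",    FALSE, 118, 75.14, 9.66, 110, 74.26, 10.90),
    def("bmi",             "kg/m2",   "normal",    FALSE, 117, 26.76, 3.75, 110, 26.55, 4.99),
    def("cholesterol",     "mg/dl",   "normal",    FALSE, 116, 178.0, 34.21, 108, 209.8, 39.45),
    def("creatinine",      "mg/dl",   "lognormal", FALSE, 116, 1.07, 0.23, 108, 0.83, 0.18),
    def("ggt",             "U/l",     "lognormal", FALSE, 116, 26.11, 16.80, 108, 22.53, 15.34),
    def("glucose",         "mg/dl",   "lognormal", FALSE, 115, 104.2, 25.77, 107, 99.9, 15.63),
    def("mcv",             "fL",      "normal",    FALSE, 114, 90.42, 4.94, 108, 89.26, 5.44),
    def("tsh",             "uIU/mL",  "lognormal", FALSE, 115, 1.92, 1.20, 109, 2.01, 1.44),
    def("thcy",            "umol/l",  "lognormal", FALSE, 118, 10.56, 2.98, 108, 9.29, 2.45),
    def("triglycerides",   "mg/dl",   "lognormal", FALSE, 116, 152.3, 91.9, 108, 133.9, 76.5),
    def("uric_acid",       "mg/dl",   "normal",    FALSE, 116, 6.03, 1.30, 108, 5.02, 1.39),
    def("vitamin_b12",     "ng/l",    "lognormal", TRUE,  113, 477.3, 317.1, 108, 600.6, 414.0)
  ))
}

#' Marker names
#' @return Character vector of the 17 marker column names.
#' @export
marker_names <- function() unique(marker_reference()$marker)

# Default coupling targets: quartile-contrast effect sizes (years) per
# gender that the generator should reproduce, and the per-gender PLS
# R-squared targets. B12 is protective in women (negative sign).
default_effect_targets <- function(gender) {
  switch(gender,
    male   = c(bmi = 7.5, dbp = 6.6, ggt = 7.5, uric_acid = 5.6),
    female = c(ggt = 6.1, ast = 3.1, alt = 5.1, vitamin_b12 = -4.8),
    stop("gender must be 'male' or 'female'", call. = FALSE))
}

default_r2_target <- function(gender) {
  switch(gender, male = 0.39, female = 0.32,
         stop("gender must be 'male' or 'female'", call. = FALSE))
}
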