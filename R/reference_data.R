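# Published per-study summary statistics for the three adult surveys the
# model was developed on, used as pooling inputs and as synthetic-generator
# targets.

#' Published per-study group summary statistics
#'
#' Group sizes and means/SDs of the analysis variables for the three
#' UK/Ireland adult surveys after exclusion filtering: the Irish National
#' Adult Nutrition Survey (NANS), the UK National Diet and Nutrition Survey
#' (NDNS) and the UK arm of the NU-AGE trial of older adults. These printed
#' summary statistics are inputs to [pooled_mean()]/[pooled_sd()] worked
#' examples and parameterise [reference_group_spec()].
#'
#' @return Data frame with columns `study`, `group`, `n`, and `mean`/`sd`
#'   pairs for age (y), weight (kg), BMI (kg/m^2), hemoglobin (g/dL), serum
#'   ferritin (\eqn{\mu}g/L), iron intake (mg/d) and iron intake from meat
#'   (mg/d). NU-AGE recruited only older adults, so it contributes no
#'   premenopausal group.
#' @export
survey_reference_table <- function() {
  tab <- rbind(
    c("NANS",   "men",            336, 42.8, 16.4, 87.1, 13.6, 28.0, 4.0,
      15.2, 1.1, 172, 135,  13.8, 5.7, 2.8, 1.7),
    c("NDNS",   "men",            494, 42.4, 12.0, 83.7, 14.1, 27.1, 4.3,
      15.1, 1.1, 119, 92.5, 13.4, 5.1, 2.6, 1.6),
    c("NU-AGE", "men",             77, 70.2,  3.8, 82.4, 12.2, 27.0, 3.7,
      14.7, 0.9, 146, 102,  14.3, 3.4, 1.3, 0.8),
    c("NANS",   "premenopausal",  197, 34.8,  9.4, 69.7, 12.1, 25.9, 4.4,
      13.3, 1.1, 57.9, 57.8, 11.1, 4.6, 1.8, 1.4),
    c("NDNS",   "premenopausal",  363, 34.9,  7.4, 67.8, 14.3, 25.9, 5.5,
      13.4, 1.0, 44.7, 37.0,  9.8, 3.8, 1.5, 1.1),
    c("NANS",   "postmenopausal", 117, 62.4,  8.9, 72.0, 12.7, 28.0, 4.7,
      13.4, 1.0, 116, 90.8,  10.2, 3.3, 1.7, 1.2),
    c("NDNS",   "postmenopausal", 158, 57.5,  4.1, 71.2, 13.2, 27.7, 5.1,
      13.5, 1.1, 77.0, 55.3, 10.9, 3.8, 1.5, 1.1),
    c("NU-AGE", "postmenopausal", 119, 69.8,  3.9, 68.7, 10.9, 26.4, 3.7,
      12.9, 3.6, 104, 67.6,  11.6, 3.1, 1.0, 0.7))
  out <- data.frame(study = tab[, 1], group = tab[, 2],
                    apply(tab[, -(1:2)], 2, as.numeric))
  names(out) <- c("study", "group", "n", "age_mean", "age_sd",
                  "weight_mean", "weight_sd", "bmi_mean", "bmi_sd",
                  "hemoglobin_mean", "hemoglobin_sd", "sf_mean", "sf_sd",
                  "iron_intake_mean", "iron_intake_sd",
                  "iron_intake_meat_mean", "iron_intake_meat_sd")
  out
}
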