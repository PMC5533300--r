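# Cohort container: a labelled data frame of survey individuals plus
# provenance notes, the unit every downstream operation consumes.

#' Canonical individual-level fields
#'
#' Column names used internally for individual records. `id`, `sex` and
#' `iron_intake` are mandatory; all other fields may be missing (`NA`),
#' which is distinct from zero throughout the package.
#'
#' @return Character vector of field names.
#' @export
individual_fields <- function() {
  c("id", "study", "sex", "menopausal_status", "age", "weight", "bmi",
    "iron_intake", "iron_intake_meat", "sf", "hemoglobin", "crp", "act",
    "iron_supplement")
}

.numeric_fields <- c("age", "weight", "bmi", "iron_intake", "iron_intake_meat",
                     "sf", "hemoglobin", "crp", "act")

#' Construct a cohort
#'
#' Bundles one-row-per-individual data with a label and provenance notes.
#' Individuals carry total daily iron intake (mg/d), serum ferritin
#' (\eqn{\mu}g/L), inflammation markers (hs-CRP mg/L, alpha-1-antichymotrypsin
#' g/L), an iron-supplement-use flag and basic covariates.
#'
#' @param individuals Data frame with (a subset of) [individual_fields()];
#'   `id`, `sex` and `iron_intake` are required. Missing optional columns are
#'   added as `NA`.
#' @param label Cohort label (study name or pooled label).
#' @param provenance Character vector of free-text provenance notes.
#' @return An object of class `iron_cohort`.
#' @examples
#' coh <- cohort(data.frame(id = c("a", "b"), sex = c("male", "female"),
#'                          menopausal_status = c(NA, "premenopausal"),
#'                          iron_intake = c(12, 9)), label = "demo")
#' cohort_size(coh)
#' @export
cohort <- function(individuals, label = "cohort", provenance = character()) {
  stopifnot(is.data.frame(individuals))
  for (f in c("id", "sex", "iron_intake")) {
    if (!f %in% names(individuals)) {
      stop("mandatory column missing: ", f, call. = FALSE)
    }
  }
  for (f in setdiff(individual_fields(), names(individuals))) {
    individuals[[f]] <- if (f == "iron_supplement") NA else
      if (f %in% .numeric_fields) NA_real_ else NA_character_
  }
  individuals <- individuals[, individual_fields()]
  individuals$id <- as.character(individuals$id)
  individuals$sex <- as.character(individuals$sex)
  individuals$iron_supplement <- as.logical(individuals$iron_supplement)
  for (f in .numeric_fields) individuals[[f]] <- as.numeric(individuals[[f]])

  # men have no menopausal status; normalise blanks to the explicit level
  male <- !is.na(individuals$sex) & individuals$sex == "male"
  ms <- as.character(individuals$menopausal_status)
  ms[male & (is.na(ms) | ms == "")] <- "not_applicable"
  individuals$menopausal_status <- ms

  validate_individuals(individuals)
  structure(list(label = label, individuals = individuals,
                 provenance = as.character(provenance)),
            class = "iron_cohort")
}

validate_individuals <- function(d) {
  if (anyDuplicated(d$id)) {
    stop("duplicate individual ids: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "), call. = FALSE)
  }
  bad_sex <- !d$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("sex must be 'male' or 'female'; offending ids: ",
         paste(d$id[bad_sex], collapse = ", "), call. = FALSE)
  }
  ok_ms <- d$menopausal_status %in%
    c("premenopausal", "postmenopausal", "not_applicable") |
    is.na(d$menopausal_status)
  if (!all(ok_ms)) {
    stop("invalid menopausal_status for ids: ",
         paste(d$id[!ok_ms], collapse = ", "), call. = FALSE)
  }
  male_ms <- d$sex == "male" & !is.na(d$menopausal_status) &
    d$menopausal_status != "not_applicable"
  if (any(male_ms)) {
    stop("male individuals must have menopausal_status 'not_applicable': ",
         paste(d$id[male_ms], collapse = ", "), call. = FALSE)
  }
  for (f in c("iron_intake", "sf", "age")) {
    neg <- !is.na(d[[f]]) & d[[f]] < 0
    if (any(neg)) {
      stop("negative ", f, " for ids: ", paste(d$id[neg], collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(d)
}

#' @export
print.iron_cohort <- function(x, ...) {
  cat("<iron_cohort> ", x$label, ": ", nrow(x$individuals),
      " individuals\n", sep = "")
  if (length(x$provenance)) {
    cat(paste0("  ", utils::tail(x$provenance, 3L), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort An `iron_cohort`.
#' @return Integer count.
#' @export
cohort_size <- function(cohort) {
  stopifnot(inherits(cohort, "iron_cohort"))
  nrow(cohort$individuals)
}

#' Iron intakes of a cohort
#' @param cohort An `iron_cohort`.
#' @return Numeric vector of total iron intakes (mg/d).
#' @export
cohort_intakes <- function(cohort) {
  stopifnot(inherits(cohort, "iron_cohort"))
  cohort$individuals$iron_intake
}

add_provenance <- function(cohort, note) {
  cohort$provenance <- c(cohort$provenance, note)
  cohort
}
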