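# Reading, filtering, stratifying, pooling and summarising survey cohorts.
# CSV dialect: comma-separated, UTF-8, header row, empty string = missing.

#' Default mapping from CSV columns to individual fields
#'
#' Names are internal field names, values the expected file headers.
#' Override entries to read files with arbitrary survey headers.
#'
#' @return Named character vector.
#' @export
default_column_map <- function() {
  c(id = "id", study = "study", sex = "sex",
    menopausal_status = "menopausal_status", age = "age",
    weight = "weight_kg", bmi = "bmi", iron_intake = "iron_intake_mg_d",
    iron_intake_meat = "iron_meat_mg_d", sf = "sf_ug_l",
    hemoglobin = "hb_g_dl", crp = "crp_mg_l", act = "act_g_l",
    iron_supplement = "iron_supplement")
}

#' Read a cohort from CSV
#'
#' One individual per data row; empty cells become missing values (`NA`),
#' never zero. `id`, `sex` and `iron_intake` columns are mandatory.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping individual fields to file
#'   headers; defaults to [default_column_map()]. Partial maps are merged
#'   over the default.
#' @param label Cohort label; defaults to the file name without extension.
#' @return An `iron_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, column_map = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- default_column_map()
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  for (f in c("id", "sex", "iron_intake")) {
    if (!map[[f]] %in% names(raw)) {
      stop("mandatory column missing from ", path, ": ", map[[f]],
           call. = FALSE)
    }
  }
  present <- names(map)[map %in% names(raw)]
  d <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in present) d[[f]] <- raw[[map[[f]]]]
  for (f in intersect(.numeric_fields, present)) {
    val <- suppressWarnings(as.numeric(d[[f]]))
    bad <- which(!is.na(d[[f]]) & is.na(val))
    if (length(bad)) {
      stop("unparseable numeric value in column '", map[[f]], "', row ",
           bad[1L], ": '", d[[f]][bad[1L]], "'", call. = FALSE)
    }
    d[[f]] <- val
  }
  if ("iron_supplement" %in% present) {
    v <- tolower(trimws(d$iron_supplement))
    flag <- rep(NA, nrow(d))
    flag[v %in% c("true", "t", "1", "yes")] <- TRUE
    flag[v %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(!is.na(v) & is.na(flag))
    if (length(bad)) {
      stop("unparseable iron_supplement value, row ", bad[1L], ": '",
           d$iron_supplement[bad[1L]], "'", call. = FALSE)
    }
    d$iron_supplement <- flag
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  cohort(d, label = label,
         provenance = sprintf("read %d rows from %s", nrow(d), path))
}

#' Write a cohort to CSV
#'
#' Uses the canonical column headers of [default_column_map()], so files
#' round-trip through [read_cohort()] unchanged.
#'
#' @param cohort An `iron_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "iron_cohort"))
  d <- cohort$individuals
  out <- d
  map <- default_column_map()
  names(out) <- unname(map[names(d)])
  out$iron_supplement <- ifelse(is.na(d$iron_supplement), "",
                                ifelse(d$iron_supplement, "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclusion criteria for cohort filtering
#'
#' Serum ferritin is an acute-phase reactant: individuals with raised
#' inflammation markers (hs-CRP above `crp_max` or alpha-1-antichymotrypsin
#' above `act_max`) are excluded because their ferritin overstates iron
#' stores. Iron-supplement users are excluded because the supplement
#' contribution to intake cannot be quantified. Thresholds are strict:
#' a value exactly at the threshold is retained.
#'
#' @param crp_max hs-CRP exclusion threshold, mg/L.
#' @param act_max alpha-1-antichymotrypsin exclusion threshold, g/L.
#' @param exclude_supplement_users Drop individuals flagged as iron-supplement
#'   users.
#' @param require_sf Drop individuals without a serum ferritin measurement.
#' @return An object of class `exclusion_criteria`.
#' @export
exclusion_criteria <- function(crp_max = 5, act_max = 0.65,
                               exclude_supplement_users = TRUE,
                               require_sf = TRUE) {
  stopifnot(crp_max > 0, act_max > 0)
  structure(list(crp_max = crp_max, act_max = act_max,
                 exclude_supplement_users = isTRUE(exclude_supplement_users),
                 require_sf = isTRUE(require_sf)),
            class = "exclusion_criteria")
}

#' Apply the exclusion pipeline to a cohort
#'
#' Filters run sequentially in a fixed order: (1) inflammation (excluded iff
#' CRP is measured and exceeds `crp_max`, or ACT is measured and exceeds
#' `act_max` — individuals with neither marker measured are retained),
#' (2) iron-supplement users, (3) missing serum ferritin. The report carries
#' sequential stage counts, so `n_input` always equals `n_retained` plus the
#' stage exclusions.
#'
#' @param cohort An `iron_cohort`.
#' @param criteria An [exclusion_criteria()] object.
#' @return List with elements `cohort` (filtered) and `report`
#'   (class `exclusion_report`: stage counts and per-rule excluded ids).
#' @examples
#' coh <- cohort(data.frame(id = 1:3, sex = "male",
#'                          iron_intake = c(10, 12, 14),
#'                          crp = c(1, 9, NA), sf = c(50, 60, 70)))
#' apply_exclusions(coh)$report$n_retained  # the crp = 9 row is dropped
#' @export
apply_exclusions <- function(cohort, criteria = exclusion_criteria()) {
  stopifnot(inherits(cohort, "iron_cohort"),
            inherits(criteria, "exclusion_criteria"))
  d <- cohort$individuals

  inflamed <- (!is.na(d$crp) & d$crp > criteria$crp_max) |
    (!is.na(d$act) & d$act > criteria$act_max)
  ids_inflammation <- d$id[inflamed]
  d <- d[!inflamed, , drop = FALSE]

  supp <- if (criteria$exclude_supplement_users) {
    !is.na(d$iron_supplement) & d$iron_supplement
  } else rep(FALSE, nrow(d))
  ids_supplements <- d$id[supp]
  d <- d[!supp, , drop = FALSE]

  nosf <- if (criteria$require_sf) is.na(d$sf) else rep(FALSE, nrow(d))
  ids_missing_sf <- d$id[nosf]
  d <- d[!nosf, , drop = FALSE]

  report <- structure(list(
    n_input = cohort_size(cohort),
    n_excluded_inflammation = length(ids_inflammation),
    n_excluded_supplements = length(ids_supplements),
    n_excluded_missing_sf = length(ids_missing_sf),
    n_retained = nrow(d),
    excluded_ids = list(inflammation = ids_inflammation,
                        supplements = ids_supplements,
                        missing_sf = ids_missing_sf)),
    class = "exclusion_report")

  out <- cohort
  out$individuals <- d
  out <- add_provenance(out, sprintf(
    "exclusions: %d in; -%d inflammation, -%d supplements, -%d missing SF; %d retained",
    report$n_input, report$n_excluded_inflammation,
    report$n_excluded_supplements, report$n_excluded_missing_sf,
    report$n_retained))
  list(cohort = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n",
      "  input:               ", x$n_input, "\n",
      "  - inflammation:      ", x$n_excluded_inflammation, "\n",
      "  - supplement users:  ", x$n_excluded_supplements, "\n",
      "  - missing ferritin:  ", x$n_excluded_missing_sf, "\n",
      "  retained:            ", x$n_retained, "\n", sep = "")
  invisible(x)
}

#' Write an exclusion report as JSON
#' @param report An `exclusion_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Analysis groups
#' @return `c("men", "premenopausal", "postmenopausal")`.
#' @export
analysis_groups <- function() c("men", "premenopausal", "postmenopausal")

#' Stratify a cohort by sex and menopausal status
#'
#' Sex and menstrual blood loss dominate iron requirements, so every analysis
#' runs within the three groups men / premenopausal / postmenopausal.
#' Menopausal status is an input classification and is never imputed from
#' age: a female record without it is an error.
#'
#' @param cohort An `iron_cohort`.
#' @return Named list of three `iron_cohort`s (possibly empty), in the order
#'   of [analysis_groups()].
#' @export
stratify <- function(cohort) {
  stopifnot(inherits(cohort, "iron_cohort"))
  d <- cohort$individuals
  female <- d$sex == "female"
  bad <- female & (is.na(d$menopausal_status) |
                     d$menopausal_status == "not_applicable")
  if (any(bad)) {
    stop("female individuals without menopausal classification: ",
         paste(d$id[bad], collapse = ", "), call. = FALSE)
  }
  grp <- ifelse(d$sex == "male", "men", d$menopausal_status)
  out <- lapply(analysis_groups(), function(g) {
    sub <- cohort
    sub$individuals <- d[grp == g, , drop = FALSE]
    sub$label <- paste(cohort$label, g, sep = "/")
    add_provenance(sub, paste("stratified:", g))
  })
  names(out) <- analysis_groups()
  out
}

#' Combine several cohorts into one
#'
#' Concatenates individuals. Ids duplicated across cohorts are disambiguated
#' by prefixing with the source cohort label (`label:id`); both records are
#' retained.
#'
#' @param cohorts List of `iron_cohort`s.
#' @param label Label for the combined cohort.
#' @return An `iron_cohort` whose size is the sum of the input sizes.
#' @export
combine_cohorts <- function(cohorts, label = "combined") {
  if (!length(cohorts)) stop("no cohorts to combine", call. = FALSE)
  stopifnot(all(vapply(cohorts, inherits, logical(1), "iron_cohort")))
  all_ids <- unlist(lapply(cohorts, function(x) x$individuals$id))
  dup <- unique(all_ids[duplicated(all_ids)])
  parts <- lapply(cohorts, function(x) {
    d <- x$individuals
    hit <- d$id %in% dup
    d$id[hit] <- paste(x$label, d$id[hit], sep = ":")
    d
  })
  d <- do.call(rbind, parts)
  rownames(d) <- NULL
  cohort(d, label = label,
         provenance = c(unlist(lapply(cohorts, `[[`, "provenance")),
                        sprintf("combined %d cohorts (%s): %d individuals",
                                length(cohorts),
                                paste(vapply(cohorts, `[[`, "", "label"),
                                      collapse = ", "),
                                nrow(d))))
}

.summary_vars <- c("age", "weight", "bmi", "hemoglobin", "sf",
                   "iron_intake", "iron_intake_meat")

#' Per-group means and SDs of cohort variables
#'
#' Arithmetic mean and sample SD (n − 1 denominator) per stratified group for
#' age, weight, BMI, hemoglobin, serum ferritin, total iron intake and iron
#' intake from meat, computed over individuals with the variable present.
#' `n_obs` records per-variable availability where missingness differs from
#' group size. Groups with no individuals are omitted with a message.
#'
#' @param cohort An `iron_cohort`.
#' @return Data frame (class `group_summary`) with columns `group`, `n`,
#'   `variable`, `n_obs`, `mean`, `sd`. A variable absent for everyone keeps
#'   `n_obs = 0` and `NA` mean/SD — absent, never zero.
#' @export
group_summary <- function(cohort) {
  groups <- stratify(cohort)
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]$individuals
    if (!nrow(d)) {
      message("group_summary: group '", g, "' is empty, omitted")
      next
    }
    for (v in .summary_vars) {
      x <- d[[v]][!is.na(d[[v]])]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, n = nrow(d), variable = v, n_obs = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' @export
print.group_summary <- function(x, digits = 1, ...) {
  y <- x
  y$`mean ± sd` <- ifelse(is.na(x$mean), "-",
                          paste0(round(x$mean, digits), " ± ",
                                 round(x$sd, digits)))
  print.data.frame(y[, c("group", "n", "variable", "n_obs", "mean ± sd")],
                   row.names = FALSE)
  invisible(x)
}

#' n-weighted pooled mean across studies
#'
#' \deqn{\bar x = \sum_i n_i \bar x_i / \sum_i n_i}
#'
#' @param means Per-study means.
#' @param ns Per-study sample sizes (all >= 1).
#' @return Pooled mean.
#' @examples
#' pooled_mean(c(13.8, 13.4, 14.3), c(336, 494, 77))  # 13.6 to 1 dp
#' @export
pooled_mean <- function(means, ns) {
  if (!length(means)) stop("empty input", call. = FALSE)
  stopifnot(length(means) == length(ns), all(ns >= 1))
  sum(ns * means) / sum(ns)
}

#' Pooled SD across studies
#'
#' Exact sample SD of the concatenated data, reconstructed from per-study
#' means, SDs (n − 1 denominator) and sizes via the law of total variance.
#'
#' @param means,sds,ns Per-study means, sample SDs and sizes.
#' @return Pooled sample SD.
#' @export
pooled_sd <- function(means, sds, ns) {
  if (!length(means)) stop("empty input", call. = FALSE)
  stopifnot(length(means) == length(sds), length(means) == length(ns),
            all(ns >= 1), all(sds >= 0))
  m <- pooled_mean(means, ns)
  ss <- sum((ns - 1) * sds^2) + sum(ns * (means - m)^2)
  sqrt(ss / (sum(ns) - 1))
}

#' Cumulative distribution of serum ferritin below cutoffs
#'
#' For each cutoff S, the percentage of the group with SF strictly below S
#' (so SF equal to a cutoff counts as sufficient, on the not-below side).
#' Every individual must have SF measured — run [apply_exclusions()] first.
#'
#' @param cohort An `iron_cohort` with SF present for all individuals.
#' @param cutoffs Ascending SF cutoffs, \eqn{\mu}g/L.
#' @return Data frame (class `sf_cdf`) with columns `cutoff` and
#'   `prevalence_below` (percent, non-decreasing).
#' @export
sf_cumulative_distribution <- function(cohort,
                                       cutoffs = c(15, 20, 30, 40, 50, 60,
                                                   80, 100)) {
  stopifnot(inherits(cohort, "iron_cohort"))
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly ascending", call. = FALSE)
  }
  sf <- cohort$individuals$sf
  if (!length(sf)) stop("empty cohort", call. = FALSE)
  if (anyNA(sf)) {
    stop("serum ferritin missing for ids: ",
         paste(cohort$individuals$id[is.na(sf)], collapse = ", "),
         "; apply exclusion filters first", call. = FALSE)
  }
  prev <- vapply(cutoffs, function(s) 100 * mean(sf < s), numeric(1))
  structure(data.frame(cutoff = cutoffs, prevalence_below = prev),
            group = cohort$label, class = c("sf_cdf", "data.frame"))
}
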