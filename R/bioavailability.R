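# The bioavailability model: predicted prevalence of inadequate intakes
# across an assumed-absorption scale, inverted against the observed
# prevalence of low serum ferritin to estimate dietary absorption.

#' Assumed-absorption grid
#'
#' The scale of assumed dietary iron absorptions over which the predicted
#' prevalence of inadequacy is evaluated. Default 1-40% in 0.5% steps; a
#' lower bound of 0 is allowed for plotting the full curve.
#'
#' @param from,to,by Grid bounds and step, percent absorption.
#' @return Strictly ascending numeric vector of absorption percentages,
#'   class `absorption_grid`.
#' @export
absorption_grid <- function(from = 1, to = 40, by = 0.5) {
  g <- seq(from, to, by = by)
  if (any(g < 0 | g > 100)) stop("absorption must lie in [0, 100]",
                                 call. = FALSE)
  if (length(g) < 2L || is.unsorted(g, strictly = TRUE)) {
    stop("grid must be strictly ascending with >= 2 points", call. = FALSE)
  }
  structure(g, class = "absorption_grid")
}

#' Absorbed iron from intake and fractional absorption
#'
#' @param intake Total iron intake, mg/d (>= 0, vectorised).
#' @param absorption Assumed absorption, percent in [0, 100].
#' @return Absorbed iron, mg/d: `intake * absorption / 100`.
#' @export
absorbed_iron <- function(intake, absorption) {
  if (any(intake < 0)) stop("intake must be >= 0", call. = FALSE)
  if (any(absorption < 0 | absorption > 100)) {
    stop("absorption must lie in [0, 100]", call. = FALSE)
  }
  intake * absorption / 100
}

#' Predicted prevalence of inadequate intakes at one assumed absorption
#'
#' Each individual's absorbed iron (intake x absorption) is compared with the
#' requirement distribution via [probability_of_inadequacy()]; the prevalence
#' is 100 times the mean probability over individuals — the estimated
#' percentage of the population requiring a higher absorption to meet their
#' needs (full-probability approach).
#'
#' @param intakes Iron intakes, mg/d (nonempty).
#' @param dist A [requirement_distribution()].
#' @param absorption Assumed absorption, percent.
#' @return Prevalence in [0, 100].
#' @export
predicted_prevalence <- function(intakes, dist, absorption) {
  if (!length(intakes)) stop("no intakes", call. = FALSE)
  100 * mean(probability_of_inadequacy(dist,
                                       absorbed_iron(intakes, absorption)))
}

#' Prevalence-of-inadequacy curve over the absorption grid
#'
#' [predicted_prevalence()] evaluated at every grid absorption; non-increasing
#' in absorption by construction.
#'
#' @param intakes Iron intakes, mg/d.
#' @param dist A [requirement_distribution()].
#' @param grid An [absorption_grid()].
#' @param group Optional group label.
#' @return Data frame (class `prevalence_curve`) with columns `absorption`
#'   and `prevalence` (percent).
#' @export
prevalence_curve <- function(intakes, dist, grid = absorption_grid(),
                             group = NA_character_) {
  stopifnot(inherits(grid, "absorption_grid"))
  prev <- vapply(as.numeric(grid),
                 function(a) predicted_prevalence(intakes, dist, a),
                 numeric(1))
  structure(data.frame(absorption = as.numeric(grid), prevalence = prev),
            group = group, n = length(intakes),
            class = c("prevalence_curve", "data.frame"))
}

#' Invert a prevalence curve at a target prevalence
#'
#' Finds the absorption at which the (non-increasing) curve crosses the
#' target, by linear interpolation between the two bracketing grid points.
#' If several grid points tie exactly at the target (a flat stretch), the
#' smallest such absorption is returned. A target above the curve's maximum
#' or below its minimum clamps to the corresponding grid endpoint and is
#' flagged rather than extrapolated.
#'
#' @param curve A `prevalence_curve`.
#' @param target Target prevalence, percent in [0, 100].
#' @return List with `absorption` (percent) and `clamped` (logical flag).
#' @examples
#' cv <- structure(data.frame(absorption = c(10, 12),
#'                            prevalence = c(40, 30)),
#'                 class = c("prevalence_curve", "data.frame"))
#' invert_prevalence(cv, 35)$absorption  # 11
#' @export
invert_prevalence <- function(curve, target) {
  stopifnot(inherits(curve, "prevalence_curve"),
            target >= 0, target <= 100)
  a <- curve$absorption
  p <- curve$prevalence
  if (any(diff(p) > 1e-9)) {
    stop("prevalence curve is not non-increasing; invalid curve upstream",
         call. = FALSE)
  }
  exact <- which(p == target)
  if (length(exact)) {
    return(list(absorption = a[exact[1L]], clamped = FALSE))
  }
  if (target > p[1L]) {
    return(list(absorption = a[1L], clamped = TRUE))
  }
  if (target < p[length(p)]) {
    return(list(absorption = a[length(a)], clamped = TRUE))
  }
  i <- max(which(p > target))  # p[i] > target >= p[i+1], no exact tie
  frac <- (p[i] - target) / (p[i] - p[i + 1L])
  list(absorption = a[i] + frac * (a[i + 1L] - a[i]), clamped = FALSE)
}

#' Estimated dietary absorption at one serum ferritin cutoff
#'
#' The model's identifying assumption: the predicted prevalence of
#' inadequate intakes equals the observed prevalence of iron insufficiency
#' (SF strictly below the cutoff). The observed prevalence is computed from
#' the group's SF values and the prevalence curve is inverted at it.
#'
#' @param group_cohort A filtered, single-group `iron_cohort` with SF present
#'   for all individuals.
#' @param dist A [requirement_distribution()].
#' @param sf_cutoff Serum ferritin cutoff, \eqn{\mu}g/L.
#' @param grid An [absorption_grid()].
#' @param curve Optional precomputed `prevalence_curve` for this cohort (to
#'   reuse across cutoffs).
#' @return List with `absorption` (percent), `clamped` flag and
#'   `observed_prevalence` (percent of the group with SF < cutoff).
#' @export
absorption_at_sf <- function(group_cohort, dist, sf_cutoff,
                             grid = absorption_grid(), curve = NULL) {
  sf <- group_cohort$individuals$sf
  if (anyNA(sf)) stop("serum ferritin missing; filter first", call. = FALSE)
  p_obs <- 100 * mean(sf < sf_cutoff)
  if (is.null(curve)) {
    curve <- prevalence_curve(cohort_intakes(group_cohort), dist, grid,
                              group = group_cohort$label)
  }
  res <- invert_prevalence(curve, p_obs)
  res$observed_prevalence <- p_obs
  res
}

#' Absorption profile across serum ferritin cutoffs
#'
#' [absorption_at_sf()] evaluated at each cutoff, reusing a single prevalence
#' curve. Where no point is clamped the profile is non-increasing in the
#' cutoff: maintaining lower iron stores implies higher absorption.
#'
#' @param group_cohort A filtered, single-group `iron_cohort`.
#' @param dist A [requirement_distribution()].
#' @param sf_cutoffs Ascending SF cutoffs, \eqn{\mu}g/L.
#' @param grid An [absorption_grid()].
#' @return Data frame (class `absorption_profile`) with columns `sf_cutoff`,
#'   `absorption`, `observed_prevalence` and `clamped`.
#' @export
absorption_profile <- function(group_cohort, dist,
                               sf_cutoffs = c(15, 20, 30, 40, 50, 60, 80,
                                              100),
                               grid = absorption_grid()) {
  if (is.unsorted(sf_cutoffs, strictly = TRUE)) {
    stop("sf_cutoffs must be strictly ascending", call. = FALSE)
  }
  curve <- prevalence_curve(cohort_intakes(group_cohort), dist, grid,
                            group = group_cohort$label)
  rows <- lapply(sf_cutoffs, function(s) {
    r <- absorption_at_sf(group_cohort, dist, s, grid, curve = curve)
    data.frame(sf_cutoff = s, absorption = r$absorption,
               observed_prevalence = r$observed_prevalence,
               clamped = r$clamped)
  })
  out <- do.call(rbind, rows)
  structure(out, group = group_cohort$label,
            class = c("absorption_profile", "data.frame"))
}

#' Plot a prevalence curve
#'
#' Predicted prevalence of inadequate intakes versus assumed absorption.
#' Requires ggplot2.
#'
#' @param curve A `prevalence_curve`.
#' @return A ggplot object.
#' @export
plot_prevalence_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data$absorption, y = .data$prevalence)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Assumed iron absorption (%)",
                  y = "Predicted prevalence of inadequate intakes (%)",
                  title = attr(curve, "group"))
}

#' Plot an absorption profile
#'
#' Estimated dietary absorption versus serum ferritin cutoff; clamped points
#' are marked. Requires ggplot2.
#'
#' @param profile An `absorption_profile`.
#' @return A ggplot object.
#' @export
plot_absorption_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(as.data.frame(profile),
                  ggplot2::aes(x = .data$sf_cutoff, y = .data$absorption)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$clamped)) +
    ggplot2::labs(x = expression("Serum ferritin cutoff (" * mu * "g/L)"),
                  y = "Estimated dietary absorption (%)",
                  title = attr(profile, "group"))
}
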