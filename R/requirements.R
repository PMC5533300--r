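# Absorbed-iron requirement distributions: a quantile function over
# population percentiles, and the per-individual probability of inadequacy
# evaluated as a step function on the half-percentile grid.

#' The fine half-percentile grid
#'
#' Population percentiles 0.5, 1.0, ..., 99.5 — the 199-point grid on which
#' the probability of inadequacy is discretised.
#'
#' @return Numeric vector of length 199.
#' @export
fine_percentile_grid <- function() seq(0.5, 99.5, by = 0.5)

#' Construct an absorbed-iron requirement distribution
#'
#' Physiological requirements for absorbed iron (mg/d) vary across a
#' population; the distribution is represented by its quantile function:
#' requirement values at an ascending grid of population percentiles.
#'
#' @param percentiles Strictly ascending percentiles in (0, 100).
#' @param requirements Non-negative, non-decreasing absorbed-iron
#'   requirements (mg/d), one per percentile.
#' @param group One of [analysis_groups()], or `NA` for unspecified.
#' @param source Free-text provenance.
#' @return An object of class `requirement_distribution`.
#' @export
requirement_distribution <- function(percentiles, requirements,
                                     group = NA_character_,
                                     source = "unspecified") {
  percentiles <- as.numeric(percentiles)
  requirements <- as.numeric(requirements)
  if (length(percentiles) < 2L) {
    stop("at least 2 percentile points required", call. = FALSE)
  }
  stopifnot(length(percentiles) == length(requirements))
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly inside (0, 100)", call. = FALSE)
  }
  if (is.unsorted(percentiles, strictly = TRUE)) {
    dup <- which(diff(percentiles) <= 0)
    stop("percentiles must be strictly ascending; violation at rows ",
         paste(dup + 1L, collapse = ", "), call. = FALSE)
  }
  if (any(requirements < 0)) stop("negative requirements", call. = FALSE)
  drop <- which(diff(requirements) < 0)
  if (length(drop)) {
    stop("requirements must be non-decreasing along percentiles; ",
         "decrease at rows ", paste(drop + 1L, collapse = ", "),
         call. = FALSE)
  }
  structure(list(group = group, percentiles = percentiles,
                 requirements = requirements, source = source),
            class = "requirement_distribution")
}

#' @export
print.requirement_distribution <- function(x, ...) {
  cat("<requirement_distribution> ", if (!is.na(x$group)) x$group else "",
      " (", length(x$percentiles), " percentiles, ",
      format(min(x$requirements), digits = 3), "-",
      format(max(x$requirements), digits = 3), " mg/d)\n  source: ",
      x$source, "\n", sep = "")
  invisible(x)
}

#' Read a requirement table from CSV
#'
#' Expects columns `percentile` and `requirement_mg_d`; lines starting with
#' `#` are provenance comments. Validation (monotone requirements,
#' percentiles inside (0, 100), no duplicates) is strict: requirement tables
#' are reference inputs and silent repair would mask data errors.
#'
#' @param path CSV path.
#' @param group Optional group label attached to the distribution.
#' @return A [requirement_distribution()].
#' @export
load_requirement_table <- function(path, group = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8")
  for (col in c("percentile", "requirement_mg_d")) {
    if (!col %in% names(d)) {
      stop("column missing from ", path, ": ", col, call. = FALSE)
    }
  }
  if (nrow(d) < 2L) stop("requirement table needs >= 2 rows", call. = FALSE)
  requirement_distribution(d$percentile, d$requirement_mg_d, group = group,
                           source = path)
}

#' Write a requirement table to CSV
#' @param dist A `requirement_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_requirement_table <- function(dist, path) {
  stopifnot(inherits(dist, "requirement_distribution"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", dist$source), con)
  utils::write.csv(data.frame(percentile = dist$percentiles,
                              requirement_mg_d = dist$requirements),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a requirement table to the half-percentile grid
#'
#' Reference tables publish requirements at a handful of percentiles; the
#' model needs them at every 0.5th percentile. Piecewise-linear interpolation
#' in the percentile domain is the default (monotone by construction on
#' monotone input); a monotone cubic (Hyman-filtered spline) alternative is
#' available. If the coarse table does not span [0.5, 99.5] the ends are
#' extended flat (clamped to the nearest value) with a warning, rather than
#' fabricating tail behaviour.
#'
#' @param coarse A `requirement_distribution` at any grid.
#' @param method `"linear"` (default) or `"monotone"`.
#' @return A `requirement_distribution` on exactly [fine_percentile_grid()];
#'   values at the coarse knots are reproduced. Idempotent on the fine grid.
#' @examples
#' coarse <- requirement_distribution(c(5, 50, 95), c(0.9, 1.3, 2.5))
#' fine <- interpolate_to_half_percentiles(coarse)
#' length(fine$percentiles)  # 199
#' @export
interpolate_to_half_percentiles <- function(coarse,
                                            method = c("linear",
                                                       "monotone")) {
  stopifnot(inherits(coarse, "requirement_distribution"))
  method <- match.arg(method)
  grid <- fine_percentile_grid()
  if (identical(coarse$percentiles, grid)) return(coarse)
  if (min(coarse$percentiles) > 0.5 || max(coarse$percentiles) < 99.5) {
    warning("coarse grid does not span [0.5, 99.5]; ",
            "tails extended flat from the nearest knot", call. = FALSE)
  }
  vals <- if (method == "linear") {
    stats::approx(coarse$percentiles, coarse$requirements, xout = grid,
                  rule = 2)$y
  } else {
    f <- stats::splinefun(coarse$percentiles, coarse$requirements,
                          method = "hyman")
    clamped <- pmin(pmax(grid, min(coarse$percentiles)),
                    max(coarse$percentiles))
    f(clamped)
  }
  requirement_distribution(grid, vals, group = coarse$group,
                           source = paste0(coarse$source,
                                           " [interpolated, ", method, "]"))
}

#' Probability that an absorbed-iron amount is inadequate
#'
#' The fraction of the population whose requirement exceeds the absorbed
#' amount, evaluated as a step function over the distribution's percentile
#' grid: the share of grid points whose requirement strictly exceeds
#' `absorbed`. A requirement exactly equal to the absorbed amount counts as
#' met, so the probability is 0 at and above the top grid value and 1 below
#' the bottom one.
#'
#' @param dist A `requirement_distribution`.
#' @param absorbed Absorbed iron, mg/d (vectorised, all >= 0).
#' @return Probabilities in [0, 1], non-increasing in `absorbed`.
#' @examples
#' d <- requirement_distribution(c(25, 50, 75), c(1.0, 1.5, 2.0))
#' probability_of_inadequacy(d, 1.6)  # 1/3: only the 2.0 point is unmet
#' @export
probability_of_inadequacy <- function(dist, absorbed) {
  stopifnot(inherits(dist, "requirement_distribution"))
  if (any(absorbed < 0)) stop("absorbed iron must be >= 0", call. = FALSE)
  n_met <- findInterval(absorbed, dist$requirements)  # count req <= absorbed
  1 - n_met / length(dist$requirements)
}
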