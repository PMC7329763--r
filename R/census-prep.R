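#' Census series and correction configuration
#'
#' `census_series()` validates a raw table of census benchmarks.
#' `correction_config()` collects the deterministic corrections applied
#' before the censuses enter the likelihood: exclusion of unreliable
#' years, an uplift of the first census, addition of an annexed region
#' interpolated from two regional anchor censuses, and an adjustment for
#' confessions missing from the counts before a given revision year.
#'
#' @param year Integer census years (strictly increasing).
#' @param population Positive enumerated populations.
#' @return `census_series()`: a data-frame-like list of class
#'   `census_series` with provenance flag columns.
#' @export
census_series <- function(year, population) {
  year <- as.integer(year)
  if (is.unsorted(year, strictly = TRUE)) stop("census years must be strictly increasing")
  if (any(population <= 0)) stop("census populations must be positive")
  structure(data.frame(year = year, population = as.numeric(population),
                       corrected_first = FALSE, region_added = FALSE,
                       confession_adjusted = FALSE),
            class = c("census_series", "data.frame"))
}

#' @rdname census_series
#' @param excluded_years Census years dropped outright (default the
#'   double-counting-era censuses 1785, 1790, 1795).
#' @param first_census_year Year receiving the undercount uplift.
#' @param uplift Fractional uplift of the first census (default 0.038).
#' @param region_anchors Named numeric vector of two regional census
#'   benchmarks, names = years (e.g. `c("1754" = ..., "1783" = ...)`).
#' @param region_merge_until Census years strictly before this year get
#'   the regional population added (default 1815).
#' @param confession_share Fraction of the true population missing from
#'   the counts before `confession_year` (default 0.02; the first-count
#'   share of 0.022 is the documented alternative).
#' @param confession_year Censuses from this year on already include all
#'   confessions (default 1830).
#' @export
correction_config <- function(excluded_years = c(1785L, 1790L, 1795L),
                              first_census_year = 1749L, uplift = 0.038,
                              region_anchors = NULL,
                              region_merge_until = 1815L,
                              confession_share = 0.02,
                              confession_year = 1830L) {
  stopifnot(uplift >= 0, uplift < 1, confession_share >= 0, confession_share < 1)
  if (!is.null(region_anchors)) {
    if (length(region_anchors) != 2L || is.null(names(region_anchors))) {
      stop("region_anchors must be two year-named populations")
    }
    region_anchors <- region_anchors[order(as.integer(names(region_anchors)))]
  }
  structure(list(excluded_years = as.integer(excluded_years),
                 first_census_year = as.integer(first_census_year),
                 uplift = uplift,
                 region_anchors = region_anchors,
                 region_merge_until = as.integer(region_merge_until),
                 confession_share = confession_share,
                 confession_year = as.integer(confession_year)),
            class = "correction_config")
}

#' Drop excluded census years
#'
#' @param series A [census_series()].
#' @param config A [correction_config()].
#' @return The series without the excluded years; years not present are
#'   ignored.
#' @export
exclude_censuses <- function(series, config) {
  stopifnot(inherits(series, "census_series"))
  series[!series$year %in% config$excluded_years, , drop = FALSE]
}

#' Uplift the first census for undercount
#'
#' Multiplies the configured first census year by `1 + uplift`.
#'
#' @inheritParams exclude_censuses
#' @export
correct_first_census <- function(series, config) {
  stopifnot(inherits(series, "census_series"))
  i <- match(config$first_census_year, series$year)
  if (is.na(i)) stop("first census year ", config$first_census_year,
                     " not present in the series")
  series$population[i] <- series$population[i] * (1 + config$uplift)
  series$corrected_first[i] <- TRUE
  series
}

# National population at an arbitrary year, log-linearly interpolated
# between census benchmarks (constant extrapolation outside).
.national_at <- function(series, year) {
  exp(stats::approx(series$year, log(series$population), xout = year,
                    rule = 2)$y)
}

#' Add an annexed region interpolated from regional anchor censuses
#'
#' For census years before `region_merge_until`, adds the regional
#' population R(t), computed from the anchor benchmark closer in time by
#' scaling with the national series' compound growth factor between the
#' anchor year and t (national values at non-census years are log-linear
#' interpolations). R(t) equals the anchor population exactly at the
#' anchor years, and the addition is continuous there.
#'
#' @inheritParams exclude_censuses
#' @export
add_annexed_region <- function(series, config) {
  stopifnot(inherits(series, "census_series"))
  if (is.null(config$region_anchors)) stop("no region anchors configured")
  anchor_years <- as.integer(names(config$region_anchors))
  if (min(anchor_years) < min(series$year) - 30 ||
      max(anchor_years) > max(series$year) + 30) {
    stop("region anchor years lie far outside the census span")
  }
  target <- series$year < config$region_merge_until
  national <- series  # growth factors read the uncorrected national series
  for (i in which(target)) {
    t <- series$year[i]
    a <- which.min(abs(anchor_years - t))
    growth <- .national_at(national, t) / .national_at(national, anchor_years[a])
    series$population[i] <- series$population[i] +
      config$region_anchors[a] * growth
    series$region_added[i] <- TRUE
  }
  series
}

#' Adjust for confessions missing from early censuses
#'
#' Census years strictly before `confession_year` are scaled by
#' `1 / (1 - confession_share)`: the missing confessions are treated as a
#' fixed share of the true population absent from the count.
#'
#' @inheritParams exclude_censuses
#' @export
adjust_confession_share <- function(series, config) {
  stopifnot(inherits(series, "census_series"))
  early <- series$year < config$confession_year
  series$population[early] <- series$population[early] /
    (1 - config$confession_share)
  series$confession_adjusted[early] <- TRUE
  series
}

#' Full census correction pipeline
#'
#' Applies, in order: exclusion, first-census uplift, annexed-region
#' addition (when anchors are configured), confession-share adjustment.
#' The remaining corrections act on disjoint quantities, so only the
#' position of the exclusion step matters.
#'
#' @inheritParams exclude_censuses
#' @return The corrected `census_series` with provenance flags set.
#' @export
prepare_censuses <- function(series, config = correction_config()) {
  series <- exclude_censuses(series, config)
  series <- correct_first_census(series, config)
  if (!is.null(config$region_anchors)) {
    series <- add_annexed_region(series, config)
  }
  adjust_confession_share(series, config)
}
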