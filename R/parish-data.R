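#' Aggregate parish event records into unit-level annual counts
#'
#' Sums per-parish baptism and burial counts into statistical units and
#' records, per unit-year and event type, whether any register row exists
#' (the availability sets the model conditions on). A unit-year counts as
#' available for a type as soon as one mapped parish has a record row for
#' that type that year -- an explicit zero row is a record, absence of
#' rows is missingness.
#'
#' @param table Data frame with columns `unit_id` (raw parish identifier),
#'   `year`, `event_type` (`"baptism"` or `"burial"`) and non-negative
#'   integer `count`. One row per parish-year-type, or several (they are
#'   summed), e.g. from pre-counted per-entry registers.
#' @param unit_map Optional data frame `(raw_id, unit_id)` mapping raw
#'   parishes to statistical units; `NULL` keeps each parish as its own
#'   unit. Every parish present in `table` must be mapped.
#' @param span Length-2 integer vector: first and last event year kept.
#'   Rows outside are dropped with a warning stating how many.
#' @param n_units_total Total number of units the coverage model accounts
#'   for; defaults to the number of mapped units.
#' @return An object of class `observed_data` holding count matrices
#'   (`b`, `d`; `NA` where no record exists), availability masks
#'   (`avail_b`, `avail_d`), empty census and zero casualty series.
#' @export
aggregate_events <- function(table, unit_map = NULL, span,
                             n_units_total = NULL) {
  need <- c("unit_id", "year", "event_type", "count")
  if (!all(need %in% names(table))) {
    stop("event table must have columns: ", paste(need, collapse = ", "))
  }
  table$unit_id <- as.character(table$unit_id)
  table$year <- as.integer(table$year)
  table$count <- as.numeric(table$count)
  if (any(table$count < 0, na.rm = TRUE)) stop("negative event counts")
  bad_type <- setdiff(unique(table$event_type), c("baptism", "burial"))
  if (length(bad_type)) {
    stop("unknown event_type: ", paste(bad_type, collapse = ", "))
  }
  span <- as.integer(span)
  stopifnot(length(span) == 2L, span[2] >= span[1])

  if (!is.null(unit_map)) {
    if (!all(c("raw_id", "unit_id") %in% names(unit_map))) {
      stop("unit_map must have columns raw_id, unit_id")
    }
    map <- stats::setNames(as.character(unit_map$unit_id),
                           as.character(unit_map$raw_id))
    unmapped <- setdiff(unique(table$unit_id), names(map))
    if (length(unmapped)) {
      stop("unmapped parish id(s): ", paste(unmapped, collapse = ", "))
    }
    table$unit_id <- unname(map[table$unit_id])
    unit_ids <- sort(unique(unname(map)))
  } else {
    unit_ids <- sort(unique(table$unit_id))
  }

  outside <- table$year < span[1] | table$year > span[2]
  if (any(outside)) {
    warning(sum(outside), " event row(s) outside the study span dropped")
    table <- table[!outside, , drop = FALSE]
  }

  event_years <- span[1]:span[2]
  p <- length(unit_ids)
  empty <- matrix(NA_real_, length(event_years), p,
                  dimnames = list(event_years, unit_ids))
  counts <- list(baptism = empty, burial = empty)
  for (type in c("baptism", "burial")) {
    rows <- table[table$event_type == type, , drop = FALSE]
    if (nrow(rows)) {
      agg <- stats::aggregate(count ~ year + unit_id, data = rows, FUN = sum)
      idx <- cbind(match(agg$year, event_years), match(agg$unit_id, unit_ids))
      counts[[type]][idx] <- agg$count
    }
  }

  structure(list(
    event_years = event_years,
    unit_ids = unit_ids,
    b = counts$baptism, d = counts$burial,
    avail_b = !is.na(counts$baptism), avail_d = !is.na(counts$burial),
    C = stats::setNames(numeric(0), character(0)),
    s = stats::setNames(rep(0, length(event_years)), event_years),
    n_units_included = p,
    n_units_total = if (is.null(n_units_total)) p else as.integer(n_units_total)
  ), class = "observed_data")
}

#' @export
print.observed_data <- function(x, ...) {
  cat("observed_data:", x$n_units_included, "units (of", x$n_units_total,
      "total), event years", min(x$event_years), "-", max(x$event_years), "\n")
  cat("  availability: baptisms ",
      round(100 * mean(x$avail_b)), "%, burials ",
      round(100 * mean(x$avail_d)), "%\n", sep = "")
  cat("  censuses:", length(x$C), " casualties total:", sum(x$s), "\n")
  invisible(x)
}

#' Drop units with too few jointly recorded years
#'
#' A unit is retained only if it has at least `min_years` years in which
#' both a baptism and a burial record exist. The boundary is inclusive:
#' exactly `min_years` joint years retains the unit.
#'
#' @param data An `observed_data` object.
#' @param min_years Minimum number of joint-record years (default 10).
#' @return The filtered `observed_data`; `n_units_total` is unchanged.
#' @export
apply_inclusion_rule <- function(data, min_years = 10L) {
  stopifnot(inherits(data, "observed_data"), min_years >= 1L)
  joint <- colSums(data$avail_b & data$avail_d)
  keep <- joint >= min_years
  if (sum(keep) < 2L) {
    warning("fewer than 2 units remain after the inclusion rule")
  }
  for (f in c("b", "d", "avail_b", "avail_d")) {
    data[[f]] <- data[[f]][, keep, drop = FALSE]
  }
  data$unit_ids <- data$unit_ids[keep]
  data$n_units_included <- sum(keep)
  data
}

#' Load the military casualty series
#'
#' Reads a CSV of `(year, deaths)` and expands it to a dense series over
#' the event years, zero where no entry exists. Duplicate years are summed
#' (with a message); negative deaths are an error.
#'
#' @param path CSV file path.
#' @param span Length-2 integer vector of first and last event year.
#' @return Named numeric vector over the event years.
#' @export
load_casualties <- function(path, span) {
  tab <- utils::read.csv(path)
  span <- as.integer(span)
  event_years <- span[1]:span[2]
  s <- stats::setNames(rep(0, length(event_years)), event_years)
  if (nrow(tab)) {
    if (!all(c("year", "deaths") %in% names(tab))) {
      stop("casualty file must have columns year, deaths")
    }
    if (any(tab$deaths < 0)) stop("negative casualty counts in ", path)
    if (anyDuplicated(tab$year)) {
      message("duplicate casualty years summed")
      tab <- stats::aggregate(deaths ~ year, data = tab, FUN = sum)
    }
    inside <- tab$year %in% event_years
    s[as.character(tab$year[inside])] <- tab$deaths[inside]
  }
  s
}

#' Attach census benchmarks and casualties to observed data
#'
#' @param data An `observed_data` object.
#' @param census Either a named numeric vector (names = years) or a
#'   `census_series` from the census-correction pipeline.
#' @param casualties Named numeric vector over (a subset of) the event
#'   years, e.g. from [load_casualties()]. Missing years stay 0.
#' @return The updated `observed_data`.
#' @export
attach_benchmarks <- function(data, census = NULL, casualties = NULL) {
  stopifnot(inherits(data, "observed_data"))
  if (!is.null(census)) {
    if (inherits(census, "census_series")) {
      census <- stats::setNames(census$population, census$year)
    }
    if (is.null(names(census))) stop("census must be named by year")
    data$C <- census[order(as.integer(names(census)))]
  }
  if (!is.null(casualties)) {
    if (is.null(names(casualties))) stop("casualties must be named by year")
    if (any(casualties < 0)) stop("negative casualty counts")
    keep <- names(casualties) %in% as.character(data$event_years)
    data$s[names(casualties)[keep]] <- casualties[keep]
  }
  data
}

#' Write an observed dataset as CSV triplets
#'
#' Produces `counts_b.csv`, `counts_d.csv` (long format, available cells
#' only), `availability.csv`, plus `censuses.csv` and `casualties.csv`
#' when present.
#'
#' @param data An `observed_data` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_observed_data <- function(data, dir) {
  stopifnot(inherits(data, "observed_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  long <- function(m) {
    idx <- which(!is.na(m), arr.ind = TRUE)
    data.frame(year = data$event_years[idx[, 1]],
               unit_id = data$unit_ids[idx[, 2]],
               count = m[idx])[order(idx[, 1], idx[, 2]), ]
  }
  for (type in c("b", "d")) {
    f <- file.path(dir, paste0("counts_", type, ".csv"))
    utils::write.csv(long(data[[type]]), f, row.names = FALSE)
    paths <- c(paths, f)
  }
  av <- expand.grid(unit_id = data$unit_ids, year = data$event_years,
                    stringsAsFactors = FALSE)[, 2:1]
  av$baptism <- as.integer(t(data$avail_b))
  av$burial <- as.integer(t(data$avail_d))
  f <- file.path(dir, "availability.csv")
  utils::write.csv(av, f, row.names = FALSE)
  paths <- c(paths, f)
  if (length(data$C)) {
    f <- file.path(dir, "censuses.csv")
    utils::write.csv(data.frame(year = as.integer(names(data$C)),
                                population = unname(data$C)),
                     f, row.names = FALSE)
    paths <- c(paths, f)
  }
  if (any(data$s > 0)) {
    f <- file.path(dir, "casualties.csv")
    nz <- data$s > 0
    utils::write.csv(data.frame(year = as.integer(names(data$s)[nz]),
                                deaths = unname(data$s[nz])),
                     f, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Read an observed dataset from CSV triplets
#'
#' Inverse of [write_observed_data()].
#'
#' @param dir Directory containing the CSV files.
#' @param n_units_total Total unit count for the coverage model; defaults
#'   to the number of units found.
#' @return An `observed_data` object.
#' @export
read_observed_data <- function(dir, n_units_total = NULL) {
  av <- utils::read.csv(file.path(dir, "availability.csv"))
  event_years <- sort(unique(av$year))
  unit_ids <- sort(unique(as.character(av$unit_id)))
  shape <- list(as.character(event_years), unit_ids)
  mk <- function() matrix(NA_real_, length(event_years), length(unit_ids),
                          dimnames = shape)
  b <- mk(); d <- mk()
  idx <- cbind(match(av$year, event_years), match(av$unit_id, unit_ids))
  avail_b <- matrix(FALSE, length(event_years), length(unit_ids), dimnames = shape)
  avail_d <- avail_b
  avail_b[idx] <- av$baptism == 1L
  avail_d[idx] <- av$burial == 1L
  for (type in c("b", "d")) {
    cc <- utils::read.csv(file.path(dir, paste0("counts_", type, ".csv")))
    if (nrow(cc)) {
      i <- cbind(match(cc$year, event_years),
                 match(as.character(cc$unit_id), unit_ids))
      if (type == "b") b[i] <- cc$count else d[i] <- cc$count
    }
  }
  data <- structure(list(
    event_years = event_years, unit_ids = unit_ids,
    b = b, d = d, avail_b = avail_b, avail_d = avail_d,
    C = stats::setNames(numeric(0), character(0)),
    s = stats::setNames(rep(0, length(event_years)), event_years),
    n_units_included = length(unit_ids),
    n_units_total = if (is.null(n_units_total)) length(unit_ids)
                    else as.integer(n_units_total)
  ), class = "observed_data")
  fc <- file.path(dir, "censuses.csv")
  if (file.exists(fc)) {
    cen <- utils::read.csv(fc)
    data <- attach_benchmarks(data,
      census = stats::setNames(cen$population, cen$year))
  }
  fs <- file.path(dir, "casualties.csv")
  if (file.exists(fs)) {
    cas <- utils::read.csv(fs)
    data <- attach_benchmarks(data,
      casualties = stats::setNames(cas$deaths, cas$year))
  }
  data
}
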