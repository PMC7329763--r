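#' Read a run configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), one dialect across all
#' subcommands. See the package vignette for the recognised blocks.
#'
#' @param path Configuration file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unrecognised config extension: ", ext)
  }
}

.scenario_from_config <- function(cfg) {
  name <- if (is.null(cfg$scenario)) "desk" else cfg$scenario
  args <- list()
  if (!is.null(cfg$n_units)) args$n_units <- as.integer(cfg$n_units)
  if (!is.null(cfg$n_years)) args$n_years <- as.integer(cfg$n_years)
  switch(name,
         desk = do.call(desk_scenario, args),
         noiseless = do.call(noiseless_scenario, args),
         stop("unknown scenario: ", name))
}

.fit_config_from <- function(cfg, seed) {
  args <- cfg[intersect(names(cfg),
                        c("chains", "iter", "warmup", "target_accept",
                          "max_treedepth", "preset"))]
  args$seed <- seed
  do.call(fit_config, args)
}

.write_manifest <- function(out_dir, subcommand, config, seed, inputs = character(0)) {
  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    config = config,
    inputs = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else list(),
    package_version = as.character(utils::packageVersion("popreconstruct")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a pipeline subcommand
#'
#' End-to-end orchestration behind the command-line interface:
#' `simulate` writes a synthetic dataset as the CSV schema the loaders
#' read; `prepare` aggregates raw event/census CSVs and applies the
#' census corrections; `priors` writes the audit table of all model
#' priors; `fit` runs the sampler and writes posterior summaries,
#' diagnostics and draws; `analyze` computes derived demographic
#' quantities from a written mu-draw file; `ppc` runs the posterior
#' predictive check. Artifacts land in `out_dir` together with a
#' manifest (config echo, input hashes, versions, seed). On error,
#' partial outputs are removed.
#'
#' @param subcommand One of `"simulate"`, `"prepare"`, `"priors"`,
#'   `"fit"`, `"analyze"`, `"ppc"`.
#' @param config Named list (see [read_run_config()]) or a path to a
#'   config file.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in all outputs.
#' @return Invisibly, a character vector of artifact paths.
#' @export
run <- function(subcommand = c("simulate", "prepare", "priors", "fit",
                               "analyze", "ppc"),
                config = list(), out_dir = ".", seed = 1L) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(seed)
  fresh <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    if (fresh) unlink(out_dir, recursive = TRUE)
    stop("pipeline step '", subcommand, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }
  inputs <- character(0)

  tryCatch({
    if (subcommand == "simulate") {
      scen <- .scenario_from_config(config)
      ds <- simulate_dataset(scen, seed)
      written <- write_observed_data(ds$data, out_dir)
      truth_f <- file.path(out_dir, "truth_params.json")
      jsonlite::write_json(ds$truth$params, truth_f, auto_unbox = TRUE,
                           digits = NA)
      written <- c(written, truth_f)
    } else if (subcommand == "prepare") {
      inputs <- unlist(config[c("events", "unit_map", "casualties",
                                "census")], use.names = FALSE)
      inputs <- inputs[!is.null(inputs) & file.exists(inputs)]
      events <- utils::read.csv(config$events)
      umap <- if (!is.null(config$unit_map))
        utils::read.csv(config$unit_map) else NULL
      span <- as.integer(config$span)
      data <- aggregate_events(events, umap, span,
                               n_units_total = config$n_units_total)
      min_years <- if (is.null(config$min_years)) 10L else
        as.integer(config$min_years)
      data <- apply_inclusion_rule(data, min_years)
      if (!is.null(config$casualties)) {
        data <- attach_benchmarks(
          data, casualties = load_casualties(config$casualties, span))
      }
      if (!is.null(config$census)) {
        cen <- utils::read.csv(config$census)
        series <- census_series(cen$year, cen$population)
        cc_args <- config$corrections
        cc <- if (is.null(cc_args)) correction_config() else {
          if (!is.null(cc_args$region_anchors)) {
            cc_args$region_anchors <- unlist(cc_args$region_anchors)
          }
          do.call(correction_config, cc_args)
        }
        series <- prepare_censuses(series, cc)
        f <- file.path(out_dir, "censuses_corrected.csv")
        utils::write.csv(series, f, row.names = FALSE)
        written <- c(written, f)
        data <- attach_benchmarks(data, census = series)
      }
      written <- c(written, write_observed_data(data, out_dir))
    } else if (subcommand == "priors") {
      mc <- model_config()
      tab <- prior_table(mc)
      f <- file.path(out_dir, "prior_table.csv")
      utils::write.csv(tab, f, row.names = FALSE)
      written <- f
      print(tab)
    } else if (subcommand %in% c("fit", "ppc")) {
      data <- read_observed_data(config$data_dir,
                                 n_units_total = config$n_units_total)
      inputs <- list.files(config$data_dir, full.names = TRUE)
      mc_args <- config$model
      mc <- if (is.null(mc_args)) {
        # infer a config matching the data span
        model_config(t_start = min(data$event_years) - 1L,
                     t_end = max(data$event_years),
                     census_years = as.integer(names(data$C)),
                     crisis_year = config$crisis_year,
                     n_units_included = data$n_units_included,
                     n_units_total = data$n_units_total,
                     midpoint_span = as.integer(
                       round(0.9 * (max(data$event_years) -
                                      min(data$event_years) + 1L))))
      } else do.call(model_config, mc_args)
      fc <- .fit_config_from(config, seed)
      ft <- fit(data, mc, fc)
      f1 <- file.path(out_dir, "diagnostics.csv")
      utils::write.csv(diagnostics(ft), f1, row.names = FALSE)
      f2 <- file.path(out_dir, "population_summary.csv")
      utils::write.csv(population_summary(ft), f2, row.names = FALSE)
      f3 <- file.path(out_dir, "param_draws.csv")
      utils::write.csv(ft$params, f3, row.names = FALSE)
      f4 <- file.path(out_dir, "mu_draws.csv")
      utils::write.csv(as.data.frame(ft$mu), f4, row.names = FALSE)
      written <- c(f1, f2, f3, f4)
      if (subcommand == "ppc") {
        n_rep <- if (is.null(config$n_rep)) 1000L else
          as.integer(config$n_rep)
        ppc <- posterior_predictive(ft, n_rep = n_rep, seed = seed)
        band <- apply(ppc$census_rep, 2, stats::quantile,
                      c(0.025, 0.5, 0.975), na.rm = TRUE)
        f5 <- file.path(out_dir, "ppc_census_band.csv")
        utils::write.csv(
          data.frame(year = as.integer(colnames(ppc$census_rep)),
                     q2.5 = band[1, ], median = band[2, ],
                     q97.5 = band[3, ],
                     observed = unname(data$C[colnames(ppc$census_rep)])),
          f5, row.names = FALSE)
        written <- c(written, f5)
      }
    } else if (subcommand == "analyze") {
      mu <- as.matrix(utils::read.csv(config$mu_draws, check.names = FALSE))
      inputs <- config$mu_draws
      reqs <- config$requests
      out <- list()
      for (rq in reqs) {
        out[[rq$name]] <- switch(rq$op,
          growth = as.list(growth_rate_probabilities(
            mu, as.integer(rq$period), as.numeric(rq$cutpoints))),
          drop = drop_magnitude(mu, rq$year_hi, rq$year_lo)[c("mean", "q2.5", "q97.5")],
          extremum = extremum_years(mu, as.integer(rq$range), rq$mode)[
            c("median_year", "magnitude_mean", "magnitude_q2.5",
              "magnitude_q97.5")],
          first_return = first_return_year(mu, rq$reference_year)[
            c("median_year", "q2.5", "q97.5", "prop_censored")],
          stop("unknown analysis op: ", rq$op))
      }
      f <- file.path(out_dir, "derived_quantities.json")
      jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
      written <- f
    }
    .write_manifest(out_dir, subcommand, config, seed, inputs)
    invisible(c(written, file.path(out_dir, "manifest.json")))
  }, error = on_fail)
}
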