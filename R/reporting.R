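#' Relative yield gain of the test group
#'
#' `100 * (mu_test - mu_control) / mu_control`, rounded half-up to the
#' nearest integer percent — the "Gain (%)" column of the results table.
#'
#' @param mu_test,mu_control group mean yields (kg/ha); `mu_control` must
#'   be positive. Vectorised.
#' @return Integer percent gain(s).
#' @examples
#' compute_gain(3540, 2550)  # 39
#' @export
compute_gain <- function(mu_test, mu_control) {
  if (any(mu_control <= 0))
    stop("mu_control must be positive", call. = FALSE)
  g <- 100 * (mu_test - mu_control) / mu_control
  as.integer(sign(g) * floor(abs(g) + 0.5))
}

#' Configure a full analysis run
#'
#' Everything [run_pipeline()] needs: where the data come from (a
#' simulation or a file), how they are prepared, how the posteriors are
#' sampled, and how the contrast is summarised. One master `seed` drives
#' derived substreams for simulation, sampling, chain initialisation and
#' the predictive contrast, so a config reproduces its run exactly.
#'
#' @param location label for the report row.
#' @param layouts a [field_layout()] for simulation; ignored when
#'   `input` is given.
#' @param sim a [sim_config()]; its `seed` is overridden by `seed`.
#' @param input optional path to a measurements file (CSV/GeoJSON)
#'   instead of simulating.
#' @param target_per_group balanced sample size per group; `NULL` for the
#'   smaller group's size.
#' @param filter_scope scope of the 3-sigma filter ([three_sigma_filter()]).
#' @param sampler a [sampler_config()]; its `seed` is overridden.
#' @param contrast_mode `"predictive"` or `"parameter"`.
#' @param hdi_mass HDI probability mass.
#' @param seed master seed for the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(location = "SIM",
                            layouts = example_layouts(),
                            sim = sim_config(),
                            input = NULL,
                            target_per_group = NULL,
                            filter_scope = "group",
                            sampler = sampler_config(),
                            contrast_mode = "predictive",
                            hdi_mass = 0.95,
                            seed = 42L) {
  structure(list(location = location, layouts = layouts, sim = sim,
                 input = input, target_per_group = target_per_group,
                 filter_scope = filter_scope, sampler = sampler,
                 contrast_mode = contrast_mode, hdi_mass = hdi_mass,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full yield-comparison pipeline
#'
#' Simulate (or ingest) polygon-level yield measurements, remove gross
#' outliers with the 3-sigma rule, balance test and control groups by
#' stratified sampling, fit each group's normal model by MCMC, and
#' summarise the treatment effect. Every stage's seed and report is kept
#' in the returned provenance so the run can be reproduced exactly.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, the measurements,
#'   posterior draws, contrast draws and the report are written there.
#' @param verbose print stage-by-stage progress (default `TRUE`).
#' @return An `analysis_report`: `location`, `mu_test`, `mu_control`,
#'   `contrast_mean`, `gain_percent`, `superiority_percent`, `hdi_low`,
#'   `hdi_high`, the full `contrast_result` and both posteriors, and a
#'   `provenance` list (config, derived seeds, filter report, sampling
#'   plan).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(layouts = example_layouts(1, 60, 200),
#'                        sampler = sampler_config(n_iterations = 2000,
#'                                                 n_burnin = 500),
#'                        seed = 7)
#' run_pipeline(cfg, verbose = FALSE)
#' }
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- derive_seeds(config$seed, 4)
  names(seeds) <- c("simulate", "sample", "mcmc", "contrast")
  stage <- "simulate/ingest"
  report <- tryCatch({
      if (is.null(config$input)) {
        sim <- config$sim; sim$seed <- seeds[["simulate"]]
        meas <- simulate_measurements(config$layouts, sim)
        say("simulate: %d measurements from %d fields", nrow(meas),
            nrow(config$layouts))
      } else {
        meas <- read_measurements(config$input)
        say("ingest: %d measurements from %s", nrow(meas), config$input)
      }

      stage <- "filter"
      flt <- three_sigma_filter(meas, scope = config$filter_scope)
      say("filter: removed %d of %d (3-sigma, per %s)",
          sum(flt$report$n_removed), nrow(meas), config$filter_scope)

      stage <- "sample"
      bal <- stratified_balance_sample(flt$kept, config$target_per_group,
                                       seed = seeds[["sample"]])
      say("sample: balanced to %d per group",
          attr(bal$plan, "target_per_group"))

      stage <- "fit"
      scfg <- config$sampler
      mcmc_seeds <- derive_seeds(seeds[["mcmc"]], 2)
      scfg$seed <- mcmc_seeds[1]
      post_t <- fit_group(bal$sample[bal$sample$group == "test", ],
                          config = scfg)
      scfg$seed <- mcmc_seeds[2]
      post_c <- fit_group(bal$sample[bal$sample$group == "control", ],
                          config = scfg)
      say("fit: mu_test %.0f, mu_control %.0f kg/ha (max rhat %.3f)",
          mean(post_t$draws$mu), mean(post_c$draws$mu),
          max(post_t$rhat, post_c$rhat))

      stage <- "contrast"
      ctr <- contrast_posterior(post_t, post_c, mode = config$contrast_mode,
                                hdi_mass = config$hdi_mass,
                                seed = seeds[["contrast"]])
      say("contrast: mean %.0f kg/ha, P(test > control) %.2f",
          ctr$contrast_mean, ctr$superiority_prob)

      mu_t <- mean(post_t$draws$mu); mu_c <- mean(post_c$draws$mu)
      structure(list(
        location = config$location,
        mu_test = mu_t, mu_control = mu_c,
        contrast_mean = ctr$contrast_mean,
        gain_percent = compute_gain(mu_t, mu_c),
        superiority_percent = 100 * ctr$superiority_prob,
        hdi_low = ctr$hdi_low, hdi_high = ctr$hdi_high,
        hdi_mass = config$hdi_mass,
        contrast = ctr, posterior_test = post_t, posterior_control = post_c,
        provenance = list(config = config, seeds = seeds,
                          filter_report = flt$report,
                          sampling_plan = bal$plan,
                          measurements = meas)
      ), class = "analysis_report")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s' (location %s, seed %d): %s",
                 stage, config$location, config$seed, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Tabulate one or more analysis reports
#'
#' Display-style rows: yields rounded to the nearest 10 kg/ha and
#' percentages to integers, matching how such results tables are printed.
#' Full precision stays in the `analysis_report` objects.
#'
#' @param ... `analysis_report` objects (or one list of them).
#' @return Data frame with one row per location.
#' @export
report_table <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && !inherits(reports[[1]], "analysis_report"))
    reports <- reports[[1]]
  do.call(rbind, lapply(reports, function(r) data.frame(
    location = r$location,
    mu_test = round(r$mu_test, -1),
    mu_control = round(r$mu_control, -1),
    contrast_mean = round(r$contrast_mean, -1),
    gain_percent = r$gain_percent,
    superiority_percent = as.integer(round(r$superiority_percent)),
    hdi_low = round(r$hdi_low, -1),
    hdi_high = round(r$hdi_high, -1)
  )))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report — %s\n", x$location))
  cat(sprintf("  mu_test      %7.0f kg/ha\n", round(x$mu_test, -1)))
  cat(sprintf("  mu_control   %7.0f kg/ha\n", round(x$mu_control, -1)))
  cat(sprintf("  contrast     %7.0f kg/ha  (%s mode)\n",
              round(x$contrast_mean, -1), x$contrast$mode))
  cat(sprintf("  gain         %7d %%\n", x$gain_percent))
  cat(sprintf("  %.0f%% HDI     [%.0f, %.0f] kg/ha\n",
              100 * x$hdi_mass, round(x$hdi_low, -1), round(x$hdi_high, -1)))
  cat(sprintf("  superiority  %7.0f %% of observed area\n",
              round(x$superiority_percent)))
  invisible(x)
}

#' Persist an analysis report
#'
#' Writes the measurements (CSV), both groups' posterior draws, the
#' contrast draws, a human-readable `report.txt` and a machine-readable
#' `report.json` mirroring the report fields (plus seeds and stage
#' reports) into `dir`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_measurements_csv(report$provenance$measurements,
                         file.path(dir, "measurements.csv"))
  write_posterior_csv(report$posterior_test,
                      file.path(dir, "posterior_test.csv"))
  write_posterior_csv(report$posterior_control,
                      file.path(dir, "posterior_control.csv"))
  write_contrast(report$contrast,
                 draws_path = file.path(dir, "contrast_draws.csv"))
  scalar <- report[c("location", "mu_test", "mu_control", "contrast_mean",
                     "gain_percent", "superiority_percent",
                     "hdi_low", "hdi_high", "hdi_mass")]
  scalar$contrast_mode <- report$contrast$mode
  scalar$seed <- report$provenance$config$seed
  scalar$stage_seeds <- as.list(report$provenance$seeds)
  scalar$filter_report <- report$provenance$filter_report
  scalar$sampling_plan <- as.data.frame(report$provenance$sampling_plan)
  jsonlite::write_json(scalar, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Three-panel summary plot
#'
#' Base-graphics figure per location: the two group posteriors of `mu`
#' (left), the contrast distribution with its HDI marked (centre), and
#' the probability of superiority (right).
#'
#' @param x an `analysis_report`.
#' @param ... further arguments, ignored.
#' @return `x`, invisibly.
#' @export
plot.analysis_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  dt <- x$posterior_test$draws$mu; dc <- x$posterior_control$draws$mu
  xr <- range(dt, dc)
  graphics::hist(dc, breaks = 40, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, xlim = xr, freq = FALSE, xlab = "mu (kg/ha)",
                 main = sprintf("%s: group posteriors", x$location))
  graphics::hist(dt, breaks = 40, col = grDevices::adjustcolor("forestgreen", 0.5),
                 border = NA, freq = FALSE, add = TRUE)
  graphics::legend("topright", c("test", "control"), bty = "n",
                   fill = grDevices::adjustcolor(c("forestgreen", "firebrick"), 0.5))
  graphics::hist(x$contrast$draws, breaks = 50, col = "grey70", border = NA,
                 freq = FALSE, xlab = "contrast (kg/ha)",
                 main = "contrast distribution")
  graphics::abline(v = c(x$hdi_low, x$hdi_high), lty = 2)
  graphics::abline(v = 0, col = "firebrick")
  graphics::mtext(sprintf("%.0f%% HDI [%.0f, %.0f]", 100 * x$hdi_mass,
                          x$hdi_low, x$hdi_high), side = 3, line = -1.5,
                  cex = 0.7)
  p <- x$superiority_percent / 100
  graphics::barplot(c(`test > control` = p, `otherwise` = 1 - p),
                    ylim = c(0, 1), col = c("forestgreen", "grey80"),
                    main = sprintf("P(superiority) = %.2f", p))
  invisible(x)
}
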