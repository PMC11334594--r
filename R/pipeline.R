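#' Run configuration for the end-to-end analysis
#'
#' Flat key-value (YAML) configuration binding the pipeline stages. Unknown
#' keys are rejected. Recognized keys and defaults:
#' `J_pde` (200), `J_dist` (300), `cfl_safety` (0.9), `coverage` (0.95),
#' `robust` (TRUE), `granularity` (1000), `x_max` (NULL = estimate from
#' data), `points` (8), `levels` (4), `coarse_levels` (2, grid-search
#' levels run at the coarser PDE resolution), `J_pde_coarse` (100),
#' `seed` (1), `time_unit` ("day").
#'
#' @param config a named list, or a path to a YAML file
#' @return validated config list of class `relax_config`
#' @export
relax_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(J_pde = 200L, J_dist = 300L, cfl_safety = 0.9,
                   coverage = 0.95, robust = TRUE, granularity = 1000,
                   x_max = NULL, points = 8L, levels = 4L,
                   coarse_levels = 2L, J_pde_coarse = 100L, seed = 1L,
                   time_unit = "day")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config, keep.null = TRUE)
  stopifnot(out$J_pde >= 2, out$J_dist >= 2,
            out$cfl_safety > 0, out$cfl_safety <= 1,
            out$coverage > 0, out$coverage < 1,
            out$points >= 1, out$levels >= 1)
  structure(out, class = "relax_config")
}

#' Generate a synthetic dataset (pipeline wrapper)
#'
#' @param cfg a [synthetic_config()]
#' @param dir output directory
#' @return the dataset manifest, invisibly
#' @export
run_synth <- function(cfg, dir) generate_experiment(cfg, dir)

#' Fit the model to a relaxation dataset (pipeline wrapper)
#'
#' Preprocesses the event files (gate, shift, rescale), estimates the
#' growth rate by log-linear regression of the counts, and calibrates
#' \eqn{(r_1, k_{on}, k_{off}, d)} by refined grid search on the summed
#' two-arm KT distance, completing \eqn{r_0} from the growth rate.
#'
#' @param data_dir directory with `<arm>_day<D>.csv` and `counts.csv`
#' @param config a [relax_config()] (or list / YAML path accepted by it)
#' @param out optional path for a JSON result file
#' @param dry_run if `TRUE`, validate the config and data layout only
#' @return list with `fit` (a `relax_fit`), `growth`, `dataset`, `prep`,
#'   `config`
#' @export
run_fit <- function(data_dir, config = list(), out = NULL,
                    dry_run = FALSE) {
  cfg <- relax_config(config)
  if (!dir.exists(data_dir)) stop("no such data directory: ", data_dir)
  if (!file.exists(file.path(data_dir, "counts.csv")))
    stop("missing counts file: ", file.path(data_dir, "counts.csv"))
  if (dry_run) return(invisible(list(config = cfg, ok = TRUE)))
  dataset <- process_dataset(data_dir, coverage = cfg$coverage,
                             robust = cfg$robust, x_max = cfg$x_max,
                             granularity = cfg$granularity)
  growth <- fit_growth_rate(dataset$counts)
  prep <- prepare_fit_data(dataset, J_pde = cfg$J_pde, J_dist = cfg$J_dist)
  prep_coarse <- if (cfg$coarse_levels > 0)
    prepare_fit_data(dataset, J_pde = cfg$J_pde_coarse,
                     J_dist = cfg$J_dist) else NULL
  fit <- grid_search(prep, growth$lambda, points = cfg$points,
                     levels = cfg$levels, cfl_safety = cfg$cfl_safety,
                     prep_coarse = prep_coarse,
                     coarse_levels = cfg$coarse_levels)
  result <- list(fit = fit, growth = growth, dataset = dataset,
                 prep = prep, config = cfg)
  if (!is.null(out)) {
    per_day <- kt_objective(fit$par[["r1"]], fit$par[["k_on"]],
                            fit$par[["k_off"]], fit$par[["d"]], prep,
                            growth$lambda, cfl_safety = cfg$cfl_safety,
                            per_day = TRUE)
    jsonlite::write_json(list(
      params = as.list(fit$par), r0 = fit$r0, lambda = fit$lambda,
      s = fit$s, objective = fit$objective,
      lambda_plus = growth$lambda_plus,
      lambda_minus = growth$lambda_minus,
      x_max = dataset$x_max,
      per_day_distances = per_day$per_day),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Per-day model/data distances and the data-vs-data reference distance
#'
#' Tabulates the modified KT distance between the fitted model and each
#' arm/day, together with the distance between the two arms' empirical
#' distributions per day; the minimum of the latter (reached once both
#' arms have relaxed) serves as the reference distance below which model
#' and data are as close as two replicate experiments.
#'
#' @param result a [run_fit()] result
#' @return list with `per_day` (data.frame `arm,day,distance`),
#'   `between_arms` (data.frame `day,distance`), `reference` (scalar)
#' @export
run_report <- function(result) {
  prep <- result$prep
  fit <- result$fit
  pd <- kt_objective(fit$par[["r1"]], fit$par[["k_on"]],
                     fit$par[["k_off"]], fit$par[["d"]], prep,
                     result$growth$lambda,
                     cfl_safety = result$config$cfl_safety,
                     per_day = TRUE)
  arms <- names(prep$arms)
  between <- if (length(arms) == 2) {
    data.frame(day = prep$obs_days,
               distance = vapply(as.character(prep$obs_days), function(dd)
                 kt_log(prep$arms[[arms[1]]]$cdfs[[dd]],
                        prep$arms[[arms[2]]]$cdfs[[dd]]),
                 numeric(1)))
  } else NULL
  list(per_day = pd$per_day, between_arms = between,
       reference = if (!is.null(between)) min(between$distance) else NA_real_)
}

#' Diagnostic plots for a fitted relaxation experiment
#'
#' Base-graphics panels: log-count growth fit, per-day distance evolution
#' against the reference distance, and a model/data overlay for selected
#' days.
#'
#' @param result a [run_fit()] result
#' @param report a [run_report()] result (recomputed if missing)
#' @export
plot_relax_fit <- function(result, report = NULL) {
  if (is.null(report)) report <- run_report(result)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cc <- result$dataset$counts
  graphics::plot(cc$day, log(cc$count),
                 col = ifelse(cc$arm == "plus", 2, 3), pch = 15,
                 xlab = "day", ylab = "log cell count",
                 main = sprintf("growth fit, lambda = %.3f",
                                result$growth$lambda))
  for (a in unique(cc$arm))
    graphics::abline(result$growth$fits[[a]], lty = 2)
  pd <- report$per_day
  graphics::plot(pd$day, pd$distance,
                 col = ifelse(pd$arm == "plus", 2, 3), pch = 4,
                 xlab = "day", ylab = "modified KT distance",
                 main = "model vs data")
  if (!is.null(report$between_arms)) {
    graphics::points(report$between_arms$day, report$between_arms$distance,
                     pch = 15)
    graphics::abline(h = report$reference, lty = 3)
  }
  invisible(report)
}
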