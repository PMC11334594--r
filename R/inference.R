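#' Exponential growth rate from cell counts
#'
#' Ordinary least-squares slope of `log(count)` against day, fitted per arm;
#' the population growth rate is estimated by the average of the two arms'
#' slopes.
#'
#' @param counts data.frame with columns `arm` (`"plus"`/`"minus"`), `day`,
#'   `count` (> 0); at least 2 days per arm
#' @return list with `lambda_plus`, `lambda_minus`, `lambda` (their mean)
#'   and the per-arm `fits`
#' @export
fit_growth_rate <- function(counts) {
  stopifnot(all(c("arm", "day", "count") %in% names(counts)))
  if (any(counts$count <= 0)) stop("counts must be positive")
  fits <- lapply(split(counts, counts$arm), function(cc) {
    if (length(unique(cc$day)) < 2)
      stop("need counts on at least 2 days per arm")
    stats::lm(log(count) ~ day, data = cc)
  })
  slope <- function(f) unname(stats::coef(f)["day"])
  lp <- if ("plus" %in% names(fits)) slope(fits$plus) else NA_real_
  lm_ <- if ("minus" %in% names(fits)) slope(fits$minus) else NA_real_
  list(lambda_plus = lp, lambda_minus = lm_,
       lambda = mean(c(lp, lm_), na.rm = TRUE), fits = fits)
}

#' Complete the constant proliferation rate from the growth rate
#'
#' Inverts \eqn{\lambda = r_0 + s(M)}: since \eqn{s(M)} depends only on
#' \eqn{(r_1, k_{on}, k_{off})}, a measured growth rate pins
#' \eqn{r_0 = \lambda - s(M)}, reducing the distribution fit to four free
#' parameters.
#'
#' @param lambda measured growth rate (per unit time)
#' @param r1,k_on,k_off the other rate parameters
#' @param strict error if the implied `r0` is negative
#' @return the implied `r0`
#' @examples
#' r0_from_lambda(0.42, -0.426, 0.261, 19.178)  # ~0.426
#' @export
r0_from_lambda <- function(lambda, r1, k_on, k_off, strict = TRUE) {
  s_M <- perron_sM(r1, k_on, k_off)
  r0 <- lambda - s_M
  if (strict && r0 < 0)
    stop("implied r0 = ", signif(r0, 6), " is negative")
  r0
}

#' Assemble the fitting inputs from a processed dataset
#'
#' Reserves the earliest day for initialization: its per-arm histogram on
#' the PDE grid seeds the solver (split by the parameter-dependent
#' asymptotic repartition at evaluation time), while every later day enters
#' the objective through its log-scale empirical CDF.
#'
#' @param dataset a `relax_dataset` from [process_dataset()]
#' @param J_pde number of PDE cells (default 200)
#' @param J_dist number of distance-grid bins (default 300)
#' @return object of class `relax_fit_data`
#' @export
prepare_fit_data <- function(dataset, J_pde = 200, J_dist = 300) {
  stopifnot(inherits(dataset, "relax_dataset"))
  grid <- pde_grid(J_pde)
  lgrid <- log_grid(J_dist, dataset$x_max)
  arms <- unique(vapply(dataset$samples, `[[`, character(1), "arm"))
  days <- sort(unique(vapply(dataset$samples, `[[`, integer(1), "day")))
  day0 <- days[1]
  obs_days <- days[-1]
  per_arm <- lapply(arms, function(a) {
    ss <- Filter(function(s) s$arm == a, dataset$samples)
    sdays <- vapply(ss, `[[`, integer(1), "day")
    s0 <- ss[[which(sdays == day0)]]
    h0 <- graphics::hist(s0$x, breaks = grid$edges, plot = FALSE)$counts
    cdfs <- lapply(obs_days, function(dd)
      data_log_cdf(ss[[which(sdays == dd)]]$x, lgrid))
    names(cdfs) <- as.character(obs_days)
    list(arm = a, hist0 = h0, cdfs = cdfs)
  })
  names(per_arm) <- arms
  structure(list(arms = per_arm, grid = grid, lgrid = lgrid,
                 x_max = dataset$x_max, day0 = day0, obs_days = obs_days),
            class = "relax_fit_data")
}

## model log-CDF at an observation snapshot: interpolate the cell-centered
## PDE density to the distance-grid nodes (endpoint nodes take the nearest
## cell-center value, consistent with the solver's cell offsets)
model_cdf_from_state <- function(state, lgrid) {
  dens <- state$n_on + state$n_off
  m <- stats::approx(state$grid$centers, dens, xout = lgrid$x, rule = 2)$y
  model_log_cdf(m, lgrid)
}

#' Summed two-arm modified KT distance objective
#'
#' For a candidate \eqn{(r_1, k_{on}, k_{off}, d)}: completes
#' \eqn{r_0 = \lambda - s(M)} from the measured growth rate, seeds the PDE
#' per arm from the initialization-day histogram split by the asymptotic
#' on-fraction, evolves to every later observation day, and sums the
#' log-scale Kantorovich-Rubinstein distances over days and arms. Returns
#' `Inf` for inadmissible candidates (implied `r0 < 0` or
#' `r0 + r1 < 0`).
#'
#' @param r1,k_on,k_off,d candidate rates
#' @param prep a `relax_fit_data` from [prepare_fit_data()]
#' @param lambda measured growth rate (held fixed)
#' @param cfl_safety time-step safety factor for the PDE solves
#' @param per_day if `TRUE`, also return the per-(arm, day) distances
#' @return the objective value (or a list when `per_day = TRUE`)
#' @export
kt_objective <- function(r1, k_on, k_off, d, prep, lambda,
                         cfl_safety = 0.9, per_day = FALSE) {
  stopifnot(inherits(prep, "relax_fit_data"))
  if (!(k_on > 0 && k_off > 0 && d > 0)) return(Inf)
  s_M <- tryCatch(perron_sM(r1, k_on, k_off), error = function(e) NA_real_)
  if (!is.finite(s_M)) return(Inf)
  r0 <- lambda - s_M
  if (r0 < 0 || r0 + r1 < 0) return(Inf)
  params <- model_params(k_on = k_on, k_off = k_off, d = d,
                         x_max = prep$x_max, r0 = r0, r1 = r1,
                         mode = "permissive")
  t_out <- prep$obs_days - prep$day0
  rows <- list()
  total <- 0
  for (arm in names(prep$arms)) {
    pa <- prep$arms[[arm]]
    state <- split_initial(pa$hist0, params, prep$grid, t0 = 0)
    traj <- pde_evolve(state, max(t_out), params, output_times = t_out,
                       cfl_safety = cfl_safety)
    for (i in seq_along(t_out)) {
      M <- model_cdf_from_state(traj$states[[i]], prep$lgrid)
      dist <- kt_log(pa$cdfs[[i]], M)
      total <- total + dist
      if (per_day)
        rows[[length(rows) + 1]] <- data.frame(
          arm = arm, day = prep$obs_days[i], distance = dist)
    }
  }
  if (per_day)
    list(objective = total, per_day = do.call(rbind, rows))
  else total
}

#' Default grid-search bounds
#'
#' Log-spaced boxes for the rates, a linear box for `r1` bounded below by
#' minus twice the measured growth rate (the admissibility constraint
#' `r0 + r1 >= 0` is additionally enforced per candidate).
#'
#' @param lambda measured growth rate
#' @return named list of `c(lo, hi)` bounds
#' @export
default_bounds <- function(lambda) {
  list(r1 = c(-2 * lambda, 0), k_on = c(0.01, 10), k_off = c(0.1, 100),
       d = c(0.01, 2))
}

## grid for one level: log-spaced except r1 (linear)
level_grid <- function(lo, hi, points, log_scale) {
  if (points == 1) return((lo + hi) / 2)
  if (log_scale) exp(seq(log(lo), log(hi), length.out = points))
  else seq(lo, hi, length.out = points)
}

#' Refined grid-search minimization of the KT objective
#'
#' Evaluates the objective on a full factorial grid (8 points per axis by
#' default; log-spaced in `k_on`, `k_off`, `d`, linear in `r1`), recentres
#' a grid shrunk by a factor 0.5 per level on the current argmin (clipped
#' to the original bounds), and repeats for `levels` refinement levels.
#' Ties are broken by the lexicographically smallest
#' \eqn{(r_1, k_{on}, k_{off}, d)} tuple.
#'
#' @param prep a `relax_fit_data`
#' @param lambda measured growth rate (held fixed)
#' @param bounds named list of `c(lo, hi)` per parameter (see
#'   [default_bounds()])
#' @param points points per axis (>= 1)
#' @param levels number of refinement levels (>= 1)
#' @param fixed optional named list pinning parameters (used by profile
#'   curves)
#' @param cfl_safety passed to [kt_objective()]
#' @param prep_coarse optional coarser `relax_fit_data` (e.g. half the PDE
#'   cells) used for the first `coarse_levels` exploration levels; the
#'   final levels always use `prep`
#' @param coarse_levels number of initial levels evaluated on `prep_coarse`
#' @return object of class `relax_fit`: list with `par` (named best tuple —
#'   the minimum over all full-resolution evaluations in the log), `r0`,
#'   `lambda`, `s`, `objective`, `log` (every evaluation), `boundary`
#'   (TRUE if the best tuple sits on an original bound)
#' @export
grid_search <- function(prep, lambda, bounds = default_bounds(lambda),
                        points = 8, levels = 4, fixed = list(),
                        cfl_safety = 0.9, prep_coarse = NULL,
                        coarse_levels = 0) {
  stopifnot(levels >= 1, points >= 1)
  if (is.null(prep_coarse)) coarse_levels <- 0
  par_names <- c("r1", "k_on", "k_off", "d")
  free <- setdiff(par_names, names(fixed))
  log_scale <- c(r1 = FALSE, k_on = TRUE, k_off = TRUE, d = TRUE)
  cur <- bounds[free]
  log_rows <- list()
  best <- NULL
  for (lev in seq_len(levels)) {
    axes <- lapply(free, function(p)
      level_grid(cur[[p]][1], cur[[p]][2], points, log_scale[[p]]))
    names(axes) <- free
    # lexicographic row order in (r1, k_on, k_off, d): expand.grid varies
    # its first factor fastest, so list axes in reverse priority
    gr <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
    gr <- gr[, rev(seq_along(free)), drop = FALSE]
    for (p in names(fixed)) gr[[p]] <- fixed[[p]]
    prep_lev <- if (lev <= coarse_levels) prep_coarse else prep
    obj <- vapply(seq_len(nrow(gr)), function(i)
      kt_objective(gr$r1[i], gr$k_on[i], gr$k_off[i], gr$d[i],
                   prep_lev, lambda, cfl_safety = cfl_safety),
      numeric(1))
    if (all(!is.finite(obj)))
      stop("no admissible parameter tuple at level ", lev)
    log_rows[[lev]] <- cbind(gr[par_names], objective = obj, level = lev,
                             fine = lev > coarse_levels)
    ib <- which.min(obj)  # first minimum = lexicographically smallest tuple
    best <- list(par = unlist(gr[ib, par_names]), objective = obj[ib])
    # shrink each free axis around the argmin by a factor 0.5, clip to bounds
    if (lev < levels) {
      cur <- lapply(free, function(p) {
        b0 <- bounds[[p]]
        ctr <- best$par[[p]]
        if (log_scale[[p]]) {
          half <- (log(cur[[p]][2]) - log(cur[[p]][1])) / 4
          lo <- exp(log(ctr) - half); hi <- exp(log(ctr) + half)
        } else {
          half <- (cur[[p]][2] - cur[[p]][1]) / 4
          lo <- ctr - half; hi <- ctr + half
        }
        c(max(lo, b0[1]), min(hi, b0[2]))
      })
      names(cur) <- free
    }
  }
  # reported best: the minimum over every full-resolution evaluation (the
  # level argmins above only steer the recentring)
  full_log <- do.call(rbind, log_rows)
  fine_log <- full_log[full_log$fine, , drop = FALSE]
  if (nrow(fine_log) == 0 || all(!is.finite(fine_log$objective)))
    fine_log <- full_log
  ib <- which.min(fine_log$objective)
  best <- list(par = unlist(fine_log[ib, par_names]),
               objective = fine_log$objective[ib])
  on_bound <- any(vapply(free, function(p) {
    b0 <- bounds[[p]]
    if (b0[1] == b0[2]) return(FALSE)  # deliberately pinned, not a hit
    v <- best$par[[p]]
    isTRUE(all.equal(v, b0[1])) || isTRUE(all.equal(v, b0[2]))
  }, logical(1)))
  if (on_bound)
    warning("grid-search argmin lies on a parameter bound")
  r0 <- r0_from_lambda(lambda, best$par[["r1"]], best$par[["k_on"]],
                       best$par[["k_off"]], strict = FALSE)
  structure(list(par = best$par, r0 = r0, lambda = lambda,
                 s = best$par[["d"]] * prep$x_max,
                 objective = best$objective,
                 log = full_log, boundary = on_bound,
                 bounds = bounds, points = points, levels = levels),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat("grid-search fit (modified KT distance)\n")
  cat(sprintf("  r1 = %.4g, k_on = %.4g, k_off = %.4g, d = %.4g\n",
              x$par[["r1"]], x$par[["k_on"]], x$par[["k_off"]],
              x$par[["d"]]))
  cat(sprintf("  implied r0 = %.4g (lambda = %.4g), s = %.4g\n",
              x$r0, x$lambda, x$s))
  cat(sprintf("  objective = %.6g over %d evaluations%s\n", x$objective,
              nrow(x$log), if (x$boundary) "  [argmin on bound]" else ""))
  invisible(x)
}

#' Profile-likelihood style identifiability curve
#'
#' Holds one parameter fixed at each of `values` and re-minimizes the KT
#' objective over the remaining three by [grid_search()]; the resulting
#' curve \eqn{S(p / p^\star)} traces how sharply the objective deteriorates
#' away from the optimum — flat curves flag weakly identified parameters.
#'
#' @param name one of `"d"`, `"k_on"`, `"k_off"`, `"r1"`
#' @param values absolute parameter values at which to profile
#' @param prep a `relax_fit_data`
#' @param lambda measured growth rate
#' @param fit the global [grid_search()] fit (supplies the optimum)
#' @param points,levels grid-search size for the nuisance re-optimization
#' @param cfl_safety passed through to the objective
#' @return object of class `profile_curve`: data.frame with columns `value`,
#'   `rel` (= value / optimum), `S`, and the re-optimized nuisance
#'   parameters
#' @param ... further arguments passed to [grid_search()] (e.g.
#'   `prep_coarse`)
#' @export
profile_curve <- function(name, values, prep, lambda, fit,
                          points = 6, levels = 3, cfl_safety = 0.9, ...) {
  stopifnot(name %in% c("d", "k_on", "k_off", "r1"),
            inherits(fit, "relax_fit"))
  opt <- fit$par[[name]]
  if (opt != 0 && (min(values) > opt || max(values) < opt))
    warning("profiled values do not bracket the optimum")
  # warm-started nuisance windows around the global optimum: a factor-4
  # log window for the rates, +/- 0.5 lambda for r1, clipped to the fit's
  # outer bounds
  nuis <- setdiff(c("r1", "k_on", "k_off", "d"), name)
  win <- lapply(nuis, function(p) {
    b0 <- fit$bounds[[p]]
    v <- fit$par[[p]]
    if (p == "r1") c(max(v - 0.5 * lambda, b0[1]),
                     min(v + 0.5 * lambda, b0[2]))
    else c(max(v / 4, b0[1]), min(v * 4, b0[2]))
  })
  names(win) <- nuis
  rows <- lapply(values, function(v) {
    fixed <- stats::setNames(list(v), name)
    sub <- suppressWarnings(
      grid_search(prep, lambda, bounds = win, points = points,
                  levels = levels, fixed = fixed,
                  cfl_safety = cfl_safety, ...))
    out <- as.list(sub$par)
    out$S <- sub$objective
    out
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$value <- values
  df$rel <- if (opt != 0) values / opt else values
  df <- df[c("value", "rel", "S",
             setdiff(c("r1", "k_on", "k_off", "d"), name))]
  structure(df, class = c("profile_curve", "data.frame"), param = name,
            optimum = opt)
}
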