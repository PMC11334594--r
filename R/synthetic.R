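#' Configuration of a synthetic relaxation experiment
#'
#' Defaults emulate the CD34 relaxation study design: the 10% most positive
#' and 10% most negative cells of the stationary law are sorted into two
#' arms, cultured, and measured on days 2, 5, 9, 13, 19, 23, 26 and 30
#' (day 2 initializes the model). Ground-truth rates default to the fitted
#' CD34 parameter set. Instrument artefacts exercised downstream: a
#' negative fluorescence baseline (removed by shifting), a debris cluster
#' in (FSC, SSC) (removed by gating), and multiplicative lognormal noise on
#' the cell counts.
#'
#' @param params true [model_params()]; default is the fitted CD34 set
#' @param sort_fraction sorted tail fraction per arm (default 0.10)
#' @param days measurement schedule (first day initializes)
#' @param n_events fluorescence events recorded per (arm, day)
#' @param n0 population size at the first day (count scale)
#' @param baseline additive fluorescence offset (< 0; removed by shifting)
#' @param debris_frac fraction of recorded events that are debris
#' @param count_sigma lognormal sd of the multiplicative count noise
#' @param seed RNG seed recorded in the manifest
#' @param J_pde PDE cells used to evolve the arms
#' @param viable_mean,viable_sd (FSC, SSC) location and sd of viable cells
#' @param debris_mean,debris_sd (FSC, SSC) location and sd of debris
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(params = model_params(k_on = 0.261,
                                                   k_off = 19.178,
                                                   d = 0.21, x_max = 2e4,
                                                   r0 = 0.426, r1 = -0.426),
                             sort_fraction = 0.10,
                             days = c(2, 5, 9, 13, 19, 23, 26, 30),
                             n_events = 20000, n0 = 1e5,
                             baseline = -50, debris_frac = 0.2,
                             count_sigma = 0.1, seed = 1, J_pde = 200,
                             viable_mean = c(130000, 45000),
                             viable_sd = c(10000, 6000),
                             debris_mean = c(15000, 25000),
                             debris_sd = c(4000, 8000)) {
  stopifnot(inherits(params, "relax_params"),
            sort_fraction > 0, sort_fraction < 0.5,
            length(days) >= 2, n_events > 0, n0 > 0,
            baseline <= 0, debris_frac >= 0, debris_frac < 1,
            count_sigma >= 0)
  structure(list(params = params, sort_fraction = sort_fraction,
                 days = sort(days), n_events = as.integer(n_events),
                 n0 = n0, baseline = baseline, debris_frac = debris_frac,
                 count_sigma = count_sigma, seed = as.integer(seed),
                 J_pde = as.integer(J_pde),
                 viable_mean = viable_mean, viable_sd = viable_sd,
                 debris_mean = debris_mean, debris_sd = debris_sd),
            class = "synthetic_config")
}

#' Sample scaled levels from a gridded density
#'
#' Inverse-CDF sampling over the grid cells with uniform within-cell
#' jitter.
#'
#' @param dens nonnegative density values at the cell centers of `grid`
#' @param grid a [pde_grid()] (or a `relax_profile`, in which case `dens`
#'   may be omitted)
#' @param n number of draws
#' @return numeric vector of levels in \[0,1\]
#' @export
sample_profile <- function(dens, grid, n) {
  if (inherits(dens, "relax_profile")) {
    pr <- dens
    dx <- diff(pr$x)
    stopifnot(max(abs(diff(dx))) < 1e-9)  # uniform grid expected
    dx <- dx[1]
    p <- pr$N
    left <- pr$x - dx / 2
  } else {
    stopifnot(inherits(grid, "pde_grid"), length(dens) == grid$J)
    p <- dens
    dx <- grid$dx
    left <- grid$edges[-length(grid$edges)]
  }
  if (n == 0) return(numeric(0))
  if (any(p < 0) || sum(p) <= 0) stop("invalid density")
  bins <- sample.int(length(p), n, replace = TRUE, prob = p)
  left[bins] + stats::runif(n) * dx
}

#' Sort a sample into plus (top) and minus (bottom) quantile arms
#'
#' @param x numeric sample
#' @param fraction tail fraction per arm (0 < fraction <= 0.5)
#' @return list with `plus` (top fraction) and `minus` (bottom fraction);
#'   ties broken by stable original order
#' @export
sort_arms <- function(x, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 0.5)
  n <- length(x)
  k <- max(1L, round(n * fraction))
  if (2 * k > n) stop("too few events to sort two disjoint arms")
  ord <- order(x)  # stable
  list(plus = x[ord[(n - k + 1):n]], minus = x[ord[1:k]])
}

## bivariate normal (FSC, SSC) cluster, mild positive correlation
rfssc <- function(n, mean, sd, rho = 0.3) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(fsc_h = mean[1] + sd[1] * z1, ssc_h = mean[2] + sd[2] * z2)
}

#' Generate a complete synthetic relaxation experiment on disk
#'
#' Draws a stationary pool from the asymptotic profile of the true
#' parameters and sorts the top/bottom `sort_fraction` into the plus/minus
#' arms at day 0. Each arm is binned on the PDE grid, split by the
#' asymptotic on-fraction, and evolved from the sort; at each scheduled
#' measurement day, `n_events` fluorescence values are sampled from the
#' normalized solution (times `X_max`, plus the negative baseline). Each
#' event file receives a viable (FSC, SSC) Gaussian cluster plus a debris
#' cluster; debris events carry near-baseline fluorescence. Counts follow
#' `n0 * exp(lambda * (day - day0))` with multiplicative lognormal noise.
#'
#' Output layout: `<arm>_day<D>.csv` (header `fsc_h,ssc_h,fl`),
#' `counts.csv` (`arm,day,count`), `manifest.json` (config, truth, seed).
#' The manifest suffices to regenerate the dataset byte-identically.
#'
#' @param cfg a [synthetic_config()]
#' @param dir output directory (created if needed)
#' @return the manifest, invisibly
#' @export
generate_experiment <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  params <- cfg$params
  grid <- pde_grid(cfg$J_pde)
  profile <- asymptotic_profile(params, grid$centers)
  lambda <- profile$lambda
  day0 <- cfg$days[1]

  n_pool <- ceiling(cfg$n_events / cfg$sort_fraction)
  pool <- sample_profile(profile$N, grid, n_pool)
  arms <- sort_arms(pool, cfg$sort_fraction)

  counts <- list()
  for (arm in c("plus", "minus")) {
    # cells are sorted at day 0 and first measured on days[1]: evolve the
    # sorted tail from t = 0 and record at the absolute scheduled days
    h0 <- graphics::hist(arms[[arm]], breaks = grid$edges,
                         plot = FALSE)$counts
    state <- split_initial(h0, params, grid, t0 = 0)
    traj <- pde_evolve(state, max(cfg$days), params,
                       output_times = cfg$days)
    for (i in seq_along(cfg$days)) {
      day <- cfg$days[i]
      st <- traj$states[[i]]
      xs <- sample_profile(st$n_on + st$n_off, grid, cfg$n_events)
      fl <- xs * params$x_max + cfg$baseline
      n_debris <- round(cfg$n_events * cfg$debris_frac /
                          (1 - cfg$debris_frac))
      viable <- rfssc(cfg$n_events, cfg$viable_mean, cfg$viable_sd)
      ev <- data.frame(viable, fl = fl)
      if (n_debris > 0) {
        debris <- rfssc(n_debris, cfg$debris_mean, cfg$debris_sd)
        fl_d <- cfg$baseline + stats::rexp(n_debris, rate = 1 / 30)
        ev <- rbind(ev, data.frame(debris, fl = fl_d))
        ev <- ev[sample.int(nrow(ev)), ]
      }
      write_events(ev, file.path(dir, sprintf("%s_day%d.csv", arm, day)))
      counts[[length(counts) + 1]] <- data.frame(
        arm = arm, day = day,
        count = round(cfg$n0 * exp(lambda * (day - day0)) *
                        exp(stats::rnorm(1, 0, cfg$count_sigma))))
    }
  }
  utils::write.csv(do.call(rbind, counts), file.path(dir, "counts.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = cfg$seed,
    truth = cfg$params[c("k_on", "k_off", "d", "x_max", "r0", "r1")],
    lambda = lambda,
    sort_fraction = cfg$sort_fraction, days = cfg$days,
    n_events = cfg$n_events, n0 = cfg$n0, baseline = cfg$baseline,
    debris_frac = cfg$debris_frac, count_sigma = cfg$count_sigma,
    J_pde = cfg$J_pde,
    viable_mean = cfg$viable_mean, viable_sd = cfg$viable_sd,
    debris_mean = cfg$debris_mean, debris_sd = cfg$debris_sd)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Rebuild a [synthetic_config()] from a dataset manifest
#' @param path path to `manifest.json`
#' @return a `synthetic_config`
#' @export
config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_config(
    params = model_params(k_on = m$truth$k_on, k_off = m$truth$k_off,
                          d = m$truth$d, x_max = m$truth$x_max,
                          r0 = m$truth$r0, r1 = m$truth$r1),
    sort_fraction = m$sort_fraction, days = m$days,
    n_events = m$n_events, n0 = m$n0, baseline = m$baseline,
    debris_frac = m$debris_frac, count_sigma = m$count_sigma,
    seed = m$seed, J_pde = m$J_pde,
    viable_mean = m$viable_mean, viable_sd = m$viable_sd,
    debris_mean = m$debris_mean, debris_sd = m$debris_sd)
}
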