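# small synthetic dataset shared across the inference tests
local_small_dataset <- function(seed = 7, n_events = 3000,
                                days = c(2, 5, 9, 13)) {
  dir <- tempfile("synth")
  cfg <- synthetic_config(n_events = n_events, n0 = 1e4, seed = seed,
                          days = days, debris_frac = 0.1)
  generate_experiment(cfg, dir)
  dir
}

test_that("growth-rate regression recovers exact and noisy exponentials", {
  days <- c(2, 5, 9, 13, 19, 23, 26, 30)
  counts <- rbind(
    data.frame(arm = "plus", day = days, count = 50 * exp(0.4 * days)),
    data.frame(arm = "minus", day = days, count = 80 * exp(0.44 * days)))
  gr <- fit_growth_rate(counts)
  expect_equal(gr$lambda_plus, 0.4, tolerance = 1e-12)
  expect_equal(gr$lambda_minus, 0.44, tolerance = 1e-12)
  expect_equal(gr$lambda, 0.42, tolerance = 1e-12)
  # constant counts: zero slope
  const <- data.frame(arm = "plus", day = days, count = 500)
  expect_equal(fit_growth_rate(const)$lambda, 0, tolerance = 1e-12)
  # lognormal noise, fixed seed: slope within the OLS sampling band
  set.seed(61)
  noisy <- data.frame(arm = "plus", day = days,
                      count = 50 * exp(0.4 * days + rnorm(8, 0, 0.1)))
  expect_lt(abs(fit_growth_rate(noisy)$lambda - 0.4), 0.03)
  expect_error(fit_growth_rate(data.frame(arm = "plus", day = 2,
                                          count = 10)), "2 days")
  expect_error(fit_growth_rate(transform(const, count = 0)), "positive")
})

test_that("r0 completion inverts the eigenvalue relation", {
  # fitted CD34 rates: the completed constant proliferation rate
  expect_equal(round(r0_from_lambda(0.42, -0.426, 0.261, 19.178), 3), 0.426)
  expect_equal(r0_from_lambda(0.37, 0, 1.2, 3.4), 0.37)  # r1 = 0: r0 = lambda
  # round trip: perron on the completed set returns lambda
  set.seed(62)
  for (i in 1:50) {
    k_on <- rlnorm(1); k_off <- rlnorm(1, 1); r1 <- -runif(1, 0, 0.3)
    lam <- runif(1, 0.1, 1)
    r0 <- r0_from_lambda(lam, r1, k_on, k_off, strict = FALSE)
    if (r0 < 0 || r0 + r1 < 0) next
    p <- model_params(k_on, k_off, d = 1, x_max = 1, r0 = r0, r1 = r1)
    expect_equal(perron(p)$lambda, lam, tolerance = 1e-12)
  }
  expect_error(r0_from_lambda(-5, -0.1, 1, 10), "negative")
})

test_that("KT objective is per-day additive, order-invariant, and curved in d", {
  dir <- local_small_dataset()
  on.exit(unlink(dir, recursive = TRUE))
  ds <- process_dataset(dir, x_max = 2e4)
  gr <- fit_growth_rate(ds$counts)
  prep <- prepare_fit_data(ds, J_pde = 100, J_dist = 200)
  obj <- kt_objective(-0.4, 0.261, 19.178, 0.21, prep, gr$lambda,
                      per_day = TRUE)
  expect_equal(nrow(obj$per_day), 2 * 3)      # 2 arms x 3 post-init days
  expect_equal(sum(obj$per_day$distance), obj$objective)
  # event order cannot matter: the preparation only uses histograms/CDFs
  ds_perm <- ds
  set.seed(63)
  ds_perm$samples <- lapply(ds$samples, function(s) {
    idx <- sample.int(length(s$x))
    s$x <- s$x[idx]; s$d <- s$d[idx]; s
  })
  prep_perm <- prepare_fit_data(ds_perm, J_pde = 100, J_dist = 200)
  expect_equal(kt_objective(-0.4, 0.261, 19.178, 0.21, prep_perm, gr$lambda),
               obj$objective)
  # degradation is strongly identified: doubling d hurts
  expect_gt(kt_objective(-0.4, 0.261, 19.178, 0.42, prep, gr$lambda),
            obj$objective)
  # inadmissible completions are rejected with an infinite objective
  expect_identical(kt_objective(-2 * gr$lambda, 0.261, 19.178, 0.21, prep,
                                gr$lambda), Inf)
})

test_that("grid search refines toward the objective minimum", {
  dir <- local_small_dataset()
  on.exit(unlink(dir, recursive = TRUE))
  ds <- process_dataset(dir, x_max = 2e4)
  gr <- fit_growth_rate(ds$counts)
  prep <- prepare_fit_data(ds, J_pde = 100, J_dist = 200)
  # degenerate single-point box: returns that point
  pt <- list(r1 = c(-0.4, -0.4), k_on = c(0.3, 0.3), k_off = c(19, 19),
             d = c(0.2, 0.2))
  fit1 <- grid_search(prep, gr$lambda, bounds = pt, points = 1, levels = 1)
  expect_equal(unname(fit1$par), c(-0.4, 0.3, 19, 0.2))
  expect_equal(fit1$objective,
               kt_objective(-0.4, 0.3, 19, 0.2, prep, gr$lambda))
  # the reported best is the minimum over the full evaluation log, and the
  # refined levels actually localize: the last level's grid is narrower
  fit <- suppressWarnings(grid_search(
    prep, gr$lambda,
    bounds = list(r1 = c(-0.8, 0), k_on = c(0.05, 2),
                  k_off = c(2, 80), d = c(0.05, 0.8)),
    points = 4, levels = 3))
  expect_equal(fit$objective, min(fit$log$objective))
  span <- function(lev) diff(range(fit$log$d[fit$log$level == lev]))
  expect_lt(span(3), span(1))
  # the implied r0 satisfies the eigenvalue relation
  p <- model_params(fit$par[["k_on"]], fit$par[["k_off"]], fit$par[["d"]],
                    2e4, r0 = fit$r0, r1 = fit$par[["r1"]],
                    mode = "permissive")
  expect_equal(perron(p)$lambda, gr$lambda, tolerance = 1e-12)
  # full evaluation log is kept
  expect_gte(nrow(fit$log), 3 * 4^4 * 0.99)
})

test_that("profiling at the optimum reproduces the fitted objective", {
  dir <- local_small_dataset()
  on.exit(unlink(dir, recursive = TRUE))
  ds <- process_dataset(dir, x_max = 2e4)
  gr <- fit_growth_rate(ds$counts)
  prep <- prepare_fit_data(ds, J_pde = 100, J_dist = 200)
  bounds <- list(r1 = c(-0.8, 0), k_on = c(0.05, 2), k_off = c(2, 80),
                 d = c(0.05, 0.8))
  fit <- grid_search(prep, gr$lambda, bounds = bounds, points = 4,
                     levels = 3)
  pc <- profile_curve("d", fit$par[["d"]], prep, gr$lambda, fit,
                      points = 4, levels = 3)
  expect_s3_class(pc, "profile_curve")
  expect_equal(pc$rel, 1)
  expect_equal(pc$S, fit$objective, tolerance = 0.05)
  expect_warning(
    profile_curve("d", 2 * fit$par[["d"]], prep, gr$lambda, fit,
                  points = 2, levels = 1),
    "bracket")
})
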