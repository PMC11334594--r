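test_that("edge velocities have the advection signs and boundary zeros", {
  g <- pde_grid(10)
  v <- velocities(g, d = 1)
  expect_equal(v$a_on[1], 1)      # x = 0
  expect_equal(v$a_off[1], 0)
  expect_equal(v$a_on[11], 0)     # x = 1
  expect_equal(v$a_off[11], -1)
  expect_true(all(v$a_on >= 0) && all(v$a_off <= 0))
  v <- velocities(g, d = 0.21)
  expect_equal(v$a_on[6], 0.105)  # x = 0.5
  expect_equal(v$a_off[6], -0.105)
})

test_that("conservative dynamics preserve discrete mass to near machine precision", {
  p <- model_params(0.7, 2.1, 0.9, 10, r0 = 0, r1 = 0)
  g <- pde_grid(200)
  set.seed(21)
  state <- density_pair(g, runif(200), runif(200))
  m0 <- pde_mass(state)
  dt <- 0.9 / (p$d * g$J + p$k_on + p$k_off)
  traj <- pde_evolve(state, 1e4 * dt, p, cfl_safety = 0.9)
  expect_lt(max(abs(traj$mass - m0)) / m0, 1e-13)
  expect_true(all(traj$states[[1]]$n_on >= 0))
})

test_that("pure switching follows the two-state ODE (matrix-exponential oracle)", {
  # negligible transport (tiny d), spatially uniform start: every cell obeys
  # dn/dt = A n with A the switching matrix
  p <- model_params(1.3, 0.6, 1e-9, 1, r0 = 0, r1 = 0)
  g <- pde_grid(50)
  state <- density_pair(g, rep(0.3, 50), rep(1.1, 50))
  Tfin <- 0.5
  traj <- pde_evolve(state, Tfin, p, cfl_safety = 0.5)
  A <- matrix(c(-p$k_off, p$k_on, p$k_off, -p$k_on), 2, byrow = TRUE)
  ev <- eigen(A)
  expA <- ev$vectors %*% diag(exp(Tfin * ev$values)) %*% solve(ev$vectors)
  exact <- expA %*% c(0.3, 1.1)
  st <- traj$states[[1]]
  expect_equal(st$n_on, rep(exact[1], 50), tolerance = 10 * traj$dt)
  expect_equal(st$n_off, rep(exact[2], 50), tolerance = 10 * traj$dt)
})

test_that("constant growth multiplies mass by (1 + r0 dt) each step exactly", {
  p <- model_params(0.5, 1.5, 0.8, 10, r0 = 0.4, r1 = 0)
  g <- pde_grid(100)
  set.seed(22)
  state <- density_pair(g, runif(100), runif(100))
  traj <- pde_evolve(state, 0.5, p)
  nst <- length(traj$mass) - 1
  expect_equal(traj$mass[nst + 1],
               pde_mass(state) * (1 + p$r0 * traj$dt)^nst,
               tolerance = 1e-12)
})

test_that("evolve to the current time returns the input snapshot", {
  p <- cd34_params()
  g <- pde_grid(50)
  state <- density_pair(g, rep(1, 50), rep(0.5, 50), t = 2)
  traj <- pde_evolve(state, 2, p)
  expect_equal(traj$states[[1]], state)
})

test_that("a time step above the stability bound is rejected with the bound", {
  p <- cd34_params()
  g <- pde_grid(100)
  state <- density_pair(g, rep(1, 100), rep(1, 100))
  bound <- 1 / (p$d * g$J + p$k_on + p$k_off + p$r0)
  expect_error(pde_step(state, 2 * bound, p), "stability bound")
  st2 <- pde_step(state, 0.9 * bound, p)
  expect_true(all(st2$n_on >= 0) && all(st2$n_off >= 0))
})

test_that("output times must be ordered and inside the integration window", {
  p <- cd34_params()
  g <- pde_grid(50)
  state <- density_pair(g, rep(1, 50), rep(1, 50))
  expect_error(pde_evolve(state, 1, p, output_times = c(0.5, 0.2)),
               "strictly increasing")
  expect_error(pde_evolve(state, 1, p, output_times = 2), "within")
})

test_that("histogram splitting reproduces the histogram and the on-fraction limits", {
  g <- pde_grid(100)
  set.seed(23)
  h <- rpois(100, 40)
  # symmetric conservative case: exactly 50/50 at x = 1/2
  p <- model_params(1.2, 1.2, 0.8, 10, r0 = 0, r1 = 0)
  st <- split_initial(h, p, g)
  expect_equal(st$n_on + st$n_off, h / g$dx)
  expect_equal(st$n_on[50] / (st$n_on[50] + st$n_off[50]), g$centers[50])
  expect_equal(on_fraction(p, 0.5), 0.5)
  # any params: partition of unity; on-fraction -> 1 as x -> 1
  p <- cd34_params()
  st <- split_initial(h, p, g)
  expect_equal(st$n_on + st$n_off, h / g$dx)
  expect_gt(on_fraction(p, 0.9999), 0.999)
  expect_error(split_initial(rep(0, 100), p, g), "all zero")
})

test_that("long-time conservative solution approaches the Beta law", {
  p <- model_params(1, 3, 0.5, 10, r0 = 0, r1 = 0)
  g <- pde_grid(200)
  state <- density_pair(g, rep(1, 200), rep(1, 200))
  traj <- pde_evolve(state, 30, p)
  st <- traj$states[[1]]
  pr <- stationary_beta(p, g$centers)
  expect_lt(w1_linear(st$n_on + st$n_off, pr$N, g$centers, g$centers), 0.02)
})

test_that("grid refinement reduces the distance to the asymptotic profile", {
  p <- rising_r_params()
  err <- vapply(c(50, 100, 200), function(J) {
    g <- pde_grid(J)
    state <- density_pair(g, rep(1, J), rep(1, J))
    traj <- pde_evolve(state, 12, p)
    st <- traj$states[[1]]
    pr <- asymptotic_profile(p, g$centers)
    w1_linear(st$n_on + st$n_off, pr$N, g$centers, g$centers)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3] / err[1], 0.5)  # first-order trend
})

test_that("growing-case log-mass slope matches the Perron growth rate", {
  p <- cd34_params()
  g <- pde_grid(400)
  pr <- asymptotic_profile(p, g$centers)
  state <- density_pair(g, pr$N_on, pr$N_off)
  traj <- pde_evolve(state, 10, p)
  n <- length(traj$mass)
  late <- (n - 1000):n
  slope <- coef(lm(log(traj$mass[late]) ~ traj$step_times[late]))[2]
  expect_equal(unname(slope), perron(p)$lambda, tolerance = 0.01)
})

test_that("trajectory snapshots export as tidy TSV", {
  p <- cd34_params()
  g <- pde_grid(20)
  state <- density_pair(g, rep(1, 20), rep(1, 20))
  traj <- pde_evolve(state, 0.5, p, output_times = c(0.25, 0.5))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_trajectory(traj, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 40)
  expect_named(tab, c("t", "x", "n_on", "n_off"))
})
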