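test_that("closed-form Perron eigenvalue matches a dense eigen-decomposition", {
  set.seed(11)
  for (p in c(random_params(200), list(cd34_params(), rising_r_params()))) {
    sol <- perron(p)
    # absolute comparison scaled by the rate magnitude: s(M) can be
    # arbitrarily close to 0, where a relative criterion is meaningless
    expect_lt(abs(sol$s_M - eigen_sM(p)),
              1e-12 * max(1, p$k_on + p$k_off + abs(p$r1)))
    expect_lt(abs(sol$lambda - (p$r0 + eigen_sM(p))),
              1e-12 * max(1, p$k_on + p$k_off + abs(p$r1)))
  }
})

test_that("eta satisfies both eigenvector identities to 1e-12 relative", {
  set.seed(12)
  for (p in random_params(1000)) {
    sol <- perron(p)
    expect_equal(sol$eta, p$k_off / (sol$s_M - p$r1 + p$k_off),
                 tolerance = 1e-12)
    expect_equal(sol$eta, (sol$s_M + p$k_on) / p$k_on, tolerance = 1e-12)
  }
})

test_that("eigenvectors are positive, sum to one, and solve the eigenproblem", {
  set.seed(13)
  for (p in random_params(50)) {
    sol <- perron(p)
    expect_true(all(sol$V > 0) && all(sol$U > 0))
    expect_equal(sum(sol$V), 1)
    expect_equal(sum(sol$U), 1)
    expect_lt(max(abs(t(sol$V) %*% sol$M - sol$s_M * t(sol$V))), 1e-12)
    expect_lt(max(abs(sol$M %*% sol$U - sol$s_M * sol$U)), 1e-12)
  }
})

test_that("conservative case collapses to s(M) = 0, lambda = r0, eta = 1 exactly", {
  p <- model_params(k_on = 0.7, k_off = 3.1, d = 0.5, x_max = 100,
                    r0 = 1.3, r1 = 0)
  sol <- perron(p)
  expect_identical(sol$s_M, 0)
  expect_identical(sol$lambda, 1.3)
  expect_identical(sol$eta, 1)
})

test_that("stationary law is the Beta(k_on/d, k_off/d) density", {
  x <- seq(0.01, 0.99, by = 0.01)
  # k_on = k_off = d: Beta(1,1), uniform
  p <- model_params(1, 1, 1, 10)
  expect_equal(stationary_beta(p, x)$N, rep(1, length(x)))
  # k_on = k_off = 2d: Beta(2,2) = 6x(1-x)
  p <- model_params(2, 2, 1, 10)
  expect_equal(stationary_beta(p, x)$N, 6 * x * (1 - x))
  # arbitrary rates: zero-flux identity (1-x) N_on = x N_off, and N matches
  # dbeta
  set.seed(14)
  for (p in random_params(20)) {
    st <- stationary_beta(p, x)
    expect_equal((1 - x) * st$N_on, x * st$N_off)
    expect_equal(st$N, dbeta(x, p$k_on / p$d, p$k_off / p$d))
    expect_equal(st$N, st$N_on + st$N_off)
  }
})

test_that("asymptotic profile reduces to the Beta law when r1 = 0", {
  x <- seq(0.005, 0.995, by = 0.005)
  p <- model_params(0.8, 4, 0.5, 100, r0 = 0.6, r1 = 0)
  pr <- asymptotic_profile(p, x)
  st <- stationary_beta(p, x)
  expect_equal(pr$N_on, st$N_on, tolerance = 1e-10)
  expect_equal(pr$N_off, st$N_off, tolerance = 1e-10)
})

test_that("asymptotic profile component ratio and normalization hold", {
  set.seed(15)
  J <- 5e4
  x <- (seq_len(J) - 0.5) / J
  for (p in c(random_params(5), list(cd34_params(), rising_r_params()))) {
    pr <- asymptotic_profile(p, x)
    expect_equal(pr$N, pr$N_on + pr$N_off)
    # N_off / N_on = eta (1 - x) / x wherever both components are positive
    # (extreme exponents underflow to 0 near the endpoints)
    ok <- pr$N_on > 0 & pr$N_off > 0
    expect_gt(mean(ok), 0.5)
    expect_equal((pr$N_off / pr$N_on)[ok], (pr$eta * (1 - x) / x)[ok],
                 tolerance = 1e-10)
  }
  # midpoint quadrature of the normalized density: exact statement needs a
  # density the grid resolves, i.e. both shape exponents >= 1
  smooth <- Filter(function(p) {
    sol <- perron(p)
    (p$k_on * sol$eta / p$d) >= 1 && (p$k_off / (p$d * sol$eta)) >= 1
  }, random_params(40))
  for (p in c(smooth, list(rising_r_params()))) {
    pr <- asymptotic_profile(p, x)
    expect_equal(sum(pr$N) / J, 1, tolerance = 1e-5)
  }
})

test_that("profile approaches the conservative limit continuously as r1 -> 0", {
  x <- seq(0.01, 0.99, by = 0.01)
  base <- model_params(0.9, 2.5, 0.7, 50, r0 = 0, r1 = 0)
  st <- stationary_beta(base, x)
  for (r1 in c(-1e-3, -1e-6)) {
    p <- model_params(0.9, 2.5, 0.7, 50, r0 = 1e-3, r1 = r1)
    sol <- perron(p)
    expect_lt(abs(sol$s_M), 1e-3)            # lambda - r0 -> 0
    expect_lt(abs(sol$eta - 1), 2e-3)        # eta -> 1
    pr <- asymptotic_profile(p, x)
    expect_lt(max(abs(pr$N - st$N) / st$N), 0.05 * max(1e3 * abs(r1), 1e-3))
  }
})

test_that("profile errors name the offending grid or exponent", {
  p <- cd34_params()
  expect_error(asymptotic_profile(p, c(0, 0.5)), "strictly inside")
  expect_error(stationary_beta(p, seq(0, 1, 0.1)), "strictly inside")
})

test_that("adjoint eigenfunctions are constant at r1 = 0 and positive in general", {
  x <- seq(0.01, 0.99, by = 0.01)
  p <- model_params(0.8, 4, 0.5, 100, r0 = 0.6, r1 = 0)
  ad <- adjoint_profile(p, x)
  expect_equal(ad$phi_on, rep(1, length(x)), tolerance = 1e-9)
  expect_equal(ad$phi_off, rep(1, length(x)), tolerance = 1e-9)
  set.seed(16)
  for (p in random_params(20)) {
    ad <- adjoint_profile(p, x)
    expect_gt(min(ad$phi_on), 0)
    expect_gt(min(ad$phi_off), 0)
  }
})

test_that("adjoint profile solves the adjoint system (finite-difference residual)", {
  p <- cd34_params()
  x <- seq(1e-3, 1 - 1e-3, by = 1e-3)
  sol <- perron(p)
  ad <- adjoint_profile(p, x)
  h <- x[2] - x[1]
  mid <- 2:(length(x) - 1)
  dphi_on <- (ad$phi_on[mid + 1] - ad$phi_on[mid - 1]) / (2 * h)
  dphi_off <- (ad$phi_off[mid + 1] - ad$phi_off[mid - 1]) / (2 * h)
  r <- proliferation_rate(p, x[mid])
  res_on <- sol$lambda * ad$phi_on[mid] - p$d * (1 - x[mid]) * dphi_on -
    (-p$k_off * ad$phi_on[mid] + p$k_off * ad$phi_off[mid] +
       r * ad$phi_on[mid])
  res_off <- sol$lambda * ad$phi_off[mid] + p$d * x[mid] * dphi_off -
    (-p$k_on * ad$phi_off[mid] + p$k_on * ad$phi_on[mid] +
       r * ad$phi_off[mid])
  expect_lt(max(abs(res_on)), 1e-4)
  expect_lt(max(abs(res_off)), 1e-4)
})

test_that("adjoint pairing with the asymptotic profile is normalized to one", {
  J <- 2e4
  x <- (seq_len(J) - 0.5) / J
  for (p in list(cd34_params(), rising_r_params())) {
    pr <- asymptotic_profile(p, x)
    ad <- adjoint_profile(p, x)
    expect_equal(sum(pr$N_on * ad$phi_on + pr$N_off * ad$phi_off) / J, 1,
                 tolerance = 1e-4)
  }
})

test_that("parameter validation enforces the proliferation constraints", {
  expect_error(model_params(0, 1, 1, 1), "k_on")
  expect_error(model_params(1, 1, 1, 1, r0 = -0.1), "r0")
  expect_error(model_params(1, 1, 1, 1, r0 = 1, r1 = -2), "r0 \\+ r1")
  expect_error(model_params(1, 1, 1, 1, r0 = 1, r1 = 0.5), "strict")
  p <- model_params(1, 1, 1, 1, r0 = 1, r1 = 0.5, mode = "permissive")
  expect_equal(p$s, 1)
})

test_that("parameters round-trip through the key-value config file", {
  p <- cd34_params()
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_params(p, path)
  q <- read_params(path)
  expect_equal(q[names(q) != "s"], p[names(p) != "s"])
  writeLines("k_on: 1\nk_off: 2\nd: 1\nbogus: 3", path)
  expect_error(read_params(path), "unknown")
})
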