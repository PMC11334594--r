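## largest eigenvalue of the 2x2 switching/proliferation matrix, by the
## cancellation-free branch of the quadratic formula
perron_sM <- function(r1, k_on, k_off) {
  if (r1 == 0) return(0)
  a <- r1 - k_on - k_off
  disc <- a^2 + 4 * k_on * r1
  if (disc < 0) stop("characteristic discriminant negative; invalid rates")
  if (a < 0) -2 * k_on * r1 / (a - sqrt(disc)) else (a + sqrt(disc)) / 2
}

#' Perron eigenvalue and eigenvectors of the switching-proliferation matrix
#'
#' The growing two-state system admits stable exponential solutions
#' \eqn{e^{\lambda t}(N_{on}(x), N_{off}(x))}. The growth rate is
#' \eqn{\lambda = r_0 + s(M)}, where \eqn{s(M)} is the largest (Perron)
#' eigenvalue of the 2x2 matrix
#' \deqn{M = \begin{pmatrix} r_1 - k_{off} & k_{on} \\ k_{off} & -k_{on}
#' \end{pmatrix},}
#' available in closed form as the larger root of the characteristic
#' quadratic:
#' \deqn{s(M) = \frac{r_1 - k_{on} - k_{off} +
#'   \sqrt{(r_1 - k_{on} - k_{off})^2 + 4 k_{on} r_1}}{2}.}
#' The ratio \eqn{\eta = V_{on}/V_{off}} of the positive left eigenvector
#' satisfies the double identity
#' \eqn{\eta = k_{off}/(s(M) - r_1 + k_{off}) = (s(M) + k_{on})/k_{on}}.
#' In the conservative case (\eqn{r_1 = 0}) the column sums of M vanish, so
#' \eqn{s(M) = 0}, \eqn{\lambda = r_0} and \eqn{\eta = 1}.
#'
#' Eigenvectors are normalized so their entries sum to 1.
#'
#' Numerically, the larger root is taken through the product-of-roots form
#' \eqn{s(M) = -2 k_{on} r_1 / (a - \sqrt{a^2 + 4 k_{on} r_1})} (with
#' \eqn{a = r_1 - k_{on} - k_{off}}) whenever \eqn{a < 0}, avoiding the
#' cancellation of the textbook quadratic formula near \eqn{s(M) = 0}.
#'
#' @param params a [model_params()] object
#' @return an object of class `spectral_solution`: list with elements
#'   `s_M`, `lambda`, `eta`, `V = c(on, off)` (left), `U = c(on, off)`
#'   (right), and `M` (the matrix itself, rows/cols ordered on, off)
#' @examples
#' sol <- perron(model_params(0.261, 19.178, 0.21, 2e4, 0.426, -0.426))
#' round(sol$lambda, 2)  # 0.42
#' @export
perron <- function(params) {
  stopifnot(inherits(params, "relax_params"))
  k_on <- params$k_on; k_off <- params$k_off; r1 <- params$r1
  s_M <- perron_sM(r1, k_on, k_off)
  eta <- 1 + s_M / k_on
  V <- c(on = eta, off = 1)
  V <- V / sum(V)
  u_ratio <- (s_M - r1 + k_off) / k_on  # U_off / U_on
  U <- c(on = 1, off = u_ratio)
  U <- U / sum(U)
  M <- matrix(c(r1 - k_off, k_on, k_off, -k_on), 2, 2, byrow = TRUE,
              dimnames = list(c("on", "off"), c("on", "off")))
  structure(list(s_M = s_M, lambda = params$r0 + s_M, eta = eta,
                 V = V, U = U, M = M, params = params),
            class = "spectral_solution")
}

#' @export
print.spectral_solution <- function(x, ...) {
  cat(sprintf("s(M) = %.6g, lambda = r0 + s(M) = %.6g, eta = %.6g\n",
              x$s_M, x$lambda, x$eta))
  invisible(x)
}

## shared helper: exponents and spectral quantities of the profile
profile_exponents <- function(params) {
  sol <- perron(params)
  # via the eigenvector identities: k_on * eta = k_on + s(M),
  # k_off / eta = k_off + s(M) - r1
  a <- (params$k_on + sol$s_M) / params$d        # = k_on * eta / d
  b <- (params$k_off + sol$s_M - params$r1) / params$d  # = k_off / (d eta)
  list(a = a, b = b, eta = sol$eta, s_M = sol$s_M, lambda = sol$lambda,
       c = -params$r1 / params$d)
}

## E[exp(c X) g(X)] under Beta(a, b) via the quantile transform, which
## absorbs the endpoint singularities into qbeta; integrand is bounded.
beta_exp_moment <- function(a, b, cc) {
  if (cc == 0) return(1)
  stats::integrate(function(u) exp(cc * stats::qbeta(u, a, b)),
                   0, 1, rel.tol = 1e-10, abs.tol = 0)$value
}

#' Stationary profile of the conservative two-state model
#'
#' Without proliferation the system is mass-preserving and converges to the
#' Beta\eqn{(k_{on}/d, k_{off}/d)} law:
#' \deqn{N(x) = C (1-x)^{k_{off}/d - 1} x^{k_{on}/d - 1},}
#' with the Gamma-function normalizing constant, split into components
#' \eqn{N_{on} = C (1-x)^{k_{off}/d - 1} x^{k_{on}/d}} and
#' \eqn{N_{off} = C (1-x)^{k_{off}/d} x^{k_{on}/d - 1}} satisfying the
#' zero-flux identity \eqn{(1-x) N_{on} = x N_{off}}.
#'
#' @param params a [model_params()] object (proliferation ignored)
#' @param x grid of evaluation points strictly inside (0, 1)
#' @return a `relax_profile` (see [asymptotic_profile()])
#' @export
stationary_beta <- function(params, x) {
  stopifnot(inherits(params, "relax_params"))
  if (any(x <= 0 | x >= 1)) stop("grid must lie strictly inside (0,1)")
  a <- params$k_on / params$d
  b <- params$k_off / params$d
  C <- exp(lgamma(a + b) - lgamma(a) - lgamma(b))
  N_on <- C * (1 - x)^(b - 1) * x^a
  N_off <- C * (1 - x)^b * x^(a - 1)
  structure(list(x = x, N_on = N_on, N_off = N_off, N = N_on + N_off,
                 C = C, eta = 1, s_M = 0, lambda = params$r0,
                 params = params),
            class = "relax_profile")
}

#' Asymptotic (stable exponential) profile of the growing system
#'
#' Closed-form shape toward which the normalized solution of the growing
#' two-state system converges:
#' \deqn{N_{on}(x) = C (1-x)^{k_{off}/(d\eta) - 1} x^{k_{on}\eta/d}
#'   e^{-(r_1/d) x}, \quad
#'   N_{off}(x) = C \eta (1-x)^{k_{off}/(d\eta)} x^{k_{on}\eta/d - 1}
#'   e^{-(r_1/d) x},}
#' so that
#' \deqn{N(x) = C (1-x)^{k_{off}/(d\eta)-1} x^{k_{on}\eta/d - 1}
#'   e^{-(r_1/d) x} (\eta + (1-\eta) x).}
#' The exponents are computed through the eigenvector identities
#' \eqn{k_{on}\eta = k_{on} + s(M)} and
#' \eqn{k_{off}/\eta = k_{off} + s(M) - r_1}. The exponential factor is
#' \eqn{e^{-(r_1/d)x}}: substituting this form into the eigenproblem makes
#' the residual vanish identically (the transformed components
#' \eqn{P = e^{+(r_1/d)x} N} satisfy the constant-coefficient system of the
#' matrix \eqn{r_0 + r_1 - \lambda} / \eqn{r_0 - \lambda}).
#'
#' The normalization constant has no closed form when \eqn{r_1 \ne 0}
#' (a Kummer-type integral); it is computed by adaptive quadrature of the
#' Beta-weighted exponential moment (relative tolerance 1e-10), with the
#' endpoint singularities absorbed by a quantile substitution, so that
#' \eqn{\int_0^1 N = 1}.
#'
#' @param params a [model_params()] object
#' @param x grid of evaluation points strictly inside (0, 1)
#' @return object of class `relax_profile`: list with `x`, `N_on`, `N_off`,
#'   `N` (= `N_on + N_off`), normalizing constant `C`, `eta`, `s_M`,
#'   `lambda`, `params`
#' @examples
#' p <- model_params(0.85, 12.71, 1, 2e4, 3.4, 3, mode = "permissive")
#' pr <- asymptotic_profile(p, seq(0.001, 0.999, by = 0.002))
#' @export
asymptotic_profile <- function(params, x) {
  stopifnot(inherits(params, "relax_params"))
  if (any(x <= 0 | x >= 1)) stop("grid must lie strictly inside (0,1)")
  ex <- profile_exponents(params)
  a <- ex$a; b <- ex$b; eta <- ex$eta; cc <- ex$c
  if (a <= 0) stop("non-integrable profile: x-exponent k_on*eta/d = ",
                   signif(a, 6), " <= 0")
  if (b <= 0) stop("non-integrable profile: (1-x)-exponent k_off/(d*eta) = ",
                   signif(b, 6), " <= 0")
  # Z = integral of (1-x)^(b-1) x^(a-1) e^(cc x) (eta + (1-eta) x) dx
  lB <- lbeta(a, b)
  E1 <- beta_exp_moment(a, b, cc)          # weight eta, Beta(a, b)
  E2 <- beta_exp_moment(a + 1, b, cc)      # weight (1-eta), Beta(a+1, b)
  Z <- exp(lB) * (eta * E1 + (1 - eta) * a / (a + b) * E2)
  C <- 1 / Z
  efac <- exp(cc * x)
  N_on <- C * (1 - x)^(b - 1) * x^a * efac
  N_off <- C * eta * (1 - x)^b * x^(a - 1) * efac
  structure(list(x = x, N_on = N_on, N_off = N_off, N = N_on + N_off,
                 C = C, eta = eta, s_M = ex$s_M, lambda = ex$lambda,
                 params = params),
            class = "relax_profile")
}

#' @export
print.relax_profile <- function(x, ...) {
  cat(sprintf(
    "asymptotic profile on %d grid points; eta = %.6g, lambda = %.6g\n",
    length(x$x), x$eta, x$lambda))
  invisible(x)
}

#' On-state fraction of the asymptotic profile
#'
#' The component ratio \eqn{N_{on}/N_{off} = x / (\eta (1 - x))} gives the
#' on-fraction \eqn{N_{on}/N = x / (x + \eta(1-x))} in closed form,
#' independent of the normalizing constant. Used to split an observed
#' day-2 histogram into on/off components.
#'
#' @param params a [model_params()] object
#' @param x scaled levels in (0, 1)
#' @return numeric vector of on-fractions in (0, 1)
#' @export
on_fraction <- function(params, x) {
  eta <- perron(params)$eta
  x / (x + eta * (1 - x))
}

#' Adjoint eigenfunctions of the growing two-state system
#'
#' The adjoint eigenproblem has the explicit solution
#' \eqn{\phi_{on/off}(x) = e^{+(r_1/d) x} V_{on/off}} with V the positive
#' left Perron eigenvector (plugging this form in makes the adjoint
#' residual vanish; for \eqn{r_1 = 0} it reduces to the constant vector).
#' The pair is rescaled so the pairing
#' \eqn{\int_0^1 N_{on}\phi_{on} + N_{off}\phi_{off}\, dx = 1}; the
#' exponential factors of N and phi cancel in the pairing, which therefore
#' has the closed form \eqn{C K \eta B(a, b)} used for the rescaling.
#' Along any solution of the growing system the pairing
#' \eqn{\int n_{on}\phi_{on} + n_{off}\phi_{off}\,dx} equals
#' \eqn{C^0 e^{\lambda t}} exactly.
#'
#' @param params a [model_params()] object
#' @param x grid of evaluation points in (0, 1)
#' @return object of class `adjoint_profile`: list with `x`, `phi_on`,
#'   `phi_off`, `C0_weight` (the pairing value, 1 after rescaling)
#' @export
adjoint_profile <- function(params, x) {
  stopifnot(inherits(params, "relax_params"))
  ex <- profile_exponents(params)
  a <- ex$a; b <- ex$b; eta <- ex$eta
  pr <- asymptotic_profile(params, if (any(x <= 0 | x >= 1))
    stop("grid must lie strictly inside (0,1)") else x)
  # pairing of unit-scaled phi with the normalized profile:
  # C * eta * B(a, b); rescale phi by its inverse
  K <- 1 / (pr$C * eta * exp(lbeta(a, b)))
  efac <- exp(params$r1 / params$d * x)
  structure(list(x = x, phi_on = K * eta * efac, phi_off = K * efac,
                 C0_weight = 1, eta = eta, lambda = ex$lambda,
                 params = params),
            class = "adjoint_profile")
}

#' Export a profile as a 3-column TSV (x, N_on, N_off)
#' @param profile a `relax_profile`
#' @param path output file
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "relax_profile"))
  utils::write.table(
    data.frame(x = profile$x, N_on = profile$N_on, N_off = profile$N_off),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
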