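#' Deterministic flow of the scaled telegraph model
#'
#' Between promoter switches the scaled protein level follows
#' \eqn{x' = d(e - x)} with \eqn{e \in \{0, 1\}}: in the on state
#' \eqn{x(t) = 1 + (x_0 - 1)e^{-dt}}, in the off state
#' \eqn{x(t) = x_0 e^{-dt}}. The level never leaves \[0,1\].
#'
#' @param x0 initial scaled level(s) in \[0,1\]
#' @param e promoter state, 0 (off) or 1 (on)
#' @param dt elapsed time (>= 0)
#' @param d degradation rate (> 0)
#' @return scaled level(s) after `dt`
#' @export
pdmp_flow <- function(x0, e, dt, d) {
  stopifnot(all(x0 >= 0 & x0 <= 1), all(e %in% c(0, 1)), all(dt >= 0), d > 0)
  ifelse(e == 1, 1 + (x0 - 1) * exp(-d * dt), x0 * exp(-d * dt))
}

#' Simulate one cell of the telegraph PDMP
#'
#' Exact stochastic simulation: exponential waiting times between promoter
#' switches (rate `k_on` when off, `k_off` when on), closed-form flow in
#' between. Uses R's RNG stream, so results are reproducible under
#' [set.seed()].
#'
#' @param params a [model_params()] object (proliferation ignored)
#' @param x0 initial scaled level in \[0,1\]
#' @param e0 initial promoter state (0/1)
#' @param T simulation horizon (>= 0)
#' @return list with final `x` and `e`
#' @export
simulate_cell <- function(params, x0, e0, T) {
  stopifnot(inherits(params, "relax_params"), T >= 0,
            x0 >= 0, x0 <= 1, e0 %in% c(0, 1))
  out <- .cpp_simulate_cell(x0, as.integer(e0), T,
                            params$k_on, params$k_off, params$d)
  list(x = out[1], e = as.integer(out[2]))
}

#' Simulate a branching PDMP population with level-dependent division
#'
#' Each cell follows the telegraph PDMP and divides with intensity
#' \eqn{r(x) = r_0 + r_1 x}, implemented by thinning against
#' \eqn{\max(r_0, r_0 + r_1)} (r is affine, so the bound is attained at an
#' endpoint). Daughters copy the mother's level and promoter state. When
#' the population exceeds `max_cells` it is uniformly subsampled and the
#' common lineage weight is multiplied by the inverse keep fraction, so
#' `weight * length(x)` remains an unbiased estimate of the true population
#' size.
#'
#' @param params a [model_params()] object
#' @param x0 initial scaled levels
#' @param e0 initial promoter states (0/1), recycled to `length(x0)`
#' @param T simulation horizon
#' @param max_cells cap on the stored population (>= `length(x0)`)
#' @return object of class `population_sample`: list with `x`, `e`,
#'   `weight`, `t`, and `size` (= `weight * length(x)`)
#' @export
simulate_population <- function(params, x0, e0, T, max_cells = 10000L) {
  stopifnot(inherits(params, "relax_params"), T >= 0,
            all(x0 >= 0 & x0 <= 1))
  e0 <- rep_len(as.integer(e0), length(x0))
  stopifnot(all(e0 %in% c(0L, 1L)), max_cells >= length(x0))
  out <- .cpp_simulate_population(x0, e0, T, params$k_on, params$k_off,
                                  params$d, params$r0, params$r1,
                                  as.integer(max_cells))
  structure(list(x = out$x, e = out$e, weight = out$weight, t = T,
                 size = out$weight * length(out$x)),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf(
    "population sample at t = %g: %d stored cells, weight %.4g, size %.6g\n",
    x$t, length(x$x), x$weight, x$size))
  invisible(x)
}

#' Export a population sample as CSV (x, state, weight)
#' @param pop a `population_sample`
#' @param path output file
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population_sample"))
  utils::write.csv(
    data.frame(x = pop$x, state = pop$e, weight = pop$weight),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
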