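#' Uniform cell-centered grid on \[0,1\]
#'
#' Densities live at the `J` cell centers \eqn{x_j = (j - 1/2)\Delta x};
#' advection fluxes live at the `J + 1` cell edges \eqn{j \Delta x}. The
#' cell-centered layout avoids evaluating the (integrably singular)
#' asymptotic profile at the endpoints.
#'
#' @param J number of cells (positive integer)
#' @return object of class `pde_grid`: list with `J`, `dx`, `centers`,
#'   `edges`
#' @export
pde_grid <- function(J) {
  J <- as.integer(J)
  stopifnot(J >= 2)
  dx <- 1 / J
  structure(list(J = J, dx = dx,
                 centers = (seq_len(J) - 0.5) * dx,
                 edges = (0:J) * dx),
            class = "pde_grid")
}

#' Advection velocities at cell edges
#'
#' The scaled characteristics are \eqn{a_{on}(x) = d(1-x) \ge 0} (on-cells
#' drift toward saturation) and \eqn{a_{off}(x) = -d x \le 0} (off-cells
#' decay toward 0); both vanish at the respective outflow boundary.
#'
#' @param grid a [pde_grid()]
#' @param d degradation rate (> 0)
#' @return list with numeric vectors `a_on`, `a_off` at the `J + 1` edges
#' @export
velocities <- function(grid, d) {
  stopifnot(inherits(grid, "pde_grid"), d > 0)
  list(a_on = d * (1 - grid$edges), a_off = -d * grid$edges)
}

#' Gridded on/off density pair
#'
#' @param grid a [pde_grid()]
#' @param n_on,n_off nonnegative densities (cells per unit x) at cell centers
#' @param t current time
#' @return object of class `density_pair`
#' @export
density_pair <- function(grid, n_on, n_off, t = 0) {
  stopifnot(inherits(grid, "pde_grid"),
            length(n_on) == grid$J, length(n_off) == grid$J)
  if (any(n_on < 0) || any(n_off < 0)) stop("densities must be nonnegative")
  if (!all(is.finite(n_on)) || !all(is.finite(n_off)))
    stop("densities must be finite")
  structure(list(grid = grid, n_on = n_on, n_off = n_off, t = t),
            class = "density_pair")
}

#' Total mass of a density pair (midpoint rule)
#' @param state a [density_pair()]
#' @return nonnegative scalar \eqn{\int (n_{on} + n_{off}) dx}
#' @export
pde_mass <- function(state) {
  stopifnot(inherits(state, "density_pair"))
  sum(state$n_on + state$n_off) * state$grid$dx
}

## stability/positivity bound for the explicit scheme: the advection CFL
## and the explicit-Euler reaction bound act on the same update, so their
## rates add; dt * (d/dx + k_on + k_off + max r) <= 1 keeps every update
## coefficient nonnegative
stable_dt <- function(params, grid) {
  rmax <- max(params$r0, params$r0 + params$r1)
  1 / (params$d / grid$dx + params$k_on + params$k_off + rmax)
}

#' One explicit upwind step
#'
#' Forward-Euler step combining conservative upwind advection (left-cell
#' value where \eqn{a_{on} > 0}, right-cell value where \eqn{a_{off} < 0}),
#' the switching exchange, and growth \eqn{r(x) n}, with no-inflow boundary
#' conditions. Errors if `dt` exceeds the stability bound
#' \eqn{\min(\Delta x / d,\; 1 / (k_{on} + k_{off} + \max_x r(x)))}.
#'
#' @param state a [density_pair()]
#' @param dt time step
#' @param params a [model_params()] object
#' @return the advanced `density_pair`
#' @export
pde_step <- function(state, dt, params) {
  stopifnot(inherits(state, "density_pair"), inherits(params, "relax_params"))
  bound <- stable_dt(params, state$grid)
  if (dt > bound)
    stop(sprintf("dt = %g exceeds the stability bound %g", dt, bound))
  r <- proliferation_rate(params, state$grid$centers)
  out <- .cpp_upwind_evolve(state$n_on, state$n_off, state$grid$dx, dt, 1L,
                            1L, params$k_on, params$k_off, params$d, r)
  density_pair(state$grid, out$n_on[, 1], out$n_off[, 1], state$t + dt)
}

#' Integrate the two-state system with the explicit upwind scheme
#'
#' Chooses \eqn{\Delta t = \code{cfl\_safety} \times \min(\Delta x / d,\;
#' 1/(k_{on} + k_{off} + \max_x r(x)))} and advances `state` to `t_end`,
#' recording snapshots at the requested output times (snapped to the
#' nearest completed step, no interpolation).
#'
#' @param state a [density_pair()] at time `state$t`
#' @param t_end final time (>= `state$t`)
#' @param params a [model_params()] object
#' @param output_times strictly increasing times within
#'   \[`state$t`, `t_end`\]; default just `t_end`
#' @param cfl_safety safety factor in (0, 1\] applied to the stability
#'   bound; 0.9 by default. Use smaller values (e.g. 0.4) when first-order
#'   time-discretization bias matters, as in eigenvalue/conservation
#'   diagnostics.
#' @return object of class `pde_trajectory`: list with `times` (actual
#'   snapshot times), `states` (list of `density_pair`), `mass` (mass at
#'   every step), `dt`, `step_times`
#' @export
pde_evolve <- function(state, t_end, params, output_times = NULL,
                       cfl_safety = 0.9) {
  stopifnot(inherits(state, "density_pair"), inherits(params, "relax_params"),
            cfl_safety > 0, cfl_safety <= 1)
  t0 <- state$t
  if (t_end < t0) stop("t_end must be >= state$t")
  if (is.null(output_times)) output_times <- t_end
  if (is.unsorted(output_times, strictly = TRUE) && length(output_times) > 1)
    stop("output_times must be strictly increasing")
  if (any(output_times < t0 - 1e-12) || any(output_times > t_end + 1e-12))
    stop("output_times must lie within [state$t, t_end]")
  if (t_end == t0) {
    return(structure(list(times = t0, states = list(state),
                          mass = pde_mass(state), dt = 0,
                          step_times = t0),
                     class = "pde_trajectory"))
  }
  dt <- cfl_safety * stable_dt(params, state$grid)
  nsteps <- ceiling((t_end - t0) / dt)
  dt <- (t_end - t0) / nsteps
  snap_steps <- as.integer(round((output_times - t0) / dt))
  snap_steps <- pmin(pmax(snap_steps, 0L), nsteps)
  r <- proliferation_rate(params, state$grid$centers)
  out <- .cpp_upwind_evolve(state$n_on, state$n_off, state$grid$dx, dt,
                            as.integer(nsteps), snap_steps,
                            params$k_on, params$k_off, params$d, r)
  times <- t0 + snap_steps * dt
  states <- lapply(seq_along(snap_steps), function(i)
    density_pair(state$grid, out$n_on[, i], out$n_off[, i], times[i]))
  structure(list(times = times, states = states, mass = out$mass, dt = dt,
                 step_times = t0 + (0:nsteps) * dt),
            class = "pde_trajectory")
}

#' Split a histogram into on/off components with the asymptotic repartition
#'
#' The on/off status of measured cells is unobserved; the initial condition
#' adopts the repartition of the asymptotic profile,
#' \eqn{n_{on/off}(t_0, x) = \frac{N_{on/off}(x)}{N(x)} h(x)}, so the sum
#' reproduces the histogram density exactly.
#'
#' @param hist_counts nonnegative per-cell counts on the grid (length `J`)
#' @param params a [model_params()] object
#' @param grid a [pde_grid()]
#' @param t0 time attached to the returned state
#' @return a [density_pair()] whose `n_on + n_off` equals
#'   `hist_counts / dx`
#' @export
split_initial <- function(hist_counts, params, grid, t0 = 0) {
  stopifnot(inherits(grid, "pde_grid"), length(hist_counts) == grid$J)
  if (any(hist_counts < 0)) stop("histogram counts must be nonnegative")
  if (sum(hist_counts) == 0) stop("histogram is all zero")
  dens <- hist_counts / grid$dx
  fon <- on_fraction(params, grid$centers)
  density_pair(grid, fon * dens, (1 - fon) * dens, t0)
}

#' Export trajectory snapshots as TSV (t, x, n_on, n_off)
#' @param traj a `pde_trajectory`
#' @param path output file
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pde_trajectory"))
  rows <- do.call(rbind, lapply(traj$states, function(s)
    data.frame(t = s$t, x = s$grid$centers, n_on = s$n_on, n_off = s$n_off)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
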