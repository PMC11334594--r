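#' Read a flow-cytometry event table
#'
#' CSV dialect: header `fsc_h,ssc_h,fl`, UTF-8, '.' decimal. Row order is
#' preserved. Fluorescence may be negative before shifting (instrument
#' baseline compensation).
#'
#' @param path CSV file path
#' @return data.frame with columns `fsc_h`, `ssc_h`, `fl`
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ev <- utils::read.csv(path)
  if (nrow(ev) == 0) stop("empty event table: ", path)
  need <- c("fsc_h", "ssc_h", "fl")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  ev[need]
}

#' @rdname read_events
#' @param events data.frame with columns `fsc_h`, `ssc_h`, `fl`
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("fsc_h", "ssc_h", "fl") %in% names(events)))
  utils::write.csv(events[c("fsc_h", "ssc_h", "fl")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ellipse gate in (FSC-H, SSC-H) space
#'
#' Selects viable cells as the points inside a statistical ellipse: events
#' whose Mahalanobis distance to a location/scatter estimate of the viable
#' cluster is at most the chi-square(2) quantile at `coverage`. With
#' `robust = TRUE` (default) the location/scatter is first estimated by the
#' minimum covariance determinant, gross outliers (robust distance above
#' the 0.999 quantile) are discarded, and the classical mean/covariance of
#' the remaining cluster defines the final ellipse — debris clusters far
#' from the viable cluster are removed without distorting the coverage.
#'
#' @param events data.frame with columns `fsc_h`, `ssc_h` (others carried
#'   through)
#' @param coverage target fraction of the viable cluster retained, in (0,1)
#' @param robust use a robust pre-gate before the classical ellipse
#' @return the gated subset of `events`, original order preserved
#' @export
gate_ellipse <- function(events, coverage = 0.95, robust = TRUE) {
  stopifnot(coverage > 0, coverage < 1)
  if (nrow(events) < 10) stop("need at least 10 events to gate")
  X <- cbind(events$fsc_h, events$ssc_h)
  keep <- rep(TRUE, nrow(X))
  if (robust) {
    # the MCD only anchors the pre-gate; a deterministic thinning keeps it
    # fast on large samples without touching the RNG stream
    sub <- unique(round(seq(1, nrow(X), length.out = min(nrow(X), 2000L))))
    rob <- tryCatch(MASS::cov.rob(X[sub, , drop = FALSE], method = "mcd"),
                    error = function(e)
                      stop("degenerate (FSC,SSC) scatter: ",
                           conditionMessage(e)))
    if (det(rob$cov) <= 0) stop("degenerate (FSC,SSC) scatter matrix")
    d2 <- stats::mahalanobis(X, rob$center, rob$cov)
    keep <- d2 <= stats::qchisq(0.999, df = 2)
    if (sum(keep) < 10) stop("robust pre-gate removed almost all events")
  }
  ctr <- colMeans(X[keep, , drop = FALSE])
  S <- stats::cov(X[keep, , drop = FALSE])
  if (!all(is.finite(S)) || det(S) <= 0)
    stop("degenerate (FSC,SSC) scatter matrix")
  d2 <- stats::mahalanobis(X, ctr, S)
  events[d2 <= stats::qchisq(coverage, df = 2), , drop = FALSE]
}

#' Shift a fluorescence distribution so its minimum is zero
#'
#' Subtracts the per-sample minimum from all values, interpreting negative
#' fluorescence as compensation of an instrument baseline. Pairwise
#' differences (the distribution's shape) are unchanged.
#'
#' @param values numeric vector (nonempty)
#' @return `values - min(values)`
#' @export
shift_to_zero <- function(values) {
  if (length(values) == 0) stop("empty input")
  values - min(values)
}

#' Estimate the maximum protein count from per-sample fluorescence maxima
#'
#' Deterministic rule: the maximum over all days/arms of the per-sample
#' maximum (shifted) fluorescence, rounded up to the configured
#' granularity.
#'
#' @param maxima numeric vector of per-sample maxima (or a list of samples,
#'   in which case per-sample maxima are taken first)
#' @param granularity rounding-up unit (default 1000; use 1 for the exact
#'   maximum)
#' @return the estimated `X_max`
#' @export
estimate_xmax <- function(maxima, granularity = 1000) {
  if (is.list(maxima)) maxima <- vapply(maxima, max, numeric(1))
  if (length(maxima) == 0) stop("need at least one sample")
  stopifnot(granularity > 0)
  ceiling(max(maxima) / granularity) * granularity
}

#' Rescale shifted fluorescence to \[0,1\]
#'
#' @param values nonnegative fluorescence values
#' @param x_max maximum protein count (>= `max(values)`)
#' @return `values / x_max`; values equal to `x_max` map to exactly 1
#' @export
rescale_fluorescence <- function(values, x_max) {
  if (any(values < 0)) stop("values must be nonnegative (shift first)")
  if (any(values > x_max)) stop("value exceeds x_max")
  values / x_max
}

#' Preprocess a directory of relaxation-experiment cytometry files
#'
#' Applies the fixed pipeline gate -> shift -> (estimate `X_max` over all
#' samples) -> rescale to every file `<arm>_day<D>.csv` in `dir`, and reads
#' the per-day counts from `counts.csv` (columns `arm,day,count`).
#'
#' @param dir directory with event CSVs and `counts.csv`
#' @param coverage ellipse-gate coverage (see [gate_ellipse()])
#' @param robust robust pre-gate (see [gate_ellipse()])
#' @param x_max fixed maximum protein count; if `NULL`, estimated from the
#'   gated, shifted samples via [estimate_xmax()]
#' @param granularity rounding unit for [estimate_xmax()]
#' @return object of class `relax_dataset`: list with `samples` (list of
#'   per-(arm, day) lists holding `arm`, `day`, `d` = shifted fluorescence,
#'   `x` = rescaled levels, `n_cells`), `counts` (data.frame), `x_max`
#' @export
process_dataset <- function(dir, coverage = 0.95, robust = TRUE,
                            x_max = NULL, granularity = 1000) {
  files <- list.files(dir, pattern = "^(plus|minus)_day[0-9]+\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no <arm>_day<D>.csv files in ", dir)
  counts_path <- file.path(dir, "counts.csv")
  if (!file.exists(counts_path)) stop("missing counts file: ", counts_path)
  counts <- utils::read.csv(counts_path)
  if (!all(c("arm", "day", "count") %in% names(counts)))
    stop("counts.csv must have columns arm,day,count")
  samples <- lapply(files, function(f) {
    m <- regmatches(basename(f),
                    regexec("^(plus|minus)_day([0-9]+)\\.csv$", basename(f)))[[1]]
    ev <- gate_ellipse(read_events(f), coverage = coverage, robust = robust)
    d <- shift_to_zero(ev$fl)
    list(arm = m[2], day = as.integer(m[3]), d = d, n_cells = length(d))
  })
  if (is.null(x_max))
    x_max <- estimate_xmax(vapply(samples, function(s) max(s$d), numeric(1)),
                           granularity = granularity)
  samples <- lapply(samples, function(s) {
    s$x <- rescale_fluorescence(s$d, x_max)
    s
  })
  ord <- order(vapply(samples, `[[`, character(1), "arm"),
               vapply(samples, `[[`, integer(1), "day"))
  structure(list(samples = samples[ord], counts = counts, x_max = x_max),
            class = "relax_dataset")
}

#' @export
print.relax_dataset <- function(x, ...) {
  cat(sprintf("relaxation dataset: %d samples, X_max = %g\n",
              length(x$samples), x$x_max))
  invisible(x)
}
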