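#' Bin occurrence records into ~1 km^2 grid cells
#'
#' Cells are defined by rounding latitude and longitude to the nearest
#' hundredth of a degree (ca. 1 km^2 in the study region), with ties
#' rounded half away from zero (explicit, because platform rounding of
#' halves differs). Each cell keeps the earliest year among its records.
#'
#' @param records `data.frame` with columns `year`, `lat`, `lon`.
#' @return Object of class `occupancy_grid`: `data.frame` with
#'   `cell_lat`, `cell_lon`, `first_year`, `n_records`.
#' @export
bin_records <- function(records) {
  stopifnot(all(c("year", "lat", "lon") %in% names(records)))
  cl <- round_half_away(records$lat, 2)
  cn <- round_half_away(records$lon, 2)
  key <- paste(sprintf("%.2f", cl), sprintf("%.2f", cn))
  first <- tapply(records$year, key, min)
  count <- tapply(records$year, key, length)
  lat <- tapply(cl, key, `[`, 1)
  lon <- tapply(cn, key, `[`, 1)
  out <- data.frame(cell_lat = as.vector(lat), cell_lon = as.vector(lon),
                    first_year = as.integer(first),
                    n_records = as.integer(count))
  out <- out[order(out$first_year, out$cell_lat, out$cell_lon), ]
  rownames(out) <- NULL
  class(out) <- c("occupancy_grid", "data.frame")
  out
}

# Round half away from zero at `digits` decimals. A small absolute guard
# compensates for decimals that are not exactly representable in binary
# (e.g. 33.815 stored slightly below the true half).
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-8) / scale
}

#' Range accumulation curve
#'
#' Counts, for every calendar year in the range, the number of newly
#' occupied grid cells and the cumulative number of cells occupied so
#' far. Years with no new cells are included.
#'
#' @param grid An [bin_records()] occupancy grid.
#' @param year_range Integer `c(first, last)`; defaults to the range of
#'   first-observation years in the grid.
#' @return Object of class `accumulation_curve`: `data.frame` with
#'   `year`, `new_cells`, `cumulative`.
#' @export
accumulation_curve <- function(grid, year_range = NULL) {
  if (nrow(grid) == 0) stop("empty occupancy grid")
  if (is.null(year_range)) year_range <- range(grid$first_year)
  years <- seq(year_range[1], year_range[2])
  new_cells <- vapply(years, function(y) sum(grid$first_year == y), integer(1))
  cumulative <- vapply(years, function(y) sum(grid$first_year <= y), integer(1))
  out <- data.frame(year = years, new_cells = new_cells,
                    cumulative = cumulative)
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Lag-phase test: log-linear regression of cumulative range on year
#'
#' Ordinary least squares of `log10(cumulative occupied cells)` on year,
#' using only years with a positive cumulative count. Exponential range
#' expansion at constant rate is exactly log-linear, so a high R-squared
#' is consistent with the absence of a lag phase; a lag (an initial flat
#' period) depresses R-squared and favours a single-breakpoint
#' alternative. The breakpoint comparison fits
#' `log10(cum) ~ max(0, year - tau)` over a grid of candidate breakpoint
#' years and reports `delta_aic = AIC(linear) - AIC(best breakpoint)`
#' (positive values favour the breakpoint model; the breakpoint model is
#' charged one extra parameter for tau). The lag decision itself is left
#' to the caller: slope, fit quality, and the AIC comparison are
#' reported as diagnostics.
#'
#' @param curve An [accumulation_curve()] (or any `data.frame` with
#'   `year` and `cumulative`).
#' @param breakpoint Also fit the single-breakpoint comparison model;
#'   default `TRUE`.
#' @return Object of class `lag_phase_fit`: list with `slope` (b, per
#'   year on the log10 scale), `intercept`, `r_squared`, `f_statistic`,
#'   `df` (`c(1, n - 2)`), `p_value`, `n_years`, `flag`, and
#'   `lag_comparison` (list with `breakpoint_year`, `delta_aic`,
#'   `r_squared`), or `NULL` if not requested.
#' @export
lag_phase_regression <- function(curve, breakpoint = TRUE) {
  use <- curve$cumulative > 0
  years <- curve$year[use]
  logc <- log10(curve$cumulative[use])
  n <- length(years)
  if (n < 3) stop("lag-phase regression needs at least 3 years with occupancy")
  flag <- ""
  if (stats::var(logc) == 0) {
    flag <- "constant cumulative range; fit undefined"
    warning(flag)
    return(structure(list(slope = 0, intercept = logc[1], r_squared = 0,
                          f_statistic = NA_real_, df = c(1, n - 2),
                          p_value = NA_real_, n_years = n, flag = flag,
                          lag_comparison = NULL),
                     class = "lag_phase_fit"))
  }
  fit <- stats::lm(logc ~ years)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  comparison <- NULL
  if (breakpoint && n >= 5) {
    aic_lm <- aic_gaussian(stats::residuals(fit), k = 2)
    taus <- years[2:(n - 2)]
    best <- NULL
    for (tau in taus) {
      hinge <- pmax(0, years - tau)
      bf <- stats::lm(logc ~ hinge)
      rss <- sum(stats::residuals(bf)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(tau = tau, rss = rss, fit = bf)
      }
    }
    aic_bp <- aic_gaussian(stats::residuals(best$fit), k = 3)
    comparison <- list(breakpoint_year = best$tau,
                       delta_aic = aic_lm - aic_bp,
                       r_squared = summary(best$fit)$r.squared)
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 f_statistic = fstat[1],
                 df = c(1, n - 2),
                 p_value = stats::pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE),
                 n_years = n, flag = flag,
                 lag_comparison = comparison),
            class = "lag_phase_fit")
}

# AIC with Gaussian errors and k mean parameters (+1 for sigma).
aic_gaussian <- function(res, k) {
  n <- length(res)
  n * log((sum(res^2) + 1e-300) / n) + 2 * (k + 1)
}

#' @export
print.lag_phase_fit <- function(x, ...) {
  cat(sprintf("log-linear range expansion: b = %.4f, R^2 = %.3f, F(%d,%d) = %.1f, p = %.3g (%d years)\n",
              x$slope, x$r_squared, x$df[1], x$df[2],
              ifelse(is.na(x$f_statistic), NaN, x$f_statistic),
              ifelse(is.na(x$p_value), NaN, x$p_value), x$n_years))
  if (!is.null(x$lag_comparison)) {
    cat(sprintf("  breakpoint comparison: tau = %d, delta AIC = %.2f (positive favours a lag)\n",
                x$lag_comparison$breakpoint_year, x$lag_comparison$delta_aic))
  }
  invisible(x)
}
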