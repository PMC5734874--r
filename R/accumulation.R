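# Linear accumulation of phenotypic mutant frequency with time in
# quiescence.

#' Fit the accumulation slope
#'
#' Ordinary least-squares regression of mutant frequency on days in
#' quiescence, pooling all points (optionally across experiments)
#' jointly. The intercept is estimated, not forced through zero: day-1
#' samples already carry the mutation load of the preceding replicative
#' growth.
#'
#' @param points data.frame with columns `day` and `frequency`
#'   (mutants per cell); an optional `experiment` column is carried
#'   through but all points are fitted jointly.
#' @return object of class `accumulation_fit`: list with `slope`
#'   (frequency per day), `intercept`, `r_squared`, `n_points` and the
#'   underlying [stats::lm] fit.
#' @export
fit_slope <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("day", "frequency") %in% names(points)))
  if (any(points$frequency < 0)) stop("frequencies must be >= 0")
  if (length(unique(points$day)) < 2L) {
    stop("at least 2 distinct day values are required to fit a slope")
  }
  fit <- stats::lm(frequency ~ day, data = points)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$frequency - mean(points$frequency))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  out <- list(slope = unname(stats::coef(fit)["day"]),
              intercept = unname(stats::coef(fit)["(Intercept)"]),
              r_squared = r2, n_points = nrow(points), lm = fit)
  class(out) <- "accumulation_fit"
  out
}

#' @export
print.accumulation_fit <- function(x, ...) {
  cat(sprintf(
    "Accumulation fit: slope %.3g per day, intercept %.3g, R^2 %.3f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
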