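# Poisson homogeneity of per-genome mutation counts: if a single
# mutational force acts equally on all genomes, counts are Poisson.

#' Chi-square goodness of fit of per-genome counts to a Poisson
#'
#' Estimates lambda by the sample mean, bins counts at 0, 1, 2, ...,
#' merges the right tail until every expected count is at least
#' `min_expected`, and compares observed to expected frequencies with a
#' chi-square statistic on `#bins - 2` degrees of freedom (one degree
#' lost to the estimated mean).
#'
#' @param counts non-negative integer vector, one entry per genome.
#' @param min_expected right-tail bins are merged until every expected
#'   count reaches this threshold (textbook default 5).
#' @return object of class `poisson_gof`: list with `lambda_hat`,
#'   `statistic`, `df`, `p_value`, `n` and `bins` (data.frame of bin
#'   label, observed, expected). With fewer than 2 usable bins (e.g.
#'   all-zero input) the test is undefined: `p_value` is `NA` and a
#'   warning is issued.
#' @export
poisson_gof <- function(counts, min_expected = 5) {
  if (length(counts) == 0L) stop("empty input")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  n <- length(counts)
  if (n < 10L) warning("fewer than 10 genomes; the chi-square test is unreliable")
  lambda <- mean(counts)

  out <- list(lambda_hat = lambda, n = n)
  class(out) <- "poisson_gof"
  if (lambda == 0) {
    warning("all counts are zero; goodness of fit is undefined")
    out$statistic <- NA_real_; out$df <- NA_integer_; out$p_value <- NA_real_
    out$bins <- data.frame(bin = "0", observed = n, expected = n)
    return(out)
  }

  # bins 0..c-1 plus a ">= c" tail; shrink c until the tail and every
  # retained bin have expected count >= min_expected
  cmax <- max(counts)
  cut <- cmax + 1L
  repeat {
    exp_low <- n * stats::dpois(0:(cut - 1L), lambda)
    exp_tail <- n * stats::ppois(cut - 1L, lambda, lower.tail = FALSE)
    if ((all(exp_low >= min_expected) && exp_tail >= min_expected) ||
        cut == 1L) break
    cut <- cut - 1L
  }
  observed <- c(tabulate(factor(pmin(counts, cut), levels = 0:cut))[1:cut],
                sum(counts >= cut))
  expected <- c(n * stats::dpois(0:(cut - 1L), lambda),
                n * stats::ppois(cut - 1L, lambda, lower.tail = FALSE))
  labels <- c(as.character(0:(cut - 1L)), paste0(">=", cut))
  df <- length(expected) - 2L
  out$bins <- data.frame(bin = labels, observed = observed,
                         expected = expected)
  if (df < 1L) {
    warning("fewer than 3 bins after merging; test is undefined")
    out$statistic <- NA_real_; out$df <- df; out$p_value <- NA_real_
    return(out)
  }
  stat <- sum((observed - expected)^2 / expected)
  out$statistic <- stat
  out$df <- df
  out$p_value <- stats::pchisq(stat, df, lower.tail = FALSE)
  out
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf("Poisson goodness of fit: lambda_hat = %.3f (n = %d)\n",
              x$lambda_hat, x$n))
  if (is.na(x$p_value)) {
    cat("  test undefined (degenerate binning)\n")
  } else {
    cat(sprintf("  chi^2 = %.3f, df = %d, p = %.3f\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}
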