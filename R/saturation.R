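# Occupancy maximum-likelihood estimation of the number of hidden
# phenotype-causing targets, and the three derived estimators of the
# fraction f of non-synonymous SNVs with a phenotype.

#' Log-likelihood of a k-distribution given k targets
#'
#' The model places m mutations uniformly and independently over k
#' exchangeable targets. The probability of observing the hit-count
#' histogram (k_1, ..., k_max), with k_0 = k - occupied unseen targets,
#' is
#' \deqn{P = \frac{m!\,k!}{\prod_{i=0}^{max} k_i!\,(i!)^{k_i}}
#'   \cdot k^{-m}.}
#' Computed via log-gamma so large counts do not overflow; all terms,
#' including those constant in k, are retained so `exp()` of the result
#' equals the closed-form probability exactly.
#'
#' @param kd a [k_distribution()].
#' @param k candidate total target count(s), integer, `k >= occupied`
#'   (vectorised over `k`).
#' @return natural log of the probability, one value per element of `k`.
#' @export
log_likelihood <- function(kd, k) {
  stopifnot(inherits(kd, "k_distribution"), kd$occupied >= 1L)
  if (any(k < kd$occupied)) {
    stop("k must be >= occupied (", kd$occupied, "): k_0 would be negative")
  }
  i <- as.integer(names(kd$counts))
  ki <- as.numeric(kd$counts)
  const <- lgamma(kd$m + 1) - sum(lgamma(ki + 1) + ki * lgamma(i + 1))
  const + lgamma(k + 1) - lgamma(k - kd$occupied + 1) - kd$m * log(k)
}

#' Maximum-likelihood estimate of the total target count
#'
#' Maximises [log_likelihood()] over integer k by grid scan and reports
#' a 95% credibility interval: the central (equal-tail) interval of the
#' likelihood normalised to sum to one over the integer grid (flat
#' prior). The grid starts at `occupied` and its upper bound doubles
#' automatically until the posterior mass in the upper half of the grid
#' falls below `tail_tol`, guarding against silent truncation.
#'
#' When every target was hit exactly once (`max == 1`) the likelihood
#' increases without bound in k and no finite maximiser exists; the
#' estimate is then flagged `unbounded` with `k_hat = NA`.
#'
#' @param kd a [k_distribution()] with `m >= 1`.
#' @param k_max initial upper search bound (default `200 * occupied`).
#' @param conf credibility level (default 0.95).
#' @param tail_tol maximum tolerated posterior mass in the upper half of
#'   the search grid before extending it.
#' @param max_doublings cap on automatic bound extensions; if reached
#'   with tail mass still above `tail_tol` the interval is truncated and
#'   a warning is issued.
#' @param k_cap absolute ceiling on the search bound (memory guard;
#'   with very few recurrent hits the likelihood tail decays so slowly
#'   that no finite grid captures it, and the interval upper bound is
#'   then reported truncated at `k_cap`).
#' @param profile if `TRUE`, attach the normalised likelihood profile
#'   (data.frame k, posterior) for plotting/dumping.
#' @return object of class `saturation_estimate`: list with `k_hat`,
#'   `ci95` (integer `c(lo, hi)`), `log_lik` at the maximum,
#'   `unbounded` flag, `k_max` actually used, `kd`, and optionally
#'   `profile`.
#' @examples
#' mle_k(k_distribution(c(41, 13, 3)))  # k_hat = 124
#' @export
mle_k <- function(kd, k_max = NULL, conf = 0.95, tail_tol = 1e-6,
                  max_doublings = 16L, k_cap = 1e6L, profile = FALSE) {
  stopifnot(inherits(kd, "k_distribution"))
  if (kd$m == 0L) stop("empty k-distribution: no hits to fit")
  est <- list(method = NA_character_, kd = kd)
  if (kd$max == 1L) {
    # no recurrences: likelihood is strictly increasing in k
    est <- c(est, list(k_hat = NA_integer_, ci95 = c(kd$occupied, Inf),
                       log_lik = NA_real_, unbounded = TRUE,
                       k_max = NA_integer_))
    class(est) <- "saturation_estimate"
    return(est)
  }
  if (is.null(k_max)) k_max <- 200L * kd$occupied
  k_max <- min(max(k_max, kd$occupied + 1L), k_cap)
  truncated <- TRUE
  for (d in 0:max_doublings) {
    ks <- kd$occupied:k_max
    ll <- log_likelihood(kd, ks)
    w <- exp(ll - max(ll))
    w <- w / sum(w)
    upper_mass <- sum(w[ks > kd$occupied + (k_max - kd$occupied) / 2])
    if (upper_mass < tail_tol) { truncated <- FALSE; break }
    if (k_max >= k_cap) break
    k_max <- min(2L * k_max, as.integer(k_cap))
  }
  if (truncated) {
    warning("likelihood tail not captured by k <= ", k_max,
            "; credibility interval upper bound is truncated")
  }
  imax <- which.max(ll)  # ties: smallest k
  cw <- cumsum(w)
  alpha <- (1 - conf) / 2
  lo <- ks[which(cw >= alpha)[1]]
  hi <- ks[which(cw >= 1 - alpha)[1]]
  est <- c(est, list(k_hat = ks[imax], ci95 = c(lo, hi),
                     log_lik = ll[imax], unbounded = FALSE, k_max = k_max))
  if (profile) est$profile <- data.frame(k = ks, posterior = w)
  class(est) <- "saturation_estimate"
  est
}

#' @export
print.saturation_estimate <- function(x, ...) {
  if (isTRUE(x$unbounded)) {
    cat("Saturation estimate: unbounded (all targets hit once;",
        "likelihood increases with k)\n")
  } else {
    cat(sprintf("Saturation estimate: k_hat = %d, 95%% CI [%d, %d]\n",
                x$k_hat, x$ci95[1], x$ci95[2]))
    if (!is.null(x$f)) {
      cat(sprintf("  f = %.3f, 95%% CI [%.3f, %.3f] (%s)\n",
                  x$f, x$f_ci95[1], x$f_ci95[2], x$method))
    }
  }
  invisible(x)
}

check_bounded <- function(est) {
  stopifnot(inherits(est, "saturation_estimate"))
  if (isTRUE(est$unbounded)) {
    stop("estimate is unbounded (no recurrent hits); f is undefined")
  }
}

#' Fraction of phenotype-causing non-synonymous SNVs, residue route
#'
#' Converts an ML target count obtained from the distribution of
#' different mutations per residue into the fraction f of residues
#' whose mutation yields the phenotype: `f = k_hat / n_aa`. Interval
#' endpoints are transformed the same way.
#'
#' @param est a bounded [mle_k()] result from a `per_residue_distinct`
#'   k-distribution.
#' @param n_aa protein length in amino acids.
#' @return the `saturation_estimate` with fields `f`, `f_ci95` and
#'   `method = "aa_saturation"` added.
#' @export
method1_f <- function(est, n_aa) {
  check_bounded(est)
  if (est$k_hat > n_aa) {
    stop("k_hat (", est$k_hat, ") exceeds the number of residues (", n_aa, ")")
  }
  est$f <- est$k_hat / n_aa
  est$f_ci95 <- pmin(est$ci95 / n_aa, 1)
  est$method <- "aa_saturation"
  est
}

#' Fraction of phenotype-causing non-synonymous SNVs, nucleotide route
#'
#' As [method1_f()], but the targets are individual non-synonymous SNVs
#' hit by independent recurrent mutations: `f = k_hat /
#' n_ns_potential`.
#'
#' @param est a bounded [mle_k()] result from a `per_site_recurrent`
#'   k-distribution.
#' @param n_ns_potential number of potential non-synonymous SNVs of the
#'   gene(s) (from [enumerate_potential_snvs()]).
#' @return the `saturation_estimate` with `f`, `f_ci95`,
#'   `method = "nt_saturation"`.
#' @export
method2_f <- function(est, n_ns_potential) {
  check_bounded(est)
  if (est$k_hat > n_ns_potential) {
    stop("k_hat (", est$k_hat, ") exceeds the number of potential ",
         "non-synonymous SNVs (", n_ns_potential, ")")
  }
  est$f <- est$k_hat / n_ns_potential
  est$f_ci95 <- pmin(est$ci95 / n_ns_potential, 1)
  est$method <- "nt_saturation"
  est
}

#' Fraction of phenotype-causing non-synonymous SNVs, STOP saturation
#'
#' Every STOP gain has a phenotype, so the fraction of potential STOPs
#' already observed measures the saturation s of the screen. Equating
#' the saturation of phenotype-causing non-synonymous SNVs to s implies
#' their total is `obs_ns / s`, and
#' `f = obs_ns / (s * pot_ns)`.
#'
#' @param obs_stops,pot_stops observed and potential STOP-gain SNVs.
#' @param obs_ns,pot_ns observed and potential non-synonymous SNVs.
#' @return list with `saturation` (s) and `f`.
#' @export
method3_f <- function(obs_stops, pot_stops, obs_ns, pot_ns) {
  stopifnot(pot_stops > 0, pot_ns > 0, obs_stops <= pot_stops)
  if (obs_stops == 0) {
    stop("no observed STOP mutations: saturation is undefined")
  }
  s <- obs_stops / pot_stops
  list(saturation = s, f = obs_ns / (s * pot_ns), method = "stop_saturation")
}
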