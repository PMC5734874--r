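# Phenotypic-to-total mutation-rate correction and genome
# extrapolation. The reporter assay only sees mutations with a
# phenotype; these corrections divide out the phenotypic fraction.

#' Correction parameters
#'
#' Bundles the quantities needed to convert observed (phenotypic)
#' mutation rates into total rates.
#'
#' @param f fraction of potential non-synonymous SNVs with a phenotype
#'   (from one of the three saturation estimators).
#' @param p_stop,p_ns,p_syn proportions of potential SNVs by codon
#'   effect (must sum to 1); from [enumerate_potential_snvs()].
#' @param p_3nt,p_6nt fractions of observed indels of size 3 nt and
#'   6 nt (the in-frame classes undercounted by the assay).
#' @param target_len length in nucleotides of the reporter target(s).
#' @param genome_len genome length in nucleotides.
#' @return validated list of class `correction_params`.
#' @export
correction_params <- function(f, p_stop, p_ns, p_syn = 1 - p_stop - p_ns,
                              p_3nt = 0, p_6nt = 0,
                              target_len = NULL, genome_len = NULL) {
  fr <- c(f = f, p_stop = p_stop, p_ns = p_ns, p_syn = p_syn,
          p_3nt = p_3nt, p_6nt = p_6nt)
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12)) {
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  }
  if (abs(p_syn + p_ns + p_stop - 1) > 1e-9) {
    stop("p_syn + p_ns + p_stop must equal 1")
  }
  if (p_3nt + p_6nt > 1 + 1e-12) stop("p_3nt + p_6nt must not exceed 1")
  if (!is.null(target_len) && !is.null(genome_len) &&
      target_len > genome_len) {
    stop("target_len exceeds genome_len")
  }
  structure(list(f = f, p_stop = p_stop, p_ns = p_ns, p_syn = p_syn,
                 p_3nt = p_3nt, p_6nt = p_6nt,
                 target_len = target_len, genome_len = genome_len),
            class = "correction_params")
}

#' Phenotypic share of potential SNVs
#'
#' All STOP gains and a fraction f of non-synonymous changes yield the
#' phenotype; synonymous changes never do. The share of all potential
#' SNVs visible to the assay is therefore
#' `phi = p_stop + f * p_ns`.
#'
#' @param params a [correction_params()] (or any list with `f`,
#'   `p_stop`, `p_ns`).
#' @return the fraction phi.
#' @export
snv_phenotypic_fraction <- function(params) {
  params$p_stop + params$f * params$p_ns
}

#' Correct an observed SNV rate to a total rate
#'
#' @param observed_rate phenotypic SNV rate (per day).
#' @param params a [correction_params()].
#' @return total SNV rate = observed / phi.
#' @export
correct_snv_rate <- function(observed_rate, params) {
  stopifnot(observed_rate >= 0)
  phi <- snv_phenotypic_fraction(params)
  if (phi <= 0) stop("phenotypic SNV fraction is zero; cannot correct")
  observed_rate / phi
}

#' Inflation factor for the observed indel rate
#'
#' Out-of-frame indels are assumed always to have a phenotype. In-frame
#' indels are only seen when they disrupt an essential residue: 3-nt
#' events with probability f, 6-nt events with probability
#' `1 - (1 - f)^2` (either of two residues essential). The phenotypic
#' fraction of indels is
#' `phi = 1 / (1 + p_3nt / f + p_6nt / (1 - (1 - f)^2))`
#' and the returned multiplier is `1 / phi`, so
#' total rate = observed rate x multiplier.
#'
#' The default (`method = "as_printed"`) applies the inflation terms to
#' the overall observed-indel fractions directly. The alternative
#' (`method = "inflate_observed"`) inflates only the \emph{observed}
#' in-frame classes, multiplier
#' `1 + p_3nt (1/f - 1) + p_6nt (1/(1-(1-f)^2) - 1)`; it is retained
#' as a named option because it treats p_3nt/p_6nt consistently as
#' already-observed fractions, but it is not the default.
#'
#' @param f fraction of essential residues, in (0, 1].
#' @param p_3nt,p_6nt fractions of observed indels of size 3 and 6 nt.
#' @param method correction variant, see above.
#' @return multiplier >= 1.
#' @export
indel_inflation_factor <- function(f, p_3nt, p_6nt,
                                   method = c("as_printed",
                                              "inflate_observed")) {
  method <- match.arg(method)
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]")
  stopifnot(p_3nt >= 0, p_6nt >= 0, p_3nt + p_6nt <= 1)
  q6 <- 1 - (1 - f)^2
  switch(method,
         as_printed = 1 + p_3nt / f + p_6nt / q6,
         inflate_observed = 1 + p_3nt * (1 / f - 1) + p_6nt * (1 / q6 - 1))
}

#' Extrapolate a target-local rate to the genome
#'
#' Assumes the per-nucleotide mutation rate measured on the reporter
#' target(s) holds genome-wide.
#'
#' @param total_rate_on_target corrected mutation rate on the target
#'   (per day).
#' @param target_len,genome_len lengths in nucleotides.
#' @return mutations per genome per day.
#' @export
extrapolate_genome <- function(total_rate_on_target, target_len,
                               genome_len) {
  stopifnot(target_len > 0, genome_len > 0)
  total_rate_on_target / target_len * genome_len
}
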