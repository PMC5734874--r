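# Synthetic-data generators reproducing the statistical structure the
# analysis assumes: uniform multinomial placement of hits over hidden
# targets, phenotype-filtered reporter mutagenesis, linear accumulation
# with multiplicative noise, and Poisson per-genome counts.
#
# Each generator seeds R's global PRNG stream once (Mersenne-Twister,
# the R default) when `seed` is supplied, so a seed fully determines
# the output.

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Random coding sequence
#'
#' Uniform-random CDS beginning with ATG and free of internal stop
#' codons (codons are redrawn until non-stop), without a trailing stop
#' codon.
#'
#' @param n_codons protein length in codons.
#' @param seed optional integer seed.
#' @return character string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  stopifnot(n_codons >= 1)
  maybe_seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1] <- "ATG"
  if (n_codons > 1L) {
    for (j in 2:n_codons) {
      repeat {
        cd <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
        if (!cd %in% stops) break
      }
      codons[j] <- cd
    }
  }
  paste(codons, collapse = "")
}

#' Simulate uniform hits over hidden targets
#'
#' Places m mutations independently and uniformly over `k_true`
#' targets and returns the hits-per-target distribution (targets with
#' zero hits are unobserved, as in a real screen). This is exactly the
#' generative model under which [mle_k()] is the maximum-likelihood
#' estimator of `k_true`.
#'
#' @param k_true hidden target count.
#' @param m number of mutations to place.
#' @param seed optional integer seed.
#' @return a [k_distribution()].
#' @export
simulate_target_hits <- function(k_true, m, seed = NULL) {
  stopifnot(k_true >= 1, m >= 1)
  maybe_seed(seed)
  hits <- tabulate(sample.int(k_true, m, replace = TRUE), nbins = k_true)
  k_distribution(table(hits[hits > 0L]))
}

#' Simulate a phenotype-filtered reporter mutagenesis screen
#'
#' A random subset of `round(f_true * n_aa)` residues is designated
#' essential. `m` candidate SNVs are drawn uniformly over all potential
#' SNVs of the CDS; a candidate is observed iff it is a STOP gain or a
#' non-synonymous change at an essential residue (synonymous changes
#' and non-synonymous changes at non-essential residues are invisible
#' to the assay). The output mimics a Sanger-sequenced table of
#' loss-of-function reporter mutants, one mutant isolate per retained
#' candidate.
#'
#' @param cds coding sequence.
#' @param f_true fraction of residues that are essential, in [0, 1]
#'   (at 0 only STOP gains are ever observed).
#' @param m number of candidate mutations drawn.
#' @param seed optional integer seed.
#' @param gene locus name written in the records.
#' @param day,population metadata written in the records.
#' @return a [mutation_records()] data.frame of the retained SNVs, with
#'   attributes `essential` (the simulated essential residue indices)
#'   and `candidates` (the full pre-filter candidate table with columns
#'   position, ref, alt, residue, effect, retained).
#' @export
simulate_phenotypic_assay <- function(cds, f_true, m, seed = NULL,
                                      gene = "gene1", day = 8,
                                      population = "sim1") {
  stopifnot(f_true >= 0, f_true <= 1, m >= 1)
  maybe_seed(seed)
  tab <- potential_snv_table(cds)
  n_aa <- max(tab$residue)
  n_ess <- if (f_true == 0) 0L else max(1L, round(f_true * n_aa))
  essential <- sort(sample.int(n_aa, n_ess))
  draw <- tab[sample.int(nrow(tab), m, replace = TRUE), ]
  retained <- draw$effect == "stop" |
    (draw$effect == "non-synonymous" & draw$residue %in% essential)
  obs <- draw[retained, , drop = FALSE]
  rec <- mutation_records(
    sample = sprintf("mut%04d", seq_len(nrow(obs))),
    population = population, day = day, locus = gene,
    position = obs$position, ref = obs$ref, alt = obs$alt)
  draw$retained <- retained
  attr(rec, "essential") <- essential
  attr(rec, "candidates") <- draw
  rec
}

#' Simulate linear accumulation of mutant frequency
#'
#' frequency(day) = max(0, (intercept + slope_true * day) * (1 + eps)),
#' eps ~ Normal(0, noise_cv), independently per point and experiment.
#'
#' @param slope_true frequency increase per day.
#' @param intercept frequency at day 0 (the replication-era load).
#' @param days vector of sampling days.
#' @param noise_cv coefficient of variation of the multiplicative
#'   noise.
#' @param n_experiments number of independent series.
#' @param seed optional integer seed.
#' @return data.frame with columns `experiment`, `day`, `frequency`.
#' @export
simulate_accumulation <- function(slope_true, intercept = 0, days,
                                  noise_cv = 0, n_experiments = 1,
                                  seed = NULL) {
  if (length(days) == 0L) stop("days must be nonempty")
  maybe_seed(seed)
  grid <- expand.grid(day = days, experiment = seq_len(n_experiments))
  mu <- intercept + slope_true * grid$day
  eps <- stats::rnorm(nrow(grid), 0, noise_cv)
  data.frame(experiment = paste0("exp", grid$experiment),
             day = grid$day,
             frequency = pmax(0, mu * (1 + eps)))
}

#' Simulate per-genome mutation counts
#'
#' @param lambda_true mean mutations per genome.
#' @param n_genomes number of genomes.
#' @param seed optional integer seed.
#' @return integer vector of i.i.d. Poisson(`lambda_true`) draws.
#' @export
simulate_genome_counts <- function(lambda_true, n_genomes, seed = NULL) {
  stopifnot(lambda_true >= 0, n_genomes >= 1)
  maybe_seed(seed)
  stats::rpois(n_genomes, lambda_true)
}
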