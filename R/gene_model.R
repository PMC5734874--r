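# Codon-level enumeration of potential SNVs and construction of
# hits-per-target (k-) distributions.

check_cds <- function(cds, on_internal_stop = c("warn", "error")) {
  on_internal_stop <- match.arg(on_internal_stop)
  if (inherits(cds, "DNAString")) cds <- as.character(cds)
  cds <- normalize_base(cds)
  if (grepl("[^ACGT]", cds)) {
    stop("CDS contains non-ACGT symbols (ambiguity codes are rejected)")
  }
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length (", nchar(cds), ") is not a multiple of 3")
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  # trailing stop codon is not part of the protein; drop it
  if (length(aa) && aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*")) {
    msg <- paste("internal stop codon at codon(s):",
                 paste(which(aa == "*"), collapse = ", "))
    if (on_internal_stop == "error") stop(msg) else warning(msg)
  }
  list(codons = codons, aa = aa)
}

# All 9 * n_aa potential single-nucleotide substitutions of a CDS with
# their codon-level effect. Workhorse shared by the enumeration, the
# observed-SNV classifier and the assay simulator.
potential_snv_table <- function(cds, on_internal_stop = c("warn", "error")) {
  p <- check_cds(cds, on_internal_stop)
  n_aa <- length(p$codons)
  if (n_aa == 0L) stop("empty CDS")
  gc <- Biostrings::GENETIC_CODE
  codon_idx <- rep(seq_len(n_aa), each = 9L)
  within <- rep(rep(1:3, each = 3L), n_aa)
  codon <- p$codons[codon_idx]
  ref <- substring(codon, within, within)
  # rows come in aligned triples per position: the 3 alternative bases
  alt_map <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
  alt <- alt_map[cbind(match(ref, BASES), rep_len(1:3, length(ref)))]
  mutated <- codon
  substr(mutated, within, within) <- alt
  aa_new <- unname(gc[mutated])
  aa_old <- p$aa[codon_idx]
  effect <- ifelse(aa_new == "*", "stop",
            ifelse(aa_new == aa_old, "synonymous", "non-synonymous"))
  data.frame(position = (codon_idx - 1L) * 3L + within,
             residue = codon_idx, ref = ref, alt = alt,
             effect = effect, stringsAsFactors = FALSE, row.names = NULL)
}

#' Enumerate potential SNVs of a coding sequence
#'
#' Classifies every possible single-nucleotide substitution of a CDS
#' (3 alternatives at each of the 3*n_aa coding positions, standard
#' genetic code) by its codon-level effect: synonymous, non-synonymous
#' or STOP gain. A trailing stop codon is excluded from the protein;
#' stop-loss changes are therefore out of scope.
#'
#' @param cds coding sequence (character string or
#'   [Biostrings::DNAString]), length divisible by 3.
#' @param name gene name carried in the result.
#' @param on_internal_stop `"warn"` (default) or `"error"` when an
#'   internal stop codon is present.
#' @return object of class `gene_model`: list with `name`, `n_aa`,
#'   counts `n_syn`, `n_ns`, `n_stop` and proportions `p_syn`, `p_ns`,
#'   `p_stop` (fractions of all 9*n_aa potential SNVs).
#' @examples
#' enumerate_potential_snvs("ATGTGG")  # Met-Trp, 18 potential SNVs
#' @export
enumerate_potential_snvs <- function(cds, name = "gene",
                                     on_internal_stop = c("warn", "error")) {
  tab <- potential_snv_table(cds, on_internal_stop)
  n <- nrow(tab)
  n_syn <- sum(tab$effect == "synonymous")
  n_ns <- sum(tab$effect == "non-synonymous")
  n_stop <- sum(tab$effect == "stop")
  out <- list(name = name, n_aa = n %/% 9L,
              n_syn = n_syn, n_ns = n_ns, n_stop = n_stop,
              p_syn = n_syn / n, p_ns = n_ns / n, p_stop = n_stop / n)
  class(out) <- "gene_model"
  out
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model '%s': %d aa, %d potential SNVs\n",
              x$name, x$n_aa, 9L * x$n_aa))
  cat(sprintf("  synonymous     %5d (%.2f)\n", x$n_syn, x$p_syn))
  cat(sprintf("  non-synonymous %5d (%.2f)\n", x$n_ns, x$p_ns))
  cat(sprintf("  STOP           %5d (%.2f)\n", x$n_stop, x$p_stop))
  invisible(x)
}

#' Classify one observed SNV within a CDS
#'
#' @param cds coding sequence.
#' @param position 1-based position of the substitution within the CDS.
#' @param alt alternate base, different from the reference base.
#' @return `"synonymous"`, `"non-synonymous"` or `"stop"`.
#' @export
classify_observed_snv <- function(cds, position, alt) {
  p <- check_cds(cds)
  alt <- normalize_base(alt)
  n_nt <- 3L * length(p$codons)
  if (position < 1L || position > n_nt) {
    stop("position ", position, " outside CDS (1..", n_nt, ")")
  }
  if (!alt %in% BASES) stop("alt must be one of A/C/G/T")
  ci <- (position - 1L) %/% 3L + 1L
  wi <- (position - 1L) %% 3L + 1L
  codon <- p$codons[ci]
  if (substring(codon, wi, wi) == alt) stop("alt equals the reference base")
  mutated <- codon
  substr(mutated, wi, wi) <- alt
  aa_new <- unname(Biostrings::GENETIC_CODE[mutated])
  if (aa_new == "*") "stop"
  else if (aa_new == p$aa[ci]) "synonymous"
  else "non-synonymous"
}

#' Construct a k-distribution from explicit counts
#'
#' A k-distribution records how many targets were hit exactly i times:
#' the sufficient statistic for the occupancy maximum-likelihood
#' estimator of the total (mostly unseen) target count.
#'
#' @param counts named non-negative integer vector; names are hit
#'   multiplicities i >= 1, values are the number of targets k_i hit
#'   exactly i times. Unnamed vectors are taken as (k_1, k_2, ...).
#' @return object of class `k_distribution`: list with `counts`
#'   (zero-entries dropped), `m` (total hits, sum i*k_i), `occupied`
#'   (sum k_i) and `max` (largest i with k_i > 0).
#' @examples
#' k_distribution(c(41, 13, 3))          # 57 residues, 76 hits
#' k_distribution(c(`1` = 64, `2` = 20, `3` = 8, `6` = 1))
#' @export
k_distribution <- function(counts) {
  if (is.null(names(counts))) names(counts) <- seq_along(counts)
  i <- as.integer(names(counts))
  ki <- as.numeric(counts)
  if (anyNA(i) || any(i < 1L)) stop("multiplicities must be integers >= 1")
  if (any(ki < 0) || any(ki != round(ki))) stop("counts must be non-negative integers")
  keep <- ki > 0
  i <- i[keep]; ki <- as.integer(ki[keep])
  ord <- order(i)
  i <- i[ord]; ki <- ki[ord]
  counts <- stats::setNames(ki, i)
  out <- list(counts = counts,
              m = sum(i * ki),
              occupied = sum(ki),
              max = if (length(i)) max(i) else 0L)
  class(out) <- "k_distribution"
  out
}

#' Build a k-distribution from observed hits
#'
#' Two counting conventions are supported, matching the two saturation
#' estimators:
#' \describe{
#'   \item{`per_residue_distinct`}{`target_id` is a residue index and
#'     `mutation_id` a distinct amino-acid-changing substitution;
#'     duplicates of the same `mutation_id` at a residue count once
#'     (the distribution of \emph{different} mutations per residue).}
#'   \item{`per_site_recurrent`}{`target_id` is a distinct
#'     non-synonymous SNV and every observation counts (the
#'     distribution of \emph{independent recurrent} hits per site).}
#' }
#'
#' @param target_id vector of target identifiers, one per observation.
#' @param mutation_id vector of mutation identifiers (required for
#'   `per_residue_distinct`; ignored otherwise).
#' @param level counting convention, see above.
#' @return a [k_distribution()].
#' @export
build_k_distribution <- function(target_id, mutation_id = NULL,
                                 level = c("per_residue_distinct",
                                           "per_site_recurrent")) {
  level <- match.arg(level)
  if (level == "per_residue_distinct") {
    if (is.null(mutation_id)) {
      stop("mutation_id is required for level = 'per_residue_distinct'")
    }
    keep <- !duplicated(paste(target_id, mutation_id, sep = "\r"))
    target_id <- target_id[keep]
  }
  hits <- table(target_id)
  if (length(hits) == 0L) {
    return(k_distribution(stats::setNames(integer(), integer())))
  }
  k_distribution(table(as.integer(hits)))
}

#' @export
print.k_distribution <- function(x, ...) {
  cat("k-distribution:",
      paste0(names(x$counts), ":", x$counts, collapse = ", "),
      sprintf("(m = %d, occupied = %d)\n", x$m, x$occupied))
  invisible(x)
}
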