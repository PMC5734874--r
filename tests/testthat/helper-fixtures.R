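# Fixtures are built in code: record sets with prescribed spectrum
# class counts, and brute-force oracles for the likelihood and the
# codon enumeration.

# SNV records realising given counts of the six strand-symmetric
# substitution classes; alternates between the two strands so the
# classifier's strand symmetry is exercised by every fixture.
make_snv_records <- function(class_counts, population = "p1", day = 1) {
  reps <- list(  # each class: pyrimidine-strand and purine-strand form
    "GC>AT" = list(c("C", "T"), c("G", "A")),
    "GC>TA" = list(c("C", "A"), c("G", "T")),
    "GC>CG" = list(c("C", "G"), c("G", "C")),
    "AT>GC" = list(c("T", "C"), c("A", "G")),
    "AT>CG" = list(c("T", "G"), c("A", "C")),
    "AT>TA" = list(c("T", "A"), c("A", "T"))
  )
  ref <- alt <- character(0)
  for (cl in names(class_counts)) {
    n <- class_counts[[cl]]
    if (n == 0) next
    strand <- rep_len(1:2, n)
    ref <- c(ref, vapply(strand, function(s) reps[[cl]][[s]][1], ""))
    alt <- c(alt, vapply(strand, function(s) reps[[cl]][[s]][2], ""))
  }
  n <- length(ref)
  mutation_records(sample = sprintf("s%03d", seq_len(n)),
                   population = population, day = day, locus = "gene1",
                   position = seq_len(n), ref = ref, alt = alt)
}

# indel records with prescribed event sizes (negative = deletion)
make_indel_records <- function(sizes, population = "p1", day = 8,
                               offset = 10000L) {
  ref <- ifelse(sizes < 0, strrep("A", pmax(-sizes, 0)), "")
  alt <- ifelse(sizes > 0, strrep("A", pmax(sizes, 0)), "")
  mutation_records(sample = sprintf("i%04d", seq_along(sizes)),
                   population = population, day = day, locus = "gene1",
                   position = offset + seq_along(sizes),
                   ref = ref, alt = alt)
}

# day-1 Ts/Tv/AT-bias published counts decomposed into the six classes
# (decomposition is not unique; this one matches every printed margin:
# 105 SNVs, 33 Ts, 63 to A/T, 17 to C/G)
day1_class_counts <- c("GC>AT" = 30, "GC>TA" = 33, "GC>CG" = 12,
                       "AT>GC" = 3, "AT>CG" = 14, "AT>TA" = 13)

# days 8+15 indel margins: 170 deletions / 1771 bp, 50 insertions /
# 500 bp
day815_indel_sizes <- c(rep(-10L, 169), -81L, rep(10L, 50))

# whole-genome 3-month indel margins: 27 deletions / 511 bp,
# 50 insertions / 296 bp
genome_indel_sizes <- c(rep(-19L, 26), -17L, rep(6L, 49), 2L)

# exact probability of a k-distribution under uniform placement of m
# hits on k targets, by exhaustive enumeration of all k^m assignments
enum_kdist_probs <- function(k, m) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  sig <- apply(grid, 1, function(row) {
    h <- tabulate(row, nbins = k)
    paste(sort(h[h > 0]), collapse = ",")
  })
  tab <- table(sig) / k^m
  tab
}

# codon-effect oracle: mutate one base, translate the whole CDS with
# Biostrings, compare proteins
oracle_effect <- function(cds, pos, alt) {
  prot <- function(s) {
    # no.init.codon: the initiator is a codon like any other here
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  mut <- cds
  substr(mut, pos, pos) <- alt
  p0 <- prot(cds); p1 <- prot(mut)
  if (grepl("\\*", p1)) "stop"
  else if (p0 == p1) "synonymous"
  else "non-synonymous"
}
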