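# Mutational spectrum: classification and summary statistics of
# reporter-gene mutation tables, after clonal-redundancy filtering.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

normalize_base <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Build a table of mutation records
#'
#' Validates and normalises a per-isolate mutation table. Each row is one
#' observed mutation: an SNV when `ref` and `alt` are single differing
#' bases, otherwise an insertion, deletion or complex event. `"-"` or the
#' empty string denotes an absent allele side (pure insertion/deletion).
#'
#' @param sample sample identifier (character).
#' @param population clonal culture / experiment of origin; the unit
#'   within which redundant mutations are collapsed.
#' @param day non-negative days in quiescence at sampling.
#' @param locus gene name or chromosome.
#' @param position 1-based coordinate (within the CDS for gene loci).
#' @param ref,alt reference and alternate allele over A/C/G/T; at most
#'   one side may be empty.
#' @return data.frame of class `mutation_records` with the seven columns
#'   above plus `type` (one of `"snv"`, `"insertion"`, `"deletion"`,
#'   `"complex"`) and `size` (signed net length change, 0 for SNVs).
#' @export
mutation_records <- function(sample, population, day, locus, position,
                             ref, alt) {
  ref <- normalize_base(ifelse(is.na(ref) | ref == "-", "", ref))
  alt <- normalize_base(ifelse(is.na(alt) | alt == "-", "", alt))
  n <- length(ref)
  stopifnot(length(alt) == n, length(position) == n)
  # recycle scalar metadata over the records
  if (n > 0L) {
    sample <- rep_len(sample, n); population <- rep_len(population, n)
    day <- rep_len(day, n); locus <- rep_len(locus, n)
  } else {
    sample <- character(); population <- character()
    day <- numeric(); locus <- character()
    position <- integer()
  }
  bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt) |
    (ref == "" & alt == "")
  if (any(bad)) {
    stop("malformed record(s) at row(s): ",
         paste(which(bad), collapse = ", "),
         " (non-ACGT allele or both sides empty)")
  }
  if (any(ref == alt)) {
    stop("ref equals alt at row(s): ",
         paste(which(ref == alt), collapse = ", "))
  }
  if (any(day < 0) || any(position < 1)) {
    stop("negative day or non-positive position")
  }
  size <- nchar(alt) - nchar(ref)
  type <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv",
          ifelse(size > 0L, "insertion",
          ifelse(size < 0L, "deletion", "complex")))
  out <- data.frame(
    sample = as.character(sample), population = as.character(population),
    day = as.numeric(day), locus = as.character(locus),
    position = as.integer(position), ref = ref, alt = alt,
    type = type, size = as.integer(size), stringsAsFactors = FALSE
  )
  class(out) <- c("mutation_records", "data.frame")
  out
}

#' Classify a single-nucleotide variant
#'
#' Assigns the transition/transversion flag and the strand-symmetric
#' base-pair change class. The six classes partition the 12 ordered
#' substitutions: a substitution and its reverse-complement map to the
#' same class (C>T and G>A are both GC>AT).
#'
#' @param ref,alt single nucleotides (vectors of equal length accepted).
#' @return data.frame with columns `is_transition` (logical) and
#'   `pair_class` (factor with levels `GC>AT`, `GC>TA`, `GC>CG`,
#'   `AT>GC`, `AT>CG`, `AT>TA`).
#' @examples
#' classify_snv("C", "T")  # transition, GC>AT
#' @export
classify_snv <- function(ref, alt) {
  ref <- normalize_base(ref)
  alt <- normalize_base(alt)
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L) ||
      any(!ref %in% BASES) || any(!alt %in% BASES)) {
    stop("ref and alt must be single A/C/G/T nucleotides")
  }
  if (any(ref == alt)) stop("ref must differ from alt")
  # normalise to the pyrimidine strand so classification is
  # strand-symmetric
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, COMPLEMENT[ref], ref)
  a <- ifelse(purine, COMPLEMENT[alt], alt)
  key <- paste0(r, a)
  map <- c(CT = "GC>AT", CA = "GC>TA", CG = "GC>CG",
           TC = "AT>GC", TG = "AT>CG", TA = "AT>TA")
  pair_class <- factor(unname(map[key]), levels = pair_class_levels())
  data.frame(is_transition = key %in% c("CT", "TC"),
             pair_class = pair_class)
}

pair_class_levels <- function() {
  c("GC>AT", "GC>TA", "GC>CG", "AT>GC", "AT>CG", "AT>TA")
}

#' Collapse redundant mutations within clonal populations
#'
#' Within each population, mutations with identical
#' (locus, position, ref, alt) are collapsed to a single representative
#' (earliest day, then first input order): repeated sightings of the
#' same mutation in one clonal culture reflect lineage expansion, not
#' independent events. Identical mutations in different populations are
#' retained independently.
#'
#' @param records a `mutation_records` data.frame.
#' @return the filtered `mutation_records`.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$population, records$locus, records$position,
               records$ref, records$alt, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), records$day,
               seq_len(nrow(records)))
  r <- records[ord, , drop = FALSE]
  k <- key[ord]
  out <- r[!duplicated(k), , drop = FALSE]
  # restore input order among representatives
  out[order(as.integer(rownames(out))), , drop = FALSE]
}

ratio_or_nan <- function(num, den) if (den == 0) NaN else num / den

#' Summarise a mutational spectrum
#'
#' Computes the spectrum statistics for a set of mutation records:
#' transition/transversion counts and ratio, AT bias, indel counts,
#' bases lost/gained and the signed indel size histogram. Complex
#' events (equal-length multi-nucleotide substitutions) are counted
#' separately and enter neither the SNV nor the indel statistics.
#'
#' The AT bias is (GC>AT + GC>TA) / (AT>GC + AT>CG); the
#' direction-neutral classes AT>TA and GC>CG enter neither side.
#'
#' @param records a `mutation_records` data.frame, already deduplicated
#'   (set `dedup = TRUE` to collapse clonal redundancy first).
#' @param dedup run [deduplicate()] before summarising.
#' @return object of class `spectrum_summary`: a list with counts
#'   (`n_snv`, `n_ts`, `n_tv`, `n_to_AT`, `n_to_GC`, `n_indel`,
#'   `n_del`, `n_ins`, `n_complex`, `bases_lost`, `bases_gained`,
#'   `net_loss`), ratios (`ts_tv_ratio`, `at_bias`, `del_ins_ratio`,
#'   `avg_loss_per_event`, `avg_gain_per_event`; `NaN` when the
#'   denominator is zero), `class_counts` (the six pair classes) and
#'   `indel_size_histogram` (signed size -> count).
#' @export
summarize_spectrum <- function(records, dedup = FALSE) {
  if (dedup) records <- deduplicate(records)
  snv <- records[records$type == "snv", , drop = FALSE]
  del <- records[records$type == "deletion", , drop = FALSE]
  ins <- records[records$type == "insertion", , drop = FALSE]
  n_complex <- sum(records$type == "complex")

  if (nrow(snv) > 0L) {
    cls <- classify_snv(snv$ref, snv$alt)
    class_counts <- table(cls$pair_class)
    n_ts <- sum(cls$is_transition)
  } else {
    class_counts <- table(factor(character(), levels = pair_class_levels()))
    n_ts <- 0L
  }
  n_snv <- nrow(snv)
  n_tv <- n_snv - n_ts
  n_to_AT <- unname(class_counts["GC>AT"] + class_counts["GC>TA"])
  n_to_GC <- unname(class_counts["AT>GC"] + class_counts["AT>CG"])

  bases_lost <- sum(-del$size)
  bases_gained <- sum(ins$size)
  sizes <- c(del$size, ins$size)
  hist <- if (length(sizes)) table(sizes) else table(integer())

  out <- list(
    n_snv = n_snv, n_ts = n_ts, n_tv = n_tv,
    ts_tv_ratio = ratio_or_nan(n_tv, n_ts),
    n_to_AT = n_to_AT, n_to_GC = n_to_GC,
    at_bias = ratio_or_nan(n_to_AT, n_to_GC),
    n_indel = nrow(del) + nrow(ins),
    n_del = nrow(del), n_ins = nrow(ins), n_complex = n_complex,
    bases_lost = bases_lost, bases_gained = bases_gained,
    net_loss = bases_lost - bases_gained,
    del_ins_ratio = ratio_or_nan(nrow(del), nrow(ins)),
    avg_loss_per_event = ratio_or_nan(bases_lost, nrow(del)),
    avg_gain_per_event = ratio_or_nan(bases_gained, nrow(ins)),
    class_counts = class_counts,
    indel_size_histogram = hist
  )
  class(out) <- "spectrum_summary"
  out
}

#' Bin signed indel sizes for reporting
#'
#' @param sizes signed indel sizes (insertions positive).
#' @param breaks upper bounds of the absolute-size bins; the default
#'   gives the bins 1, 2-3, 4-10, >10 on each side.
#' @return table of counts by signed bin label.
#' @export
bin_indel_sizes <- function(sizes, breaks = c(1, 3, 10)) {
  stopifnot(all(sizes != 0))
  b <- c(0, breaks, Inf)
  lab <- function(lo, hi) {
    if (is.infinite(hi)) paste0(">", lo) else
      if (lo + 1 == hi) as.character(hi) else paste0(lo + 1, "-", hi)
  }
  labs <- mapply(lab, b[-length(b)], b[-1])
  # right-closed integer bins: |size| in (b[j], b[j+1]] -> bin j
  idx <- findInterval(abs(sizes) - 0.5, b[-length(b)])
  signed <- paste0(ifelse(sizes < 0, "-", "+"), labs[idx])
  levels <- c(paste0("-", rev(labs)), paste0("+", labs))
  table(factor(signed, levels = levels))
}

#' @export
print.spectrum_summary <- function(x, digits = 2, ...) {
  fr <- function(v) if (is.nan(v)) "NA" else format(round(v, digits))
  cat("Mutational spectrum summary\n")
  cat(sprintf("  SNVs: %d (Ts %d, Tv %d; Ts:Tv 1:%s)\n",
              x$n_snv, x$n_ts, x$n_tv, fr(x$ts_tv_ratio)))
  cat(sprintf("  to A/T: %d, to C/G: %d, AT bias %s\n",
              x$n_to_AT, x$n_to_GC, fr(x$at_bias)))
  cat(sprintf("  indels: %d (%d del / %d ins, ratio %s)\n",
              x$n_indel, x$n_del, x$n_ins, fr(x$del_ins_ratio)))
  cat(sprintf("  bases lost %d, gained %d, net loss %d\n",
              x$bases_lost, x$bases_gained, x$net_loss))
  if (x$n_complex > 0) cat(sprintf("  complex events: %d\n", x$n_complex))
  invisible(x)
}

#' @export
as.data.frame.spectrum_summary <- function(x, ...) {
  keep <- c("n_snv", "n_ts", "n_tv", "ts_tv_ratio", "n_to_AT", "n_to_GC",
            "at_bias", "n_indel", "n_del", "n_ins", "n_complex",
            "bases_lost", "bases_gained", "net_loss", "del_ins_ratio",
            "avg_loss_per_event", "avg_gain_per_event")
  data.frame(statistic = keep,
             value = vapply(x[keep], as.numeric, numeric(1)),
             row.names = NULL)
}
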