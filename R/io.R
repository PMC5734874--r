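# File formats: tab-separated mutation tables, k-distributions and
# result tables; FASTA coding sequences via Biostrings.

#' Read a mutation table
#'
#' Tab-separated text with a header row and columns `sample`,
#' `population`, `day`, `locus`, `position` (1-based within the CDS),
#' `ref`, `alt`; `"-"` or an empty field denotes an absent allele side.
#'
#' @param path file path.
#' @return a [mutation_records()] data.frame.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = character())
  required <- c("sample", "population", "day", "locus", "position",
                "ref", "alt")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("mutation table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(mutation_records(character(), character(), numeric(),
                            character(), integer(), character(),
                            character()))
  }
  mutation_records(df$sample, df$population, as.numeric(df$day),
                   df$locus, as.integer(df$position), df$ref, df$alt)
}

#' Write a mutation table
#'
#' @param records a [mutation_records()] data.frame.
#' @param path output file path.
#' @export
write_mutation_table <- function(records, path) {
  df <- records[, c("sample", "population", "day", "locus", "position",
                    "ref", "alt")]
  df$ref[df$ref == ""] <- "-"
  df$alt[df$alt == ""] <- "-"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA file; record ids are gene names.
#' @return named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Read a k-distribution from TSV
#'
#' Expects a header row and two columns: `i` (hit multiplicity) and
#' `k_i` (number of targets hit exactly i times).
#'
#' @param path file path.
#' @return a [k_distribution()].
#' @export
read_k_distribution <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("i", "k_i") %in% names(df))) {
    stop("k-distribution file ", path, " must have columns i and k_i")
  }
  k_distribution(stats::setNames(df$k_i, df$i))
}

#' @rdname read_k_distribution
#' @param kd a [k_distribution()].
#' @export
write_k_distribution <- function(kd, path) {
  utils::write.table(
    data.frame(i = as.integer(names(kd$counts)), k_i = kd$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
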