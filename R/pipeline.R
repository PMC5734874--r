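# End-to-end analysis: redundancy filtering -> spectrum ->
# k-distributions -> saturation estimators -> rate correction ->
# genome extrapolation.

#' Saturation analysis of a mutation table against coding sequences
#'
#' Runs the three estimators of the fraction f of phenotype-causing
#' non-synonymous SNVs, per gene and pooled:
#' \itemize{
#'   \item Method 1 (residue saturation): ML target count from the
#'     distribution of different non-synonymous mutations per residue;
#'     f = k_hat / n_aa.
#'   \item Method 2 (nucleotide saturation): ML target count from the
#'     distribution of independent recurrent hits per distinct
#'     non-synonymous SNV; f = k_hat / potential non-synonymous SNVs.
#'   \item Method 3 (STOP saturation): observed/potential STOP fraction
#'     as the saturation level; f = obs_ns / (s * pot_ns).
#' }
#'
#' Method 1 counts only non-synonymous (amino-acid-changing, non-STOP)
#' SNVs as residue hits; recurrent identical mutations collapse to one.
#'
#' @param records deduplicated [mutation_records()].
#' @param cds named character vector of coding sequences (names match
#'   `locus` values); see [read_cds_fasta()].
#' @return data.frame with one row per gene (plus `"total"`) and
#'   method: columns `gene`, `method`, `m`, `occupied`, `k_hat`,
#'   `ci_lo`, `ci_hi`, `f`, `f_lo`, `f_hi`, `saturation`, `unbounded`.
#' @export
saturation_analysis <- function(records, cds) {
  snv <- records[records$type == "snv", , drop = FALSE]
  loci <- intersect(unique(snv$locus), names(cds))
  if (length(loci) == 0L) stop("no SNV locus matches a CDS record name")
  unknown <- setdiff(unique(snv$locus), names(cds))
  if (length(unknown)) {
    warning("locus without CDS, ignored: ", paste(unknown, collapse = ", "))
  }
  snv <- snv[snv$locus %in% loci, , drop = FALSE]

  effects <- character(nrow(snv))
  for (g in loci) {
    idx <- which(snv$locus == g)
    n_nt <- (nchar(cds[[g]]) %/% 3L) * 3L
    out_of_range <- snv$position[idx] > n_nt
    if (any(out_of_range)) {
      stop("SNV position beyond CDS for ", g, " at row(s): ",
           paste(idx[out_of_range], collapse = ", "))
    }
    effects[idx] <- vapply(idx, function(j) {
      classify_observed_snv(cds[[g]], snv$position[j], snv$alt[j])
    }, character(1))
  }
  snv$effect <- effects
  models <- lapply(loci, function(g) enumerate_potential_snvs(cds[[g]], g))
  names(models) <- loci

  one_gene <- function(sub, n_aa, n_ns_pot, n_stop_pot, gene) {
    ns <- sub[sub$effect == "non-synonymous", , drop = FALSE]
    site <- paste(ns$locus, ns$position, ns$alt)
    res <- list()
    kd1 <- build_k_distribution(paste(ns$locus, (ns$position - 1L) %/% 3L),
                                site, level = "per_residue_distinct")
    kd2 <- build_k_distribution(site, level = "per_site_recurrent")
    row <- function(method, est, sat = NA_real_) {
      data.frame(gene = gene, method = method,
                 m = if (!is.null(est$kd)) est$kd$m else NA_integer_,
                 occupied = if (!is.null(est$kd)) est$kd$occupied else NA_integer_,
                 k_hat = if (is.null(est$k_hat)) NA_integer_ else est$k_hat,
                 ci_lo = if (is.null(est$ci95)) NA_real_ else est$ci95[1],
                 ci_hi = if (is.null(est$ci95)) NA_real_ else est$ci95[2],
                 f = if (is.null(est$f)) NA_real_ else est$f,
                 f_lo = if (is.null(est$f_ci95)) NA_real_ else est$f_ci95[1],
                 f_hi = if (is.null(est$f_ci95)) NA_real_ else est$f_ci95[2],
                 saturation = sat,
                 unbounded = isTRUE(est$unbounded))
    }
    e1 <- if (kd1$m > 0) mle_k(kd1) else NULL
    if (!is.null(e1) && !e1$unbounded && e1$k_hat <= n_aa) {
      e1 <- method1_f(e1, n_aa)
    }
    res$m1 <- row("aa_saturation", if (is.null(e1)) list() else e1)
    e2 <- if (kd2$m > 0) mle_k(kd2) else NULL
    if (!is.null(e2) && !e2$unbounded && e2$k_hat <= n_ns_pot) {
      e2 <- method2_f(e2, n_ns_pot)
    }
    res$m2 <- row("nt_saturation", if (is.null(e2)) list() else e2)
    obs_stops <- length(unique(paste(sub$locus, sub$position, sub$alt)[
      sub$effect == "stop"]))
    obs_ns <- length(unique(site))
    if (obs_stops > 0 && obs_ns > 0) {
      e3 <- method3_f(obs_stops, n_stop_pot, obs_ns, n_ns_pot)
      res$m3 <- data.frame(gene = gene, method = "stop_saturation",
                           m = obs_ns + obs_stops, occupied = NA_integer_,
                           k_hat = NA_integer_, ci_lo = NA_real_,
                           ci_hi = NA_real_, f = e3$f, f_lo = NA_real_,
                           f_hi = NA_real_, saturation = e3$saturation,
                           unbounded = FALSE)
    } else {
      res$m3 <- data.frame(gene = gene, method = "stop_saturation",
                           m = obs_ns + obs_stops, occupied = NA_integer_,
                           k_hat = NA_integer_, ci_lo = NA_real_,
                           ci_hi = NA_real_, f = NA_real_, f_lo = NA_real_,
                           f_hi = NA_real_, saturation = NA_real_,
                           unbounded = FALSE)
    }
    do.call(rbind, res)
  }

  out <- lapply(loci, function(g) {
    one_gene(snv[snv$locus == g, , drop = FALSE], models[[g]]$n_aa,
             models[[g]]$n_ns, models[[g]]$n_stop, g)
  })
  if (length(loci) > 1L) {
    out <- c(out, list(one_gene(snv,
                                sum(vapply(models, `[[`, 0, "n_aa")),
                                sum(vapply(models, `[[`, 0, "n_ns")),
                                sum(vapply(models, `[[`, 0, "n_stop")),
                                "total")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline
#'
#' Executes redundancy filtering, spectrum summary, saturation
#' estimation and, when observed rates are supplied, phenotypic-rate
#' correction and genome extrapolation, writing one TSV per stage plus
#' a human-readable summary.
#'
#' @param config named list:
#'   \describe{
#'     \item{mutations}{path to a mutation table (required).}
#'     \item{cds}{path to a CDS FASTA; enables the saturation stage.}
#'     \item{out_dir}{output directory, created if absent (required).}
#'     \item{observed_snv_rate, observed_indel_rate}{phenotypic rates
#'       per day; enable the correction stage.}
#'     \item{p_3nt, p_6nt}{observed in-frame indel fractions
#'       (default 0).}
#'     \item{f_method}{which estimator supplies f for the correction:
#'       `"aa_saturation"` (default), `"nt_saturation"`,
#'       `"stop_saturation"`.}
#'     \item{target_len, genome_len}{lengths for extrapolation.}
#'   }
#' @return invisibly, a list with `records`, `spectrum`, `saturation`
#'   (or NULL) and `correction` (or NULL).
#' @export
run_pipeline <- function(config) {
  known <- c("mutations", "cds", "out_dir", "observed_snv_rate",
             "observed_indel_rate", "p_3nt", "p_6nt", "f_method",
             "target_len", "genome_len")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$mutations) || is.null(config$out_dir)) {
    stop("config must name 'mutations' and 'out_dir'")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("quiesmut %s",
                         as.character(utils::packageVersion("quiesmut"))),
                 sprintf("config: %s",
                         paste(names(config), unlist(lapply(config, format)),
                               sep = "=", collapse = " ")))

  records <- deduplicate(read_mutation_table(config$mutations))
  spec <- summarize_spectrum(records)
  write_tsv(as.data.frame(spec), file.path(config$out_dir, "spectrum.tsv"))

  sat <- NULL
  if (nrow(records) == 0L) {
    warning("empty mutation table: saturation stage skipped")
    log_lines <- c(log_lines, "saturation: skipped (no mutations)")
  } else if (!is.null(config$cds)) {
    sat <- saturation_analysis(records, read_cds_fasta(config$cds))
    write_tsv(sat, file.path(config$out_dir, "saturation.tsv"))
  }

  corr <- NULL
  if (!is.null(config$observed_snv_rate)) {
    if (is.null(sat)) stop("correction requires the saturation stage (cds)")
    f_method <- if (is.null(config$f_method)) "aa_saturation" else config$f_method
    f_gene <- if ("total" %in% sat$gene) "total" else sat$gene[1]
    frow <- sat[sat$gene == f_gene & sat$method == f_method, , drop = FALSE]
    if (nrow(frow) == 0L || is.na(frow$f[1])) {
      stop("correction requested but no f estimate available from method ",
           f_method)
    }
    f <- frow$f[1]
    # pooled potential-SNV proportions across the analysed genes
    models <- lapply(read_cds_fasta(config$cds), enumerate_potential_snvs)
    tot <- 9 * sum(vapply(models, `[[`, 0, "n_aa"))
    p_stop <- sum(vapply(models, `[[`, 0, "n_stop")) / tot
    p_ns <- sum(vapply(models, `[[`, 0, "n_ns")) / tot
    params <- correction_params(f, p_stop, p_ns)
    snv_total <- correct_snv_rate(config$observed_snv_rate, params)
    corr <- data.frame(quantity = c("f", "phi_snv", "snv_total_rate"),
                       value = c(f, snv_phenotypic_fraction(params),
                                 snv_total))
    total_rate <- snv_total
    if (!is.null(config$observed_indel_rate)) {
      p3 <- if (is.null(config$p_3nt)) 0 else config$p_3nt
      p6 <- if (is.null(config$p_6nt)) 0 else config$p_6nt
      mult <- indel_inflation_factor(f, p3, p6)
      indel_total <- config$observed_indel_rate * mult
      total_rate <- snv_total + indel_total
      corr <- rbind(corr,
                    data.frame(quantity = c("indel_multiplier",
                                            "indel_total_rate",
                                            "combined_total_rate"),
                               value = c(mult, indel_total, total_rate)))
    }
    if (!is.null(config$target_len) && !is.null(config$genome_len)) {
      corr <- rbind(corr,
                    data.frame(quantity = "genome_rate_per_day",
                               value = extrapolate_genome(
                                 total_rate, config$target_len,
                                 config$genome_len)))
    }
    write_tsv(corr, file.path(config$out_dir, "correction.tsv"))
  }

  summary_path <- file.path(config$out_dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  writeLines(log_lines, con)
  writeLines(utils::capture.output(print(spec)), con)
  if (!is.null(sat)) {
    writeLines(utils::capture.output(print(sat, digits = 3)), con)
  }
  if (!is.null(corr)) {
    writeLines(utils::capture.output(print(corr, digits = 3)), con)
  }
  invisible(list(records = records, spectrum = spec, saturation = sat,
                 correction = corr))
}
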