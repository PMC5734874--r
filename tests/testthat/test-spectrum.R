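test_that("classify_snv partitions the 12 substitutions strand-symmetrically", {
  combos <- expand.grid(ref = BASES <- c("A", "C", "G", "T"),
                        alt = BASES, stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  cls <- classify_snv(combos$ref, combos$alt)
  # each class captures exactly two ordered substitutions
  expect_equal(as.integer(table(cls$pair_class)), rep(2L, 6))
  # strand symmetry: substitution and its reverse complement agree
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cls_rc <- classify_snv(comp[combos$ref], comp[combos$alt])
  expect_equal(cls$pair_class, cls_rc$pair_class)
  expect_equal(cls$is_transition, cls_rc$is_transition)
  # definitional examples
  expect_equal(as.character(classify_snv("C", "T")$pair_class), "GC>AT")
  expect_true(classify_snv("C", "T")$is_transition)
  expect_equal(as.character(classify_snv("G", "T")$pair_class), "GC>TA")
  expect_false(classify_snv("G", "T")$is_transition)
  expect_equal(as.character(classify_snv("A", "T")$pair_class), "AT>TA")
  # lower case and U are normalised
  expect_equal(classify_snv("c", "u"), classify_snv("C", "T"))
  expect_error(classify_snv("A", "A"), "differ")
  expect_error(classify_snv("A", "N"), "A/C/G/T")
})

test_that("deduplicate collapses within populations only", {
  r <- mutation_records(
    sample = paste0("s", 1:6),
    population = c("p1", "p1", "p1", "p1", "p2", "p1"),
    day = c(8, 1, 8, 8, 8, 8),
    locus = "gene1",
    position = c(5, 5, 5, 9, 5, 9),
    ref = c("C", "C", "C", "A", "C", ""),
    alt = c("T", "T", "T", "G", "T", "AA"))
  out <- deduplicate(r)
  # 3 copies of C5T in p1 -> 1 (earliest day), distinct SNV + indel kept,
  # same SNV in p2 kept independently
  expect_equal(nrow(out), 4L)
  expect_equal(out$sample[out$population == "p1" & out$position == 5], "s2")
  expect_true("p2" %in% out$population)
  expect_equal(nrow(deduplicate(r[0, ])), 0L)
})

test_that("deduplicate matches a brute-force grouping on random input", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 200
    r <- mutation_records(
      sample = sprintf("s%03d", 1:n),
      population = sample(paste0("p", 1:3), n, replace = TRUE),
      day = sample(c(1, 8, 15), n, replace = TRUE),
      locus = sample(c("g1", "g2"), n, replace = TRUE),
      position = sample(1:30, n, replace = TRUE),
      ref = sample(c("A", "C"), n, replace = TRUE),
      alt = sample(c("G", "T"), n, replace = TRUE))
    out <- deduplicate(r)
    key <- function(x) paste(x$population, x$locus, x$position, x$ref, x$alt)
    # one representative per distinct key, at that key's earliest day
    expect_equal(sort(unique(key(r))), sort(key(out)))
    min_day <- tapply(r$day, key(r), min)
    expect_equal(as.numeric(min_day[key(out)]), out$day)
  }
})

test_that("summarize_spectrum reproduces the published day-1 margins", {
  s <- summarize_spectrum(make_snv_records(day1_class_counts))
  expect_equal(s$n_snv, 105L)
  expect_equal(s$n_ts, 33L)
  expect_equal(s$n_tv, 72L)
  expect_equal(round(s$ts_tv_ratio, 2), 2.18)
  expect_equal(s$n_to_AT, 63L)
  expect_equal(s$n_to_GC, 17L)
  expect_equal(round(s$at_bias, 2), 3.71)
  expect_equal(s$n_indel, 0L)
  expect_true(is.nan(s$del_ins_ratio))
})

test_that("summarize_spectrum reproduces the published indel margins", {
  s <- summarize_spectrum(make_indel_records(day815_indel_sizes))
  expect_equal(s$n_del, 170L)
  expect_equal(s$n_ins, 50L)
  expect_equal(s$bases_lost, 1771L)
  expect_equal(s$bases_gained, 500L)
  expect_equal(s$net_loss, 1271L)
  expect_equal(round(s$del_ins_ratio, 1), 3.4)
  # day-1 average loss: 334 bp over 16 deletions ~ 21
  s1 <- summarize_spectrum(
    make_indel_records(c(-165L, -95L, rep(-4L, 13), -22L, rep(11L, 24)),
                       day = 1))
  expect_equal(s1$bases_lost, 334L)
  expect_equal(round(s1$avg_loss_per_event), 21)
})

test_that("spectrum invariants hold on random record sets", {
  set.seed(7)
  for (rep in 1:5) {
    cc <- stats::setNames(sample(0:20, 6, replace = TRUE),
                          names(day1_class_counts))
    sizes <- sample(c(-10:-1, 1:10), 30, replace = TRUE)
    rec <- rbind(make_snv_records(cc),
                 make_indel_records(sizes))
    s <- summarize_spectrum(rec)
    expect_equal(s$n_ts + s$n_tv, s$n_snv)
    expect_equal(sum(s$class_counts), s$n_snv)
    expect_true(s$n_to_AT + s$n_to_GC <= s$n_snv)
    expect_equal(s$n_del + s$n_ins, s$n_indel)
    expect_equal(s$net_loss, s$bases_lost - s$bases_gained)
    # permutation invariance
    perm <- rec[sample(nrow(rec)), ]
    expect_equal(summarize_spectrum(perm), s)
  }
})

test_that("empty input and complex events are handled", {
  empty <- make_snv_records(c("GC>AT" = 0))
  s <- summarize_spectrum(empty)
  expect_equal(s$n_snv + s$n_indel + s$n_complex, 0L)
  expect_true(is.nan(s$ts_tv_ratio) && is.nan(s$at_bias))
  # equal-length multi-nucleotide substitution counts as complex only
  cx <- mutation_records("s1", "p1", 8, "g", 1, "ACG", "TGA")
  s2 <- summarize_spectrum(cx)
  expect_equal(s2$n_complex, 1L)
  expect_equal(s2$n_snv, 0L)
  expect_equal(s2$n_indel, 0L)
})

test_that("malformed records are rejected with their row index", {
  expect_error(mutation_records("s", "p", 1, "g", 1, "AX", "A"), "1")
  expect_error(mutation_records("s", "p", 1, "g", 1, "", ""), "empty")
})

test_that("bin_indel_sizes uses signed default bins", {
  b <- bin_indel_sizes(c(-1, -1, -2, -5, -20, 1, 3, 12))
  expect_equal(unname(b[["-1"]]), 2L)
  expect_equal(unname(b[["-2-3"]]), 1L)
  expect_equal(unname(b[["-4-10"]]), 1L)
  expect_equal(unname(b[["->10"]]), 1L)
  expect_equal(unname(b[["+>10"]]), 1L)
  expect_equal(sum(b), 8L)
})
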