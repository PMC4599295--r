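test_that("arm assignment routes canonical reads and rejects short ones", {
  loc <- mir200b_locus()
  fx <- mir200b_fixture()
  expect_equal(assign_arm(fx$mature5p, loc), "5p")
  expect_equal(assign_arm(fx$mature3p, loc), "3p")
  expect_equal(assign_arm("UAAUACUG", loc), "unassigned")  # 8 nt anchor
  # works identically with a precursor annotation
  sloc <- synthetic_locus("toy", fx$mature5p, fx$mature3p, seed = 2)
  expect_equal(assign_arm(fx$mature5p, sloc), "5p")
  expect_equal(assign_arm(fx$mature3p, sloc), "3p")
})

test_that("classifying a canonical mature yields the all-zero call", {
  loc <- mir200b_locus()
  fx <- mir200b_fixture()
  for (m in c(fx$mature5p, fx$mature3p)) {
    call <- classify_read(m, loc)
    expect_true(call$is_canonical)
    expect_equal(call$offset5, 0L)
    expect_equal(call$offset3, 0L)
    expect_equal(call$n_subs, 0L)
    expect_equal(call$nta, "")
  }
})

test_that("published example reads classify to their documented classes", {
  loc <- mir200b_locus()
  # one-base 3' truncation
  c1 <- classify_read("CAUCUUACUGGGCAGCAUUGG", loc)
  expect_equal(c1[, c("arm", "offset5", "offset3", "n_subs", "nta")],
               tibble::tibble(arm = "5p", offset5 = 0L, offset3 = -1L,
                              n_subs = 0L, nta = ""))
  # 5' trim by one plus a one-base U tail
  c2 <- classify_read("AUCUUACUGGGCAGCAUUGGAU", loc)
  expect_equal(c2$arm, "5p")
  expect_equal(c2$offset5, 1L)
  expect_equal(c2$nta, "U")
  expect_equal(c2$n_subs, 0L)
  # internal substitution at read position 7 (A -> C)
  c3 <- classify_read("CAUCUUCCUGGGCAGCAUUGGA", loc)
  expect_equal(c3$offset5, 0L)
  expect_equal(c3$offset3, 0L)
  expect_equal(c3$n_subs, 1L)
  expect_equal(as.data.frame(c3$subs[[1]]),
               data.frame(pos = 7L, canonical = "A", read = "C"))
})

test_that("terminal mismatches beat trim-plus-tail at equal cost", {
  loc <- mir200b_locus()
  call <- classify_read("CAUCUUACUGGGCAGCAUUGU", loc)
  expect_equal(call$offset3, -1L)
  expect_equal(call$n_subs, 1L)
  expect_equal(call$nta, "")
})

test_that("classification is a pure function of read and locus", {
  loc <- mir200b_locus()
  a <- classify_read("CAUCUUACUGGGCAGCAUU", loc)
  b <- classify_read("CAUCUUACUGGGCAGCAUU", loc)
  expect_identical(a, b)
})

test_that("templated extensions are honoured when a precursor is given", {
  fx <- mir200b_fixture()
  sloc <- synthetic_locus("toy", fx$mature5p, fx$mature3p, seed = 12)
  nxt <- substr(sloc$precursor, sloc$pos5["end"] + 1, sloc$pos5["end"] + 1)
  ext <- paste0(fx$mature5p, nxt)
  call <- classify_read(ext, sloc)
  expect_equal(call$offset3, 1L)
  expect_equal(call$nta, "")
  # an extension base that contradicts the template is a tail, not a
  # templated extension
  other <- setdiff(c("A", "C", "G", "U"), nxt)[1]
  call2 <- classify_read(paste0(fx$mature5p, other), sloc)
  expect_equal(call2$offset3, 0L)
  expect_equal(call2$nta, other)
  expect_equal(call2$n_subs, 0L)
})

test_that("tabulation is multiplicity-weighted with deterministic order", {
  loc <- mir200b_locus()
  expect_equal(nrow(tabulate_isomirs(
    classify_reads(character(0), loc))), 0)

  two <- classify_reads(c("CAUCUUACUGGGCAGCAUUGG",
                          "CAUCUUACUGGGCAGCAUUGG"), loc)
  tab <- tabulate_isomirs(two)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count, 2L)

  fx <- mir200b_fixture()
  calls <- classify_reads(fx$reads[, c("seq", "count")], loc)
  tab2 <- tabulate_isomirs(calls)
  # per-arm tabulated totals equal the reads assigned to that arm
  for (a in c("5p", "3p")) {
    expect_equal(sum(tab2$count[tab2$arm == a]),
                 sum(calls$count[calls$arm == a]))
  }
  expect_equal(sum(tab2$count), sum(fx$reads$count))
})

test_that("classifier round-trips the generator at low noise", {
  mir <- default_mirnas()
  loc <- synthetic_locus("toy", mir$mature[1], mir$mature[2], seed = 3)
  d <- isomir_distribution(sub_rate = 0.015, nta_rate = 0.015)
  sr <- simulate_small_rna_reads(loc, d, 3000, seed = 9)
  calls <- classify_reads(sr$reads$seq, loc)
  joined <- dplyr::left_join(dplyr::mutate(sr$truth, seq = sr$reads$seq),
                             calls, by = "seq",
                             relationship = "many-to-many")
  hit <- with(joined, arm.x == arm.y & offset5.x == offset5.y &
                offset3.x == offset3.y)
  expect_gte(mean(hit), 0.99)
})

test_that("heterogeneity summary reports fractions and the dominant isomiR", {
  loc <- mir200b_locus()
  single <- classify_reads("CAUCUUACUGGGCAGCAUUGGA", loc)
  hs <- heterogeneity_summary(single)
  expect_equal(hs$frac_het5, 0)
  expect_equal(hs$frac_het3, 0)
  expect_equal(hs$dominant_seq, "CAUCUUACUGGGCAGCAUUGGA")

  mir <- default_mirnas()
  sloc <- synthetic_locus("toy", mir$mature[1], mir$mature[2], seed = 5)
  d <- isomir_distribution(sub_rate = 0, nta_rate = 0)
  n <- 6000
  sr <- simulate_small_rna_reads(sloc, d, n, seed = 6)
  hs2 <- heterogeneity_summary(classify_reads(sr$reads$seq, sloc))
  p5 <- 1 - d$p_offset5[["0"]]
  for (a in c("5p", "3p")) {
    row <- hs2[hs2$arm == a, ]
    sigma <- sqrt(p5 * (1 - p5) / row$n_reads)
    expect_lt(abs(row$frac_het5 - p5), 3 * sigma + 1e-9)
  }
})
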