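test_that("transcriptome generation is deterministic and honours the APA fraction", {
  a <- make_transcriptome(4, seed = 9)
  b <- make_transcriptome(4, seed = 9)
  expect_identical(a$genome, b$genome)
  expect_identical(as.data.frame(a$tx[, c("gene_id", "strand",
                                          "proximal_polya")]),
                   as.data.frame(b$tx[, c("gene_id", "strand",
                                          "proximal_polya")]))

  none <- make_transcriptome(10, seed = 2, apa_fraction = 0)
  expect_true(all(is.na(none$tx$proximal_polya)))
  all_apa <- make_transcriptome(50, seed = 3, apa_fraction = 1,
                                two_isoform_fraction = 0)
  expect_equal(sum(!is.na(all_apa$tx$proximal_polya)), 50)
  expect_silent(validate_transcript_models(all_apa$tx))
})

test_that("implanted seed sites are recovered exactly by scanning", {
  mir <- default_mirnas()
  w <- make_transcriptome(50, seed = 21, two_isoform_fraction = 0)
  imp <- implant_seed_sites(w$tx, w$genome, mir, n_sites_per_gene = 2,
                            site_class = "8mer", seed = 22,
                            mirna_name = "miR-200b-3p")
  sites <- scan_transcriptome(w$tx, mir, genome = imp$genome)
  expect_equal(nrow(sites), 100)            # 2 sites x 50 genes
  expect_equal(nrow(imp$truth), 100)
  expect_equal(
    dplyr::arrange(sites[, c("transcript_id", "utr_position",
                             "site_class")],
                   transcript_id, utr_position),
    dplyr::arrange(imp$truth[, c("transcript_id", "utr_position",
                                 "site_class")],
                   transcript_id, utr_position))

  clean <- implant_seed_sites(w$tx, w$genome, mir, n_sites_per_gene = 0,
                              site_class = "8mer", seed = 23)
  expect_equal(nrow(scan_transcriptome(w$tx, mir,
                                       genome = clean$genome)), 0)
})

test_that("implanting fails loudly when the UTR cannot host the sites", {
  mir <- default_mirnas()
  w <- make_transcriptome(1, seed = 5, utr_len = 50L)
  expect_error(
    implant_seed_sites(w$tx, w$genome, mir, n_sites_per_gene = 8,
                       site_class = "8mer", seed = 6),
    "too short")
})

test_that("zero-noise read simulation emits exact canonical matures", {
  mir <- default_mirnas()
  loc <- synthetic_locus("toy", mir$mature[1], mir$mature[2], seed = 7)
  quiet <- isomir_distribution(
    p_offset5 = c(`-2` = 0, `-1` = 0, `0` = 1, `1` = 0, `2` = 0),
    p_offset3 = c(`-6` = 0, `-5` = 0, `-4` = 0, `-3` = 0, `-2` = 0,
                  `-1` = 0, `0` = 1, `1` = 0, `2` = 0, `3` = 0),
    sub_rate = 0, nta_rate = 0)
  sr <- simulate_small_rna_reads(loc, quiet, 50, seed = 8)
  expect_true(all(sr$reads$seq %in% c(mir$mature[1], mir$mature[2])))
  expect_true(all(sr$truth$offset5 == 0 & sr$truth$offset3 == 0 &
                    sr$truth$n_subs == 0 & sr$truth$nta == ""))
  # truth completeness: exactly one record per read
  expect_equal(sr$truth$read_id, sr$reads$read_id)
  again <- simulate_small_rna_reads(loc, quiet, 50, seed = 8)
  expect_identical(sr$reads$seq, again$reads$seq)
})

test_that("simulated offset frequencies match the distribution within 3 sigma", {
  mir <- default_mirnas()
  loc <- synthetic_locus("toy", mir$mature[1], mir$mature[2], seed = 7)
  d <- isomir_distribution(sub_rate = 0, nta_rate = 0)
  n <- 10000
  sr <- simulate_small_rna_reads(loc, d, n, seed = 44)
  for (off in names(d$p_offset3)) {
    p <- d$p_offset3[[off]]
    obs <- sum(sr$truth$offset3 == as.integer(off))
    sigma <- sqrt(n * p * (1 - p))
    expect_lt(abs(obs - n * p), max(3 * sigma, 1e-9) + 1e-9)
  }
  p5 <- mean(sr$truth$arm == "5p")
  expect_lt(abs(p5 - 0.65), 3 * sqrt(0.65 * 0.35 / n))
})

test_that("NB count simulation recovers the implanted effect and limits", {
  gt <- tibble::tibble(gene_id = sprintf("g%04d", 1:500),
                       is_target = TRUE, utr_lost = FALSE)
  sim <- simulate_mrna_counts(gt, baseline_mean = 1000, dispersion = 0.05,
                              effect_log2fc = -1, n_reps = 3, seed = 13)
  wide <- tidyr::pivot_wider(sim$counts, names_from = sample_id,
                             values_from = count)
  ma <- rowMeans(wide[, c("A1", "A2", "A3")])
  mb <- rowMeans(wide[, c("B1", "B2", "B3")])
  emp <- mean(log2(mb / ma))
  expect_gt(emp, -1.15)
  expect_lt(emp, -0.85)

  # dispersion 0, no effect: Poisson, equal group means in expectation
  sim0 <- simulate_mrna_counts(gt, baseline_mean = 500, dispersion = 0,
                               effect_log2fc = 0, n_reps = 3, seed = 14)
  w0 <- tidyr::pivot_wider(sim0$counts, names_from = sample_id,
                           values_from = count)
  m0a <- mean(as.matrix(w0[, c("A1", "A2", "A3")]))
  m0b <- mean(as.matrix(w0[, c("B1", "B2", "B3")]))
  expect_lt(abs(m0a - m0b) / 500, 0.02)

  # fixed seed: identical matrix
  rep1 <- simulate_mrna_counts(gt, seed = 15)
  rep2 <- simulate_mrna_counts(gt, seed = 15)
  expect_identical(rep1$counts$count, rep2$counts$count)
  # escape mechanism: utr_lost targets get zero true effect
  gt2 <- dplyr::mutate(gt, utr_lost = c(TRUE, rep(FALSE, 499)))
  simL <- simulate_mrna_counts(gt2, seed = 16)
  expect_equal(simL$truth$true_log2fc[1], 0)
  expect_equal(simL$truth$true_log2fc[2], -1)
})

test_that("coverage simulation matches its construction", {
  w <- make_transcriptome(1, seed = 3, apa_fraction = 1)
  row <- w$tx[1, ]
  flat <- simulate_coverage(row, utr_lost = FALSE, depth = 50,
                            noise_sd = 0, seed = 1)
  sp <- row$proximal_polya
  prox <- mean(flat$depth[flat$pos < sp])
  dist <- mean(flat$depth[flat$pos >= sp])
  expect_equal(dist / prox, 1)

  lost <- simulate_coverage(row, utr_lost = TRUE, depth = 50,
                            noise_sd = 0, seed = 1)
  expect_equal(mean(lost$depth[lost$pos >= sp]) /
                 mean(lost$depth[lost$pos < sp]), 0.05)

  # with noise, the mean ratio matches the construction within 3 sigma;
  # the construction value accounts for the truncation of negative
  # coverage at zero: a base at level mu with N(0, sd) noise has mean
  # mu * pnorm(mu/sd) + sd * dnorm(mu/sd) after truncation
  trunc_mean <- function(mu, sd) mu * pnorm(mu / sd) + sd * dnorm(mu / sd)
  expected <- trunc_mean(5, 10) / trunc_mean(100, 10)
  ratios <- vapply(1:100, function(s) {
    cv <- simulate_coverage(row, utr_lost = TRUE, depth = 100,
                            noise_sd = 10, seed = s)
    mean(cv$depth[cv$pos >= sp]) / mean(cv$depth[cv$pos < sp])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - expected),
            3 * stats::sd(ratios) / sqrt(100))
  expect_error(simulate_coverage(make_transcriptome(1, seed = 4,
                                                    apa_fraction = 0)$tx[1, ],
                                 utr_lost = FALSE),
               "polyA")
})

test_that("the embedded prevalence fixture matches the published table", {
  fx <- mir200b_fixture()
  expect_equal(nchar(fx$mature5p), 22)
  expect_equal(nchar(fx$mature3p), 22)
  pick <- function(s) fx$reads$count[fx$reads$seq == s]
  expect_equal(pick("CAUCUUACUGGGCAGCAUUGG"), 19L)
  expect_equal(pick("UAAUACUGCCUGGUAAU"), 17L)
  expect_equal(sum(fx$reads$count), 221L)
  expect_equal(sum(fx$reads$count[fx$reads$arm == "5p"]), 144L)
  # the DNA/RNA-ambiguous row is stored verbatim and flagged
  amb <- fx$reads[fx$reads$alphabet_ambiguous, ]
  expect_equal(amb$seq, "UAAUACUGCCUGGUAAUGAAT")
  expect_equal(amb$count, 6L)
})
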