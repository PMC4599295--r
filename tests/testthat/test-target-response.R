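test_that("CPM normalization is exact and scale-invariant", {
  counts <- tibble::tibble(gene_id = c("g1", "g1"),
                           sample_id = c("s1", "s2"),
                           count = c(100L, 100L))
  samples <- tibble::tibble(sample_id = c("s1", "s2"),
                            lib_size = c(1e6, 2e6))
  out <- normalize_cpm(counts, samples)
  expect_equal(out$cpm, c(100, 50))
  # doubling counts and library sizes leaves cpm unchanged
  out2 <- normalize_cpm(dplyr::mutate(counts, count = count * 2L),
                        dplyr::mutate(samples, lib_size = lib_size * 2))
  expect_equal(out2$cpm, out$cpm)
  expect_error(normalize_cpm(counts,
                             dplyr::mutate(samples, lib_size = 0)),
               "positive")
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  gt <- tibble::tibble(gene_id = sprintf("g%04d", 1:2000),
                       is_target = FALSE, utr_lost = FALSE)
  pois <- simulate_mrna_counts(gt, baseline_mean = 200, dispersion = 0,
                               effect_log2fc = 0, n_reps = 3, seed = 81)
  expect_lt(estimate_dispersion(pois$counts, pois$samples), 0.01)

  nb <- simulate_mrna_counts(gt, baseline_mean = 200, dispersion = 0.2,
                             effect_log2fc = 0, n_reps = 2, seed = 82)
  est <- estimate_dispersion(nb$counts, nb$samples)
  expect_gt(est, 0.15)
  expect_lt(est, 0.25)

  const <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), each = 4),
    sample_id = rep(c("A1", "A2", "B1", "B2"), 2),
    count = rep(c(50L, 7L), each = 4))
  samp <- tibble::tibble(sample_id = c("A1", "A2", "B1", "B2"),
                         condition = rep(c("A", "B"), each = 2),
                         lib_size = 1e6)
  expect_equal(estimate_dispersion(const, samp), 0)

  tw <- estimate_dispersion(nb$counts, nb$samples, method = "tagwise",
                            prior_n = 10)
  expect_equal(nrow(tw), 2000)
  expect_true(all(tw$dispersion >= 0))
  # shrinkage keeps tagwise values near the common estimate
  expect_lt(stats::sd(tw$dispersion), 0.2)
})

test_that("the exact test matches closed forms and an enumeration oracle", {
  expect_equal(nb_exact_test(c(10, 12, 11), c(10, 12, 11), 0.1), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.1), 1)

  # dispersion 0, 0 vs 20 at equal libraries: two-sided binomial point tail
  p <- nb_exact_test(0, 20, 0)
  expect_equal(p, 2 * stats::dbinom(20, 20, 0.5))
  expect_lt(p, 1e-4)

  # independent oracle: explicit dnbinom enumeration of the conditional
  # distribution (any common mean cancels)
  cond_oracle <- function(sa, sb, na, nb, phi) {
    t <- sa + sb
    k <- 0:t
    mu <- 7.3
    lw <- stats::dnbinom(k, size = nb / phi, mu = nb * mu, log = TRUE) +
      stats::dnbinom(t - k, size = na / phi, mu = na * mu, log = TRUE)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    min(1, 2 * min(sum(w[k <= sb]), sum(w[k >= sb])))
  }
  set.seed(90)
  for (i in 1:20) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- rnbinom(na, size = 10, mu = 60)
    b <- rnbinom(nb, size = 10, mu = 60 * sample(c(1, 2), 1))
    phi <- runif(1, 0.02, 0.3)
    expect_equal(nb_exact_test(a, b, phi),
                 cond_oracle(sum(a), sum(b), na, nb, phi),
                 tolerance = 1e-10)
    # symmetry: swapping groups leaves p unchanged
    expect_equal(nb_exact_test(a, b, phi), nb_exact_test(b, a, phi))
  }
})

test_that("the exact test ranks genes like the established NB exact test", {
  skip_if_not_installed("edgeR")
  gt <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                       is_target = c(rep(TRUE, 50), rep(FALSE, 150)),
                       utr_lost = FALSE)
  sim <- simulate_mrna_counts(gt, baseline_mean = 150, dispersion = 0.1,
                              effect_log2fc = -1.5, n_reps = 3, seed = 91)
  de <- de_exact_test(sim$counts, sim$samples, dispersion = 0.1)
  wide <- tidyr::pivot_wider(sim$counts, names_from = sample_id,
                             values_from = count)
  m <- as.matrix(wide[, -1]); rownames(m) <- wide$gene_id
  dg <- edgeR::DGEList(m, group = sim$samples$condition,
                       lib.size = sim$samples$lib_size)
  et <- edgeR::exactTest(dg, dispersion = 0.1)
  expect_gt(stats::cor(rank(de$p_value), rank(et$table$PValue),
                       method = "spearman"), 0.99)
  expect_gt(stats::cor(de$log2fc, et$table$logFC), 0.99)
})

test_that("the target-shift test detects construction and degenerate cases", {
  x <- rnorm(200)
  same <- target_shift_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(92)
  bg <- rnorm(2000, 0, 0.5)
  tg <- rnorm(200, -1, 0.5)
  shifted <- target_shift_test(tg, bg)
  expect_lt(shifted$p_value, 1e-6)
  expect_equal(shifted$direction, -1)

  up <- target_shift_test(rnorm(200, 1, 0.5), bg)
  expect_equal(up$direction, 1)

  expect_warning(target_shift_test(rnorm(3), bg), "low power")
  expect_error(target_shift_test(numeric(0), bg), "non-empty")

  td <- tidy(shifted)
  expect_equal(td$p_value, shifted$p_value)
})

test_that("target outcomes classify by the fold and significance screen", {
  de <- tibble::tibble(
    gene_id = c("down", "up", "flat"),
    log2fc = c(-2, 1.96, 0.1),
    p_value = c(0.001, 0.0005, 0.8))
  lost <- tibble::tibble(gene_id = "up", utr_lost = TRUE)
  oc <- classify_target_outcome(de, lost)
  expect_equal(oc$category, c("repressed", "increased", "unchanged"))
  expect_equal(oc$utr_lost, c(FALSE, TRUE, FALSE))
})

test_that("relative expression follows the ddCt closed form", {
  ct <- tibble::tibble(
    sample = c("cal", "s1", "s2"),
    ct_target = c(25, 24, 27),
    ct_reference = c(20, 21, 22),
    calibrator = c(TRUE, FALSE, FALSE))
  out <- ddct(ct)
  expect_equal(out$rel_expr[1], 1)        # calibrator is exactly 1
  expect_equal(out$rel_expr[2], 4)        # dCt two cycles below calibrator
  expect_equal(out$rel_expr[3], 1)        # dCt equal to calibrator
  expect_error(ddct(dplyr::mutate(ct, calibrator = TRUE)),
               "exactly one")
  expect_error(ddct(dplyr::mutate(ct, ct_target = c(Inf, 24, 27))),
               "finite")
})

test_that("de_exact_test output carries tidy and glance methods", {
  gt <- tibble::tibble(gene_id = sprintf("g%03d", 1:50),
                       is_target = FALSE, utr_lost = FALSE)
  sim <- simulate_mrna_counts(gt, baseline_mean = 100, dispersion = 0.1,
                              effect_log2fc = 0, n_reps = 3, seed = 93)
  de <- de_exact_test(sim$counts, sim$samples)
  expect_s3_class(de, "mirsight_de")
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  gl <- glance(de)
  expect_equal(gl$n_genes, 50)
  expect_true(gl$dispersion >= 0)
  expect_false("mirsight_de" %in% class(tidy(de)))
})
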