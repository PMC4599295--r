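# Differential expression: a deliberately simple, fully specified
# negative-binomial exact test. Counts are rescaled to a common (geometric
# mean) library size with half-even rounding, dispersion is plugged in, and
# the two-sided p-value is computed on the exact conditional distribution of
# the condition-B group total given the overall total (the NB analogue of
# the binomial two-sample test, which it reduces to at dispersion zero).

#' Counts per million
#'
#' @param counts long count tibble (`gene_id`, `sample_id`, `count`).
#' @param samples sample tibble with `sample_id`, `lib_size` (> 0).
#' @return `counts` with a `cpm` column added.
#' @export
normalize_cpm <- function(counts, samples) {
  if (any(samples$lib_size <= 0)) abort("library sizes must be positive")
  counts |>
    left_join(select(samples, "sample_id", "lib_size"), by = "sample_id") |>
    mutate(cpm = .data$count / .data$lib_size * 1e6) |>
    select(-"lib_size")
}

# counts rescaled to the geometric-mean library size, half-even rounding
equalize_counts <- function(mat, lib_sizes) {
  ref <- exp(mean(log(lib_sizes)))
  sweep_fac <- ref / lib_sizes
  round(sweep(mat, 2, sweep_fac, `*`))
}

counts_matrix <- function(counts) {
  wide <- tidyr::pivot_wider(counts, names_from = "sample_id",
                             values_from = "count")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}

#' Estimate negative-binomial dispersion by pooled moments
#'
#' Common mode: counts are rescaled to a common library size, within-group
#' means and variances are computed per gene, and the dispersion is the
#' pooled method-of-moments ratio
#' `sum(variance - mean) / sum(mean^2 - variance / n)` across genes
#' (the denominator correction removes the upward bias of the squared
#' sample mean), clipped at zero. Tagwise mode shrinks each gene's own
#' moment estimate toward the common value with weight `n - 1` against a
#' prior weight `prior_n`.
#'
#' @param counts long count tibble.
#' @param samples tibble `sample_id`, `condition`, `lib_size`.
#' @param method `"common"` or `"tagwise"`.
#' @param prior_n prior weight for tagwise shrinkage (default 10).
#' @param default dispersion returned (with a warning) when no condition
#'   has two or more samples.
#' @return scalar dispersion (common) or tibble `gene_id`, `dispersion`
#'   (tagwise).
#' @export
estimate_dispersion <- function(counts, samples,
                                method = c("common", "tagwise"),
                                prior_n = 10, default = 0.1) {
  method <- match.arg(method)
  m <- counts_matrix(counts)
  m <- m[, samples$sample_id, drop = FALSE]
  groups <- split(seq_len(ncol(m)), samples$condition)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0) {
    warn("no condition has >= 2 samples; returning the default dispersion")
    return(if (method == "common") default else
      tibble(gene_id = rownames(m), dispersion = default))
  }
  eq <- equalize_counts(m, samples$lib_size)
  num <- den <- 0
  g_num <- g_den <- rep(0, nrow(m))
  for (ix in groups) {
    n <- length(ix)
    mu <- rowMeans(eq[, ix, drop = FALSE])
    v <- apply(eq[, ix, drop = FALSE], 1, stats::var)
    g_num <- g_num + (v - mu)
    g_den <- g_den + pmax(mu^2 - v / n, 0)
  }
  common <- max(0, sum(g_num) / max(sum(g_den), .Machine$double.eps))
  if (method == "common") return(common)
  w <- sum(vapply(groups, length, integer(1))) - length(groups)
  tag_raw <- ifelse(g_den > 0, pmax(g_num / g_den, 0), common)
  tibble(gene_id = rownames(m),
         dispersion = (w * tag_raw + prior_n * common) / (w + prior_n))
}

#' Exact conditional NB test for one gene
#'
#' Tests equality of means between two groups of equalized NB counts: the
#' group-B total given the overall total follows a negative hypergeometric
#' distribution free of the mean, and the two-sided p-value doubles the
#' smaller tail (point mass included), capped at 1. Dispersion 0 reduces to
#' the conditional binomial (exact Poisson two-sample) test.
#'
#' @param counts_a,counts_b integer count vectors (one per sample).
#' @param dispersion NB dispersion (>= 0).
#' @param lib_sizes_a,lib_sizes_b library sizes; counts are rescaled to
#'   their common geometric mean before testing (default: already equal).
#' @return two-sided p-value in \[0, 1\].
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion,
                          lib_sizes_a = NULL, lib_sizes_b = NULL) {
  stopifnot(dispersion >= 0)
  if (!is.null(lib_sizes_a) || !is.null(lib_sizes_b)) {
    libs <- c(lib_sizes_a, lib_sizes_b)
    m <- matrix(c(counts_a, counts_b), nrow = 1)
    m <- equalize_counts(m, libs)
    counts_a <- m[1, seq_along(counts_a)]
    counts_b <- m[1, length(counts_a) + seq_along(counts_b)]
  }
  sa <- sum(counts_a); sb <- sum(counts_b)
  t <- sa + sb
  if (t == 0) return(1)
  na <- length(counts_a); nb <- length(counts_b)
  k <- 0:t
  if (dispersion == 0) {
    lw <- dbinom(k, t, nb / (na + nb), log = TRUE)
  } else {
    ra <- na / dispersion; rb <- nb / dispersion
    lw <- lgamma(k + rb) - lgamma(k + 1) +
      lgamma(t - k + ra) - lgamma(t - k + 1)
  }
  p <- exp(lw - max(lw))
  p <- p / sum(p)
  lo <- sum(p[k <= sb])
  hi <- sum(p[k >= sb])
  min(1, 2 * min(lo, hi))
}

#' Two-condition differential expression with the simplified exact test
#'
#' Runs [nb_exact_test()] per gene at a common (or supplied) dispersion,
#' reports log2 fold changes of group mean CPM with a pseudocount of 0.5
#' (reporting only, never testing), raw p-values, Benjamini-Hochberg FDR,
#' and a significance call at `alpha` and `min_fold` (significance follows
#' the raw p-value, matching the screening convention the thresholds come
#' from).
#'
#' @param counts long count tibble.
#' @param samples tibble `sample_id`, `condition` (two levels; the
#'   lexicographically second is "B"), `lib_size`.
#' @param dispersion NB dispersion; `NULL` estimates the common dispersion.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param min_fold fold-change threshold (default 2: |log2fc| >= 1).
#' @return object of class `mirsight_de`: tibble `gene_id`, `log2fc`,
#'   `p_value`, `fdr`, `significant`, with the dispersion and thresholds in
#'   attributes.
#' @export
de_exact_test <- function(counts, samples, dispersion = NULL,
                          alpha = 0.05, min_fold = 2) {
  m <- counts_matrix(counts)
  m <- m[, samples$sample_id, drop = FALSE]
  conds <- sort(unique(samples$condition))
  if (length(conds) != 2) abort("exactly two conditions are required")
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, samples, method = "common")
  }
  eq <- equalize_counts(m, samples$lib_size)
  ia <- which(samples$condition == conds[1])
  ib <- which(samples$condition == conds[2])
  pv <- vapply(seq_len(nrow(eq)), function(g) {
    nb_exact_test(eq[g, ia], eq[g, ib], dispersion)
  }, numeric(1))
  ma <- rowMeans(eq[, ia, drop = FALSE])
  mb <- rowMeans(eq[, ib, drop = FALSE])
  lfc <- log2((mb + 0.5) / (ma + 0.5))
  res <- tibble(gene_id = rownames(m), log2fc = lfc, p_value = pv,
                fdr = p.adjust(pv, method = "BH"),
                significant = pv < alpha & abs(lfc) >= log2(min_fold))
  structure(res, class = c("mirsight_de", class(res)),
            dispersion = dispersion, alpha = alpha, min_fold = min_fold,
            conditions = conds)
}

#' Fold-change shift of a target set against background
#'
#' One-sided two-sample Kolmogorov-Smirnov test for the target genes'
#' log2 fold changes being shifted downward relative to background (the
#' cumulative-distribution comparison classically used to show seed-target
#' repression), plus the direction of the median difference.
#'
#' @param log2fc_targets,log2fc_background numeric vectors.
#' @param alternative `"less"` (targets shifted down, default) or
#'   `"greater"`.
#' @return object of class `mirsight_shift`: list with `statistic`,
#'   `p_value`, `direction` (sign of median(targets) - median(background)),
#'   `n_targets`, `n_background`.
#' @export
target_shift_test <- function(log2fc_targets, log2fc_background,
                              alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(log2fc_targets) == 0 || length(log2fc_background) == 0) {
    abort("both target and background sets must be non-empty")
  }
  if (length(log2fc_targets) < 5 || length(log2fc_background) < 5) {
    warn("fewer than 5 observations in a set; the shift test has low power")
  }
  # ks.test alternative 'greater' = ECDF(x) above ECDF(y) = x shifted down
  ks_alt <- if (alternative == "less") "greater" else "less"
  kt <- suppressWarnings(
    ks.test(log2fc_targets, log2fc_background, alternative = ks_alt,
            exact = FALSE))
  structure(list(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 direction = sign(median(log2fc_targets) -
                                    median(log2fc_background)),
                 n_targets = length(log2fc_targets),
                 n_background = length(log2fc_background),
                 alternative = alternative),
            class = "mirsight_shift")
}

#' @export
print.mirsight_shift <- function(x, ...) {
  cat("Target-set fold-change shift (one-sided KS)\n")
  cat(sprintf("  targets n=%d, background n=%d\n", x$n_targets,
              x$n_background))
  cat(sprintf("  D = %.4f, p = %.3g, direction %+d\n", x$statistic,
              x$p_value, x$direction))
  invisible(x)
}

#' Classify per-gene target outcomes
#'
#' Joins differential-expression calls with 3'UTR-loss calls: a gene is
#' `repressed` when significant with fold <= 1/min_fold, `increased` when
#' significant with fold >= min_fold, else `unchanged`; the UTR-loss flag is
#' carried alongside (FALSE when the gene has no loss call).
#'
#' @param de `mirsight_de` result (or plain tibble with `gene_id`,
#'   `log2fc`, `p_value`).
#' @param loss_calls optional [call_utr_loss()] output joined by gene via
#'   `gene_map` (tibble `transcript_id`, `gene_id`); or a tibble
#'   `gene_id`, `utr_lost`.
#' @param alpha significance level (default 0.05).
#' @param min_fold fold threshold (default 2).
#' @param gene_map optional transcript-to-gene map when `loss_calls` is
#'   transcript-level.
#' @return tibble `gene_id`, `log2fc`, `p_value`, `category`, `utr_lost`.
#' @export
classify_target_outcome <- function(de, loss_calls = NULL, alpha = 0.05,
                                    min_fold = 2, gene_map = NULL) {
  x <- as_tibble(de)
  lf <- log2(min_fold)
  x <- mutate(x, category = dplyr::case_when(
    .data$p_value < alpha & .data$log2fc <= -lf ~ "repressed",
    .data$p_value < alpha & .data$log2fc >= lf ~ "increased",
    .default = "unchanged"))
  lost <- tibble(gene_id = character(0), utr_lost = logical(0))
  if (!is.null(loss_calls)) {
    if ("utr_lost" %in% names(loss_calls)) {
      lost <- select(loss_calls, "gene_id", "utr_lost")
    } else {
      if (is.null(gene_map)) {
        abort("gene_map is required for transcript-level loss calls")
      }
      lost <- loss_calls |>
        inner_join(gene_map, by = "transcript_id") |>
        group_by(.data$gene_id) |>
        summarise(utr_lost = any(!is.na(.data$loss) & .data$loss),
                  .groups = "drop")
    }
  }
  x |>
    left_join(lost, by = "gene_id") |>
    mutate(utr_lost = !is.na(.data$utr_lost) & .data$utr_lost) |>
    select("gene_id", "log2fc", "p_value", "category", "utr_lost")
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample: dCt = Ct_target - Ct_reference; ddCt = dCt - dCt(calibrator);
#' relative expression = 2^-ddCt, so the calibrator maps to 1 exactly.
#'
#' @param ct tibble `sample`, `ct_target`, `ct_reference`, `calibrator`
#'   (logical; exactly one TRUE).
#' @return `ct` with `dct`, `ddct`, `rel_expr` columns added.
#' @export
ddct <- function(ct) {
  if (sum(ct$calibrator) != 1) {
    abort("exactly one calibrator sample is required")
  }
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference))) {
    abort("Ct values must be finite")
  }
  ct <- mutate(ct, dct = .data$ct_target - .data$ct_reference)
  cal <- ct$dct[ct$calibrator]
  mutate(ct, ddct = .data$dct - cal, rel_expr = 2^(-.data$ddct))
}
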