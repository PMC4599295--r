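# Synthetic-data generators. Every generator is deterministic under its
# `seed` argument (RNG state is restored afterwards) and returns recorded
# ground truth alongside the data, so analyzers can be scored against the
# construction.

#' IsomiR generative distribution
#'
#' Probabilities over 5' offsets in \[-2, +2\] and templated 3' offsets in
#' \[-6, +3\], a per-base substitution rate, and a non-templated-addition
#' rate with nucleotide weights. Defaults are loosely matched to the
#' heterogeneity pattern of the embedded miR-200b prevalence table (mostly
#' canonical 5' ends, substantial 3' trimming and mono-uridylation); they
#' are illustrative, not fitted.
#'
#' @param p_offset5 named probability vector over offsets -2..2.
#' @param p_offset3 named probability vector over offsets -6..3.
#' @param sub_rate per-base substitution probability.
#' @param nta_rate probability of one non-templated 3' addition.
#' @param nta_weights nucleotide weights for the added base.
#' @param arm_prob probability vector over arms c("5p", "3p").
#' @return object of class `isomir_distribution`.
#' @export
isomir_distribution <- function(
    p_offset5 = c(`-2` = 0.01, `-1` = 0.02, `0` = 0.90, `1` = 0.06,
                  `2` = 0.01),
    p_offset3 = c(`-6` = 0.01, `-5` = 0.10, `-4` = 0.08, `-3` = 0.06,
                  `-2` = 0.04, `-1` = 0.12, `0` = 0.40, `1` = 0.12,
                  `2` = 0.05, `3` = 0.02),
    sub_rate = 0.01, nta_rate = 0.15,
    nta_weights = c(U = 0.6, A = 0.25, C = 0.1, G = 0.05),
    arm_prob = c(`5p` = 0.65, `3p` = 0.35)) {
  for (p in list(p_offset5, p_offset3, arm_prob)) {
    if (abs(sum(p) - 1) > 1e-8) abort("probability vectors must sum to 1")
  }
  if (sub_rate < 0 || sub_rate > 1 || nta_rate < 0 || nta_rate > 1) {
    abort("rates must lie in [0, 1]")
  }
  structure(list(p_offset5 = p_offset5, p_offset3 = p_offset3,
                 sub_rate = sub_rate, nta_rate = nta_rate,
                 nta_weights = nta_weights / sum(nta_weights),
                 arm_prob = arm_prob),
            class = "isomir_distribution")
}

#' Build a synthetic precursor hairpin around two matures
#'
#' Layout: 20 nt random 5' flank, 5p mature, 15 nt loop, 3p mature, 20 nt
#' random 3' flank.
#'
#' @param name locus name.
#' @param mature5p,mature3p canonical matures (RNA).
#' @param seed integer seed for the random flanks.
#' @param flank,loop flank and loop lengths (nt).
#' @return a [mirna_locus()] with precursor.
#' @export
synthetic_locus <- function(name, mature5p, mature3p, seed,
                            flank = 20L, loop = 15L) {
  withr::with_seed(seed, {
    pre <- paste0(random_seq(flank), as_rna(mature5p), random_seq(loop),
                  as_rna(mature3p), random_seq(flank))
    mirna_locus(name, mature5p = mature5p, mature3p = mature3p,
                precursor = pre)
  })
}

#' Generate a toy transcriptome
#'
#' Each gene sits on its own chromosome and has one or two isoforms built
#' from two exons; the second exon carries the 3'UTR. A configurable
#' fraction of genes gets a proximal polyA site inside the UTR (the
#' alternative-polyadenylation structure used by the 3'UTR-loss caller).
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed.
#' @param apa_fraction fraction of genes given a proximal polyA site.
#' @param utr_len 3'UTR length per gene (nt).
#' @param exon_len length of each of the two coding exons.
#' @param two_isoform_fraction fraction of genes with a second (single-exon)
#'   isoform.
#' @param minus_strand_fraction fraction of genes placed on the minus
#'   strand.
#' @return list with `genome` (named character vector, DNA) and `tx`
#'   (transcript-model tibble; first isoform per gene carries the UTR).
#' @export
make_transcriptome <- function(n_genes, seed, apa_fraction = 0.5,
                               utr_len = 400L, exon_len = 300L,
                               two_isoform_fraction = 0.3,
                               minus_strand_fraction = 0.3) {
  stopifnot(n_genes >= 1)
  withr::with_seed(seed, {
    dna <- c("A", "C", "G", "T")
    intron <- 100L
    gap <- 50L
    rows <- list()
    genome <- character(n_genes)
    names(genome) <- paste0("chr", seq_len(n_genes))
    has_apa <- runif(n_genes) < apa_fraction
    two_iso <- runif(n_genes) < two_isoform_fraction
    minus <- runif(n_genes) < minus_strand_fraction
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", g)
      chrom <- names(genome)[g]
      strand <- if (minus[g]) "-" else "+"
      # the UTR lives in the transcript's terminal exon: genomic-right exon
      # on the plus strand, genomic-left exon on the minus strand
      if (strand == "+") {
        e1 <- c(gap, gap + exon_len)
        e2 <- c(e1[2] + intron, e1[2] + intron + exon_len + utr_len)
        utr <- c(e2[2] - utr_len, e2[2])
      } else {
        e1 <- c(gap, gap + utr_len + exon_len)
        e2 <- c(e1[2] + intron, e1[2] + intron + exon_len)
        utr <- c(gap, gap + utr_len)
      }
      chrom_len <- e2[2] + gap
      genome[g] <- random_seq(chrom_len, alphabet = dna)
      utr_exon <- if (strand == "+") e2 else e1
      pp <- if (has_apa[g]) as.integer(round(utr_len * runif(1, 0.35, 0.65)))
            else NA_integer_
      rows[[length(rows) + 1]] <- tibble(
        gene_id = gid, transcript_id = paste0(gid, ".1"), chrom = chrom,
        strand = strand,
        exons = list(intervals_tbl(c(e1[1], e2[1]), c(e1[2], e2[2]))),
        utr3 = list(intervals_tbl(utr[1], utr[2])),
        proximal_polya = pp, repeat_flag = FALSE)
      if (two_iso[g]) {
        rows[[length(rows) + 1]] <- tibble(
          gene_id = gid, transcript_id = paste0(gid, ".2"), chrom = chrom,
          strand = strand,
          exons = list(intervals_tbl(utr_exon[1], utr_exon[2])),
          utr3 = list(intervals_tbl(integer(0), integer(0))),
          proximal_polya = NA_integer_, repeat_flag = FALSE)
      }
    }
    tx <- list_rbind(rows)
    validate_transcript_models(tx)
    list(genome = genome, tx = tx)
  })
}

# write an RNA-alphabet UTR string back into the genome, strand-aware
write_utr_seq <- function(genome, tx_row, utr_rna) {
  u <- arrange(tx_row$utr3[[1]], .data$start)
  dna <- as_dna(if (tx_row$strand == "-") rc_rna(utr_rna) else utr_rna)
  # in genomic orientation the chunks always run left to right
  off <- 0L
  chromseq <- genome[[tx_row$chrom]]
  for (k in seq_len(nrow(u))) {
    w <- u$end[k] - u$start[k]
    substr(chromseq, u$start[k] + 1L, u$end[k]) <-
      substr(dna, off + 1L, off + w)
    off <- off + w
  }
  genome[[tx_row$chrom]] <- chromseq
  genome
}

#' Implant seed sites into 3'UTRs
#'
#' Background UTR sequence is rejection-sampled so it contains no spurious
#' seed match for any of the given miRNAs, then the exact match string of
#' the requested class is written at random non-overlapping positions; the
#' construction is re-scanned and retried until recovered sites equal the
#' implanted truth exactly.
#'
#' @param tx transcript-model tibble (UTR-bearing isoforms are used).
#' @param genome named character vector of chromosome sequences.
#' @param mirnas tibble `name`, `mature` — the miRNAs under test.
#' @param n_sites_per_gene sites implanted per UTR-bearing transcript (for
#'   the first miRNA in `mirnas` unless `mirna_name` is given).
#' @param site_class `"8mer"`, `"7mer-m8"` or `"7mer-A1"`.
#' @param seed integer seed.
#' @param mirna_name which miRNA's sites to implant (default first).
#' @param target_transcripts optional transcript_ids to implant into
#'   (default: all transcripts with a 3'UTR).
#' @return list with modified `genome` and `truth` tibble
#'   (`transcript_id`, `gene_id`, `mirna`, `site_class`, `utr_position`).
#' @export
implant_seed_sites <- function(tx, genome, mirnas, n_sites_per_gene,
                               site_class = c("8mer", "7mer-m8", "7mer-A1"),
                               seed = 1L, mirna_name = NULL,
                               target_transcripts = NULL) {
  site_class <- match.arg(site_class)
  pats <- list_rbind(lapply(seq_len(nrow(mirnas)), function(i) {
    seed_patterns(mirnas$mature[i], mirnas$name[i])
  }))
  if (is.null(mirna_name)) mirna_name <- mirnas$name[1]
  p <- pats[pats$mirna == mirna_name, ]
  site <- switch(site_class, "8mer" = p$site_8mer,
                 "7mer-m8" = p$site_7mer_m8, "7mer-A1" = p$site_7mer_a1)
  slen <- nchar(site)
  guard8_first <- substr(p$site_8mer, 1, 1)  # base that would upgrade A1->8mer
  truth <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(tx))) {
      if (nrow(tx$utr3[[i]]) == 0) next
      is_target <- is.null(target_transcripts) ||
        tx$transcript_id[i] %in% target_transcripts
      n_this <- if (is_target) n_sites_per_gene else 0L
      ulen <- sum(tx$utr3[[i]]$end - tx$utr3[[i]]$start)
      if (n_this > 0 &&
          ulen < n_this * (slen + 2L) + 2L) {
        abort(paste0("3'UTR of ", tx$transcript_id[i],
                     " is too short to host ", n_sites_per_gene, " sites"))
      }
      for (try in 1:25) {
        useq <- clean_background_utr(ulen, pats)
        pos <- integer(0)
        if (n_this > 0) {
          pos <- sample_nonoverlapping(ulen, slen, n_this, margin = 1L)
          for (q in pos) {
            substr(useq, q + 1L, q + slen) <- site
            if (site_class == "7mer-m8" &&
                substr(useq, q + slen + 1L, q + slen + 1L) == "A") {
              substr(useq, q + slen + 1L, q + slen + 1L) <-
                sample(c("C", "G", "U"), 1)
            }
            if (site_class == "7mer-A1" && q >= 1L &&
                substr(useq, q, q) == guard8_first) {
              substr(useq, q, q) <- sample(setdiff(c("A", "C", "G", "U"),
                                                   guard8_first), 1)
            }
          }
        }
        found <- scan_sequence(useq, pats)
        ok <- nrow(found) == length(pos) &&
          (length(pos) == 0 ||
             (all(sort(found$position) == sort(pos)) &&
                all(found$site_class == site_class) &&
                all(found$mirna == mirna_name)))
        if (ok) break
        if (try == 25) abort("failed to build a clean UTR; widen the UTR")
      }
      genome <- write_utr_seq(genome, tx[i, ], useq)
      if (length(pos) > 0) {
        truth[[length(truth) + 1]] <- tibble(
          transcript_id = tx$transcript_id[i], gene_id = tx$gene_id[i],
          mirna = mirna_name, site_class = site_class,
          utr_position = as.integer(sort(pos)))
      }
    }
  })
  truth <- if (length(truth)) list_rbind(truth) else
    tibble(transcript_id = character(0), gene_id = character(0),
           mirna = character(0), site_class = character(0),
           utr_position = integer(0))
  list(genome = genome, truth = truth)
}

# random UTR with no seed match for any pattern row (resample until clean)
clean_background_utr <- function(len, pats) {
  for (try in 1:200) {
    s <- random_seq(len)
    hits <- scan_sequence(s, pats)
    if (nrow(hits) == 0) return(s)
  }
  abort("could not sample a seed-free background UTR")
}

# n non-overlapping 0-based start positions for sites of length slen,
# keeping `margin` free bases around each site
sample_nonoverlapping <- function(len, slen, n, margin = 0L) {
  for (try in 1:500) {
    pos <- sort(sample.int(len - slen - margin, n) - 1L + margin)
    if (n == 1 || all(diff(pos) >= slen + margin)) return(pos)
  }
  abort("could not place non-overlapping sites")
}

#' Simulate small-RNA reads from a precursor
#'
#' Each read picks an arm, draws 5'/3' offsets (resampled if they run off
#' the precursor), takes the templated substring, applies per-base
#' substitutions, and appends a non-templated addition drawn to differ from
#' the next templated base (an addition matching the template would be
#' templated, not an NTA).
#'
#' @param locus a [mirna_locus()] with precursor.
#' @param dist an [isomir_distribution()].
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @return list with `reads` (tibble `read_id`, `seq`) and `truth`
#'   (tibble `read_id`, `arm`, `offset5`, `offset3`, `n_subs`, `nta`).
#' @export
simulate_small_rna_reads <- function(locus, dist, n_reads, seed) {
  stopifnot(n_reads >= 1)
  if (is.null(locus$precursor)) abort("locus must carry a precursor")
  pre <- strsplit(locus$precursor, "", fixed = TRUE)[[1]]
  plen <- length(pre)
  bases <- c("A", "C", "G", "U")
  withr::with_seed(seed, {
    arms <- sample(names(dist$arm_prob), n_reads, replace = TRUE,
                   prob = dist$arm_prob)
    out_seq <- character(n_reads)
    out_off5 <- out_off3 <- out_nsub <- integer(n_reads)
    out_nta <- character(n_reads)
    for (i in seq_len(n_reads)) {
      arm <- arms[i]
      pos <- if (arm == "5p") locus$pos5 else locus$pos3
      repeat {
        off5 <- as.integer(sample(names(dist$p_offset5), 1,
                                  prob = dist$p_offset5))
        off3 <- as.integer(sample(names(dist$p_offset3), 1,
                                  prob = dist$p_offset3))
        s <- pos["start"] + off5
        e <- pos["end"] + off3
        if (s >= 1 && e <= plen && s < e) break
      }
      rv <- pre[s:e]
      # substitutions only within the canonical mature span: an edit in a
      # templated extension is string-identical to a shorter extension
      # plus a non-templated tail, so it has no recoverable truth
      canon_lo <- max(1L, unname(pos["start"]) - s + 1L)
      canon_hi <- min(length(rv), unname(pos["end"]) - s + 1L)
      sub_ok <- seq.int(canon_lo, canon_hi)
      sub_at <- sub_ok[runif(length(sub_ok)) < dist$sub_rate]
      for (k in sub_at) rv[k] <- sample(setdiff(bases, rv[k]), 1)
      nta <- ""
      n_subs <- length(sub_at)
      if (runif(1) < dist$nta_rate) {
        next_t <- if (e + 1 <= plen) pre[e + 1] else ""
        cand <- setdiff(bases, next_t)
        w <- dist$nta_weights[cand]
        nta <- sample(cand, 1, prob = w / sum(w))
      }
      if (nta != "" && off3 < 0L) {
        # a tail on a trimmed read is string-identical to one less trim
        # plus a terminal mismatch; record the canonical minimal form
        # (fewer invented bases) the classifier is specified to prefer
        off3 <- off3 + 1L
        n_subs <- n_subs + 1L
        rv <- c(rv, nta)
        nta <- ""
        e <- e + 1L
      }
      out_seq[i] <- paste0(paste(rv, collapse = ""), nta)
      out_off5[i] <- off5; out_off3[i] <- off3
      out_nsub[i] <- n_subs; out_nta[i] <- nta
    }
    ids <- sprintf("r%06d", seq_len(n_reads))
    list(reads = tibble(read_id = ids, seq = out_seq),
         truth = tibble(read_id = ids, arm = arms, offset5 = out_off5,
                        offset3 = out_off3, n_subs = out_nsub,
                        nta = out_nta))
  })
}

#' Simulate a two-condition mRNA count matrix
#'
#' Counts are negative binomial with variance mu + dispersion * mu^2, gene
#' means scaled by library size. Genes flagged as seed targets receive
#' `effect_log2fc` in condition B unless their 3'UTR is lost, in which case
#' the effect is zero (targets escape repression).
#'
#' @param gene_truth tibble `gene_id`, `is_target`, `utr_lost`.
#' @param baseline_mean scalar or per-gene baseline expression (at the
#'   reference library size).
#' @param dispersion NB dispersion (>= 0; 0 gives Poisson counts).
#' @param effect_log2fc log2 fold change applied to intact targets in B.
#' @param lib_sizes numeric vector, one per sample (A reps then B reps);
#'   default all 1e6.
#' @param n_reps replicates per condition.
#' @param seed integer seed.
#' @return list with `counts` (long tibble), `samples` (tibble `sample_id`,
#'   `condition`, `lib_size`) and `truth` (gene_truth plus `true_log2fc`).
#' @export
simulate_mrna_counts <- function(gene_truth, baseline_mean = 1000,
                                 dispersion = 0.05, effect_log2fc = -1,
                                 lib_sizes = NULL, n_reps = 3L, seed = 1L) {
  stopifnot(dispersion >= 0, n_reps >= 1)
  n_genes <- nrow(gene_truth)
  if (length(baseline_mean) == 1) baseline_mean <- rep(baseline_mean,
                                                       n_genes)
  if (is.null(lib_sizes)) lib_sizes <- rep(1e6, 2L * n_reps)
  stopifnot(length(lib_sizes) == 2L * n_reps)
  samples <- tibble(
    sample_id = c(sprintf("A%d", seq_len(n_reps)),
                  sprintf("B%d", seq_len(n_reps))),
    condition = rep(c("A", "B"), each = n_reps),
    lib_size = as.numeric(lib_sizes))
  true_lfc <- ifelse(gene_truth$is_target & !gene_truth$utr_lost,
                     effect_log2fc, 0)
  ref <- exp(mean(log(samples$lib_size)))
  withr::with_seed(seed, {
    mats <- lapply(seq_len(nrow(samples)), function(j) {
      mu <- baseline_mean * (samples$lib_size[j] / ref)
      if (samples$condition[j] == "B") mu <- mu * 2^true_lfc
      y <- if (dispersion == 0) rpois(n_genes, mu) else
        rnbinom(n_genes, size = 1 / dispersion, mu = mu)
      tibble(gene_id = gene_truth$gene_id, sample_id = samples$sample_id[j],
             count = as.integer(y))
    })
    counts <- list_rbind(mats)
  })
  truth <- mutate(gene_truth, true_log2fc = true_lfc)
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate per-base 3'UTR coverage
#'
#' Proximal-segment coverage sits at `depth`; the distal segment (beyond the
#' proximal polyA site) sits at `depth` when the UTR is intact or
#' `depth * residual_fraction` when lost. Gaussian noise is added per base
#' and truncated at zero.
#'
#' @param tx_row one row of a transcript-model tibble with
#'   `proximal_polya` set.
#' @param utr_lost logical; is the distal segment lost?
#' @param depth mean proximal coverage (reads/base).
#' @param noise_sd per-base Gaussian noise sd.
#' @param residual_fraction distal residual when lost (default 0.05).
#' @param seed integer seed.
#' @return tibble `transcript_id`, `pos` (0-based UTR offset), `depth`.
#' @export
simulate_coverage <- function(tx_row, utr_lost, depth = 100,
                              noise_sd = 0, residual_fraction = 0.05,
                              seed = 1L) {
  pp <- tx_row$proximal_polya[1]
  if (is.na(pp)) abort("transcript has no proximal polyA site")
  ulen <- sum(tx_row$utr3[[1]]$end - tx_row$utr3[[1]]$start)
  base <- c(rep(depth, pp),
            rep(depth * (if (utr_lost) residual_fraction else 1),
                ulen - pp))
  withr::with_seed(seed, {
    cov <- pmax(0, base + rnorm(ulen, 0, noise_sd))
  })
  tibble(transcript_id = tx_row$transcript_id[1],
         pos = seq_len(ulen) - 1L, depth = cov)
}

#' Simulate mRNA-seq reads as exact exon-union substrings
#'
#' Convenience generator for exercising the read counter: draws sense-strand
#' substrings uniformly from gene exon-union sequences.
#'
#' @param tx transcript-model tibble.
#' @param genome named character vector.
#' @param n_reads number of reads.
#' @param read_len read length.
#' @param seed integer seed.
#' @return list `reads` (tibble `read_id`, `seq`) and `truth` (`read_id`,
#'   `gene_id`).
#' @export
simulate_mrna_reads <- function(tx, genome, n_reads, read_len = 50L,
                                seed = 1L) {
  idx <- build_gene_index(tx, genome)
  ok <- idx[nchar(idx$seq) >= read_len, ]
  withr::with_seed(seed, {
    g <- sample.int(nrow(ok), n_reads, replace = TRUE)
    start <- vapply(g, function(k) sample.int(nchar(ok$seq[k]) - read_len +
                                                1L, 1L), integer(1))
    tibble(read_id = sprintf("m%06d", seq_len(n_reads)),
           seq = substr(rep(ok$seq[g], 1), start, start + read_len - 1L),
           gene_id = ok$gene_id[g])
  }) -> out
  list(reads = select(out, "read_id", "seq"),
       truth = select(out, "read_id", "gene_id"))
}
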