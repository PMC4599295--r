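# shared builders and independent oracles for the test suite

# a hand-built two-chromosome toy annotation with known sequences:
#   geneA: two exons on chr1 (+)
#   geneB: single exon on chr1 overlapping geneA's second exon (shared locus)
#   geneC: single exon on chr2 whose sequence duplicates part of geneA
#     (a second genomic location for multi-location tests)
toy_world <- function(repeat_b = FALSE, duplicate_locus = FALSE) {
  set.seed(404)
  a1 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
              collapse = "")
  a2 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
              collapse = "")
  spacer <- strrep("T", 20)
  chr1 <- paste0(spacer, a1, spacer, a2, spacer)
  chr2 <- if (duplicate_locus) paste0(spacer, a2, spacer) else
    paste0(spacer, paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                         collapse = ""), spacer)
  genome <- c(chr1 = chr1, chr2 = chr2)
  ex_a <- tibble::tibble(start = c(20L, 100L), end = c(80L, 160L))
  ex_b <- tibble::tibble(start = 100L, end = 160L)
  ex_c <- tibble::tibble(start = 20L, end = 80L)
  no_utr <- tibble::tibble(start = integer(0), end = integer(0))
  tx <- transcript_models(
    gene_id = c("geneA", "geneB", "geneC"),
    transcript_id = c("geneA.1", "geneB.1", "geneC.1"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = "+",
    exons = list(ex_a, ex_b, ex_c),
    utr3 = list(no_utr, no_utr, no_utr),
    proximal_polya = NA_integer_,
    repeat_flag = c(FALSE, repeat_b, FALSE))
  list(genome = genome, tx = tx, exonA1 = a1, exonA2 = a2)
}

# naive all-substrings seed scan (independent of the package scanner):
# vectorized substring equality at every position, then the same
# class-collapsing arithmetic applied directly
brute_scan <- function(sequence, patterns) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  n <- nchar(sequence)
  starts_of <- function(pat) {
    w <- nchar(pat)
    if (n < w) return(integer(0))
    idx <- seq_len(n - w + 1L)
    idx[substring(sequence, idx, idx + w - 1L) == pat] - 1L
  }
  out <- lapply(seq_len(nrow(patterns)), function(i) {
    p <- patterns[i, ]
    p8 <- starts_of(p$site_8mer)
    m8 <- setdiff(starts_of(p$site_7mer_m8), p8)
    a1 <- setdiff(starts_of(p$site_7mer_a1), p8 + 1L)
    dplyr::bind_rows(
      tibble::tibble(position = p8, site_class = "8mer"),
      tibble::tibble(position = m8, site_class = "7mer-m8"),
      tibble::tibble(position = a1, site_class = "7mer-A1")) |>
      dplyr::mutate(mirna = p$mirna, .before = 1) |>
      dplyr::arrange(position)
  })
  purrr::list_rbind(out)
}

# brute-force all-positions Hamming scan of a read against a gene's spliced
# exon-union sequence (with end overhangs allowed), independent of the
# Biostrings-based mapper
brute_best_hit <- function(read, gene_seq, max_unmatched) {
  rlen <- nchar(read)
  glen <- nchar(gene_seq)
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  best <- NULL
  for (s in seq.int(1L - max_unmatched, glen - rlen + 1L + max_unmatched)) {
    idx <- seq.int(s, s + rlen - 1L)
    inb <- idx >= 1L & idx <= glen
    gv <- rep(NA_character_, rlen)
    gv[inb] <- strsplit(substr(gene_seq, max(1L, s),
                               min(glen, s + rlen - 1L)), "",
                        fixed = TRUE)[[1]]
    unmatched <- sum(!inb) + sum(rv[inb] != gv[inb])
    if (unmatched <= max_unmatched &&
        (is.null(best) || unmatched < best$unmatched)) {
      best <- list(start = s, unmatched = unmatched)
    }
  }
  best
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
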