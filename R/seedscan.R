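# Seed-site scanning. Site classes follow the canonical target-site
# definitions: seed = miRNA positions 2-8; the 8mer site is a perfect match
# to positions 2-8 plus an A opposite position 1; 7mer-m8 drops the A;
# 7mer-A1 matches positions 2-7 plus the A. The A is a literal A in the
# target mRNA, not complementarity to miRNA position 1. Sites are written
# 5'->3' in mRNA sense, so they are reverse complements of the miRNA seed.

#' Derive seed-site match strings for a mature miRNA
#'
#' @param mature mature miRNA sequence (>= 8 nt; RNA or DNA).
#' @param name optional miRNA name carried into the result.
#' @return tibble with `mirna`, `site_8mer`, `site_7mer_m8`, `site_7mer_a1`
#'   (match strings in mRNA sense, RNA alphabet).
#' @export
#' @examples
#' seed_patterns("UAAUACUGCCUGGUAAUGAUGA", "miR-200b-3p")
seed_patterns <- function(mature, name = NA_character_) {
  mature <- as_rna(mature)
  if (nchar(mature) < 8) abort("mature must be at least 8 nt for a seed")
  m8 <- rc_rna(substr(mature, 2, 8))
  tibble(
    mirna = name,
    site_8mer = paste0(m8, "A"),
    site_7mer_m8 = m8,
    site_7mer_a1 = paste0(rc_rna(substr(mature, 2, 7)), "A")
  )
}

# all (overlap-allowing) 0-based start positions of a pattern in a sequence
match_starts <- function(pattern, sequence) {
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  hits <- Biostrings::matchPattern(pattern,
                                   Biostrings::RNAString(sequence))
  as.integer(Biostrings::start(hits)) - 1L
}

#' Scan one sequence for seed sites
#'
#' Every position is tested; where classes overlap at the same site the
#' strongest wins (8mer > 7mer-m8 > 7mer-A1), so an 8mer occurrence is not
#' additionally reported as its two contained 7mers. Distinct sites may
#' still overlap each other. Input may be DNA or RNA.
#'
#' @param sequence target sequence (e.g. a 3'UTR), 5'->3'.
#' @param patterns one row of [seed_patterns()] output (or a tibble whose
#'   rows are scanned in turn).
#' @param collapse collapse contained 7mers under their 8mer (default TRUE);
#'   `FALSE` reports all raw matches of all three patterns.
#' @return tibble `mirna`, `position` (0-based), `site_class`.
#' @export
scan_sequence <- function(sequence, patterns, collapse = TRUE) {
  sequence <- as_rna(sequence)
  out <- lapply(seq_len(nrow(patterns)), function(i) {
    p <- patterns[i, ]
    p8 <- match_starts(p$site_8mer, sequence)
    m8 <- match_starts(p$site_7mer_m8, sequence)
    a1 <- match_starts(p$site_7mer_a1, sequence)
    if (collapse) {
      # an 8mer at p implies 7mer-m8 at p and 7mer-A1 at p+1
      m8 <- setdiff(m8, p8)
      a1 <- setdiff(a1, p8 + 1L)
    }
    bind_rows(
      tibble(position = p8, site_class = "8mer"),
      tibble(position = m8, site_class = "7mer-m8"),
      tibble(position = a1, site_class = "7mer-A1")
    ) |>
      mutate(mirna = p$mirna, .before = 1) |>
      arrange(.data$position)
  })
  list_rbind(out)
}

#' Scan transcriptome 3'UTRs for seed sites
#'
#' UTR sequences are extracted (or supplied) in transcript orientation and
#' scanned in mRNA sense only; the antisense strand is never searched.
#' Transcripts without a 3'UTR yield zero sites.
#'
#' @param tx transcript-model tibble.
#' @param mirnas tibble with columns `name` and `mature`.
#' @param genome named character vector of chromosome sequences; ignored
#'   when `utr_seqs` is supplied.
#' @param utr_seqs optional precomputed [utr_sequences()] tibble.
#' @param collapse see [scan_sequence()].
#' @return tibble `transcript_id`, `gene_id`, `mirna`, `utr_position`
#'   (0-based offset in the concatenated 3'UTR), `site_class`.
#' @export
scan_transcriptome <- function(tx, mirnas, genome = NULL, utr_seqs = NULL,
                               collapse = TRUE) {
  if (is.null(utr_seqs)) {
    if (is.null(genome)) abort("either genome or utr_seqs is required")
    utr_seqs <- utr_sequences(tx, genome)
  }
  pats <- list_rbind(lapply(seq_len(nrow(mirnas)), function(i) {
    seed_patterns(mirnas$mature[i], mirnas$name[i])
  }))
  rows <- lapply(seq_len(nrow(utr_seqs)), function(i) {
    if (utr_seqs$utr_len[i] == 0) return(NULL)
    hits <- scan_sequence(utr_seqs$utr_seq[i], pats, collapse = collapse)
    if (nrow(hits) == 0) return(NULL)
    hits$transcript_id <- utr_seqs$transcript_id[i]
    hits$gene_id <- utr_seqs$gene_id[i]
    hits
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble(transcript_id = character(0), gene_id = character(0),
                  mirna = character(0), utr_position = integer(0),
                  site_class = character(0)))
  }
  list_rbind(rows) |>
    rename(utr_position = "position") |>
    select("transcript_id", "gene_id", "mirna", "utr_position",
           "site_class") |>
    arrange(.data$transcript_id, .data$mirna, .data$utr_position)
}

#' Predicted target gene sets per miRNA
#'
#' @param sites site table from [scan_transcriptome()].
#' @param require_8mer keep only genes with at least one 8mer site (the
#'   stringent filter used for downstream 3'UTR-architecture evaluation);
#'   `FALSE` admits any site class.
#' @return tibble `mirna`, `gene_id`, `n_8mer`, `n_7mer_m8`, `n_7mer_a1`.
#' @export
predicted_targets <- function(sites, require_8mer = TRUE) {
  if (nrow(sites) == 0) {
    return(tibble(mirna = character(0), gene_id = character(0),
                  n_8mer = integer(0), n_7mer_m8 = integer(0),
                  n_7mer_a1 = integer(0)))
  }
  tab <- sites |>
    group_by(.data$mirna, .data$gene_id) |>
    summarise(
      n_8mer = sum(.data$site_class == "8mer"),
      n_7mer_m8 = sum(.data$site_class == "7mer-m8"),
      n_7mer_a1 = sum(.data$site_class == "7mer-A1"),
      .groups = "drop"
    )
  if (require_8mer) tab <- filter(tab, .data$n_8mer >= 1) else
    tab <- filter(tab, .data$n_8mer + .data$n_7mer_m8 + .data$n_7mer_a1 >= 1)
  arrange(tab, .data$mirna, .data$gene_id)
}
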