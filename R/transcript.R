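# Transcript models live in a tibble with one row per transcript:
#   gene_id, transcript_id, chrom, strand,
#   exons  - list column of tibbles (start, end), 0-based half-open, genomic,
#            sorted by start, non-overlapping
#   utr3   - list column of tibbles (start, end), genomic, subset of exons
#   proximal_polya - integer offset in the concatenated 3'UTR (transcript
#            orientation) of an annotated proximal polyA site, or NA
#   repeat_flag - TRUE when the locus lies in repeat-masked space
# All internal interval arithmetic is 0-based half-open; GFF3 (1-based
# closed) and BED12 (0-based half-open) are converted at the I/O boundary.

intervals_tbl <- function(start, end) {
  tibble(start = as.integer(start), end = as.integer(end)) |>
    arrange(.data$start)
}

#' Build a transcript-model tibble
#'
#' @param gene_id,transcript_id character vectors.
#' @param chrom,strand character vectors (strand `"+"` or `"-"`).
#' @param exons,utr3 list of interval tibbles (`start`, `end`; 0-based
#'   half-open genomic coordinates).
#' @param proximal_polya integer offset of an annotated proximal polyA site
#'   in the concatenated 3'UTR (transcript orientation), or `NA`.
#' @param repeat_flag logical; transcript lies in repeat-masked space.
#' @return validated transcript-model tibble.
#' @export
transcript_models <- function(gene_id, transcript_id, chrom, strand,
                              exons, utr3, proximal_polya = NA_integer_,
                              repeat_flag = FALSE) {
  tx <- tibble(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    exons = exons,
    utr3 = utr3,
    proximal_polya = as.integer(proximal_polya),
    repeat_flag = as.logical(repeat_flag)
  )
  validate_transcript_models(tx)
}

#' Validate a transcript-model tibble
#'
#' Checks interval sanity, containment of the 3'UTR in the exon union, and
#' that any proximal polyA offset lies strictly inside the concatenated
#' 3'UTR. Returns the tibble invisibly unchanged on success.
#'
#' @param tx transcript-model tibble.
#' @param seqlens optional named vector of chromosome lengths; when given,
#'   exons beyond the declared bounds are an error.
#' @return `tx` (invisibly validated).
#' @export
validate_transcript_models <- function(tx, seqlens = NULL) {
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    ex <- tx$exons[[i]]
    if (nrow(ex) == 0) abort(paste0("transcript ", id, " has no exons"))
    if (any(ex$start < 0 | ex$start >= ex$end)) {
      abort(paste0("transcript ", id, " has an invalid exon interval"))
    }
    ex <- arrange(ex, .data$start)
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(paste0("transcript ", id, " has overlapping exons"))
    }
    if (!is.null(seqlens)) {
      lim <- seqlens[[tx$chrom[i]]]
      if (!is.null(lim) && any(ex$end > lim)) {
        abort(paste0("transcript ", id, " has exons beyond the end of ",
                     tx$chrom[i]))
      }
    }
    u <- tx$utr3[[i]]
    if (nrow(u) > 0) {
      inside <- vapply(seq_len(nrow(u)), function(k) {
        any(u$start[k] >= ex$start & u$end[k] <= ex$end)
      }, logical(1))
      if (!all(inside)) {
        abort(paste0("3'UTR of transcript ", id,
                     " is not contained in its exons"))
      }
    }
    pp <- tx$proximal_polya[i]
    if (!is.na(pp)) {
      ulen <- sum(u$end - u$start)
      if (pp <= 0 || pp >= ulen) {
        abort(paste0("proximal polyA of transcript ", id,
                     " does not lie strictly inside its 3'UTR"))
      }
    }
  }
  invisible(tx)
}

# spliced sequence of a set of genomic intervals, 5'->3' in transcript
# orientation; genome is a named character vector of chromosome sequences
spliced_seq <- function(genome, chrom, strand, ivs) {
  chromseq <- genome[[chrom]]
  if (is.null(chromseq)) abort(paste0("chromosome ", chrom, " not in genome"))
  ivs <- arrange(ivs, .data$start)
  pieces <- substring(chromseq, ivs$start + 1L, ivs$end)
  s <- paste(pieces, collapse = "")
  if (strand == "-") s <- as_dna(rc_rna(s))
  s
}

#' Extract concatenated 3'UTR sequences in transcript orientation
#'
#' @param tx transcript-model tibble.
#' @param genome named character vector of chromosome sequences (DNA or RNA).
#' @param alphabet `"RNA"` (default; T converted to U) or `"DNA"`.
#' @return tibble `transcript_id`, `gene_id`, `utr_seq`, `utr_len`.
#' @export
utr_sequences <- function(tx, genome, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  seqs <- vapply(seq_len(nrow(tx)), function(i) {
    u <- tx$utr3[[i]]
    if (nrow(u) == 0) return("")
    spliced_seq(genome, tx$chrom[i], tx$strand[i], u)
  }, character(1))
  if (alphabet == "RNA") seqs <- as_rna(seqs) else seqs <- as_dna(seqs)
  tibble(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
         utr_seq = seqs, utr_len = nchar(seqs))
}

# genomic 0-based positions of each base of the concatenated 3'UTR, ordered
# 5'->3' in transcript orientation
utr_genomic_positions <- function(tx_row) {
  u <- arrange(tx_row$utr3[[1]], .data$start)
  pos <- unlist(lapply(seq_len(nrow(u)),
                       function(k) seq.int(u$start[k], u$end[k] - 1L)))
  if (tx_row$strand == "-") pos <- rev(pos)
  pos
}

# merge possibly-overlapping intervals (tibble start/end) into a union
merge_intervals <- function(ivs) {
  if (nrow(ivs) <= 1) return(arrange(ivs, .data$start))
  ivs <- arrange(ivs, .data$start)
  out_s <- ivs$start[1]; out_e <- ivs$end[1]
  res_s <- integer(0); res_e <- integer(0)
  for (k in 2:nrow(ivs)) {
    if (ivs$start[k] <= out_e) {
      out_e <- max(out_e, ivs$end[k])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- ivs$start[k]; out_e <- ivs$end[k]
    }
  }
  intervals_tbl(c(res_s, out_s), c(res_e, out_e))
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 is read 1-based closed, BED12 0-based half-open; both are converted
#' to the internal 0-based half-open convention, and minus-strand 3'UTRs are
#' oriented so transcript coordinates run 5' to 3'. In GFF3 the features
#' `exon` and `three_prime_UTR` are grouped under their `Parent` mRNA;
#' optional mRNA attributes `proximal_polya` (UTR offset) and `repeat_flag`
#' are honoured. In BED12 the 3'UTR is derived from the thick (CDS) range.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"bed12"` (default inferred from extension).
#' @param seqlens optional named chromosome lengths for bounds checking.
#' @return transcript-model tibble (see [transcript_models()]).
#' @export
read_gene_models <- function(path, dialect = NULL, seqlens = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.bed(\\.gz)?$", path)) "bed12" else "gff3"
  }
  dialect <- match.arg(dialect, c("gff3", "bed12"))
  tx <- if (dialect == "gff3") read_models_gff3(path) else
    read_models_bed12(path)
  validate_transcript_models(tx, seqlens = seqlens)
  tx
}

read_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna) == 0) abort(paste0("no mRNA/transcript features in ", path))
  get_attr <- function(d, nm, default) {
    if (nm %in% names(d)) d[[nm]] else rep(default, nrow(d))
  }
  parent_of <- function(d) {
    vapply(d$Parent, function(p) if (length(p)) as.character(p[1]) else
      NA_character_, character(1))
  }
  mrna_gene <- parent_of(mrna)
  kids <- df[df$type %in% c("exon", "three_prime_UTR"), , drop = FALSE]
  kid_parent <- parent_of(kids)
  rows <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- as.character(mrna$ID[i])
    mine <- kids[kid_parent == tid, , drop = FALSE]
    ex <- mine[mine$type == "exon", , drop = FALSE]
    ut <- mine[mine$type == "three_prime_UTR", , drop = FALSE]
    if (nrow(ex) == 0) abort(paste0("transcript ", tid, " has no exons"))
    pp <- suppressWarnings(as.integer(get_attr(mrna, "proximal_polya",
                                               NA_integer_)[i]))
    rf <- isTRUE(as.logical(get_attr(mrna, "repeat_flag", FALSE)[i]))
    tibble(
      gene_id = if (!is.na(mrna_gene[i])) mrna_gene[i] else tid,
      transcript_id = tid,
      chrom = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      exons = list(intervals_tbl(ex$start - 1L, ex$end)),
      utr3 = list(intervals_tbl(ut$start - 1L, ut$end)),
      proximal_polya = pp,
      repeat_flag = rf
    )
  })
  list_rbind(rows)
}

read_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  rows <- lapply(seq_along(gr), function(i) {
    g <- gr[i]
    chrom_start <- GenomicRanges::start(g) - 1L  # back to BED 0-based
    blocks <- S4Vectors::mcols(g)$blocks[[1]]
    if (is.null(blocks)) {
      ex <- intervals_tbl(chrom_start, GenomicRanges::end(g))
    } else {
      ex <- intervals_tbl(chrom_start + IRanges::start(blocks) - 1L,
                          chrom_start + IRanges::end(blocks))
    }
    thick <- S4Vectors::mcols(g)$thick
    strand <- as.character(GenomicRanges::strand(g))
    if (is.null(thick) || IRanges::width(thick) == 0) {
      ut <- intervals_tbl(integer(0), integer(0))
    } else {
      t_start <- IRanges::start(thick) - 1L
      t_end <- IRanges::end(thick)
      ut <- if (strand == "-") {
        clip_intervals(ex, upper = t_start)
      } else {
        clip_intervals(ex, lower = t_end)
      }
    }
    tibble(
      gene_id = as.character(S4Vectors::mcols(g)$name %||%
                               paste0("bed", i)),
      transcript_id = as.character(S4Vectors::mcols(g)$name %||%
                                     paste0("bed", i)),
      chrom = as.character(GenomicRanges::seqnames(g)),
      strand = strand,
      exons = list(ex), utr3 = list(ut),
      proximal_polya = NA_integer_, repeat_flag = FALSE
    )
  })
  list_rbind(rows)
}

# intersect intervals with [lower, upper)
clip_intervals <- function(ivs, lower = -Inf, upper = Inf) {
  s <- pmax(ivs$start, lower)
  e <- pmin(ivs$end, upper)
  keep <- s < e
  intervals_tbl(s[keep], e[keep])
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()] for the GFF3 dialect (gene, mRNA, exon
#' and three_prime_UTR features; `proximal_polya` and `repeat_flag` stored
#' as mRNA attributes).
#'
#' @param tx transcript-model tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(tx, path) {
  feats <- list()
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    ex <- tx$exons[[i]]; ut <- tx$utr3[[i]]
    mrna <- GenomicRanges::GRanges(
      tx$chrom[i],
      IRanges::IRanges(min(ex$start) + 1L, max(ex$end)),
      strand = tx$strand[i])
    S4Vectors::mcols(mrna)$type <- "mRNA"
    S4Vectors::mcols(mrna)$ID <- tid
    S4Vectors::mcols(mrna)$Parent <- tx$gene_id[i]
    S4Vectors::mcols(mrna)$proximal_polya <-
      if (is.na(tx$proximal_polya[i])) NA_character_ else
        as.character(tx$proximal_polya[i])
    S4Vectors::mcols(mrna)$repeat_flag <-
      if (tx$repeat_flag[i]) "TRUE" else NA_character_
    mk <- function(ivs, type) {
      if (nrow(ivs) == 0) return(NULL)
      g <- GenomicRanges::GRanges(
        tx$chrom[i], IRanges::IRanges(ivs$start + 1L, ivs$end),
        strand = tx$strand[i])
      S4Vectors::mcols(g)$type <- type
      S4Vectors::mcols(g)$ID <- NA_character_
      S4Vectors::mcols(g)$Parent <- tid
      S4Vectors::mcols(g)$proximal_polya <- NA_character_
      S4Vectors::mcols(g)$repeat_flag <- NA_character_
      g
    }
    feats <- c(feats, list(mrna), list(mk(ex, "exon")),
               list(mk(ut, "three_prime_UTR")))
  }
  feats <- feats[!vapply(feats, is.null, logical(1))]
  all <- suppressWarnings(do.call(c, feats))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
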