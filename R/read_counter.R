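# Read-to-gene counting. A read is considered mapped to a gene when all but
# max_unmatched (default 2) of its bases align gaplessly to the gene's
# exon-union (spliced) sequence; mismatches and end-overhangs both count as
# unmatched. Multi-gene single-location reads increment every gene;
# multi-location reads are ambiguous and count nowhere; repeat-flagged loci
# only receive uniquely mapped reads.

#' Collapse reads to unique sequences with multiplicities
#'
#' @param reads character vector of read sequences, or a tibble with a
#'   `seq` column (an existing `count` column is summed).
#' @return tibble `seq`, `count`, one row per distinct sequence;
#'   multiplicities are conserved.
#' @export
collapse_reads <- function(reads) {
  if (is.character(reads)) reads <- tibble(seq = reads, count = 1L)
  if (!"count" %in% names(reads)) reads$count <- 1L
  reads |>
    group_by(.data$seq) |>
    summarise(count = as.integer(sum(.data$count)), .groups = "drop") |>
    arrange(desc(.data$count), .data$seq)
}

#' Build the gene exon-union index for read mapping
#'
#' One entry per gene: the union of all annotated exons across isoforms,
#' spliced into a single sequence in transcript orientation (so exon
#' boundaries need not correspond to any one isoform), plus the genomic
#' coordinate of every spliced base for location deduplication.
#'
#' @param tx transcript-model tibble.
#' @param genome named character vector of chromosome sequences.
#' @return tibble `gene_id`, `chrom`, `strand`, `repeat_flag`, `seq`
#'   (RNA), `gpos` (list column: genomic 0-based position of each spliced
#'   base, 5'->3').
#' @export
build_gene_index <- function(tx, genome) {
  genes <- split(seq_len(nrow(tx)), tx$gene_id)
  rows <- lapply(names(genes), function(gid) {
    ix <- genes[[gid]]
    chrom <- tx$chrom[ix[1]]
    strand <- tx$strand[ix[1]]
    ivs <- merge_intervals(list_rbind(tx$exons[ix]))
    s <- as_rna(spliced_seq(genome, chrom, strand, ivs))
    gp <- unlist(lapply(seq_len(nrow(ivs)),
                        function(k) seq.int(ivs$start[k], ivs$end[k] - 1L)))
    if (strand == "-") gp <- rev(gp)
    tibble(gene_id = gid, chrom = chrom, strand = strand,
           repeat_flag = any(tx$repeat_flag[ix]),
           seq = s, gpos = list(gp))
  })
  list_rbind(rows)
}

# best gapless hit of one read against one padded gene sequence;
# returns NULL or list(unmatched, spliced_pos (1-based, may be <1 on a 5'
# overhang), gpos_key)
best_gene_hit <- function(read, idx_row, max_unmatched) {
  pad <- strrep("N", max_unmatched)
  subject <- paste0(pad, idx_row$seq, pad)
  hits <- Biostrings::matchPattern(read, Biostrings::BString(subject),
                                   max.mismatch = max_unmatched,
                                   with.indels = FALSE)
  if (length(hits) == 0) return(NULL)
  starts <- Biostrings::start(hits)
  mm <- vapply(starts, function(s) {
    frag <- substr(subject, s, s + nchar(read) - 1L)
    sum(strsplit(frag, "", fixed = TRUE)[[1]] !=
          strsplit(read, "", fixed = TRUE)[[1]])
  }, numeric(1))
  keep <- which(mm <= max_unmatched)
  if (length(keep) == 0) return(NULL)
  best_mm <- min(mm[keep])
  cand <- keep[mm[keep] == best_mm]
  s <- min(starts[cand])                       # leftmost among ties
  spliced <- s - max_unmatched                 # 1-based in unpadded seq
  anchor <- max(1L, spliced)                   # first in-bounds base
  gp <- idx_row$gpos[[1]][anchor]
  list(unmatched = as.integer(best_mm), spliced_pos = as.integer(spliced),
       location = paste0(idx_row$chrom, ":", idx_row$strand, ":", gp))
}

#' Map reads to genes by the exon-union rule
#'
#' @param reads collapsed reads ([collapse_reads()] output) or a character
#'   vector.
#' @param index gene index from [build_gene_index()].
#' @param max_unmatched tolerance: a hit needs at least
#'   `nchar(read) - max_unmatched` matching bases (default 2).
#' @param both_strands also search the reverse complement (for unstranded
#'   protocols; default FALSE, reads are assumed sense-stranded).
#' @param min_read_len reads shorter than this are reported unmapped with a
#'   warning (default 10).
#' @return tibble `seq`, `count`, `status` (`unique`,
#'   `multi_gene_one_location`, `ambiguous_multi_location`, `unmapped`,
#'   `repeat_discarded`), `genes_hit` (list), `n_locations`, `unmatched`.
#' @export
map_reads <- function(reads, index, max_unmatched = 2L,
                      both_strands = FALSE, min_read_len = 10L) {
  reads <- collapse_reads(reads)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    raw <- reads$seq[i]
    read <- as_rna(raw)
    if (nchar(read) < min_read_len) {
      warn(paste0("read shorter than ", min_read_len, " nt left unmapped: ",
                  raw))
      return(tibble(seq = raw, count = reads$count[i], status = "unmapped",
                    genes_hit = list(character(0)), n_locations = 0L,
                    unmatched = NA_integer_))
    }
    queries <- if (both_strands) c(read, rc_rna(read)) else read
    hits <- list()
    for (g in seq_len(nrow(index))) {
      for (q in queries) {
        h <- best_gene_hit(q, index[g, ], max_unmatched)
        if (!is.null(h)) {
          hits[[length(hits) + 1]] <- tibble(
            gene_id = index$gene_id[g], repeat_flag = index$repeat_flag[g],
            unmatched = h$unmatched, location = h$location)
        }
      }
    }
    if (length(hits) == 0) {
      return(tibble(seq = raw, count = reads$count[i], status = "unmapped",
                    genes_hit = list(character(0)), n_locations = 0L,
                    unmatched = NA_integer_))
    }
    hits <- list_rbind(hits) |>
      group_by(.data$gene_id) |>
      slice(which.min(.data$unmatched)) |>   # one location per gene
      ungroup()
    n_loc <- dplyr::n_distinct(hits$location)
    all_repeat <- all(hits$repeat_flag)
    status <- if (n_loc == 1 && nrow(hits) == 1) "unique"
      else if (n_loc == 1) "multi_gene_one_location"
      else if (all_repeat) "repeat_discarded"
      else "ambiguous_multi_location"
    tibble(seq = raw, count = reads$count[i], status = status,
           genes_hit = list(hits$gene_id), n_locations = n_loc,
           unmatched = min(hits$unmatched))
  })
  list_rbind(rows)
}

#' Count reads per gene from mapping results
#'
#' Unique reads add their multiplicity to their gene;
#' multi-gene-one-location reads add it to every gene hit; ambiguous
#' multi-location reads count nowhere; repeat-flagged genes only receive
#' counts from uniquely mapped reads. Counts are on the expanded
#' (multiplicity-weighted) scale.
#'
#' @param mapping output of [map_reads()].
#' @param index gene index (supplies the full gene universe and repeat
#'   flags).
#' @return tibble `gene_id`, `count` covering every gene in the index.
#' @export
count_genes <- function(mapping, index) {
  counts <- setNames(rep(0L, nrow(index)), index$gene_id)
  rpt <- setNames(index$repeat_flag, index$gene_id)
  for (i in seq_len(nrow(mapping))) {
    st <- mapping$status[i]
    gh <- mapping$genes_hit[[i]]
    if (st == "unique") {
      counts[gh] <- counts[gh] + mapping$count[i]
    } else if (st == "multi_gene_one_location") {
      add <- gh[!rpt[gh]]
      counts[add] <- counts[add] + mapping$count[i]
    }
  }
  tibble(gene_id = names(counts), count = as.integer(counts))
}
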