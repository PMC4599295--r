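#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased; both T and U are accepted and the alphabet
#' actually seen (DNA/RNA/ambiguous) is recorded per record.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return tibble with columns `id`, `seq`, `alphabet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  bad <- which(!nzchar(seqs) | !nzchar(ids))
  if (length(bad) > 0) {
    abort(paste0("FASTA record ", bad[1], " ('", ids[bad[1]],
                 "') has an empty header or sequence in ", path))
  }
  tibble(
    id = unname(ids),
    seq = unname(seqs),
    alphabet = dplyr::case_when(
      is_alphabet_ambiguous(seqs) ~ "ambiguous",
      grepl("U", seqs, fixed = TRUE) ~ "RNA",
      .default = "DNA"
    )
  )
}

#' Write sequences to a FASTA file
#'
#' @param x tibble with columns `id` and `seq` (extra columns ignored), or a
#'   named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- tibble(id = names(x), seq = unname(x))
  stopifnot(all(c("id", "seq") %in% names(x)))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Qualities are ignored. FASTA headers of the form `id_xN` or headers
#' carrying a `count=N` token are interpreted as collapsed reads with
#' multiplicity N; otherwise every record has multiplicity 1.
#'
#' @param path reads file; format inferred from extension unless given.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return tibble with columns `id`, `seq`, `count`.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  set <- Biostrings::readBStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(set))
  mult <- rep(1L, length(ids))
  has_x <- grepl("_x[0-9]+$", ids)
  mult[has_x] <- as.integer(sub("^.*_x", "", ids[has_x]))
  has_cnt <- grepl("count=[0-9]+", names(set))
  mult[has_cnt] <- as.integer(sub("^.*count=([0-9]+).*$", "\\1",
                                  names(set)[has_cnt]))
  tibble(id = unname(ids), seq = unname(toupper(as.character(set))),
         count = mult)
}

#' Read a gene-by-sample count table
#'
#' Expects a TSV with a header row, a `gene_id` first column and one integer
#' column per sample. Library sizes default to column sums unless a
#' `lib_sizes` vector is supplied.
#'
#' @param path TSV path.
#' @param lib_sizes optional named numeric vector of library sizes per
#'   sample; defaults to column sums.
#' @return a list with `counts` (long tibble: gene_id, sample_id, count) and
#'   `samples` (tibble: sample_id, lib_size).
#' @export
read_counts <- function(path, lib_sizes = NULL) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene_id" %in% names(wide)) {
    abort(paste0("count table ", path,
                 " is missing the header column 'gene_id'"))
  }
  samp <- setdiff(names(wide), "gene_id")
  if (length(samp) == 0) abort("count table has no sample columns")
  for (s in samp) {
    v <- wide[[s]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      abort(paste0("count table ", path, ": negative or non-integer count ",
                   "at row ", bad[1], ", column '", s, "'"))
    }
  }
  counts <- tidyr::pivot_longer(wide, -"gene_id", names_to = "sample_id",
                                values_to = "count")
  counts$count <- as.integer(counts$count)
  if (is.null(lib_sizes)) {
    lib_sizes <- vapply(samp, function(s) sum(wide[[s]]), numeric(1))
  }
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")
  list(counts = counts,
       samples = tibble(sample_id = samp,
                        lib_size = as.numeric(lib_sizes[samp])))
}

#' Write a count table (wide TSV)
#'
#' @param counts long tibble with gene_id, sample_id, count.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  wide <- tidyr::pivot_wider(counts, names_from = "sample_id",
                             values_from = "count")
  write_table(wide, path)
}

#' Write a tibble as a TSV with fixed numeric formatting
#'
#' Columns are written in their current order; doubles are rendered with six
#' significant digits so repeated runs are byte-identical.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- formatC(x[[j]], digits = 6,
                                             format = "g")
    if (is.list(x[[j]])) {
      x[[j]] <- vapply(x[[j]], function(v) paste(unlist(v), collapse = ","),
                       character(1))
    }
  }
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
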