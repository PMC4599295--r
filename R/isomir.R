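# isomiR classification: each small-RNA read is interpreted against the
# canonical mature of its arm as a 5' offset, a templated 3' offset, internal
# substitutions and a non-templated 3' tail. The minimum-cost interpretation
# wins, with deterministic tie-breaking.

#' Construct a miRNA locus
#'
#' A locus anchors isomiR classification: the two canonical mature arms and,
#' optionally, the precursor hairpin they sit in. When a precursor is given,
#' 5' extensions and templated 3' extensions are resolved against it; without
#' one, classification is purely mature-relative and every 3' base beyond
#' the canonical end is a (non-templated) addition.
#'
#' @param name locus name.
#' @param mature5p,mature3p canonical mature sequences (RNA or DNA; stored
#'   as RNA). At least one must be given.
#' @param precursor optional precursor hairpin sequence containing both
#'   matures, 5p arm first.
#' @return object of class `mirna_locus`.
#' @export
mirna_locus <- function(name, mature5p = NULL, mature3p = NULL,
                        precursor = NULL) {
  if (is.null(mature5p) && is.null(mature3p)) {
    abort("at least one mature arm is required")
  }
  mature5p <- if (!is.null(mature5p)) as_rna(mature5p)
  mature3p <- if (!is.null(mature3p)) as_rna(mature3p)
  pos5 <- pos3 <- NULL
  if (!is.null(precursor)) {
    precursor <- as_rna(precursor)
    locate <- function(m, arm) {
      if (is.null(m)) return(NULL)
      at <- regexpr(m, precursor, fixed = TRUE)
      if (at < 0) abort(paste0("mature ", arm,
                               " not found in precursor of ", name))
      c(start = as.integer(at), end = as.integer(at + nchar(m) - 1L))
    }
    pos5 <- locate(mature5p, "5p")
    pos3 <- locate(mature3p, "3p")
    if (!is.null(pos5) && !is.null(pos3)) {
      if (pos5["end"] >= pos3["start"]) {
        abort(paste0("mature arms of ", name,
                     " overlap or are out of order in the precursor"))
      }
    }
  }
  structure(list(name = name, precursor = precursor,
                 mature5p = mature5p, mature3p = mature3p,
                 pos5 = pos5, pos3 = pos3),
            class = "mirna_locus")
}

#' @export
print.mirna_locus <- function(x, ...) {
  cat("<mirna_locus>", x$name, "\n")
  if (!is.null(x$mature5p)) cat("  5p:", x$mature5p, "\n")
  if (!is.null(x$mature3p)) cat("  3p:", x$mature3p, "\n")
  cat("  precursor:", if (is.null(x$precursor)) "none (mature-relative)"
      else paste0(nchar(x$precursor), " nt"), "\n")
  invisible(x)
}

# longest common substring length between two strings (dynamic programming)
lcs_length <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(av); nb <- length(bv)
  if (na == 0 || nb == 0) return(0L)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    hit <- av[i] == bv
    cur[hit] <- c(0L, prev)[seq_len(nb)][hit] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

#' Assign a read to a miRNA arm
#'
#' The read goes to the arm whose canonical region (precursor window around
#' the mature when a precursor is available, the mature itself otherwise)
#' shares the longest exact substring with it. Reads whose best anchor is
#' shorter than `min_anchor`, or that tie between arms, are unassigned.
#'
#' @param read sequence (RNA or DNA).
#' @param locus a [mirna_locus()].
#' @param min_anchor minimum anchor length (default 10 nt).
#' @param bound5,bound3_hi window extension around each mature when a
#'   precursor is present (match the classifier bounds).
#' @return `"5p"`, `"3p"` or `"unassigned"`.
#' @export
assign_arm <- function(read, locus, min_anchor = 10L, bound5 = 4L,
                       bound3_hi = 4L) {
  read <- as_rna(read)
  window <- function(m, pos) {
    if (is.null(m)) return(NULL)
    if (is.null(locus$precursor)) return(m)
    substr(locus$precursor, max(1L, pos["start"] - bound5),
           min(nchar(locus$precursor), pos["end"] + bound3_hi))
  }
  w5 <- window(locus$mature5p, locus$pos5)
  w3 <- window(locus$mature3p, locus$pos3)
  a5 <- if (is.null(w5)) 0L else lcs_length(read, w5)
  a3 <- if (is.null(w3)) 0L else lcs_length(read, w3)
  if (max(a5, a3) < min_anchor || a5 == a3) return("unassigned")
  if (a5 > a3) "5p" else "3p"
}

empty_call <- function(seq, arm = "unassigned") {
  tibble(seq = seq, arm = arm, offset5 = NA_integer_, offset3 = NA_integer_,
         n_subs = NA_integer_, subs = list(tibble(pos = integer(0),
                                                  canonical = character(0),
                                                  read = character(0))),
         nta = NA_character_, cost = NA_integer_, is_canonical = FALSE)
}

#' Classify one read as an isomiR
#'
#' Enumerates interpretations over 5' offsets in `[-bound5, +bound5]` and
#' 3' offsets in `[bound3_lo, bound3_hi]`; each interpretation aligns the
#' read gaplessly to the canonical mature (extended into the precursor when
#' available), counts mismatches in the overlap, and treats read 3' bases
#' beyond the templated region as a non-templated addition (NTA). The
#' interpretation minimizing `cost = substitutions + NTA length` wins; ties
#' are broken by fewer NTA bases, then smaller |5' offset|, then smaller
#' |3' offset|. A best cost above `max_cost` rejects the read.
#'
#' Offset signs: `offset5 = +k` means the read 5' end is trimmed by k;
#' `offset3 = -k` trimmed, `+k` templated extension.
#'
#' @param read sequence.
#' @param locus a [mirna_locus()].
#' @param arm arm to classify against; `NULL` calls [assign_arm()] first.
#' @param bound5,bound3_lo,bound3_hi offset bounds (defaults 4, -8, +4).
#' @param max_cost rejection threshold on the winning cost (default 2).
#' @return one-row tibble: `seq`, `arm`, `offset5`, `offset3`, `n_subs`,
#'   `subs` (list column of per-substitution tibbles), `nta`, `cost`,
#'   `is_canonical`.
#' @export
classify_read <- function(read, locus, arm = NULL, bound5 = 4L,
                          bound3_lo = -8L, bound3_hi = 4L, max_cost = 2L) {
  raw <- read
  read <- as_rna(read)
  if (is.null(arm)) {
    arm <- assign_arm(read, locus, bound5 = bound5, bound3_hi = bound3_hi)
    if (arm == "unassigned") {
      # anchor failed (e.g. a substitution splits a short read's exact
      # match below the anchor length): fall back to full classification
      # against both arms and accept a unique minimum-cost winner
      arms <- c(if (!is.null(locus$mature5p)) "5p",
                if (!is.null(locus$mature3p)) "3p")
      cands <- lapply(arms, function(a) {
        best_interpretation(read, locus, a, bound5, bound3_lo, bound3_hi)
      })
      ok <- !vapply(cands, is.null, logical(1))
      arms <- arms[ok]; cands <- cands[ok]
      if (length(cands) == 0) return(empty_call(raw))
      keys <- lapply(cands, `[[`, "key")
      if (length(cands) == 2) {
        if (lex_less(keys[[1]], keys[[2]])) {
          pick <- 1L
        } else if (lex_less(keys[[2]], keys[[1]])) {
          pick <- 2L
        } else {
          return(empty_call(raw))        # inter-arm tie stays unassigned
        }
      } else pick <- 1L
      return(finish_call(raw, arms[pick], cands[[pick]], max_cost))
    }
  }
  if (arm == "unassigned") return(empty_call(raw))
  mature <- if (arm == "5p") locus$mature5p else locus$mature3p
  if (is.null(mature)) return(empty_call(raw))
  best <- best_interpretation(read, locus, arm, bound5, bound3_lo,
                              bound3_hi)
  finish_call(raw, arm, best, max_cost)
}

# enumerate interpretations of a read against one arm; returns the best
# (minimum cost; ties: fewer NTA bases, smaller |offset5|, smaller
# |offset3|) or NULL when no interpretation is geometrically valid.
# Extension bases beyond the canonical mature (5' or templated 3') must
# match the precursor exactly: a mismatched "templated" base is no
# templated base at all, and the 3' case is an NTA interpretation instead.
best_interpretation <- function(read, locus, arm, bound5, bound3_lo,
                                bound3_hi) {
  mature <- if (arm == "5p") locus$mature5p else locus$mature3p
  if (is.null(locus$precursor)) {
    ref <- mature
    cstart <- 1L
  } else {
    ref <- locus$precursor
    cstart <- unname((if (arm == "5p") locus$pos5 else locus$pos3)["start"])
  }
  canon_len <- nchar(mature)
  cend <- cstart + canon_len - 1L          # ref index of canonical 3' end
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  rlen <- length(rv)
  best <- NULL
  for (off5 in seq.int(-bound5, bound5)) {
    rs <- cstart + off5                    # ref index of read base 1
    if (rs < 1L) next
    for (off3 in seq.int(bound3_lo, bound3_hi)) {
      tlen <- canon_len + off3 - off5      # templated bases of the read
      if (tlen < 1L || tlen > rlen) next
      re <- rs + tlen - 1L
      if (re > length(refv)) next
      nta_len <- rlen - tlen
      mism <- which(rv[seq_len(tlen)] != refv[rs:re])
      ref_at <- rs + mism - 1L
      if (any(ref_at < cstart) || any(ref_at > cend)) next
      cost <- length(mism) + nta_len
      key <- c(cost, nta_len, abs(off5), abs(off3))
      if (is.null(best) || lex_less(key, best$key)) {
        best <- list(key = key, off5 = off5, off3 = off3, mism = mism,
                     rs = rs, tlen = tlen, nta_len = nta_len,
                     rv = rv, refv = refv)
      }
    }
  }
  best
}

finish_call <- function(raw, arm, best, max_cost) {
  if (is.null(best) || best$key[1] > max_cost) {
    return(empty_call(raw, arm = "unassigned"))
  }
  subs <- tibble(pos = as.integer(best$mism),
                 canonical = best$refv[best$rs + best$mism - 1L],
                 read = best$rv[best$mism])
  nta <- if (best$nta_len > 0)
    paste(best$rv[(best$tlen + 1L):length(best$rv)], collapse = "") else ""
  is_can <- best$off5 == 0L && best$off3 == 0L && nrow(subs) == 0L &&
    nta == ""
  tibble(seq = raw, arm = arm,
         offset5 = as.integer(best$off5), offset3 = as.integer(best$off3),
         n_subs = nrow(subs), subs = list(subs), nta = nta,
         cost = as.integer(best$key[1]),
         is_canonical = is_can)
}

# strict lexicographic comparison of equal-length numeric keys
lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' Classify a set of reads
#'
#' Vectorized driver over [classify_read()]: reads are collapsed to unique
#' sequences first, classified once each, and returned with multiplicities.
#' Sequences mixing T and U are flagged `alphabet_ambiguous` (classified on
#' the normalized sequence, but callers should exclude them from exact
#' class tallies).
#'
#' @param reads character vector of sequences, or a tibble with columns
#'   `seq` and optionally `count`.
#' @param locus a [mirna_locus()].
#' @inheritParams classify_read
#' @return tibble of calls, one row per distinct sequence, with `count` and
#'   `alphabet_ambiguous` columns added.
#' @export
classify_reads <- function(reads, locus, bound5 = 4L, bound3_lo = -8L,
                           bound3_hi = 4L, max_cost = 2L) {
  if (is.character(reads)) {
    reads <- tibble(seq = reads) |> count(.data$seq, name = "count")
  }
  if (!"count" %in% names(reads)) reads$count <- 1L
  uni <- reads |> group_by(.data$seq) |>
    summarise(count = sum(.data$count), .groups = "drop")
  if (nrow(uni) == 0) {
    out <- empty_call(character(0))[0, ]
    out$count <- integer(0)
    out$alphabet_ambiguous <- logical(0)
    return(out)
  }
  calls <- list_rbind(lapply(uni$seq, function(s) {
    classify_read(s, locus, bound5 = bound5, bound3_lo = bound3_lo,
                  bound3_hi = bound3_hi, max_cost = max_cost)
  }))
  calls$count <- uni$count[match(calls$seq, uni$seq)]
  calls$alphabet_ambiguous <- is_alphabet_ambiguous(calls$seq)
  calls
}

#' Tabulate isomiR classes
#'
#' One row per distinct sequence per arm, multiplicity-weighted, ordered by
#' arm, descending count, then sequence.
#'
#' @param calls output of [classify_reads()].
#' @return tibble `arm`, `seq`, `offset5`, `offset3`, `n_subs`, `nta`,
#'   `is_canonical`, `alphabet_ambiguous`, `count`.
#' @export
tabulate_isomirs <- function(calls) {
  calls |>
    group_by(.data$arm, .data$seq, .data$offset5, .data$offset3,
             .data$n_subs, .data$nta, .data$is_canonical,
             .data$alphabet_ambiguous) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$arm, desc(.data$count), .data$seq)
}

#' Summarize 5'/3' heterogeneity per arm
#'
#' Fractions of reads whose 5' end (offset5 != 0) or 3' end (templated
#' offset or non-templated tail) differs from canonical, plus the dominant
#' isomiR of each arm (count ties broken by lexicographically smallest
#' sequence).
#'
#' @param calls output of [classify_reads()].
#' @param exclude_ambiguous drop alphabet-ambiguous sequences (default TRUE).
#' @return tibble per arm: `arm`, `n_reads`, `frac_het5`, `frac_het3`,
#'   `dominant_seq`, `dominant_offset5`, `dominant_offset3`, `dominant_nta`.
#' @export
heterogeneity_summary <- function(calls, exclude_ambiguous = TRUE) {
  x <- filter(calls, .data$arm %in% c("5p", "3p"))
  if (exclude_ambiguous) x <- filter(x, !.data$alphabet_ambiguous)
  if (nrow(x) == 0) abort("no classified reads to summarize")
  x |>
    group_by(.data$arm) |>
    summarise(
      n_reads = sum(.data$count),
      frac_het5 = sum(.data$count[.data$offset5 != 0]) / sum(.data$count),
      frac_het3 = sum(.data$count[.data$offset3 != 0 | .data$nta != ""]) /
        sum(.data$count),
      dominant_seq = {
        o <- order(-.data$count, .data$seq)
        .data$seq[o[1]]
      },
      dominant_offset5 = {
        o <- order(-.data$count, .data$seq)
        .data$offset5[o[1]]
      },
      dominant_offset3 = {
        o <- order(-.data$count, .data$seq)
        .data$offset3[o[1]]
      },
      dominant_nta = {
        o <- order(-.data$count, .data$seq)
        .data$nta[o[1]]
      },
      .groups = "drop"
    )
}
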