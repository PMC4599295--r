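# 3'UTR-loss calling. The annotated UTR is split into a proximal and a
# distal segment (at the annotated proximal polyA site when available,
# else at the midpoint) and loss is called when distal coverage collapses
# relative to proximal coverage, subject to an evidence gate on proximal
# depth. Seed sites starting in a lost distal segment are counted as lost.

#' Segment 3'UTRs into proximal and distal parts
#'
#' Splits at the annotated proximal polyA offset when present, else at the
#' UTR midpoint. UTRs shorter than `min_utr_len` are skipped (too short to
#' segment meaningfully).
#'
#' @param tx transcript-model tibble.
#' @param min_utr_len minimum UTR length to segment (default 40 nt).
#' @return tibble `transcript_id`, `utr_len`, `split` (0-based UTR offset:
#'   proximal is `[0, split)`, distal `[split, utr_len)`), `skipped`,
#'   `skip_reason`.
#' @export
segment_utr <- function(tx, min_utr_len = 40L) {
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    ulen <- sum(tx$utr3[[i]]$end - tx$utr3[[i]]$start)
    if (ulen < min_utr_len) {
      return(tibble(transcript_id = tx$transcript_id[i],
                    utr_len = as.integer(ulen), split = NA_integer_,
                    skipped = TRUE,
                    skip_reason = paste0("3'UTR shorter than ",
                                         min_utr_len, " nt")))
    }
    pp <- tx$proximal_polya[i]
    split <- if (!is.na(pp)) pp else as.integer(ulen %/% 2L)
    tibble(transcript_id = tx$transcript_id[i], utr_len = as.integer(ulen),
           split = as.integer(split), skipped = FALSE,
           skip_reason = NA_character_)
  })
  list_rbind(rows)
}

#' Call 3'UTR loss from per-base coverage
#'
#' The loss statistic is the ratio of mean distal to mean proximal coverage;
#' loss is called when the ratio falls below `tau` and the proximal mean
#' clears the evidence gate `min_proximal`. The ratio is reported even when
#' no call is made. The statistic is scale-invariant in coverage.
#'
#' @param coverage tibble `transcript_id`, `pos` (0-based UTR offset),
#'   `depth`.
#' @param segments [segment_utr()] output.
#' @param tau loss threshold on the distal/proximal ratio (default 0.2).
#' @param min_proximal minimum mean proximal coverage to make a call
#'   (default 10 reads/base).
#' @return tibble `transcript_id`, `proximal_mean`, `distal_mean`, `ratio`,
#'   `call_made`, `loss` (NA when no call).
#' @export
call_utr_loss <- function(coverage, segments, tau = 0.2,
                          min_proximal = 10) {
  seg <- filter(segments, !.data$skipped)
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    tid <- seg$transcript_id[i]
    cv <- filter(coverage, .data$transcript_id == tid)
    if (nrow(cv) == 0) return(NULL)
    split <- seg$split[i]
    pm <- mean(cv$depth[cv$pos < split])
    dm <- mean(cv$depth[cv$pos >= split])
    ratio <- if (pm > 0) dm / pm else NA_real_
    call_made <- pm >= min_proximal
    tibble(transcript_id = tid, proximal_mean = pm, distal_mean = dm,
           ratio = ratio, call_made = call_made,
           loss = if (call_made) ratio < tau else NA)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble(transcript_id = character(0), proximal_mean = numeric(0),
                  distal_mean = numeric(0), ratio = numeric(0),
                  call_made = logical(0), loss = logical(0)))
  }
  list_rbind(rows)
}

#' Two-sample 3'UTR-loss comparison
#'
#' Compares distal/proximal ratios between two conditions (e.g. vector vs
#' over-expression): relative loss is called when the condition-B ratio
#' drops below `tau_rel` times the condition-A ratio.
#'
#' @param calls_a,calls_b [call_utr_loss()] outputs for the two conditions.
#' @param tau_rel relative threshold (default 0.5).
#' @return tibble `transcript_id`, `ratio_a`, `ratio_b`, `rel_ratio`,
#'   `loss_rel`.
#' @export
compare_utr_loss <- function(calls_a, calls_b, tau_rel = 0.5) {
  inner_join(
    select(calls_a, "transcript_id", ratio_a = "ratio"),
    select(calls_b, "transcript_id", ratio_b = "ratio"),
    by = "transcript_id") |>
    mutate(rel_ratio = .data$ratio_b / .data$ratio_a,
           loss_rel = .data$rel_ratio < tau_rel)
}

#' Count retained vs lost seed sites under a 3'UTR-loss call
#'
#' When loss is called, sites starting in the distal segment (0-based
#' position >= split; half-open convention, so a site exactly at the split
#' counts distal) are lost and proximal sites are retained; without loss
#' every site is retained.
#'
#' @param sites seed-site table ([scan_transcriptome()] output).
#' @param loss_calls [call_utr_loss()] output.
#' @param segments [segment_utr()] output.
#' @return tibble `transcript_id`, `mirna`, `total_sites`, `retained`,
#'   `lost`.
#' @export
site_retention <- function(sites, loss_calls, segments) {
  x <- sites |>
    inner_join(select(segments, "transcript_id", "split"),
               by = "transcript_id") |>
    left_join(select(loss_calls, "transcript_id", "loss"),
              by = "transcript_id") |>
    mutate(loss = !is.na(.data$loss) & .data$loss,
           is_lost = .data$loss & .data$utr_position >= .data$split)
  x |>
    group_by(.data$transcript_id, .data$mirna) |>
    summarise(total_sites = n(),
              retained = sum(!.data$is_lost),
              lost = sum(.data$is_lost), .groups = "drop")
}
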