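# Embedded worked example: the published prevalence table of miR-200b-5p and
# miR-200b-3p isomiR reads observed after pri-miR-200b over-expression in
# MDA-MB-231 cells. Sequences are stored verbatim; one 3p row mixes T and U
# and is flagged alphabet-ambiguous rather than silently normalized.

#' IsomiR prevalence fixture for miR-200b (both arms)
#'
#' Returns the embedded read multiset of the miR-200b over-expression worked
#' example: one row per distinct published sequence with its read count,
#' plus the canonical mature sequences for the two arms. Rows that mix DNA
#' and RNA characters are flagged `alphabet_ambiguous` and should be
#' excluded from exact class tallies.
#'
#' @return list with elements
#'   * `reads`: tibble `arm` (published arm), `seq`, `count`,
#'     `alphabet_ambiguous`
#'   * `mature5p`, `mature3p`: canonical mature sequences (RNA)
#' @export
#' @examples
#' fx <- mir200b_fixture()
#' sum(fx$reads$count)
mir200b_fixture <- function() {
  r5 <- c(
    "CAUCUUACUGGGCAGCAUUGGA", 64,
    "CAUCUUCCUGGGCAGCAUUGGA", 1,
    "CACCUUACUGGGCAGCAUUGGA", 1,
    "CAUCUUACUGGGCAGCAUUG", 3,
    "CAUCUUACUGGGCAGCAUUU", 1,
    "CAUCUUACUGGGCAGCAUUGG", 19,
    "CAUCUUACUGGGCAGCAUUGU", 2,
    "CACCUUACUGGGCAGCAUUGG", 1,
    "CAUCUUACUGGGCAGCAUU", 8,
    "CAUCUUACUGGGCAGCAU", 1,
    "CAUCUUACUGGGCAGCAUUGGAU", 11,
    "CAUCUUACUGGGCAGCAUUGGAG", 1,
    "CAUCUUACUGGGCAGCAUUGGAA", 1,
    "CAUCUUACUGGGCAGCAUUGGAUU", 17,
    "CAUCUUACUGGGCAGCAUUGGAUA", 4,
    "CAUCUUACUGGGCAGCAUUGGGUA", 1,
    "AUCUUACUGGGCAGCAUUGGA", 1,
    "AUCUUACUGGGCAGCAUUG", 1,
    "AUCUUACUGGGCAGCAUUGGAU", 6
  )
  r3 <- c(
    "UAAUACUGCCUGGUAAUGAUGA", 3,
    "UAAUACGGCCUGGUAAUGAUGA", 1,
    "UAAUACUGCCUGGUAAUGACGA", 1,
    "UAAUACUGCCUGGUAAAGAUGA", 1,
    "UAAUACUGCCUGGUACUGAUGA", 1,
    "UAAUACUGCCUGGUGCUGAUGA", 1,
    "UGAUACUGCCUGGUAAUGAUGAC", 4,
    "UAAUACUGCCUGGUGAUGAUGAC", 5,
    "UAAUACUGCCUGGUAAUGAGGAC", 2,
    "UAAUACUGCCUGGUAAAGAUGAC", 4,
    "UAAUACUGCCUGGUAAGGAUGAC", 8,
    "UAAUACUGCCUGGUAACGAUGAC", 2,
    "UAAUACUGCCUGGUAGUGAUGAC", 2,
    "UAAUACUGCCUGGUAAUAAUGAC", 1,
    "UAAUACUGCCUGGUACUGAUGAC", 1,
    "UAAUACUGCCUGGUAAGGAUGACA", 1,
    "UAAUACUGCCUGGUAAGGAUGACC", 1,
    "UAAUACUGCCUGGUAGUGAUGACU", 1,
    "UAAUACGGCCUGGUAAUGAUGACU", 1,
    "AAUACUGCCUGGUAUUCAUGACU", 1,
    "AAUACUGCCUGGUAUUCAUGACU", 1,
    "UAAUACUGCCUGGUAAUGAAT", 6,
    "UAAUACUGCCUGGUAAUG", 11,
    "UAAUACUGCCUGGUAAU", 17
  )
  unpack <- function(x, arm) {
    m <- matrix(x, ncol = 2, byrow = TRUE)
    tibble(arm = arm, seq = m[, 1], count = as.integer(m[, 2]))
  }
  reads <- bind_rows(unpack(r5, "5p"), unpack(r3, "3p"))
  reads$alphabet_ambiguous <- is_alphabet_ambiguous(reads$seq)
  list(
    reads = reads,
    mature5p = "CAUCUUACUGGGCAGCAUUGGA",
    mature3p = "UAAUACUGCCUGGUAAUGAUGA"
  )
}

#' miRNA locus for the embedded miR-200b worked example
#'
#' Builds a [mirna_locus()] from the fixture's canonical matures without a
#' precursor annotation, so classification is purely mature-relative (all
#' 3' extensions are treated as additions; no templation is inferred).
#'
#' @return a `mirna_locus` object.
#' @export
mir200b_locus <- function() {
  fx <- mir200b_fixture()
  mirna_locus("hsa-mir-200b", mature5p = fx$mature5p,
              mature3p = fx$mature3p)
}
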