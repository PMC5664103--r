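#' Classify an inserted sequence against a repeat-consensus library
#'
#' Local (Smith–Waterman) alignment of the insert against every consensus
#' in the library and its reverse complement, with BLASTN-like scoring for
#' short queries (+1 match, -1 mismatch, -2 per gapped base by default).
#' Identity is computed over aligned columns excluding gaps, i.e. the
#' "matches / aligned bp" convention. Hits are returned best-score first;
#' an empty result (with a warning) is returned for inserts shorter than
#' the word size.
#'
#' @param insert_seq The inserted sequence to classify.
#' @param library A consensus panel as returned by [l1_panel()], or a path
#'   to a FASTA file of consensus sequences.
#' @param min_score Minimum alignment score to report.
#' @param match,mismatch,gap Scoring parameters (gap is the per-base
#'   linear gap penalty, given as a positive number).
#' @param word_size Inserts shorter than this yield an empty result.
#' @return A tibble with one row per hit: `family`, `score`, `identity`,
#'   `matches`, `aligned_len`, `insert_start`, `insert_end`,
#'   `consensus_start`, `consensus_end`, `strand`. Insert spans are 1-based
#'   closed coordinates on the insert as given (strand `-` spans are
#'   reported on the plus strand of the insert).
#' @export
classify_insert <- function(insert_seq, library = l1_panel(), min_score = 20,
                            match = 1, mismatch = -1, gap = 2, word_size = 8L) {
  check_dna(insert_seq)
  if (is.character(library) && length(library) == 1L) library <- l1_panel(fasta = library)
  if (!length(library)) abort_exz("empty consensus library", "exz_bad_input")
  empty <- tibble::tibble(family = character(0), score = numeric(0),
                          identity = numeric(0), matches = integer(0),
                          aligned_len = integer(0), insert_start = integer(0),
                          insert_end = integer(0), consensus_start = integer(0),
                          consensus_end = integer(0), strand = character(0))
  if (nchar(insert_seq) < word_size) {
    warning(sprintf("insert shorter than word size (%d); no classification attempted", word_size))
    return(empty)
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = TRUE)
  n <- nchar(insert_seq)
  rows <- list()
  for (fam in names(library)) {
    cons <- library[[fam]]$seq
    for (strand in c("+", "-")) {
      qry <- if (strand == "+") insert_seq else revcomp(insert_seq)
      aln <- Biostrings::pairwiseAlignment(qry, cons, type = "local",
                                           substitutionMatrix = submat,
                                           gapOpening = 0, gapExtension = gap)
      sc <- Biostrings::score(aln)
      if (sc < min_score) next
      nm <- Biostrings::nmatch(aln)
      nmm <- Biostrings::nmismatch(aln)
      qs <- Biostrings::start(Biostrings::pattern(aln))
      qe <- Biostrings::end(Biostrings::pattern(aln))
      if (strand == "-") { tmp <- qs; qs <- n - qe + 1L; qe <- n - tmp + 1L }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = fam, score = sc,
        identity = nm / (nm + nmm), matches = nm, aligned_len = nm + nmm,
        insert_start = qs, insert_end = qe,
        consensus_start = Biostrings::start(Biostrings::subject(aln)),
        consensus_end = Biostrings::end(Biostrings::subject(aln)),
        strand = strand)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$score), , drop = FALSE]
}
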