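#' Find sense-strand open reading frames
#'
#' Enumerates every ATG-to-stop ORF of at least `min_aa` codons (stop
#' excluded) in the three sense frames — each ATG is extended to the first
#' in-frame stop — then greedily resolves the candidates to a maximal
#' non-overlapping set by decreasing length (ties broken by start
#' position). For an intact L1-like element this yields exactly the two
#' hallmark ORFs: ORF1 (RNA-binding protein) and ORF2 (endonuclease +
#' reverse transcriptase).
#'
#' @param seq Element (or any) DNA sequence.
#' @param min_aa Minimum ORF length in amino acids (>= 1), stop excluded.
#' @return A tibble with `start`, `end` (1-based closed, including the
#'   stop codon), `frame` (1-3) and `length_aa`, ordered by `start`.
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  check_dna(seq)
  if (min_aa < 1L) abort_exz("`min_aa` must be >= 1", "exz_bad_input")
  n <- nchar(seq)
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          frame = integer(0), length_aa = integer(0))
  if (n < (min_aa + 1L) * 3L) return(empty)
  v <- strsplit(seq, "")[[1]]
  cand <- list()
  for (f in 1:3) {
    idx <- seq.int(f, n - 2L, by = 3L)
    if (!length(idx)) next
    cod <- paste0(v[idx], v[idx + 1L], v[idx + 2L])
    atg <- which(cod == "ATG")
    stp <- which(cod %in% c("TAA", "TAG", "TGA"))
    if (!length(atg) || !length(stp)) next
    nxt <- stp[findInterval(atg, stp) + 1L]   # first stop strictly after each ATG
    ok <- !is.na(nxt)
    aa <- nxt - atg
    keep <- ok & aa >= min_aa
    if (!any(keep)) next
    cand[[f]] <- data.frame(start = idx[atg[keep]],
                            end = idx[nxt[keep]] + 2L,
                            frame = f, length_aa = aa[keep])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand <- cand[order(-cand$length_aa, cand$start), , drop = FALSE]
  kept <- logical(0); ks <- integer(0); ke <- integer(0)
  pick <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= ke & cand$end[i] >= ks)) {
      pick[i] <- TRUE
      ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
    }
  }
  out <- cand[pick, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Annotate L1 hallmark architecture of an element sequence
#'
#' Decides the five structural hallmarks of a full-length L1: a 5'UTR
#' (sequence upstream of ORF1), two non-overlapping ORFs whose lengths are
#' within `orf_tol` of the matched consensus ORFs, a 3'UTR between the
#' ORF2 stop and the poly-A tail, and the tail itself. `full_length`
#' requires all five.
#'
#' @param seq Element sequence.
#' @param orfs Optional precomputed [find_orfs()] table.
#' @param polyA_len Optional known poly-A length; measured with
#'   [detect_polyA()] if `NULL`.
#' @param panel Consensus panel used for subfamily assignment and for the
#'   expected ORF lengths.
#' @param min_utr Minimum length, in nt, for a UTR to be called present.
#' @param orf_tol Relative ORF-length tolerance against the consensus.
#' @param min_aa Passed to [find_orfs()].
#' @return An object of class `element_annotation`: list with `orfs`,
#'   `hallmark_flags` (named logical: `has_5UTR`, `has_ORF1`, `has_ORF2`,
#'   `has_3UTR`, `has_polyA`), `full_length`, `subfamily`,
#'   `subfamily_identity`, `polyA_len` and `domains` (schematic
#'   proportional sub-spans of the hallmark ORFs: CC/RRM/CTD on ORF1,
#'   EN/Z/RT/C on ORF2 — reported as fixed fractions of the matched ORFs,
#'   not motif hits).
#' @export
annotate_structure <- function(seq, orfs = NULL, polyA_len = NULL,
                               panel = l1_panel(), min_utr = 20L,
                               orf_tol = 0.05, min_aa = 100L) {
  check_dna(seq)
  if (is.null(orfs)) orfs <- find_orfs(seq, min_aa = min_aa)
  if (is.null(polyA_len)) polyA_len <- detect_polyA(seq)
  sf <- assign_subfamily(seq, panel)
  cons <- panel[[sf$subfamily]]
  cons_orf <- cons$features[cons$features$feature %in% c("ORF1", "ORF2"), ]
  expect_len <- setNames(cons_orf$end - cons_orf$start + 1L, cons_orf$feature)

  match_orf <- function(nm) {
    if (!nm %in% names(expect_len) || !nrow(orfs)) return(NA_integer_)
    want <- expect_len[[nm]]
    d <- abs((orfs$end - orfs$start + 1L) - want) / want
    i <- which.min(d)
    if (d[i] <= orf_tol) i else NA_integer_
  }
  i1 <- match_orf("ORF1"); i2 <- match_orf("ORF2")
  if (!is.na(i1) && !is.na(i2)) {
    if (orfs$start[i1] >= orfs$start[i2]) { i1 <- NA_integer_ }  # ORF1 must precede ORF2
  }
  flags <- c(has_5UTR = !is.na(i1) && orfs$start[i1] - 1L >= min_utr,
             has_ORF1 = !is.na(i1),
             has_ORF2 = !is.na(i2),
             has_3UTR = !is.na(i2) &&
               (nchar(seq) - polyA_len) - orfs$end[i2] >= min_utr,
             has_polyA = polyA_len > 0L)
  domains <- schematic_domains(orfs, i1, i2)
  structure(list(orfs = orfs, hallmark_flags = flags,
                 full_length = all(flags), subfamily = sf$subfamily,
                 subfamily_identity = sf$identity,
                 polyA_len = as.integer(polyA_len), domains = domains),
            class = "element_annotation")
}

# schematic (proportional) protein-domain sub-spans; labelled as such
schematic_domains <- function(orfs, i1, i2) {
  prop_spans <- function(s, e, names, fracs) {
    b <- s + round((e - s + 1L) * cumsum(c(0, fracs[-length(fracs)])))
    data.frame(domain = names, start = as.integer(b),
               end = as.integer(c(b[-1] - 1L, e)), basis = "schematic")
  }
  out <- NULL
  if (!is.na(i1))
    out <- rbind(out, prop_spans(orfs$start[i1], orfs$end[i1],
                                 c("CC", "RRM", "CTD"), c(0.35, 0.35, 0.30)))
  if (!is.na(i2))
    out <- rbind(out, prop_spans(orfs$start[i2], orfs$end[i2],
                                 c("EN", "Z", "RT", "C"), c(0.20, 0.10, 0.55, 0.15)))
  if (is.null(out)) data.frame(domain = character(0), start = integer(0),
                               end = integer(0), basis = character(0))
  else out
}

#' @export
print.element_annotation <- function(x, ...) {
  f <- x$hallmark_flags
  cat(sprintf("<element_annotation> subfamily %s (identity %.3f); hallmarks: %s; full_length=%s\n",
              x$subfamily, x$subfamily_identity,
              paste(names(f)[f], collapse = ","), x$full_length))
  invisible(x)
}

#' Assign an element to its nearest consensus subfamily
#'
#' Global-alignment identity of the element (terminal poly-A trimmed)
#' against each panel consensus; equal-length comparisons use a direct
#' column-wise identity, shorter (5'-truncated) queries a global-local
#' alignment. Ties are broken alphabetically and flagged.
#'
#' @param seq Element sequence.
#' @param panel Consensus panel ([l1_panel()]).
#' @return A list with `subfamily`, `identity`, `tie` (logical) and the
#'   full `identities` vector.
#' @export
assign_subfamily <- function(seq, panel = l1_panel()) {
  check_dna(seq)
  if (!length(panel)) abort_exz("empty consensus panel", "exz_bad_input")
  q <- sub("A+$", "", seq)
  ids <- vapply(panel, function(entry) {
    cons <- entry$seq
    if (nchar(q) == nchar(cons)) {
      mean(charToRaw(q) == charToRaw(cons))
    } else {
      aln <- Biostrings::pairwiseAlignment(
        q, cons, type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE),
        gapOpening = 4, gapExtension = 1)
      nm <- Biostrings::nmatch(aln)
      nm / (nm + Biostrings::nmismatch(aln))
    }
  }, numeric(1))
  best <- max(ids)
  hits <- sort(names(ids)[ids == best])
  list(subfamily = hits[1L], identity = unname(best),
       tie = length(hits) > 1L, identities = ids)
}
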