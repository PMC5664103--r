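#' Discover a transcript insertion by comparison with the reference mRNA
#'
#' Delimits a single contiguous insertion in an observed transcript. The
#' scan computes, for every possible insertion point `p`, the number of
#' substitutions needed to explain the observed sequence as
#' `ref[1..p] + insert + ref[p+1..n]`, using cumulative prefix/suffix
#' mismatch counts (O(n) overall). With `max_subs = 0` this reduces to
#' longest-common-prefix/suffix anchoring. When the insertion is flanked by
#' repeats of itself the placement is ambiguous; the insertion is
#' normalized to the leftmost placement internally, and the rightmost
#' (3'-most) placement is kept alongside for HGVS output, following
#' nomenclature convention.
#'
#' @param ref_mrna Reference mRNA sequence.
#' @param observed Observed transcript sequence.
#' @param model Optional [make_gene_model()] object; when given, the exon
#'   indices flanking the insertion are reported.
#' @param max_subs Maximum number of isolated substitutions tolerated in
#'   addition to the single insertion (default 2).
#' @return An object of class `transcript_insertion`: list with `left_pos`
#'   (last matching mRNA base before the insert, leftmost placement),
#'   `right_pos` (3'-most placement), `insert_seq`, `insert_len`,
#'   `left_exon`/`right_exon` (or `NA`), `wt_detected`, `n_subs`, and
#'   `prefix`/`element_part` placeholders filled by [split_insert()].
#'   Equal sequences yield an empty insertion with `wt_detected = TRUE`.
#' @examples
#' ti <- find_insertion("ACGTACGT", "ACGTTTACGT")
#' ti$insert_seq  # "TT" after position 4
#' @export
find_insertion <- function(ref_mrna, observed, model = NULL, max_subs = 2L) {
  check_dna(ref_mrna); check_dna(observed)
  n <- nchar(ref_mrna)
  L <- nchar(observed) - n
  if (L < 0L)
    abort_exz("observed transcript is shorter than the reference (not a simple insertion)",
              "exz_not_simple_insertion")

  if (L == 0L) {
    same <- identical(ref_mrna, observed)
    if (!same) {
      d <- sum(charToRaw(ref_mrna) != charToRaw(observed))
      if (d > max_subs)
        abort_exz(sprintf("sequences differ at %d positions with no length change (not a simple insertion)", d),
                  "exz_not_simple_insertion")
    }
    return(new_transcript_insertion(0L, 0L, "", model, wt = same,
                                    n_subs = if (same) 0L else
                                      sum(charToRaw(ref_mrna) != charToRaw(observed))))
  }

  ro <- charToRaw(observed); rr <- charToRaw(ref_mrna)
  pref <- cumsum(ro[seq_len(n)] != rr)                     # mismatches of obs[1..p] vs ref[1..p]
  tailv <- as.integer(ro[(L + 1L):(L + n)] != rr)          # obs[p+L] vs ref[p]
  suff <- rev(cumsum(rev(tailv)))                          # mismatches for positions p..n
  tot <- c(0, pref) + c(suff, 0)                           # index p+1 <-> insertion after p
  best <- min(tot)
  if (best > max_subs)
    abort_exz(sprintf("no single-insertion placement with <= %d substitutions (best needs %d); not a simple insertion",
                      max_subs, best),
              "exz_not_simple_insertion", best = best)
  hits <- which(tot == best) - 1L
  p_left <- hits[1L]; p_right <- hits[length(hits)]

  ti <- new_transcript_insertion(p_left, p_right,
                                 substr_(observed, p_left + 1L, p_left + L),
                                 model, wt = FALSE, n_subs = as.integer(best),
                                 insert_3p = substr_(observed, p_right + 1L, p_right + L))
  # reconstruction invariant, asserted on every call
  rec <- paste0(substr_(ref_mrna, 1L, p_left), ti$insert_seq,
                substr_(ref_mrna, p_left + 1L, n))
  if (best == 0L) stopifnot(identical(rec, observed))
  else stopifnot(sum(charToRaw(rec) != charToRaw(observed)) == best)
  ti
}

new_transcript_insertion <- function(p_left, p_right, insert_seq, model,
                                     wt, n_subs, insert_3p = insert_seq) {
  le <- re <- NA_integer_
  if (!is.null(model) && nchar(insert_seq)) {
    # exon flanks follow the 3'-most placement (the convention used for HGVS
    # and for naming the flanking exons of a boundary insertion)
    cum <- cumsum(model$exons$end - model$exons$start + 1L)
    le <- findInterval(p_right, cum + 1L) + 1L
    if (p_right %in% cum) re <- le + 1L else re <- le
  }
  structure(list(left_pos = as.integer(p_left), right_pos = as.integer(p_right),
                 insert_seq = insert_seq, insert_seq_3p = insert_3p,
                 insert_len = nchar(insert_seq),
                 left_exon = le, right_exon = re,
                 prefix = NA_character_, element_part = NA_character_,
                 wt_detected = wt, n_subs = n_subs),
            class = "transcript_insertion")
}

#' @export
print.transcript_insertion <- function(x, ...) {
  if (x$insert_len == 0L)
    cat(sprintf("<transcript_insertion> no insertion (wt_detected=%s)\n", x$wt_detected))
  else
    cat(sprintf("<transcript_insertion> %d nt after mRNA position %d (exons %s/%s), %d substitution(s)\n",
                x$insert_len, x$right_pos, x$left_exon, x$right_exon, x$n_subs))
  invisible(x)
}

#' Classify several observed transcripts against the reference mRNA
#'
#' Runs [find_insertion()] independently on each observed transcript and
#' aggregates wild-type detection: `wt_detected` is `TRUE` on every result
#' if any input equals the reference.
#'
#' @param ref_mrna Reference mRNA.
#' @param observed Character vector of observed transcript sequences.
#' @inheritParams find_insertion
#' @return A list of `transcript_insertion` objects.
#' @export
classify_transcripts <- function(ref_mrna, observed, model = NULL, max_subs = 2L) {
  res <- lapply(observed, function(o) find_insertion(ref_mrna, o, model, max_subs))
  any_wt <- any(vapply(res, `[[`, logical(1), "wt_detected"))
  lapply(res, function(r) { r$wt_detected <- any_wt; r })
}

#' Split an insert into retained-intron prefix and element-derived part
#'
#' The repeat hit supplies the insert-side span matched to the element
#' consensus; bases 5' of the matched span are the retained-intron prefix
#' (possibly empty). If the matched span is not terminal on the 3' side a
#' `retained_suffix` flag is set (possible retained intronic suffix), and
#' both parts are still returned (the element part then includes the
#' unmatched 3' tail).
#'
#' For a `transcript_insertion` the split is applied to the 3'-shifted
#' representation of the insert (`insert_seq_3p`), the same representation
#' used for HGVS output and exon naming, so the prefix corresponds to the
#' intronic bases sitting immediately 5' of the element in the mature
#' transcript.
#'
#' @param ti A `transcript_insertion` (or a plain insert sequence string).
#' @param element_hit One row of a [classify_insert()] result (needs
#'   `insert_start`/`insert_end`).
#' @return The `transcript_insertion` with `prefix` and `element_part`
#'   filled (or, for a string input, a list with those fields) and
#'   attribute `retained_suffix`.
#' @export
split_insert <- function(ti, element_hit) {
  ins <- if (inherits(ti, "transcript_insertion")) ti$insert_seq_3p else check_dna(ti)
  s <- as.integer(element_hit$insert_start)
  e <- as.integer(element_hit$insert_end)
  if (is.na(s) || s < 1L || e > nchar(ins))
    abort_exz("element hit span outside the insert", "exz_bad_input")
  prefix <- substr_(ins, 1L, s - 1L)
  element_part <- substr_(ins, s, nchar(ins))
  retained_suffix <- e < nchar(ins)
  if (retained_suffix)
    warning("element match is not 3'-terminal on the insert; possible retained intronic suffix")
  if (inherits(ti, "transcript_insertion")) {
    ti$prefix <- prefix; ti$element_part <- element_part
    attr(ti, "retained_suffix") <- retained_suffix
    stopifnot(identical(paste0(ti$prefix, ti$element_part), ti$insert_seq_3p))
    ti
  } else {
    structure(list(prefix = prefix, element_part = element_part),
              retained_suffix = retained_suffix)
  }
}

#' HGVS r. description of a transcript insertion
#'
#' Emits `r.<L>_<L+1>ins(<N>)` with `L` in CDS-based numbering, using the
#' 3'-most placement of an ambiguous insertion (HGVS 3' rule). Insertions
#' upstream of the CDS start use the standard negative-offset numbering and
#' carry a `upstream_of_cds` attribute.
#'
#' @param ti A `transcript_insertion`.
#' @param model The gene model supplying the CDS anchor.
#' @return The HGVS string, or `NULL` for an empty insertion.
#' @export
to_hgvs_r <- function(ti, model) {
  if (ti$insert_len == 0L) return(NULL)
  cpos <- function(p) {
    cp <- p - model$cds_start_mrna + 1L
    if (cp <= 0L) cp - 1L else cp   # no position 0 in HGVS numbering
  }
  l <- cpos(ti$right_pos)
  r <- cpos(ti$right_pos + 1L)
  s <- sprintf("r.%d_%dins(%d)", l, r, ti$insert_len)
  if (l < 0L) attr(s, "upstream_of_cds") <- TRUE
  s
}
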