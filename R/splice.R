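#' Scan an intron for AG + prefix cryptic-acceptor motifs
#'
#' Finds every sense-strand occurrence of the motif `AG` followed by
#' `prefix` — the signature of a cryptic 3' acceptor site that would retain
#' `prefix` in the mature transcript. IUPAC ambiguity codes in `prefix`
#' are expanded per the IUPAC convention. Overlapping occurrences are all
#' reported, in order.
#'
#' @param intron_seq Intron sequence (sense strand).
#' @param prefix The retained-prefix query (non-empty).
#' @return A tibble with one row per candidate: `intron_offset` (1-based
#'   position, within the intron, of the first base after the AG),
#'   `motif_seq` (the matched prefix bases), and placeholder scoring
#'   columns (`acceptor_score`, `bp_offset`, `bp_score`, `composite_pass`)
#'   filled by [score_candidates()].
#' @examples
#' scan_motif("TTAGAATTCGGAGAATTC", "AATTC")
#' @export
scan_motif <- function(intron_seq, prefix) {
  check_dna(intron_seq)
  check_dna(prefix, allow_iupac = TRUE)
  if (!nchar(prefix)) abort_exz("`prefix` must be non-empty", "exz_bad_input")
  motif <- paste0("AG", prefix)
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(intron_seq),
                                   fixed = FALSE)
  off <- Biostrings::start(hits) + 2L
  tibble::tibble(intron_offset = off,
                 motif_seq = if (length(off))
                   substring(intron_seq, off, off + nchar(prefix) - 1L)
                 else character(0),
                 acceptor_score = NA_real_, bp_offset = NA_integer_,
                 bp_score = NA_real_, composite_pass = NA)
}

#' Score a 3' acceptor-site context window
#'
#' Log-odds sum of a `-20..+3` window around a putative 3' splice site
#' under the packaged acceptor position weight matrix (see
#' [acceptor_pwm()]); higher scores indicate stronger acceptors. The window
#' must cover positions -20..-1 (intron, ending with the AG) followed by
#' +1..+3 (exon); characters other than ACGT (e.g. `N` padding at sequence
#' ends) contribute the background score 0 and set a `padded` attribute.
#'
#' @param context A window of width `ncol(pwm)` (23 by default).
#' @param pwm Log-odds matrix (defaults to the bundled acceptor matrix).
#' @return The log2-odds score (with attribute `padded` if applicable).
#' @export
score_acceptor <- function(context, pwm = acceptor_pwm()) {
  if (nchar(context) != ncol(pwm))
    abort_exz(sprintf("acceptor context must be %d nt", ncol(pwm)), "exz_bad_input")
  s <- pwm_score_many(context, pwm)
  if (grepl("[^ACGT]", context)) attr(s, "padded") <- TRUE
  s
}

#' Locate the best branch-point candidate in an upstream window
#'
#' Scans every 5-mer of the window with the branch-point weight matrix
#' (consensus yUnAy, branch adenosine at matrix position 4) and returns the
#' best-scoring candidate at or above `min_score`, or `NULL`. Windows
#' shorter than the motif yield `NULL`.
#'
#' @param upstream The sequence window upstream of a candidate acceptor.
#' @param pwm Branch-point log-odds matrix.
#' @param min_score Minimum reportable score; defaults to 70% of the
#'   matrix maximum.
#' @return `NULL`, or a list with `offset` (position of the branch A
#'   counted from the 3' end of the window; 1 = last base) and `score`.
#' @export
find_branchpoint <- function(upstream, pwm = branchpoint_pwm(), min_score = NULL) {
  check_dna(upstream, allow_iupac = TRUE)
  w <- ncol(pwm)
  n <- nchar(upstream)
  if (n < w) return(NULL)
  if (is.null(min_score)) min_score <- 0.7 * pwm_max_score(pwm)
  starts <- seq_len(n - w + 1L)
  sc <- pwm_score_many(substring(upstream, starts, starts + w - 1L), pwm)
  # require an actual adenosine at the branch position
  sc[substring(upstream, starts + 3L, starts + 3L) != "A"] <- -Inf
  best <- which.max(sc)
  if (sc[best] < min_score) return(NULL)
  a_pos <- starts[best] + 3L
  list(offset = n - a_pos + 1L, score = sc[best])
}

#' Score acceptor strength and branch-point context for scanned candidates
#'
#' Completes the "composite splice-site analysis" columns of a
#' [scan_motif()] table: for each candidate the acceptor window
#' (-20..+3 around the junction; off-end windows are N-padded) is scored
#' against the acceptor PWM, and the best branch-point within
#' `bp_min..bp_max` nt upstream of the junction is recorded. `bp_offset`
#' is reported as the distance from the branch adenosine to the cryptic
#' junction (the first retained base).
#'
#' @param intron_seq The intron that was scanned.
#' @param cands A [scan_motif()] tibble.
#' @param apwm,bpwm Acceptor / branch-point matrices.
#' @param bp_min,bp_max Branch-point search interval (nt upstream of the
#'   junction), standard human spliceosome geometry by default.
#' @return `cands` with `acceptor_score`, `bp_offset`, `bp_score` filled.
#' @export
score_candidates <- function(intron_seq, cands, apwm = acceptor_pwm(),
                             bpwm = branchpoint_pwm(), bp_min = 18L, bp_max = 44L) {
  if (!nrow(cands)) return(cands)
  n <- nchar(intron_seq)
  w <- ncol(apwm)
  n_up <- w - 3L   # intronic positions in the window
  win <- vapply(cands$intron_offset, function(o) {
    s <- o - n_up; e <- o + 2L
    raw <- substr_(intron_seq, max(1L, s), min(n, e))
    paste0(strrep("N", max(0L, 1L - s)), raw, strrep("N", max(0L, e - n)))
  }, character(1))
  cands$acceptor_score <- pwm_score_many(win, apwm)
  wb <- ncol(bpwm)
  for (i in seq_len(nrow(cands))) {
    o <- cands$intron_offset[i]
    s <- max(1L, o - bp_max - 3L)               # leftmost 5-mer start so branch A >= o - bp_max
    e <- min(n, o - bp_min + (wb - 4L))         # rightmost base so branch A <= o - bp_min
    if (e - s + 1L < wb) next
    hit <- find_branchpoint(substr_(intron_seq, s, e), pwm = bpwm, min_score = -Inf)
    if (is.null(hit)) next
    a_abs <- e - hit$offset + 1L
    cands$bp_offset[i] <- o - a_abs
    cands$bp_score[i] <- hit$score
  }
  cands
}

#' Composite filtering and ranking of cryptic-acceptor candidates
#'
#' A candidate passes the composite filter when its acceptor score reaches
#' `t1` and a branch point scoring at least `t2` lies in the upstream
#' search window — mirroring the "high splice-site score plus suitable
#' nearby branch point" narrowing logic used when prioritizing candidate
#' cryptic sites. Passing candidates are returned sorted by acceptor score
#' and truncated at `k`.
#'
#' @param cands A scored candidate table ([score_candidates()]); unscored
#'   tables are scored first if `intron_seq` is supplied.
#' @param k Maximum number of candidates returned (default all).
#' @param t1 Acceptor-score threshold; default 60% of the matrix maximum.
#' @param t2 Branch-point threshold; default 70% of the matrix maximum.
#' @param intron_seq Optional intron sequence for on-the-fly scoring.
#' @param apwm,bpwm Matrices used for defaults and optional scoring.
#' @return The passing candidates, `composite_pass = TRUE`, sorted by
#'   `acceptor_score` (descending), at most `k` rows.
#' @export
rank_candidates <- function(cands, k = Inf, t1 = NULL, t2 = NULL,
                            intron_seq = NULL, apwm = acceptor_pwm(),
                            bpwm = branchpoint_pwm()) {
  if (nrow(cands) && all(is.na(cands$acceptor_score))) {
    if (is.null(intron_seq))
      abort_exz("candidates are unscored; supply `intron_seq` or run score_candidates()",
                "exz_bad_input")
    cands <- score_candidates(intron_seq, cands, apwm, bpwm)
  }
  if (is.null(t1)) t1 <- 0.6 * pwm_max_score(apwm)
  if (is.null(t2)) t2 <- 0.7 * pwm_max_score(bpwm)
  cands$composite_pass <- cands$acceptor_score >= t1 &
    !is.na(cands$bp_score) & cands$bp_score >= t2
  out <- cands[cands$composite_pass, , drop = FALSE]
  out <- out[order(-out$acceptor_score), , drop = FALSE]
  head(out, n = if (is.finite(k)) as.integer(k) else nrow(out))
}
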