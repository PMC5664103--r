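#' Map element junctions in an insertion-allele genomic sequence
#'
#' Anchors the allele against the reference locus by longest common
#' prefix/suffix to delimit the single inserted block. When the insertion
#' carries a target-site duplication the two anchors disagree by exactly
#' the duplication length (the block can be slid across the duplicated
#' target); both extreme placements are reported, with the leftmost used
#' for the block sequence and the rightmost taken as the insertion point
#' (the case-report-style coordinate, i.e. the last reference base 5' of the
#' element in the TSD-resolved orientation). Orientation is determined by
#' k-mer votes of the block interior against the consensus panel and its
#' reverse complement.
#'
#' @param allele_seq Insertion-allele genomic sequence.
#' @param ref_locus Reference genomic sequence of the same locus.
#' @param panel Consensus panel for orientation calls (a [l1_panel()] list,
#'   a single sequence string, or `NULL` to skip orientation).
#' @return A list with `pos5`/`pos3` (both equal to the rightmost anchor:
#'   a clean TPRT insertion has a single target site), `p_left`/`p_right`
#'   (extreme anchor placements; their difference is the junction-homology
#'   width, i.e. the TSD length for a clean insertion), `ins_len`, `block`
#'   (inserted sequence at the leftmost placement), and `orientation`
#'   (`"sense"`, `"antisense"` or `NA`).
#' @export
map_junctions <- function(allele_seq, ref_locus, panel = l1_panel()) {
  check_dna(allele_seq); check_dna(ref_locus)
  n <- nchar(ref_locus)
  L <- nchar(allele_seq) - n
  if (L < 0L)
    abort_exz("allele is shorter than the reference (not a simple insertion)",
              "exz_not_simple_insertion")
  if (L == 0L) {
    if (!identical(allele_seq, ref_locus))
      abort_exz("equal-length sequences differ (substitution or rearrangement, not a simple insertion)",
                "exz_not_simple_insertion")
    return(list(pos5 = NA_integer_, pos3 = NA_integer_, p_left = NA_integer_,
                p_right = NA_integer_, ins_len = 0L, block = "",
                orientation = NA_character_))
  }
  p_right <- min(lcp_len(allele_seq, ref_locus), n)
  p_left <- n - min(lcs_len(allele_seq, ref_locus), n)
  if (p_left > p_right)
    abort_exz("prefix/suffix anchors overlap inconsistently (more than one difference; not a simple insertion)",
              "exz_not_simple_insertion")
  block <- substr_(allele_seq, p_left + 1L, p_left + L)
  orientation <- orient_block(block, panel)
  list(pos5 = p_right, pos3 = p_right, p_left = p_left, p_right = p_right,
       ins_len = L, block = block, orientation = orientation)
}

# orientation by k-mer votes of the block interior against the panel
orient_block <- function(block, panel, k = 21L, max_samples = 60L) {
  if (is.null(panel)) return(NA_character_)
  if (is.character(panel)) panel <- list(list(seq = check_dna(panel)))
  core <- sub("^[AT]{5,}", "", sub("[AT]{5,}$", "", block))  # drop terminal poly-A/T
  if (nchar(core) < k) return(NA_character_)
  starts <- unique(round(seq(1L, nchar(core) - k + 1L,
                             length.out = min(max_samples, nchar(core) - k + 1L))))
  kmers <- substring(core, starts, starts + k - 1L)
  kmers <- kmers[!grepl("^[AT]+$", kmers)]
  if (!length(kmers)) return(NA_character_)
  sense <- 0L; anti <- 0L
  for (entry in panel) {
    subj <- Biostrings::DNAString(entry$seq)
    subj_rc <- Biostrings::reverseComplement(subj)
    for (km in kmers) {
      if (Biostrings::countPattern(km, subj) > 0L) sense <- sense + 1L
      if (Biostrings::countPattern(km, subj_rc) > 0L) anti <- anti + 1L
    }
  }
  if (sense == 0L && anti == 0L) return(NA_character_)
  if (sense >= anti) "sense" else "antisense"
}

#' Detect a target-site duplication at an insertion junction
#'
#' Returns the largest `k <= max_len` such that the `k`-suffix of the left
#' junction equals the `k`-prefix of the right junction. When the
#' reference context of the insertion point is supplied, a candidate `k`
#' is additionally required to correspond to a single target copy in the
#' reference: the duplicated `k`-mer must be the reference `k`-mer ending
#' at the insertion point and must not be immediately repeated after it
#' (which would indicate a pre-existing tandem copy rather than a
#' TPRT duplication).
#'
#' @param left_junction Allele bases immediately 5' of the inserted block
#'   (length >= `max_len`).
#' @param right_junction Allele bases immediately 3' of the block.
#' @param max_len Maximum duplication length considered (default 30, the
#'   upper end of the 7-20 bp range typical of L1 endonuclease targets,
#'   with margin).
#' @param ref_point Optional list `list(ref = <reference sequence>,
#'   pos = <insertion point>)` enabling the single-target-copy check.
#' @return A list with `tsd_seq` and `tsd_len` (`k = 0` gives `""`/`0`).
#' @export
detect_tsd <- function(left_junction, right_junction, max_len = 30L,
                       ref_point = NULL) {
  check_dna(left_junction); check_dna(right_junction)
  kmax <- min(max_len, nchar(left_junction), nchar(right_junction))
  for (k in rev(seq_len(kmax))) {
    kmer <- substr_(left_junction, nchar(left_junction) - k + 1L, nchar(left_junction))
    if (!identical(kmer, substr_(right_junction, 1L, k))) next
    if (!is.null(ref_point)) {
      ref <- ref_point$ref; pos <- ref_point$pos
      at_target <- identical(kmer, substr_(ref, pos - k + 1L, pos))
      tandem <- identical(kmer, substr_(ref, pos + 1L, pos + k))
      if (!at_target || tandem) next
    }
    return(list(tsd_seq = kmer, tsd_len = k))
  }
  list(tsd_seq = "", tsd_len = 0L)
}

#' Measure a 3'-terminal poly-A tail
#'
#' Length of the longest terminal window that starts and ends with `A`,
#' has an A-fraction of at least `purity`, contains no two consecutive
#' non-A bases, and is at least `min_len` long; 0 otherwise. Isolated
#' non-A bases inside a long tail (sequencing errors, post-insertion
#' substitutions) are tolerated, while a block of flanking non-A sequence
#' stops the tail even when a high A-fraction window could absorb it.
#'
#' @param element_3prime Element sequence read 5'->3', ending at the 3'
#'   junction.
#' @param min_len Minimum reportable tail length.
#' @param purity Minimum A-fraction of the reported window.
#' @return Integer tail length.
#' @examples
#' detect_polyA(paste0("GATC", strrep("A", 20)))  # 20
#' @export
detect_polyA <- function(element_3prime, min_len = 5L, purity = 0.9) {
  check_dna(element_3prime)
  n <- nchar(element_3prime)
  if (!n) return(0L)
  v <- rev(strsplit(element_3prime, "")[[1]] == "A")  # v[w]: base w from the end
  if (!v[1L]) return(0L)
  frac <- cumsum(v) / seq_len(n)
  cap <- n
  if (n > 1L) {
    pair <- which(!v[-1L] & !v[-n]) + 1L   # w with v[w] and v[w-1] both non-A
    if (length(pair)) cap <- pair[1L] - 1L
  }
  ok <- which(v & frac >= purity & seq_len(n) >= min_len & seq_len(n) <= cap)
  if (!length(ok)) 0L else max(ok)
}

#' Full junction call for an insertion allele
#'
#' Composes [map_junctions()], TSD resolution and poly-A detection into a
#' complete junction call. The TSD is taken as the junction-homology width
#' (the distance between the extreme anchor placements, capped at
#' `max_tsd`), cross-checked against [detect_tsd()] on the junction
#' sequences; the element sequence is the inserted block minus the TSD
#' copy, reverse-complemented for antisense insertions before poly-A
#' measurement.
#'
#' @param allele_seq Insertion-allele sequence.
#' @param model Reference [make_gene_model()].
#' @param panel Consensus panel (orientation and subfamily context).
#' @param max_tsd Maximum TSD length considered.
#' @param polyA_min,polyA_purity Poly-A detection parameters.
#' @return An object of class `junction_call`: list with `pos5`, `pos3`,
#'   `tsd_seq`, `tsd_len`, `polyA_len`, `element_len`, `element_seq`,
#'   `orientation`, `intron_index`, `hgvs_c`, `ambiguity`
#'   (`c(p_left, p_right)`).
#' @export
call_junctions <- function(allele_seq, model, panel = l1_panel(),
                           max_tsd = 30L, polyA_min = 5L, polyA_purity = 0.9) {
  validate_gene_model(model)
  ref <- model$genomic_seq
  mj <- map_junctions(allele_seq, ref, panel)
  if (mj$ins_len == 0L) {
    return(structure(list(pos5 = NA_integer_, pos3 = NA_integer_, tsd_seq = "",
                          tsd_len = 0L, polyA_len = 0L, element_len = 0L,
                          element_seq = "", orientation = NA_character_,
                          intron_index = NA_integer_, hgvs_c = NULL,
                          ambiguity = c(NA_integer_, NA_integer_)),
                     class = "junction_call"))
  }
  width <- mj$p_right - mj$p_left
  tsd_len <- min(width, max_tsd)
  capped <- width > max_tsd
  tsd_seq <- substr_(ref, mj$p_right - tsd_len + 1L, mj$p_right)
  if (!capped && tsd_len > 0L) {
    chk <- detect_tsd(substr_(allele_seq, 1L, mj$p_right),
                      substr_(allele_seq, mj$p_left + mj$ins_len + 1L,
                              nchar(allele_seq)),
                      max_len = max_tsd)
    if (chk$tsd_len < tsd_len)
      warning("junction homology width and suffix/prefix TSD check disagree")
  }
  core <- substr_(mj$block, tsd_len + 1L, mj$ins_len)
  element_seq <- if (identical(mj$orientation, "antisense")) revcomp(core) else core
  polyA_len <- detect_polyA(element_seq, min_len = polyA_min, purity = polyA_purity)
  element_len <- mj$ins_len - tsd_len
  stopifnot(element_len + tsd_len + nchar(ref) == nchar(allele_seq))

  itab <- intron_table(model)
  hit <- which(itab$start <= mj$pos5 & mj$pos5 <= itab$end)
  intron_index <- if (length(hit) == 1L) itab$index[hit] else NA_integer_
  hgvs <- tryCatch(to_hgvs_c(mj$pos5, model, ins_desc = sprintf("(%d)", mj$ins_len)),
                   error = function(e) NULL)
  structure(list(pos5 = mj$pos5, pos3 = mj$pos3, tsd_seq = tsd_seq,
                 tsd_len = tsd_len, polyA_len = polyA_len,
                 element_len = element_len, element_seq = element_seq,
                 orientation = mj$orientation, intron_index = intron_index,
                 hgvs_c = hgvs, ambiguity = c(mj$p_left, mj$p_right)),
            class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("<junction_call> insertion point %s (intron %s), element %d nt (%s), TSD %d nt '%s', polyA %d\n  %s\n",
              x$pos5, x$intron_index, x$element_len, x$orientation,
              x$tsd_len, x$tsd_seq, x$polyA_len,
              if (is.null(x$hgvs_c)) "" else x$hgvs_c))
  invisible(x)
}

#' HGVS c. description of an intronic insertion point
#'
#' Converts a genomic insertion point inside an intron to coding-DNA
#' nomenclature `c.<E>+<off>_<E>+<off+1>ins...`, where `E` is the coding
#' position of the last base of the upstream exon and `off` the distance
#' into the intron. Positive donor-anchored offsets are used throughout
#' the intron (no switch to acceptor-anchored negative offsets mid-intron),
#' so deep insertion points read like `c.7542+8951_7542+8952ins...`.
#'
#' @param pos Genomic insertion point (element lands after this base);
#'   must be intronic.
#' @param model Gene model supplying exon table and CDS anchor.
#' @param ins_desc Insertion description appended after `ins` (e.g.
#'   `"(6029)"`).
#' @return The HGVS c. string.
#' @export
to_hgvs_c <- function(pos, model, ins_desc = "") {
  validate_gene_model(model)
  itab <- intron_table(model)
  hit <- which(itab$start <= pos & pos <= itab$end - 1L)
  if (length(hit) != 1L)
    abort_exz("position is not strictly inside an intron (exonic insertions are out of scope)",
              "exz_exonic_insertion")
  i <- itab$index[hit]
  ex <- model$exons
  cum <- cumsum(ex$end - ex$start + 1L)
  c_last <- cum[i] - model$cds_start_mrna + 1L
  if (c_last < 1L)
    abort_exz("upstream exon is non-coding; intron-offset numbering needs a coding anchor",
              "exz_bad_input")
  off <- pos - itab$start[hit] + 1L
  sprintf("c.%d+%d_%d+%dins%s", c_last, off, c_last, off + 1L, ins_desc)
}
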