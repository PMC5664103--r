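AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "*")

aa3 <- function(x) unname(AA3[x])

#' Reading-frame effect of an insertion
#'
#' @param insert_len Insertion length in nucleotides (>= 0).
#' @return `"frameshift"` if `insert_len %% 3 != 0`, else `"in-frame"`
#'   (length 0 is in-frame).
#' @examples
#' frame_effect(103)  # frameshift
#' frame_effect(102)  # in-frame
#' @export
frame_effect <- function(insert_len) {
  insert_len <- as.integer(insert_len)
  if (insert_len < 0L) abort_exz("`insert_len` must be >= 0", "exz_bad_input")
  if (insert_len %% 3L != 0L) "frameshift" else "in-frame"
}

#' First codon affected by an insertion after a coding position
#'
#' For an insertion sitting after coding nucleotide `cds_insert_pos`, the
#' first codon whose sequence can change is `ceiling((pos + 1) / 3)`: an
#' insertion at a codon boundary affects the following codon, an insertion
#' inside a codon affects that codon.
#'
#' @param cds_insert_pos Coding-nucleotide index (1-based) after which the
#'   insert sits; must be >= 1 (insertions 5' of the CDS have no affected
#'   codon).
#' @return Integer codon number.
#' @examples
#' first_affected_codon(7542)  # 2515
#' @export
first_affected_codon <- function(cds_insert_pos) {
  cds_insert_pos <- as.integer(cds_insert_pos)
  if (cds_insert_pos < 1L)
    abort_exz("insertion lies 5' of the CDS; no affected codon", "exz_upstream_of_cds")
  as.integer(ceiling((cds_insert_pos + 1L) / 3L))
}

translate_dna <- function(x) {
  if (nchar(x) < 3L) return("")
  x <- substr_(x, 1L, (nchar(x) %/% 3L) * 3L)
  strsplit(as.character(Biostrings::translate(Biostrings::DNAString(x),
                                              if.fuzzy.codon = "X")), "")[[1]]
}

#' Protein-level consequence of a CDS insertion
#'
#' Translates the mutant CDS, locates the first residue differing from the
#' reference protein and reports the consequence in HGVS p. notation. For
#' a frameshift with a downstream stop the notation is
#' `p.<Ref><codon><New>fs*<N>`, where the new stop is the `N`-th codon
#' counting the first changed residue as 1 (so an immediately created stop
#' is `fs*1`, reported as `p.<Ref><codon>*`). Frameshifts running off the
#' sequence end without a stop use the `fs*?` convention. In-frame
#' insertions are reported as residue insertions.
#'
#' @param cds Reference CDS (starts `ATG`, length divisible by 3).
#' @param insert_seq Inserted sequence.
#' @param cds_insert_pos Coding-nucleotide index after which the insert
#'   sits; values outside `[1, nchar(cds) - 1]` (UTR insertions) return
#'   `NULL` (no protein consequence).
#' @param table Codon table; only `"standard"` is supported.
#' @return `NULL`, or an object of class `protein_consequence`: list with
#'   `frameshift`, `first_affected_codon`, `ref_residue`, `new_residue`,
#'   `stop_offset` (`NA` when no downstream stop), and `hgvs_p`.
#' @export
protein_consequence <- function(cds, insert_seq, cds_insert_pos,
                                table = "standard") {
  check_dna(cds); check_dna(insert_seq)
  if (!identical(table, "standard"))
    abort_exz("only the standard nuclear codon table is supported", "exz_bad_input")
  if (nchar(cds) %% 3L != 0L || !identical(substr_(cds, 1L, 3L), "ATG"))
    abort_exz("`cds` must start with ATG and have length divisible by 3", "exz_bad_input")
  cds_insert_pos <- as.integer(cds_insert_pos)
  if (cds_insert_pos < 1L || cds_insert_pos >= nchar(cds)) return(NULL)

  ref_pep <- translate_dna(cds)
  mut_cds <- paste0(substr_(cds, 1L, cds_insert_pos), insert_seq,
                    substr_(cds, cds_insert_pos + 1L, nchar(cds)))
  mut_full <- translate_dna(mut_cds)
  stop_at <- which(mut_full == "*")[1L]
  mut_pep <- if (is.na(stop_at)) mut_full else mut_full[seq_len(stop_at)]

  fs <- nchar(insert_seq) %% 3L != 0L
  m <- min(length(ref_pep), length(mut_pep))
  diff <- which(ref_pep[seq_len(m)] != mut_pep[seq_len(m)])
  first <- if (length(diff)) diff[1L] else m + 1L
  if (first > length(mut_pep)) {
    # no residue-level change within the mutant peptide (e.g. in-frame silent)
    return(structure(list(frameshift = fs, first_affected_codon = NA_integer_,
                          ref_residue = NA_character_, new_residue = NA_character_,
                          stop_offset = NA_integer_, hgvs_p = "p.(=)"),
                     class = "protein_consequence"))
  }
  ref_aa <- ref_pep[first]
  new_aa <- mut_pep[first]

  if (fs) {
    stop_offset <- if (is.na(stop_at)) NA_integer_ else stop_at - first + 1L
    hgvs <- if (!is.na(stop_offset) && new_aa == "*") {
      sprintf("p.%s%d*", aa3(ref_aa), first)
    } else if (!is.na(stop_offset)) {
      sprintf("p.%s%d%sfs*%d", aa3(ref_aa), first, aa3(new_aa), stop_offset)
    } else {
      sprintf("p.%s%d%sfs*?", aa3(ref_aa), first, aa3(new_aa))
    }
  } else {
    # in-frame: delimit the inserted residues by peptide prefix/suffix match
    n_ins <- nchar(insert_seq) %/% 3L
    stop_offset <- if (is.na(stop_at)) NA_integer_ else stop_at - first + 1L
    lcp <- first - 1L
    if (lcp >= 1L && lcp + n_ins <= length(mut_pep) && lcp + 1L <= length(ref_pep)) {
      ins_res <- mut_pep[(lcp + 1L):(lcp + n_ins)]
      hgvs <- sprintf("p.%s%d_%s%dins%s",
                      aa3(ref_pep[lcp]), lcp,
                      aa3(ref_pep[lcp + 1L]), lcp + 1L,
                      paste(aa3(ins_res), collapse = ""))
    } else {
      hgvs <- sprintf("p.%s%d%s", aa3(ref_aa), first, aa3(new_aa))
    }
  }
  structure(list(frameshift = fs, first_affected_codon = first,
                 ref_residue = aa3(ref_aa), new_residue = aa3(new_aa),
                 stop_offset = stop_offset, hgvs_p = hgvs),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("<protein_consequence> %s (frameshift=%s, first affected codon %s)\n",
              x$hgvs_p, x$frameshift, x$first_affected_codon))
  invisible(x)
}
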