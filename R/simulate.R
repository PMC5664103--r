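#' Construct a synthetic multi-exon gene model
#'
#' Generates a gene locus with the requested exon/intron geometry and i.i.d.
#' background sequence at a given GC content. Introns are canonical by
#' default (begin `GT`, end `AG`). The model is the ground-truth container
#' used by all downstream stages: it carries the genomic sequence, the exon
#' table and the CDS anchor needed for HGVS coordinate arithmetic.
#'
#' @param n_exons Number of exons (>= 2).
#' @param exon_len Exon length; a scalar (recycled) or a vector of
#'   `n_exons` lengths.
#' @param intron_lens Integer vector of `n_exons - 1` intron lengths.
#' @param cds_start 1-based position of the first coding base within the
#'   spliced mRNA.
#' @param gc Background GC fraction.
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @param canonical Force `GT...AG` intron boundaries (default `TRUE`).
#' @param gene_id Identifier stored in the model.
#' @return An object of class `gene_model`: a list with `gene_id`,
#'   `genomic_seq`, `exons` (data.frame of 1-based closed `start`/`end`),
#'   `cds_start_mrna` and `strand`.
#' @examples
#' gm <- make_gene_model(3, 120, c(500, 2000), cds_start = 10, seed = 1)
#' nchar(spliced_mrna(gm))  # 360
#' @export
make_gene_model <- function(n_exons, exon_len, intron_lens, cds_start = 1L,
                            gc = 0.4, seed = 1L, canonical = TRUE,
                            gene_id = "simulated_gene") {
  n_exons <- as.integer(n_exons)
  if (n_exons < 2L) abort_exz("`n_exons` must be >= 2", "exz_bad_input")
  exon_len <- as.integer(rep_len(exon_len, n_exons))
  intron_lens <- as.integer(intron_lens)
  if (length(intron_lens) != n_exons - 1L)
    abort_exz("`intron_lens` must have n_exons - 1 entries", "exz_bad_input")
  if (any(exon_len <= 0L) || any(intron_lens <= 0L))
    abort_exz("exon and intron lengths must be positive", "exz_bad_input")
  if (canonical && any(intron_lens < 4L))
    abort_exz("canonical introns need length >= 4", "exz_bad_input")
  mrna_len <- sum(exon_len)
  cds_start <- as.integer(cds_start)
  if (cds_start < 1L || cds_start > mrna_len)
    abort_exz("`cds_start` must fall inside the spliced mRNA", "exz_bad_input")

  total <- sum(exon_len) + sum(intron_lens)
  seq <- random_dna(total, gc = gc, seed = seed)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- 1L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + exon_len[i] - 1L
    pos <- ends[i] + 1L
    if (i < n_exons) {
      if (canonical) {
        seq <- splice_in(seq, pos, "GT")
        seq <- splice_in(seq, pos + intron_lens[i] - 2L, "AG")
      }
      pos <- pos + intron_lens[i]
    }
  }
  model <- structure(list(gene_id = gene_id, genomic_seq = seq,
                          exons = data.frame(start = starts, end = ends),
                          cds_start_mrna = cds_start, strand = "+"),
                     class = "gene_model")
  validate_gene_model(model)
  model
}

validate_gene_model <- function(model) {
  ex <- model$exons
  stopifnot(all(ex$end >= ex$start),
            all(diff(ex$start) > 0),
            all(ex$start[-1] > ex$end[-nrow(ex)]),
            ex$end[nrow(ex)] <= nchar(model$genomic_seq),
            model$cds_start_mrna >= 1L,
            model$cds_start_mrna <= sum(ex$end - ex$start + 1L))
  invisible(model)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d exons, genomic %d nt, mRNA %d nt, CDS from mRNA pos %d\n",
              x$gene_id, nrow(x$exons), nchar(x$genomic_seq),
              sum(x$exons$end - x$exons$start + 1L), x$cds_start_mrna))
  invisible(x)
}

#' Spliced mRNA of a gene model
#'
#' @param model A [make_gene_model()] object.
#' @return The spliced mRNA (exons concatenated 5'->3') as a DNA string.
#' @export
spliced_mrna <- function(model) {
  paste(substring(model$genomic_seq, model$exons$start, model$exons$end), collapse = "")
}

# 1-based intron table; intron i sits between exons i and i+1
intron_table <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  data.frame(index = seq_len(n - 1L),
             start = ex$end[-n] + 1L,
             end = ex$start[-1L] - 1L)
}

#' Derive a mobile element from the packaged consensus panel
#'
#' The element is the 3'-anchored tail of the chosen consensus (full length
#' by default), point-mutated at `mutation_rate`, optionally 5'-truncated,
#' and finished with a poly-A tail. 5' truncation is the biologically
#' dominant mode of incomplete L1 integration, so `length` (when smaller
#' than the consensus) keeps the 3'-most `length` bases. Feature
#' annotations are inherited from the panel; features not fully contained
#' in the retained span are dropped.
#'
#' @param family Panel family name (e.g. `"L1_consensus"`, `"L1HS_like"`).
#' @param length Length of consensus-derived body to retain (default: full
#'   consensus). Equivalent to a 5' truncation of `cons_len - length`.
#' @param polyA_len Number of terminal adenosines appended.
#' @param mutation_rate Per-base substitution probability applied to the
#'   body (the poly-A tail is left unmutated).
#' @param truncate_5p Number of bases removed from the consensus 5' end;
#'   must agree with `length` if both are given.
#' @param seed Integer seed.
#' @param panel Consensus panel (defaults to the bundled [l1_panel()]).
#' @return An object of class `mobile_element`: list with `seq`, `family`,
#'   `features` (name/start/end in element coordinates), `polyA_len`,
#'   `truncate_5p`, `n_sub` and `intact`. `intact` is `TRUE` iff the element
#'   is untruncated and both ORFs are still open reading frames.
#' @export
make_element <- function(family, length = NULL, polyA_len = 20L,
                         mutation_rate = 0, truncate_5p = 0L, seed = 1L,
                         panel = l1_panel()) {
  if (!family %in% names(panel))
    abort_exz(sprintf("unknown element family '%s'", family), "exz_unknown_family")
  cons <- panel[[family]]
  clen <- nchar(cons$seq)
  truncate_5p <- as.integer(truncate_5p)
  if (!is.null(length)) {
    length <- as.integer(length)
    if (length < 1L || length > clen)
      abort_exz("`length` must be in [1, consensus length]", "exz_bad_input")
    t_from_len <- clen - length
    if (truncate_5p != 0L && truncate_5p != t_from_len)
      abort_exz("`length` and `truncate_5p` disagree", "exz_bad_input")
    truncate_5p <- t_from_len
  }
  if (truncate_5p < 0L || truncate_5p >= clen)
    abort_exz("`truncate_5p` must be in [0, consensus length)", "exz_bad_input")
  if (polyA_len < 0L) abort_exz("`polyA_len` must be >= 0", "exz_bad_input")

  body <- substr_(cons$seq, truncate_5p + 1L, clen)
  mut <- mutate_seq(body, mutation_rate, seed)
  body <- mut$seq
  seq <- paste0(body, strrep("A", polyA_len))

  fe <- cons$features
  keep <- fe$start > truncate_5p  # fully retained features only
  fe <- fe[keep & fe$end <= clen, , drop = FALSE]
  fe$start <- fe$start - truncate_5p
  fe$end <- fe$end - truncate_5p
  if (polyA_len > 0L)
    fe <- rbind(fe, data.frame(feature = "polyA",
                               start = nchar(body) + 1L,
                               end = nchar(seq)))
  rownames(fe) <- NULL

  orf_open <- function(nm) {
    r <- fe[fe$feature == nm, ]
    if (nrow(r) != 1L) return(FALSE)
    s <- substr_(seq, r$start, r$end)
    cods <- substring(s, seq(1L, nchar(s) - 2L, 3L), seq(3L, nchar(s), 3L))
    identical(cods[1L], "ATG") &&
      cods[length(cods)] %in% c("TAA", "TAG", "TGA") &&
      !any(cods[-length(cods)][-1L] %in% c("TAA", "TAG", "TGA"))
  }
  intact <- truncate_5p == 0L && orf_open("ORF1") && orf_open("ORF2")

  structure(list(seq = seq, family = family, features = fe,
                 polyA_len = as.integer(polyA_len), truncate_5p = truncate_5p,
                 n_sub = mut$n_sub, intact = intact),
            class = "mobile_element")
}

#' @export
print.mobile_element <- function(x, ...) {
  cat(sprintf("<mobile_element> %s: %d nt (polyA %d), features: %s, intact=%s\n",
              x$family, nchar(x$seq), x$polyA_len,
              paste(x$features$feature, collapse = ","), x$intact))
  invisible(x)
}

#' Insert a mobile element into an intron with TPRT signatures
#'
#' Builds the insertion allele produced by target-site primed reverse
#' transcription: the element copy (reverse-complemented for antisense
#' integrations) is placed after `insert_pos`, and the `tsd_len`-mer of
#' reference sequence ending at `insert_pos` is duplicated so that both
#' flanks of the element read the same target-site duplication.
#'
#' @param model A [make_gene_model()] object.
#' @param insert_pos 1-based genomic coordinate; the element lands between
#'   `insert_pos` and `insert_pos + 1`, which must both be intronic.
#' @param element A [make_element()] object.
#' @param tsd_len Target-site duplication length (0-30).
#' @param orientation `"sense"` or `"antisense"` relative to the gene.
#' @return An object of class `insertion_allele`: list with `allele_seq`,
#'   `insert_pos`, `element`, `tsd_len`, `tsd_seq`, `orientation`,
#'   `ref_len` and `intron_index`.
#' @export
insert_element <- function(model, insert_pos, element, tsd_len = 9L,
                           orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  validate_gene_model(model)
  insert_pos <- as.integer(insert_pos)
  tsd_len <- as.integer(tsd_len)
  if (tsd_len < 0L || tsd_len > 30L)
    abort_exz("`tsd_len` must be in [0, 30]", "exz_bad_input")
  itab <- intron_table(model)
  hit <- which(itab$start <= insert_pos & insert_pos <= itab$end - 1L)
  if (length(hit) != 1L)
    abort_exz("insertion point must lie strictly inside an intron (exonic insertions are out of scope)",
              "exz_exonic_insertion")
  if (insert_pos - tsd_len + 1L < itab$start[hit])
    abort_exz("target-site duplication would extend outside the intron", "exz_bad_input")

  ref <- model$genomic_seq
  n <- nchar(ref)
  ins_seq <- if (orientation == "sense") element$seq else revcomp(element$seq)
  tsd_seq <- substr_(ref, insert_pos - tsd_len + 1L, insert_pos)
  allele <- paste0(substr_(ref, 1L, insert_pos), ins_seq,
                   substr_(ref, insert_pos - tsd_len + 1L, n))
  stopifnot(nchar(allele) == n + nchar(ins_seq) + tsd_len)
  # both flanks of the element copy carry the duplicated target
  stopifnot(identical(substr_(allele, insert_pos - tsd_len + 1L, insert_pos), tsd_seq),
            identical(substr_(allele, insert_pos + nchar(ins_seq) + 1L,
                              insert_pos + nchar(ins_seq) + tsd_len), tsd_seq))

  structure(list(allele_seq = allele, insert_pos = insert_pos,
                 element = element, tsd_len = tsd_len, tsd_seq = tsd_seq,
                 orientation = orientation, ref_len = n,
                 intron_index = itab$index[hit]),
            class = "insertion_allele")
}

#' @export
print.insertion_allele <- function(x, ...) {
  cat(sprintf("<insertion_allele> %s insertion of %d nt after position %d (intron %d), TSD %d nt '%s'\n",
              x$orientation, nchar(x$allele_seq) - x$ref_len - x$tsd_len,
              x$insert_pos, x$intron_index, x$tsd_len, x$tsd_seq))
  invisible(x)
}

#' Splice transcripts from an insertion allele
#'
#' Emulates cryptic-splice-site usage at the insertion: the mutant
#' transcript keeps `acceptor_offset` intronic bases immediately 5' of the
#' element copy (the retained prefix recognized through a cryptic intronic
#' acceptor) followed by the first `donor_offset` bases of the (oriented)
#' element (exonized up to an element-internal donor). A wild-type
#' transcript is emitted alongside with weight `wt_fraction`, modelling the
#' residual correctly spliced mRNA fraction. The operation is deterministic;
#' `seed` is accepted for interface uniformity but no random draws are made
#' (weights are parameters of the transcript mixture).
#'
#' @param allele An [insert_element()] allele.
#' @param model The gene model the allele was built from.
#' @param acceptor_offset Number of intronic bases retained 5' of the
#'   element junction.
#' @param donor_offset Number of element bases exonized.
#' @param wt_fraction Weight of the wild-type transcript in `[0, 1]`.
#' @param seed Unused; kept for a uniform simulator interface.
#' @return A data.frame with columns `label`, `seq`, `weight`
#'   (zero-weight transcripts are dropped).
#' @export
splice_transcripts <- function(allele, model, acceptor_offset = 5L,
                               donor_offset = 98L, wt_fraction = 0.05,
                               seed = NULL) {
  acceptor_offset <- as.integer(acceptor_offset)
  donor_offset <- as.integer(donor_offset)
  if (acceptor_offset < 0L || donor_offset < 0L)
    abort_exz("splice offsets must be >= 0", "exz_bad_input")
  ins_seq <- if (allele$orientation == "sense") allele$element$seq else revcomp(allele$element$seq)
  if (donor_offset > nchar(ins_seq))
    abort_exz("`donor_offset` exceeds the element length", "exz_bad_input")
  if (wt_fraction < 0 || wt_fraction > 1)
    abort_exz("`wt_fraction` must be in [0, 1]", "exz_bad_input")

  i <- allele$intron_index
  ex <- model$exons
  up <- paste(substring(model$genomic_seq, ex$start[seq_len(i)], ex$end[seq_len(i)]), collapse = "")
  dn_idx <- seq(i + 1L, nrow(ex))
  dn <- paste(substring(model$genomic_seq, ex$start[dn_idx], ex$end[dn_idx]), collapse = "")
  prefix <- substr_(model$genomic_seq, allele$insert_pos - acceptor_offset + 1L, allele$insert_pos)
  mutant <- paste0(up, prefix, substr_(ins_seq, 1L, donor_offset), dn)

  out <- data.frame(label = c("mutant", "wildtype"),
                    seq = c(mutant, spliced_mrna(model)),
                    weight = c(1 - wt_fraction, wt_fraction),
                    stringsAsFactors = FALSE)
  out <- out[out$weight > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "insert_len") <- acceptor_offset + donor_offset
  out
}

#' Remove every occurrence of a motif from a sequence
#'
#' Support utility for building "clean" introns for exact-count experiments:
#' each occurrence of `motif` is destroyed by substituting one of its bases,
#' iterating until no occurrence remains. Regions listed in `protect`
#' (data.frame of start/end) are left untouched.
#'
#' @param seq DNA string.
#' @param motif Motif to scrub (plain ACGT).
#' @param protect Optional data.frame with `start`/`end` columns (1-based,
#'   closed) of regions that must not be modified.
#' @return The scrubbed sequence.
#' @export
scrub_motif <- function(seq, motif, protect = NULL) {
  check_dna(motif)
  k <- nchar(motif)
  is_protected <- function(s, e) {
    if (is.null(protect) || !nrow(protect)) return(FALSE)
    any(s <= protect$end & e >= protect$start)
  }
  repeat {
    hits <- Biostrings::start(Biostrings::matchPattern(motif, Biostrings::DNAString(seq)))
    hits <- hits[!vapply(hits, function(s) is_protected(s, s + k - 1L), logical(1))]
    if (!length(hits)) return(seq)
    for (s in hits) {
      # flip the middle base to a different, non-trivial substitute
      p <- s + (k %/% 2L)
      cur <- substr(seq, p, p)
      repl <- setdiff(DNA_BASES, c(cur, "A", "G"))[1L]  # avoid re-creating AG cores
      substr(seq, p, p) <- repl
    }
  }
}

#' Write a motif at fixed positions of a sequence
#'
#' @param seq DNA string.
#' @param motif Motif to plant.
#' @param positions 1-based start positions.
#' @return The modified sequence.
#' @export
plant_sites <- function(seq, motif, positions) {
  for (p in positions) seq <- splice_in(seq, p, motif)
  seq
}
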