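#' Simulate a complete exonization case with ground truth
#'
#' One-call generator for the full study design: a multi-exon gene with a
#' long host intron, an L1-like element carrying retrotransposition
#' hallmarks, a TPRT insertion allele with target-site duplication, and the
#' spliced transcript mixture (aberrant exonized transcript plus a residual
#' wild-type fraction). Defaults reproduce the geometry of a dystrophin-like
#' case: 52 exons with 7,542 coding bases upstream of the host intron, a
#' 44,000-nt host intron, a 6,020-nt element (6,000-nt body + 20-nt poly-A)
#' inserted 8,951 nt into the intron with a 9-bp target-site duplication
#' ending in the cryptic-acceptor context `AG|AATTC`, and splicing that
#' retains 5 intronic bases plus the first 98 element bases (a 103-nt,
#' frame-shifting insertion).
#'
#' When `plant_context = TRUE` a strong acceptor context (branch point
#' `CTAAC` 25 nt upstream of the cryptic junction, a 16-nt polypyrimidine
#' tract, and `AG` immediately 5' of the retained prefix) is written into
#' the intron so that the duplicated target ends `...AG + prefix`
#' (`AAAGAATTC` at the defaults). `clean_intron = TRUE` scrubs all other
#' `AG + prefix` occurrences from the host intron and optionally plants
#' `n_decoys` bare motif copies, enabling exact-count experiments.
#'
#' By default junctions are "clean": the reference base immediately 3' of
#' the insertion point is forced to differ from the first base of the
#' oriented element, and the base immediately 5' of the duplicated target
#' differs from the element's last base (and from A). Under TPRT these
#' homology accidents are the only signal that can blur the junction
#' anchors, so clean junctions make the TSD exactly recoverable.
#'
#' @param geometry `"dystrophin"` (52-exon dystrophin-like locus) or `"compact"`
#'   (3 exons, 4,500-nt host intron; used by [run_validation()]).
#' @param family,element_len,polyA_len Element parameters; `element_len` is
#'   the total element length including the poly-A tail.
#' @param tsd_len,orientation Insertion parameters.
#' @param intron_offset 1-based offset of the insertion point within the
#'   host intron (the element lands after that intron base).
#' @param acceptor_offset,donor_offset,wt_fraction Splicing parameters
#'   (see [splice_transcripts()]).
#' @param prefix Retained-prefix sequence planted 5' of the element
#'   (also the expected cryptic-acceptor motif suffix).
#' @param mutation_rate Element point-mutation rate.
#' @param plant_context,clean_intron,n_decoys,clean_junctions See above.
#' @param gc Background GC fraction.
#' @param seed Integer seed controlling the whole simulation.
#' @return An object of class `l1_simulation`: list with `model`, `element`,
#'   `allele`, `transcripts`, `intron` (host-intron coordinates and
#'   sequence) and `truth` (all planted parameters).
#' @examples
#' sim <- simulate_locus(geometry = "compact", seed = 7)
#' sim$truth$insert_tx_len
#' @export
simulate_locus <- function(geometry = c("dystrophin", "compact"),
                           family = "L1HS_like", element_len = 6020L,
                           polyA_len = 20L, tsd_len = 9L,
                           orientation = "sense", intron_offset = 8951L,
                           acceptor_offset = 5L, donor_offset = 98L,
                           wt_fraction = 0.05, prefix = "AATTC",
                           mutation_rate = 0, plant_context = TRUE,
                           clean_intron = FALSE, n_decoys = 0L,
                           clean_junctions = TRUE, gc = 0.4, seed = 1L) {
  geometry <- match.arg(geometry)
  seed <- as.integer(seed)
  if (geometry == "dystrophin") {
    exon_lens <- c(rep(148L, 50L), 142L, 200L)   # coding bases 1..7542 end at exon 51
    intron_lens <- c(rep(300L, 50L), 44000L)
    target_intron <- 51L
    model <- make_gene_model(52L, exon_lens, intron_lens, cds_start = 1L,
                             gc = gc, seed = seed, gene_id = "sim_locus")
    model <- open_reading_frame(model, seed = seed + 101L)
  } else {
    exon_lens <- c(150L, 150L, 150L)
    intron_lens <- c(400L, 4500L)
    target_intron <- 2L
    model <- make_gene_model(3L, exon_lens, intron_lens, cds_start = 1L,
                             gc = gc, seed = seed, gene_id = "sim_locus")
    model <- open_reading_frame(model, seed = seed + 101L)
    if (intron_offset > 4400L) intron_offset <- 2500L
  }
  itab <- intron_table(model)
  ir <- itab[itab$index == target_intron, ]
  P <- ir$start + as.integer(intron_offset) - 1L
  if (P - 60L < ir$start || P + 60L > ir$end)
    abort_exz("`intron_offset` too close to the intron boundaries", "exz_bad_input")

  element <- make_element(family, length = element_len - polyA_len,
                          polyA_len = polyA_len, mutation_rate = mutation_rate,
                          seed = seed + 7L)
  ins_seq <- if (orientation == "sense") element$seq else revcomp(element$seq)

  protect <- NULL
  if (plant_context) {
    pad_len <- max(0L, as.integer(tsd_len) - 2L - nchar(prefix))
    context <- paste0("CTAAC", "TCT", strrep("T", 16L),
                      strrep("A", pad_len), "AG", prefix)
    cstart <- P - nchar(context) + 1L
    stopifnot(cstart > ir$start)
    model$genomic_seq <- splice_in(model$genomic_seq, cstart, context)
    protect <- data.frame(start = cstart, end = P + 1L)
  }

  if (clean_junctions) {
    g <- model$genomic_seq
    if (substr(g, P + 1L, P + 1L) == substr(ins_seq, 1L, 1L)) {
      repl <- setdiff(DNA_BASES, c(substr(ins_seq, 1L, 1L), "A", "G"))[1L]
      substr(g, P + 1L, P + 1L) <- repl
    }
    q <- P - as.integer(tsd_len)
    if (q >= ir$start) {
      last <- substr(ins_seq, nchar(ins_seq), nchar(ins_seq))
      if (substr(g, q, q) %in% c(last, "A")) {
        repl <- setdiff(c("C", "T", "G"), c(last, "A"))[1L]
        substr(g, q, q) <- repl
      }
    }
    model$genomic_seq <- g
  }

  motif <- paste0("AG", prefix)
  decoy_pos <- integer(0)
  if (clean_intron) {
    intr <- substr_(model$genomic_seq, ir$start, ir$end)
    prot_local <- data.frame(start = c(1L, nchar(intr) - 1L),
                             end = c(2L, nchar(intr)))
    if (!is.null(protect))
      prot_local <- rbind(prot_local,
                          data.frame(start = protect$start - ir$start + 1L,
                                     end = protect$end - ir$start + 1L))
    intr <- scrub_motif(intr, motif, protect = prot_local)
    if (n_decoys > 0L) {
      span <- nchar(intr) - 200L
      decoy_local <- round(seq(100L, span, length.out = n_decoys + 2L))[2:(n_decoys + 1L)]
      # keep decoys away from the planted context and the insertion point
      decoy_local <- decoy_local[abs(decoy_local - (P - ir$start + 1L)) > 100L]
      intr <- plant_sites(intr, motif, decoy_local)
      prot_local <- rbind(prot_local,
                          data.frame(start = decoy_local,
                                     end = decoy_local + nchar(motif) - 1L))
      intr <- scrub_motif(intr, motif, protect = prot_local)
      decoy_pos <- decoy_local + ir$start - 1L
    }
    model$genomic_seq <- paste0(substr_(model$genomic_seq, 1L, ir$start - 1L),
                                intr,
                                substr_(model$genomic_seq, ir$end + 1L,
                                        nchar(model$genomic_seq)))
  }

  allele <- insert_element(model, P, element, tsd_len = tsd_len,
                           orientation = orientation)
  transcripts <- splice_transcripts(allele, model,
                                    acceptor_offset = acceptor_offset,
                                    donor_offset = donor_offset,
                                    wt_fraction = wt_fraction)

  ex <- model$exons
  cum <- cumsum(ex$end - ex$start + 1L)
  truth <- list(insert_pos = P, intron_index = target_intron,
                intron_offset = as.integer(intron_offset),
                tsd_len = as.integer(tsd_len),
                tsd_seq = allele$tsd_seq,
                polyA_len = as.integer(polyA_len),
                element_len = nchar(element$seq),
                orientation = orientation,
                family = family,
                acceptor_offset = as.integer(acceptor_offset),
                donor_offset = as.integer(donor_offset),
                insert_tx_len = as.integer(acceptor_offset + donor_offset),
                wt_fraction = wt_fraction,
                mrna_insert_after = cum[target_intron],
                cryptic_junction = P - nchar(prefix) + 1L,
                prefix = prefix,
                decoy_positions = decoy_pos,
                mutation_rate = mutation_rate,
                seed = seed)
  structure(list(model = model, element = element, allele = allele,
                 transcripts = transcripts,
                 intron = list(index = target_intron, start = ir$start,
                               end = ir$end,
                               seq = substr_(model$genomic_seq, ir$start, ir$end)),
                 truth = truth),
            class = "l1_simulation")
}

#' @export
print.l1_simulation <- function(x, ...) {
  cat(sprintf(paste0("<l1_simulation> %d-exon gene, element %d nt (%s, %s), TSD %d, ",
                     "insertion %d nt into intron %d; transcript insert %d nt\n"),
              nrow(x$model$exons), x$truth$element_len, x$truth$family,
              x$truth$orientation, x$truth$tsd_len, x$truth$intron_offset,
              x$truth$intron_index, x$truth$insert_tx_len))
  invisible(x)
}

# rewrite the spliced exonic sequence so the CDS is a single open reading
# frame: ATG, non-stop codons, terminal TAA (trailing sub-codon bases left
# random). Needed when protein-level consequences are to be computed.
open_reading_frame <- function(model, seed = 1L) {
  mrna_len <- sum(model$exons$end - model$exons$start + 1L)
  cds_len <- ((mrna_len - model$cds_start_mrna + 1L) %/% 3L) * 3L
  n_mid <- cds_len %/% 3L - 2L
  stopifnot(n_mid > 0L)
  cods <- all_codons()
  nonstop <- setdiff(cods, c("TAA", "TAG", "TGA"))
  cds <- withr::with_seed(as.integer(seed), paste0(
    "ATG", paste(sample(nonstop, n_mid, replace = TRUE), collapse = ""), "TAA"))
  g <- model$genomic_seq
  # write cds back into the exonic positions covering the CDS
  mpos <- model$cds_start_mrna
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons$start[i]; e <- model$exons$end[i]
    exlen <- e - s + 1L
    mstart <- sum(model$exons$end[seq_len(i - 1L)] - model$exons$start[seq_len(i - 1L)] + 1L) + 1L
    mend <- mstart + exlen - 1L
    ov_s <- max(mstart, model$cds_start_mrna)
    ov_e <- min(mend, model$cds_start_mrna + cds_len - 1L)
    if (ov_s > ov_e) next
    piece <- substr_(cds, ov_s - model$cds_start_mrna + 1L, ov_e - model$cds_start_mrna + 1L)
    g <- splice_in(g, s + (ov_s - mstart), piece)
  }
  model$genomic_seq <- g
  model
}

all_codons <- function() {
  as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
}

#' Write a simulation bundle to disk
#'
#' Exports the standard file set for a simulated case: locus FASTA, exon
#' BED (0-based half-open) and GFF3 (1-based closed), insertion-allele
#' FASTA, transcripts FASTA, and a ground-truth JSON with every simulation
#' parameter.
#'
#' @param sim A [simulate_locus()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- character(0)
  fa <- function(seqs, names, file) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names
    Biostrings::writeXStringSet(x, file)
    file
  }
  f[1] <- fa(sim$model$genomic_seq, sim$model$gene_id, file.path(dir, "locus.fa"))
  f[2] <- fa(sim$allele$allele_seq, paste0(sim$model$gene_id, "_allele"),
             file.path(dir, "allele.fa"))
  f[3] <- fa(sim$transcripts$seq, sim$transcripts$label, file.path(dir, "transcripts.fa"))
  gr <- GenomicRanges::GRanges(sim$model$gene_id,
                               IRanges::IRanges(sim$model$exons$start, sim$model$exons$end),
                               strand = sim$model$strand)
  gr$name <- paste0("exon", seq_len(nrow(sim$model$exons)))
  bed <- file.path(dir, "exons.bed")
  rtracklayer::export(gr, bed, format = "BED")
  gff <- file.path(dir, "exons.gff3")
  gr$type <- "exon"
  rtracklayer::export(gr, gff, format = "GFF3")
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, tj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(f, bed, gff, tj))
}
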