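#' Run the full insertion-characterization pipeline
#'
#' Orchestrates every stage on one case: transcript-insertion discovery,
#' repeat classification of the insert, prefix/element splitting,
#' cryptic-acceptor scanning and composite ranking in the host intron,
#' genomic junction mapping with TSD and poly-A detection (when an
#' insertion-allele sequence is available), element architecture and
#' subfamily annotation, and the protein-level consequence with HGVS
#' strings. Sections whose inputs are absent are `NULL` in the report.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{model}{a [make_gene_model()] object, or a list of paths
#'       `list(fasta=, exons=)` where `exons` is a BED/GFF3 exon table
#'       (plus `cds_start`, defaulting to 1).}
#'     \item{observed}{character vector of observed transcript sequences,
#'       or a FASTA path.}
#'     \item{allele}{optional insertion-allele sequence or FASTA path.}
#'     \item{panel}{optional consensus panel / FASTA path
#'       (default: bundled panel).}
#'     \item{params}{optional overrides: `max_subs`, `min_score`,
#'       `max_tsd`, `polyA_min`, `polyA_purity`, `bp_min`, `bp_max`,
#'       `rank_k`, `t1`, `t2`.}
#'   }
#' @param out Optional path; when given, the report is written there as
#'   JSON (with a human-readable summary printed alongside).
#' @return An object of class `characterization_report`: list with
#'   `transcript_insertion`, `repeat_hits`, `splice_candidates`,
#'   `junction_call`, `element_annotation`, `protein_consequence`,
#'   `hgvs` (`r.`, `c.`, `p.`), `wt_detected` and `provenance`.
#' @export
run_characterize <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$model) || is.null(config$observed))
    abort_exz("config must name at least `model` and `observed`", "exz_bad_config")

  model <- load_model(config$model)
  panel <- if (is.null(config$panel)) l1_panel()
           else if (is.character(config$panel)) l1_panel(fasta = config$panel)
           else config$panel
  observed <- load_seqs(config$observed)
  allele_seq <- if (is.null(config$allele)) NULL else load_seqs(config$allele)[[1L]]
  p <- config$params %||% list()

  ref_mrna <- spliced_mrna(model)
  tis <- classify_transcripts(ref_mrna, observed, model = model,
                              max_subs = p$max_subs %||% 2L)
  wt <- any(vapply(tis, `[[`, logical(1), "wt_detected"))
  lens <- vapply(tis, `[[`, integer(1), "insert_len")
  ti <- if (any(lens > 0L)) tis[[which.max(lens)]] else tis[[1L]]

  hits <- NULL; splice <- NULL; jc <- NULL; ann <- NULL; pc <- NULL
  hgvs_r <- NULL; hgvs_c <- NULL; hgvs_p <- NULL

  if (ti$insert_len > 0L) {
    hits <- classify_insert(ti$insert_seq_3p, library = panel,
                            min_score = p$min_score %||% 20)
    if (nrow(hits)) ti <- split_insert(ti, hits[1L, ])
    else { ti$prefix <- ""; ti$element_part <- ti$insert_seq_3p }
    hgvs_r <- to_hgvs_r(ti, model)

    # scan the host intron for the cryptic acceptor implied by the prefix
    if (!is.na(ti$left_exon) && isTRUE(!is.na(ti$prefix) && nzchar(ti$prefix)) &&
        ti$left_exon < nrow(model$exons)) {
      itab <- intron_table(model)
      ir <- itab[itab$index == ti$left_exon, ]
      intron_seq <- substr_(model$genomic_seq, ir$start, ir$end)
      cands <- scan_motif(intron_seq, ti$prefix)
      cands <- score_candidates(intron_seq, cands,
                                bp_min = p$bp_min %||% 18L,
                                bp_max = p$bp_max %||% 44L)
      splice <- list(intron_index = ir$index,
                     candidates = cands,
                     passing = rank_candidates(cands, k = p$rank_k %||% Inf,
                                               t1 = p$t1, t2 = p$t2))
    }
  }

  if (!is.null(allele_seq)) {
    jc <- call_junctions(allele_seq, model, panel = panel,
                         max_tsd = p$max_tsd %||% 30L,
                         polyA_min = p$polyA_min %||% 5L,
                         polyA_purity = p$polyA_purity %||% 0.9)
    hgvs_c <- jc$hgvs_c
    if (jc$element_len > 0L)
      ann <- annotate_structure(jc$element_seq, polyA_len = jc$polyA_len,
                                panel = panel)
    if (!is.null(hits) && nrow(hits) &&
        jc$element_len < (hits$consensus_end[1L] - hits$consensus_start[1L] + 1L))
      warning("junction element length is shorter than the repeat-hit consensus span")
  }

  if (ti$insert_len > 0L) {
    cds_len <- ((nchar(ref_mrna) - model$cds_start_mrna + 1L) %/% 3L) * 3L
    cds <- substr_(ref_mrna, model$cds_start_mrna,
                   model$cds_start_mrna + cds_len - 1L)
    cds_pos <- ti$right_pos - model$cds_start_mrna + 1L
    if (identical(substr_(cds, 1L, 3L), "ATG"))
      pc <- protein_consequence(cds, ti$insert_seq, cds_pos)
    hgvs_p <- if (!is.null(pc)) pc$hgvs_p else NULL
  }

  report <- structure(list(
    transcript_insertion = ti, repeat_hits = hits, splice_candidates = splice,
    junction_call = jc, element_annotation = ann, protein_consequence = pc,
    hgvs = list(r = hgvs_r, c = hgvs_c, p = hgvs_p),
    wt_detected = wt,
    provenance = list(package = "exonizeL1",
                      version = as.character(utils::packageVersion("exonizeL1")),
                      params = p)),
    class = "characterization_report")
  validate_report(report)
  if (!is.null(out)) {
    jsonlite::write_json(report_to_list(report), out, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_model <- function(x) {
  if (inherits(x, "gene_model")) return(validate_gene_model(x))
  if (!is.list(x) || is.null(x$fasta) || is.null(x$exons))
    abort_exz("`model` must be a gene_model or list(fasta=, exons=)", "exz_bad_config")
  seq <- load_seqs(x$fasta)[[1L]]
  gr <- rtracklayer::import(x$exons)
  ex <- data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
  ex <- ex[order(ex$start), , drop = FALSE]
  m <- structure(list(gene_id = x$gene_id %||% "gene", genomic_seq = seq,
                      exons = ex, cds_start_mrna = as.integer(x$cds_start %||% 1L),
                      strand = "+"),
                 class = "gene_model")
  validate_gene_model(m)
}

load_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fa|fasta|fna)$", x, ignore.case = TRUE)) {
    ss <- Biostrings::readDNAStringSet(x)
    stats::setNames(as.character(ss), names(ss))
  } else {
    as.character(x)
  }
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("== characterization report ==\n")
  print(x$transcript_insertion)
  if (!is.null(x$hgvs$r)) cat("  HGVS r.: ", x$hgvs$r, "\n", sep = "")
  if (!is.null(x$repeat_hits) && nrow(x$repeat_hits))
    cat(sprintf("  repeat origin: %s (identity %.3f over %d bp, strand %s)\n",
                x$repeat_hits$family[1], x$repeat_hits$identity[1],
                x$repeat_hits$aligned_len[1], x$repeat_hits$strand[1]))
  if (!is.null(x$splice_candidates))
    cat(sprintf("  cryptic acceptors: %d motif hits, %d pass composite filter\n",
                nrow(x$splice_candidates$candidates),
                nrow(x$splice_candidates$passing)))
  if (!is.null(x$junction_call)) print(x$junction_call)
  if (!is.null(x$element_annotation)) print(x$element_annotation)
  if (!is.null(x$protein_consequence)) print(x$protein_consequence)
  cat(sprintf("  residual wild-type transcript detected: %s\n", x$wt_detected))
  invisible(x)
}

report_to_list <- function(r) {
  strip <- function(x) {
    if (inherits(x, c("transcript_insertion", "junction_call",
                      "element_annotation", "protein_consequence")))
      x <- unclass(x)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(r))
}

#' Validate the structural schema of a characterization report
#'
#' Checks presence and types of the mandatory report fields and the
#' internal consistency invariants (insert = prefix + element part;
#' junction element length compatible with the allele arithmetic).
#'
#' @param report A [run_characterize()] result.
#' @return `TRUE` (invisibly); errors describe the first violation.
#' @export
validate_report <- function(report) {
  need <- c("transcript_insertion", "repeat_hits", "splice_candidates",
            "junction_call", "element_annotation", "protein_consequence",
            "hgvs", "wt_detected", "provenance")
  missing <- setdiff(need, names(report))
  if (length(missing))
    abort_exz(paste("report lacks fields:", paste(missing, collapse = ", ")),
              "exz_bad_report")
  ti <- report$transcript_insertion
  if (!inherits(ti, "transcript_insertion"))
    abort_exz("transcript_insertion has the wrong class", "exz_bad_report")
  if (!is.na(ti$prefix) && !is.na(ti$element_part) &&
      nchar(ti$prefix) + nchar(ti$element_part) != ti$insert_len)
    abort_exz("insert length != prefix + element_part", "exz_bad_report")
  if (!is.logical(report$wt_detected))
    abort_exz("wt_detected must be logical", "exz_bad_report")
  invisible(TRUE)
}

#' Simulation-driven validation of the pipeline
#'
#' Draws `n_cases` parameter combinations from the recovery grid (element
#' length 300/1,500/6,020 nt; TSD 0/7/9/20 bp; poly-A 0/5/20 nt; both
#' orientations; random splice offsets), simulates each case with
#' [simulate_locus()] on the compact geometry, runs the transcript and
#' junction stages, and scores exact recovery of the planted parameters.
#'
#' @param n_cases Number of simulated cases (>= 1).
#' @param seed Integer seed for the whole run.
#' @param mutation_rate Element point-mutation rate for every case.
#' @param out_csv Optional path for the per-case table.
#' @return A tibble with one row per case: planted parameters, recovered
#'   values, and logical `site_ok`, `tsd_ok`, `polyA_ok`, `orient_ok`,
#'   `frame_ok`, `len_ok` columns. A `summary` attribute holds the
#'   per-parameter recovery rates.
#' @export
run_validation <- function(n_cases = 200L, seed = 42L, mutation_rate = 0,
                           out_csv = NULL) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 1L) abort_exz("`n_cases` must be >= 1", "exz_bad_input")
  grid <- expand.grid(element_len = c(300L, 1500L, 6020L),
                      tsd_len = c(0L, 7L, 9L, 20L),
                      polyA_len = c(0L, 5L, 20L),
                      orientation = c("sense", "antisense"),
                      stringsAsFactors = FALSE)
  draws <- withr::with_seed(as.integer(seed), {
    idx <- rep_len(seq_len(nrow(grid)), n_cases)
    data.frame(grid[idx, , drop = FALSE],
               offset = sample(500L:3800L, n_cases, replace = TRUE),
               acceptor_offset = sample(0L:10L, n_cases, replace = TRUE),
               donor_offset = sample(20L:140L, n_cases, replace = TRUE),
               case_seed = sample.int(1e6L, n_cases))
  })
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    d <- draws[i, ]
    # total length cannot exceed consensus body + tail; cap the body at the
    # consensus length (affects the 6,020-nt level when the tail is short)
    eff_len <- min(d$element_len, 6000L + d$polyA_len)
    sim <- simulate_locus(geometry = "compact",
                          element_len = eff_len,
                          polyA_len = d$polyA_len, tsd_len = d$tsd_len,
                          orientation = d$orientation,
                          intron_offset = d$offset,
                          acceptor_offset = d$acceptor_offset,
                          donor_offset = d$donor_offset,
                          wt_fraction = 0, plant_context = FALSE,
                          mutation_rate = mutation_rate,
                          seed = d$case_seed)
    jc <- call_junctions(sim$allele$allele_seq, sim$model)
    mut <- sim$transcripts$seq[sim$transcripts$label == "mutant"]
    ti <- find_insertion(spliced_mrna(sim$model), mut)
    tr <- sim$truth
    rows[[i]] <- tibble::tibble(
      element_len = d$element_len, tsd_len = d$tsd_len,
      polyA_len = d$polyA_len, orientation = d$orientation,
      rec_pos = jc$pos5, rec_tsd = jc$tsd_len, rec_polyA = jc$polyA_len,
      rec_orient = jc$orientation, rec_elem_len = jc$element_len,
      rec_tx_len = ti$insert_len,
      site_ok = jc$pos5 == tr$insert_pos,
      tsd_ok = jc$tsd_len == tr$tsd_len,
      tsd_err = jc$tsd_len - tr$tsd_len,
      polyA_ok = jc$polyA_len == tr$polyA_len,
      orient_ok = identical(jc$orientation, tr$orientation),
      len_ok = jc$element_len == tr$element_len,
      frame_ok = identical(frame_effect(ti$insert_len),
                           frame_effect(tr$insert_tx_len)))
  }
  out <- do.call(rbind, rows)
  okcols <- c("site_ok", "tsd_ok", "polyA_ok", "orient_ok", "len_ok", "frame_ok")
  attr(out, "summary") <- colMeans(out[okcols])
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
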