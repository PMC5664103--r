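# Independent brute-force oracles. These deliberately avoid the code paths
# (and the packages) used by the implementation so that agreement is a real
# cross-check, not a tautology.

BASES <- c("A", "C", "G", "T")

rdna <- function(n, seed = NULL, p = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# sliding-window motif counter (exact, ACGT motifs only)
oracle_count_motif <- function(seq, motif) {
  k <- nchar(motif); n <- nchar(seq)
  if (n < k) return(0L)
  starts <- seq_len(n - k + 1L)
  sum(substring(seq, starts, starts + k - 1L) == motif)
}

oracle_motif_starts <- function(seq, motif) {
  k <- nchar(motif); n <- nchar(seq)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(seq, starts, starts + k - 1L) == motif]
}

# quadratic Smith-Waterman with linear gap penalty; returns the best score
oracle_sw_score <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  prev <- numeric(m + 1L); best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    sub <- ifelse(va[i] == vb, match, mismatch)
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(0, prev[j] + sub[j], prev[j + 1L] - gap, cur[j] - gap)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# brute-force sense-frame ORF scan + the same greedy maximal-set rule
oracle_orfs <- function(seq, min_aa) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  cand <- NULL
  for (s in seq_len(max(0L, n - 2L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    j <- s + 3L; e <- NA_integer_
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% stops) { e <- j + 2L; break }
      j <- j + 3L
    }
    if (is.na(e)) next
    aa <- (e - s + 1L) %/% 3L - 1L
    if (aa >= min_aa)
      cand <- rbind(cand, data.frame(start = s, end = e,
                                     frame = ((s - 1L) %% 3L) + 1L,
                                     length_aa = aa))
  }
  if (is.null(cand)) return(data.frame(start = integer(0), end = integer(0),
                                       frame = integer(0), length_aa = integer(0)))
  cand <- cand[order(-cand$length_aa, cand$start), , drop = FALSE]
  ks <- integer(0); ke <- integer(0); pick <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= ke & cand$end[i] >= ks)) {
      pick[i] <- TRUE; ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
    }
  }
  out <- cand[pick, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# exhaustive single-insertion placement scan
oracle_insertion_placements <- function(ref, obs) {
  n <- nchar(ref); L <- nchar(obs) - n
  ok <- integer(0)
  for (p in 0:n) {
    ins <- substr(obs, p + 1L, p + L)
    rec <- paste0(substr(ref, 0L + 1L, p), ins, substr(ref, p + 1L, n))
    if (identical(rec, obs)) ok <- c(ok, p)
  }
  ok
}

# independent coding-coordinate arithmetic for intronic insertion points
oracle_hgvs_c_prefix <- function(model, pos) {
  ex <- model$exons
  for (i in seq_len(nrow(ex) - 1L)) {
    if (pos > ex$end[i] && pos < ex$start[i + 1L]) {
      cum <- 0L
      for (j in seq_len(i)) cum <- cum + (ex$end[j] - ex$start[j] + 1L)
      cl <- cum - model$cds_start_mrna + 1L
      off <- pos - ex$end[i]
      return(sprintf("c.%d+%d_%d+%dins", cl, off, cl, off + 1L))
    }
  }
  NA_character_
}

# hand-rolled standard-code translator (independent of Biostrings)
ORACLE_CODE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_translate <- function(dna) {
  n <- (nchar(dna) %/% 3L) * 3L
  if (n == 0L) return(character(0))
  starts <- seq(1L, n, by = 3L)
  unname(ORACLE_CODE[substring(dna, starts, starts + 2L)])
}

# brute-force terminal poly-A window rule
oracle_polyA <- function(seq, min_len = 5L, purity = 0.9) {
  n <- nchar(seq)
  best <- 0L
  for (w in seq_len(n)) {
    win <- strsplit(substr(seq, n - w + 1L, n), "")[[1]]
    isa <- win == "A"
    if (w > 1L && any(!isa[-1L] & !isa[-w])) break   # two consecutive non-A
    if (!isa[1L] || !isa[w]) next
    if (sum(isa) / w >= purity && w >= min_len) best <- w
  }
  best
}

# a memoized dystrophin-geometry showcase simulation shared by slower test files
.fixtures <- new.env()
showcase_sim <- function() {
  if (is.null(.fixtures$showcase))
    .fixtures$showcase <- simulate_locus(seed = 1, clean_intron = TRUE, n_decoys = 7)
  .fixtures$showcase
}
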