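DNA_BASES <- c("A", "C", "G", "T")

abort_exz <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "exonizeL1_error"), ...))
}

check_dna <- function(x, arg = deparse(substitute(x)), allow_iupac = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    abort_exz(sprintf("`%s` must be a single DNA string", arg), "exz_bad_input")
  pat <- if (allow_iupac) "^[ACGTRYSWKMBDHVN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x))
    abort_exz(sprintf("`%s` contains non-DNA characters", arg), "exz_bad_input")
  x
}

#' Generate a random DNA sequence
#'
#' Bases are drawn i.i.d. with the requested GC content. Used throughout the
#' simulator for background genomic sequence.
#'
#' @param n Sequence length in nucleotides.
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; the draw is deterministic for a fixed seed and
#'   does not touch the global RNG state.
#' @return A single uppercase DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.4, seed = NULL) {
  if (n < 0) abort_exz("`n` must be non-negative", "exz_bad_input")
  if (gc < 0 || gc > 1) abort_exz("`gc` must be in [0, 1]", "exz_bad_input")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function() paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Reverse complement of a DNA string
#'
#' @param x A DNA string.
#' @return The reverse complement as a plain character string.
#' @export
revcomp <- function(x) {
  check_dna(x, allow_iupac = TRUE)
  if (!nchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# longest common prefix length of two strings, via raw vectors
lcp_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0L)
  d <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(d)) d[1L] - 1L else m
}

lcs_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0L)
  d <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(d)) d[1L] - 1L else m
}

substr_ <- function(x, i, j) {
  if (j < i) "" else substr(x, i, j)
}

# replace bases of `seq` at 1-based position `at` with `piece`
splice_in <- function(seq, at, piece) {
  stopifnot(at >= 1L, at + nchar(piece) - 1L <= nchar(seq))
  paste0(substr_(seq, 1L, at - 1L), piece, substr_(seq, at + nchar(piece), nchar(seq)))
}

mutate_seq <- function(seq, rate, seed) {
  if (rate <= 0) return(list(seq = seq, n_sub = 0L, pos = integer(0)))
  withr::with_seed(as.integer(seed), {
    v <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    for (p in hit) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
    list(seq = paste(v, collapse = ""), n_sub = length(hit), pos = hit)
  })
}

pkg_env <- new.env(parent = emptyenv())

extdata <- function(fname) {
  p <- system.file("extdata", fname, package = "exonizeL1")
  if (!nzchar(p)) abort_exz(sprintf("bundled data file '%s' not found", fname), "exz_missing_data")
  p
}
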