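#' Bundled synthetic L1 consensus panel
#'
#' Loads the repeat-consensus library shipped with the package: a synthetic
#' 6,000-nt full-length L1-like consensus (`L1_consensus`) plus two derived
#' "subfamily" variants (`L1HS_like`, `L1PA2_like`) that differ from the base
#' consensus at ~150 diagnostic positions confined to the untranslated
#' regions. Each entry carries annotated 5'UTR, ORF1, ORF2 and 3'UTR spans
#' (1-based, closed). The panel is synthetic by construction — it reproduces
#' the architecture of a human L1 (a ~1 kb 5'UTR, a 338-codon ORF1, a
#' 1275-codon ORF2 and a short 3'UTR) without redistributing any real
#' repeat-database sequence; users may substitute a real L1/Alu library via
#' the `library`/`panel` arguments of the downstream functions.
#'
#' @param fasta Optional path to a user-supplied consensus FASTA (family
#'   names taken from headers). Feature annotations are then unavailable
#'   unless `features` is also given.
#' @param features Optional path to a tab-separated feature table with
#'   columns `family`, `feature`, `start`, `end`.
#' @return A named list with one entry per family; each entry is a list with
#'   `seq` (DNA string) and `features` (data.frame of name/start/end).
#' @export
l1_panel <- function(fasta = NULL, features = NULL) {
  if (is.null(fasta)) {
    if (!is.null(pkg_env$panel)) return(pkg_env$panel)
    fasta <- extdata("l1_panel_synthetic.fa")
    features <- extdata("l1_panel_synthetic_features.tsv")
  }
  ss <- Biostrings::readDNAStringSet(fasta)
  ft <- if (!is.null(features)) read.delim(features, stringsAsFactors = FALSE) else NULL
  panel <- lapply(seq_along(ss), function(i) {
    nm <- names(ss)[i]
    fe <- if (!is.null(ft)) ft[ft$family == nm, c("feature", "start", "end")] else
      data.frame(feature = character(0), start = integer(0), end = integer(0))
    list(family = nm, seq = as.character(ss[[i]]), features = fe)
  })
  names(panel) <- names(ss)
  if (identical(fasta, extdata("l1_panel_synthetic.fa"))) pkg_env$panel <- panel
  panel
}

read_pwm <- function(fname) {
  d <- read.delim(extdata(fname), stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$base
  storage.mode(m) <- "double"
  stopifnot(all(rownames(m) == DNA_BASES), all(abs(colSums(m) - 1) < 1e-6))
  # log2 odds against a uniform background
  log2(m / 0.25)
}

#' Position weight matrices for splice-signal scoring
#'
#' `acceptor_pwm()` returns the 23-column log-odds matrix (log2, uniform
#' background) describing a human-style 3' acceptor site over positions
#' -20..+3 relative to the intron/exon junction: a pyrimidine-rich tract,
#' the near-invariant AG dinucleotide at -2/-1, and three weakly constrained
#' exonic positions. `branchpoint_pwm()` returns the 5-column matrix for the
#' branch-point consensus yUnAy with the branch adenosine at column 4.
#' Frequencies are bundled as versioned data files under `inst/extdata`.
#'
#' @return A numeric matrix with rows A, C, G, T of log2-odds scores.
#' @export
acceptor_pwm <- function() {
  if (is.null(pkg_env$apwm)) pkg_env$apwm <- read_pwm("acceptor_pwm.tsv")
  pkg_env$apwm
}

#' @rdname acceptor_pwm
#' @export
branchpoint_pwm <- function() {
  if (is.null(pkg_env$bpwm)) pkg_env$bpwm <- read_pwm("branchpoint_pwm.tsv")
  pkg_env$bpwm
}

#' Maximum attainable score of a position weight matrix
#'
#' @param pwm A log-odds matrix as returned by [acceptor_pwm()].
#' @return The score of the argmax (consensus) sequence.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm, 2L, max))

# score many equal-length windows against a PWM; non-ACGT characters
# contribute 0 (background)
pwm_score_many <- function(windows, pwm) {
  if (!length(windows)) return(numeric(0))
  w <- ncol(pwm)
  stopifnot(all(nchar(windows) == w))
  mat <- matrix(unlist(strsplit(windows, "")), ncol = w, byrow = TRUE)
  sc <- matrix(0, nrow = length(windows), ncol = w)
  for (b in DNA_BASES) {
    hit <- mat == b
    sc[hit] <- rep(pwm[b, ], each = length(windows))[hit]
  }
  rowSums(sc)
}
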