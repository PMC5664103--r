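# One-off generator for the synthetic L1 consensus panel and splice-site PWMs
# shipped under inst/extdata/. Deterministic (seeded); rerunning reproduces the
# same files byte for byte. Run from the package root:
#   Rscript data-raw/gen_panel.R

set.seed(8100253L)
bases <- c("A", "C", "G", "T")

# L1 elements are AT-rich (~60% AT)
rdna <- function(n, p = c(A = .30, C = .20, G = .20, T = .30)) {
  paste(sample(bases, n, replace = TRUE, prob = p), collapse = "")
}

codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
stops <- c("TAA", "TAG", "TGA")
nonstop <- setdiff(codons, stops)
nonstop_noatg <- setdiff(nonstop, "ATG")

make_orf <- function(n_aa) {
  # ATG + (n_aa - 1) internal codons + stop -> protein of n_aa residues
  paste0("ATG", paste(sample(nonstop, n_aa - 1L, replace = TRUE), collapse = ""), "TAA")
}

# Layout (1-based): 5UTR 1-900 | ORF1 901-1917 (338 aa) | spacer 1918-1980 |
# ORF2 1981-5808 (1275 aa) | 3UTR 5809-6000
utr5 <- rdna(900)
# stop just before ORF1 start, in ORF1's frame (positions 898-900)
substr(utr5, 898, 900) <- "TAA"
orf1 <- make_orf(338)
spacer <- paste(sample(nonstop_noatg, 20, replace = TRUE), collapse = "")  # 60 nt
spacer <- paste0(spacer, "TAA")                                            # 63 nt, stop before ORF2
orf2 <- make_orf(1275)
utr3 <- rdna(192)
# the consensus 3' end must carry several non-A bases: the poly-A tail is
# appended downstream and purity-window detection must not leak into the UTR
substr(utr3, 188, 192) <- "GTCGC"

cons <- paste0(utr5, orf1, spacer, orf2, utr3)
stopifnot(nchar(cons) == 6000, nchar(orf1) == 1017, nchar(orf2) == 3828)

# squash homopolymer A/T runs >= 8 (would confound poly-A detection / k-mer orientation)
squash_runs <- function(s) {
  repeat {
    m <- regexpr("A{8,}|T{8,}", s)
    if (m < 0) return(s)
    i <- as.integer(m) + 3L
    substr(s, i, i) <- if (substr(s, i - 1L, i - 1L) == "A") "G" else "C"
    s
  }
}
# only squash runs outside ORFs (inside ORFs a substitution could create a stop);
# check ORFs don't contain such runs instead
stopifnot(!grepl("A{8,}|T{8,}", orf1), !grepl("A{8,}|T{8,}", orf2))
u5 <- squash_runs(utr5); u3 <- squash_runs(utr3); sp <- spacer
stopifnot(!grepl("A{8,}|T{8,}", sp))
cons <- paste0(u5, orf1, sp, orf2, u3)
stopifnot(nchar(cons) == 6000)

# --- verify no spurious ORF >= 100 aa fully outside the two planted ORFs -----
orf_scan <- function(seq, min_aa) {
  n <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  out <- NULL
  for (f in 1:3) {
    idx <- seq(f, n - 2L, by = 3L)
    cod <- paste0(v[idx], v[idx + 1L], v[idx + 2L])
    st <- which(cod == "ATG"); sp_ <- which(cod %in% stops)
    for (s in st) {
      nxt <- sp_[sp_ > s]
      if (!length(nxt)) next
      e <- nxt[1]
      if (e - s >= min_aa + 1L || (e - s) >= min_aa) { # aa count = e - s
        if ((e - s) >= min_aa) out <- rbind(out, c(idx[s], idx[e] + 2L, e - s))
      }
    }
  }
  out
}
sc <- orf_scan(cons, 100L)
# keep only maximal ones that are not the planted ORFs and don't overlap them
planted <- rbind(c(901, 1917), c(1981, 5808))
ok <- TRUE
if (!is.null(sc)) {
  for (r in seq_len(nrow(sc))) {
    s <- sc[r, 1]; e <- sc[r, 2]
    if ((s == 901 && e == 1917) || (s == 1981 && e == 5808)) next
    overl <- any(s <= planted[, 2] & e >= planted[, 1])
    if (!overl) { ok <- FALSE; message("spurious non-overlapping ORF at ", s, "-", e) }
  }
}
stopifnot(ok)

# --- subfamily variants: substitutions confined to UTRs + spacer -------------
nonorf_pos <- c(1:897, 1918:1977, 5809:5990)  # keep planted stops and the non-A 3' tail
mutate_at <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
  paste(v, collapse = "")
}
v1 <- mutate_at(cons, sort(sample(nonorf_pos, 150)))  # L1HS_like
v2 <- mutate_at(cons, sort(sample(nonorf_pos, 150)))  # L1PA2_like
hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
message("divergences: cons-v1=", hd(cons, v1), " cons-v2=", hd(cons, v2), " v1-v2=", hd(v1, v2))
stopifnot(hd(cons, v1) >= 120, hd(cons, v2) >= 120, hd(v1, v2) >= 120)
for (s in c(v1, v2)) stopifnot(!grepl("A{8,}|T{8,}", s), substr(s, 6000, 6000) != "A")

panel <- c(L1_consensus = cons, L1HS_like = v1, L1PA2_like = v2)

wrap <- function(s, w = 70) {
  n <- nchar(s)
  starts <- seq(1L, n, by = w)
  substring(s, starts, pmin(starts + w - 1L, n))
}
fa <- unlist(lapply(names(panel), function(nm) c(paste0(">", nm), wrap(panel[[nm]]))))
writeLines(fa, "inst/extdata/l1_panel_synthetic.fa")

feat <- do.call(rbind, lapply(names(panel), function(nm) {
  data.frame(family = nm,
             feature = c("5UTR", "ORF1", "ORF2", "3UTR"),
             start = c(1L, 901L, 1981L, 5809L),
             end = c(900L, 1917L, 5808L, 6000L))
}))
write.table(feat, "inst/extdata/l1_panel_synthetic_features.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# --- acceptor 3' splice-site PWM (-20..+3, AG at -2/-1) ----------------------
ap <- rbind(
  #      -20  -19  -18  -17  -16  -15  -14  -13  -12  -11  -10   -9   -8   -7   -6   -5   -4   -3   -2   -1   +1   +2   +3
  A = c(.10, .09, .08, .09, .09, .09, .08, .07, .08, .08, .09, .09, .09, .09, .08, .07, .24, .06, .97, .01, .25, .30, .25),
  C = c(.28, .30, .30, .29, .31, .30, .31, .32, .33, .34, .35, .36, .37, .38, .39, .36, .28, .40, .01, .01, .15, .25, .22),
  G = c(.12, .11, .11, .12, .10, .10, .11, .10, .10, .09, .09, .08, .09, .08, .08, .07, .22, .04, .01, .97, .50, .20, .28),
  T = c(.50, .50, .51, .50, .50, .51, .50, .51, .49, .49, .47, .47, .45, .45, .45, .50, .26, .50, .01, .01, .10, .25, .25))
stopifnot(all(abs(colSums(ap) - 1) < 1e-9))
colnames(ap) <- c(paste0("m", 20:1), paste0("p", 1:3))
write.table(cbind(base = rownames(ap), as.data.frame(ap)),
            "inst/extdata/acceptor_pwm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

# --- branch-point PWM (yUnAy, branch A at position 4) ------------------------
bp <- rbind(
  A = c(.12, .08, .30, .96, .10),
  C = c(.38, .07, .25, .01, .45),
  G = c(.10, .05, .20, .01, .10),
  T = c(.40, .80, .25, .02, .35))
stopifnot(all(abs(colSums(bp) - 1) < 1e-9))
colnames(bp) <- paste0("b", 1:5)
write.table(cbind(base = rownames(bp), as.data.frame(bp)),
            "inst/extdata/branchpoint_pwm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

message("written.")
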