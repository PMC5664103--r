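---
title: "Characterizing deep-intronic LINE-1 insertions that cause exonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing deep-intronic LINE-1 insertions that cause exonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonizeL1)
```

## The mutational mechanism

LINE-1 (L1) is the only autonomous retrotransposon active in the human
genome. A full-length element is roughly 6 kb and carries a 5′UTR with
internal promoter activity, two non-overlapping open reading frames — ORF1
(an RNA-binding protein) and ORF2 (endonuclease plus reverse
transcriptase) — a short 3′UTR and a poly-A tail. Integration proceeds by
target-site primed reverse transcription (TPRT): the ORF2 endonuclease
nicks the target, reverse transcription is primed at the nick, and repair
leaves a characteristic 7–20 bp target-site duplication (TSD) flanking
the new copy.

When such an element lands deep inside an intron of a large gene, the
genomic change is invisible to exon-centric assays (MLPA, exome or
amplicon sequencing of exons). What betrays it is the transcript: if the
intron carries a usable cryptic 3′ acceptor site just upstream of the
integration site and the element contributes a 5′ donor, the spliceosome
stitches a chimeric exon into the mRNA — a short stretch of retained
intron followed by the 5′ end of the element. The inserted block is
usually not a multiple of three, so the reading frame shifts and a
premature stop truncates the protein. Because the canonical splice sites
still compete, a minor fraction of correctly spliced transcript often
persists, which can soften the phenotype (in the dystrophin gene, the
difference between Duchenne- and Becker-type severity).

`exonizeL1` implements the complete characterization of such an event as
a reusable pipeline, and pairs it with a simulator that generates loci
with known ground truth so every stage can be validated by parameter
recovery.

## Pipeline stages and their models

### Transcript comparison

`find_insertion()` explains an observed transcript as the reference mRNA
with one contiguous insertion plus at most `max_subs` isolated
substitutions (default 2). For every possible insertion point $p$ the
number of substitutions needed is

$$ m(p) = \mathrm{mismatch}\big(\text{obs}_{1..p},\ \text{ref}_{1..p}\big)
        + \mathrm{mismatch}\big(\text{obs}_{p+L+1..n+L},\ \text{ref}_{p+1..n}\big), $$

computed for all $p$ in one pass from cumulative prefix and suffix
mismatch counts ($L$ is the length difference). With `max_subs = 0` this
is exactly longest-common-prefix/suffix anchoring. All placements
achieving the minimum form the ambiguity interval; the leftmost placement
is the stored normal form and the rightmost (3′-most) placement drives
HGVS output and the prefix/element split, following the HGVS 3′ rule.
Inserting the reported sequence back into the reference must reproduce
the observed transcript — this reconstruction invariant is asserted on
every call.

### Repeat classification

`classify_insert()` aligns the insert locally (Smith–Waterman through
`Biostrings::pairwiseAlignment`) against each consensus in the panel and
its reverse complement, with BLASTN-like scoring for short queries:
match +1, mismatch −1, linear gap −2 per base. Identity is reported as
matches over aligned columns excluding gaps — the convention in which a
103-nt insert with a 98-nt perfect element match reads "98/98 = 1.00 over
98 bp". The insert-side span of the best hit feeds `split_insert()`,
which divides the insert into the retained intronic prefix and the
element-derived part.

### Cryptic acceptor scanning

Given the retained prefix (e.g. `AATTC`), `scan_motif()` finds every
`AG` + prefix occurrence in the host intron — each one marks a position
where a cryptic acceptor would produce exactly that retained sequence.
Candidates are then ranked by a *composite* criterion
(`score_candidates()` + `rank_candidates()`):

* an acceptor score — log₂-odds of the −20..+3 window under a bundled
  position weight matrix describing a human-style 3′ splice site
  (pyrimidine-rich tract, near-invariant `AG` at −2/−1, weak exonic
  positions), against a uniform background;
* a branch-point score — best match of a 5-position weight matrix
  (consensus `yUnAy`, invariant branch adenosine) in the window 18–44 nt
  upstream of the junction, the standard geometry of human lariat
  formation.

A candidate passes when the acceptor score reaches `t1` (default 60% of
the matrix maximum) and a branch point scores at least `t2` (default 70%
of its maximum). The published scorers used in diagnostic practice are
proprietary; this package deliberately ships a single transparent PWM
scorer with versioned frequency tables under `inst/extdata/`, plus the
`apwm`/`bpwm` arguments as a pluggable scorer interface. Reproducing any
proprietary score is explicitly not a goal — the narrowing logic
(many motif hits, few composite passes) is the reproducible content.

### Junction mapping, TSD and poly-A

`map_junctions()` anchors the insertion allele against the reference by
longest common prefix and suffix. With a TSD present the two anchors
disagree by exactly the duplication length: the inserted block can slide
across the duplicated target. That width *is* the TSD call
(`call_junctions()`), cross-checked by the suffix/prefix comparison in
`detect_tsd()`; the rightmost anchor is reported as the insertion point,
which matches donor-anchored HGVS coordinates of the form
`c.7542+8951_7542+8952ins…` produced by `to_hgvs_c()`. Positive
(`+offset`) numbering from the upstream exon is used throughout the
intron rather than switching to acceptor-anchored negative offsets
mid-intron, so deep insertion points read the way they are usually
reported in case descriptions.

The element sequence is the inserted block minus the TSD copy
(reverse-complemented for antisense integrations). `detect_polyA()`
measures the longest terminal window that starts and ends with `A`, has
A-fraction ≥ `purity` (default 0.9), is at least `min_len` (default 5)
long, and contains no two consecutive non-A bases. The last condition is
what lets the rule tolerate isolated substitutions inside a genuine tail
while refusing to leak across a block of flanking non-A sequence.

### Element architecture and subfamily

`find_orfs()` enumerates every sense-strand ATG-to-stop ORF of at least
`min_aa` codons (default 100) and resolves them greedily to a maximal
non-overlapping set by length. `annotate_structure()` then decides the
five hallmarks — 5′UTR, ORF1, ORF2, 3′UTR, poly-A — calling an ORF
present when its length is within 5% of the matched consensus ORF
(a stated proxy for element-intactness criteria; functional
retrotransposition competence is out of scope). The ORF1/ORF2 protein
domains (CC, RRM, CTD; EN, Z, RT, C) are reported as fixed proportional
sub-spans labelled `schematic`: domain-level HMM search is deliberately
not reimplemented here. `assign_subfamily()` picks the nearest panel
consensus by global identity (column-wise for equal lengths,
global-local alignment for 5′-truncated elements), breaking ties
alphabetically with a flag.

### Protein consequence

`frame_effect()` is the modulo-3 rule. `protein_consequence()` translates
the mutant CDS, finds the first residue differing from the reference and
reports `p.<Ref><codon><New>fs*<N>` where the new stop is the `N`-th
codon counting the first changed residue as 1 (HGVS convention: a stop
created immediately at the first changed codon would be `fs*1` and is
emitted in nonsense form `p.<Ref><codon>*`). Worked diagram for a
frameshift at codon 2515 with the stop 20 codons later:

```
codon:      2514   2515   2516  ...  2533   2534
reference:   Lys    Asp    Ser  ...   Leu    Gly
mutant:      Lys    Glu*   ...frameshifted... *      -> p.Asp2515Glufs*20
                    ^ first changed (counted as 1)   ^ stop = codon 20
```

Only the standard nuclear codon table is supported (no selenocysteine
recoding). The residual wild-type transcript is reported as a boolean
(`wt_detected`) next to the frameshift call; the package makes no attempt
to model the genotype–phenotype inference quantitatively.

## The simulator: what it emulates, and what it does not

`simulate_locus()` generates the complete study design with ground truth:

* a multi-exon gene with canonical `GT…AG` introns and (optionally) an
  open CDS, at configurable GC content — the default "dystrophin" geometry is
  a dystrophin-like locus: 52 exons, 7,542 coding bases upstream of the
  host intron, a 44,000-nt intron 51;
* an element derived from the bundled consensus: 3′-anchored truncation
  (the dominant mode of incomplete L1 integration), per-base point
  mutations at `mutation_rate`, and a poly-A tail — 6,020 nt total
  (6,000 + 20) at the defaults;
* a TPRT insertion allele: duplicated target of `tsd_len` (default 9)
  ending at the insertion point, sense or antisense orientation —
  default insertion 8,951 nt into the host intron;
* the spliced transcript mixture: the aberrant transcript retains
  `acceptor_offset` intronic bases (default 5) and exonizes
  `donor_offset` element bases (default 98; 103-nt insertion in total),
  next to a wild-type transcript of weight `wt_fraction`. Published case
  descriptions report the residual wild-type band qualitatively, so the
  fraction is exposed as a free parameter (default 0.05) rather than
  fixed.

When `plant_context = TRUE` the simulator writes a strong acceptor
context upstream of the insertion point — branch point `CTAAC` 25 nt
upstream of the cryptic junction, a 16-nt consensus polypyrimidine
tract, and the `AG` completing a duplicated target that ends
`…AG + prefix` (`AAAGAATTC` at the defaults). `clean_intron = TRUE`
scrubs all other `AG`+prefix occurrences and can plant a chosen number
of bare decoy motifs, enabling exact-count experiments such as an
8-hit scan that narrows to the single complete context.

Two properties of the generator are deliberate design choices rather
than accidents:

* **Clean junctions (default).** The reference base immediately 3′ of
  the insertion point is forced to differ from the element's first
  (oriented) base, and the base immediately 5′ of the duplicated target
  differs from the element's last base and from `A`. TPRT leaves no
  signal that could disambiguate chance junction homology, so without
  this constraint the anchor interval overestimates the TSD by one base
  in a quarter of random draws — a property of the sequences themselves,
  not of any detector. Clean junctions make exact TSD recovery a
  well-posed target; `clean_junctions = FALSE` restores fully random
  flanks.
* **Background is i.i.d.** Real intronic sequence is repeat-rich and
  autocorrelated; the simulator's background is not. Passing recovery
  tests therefore demonstrates correctness of the junction arithmetic,
  scanning and scoring machinery — not robustness to segmental
  duplications, nested repeats, or homopolymer-rich targets. Orientation
  calls use interior 21-mers and would need longer seeds in
  repeat-dense real data.

The simulator also does not model sequencing reads, sequencing error,
exonic insertions, 5′ inversions, or somatic mosaicism.

## Coordinates and numerical choices

* All internal coordinates are 1-based and closed, the
  IRanges/Bioconductor convention; HGVS output is produced from the
  3′-most placement. Spans reported by `classify_insert()` follow the
  same convention (a 98-nt match after a 5-nt prefix spans 6..103).
* Anchor ties at junction homopolymers resolve to the leftmost block
  placement, with both extreme placements kept in the `ambiguity` field.
* PWM scores are log₂-odds against a uniform background; `N` or padded
  positions contribute 0. Thresholds are expressed as fractions of each
  matrix's maximum so they survive matrix replacement.
* The branch-point scan requires a literal `A` at the branch position —
  a weight-matrix high-scorer without an adenosine is not a usable
  branch point.
* `splice_transcripts()` accepts a `seed` argument for interface
  uniformity but is deterministic: transcript weights are mixture
  parameters, not draws.
* Report serialization uses plain JSON; `validate_report()` is a
  structural validator implemented in the package.

## Validation design and problem sizes

The test suite validates every stage against independent brute-force
oracles (sliding-window motif counts, quadratic Smith–Waterman,
exhaustive ORF scan, exon-table coordinate arithmetic, a hand-rolled
translator) on over a thousand random instances, and validates the
pipeline end-to-end by parameter recovery: 200 simulated insertions over
the grid element length {300, 1,500, 6,020} × TSD {0, 7, 9, 20} ×
poly-A {0, 5, 20} × both orientations, on a compact 3-exon locus with a
4,500-nt host intron. At mutation rate 0 the suite requires exact
recovery of insertion coordinate, TSD length, poly-A length, orientation
and frameshift classification in all cases; at mutation rate 0.01 it
requires TSD calls within ±1 in at least 95% of cases. The compact locus
keeps the full grid inexpensive; the dystrophin-scale geometry (52
exons, 44-kb intron, 6-kb element) is exercised by the showcase tests
and the acceptance script.

## Known limitations

* One contiguous insertion per allele; multiple or nested insertions and
  rearrangements produce structured errors rather than calls.
* TSD/poly-A ambiguity at A-rich targets is resolved by convention (the
  poly-A is measured after removing the TSD copy); on real data with an
  adenosine immediately 5′ of the target the split between tail and
  duplication is genuinely underdetermined.
* The acceptor/branch-point matrices are compact summaries, not
  maximum-entropy or deep models; ranking is meant to narrow candidates
  for confirmation, not to predict splicing efficiency.
* Subfamily assignment is nearest-consensus identity; it does not model
  phylogenetic structure among subfamilies.
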