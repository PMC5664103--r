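test_that("frame effect follows insertion length modulo 3", {
  expect_identical(frame_effect(103), "frameshift")
  expect_identical(frame_effect(102), "in-frame")
  expect_identical(frame_effect(0), "in-frame")
  expect_error(frame_effect(-1), class = "exz_bad_input")
})

test_that("first affected codon arithmetic matches the translation oracle", {
  expect_equal(first_affected_codon(7542), 2515)
  expect_equal(first_affected_codon(3), 2)
  expect_equal(first_affected_codon(1), 1)
  expect_error(first_affected_codon(0), class = "exz_upstream_of_cds")

  # against a brute-force translate-and-compare oracle: a frameshifting
  # insert can first change no codon earlier than ceiling((pos+1)/3)
  set.seed(22)
  nonstop <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  for (i in 1:40) {
    cds <- paste0("ATG", paste(sample(nonstop, 60, TRUE), collapse = ""), "TAA")
    pos <- sample(seq_len(nchar(cds) - 4), 1)
    ins <- rdna(sample(c(1, 2, 4, 5), 1))
    mut <- paste0(substr(cds, 1, pos), ins, substr(cds, pos + 1, nchar(cds)))
    ref_pep <- oracle_translate(cds)
    mut_pep <- oracle_translate(mut)
    m <- min(length(ref_pep), length(mut_pep))
    first_diff <- which(ref_pep[1:m] != mut_pep[1:m])[1]
    if (is.na(first_diff)) next
    expect_gte(first_diff, first_affected_codon(pos))
  }
})

test_that("protein consequences agree with independent translation", {
  set.seed(23)
  nonstop <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  for (i in 1:30) {
    cds <- paste0("ATG", paste(sample(nonstop, 80, TRUE), collapse = ""), "TAA")
    pos <- sample(3:(nchar(cds) - 10), 1)
    ins <- rdna(sample(c(1, 2, 4, 5, 7), 1))
    pc <- protein_consequence(cds, ins, pos)
    expect_true(pc$frameshift)
    expect_identical(frame_effect(nchar(ins)), "frameshift")
    mut <- paste0(substr(cds, 1, pos), ins, substr(cds, pos + 1, nchar(cds)))
    mut_pep <- oracle_translate(mut)
    ref_pep <- oracle_translate(cds)
    if (!is.na(pc$first_affected_codon)) {
      k <- pc$first_affected_codon
      if (k > 1)
        expect_identical(mut_pep[1:(k - 1)], ref_pep[1:(k - 1)])
      if (!is.na(pc$stop_offset)) {
        # the new stop sits exactly stop_offset codons from the first change
        expect_identical(mut_pep[k + pc$stop_offset - 1], "*")
        if (pc$stop_offset > 1)
          expect_false(any(mut_pep[k:(k + pc$stop_offset - 2)] == "*"))
      }
    }
  }
})

test_that("constructed edge cases produce the documented notation", {
  # immediate in-frame stop right at the first affected codon
  cds <- "ATGAAACCCGGGTAA"
  pc <- protein_consequence(cds, "TAAT", 3)
  expect_true(pc$frameshift)
  expect_equal(pc$first_affected_codon, 2)
  expect_equal(pc$stop_offset, 1)
  expect_identical(pc$hgvs_p, "p.Lys2*")

  # in-frame single-residue insertion
  pc2 <- protein_consequence(cds, "GCT", 3)
  expect_false(pc2$frameshift)
  expect_identical(pc2$hgvs_p, "p.Met1_Lys2insAla")

  # UTR insertions yield no protein consequence record
  expect_null(protein_consequence(cds, "AAA", 0))
  expect_null(protein_consequence(cds, "AAA", nchar(cds)))
  expect_error(protein_consequence("AAATTT", "A", 2), class = "exz_bad_input")
})

test_that("the dystrophin-like showcase yields a codon-2515 frameshift", {
  sim <- showcase_sim()
  mrna <- spliced_mrna(sim$model)
  mut <- sim$transcripts$seq[sim$transcripts$label == "mutant"]
  ti <- find_insertion(mrna, mut, model = sim$model)
  cds_len <- (nchar(mrna) %/% 3) * 3
  cds <- substr(mrna, 1, cds_len)
  pc <- protein_consequence(cds, ti$insert_seq_3p, ti$right_pos)
  expect_true(pc$frameshift)
  expect_equal(pc$first_affected_codon, 2515)
  expect_match(pc$hgvs_p, "^p\\.[A-Z][a-z]{2}2515[A-Z][a-z]{2}fs\\*[0-9]+$")
})
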