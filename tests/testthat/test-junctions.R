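test_that("junction mapping recovers all planted parameters on the showcase case", {
  sim <- showcase_sim()
  jc <- call_junctions(sim$allele$allele_seq, sim$model)
  expect_equal(jc$pos5, sim$truth$insert_pos)
  expect_equal(jc$pos3, jc$pos5)
  expect_equal(jc$tsd_len, 9)
  expect_identical(jc$tsd_seq, "AAAGAATTC")
  expect_equal(jc$polyA_len, 20)
  expect_equal(jc$element_len, 6020)
  expect_identical(jc$orientation, "sense")
  expect_equal(jc$intron_index, 51)
  # inserted block = element + one TSD copy
  expect_equal(diff(jc$ambiguity), jc$tsd_len)
  # length bookkeeping invariant
  expect_equal(jc$element_len + jc$tsd_len + nchar(sim$model$genomic_seq),
               nchar(sim$allele$allele_seq))
  expect_match(jc$hgvs_c, "^c\\.7542\\+8951_7542\\+8952ins")
})

test_that("an unchanged allele maps to a zero-length insertion", {
  gm <- make_gene_model(3, 100, c(300, 800), seed = 9)
  mj <- map_junctions(gm$genomic_seq, gm$genomic_seq)
  expect_equal(mj$ins_len, 0)
  jc <- call_junctions(gm$genomic_seq, gm)
  expect_equal(jc$element_len, 0)
  expect_error(map_junctions(substr(gm$genomic_seq, 1, 100), gm$genomic_seq),
               class = "exz_not_simple_insertion")
})

test_that("antisense insertions are recognized and measured", {
  sim <- simulate_locus(geometry = "compact", orientation = "antisense",
                        element_len = 1500, polyA_len = 20, tsd_len = 12,
                        intron_offset = 1500, plant_context = FALSE, seed = 14)
  jc <- call_junctions(sim$allele$allele_seq, sim$model)
  expect_identical(jc$orientation, "antisense")
  expect_equal(jc$tsd_len, 12)
  expect_equal(jc$polyA_len, 20)
  expect_equal(jc$element_len, 1500)
  expect_equal(jc$pos5, sim$truth$insert_pos)
})

test_that("TSD lengths 0..30 round-trip exactly with clean flanks", {
  for (tsd in 0:30) {
    for (s in 1:2) {
      sim <- simulate_locus(geometry = "compact", element_len = 320,
                            polyA_len = 20, tsd_len = tsd,
                            intron_offset = 800 + 37 * tsd + s,
                            plant_context = FALSE, seed = 1000 + 31 * s + tsd)
      jc <- call_junctions(sim$allele$allele_seq, sim$model)
      expect_equal(jc$tsd_len, tsd)
      expect_identical(jc$tsd_seq, sim$truth$tsd_seq)
    }
  }
})

test_that("detect_tsd follows the suffix/prefix contract", {
  left <- paste0(rdna(30, seed = 3), "C", "AAAGAATTC")
  right <- paste0("AAAGAATTC", "G", rdna(30, seed = 4))
  got <- detect_tsd(left, right)
  expect_equal(got$tsd_len, 9)
  expect_identical(got$tsd_seq, "AAAGAATTC")
  expect_equal(detect_tsd("ACGT", "GGGG")$tsd_len, 0)

  # single-target-copy check rejects a pre-existing tandem k-mer
  ref <- paste0(rdna(20, seed = 5), "TT", rdna(20, seed = 6))
  pos <- 21
  expect_equal(detect_tsd(substr(ref, 1, 21), substr(ref, 22, 42),
                          ref_point = list(ref = ref, pos = pos))$tsd_len, 0)
})

test_that("poly-A detection applies the purity-window rule", {
  expect_equal(detect_polyA(paste0("GATC", strrep("A", 20))), 20)
  expect_equal(detect_polyA("GATC"), 0)
  expect_equal(detect_polyA(""), 0)
  mixed <- paste0("GCGC", strrep("A", 19), "G", strrep("A", 5))
  expect_equal(detect_polyA(mixed, min_len = 5, purity = 0.9), 25)
  expect_equal(detect_polyA(mixed, min_len = 5, purity = 0.99), 5)
  # brute-force agreement on random tails
  set.seed(15)
  for (i in 1:50) {
    s <- paste0(rdna(30), paste(sample(c("A", "G"), 25, TRUE, c(.9, .1)), collapse = ""))
    expect_equal(detect_polyA(s), oracle_polyA(s))
  }
})

test_that("intronic HGVS c. coordinates match the exon-table oracle", {
  gm <- make_gene_model(6, c(100, 200, 150, 90, 60, 120),
                        c(500, 1000, 2000, 800, 3000), cds_start = 30, seed = 16)
  expect_error(to_hgvs_c(50, gm), class = "exz_exonic_insertion")
  itab_first_base <- gm$exons$end[1] + 1
  expect_match(to_hgvs_c(itab_first_base, gm), "\\+1_[0-9]+\\+2ins")
  set.seed(17)
  for (i in 1:100) {
    intr <- sample(1:5, 1)
    lo <- gm$exons$end[intr] + 1
    hi <- gm$exons$start[intr + 1] - 2
    pos <- sample(lo:hi, 1)
    expect_identical(to_hgvs_c(pos, gm),
                     oracle_hgvs_c_prefix(gm, pos))
  }
})
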