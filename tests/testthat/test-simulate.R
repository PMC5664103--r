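test_that("gene models have the requested geometry and canonical introns", {
  gm <- make_gene_model(3, 120, c(500, 44000), cds_start = 10, gc = 0.4, seed = 1)
  expect_s3_class(gm, "gene_model")
  expect_equal(nchar(spliced_mrna(gm)), 360)
  expect_equal(nrow(gm$exons), 3)
  it <- gm$exons$start[3] - gm$exons$end[2] - 1
  expect_equal(it, 44000)
  # every intron begins GT and ends AG
  for (i in 1:2) {
    s <- gm$exons$end[i] + 1
    e <- gm$exons$start[i + 1] - 1
    expect_equal(substr(gm$genomic_seq, s, s + 1), "GT")
    expect_equal(substr(gm$genomic_seq, e - 1, e), "AG")
  }

  tiny <- make_gene_model(2, 3, 10, cds_start = 1, gc = 0.5, seed = 0)
  expect_equal(nchar(spliced_mrna(tiny)), 6)
  expect_equal(nchar(tiny$genomic_seq), 16)

  expect_error(make_gene_model(2, 0, 10), class = "exz_bad_input")
  expect_error(make_gene_model(2, 10, c(10, 10)), class = "exz_bad_input")
})

test_that("generation is deterministic for a fixed seed", {
  a <- make_gene_model(4, 80, c(200, 300, 400), seed = 7)
  b <- make_gene_model(4, 80, c(200, 300, 400), seed = 7)
  expect_identical(a$genomic_seq, b$genomic_seq)
  ea <- make_element("L1_consensus", polyA_len = 10, mutation_rate = 0.02, seed = 7)
  eb <- make_element("L1_consensus", polyA_len = 10, mutation_rate = 0.02, seed = 7)
  expect_identical(ea$seq, eb$seq)
  sa <- simulate_locus(geometry = "compact", seed = 7)
  sb <- simulate_locus(geometry = "compact", seed = 7)
  expect_identical(sa$allele$allele_seq, sb$allele$allele_seq)
  expect_identical(sa$transcripts$seq, sb$transcripts$seq)
})

test_that("elements carry hallmark features, truncation removes them", {
  el <- make_element("L1_consensus", length = 6000, polyA_len = 20,
                     mutation_rate = 0, seed = 3)
  expect_equal(nchar(el$seq), 6020)
  expect_true(all(c("5UTR", "ORF1", "ORF2", "3UTR", "polyA") %in% el$features$feature))
  expect_true(el$intact)

  tr <- make_element("L1_consensus", truncate_5p = 5800, polyA_len = 20, seed = 3)
  expect_equal(nchar(tr$seq), 220)
  expect_false(any(c("5UTR", "ORF1") %in% tr$features$feature))
  expect_false(tr$intact)

  expect_error(make_element("NoSuchFamily"), class = "exz_unknown_family")
})

test_that("element mutation load matches the binomial expectation", {
  el <- make_element("L1_consensus", length = 6000, polyA_len = 0,
                     mutation_rate = 0.05, seed = 11)
  cons <- l1_panel()[["L1_consensus"]]$seq
  ham <- sum(strsplit(el$seq, "")[[1]] != strsplit(cons, "")[[1]])
  expect_equal(ham, el$n_sub)        # oracle: direct count of applied substitutions
  expect_lt(abs(ham / 6000 - 0.05), 0.01)
})

test_that("insertion alleles satisfy the TPRT length and TSD invariants", {
  gm <- make_gene_model(3, 150, c(400, 3000), seed = 5)
  el <- make_element("L1_consensus", truncate_5p = 5500, polyA_len = 10, seed = 5)
  itab_start <- gm$exons$end[2] + 1

  for (tsd in c(0L, 9L, 12L, 30L)) {
    al <- insert_element(gm, itab_start + 1000, el, tsd_len = tsd)
    expect_equal(nchar(al$allele_seq), nchar(gm$genomic_seq) + nchar(el$seq) + tsd)
    if (tsd > 0) {
      left <- substr(al$allele_seq, al$insert_pos - tsd + 1, al$insert_pos)
      right <- substr(al$allele_seq, al$insert_pos + nchar(el$seq) + 1,
                      al$insert_pos + nchar(el$seq) + tsd)
      expect_identical(left, right)
      expect_identical(left, al$tsd_seq)
    }
  }

  # exonic insertion points are rejected
  expect_error(insert_element(gm, gm$exons$start[1] + 10, el),
               class = "exz_exonic_insertion")
  expect_error(insert_element(gm, itab_start + 1000, el, tsd_len = 31),
               class = "exz_bad_input")
})

test_that("length conservation holds across random simulator draws", {
  set.seed(99)
  for (i in 1:15) {
    tsd <- sample(0:30, 1)
    pa <- sample(0:25, 1)
    len <- sample(c(300, 1200, 6020), 1)
    ori <- sample(c("sense", "antisense"), 1)
    sim <- simulate_locus(geometry = "compact", element_len = min(len, 6000 + pa),
                          polyA_len = pa, tsd_len = tsd, orientation = ori,
                          intron_offset = sample(500:3500, 1),
                          plant_context = FALSE, seed = sample.int(1e6, 1))
    expect_equal(nchar(sim$allele$allele_seq),
                 nchar(sim$model$genomic_seq) + sim$truth$element_len + tsd)
  }
})

test_that("splice_transcripts composes the exonized transcript correctly", {
  sim <- simulate_locus(geometry = "compact", seed = 21, acceptor_offset = 5,
                        donor_offset = 98, wt_fraction = 0.05)
  expect_setequal(sim$transcripts$label, c("mutant", "wildtype"))
  mut <- sim$transcripts$seq[sim$transcripts$label == "mutant"]
  expect_equal(nchar(mut), nchar(spliced_mrna(sim$model)) + 103)

  # identity splicing returns the reference mRNA only
  tr0 <- splice_transcripts(sim$allele, sim$model, acceptor_offset = 0,
                            donor_offset = 0, wt_fraction = 1)
  expect_equal(nrow(tr0), 1)
  expect_identical(tr0$seq, spliced_mrna(sim$model))

  expect_error(splice_transcripts(sim$allele, sim$model, donor_offset = 1e6),
               class = "exz_bad_input")
})

test_that("scrub_motif removes and plant_sites adds motif occurrences", {
  set.seed(4)
  s <- rdna(5000)
  s2 <- scrub_motif(s, "AGAATTC")
  expect_equal(oracle_count_motif(s2, "AGAATTC"), 0L)
  s3 <- plant_sites(s2, "AGAATTC", c(100, 900, 2500))
  expect_equal(oracle_count_motif(s3, "AGAATTC"), 3L)
})
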