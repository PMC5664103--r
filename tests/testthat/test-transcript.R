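test_that("find_insertion recovers a simple insertion (exhaustive-scan oracle)", {
  ref <- "ACGTACGT"
  obs <- "ACGTTTACGT"
  ti <- find_insertion(ref, obs)
  placements <- oracle_insertion_placements(ref, obs)
  expect_equal(ti$left_pos, min(placements))
  expect_equal(ti$right_pos, max(placements))
  expect_equal(ti$insert_len, 2)
  expect_equal(ti$insert_seq, substr(obs, min(placements) + 1, min(placements) + 2))
  expect_equal(ti$insert_seq, "TT")
})

test_that("equal sequences give an empty insertion with wild-type flag", {
  ti <- find_insertion("ACGTACGT", "ACGTACGT")
  expect_equal(ti$insert_len, 0)
  expect_true(ti$wt_detected)
  expect_null(to_hgvs_r(ti, make_gene_model(2, 4, 10, seed = 1)))
})

test_that("non-insertion differences raise structured errors", {
  expect_error(find_insertion("ACGTACGT", "ACGT"),
               class = "exz_not_simple_insertion")
  # two separated insertions cannot be explained by one placement
  set.seed(1)
  ref <- rdna(400)
  obs <- paste0(substr(ref, 1, 100), "GGGGCCCC", substr(ref, 101, 300),
                "TTTTAAAA", substr(ref, 301, 400))
  expect_error(find_insertion(ref, obs, max_subs = 2),
               class = "exz_not_simple_insertion")
})

test_that("isolated substitutions are tolerated up to max_subs", {
  set.seed(2)
  ref <- rdna(600)
  ins <- rdna(40)
  obs <- paste0(substr(ref, 1, 250), ins, substr(ref, 251, 600))
  # two substitutions away from the insertion
  substr(obs, 50, 50) <- setdiff(BASES, substr(obs, 50, 50))[1]
  substr(obs, 500, 500) <- setdiff(BASES, substr(obs, 500, 500))[1]
  ti <- find_insertion(ref, obs, max_subs = 2)
  expect_equal(ti$insert_len, 40)
  expect_equal(ti$n_subs, 2)
  expect_error(find_insertion(ref, obs, max_subs = 1),
               class = "exz_not_simple_insertion")
})

test_that("insertion length and placement are recovered across 200 simulated cases", {
  set.seed(33)
  for (i in 1:200) {
    n <- 1000
    ref <- rdna(n)
    L <- sample(1:500, 1)
    p <- sample(0:n, 1)
    ins <- rdna(L)
    obs <- paste0(substr(ref, 1, p), ins, substr(ref, p + 1, n))
    ti <- find_insertion(ref, obs)
    expect_equal(ti$insert_len, L)
    # reported placement interval brackets the true placement; unique flanks
    # mean an exact call
    expect_true(ti$left_pos <= p && p <= ti$right_pos)
    if (ti$left_pos == ti$right_pos) expect_equal(ti$left_pos, p)
    # reconstruction invariant
    rec <- paste0(substr(ref, 1, ti$left_pos), ti$insert_seq,
                  substr(ref, ti$left_pos + 1, n))
    expect_identical(rec, obs)
  }
})

test_that("split_insert separates retained prefix from element part", {
  sim <- showcase_sim()
  mut <- sim$transcripts$seq[sim$transcripts$label == "mutant"]
  ti <- find_insertion(spliced_mrna(sim$model), mut, model = sim$model)
  expect_equal(ti$insert_len, 103)
  expect_equal(ti$left_exon, 51)
  expect_equal(ti$right_exon, 52)
  hits <- classify_insert(ti$insert_seq_3p)
  expect_equal(hits$insert_start[1], 6)
  ti <- split_insert(ti, hits[1, ])
  expect_equal(nchar(ti$prefix), 5)
  expect_identical(ti$prefix, "AATTC")
  expect_identical(paste0(ti$prefix, ti$element_part), ti$insert_seq_3p)

  # a hit covering the whole insert leaves an empty prefix
  full <- split_insert("ACGTACGTACGT", list(insert_start = 1, insert_end = 12))
  expect_identical(full$prefix, "")
  # a non-terminal hit flags a possible retained suffix
  expect_warning(part <- split_insert("ACGTACGTACGT",
                                      list(insert_start = 3, insert_end = 8)),
                 "retained")
  expect_true(attr(part, "retained_suffix"))
  expect_identical(part$prefix, "AC")
})

test_that("simulator prefix length round-trips through the split", {
  sim <- simulate_locus(geometry = "compact", acceptor_offset = 7,
                        donor_offset = 60, seed = 12)
  mut <- sim$transcripts$seq[sim$transcripts$label == "mutant"]
  ti <- find_insertion(spliced_mrna(sim$model), mut, model = sim$model)
  hits <- classify_insert(ti$insert_seq_3p, min_score = 15)
  ti <- split_insert(ti, hits[1, ])
  expect_equal(nchar(ti$prefix), 7)
  expect_equal(ti$insert_len, 67)
})

test_that("HGVS r. strings are well formed and parse back to the call", {
  sim <- showcase_sim()
  mut <- sim$transcripts$seq[sim$transcripts$label == "mutant"]
  ti <- find_insertion(spliced_mrna(sim$model), mut, model = sim$model)
  s <- to_hgvs_r(ti, sim$model)
  expect_identical(s, "r.7542_7543ins(103)")
  m <- regmatches(s, regexec("^r\\.(\\d+)_(\\d+)ins\\((\\d+)\\)$", s))[[1]]
  expect_length(m, 4)
  expect_equal(as.integer(m[3]), as.integer(m[2]) + 1L)   # parse-and-rebuild oracle
  expect_equal(as.integer(m[2]), ti$right_pos - sim$model$cds_start_mrna + 1L)
  expect_equal(as.integer(m[4]), ti$insert_len)
})

test_that("wild-type detection aggregates across transcripts", {
  sim <- simulate_locus(geometry = "compact", seed = 3, wt_fraction = 0.05)
  res <- classify_transcripts(spliced_mrna(sim$model), sim$transcripts$seq,
                              model = sim$model)
  expect_true(all(vapply(res, `[[`, logical(1), "wt_detected")))
  lens <- vapply(res, `[[`, integer(1), "insert_len")
  expect_setequal(lens, c(sim$truth$insert_tx_len, 0L))
})
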