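test_that("scan_motif equals the sliding-window oracle on random sequences", {
  set.seed(5)
  for (i in 1:40) {
    s <- rdna(sample(500:2000, 1), p = c(.3, .2, .2, .3))
    pf <- rdna(sample(3:6, 1))
    cands <- scan_motif(s, pf)
    want <- oracle_motif_starts(s, paste0("AG", pf)) + 2L
    expect_equal(cands$intron_offset, want)
    expect_true(all(cands$motif_seq == pf))
  }
  expect_equal(nrow(scan_motif("AAAA", "AATTC")), 0)
})

test_that("IUPAC codes in the prefix are expanded", {
  s <- "TTAGAATTCGGAGAACTCTT"
  expect_equal(nrow(scan_motif(s, "AATTC")), 1)
  expect_equal(scan_motif(s, "AAYTC")$intron_offset, c(5L, 14L))
})

test_that("the PWM consensus window attains the maximal acceptor score", {
  pwm <- acceptor_pwm()
  consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  expect_equal(as.numeric(score_acceptor(consensus)), pwm_max_score(pwm))
  expect_error(score_acceptor("ACGT"), class = "exz_bad_input")
})

test_that("random windows score well below the consensus (Monte Carlo)", {
  set.seed(6)
  pwm <- acceptor_pwm()
  wins <- vapply(1:10000, function(i) rdna(ncol(pwm)), character(1))
  scores <- vapply(wins, function(w) as.numeric(score_acceptor(w, pwm)), numeric(1))
  expect_lt(mean(scores), pwm_max_score(pwm))
  expect_lt(mean(scores), 0.5 * pwm_max_score(pwm))
})

test_that("branch points are located at the branch adenosine", {
  fb <- find_branchpoint("GGGTACTAACGGG")
  expect_false(is.null(fb))
  # the A of 'TACTAAC' position 6 (absolute position 9 of the window)
  expect_equal(13 - fb$offset + 1, 9)
  expect_null(find_branchpoint(strrep("G", 30)))
  expect_null(find_branchpoint("ACG"))
})

test_that("planted branch points are recovered in >= 90% of 100 seeds", {
  set.seed(7)
  hits <- 0
  for (i in 1:100) {
    w <- rdna(27)
    w <- paste0(substr(w, 1, 9), "CTAAC", substr(w, 15, 27))  # branch A at 13
    fb <- find_branchpoint(w)
    if (!is.null(fb) && (27 - fb$offset + 1) == 13) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("acceptor scores depend only on the window, not the flanks", {
  # the same 23-nt context embedded in two different backgrounds scores equally
  ctx <- paste0(rdna(18, seed = 42), "AG", "AATTC", rdna(30, seed = 43))
  sA <- paste0(rdna(40, seed = 1), ctx, rdna(40, seed = 2))
  sB <- paste0(rdna(40, seed = 3), ctx, rdna(40, seed = 4))
  o <- 40 + 18 + 2 + 1
  cA <- score_candidates(sA, scan_motif(sA, "AATTC"))
  cB <- score_candidates(sB, scan_motif(sB, "AATTC"))
  expect_equal(cA$acceptor_score[cA$intron_offset == o],
               cB$acceptor_score[cB$intron_offset == o])
})

test_that("rank_candidates applies the composite filter and k-truncation", {
  sim <- showcase_sim()
  cands <- scan_motif(sim$intron$seq, "AATTC")
  expect_equal(nrow(cands), 8)   # 1 planted acceptor context + 7 decoys
  sc <- score_candidates(sim$intron$seq, cands)
  all_pass <- rank_candidates(sc, t1 = -Inf, t2 = -Inf)
  expect_equal(nrow(all_pass), 8)
  none <- rank_candidates(sc, t1 = Inf, t2 = Inf)
  expect_equal(nrow(none), 0)
  top5 <- rank_candidates(sc, k = 5, t1 = -Inf, t2 = -Inf)
  expect_equal(nrow(top5), 5)
  expect_true(all(diff(top5$acceptor_score) <= 0))

  # at default thresholds the true planted acceptor passes
  def <- rank_candidates(sc)
  true_off <- sim$truth$cryptic_junction - sim$intron$start + 1
  expect_true(true_off %in% def$intron_offset)
  # and it carries the planted branch point 25 nt upstream
  i <- which(sc$intron_offset == true_off)
  expect_equal(sc$bp_offset[i], 25)
})
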