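test_that("pair scores implement the wobble-aware complementarity scheme", {
  expect_equal(pair_score("G", "C"), 4L)
  expect_equal(pair_score("C", "G"), 4L)
  expect_equal(pair_score("A", "T"), 2L)
  expect_equal(pair_score("G", "T"), 1L)  # G:U wobble in the DNA alphabet
  expect_equal(pair_score("T", "G"), 1L)
  expect_equal(pair_score("A", "C"), -6L)
  expect_equal(pair_score("A", "A"), -6L)
  expect_equal(pair_score("N", "C"), -6L)
  m <- complementarity_matrix()
  expect_true(isSymmetric(m))
  expect_equal(sort(unique(as.vector(m))), c(-6L, 1L, 2L, 4L))
  expect_error(pair_score("X", "A"), "non-nucleotide")
})

test_that("a perfect reverse-complement duplex scores its column sum", {
  set.seed(31)
  p <- scoring_params(min_score = 10L)
  for (rep in 1:20) {
    target <- random_dna(sample(20:60, 1))
    lnc <- revcomp(target)
    hits <- align_duplex(lnc, target, p)
    expect_gt(length(hits), 0)
    cols <- strsplit(lnc, "")[[1]]
    tgt_rev <- strsplit(rev_str(target), "")[[1]]
    full <- sum(vapply(seq_along(cols),
                       function(i) pair_score(cols[i], tgt_rev[i]), 0L))
    best <- hits[[1]]
    # the best local alignment scores at least the full-length pairing
    expect_gte(best$score, full)
    expect_equal(score_from_pairing(best, p), best$score)
  }
})

test_that("alignment scores equal the explicit-gap oracle on random pairs", {
  set.seed(32)
  p <- scoring_params(min_score = 1L)
  for (rep in 1:120) {
    q <- random_dna(sample(4:12, 1))
    t <- random_dna(sample(4:12, 1))
    oracle <- oracle_local_score(q, rev_str(t), p)
    hits <- align_duplex(q, t, p)
    if (oracle < 1L) {
      expect_length(hits, 0)
    } else {
      expect_equal(hits[[1]]$score, oracle,
                   info = paste(q, t))
    }
  }
})

test_that("alignment scores equal exhaustive enumeration on tiny pairs", {
  set.seed(33)
  p <- scoring_params(min_score = 1L)
  for (rep in 1:150) {
    q <- random_dna(sample(2:5, 1))
    t <- random_dna(sample(2:5, 1))
    oracle <- oracle_exhaustive_score(q, rev_str(t), p)
    hits <- align_duplex(q, t, p)
    best <- if (length(hits)) hits[[1]]$score else 0L
    expect_equal(best, oracle, info = paste(q, t))
  }
})

test_that("alignment scores agree with an established affine-gap aligner", {
  set.seed(34)
  p <- scoring_params(min_score = 1L)
  for (rep in 1:25) {
    q <- random_dna(sample(80:150, 1))
    t <- random_dna(sample(80:150, 1))
    ref <- biostrings_best_score(q, rev_str(t), p)
    hits <- align_duplex(q, t, p)
    best <- if (length(hits)) hits[[1]]$score else 0L
    # the reference aligner never reports the empty alignment, so scores
    # agree whenever anything positive exists
    if (ref > 0) expect_equal(best, ref)
  }
})

test_that("gaps cost opening plus per-base extension", {
  p <- scoring_params(min_score = 1L)
  run <- function(ch, n) paste(rep(ch, n), collapse = "")
  # 15 lnc bases bulged out of an otherwise perfect duplex: bridging with
  # one gap (4*80 - 20 - 8*15 = 180) beats mismatching through the bulge
  # (65*4 - 15*6 = 170) and beats one flank alone (4*40 = 160)
  lnc <- paste0(run("C", 40), run("A", 15), run("C", 40))
  hits <- align_duplex(lnc, run("G", 80), p)
  expect_equal(hits[[1]]$score, 4L * 80L - (20L + 8L * 15L))
  expect_equal(score_from_pairing(hits[[1]], p), hits[[1]]$score)
  # a longer bulge pays open once plus extension per base
  lnc2 <- paste0(run("C", 60), run("A", 20), run("C", 60))
  expect_equal(align_duplex(lnc2, run("G", 120), p)[[1]]$score,
               4L * 120L - (20L + 8L * 20L))
})

test_that("reported coordinates index the original strings and spans pair up", {
  set.seed(35)
  p <- scoring_params(min_score = 30L)
  for (rep in 1:20) {
    target <- random_dna(200)
    core <- substr(target, 81, 140)
    lnc <- paste0(random_dna(40), revcomp(core), random_dna(40))
    hits <- align_duplex(lnc, target, p)
    expect_gt(length(hits), 0)
    h <- hits[[1]]
    # aligned strings (gaps removed) equal the claimed substrings
    expect_equal(gsub("-", "", h$lnc_aln, fixed = TRUE),
                 substr(lnc, h$lnc_start + 1L, h$lnc_end))
    expect_equal(gsub("-", "", rev_str(h$target_aln), fixed = TRUE),
                 substr(target, h$target_start + 1L, h$target_end))
    # the planted core is recovered
    expect_lte(h$target_start, 85L)
    expect_gte(h$target_end, 135L)
  }
})

test_that("suboptimal alignments are disjoint and ordered deterministically", {
  set.seed(36)
  p <- scoring_params(min_score = 40L)
  target <- paste0(random_dna(50), "GGGGGGGGGGGGGGGG", random_dna(50),
                   "GGGGGGGGGGGGGGGG", random_dna(50))
  lnc <- paste0(random_dna(20), "CCCCCCCCCCCCCCCC", random_dna(20))
  hits <- align_duplex(lnc, target, p)
  expect_gte(length(hits), 2)
  scores <- vapply(hits, `[[`, 0L, "score")
  expect_true(all(diff(scores) <= 0))
  expect_true(all(scores >= 40L))
  # every alignment's score is reproducible from its columns
  for (h in hits) expect_equal(score_from_pairing(h, p), h$score)
  # byte-identical reruns
  again <- align_duplex(lnc, target, p)
  expect_identical(duplexes_to_df(hits)[, -(1:2)], duplexes_to_df(again)[, -(1:2)])
})

test_that("raising the threshold only removes alignments", {
  set.seed(37)
  target <- random_dna(400)
  lnc <- paste0(random_dna(30), revcomp(substr(target, 100, 220)), random_dna(30))
  lo <- align_duplex(lnc, target, scoring_params(min_score = 50L))
  hi <- align_duplex(lnc, target, scoring_params(min_score = 300L))
  key <- function(hits) vapply(hits, function(h) {
    paste(h$score, h$lnc_start, h$lnc_end, h$target_start, h$target_end)
  }, "")
  expect_true(all(key(hi) %in% key(lo)))
  expect_setequal(key(hi), key(lo)[vapply(lo, `[[`, 0L, "score") >= 300L])
})

test_that("U is accepted as T and empty input yields no alignments", {
  p <- scoring_params(min_score = 10L)
  hits_t <- align_duplex("CCCCCCCC", "GGGGGGGG", p)
  expect_equal(hits_t[[1]]$score, 32L)
  expect_equal(align_duplex(gsub("T", "U", "TTTTTTTTTT"),
                            "AAAAAAAAAA", scoring_params(min_score = 5L))[[1]]$score,
               20L)
  expect_length(align_duplex("", "ACGT", p), 0)
  expect_length(align_duplex("ACGT", "", p), 0)
})

test_that("enumerate_interactions skips self-pairs and non-DE targets", {
  seqs <- c(L1 = paste(rep("C", 150), collapse = ""))
  targets <- list(
    list(id = "T1", seq = paste(rep("G", 150), collapse = ""),
         space = "spliced", de = TRUE),
    list(id = "T2", seq = paste(rep("G", 150), collapse = ""),
         space = "spliced", de = FALSE),
    list(id = "L1", seq = paste(rep("G", 150), collapse = ""),
         space = "spliced", de = TRUE)
  )
  hits <- enumerate_interactions(seqs, targets)
  expect_true(all(vapply(hits, `[[`, "", "target_id") == "T1"))
  expect_gt(length(hits), 0)
})
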