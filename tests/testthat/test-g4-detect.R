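test_that("QGRS enumeration finds the canonical examples", {
  m <- enumerate_qgrs("GGTGGTGGTGG")
  expect_equal(nrow(m), 1L)
  expect_equal(m$g, 2L)
  expect_equal(c(m$l1, m$l2, m$l3), c(1L, 1L, 1L))
  expect_equal(m$score, 20L)

  expect_equal(nrow(enumerate_qgrs("ATATATAT")), 0L)

  tel <- enumerate_qgrs("GGGTTAGGGTTAGGGTTAGGG")
  expect_true(any(tel$g == 3 & tel$l1 == 3 & tel$l2 == 3 & tel$l3 == 3))
  expect_equal(tel$score[tel$g == 3], 39L)
})

test_that("QGRS enumeration agrees with brute-force substring enumeration", {
  set.seed(21)
  probs <- list(c(.25, .25, .25, .25), c(.2, .2, .4, .2), c(.15, .25, .45, .15))
  for (i in 1:40) {
    s <- rand_dna(sample(20:150, 1), probs[[1 + i %% 3]])
    got <- enumerate_qgrs(s)
    want <- brute_qgrs(s)
    expect_identical(motif_keys(got), brute_keys(want))
  }
  # non-default parameters exercise the loop bounds
  p <- detection_params(max_length = 20L, min_g = 2L, loop_min = 1L,
                        loop_max = 5L)
  for (i in 1:15) {
    s <- rand_dna(80, c(.2, .2, .4, .2))
    got <- enumerate_qgrs(s, p)
    want <- brute_qgrs(s, max_length = 20, loop_min = 1, loop_max = 5)
    expect_identical(motif_keys(got), brute_keys(want))
  }
})

test_that("G-score matches its calibration anchors and monotonicity", {
  expect_equal(score_qgrs(2, c(1, 1, 1)), 20L)
  expect_equal(score_qgrs(3, c(1, 1, 1)), 41L)
  expect_equal(score_qgrs(3, c(3, 3, 3)), 39L)
  expect_error(score_qgrs(1, c(1, 1, 1)), ">= 2")
  # strictly increasing in g; non-increasing in loop length and spread
  set.seed(5)
  for (i in 1:50) {
    l <- sample(0:12, 3, replace = TRUE)
    g <- sample(2:5, 1)
    expect_lt(score_qgrs(g, l), score_qgrs(g + 1L, l))
    expect_gte(score_qgrs(g, l), score_qgrs(g, l + c(3L, 3L, 3L)))
  }
  # stability cut of 25 separates 2- from 3-tetrad motifs at default loops
  expect_lte(score_qgrs(2, c(0, 0, 0)), 25L)
  expect_gt(score_qgrs(3, c(7, 7, 7)), 25L)
})

test_that("non-overlapping selection is greedy, tie-broken and order-free", {
  m <- enumerate_qgrs("GGGAGGGAGGGAGGGGTGGTGGTGG")
  sel <- select_nonoverlapping(m)
  expect_equal(max(sel$score), max(m$score))
  # no overlaps among retained motifs
  sel <- sel[order(sel$start), ]
  if (nrow(sel) > 1) {
    expect_true(all(sel$start[-1] >= sel$end[-nrow(sel)]))
  }
  # permutation invariance
  set.seed(9)
  for (i in 1:10) {
    perm <- m[sample(nrow(m)), ]
    expect_equal(motif_keys(select_nonoverlapping(perm)), motif_keys(sel))
  }
  # equal score, equal start: shortest wins
  a <- m[1, ]; b <- m[1, ]
  a$start <- 0L; a$end <- 15L; a$score <- 30L
  b$start <- 0L; b$end <- 21L; b$score <- 30L
  expect_equal(select_nonoverlapping(rbind(b, a))$end, 15L)
  # mixed seq ids rejected
  bad <- rbind(a, b); bad$seq_id <- c("x", "y")
  expect_error(select_nonoverlapping(bad), "mixed seq_ids")
})

test_that("G4Hunter base scores follow run-length rules", {
  expect_equal(hunter_base_scores("GGGCAA"), c(3, 3, 3, -1, 0, 0))
  expect_equal(hunter_base_scores(strrep("G", 25)), rep(4, 25))
  expect_equal(hunter_base_scores("GGNGG"), c(2, 2, 0, 2, 2))
  # reverse complement mirrors and negates
  set.seed(13)
  for (i in 1:30) {
    s <- rand_dna(sample(10:120, 1))
    expect_equal(hunter_base_scores(reverse_complement(s)),
                 rev(-hunter_base_scores(s)))
  }
})

test_that("G4Hunter regions qualify, merge and respect polarity", {
  r <- hunter_regions(strrep("G", 25))
  expect_equal(nrow(r), 1L)
  expect_equal(r$mean_score, 4)
  expect_equal(r$polarity, "+")

  tel <- paste0("GGGTTAGGGTTAGGGTTAGGG", strrep("A", 10))
  r2 <- hunter_regions(tel)
  expect_equal(nrow(r2), 1L)
  expect_equal(sum(hunter_base_scores("GGGTTAGGGTTAGGGTTAGGG")) / 21, 36 / 21)

  expect_equal(nrow(hunter_regions(strrep("GC", 20))), 0L)

  expect_warning(short <- hunter_regions("GGGG"), "shorter than window")
  expect_equal(nrow(short), 0L)

  cr <- hunter_regions(strrep("C", 30))
  expect_equal(cr$polarity, "-")
  expect_true(all(abs(hunter_base_scores(rand_dna(200))) <= 4))
})

test_that("strand-aware scanning maps minus-strand hits back to forward", {
  core <- "GGGTTAGGGTTAGGGTTAGGG"
  fwd <- paste0(strrep("A", 10), core, strrep("T", 10))
  p <- detection_params(strands = "both")
  hits <- scan_species(fwd, p, "qgrs", "s")
  plus3 <- hits[hits$strand == "+" & hits$g == 3, ]
  expect_equal(nrow(plus3), 1L)
  expect_equal(c(plus3$start, plus3$end), c(10L, 31L))

  rev <- reverse_complement(fwd)
  hits_r <- scan_species(rev, p, "qgrs", "s")
  minus3 <- hits_r[hits_r$strand == "-" & hits_r$g == 3, ]
  expect_equal(nrow(minus3), 1L)
  expect_equal(c(minus3$start, minus3$end), c(10L, 31L))

  # a C-rich-only sequence has no plus-strand QGRS hits
  ponly <- detection_params(strands = "plus")
  expect_equal(nrow(scan_species(reverse_complement(fwd), ponly, "qgrs")), 0L)

  # hunter polarity flips under reverse complement, coordinates mirror
  hr <- scan_species(fwd, p, "hunter", "s")
  hr_rc <- scan_species(rev, p, "hunter", "s")
  expect_equal(hr$mean_score, -rev(hr_rc$mean_score))
  n <- nchar(fwd)
  expect_equal(hr$start, rev(n - hr_rc$end))
})

test_that("planted canonical motifs are detected with near-zero background", {
  set.seed(31)
  found <- 0L
  for (i in 1:50) {
    bg <- rand_dna(300, c(.45, .05, .05, .45))  # AT-rich background
    pos <- sample(0:(300 - 21), 1)
    res <- plant_g4(bg, 3L, c(3L, 3L, 3L), pos)
    hits <- enumerate_qgrs(res$seq)
    hit3 <- hits[hits$g >= 3 & hits$start >= pos - 1 & hits$end <= pos + 22, ]
    if (nrow(hit3) > 0) found <- found + 1L
  }
  expect_gte(found / 50, 0.99)
  # false positives on pure AT-rich background
  fp <- sum(vapply(1:50, function(i) {
    nrow(enumerate_qgrs(rand_dna(300, c(.45, .05, .05, .45))))
  }, numeric(1)))
  expect_lte(fp / 50, 0.2)
})
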