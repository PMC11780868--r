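test_that("K2P distance matches its closed form and error conditions", {
  expect_equal(k2p_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  # one transition in 10 sites
  expect_equal(k2p_distance("AAAAAAAAAA", "GAAAAAAAAA"), -0.5 * log(0.8),
               tolerance = 1e-12)
  # one transversion in 10 sites
  expect_equal(k2p_distance("AAAAAAAAAA", "TAAAAAAAAA"),
               -0.5 * log(0.9) - 0.25 * log(0.8), tolerance = 1e-12)
  # pairwise deletion of gaps and N
  expect_equal(k2p_distance("A-GTN", "AAGTC"), 0)
  expect_error(k2p_distance("----", "AAAA"), "zero usable")
  # saturation
  expect_error(k2p_distance("AAAAAAAAAA", "GGGGGGGGGG"), "saturation")
  # symmetry, zero iff identical on usable sites
  set.seed(4)
  for (i in 1:10) {
    a <- rand_dna(60); b <- rand_dna(60)
    d1 <- tryCatch(k2p_distance(a, b), error = function(e) NA)
    d2 <- tryCatch(k2p_distance(b, a), error = function(e) NA)
    expect_equal(d1, d2)
  }
})

test_that("distance matrices agree with per-pair K2P and with ape", {
  set.seed(8)
  al <- setNames(replicate(5, rand_dna(400, c(.3, .2, .2, .3))),
                 paste0("t", 1:5))
  # make the taxa similar enough not to saturate: derive from one ancestor
  anc <- rand_dna(400)
  al <- vapply(1:5, function(i) {
    ch <- strsplit(anc, "")[[1]]
    mut <- sample(400, 25)
    ch[mut] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  names(al) <- paste0("t", 1:5)
  dm <- distance_matrix(al)
  expect_true(isSymmetric(dm))
  expect_equal(unname(diag(dm)), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(dm[i, j], k2p_distance(al[[i]], al[[j]]), tolerance = 1e-12)
  }
  # independent route: ape::dist.dna on the same alignment
  bin <- ape::as.DNAbin(t(sapply(al, function(s) strsplit(tolower(s), "")[[1]])))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(dm), unname(ref[rownames(dm), colnames(dm)]),
               tolerance = 1e-10)
  # identical records give a zero matrix
  same <- setNames(rep(strrep("ACGT", 30), 3), c("a", "b", "c"))
  expect_equal(unname(distance_matrix(same)), matrix(0, 3, 3))
  # label permutation permutes entries consistently
  perm <- sample(names(al))
  dmp <- distance_matrix(al[perm])
  expect_equal(dmp[names(al), names(al)], dm)
})

test_that("NJ solves the three-point configuration exactly", {
  dm <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[c("A", "B", "C")], c(A = .05, B = .15, C = .25))
  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3")
})

test_that("NJ is exact on additive matrices (path-sum oracle)", {
  for (seed in 1:25) {
    k <- sample(5:8, 1)
    ra <- random_additive(k, seed)
    tr <- nj_tree(ra$d)
    got <- path_sums(tr)[rownames(ra$d), colnames(ra$d)]
    expect_lt(max(abs(got - ra$d)), 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ra$tree), tr)), 0)
  }
})

test_that("NJ clamps negative branch lengths to zero", {
  # near-star configuration with noise can produce negative estimates
  set.seed(99)
  for (i in 1:20) {
    d <- matrix(0.5, 5, 5) + matrix(runif(25, 0, 0.05), 5, 5)
    d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(letters[1:5], letters[1:5])
    tr <- nj_tree(d)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("bootstrap supports are reproducible fractions in [0, 1]", {
  set.seed(17)
  # two divergent clades: within-clade distance tiny, between large
  mk <- function(anc, nmut) {
    ch <- strsplit(anc, "")[[1]]
    i <- sample(300, nmut)
    ch[i] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    paste(ch, collapse = "")
  }
  anc1 <- rand_dna(300); anc2 <- mk(anc1, 80)  # diverged, not saturated
  al <- c(a1 = mk(anc1, 5), a2 = mk(anc1, 5), a3 = mk(anc1, 5),
          b1 = mk(anc2, 5), b2 = mk(anc2, 5), b3 = mk(anc2, 5))
  tr <- bootstrap_support(al, B = 100, seed = 7)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 1))
  # the two-clade split must be near-certain
  expect_gte(max(sup), 0.95)
  tr2 <- bootstrap_support(al, B = 100, seed = 7)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # degenerate alignment: no resolved bipartitions
  same <- setNames(rep(strrep("ACGT", 25), 4), paste0("s", 1:4))
  star <- bootstrap_support(same, B = 10, seed = 1)
  expect_equal(star$Nnode, 1L)
})

test_that("Newick round-trips and defaults missing branch lengths", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tr <- read_newick(tf)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  d <- path_sums(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  write_newick(tr, tf)
  tr2 <- read_newick(tf)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
  writeLines("((A,B),C);", tf)
  expect_warning(tr3 <- read_newick(tf), "branch length")
  expect_equal(tr3$edge.length, rep(0, nrow(tr3$edge)))
  writeLines("((A:1,B:1:1,C;", tf)
  expect_error(suppressWarnings(read_newick(tf)))
})
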