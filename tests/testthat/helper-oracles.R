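# Independent oracles and small fixture builders used across the suite.

# Random sequence with given base probabilities (A, C, G, T).
rand_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Brute-force QGRS enumeration: directly tests every candidate tuple
# (start, g, l1, l2, l3) against the pattern definition by inspecting the
# characters, with no shared machinery with the implementation.
brute_qgrs <- function(seq, max_length = 30, min_g = 2,
                       loop_min = 0, loop_max = 36) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_run <- function(s, g) s >= 1 && s + g - 1 <= n && all(ch[s:(s + g - 1)] == "G")
  res <- list()
  for (s in seq_len(n)) {
    for (g in min_g:(max_length %/% 4)) {
      if (!is_run(s, g)) next
      for (l1 in loop_min:loop_max) {
        if (4 * g + l1 + 2 * loop_min > max_length) break
        s2 <- s + g + l1
        if (!is_run(s2, g)) next
        for (l2 in loop_min:loop_max) {
          if (4 * g + l1 + l2 + loop_min > max_length) break
          s3 <- s2 + g + l2
          if (!is_run(s3, g)) next
          for (l3 in loop_min:loop_max) {
            if (4 * g + l1 + l2 + l3 > max_length) break
            s4 <- s3 + g + l3
            if (!is_run(s4, g)) next
            res[[length(res) + 1]] <- c(start = s - 1, end = s4 + g - 1,
                                        g = g, l1 = l1, l2 = l2, l3 = l3)
          }
        }
      }
    }
  }
  if (!length(res)) {
    return(matrix(integer(0), ncol = 6,
                  dimnames = list(NULL, c("start", "end", "g",
                                          "l1", "l2", "l3"))))
  }
  m <- do.call(rbind, res)
  m[order(m[, "start"], m[, "end"], m[, "g"], m[, "l1"], m[, "l2"]),
    , drop = FALSE]
}

# canonical candidate key for set comparison
motif_keys <- function(df) {
  sort(paste(df$start, df$end, df$g, df$l1, df$l2, df$l3, sep = ":"))
}

brute_keys <- function(m) {
  sort(paste(m[, "start"], m[, "end"], m[, "g"],
             m[, "l1"], m[, "l2"], m[, "l3"], sep = ":"))
}

# random additive distance matrix from a random tree with known path sums
random_additive <- function(k, seed) {
  set.seed(seed)
  tr <- ape::rtree(k)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# leaf-to-leaf path-sum matrix of a phylo tree (the NJ exactness oracle)
path_sums <- function(tree) ape::cophenetic.phylo(tree)
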