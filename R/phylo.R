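# Kimura 2-parameter distances from aligned 16S sequences, neighbour-joining
# tree construction, bootstrap supports and Newick I/O. Trees are ape "phylo"
# objects throughout.

# alignment (named character vector) or character matrix -> taxa x sites
# character matrix
alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  al <- as_alignment(alignment)
  x <- do.call(rbind, strsplit(al, "", fixed = TRUE))
  rownames(x) <- names(al)
  x
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either residue is a gap or `N` are excluded (pairwise
#' deletion). With transition proportion `P` (A<->G, C<->T) and transversion
#' proportion `Q` over usable sites,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param a,b Aligned sequences (equal length, gaps allowed).
#' @return The K2P distance.
#' @export
k2p_distance <- function(a, b) {
  ac <- strsplit(validate_dna(a, allow_gaps = TRUE), "", fixed = TRUE)[[1]]
  bc <- strsplit(validate_dna(b, allow_gaps = TRUE), "", fixed = TRUE)[[1]]
  if (length(ac) != length(bc)) stop("sequences differ in length", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  usable <- ac %in% bases & bc %in% bases
  nu <- sum(usable)
  if (nu == 0) stop("zero usable sites", call. = FALSE)
  diff <- usable & ac != bc
  ti <- diff & ((ac == "A" & bc == "G") | (ac == "G" & bc == "A") |
                (ac == "C" & bc == "T") | (ac == "T" & bc == "C"))
  P <- sum(ti) / nu
  Q <- (sum(diff) - sum(ti)) / nu
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturation: distance undefined", call. = FALSE)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix
#'
#' All pairwise distances under the Kimura 2-parameter model with pairwise
#' deletion of gap/N sites. Saturated pairs (where the K2P logarithms are
#' undefined) raise an error naming the pair, unless `cap` supplies a finite
#' substitute distance.
#'
#' @param alignment Named character vector of aligned sequences (>= 3), or a
#'   character matrix (taxa x sites).
#' @param cap Optional distance substituted for saturated pairs.
#' @return A symmetric numeric matrix with zero diagonal and taxon dimnames.
#' @export
distance_matrix <- function(alignment, cap = NULL) {
  X <- alignment_matrix(alignment)
  if (nrow(X) < 3) stop("need at least 3 sequences", call. = FALSE)
  labels <- rownames(X)
  bases <- c("A", "C", "G", "T")
  M <- lapply(bases, function(b) (X == b) * 1)
  names(M) <- bases
  U <- tcrossprod(M$A + M$C + M$G + M$T)   # usable site counts
  if (any(U[upper.tri(U)] == 0)) {
    ij <- which(U == 0 & upper.tri(U), arr.ind = TRUE)[1, ]
    stop(sprintf("zero usable sites for pair (%s, %s)",
                 labels[ij[1]], labels[ij[2]]), call. = FALSE)
  }
  AG <- tcrossprod(M$A, M$G); CT <- tcrossprod(M$C, M$T)
  ti <- AG + t(AG) + CT + t(CT)
  same <- Reduce(`+`, lapply(M, tcrossprod))
  tv <- U - same - ti
  P <- ti / U; Q <- tv / U
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  sat <- (w1 <= 0 | w2 <= 0) & upper.tri(w1)
  d <- matrix(NA_real_, nrow(X), nrow(X), dimnames = list(labels, labels))
  ok <- w1 > 0 & w2 > 0
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  if (any(sat)) {
    if (is.null(cap)) {
      ij <- which(sat, arr.ind = TRUE)[1, ]
      stop(sprintf("saturation: distance undefined for pair (%s, %s)",
                   labels[ij[1]], labels[ij[2]]), call. = FALSE)
    }
    d[sat | t(sat)] <- cap
  }
  diag(d) <- 0
  d
}

#' Neighbour-joining tree
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]). Negative estimated
#' branch lengths are clamped to 0 with the deficit transferred to the sister
#' branch, the usual practice for distance trees.
#'
#' @param dm Symmetric distance matrix with taxon dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (is.null(dim(dm)) || nrow(dm) < 3) stop("need >= 3 taxa", call. = FALSE)
  tr <- ape::nj(as.matrix(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sib <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
    if (length(sib)) {
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    }
  }
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree for each replicate, and reports for every internal bipartition of the
#' full-data tree the fraction of replicates containing it (stored in
#' `node.label`). Replicates whose distance matrix is saturated are dropped
#' with a warning and the denominator adjusted. Fixing `seed` fixes the
#' output.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the column resampling.
#' @param cap Optional saturation cap passed to [distance_matrix()].
#' @return The full-data NJ tree with support fractions in `node.label` and
#'   an attribute `dropped` (number of discarded replicates).
#' @export
bootstrap_support <- function(alignment, B = 1000L, seed = 1L, cap = NULL) {
  stopifnot(B >= 1)
  X <- alignment_matrix(alignment)
  if (all(apply(X, 2, function(cl) length(unique(cl)) == 1))) {
    # no variation: no resolved bipartitions to support
    n <- nrow(X)
    star <- ape::stree(n, type = "star", tip.label = rownames(X))
    star$edge.length <- rep(0, nrow(star$edge))
    star$node.label <- NA_character_
    attr(star, "dropped") <- 0L
    return(star)
  }
  full <- nj_tree(distance_matrix(X, cap = cap))
  L <- ncol(X)
  set.seed(seed)
  reps <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    dm <- tryCatch(distance_matrix(X[, cols, drop = FALSE], cap = cap),
                   error = function(e) NULL)
    if (is.null(dm)) { dropped <- dropped + 1L; next }
    reps[[b]] <- nj_tree(dm)
  }
  reps <- Filter(Negate(is.null), reps)
  if (dropped > 0) {
    warning(sprintf("%d saturated bootstrap replicate(s) dropped", dropped))
  }
  if (length(reps) == 0) stop("all bootstrap replicates saturated", call. = FALSE)
  cnt <- ape::prop.clades(full, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  full$node.label <- formatC(cnt / length(reps), digits = 3, format = "f")
  attr(full, "dropped") <- dropped
  full
}

#' Read a Newick tree file
#'
#' Missing branch lengths default to 0 with a warning.
#'
#' @param path Path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (is.null(tr$edge.length)) {
    warning("no branch lengths in ", path, "; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch length(s) in ", path, "; defaulting to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Midpoint rooting (for display and PGLS)
#'
#' @param tree An unrooted `phylo` tree.
#' @return A rooted `phylo` tree.
#' @export
root_midpoint <- function(tree) {
  phangorn::midpoint(tree)
}
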