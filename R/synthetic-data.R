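# Seeded generator for complete comparative test datasets: an ultrametric
# phylogeny, Brownian-motion optimal growth temperatures, 16S-like sequences
# whose GC content and planted G4 motif density/stability increase with
# temperature, and point mutations that disrupt planted motifs. A ground
# truth registry records every plant.

#' Simulation parameter set
#'
#' The defaults are the "paperlike" preset: 96 species with optimal growth
#' temperatures spanning 10-85 degrees C (mostly mesophiles, few
#' hyperthermophiles), 1.5 kb 16S-like sequences, GC content rising linearly
#' with temperature, an expected 2 planted motifs per sequence at 20 C
#' rising to 10 at 85 C, a logistic increase in the chance a planted motif
#' has three stacked tetrads, and a motif-disruption rate that falls with
#' temperature.
#'
#' @param n_species Number of species (tree leaves), >= 3.
#' @param seed Master seed; fixes the entire dataset.
#' @param birth_rate Pure-birth (Yule) speciation rate.
#' @param bm_sigma2 Brownian-motion rate of the latent temperature trait.
#' @param bm_root Root value of the latent temperature trait (degrees C).
#' @param lambda_true Pagel's lambda used when simulating traits.
#' @param gc_intercept,gc_slope Linear GC-temperature link (fraction,
#'   fraction per degree C); targets are clipped to `[0.25, 0.75]`.
#' @param gc_noise_sd Species-level Gaussian jitter (sd, fraction) added to
#'   the GC target, so the realized GC-temperature correlation is strong but
#'   not degenerate.
#' @param seq_length 16S-like sequence length (nt).
#' @param mut_rate Expected substitutions per site from root to leaf (the
#'   tree is scaled to unit height before sequence evolution).
#' @param motif_rate_low,motif_rate_high Expected planted motifs per sequence
#'   at 20 and 85 degrees C (linear in between, clipped at 0).
#' @param p3_t0,p3_scale Logistic parameters of the probability that a
#'   planted motif has three tetrads: `plogis((t - p3_t0)/p3_scale)`.
#' @param disruption_high,disruption_low Per-motif disruption probability at
#'   20 and 85 degrees C (linear in between, clipped to `[0, 1]`).
#' @param rescale_t Monotonically rescale the realized latent trait to
#'   `t_range`, so every dataset spans the full thermal spectrum.
#' @param t_range Target temperature range after rescaling.
#' @param t_skew Exponent of the rescaling map
#'   `t = t_range[1] + diff(t_range) * u^t_skew` (u the unit-scaled trait);
#'   values > 1 concentrate species at moderate temperatures, mirroring the
#'   predominance of mesophiles over (hyper)thermophiles in growth-
#'   temperature databases.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_species = 96L, seed = 1L,
                              birth_rate = 1, bm_sigma2 = 100,
                              bm_root = 35, lambda_true = 1,
                              gc_intercept = 0.40, gc_slope = 0.003,
                              gc_noise_sd = 0.02,
                              seq_length = 1500L, mut_rate = 0.15,
                              motif_rate_low = 2, motif_rate_high = 10,
                              p3_t0 = 70, p3_scale = 7,
                              disruption_high = 0.5, disruption_low = 0.05,
                              rescale_t = TRUE, t_range = c(10, 85),
                              t_skew = 1.6) {
  p <- list(n_species = as.integer(n_species), seed = as.integer(seed),
            birth_rate = birth_rate, bm_sigma2 = bm_sigma2,
            bm_root = bm_root, lambda_true = lambda_true,
            gc_intercept = gc_intercept, gc_slope = gc_slope,
            gc_noise_sd = gc_noise_sd,
            seq_length = as.integer(seq_length),
            mut_rate = mut_rate,
            motif_rate_low = motif_rate_low,
            motif_rate_high = motif_rate_high,
            p3_t0 = p3_t0, p3_scale = p3_scale,
            disruption_high = disruption_high,
            disruption_low = disruption_low,
            rescale_t = isTRUE(rescale_t), t_range = t_range,
            t_skew = t_skew)
  errs <- character(0)
  if (p$n_species < 3) errs <- c(errs, "n_species must be >= 3")
  if (p$birth_rate <= 0) errs <- c(errs, "birth_rate must be > 0")
  if (p$bm_sigma2 < 0) errs <- c(errs, "bm_sigma2 must be >= 0")
  if (p$lambda_true < 0 || p$lambda_true > 1) {
    errs <- c(errs, "lambda_true must be in [0, 1]")
  }
  if (p$seq_length < 300) errs <- c(errs, "seq_length must be >= 300")
  if (p$mut_rate <= 0) errs <- c(errs, "mut_rate must be > 0")
  if (p$gc_noise_sd < 0) errs <- c(errs, "gc_noise_sd must be >= 0")
  if (p$t_skew <= 0) errs <- c(errs, "t_skew must be > 0")
  if (p$motif_rate_low < 0 || p$motif_rate_high < 0) {
    errs <- c(errs, "motif rates must be >= 0")
  }
  if (any(p$disruption_high < 0, p$disruption_high > 1,
          p$disruption_low < 0, p$disruption_low > 1)) {
    errs <- c(errs, "disruption rates must be in [0, 1]")
  }
  if (length(errs)) {
    stop("invalid simulation parameters:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

#' Ultrametric pure-birth (Yule) tree
#'
#' @param n Number of leaves, >= 3.
#' @param birth_rate Speciation rate.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A rooted ultrametric `phylo` tree with tips `sp001..`.
#' @export
yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (n < 3) stop("need n >= 3 leaves", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Draws leaf values from a multivariate normal with mean `root_value` and
#' covariance `sigma2 * lambda_transform(bm_covariance(tree), lambda_true)`.
#'
#' @param tree Rooted `phylo` tree.
#' @param sigma2 Brownian rate, >= 0.
#' @param root_value Trait value at the root.
#' @param lambda_true Pagel's lambda of the simulated covariance.
#' @param seed Optional seed.
#' @return Named numeric vector of leaf trait values.
#' @export
simulate_bm <- function(tree, sigma2, root_value, lambda_true = 1,
                        seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    return(setNames(rep(root_value, n), tree$tip.label))
  }
  V <- sigma2 * lambda_transform(bm_covariance(tree), lambda_true)
  R <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-10, n)))
  z <- rnorm(n)
  setNames(root_value + drop(crossprod(R, z)), tree$tip.label)
}

#' Random sequence with a target GC content
#'
#' I.i.d. bases with `P(G) = P(C) = gc_target / 2`.
#'
#' @param length Sequence length.
#' @param gc_target GC fraction in `(0, 1)`.
#' @param seed Optional seed.
#' @return A character scalar.
#' @export
generate_sequence <- function(length, gc_target, seed = NULL) {
  gc_target <- unname(gc_target)
  stopifnot(gc_target > 0, gc_target < 1, length >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
         (1 - gc_target) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
        collapse = "")
}

#' Plant a G4 motif into a sequence
#'
#' Writes four G-runs of length `g` separated by random non-G loop bases at
#' `position` (0-based). The bases immediately flanking the motif are forced
#' to non-G so that the planted G-group size is exactly `g`. When
#' `disrupted`, one G in a randomly chosen run is replaced by A or T, which
#' guarantees that no motif of G-group size `g` remains within the planted
#' footprint.
#'
#' @param seq Host sequence.
#' @param g G-group size (>= 2).
#' @param loops Integer vector of 3 loop lengths.
#' @param position 0-based start of the motif.
#' @param disrupted Disrupt the planted motif?
#' @param seed Optional seed.
#' @param existing Optional data.frame of previously planted `start`/`end`
#'   footprints (0-based half-open); overlap is an error.
#' @return List with `seq` (modified sequence) and `entry` (one-row registry
#'   data.frame: start, end, g, l1..l3, disrupted, score — the QGRS score the
#'   intact plant would attain).
#' @export
plant_g4 <- function(seq, g, loops, position, disrupted = FALSE,
                     seed = NULL, existing = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(g >= 2, length(loops) == 3, all(loops >= 0), position >= 0)
  len <- 4L * g + sum(loops)
  n <- nchar(seq)
  if (position + len > n) stop("motif does not fit at position", call. = FALSE)
  if (!is.null(existing) && nrow(existing) > 0 &&
      any(position < existing$end + 1 & position + len > existing$start - 1)) {
    stop("overlap with a previously planted locus", call. = FALSE)
  }
  nonG <- c("A", "C", "T")
  parts <- character(0)
  for (i in 1:3) {
    parts <- c(parts, strrep("G", g),
               paste(sample(nonG, loops[i], replace = TRUE), collapse = ""))
  }
  motif <- paste0(paste(parts, collapse = ""), strrep("G", g))
  if (disrupted) {
    run <- sample.int(4L, 1L)
    offs <- c(0L, cumsum(g + loops))[run]        # run start offset in motif
    within <- sample.int(g, 1L)
    substr(motif, offs + within, offs + within) <-
      sample(c("A", "T"), 1L)
  }
  substr(seq, position + 1L, position + len) <- motif
  # non-G guard bases so the planted run length is exact
  if (position >= 1L) {
    substr(seq, position, position) <- sample(nonG, 1L)
  }
  if (position + len < n) {
    substr(seq, position + len + 1L, position + len + 1L) <- sample(nonG, 1L)
  }
  entry <- data.frame(start = position, end = position + len, g = g,
                      l1 = loops[1], l2 = loops[2], l3 = loops[3],
                      disrupted = disrupted,
                      score = score_qgrs(g, loops))
  list(seq = seq, entry = entry)
}

# Evolve a root sequence along the tree: on each edge every site mutates
# with probability 1 - exp(-rate * edge_length), the replacement drawn
# uniformly from the other three bases. Returns the leaf sequences as a
# character matrix (taxa x sites).
evolve_sequences <- function(tree, root_seq, rate) {
  bases <- c("A", "C", "G", "T")
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  tr <- stats::reorder(tree, "cladewise")   # parents precede children
  n <- length(tr$tip.label)
  node_seq <- vector("list", n + tr$Nnode)
  root_chars <- strsplit(root_seq, "", fixed = TRUE)[[1]]
  L <- length(root_chars)
  node_seq[[n + 1L]] <- root_chars
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    ch <- node_seq[[parent]]
    p_mut <- 1 - exp(-rate * tr$edge.length[e])
    hit <- which(runif(L) < p_mut)
    if (length(hit)) {
      ch[hit] <- alt[cbind(match(ch[hit], bases),
                           sample.int(3L, length(hit), replace = TRUE))]
    }
    node_seq[[child]] <- ch
  }
  out <- do.call(rbind, node_seq[seq_len(n)])
  rownames(out) <- tr$tip.label
  out
}

# flip randomly chosen sites to move a sequence's GC content to the target
adjust_gc <- function(ch, target) {
  L <- length(ch)
  delta <- round((target - mean(ch %in% c("G", "C"))) * L)
  if (delta > 0) {
    at <- which(ch %in% c("A", "T"))
    pick <- sample(at, min(delta, length(at)))
    ch[pick] <- sample(c("G", "C"), length(pick), replace = TRUE)
  } else if (delta < 0) {
    gc <- which(ch %in% c("G", "C"))
    pick <- sample(gc, min(-delta, length(gc)))
    ch[pick] <- sample(c("A", "T"), length(pick), replace = TRUE)
  }
  ch
}

# linear interpolation of a rate between 20 and 85 degrees C, clipped
temp_ramp <- function(t, low, high, lo_clip = 0, hi_clip = Inf) {
  r <- low + (high - low) * (t - 20) / (85 - 20)
  pmin(pmax(r, lo_clip), hi_clip)
}

#' Build a complete synthetic comparative dataset
#'
#' Simulates the tree, temperature traits, per-species 16S-like sequences
#' with temperature-linked GC content and planted G4 motifs, applies seeded
#' disruptions, and returns the ground truth registry. All species share the
#' same candidate locus positions and all sequences have equal length with
#' no gaps, so the sequences double as an alignment by construction.
#'
#' @param params A [simulation_params()] object.
#' @param dir Optional output directory; when given, writes `rrna.fasta`,
#'   `aligned.fasta`, `metadata.tsv`, `truth.tsv` and `manifest.json`.
#' @return List with `tree`, `metadata` (species table with temperatures,
#'   group, GC), `sequences` (named character vector), `alignment` (same, by
#'   construction), `truth` (registry of planted motifs), `loci` (candidate
#'   locus start positions) and `params`.
#' @export
build_dataset <- function(params = simulation_params(), dir = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_species
  tree <- yule_tree(n, params$birth_rate)
  # unit height, so bm_sigma2 and mut_rate are per total root-to-leaf time
  tree$edge.length <- tree$edge.length /
    max(ape::node.depth.edgelength(tree))
  raw <- simulate_bm(tree, params$bm_sigma2, params$bm_root,
                     params$lambda_true)
  t_opt <- raw
  if (params$rescale_t && diff(range(raw)) > 0) {
    u <- (raw - min(raw)) / diff(range(raw))
    t_opt <- params$t_range[1] + diff(params$t_range) * u^params$t_skew
  }
  t_min <- t_opt - runif(n, 5, 15)
  t_max <- t_opt + runif(n, 3, 10)

  L <- params$seq_length
  # candidate locus grid: spacing comfortably above the largest plant (~33 nt)
  n_loci <- max(8L, L %/% 62L)
  loci_start <- round(seq(15, L - 48, length.out = n_loci))

  truth <- vector("list", n)
  gc_target <- pmin(pmax(params$gc_intercept + params$gc_slope * t_opt +
                           rnorm(n, 0, params$gc_noise_sd),
                         0.25), 0.75)
  rate <- temp_ramp(t_opt, params$motif_rate_low, params$motif_rate_high)
  p3 <- stats::plogis((t_opt - params$p3_t0) / params$p3_scale)
  disr <- temp_ramp(t_opt, params$disruption_high, params$disruption_low,
                    lo_clip = 0, hi_clip = 1)
  gc_root <- min(max(params$gc_intercept + params$gc_slope * params$bm_root,
                     0.25), 0.75)
  root_seq <- generate_sequence(L, gc_root)
  leafmat <- evolve_sequences(tree, root_seq, params$mut_rate)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- paste(adjust_gc(leafmat[tree$tip.label[i], ], gc_target[i]),
               collapse = "")
    k <- min(rpois(1, rate[i]), n_loci)
    reg <- NULL
    if (k > 0) {
      at <- sort(sample.int(n_loci, k))
      for (j in at) {
        g <- if (runif(1) < p3[i]) 3L else 2L
        # loop draw keeps 4g + sum(loops) within the default QGRS max length
        loops <- sample.int(if (g >= 3L) 6L else 7L, 3L, replace = TRUE)
        res <- plant_g4(s, g, loops, loci_start[j],
                        disrupted = runif(1) < disr[i])
        s <- res$seq
        e <- res$entry
        e$species_id <- tree$tip.label[i]
        e$locus <- j
        reg <- rbind(reg, e)
      }
    }
    seqs[i] <- s
    truth[[i]] <- reg
  }
  names(seqs) <- tree$tip.label
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(start = integer(), end = integer(), g = integer(),
                        l1 = integer(), l2 = integer(), l3 = integer(),
                        disrupted = logical(), score = integer(),
                        species_id = character(), locus = integer())
  }
  metadata <- data.frame(species_id = tree$tip.label,
                         t_min = unname(t_min), t_opt = unname(t_opt),
                         t_max = unname(t_max),
                         group = classify_topt(t_opt),
                         rrna_length = L,
                         rrna_gc = vapply(seqs, gc_content, numeric(1),
                                          USE.NAMES = FALSE),
                         stringsAsFactors = FALSE)
  out <- list(tree = tree, metadata = metadata, sequences = seqs,
              alignment = seqs, truth = truth, loci = loci_start,
              params = params)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(seqs, file.path(dir, "rrna.fasta"))
    write_fasta(seqs, file.path(dir, "aligned.fasta"))
    write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_newick(tree, file.path(dir, "true_tree.nwk"))
    jsonlite::write_json(unclass(params), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
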