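# G-quadruplex detection: a QGRS-style candidate enumerator with a per-motif
# G-score, and a G4Hunter-style per-base/window propensity scorer. C-rich
# mirror structures (i-motif-prone) surface as minus-polarity Hunter regions
# and as minus-strand QGRS hits.

#' Detection parameter set
#'
#' Defaults follow the QGRS settings used for 16S scans (max length 30, min
#' G-group size 2, loops 0-36) and the published G4Hunter defaults (window 25,
#' threshold 1.2).
#'
#' @param max_length Maximum motif length (nt).
#' @param min_g Minimum G-group (tetrad) size, >= 2.
#' @param loop_min,loop_max Allowed loop lengths.
#' @param window G4Hunter sliding-window size.
#' @param hunter_threshold Absolute window-mean score needed to report.
#' @param strands Which strands to scan: "plus", "minus" or "both".
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(max_length = 30L, min_g = 2L,
                             loop_min = 0L, loop_max = 36L,
                             window = 25L, hunter_threshold = 1.2,
                             strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  stopifnot(min_g >= 2, max_length >= 4 * min_g, loop_min >= 0,
            loop_min <= loop_max, window >= 1, hunter_threshold > 0)
  structure(list(max_length = as.integer(max_length),
                 min_g = as.integer(min_g),
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 window = as.integer(window),
                 hunter_threshold = hunter_threshold,
                 strands = strands),
            class = "detection_params")
}

empty_motifs <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), g = integer(),
             l1 = integer(), l2 = integer(), l3 = integer(),
             score = integer(), motif = character(),
             stringsAsFactors = FALSE)
}

# per-position length of the G-run starting at that position
g_run_lengths <- function(ch) {
  r <- rle(ch == "G")
  unlist(lapply(seq_along(r$lengths), function(i) {
    if (r$values[i]) rev(seq_len(r$lengths[i])) else integer(r$lengths[i])
  }), use.names = FALSE)
}

#' Enumerate QGRS candidates
#'
#' Emits every candidate `G{g} N{l1} G{g} N{l2} G{g} N{l3} G{g}` with
#' `g >= min_g`, loops within `[loop_min, loop_max]` (loops may themselves
#' contain G) and total length at most `max_length`. All candidates are
#' returned; use [select_nonoverlapping()] for a non-redundant set.
#'
#' @param seq A single sequence (character scalar) over `{A,C,G,T,N}`.
#' @param params A [detection_params()] object.
#' @param seq_id Identifier used in the output table.
#' @return A data.frame with 0-based half-open `start`/`end`, `strand` ("+"),
#'   G-group size `g`, loop lengths `l1..l3`, integer `score` and the motif
#'   sequence.
#' @export
enumerate_qgrs <- function(seq, params = detection_params(), seq_id = "seq") {
  stopifnot(inherits(params, "detection_params"))
  seq <- validate_dna(seq, id = seq_id)
  n <- nchar(seq)
  out_s <- integer(0); out_e <- integer(0); out_g <- integer(0)
  out_l <- matrix(integer(0), ncol = 3)
  if (n >= 4 * params$min_g) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    grun <- g_run_lengths(ch)
    lmin <- params$loop_min; lmax <- params$loop_max
    maxlen <- params$max_length
    acc <- vector("list", 64L); nacc <- 0L
    for (g in params$min_g:(maxlen %/% 4L)) {
      starts <- which(grun >= g)
      if (length(starts) < 4L) next
      for (s1 in starts) {
        # run i+1 must start within [s_i + g + lmin, s_i + g + lmax] and the
        # whole motif must fit in maxlen
        hi1 <- min(s1 + g + lmax, s1 + maxlen - 3L * g - 2L * lmin)
        c2 <- starts[starts >= s1 + g + lmin & starts <= hi1]
        for (s2 in c2) {
          hi2 <- min(s2 + g + lmax, s1 + maxlen - 2L * g - lmin)
          c3 <- starts[starts >= s2 + g + lmin & starts <= hi2]
          for (s3 in c3) {
            hi3 <- min(s3 + g + lmax, s1 + maxlen - g)
            c4 <- starts[starts >= s3 + g + lmin & starts <= hi3]
            for (s4 in c4) {
              nacc <- nacc + 1L
              if (nacc > length(acc)) acc <- c(acc, vector("list", length(acc)))
              acc[[nacc]] <- c(s1, s2, s3, s4, g)
            }
          }
        }
      }
    }
    if (nacc > 0L) {
      m <- do.call(rbind, acc[seq_len(nacc)])
      out_s <- m[, 1L]; out_g <- m[, 5L]
      out_e <- m[, 4L] + out_g - 1L  # 1-based inclusive == 0-based half-open end
      out_l <- cbind(m[, 2L] - m[, 1L] - out_g,
                     m[, 3L] - m[, 2L] - out_g,
                     m[, 4L] - m[, 3L] - out_g)
    }
  }
  if (length(out_s) == 0L) return(empty_motifs())
  score <- score_qgrs(out_g, out_l)
  res <- data.frame(seq_id = seq_id, start = out_s - 1L, end = out_e,
                    strand = "+", g = out_g,
                    l1 = out_l[, 1L], l2 = out_l[, 2L], l3 = out_l[, 3L],
                    score = score,
                    motif = substring(seq, out_s, out_e),
                    stringsAsFactors = FALSE)
  res[order(res$start, res$end, res$g), , drop = FALSE]
}

#' QGRS G-score
#'
#' `score = 21*(g - 1) - round(mean pairwise |li - lj|) - round(mean loop
#' length)` with half-up rounding. Calibrated so that minimal-loop 2- and
#' 3-tetrad motifs score 20 and 41 and the stability cut of 25 separates 2-
#' from 3-tetrad motifs. The score increases strictly in the number of
#' stacked tetrads and weakly decreases in total loop length and loop-length
#' spread.
#'
#' @param g G-group size(s), >= 2. Vectorized.
#' @param loops Numeric vector of 3 loop lengths, or a matrix with 3 columns
#'   (one row per `g`).
#' @return Integer score(s).
#' @export
score_qgrs <- function(g, loops) {
  if (is.null(dim(loops))) loops <- matrix(loops, ncol = 3, byrow = TRUE)
  stopifnot(ncol(loops) == 3, nrow(loops) == length(g))
  if (any(g < 2)) stop("G-group size must be >= 2", call. = FALSE)
  if (any(loops < 0)) stop("negative loop length", call. = FALSE)
  spread <- (abs(loops[, 1] - loops[, 2]) + abs(loops[, 1] - loops[, 3]) +
             abs(loops[, 2] - loops[, 3])) / 3
  as.integer(21L * (g - 1L) - round_half_up(spread) -
             round_half_up(rowMeans(loops)))
}

#' Greedy non-overlapping motif selection
#'
#' Keeps candidates by descending score, ties broken by leftmost start and
#' then shortest length; a candidate overlapping an already retained motif is
#' dropped. The result is independent of input ordering.
#'
#' @param motifs Candidate table from [enumerate_qgrs()], one seq_id and one
#'   strand.
#' @return The retained subset, in selection order.
#' @export
select_nonoverlapping <- function(motifs) {
  if (nrow(motifs) == 0) return(motifs)
  if (length(unique(motifs$seq_id)) > 1) {
    stop("mixed seq_ids in select_nonoverlapping", call. = FALSE)
  }
  if (length(unique(motifs$strand)) > 1) {
    stop("mixed strands in select_nonoverlapping", call. = FALSE)
  }
  ord <- order(-motifs$score, motifs$start, motifs$end - motifs$start)
  m <- motifs[ord, , drop = FALSE]
  kept <- logical(nrow(m))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(m))) {
    if (!any(m$start[i] < ke & m$end[i] > ks)) {
      kept[i] <- TRUE
      ks <- c(ks, m$start[i]); ke <- c(ke, m$end[i])
    }
  }
  m[kept, , drop = FALSE]
}

#' G4Hunter per-base scores
#'
#' Each base in a maximal run of `n` guanines scores `+min(n, 4)`; each base
#' in a maximal run of `n` cytosines scores `-min(n, 4)`; A, T and N score 0
#' (N breaks runs).
#'
#' @param seq A single sequence over `{A,C,G,T,N}`.
#' @return Numeric vector of per-base scores in `[-4, 4]`.
#' @export
hunter_base_scores <- function(seq) {
  seq <- validate_dna(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  v <- ifelse(r$values == "G", pmin(r$lengths, 4),
              ifelse(r$values == "C", -pmin(r$lengths, 4), 0))
  rep(v, r$lengths)
}

#' G4Hunter regions
#'
#' Slides a window of `params$window` (step 1) over the per-base scores and
#' reports windows whose absolute mean reaches `params$hunter_threshold`.
#' Overlapping qualifying windows of the same sign are merged into one region
#' whose `mean_score` is recomputed over the merged span. Positive polarity
#' marks G-rich (G4-prone) regions, negative marks C-rich (i-motif-prone on
#' the given strand).
#'
#' @inheritParams enumerate_qgrs
#' @return A data.frame with 0-based half-open `start`/`end`, `mean_score`
#'   and `polarity` ("+" or "-").
#' @export
hunter_regions <- function(seq, params = detection_params(), seq_id = "seq") {
  stopifnot(inherits(params, "detection_params"))
  seq <- validate_dna(seq, id = seq_id)
  n <- nchar(seq); w <- params$window
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), mean_score = numeric(),
                      polarity = character(), stringsAsFactors = FALSE)
  if (n < w) {
    warning(sprintf("sequence '%s' (%d nt) shorter than window (%d); no scan",
                    seq_id, n, w))
    return(empty)
  }
  s <- hunter_base_scores(seq)
  cs <- c(0, cumsum(s))
  wm <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  qual <- which(abs(wm) >= params$hunter_threshold - 1e-12)
  if (length(qual) == 0) return(empty)
  sgn <- sign(wm[qual])
  reg_s <- integer(0); reg_e <- integer(0); reg_sgn <- numeric(0)
  cur_s <- qual[1]; cur_e <- qual[1] + w - 1L; cur_sgn <- sgn[1]
  for (i in seq_along(qual)[-1]) {
    if (sgn[i] == cur_sgn && qual[i] <= cur_e) {
      cur_e <- qual[i] + w - 1L
    } else {
      reg_s <- c(reg_s, cur_s); reg_e <- c(reg_e, cur_e)
      reg_sgn <- c(reg_sgn, cur_sgn)
      cur_s <- qual[i]; cur_e <- qual[i] + w - 1L; cur_sgn <- sgn[i]
    }
  }
  reg_s <- c(reg_s, cur_s); reg_e <- c(reg_e, cur_e)
  reg_sgn <- c(reg_sgn, cur_sgn)
  ms <- (cs[reg_e + 1L] - cs[reg_s]) / (reg_e - reg_s + 1L)
  data.frame(seq_id = seq_id, start = reg_s - 1L, end = reg_e,
             mean_score = ms,
             polarity = ifelse(reg_sgn > 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Scan one sequence on the requested strands
#'
#' For `method = "qgrs"`, minus-strand hits are found by scanning the reverse
#' complement and mapping coordinates back to the forward frame. For
#' `method = "hunter"`, a single forward scan yields both polarities (C-rich
#' regions are the minus-strand/i-motif signal); the `strands` setting then
#' filters polarities.
#'
#' @inheritParams enumerate_qgrs
#' @param method "qgrs" or "hunter".
#' @return A motif table (qgrs) or region table (hunter).
#' @export
scan_species <- function(seq, params = detection_params(),
                         method = c("qgrs", "hunter"), seq_id = "seq") {
  method <- match.arg(method)
  if (method == "qgrs") {
    res <- empty_motifs()
    if (params$strands %in% c("plus", "both")) {
      res <- enumerate_qgrs(seq, params, seq_id)
    }
    if (params$strands %in% c("minus", "both")) {
      n <- nchar(seq)
      rcm <- enumerate_qgrs(reverse_complement(seq), params, seq_id)
      if (nrow(rcm) > 0) {
        new_start <- n - rcm$end
        rcm$end <- n - rcm$start
        rcm$start <- new_start
        rcm$strand <- "-"
        res <- rbind(res, rcm)
      }
    }
    res[order(res$start, res$end, res$g), , drop = FALSE]
  } else {
    reg <- hunter_regions(seq, params, seq_id)
    if (params$strands == "plus") reg <- reg[reg$polarity == "+", , drop = FALSE]
    if (params$strands == "minus") reg <- reg[reg$polarity == "-", , drop = FALSE]
    reg
  }
}
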