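# Conservation analysis on aligned 16S regions: column profiles (the numeric
# backbone of a sequence logo), presence/absence and scores of orthologous G4
# loci across species, and identification of G4-disrupting substitutions.

#' Per-column base frequencies and information content
#'
#' Gap- and N-excluded frequencies over `{A, C, G, T}` per alignment column,
#' plus the information content `IC = 2 - H` (bits), the height basis of a
#' sequence logo. Columns with no usable base are flagged `all_gap`.
#'
#' @param alignment Named character vector of aligned sequences.
#' @return A data.frame with one row per column: `column` (1-based), `A`,
#'   `C`, `G`, `T` frequencies, `nongap_count`, `ic`, `all_gap`.
#' @export
column_profile <- function(alignment) {
  X <- alignment_matrix(alignment)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(X == b),
                   numeric(ncol(X)))
  if (ncol(X) == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, bases))
  tot <- rowSums(counts)
  nongap <- colSums(X != "-")
  freq <- counts / ifelse(tot > 0, tot, NA_real_)
  h <- apply(freq, 1, function(p) {
    p <- p[is.finite(p) & p > 0]
    if (!length(p)) return(NA_real_)
    -sum(p * log2(p))
  })
  data.frame(column = seq_len(ncol(X)),
             A = freq[, "A"], C = freq[, "C"],
             G = freq[, "G"], T = freq[, "T"],
             nongap_count = nongap,
             ic = 2 - h,
             all_gap = tot == 0,
             row.names = NULL)
}

# ungapped 0-based coordinates <-> alignment columns for one gapped sequence
ungapped_index <- function(gapped_chars) cumsum(gapped_chars != "-")

#' Map a reference window through an alignment
#'
#' Maps a 0-based half-open window on the ungapped reference sequence through
#' the alignment columns to every species' own ungapped coordinates, and
#' extracts each species' (ungapped) subsequence spanning those columns.
#' Windows extending past the reference end are clamped with a warning.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param reference_id Name of the reference record.
#' @param ref_start,ref_end 0-based half-open window on the ungapped
#'   reference.
#' @return A data.frame with `species_id`, `start`, `end` (0-based half-open,
#'   per species, ungapped) and `subseq`.
#' @export
map_window <- function(alignment, reference_id, ref_start, ref_end) {
  X <- alignment_matrix(alignment)
  if (!reference_id %in% rownames(X)) {
    stop("reference '", reference_id, "' not in alignment", call. = FALSE)
  }
  stopifnot(ref_start >= 0, ref_end > ref_start)
  ref <- X[reference_id, ]
  upos <- ungapped_index(ref)          # per column: ungapped length so far
  ref_len <- upos[length(upos)]
  if (ref_start >= ref_len) {
    stop("window starts beyond the ungapped reference length", call. = FALSE)
  }
  if (ref_end > ref_len) {
    warning("window clamped to the reference end")
    ref_end <- ref_len
  }
  col_start <- which(upos == ref_start + 1 & ref != "-")[1]
  col_end <- which(upos == ref_end & ref != "-")[1]
  res <- lapply(rownames(X), function(sp) {
    row <- X[sp, ]
    u <- ungapped_index(row)
    sub <- row[col_start:col_end]
    sub <- sub[sub != "-"]
    start0 <- if (col_start > 1) u[col_start - 1] else 0L
    data.frame(species_id = sp, start = start0,
               end = u[col_end],
               subseq = paste(sub, collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Presence/score matrix of G4 loci across species
#'
#' For each species and each reference-coordinate locus, maps the locus
#' through the alignment, rescans the mapped subsequence (plus a small flank
#' to tolerate indel shifts) with [enumerate_qgrs()] and
#' [select_nonoverlapping()], and records the best score, or `NA` when no
#' motif is found (or the mapping fails for that cell).
#'
#' @param alignment Named character vector of aligned sequences.
#' @param reference_id Reference record name.
#' @param loci Data.frame with 0-based half-open `start`/`end` windows on the
#'   ungapped reference.
#' @param params [detection_params()] used for rescanning.
#' @param flank Flank (nt) added on both sides of each mapped locus.
#' @return Integer matrix, species x loci; `NA` marks absence.
#' @export
g4_presence_matrix <- function(alignment, reference_id, loci,
                               params = detection_params(), flank = 5L) {
  al <- as_alignment(alignment)
  species <- names(al)
  ungapped <- gsub("-", "", al, fixed = TRUE)
  pm <- matrix(NA_integer_, nrow = length(species), ncol = nrow(loci),
               dimnames = list(species,
                               paste0("locus_", loci$start, "_", loci$end)))
  for (j in seq_len(nrow(loci))) {
    mapped <- tryCatch(
      map_window(al, reference_id, loci$start[j], loci$end[j]),
      error = function(e) NULL)
    if (is.null(mapped)) {
      warning(sprintf("locus %d could not be mapped; column left missing", j))
      next
    }
    for (i in seq_along(species)) {
      row <- mapped[mapped$species_id == species[i], ]
      seqi <- ungapped[[species[i]]]
      s <- max(0L, row$start - flank)
      e <- min(nchar(seqi), row$end + flank)
      if (e <= s) next
      sub <- substring(seqi, s + 1L, e)
      hits <- select_nonoverlapping(
        enumerate_qgrs(sub, params, seq_id = species[i]))
      if (nrow(hits) > 0) pm[i, j] <- max(hits$score)
    }
  }
  pm
}

#' Write a presence matrix as TSV
#'
#' Absent cells are written as ".".
#'
#' @param pm Matrix from [g4_presence_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_presence_matrix <- function(pm, path) {
  out <- cbind(species_id = rownames(pm),
               as.data.frame(ifelse(is.na(pm), ".", pm)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Substitutions disrupting a G4 motif
#'
#' Lists every mismatch or indel between an aligned reference/species pair
#' inside a motif footprint, flags those falling in one of the motif's four
#' G-runs, and classifies the species locus as forming / non-forming by
#' rescanning the species subsequence for a motif with at least the
#' reference's G-group size.
#'
#' @param reference_seq,species_seq Aligned (gapped) sequences of equal
#'   length.
#' @param motif One-row motif table (reference ungapped coordinates), as
#'   produced by [enumerate_qgrs()].
#' @param params Detection parameters for the rescan.
#' @return List with `substitutions` (position, ref_base, alt_base,
#'   in_g_run) and `forming` (logical).
#' @export
disrupting_substitutions <- function(reference_seq, species_seq, motif,
                                     params = detection_params()) {
  al <- c(ref = unname(reference_seq), sp = unname(species_seq))
  al <- vapply(al, validate_dna, character(1), allow_gaps = TRUE)
  if (nchar(al[1]) != nchar(al[2])) {
    stop("aligned pair differs in length", call. = FALSE)
  }
  refc <- strsplit(al[["ref"]], "", fixed = TRUE)[[1]]
  ref_len <- sum(refc != "-")
  if (motif$end > ref_len) stop("motif outside the aligned window", call. = FALSE)
  mapped <- map_window(setNames(al, c("ref", "sp")), "ref",
                       motif$start, motif$end)
  spc <- strsplit(al[["sp"]], "", fixed = TRUE)[[1]]
  upos <- ungapped_index(refc)
  cols <- which(refc != "-" & upos >= motif$start + 1 & upos <= motif$end)
  cols <- range(cols)
  idx <- cols[1]:cols[2]
  # offsets of the four G-runs within the motif footprint
  g <- motif$g
  runs <- c(0, g + motif$l1, 2 * g + motif$l1 + motif$l2,
            3 * g + motif$l1 + motif$l2 + motif$l3)
  in_run <- function(off) any(off >= runs & off < runs + g)
  subs <- list()
  for (cc in idx) {
    rb <- refc[cc]; sb <- spc[cc]
    if (rb == sb) next
    off <- if (rb != "-") upos[cc] - (motif$start + 1) else NA_integer_
    pos <- if (rb != "-") upos[cc] - 1L else NA_integer_  # 0-based ref coord
    subs[[length(subs) + 1]] <- data.frame(
      position = pos, ref_base = rb, alt_base = sb,
      in_g_run = if (!is.na(off)) in_run(off) else FALSE,
      stringsAsFactors = FALSE)
  }
  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(position = integer(), ref_base = character(),
               alt_base = character(), in_g_run = logical())
  sp_row <- mapped[mapped$species_id == "sp", ]
  hits <- enumerate_qgrs(sp_row$subseq, params, seq_id = "sp")
  forming <- nrow(hits) > 0 && any(hits$g >= g)
  list(substitutions = subs, forming = forming)
}
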