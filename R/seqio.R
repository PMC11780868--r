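# FASTA / BED / metadata readers and writers, plus basic sequence utilities.
# Sequences are represented as named character vectors of uppercase residues
# over {A,C,G,T,N}; alignments additionally allow the gap character '-'.

# Normalize and validate residues. U (RNA) is accepted and mapped to T so that
# motifs can be discussed on DNA and rRNA alike; lowercase is uppercased.
# Errors report the 1-based position of the first offending character.
validate_dna <- function(x, allow_gaps = FALSE, id = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  up <- chartr("U", "T", toupper(x))
  pat <- if (allow_gaps) "[^ACGTN-]" else "[^ACGTN]"
  bad <- regexpr(pat, up)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d%s",
                 substr(up, bad, bad), bad,
                 if (is.null(id)) "" else paste0(" in sequence '", id, "'")),
         call. = FALSE)
  }
  up
}

#' Read sequences from a FASTA file
#'
#' Residues are uppercased, `U` is normalized to `T`, and characters outside
#' `A/C/G/T/N` (plus `-` when `allow_gaps = TRUE`) are rejected with the
#' offending position. Duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Allow the alignment gap character `-`.
#' @return A named character vector, one element per record.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  seqs <- as.character(set)
  out <- vapply(seq_along(seqs), function(i) {
    validate_dna(seqs[[i]], allow_gaps = allow_gaps, id = ids[i])
  }, character(1))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrapping width (columns).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (length(seqs) == 0) stop("no records to write", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all records need ids", call. = FALSE)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Requires at least two records, all of identical (gapped) length.
#'
#' @inheritParams read_fasta
#' @return A named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path) {
  al <- read_fasta(path, allow_gaps = TRUE)
  as_alignment(al)
}

#' Validate an alignment
#'
#' @param seqs Named character vector with gaps allowed.
#' @return `seqs`, after checking >= 2 records of identical length.
#' @export
as_alignment <- function(seqs) {
  if (length(seqs) < 2) stop("an alignment needs at least 2 records", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1) {
    stop("alignment records differ in length", call. = FALSE)
  }
  seqs
}

#' Read the species metadata table
#'
#' Tab-separated file with header columns `species_id`, `t_min`, `t_opt`,
#' `t_max` (growth temperatures, degrees C) and optionally `genome_fasta` and
#' `rrna_fasta` paths. A thermal `group` column is assigned from `t_opt` via
#' [classify_topt()].
#'
#' @param path Path to the TSV file.
#' @return A data.frame, one row per species.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  req <- c("species_id", "t_min", "t_opt", "t_max")
  miss <- setdiff(req, names(md))
  if (length(miss)) {
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cc in c("t_min", "t_opt", "t_max")) {
    md[[cc]] <- as.numeric(md[[cc]])
    if (any(!is.finite(md[[cc]]))) {
      stop("non-numeric or missing values in column ", cc, call. = FALSE)
    }
  }
  bad <- which(md$t_min > md$t_opt | md$t_opt > md$t_max)
  if (length(bad)) {
    stop(sprintf("temperature ordering violated (t_min <= t_opt <= t_max) in row %d (species '%s')",
                 bad[1L], md$species_id[bad[1L]]), call. = FALSE)
  }
  if (anyDuplicated(md$species_id)) {
    stop("duplicate species_id: ", md$species_id[duplicated(md$species_id)][1L],
         call. = FALSE)
  }
  md$group <- classify_topt(md$t_opt)
  md
}

#' Write detected motifs or regions as BED6
#'
#' Accepts either QGRS motif tables (from [enumerate_qgrs()]/[scan_species()];
#' BED score = G-score) or G4Hunter region tables (from [hunter_regions()];
#' BED score = `round(100 * |mean_score|)`, strand column = polarity). Output
#' is 0-based half-open, tab-separated and deterministically sorted by
#' (seq_id, start, end).
#'
#' @param x Motif or region data.frame.
#' @param path Output path.
#' @param name_prefix Prefix for the BED name column.
#' @return The path, invisibly.
#' @export
write_bed <- function(x, path, name_prefix = "G4") {
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if ("mean_score" %in% names(x)) {
    score <- round_half_up(100 * abs(x$mean_score))
    strand <- x$polarity
  } else {
    score <- x$score
    strand <- x$strand
  }
  stopifnot(all(x$start >= 0), all(x$end > x$start))
  ord <- order(x$seq_id, x$start, x$end)
  bed <- data.frame(seq_id = x$seq_id[ord],
                    start = x$start[ord], end = x$end[ord],
                    name = paste0(name_prefix, "_", seq_len(nrow(x))),
                    score = score[ord], strand = strand[ord])
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#'
#' @param path Path to a 6-column BED file.
#' @return A data.frame with columns seq_id, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character()))
  }
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("expected 6 BED columns", call. = FALSE)
  names(bed)[1:6] <- c("seq_id", "start", "end", "name", "score", "strand")
  bed[, 1:6]
}

#' Reverse complement
#'
#' Standard complement, reversed; `N` maps to `N`. Used computationally for
#' minus-strand G4 scanning and for C-rich (i-motif) mirror analysis.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  nm <- names(seq)
  seq <- vapply(seq, validate_dna, character(1), USE.NAMES = FALSE)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- nm
  out
}
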