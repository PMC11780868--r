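# Per-species and per-region summary statistics: GC content, G4 frequency,
# score summaries, stability flags and thermal-group classification.

#' GC content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` is excluded from numerator and
#' denominator. Invariant under reverse complement.
#'
#' @param seq A single sequence over `{A,C,G,T,N}`.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- validate_dna(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  informative <- ch %in% c("A", "C", "G", "T")
  if (!any(informative)) stop("no informative (non-N) bases", call. = FALSE)
  sum(ch %in% c("G", "C")) / sum(informative)
}

#' Thermal group from optimal growth temperature
#'
#' Psychrophile `T_opt < 20`, mesophile `[20, 45)`, thermophile `[45, 80)`,
#' hyperthermophile `>= 80` (degrees C). The four intervals partition the
#' real line.
#'
#' @param t_opt Numeric vector of optimal growth temperatures (degrees C).
#' @return Factor with levels psychrophile, mesophile, thermophile,
#'   hyperthermophile.
#' @export
classify_topt <- function(t_opt) {
  if (any(!is.finite(t_opt))) stop("non-finite t_opt", call. = FALSE)
  cut(t_opt, breaks = c(-Inf, 20, 45, 80, Inf), right = FALSE,
      labels = thermal_groups())
}

#' @rdname classify_topt
#' @export
thermal_groups <- function() {
  c("psychrophile", "mesophile", "thermophile", "hyperthermophile")
}

#' G4 frequency per kilobase
#'
#' Number of G4 sequences divided by region length, reported per kb.
#'
#' @param motif_count Number of motifs.
#' @param length_bp Region length in bp (> 0).
#' @return Motifs per kb.
#' @export
g4_frequency <- function(motif_count, length_bp) {
  if (any(length_bp <= 0)) stop("region length must be > 0", call. = FALSE)
  1000 * motif_count / length_bp
}

#' Summarise detected motifs for one species/region
#'
#' A species has a "stable" G4 when its best motif score exceeds
#' `stable_score_threshold` (default 25, the cut that separates motifs with
#' three or more stacked G-tetrads from two-tetrad motifs under the default
#' score formula). An empty motif set is a legitimate observation: counts and
#' scores are reported as 0 with `has_motifs = FALSE`.
#'
#' @param species_id Species identifier.
#' @param motifs Motif table for this species/region (e.g. after
#'   [select_nonoverlapping()]).
#' @param region_kind "genome" or "rrna16s".
#' @param length_bp Region length in bp.
#' @param stable_score_threshold Stability cut on the best score.
#' @return One-row data.frame of region metrics.
#' @export
summarize_region <- function(species_id, motifs,
                             region_kind = c("rrna16s", "genome"),
                             length_bp, stable_score_threshold = 25) {
  region_kind <- match.arg(region_kind)
  n <- nrow(motifs)
  data.frame(species_id = species_id,
             region_kind = region_kind,
             length_bp = as.integer(length_bp),
             motif_count = n,
             freq_per_kb = g4_frequency(n, length_bp),
             mean_score = if (n) mean(motifs$score) else 0,
             max_score = if (n) as.integer(max(motifs$score)) else 0L,
             has_motifs = n > 0,
             has_stable_g4 = n > 0 && max(motifs$score) > stable_score_threshold,
             stringsAsFactors = FALSE)
}

#' Fraction of species in a thermal group with a stable G4
#'
#' @param metrics Row-bound [summarize_region()] output, one row per species.
#'   May already contain a `group` column.
#' @param meta Metadata data.frame with `species_id` and `group` columns
#'   (see [read_metadata()]); only used when `metrics` lacks `group`.
#' @param group Thermal group name.
#' @return Fraction in `[0, 1]`.
#' @export
stable_ratio <- function(metrics, meta = NULL, group) {
  if (!"group" %in% names(metrics)) {
    metrics <- merge(metrics, meta[, c("species_id", "group")],
                     by = "species_id")
  }
  sel <- as.character(metrics$group) == group
  if (!any(sel)) stop("no species in group '", group, "'", call. = FALSE)
  mean(metrics$has_stable_g4[sel])
}
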