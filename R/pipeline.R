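# End-to-end orchestration: simulate (or load) -> detect -> metrics -> tree
# -> comparative stats -> conservation -> report. Configuration is a flat
# key = value text file; every stage writes deterministic TSV/BED/Newick
# outputs and the run report is recomputable from them.

config_defaults <- function() {
  list(
    # data source: when metadata/rrna_fasta are empty, simulate
    metadata = "", rrna_fasta = "", alignment = "", tree = "",
    outdir = "g4therm_out",
    seed = 1L,
    # synthetic preset (paperlike; see simulation_params())
    n_species = 96L, seq_length = 1500L, birth_rate = 1,
    bm_sigma2 = 100, bm_root = 35, lambda_true = 1,
    gc_intercept = 0.40, gc_slope = 0.003, gc_noise_sd = 0.02,
    motif_rate_low = 2, motif_rate_high = 10,
    p3_t0 = 70, p3_scale = 7,
    disruption_high = 0.5, disruption_low = 0.05,
    # detection (QGRS defaults for 16S scans)
    max_length = 30L, min_g = 2L, loop_min = 0L, loop_max = 36L,
    window = 25L, hunter_threshold = 1.2,
    strands = "plus", method = "qgrs",
    stable_score_threshold = 25,
    # statistics
    lambda_mode = "ml", lambda_fixed = 1, anova_transform = "auto",
    bootstrap = 0L,
    # stage toggles
    run_conservation = TRUE, verbose = TRUE
  )
}

config_spec <- function() {
  d <- config_defaults()
  data.frame(key = names(d),
             type = vapply(d, function(v) class(v)[1], character(1)),
             stringsAsFactors = FALSE)
}

#' Validate a pipeline configuration
#'
#' Reads a flat `key = value` text file (`#` comments and `[section]`
#' headers are ignored; an empty file yields the defaults), applies typed
#' overrides, and bounds-checks everything. All violations are reported
#' together in a single error.
#'
#' @param path Optional path to a config file.
#' @param ... Named overrides applied after the file.
#' @return A validated config list of class `pipeline_config`, with defaults
#'   filled in.
#' @export
validate_config <- function(path = NULL, ...) {
  cfg <- config_defaults()
  errs <- character(0)
  kv <- list(...)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !grepl("^\\[.*\\]$", lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        errs <- c(errs, paste0("cannot parse line: '", ln, "'"))
        next
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      kv[[key]] <- val
    }
  }
  for (key in names(kv)) {
    if (!key %in% names(cfg)) {
      errs <- c(errs, paste0("unknown key: '", key, "'"))
      next
    }
    val <- kv[[key]]
    tgt <- class(cfg[[key]])[1]
    conv <- switch(tgt,
      integer = suppressWarnings(as.integer(val)),
      numeric = suppressWarnings(as.numeric(val)),
      logical = if (is.logical(val)) val else
        isTRUE(toupper(as.character(val)) %in% c("TRUE", "T", "1", "YES")),
      as.character(val))
    if (tgt %in% c("integer", "numeric") && anyNA(conv)) {
      errs <- c(errs, sprintf("key '%s' must be %s", key, tgt))
      next
    }
    cfg[[key]] <- conv
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$min_g >= 2, "min_g must be >= 2")
  chk(cfg$max_length >= 4 * cfg$min_g, "max_length must be >= 4 * min_g")
  chk(cfg$loop_min >= 0 && cfg$loop_min <= cfg$loop_max,
      "need 0 <= loop_min <= loop_max")
  chk(cfg$window >= 1, "window must be >= 1")
  chk(cfg$hunter_threshold > 0, "hunter_threshold must be > 0")
  chk(cfg$strands %in% c("plus", "minus", "both"),
      "strands must be plus/minus/both")
  chk(cfg$method %in% c("qgrs", "hunter"), "method must be qgrs/hunter")
  chk(cfg$lambda_mode %in% c("ml", "fixed"), "lambda_mode must be ml/fixed")
  chk(cfg$lambda_fixed >= 0 && cfg$lambda_fixed <= 1,
      "lambda_fixed must be in [0, 1]")
  chk(cfg$anova_transform %in% c("none", "log10", "auto"),
      "anova_transform must be none/log10/auto")
  chk(cfg$bootstrap >= 0, "bootstrap must be >= 0")
  chk(cfg$n_species >= 3, "n_species must be >= 3")
  chk(cfg$seq_length >= 300, "seq_length must be >= 300")
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(cfg, stage, fmt, ...) {
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order (data, detect, metrics, tree, stats,
#' conservation, report), writing all intermediate files under
#' `cfg$outdir`. Outputs are deterministic for a fixed seed: rerunning
#' produces byte-identical TSV/BED/Newick files. Any stage error aborts with
#' the stage name.
#'
#' @param cfg A [validate_config()] object.
#' @return The run report (class `g4therm_report`), invisibly a list of
#'   per-stage counts, parameter echo and headline statistics.
#' @export
run_pipeline <- function(cfg = validate_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- data ------------------------------------------------------------
  dat <- stage("data", {
    if (nzchar(cfg$metadata)) {
      md <- read_metadata(cfg$metadata)
      seqs <- read_fasta(cfg$rrna_fasta)
      miss <- setdiff(md$species_id, names(seqs))
      if (length(miss)) stop("no sequence for species: ", miss[1])
      seqs <- seqs[md$species_id]
      al <- if (nzchar(cfg$alignment)) read_alignment(cfg$alignment) else NULL
      md$rrna_length <- nchar(seqs)
      md$rrna_gc <- vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE)
      tru <- NULL
      tree_true <- if (nzchar(cfg$tree)) read_newick(cfg$tree) else NULL
      list(metadata = md, sequences = seqs, alignment = al, truth = tru,
           tree_true = tree_true)
    } else {
      sp <- simulation_params(
        n_species = cfg$n_species, seed = cfg$seed,
        birth_rate = cfg$birth_rate, bm_sigma2 = cfg$bm_sigma2,
        bm_root = cfg$bm_root, lambda_true = cfg$lambda_true,
        gc_intercept = cfg$gc_intercept, gc_slope = cfg$gc_slope,
        gc_noise_sd = cfg$gc_noise_sd,
        seq_length = cfg$seq_length,
        motif_rate_low = cfg$motif_rate_low,
        motif_rate_high = cfg$motif_rate_high,
        p3_t0 = cfg$p3_t0, p3_scale = cfg$p3_scale,
        disruption_high = cfg$disruption_high,
        disruption_low = cfg$disruption_low)
      ds <- build_dataset(sp, dir = outdir)
      list(metadata = ds$metadata, sequences = ds$sequences,
           alignment = ds$alignment, truth = ds$truth,
           tree_true = ds$tree)
    }
  })
  md <- dat$metadata
  pipeline_log(cfg, "data", "%d species, %d sequences",
               nrow(md), length(dat$sequences))

  # -- detect ----------------------------------------------------------
  params <- detection_params(max_length = cfg$max_length, min_g = cfg$min_g,
                             loop_min = cfg$loop_min, loop_max = cfg$loop_max,
                             window = cfg$window,
                             hunter_threshold = cfg$hunter_threshold,
                             strands = cfg$strands)
  hits <- stage("detect", {
    lapply(md$species_id, function(sp) {
      h <- scan_species(dat$sequences[[sp]], params, method = cfg$method,
                        seq_id = sp)
      if (cfg$method == "qgrs" && nrow(h) > 0) {
        h <- do.call(rbind, lapply(split(h, h$strand), select_nonoverlapping))
        rownames(h) <- NULL
        h <- h[order(h$start, h$end), , drop = FALSE]
      }
      h
    })
  })
  all_hits <- do.call(rbind, hits)
  stage("detect", {
    write.table(all_hits, file.path(outdir, "motifs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_bed(all_hits, file.path(outdir, "motifs.bed"))
  })
  pipeline_log(cfg, "detect", "%d motifs/regions across %d species",
               nrow(all_hits), nrow(md))

  # -- metrics ---------------------------------------------------------
  metrics <- stage("metrics", {
    m <- do.call(rbind, lapply(seq_len(nrow(md)), function(i) {
      summarize_region(md$species_id[i], hits[[i]], "rrna16s",
                       nchar(dat$sequences[[md$species_id[i]]]),
                       stable_score_threshold = cfg$stable_score_threshold)
    }))
    out <- merge(md, m, by = "species_id", sort = TRUE)
    write.table(out, file.path(outdir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out
  })
  pipeline_log(cfg, "metrics", "%d species summarised", nrow(metrics))

  # -- tree ------------------------------------------------------------
  tree <- stage("tree", {
    al <- dat$alignment %||% dat$sequences
    tr <- if (cfg$bootstrap > 0) {
      bootstrap_support(al, B = cfg$bootstrap, seed = cfg$seed)
    } else {
      nj_tree(distance_matrix(al))
    }
    write_newick(tr, file.path(outdir, "tree.nwk"))
    tr
  })
  pipeline_log(cfg, "tree", "NJ tree with %d tips%s", length(tree$tip.label),
               if (cfg$bootstrap > 0) sprintf(" (%d bootstrap replicates)",
                                              cfg$bootstrap) else "")

  # -- stats -----------------------------------------------------------
  stats_out <- stage("stats", {
    rtree <- root_midpoint(tree)
    responses <- c("freq_per_kb", "mean_score", "max_score", "rrna_gc")
    predictors <- c("t_min", "t_opt", "t_max")
    rows <- list()
    for (resp in responses) {
      for (pred in predictors) {
        y <- setNames(metrics[[resp]], metrics$species_id)
        x <- setNames(metrics[[pred]], metrics$species_id)
        fit <- pgls_fit(y, x, rtree, lambda_mode = cfg$lambda_mode,
                        lambda_fixed = cfg$lambda_fixed)
        pr <- pearson(unname(x), unname(y))
        rows[[length(rows) + 1]] <- data.frame(
          response = resp, predictor = pred,
          slope = unname(fit$coefficients[2]), se = unname(fit$se[2]),
          t = unname(fit$t_stats[2]), p_pgls = unname(fit$p_values[2]),
          lambda = fit$lambda, pearson_r = pr$r, p_pearson = pr$p)
      }
    }
    panel <- do.call(rbind, rows)
    write.table(panel, file.path(outdir, "pgls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    grp_sizes <- table(metrics$group)
    usable <- names(grp_sizes)[grp_sizes >= 2]
    anova_res <- lapply(c(freq = "freq_per_kb", score = "mean_score"),
                        function(resp) {
      gl <- split(metrics[[resp]], as.character(metrics$group))[usable]
      if (length(gl) >= 2) anova_oneway(gl, transform = cfg$anova_transform)
      else NULL
    })
    ratios <- vapply(thermal_groups(), function(g) {
      if (any(metrics$group == g)) stable_ratio(metrics, md, g) else NA_real_
    }, numeric(1))
    sr <- data.frame(group = thermal_groups(),
                     n = as.integer(table(factor(metrics$group,
                                                 levels = thermal_groups()))),
                     stable_ratio = unname(ratios))
    write.table(sr, file.path(outdir, "stable_ratio.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(panel = panel, anova = anova_res, stable = sr)
  })
  pipeline_log(cfg, "stats", "%d PGLS fits, %d thermal groups present",
               nrow(stats_out$panel), sum(!is.na(stats_out$stable$stable_ratio)))

  # -- conservation ----------------------------------------------------
  conserved <- NULL
  if (isTRUE(cfg$run_conservation) && !is.null(dat$truth) &&
      nrow(dat$truth) > 0) {
    conserved <- stage("conservation", {
      tr <- dat$truth
      # loci planted in at least half the species, rescanned across all
      tab <- table(tr$locus)
      keep <- as.integer(names(tab)[tab >= nrow(md) / 2])
      if (length(keep) == 0) {
        keep <- as.integer(names(sort(tab, decreasing = TRUE)))[
          seq_len(min(4L, length(tab)))]
      }
      loci <- unique(tr[tr$locus %in% keep, c("locus", "start", "end")])
      loci <- loci[!duplicated(loci$locus), ]
      loci <- loci[order(loci$start), ]
      al <- dat$alignment %||% dat$sequences
      pm <- g4_presence_matrix(al, md$species_id[1],
                               loci[, c("start", "end")], params)
      write_presence_matrix(pm, file.path(outdir, "presence.tsv"))
      prof <- column_profile(al)
      write.table(prof, file.path(outdir, "profile.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      pm
    })
    pipeline_log(cfg, "conservation", "%d loci rescanned", ncol(conserved))
  }

  # -- report ----------------------------------------------------------
  report <- stage("report", {
    panel <- stats_out$panel
    key <- panel[panel$response == "mean_score" & panel$predictor == "t_opt", ]
    rep <- list(
      version = as.character(packageVersion("g4therm")),
      seed = cfg$seed,
      n_species = nrow(md),
      n_motifs = nrow(all_hits),
      group_counts = as.list(table(factor(metrics$group,
                                          levels = thermal_groups()))),
      group_mean_freq = as.list(tapply(metrics$freq_per_kb, metrics$group,
                                       mean)),
      pgls_slope_score_topt = key$slope,
      pgls_p_score_topt = key$p_pgls,
      pgls_lambda_score_topt = key$lambda,
      pgls_positive_significant = key$slope > 0 & key$p_pgls < 0.05,
      pearson_r_gc_topt = panel$pearson_r[panel$response == "rrna_gc" &
                                            panel$predictor == "t_opt"],
      stable_ratio = setNames(as.list(stats_out$stable$stable_ratio),
                              stats_out$stable$group),
      params = unclass(cfg)
    )
    jsonlite::write_json(rep, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    rep
  })
  pipeline_log(cfg, "report", "written to %s", file.path(outdir, "report.json"))
  class(report) <- "g4therm_report"
  invisible(report)
}

#' @export
print.g4therm_report <- function(x, ...) {
  cat("g4therm pipeline report\n")
  cat(sprintf("  species: %d, motifs: %d, seed: %d\n",
              x$n_species, x$n_motifs, x$seed))
  cat(sprintf("  PGLS 16S G4 score ~ T_opt: slope %.4g (p = %.3g, lambda = %.3f)\n",
              x$pgls_slope_score_topt, x$pgls_p_score_topt,
              x$pgls_lambda_score_topt))
  cat(sprintf("  Pearson r (16S GC, T_opt): %.3f\n", x$pearson_r_gc_topt))
  cat("  stable-G4 ratio by group:\n")
  for (g in names(x$stable_ratio)) {
    cat(sprintf("    %-16s %s\n", g,
                ifelse(is.na(x$stable_ratio[[g]]), "absent",
                       sprintf("%.3f", x$stable_ratio[[g]]))))
  }
  invisible(x)
}
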