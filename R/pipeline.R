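# Orchestration: validated run configuration, the three stage runners
# (homologue Ka/Ks chain, SNP discovery, decoupling statistics), reason-coded
# discard logs and a reconciling run manifest. Invalid inputs signal
# condition class "kakspipe_config_error"; structurally valid runs with an
# empty result signal "kakspipe_empty_result" (the command-line wrapper maps
# these to exit codes 2 and 3).

config_error <- function(...) {
  stop(structure(class = c("kakspipe_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

empty_result <- function(...) {
  stop(structure(class = c("kakspipe_empty_result", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

RUN_CONFIG_KEYS <- c("fasta_a", "fasta_b", "hits_ab", "hits_ba", "kaks_tsv",
                     "expression_table", "pileup", "contigs", "out_dir",
                     "max_evalue", "min_score", "min_aln_bp",
                     "snp_min_depth_low", "snp_min_depth_medium",
                     "snp_min_depth_high", "snp_min_maf_low",
                     "snp_min_maf_medium", "snp_min_maf_high",
                     "min_flank", "max_homopolymer", "transform_profile",
                     "zero_ratio", "seed")

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected; every referenced input path must exist;
#' thresholds must be positive. Only the keys needed by the stage being run
#' have to be set.
#'
#' @param ... Named configuration values; see `RUN_CONFIG_KEYS` in the
#'   package source, [run_kaks_pipeline()], [run_snp_pipeline()] and
#'   [run_decoupling_analysis()] for their meaning.
#' @return A validated list of class `kakspipe_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(!nzchar(names(cfg))))) {
    config_error("all config values must be named")
  }
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    config_error("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(max_evalue = 1e-5, min_aln_bp = 150,
                   snp_min_depth_low = 8, snp_min_depth_medium = 12,
                   snp_min_depth_high = 15, snp_min_maf_low = 0.15,
                   snp_min_maf_medium = 0.20, snp_min_maf_high = 0.25,
                   min_flank = 50, max_homopolymer = 2,
                   transform_profile = "methods", zero_ratio = "exclude",
                   seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("fasta_a", "fasta_b", "hits_ab", "hits_ba", "kaks_tsv",
              "expression_table", "pileup", "contigs")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      config_error("config key '", k, "' references a missing path: ", cfg[[k]])
    }
  }
  for (k in c("max_evalue", "min_aln_bp", "min_flank",
              grep("^snp_", RUN_CONFIG_KEYS, value = TRUE))) {
    v <- cfg[[k]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
      config_error("config key '", k, "' must be a positive number")
    }
  }
  if (is.null(cfg$out_dir)) config_error("config key 'out_dir' is required")
  structure(cfg, class = "kakspipe_config")
}

#' Read a flat key=value run configuration file
#'
#' INI-style: one `key = value` per line; `#` starts a comment; numeric
#' values are converted. The raw text is echoed into the run manifest.
#'
#' @param path Path to the configuration file.
#' @return A validated `kakspipe_config` with attribute `raw_text`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  cfg <- list()
  for (line in lines[keep]) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) config_error("malformed config line: ", line)
    key <- trimws(kv[[1]])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  out <- do.call(run_config, cfg)
  attr(out, "raw_text") <- lines
  out
}

config_tiers <- function(cfg) {
  snp_tiers(min_depth = c(low = cfg$snp_min_depth_low,
                          medium = cfg$snp_min_depth_medium,
                          high = cfg$snp_min_depth_high),
            min_maf = c(low = cfg$snp_min_maf_low,
                        medium = cfg$snp_min_maf_medium,
                        high = cfg$snp_min_maf_high))
}

write_manifest <- function(out_dir, stage, cfg, counts, t0) {
  manifest <- list(
    stage = stage,
    tool_version = as.character(utils::packageVersion("kakspipe")),
    config = cfg[!vapply(unclass(cfg), is.null, logical(1))],
    config_text = attr(cfg, "raw_text"),
    counts = counts,
    wall_clock_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

read_input <- function(reader, path, what) {
  tryCatch(reader(path), error = function(e) {
    config_error("invalid ", what, " (", path, "): ", conditionMessage(e))
  })
}

#' Run the full homologue Ka/Ks pipeline
#'
#' Stages, in order: six-frame translated search in both directions (or
#' ingestion of precomputed tabular hits), reciprocal-best-hit pairing,
#' trimming to the overlapping hit region, global protein alignment, codon
#' threading, stop/nonsense-column removal, the minimum-length filter, NG86
#' Ka/Ks estimation and selection classification. Writes `pairs.tsv`,
#' `kaks.tsv`, `discards.tsv`, per-pair aligned codon FASTA under
#' `alignments/`, and a reconciling `manifest.json` to the output directory.
#'
#' @param cfg A `kakspipe_config` with `fasta_a`, `fasta_b` (and optionally
#'   `hits_ab`/`hits_ba` tabular hit files), `out_dir`, and thresholds
#'   `max_evalue`/`min_score`/`min_aln_bp`.
#' @return Invisibly, a list with `kaks` (the results table) and `manifest`.
#' @export
run_kaks_pipeline <- function(cfg) {
  t0 <- Sys.time()
  if (is.null(cfg$fasta_a) || is.null(cfg$fasta_b)) {
    config_error("fasta_a and fasta_b are required")
  }
  seqs_a <- read_input(read_fasta, cfg$fasta_a, "fasta_a")
  seqs_b <- read_input(read_fasta, cfg$fasta_b, "fasta_b")
  dir.create(file.path(cfg$out_dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  scoring <- blosum62_scoring()
  if (!is.null(cfg$hits_ab)) {
    hits_ab <- read_input(read_tabular_hits, cfg$hits_ab, "hits_ab")
    hits_ba <- read_input(read_tabular_hits, cfg$hits_ba, "hits_ba")
  } else {
    hits_ab <- translated_search(seqs_a, seqs_b, scoring,
                                 max_evalue = cfg$max_evalue,
                                 min_score = cfg$min_score)
    hits_ba <- translated_search(seqs_b, seqs_a, scoring,
                                 max_evalue = cfg$max_evalue,
                                 min_score = cfg$min_score)
  }
  pairs <- reciprocal_best_hits(hits_ab, hits_ba)
  write_tsv(pairs, file.path(cfg$out_dir, "pairs.tsv"))
  discards <- data.frame(pair_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  alns <- list()
  ids <- data.frame(pair_id = character(0), id_a = character(0),
                    id_b = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    trimmed <- trim_to_overlap(p, seqs_a[[p$id_a]], seqs_b[[p$id_b]])
    if (inherits(trimmed, "pair_discard")) {
      discards <- rbind(discards, data.frame(pair_id = p$pair_id,
                                             reason = attr(trimmed, "reason")))
      next
    }
    aln <- codon_align_pair(trimmed$cds_a, trimmed$cds_b, scoring)
    keep <- filter_min_length(aln, cfg$min_aln_bp)
    if (!keep) {
      discards <- rbind(discards, data.frame(pair_id = p$pair_id,
                                             reason = attr(keep, "reason")))
      next
    }
    alns[[p$pair_id]] <- aln
    ids <- rbind(ids, data.frame(pair_id = p$pair_id, id_a = p$id_a,
                                 id_b = p$id_b, stringsAsFactors = FALSE))
    write_codon_alignment(aln, c(p$id_a, p$id_b),
                          file.path(cfg$out_dir, "alignments",
                                    paste0(gsub("[^A-Za-z0-9_.-]", "_", p$pair_id),
                                           ".fasta")))
  }
  write_tsv(discards, file.path(cfg$out_dir, "discards.tsv"))
  kt <- if (length(alns)) kaks_table(alns, ids) else NULL
  counts <- list(n_seqs_a = length(seqs_a), n_seqs_b = length(seqs_b),
                 n_hits_ab = nrow(hits_ab), n_hits_ba = nrow(hits_ba),
                 pairs_in = nrow(pairs), pairs_kept = length(alns),
                 pairs_discarded_by_reason = as.list(table(discards$reason)),
                 estimates_by_status = if (!is.null(kt)) as.list(table(kt$status)) else list())
  if (is.null(kt)) {
    write_manifest(cfg$out_dir, "kaks", cfg, counts, t0)
    empty_result("no homologue pairs survived the pipeline")
  }
  write_tsv(kt, file.path(cfg$out_dir, "kaks.tsv"))
  sel <- as.data.frame(table(selection_class = kt$selection_class),
                       stringsAsFactors = FALSE)
  write_tsv(sel, file.path(cfg$out_dir, "selection_summary.tsv"))
  manifest <- write_manifest(cfg$out_dir, "kaks", cfg, counts, t0)
  invisible(list(kaks = kt, pairs = pairs, discards = discards,
                 manifest = manifest))
}

#' Run tiered SNP discovery
#'
#' Reads a base-count pileup and its contig FASTA, calls SNPs at the
#' configured tier thresholds, and writes `snp.tsv`, `snp.vcf`, a per-tier
#' `tier_summary.tsv` (SNPs, contigs, transversions, transitions) and a
#' `manifest.json`.
#'
#' @param cfg A `kakspipe_config` with `pileup`, `contigs`, `out_dir` and
#'   optional `snp_*`, `min_flank`, `max_homopolymer` thresholds.
#' @return Invisibly, a list with `calls`, `summary` and `manifest`.
#' @export
run_snp_pipeline <- function(cfg) {
  t0 <- Sys.time()
  if (is.null(cfg$pileup) || is.null(cfg$contigs)) {
    config_error("pileup and contigs are required")
  }
  pileup <- read_input(read_pileup, cfg$pileup, "pileup")
  contigs <- read_input(read_fasta, cfg$contigs, "contigs")
  tiers <- config_tiers(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  calls <- tryCatch(
    call_snps(pileup, contigs, tiers, min_flank = cfg$min_flank,
              max_homopolymer = cfg$max_homopolymer),
    error = function(e) config_error(conditionMessage(e)))
  summary <- summarize_snps(calls, tiers)
  write_tsv(calls, file.path(cfg$out_dir, "snp.tsv"))
  write_snp_vcf(calls, contigs, file.path(cfg$out_dir, "snp.vcf"))
  write_tsv(summary, file.path(cfg$out_dir, "tier_summary.tsv"))
  counts <- list(n_pileup_columns = nrow(pileup), n_contigs = length(contigs),
                 snps_by_tier = stats::setNames(as.list(summary$n_snps),
                                                summary$tier))
  manifest <- write_manifest(cfg$out_dir, "snp", cfg, counts, t0)
  invisible(list(calls = calls, summary = summary, manifest = manifest))
}

#' Run the decoupling statistics stage
#'
#' Joins a Ka/Ks results table to a per-gene expression-bias table (on the
#' focal-species identifier, `gene_id` against `id_a`), writes a descriptive
#' block (group summaries and the Mann-Whitney comparison of the horn-biased
#' stratum against the background, when flags are present) and the general
#' linear model report with per-term partial r-squared.
#'
#' @param cfg A `kakspipe_config` with `kaks_tsv` (as written by
#'   [run_kaks_pipeline()]), `expression_table`, `out_dir`, and optional
#'   `transform_profile` / `zero_ratio`.
#' @return Invisibly, a list with `fit`, `stratified` and `manifest`.
#' @export
run_decoupling_analysis <- function(cfg) {
  t0 <- Sys.time()
  if (is.null(cfg$kaks_tsv) || is.null(cfg$expression_table)) {
    config_error("kaks_tsv and expression_table are required")
  }
  kt <- read_input(function(p) read_tsv_strict(p, c("id_a", "ratio", "aln_len_bp")),
                   cfg$kaks_tsv, "kaks_tsv")
  expr <- read_input(function(p) read_tsv_strict(p, c("gene_id", "overall_expression",
                                                      "sex_bias", "morph_bias",
                                                      "n_tissues", "sequence_length")),
                     cfg$expression_table, "expression_table")
  joined <- merge(expr, kt[, c("id_a", "ratio", "aln_len_bp")],
                  by.x = "gene_id", by.y = "id_a")
  joined$aln_length <- joined$aln_len_bp
  if (nrow(joined) < 20) {
    empty_result("join of Ka/Ks and expression tables has fewer than 20 rows")
  }
  if (all(is.na(joined$ratio))) empty_result("Ka/Ks ratio column is all NA")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  strat <- NULL
  if ("horn_biased" %in% names(expr) && any(as.logical(joined$horn_biased))) {
    strat <- stratified_kaks_compare(
      cbind(joined, id_a = joined$gene_id),
      joined$gene_id[as.logical(joined$horn_biased)])
    desc <- do.call(rbind, lapply(c("horn", "background"), function(g) {
      s <- strat[[g]]
      data.frame(group = g, n = s$n, mean = s$mean, sd = s$sd,
                 median = s$median, q1 = s$q1, q3 = s$q3,
                 n_positive = s$n_positive, frac_positive = s$frac_positive,
                 stringsAsFactors = FALSE)
    }))
    desc$mann_whitney_w <- strat$test$w
    desc$mann_whitney_p <- strat$test$p_two_sided
    write_tsv(desc, file.path(cfg$out_dir, "stratified_summary.tsv"))
  }
  fit <- tryCatch(
    fit_decoupling_glm(joined, transform_profile = cfg$transform_profile,
                       zero_ratio = cfg$zero_ratio),
    error = function(e) empty_result(conditionMessage(e)))
  report <- fit$terms
  report$adjusted_r2 <- fit$adjusted_r2
  report$residual_df <- fit$residual_df
  report$n <- fit$n
  write_tsv(report, file.path(cfg$out_dir, "glm_report.tsv"))
  counts <- list(n_joined = nrow(joined), n_fitted = fit$n,
                 n_excluded = as.list(fit$n_excluded),
                 residual_df = fit$residual_df)
  manifest <- write_manifest(cfg$out_dir, "decoupling", cfg, counts, t0)
  invisible(list(fit = fit, stratified = strat, manifest = manifest))
}
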