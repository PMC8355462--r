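# End-to-end orchestration. Stages communicate only through TSV/FASTA
# files in the output directory, so each stage can be re-run and tested
# independently; every run writes a manifest. The simulate stage produces
# two samples of the same community — a "slurry" preparation (the primary
# sample all curation stages run on) and a "bulk" preparation used by the
# enrichment stage.

pipeline_stages <- function() {
  c("simulate", "qc", "taxonomy", "merge", "enrich", "secretome", "rescue")
}

artifact_path <- function(outdir, name) file.path(outdir, name)

write_manifest <- function(outdir, subcommand, thresholds, seed, paths) {
  manifest <- list(
    subcommand = subcommand,
    thresholds = thresholds,
    seed = seed,
    paths = as.list(paths),
    version = as.character(utils::packageVersion("magcurate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest,
                       artifact_path(outdir, paste0("manifest_", subcommand,
                                                    ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

pipeline_config_defaults <- function() {
  list(split_dominant_into = 5, total_depth_budget = 500,
       per_bin_proteins = 250, secreted_frac = 0.10,
       completeness_target = 99, dup_target = 0.5,
       write_sequences = TRUE)
}

resolve_pipeline_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- pipeline_config_defaults()
  for (k in intersect(names(config), names(cfg))) cfg[[k]] <- config[[k]]
  cfg
}

stage_simulate <- function(outdir, config = NULL, seed = 1L,
                           thresholds = default_thresholds()) {
  cfg <- resolve_pipeline_config(config)
  log_info("simulate: building synthetic community (seed ", seed, ")")
  sl <- generate_community(default_community_specs("slurry"),
                           total_depth_budget = cfg$total_depth_budget,
                           seed = derive_seed(seed, 1))
  bk <- generate_community(default_community_specs("bulk"),
                           total_depth_budget = cfg$total_depth_budget,
                           seed = derive_seed(seed, 2))
  bins <- inject_binning_errors(sl$truth, sl$contigs,
                                split_dominant_into = cfg$split_dominant_into,
                                seed = derive_seed(seed, 3))
  hits <- simulate_hits(sl$truth, sl$contigs, bins,
                        per_bin = cfg$per_bin_proteins,
                        seed = derive_seed(seed, 4))
  markers <- place_markers(sl$truth,
                           completeness_target = cfg$completeness_target,
                           dup_target = cfg$dup_target,
                           seed = derive_seed(seed, 5))
  ann <- simulate_annotations(sl$truth, secreted_frac = cfg$secreted_frac,
                              seed = derive_seed(seed, 6))
  dom_hits <- simulate_domain_hits(sl$truth, ann, bins,
                                   seed = derive_seed(seed, 7))
  catalogs <- unique(do.call(rbind, lapply(sl$truth$specs, function(sp) {
    data.frame(catalog = substr(sp$marker_ids[1], 1, 3),
               marker_id = sp$marker_ids, stringsAsFactors = FALSE)
  })))
  truth_tbl <- data.frame(
    contig_id = sl$contigs$contig_id,
    genome_id = sl$contigs$truth_genome_id, stringsAsFactors = FALSE)
  genomes_tbl <- do.call(rbind, lapply(sl$truth$specs, function(sp) {
    data.frame(genome_id = sp$genome_id,
               lineage = format_lineage(sp$lineage),
               genome_size = sp$genome_size,
               abundance = sp$abundance,
               depth = round(sl$truth$genome_depth[[sp$genome_id]], 3),
               marker_contig = sl$truth$marker_contig[[sp$genome_id]],
               dominant = sp$genome_id == sl$truth$dominant,
               stringsAsFactors = FALSE)
  }))
  paths <- c(
    contigs = write_tsv(sl$contigs, artifact_path(outdir, "contigs.tsv")),
    contigs_bulk = write_tsv(bk$contigs,
                             artifact_path(outdir, "contigs_bulk.tsv")),
    truth_bulk = write_tsv(
      data.frame(contig_id = bk$contigs$contig_id,
                 genome_id = bk$contigs$truth_genome_id,
                 stringsAsFactors = FALSE),
      artifact_path(outdir, "truth_bulk.tsv")),
    genomes_bulk = write_tsv(
      do.call(rbind, lapply(bk$truth$specs, function(sp) {
        data.frame(genome_id = sp$genome_id,
                   lineage = format_lineage(sp$lineage),
                   marker_contig = bk$truth$marker_contig[[sp$genome_id]],
                   dominant = sp$genome_id == bk$truth$dominant,
                   stringsAsFactors = FALSE)
      })), artifact_path(outdir, "genomes_bulk.tsv")),
    bins = write_tsv(bins, artifact_path(outdir, "bins.tsv")),
    hits = write_tsv(hits, artifact_path(outdir, "hits.tsv")),
    markers = write_tsv(markers, artifact_path(outdir, "markers.tsv")),
    annotations = write_tsv(ann, artifact_path(outdir, "annotations.tsv")),
    domain_hits = write_tsv(dom_hits,
                            artifact_path(outdir, "domain_hits.tsv")),
    catalog = write_tsv(catalogs, artifact_path(outdir, "catalog.tsv")),
    truth = write_tsv(truth_tbl, artifact_path(outdir, "truth.tsv")),
    genomes = write_tsv(genomes_tbl, artifact_path(outdir, "genomes.tsv"))
  )
  if (isTRUE(cfg$write_sequences) || identical(cfg$write_sequences, "TRUE")) {
    paths <- c(paths, fasta = write_community_fasta(
      sl$contigs, artifact_path(outdir, "contigs.fasta"),
      seed = derive_seed(seed, 8)))
  }
  write_manifest(outdir, "simulate", thresholds, seed, paths)
  invisible(paths)
}

read_catalogs <- function(outdir) {
  cat_tbl <- read_tsv(artifact_path(outdir, "catalog.tsv"),
                      required = c("catalog", "marker_id"))
  split(cat_tbl$marker_id, cat_tbl$catalog)
}

# Shared by the qc stage and the post-merge re-run.
qc_tables <- function(contigs, bins, markers, catalogs, thresholds) {
  bm <- markers_by_bin(markers, bins)
  qc <- quality_for_bins(bm, catalogs)
  passing <- quality_gate(qc, thresholds)
  qc$passes_gate <- qc$bin_id %in% passing
  summaries <- bin_summaries(contigs, bins)
  list(qc = qc, summaries = summaries, bin_markers = bm)
}

stage_qc <- function(outdir, config = NULL, seed = 1L,
                     thresholds = default_thresholds(),
                     bins_file = "bins.tsv", suffix = "") {
  log_info("qc: estimating bin quality")
  contigs <- read_contig_table(artifact_path(outdir, "contigs.tsv"))
  bins <- read_bin_table(artifact_path(outdir, bins_file))
  markers <- read_tsv(artifact_path(outdir, "markers.tsv"),
                      required = c("contig_id", "marker_id", "copy_count"))
  res <- qc_tables(contigs, bins, markers, read_catalogs(outdir), thresholds)
  paths <- c(
    qc = write_tsv(res$qc, artifact_path(outdir, paste0("qc", suffix, ".tsv"))),
    summaries = write_tsv(res$summaries,
                          artifact_path(outdir,
                                        paste0("summaries", suffix, ".tsv"))),
    gc_coverage = write_tsv(
      gc_coverage_table(merge(contigs, bins, by = "contig_id")),
      artifact_path(outdir, paste0("gc_coverage", suffix, ".tsv")))
  )
  write_manifest(outdir, paste0("qc", suffix), thresholds, seed, paths)
  invisible(paths)
}

stage_taxonomy <- function(outdir, config = NULL, seed = 1L,
                           thresholds = default_thresholds()) {
  log_info("taxonomy: majority-vote LCA per bin")
  hits <- read_hit_table(artifact_path(outdir, "hits.tsv"))
  lca <- assign_all_bins(hits, thresholds = thresholds, seed = seed)
  paths <- c(bin_lca = write_tsv(lca, artifact_path(outdir, "bin_lca.tsv")))
  write_manifest(outdir, "taxonomy", thresholds, seed, paths)
  invisible(paths)
}

stage_merge <- function(outdir, config = NULL, seed = 1L,
                        thresholds = default_thresholds()) {
  log_info("merge: resolving linear-cloud bins")
  contigs <- read_contig_table(artifact_path(outdir, "contigs.tsv"))
  bins <- read_bin_table(artifact_path(outdir, "bins.tsv"))
  qc <- read_tsv(artifact_path(outdir, "qc.tsv"),
                 required = c("bin_id", "completeness", "contamination"))
  summaries <- read_tsv(artifact_path(outdir, "summaries.tsv"))
  lca <- read_tsv(artifact_path(outdir, "bin_lca.tsv"),
                  required = c("bin_id", "lineage"))
  lca$lineage[is.na(lca$lineage)] <- ""
  markers <- read_tsv(artifact_path(outdir, "markers.tsv"))
  catalogs <- read_catalogs(outdir)
  summaries$lineage <- lca$lineage[match(summaries$bin_id, lca$bin_id)]
  summaries$completeness <- qc$completeness[match(summaries$bin_id, qc$bin_id)]
  passing <- qc$bin_id[qc$passes_gate]
  bm <- markers_by_bin(markers, bins)
  res <- merge_pass(summaries, passing, bm, catalogs, bins, thresholds)
  report <- do.call(rbind, c(lapply(res$decisions, function(d) {
    data.frame(anchor = d$group$anchor,
               members = paste(d$group$members, collapse = ","),
               pre_completeness = d$pre_completeness,
               post_completeness = d$post_completeness,
               pre_contamination = d$pre_contamination,
               post_contamination = d$post_contamination,
               accepted = d$accepted, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  if (is.null(report)) {
    report <- data.frame(anchor = character(0), members = character(0),
                         pre_completeness = numeric(0),
                         post_completeness = numeric(0),
                         pre_contamination = numeric(0),
                         post_contamination = numeric(0),
                         accepted = logical(0))
  }
  paths <- c(
    merged_bins = write_tsv(res$bins,
                            artifact_path(outdir, "merged_bins.tsv")),
    merge_report = write_tsv(report,
                             artifact_path(outdir, "merge_report.tsv"))
  )
  write_manifest(outdir, "merge", thresholds, seed, paths)
  invisible(paths)
}

stage_enrich <- function(outdir, config = NULL, seed = 1L,
                         thresholds = default_thresholds()) {
  log_info("enrich: symbiont coverage ratios between samples")
  slurry <- read_contig_table(artifact_path(outdir, "contigs.tsv"))
  bulk <- read_contig_table(artifact_path(outdir, "contigs_bulk.tsv"))
  genomes_sl <- read_tsv(artifact_path(outdir, "genomes.tsv"))
  genomes_bk <- read_tsv(artifact_path(outdir, "genomes_bulk.tsv"))
  truth_sl <- read_tsv(artifact_path(outdir, "truth.tsv"))
  truth_bk <- read_tsv(artifact_path(outdir, "truth_bulk.tsv"))
  shared <- setdiff(intersect(genomes_sl$genome_id, genomes_bk$genome_id),
                    genomes_sl$genome_id[genomes_sl$dominant])
  marker_a <- stats::setNames(
    genomes_bk$marker_contig[match(shared, genomes_bk$genome_id)], shared)
  marker_b <- stats::setNames(
    genomes_sl$marker_contig[match(shared, genomes_sl$genome_id)], shared)
  dom_sl <- genomes_sl$genome_id[genomes_sl$dominant][1L]
  dom_bk <- genomes_bk$genome_id[genomes_bk$dominant][1L]
  dom_contigs_a <- bulk[bulk$contig_id %in%
                          truth_bk$contig_id[truth_bk$genome_id == dom_bk], ]
  dom_contigs_b <- slurry[slurry$contig_id %in%
                            truth_sl$contig_id[truth_sl$genome_id == dom_sl], ]
  # marker contig ids differ between the independently generated samples,
  # so compute per-sample ratios and combine
  rep_a <- enrichment_report(bulk, bulk, marker_a, dom_contigs_a,
                             dom_contigs_a, labels = c("bulk", "bulk"))
  rep_b <- enrichment_report(slurry, slurry, marker_b, dom_contigs_b,
                             dom_contigs_b, labels = c("slurry", "slurry"))
  out <- data.frame(
    symbiont = rep_a$symbiont,
    sample_a = "bulk", ratio_a = rep_a$ratio_a,
    sample_b = "slurry",
    ratio_b = rep_b$ratio_b[match(rep_a$symbiont, rep_b$symbiont)],
    stringsAsFactors = FALSE)
  out$fold_change <- ifelse(
    is.na(out$ratio_a) | is.na(out$ratio_b), NA_real_,
    mapply(fold_enrichment, out$ratio_a, out$ratio_b))
  out$status <- ifelse(is.na(out$fold_change), "missing_marker_contig", "ok")
  paths <- c(enrichment = write_tsv(out,
                                    artifact_path(outdir, "enrichment.tsv")))
  write_manifest(outdir, "enrich", thresholds, seed, paths)
  invisible(paths)
}

stage_secretome <- function(outdir, config = NULL, seed = 1L,
                            thresholds = default_thresholds()) {
  log_info("secretome: three-step cascade and family summaries")
  ann <- read_annotation_table(artifact_path(outdir, "annotations.tsv"))
  calls <- classify_secreted(ann, thresholds)
  fam_to_tsv <- function(m, path) {
    df <- as.data.frame.matrix(if (length(m) == 0L) matrix(0L, 0L, 0L) else m)
    df <- cbind(family = rownames(m), df, stringsAsFactors = FALSE)
    write_tsv(df, path)
  }
  cazy <- family_summary(ann, "CAZy", secreted_only = TRUE, calls = calls)
  merops <- family_summary(ann, "MEROPS", secreted_only = TRUE, calls = calls)
  pct <- secreted_percentage(calls)
  paths <- c(
    calls = write_tsv(calls, artifact_path(outdir, "secretome_calls.tsv")),
    families_cazy = fam_to_tsv(cazy,
                               artifact_path(outdir, "families_cazy.tsv")),
    families_merops = fam_to_tsv(merops,
                                 artifact_path(outdir, "families_merops.tsv")),
    secreted_pct = write_tsv(
      data.frame(mag_id = names(pct), secreted_pct = round(unname(pct), 4),
                 stringsAsFactors = FALSE),
      artifact_path(outdir, "secreted_pct.tsv"))
  )
  write_manifest(outdir, "secretome", thresholds, seed, paths)
  invisible(paths)
}

stage_rescue <- function(outdir, config = NULL, seed = 1L,
                         thresholds = default_thresholds()) {
  log_info("rescue: missing-family check")
  hits <- read_tsv(artifact_path(outdir, "domain_hits.tsv"),
                   required = c("protein_id", "contig_id", "pfam_accession",
                                "evalue", "taxa"))
  bins_file <- artifact_path(outdir, "merged_bins.tsv")
  if (!file.exists(bins_file)) bins_file <- artifact_path(outdir, "bins.tsv")
  bins <- read_bin_table(bins_file)
  mag_contigs <- split(bins$contig_id[!is.na(bins$bin_id)],
                       bins$bin_id[!is.na(bins$bin_id)])
  verdicts <- rescue_families(hits, mag_contigs,
                              cutoff = thresholds$rescue_evalue)
  paths <- c(rescue = write_tsv(verdicts,
                                artifact_path(outdir, "rescue.tsv")))
  write_manifest(outdir, "rescue", thresholds, seed, paths)
  invisible(paths)
}

#' Run the full curation pipeline on a synthetic community
#'
#' Executes simulate, qc, taxonomy, merge (with a post-merge qc re-run),
#' enrich, secretome and rescue in order. Stages communicate only through
#' files in `outdir`; the run is deterministic under `seed` and each stage
#' writes a JSON manifest.
#'
#' @param outdir Output directory (created if needed).
#' @param config Optional path to a `key = value` config file, or a named
#'   list; keys may override thresholds and generator settings
#'   (`split_dominant_into`, `total_depth_budget`, `per_bin_proteins`,
#'   `secreted_frac`, `completeness_target`, `dup_target`,
#'   `write_sequences`).
#' @param seed Integer seed governing all randomness.
#' @return Invisibly, a named list of artifact paths per stage.
#' @export
run_pipeline <- function(outdir, config = NULL, seed = 42L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(config)) config <- read_config(config)
  thresholds <- resolve_thresholds(config)
  res <- list()
  run_stage <- function(name, fun, ...) {
    tryCatch(fun(outdir, config = config, seed = seed,
                 thresholds = thresholds, ...),
             error = function(e) {
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  res$simulate <- run_stage("simulate", stage_simulate)
  res$qc <- run_stage("qc", stage_qc)
  res$taxonomy <- run_stage("taxonomy", stage_taxonomy)
  res$merge <- run_stage("merge", stage_merge)
  res$qc_merged <- run_stage("qc_merged", stage_qc,
                             bins_file = "merged_bins.tsv",
                             suffix = "_merged")
  res$enrich <- run_stage("enrich", stage_enrich)
  res$secretome <- run_stage("secretome", stage_secretome)
  res$rescue <- run_stage("rescue", stage_rescue)
  log_info("pipeline complete: ", outdir)
  invisible(res)
}

#' Command-line entry point
#'
#' Backs the thin `magcurate` Rscript front-end
#' (`inst/scripts/magcurate.R`). Subcommands: `simulate`, `qc`,
#' `taxonomy`, `merge`, `enrich`, `secretome`, `rescue`, `all`; options
#' `--config <file>`, `--seed <int>`, `--outdir <dir>`,
#' `--log-level <DEBUG|INFO|WARN>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
magcurate_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: magcurate <", paste(c(pipeline_stages(), "all"),
                                        collapse = "|"),
            "> --outdir DIR [--config FILE] [--seed INT] [--log-level LVL]")
    return(invisible(1L))
  }
  sub <- args[1L]
  opts <- list(config = NULL, seed = "42", outdir = ".",
               `log-level` = "INFO")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message("unknown or incomplete option: ", args[i])
      return(invisible(1L))
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  old <- options(magcurate.log_level = opts$`log-level`)
  on.exit(options(old))
  seed <- as.integer(opts$seed)
  outdir <- opts$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  status <- tryCatch({
    config <- if (!is.null(opts$config)) read_config(opts$config) else NULL
    thresholds <- resolve_thresholds(config)
    switch(sub,
      all = run_pipeline(outdir, config, seed),
      simulate = stage_simulate(outdir, config, seed, thresholds),
      qc = stage_qc(outdir, config, seed, thresholds),
      taxonomy = stage_taxonomy(outdir, config, seed, thresholds),
      merge = stage_merge(outdir, config, seed, thresholds),
      enrich = stage_enrich(outdir, config, seed, thresholds),
      secretome = stage_secretome(outdir, config, seed, thresholds),
      rescue = stage_rescue(outdir, config, seed, thresholds),
      stop("unknown subcommand: ", sub))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
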