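# Per-bin GC/coverage summaries, marker-based completeness/contamination,
# the retention gate, and per-taxon deduplication.

#' Length-weighted median coverage of a contig set
#'
#' The depth at the 50% point of cumulative contig length when contigs are
#' sorted by depth — i.e. the per-base median under constant within-contig
#' depth. On an even split of length mass the lower of the two straddling
#' depths is returned.
#'
#' @param contigs Contig table with `length` and `mean_depth`.
#' @return Median genome coverage.
#' @export
median_genome_coverage <- function(contigs) {
  if (nrow(contigs) == 0L) stop("cannot take the coverage of zero contigs")
  ord <- order(contigs$mean_depth)
  len <- contigs$length[ord]
  dep <- contigs$mean_depth[ord]
  half <- sum(len) / 2
  dep[which(cumsum(len) >= half)[1]]
}

#' Estimate completeness and contamination from single-copy markers
#'
#' Completeness is the percentage of the expected marker set observed at
#' least once; contamination is the percentage of excess copies (copies
#' beyond the first of each expected marker) relative to the expected set
#' size. Markers outside the expected set are ignored.
#'
#' @param bin_markers Marker observations for one bin (`marker_id`,
#'   `copy_count`); zero rows give (0, 0).
#' @param expected Character vector of expected marker ids (non-empty).
#' @param bin_id Bin label carried into the result.
#' @return One-row data.frame: `bin_id`, `estimator_label` (`"marker_sc"`),
#'   `completeness`, `contamination` (both percent).
#' @export
estimate_quality <- function(bin_markers, expected, bin_id = NA_character_) {
  if (length(expected) == 0L) stop("expected marker set must be non-empty")
  n_exp <- length(unique(expected))
  if (is.null(bin_markers) || nrow(bin_markers) == 0L) {
    obs <- integer(0)
  } else {
    keep <- bin_markers$marker_id %in% expected
    obs <- bin_markers$copy_count[keep]
  }
  completeness <- 100 * length(obs) / n_exp
  contamination <- 100 * sum(pmax(obs - 1L, 0L)) / n_exp
  data.frame(bin_id = bin_id, estimator_label = "marker_sc",
             completeness = completeness, contamination = contamination,
             stringsAsFactors = FALSE)
}

#' Retention gate on bin quality estimates
#'
#' A bin is retained when its completeness exceeds `min_completeness`
#' (strictly) under at least one estimator AND its contamination stays
#' strictly below `max_contamination` under every estimator. The
#' every-estimator contamination rule is deliberately conservative: one lax
#' estimator cannot pass a contaminated bin.
#'
#' @param estimates Quality table (`bin_id`, `estimator_label`,
#'   `completeness`, `contamination`), possibly several estimators per bin.
#' @param thresholds Threshold list ([default_thresholds()]).
#' @return Character vector of retained bin ids (sorted).
#' @export
quality_gate <- function(estimates, thresholds = default_thresholds()) {
  if (nrow(estimates) == 0L) return(character(0))
  if (any(is.na(estimates$completeness)) || any(is.na(estimates$contamination))) {
    stop("quality estimates must be complete")
  }
  by_bin <- split(estimates, estimates$bin_id)
  keep <- vapply(by_bin, function(e) {
    if (nrow(e) == 0L) stop("bin with zero quality estimates")
    max(e$completeness) > thresholds$min_completeness &&
      all(e$contamination < thresholds$max_contamination)
  }, logical(1))
  sort(names(by_bin)[keep])
}

#' Pick one representative bin per taxon
#'
#' Bins sharing an identical lineage at their deepest commonly assigned
#' rank are treated as duplicates of one genome; within each group the bin
#' with the highest best-completeness is kept. Ties break to the larger
#' total length, then to the lexicographically smaller bin id.
#'
#' @param bins data.frame with `bin_id`, `lineage` (string form),
#'   `completeness` (best across estimators) and `total_length`.
#' @return Subset of `bins` holding the representatives, in input order.
#' @export
deduplicate_by_taxon <- function(bins) {
  if (nrow(bins) == 0L) return(bins)
  grp <- dedup_groups(bins$lineage)
  keep <- logical(nrow(bins))
  for (g in unique(grp)) {
    i <- which(grp == g)
    o <- i[order(-bins$completeness[i], -bins$total_length[i], bins$bin_id[i])]
    keep[o[1L]] <- TRUE
  }
  bins[keep, , drop = FALSE]
}

# Group indices such that two bins share a group iff their lineages agree
# at the deepest rank assigned in both (i.e. one is a prefix of the other
# or they are identical); transitively closed by union-find.
dedup_groups <- function(lineages) {
  n <- length(lineages)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  m <- lineage_matrix(lineages)
  d <- matrix_depths(m)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dd <- min(d[i], d[j])
      if (dd > 0L && all(m[i, seq_len(dd)] == m[j, seq_len(dd)])) {
        parent[find(j)] <- find(i)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Per-bin summaries
#'
#' One row per bin: contig count, total length, length-weighted GC,
#' length-weighted median coverage and the bin's GC range. Lineages are
#' joined on afterwards by the taxonomy stage.
#'
#' @param contigs Contig table.
#' @param bins Bin table (`contig_id`, `bin_id`).
#' @return data.frame of bin summaries sorted by bin id.
#' @export
bin_summaries <- function(contigs, bins) {
  m <- merge(contigs, bins, by = "contig_id")
  m <- m[!is.na(m$bin_id), , drop = FALSE]
  parts <- split(m, m$bin_id)
  out <- lapply(parts, function(b) {
    data.frame(bin_id = b$bin_id[1L],
               n_contigs = nrow(b),
               total_length = sum(b$length),
               length_weighted_gc = sum(b$gc * b$length) / sum(b$length),
               median_coverage = median_genome_coverage(b),
               gc_min = min(b$gc), gc_max = max(b$gc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$bin_id), , drop = FALSE]
}

#' GC-coverage plot table
#'
#' One row per contig with raw depth and a log10 depth column for plotting;
#' zero-depth contigs get a missing log value.
#'
#' @param contigs Contig table (optionally carrying `bin_id`).
#' @return data.frame: `contig_id`, `gc`, `mean_depth`, `log10_depth`,
#'   `bin_id`.
#' @export
gc_coverage_table <- function(contigs) {
  data.frame(
    contig_id = contigs$contig_id,
    gc = contigs$gc,
    mean_depth = contigs$mean_depth,
    log10_depth = ifelse(contigs$mean_depth > 0,
                         log10(contigs$mean_depth), NA_real_),
    bin_id = if ("bin_id" %in% names(contigs)) contigs$bin_id
             else NA_character_,
    stringsAsFactors = FALSE)
}

# Quality estimates for every bin in a bin-level marker table, each bin
# scored against the expected catalog giving it the highest completeness
# (stand-in for running several lineage-specific estimators).
quality_for_bins <- function(bin_markers, catalogs) {
  bins <- unique(bin_markers$bin_id)
  out <- lapply(sort(bins), function(b) {
    bm <- bin_markers[bin_markers$bin_id == b, , drop = FALSE]
    ests <- lapply(catalogs, estimate_quality, bin_markers = bm, bin_id = b)
    ests[[which.max(vapply(ests, `[[`, numeric(1), "completeness"))]]
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
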