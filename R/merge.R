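# Linear-cloud detection and merging: same-genome bins betray themselves
# on a GC-coverage plot as a set of bins at near-identical coverage
# spanning a wide GC range. Groups are seeded at quality-gate-passing
# bins; a merge is accepted only when pooling the members' markers
# improves completeness without materially raising contamination.

#' Detect linear-cloud merge groups
#'
#' Each quality-gate-passing bin seeds a candidate group. A bin joins a
#' seed's group when its median coverage deviates from the seed's by at
#' most `cloud_cov_tol` (relative) AND its lineage does not conflict with
#' the seed's at any mutually assigned rank (incomplete bins often
#' classify shallowly, so prefix agreement suffices). A bin eligible for
#' several seeds goes to the one with the smallest coverage deviation;
#' gate-passing bins always anchor their own group. Groups of size one are
#' dropped.
#'
#' @param summaries Bin summaries carrying `bin_id`, `median_coverage`,
#'   `completeness` (best across estimators), `lineage` (string),
#'   `gc_min`, `gc_max`.
#' @param passing Character vector of gate-passing bin ids (the seeds).
#' @param thresholds Threshold list.
#' @return List of `merge_group` lists: `members`, `anchor` (highest
#'   completeness member), `lineage` (the seed's), `coverage_spread`
#'   (max relative deviation from the group median), `gc_range`.
#' @export
detect_linear_cloud <- function(summaries, passing,
                                thresholds = default_thresholds()) {
  seeds <- summaries[summaries$bin_id %in% passing, , drop = FALSE]
  if (nrow(seeds) == 0L) return(list())
  seeds <- seeds[order(-seeds$completeness, seeds$bin_id), , drop = FALSE]
  tol <- thresholds$cloud_cov_tol
  n <- nrow(summaries)
  assigned_seed <- rep(NA_character_, n)
  assigned_dev <- rep(Inf, n)
  for (s in seq_len(nrow(seeds))) {
    scov <- seeds$median_coverage[s]
    slin <- seeds$lineage[s]
    sid <- seeds$bin_id[s]
    for (i in seq_len(n)) {
      b <- summaries[i, ]
      if (b$bin_id %in% passing && b$bin_id != sid) next  # seeds anchor themselves
      dev <- abs(b$median_coverage - scov) / scov
      if (dev > tol) next
      if (!lineage_compatible(slin, b$lineage)) next
      if (dev < assigned_dev[i]) {
        assigned_dev[i] <- dev
        assigned_seed[i] <- sid
      }
    }
  }
  groups <- list()
  for (sid in unique(stats::na.omit(assigned_seed))) {
    members <- summaries[which(assigned_seed == sid), , drop = FALSE]
    if (nrow(members) < 2L) next
    anchor <- members$bin_id[order(-members$completeness, members$bin_id)][1L]
    med <- stats::median(members$median_coverage)
    groups[[length(groups) + 1L]] <- structure(list(
      members = members$bin_id,
      anchor = anchor,
      lineage = summaries$lineage[summaries$bin_id == sid][1L],
      coverage_spread = max(abs(members$median_coverage - med) / med),
      gc_range = c(min(members$gc_min), max(members$gc_max))
    ), class = "merge_group")
  }
  groups
}

#' Evaluate a candidate merge on pooled marker evidence
#'
#' Completeness and contamination are recomputed on the pooled marker
#' multiset of all group members and compared with the anchor bin's own
#' estimates. The merge is accepted iff pooled completeness strictly
#' exceeds the anchor's and the contamination increase stays below
#' `merge_contam_delta` percentage points.
#'
#' @param group A `merge_group` from [detect_linear_cloud()].
#' @param bin_markers Bin-level marker table (`bin_id`, `marker_id`,
#'   `copy_count`); every member must be present.
#' @param expected Expected marker catalog for the group's lineage.
#' @param thresholds Threshold list.
#' @param allow_empty Treat a member bin absent from `bin_markers` as an
#'   empty observation set instead of raising an error. The default errors
#'   because absence usually means the marker scan was not run on that
#'   bin; the pipeline, whose generator scores every bin, opts in (a small
#'   GC-tail bin can genuinely carry zero markers).
#' @return List: `group`, `pre_completeness`, `post_completeness`,
#'   `pre_contamination`, `post_contamination`, `accepted`.
#' @export
evaluate_merge <- function(group, bin_markers, expected,
                           thresholds = default_thresholds(),
                           allow_empty = FALSE) {
  missing <- setdiff(group$members, unique(bin_markers$bin_id))
  if (length(missing) > 0L && !allow_empty) {
    stop("no marker observations for group member(s): ",
         paste(missing, collapse = ", "))
  }
  anchor_m <- bin_markers[bin_markers$bin_id == group$anchor, , drop = FALSE]
  pooled <- bin_markers[bin_markers$bin_id %in% group$members, , drop = FALSE]
  pooled <- stats::aggregate(list(copy_count = pooled$copy_count),
                             pooled["marker_id"], sum)
  pre <- estimate_quality(anchor_m, expected, group$anchor)
  post <- estimate_quality(pooled, expected, paste0(group$anchor, "+merged"))
  accepted <- post$completeness > pre$completeness &&
    (post$contamination - pre$contamination) < thresholds$merge_contam_delta
  list(group = group,
       pre_completeness = pre$completeness,
       post_completeness = post$completeness,
       pre_contamination = pre$contamination,
       post_contamination = post$contamination,
       accepted = accepted)
}

#' Apply accepted merges to a bin table
#'
#' Contigs of each accepted group's members are reassigned to a new bin
#' `"<anchor>+merged"`; all other assignments are untouched. The contig
#' multiset is conserved. Accepted groups must be disjoint.
#'
#' @param bins Bin table (`contig_id`, `bin_id`).
#' @param decisions List of decisions from [evaluate_merge()]; only
#'   accepted ones are applied.
#' @return Updated bin table.
#' @export
apply_merges <- function(bins, decisions) {
  accepted <- Filter(function(d) isTRUE(d$accepted), decisions)
  if (length(accepted) == 0L) return(bins)
  all_members <- unlist(lapply(accepted, function(d) d$group$members))
  if (anyDuplicated(all_members)) {
    stop("accepted merge groups overlap")
  }
  out <- bins
  for (d in accepted) {
    sel <- out$bin_id %in% d$group$members
    out$bin_id[sel] <- paste0(d$group$anchor, "+merged")
  }
  out
}

#' Run the full detect-evaluate-apply merge pass
#'
#' @param summaries Bin summaries with lineages and completeness (see
#'   [detect_linear_cloud()]).
#' @param passing Gate-passing bin ids.
#' @param bin_markers Bin-level marker table.
#' @param catalogs Named list of expected marker catalogs; each group is
#'   evaluated against the catalog giving its anchor the highest
#'   completeness.
#' @param bins Bin table to update.
#' @param thresholds Threshold list.
#' @return List: `bins` (updated), `decisions`.
#' @export
merge_pass <- function(summaries, passing, bin_markers, catalogs, bins,
                       thresholds = default_thresholds()) {
  groups <- detect_linear_cloud(summaries, passing, thresholds)
  decisions <- lapply(groups, function(g) {
    anchor_m <- bin_markers[bin_markers$bin_id == g$anchor, , drop = FALSE]
    comp <- vapply(catalogs, function(cat) {
      estimate_quality(anchor_m, cat, g$anchor)$completeness
    }, numeric(1))
    evaluate_merge(g, bin_markers, catalogs[[which.max(comp)]], thresholds,
                   allow_empty = TRUE)
  })
  list(bins = apply_merges(bins, decisions), decisions = decisions)
}
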