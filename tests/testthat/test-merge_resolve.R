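asco <- "d__Eukaryota;k__Fungi;p__Ascomycota"

mk_summary <- function(bin_id, cov, gc_lo, gc_hi, lineage, comp) {
  data.frame(bin_id = bin_id, median_coverage = cov, gc_min = gc_lo,
             gc_max = gc_hi, lineage = lineage, completeness = comp,
             stringsAsFactors = FALSE)
}

test_that("linear-cloud detection groups same-lineage bins at near-identical coverage", {
  s <- rbind(
    mk_summary("b1", 100, 0.30, 0.36, asco, 91),
    mk_summary("b2", 98, 0.36, 0.42, asco, 10),
    mk_summary("b3", 102, 0.42, 0.48, "d__Eukaryota;k__Fungi", 8),
    mk_summary("b4", 101, 0.48, 0.54, asco, 12),
    mk_summary("b5", 400, 0.50, 0.53, asco, 95),        # coverage far off
    mk_summary("b6", 25, 0.50, 0.55, "d__Eukaryota;k__Fungi;p__Basidiomycota", 97))
  groups <- detect_linear_cloud(s, passing = c("b1", "b5", "b6"))
  expect_length(groups, 1)
  g <- groups[[1]]
  # brute force: exactly the compatible bins within 25% of the seed
  expect_setequal(g$members, c("b1", "b2", "b3", "b4"))
  expect_equal(g$anchor, "b1")
  expect_lte(g$coverage_spread, 0.25)
  expect_equal(g$gc_range, c(0.30, 0.54))

  # lineage conflict blocks grouping even at identical coverage
  s2 <- rbind(mk_summary("x1", 100, 0.3, 0.4, asco, 95),
              mk_summary("x2", 99, 0.4, 0.5,
                         "d__Eukaryota;k__Fungi;p__Basidiomycota", 10))
  expect_length(detect_linear_cloud(s2, passing = "x1"), 0)

  # coverage outside tolerance blocks grouping
  s3 <- rbind(mk_summary("y1", 100, 0.3, 0.4, asco, 95),
              mk_summary("y2", 300, 0.4, 0.5, asco, 10))
  expect_length(detect_linear_cloud(s3, passing = "y1"), 0)

  # a bin eligible for two seeds joins the closer one in coverage
  s4 <- rbind(mk_summary("z1", 100, 0.30, 0.40, asco, 95),
              mk_summary("z2", 120, 0.40, 0.50, asco, 93),
              mk_summary("z3", 118, 0.42, 0.48, "d__Eukaryota;k__Fungi", 5))
  groups <- detect_linear_cloud(s4, passing = c("z1", "z2"))
  in_group <- vapply(groups, function(g) "z3" %in% g$members, logical(1))
  expect_equal(groups[[which(in_group)]]$anchor, "z2")
})

test_that("merge evaluation accepts only completeness gains with bounded contamination", {
  exp_set <- sprintf("M%03d", 1:100)
  g <- structure(list(members = c("a", "b"), anchor = "a",
                      lineage = asco, coverage_spread = 0.01,
                      gc_range = c(0.3, 0.5)), class = "merge_group")
  bm <- rbind(
    data.frame(bin_id = "a", marker_id = exp_set[1:86], copy_count = 1L),
    data.frame(bin_id = "b", marker_id = exp_set[75:98], copy_count = 1L))
  d <- evaluate_merge(g, bm, exp_set)
  expect_equal(d$pre_completeness, 86)
  expect_equal(d$post_completeness, 98)
  # overlap 75:86 becomes duplicate copies -> contamination 12%
  expect_equal(d$post_contamination - d$pre_contamination, 12)
  expect_false(d$accepted)

  bm2 <- rbind(
    data.frame(bin_id = "a", marker_id = exp_set[1:86], copy_count = 1L),
    data.frame(bin_id = "b", marker_id = exp_set[87:98], copy_count = 1L))
  d2 <- evaluate_merge(g, bm2, exp_set)
  expect_true(d2$accepted)
  expect_equal(d2$post_completeness, 98)
  expect_equal(d2$post_contamination, d2$pre_contamination)

  # equal completeness is rejected: strict improvement required
  bm3 <- rbind(
    data.frame(bin_id = "a", marker_id = exp_set[1:86], copy_count = 1L),
    data.frame(bin_id = "b", marker_id = exp_set[10:20], copy_count = 1L))
  d3 <- evaluate_merge(g, bm3, exp_set)
  expect_false(d3$accepted)

  expect_error(evaluate_merge(g, bm3[bm3$bin_id == "a", ], exp_set),
               "member")
})

test_that("applying merges conserves contigs and renames only group members", {
  bins <- data.frame(contig_id = sprintf("c%02d", 1:10),
                     bin_id = rep(c("a", "b", "c", "d", "e"), each = 2),
                     stringsAsFactors = FALSE)
  g <- structure(list(members = c("a", "b", "c"), anchor = "a"),
                 class = "merge_group")
  dec <- list(list(group = g, accepted = TRUE))
  out <- apply_merges(bins, dec)
  expect_setequal(out$contig_id, bins$contig_id)
  expect_equal(sum(out$bin_id == "a+merged"), 6)
  expect_identical(out$bin_id[out$bin_id %in% c("d", "e")],
                   bins$bin_id[bins$bin_id %in% c("d", "e")])

  # no accepted groups -> identity
  expect_identical(apply_merges(bins, list(list(group = g,
                                                accepted = FALSE))), bins)
  # overlapping accepted groups are refused
  g2 <- structure(list(members = c("c", "d"), anchor = "c"),
                  class = "merge_group")
  expect_error(apply_merges(bins, list(list(group = g, accepted = TRUE),
                                       list(group = g2, accepted = TRUE))),
               "overlap")
})

test_that("a split dominant genome is reunified with high contig-level F1", {
  cm <- generate_community(small_specs(), seed = 7)
  bins <- inject_binning_errors(cm$truth, cm$contigs, 5, seed = 7)
  mk <- place_markers(cm$truth, 99, 0.5, seed = 7)
  bm <- markers_by_bin(mk, bins)
  catalogs <- list(EUK = sprintf("EUK%04d", 1:400),
                   BAC = sprintf("BAC%04d", 1:120))
  qc <- magcurate:::quality_for_bins(bm, catalogs)
  passing <- quality_gate(qc)
  hits <- simulate_hits(cm$truth, cm$contigs, bins, per_bin = 100, seed = 7)
  lca <- assign_all_bins(hits, seed = 7)
  summaries <- bin_summaries(cm$contigs, bins)
  summaries$lineage <- lca$lineage[match(summaries$bin_id, lca$bin_id)]
  summaries$completeness <- qc$completeness[match(summaries$bin_id,
                                                  qc$bin_id)]
  res <- merge_pass(summaries, passing, bm, catalogs, bins)

  expect_length(res$decisions, 1)
  d <- res$decisions[[1]]
  expect_true(d$accepted)
  expect_gt(d$post_completeness, d$pre_completeness)
  expect_lt(d$post_contamination - d$pre_contamination, 1)

  merged_id <- paste0(d$group$anchor, "+merged")
  got <- res$bins$contig_id[res$bins$bin_id == merged_id]
  want <- cm$contigs$contig_id[cm$contigs$truth_genome_id == "dom"]
  tp <- length(intersect(got, want))
  f1 <- 2 * tp / (length(got) + length(want))
  expect_gte(f1, 0.95)
  # contig conservation through the merge
  expect_setequal(res$bins$contig_id, bins$contig_id)

  # idempotence: a second pass finds nothing left to merge
  bm2 <- markers_by_bin(mk, res$bins)
  qc2 <- magcurate:::quality_for_bins(bm2, catalogs)
  summaries2 <- bin_summaries(cm$contigs, res$bins)
  summaries2$lineage <- c(stats::setNames(summaries$lineage,
                                          summaries$bin_id),
                          stats::setNames(d$group$lineage, merged_id)
                          )[summaries2$bin_id]
  summaries2$completeness <- qc2$completeness[match(summaries2$bin_id,
                                                    qc2$bin_id)]
  res2 <- merge_pass(summaries2, quality_gate(qc2), bm2, catalogs, res$bins)
  expect_length(Filter(function(x) x$accepted, res2$decisions), 0)
  expect_identical(res2$bins, res$bins)
})
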