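test_that("genome specs enforce their invariants", {
  expect_error(genome_spec("g", lineage("Eukaryota", "Fungi"), 1e6,
                           0.4, 0.02, 1, "M1"), "depth 3")
  expect_error(genome_spec("g", lineage("Eukaryota", "Fungi", "Ascomycota"),
                           1e6, 0.05, 0.02, 1, "M1"), "gc_mean")
  expect_error(generate_community(list()), "at least one")
  expect_error(generate_community(small_specs(), total_depth_budget = -1),
               "positive")
})

test_that("community generation conserves genome size and scales depth with abundance", {
  specs <- small_specs()
  cm <- generate_community(specs, total_depth_budget = 500, seed = 42)
  ctg <- cm$contigs

  # mass conservation within one (max) contig length per genome
  for (sp in specs) {
    tot <- sum(ctg$length[ctg$truth_genome_id == sp$genome_id])
    expect_gte(tot, sp$genome_size)
    expect_lte(tot - sp$genome_size, 2e5)
  }

  # contig lengths live in the truncation window
  expect_true(all(ctg$length >= 1e3 & ctg$length <= 2e5))
  expect_true(all(ctg$gc >= 0.15 & ctg$gc <= 0.75))

  # depth ratio tracks the 100:20:5 abundances
  mean_depth_of <- function(g) {
    sel <- ctg$truth_genome_id == g
    sum(ctg$mean_depth[sel] * ctg$length[sel]) / sum(ctg$length[sel])
  }
  expect_equal(mean_depth_of("dom") / mean_depth_of("sym"), 5,
               tolerance = 0.1)
  expect_equal(mean_depth_of("dom") / mean_depth_of("bac"), 20,
               tolerance = 0.1)

  # extreme two-genome ratio check
  sp2 <- list(
    genome_spec("a", lineage("Eukaryota", "Fungi", "Ascomycota"), 5e5,
                0.45, 0.02, 100, "M1"),
    genome_spec("b", lineage("Eukaryota", "Fungi", "Basidiomycota"), 5e5,
                0.5, 0.02, 1, "M1"))
  cm2 <- generate_community(sp2, total_depth_budget = 300, seed = 42)
  c2 <- cm2$contigs
  r <- with(c2, sum(mean_depth[truth_genome_id == "a"] *
                      length[truth_genome_id == "a"]) /
              sum(length[truth_genome_id == "a"])) /
    with(c2, sum(mean_depth[truth_genome_id == "b"] *
                   length[truth_genome_id == "b"]) /
           sum(length[truth_genome_id == "b"]))
  expect_equal(r, 100, tolerance = 0.1)
})

test_that("generation is byte-deterministic under a fixed seed", {
  a <- generate_community(small_specs(), seed = 9)
  b <- generate_community(small_specs(), seed = 9)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$truth$genome_depth, b$truth$genome_depth)
  c <- generate_community(small_specs(), seed = 10)
  expect_false(identical(a$contigs, c$contigs))
})

test_that("binning errors split the dominant genome into GC strata at constant coverage", {
  cm <- generate_community(small_specs(), seed = 7)
  bins1 <- inject_binning_errors(cm$truth, cm$contigs, 1, seed = 7)
  # k = 1 reproduces the truth partition
  expect_identical(bins1$bin_id, paste0("bin_", cm$contigs$truth_genome_id))

  # equal-mass strata (anchor_frac = 1/k) on the full-size dominant
  # genome: near-identical coverage, pairwise within 10%
  cm_full <- generate_community(default_community_specs("slurry"), seed = 7)
  dom_full <- cm_full$truth$dominant
  bins_eq <- inject_binning_errors(cm_full$truth, cm_full$contigs, 5,
                                   anchor_frac = 0.2, seed = 7)
  m <- merge(bins_eq, cm_full$contigs, by = "contig_id")
  dom_bins <- sort(unique(m$bin_id[m$truth_genome_id == dom_full]))
  expect_length(dom_bins, 5)
  med <- vapply(dom_bins, function(b) {
    median_genome_coverage(m[m$bin_id == b, ])
  }, numeric(1))
  expect_lt((max(med) - min(med)) / min(med), 0.10)

  # GC ranges tile the genome's span: orderable, non-nested coverage of
  # the full range
  rng <- t(vapply(dom_bins, function(b) {
    range(m$gc[m$bin_id == b])
  }, numeric(2)))
  ord <- order(rng[, 1])
  expect_true(all(diff(rng[ord, 1]) > 0))
  dom_gc <- range(m$gc[m$truth_genome_id == dom_full])
  expect_equal(min(rng[, 1]), dom_gc[1])
  expect_equal(max(rng[, 2]), dom_gc[2])

  # default anchored split: one central bin holds ~92% of the genome
  bins <- inject_binning_errors(cm$truth, cm$contigs, 5, seed = 7)
  m2 <- merge(bins, cm$contigs, by = "contig_id")
  dom_m2 <- m2[m2$truth_genome_id == "dom", ]
  share <- tapply(dom_m2$length, dom_m2$bin_id, sum) / sum(dom_m2$length)
  expect_length(share, 5)
  expect_equal(unname(max(share)), 0.92, tolerance = 0.05)

  expect_error(inject_binning_errors(cm$truth, cm$contigs, 10000),
               "more bins")
})

test_that("simulated hits carry the commanded noise level", {
  cm <- generate_community(small_specs(), seed = 11)
  bins <- inject_binning_errors(cm$truth, cm$contigs, 1, seed = 11)
  true_lin <- magcurate:::bin_true_lineage(cm$truth, cm$contigs, bins)

  h0 <- simulate_hits(cm$truth, cm$contigs, bins, per_bin = 50,
                      p_wrong = 0, seed = 11)
  expect_true(all(h0$lineage == true_lin[h0$bin_id]))

  h1 <- simulate_hits(cm$truth, cm$contigs, bins, per_bin = 50,
                      p_wrong = 1, seed = 11)
  expect_true(all(h1$lineage != true_lin[h1$bin_id]))

  h <- simulate_hits(cm$truth, cm$contigs, bins, per_bin = 400,
                     p_wrong = 0.2, seed = 11)
  expect_gte(nrow(h), 3000)
  wrong_frac <- mean(h$lineage != true_lin[h$bin_id])
  expect_lt(abs(wrong_frac - 0.2), 0.03)

  expect_identical(h, simulate_hits(cm$truth, cm$contigs, bins,
                                    per_bin = 400, p_wrong = 0.2,
                                    seed = 11))
})

test_that("marker placement matches its closed-form targets on clean bins", {
  cm <- generate_community(small_specs(), seed = 3)
  bins <- inject_binning_errors(cm$truth, cm$contigs, 1, seed = 3)

  cases <- list(c(100, 0), c(90, 0), c(95, 2))
  for (tc in cases) {
    mk <- place_markers(cm$truth, tc[1], tc[2], seed = 3)
    bm <- markers_by_bin(mk, bins)
    # genome "dom": 400-marker catalog
    q <- estimate_quality(bm[bm$bin_id == "bin_dom", ],
                          sprintf("EUK%04d", 1:400), "bin_dom")
    n_obs <- round(tc[1] / 100 * 400)
    n_dup <- round(tc[2] / 100 * n_obs)
    expect_equal(q$completeness, 100 * n_obs / 400)
    expect_equal(q$contamination, 100 * n_dup / 400)
  }

  # hand-checked case: 400 markers at (95, 2) -> 380 observed,
  # round(7.6) = 8 duplicated -> (95, 2)
  mk <- place_markers(cm$truth, 95, 2, seed = 3)
  bm <- markers_by_bin(mk, bins)
  q <- estimate_quality(bm[bm$bin_id == "bin_dom", ],
                        sprintf("EUK%04d", 1:400), "bin_dom")
  expect_equal(q$completeness, 95)
  expect_equal(q$contamination, 2)
})

test_that("annotation generation plants boundary cases and is deterministic", {
  cm <- generate_community(small_specs(), seed = 5)
  ann <- simulate_annotations(cm$truth, secreted_frac = 0.3, seed = 5)
  expect_identical(ann, simulate_annotations(cm$truth, secreted_frac = 0.3,
                                             seed = 5))
  # deliberate boundary material is present
  expect_true(any(grepl("-60$", ann$tm_segments)))
  expect_true(any(ann$secreted_neighbor_fraction == 0.60))
  expect_true(any(ann$length == 300))
  expect_true(any(ann$length == 299))

  ann0 <- simulate_annotations(cm$truth, secreted_frac = 0, seed = 5)
  expect_false(any(classify_secreted(ann0)$secreted))
})
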