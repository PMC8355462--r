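asco <- "d__Eukaryota;k__Fungi;p__Ascomycota"
basidio <- "d__Eukaryota;k__Fungi;p__Basidiomycota"

mk_hits <- function(lineages, evalues = rep(1e-50, length(lineages))) {
  data.frame(protein_id = "p", bin_id = "b",
             rank_order = seq_along(lineages), lineage = lineages,
             evalue = evalues, bitscore = 100, stringsAsFactors = FALSE)
}

test_that("protein LCA follows the 60% vote down the rank ladder", {
  deep <- paste0(asco, ";c__Lecanoromycetes")
  r <- protein_lca(mk_hits(rep(deep, 3)))
  expect_equal(r$lineage, deep)
  expect_equal(r$depth, 4)

  # 2/3 at phylum (66.7% >= 60%)
  r <- protein_lca(mk_hits(c(asco, asco, basidio)))
  expect_equal(r$lineage, asco)
  # 50/50 phylum split stops at kingdom
  r <- protein_lca(mk_hits(c(asco, basidio)))
  expect_equal(r$lineage, "d__Eukaryota;k__Fungi")
  expect_equal(r$depth, 2)

  # e-value filtering: nothing passes -> unclassified
  r <- protein_lca(mk_hits(rep(asco, 3), evalues = rep(1e-10, 3)))
  expect_false(r$classified)
  expect_equal(r$depth, 0)
  # threshold is strict: exactly 1e-20 fails
  r <- protein_lca(mk_hits(rep(asco, 3), evalues = rep(1e-20, 3)))
  expect_false(r$classified)

  # only the top 3 passing hits vote: 3 asco then 3 basidio -> asco
  r <- protein_lca(mk_hits(c(asco, asco, asco, basidio, basidio, basidio)))
  expect_equal(r$lineage, asco)

  expect_error(protein_lca(mk_hits(c(asco, basidio))[2:1, ]), "sorted")
})

test_that("bin LCA votes over classified proteins and honors the boundary convention", {
  lcas <- c(rep(asco, 7), rep(basidio, 3))
  r <- bin_lca(lcas)
  expect_equal(r$lineage, asco)
  expect_equal(r$support, 0.7)

  # exact 60% passes under the default weak inequality
  r <- bin_lca(c(rep(asco, 6), rep(basidio, 4)))
  expect_equal(r$lineage, asco)
  expect_equal(r$support, 0.6)
  # and fails under the strict option
  th <- default_thresholds(); th$vote_strict <- TRUE
  r <- bin_lca(c(rep(asco, 6), rep(basidio, 4)), th)
  expect_equal(r$lineage, "d__Eukaryota;k__Fungi")

  # unclassified proteins excluded by default ...
  r <- bin_lca(c(rep(asco, 3), rep("", 7)))
  expect_equal(r$lineage, asco)
  expect_equal(r$n_proteins_used, 3)
  # ... but counted in the denominator when configured
  th <- default_thresholds(); th$count_unclassified <- TRUE
  r <- bin_lca(c(rep(asco, 3), rep("", 7)), th)
  expect_equal(r$status, "unassignable")

  r <- bin_lca(rep("", 5))
  expect_equal(r$status, "unassignable")
})

test_that("streaming vote equals exhaustive enumeration on random cases", {
  set.seed(202)
  th <- default_thresholds()
  for (rep in 1:300) {
    n <- sample(1:10, 1)
    lins <- vapply(seq_len(n), function(i) random_lineage(), character(1))
    ev <- 10^stats::runif(n, -60, -10)
    hits <- mk_hits(lins, ev)
    got <- protein_lca(hits, th)
    want <- oracle_protein_lca(hits)
    expect_equal(got$lineage, want$lineage)
    expect_equal(got$depth, want$depth)

    got_bin <- bin_lca(lins, th)
    want_bin <- oracle_vote(lins)
    expect_equal(got_bin$lineage, want_bin$lineage)
    expect_equal(got_bin$depth, want_bin$depth)
    if (want_bin$depth > 0) {
      expect_gte(got_bin$support, th$vote_frac)
      expect_equal(got_bin$support, want_bin$support)
    }
    # assigned lineages always satisfy the no-gap invariant
    expect_silent(parse_lineage(got$lineage))
  }
})

test_that("extending support never decreases assigned depth", {
  set.seed(203)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    lins <- vapply(seq_len(n), function(i) random_lineage(), character(1))
    base <- bin_lca(lins)
    if (base$depth == 0 || base$depth >= 8) next
    # append a voter carrying a strict extension of the current LCA
    ext <- paste0(base$lineage, ";",
                  magcurate:::.rank_prefixes[base$depth + 1], "Extension")
    more <- bin_lca(c(lins, ext))
    expect_gte(more$depth, base$depth)
  }
})

test_that("subsampling caps, preserves order below the cap, and is seeded", {
  ids <- sprintf("p%04d", 1:150)
  expect_identical(subsample_proteins(ids, cap = 200, seed = 1), ids)
  big <- sprintf("p%04d", 1:1000)
  s1 <- subsample_proteins(big, cap = 200, seed = 5)
  expect_length(unique(s1), 200)
  expect_identical(s1, subsample_proteins(big, cap = 200, seed = 5))
  expect_false(identical(s1, subsample_proteins(big, cap = 200, seed = 6)))
})

test_that("whole-bin assignment recovers the community taxonomy", {
  cm <- generate_community(small_specs(), seed = 5)
  bins <- inject_binning_errors(cm$truth, cm$contigs, 1, seed = 5)
  true_lin <- magcurate:::bin_true_lineage(cm$truth, cm$contigs, bins)

  # noise-free hits give exact recovery
  h0 <- simulate_hits(cm$truth, cm$contigs, bins, per_bin = 40,
                      p_wrong = 0, evalue_fail_frac = 0, seed = 5)
  lca0 <- assign_all_bins(h0, seed = 5)
  expect_identical(stats::setNames(lca0$lineage, lca0$bin_id),
                   true_lin[lca0$bin_id])

  # 20% wrong hits still recover every bin at phylum
  h <- simulate_hits(cm$truth, cm$contigs, bins, per_bin = 200,
                     p_wrong = 0.2, seed = 5)
  lca <- assign_all_bins(h, seed = 5)
  for (i in seq_len(nrow(lca))) {
    got <- as.character(parse_lineage(lca$lineage[i]))[3]
    want <- as.character(parse_lineage(true_lin[[lca$bin_id[i]]]))[3]
    expect_equal(got, want)
  }
  # deterministic under the seed
  expect_identical(lca, assign_all_bins(h, seed = 5))

  # a bin with zero proteins is unassignable, not an error
  lcaz <- assign_all_bins(h, bin_ids = c("bin_dom", "ghost_bin"), seed = 5)
  expect_equal(lcaz$status[lcaz$bin_id == "ghost_bin"], "unassignable")
})
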