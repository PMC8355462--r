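# Two-level majority-vote LCA taxonomy: per protein over ranked homology
# hits, then per bin over protein LCAs, with a seeded subsample cap per
# bin. The vote at each rank needs a fraction of at least `vote_frac`
# (default 0.60, weak inequality); the walk down the rank ladder stops at
# the first rank where no taxon reaches it, which guarantees gap-free
# lineages.

#' Subsample protein ids for a bin
#'
#' Returns all ids (original order) when at or below the cap, otherwise a
#' seeded uniform sample without replacement of exactly `cap` ids.
#'
#' @param protein_ids Character vector.
#' @param cap Maximum number to keep (default 200).
#' @param seed Integer seed.
#' @return Character vector of kept ids.
#' @export
subsample_proteins <- function(protein_ids, cap = 200L, seed = 1L) {
  stopifnot(cap >= 1L)
  if (length(protein_ids) <= cap) return(protein_ids)
  with_seed(seed, protein_ids[sort(sample.int(length(protein_ids), cap))])
}

# Core vote: given an n x 8 lineage matrix, walk ranks shallow -> deep and
# keep the taxon reaching the vote fraction at each rank; stop at the first
# rank without one. Denominator = all n voters (rows with an empty name at
# a rank support no taxon there). Returns list(lineage chr8, support).
vote_walk <- function(m, vote_frac, strict = FALSE) {
  n <- nrow(m)
  out <- rep("", 8L)
  support <- NA_real_
  if (n == 0L) return(list(lineage = out, support = support))
  for (r in seq_len(8L)) {
    names_r <- m[, r]
    names_r <- names_r[nzchar(names_r)]
    if (length(names_r) == 0L) break
    tab <- table(names_r)
    frac <- max(tab) / n
    ok <- if (strict) frac > vote_frac else frac >= vote_frac
    # two taxa can tie below the threshold; at or above it the winner is
    # unique whenever vote_frac > 0.5
    if (!ok) break
    winner <- names(tab)[which.max(tab)]
    out[r] <- winner
    support <- frac
  }
  list(lineage = out, support = support)
}

#' Per-protein LCA by majority vote over ranked hits
#'
#' Hits are taken in rank order, filtered to those with e-value strictly
#' below `evalue_lca`, and truncated to the best `top_hits` (default 3).
#' Walking the rank ladder from domain downwards, each rank is assigned the
#' taxon supported by at least `vote_frac` of the passing hits; the walk
#' stops at the first rank without such a taxon. With no passing hits the
#' protein is unclassified (depth-0 lineage).
#'
#' @param hits data.frame of one protein's hits (`rank_order`, `lineage`,
#'   `evalue`), sorted by `rank_order`.
#' @param thresholds Threshold list.
#' @return List: `lineage` (string), `depth`, `n_hits_used`, `classified`.
#' @export
protein_lca <- function(hits, thresholds = default_thresholds()) {
  if (nrow(hits) > 1L && is.unsorted(hits$rank_order)) {
    stop("hits must be sorted by rank_order")
  }
  pass <- hits[hits$evalue < thresholds$evalue_lca, , drop = FALSE]
  if (nrow(pass) > thresholds$top_hits) {
    pass <- pass[seq_len(thresholds$top_hits), , drop = FALSE]
  }
  if (nrow(pass) == 0L) {
    return(list(lineage = "", depth = 0L, n_hits_used = 0L,
                classified = FALSE))
  }
  v <- vote_walk(lineage_matrix(pass$lineage), thresholds$vote_frac,
                 thresholds$vote_strict)
  depth <- sum(cumprod(nzchar(v$lineage)))
  list(lineage = format_lineage(v$lineage), depth = as.integer(depth),
       n_hits_used = nrow(pass), classified = depth > 0L)
}

#' Per-bin LCA by majority vote over protein LCAs
#'
#' The same rank-by-rank vote applied to the sampled proteins' LCA
#' lineages. By default unclassified proteins (depth 0) are excluded from
#' both numerator and denominator; set `count_unclassified` in the
#' thresholds to keep them in the denominator instead.
#'
#' @param protein_lineages Character vector of protein LCA lineage strings
#'   (`""` = unclassified).
#' @param thresholds Threshold list.
#' @return List: `lineage` (string), `depth`, `n_proteins_used`,
#'   `support`, `status` (`"assigned"` or `"unassignable"`).
#' @export
bin_lca <- function(protein_lineages, thresholds = default_thresholds()) {
  classified <- nzchar(protein_lineages) & !is.na(protein_lineages)
  voters <- protein_lineages[classified]
  if (length(voters) == 0L) {
    return(list(lineage = "", depth = 0L, n_proteins_used = 0L,
                support = NA_real_, status = "unassignable"))
  }
  m <- lineage_matrix(voters)
  if (thresholds$count_unclassified) {
    # pad the denominator with empty rows for unclassified proteins
    pad <- matrix("", nrow = sum(!classified), ncol = 8L)
    m <- rbind(m, pad)
  }
  v <- vote_walk(m, thresholds$vote_frac, thresholds$vote_strict)
  depth <- sum(cumprod(nzchar(v$lineage)))
  list(lineage = format_lineage(v$lineage), depth = as.integer(depth),
       n_proteins_used = length(voters),
       support = v$support,
       status = if (depth > 0L) "assigned" else "unassignable")
}

#' Assign an LCA to every bin
#'
#' Full pipeline per bin: subsample its proteins to
#' `max_proteins_per_bin`, compute each protein's LCA from its ranked
#' hits, then the bin LCA from the protein LCAs. Deterministic under
#' `seed`; a bin with zero proteins yields an `"unassignable"` row rather
#' than an error.
#'
#' @param hits Hit table (`protein_id`, `bin_id`, `rank_order`, `lineage`,
#'   `evalue`).
#' @param bin_ids Bins to assign; defaults to all bins in the hit table.
#' @param thresholds Threshold list.
#' @param seed Integer seed for the subsampling.
#' @return data.frame: `bin_id`, `lineage`, `depth`, `n_proteins_used`,
#'   `support`, `status`.
#' @export
assign_all_bins <- function(hits, bin_ids = NULL,
                            thresholds = default_thresholds(), seed = 1L) {
  if (is.null(bin_ids)) bin_ids <- sort(unique(hits$bin_id))
  out <- lapply(seq_along(bin_ids), function(i) {
    b <- bin_ids[i]
    h <- hits[hits$bin_id == b, , drop = FALSE]
    prot <- unique(h$protein_id)
    prot <- subsample_proteins(prot, thresholds$max_proteins_per_bin,
                               seed = derive_seed(seed, i))
    lcas <- vapply(prot, function(p) {
      ph <- h[h$protein_id == p, , drop = FALSE]
      ph <- ph[order(ph$rank_order), , drop = FALSE]
      protein_lca(ph, thresholds)$lineage
    }, character(1))
    bl <- bin_lca(unname(lcas), thresholds)
    data.frame(bin_id = b, lineage = bl$lineage, depth = bl$depth,
               n_proteins_used = bl$n_proteins_used,
               support = bl$support, status = bl$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
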