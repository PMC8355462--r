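# Shared fixtures and independent oracles. The oracles deliberately take a
# different route than the implementation: votes by exhaustive enumeration
# over all (rank, taxon) pairs, medians by expanding to per-base vectors.

options(magcurate.log_level = "WARN")

withr_local_tempfile <- function(fileext = "") tempfile(fileext = fileext)

# small taxonomy pool for random lineage draws
taxonomy_pool <- function() {
  c("d__Eukaryota;k__Fungi;p__Ascomycota;c__Lecanoromycetes;o__Lecanorales;f__Parmeliaceae;g__Alectoria;s__Alectoria sarmentosa",
    "d__Eukaryota;k__Fungi;p__Ascomycota;c__Eurotiomycetes;o__Eurotiales;f__Aspergillaceae;g__Aspergillus",
    "d__Eukaryota;k__Fungi;p__Basidiomycota;c__Cystobasidiomycetes;o__Cyphobasidiales;f__Cyphobasidiaceae;g__Cyphobasidium",
    "d__Eukaryota;k__Fungi;p__Basidiomycota;c__Tremellomycetes;o__Tremellales;f__Tremellaceae;g__Tremella",
    "d__Eukaryota;k__Viridiplantae;p__Chlorophyta;c__Trebouxiophyceae",
    "d__Bacteria;k__Bacteria;p__Proteobacteria;c__Alphaproteobacteria",
    "d__Bacteria;k__Bacteria;p__Acidobacteria")
}

# random lineage: a pool entry truncated to a random depth >= 1
random_lineage <- function(pool = taxonomy_pool()) {
  full <- sample(pool, 1L)
  parts <- strsplit(full, ";", fixed = TRUE)[[1]]
  d <- sample.int(length(parts), 1L)
  paste(parts[seq_len(d)], collapse = ";")
}

# ORACLE: majority vote by exhaustive enumeration over all (rank, taxon)
# pairs. Support of (r, t) = fraction of the n voters naming t at rank r;
# the assigned depth is the largest d such that every rank <= d has a
# taxon with support >= frac; the lineage takes the best-supported taxon
# at each such rank.
oracle_vote <- function(lineage_strings, frac = 0.60) {
  n <- length(lineage_strings)
  ranks <- lineage_ranks()
  mats <- lapply(lineage_strings, function(s) as.character(parse_lineage(s)))
  out <- character(0)
  support <- NA_real_
  for (r in seq_along(ranks)) {
    names_r <- vapply(mats, `[[`, character(1), r)
    names_r <- names_r[nzchar(names_r)]
    pairs <- unique(names_r)
    sup <- vapply(pairs, function(t) sum(names_r == t) / n, numeric(1))
    winners <- pairs[sup >= frac]
    if (length(winners) == 0L) break
    best <- winners[which.max(sup[match(winners, pairs)])]
    out <- c(out, best)
    support <- max(sup)
  }
  list(lineage = if (length(out)) paste0(
         magcurate:::.rank_prefixes[seq_along(out)], out, collapse = ";")
       else "",
       depth = length(out), support = support)
}

# ORACLE: protein LCA = e-value filter in rank order, truncate to top 3,
# then the enumeration vote.
oracle_protein_lca <- function(hits, frac = 0.60, evalue_max = 1e-20,
                               top = 3L) {
  pass <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (nrow(pass) > top) pass <- pass[seq_len(top), , drop = FALSE]
  if (nrow(pass) == 0L) return(list(lineage = "", depth = 0L))
  oracle_vote(pass$lineage, frac)
}

# ORACLE: length-weighted median by expansion to a per-base depth vector
# (lower value on even-mass ties).
oracle_lw_median <- function(len, dep) {
  v <- sort(rep(dep, times = len))
  v[ceiling(length(v) / 2)]
}

# tiny deterministic contig table
toy_contigs <- function() {
  data.frame(
    contig_id = c("c1", "c2", "c3", "c4"),
    length = c(100, 300, 200, 400),
    gc = c(0.38, 0.42, 0.51, 0.55),
    mean_depth = c(10, 30, 20, 30),
    stringsAsFactors = FALSE)
}

# small community used across module tests (kept light: ~1.3 Mb total)
small_specs <- function() {
  list(
    genome_spec("dom",
                lineage("Eukaryota", "Fungi", "Ascomycota",
                        "Lecanoromycetes"),
                genome_size = 8e5, gc_mean = 0.425, gc_sd = 0.0417,
                abundance = 100, marker_ids = sprintf("EUK%04d", 1:400)),
    genome_spec("sym",
                lineage("Eukaryota", "Fungi", "Basidiomycota",
                        "Tremellomycetes"),
                genome_size = 3e5, gc_mean = 0.52, gc_sd = 0.015,
                abundance = 20, marker_ids = sprintf("EUK%04d", 1:400)),
    genome_spec("bac",
                lineage("Bacteria", "Bacteria", "Proteobacteria"),
                genome_size = 2e5, gc_mean = 0.63, gc_sd = 0.01,
                abundance = 5, marker_ids = sprintf("BAC%04d", 1:120)))
}
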