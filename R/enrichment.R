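# Symbiont enrichment between preparation protocols, measured as the
# ratio of a symbiont marker contig's coverage to the dominant genome's
# median coverage within each sample, and the fold change of that ratio
# between samples.

#' Coverage ratio of a marker contig to the dominant genome
#'
#' @param marker_contig_depth Mean depth of the symbiont's marker (e.g.
#'   rDNA ITS) contig.
#' @param dominant_median_depth Length-weighted median depth of the
#'   dominant genome.
#' @return `marker_contig_depth / dominant_median_depth`.
#' @examples
#' coverage_ratio(1, 336)   # symbiont 336 times lower than the host
#' @export
coverage_ratio <- function(marker_contig_depth, dominant_median_depth) {
  if (dominant_median_depth <= 0) stop("dominant depth must be positive")
  if (marker_contig_depth <= 0) stop("marker contig depth must be positive")
  marker_contig_depth / dominant_median_depth
}

#' Fold enrichment between two coverage ratios
#'
#' @param ratio_a Coverage ratio in the reference sample.
#' @param ratio_b Coverage ratio in the comparison sample.
#' @return `ratio_b / ratio_a`; satisfies
#'   `fold_enrichment(a, b) * fold_enrichment(b, a) == 1`.
#' @examples
#' fold_enrichment(coverage_ratio(1, 336), coverage_ratio(1, 4))  # 84
#' @export
fold_enrichment <- function(ratio_a, ratio_b) {
  if (ratio_a <= 0 || ratio_b <= 0) stop("ratios must be positive")
  ratio_b / ratio_a
}

#' Per-symbiont enrichment report across two samples
#'
#' For each symbiont's marker contig, computes its coverage ratio to the
#' dominant genome in each sample and the fold change between them. Folds
#' are reported at full precision; rounding is presentation-layer only. A
#' marker contig absent from a sample flags the row as missing instead of
#' raising an error.
#'
#' @param contigs_a,contigs_b Contig tables of the two samples.
#' @param marker_contigs Named character vector: symbiont label ->
#'   marker contig id (ids may differ per sample if given as a two-column
#'   data.frame `symbiont`, `contig_id` shared by both samples).
#' @param dominant_contigs_a,dominant_contigs_b Contig tables (subsets) of
#'   the dominant genome's bin in each sample, used for its median depth.
#' @param labels Length-2 sample labels.
#' @return data.frame: `symbiont`, `sample_a`, `ratio_a`, `sample_b`,
#'   `ratio_b`, `fold_change`, `status`.
#' @export
enrichment_report <- function(contigs_a, contigs_b, marker_contigs,
                              dominant_contigs_a, dominant_contigs_b,
                              labels = c("sample_a", "sample_b")) {
  dom_a <- median_genome_coverage(dominant_contigs_a)
  dom_b <- median_genome_coverage(dominant_contigs_b)
  depth_of <- function(contigs, id) {
    d <- contigs$mean_depth[contigs$contig_id == id]
    if (length(d) == 0L) NA_real_ else d[1L]
  }
  out <- lapply(names(marker_contigs), function(sym) {
    id <- marker_contigs[[sym]]
    da <- depth_of(contigs_a, id)
    db <- depth_of(contigs_b, id)
    if (is.na(da) || is.na(db)) {
      return(data.frame(symbiont = sym, sample_a = labels[1],
                        ratio_a = NA_real_, sample_b = labels[2],
                        ratio_b = NA_real_, fold_change = NA_real_,
                        status = "missing_marker_contig",
                        stringsAsFactors = FALSE))
    }
    ra <- coverage_ratio(da, dom_a)
    rb <- coverage_ratio(db, dom_b)
    data.frame(symbiont = sym, sample_a = labels[1], ratio_a = ra,
               sample_b = labels[2], ratio_b = rb,
               fold_change = fold_enrichment(ra, rb), status = "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
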