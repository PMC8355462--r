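# The three-step secretome cascade. A protein is called secreted when it
# (1) carries a predicted secretion signal, (2) has no transmembrane
# segment — except that a single segment lying entirely within the
# N-terminal window is excused, since the signal peptide itself is often
# predicted as a TM helix — and (3) has strictly more than 60% of its
# localization nearest neighbors annotated as secreted. Small secreted
# proteins (SSPs) are secreted proteins strictly shorter than 300 aa.

#' Classify proteins through the secretion cascade
#'
#' Vectorized over the rows of an annotation table. Step 2 passes when
#' there are no TM segments, or exactly one whose end coordinate is at or
#' before `tm_nterm_window` (default 60). Step 3 uses a strict `>` on
#' `neighbor_frac`: a fraction of exactly 0.60 fails.
#'
#' @param annotations Annotation table ([read_annotation_table()] layout).
#' @param thresholds Threshold list.
#' @return data.frame: `protein_id`, `mag_id`, `length`, `step1_signal`,
#'   `step2_topology`, `step3_localization`, `secreted`, `is_ssp`.
#' @export
classify_secreted <- function(annotations,
                              thresholds = default_thresholds()) {
  n <- nrow(annotations)
  step2 <- logical(n)
  for (i in seq_len(n)) {
    seg <- parse_tm_segments(annotations$tm_segments[i],
                             annotations$length[i])
    step2[i] <- nrow(seg) == 0L ||
      (nrow(seg) == 1L && seg[1L, "end"] <= thresholds$tm_nterm_window)
  }
  step1 <- as.logical(annotations$has_signal)
  step3 <- annotations$secreted_neighbor_fraction > thresholds$neighbor_frac
  secreted <- step1 & step2 & step3
  data.frame(protein_id = annotations$protein_id,
             mag_id = annotations$mag_id,
             length = annotations$length,
             step1_signal = step1,
             step2_topology = step2,
             step3_localization = step3,
             secreted = secreted,
             is_ssp = secreted & annotations$length < thresholds$ssp_max_len,
             stringsAsFactors = FALSE)
}

#' Call a small secreted protein
#'
#' @param secreted Logical: did the protein pass the full cascade?
#' @param length Protein length in amino acids (>= 1).
#' @param thresholds Threshold list.
#' @return `TRUE` iff secreted and strictly shorter than `ssp_max_len`.
#' @export
call_ssp <- function(secreted, length, thresholds = default_thresholds()) {
  stopifnot(all(length >= 1))
  secreted & length < thresholds$ssp_max_len
}

#' Family count matrix across MAGs
#'
#' Counts proteins per family per MAG within one label namespace. CAZy
#' subfamily labels (`GH5_7`) are collapsed to the family (`GH5`) before
#' counting. Optionally restricted to proteins called secreted.
#'
#' @param annotations Annotation table.
#' @param namespace One of `"CAZy"`, `"MEROPS"`, `"PFAM"`.
#' @param secreted_only Restrict to secreted proteins.
#' @param calls Secretion calls from [classify_secreted()]; required when
#'   `secreted_only`.
#' @return Integer matrix (families x MAGs); 0 x 0 when no labels match.
#' @export
family_summary <- function(annotations, namespace = c("CAZy", "MEROPS", "PFAM"),
                           secreted_only = FALSE, calls = NULL) {
  namespace <- match.arg(namespace)
  df <- annotations
  if (secreted_only) {
    if (is.null(calls)) stop("secreted_only requires secretion calls")
    sec_ids <- calls$protein_id[calls$secreted]
    df <- df[df$protein_id %in% sec_ids, , drop = FALSE]
  }
  prefix <- paste0(namespace, ":")
  rows <- list()
  for (i in seq_len(nrow(df))) {
    labs <- df$family_labels[i]
    if (is.na(labs) || labs == "" || labs == ".") next
    labs <- strsplit(labs, ",", fixed = TRUE)[[1]]
    labs <- labs[startsWith(labs, prefix)]
    if (length(labs) == 0L) next
    fam <- substring(labs, nchar(prefix) + 1L)
    if (namespace == "CAZy") fam <- sub("_.*$", "", fam)
    rows[[length(rows) + 1L]] <- data.frame(family = fam,
                                            mag_id = df$mag_id[i],
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(matrix(integer(0), 0L, 0L))
  }
  long <- do.call(rbind, rows)
  tab <- table(long$family, long$mag_id)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Secreted-protein percentage per MAG
#'
#' Share of each MAG's proteins called secreted, with all predicted
#' proteins of the MAG as the denominator.
#'
#' @param calls Secretion calls from [classify_secreted()].
#' @return Named numeric vector of percentages.
#' @export
secreted_percentage <- function(calls) {
  p <- tapply(calls$secreted, calls$mag_id, mean)
  stats::setNames(100 * as.numeric(p), names(p))
}
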