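# On-disk interchange: tab-delimited tables with a header row, UTF-8, "."
# for missing values; FASTA for sequences. All readers validate against the
# domain-type invariants and preserve input row order.

#' Read a tab-delimited table
#'
#' Package-wide TSV dialect: tab separator, header row, UTF-8, `"."` read
#' as missing. Rows come back in file order.
#'
#' @param path Path to a TSV file.
#' @param required Character vector of column names that must be present.
#' @return A data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = ".", quote = "",
                          stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop("'", path, "' lacks required column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

#' Write a tab-delimited table
#'
#' Counterpart of [read_tsv()]: missing values are written as `"."`, no
#' quoting, no row names.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-contig table
#'
#' Columns: `contig_id`, `length` (bp), `gc` (fraction), `mean_depth`
#' (read coverage), optional `bin_id` (missing = unbinned) and
#' `truth_genome_id` (synthetic data only). Each row is validated; a bad
#' row is reported with its line number (header = line 1).
#'
#' @param path Path to the contig TSV.
#' @return data.frame of validated contig records in file order.
#' @export
read_contig_table <- function(path) {
  df <- read_tsv(path, required = c("contig_id", "length", "gc",
                                    "mean_depth"))
  if (nrow(df) == 0L) return(df)
  df$length <- as.numeric(df$length)
  df$gc <- as.numeric(df$gc)
  df$mean_depth <- as.numeric(df$mean_depth)
  bad <- which(is.na(df$contig_id) | !nzchar(df$contig_id) |
                 is.na(df$length) | df$length < 1 |
                 is.na(df$gc) | df$gc < 0 | df$gc > 1 |
                 is.na(df$mean_depth) | df$mean_depth < 0)
  if (length(bad) > 0L) {
    stop("'", path, "' line ", bad[1] + 1L,
         ": invalid contig record (need length >= 1, gc in [0,1], ",
         "mean_depth >= 0)")
  }
  if (anyDuplicated(df$contig_id)) {
    stop("'", path, "': duplicated contig_id '",
         df$contig_id[anyDuplicated(df$contig_id)], "'")
  }
  df
}

#' Read a contig-to-bin assignment table
#'
#' Columns `contig_id`, `bin_id`; a missing `bin_id` marks an unbinned
#' contig.
#'
#' @param path Path to the bin TSV.
#' @return data.frame with `contig_id`, `bin_id`.
#' @export
read_bin_table <- function(path) {
  df <- read_tsv(path, required = c("contig_id", "bin_id"))
  if (anyDuplicated(df$contig_id)) {
    stop("'", path, "': a contig is assigned to more than one bin")
  }
  df
}

#' Read a protein homology-hit table
#'
#' Columns: `protein_id`, `bin_id`, `rank_order` (1 = best hit),
#' `lineage` (string form, see [parse_lineage()]), `evalue`, `bitscore`.
#' Per protein, rank orders must start at 1 and be gap-free.
#'
#' @param path Path to the hit TSV.
#' @return data.frame of hits in file order.
#' @export
read_hit_table <- function(path) {
  df <- read_tsv(path, required = c("protein_id", "bin_id", "rank_order",
                                    "lineage", "evalue"))
  df$rank_order <- as.integer(df$rank_order)
  df$evalue <- as.numeric(df$evalue)
  if (nrow(df) > 0L) {
    if (any(df$evalue <= 0, na.rm = TRUE)) {
      stop("'", path, "': e-values must be positive")
    }
    ok <- tapply(df$rank_order, df$protein_id, function(r) {
      identical(sort(r), seq_along(r))
    })
    if (!all(ok)) {
      stop("'", path, "': protein '", names(ok)[!ok][1],
           "' has gapped or duplicated rank_order")
    }
  }
  if (is.null(df$lineage)) df$lineage <- character(0)
  df$lineage[is.na(df$lineage)] <- ""
  df
}

#' Read a marker observation table
#'
#' Bin-level single-copy marker evidence: `bin_id`, `marker_id`,
#' `copy_count` (>= 1), one row per (bin, marker).
#'
#' @param path Path to the marker TSV.
#' @return data.frame of marker observations.
#' @export
read_marker_table <- function(path) {
  df <- read_tsv(path, required = c("bin_id", "marker_id", "copy_count"))
  df$copy_count <- as.integer(df$copy_count)
  if (nrow(df) > 0L) {
    if (any(df$copy_count < 1L, na.rm = TRUE)) {
      stop("'", path, "': copy_count must be >= 1")
    }
    if (anyDuplicated(df[c("bin_id", "marker_id")])) {
      stop("'", path, "': duplicated (bin_id, marker_id) pair")
    }
  }
  df
}

#' Read a protein annotation table
#'
#' Secretion-relevant features per protein: `protein_id`, `mag_id`,
#' `length` (aa), `has_signal` (logical), `tm_segments` (comma-separated
#' `start-end` pairs, 1-based inclusive, `"."` for none),
#' `secreted_neighbor_fraction` in `[0,1]`, `family_labels`
#' (comma-separated, namespaced `CAZy:`/`MEROPS:`/`PFAM:`, `"."` for none).
#'
#' @param path Path to the annotation TSV.
#' @return data.frame of annotations; `tm_segments` stays in string form
#'   (use [parse_tm_segments()] to expand).
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv(path, required = c("protein_id", "mag_id", "length",
                                    "has_signal", "tm_segments",
                                    "secreted_neighbor_fraction",
                                    "family_labels"))
  df$length <- as.integer(df$length)
  df$has_signal <- as.logical(df$has_signal)
  df$secreted_neighbor_fraction <- as.numeric(df$secreted_neighbor_fraction)
  df$tm_segments[is.na(df$tm_segments)] <- ""
  df$family_labels[is.na(df$family_labels)] <- ""
  if (nrow(df) > 0L) {
    if (any(df$length < 1L)) stop("'", path, "': protein length must be >= 1")
    f <- df$secreted_neighbor_fraction
    if (any(f < 0 | f > 1)) {
      stop("'", path, "': secreted_neighbor_fraction must lie in [0,1]")
    }
    for (i in seq_len(nrow(df))) {
      parse_tm_segments(df$tm_segments[i], df$length[i])
    }
  }
  df
}

#' Parse transmembrane segments
#'
#' Expands the `"start-end,start-end"` string form into a two-column
#' matrix of 1-based inclusive amino-acid coordinates. Segments must be
#' sorted, non-overlapping and contained in `[1, length]`.
#'
#' @param text Segment string; `""` or `"."` means no segments.
#' @param length Protein length in amino acids (for bounds checking);
#'   `NULL` skips the upper-bound check.
#' @return Integer matrix with columns `start`, `end` (0 rows if none).
#' @export
parse_tm_segments <- function(text, length = NULL) {
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (is.na(text) || text == "" || text == ".") return(out)
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  seg <- t(vapply(parts, function(p) {
    se <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
    if (length(se) != 2L || anyNA(se)) {
      stop("malformed TM segment: '", p, "'")
    }
    se
  }, integer(2)))
  dimnames(seg) <- list(NULL, c("start", "end"))
  if (any(seg[, "start"] > seg[, "end"]) || any(seg[, "start"] < 1L)) {
    stop("TM segment with start > end or start < 1")
  }
  if (!is.null(length) && any(seg[, "end"] > length)) {
    stop("TM segment extends past protein length")
  }
  if (nrow(seg) > 1L) {
    if (is.unsorted(seg[, "start"], strictly = TRUE) ||
        any(seg[-1L, "start"] <= seg[-nrow(seg), "end"])) {
      stop("TM segments must be sorted and non-overlapping")
    }
  }
  seg
}

format_tm_segments <- function(seg) {
  if (is.null(seg) || nrow(seg) == 0L) return(".")
  paste(paste0(seg[, 1L], "-", seg[, 2L]), collapse = ",")
}

#' Read a quality-estimate table
#'
#' Columns `bin_id`, `estimator_label`, `completeness` (percent, `<= 100`),
#' `contamination` (percent, `>= 0`).
#'
#' @param path Path to the quality TSV.
#' @return data.frame of quality estimates.
#' @export
read_quality_table <- function(path) {
  df <- read_tsv(path, required = c("bin_id", "estimator_label",
                                    "completeness", "contamination"))
  df$completeness <- as.numeric(df$completeness)
  df$contamination <- as.numeric(df$contamination)
  if (nrow(df) > 0L &&
      (any(df$completeness < 0 | df$completeness > 100) ||
       any(df$contamination < 0))) {
    stop("'", path, "': completeness must lie in [0,100], ",
         "contamination must be >= 0")
  }
  df
}

# --- FASTA -------------------------------------------------------------

#' Write contig sequences as FASTA
#'
#' Sequences must use the alphabet `{A,C,G,T,N}` only. Output is standard
#' FASTA wrapped at 80 columns; [read_fasta()] round-trips it bit-exact in
#' sequence content.
#'
#' @param seqs Named character vector of sequences (names become headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence '", names(seqs)[bad][1],
         "' contains characters outside {A,C,G,T,N}")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
  invisible(path)
}

#' Read a FASTA file of nucleotide sequences
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
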