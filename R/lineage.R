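#' Taxonomic rank ladder
#'
#' The fixed eight-rank ladder used for every lineage in the package, from
#' shallowest (domain) to deepest (species). Fixing the ladder makes depth
#' comparisons between lineages well defined.
#'
#' @return Character vector of the eight rank names.
#' @export
lineage_ranks <- function() {
  c("domain", "kingdom", "phylum", "class", "order", "family",
    "genus", "species")
}

.rank_prefixes <- c("d__", "k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Construct a lineage
#'
#' A lineage is a character vector over the eight fixed ranks; empty strings
#' mark unassigned ranks. Lineages must have no gaps: a named rank implies
#' all shallower ranks are named too.
#'
#' @param ... Rank names in ladder order (domain first); trailing ranks may
#'   be omitted.
#' @return A `lineage` object (named character vector of length 8).
#' @examples
#' lineage("Eukaryota", "Fungi", "Ascomycota")
#' @export
lineage <- function(...) {
  parts <- as.character(c(...))
  if (length(parts) > 8L) {
    stop("a lineage has at most 8 ranks")
  }
  x <- c(parts, rep("", 8L - length(parts)))
  names(x) <- lineage_ranks()
  validate_lineage(x)
  structure(x, class = "lineage")
}

validate_lineage <- function(x) {
  if (length(x) != 8L) stop("lineage must have exactly 8 rank slots")
  x <- as.character(x)
  x[is.na(x)] <- ""
  filled <- nzchar(x)
  if (any(filled & !cumall_shallower(filled))) {
    stop("gapped lineage: empty rank precedes a named rank")
  }
  invisible(x)
}

# TRUE at position i iff all positions 1..i are TRUE
cumall_shallower <- function(filled) cumprod(filled) > 0

#' Depth of a lineage
#'
#' Number of contiguous named ranks starting at domain; the root (fully
#' unassigned) lineage has depth 0.
#'
#' @param x A `lineage` or a lineage string.
#' @return Integer depth in `[0, 8]`.
#' @export
lineage_depth <- function(x) {
  if (is.character(x) && is.null(attr(x, "class")) && length(x) == 1L) {
    x <- parse_lineage(x)
  }
  sum(cumall_shallower(nzchar(as.character(x))))
}

#' Parse a lineage string
#'
#' Reads semicolon-delimited ranked names with the prefixes
#' `d__,k__,p__,c__,o__,f__,g__,s__`. Trailing ranks may be omitted; the
#' empty string parses to the root lineage. A named rank below an empty one
#' (a gap) is an error, as is an out-of-order or unknown prefix.
#'
#' @param text A single lineage string, e.g. `"d__Eukaryota;k__Fungi"`.
#' @return A `lineage` object.
#' @examples
#' parse_lineage("d__Eukaryota;k__Fungi;p__Ascomycota")
#' parse_lineage("")   # root, depth 0
#' @export
parse_lineage <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || text == "" || text == ".") {
    return(lineage())
  }
  fields <- strsplit(text, ";", fixed = TRUE)[[1]]
  fields <- trimws(fields)
  x <- rep("", 8L)
  for (f in fields) {
    if (nchar(f) < 3L) stop("malformed lineage field: '", f, "'")
    pre <- substr(f, 1L, 3L)
    i <- match(pre, .rank_prefixes)
    if (is.na(i)) stop("unknown rank prefix in lineage field: '", f, "'")
    x[i] <- substr(f, 4L, nchar(f))
  }
  filled <- nzchar(x)
  if (any(filled & !cumall_shallower(filled))) {
    stop("gapped lineage: '", text, "'")
  }
  names(x) <- lineage_ranks()
  structure(x, class = "lineage")
}

#' Format a lineage as a string
#'
#' Inverse of [parse_lineage()]: emits the prefixed, semicolon-delimited
#' form, dropping trailing empty ranks. The root lineage formats as `""`.
#'
#' @param x A `lineage` (or plain 8-vector of rank names).
#' @return A single string.
#' @export
format_lineage <- function(x) {
  x <- as.character(x)
  d <- sum(cumall_shallower(nzchar(x)))
  if (d == 0L) return("")
  paste0(.rank_prefixes[seq_len(d)], x[seq_len(d)], collapse = ";")
}

#' @export
print.lineage <- function(x, ...) {
  s <- format_lineage(x)
  cat("<lineage depth ", lineage_depth(x), "> ",
      if (nzchar(s)) s else "(root)", "\n", sep = "")
  invisible(x)
}

# Parse a character vector of lineage strings into an n x 8 character
# matrix (rows = lineages, cols = ranks). Vectorised workhorse for the
# vote machinery; validates the no-gap invariant per row.
lineage_matrix <- function(texts) {
  n <- length(texts)
  m <- matrix("", nrow = n, ncol = 8L,
              dimnames = list(NULL, lineage_ranks()))
  if (n == 0L) return(m)
  for (i in seq_len(n)) {
    m[i, ] <- as.character(parse_lineage(texts[i]))
  }
  m
}

# Depths for each row of a lineage matrix.
matrix_depths <- function(m) {
  if (nrow(m) == 0L) return(integer(0))
  filled <- matrix(nzchar(m), nrow = nrow(m))
  apply(filled, 1L, function(f) sum(cumprod(f)))
}

#' Do two lineages conflict?
#'
#' Two lineages are compatible when they name the same taxon at every rank
#' where both are assigned; one being a prefix of the other is compatible.
#' Used when grouping bins that may be classified to different depths.
#'
#' @param a,b Lineages or lineage strings.
#' @return `TRUE` if compatible (no conflict at mutually assigned ranks).
#' @export
lineage_compatible <- function(a, b) {
  if (is.character(a) && length(a) == 1L && is.null(attr(a, "class"))) {
    a <- parse_lineage(a)
  }
  if (is.character(b) && length(b) == 1L && is.null(attr(b, "class"))) {
    b <- parse_lineage(b)
  }
  a <- as.character(a); b <- as.character(b)
  both <- nzchar(a) & nzchar(b)
  all(a[both] == b[both])
}
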