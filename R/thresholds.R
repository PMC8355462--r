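#' Default analysis thresholds
#'
#' All numeric decision thresholds of the curation pipeline in one place.
#' Inequality conventions (strict vs weak) are applied by the functions that
#' consume each threshold and are documented there; in brief: completeness
#' must exceed `min_completeness` strictly, contamination must stay strictly
#' below `max_contamination`, the LCA vote is a weak `>=` on `vote_frac`,
#' the secreted-neighbor vote is a strict `>` on `neighbor_frac`, and SSPs
#' are strictly shorter than `ssp_max_len`.
#'
#' @return Named list of thresholds:
#' \describe{
#'   \item{evalue_lca}{e-value ceiling for homology hits entering the LCA
#'     vote (1e-20).}
#'   \item{vote_frac}{majority-vote fraction for LCA assignment (0.60,
#'     weak inequality by default).}
#'   \item{max_proteins_per_bin}{protein subsample cap per bin (200).}
#'   \item{top_hits}{ranked hits considered per protein (3).}
#'   \item{min_completeness}{percent completeness a bin must exceed,
#'     strictly, under at least one estimator (90).}
#'   \item{max_contamination}{percent contamination a bin must stay
#'     strictly below under every estimator (5).}
#'   \item{ssp_max_len}{small secreted proteins are strictly shorter than
#'     this many amino acids (300).}
#'   \item{tm_nterm_window}{a single transmembrane segment ending at or
#'     before this residue is excused as the signal peptide (60).}
#'   \item{neighbor_frac}{fraction of secreted nearest neighbors a protein
#'     must exceed, strictly (0.60).}
#'   \item{rescue_evalue}{e-value cutoff for the missing-family rescue
#'     search (1e-5).}
#'   \item{cloud_cov_tol}{maximum relative deviation in median coverage for
#'     bins in one linear-cloud group (0.25).}
#'   \item{merge_contam_delta}{maximum contamination increase, in
#'     percentage points, an accepted merge may cause (1.0).}
#'   \item{vote_strict}{if TRUE the LCA vote uses a strict `>` instead of
#'     the default weak `>=` (FALSE).}
#'   \item{count_unclassified}{if TRUE, proteins with no passing hits are
#'     counted in the per-bin vote denominator (FALSE).}
#' }
#' @export
default_thresholds <- function() {
  list(
    evalue_lca          = 1e-20,
    vote_frac           = 0.60,
    max_proteins_per_bin = 200L,
    top_hits            = 3L,
    min_completeness    = 90,
    max_contamination   = 5,
    ssp_max_len         = 300L,
    tm_nterm_window     = 60L,
    neighbor_frac       = 0.60,
    rescue_evalue       = 1e-5,
    cloud_cov_tol       = 0.25,
    merge_contam_delta  = 1.0,
    vote_strict         = FALSE,
    count_unclassified  = FALSE
  )
}

#' Read a key = value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values are coerced to numeric or logical where possible.
#'
#' @param path Path to the config file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected key = value): '", ln, "'")
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- coerce_config_value(val)
  }
  out
}

coerce_config_value <- function(val) {
  if (toupper(val) %in% c("TRUE", "FALSE")) return(as.logical(toupper(val)))
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' Resolve thresholds from defaults and overrides
#'
#' @param config Named list of overrides (e.g. from [read_config()]), or
#'   `NULL` for pure defaults. Keys not naming a threshold are ignored so a
#'   pipeline config can carry extra settings.
#' @return Threshold list as in [default_thresholds()].
#' @export
resolve_thresholds <- function(config = NULL) {
  th <- default_thresholds()
  if (is.null(config)) return(th)
  stopifnot(is.list(config))
  for (key in intersect(names(config), names(th))) {
    th[[key]] <- config[[key]]
  }
  validate_thresholds(th)
  th
}

validate_thresholds <- function(th) {
  num <- vapply(th[setdiff(names(th), c("vote_strict", "count_unclassified"))],
                as.numeric, numeric(1))
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all numeric thresholds must be positive and finite")
  }
  for (f in c("vote_frac", "neighbor_frac")) {
    if (th[[f]] <= 0 || th[[f]] >= 1) {
      stop("'", f, "' must lie strictly inside (0, 1)")
    }
  }
  invisible(th)
}

# --- logging -----------------------------------------------------------

.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)

log_msg <- function(level, ...) {
  active <- getOption("magcurate.log_level", "INFO")
  if (.log_levels[[level]] >= .log_levels[[active]]) {
    message(sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%H:%M:%S"), paste0(...)))
  }
  invisible(NULL)
}

log_info <- function(...) log_msg("INFO", ...)
log_debug <- function(...) log_msg("DEBUG", ...)

# --- seeding -----------------------------------------------------------

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation takes an explicit seed and routes through here,
# so stages are reproducible when re-run independently.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stage-specific seed from one global seed, kept inside 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}
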