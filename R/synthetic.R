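# Synthetic metagenomic communities with the statistical structure the
# curation pipeline assumes: one dominant high-coverage genome plus several
# low-coverage genomes of distinct lineages, genome-specific GC
# distributions, single-copy marker complements, noisy homology hits, and a
# configurable binning error that splits the dominant genome across bins
# spanning a wide GC range at near-identical coverage. Every operation is
# deterministic under its seed; truth tables accompany every artifact.

#' Specify one genome of a synthetic community
#'
#' @param genome_id Unique genome label.
#' @param lineage A [lineage()] of depth >= 3.
#' @param genome_size Genome size in bp.
#' @param gc_mean Mean GC fraction of the genome's contigs.
#' @param gc_sd Between-contig GC standard deviation; `gc_mean +/- 3*gc_sd`
#'   must stay inside `[0, 1]`.
#' @param abundance Relative abundance weight (> 0); sequencing depth is
#'   proportional to it.
#' @param marker_ids Character vector of expected single-copy marker ids
#'   (the genome's marker catalog).
#' @param n_proteins Number of predicted proteins to simulate for the
#'   genome.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(genome_id, lineage, genome_size, gc_mean, gc_sd,
                        abundance, marker_ids, n_proteins = 300L) {
  stopifnot(is.character(genome_id), nzchar(genome_id),
            genome_size >= 1e4, abundance > 0, n_proteins >= 1,
            length(marker_ids) >= 1L)
  if (lineage_depth(lineage) < 3L) {
    stop("genome lineage must be assigned at least to phylum (depth 3)")
  }
  if (gc_mean - 3 * gc_sd < 0 || gc_mean + 3 * gc_sd > 1) {
    stop("gc_mean +/- 3*gc_sd must lie inside [0, 1]")
  }
  structure(list(genome_id = genome_id, lineage = lineage,
                 genome_size = genome_size, gc_mean = gc_mean,
                 gc_sd = gc_sd, abundance = abundance,
                 marker_ids = as.character(marker_ids),
                 n_proteins = as.integer(n_proteins)),
            class = "genome_spec")
}

euk_marker_catalog <- function(n = 400L) sprintf("EUK%04d", seq_len(n))
bac_marker_catalog <- function(n = 120L) sprintf("BAC%04d", seq_len(n))

#' Default synthetic community specifications
#'
#' Two preset communities emulating a lichen metagenome sequenced under two
#' preparation protocols. Both contain a dominant lecanoromycete (an
#' ascomycete whose contigs span a wide GC range, 0.30-0.55) plus
#' low-abundance basidiomycete yeasts. In the bulk preparation the yeasts
#' sit at 1/336 and 1/184 of the dominant genome's coverage; in the
#' cortex-slurry preparation at 1/4 and 1/5 — an 84- and 36.8-fold
#' enrichment. Genome sizes are scaled-down stand-ins (a few Mb) so
#' end-to-end analyses run at desk scale; eukaryotes share one marker
#' catalog of 400 single-copy markers, bacteria one of 120.
#'
#' @param sample `"slurry"` (dominant fungus, two basidiomycete yeasts, two
#'   bacteria) or `"bulk"` (dominant fungus, chlorophyte alga, trace
#'   yeasts).
#' @return List of [genome_spec()] objects.
#' @export
default_community_specs <- function(sample = c("slurry", "bulk")) {
  sample <- match.arg(sample)
  euk <- euk_marker_catalog()
  lecanoromycete <- genome_spec(
    "lecanoromycete",
    lineage("Eukaryota", "Fungi", "Ascomycota", "Lecanoromycetes",
            "Lecanorales", "Parmeliaceae", "Alectoria"),
    genome_size = 3e6, gc_mean = 0.425, gc_sd = 0.0417,
    abundance = 100, marker_ids = euk, n_proteins = 400L)
  cyphobasidium <- function(ab) genome_spec(
    "cyphobasidium",
    lineage("Eukaryota", "Fungi", "Basidiomycota", "Cystobasidiomycetes",
            "Cyphobasidiales", "Cyphobasidiaceae", "Cyphobasidium"),
    genome_size = 1.2e6, gc_mean = 0.51, gc_sd = 0.015,
    abundance = ab, marker_ids = euk, n_proteins = 300L)
  tremella <- function(ab) genome_spec(
    "tremella",
    lineage("Eukaryota", "Fungi", "Basidiomycota", "Tremellomycetes",
            "Tremellales", "Tremellaceae", "Tremella"),
    genome_size = 1.2e6, gc_mean = 0.52, gc_sd = 0.015,
    abundance = ab, marker_ids = euk, n_proteins = 300L)
  if (sample == "slurry") {
    list(
      lecanoromycete,
      cyphobasidium(25),
      tremella(20),
      genome_spec("sphingomonas",
                  lineage("Bacteria", "Bacteria", "Proteobacteria",
                          "Alphaproteobacteria", "Sphingomonadales",
                          "Sphingomonadaceae", "Sphingomonas"),
                  genome_size = 2e6, gc_mean = 0.63, gc_sd = 0.01,
                  abundance = 8, marker_ids = bac_marker_catalog(),
                  n_proteins = 250L),
      genome_spec("acidobacterium",
                  lineage("Bacteria", "Bacteria", "Acidobacteria",
                          "Acidobacteriia", "Acidobacteriales",
                          "Acidobacteriaceae", "Acidobacterium"),
                  genome_size = 2e6, gc_mean = 0.58, gc_sd = 0.01,
                  abundance = 5, marker_ids = bac_marker_catalog(),
                  n_proteins = 250L))
  } else {
    list(
      lecanoromycete,
      genome_spec("trebouxia",
                  lineage("Eukaryota", "Viridiplantae", "Chlorophyta",
                          "Trebouxiophyceae", "Trebouxiales",
                          "Trebouxiaceae", "Trebouxia"),
                  genome_size = 2e6, gc_mean = 0.50, gc_sd = 0.02,
                  abundance = 40, marker_ids = euk, n_proteins = 300L),
      cyphobasidium(100 / 336),
      tremella(100 / 184))
  }
}

# Draw contig lengths from a log-normal (median 10 kb) truncated by
# rejection to [1 kb, 200 kb].
draw_contig_lengths <- function(n, meanlog = log(1e4), sdlog = 0.9) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 8L, meanlog, sdlog)
    out <- c(out, x[x >= 1e3 & x <= 2e5])
  }
  round(out[seq_len(n)])
}

#' Generate a synthetic metagenomic community
#'
#' Per genome, contig lengths are drawn from a log-normal (median 10 kb,
#' truncated to 1-200 kb) until they cover the genome size (the total may
#' overshoot by at most one contig); per-contig GC is Normal(gc_mean,
#' gc_sd) clipped to `[0.15, 0.75]`; per-contig depth is Normal around the
#' genome depth with 10% coefficient of variation, where genome depth is
#' `total_depth_budget * abundance / sum(abundances)`. The first contig of
#' each genome is recorded as its rDNA marker ("ITS") contig in the truth.
#'
#' @param specs List of [genome_spec()] objects.
#' @param total_depth_budget Total coverage shared by the genomes in
#'   proportion to abundance.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `contigs` (contig table: contig_id, length, gc,
#'   mean_depth, truth_genome_id) and `truth` (a `community_truth` object
#'   carrying the specs, genome depths, contig genome-coordinate layout,
#'   marker-contig ids and hit-noise defaults).
#' @export
generate_community <- function(specs, total_depth_budget = 500, seed = 1L) {
  if (length(specs) == 0L) stop("at least one genome spec is required")
  if (total_depth_budget <= 0) stop("depth budget must be positive")
  stopifnot(all(vapply(specs, inherits, logical(1), "genome_spec")))
  ids <- vapply(specs, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) stop("genome ids must be unique")
  names(specs) <- ids
  ab <- vapply(specs, `[[`, numeric(1), "abundance")
  depth <- total_depth_budget * ab / sum(ab)

  with_seed(seed, {
    pieces <- lapply(specs, function(sp) {
      lens <- numeric(0)
      while (sum(lens) < sp$genome_size) {
        need <- ceiling((sp$genome_size - sum(lens)) / 1.5e4) + 4L
        lens <- c(lens, draw_contig_lengths(need))
        if (sum(lens) >= sp$genome_size) {
          lens <- lens[seq_len(which(cumsum(lens) >= sp$genome_size)[1])]
        }
      }
      n <- length(lens)
      gc <- pmin(0.75, pmax(0.15, stats::rnorm(n, sp$gc_mean, sp$gc_sd)))
      d <- depth[[sp$genome_id]]
      dep <- pmax(1e-3, stats::rnorm(n, d, 0.10 * d))
      data.frame(length = lens, gc = round(gc, 4),
                 mean_depth = round(dep, 3),
                 truth_genome_id = sp$genome_id,
                 genome_start = cumsum(lens) - lens + 1,
                 genome_end = cumsum(lens),
                 stringsAsFactors = FALSE)
    })
    contigs <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
    contigs <- cbind(contig_id = sprintf("ctg%05d", seq_len(nrow(contigs))),
                     contigs, stringsAsFactors = FALSE)
    layout <- contigs[c("contig_id", "truth_genome_id",
                        "genome_start", "genome_end")]
    names(layout)[2] <- "genome_id"
    contigs$genome_start <- contigs$genome_end <- NULL
    marker_contig <- vapply(ids, function(g) {
      contigs$contig_id[contigs$truth_genome_id == g][1]
    }, character(1))
    truth <- structure(list(
      specs = specs,
      genome_depth = depth,
      dominant = ids[which.max(ab)],
      layout = layout,
      marker_contig = marker_contig,
      p_wrong_lineage = 0.05,
      evalue_fail_frac = 0.10
    ), class = "community_truth")
    list(contigs = contigs, truth = truth)
  })
}

#' Generate contig sequences and write them as FASTA
#'
#' Draws each contig's sequence i.i.d. at its recorded GC fraction.
#' Sequence content is cosmetic (the pipeline consumes the contig table);
#' this exists so the on-disk artifact set matches a real assembly.
#'
#' @param contigs Contig table from [generate_community()].
#' @param path Output FASTA path.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
write_community_fasta <- function(contigs, path, seed = 1L) {
  with_seed(seed, {
    seqs <- vapply(seq_len(nrow(contigs)), function(i) {
      gc <- contigs$gc[i]
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(names(p), contigs$length[i], replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    names(seqs) <- contigs$contig_id
    write_fasta(seqs, path)
  })
}

#' Inject binning errors into a community
#'
#' Emulates the characteristic failure mode of composition-based binning on
#' a GC-heterogeneous dominant genome: its contigs are split into `k` bins
#' by GC strata, so the bins jointly tile the genome's GC span while each
#' keeps the genome's coverage (the "linear cloud"). One central stratum
#' holding `anchor_frac` of the genome's length plays the role of the main
#' bin binning would recover; the remaining length is split across `k - 1`
#' peripheral GC-tail bins. Every other genome gets one clean bin.
#'
#' @param truth `community_truth` from [generate_community()].
#' @param contigs Matching contig table.
#' @param split_dominant_into Number of bins `k >= 1` for the dominant
#'   (highest-abundance) genome; `k = 1` reproduces the truth partition.
#' @param gc_stratified If `TRUE` (default) split by GC strata; otherwise
#'   assign the dominant genome's contigs to bins at random.
#' @param anchor_frac Fraction of the dominant genome's length kept in the
#'   central anchor stratum when `gc_stratified` (default 0.92, so the
#'   anchor bin is nearly, but not fully, complete).
#' @param seed Integer seed (used by the unstratified mode).
#' @return Bin table (`contig_id`, `bin_id`).
#' @export
inject_binning_errors <- function(truth, contigs, split_dominant_into = 1L,
                                  gc_stratified = TRUE, anchor_frac = 0.92,
                                  seed = 1L) {
  k <- as.integer(split_dominant_into)
  stopifnot(inherits(truth, "community_truth"), k >= 1L,
            anchor_frac > 0, anchor_frac < 1)
  dom <- truth$dominant
  bin_id <- paste0("bin_", contigs$truth_genome_id)
  is_dom <- contigs$truth_genome_id == dom
  if (k > sum(is_dom)) {
    stop("cannot split the dominant genome into more bins than it has contigs")
  }
  if (k > 1L) {
    idx <- which(is_dom)
    if (gc_stratified) {
      ord <- idx[order(contigs$gc[idx])]
      frac <- cumsum(contigs$length[ord]) / sum(contigs$length[ord])
      lo <- (1 - anchor_frac) / 2
      hi <- 1 - lo
      n_low <- floor((k - 1L) / 2)
      n_high <- (k - 1L) - n_low
      breaks <- c(if (n_low > 0L) seq(0, lo, length.out = n_low + 1L)[-1L],
                  hi,
                  if (n_high > 1L) seq(hi, 1, length.out = n_high + 1L)[-c(1L, n_high + 1L)])
      stratum <- findInterval(frac, c(breaks), left.open = FALSE) + 1L
      # contig granularity can leave a narrow stratum empty; repair by
      # pulling one contig across the boundary from a multi-contig
      # neighbor so all k strata are populated
      for (s in seq_len(k)) {
        while (!any(stratum == s)) {
          nb <- if (any(stratum < s)) max(stratum[stratum < s])
                else min(stratum[stratum > s])
          cand <- which(stratum == nb)
          donor <- if (nb < s) cand[length(cand)] else cand[1L]
          stratum[donor] <- s
        }
      }
      # strata are indexed in GC order; the widest is the anchor
      bin_id[ord] <- paste0("bin_", dom, "_s", stratum)
    } else {
      with_seed(seed, {
        stratum <- sample(rep_len(seq_len(k), length(idx)))
        bin_id[idx] <- paste0("bin_", dom, "_s", stratum)
      })
    }
  }
  data.frame(contig_id = contigs$contig_id, bin_id = bin_id,
             stringsAsFactors = FALSE)
}

# True lineage string of the genome contributing most length to each bin.
bin_true_lineage <- function(truth, contigs, bins) {
  merged <- merge(bins, contigs[c("contig_id", "length", "truth_genome_id")],
                  by = "contig_id")
  split_bins <- split(merged, merged$bin_id)
  vapply(split_bins, function(b) {
    g <- names(which.max(tapply(b$length, b$truth_genome_id, sum)))
    format_lineage(truth$specs[[g]]$lineage)
  }, character(1))
}

#' Simulate protein homology hits for each bin
#'
#' Emulates a translated search of a bin's predicted proteins against a
#' reference protein database: up to `per_bin` proteins per bin, three
#' ranked hits each. A hit carries the bin's true lineage with probability
#' `1 - p_wrong`, otherwise a random other lineage from the community. Hit
#' e-values are log-uniform, with a fraction `evalue_fail_frac` drawn above
#' the LCA threshold of 1e-20 (in `[1e-20, 1e-5]`) and the rest in
#' `[1e-200, 1e-20]`.
#'
#' @param truth `community_truth`.
#' @param contigs Contig table.
#' @param bins Bin table from [inject_binning_errors()].
#' @param per_bin Proteins simulated per bin.
#' @param p_wrong Probability a hit's lineage is wrong; defaults to the
#'   community's `p_wrong_lineage`.
#' @param evalue_fail_frac Fraction of hits failing the 1e-20 threshold;
#'   defaults to the community's setting.
#' @param seed Integer seed.
#' @return Hit table (`protein_id`, `bin_id`, `rank_order`, `lineage`,
#'   `evalue`, `bitscore`).
#' @export
simulate_hits <- function(truth, contigs, bins, per_bin = 250L,
                          p_wrong = NULL, evalue_fail_frac = NULL,
                          seed = 1L) {
  if (is.null(p_wrong)) p_wrong <- truth$p_wrong_lineage
  if (is.null(evalue_fail_frac)) evalue_fail_frac <- truth$evalue_fail_frac
  stopifnot(p_wrong >= 0, p_wrong <= 1)
  lineages <- vapply(truth$specs, function(s) format_lineage(s$lineage),
                     character(1))
  true_lin <- bin_true_lineage(truth, contigs, bins)
  with_seed(seed, {
    out <- lapply(names(true_lin), function(b) {
      n <- per_bin
      tl <- true_lin[[b]]
      others <- setdiff(lineages, tl)
      nh <- 3L * n
      wrong <- stats::runif(nh) < p_wrong
      lin <- rep(tl, nh)
      if (any(wrong) && length(others) > 0L) {
        lin[wrong] <- sample(others, sum(wrong), replace = TRUE)
      }
      fail <- stats::runif(nh) < evalue_fail_frac
      ev <- ifelse(fail,
                   10^stats::runif(nh, -20, -5),
                   10^stats::runif(nh, -200, -20))
      data.frame(protein_id = rep(paste0(b, "_p", seq_len(n)), each = 3L),
                 bin_id = b,
                 rank_order = rep(1:3, n),
                 lineage = lin,
                 evalue = ev,
                 bitscore = round(stats::runif(nh, 50, 800), 1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Simulate secretion-relevant protein annotations with truth labels
#'
#' Emulates the annotation tables consumed by the secretome cascade
#' (signal-peptide flag, transmembrane topology, localization neighbor
#' vote, family labels). Each protein is constructed to either satisfy or
#' fail the cascade by design, and the intended outcome is stored in
#' `truth_secreted` / `truth_ssp` so the classifier can be checked by
#' round trip. Boundary cases are planted deliberately: a single TM segment
#' ending exactly at residue 60 (permitted), neighbor fractions of exactly
#' 0.60 (rejected, strict `>`), and lengths of exactly 300 aa (secreted but
#' not an SSP).
#'
#' @param truth `community_truth`.
#' @param secreted_frac Fraction of proteins built to pass the cascade.
#' @param seed Integer seed.
#' @param n_per_genome Optional override of each genome's `n_proteins`.
#' @return Annotation table with truth columns.
#' @export
simulate_annotations <- function(truth, secreted_frac = 0.10, seed = 1L,
                                 n_per_genome = NULL) {
  stopifnot(secreted_frac >= 0, secreted_frac <= 1)
  cazy <- c("CAZy:GH5", "CAZy:GH5_7", "CAZy:GH12", "CAZy:GH18_3",
            "CAZy:CE5", "CAZy:AA9", "CAZy:GT2", "CAZy:CBM1")
  merops <- c("MEROPS:S1", "MEROPS:A1", "MEROPS:M35", "MEROPS:S8")
  pfam <- c("PFAM:PF01083", "PFAM:PF01670", "PFAM:PF00089", "PFAM:PF01583",
            "PFAM:PF00082", "PFAM:PF00734")
  pools <- c(cazy, merops, pfam)
  with_seed(seed, {
    out <- lapply(truth$specs, function(sp) {
      n <- if (is.null(n_per_genome)) sp$n_proteins else as.integer(n_per_genome)
      len <- sample(130:1200, n, replace = TRUE)
      # plant exact-boundary lengths
      nb <- max(1L, n %/% 50L)
      len[sample(n, min(2L * nb, n))] <- rep(c(299L, 300L), nb)[seq_len(min(2L * nb, n))]
      sec <- stats::runif(n) < secreted_frac
      has_signal <- logical(n)
      tm <- character(n)
      frac <- numeric(n)
      for (i in seq_len(n)) {
        if (sec[i]) {
          has_signal[i] <- TRUE
          mode <- sample(c("no_tm", "nterm_tm", "nterm_tm_edge60"), 1L,
                         prob = c(0.6, 0.3, 0.1))
          tm[i] <- switch(mode,
            no_tm = ".",
            nterm_tm = {
              s <- sample(1:15, 1L); e <- s + sample(15:30, 1L)
              paste0(s, "-", min(e, 59L))
            },
            nterm_tm_edge60 = paste0(sample(30:40, 1L), "-60"))
          frac[i] <- round(stats::runif(1L, 0.61, 1.00), 2)
        } else {
          fail <- sample(c("no_signal", "multi_tm", "internal_tm",
                           "frac_low", "frac_edge60"), 1L)
          has_signal[i] <- fail != "no_signal"
          tm[i] <- switch(fail,
            no_signal = if (stats::runif(1L) < 0.5) "." else "10-30",
            multi_tm = "10-30,101-125",
            internal_tm = {
              s <- sample(61:(len[i] - 21L), 1L)
              paste0(s, "-", s + 20L)
            },
            frac_low = ".",
            frac_edge60 = ".")
          frac[i] <- switch(fail,
            frac_low = round(stats::runif(1L, 0, 0.59), 2),
            frac_edge60 = 0.60,
            round(stats::runif(1L, 0, 1), 2))
        }
      }
      nlab <- sample(0:3, n, replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
      labels <- vapply(nlab, function(m) {
        if (m == 0L) "." else paste(sample(pools, m), collapse = ",")
      }, character(1))
      data.frame(protein_id = paste0(sp$genome_id, "_g", seq_len(n)),
                 mag_id = sp$genome_id,
                 length = len,
                 has_signal = has_signal,
                 tm_segments = tm,
                 secreted_neighbor_fraction = frac,
                 family_labels = labels,
                 truth_secreted = sec,
                 truth_ssp = sec & len < 300L,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Place single-copy markers on a community's contigs
#'
#' Per genome, a seeded random `completeness_target`% subset of its marker
#' catalog is observed; `dup_target`% of the observed markers get a second
#' copy on a random contig of the genome. Each observed marker is anchored
#' at an evenly spaced canonical genome coordinate and inherits the contig
#' (hence, via any bin table, the bin) containing that coordinate — so a
#' bin holding a fraction of a genome's length holds about that fraction of
#' its markers. On an unsplit genome the marker estimator recovers
#' `(completeness_target, dup_target * completeness_target / 100)` up to
#' integer rounding of marker counts.
#'
#' @param truth `community_truth`.
#' @param completeness_target,dup_target Percent targets in `[0, 100]`.
#' @param seed Integer seed.
#' @return Contig-level marker table (`contig_id`, `marker_id`,
#'   `copy_count`); collapse to bins with [markers_by_bin()].
#' @export
place_markers <- function(truth, completeness_target = 99, dup_target = 0.5,
                          seed = 1L) {
  stopifnot(completeness_target >= 0, completeness_target <= 100,
            dup_target >= 0, dup_target <= 100)
  with_seed(seed, {
    out <- lapply(truth$specs, function(sp) {
      cat_ids <- sp$marker_ids
      n <- length(cat_ids)
      layout <- truth$layout[truth$layout$genome_id == sp$genome_id, ]
      gsize <- max(layout$genome_end)
      n_obs <- round(completeness_target / 100 * n)
      if (n_obs == 0L) return(NULL)
      obs_idx <- sort(sample.int(n, n_obs))
      pos <- (obs_idx - 0.5) / n * gsize
      ci <- layout$contig_id[findInterval(pos, c(0, layout$genome_end),
                                          left.open = TRUE)]
      rows <- data.frame(contig_id = ci, marker_id = cat_ids[obs_idx],
                         stringsAsFactors = FALSE)
      n_dup <- round(dup_target / 100 * n_obs)
      if (n_dup > 0L) {
        dup <- sample(seq_len(n_obs), n_dup)
        rows <- rbind(rows, data.frame(
          contig_id = sample(layout$contig_id, n_dup, replace = TRUE),
          marker_id = cat_ids[obs_idx[dup]],
          stringsAsFactors = FALSE))
      }
      rows
    })
    rows <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    agg <- stats::aggregate(list(copy_count = rep(1L, nrow(rows))),
                            rows[c("contig_id", "marker_id")], sum)
    agg[order(agg$contig_id, agg$marker_id), , drop = FALSE]
  })
}

#' Collapse contig-level marker observations to bins
#'
#' @param markers Contig-level marker table from [place_markers()].
#' @param bins Bin table (`contig_id`, `bin_id`); unbinned contigs are
#'   dropped.
#' @return Bin-level marker table (`bin_id`, `marker_id`, `copy_count`).
#' @export
markers_by_bin <- function(markers, bins) {
  m <- merge(markers, bins, by = "contig_id")
  m <- m[!is.na(m$bin_id), , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(bin_id = character(0), marker_id = character(0),
                      copy_count = integer(0)))
  }
  agg <- stats::aggregate(list(copy_count = m$copy_count),
                          m[c("bin_id", "marker_id")], sum)
  agg[order(agg$bin_id, agg$marker_id), , drop = FALSE]
}

#' Simulate domain (Pfam) hits across all community proteins
#'
#' Emulates an HMM search of metagenome-wide protein predictions for a set
#' of Pfam domains, with a reference-search taxonomy (up to three lineages)
#' attached to every hit: proteins whose simulated family labels carry the
#' domain yield a strong hit on a contig of their genome; a configurable
#' share of hits is left unbinned, and decoy hits failing the e-value
#' cutoff are added.
#'
#' @param truth `community_truth`.
#' @param annotations Annotation table from [simulate_annotations()].
#' @param bins Bin table; a hit's contig is looked up there (unbinned
#'   contigs give unbinned hits).
#' @param pfams Pfam accessions to search for (without the `PFAM:` prefix).
#' @param unbinned_frac Fraction of true hits placed on an unbinned contig.
#' @param seed Integer seed.
#' @return Domain-hit table (`protein_id`, `contig_id`, `pfam_accession`,
#'   `evalue`, `bin_id`, `taxa` — pipe-separated lineage strings).
#' @export
simulate_domain_hits <- function(truth, annotations, bins,
                                 pfams = rescue_default_pfams(),
                                 unbinned_frac = 0.1, seed = 1L) {
  bin_of <- stats::setNames(bins$bin_id, bins$contig_id)
  with_seed(seed, {
    rows <- list()
    for (pf in pfams) {
      hitters <- annotations[grepl(paste0("PFAM:", pf),
                                   annotations$family_labels, fixed = TRUE), ]
      if (nrow(hitters) > 0L) {
        for (i in seq_len(nrow(hitters))) {
          g <- hitters$mag_id[i]
          ctg <- sample(truth$layout$contig_id[truth$layout$genome_id == g], 1L)
          unb <- stats::runif(1L) < unbinned_frac
          lin <- format_lineage(truth$specs[[g]]$lineage)
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = hitters$protein_id[i],
            contig_id = if (unb) paste0(ctg, "_unb") else ctg,
            pfam_accession = pf,
            evalue = 10^stats::runif(1L, -60, -8),
            bin_id = if (unb) NA_character_ else unname(bin_of[ctg]),
            taxa = paste(rep(lin, 3L), collapse = "|"),
            stringsAsFactors = FALSE)
        }
      }
      # decoy failing the cutoff
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = paste0("decoy_", pf), contig_id = "ctg_decoy",
        pfam_accession = pf, evalue = 10^stats::runif(1L, -4, -1),
        bin_id = NA_character_,
        taxa = format_lineage(lineage("Bacteria", "Bacteria")),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
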