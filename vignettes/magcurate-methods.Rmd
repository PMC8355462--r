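---
title: "Curating low-abundance eukaryotic genomes from metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating low-abundance eukaryotic genomes from metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcurate)
options(magcurate.log_level = "WARN")
```

## The problem

Lichens host, beyond their dominant fungal partner, low-abundance
eukaryotic symbionts — basidiomycete yeasts, algae — whose genomes are
hard to recover from shotgun metagenomes: their coverage can be hundreds
of times below the dominant fungus, and composition-based binning tends
to shatter GC-heterogeneous fungal genomes into multiple bins.
`magcurate` implements the decision procedures needed to curate such
assemblies into usable metagenome-assembled genomes (MAGs): taxonomy by
majority-vote LCA, marker-based quality gating, linear-cloud bin
merging, enrichment quantification between preparation protocols, a
secretome classification cascade, and a rescue search for gene families
that appear missing from a MAG. A seeded synthetic-community generator
provides ground truth for every stage.

## Majority-vote LCA taxonomy

Bins are classified from protein homology hits. Per bin, up to 200
proteins are sampled (uniformly, seeded). Per protein, hits are taken in
rank order, filtered to e-value < 1e-20 (strict), and truncated to the
top 3. Walking the eight-rank ladder (domain … species) from the top,
each rank is assigned the taxon supported by at least 60% of the passing
hits; the walk stops at the first rank where no taxon reaches that
fraction, which guarantees gap-free lineages. The same vote, applied to
the protein LCAs, yields the bin LCA.

Two points are genuinely open and are exposed as configuration:

* **Boundary of the 60% vote.** We use a weak inequality (6 of 10
  passes). `vote_strict = TRUE` switches to a strict `>`. With either
  convention the winner at a rank is unique because the fraction exceeds
  one half.
* **The per-bin denominator.** Proteins with no passing hits are
  excluded from both numerator and denominator by default; counting all
  sampled proteins would make sparsely annotated bins systematically
  unclassifiable. `count_unclassified = TRUE` selects the alternative.

## Marker-based quality and the retention gate

Completeness is the percentage of an expected single-copy marker
catalog observed at least once in a bin; contamination is the
percentage of excess copies relative to the catalog size. This
estimator is a transparent stand-in for tools such as CheckM or EukCC —
the package consumes marker observation tables, not read data.

The gate retains a bin iff completeness exceeds 90% **strictly under at
least one estimator** and contamination stays **strictly below 5% under
every estimator**. The "every estimator" contamination rule is a
deliberate conservative choice: tools disagree, and one lax estimator
should not pass a contaminated bin. When several retained bins share a
taxon (identical lineage at the deepest rank assigned in both), the one
with the highest completeness is kept; ties break to the larger bin,
then to the lexicographically smaller id, so deduplication is
deterministic.

Median genome coverage is the length-weighted median of contig depths —
the per-base median under constant within-contig depth — taking the
lower value on an even split of length mass.

## Linear-cloud merging

A genome split across bins betrays itself on a GC–coverage plot: several
bins at near-identical coverage spanning a wide GC band. Detection seeds
a candidate group at every gate-passing bin and adds any bin whose
median coverage deviates by at most 25% (relative) from the seed's and
whose lineage does not conflict with the seed's at any mutually assigned
rank. Prefix compatibility, rather than lineage equality, matters
because small fragments classify shallowly. A bin eligible for several
seeds joins the one with the smallest coverage deviation; two
gate-passing seeds never absorb each other (each anchors its own group),
a tie-break we fixed so that two genuinely complete genomes at similar
coverage are never collapsed.

The 25% coverage tolerance is our own calibration: wide enough to
accommodate 10% depth noise across strata of one genome, narrow enough
to keep symbionts 4-fold (let alone 84-fold) apart in coverage out of
the group.

A merge is accepted only on marker evidence: completeness recomputed on
the pooled marker multiset must strictly exceed the anchor bin's, and
contamination may rise by less than 1 percentage point. Accepted groups
are disjoint by construction and merging conserves the contig multiset.
Because pooled completeness can only grow and pooling is idempotent, a
second pass finds nothing new to merge — a property the test suite
asserts.

## Enrichment between preparation protocols

The abundance of a symbiont is summarized by the ratio of its rDNA
(ITS) marker contig's depth to the dominant genome's median coverage
within a sample; the fold enrichment between two preparations is the
ratio of those ratios. We use the single marker contig's `mean_depth`,
not a bin aggregate, because trace symbionts often have no bin at all —
only their high-copy rDNA contig assembles. Folds are reported at full
precision; integer rounding is presentation only. The identity
`fold(a,b) * fold(b,a) = 1` and invariance under joint depth rescaling
hold exactly and are tested.

## The secretome cascade and SSPs

A protein is secreted when all three steps pass: (1) a predicted
secretion signal; (2) no transmembrane segment, except that exactly one
segment ending at or before residue 60 is excused — the signal peptide
itself is frequently predicted as an N-terminal TM helix; (3) strictly
more than 60% of its localization nearest neighbors are secreted
proteins. Small secreted proteins (SSPs) are secreted proteins strictly
shorter than 300 aa. The boundaries are pinned by tests: a TM segment
ending exactly at 60 passes step 2; a neighbor fraction of exactly 0.60
fails step 3; a 300-aa secreted protein is not an SSP.

Family summaries count proteins per family per MAG within one namespace
(CAZy, MEROPS, PFAM), collapsing CAZy subfamilies (`GH5_7` → `GH5`)
first, optionally restricted to secreted proteins; the secreted
percentage uses all predicted proteins of the MAG as denominator.

## Missing-family rescue

A family reported absent from a MAG is double-checked against
metagenome-wide domain hits: hits are filtered at e-value < 1e-5, kept
only when their reference taxonomy is eukaryotic by strict majority
(2 of 3; a 1-of-2 split fails), and then assigned — a hit on a contig of
the MAG confirms presence (`present_binned`); failing that, an unbinned
hit with fungal strict-majority taxonomy rescues the family
(`present_unbinned_fungal`); only when nothing survives is the family
confirmed `missing`. Adding hits can upgrade but never demote a verdict.
The default query set is PF01083 (cutinase/CE5), PF01670 (GH12),
PF00089 (trypsin/S1) and PF01583 (adenylylsulphate kinase). The
conventional cutoff notation "10e-5" is read as 1e-5; the literal
reading (1e-4) is available via the `cutoff` argument.

## The synthetic community generator

The generator emulates the statistical structure the curation
procedures assume, not real sequence evolution:

* **Community.** One dominant lecanoromycete-like genome (GC spread
  0.30–0.55 across contigs: mean 0.425, between-contig SD 0.0417) plus
  low-abundance basidiomycete yeasts and bacteria. Default abundances
  put the yeasts at 1/4 and 1/5 of the dominant coverage in the
  "slurry" preset and at 1/336 and 1/184 in the "bulk" preset, so the
  two presets differ by 84- and 36.8-fold in relative symbiont
  coverage.
* **Contigs.** Lengths are log-normal with median 10 kb (sdlog 0.9),
  truncated to 1–200 kb, drawn until they cover the genome size (total
  overshoots by at most one contig). Per-contig GC is Normal around the
  genome mean; per-contig depth is Normal around the genome depth with
  10% coefficient of variation, with genome depth proportional to
  abundance.
* **Scale.** Genome sizes are scaled-down stand-ins (dominant 3 Mb,
  yeasts 1.2 Mb, bacteria 2 Mb) so that full pipeline runs, including
  sequence emission, complete in seconds; real fungal genomes are an
  order of magnitude larger, but none of the implemented statistics
  depends on absolute genome size.
* **Binning errors.** The dominant genome is split into `k` GC strata
  at unchanged coverage — the "linear cloud". By default one central
  stratum keeps 92% of the genome's length and the tails are split
  across the remaining bins, mirroring the situation where the main bin
  is nearly (but not >92%) complete and small GC-tail fragments hold
  the rest; `anchor_frac = 1/k` gives equal strata instead.
* **Markers.** Each genome shares a kingdom-level catalog (400
  eukaryotic, 120 bacterial markers). A random `completeness_target`%
  subset is observed; `dup_target`% of observed markers get a second
  copy. Markers are anchored at evenly spaced genome coordinates and
  inherit contig membership, so a bin's marker complement tracks its
  share of genome length with minimal sampling noise. Defaults
  (completeness 99%, duplication 0.5%, anchor fraction 0.92) make the
  anchor bin land near 91% completeness — above the gate, below full —
  and the merged genome near 99% with a sub-point contamination change.
* **Hits and annotations.** Homology hits carry the bin's true lineage
  with probability 0.95 by default; e-values are log-uniform with 10%
  drawn above the 1e-20 threshold. Annotation tables are built so the
  secretome cascade provably reproduces planted truth labels, with
  boundary cases (TM ending at 60, fraction exactly 0.60, length
  exactly 300) planted on purpose.

One global seed drives a per-operation derived seed stream, so each
stage is reproducible when re-run alone and the whole pipeline is
byte-deterministic. What the generator does **not** emulate —
tetranucleotide composition, chimeric contigs, strain variation,
assembly-graph artifacts, correlated depth along the genome — bounds
what passing tests show: they validate the decision procedures, not the
upstream assembler or binner.

## A worked pass

```{r pipeline, eval = FALSE}
out <- tempfile("magcurate_run_")
run_pipeline(out, seed = 42)
read_tsv(file.path(out, "merge_report.tsv"))
read_tsv(file.path(out, "enrichment.tsv"))
```

On the default community under seed 42 this reunifies the five-way-split
dominant genome (completeness 90.75% → 99%, contamination 0.25% → 0.5%)
and reports slurry-over-bulk enrichment folds near the design values of
84 and 36.8 for the two yeasts (76.6 and 36.9 under this seed; the
marker-contig depth carries the generator's 10% noise).

## Numerical choices and degenerate inputs

* Strict inequalities throughout where the rule says "more than" /
  "less than": >90 completeness, <5 contamination, e-value < 1e-20,
  neighbor fraction > 0.60, length < 300, rescue e-value < 1e-5.
* Zero passing hits → protein unclassified; all proteins unclassified →
  bin `unassignable` (a record, not an error). A bin with zero marker
  observations scores (0, 0).
* Zero-depth contigs get a missing log10 column in plot tables; depth
  draws are floored at a small positive value so ratios stay defined.
* Ties: dedup and merge-group assignment have total, documented
  tie-break orders; the vote walk has none to break (fraction > 1/2).
* Test and pipeline problem sizes (communities of 1.3–9.4 Mb, 10,000
  annotation rows, 1,000 oracle-checked vote cases) were chosen so the
  default suite completes in well under a minute per file.

## Known limitations

* The marker estimator ignores markers outside the expected catalog, so
  cross-kingdom contamination in a bin depresses nothing: completeness
  and contamination are blind to foreign contigs that carry no shared
  markers. Real estimators see this; the merge acceptance rule
  partially compensates by bounding contamination growth.
* Linear-cloud detection keys on coverage and lineage compatibility
  only; two distinct same-phylum genomes at similar coverage would
  group, and only the marker-based acceptance test would (and in our
  simulations does) reject the merge.
* The enrichment estimate rests on a single marker contig per symbiont
  and inherits its depth noise directly; replicate marker contigs would
  shrink it but are not modeled.
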