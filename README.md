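# magcurate

Curation of low-abundance eukaryotic genomes from metagenomic
assemblies, for people assembling host–symbiont systems (lichens and
similar consortia) where a dominant fungal genome coexists with
symbionts at a small fraction of its coverage.

Shotgun metagenomes of such systems fail in two characteristic ways:
composition-based binning shatters the GC-heterogeneous dominant genome
into several bins forming a "linear cloud" (near-identical coverage,
wide GC range) on a GC–coverage plot, and the symbionts are too shallow
to bin at all unless the preparation protocol enriches them. `magcurate`
implements the decision procedures to curate the result:

* **Majority-vote LCA taxonomy** — per protein, the top 3 homology hits
  with e-value < 1e-20 vote at each rank of a fixed eight-rank ladder;
  a taxon is assigned where its support fraction is ≥ 0.60, and the
  walk stops at the first rank without one. The same vote over protein
  LCAs (up to 200 subsampled proteins per bin) classifies the bin.
* **Marker-based quality gate** — completeness
  `C = 100 · |distinct expected markers observed| / |expected|` and
  contamination `X = 100 · Σ(copies − 1) / |expected|`; a bin is
  retained iff `C > 90` under at least one estimator and `X < 5` under
  every estimator, with the most complete bin kept per taxon.
* **Linear-cloud merging** — bins within 25% relative median coverage
  of a gate-passing seed and with non-conflicting lineages are grouped;
  a merge is accepted iff pooled-marker completeness strictly rises and
  contamination grows by < 1 point.
* **Coverage-ratio enrichment** — per sample, a symbiont's marker (ITS)
  contig depth over the dominant genome's length-weighted median depth;
  between protocols, the fold change of that ratio.
* **Secretome cascade and SSPs** — secreted = secretion signal ∧ (no TM
  segment, or one ending ≤ residue 60) ∧ secreted-neighbor fraction
  > 0.60; SSP = secreted ∧ length < 300 aa; CAZy/MEROPS family count
  matrices across MAGs.
* **Missing-family rescue** — domain hits at e-value < 1e-5, kept by
  strict-majority eukaryote vote over up to 3 reference lineages, then
  assigned to MAGs binned-first, unbinned-but-fungal second.
* **Synthetic community generator** — seeded communities with truth
  tables (contig→genome, marker placements, hit noise, annotation
  labels) to validate every stage end to end.

## Worked example

The headline arithmetic needs nothing but two printed coverage ratios.
In a bulk-lichen metagenome the ITS contig of the yeast *Cyphobasidium*
sat at 1:336 of the dominant fungus's coverage; in a cortex-slurry
preparation of the same lichen, at 1:4:

```r
library(magcurate)
ratio_bulk   <- coverage_ratio(1, 336)   # 0.002976
ratio_slurry <- coverage_ratio(1, 4)     # 0.25
fold_enrichment(ratio_bulk, ratio_slurry)
#> [1] 84
```

The slurry protocol enriched the yeast 84-fold relative to the host.
For *Tremella* (1:184 → 1:5) the same computation prints `36.8`.

The full pipeline on a synthetic community (simulate → qc → taxonomy →
merge → qc → enrich → secretome → rescue, all artifacts as TSV):

```r
run_pipeline("run42", seed = 42)
read_tsv("run42/merge_report.tsv")[, c(1, 3:7)]
#>                  anchor pre_completeness post_completeness pre_contamination post_contamination accepted
#> 1 bin_lecanoromycete_s3            90.75                99              0.25                0.5     TRUE
read_tsv("run42/enrichment.tsv")[, c("symbiont", "ratio_a", "ratio_b", "fold_change")]
#>        symbiont     ratio_a   ratio_b fold_change
#> 1 cyphobasidium 0.002826807 0.2165626    76.61034
#> 2      tremella 0.005845837 0.2159555    36.94175
```

The dominant genome, deliberately split five ways by the generator, is
detected as a linear cloud and re-merged: completeness rises from 90.75%
to 99% while contamination moves by 0.25 points. The recovered
enrichment folds (76.6, 36.9) scatter around the community's design
values (84, 36.8) because each rests on a single marker contig carrying
the generator's 10% depth noise.

A thin command-line front-end is included:

```sh
Rscript inst/scripts/magcurate.R all --outdir run42 --seed 42
```

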