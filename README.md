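# intrapop

Intrapopulation genomics of single-species-dominated metagenomes.

Some natural microbial communities — e.g. the gelatinous biostalactites
("snottites") that grow at acid mine drainage seepages — are ~99% one
chemolithotrophic species. Mapping the community's own shotgun reads back
onto its complete metagenome-assembled genome (MAG) measures the genetic
variability *within* one natural population. `intrapop` is an R package for
that analysis. It is aimed at microbial population genomicists who have a
circular MAG, its gene annotations, long-read (nanopore-style) and
short-read (Illumina-style) alignments, and want to characterize:

* **Scrapyard genome islands** — non-recombinogenic regions that accumulate
  hypothetical proteins (HP), mobile elements (ME) and phage genes,
  concentrate short sequence variants (SSVs), and show scattered GC skew.
* **Variable gene disruptions** — polymorphic IS-element insertions where
  disrupted and intact alleles of a gene coexist in one population.

## What it computes

For a region *R* of length *L* with per-category ORF counts
*n<sub>c</sub>*, the package reports the content statistics
*pct<sub>c</sub>* = 100·*n<sub>c</sub>*/ORF<sub>total</sub> and
*dens<sub>c</sub>* = 10⁴·*n<sub>c</sub>*/*L* (per 10 kbp), SSV density
likewise, and inside/outside fold enrichments (percent basis for gene
categories, density basis for SSVs), with significance from an exact
Mann–Whitney U test (full enumeration of all C(m+n, n) labelings when
there are no ties and m+n ≤ 20; tie-corrected normal approximation with
continuity correction otherwise).

Insertion calling from long reads follows the SV-signal recipe: CIGAR
insertions ≥ 10 bp and soft clips ≥ 100 bp on reads ≥ 1 kbp are clustered
by breakpoint; a site is a **variable** disruption when both the
insertion-bearing and the intact allele are supported by ≥ 2 reads. The
inserted consensus is classified against an IS library by local alignment,
and the disruption ratio *y/n* (disrupted : intact junction-spanning short
reads) estimates *f*/(1−*f*) for an insertion at population frequency *f*.
SSVs are called by a transparent pileup (depth ≥ 10, alt reads ≥ 2, alt
fraction ≥ 0.1). GC skew (G−C)/(G+C), its sign-flip "scatter" statistic,
and Nei–Gojobori (counting-method) dN/dS with Jukes–Cantor correction round
out the toolkit.

A bundled synthetic-population generator (`sim_config()`,
`simulate_genome()`, `simulate_population()`, `simulate_reads()`) emulates
the study system — a ~54% GC circular chromosome with a planted scrapyard,
20 haplotypes carrying SSVs and IS insertions at set frequencies, long and
short reads with realistic error rates — and emits complete ground truth,
so every caller is benchmarked without any downloads.

## Worked example

Simulate a 120 kbp population at the default study conditions (scrapyard
island, five IS insertions at frequencies 0.3–0.7, 20× long / 50× short
coverage) and run the callers:

```r
library(intrapop)
cfg   <- sim_config(seed = 7, genome_length = 120000)
pop   <- simulate_population(simulate_genome(cfg))
reads <- simulate_reads(pop)

calls <- cluster_and_call(collect_insertion_signals(reads$long), reads$long)
calls <- assign_disruption(classify_insertion(calls, pop$elements),
                           pop$genome$features)
calls[, c("breakpoint", "supporting", "spanning", "variability",
          "classification", "disruption")]
```

```
 breakpoint supporting spanning           variability classification      disruption
      14422          9       14              variable       ME:ISFm4              HP
      57946          3       19              variable       ME:ISFm1 FUNCTIONAL-GENE
      92474         16        7              variable       ME:ISFm5      INTERGENIC
      92800         11       12              variable       ME:ISFm2 FUNCTIONAL-GENE
     119008          6        1 possibly-non-variable       ME:ISFm3 FUNCTIONAL-GENE
```

All five planted insertions are recovered at their exact breakpoints and
classified to the correct library element. Four are *variable* (≥ 2 reads
per allele); the last sits too close to the genome end for two spanning
reads, so it is flagged *possibly non-variable*. Disruptions of functional
genes are the headline events; the HP and intergenic hits are reported but
excluded from disruption totals. Genotyping the second call from the short
reads:

```r
genotype_junctions(calls[2, ], reads$short$aln, pop$genome)$formatted
#> "y/n = 0.41"
```

The ratio 0.41 estimates f/(1−f); the implied frequency 0.29 matches the
planted 0.3. Region statistics around the tRNA-anchored island:

```r
v  <- call_ssv(reads$short$aln, pop$genome)
reg <- delimit_by_anchors(pop$genome$features, "tRNA-Ser-CGA", "tRNA-Val-CAC")
st <- region_content_stats(pop$genome$features, v, reg, 120000)
enrichment_ratios(st$inside, st$outside)
```

```
     metric   basis inside outside     fold direction
         HP percent     76   40.00 1.900000    inside
      PHAGE percent      0    0.00 1.000000      none
         ME percent     12    6.25 1.920000    inside
 FUNCTIONAL percent     12   53.75 4.479167   outside
        SSV density     13    2.00 6.500000    inside
```

The island shows the scrapyard signature: HP enriched ~1.9×, functional
genes depleted ~4.5×, and SSVs concentrated 6.5× — the same contrasts
reported for natural populations of *Ferrovum myxofaciens*, whose published
per-region tabulation ships with the package (`ferrovum_island_counts()`).

The file-level pipeline (`simulate_dataset()` to write a dataset,
`pipeline_config()` + `run_pipeline()` to process one) produces
`summary.json`, region and junction tables, `ssv.vcf`, `insertions.vcf`,
`regions.bed` and `skew.tsv`.

## Package layout

* `R/core_io.R` — domain types, GFF3/SAM/VCF/BED/FASTA-FASTQ readers and
  writers, gene-category classification.
* `R/synthetic_data.R`, `R/synthetic_reads.R` — the population generator
  and truth tables.
* `R/stats_kernels.R` — GC skew, skew scatter, exact Mann–Whitney, NG86
  dN/dS.
* `R/ssv_calling.R` — pileup SSV caller, VCF ingest, region densities.
* `R/insertion_calling.R` — insertion signals, clustering, classification,
  disruption assignment, junction genotyping.
* `R/scrapyard.R` — region statistics, enrichment, anchor delimitation,
  de novo island detection.
* `R/pipeline.R` — configuration and end-to-end orchestration.
* `vignettes/intrapopulation-genomics.Rmd` — the methods vignette: models,
  assumptions, parameter defaults and their basis, numerical choices, and
  known limitations.
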