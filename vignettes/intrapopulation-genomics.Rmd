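---
title: "Methods: intrapopulation genomics of single-species metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrapopulation genomics of single-species metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrapop)
```

## The problem

Some natural microbial communities — gelatinous biostalactites at acid mine
drainage seepages are the canonical case — are dominated to ~99% by a single
chemolithotrophic species.  Mapping the community's own shotgun reads back
onto its complete metagenome-assembled genome then measures *intrapopulation*
genetic variability directly, without binning or cultivation.  Two phenomena
dominate that variability:

* **Scrapyard genome islands** — regions with depleted functional gene
  content, accumulated hypothetical proteins (HP), mobile elements (ME) and
  phage genes, strongly concentrated short sequence variants (SSVs), and
  erratically fluctuating GC skew.  They are interpreted as regions of
  locally suppressed horizontal gene flow, where neutral variation escapes
  the homogenizing recombination that sweeps the rest of the genome.
* **Variable gene disruptions** — polymorphic transposon (IS element)
  insertions segregating within one population, so that disrupted and intact
  alleles of the same gene coexist; conserved diguanylate cyclases are the
  most frequently hit class.

`intrapop` implements the full desk-side analysis chain for these phenomena:
SSV calling from short-read alignments, ME insertion calling from long
reads, junction genotyping of disruption ratios, island statistics and
detection, and the supporting statistics (GC skew and its scatter, an exact
Mann–Whitney U test, NG86 dN/dS).  A synthetic population generator with
complete ground truth makes every stage testable offline.

## Coordinate and container conventions

All internal coordinates are 0-based half-open; GFF3 and VCF are read and
written in their standard 1-based dialects, and the conversion is a strict
involution.  Genomes are circular but linearized at position 0 for analysis;
a feature belongs to a region when its *start* lies inside it.  A
tRNA-delimited island spans from the end of the left anchor to the start of
the right anchor, both exclusive — under this convention the characterized
island of the MI1A genome (anchors tRNA-Ser-CGA and tRNA-Val-CAC) has
length 193,839 bp, matching its published tabulation.

Gene content categories (HP / ME / PHAGE / FUNCTIONAL, with tRNA/rRNA taken
from the feature type) are assigned from free-text product annotations by a
case-insensitive keyword lexicon applied in priority order ME > PHAGE > HP.
The exact lexicon behind any published annotation pipeline is unknowable, so
the lexicon is exposed and overridable (`default_category_lexicon()`).

## Region statistics and enrichment

`region_stats_row()` / `region_content_stats()` compute, per region: ORF
counts by category, percent of ORFs, density per 10 kbp, and SSV count and
density.  Two conventions matter:

* The percent denominator is the region's ORF total.  One published
  outside-region tabulation (genome S2.4) carries an ORF total (2,497)
  larger than the sum of its four category counts (2,436); `region_stats_row`
  therefore accepts an explicit `orf_total`, and the bundled table
  (`ferrovum_island_counts()`) carries the published totals.
* Enrichment ratios (`enrichment_ratios()`) compare gene categories on
  their *percent* values but SSVs on their *density* values.  Only this
  combination reproduces the published contrasts simultaneously: SSV
  concentration 6.7× / 5.2× / 2.8× higher inside the island (and 6.1× lower
  in S2.4), HP 1.8–1.9× and ME 1.6–2.5× depleted outside, functional genes
  1.8–3.7× enriched outside.

The three published island-versus-bulk significance values reproduce
exactly through `mann_whitney_exact()`: the functional-gene ("rest of ORF")
percent columns give the exact enumeration p = 2/252 = 0.0079; the HP
percent columns contain a tie, forcing the tie-corrected normal
approximation with continuity correction, p = 0.0119; the ME *density*
columns give the exact p = 4/252 = 0.0159.  (The ME percent columns give
0.032 and cannot be the published 0.016; the density basis is the one that
reproduces the printed value.)  A fourth published value (p = 0.057 for an
alternative-island grouping) is not reproducible from any tabulated
grouping and is deliberately not a target.

`mann_whitney_exact()` enumerates all `choose(m+n, n)` labelings whenever
there are no ties and `m + n <= 20`; otherwise it matches the conventional
tie-corrected normal approximation with continuity correction.  The exact
branch is verified against the reference rank-sum implementation for all
group sizes up to 6.

## GC skew and its scatter

`gc_skew_profile()` computes (G−C)/(G+C) in sliding windows (10 kbp default),
circularly if requested; windows without G or C get value 0 and sign 0.  A
correctly assembled circular chromosome shows exactly two sign changes
(origin and terminus).  "Scattered" skew is operationalized by
`skew_scatter()` as the fraction of adjacent window pairs with differing
nonzero signs; a region is flagged scattered when its flip fraction is at
least twice the genome background.  The statistic is this package's
formalization — the source observation is qualitative.

## SSV calling

`call_ssv()` is a transparent pileup caller: per-column allele counts from
M/=/X operations (with an optional base-quality floor), insertions and
deletions taken from I/D CIGAR operations and reported VCF-style,
left-anchored on the base before the event.  Variants are population
polymorphisms — there is no diploid genotype model; the alt fraction *is*
the frequency estimate.  Default thresholds (depth ≥ 10, alt support ≥ 2,
alt fraction ≥ 0.1, base quality ≥ 10) are this package's choices, exposed
in configuration; the external-caller ingest path (`read_vcf_variants()`)
exists for parity and agrees exactly with the internal caller on error-free
synthetic alignments.  Raising any threshold can only shrink the call set
(tested as a subset property).

## Insertion calling and junction genotyping

Signal extraction mirrors long-read SV calling practice: every CIGAR
insertion ≥ 10 bp yields a signal at its reference anchor, soft clips
≥ 100 bp yield clip signals at the aligned end, and reads shorter than
1,000 bp are ignored (these three gates mirror a minimum-signal,
minimum-length, minimum-read-length parameterization of long-read SV
callers).  Signals are clustered by breakpoint proximity (single linkage,
100 bp); supporting reads are the distinct signal-bearing reads, spanning
reads are those covering breakpoint ± 50 bp without a signal.  A call is
**variable** exactly when both alleles are seen at least twice
(`min(supporting, spanning) >= 2` — the "at least two reads for the less
common variant" rule); otherwise it is *possibly non-variable*.  The
consensus inserted sequence is the medoid by edit distance — breakpoint
accuracy, not base-perfect consensus, is what drives classification — and
is classified against a user-supplied element library by best local
alignment on both strands (identity ≥ 0.8 over aligned columns, consensus
coverage ≥ 0.5).  Disruption classes follow the published
inclusion/exclusion rules: insertions into functionally annotated genes are
the headline disruptions; HP disruptions are reported separately (the
source groups "IS outside ORFs or inside hypothetical proteins" in one
display class, so both totals are derivable); insertions into ME/phage ORFs
and intergenic insertions are excluded from totals.

`genotype_junctions()` rebuilds the three diagnostic sequences (left flank +
element start, element end + right flank, intact flank-through-flank) and
counts reads carrying an exact junction-spanning match with ≥ 20 bp on each
side, in either orientation.  One design point deserves emphasis: the
disrupted allele has *two* junctions while the intact allele has one, so
counting every read that touches either disrupted junction estimates
2f/(1−f), not f/(1−f).  `y` is therefore the average of the two
disrupted-junction read counts, which restores `y/n → f/(1−f)` (verified by
simulation at 200× coverage) while keeping the published report formats
("y/n = 0.32", "n (0/114)").

## De novo island detection

The source delimits its islands by conserved tRNA anchors and describes
their properties without giving an algorithm, so detection is this
package's operationalization.  Overlapping 10 kbp windows (2 kbp step) are
scored on up to four criteria: HP proportion ≥ 0.55, mobilome+phage density
≥ 2.0/10 kbp, SSV density ≥ 3× the genome median window density, and skew
scatter ≥ 2× background.  A window qualifies when it meets **at least two**
of the available criteria.  Two parameter choices came out of validation
on simulated islands rather than first guesses, and are worth recording:

* With 10 kbp windows, a mobilome threshold of 1.0/10 kbp is met by a
  *single* mobilome gene, which ~40% of non-island windows contain by
  chance; this inflated detected islands by tens of kbp.  The 2.0/10 kbp
  default is the smallest threshold above that single-gene noise floor, and
  sits between the characterized inside (~1.6) and outside (~0.5) densities
  once window-level discreteness is accounted for.
* Making the HP criterion mandatory truncates genuine island stretches
  whose HP fraction fluctuates below 0.55 across a ~10-gene window even
  though their SSV concentration is unambiguous; the 2-of-k rule lets the
  strongest published discriminator (SSV concentration, 6.7×) carry such
  stretches.

Window verdicts become per-position votes (a position is flagged when at
least half its covering windows pass); flagged runs are merged across gaps
≤ 20 kbp and islands ≥ 50 kbp are reported with full region statistics.
Detection is monotone: relaxing any threshold never shrinks reported
coverage.  On the default simulated conditions (150 kbp island, 600 kbp
genome) a 25-seed validation panel gave exactly one island per genome with
Jaccard overlap ≥ 0.92 against truth (median 0.97), and no islands on
compositionally uniform genomes.

## dN/dS

`dnds_ng86()` implements counting-method dN/dS: per-codon synonymous site
fractions averaged over both sequences, observed differences in
multi-substitution codons averaged over all minimal mutational pathways
(pathways through stop codons excluded; mutations *to* stop codons count as
nonsynonymous in site counting), and the Jukes–Cantor correction
d = −(3/4)·ln(1 − (4/3)p) applied to both proportions.  The ratio is
reported as undefined when dS = 0 or a correction saturates.  The
implementation is verified against a brute-force codon-pathway enumeration
oracle to 10⁻⁹.  A ratio well below 1 (the source reports 0.36 for a
twice-disrupted diguanylate cyclase) indicates purifying selection on genes
that are nonetheless variably disrupted — the observation motivating the
disruption analysis.

## The synthetic population generator

`sim_config()` defaults *are* the emulated study conditions:

| Parameter | Default | Basis |
|---|---|---|
| GC content | 0.541 | characterized genome composition |
| Island composition (HP/ME/phage/functional) | 0.717/0.090/0.037/0.156 | island ORF table |
| Bulk composition | 0.374/0.042/0.005/0.579 | outside-region ORF table |
| SSV rate inside / outside | 11.9 / 1.77 per 10 kbp | SSV density table |
| Haplotype pool | 20 | modeling choice (source gives no count) |
| SSV frequency law | Uniform(0.05, 0.95) | modeling choice |
| Insertion frequencies | 0.3, 0.5, 0.7, 0.4, 0.6 | published disruption ratios imply f ≈ 0.22–0.60 |
| Long reads | lognormal, mean 8 kbp; 2%/3%/4% sub/ins/del | nanopore-scale error model |
| Short reads | 2 × 250 bp, 0.3% substitutions | the sequencing technology used |

Reads are sampled from a finite haplotype pool rather than per-read
Bernoulli draws, so linked variants co-occur as in a clonal population.
IS elements carry 15–25 bp terminal inverted repeats and insertions
duplicate a 4–8 bp target site, so junction genotyping faces realistic
micro-homology.  Each stage draws from its own seeded RNG stream, making
every stage reproducible in isolation; the same seed reproduces the output
files byte for byte.

The generator's truth SAM stands in for an external long-read mapper: its
CIGARs expose planted insertions as I operations (or soft clips at read
boundaries), and 1 bp error indels are folded into the CIGARs so the
SAM length contract holds exactly.  What the generator does **not**
emulate: homopolymer-biased nanopore errors, long indel errors, chimeric
reads, inter-species contamination, mapping ambiguity in repeats, and
coverage bias.  Passing tests therefore demonstrate algorithmic
correctness under idealized mapping, not robustness to every artifact of
real mappers — the pipeline accepts real mapper SAM for that.

## Problem sizes used in tests and reporting

The bundled checks run the generator at 60–600 kbp (callers benchmarked at
50× short-read and 20× long-read coverage on 120–300 kbp genomes; island
detection at its default 150 kbp island in 600 kbp genomes).  These sizes
were chosen so the whole suite exercises every claim in a few minutes while
leaving every per-window and per-read quantity at its full-scale value;
all statistics are intensive (densities, fractions, ratios), so genome
length only sets the sampling noise, which the tests bound explicitly
(3σ criteria).

## Known limitations

* The category lexicon approximates an unpublished annotation vocabulary;
  category-dependent statistics on real annotations inherit that
  approximation.
* The pileup SSV caller does no local reassembly; dense variant clusters
  within one read footprint are called per-column, and MNVs arrive only via
  the VCF ingest path.
* Junction genotyping uses exact probe matching; at the default 0.3%
  short-read error rate ~11% of junction reads are silently dropped, which
  is allele-symmetric and leaves the ratio unbiased but widens its
  confidence interval.
* Insertion consensus is a medoid, not a polished assembly; classification
  thresholds (0.8 identity / 0.5 coverage) absorb that roughness.
* De novo detection reports content boundaries; when a true island's edge
  is compositionally unremarkable for tens of kbp (a real possibility at
  ~12 genes per window), those stretches are honestly assigned to the bulk.
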