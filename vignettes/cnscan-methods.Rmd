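---
title: "cnscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cnscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnscan)
```

## The problem

Conserved noncoding sequences (CNSs) are stretches of DNA outside
protein-coding regions that evolution has kept nearly intact across
species, the classic signature of purifying selection on regulatory
elements.  In plant genomes — where noncoding annotation lags far behind
exon annotation — a simple and robust way to find them is phylogenetic
footprinting over a reference-anchored multiple alignment: align many
related genomes to one reference (e.g. rice for the grasses), score every
reference base by how many species retain it, and call contiguous
high-scoring noncoding segments.

`cnscan` implements that pipeline end to end: alignment ingestion (MAF),
per-base per-clade scoring, CNS calling, gene-level scores and positional
profiles, population-level selection statistics against SNP data (VCF),
IUPAC motif enrichment, and a synthetic-data generator used as ground
truth by the test suite.

## The conservation score

For a clade $C$ of $n$ non-reference species, the score of reference
position $i$ is

$$ s_i = \frac{m_i}{n}, \qquad
   m_i = \#\{\, c \in C : \text{the aligned base of } c
         \text{ at } i \text{ equals the reference base} \,\} $$

so $s_i = 1$ means the site is retained identically in every compared
species and $s_i = 0$ that no species shows it.  Three choices deserve
spelling out:

* **Identity, not mere alignment.**  A species counts toward $m_i$ only
  when its aligned base is identical (case-insensitive) to the reference
  base.  Downstream invariant-site analysis ("columns with no
  mismatches") only makes sense under identity counting.  For
  sensitivity analysis `score_genome(..., match_mode = "aligned")`
  counts any aligned base.
* **Fixed denominator.**  $n$ is the clade size, not the number of
  species aligned at the site: an unaligned species is evidence of
  non-conservation, not missing data.  The reference itself is never
  counted (it would add a constant self-match).
* **Exact rationals at thresholds.**  Counts are stored as integers and
  every threshold comparison is done as
  $m \cdot 10^6 \ge \lfloor t \cdot 10^6 \rceil \cdot n$, so a site with
  $m/n$ exactly at the threshold can never flip sides through
  floating-point noise.

`N` (or any non-ACGT character) never matches on either side: unknown
bases cannot evidence conservation.  If two alignment blocks give one
species two bases at the same reference position — which single-coverage
chain/net filtering upstream should prevent — the earlier block in file
order wins, deterministically, and a warning reports the count.

## CNS calling

With the default parameters (all exposed, none hidden):

1. mask CDS-labeled bases;
2. take maximal runs of non-CDS bases with $s_i \ge 0.7$;
3. merge runs separated by $\le 3$ bp, **unless** the gap contains a CDS
   base — a CNS never bridges coding sequence;
4. drop merged fragments shorter than 6 bp.

The mean score of a merged CNS averages over *all* its bases including
the sub-threshold gap bases; the interval is reported as one element and
per-base provenance stays in the track.  The 0.7 threshold is where coverage
curves for coding versus noncoding sequence typically stabilize; it is a
convention, not a law, hence a flag.

Each CNS is categorized whole (not split) by majority base overlap among
5'-UTR, 3'-UTR, intron and intergenic, with ties broken in that fixed
order, so that per-category percentages always partition the CNS count.  When transcripts overlap, per-base labels
follow the precedence CDS > UTR5 > UTR3 > intron > intergenic.
Masking happens *before* merging: mask-first is the only order under
which "noncoding" holds for every intermediate of the pipeline.

Reported mean lengths are `round(total_length / total_number)` to the
nearest bp; the median of an even count is the lower middle value.

## Gene scores, downstream association, bigfoot genes

A gene's score is the mean $s_i$ over its span — TSS to TES, introns and
UTRs included ("every base within the gene"); an exon-only mode sits
behind a flag.  For multi-transcript genes the span is the union extent
and TSS/TES are the extreme 5'/3' transcript coordinates, which is
deterministic without expression data.  Genes at or above 0.9 form the
highly-conserved set (the boundary is inclusive); per-clade exclusive
sets are plain set differences.

"Genes downstream of a CNS" is read cis-regulatorily: a gene is
associated when its TSS lies within 1 kb downstream of a CNS *on the
gene's strand*; the mirrored reading is available via a flag.  "Bigfoot" genes have a span above 4 kb
and at least six CNSs overlapping the span ± 1 kb; both numbers are
parameters, as is the flank.

## Population-level selection statistics

SNP sites are classed by conservation score: nonconserved $[0, 0.2]$,
conserved $[0.7, 0.9)$, extreme $[0.9, 1.0]$ — the conventional ranges
touch at 0.9, which is assigned to extreme so the classes partition;
$(0.2, 0.7)$ is deliberately unclassified.  Folded minor allele
frequencies ($\mathrm{MAF} = \min(p, 1-p) \le 0.5$) are binned into a
rare bin $[0, 0.01)$ plus ten equal bins up to 0.5.  Multiallelic
records are excluded from MAF analyses (folding is ill-defined with more
than two alleles) and counted.

SNP depletion is the genome-wide SNP density divided by the density
inside constrained regions; invariant sites are positions with
$m_i = n$, and their SnpEff-style effect strings (consumed from the
`ANN` field, never computed) are tabulated one count per effect record.
Intra- vs inter-specific variation is, per gene, the SNP count in the
span versus the number of span positions with at least one aligned,
mismatching species (a species-summed mode exists behind a flag); the
Pearson correlation is reported with a t-approximation p-value.

## Motif enrichment

Motifs are IUPAC patterns scanned over every (position, strand) window;
overlapping hits all count and a palindromic site counts once per strand
(a dedup flag collapses strands).  `N` in sequence satisfies only the
pattern letter `N`.  The background is the genome with CNS bases
excised, keeping the 2×2 contingency tables disjoint.  With background
rate $p$ estimated from the background scan,

$$ z = \frac{\mathrm{obs} - p\,n_w}{\sqrt{n_w\,p(1-p)}} $$

over the $n_w$ scanned windows, plus the 1-df chi-squared from the 2×2
table without continuity correction.  "Enriched" means $z > 2$,
strictly.  The binomial-per-window null is the package's adopted choice,
with two documented limitations: it ignores the
positive correlation among overlapping windows (low-complexity motifs
such as `AAAAA` clump, inflating variance) and it treats the estimated
$p$ as known, which is safe only while the background is much larger
than the scanned CNS set (variance inflation is $1 + n_w/n_{bg}$).  The
calibration test therefore uses PLACE-like motifs (5–6 bp, ~10%
degenerate positions) and a background 20× the test set, each motif in
its own independently generated null world.

## The synthetic world

The generator plants what the pipeline must find, with truth files for
every claim:

* a uniform-random reference chromosome (default 100 kb) with gene
  models (default 20 genes, 3 exons of 300 bp, 400 bp introns, 150/250
  bp UTRs — compact but rice-like geometry);
* conserved elements (default 60, 20–150 bp, kept out of CDS and at
  least 20 bp apart so distinct elements cannot merge during calling)
  where every species aligns and matches the reference with probability
  0.95 per base;
* background where each species joins a ~90 bp alignment block with
  probability 0.6 and, when aligned, matches at 0.5 per base.  The
  alignability parameter is essential realism, not a tuning knob: if all
  ten species aligned everywhere at match 0.5, ~17% of background bases
  would clear the 0.7 threshold by chance (binomial tail) and ~16% of
  background bp would be called CNS after merging, which no real
  reference-anchored plant alignment resembles — most noncoding sequence
  simply fails to align across genera, which is exactly why a
  fixed-denominator score is informative.  CDS aligns at 0.95 and
  matches at 0.9.
* SNPs whose genome-average density (default 0.01/bp; the depletion
  test uses 0.05/bp, the density of large rice population panels) is
  depleted inside constrained regions by a configured fold — the inside
  rate is solved from
  $r_{in} = \bar r / f$ with $\bar r$ the genome average, so the planted
  truth fold is *exactly* $f$; folded MAFs are drawn per conservation
  class from $0.5\,\mathrm{Beta}(a, b)$ with defaults making rare
  alleles (MAF < 0.01) increasingly common from nonconserved to extreme
  sites; AC/AN are emitted for AN = 6000 (3,000 diploid genomes);
* motif instances written into the reference inside elements, plus
  SnpEff-style `ANN` strings on a configurable fraction of SNPs.

Every stage draws from its own RNG substream derived from the master
seed, so adding an output never perturbs the others; the same seed gives
byte-identical files.  What a green test does **not** establish: the
generator has no phylogeny (species are i.i.d. given the reference, so
no tree-correlated substitutions), indel-free blocks by default (a
per-base gap probability exists and exercises the unaligned path),
no repeats, no GC structure, and uniform SNP placement within a region
class.  Conclusions about real genomes still require real alignments.

For the intra/inter correlation recovery, per-gene counts are drawn from
a bivariate Poisson-lognormal whose latent correlation is calibrated in
closed form so the *count-scale* Pearson correlation hits the target
(Poisson noise and lognormal skew would otherwise attenuate it), and the
counts are materialized as genes, SNPs and a track so the measurement
runs through the real `variation_correlation()` path.

## Numerical and degenerate-input conventions

* All internal coordinates are 0-based half-open; GFF3/VCF (1-based) and
  BED/bedGraph/MAF (0-based) conversions happen only at I/O boundaries.
* Empty region classes report `NA` fractions, never 0; zero constrained
  SNPs report an infinite depletion fold; a constant count vector makes
  the correlation `NA`, never an error.
* Score-threshold ties: `>=` everywhere ("at least 0.7", "at least
  0.9"); the enrichment flag alone is strict (`z > 2`).
* bedGraph output merges runs of equal value and prints 10 significant
  digits so tracks round-trip.

## Known limitations

Scoring holds per-species visited masks in memory (fine up to a few Mb
of toy genome per clade; a real 400 Mb genome would want a chunked
implementation).  The CLI maps error classes to exit codes by message
matching.  YAML configs are not supported (flat key=value or JSON only).
GO enrichment, repeat masking, lncRNA/miRNA discovery, and the upstream
aligner/chainer/netter are out of scope by design.
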