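---
title: "Methods: bulked-segregant QTL-seq with simulation-based confidence bands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant QTL-seq with simulation-based confidence bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The mapping strategy

Bulked-segregant analysis with pooled whole-genome sequencing (QTL-seq)
maps a quantitative trait locus by comparing the allele frequencies of two
DNA pools built from the phenotypic extremes of a segregating population.
`bsaqtl` implements this strategy for a biparental selfing design carried
to the F3 generation, together with a synthetic-data generator that
simulates the whole experiment with known ground truth, so every stage of
the pipeline can be validated without raw sequencing data.

The pipeline has five computational stages:

1. **Phenotype statistic.** Lines are scored by a relative-response ratio
   computed from fresh weights under a treatment and its control,
   normalised to a reference accession grown alongside:
   \[
   \mathrm{RR}_i \;=\; \frac{G^{trt}_i / G^{ctl}_i}{G^{trt}_{ref} / G^{ctl}_{ref}} .
   \]
   RR is dimensionless and scale-free; the reference has RR = 1 by
   construction. By default replicate weights are averaged per condition
   before the ratio is formed; a per-replicate mode (ratio within each
   replicate, then averaged) is available because the raw-data layout does
   not dictate either choice. On balanced data with identical replicates
   the two modes coincide; with heteroscedastic replicates they differ
   slightly, and condition-means is the default because it is the more
   common aggregation for plate-grown biomass data.

2. **Tail selection.** Lines are ranked by RR; the lowest tail forms the
   hyper-sensitive bulk and the highest the hyper-resistant bulk. The tail
   is specified either as a fraction (default 10%) or as an explicit count.
   The emulated design pools 42 lines per 10% tail of 400 F3 — slightly
   more than 400/10; since either convention is defensible the bulk size is
   an explicit parameter (default 42) rather than something derived from
   the fraction. Ties at a tail boundary are broken by a stable sort on
   (value, line id), and both tails come from the same ordering, so bulks
   are deterministic, disjoint, and invariant under any strictly monotone
   transform of the phenotype.

3. **SNP-index track.** For each biallelic site, the SNP-index of a pool is
   the fraction of its reads carrying the non-reference allele, and
   \(\Delta\mathrm{SNP}\text{-}\mathrm{index} = \mathrm{index}_S - \mathrm{index}_R\)
   (sensitive minus resistant). Far from any QTL both bulks are random
   draws of segregants and \(\Delta\) fluctuates around 0; at a QTL linked
   to the selected trait the bulks are enriched for opposite parental
   alleles and \(\Delta\) moves toward \(\pm 1\). Sites with fewer than 10
   reads in either pool are dropped by default: the variance of a
   read-fraction scales as \(1/\mathrm{depth}\), so a handful of very
   shallow sites would otherwise dominate window averages. An optional
   combined-index floor can remove monomorphic-reference artifacts; it is
   off by default. Only the two-pool allele counts enter the statistic —
   genotype likelihoods and indels are out of scope.

4. **Sliding-window scan.** Indices and \(\Delta\) are averaged in 1 Mb
   windows advanced in 10 kb steps. Windows are anchored at position 1;
   partial terminal windows are dropped by default (a `keep_partial` switch
   retains them) so every window mean is comparable. Averages are
   unweighted arithmetic means over the retained sites in the window;
   windows without sites are reported missing rather than interpolated or
   zeroed.

5. **Null confidence bands and region calls.** Significance is judged
   against Monte-Carlo bands built under the no-QTL null for the actual
   experimental design: each replication draws two independent bulks of 42
   unselected F3 genotypes, converts each bulk to its pool allele
   frequency, adds binomial read noise at a fixed depth, and records
   \(\Delta\). 10,000 replications per depth over an integer depth grid of
   80–120 give the two-sided equal-tail 95% and 99% empirical quantiles per
   depth. Windows whose mean \(\Delta\) falls outside the band for their
   depth are significant; overlapping or adjacent significant windows of
   the same sign merge into candidate regions, and a gap of at least one
   full window of non-significance (or a sign change) splits them.

# The null model in detail

F3 genotype frequencies at any locus are \((3/8, 1/4, 3/8)\) for dosages
\((0, 1, 2)\): an F2 population is \((1/4, 1/2, 1/4)\) and one round of
selfing halves the heterozygote class. Two null sampling schemes are
provided: i.i.d. F3 draws (default) and an explicit two-stage
F2-then-selfing draw (`one_per_family`); they are marginally identical,
and the second is retained for fidelity to the one-progeny-per-family
population design. The variance of the null \(\Delta\) decomposes by the
law of total variance into a finite-bulk composition term,
\(2\,\mathrm{Var}(d)/(4 n_{bulk})\) with \(\mathrm{Var}(d) = 3/4\), and a
read-sampling term, \(2\,E[f(1-f)]/\mathrm{depth}\); the test suite checks
the simulated variance against this enumeration and the infinite-bulk
limit against the exact binomial difference distribution.

Two readings of the emulated design's pool size are possible ("84 pooled"
could mean 84 per bulk or 42 + 42). The default is 42 individuals per bulk
— two bulks of 42 total 84, matching the tails actually pooled — and
`bulk_size` is exposed so the other reading is one argument away.

Bands are reported exactly as simulated (empirical quantiles, no smoothing
across depth and no symmetrisation), which preserves any genuine skew at
the cost of small Monte-Carlo asymmetries (\(|q_{lo}| \ne q_{hi}\) by a few
thousandths at 10,000 replications). Band lookup for a window uses the
window's mean pooled depth, clipped to the simulated grid and rounded to
the nearest grid depth with ties going down; clip events are counted so a
grid that badly misses the data is visible.

Because read noise is part of the simulated statistic but is averaged
~100-fold inside a 1 Mb window (at the default 10 kb marker spacing), the
per-site band is conservative for window means: under the null roughly 1%
of windows, rather than 5%, cross the 95% band. The calibration tests
therefore check nominal coverage where it is exact — per site, and for
window scans in which each non-overlapping window holds a single site —
and treat the windowed scan's conservatism as a feature shared with the
standard QTL-seq plotting convention, which draws per-depth site bands
over window-averaged curves.

# The synthetic experiment generator

The generator simulates the full design forward from meiosis:

* **Genetic map.** Five 20 Mb chromosomes with markers every 10 kb and a
  uniform 4 cM/Mb — an Arabidopsis-scale genome at desk scale (the real
  genome's five chromosomes are 18–30 Mb with a similar genome-wide
  average recombination rate). Arbitrary maps (non-uniform cM, any marker
  set) are accepted.
* **Meiosis.** Haldane's model: crossover counts per chromosome are
  Poisson with mean equal to the genetic length in Morgans, crossover
  positions uniform in genetic distance, no interference. This is the
  standard analytically checkable choice; the recombinant fraction between
  two markers d cM apart is \((1 - e^{-2d/100})/2\), which the tests
  verify at 1, 10 and 50 cM.
* **Population.** Two inbred parents differing at every marker; the F1 is
  selfed to 400 F2, each F3 is produced by selfing its F2 parent, one
  progeny per family by default (400 F2 to 400 F3). Family ids are kept:
  family structure is what makes the bulks draws of related individuals in
  larger-family designs.
* **Trait.** One planted QTL at a marker (the nearest marker at or left of
  the requested bp position, avoiding off-marker bookkeeping):
  `baseline + a (dosage - 1) + d [dosage = 1] + N(0, sd)`. Defaults put
  the QTL at Chr2:18.5 Mb with `a = -0.3`, `sd = 0.15` and baseline 0.85 —
  a strong single locus (additive effect twice the residual SD) on an
  RR-like scale spanning roughly 0.25–1.5 across the population, with the
  alternate parent's allele conferring sensitivity.
* **Pooled sequencing.** Per site, the depth is Poisson (mean 100 per pool
  by default, inside the 80–120 band-calibration range); each read picks a
  pool member uniformly, then an allele with probability dosage/2, then
  flips with the error rate (0 by default). The two-stage scheme carries
  the finite composition of the actual bulk; because members are chosen
  independently per read it coincides in distribution with binomial
  sampling at the realized pool frequency, which is what the null
  simulation uses — a cross-module test asserts the agreement.

All randomness flows from one master seed through named child streams
(`f2`, `f3`, `phenotype`, `poolseq:S`, …), so any stage can be reproduced
in isolation and identical configurations give bit-identical outputs.

What the generator does **not** emulate: alignment and variant-calling
artifacts (mapping bias, paralogy, genotyping error beyond a symmetric
per-read flip), non-crossover interference, segregation distortion,
polygenic backgrounds, uninformative markers where both parents carry the
same non-reference allele, and uneven marker density. Passing tests
therefore demonstrate the statistical machinery under an idealised
segregation-and-sampling model, not robustness to upstream calling noise;
real inputs should arrive as filtered biallelic counts polarized against
the reference accession.

# Region-call semantics with a strong QTL

With a major QTL and sharp truncation selection, the bulks are nearly
fixed for opposite alleles at the locus, and the expected \(\Delta\)
decays with genetic distance over tens of cM. On a 20 Mb (80 cM)
chromosome the signal can therefore exceed the band far from the QTL and
hover near the threshold at the edges of that span, occasionally
fragmenting into more than one called interval; independently, ~1% of
null windows cross the per-site band, so a 95-Mb genome can produce a
flanking excursion. The recovery guarantee the package tests is
accordingly stated on coverage: called regions are disjoint, exactly one
of them contains the planted QTL, and the genome-wide peak window lies
within 2 Mb of the truth. At the 99% level null excursions are rare
(about 0.1% of windows) and a no-QTL genome is clean in almost every run.

# Numerical and interface choices

* Empirical quantiles use R's default (type 7) interpolation; with 10,000
  replications a 99% band has 25 expected exceedances per tail, and a
  warning is raised when a requested level would leave fewer than 20.
* Coordinates are 1-based inclusive everywhere internally and in TSV;
  only BED output converts to 0-based half-open, at the writing boundary.
* Chromosome names are reconciled against annotations through an explicit
  alias map; the package never guesses.
* Multi-allelic VCF records are skipped and counted, never coerced.
* Writers emit `# key: value` provenance headers (config hash and seed,
  no timestamps); readers skip and preserve them. Pipeline reruns with the
  same configuration are byte-identical, which the tests check by file
  hash.
* Problem sizes in the bundled analysis scripts and tests — 400 F3, 42 +
  42 bulks, 10,000 markers over 100 Mb, 10,000-replication bands — are the
  emulated study's own design points, run at full size.

# Known limitations

* The null bands are pointwise per depth; no genome-wide multiplicity
  control (FDR across windows) is attempted, matching standard QTL-seq
  practice where the 95%/99% bands are read as plotting thresholds.
* Only selfing-series designs (F2/F3) are modelled; backcross or
  outcrossing designs would need a different null genotype vector,
  although the machinery accepts any dosage distribution internally.
* The read model treats reads as independent draws; duplicated fragments,
  overlapping mates and mapping bias are not represented.
* \(\Delta\) is computed sensitive-minus-resistant by convention; since
  every band is two-sided, the convention affects signs in reports but
  never which regions are called.
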