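---
title: "Models and methods behind methylrrbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylrrbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`methylrrbs` implements the downstream half of a reduced representation
bisulfite sequencing (RRBS) study: everything that happens after a
per-cytosine methylation caller has produced count files. This vignette
explains the statistical model of each stage, the tunable parameters and
their defaults, what the bundled synthetic-methylome generator does and does
not emulate, and the numerical conventions used throughout. The motivating
design is a hypothalamus methylome study across three pubertal stages in
gilts (Pre-, In-, Post-puberty, three animals each), but every stage is
generic RRBS methodology.

## Site model and filtering

A *site* is a single cytosine, identified by chromosome, 1-based position
and strand; the two cytosines of one CpG dinucleotide are always two sites,
never merged, matching the granularity of CGmap-style callers. A site's
methylation level is `methylated reads / total reads`. Sites are retained
for analysis only when they are covered by at least `min_cov` reads
(default 5) in *every* sample — the co-existence rule. This is deliberately
strict: all downstream group comparisons assume a complete site-by-sample
matrix, so no imputation or missing-data handling is needed.

Two distinct level estimators are used, on purpose:

* the **group level** of a site is the unweighted mean of its replicate
  levels — not the pooled-read ratio. With coverages (100, 10, 10) and
  levels (0.01, 0.9, 0.5) the group level is 0.47 while the pooled ratio
  would be 0.125; averaging replicate ratios weighs animals equally rather
  than reads.
* the **site-level test** (below) pools reads within a group, because a
  2x2 exact test needs raw counts.

## CpG-island calling

Islands follow the classic sequence-composition definition: length
strictly greater than 200 bp, GC fraction strictly greater than 0.5, and
observed/expected CpG ratio strictly greater than 0.6, with
`expected = (#C x #G) / length`. `N` bases count toward length but not
composition, and no island spans a run of `N`.

The definition says what an island *is* but not how to pick maximal
regions, so the algorithm is a package design choice. On short N-free
blocks (up to `exhaustive_limit`, default 5 kb) `call_cgis()` selects,
exhaustively, the longest qualifying sub-segment (leftmost on ties) and
recurses into the flanks; this makes the caller provably equal to an
exhaustive-substring oracle on small inputs, which is how it is tested. On
longer blocks a 200-bp sliding-window screen (GC and O/E criteria) first
merges qualifying windows into candidate regions, and the same exhaustive
selection runs inside each candidate. The window screen bounds how far an
island can bleed into a flank; on unscreened small inputs the maximal
qualifying sub-segment necessarily absorbs some flank, since diluting GC
from, say, 0.66 toward 0.50 takes hundreds of bases. Recovery of planted
islands is therefore asserted at 80% reciprocal overlap, not exact
boundaries.

Shores are the 2 kb flanks of islands and shelves the next 2 kb, clipped
to the chromosome, with precedence island > shore > shelf so the classes
partition the genome together with the remaining open sea. In a real
analysis the islands themselves are typically an input (a downloaded
annotation track); the caller exists so that synthetic and
annotation-free genomes can be processed end to end.

## Genic annotation

Each site receives exactly one of five genic labels with precedence
`exon > intron > upstream > downstream > intergenic`. Upstream is the 5 kb
region before the TSS and downstream the 5 kb after the TES, both
strand-aware. The precedence rule is needed because flanks of one gene can
overlap another gene; gene-body-first is the convention that makes the
five labels a true partition (the published per-feature site counts sum
exactly to the total, which is one of the package's acceptance checks).
Separately from this partition, every site carries a CGI-related label and
a QTL membership flag (QTL intervals are merged before testing so
overlapping QTLs never double-count a site). For "regarding-gene" rules a
gene's *extended span* is its body plus 5 kb on both sides; a site may lie
in several extended spans.

## Differential methylation

**Sites (DMCs / DMHs).** For a stage comparison A vs B, reads are pooled
across the three replicates within each group and the 2x2 table of
methylated/unmethylated counts is tested with a two-tail Fisher exact test
(the two-sided p is the sum of hypergeometric probabilities of all tables
at most as probable as the observed one; implemented in vectorised form
and verified against full enumeration). The methylation difference `delta`
is the difference of pooled ratios. P-values are Benjamini–Hochberg
adjusted within each context (CpG / CpH) of each comparison, and a site is
called differentially methylated when `q <= 0.05` *and* `|delta| > 0.20`
(strictly more than a 20% change). Pooling replicates before the exact
test is a stated design choice: a 2x2 exact test has no replicate
dimension, and the delta threshold guards against pooled-count artefacts.
The polarity labels mark the group with the higher level as
hyper-methylated.

**Regions (DMIs / DMGs).** Islands, and genes extended by their 5 kb
flanks, are tested when they contain at least 20 covered sites of the
tested context. Each replicate contributes its mean site level in the
region; the two groups of three replicate means are compared with the
classical pooled-variance Student's t (df = 4), with Welch available via
`var_equal = FALSE`. Degenerate inputs follow explicit conventions: zero
pooled variance with equal means gives p = 1, with unequal means p = 0
plus a flag. FDR adjustment runs across the tested regions of each
(kind x context x comparison) call, and significance alone (`q <= 0.05`)
defines a DM region — no delta threshold, unlike sites.

## Enrichment

For each feature class the 2x2 table `[[dm_in, dm_out], [nondm_in,
nondm_out]]` is tested against the class' complement with the same
two-tail Fisher test. The reported *relative enrichment* is the proportion
ratio `(dm_in / dm_total) / (sites_in / sites_total)`; this definition
exactly reproduces the published QTL-row enrichment values from their
printed counts, which is why it is the headline statistic, and the sample
odds ratio is emitted alongside for transparency. (For some published
non-QTL rows neither the proportion ratio nor the odds ratio reproduces
the printed value from the printed counts; the formula behind those rows
is not recoverable, so they are not used as checks.) Display rounding is
half-up to 2 decimals.

## The synthetic methylome generator

The generator exists so that every stage has a ground-truth test without
any external data. Its defaults describe the emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_chrom`, `chrom_length` | 2 x 1.5 Mb | desk-scale genome (~2e4 CpG, ~5e4 CpH covered sites) |
| `background_gc` / `island_gc` | 0.40 / 0.66 | background fails the island criteria with margin; islands pass them by construction (iid composition, O/E near 1) |
| `n_genes`, `n_cgis`, `n_qtls` | 80, 120, 8 | 60% of islands anchored at a TSS (900 bp upstream, 100 bp into the body), mimicking promoter islands |
| `frag_min`, `frag_max` | 110, 220 bp | MspI size selection; only cytosines inside retained inter-cut fragments are ever observed |
| `mean_coverage`, `coverage_dispersion` | 20, 5 | negative-binomial per-site coverage (size 5 gives RRBS-like overdispersion); pooled group coverage ~60 |
| `cpg_level_island`, `cpg_level_open` | 0.22, 0.87 | bimodal CpG methylation; roughly half the covered CpGs are island sites, so the site-averaged genome level lands near 53% |
| `cph_level` | 0.007 | very low CpH methylation |
| `stage_deltas` | 0, -0.005, -0.015 | small monotone Pre > In > Post decrease, applied additively to CpG levels and rescaled by `cph_level / cpg_level_open` for CpH (an additive -0.015 would clip the 0.007 CpH baseline to zero) |
| `beta_binomial_rho` | 0.01 | replicate-level Beta perturbation of the site probability, giving the region t-test genuine between-replicate variance |
| `dm_site_fraction`, `dm_effect` | 0.02, 0.5 | planted sites are shifted by +/-0.5 in *one* target stage, so each is truly differential exactly for the two comparisons involving that stage |
| `dm_region_count`, `dm_region_effect` | 12, 0.3 | islands get +0.3, genes -0.3, again in one target stage |

Coverage model, replicate noise and comparison-specific planting are
generator design choices — the emulated study describes no read-level
model. Effect signs keep probabilities inside [0, 1]: open-sea CpG sites
(baseline 0.87) receive negative site effects, island and CpH sites
positive ones.

What the generator does *not* emulate: read-level FASTQ data, bisulfite
conversion errors, alignment and mapping artefacts, SNP-induced miscalls,
chromosome-scale composition heterogeneity, and the real genome's size
(three orders of magnitude larger). Passing tests on synthetic data
therefore validate the arithmetic, the calling rules and the statistical
calibration of the pipeline — not its behaviour under alignment artefacts
or genome-scale compositional structure.

One scale consequence matters for interpreting the bundled experiments:
at ~18,000 CpG sites, a few hundred planted +/-0.5 effects concentrated in
single stages perturb the genome-wide mean by the same order as the
0.005-0.015 global drift. The global-ordering experiment (Pre > In > Post)
is therefore run on a configuration with the default stage deltas but no
planted differential effects, which isolates the property being asserted;
on a genome the size of a real one the drift would dominate and the
separation would not be needed. For the same reason the FDR-calibration
experiment uses a null configuration (no deltas, no plants).

## Numerical conventions

* Sites are 1-based; intervals are 0-based half-open (BED). A site at
  position p lies in interval [s, e) iff s <= p-1 < e.
* Binned profiles: genes use 20 fixed 250-bp upstream bins, 40
  length-proportional body bins and 20 downstream bins; islands use
  20/20/20 with 2 kb flanks. Bin 1 is always 5'-most (minus-strand genes
  are flipped); a site exactly on a bin boundary goes to the lower bin
  (`ceiling` rule); flank bins beyond a chromosome end simply receive no
  sites; regions shorter than their body-bin count are skipped with a
  warning; a site inside two regions' spans contributes to both profiles.
* Window tracks tile each chromosome from 0 with a fixed width (default
  1 Mb; the desk-scale experiments use 100 kb so that ~30 windows support
  a correlation); intervals are counted at their midpoint.
* All thresholds (`min_cov = 5`, `delta_min = 0.20`, `q_max = 0.05`,
  `min_sites = 20`, 5 kb / 2 kb flanks) are arguments, never hard-coded;
  `delta_min` is strict, `q_max` inclusive.
* Ties in the Fisher two-tail summation use the customary `(1 + 1e-7)`
  relative tolerance when comparing table probabilities.
* Every random step derives its seed deterministically from the
  configuration seed, so identical configurations give byte-identical
  outputs, including written files.

## Known limitations

* The site-level test treats pooled replicates as one binomial sample;
  with strong replicate overdispersion it is anti-conservative at the
  p-value level, mitigated in practice by the delta threshold and FDR
  step (the null-configuration experiment confirms calibration at the
  default `rho = 0.01`). A beta-binomial site model is out of scope.
* The CGI caller guarantees oracle-exact behaviour only on short N-free
  blocks; at genome scale the window screen is a heuristic, and island
  boundaries can shift by up to ~200 bp into GC-moderate flanks.
* Region tests with three replicates per group have df = 4; power is
  limited and zero-variance edge cases are real, hence the explicit
  conventions above.
* Enrichment tests treat sites as independent; no correction is made for
  the spatial correlation of methylation along fragments.
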