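---
title: "Assay design and haplotype typing for dreissenid metabarcoding: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assay design and haplotype typing for dreissenid metabarcoding: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreissamp)
```

## The problem

Zebra mussels (*Dreissena polymorpha*, "ZM") and quagga mussels
(*D. rostriformis*, "QM") are invasive freshwater bivalves whose planktonic
larvae (veligers) and eDNA traces cannot be told apart morphologically.
A targeted metabarcoding assay amplifies a short, diagnostic fragment of
the mitochondrial COI gene from mixed-template samples — laboratory mock
communities of purified DNA, aquarium water, field-collected water, or
bulk plankton containing thousands of larvae — and reads it out on a
high-throughput sequencer. If the amplicon is chosen well, a single primer
pair simultaneously (i) separates the two species and (ii) resolves
within-species haplotypes, so one sequencing run yields both species
proportions and population-genetic composition.

`dreissamp` implements the full computational side of this workflow:
finding such amplicons on an aligned haplotype panel, scoring what they
can and cannot resolve, typing read sets into haplotype-group abundance
profiles, validating quantification against known compositions, and
comparing multi-sample profiles.

## Assay design on an aligned panel

The reference panel is an aligned FASTA of named haplotypes
(`read_reference_alignment()`), by convention labelled `ZM-A` … `ZM-T` and
`QM-A` … `QM-Q` over a 570-column COI alignment. Three primitives drive
design:

* **Degenerate consensus** (`degenerate_consensus()`): over a gapless
  window, each column is collapsed to the minimal IUPAC code covering all
  observed bases. The primer's *degeneracy* is the product of per-column
  code cardinalities — the number of concrete oligos in the synthesis
  pool. A conserved window has low degeneracy; the published forward
  primer `AGTGTTYTKATTCGTTTRGAGCTWAGKGC`, with five two-fold codes, has
  degeneracy 32.
* **Fixed differences** (`fixed_differences()`): a column is diagnostic
  for a species pair when the two species' residue sets are disjoint —
  the standard fixed-SNP criterion. Mere frequency differences do not
  count, and `N` expands to all four bases so ambiguity can only destroy,
  never create, a diagnostic column.
* **Resolvability partition** (`resolvability_partition()`): haplotypes
  whose gap-stripped amplicon substrings are identical are
  indistinguishable to the assay and collapse into one group (e.g. the
  `ZM-A,M,O` group of a COIA-style amplicon). The partition is the exact
  unit of downstream counting: one group = one expected ASV.

`scan_primer_windows()` enumerates all pairs of gapless windows whose
consensus degeneracy stays at or below a cap and whose inter-primer
distance falls inside the amplicon-length bounds, then ranks candidates
by: more interspecific fixed differences, then more resolvability groups,
then less combined degeneracy. The literature gives no ranking rule, so
the order is this package's own convention; two further deterministic
tie-breaks (longer primers, then left-most position) make the ranking a
total order, so identical inputs always produce identical output.

Coordinates are 1-based inclusive alignment columns throughout — the
native R and IRanges convention.

## Typing reads into profiles

Merged amplicon reads are processed per sample:

1. **Trimming** (`trim_reads()`): reads carry random-length spacers
   (7–17 nt, a cluster-diversity trick of the library chemistry) and the
   primers themselves. The forward primer and the reverse complement of
   the reverse primer are located IUPAC-aware; the inter-primer core is
   kept. By default primers must match exactly (`max_mismatch = 0`);
   reads without both sites are rejected and counted, never silently
   dropped.
2. **Dereplication** (`dereplicate()`): exact-sequence ASVs with counts,
   ordered deterministically (count descending, then sequence). There is
   deliberately *no* learned-error denoising model: errors are handled by
   the reference-constrained assignment step and by the cross-sample
   filter, and dereplication keeps the counting model transparent. No
   chimera removal is attempted either (automated chimera detection is
   known to misclassify genuine haplotypes in this system).
3. **Cross-sample artifact filter** (`filter_single_sample_asvs()`): an
   ASV present in only one sample of a batch is removed everywhere. This
   is the screening rule used for environmental samples; it is undefined
   for a single-sample batch, which passes through with a warning.
4. **Assignment** (`assign_asvs()`): each ASV goes to the nearest group
   representative by Hamming distance. Exact matches assign at distance
   0; distances above `max_dist` (default 1) and ties between groups
   yield `unassigned` — a tie is evidence, not a coin flip, so the
   conservative call is no call. Length differences are unassignable
   unless an explicit `indel_tolerance` allows end-gapped comparison.
5. **Profiles** (`profile_samples()`): read sums and proportions per
   group and per species, with unassigned reads reported separately and
   excluded from denominators. Reads are conserved: assigned +
   unassigned + trim-rejected = raw input, per sample.

Reported percentages round half-up to one decimal place, matching the
presentation convention of the published benchmark tables.

## Validating quantification

Mock communities mix known template copy numbers per haplotype
(`mock_design()` reproduces the published eight-community rotation of
6,000 / 3,000 / 1,500 / 750 / 375 / 188 / 94 / 47 copies).
`expected_group_proportions()` collapses copies by the assay's partition;
expected percentage = 100 × group copies / total.

`loglog_fit()` regresses log10 observed on log10 expected percentages by
OLS and tests the slope against 1 with `t = (slope − 1)/SE`, n − 2 df,
two-sided. A perfectly quantitative assay has slope 1; compression of
abundant templates and inflation of rare ones shows up as slope < 1. Base
10 is cosmetic — the slope and both tests are base-invariant. Groups with
zero observed reads are dropped before fitting (their log is undefined)
and the drop is the caller's to record. Fits pool all groups of a
community; with the published per-community group counts (5–6 points) the
slope-vs-1 test has little power, which is worth remembering when
interpreting non-significance.

`g_test()` is the likelihood-ratio contingency test
`G = 2 Σ O ln(O/E)`, as goodness of fit against a known composition
(individual counts, biomass shares, template copies — proportions are
scaled to the observed read total, the only coherent scaling) or as a
2×k independence test between two read vectors (expected counts from the
table margins, df = k − 1). The Williams small-sample correction is
available as a flag and off by default. `composition_comparison_suite()`
runs a planned set of such tests and stars them at 0.05 / 0.01 / 0.001.

## Comparing communities

`bray_curtis()` and `kulczynski()` implement the two abundance-based
dissimilarities directly (both in [0, 1]; 0 for identical, 1 for disjoint
support); matrix versions are cross-checked against `vegan::vegdist` in
the test suite. `nmds()` and `anosim_test()` wrap `vegan::metaMDS` and
`vegan::anosim` — the standard engines for Kruskal stress-1 minimisation
and the rank-based grouping test — behind seeded, tidy interfaces.
Defaults: k = 2 dimensions, 50 random restarts, and the permutation
convention that includes the observed statistic in both numerator and
denominator of the p-value. `kruskal_stress()` recomputes stress-1
independently from a configuration (isotonic regression of configuration
distances on the dissimilarity order), which the tests use to confirm the
reported stress.

For location-level comparisons (`pool_profiles()`), samples are pooled by
summing read counts before recomputing proportions; averaging per-sample
proportions instead is available by flag but weights small samples up.

`build_haplotype_network()` reduces the complete Hamming-distance graph
over group representatives to a minimum spanning tree — the conventional
haplotype-network display — using Kruskal's algorithm with lexicographic
tie-breaking on edge labels so the tree is reproducible. Representatives
must share one length within a species; species blocks of unequal
amplicon length are joined by the single shortest end-gapped cross edge,
giving one connected display without inventing base-level homology
between the blocks.

## Field metrics

`veliger_density()` scales the mean aliquot count by sample volume /
aliquot volume (default 15 ml / 0.5 ml) to a per-sample total, and
divides by the filtered tow volume (default 190 L) for veligers per
litre. Replicate tows summarise as mean ± SE across replicates
(`density_table()`); the within-tow aliquot spread stays in the per-tow
table rather than leaking into the replicate SE. `compare_counts()` is a
paired (or two-sample) Student's t-test.

## The synthetic-data generator

`make_panel()` generates panels whose ground truth is known by
construction, which is what makes the pipeline testable end to end
without any sequence download. The default spec mirrors the study
system's structure:

* 20 ZM + 17 QM haplotypes over 570 columns;
* two planted assays: a 169-nt core with 24 interspecific fixed
  differences inside 29/24-nt conserved flanks, and a 175-nt core with 26
  differences inside 25/25-nt flanks;
* collapse plans dictating the resolvability partitions — by default 10
  ZM + 8 QM groups for the first assay (with the focal
  `ZM-A,M,O` / `ZM-C` / `ZM-G` / `QM-A` / `QM-F` / `QM-G` six-group
  structure over the mock-community haplotypes) and 7 + 9 for the second
  (five focal groups, `ZM-A,C` and `QM-A,F,G` collapsed);
* every distinct within-species group differs from every other by at
  least 3 columns (each non-reference group owns a private 3-column
  block). This margin is a design property a usable haplotype assay
  needs anyway — single-substitution sequencing errors must not convert
  one group's reads into another's — and it is what lets
  nearest-reference assignment absorb low-rate error cleanly;
* conserved sequence exists *only* in the planted flanks: pad regions
  carry a four-base "decoy" column every eighth position, so the planted
  windows are the unique low-degeneracy solution and window scanning has
  a well-defined right answer.

`simulate_reads()` draws read counts from a multinomial on the template
copy numbers, assembles spacer + primer realisation + core + reverse
site + spacer per read, and applies i.i.d. per-base substitution errors.
The error model is substitution-only (assignment distance is
Hamming-based; indels are a stretch goal exposed via `indel_tolerance`
on the assignment side), with optional forward-primer corruption to
exercise trim rejection. All generators are bit-reproducible under a
fixed seed.

What the generator does **not** emulate: PCR chimeras, per-cycle
amplification bias, quality-score structure, template degradation, and
copy-number variation between mitochondria and cells. Passing the
end-to-end recovery tests therefore demonstrates that the *computational*
pipeline is unbiased and correctly calibrated under multinomial sampling
with substitution error — not that wet-lab quantification is unbiased,
which is exactly what the published mock-community benchmarks (slopes
different from 1 for one of the two assays) show must be checked
empirically per assay.

## Numerical conventions and degenerate inputs

* Intervals: 1-based, inclusive, on alignment columns.
* Percentages: half-up rounding at 1 decimal (2 decimals for census
  shares), applied only at presentation; internal arithmetic is full
  precision.
* Perfect log-log fits (observed ≡ expected) degenerate the slope-vs-1
  t statistic (0/0); the test reports p = 1 there, by construction.
* Zero assigned reads in a sample: proportions are undefined; the sample
  is flagged and dropped from the proportion table.
* All-equal dissimilarity matrices carry no ordination information and
  are flagged before NMDS.
* `in_silico_pcr()` distinguishes a no-hit (`NA`) from an error; trimming
  rejects are counted, not fatal.
* Test problem sizes: the recovery suite simulates the eight-community
  design at 100,000 reads per community with error rate 0.001, the
  G-test calibration uses 2,000 multinomial null draws (k = 6, n =
  10,000), and the ANOSIM null uses 300 twelve-sample datasets at 199
  permutations — sizes chosen to make the binomial tolerance bands tight
  enough to be informative while keeping the default test run fast.

## Known limitations

* Assignment assumes the reference panel spans the haplotypes actually
  present; a genuinely novel haplotype lands in `unassigned` (or, if
  within `max_dist` of a known group, is silently absorbed by it). Survey
  designs expecting novelty should inspect the unassigned ASV table.
* The cross-sample singleton filter trades sensitivity for specificity:
  a real haplotype genuinely confined to one sample is removed.
* The naive pair merger (`merge_pairs()`) is a convenience for
  pre-merged-input workflows, not a substitute for a quality-aware
  merger.
* Thermodynamic primer properties (Tm, dimers, hairpins) are out of
  scope; candidate assays from `scan_primer_windows()` still need a
  bench check before synthesis.
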