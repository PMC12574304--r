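---
title: "Anchoring a eukaryotic MAG to a ribosomal marker: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring a eukaryotic MAG to a ribosomal marker: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetag)
```

## The problem

Obligate biotrophs such as arbuscular mycorrhizal fungi are difficult or
impossible to culture, so their genomes must be recovered directly from
mixed-community shotgun sequencing as metagenome-assembled genomes (MAGs).
Eukaryotic MAGs are especially fragile: the genomes are large and
heterozygous, the rDNA cassette assembles poorly because its conserved
repeats collapse, and standard binning gives no taxonomic identity. The
procedure implemented here validates a candidate fungal bin by triangulating
three independent signals:

1. **Graph context.** Unitigs matching a trusted reference ribosomal operon
   are flagged in the assembly graph; the bounded neighbourhood around them
   is extracted, and candidate bins are ranked by how much sequence they
   place inside that neighbourhood. A genome is a path through the assembly
   graph, so the true bin must pass near its own rDNA even when the rDNA
   itself failed to assemble into the bin.
2. **Coverage correlation.** Across many samples, the normalized depth of
   the true bin must co-vary with the read abundance of the corresponding
   marker taxon (e.g. an 18S rRNA consensus sequence quantified by an SSU
   profiler). Pearson correlation against all detected taxa, with
   multiplicity control, identifies the matching taxon.
3. **Copy-number consistency.** The regression slope of marker depth on
   genome depth estimates the per-genome rDNA operon copy number, which
   must be biologically plausible for the lineage (tens of copies for most
   fungi).

The remaining modules score the candidate MAG's quality (assembly
statistics, marker-based completion, variant-frequency spectrum, ORF depth
distribution) and compare its functional repertoire (CAZymes, proteases,
lipases, transporters, secreted proteins) to reference genomes grouped by
ecological lifestyle.

## Graph-context extraction

`parse_gfa()` reads GFA1 S/L records; segments may carry `*` sequences with
`LN:i:` length tags, and mean depth is taken from `dp:f:`/`DP:f:` or derived
from `KC:i:`. Other record types are skipped with a warning rather than an
error, because assembler dialects vary and only segments and links matter
here.

`flag_marker_unitigs()` consumes alignment records (PAF native, SAM
converted on read, or the built-in `align_fragments()` semi-global aligner
for operon-scale sequences) and keeps records at or above an identity
threshold (default 0.98) and a minimum alignment length (default 500 bp).
The identity default mirrors the high-similarity regime the method targets;
the length floor suppresses spurious hits to short conserved rDNA motifs,
which would otherwise drag unrelated unitigs into the context. Breadth of
reference coverage is computed on the interval union (IRanges), so
overlapping hits are never double-counted. All coordinates are 0-based
half-open internally; SAM positions are converted on read. Alignments on
either strand are accepted and reported on the forward reference, because
the operon's orientation in the graph is arbitrary.

**Distance convention.** "All of *r* bp around the seeds" is read as a
radius on sequence context, not hop count. The distance of a candidate
unitig is the minimum over paths of the summed lengths of the *intervening*
unitigs between a seed and the candidate's near end; each intervening
unitig contributes `max(0, length − overlap of the link leaving it toward
the candidate)`, so overlap-shared bases are counted once. Seeds contribute
nothing and the candidate's own length is not counted, which makes direct
neighbours of a seed sit at distance 0. This cost is edge-local, so plain
Dijkstra applies; tests check it against a Floyd–Warshall oracle on the
transformed edge-weighted graph and hand-computed chains. The alternative
reading (counting overlap bases twice) would only enlarge distances by the
overlap lengths and is not offered.

Ranked colocation output uses a stable sort with bin id as the secondary
key, so reports are reproducible run to run.

## Coverage linking and copy number

Raw depth of a bin in a sample is the length-weighted mean depth of its
member contigs (total mapped bases over total contig length). Both bins and
taxa are normalized per sample as `raw / sample total × 10^6`. The
per-million scale is a convention: it cancels in the correlation and in the
slope as long as both matrices share a unit, which the `coverage_matrix`
unit label enforces. Taxa with fewer than 10 reads across all samples are
removed before testing (the retained/removed split is reported), matching
the low-count floor such SSU profilers need.

Correlations use Pearson's r with two-sided p-values and
Benjamini–Hochberg adjustment across all tested taxa. BH is the default
because the source ecosystem's convention for "adjusted p-value" is FDR
control; the method is a parameter (`adjust`) for users who prefer Holm.
Zero-variance taxa have undefined correlation and are excluded from the
ranking rather than silently assigned r = 0; a zero-variance bin profile is
an error because every result downstream would be meaningless.

The copy-number slope is least squares **through the origin**,
`sum(x·y)/sum(x²)`: at zero genome depth there are zero marker reads, and
only the no-intercept slope is interpretable as the marker:genome depth
ratio, i.e. the operon copy number. A free-intercept fit is available
behind a flag for diagnostics. The confidence interval is a seeded
percentile bootstrap over samples (default 1000 replicates, seed 20251029);
all randomized operations in the package take explicit seeds so reports are
bit-reproducible.

## MAG quality diagnostics

* `assembly_stats()`: N50 by the standard descending cumulative scan; GC
  over unambiguous bases only (N and IUPAC codes excluded from the
  denominator).
* `effective_completion()`: complete + fragmented marker percentages;
  fragmented markers are present in the assembly, so the sum is the
  effective completion. The duplicated fraction is carried as a
  contamination proxy; a report may supply either a duplication or an
  explicit contamination field, since tools disagree on which one they
  print. Display values round to one decimal; computations keep full
  precision.
* `snv_spectrum()`: separates strain diversity (allele frequencies spread
  evenly) from a diploid/two-haplotype signal (frequencies piled near 0.5).
  The uniformity test is a Kolmogorov–Smirnov test restricted to
  (0.05, 0.95) — the trim avoids detection-limit edge effects where callers
  censor rare alleles — at α = 0.01, and the central-mode score is the
  fraction of frequencies in [0.4, 0.6] with threshold 0.5. All four
  numbers are parameters; the defaults encode a qualitative criterion as a
  reproducible rule, not a fitted cutoff.
* `orf_coverage_distribution()`: the modal ORF depth is the histogram peak
  (ties resolved to the lowest bin, deterministically) and the single-copy
  fraction is the share of ORFs within ±50% of the mode. The
  "single-copy-dominant" label requires the fraction to *strictly* exceed
  0.5: an exact two-copy 50/50 split yields fraction 0.5 and must not be
  read as single-copy dominance.

## Comparative functional profiling

CAZy families map to substrate groups through an editable named list
(`default_substrate_map()`); plant-side groups (cellulose, hemicellulose,
lignin, pectin) and microbial-side groups (chitin, glycan, mannan,
peptidoglycan) define the PCWDE/MCWDE split. Family-to-substrate
assignments drift with CAZy releases, so the map is data, not code; the
shipped map covers the families named in the package's analyses and routes
anything else to `unclassified`. Side totals count unique proteins by
default — a protein whose family maps to two plant-wall groups counts once
toward PCWDE — because per-group sums inflate the totals; per-group sums
remain available.

Pathway completeness is role-based: a pathway is complete when every role
has at least one satisfying identifier (EC number, with trailing dashes as
wildcards since annotation tools emit partial ECs, or CAZy family code).
Roles may also carry identifier *groups* that must be jointly present, used
for multi-step bypasses — e.g. the vitamin B6 panel accepts either
pyridoxine 4-dehydrogenase or a three-step pyridoxal→pyridoxine conversion
group. The shipped panels (cellulose, chitin, thiamine, cytosolic
fatty-acid synthesis, vitamin B6) encode the roles by name; the exact
identifier lists are a JSON-loadable config (`load_pathway_defs()`) that
users should reconcile against their annotation tool's vocabulary.

Lifestyle comparisons use Kruskal–Wallis with tie correction at α = 0.01,
then Dunn's pairwise z-tests (tie-corrected pooled variance) with BH
adjustment at α = 0.05, and a compact letter display built from the maximal
cliques of the non-significant-pair graph, letters assigned in descending
group-median order. Clique-based letters guarantee the audit invariant that
two groups share a letter exactly when their adjusted pairwise p is ≥ α.
When the omnibus test is not significant (including the all-tied case,
where H is defined as 0), every group receives the single letter "a".

## What the synthetic generators emulate

The generators exist so every stage — and the full
flag→context→colocate→link→copy-number loop — runs against data with known
truth. Their defaults are the study conditions the pipeline targets:

* `gen_assembly()`: a fragmented target genome (fragment N50 ≈ 5 kbp, the
  scale of the MAG this method was built to recover) carrying a 4.5-kbp
  operon in several identical copies, each forced to split across at least
  two unitigs — mimicking the way rDNA fails to assemble; decoy genomes as
  disconnected components; bins equal to genome partitions with an optional
  misassignment rate. The default genome length (300 kbp) and 5 decoys are
  a desk-scale choice: they preserve the structure that matters (dozens to
  hundreds of unitigs, multi-unitig operon context) while keeping a full
  closed-loop replicate under 50 ms. Fragmentation is a Poisson breakpoint
  process tuned so exponential fragment lengths hit the target N50 in
  expectation (length-biased median ≈ 1.678 × mean); exact N50 matching is
  not attempted and tests accept a factor-two band.
* `gen_coverage()`: 12 samples, target-bin depths log-uniform on 1–568×,
  one planted taxon proportional to the bin with slope 63 under
  multiplicative lognormal noise (CV 10%, mean-corrected), 250 decoy taxa
  independent of the bin, of which 20 fall below the 10-read floor so the
  filter has known casualties. Depths are positive and heteroscedastic,
  hence the multiplicative noise model.
* `gen_snvs()`: allele frequencies uniform on (0.05, 0.95)
  (strain-diversity regime) or normal(0.5, 0.05) truncated to (0, 1)
  (diploid regime), realized as read-depth pairs at mean depth 200.
* `gen_annotations()`: per-genome category counts drawn negative-binomial
  (dispersion 10 by default; `Inf` gives the Poisson limit — the
  overdispersion reflects the large intra-lifestyle variance seen in
  saprotrophs) around lifestyle means; published group means are used where
  available (e.g. CAZymes 175/240/629 for G-AMF/ECM/ERM, transporters 3900
  for G-AMF) and the remaining means are fixed once at values consistent
  with the published group ordering. G-AMF-like genomes omit
  β-glucosidase (EC 3.2.1.21) and pyridoxine kinase (EC 2.7.1.35) by
  construction, so pathway scoring has planted truth. Because the category
  vocabulary is closed, the metabolic EC carriers ride on existing
  annotation rows.

What the generators do **not** emulate: read-level error, chimeric
contigs, host-plant contamination, cross-sample compositional coupling,
repeat-induced misassembly, or correlated decoy taxa that share a habitat
preference with the target. Passing closed-loop tests therefore shows the
statistical machinery is correct under the stated model, not that the
pipeline is robust to every artefact of real metagenomes — in particular,
a decoy taxon ecologically coupled to the target genome could correlate
strongly without being the right marker, which is why the graph-context and
copy-number lines of evidence exist at all.

## Numerical choices and degenerate inputs

* Interval unions, N50, Pearson r, and subgraph membership are each tested
  against independent brute-force oracles on 1000 random instances.
* Sorting everywhere uses stable order with id as secondary key.
* `estimate_copy_number()` bootstrap resamples that lose all non-zero bin
  depths are dropped (NA) from the percentile interval.
* Degenerate inputs fail loudly: empty seed sets, unknown ids, zero-length
  references, all-zero bin profiles, frequencies outside (0, 1) (rejected
  per record with a count), all-zero ORF depths.
* Simulation problem sizes used by the test suite and the acceptance
  script — 200 closed-loop replicates, 200 replicates per SNV regime,
  1000 oracle instances per statistic, 2000 null simulations for the
  omnibus-test calibration — were chosen as the smallest sizes at which
  the binomial uncertainty on the checked rates is comfortably below the
  margins being asserted.

## Known limitations

* GFA1 only; GFA2 E-lines and containment records are not parsed.
* The SAM reader is minimal (single reference, NM-based identity) — it
  exists for interoperability, not as a general SAM parser.
* The built-in aligner is quadratic and intended for operon-scale
  fragments; genome-scale alignment should be done externally and imported
  as PAF.
* Copy-number slopes inherit any systematic bias between the marker and
  genome quantification units; the estimate is a consistency check, not a
  calibrated assay.
* The compact-letter construction enumerates maximal cliques and is meant
  for the ~10 lifestyle groups of this analysis, not for hundreds of
  groups.
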