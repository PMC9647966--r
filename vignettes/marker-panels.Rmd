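---
title: "From a variant database to a cultivar fingerprint: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a variant database to a cultivar fingerprint: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpfinger)
```

## The problem

Crop cultivars — here the motivating case is cauliflower (*Brassica
oleracea* var. *botrytis*), a crop with a notoriously narrow genetic base —
need cheap, reproducible molecular identification: seed lots must be
verifiable, variety rights protectable, and synonymous accessions
detectable. A practical solution is a small panel of SNP markers assayed on
a fluorescence platform such as KASP, with each cultivar represented by the
ordered string of its genotype calls over the panel: its DNA fingerprint.

Building such a system from a whole-genome variant database has four
stages, each a module of this package:

1. **screen** — reduce millions of raw variants to a pool of high-quality
   candidate markers;
2. **divstats** — quantify how informative each candidate is;
3. **panel** — find small marker subsets that distinguish the cohort as
   well as the full set does;
4. **fingerprint** — fix a panel, store every cultivar's genotype string,
   and group identical genotypes.

Two infrastructure modules support them: **genomat** (the genotype-matrix
data model and VCF/FASTA/GFF3/TSV I/O) and **synthgen** (a generator of toy
genomes and genotype sets with planted, fully known structure, used by the
test suite and usable for pipeline rehearsal).

## The candidate filter

A raw variant record survives screening iff it passes all six criteria:

1. it is a biallelic SNP;
2. its site is fourfold degenerate (4D) in every covering transcript;
3. observed heterozygosity < 0.2;
4. missing rate < 0.05;
5. minor allele frequency (MAF) > 0.3;
6. no other variant — SNP or InDel — lies within 100 bp of the site.

All threshold comparisons are **strict**. A marker with MAF exactly 0.300
or heterozygosity exactly 0.200 is rejected. Boundary cases are rare in
real data but common in tests, and the strictness changes survivor counts,
so it is worth stating prominently. The surviving set is the intersection
of the per-criterion pass sets and therefore independent of evaluation
order; only the *attribution* of a rejected marker to a criterion (for the
report) follows the order above, crediting the first failure. Filtering is
idempotent by construction.

Three rationale notes:

* Criterion 2 restricts markers to sites where any nucleotide encodes the
  same amino acid, i.e. sites under the weakest directional selection.
  Neutral markers drift to intermediate frequencies and stay polymorphic
  across germplasm, which is exactly what a fingerprinting marker needs.
* Criterion 3 is screened on an inbred discovery panel, where residual
  heterozygosity mostly indicates paralogy or mismapping rather than true
  heterozygosity — a low ceiling is a quality filter, not a population
  statement. The same markers genotyped on hybrid market cultivars then
  show high heterozygosity, which is expected and desirable.
* Criterion 6 consults the **full raw variant set**, not the filtered one:
  a flanking InDel that itself failed screening still disturbs primer
  annealing. `filter_candidates()` therefore takes `all_variants`
  separately from the matrix being filtered.

Each statistic in criteria 3–5 is computed over the full sample set,
independently of the other criteria (no sequential re-estimation after
partial filtering).

## Fourfold-degeneracy classification

For a site covered by a CDS, the containing codon is reconstructed from
the genome: segments of the transcript are concatenated in reading order
(reverse-complemented for minus-strand transcripts, including codons that
span splice junctions), the reading-start phase is trimmed, and the site's
position within its codon is located. The site's fold class is the number
of nucleotides at that position that leave the amino acid unchanged under
the standard genetic code (translation table 1 — the nuclear genome of any
brassica needs nothing else): 1 → `NONDEGENERATE`, 2 → `TWOFOLD`,
3 → `THREEFOLD`, 4 → `FOURFOLD`. Under that code exactly eight codon
families (Leu-CTN, Val, Ser-TCN, Pro, Thr, Ala, Gly, Arg-CGN) are fourfold,
always at the third position.

Three conservative choices where conventions differ between tools:

* A site covered by several transcripts must classify identically in all
  of them; disagreement yields `CONFLICT`, which never passes the 4D
  criterion. Requiring unanimity maximizes the neutrality guarantee.
* Codons containing `N` or other ambiguity codes are `NONDEGENERATE` —
  synonymy is undefined there, and such sites must never be selected.
* A transcript whose phase-adjusted CDS length is not a codon multiple is
  an annotation error: `read_cds()` reports it as a warning and
  `classify_site()` raises an error naming the transcript rather than
  guessing a frame.

The correctness argument is exhaustive rather than anecdotal: the test
suite builds a genome whose genes tile all 64 codons on both strands and
compares every one of the 384 (codon, position, strand) classifications
against a brute-force oracle derived directly from the codon table.

## Marker statistics

With `p` the alternate-allele frequency estimated from called alleles only
(complete case, no small-sample correction) and `q = 1 − p`:

* minor allele frequency: `maf = min(p, q)` ∈ [0, 0.5];
* gene diversity (expected heterozygosity): `D = 1 − p² − q²`, maximum 0.5;
* polymorphism information content, biallelic Botstein form:
  `PIC = 1 − (p² + q²) − 2 p² q²`, maximum 0.375;
* observed heterozygosity: `n_het / n_called`;
* missing rate: `n_missing / n_samples`.

`PIC ≤ D` always, with equality only at `maf = 0`; both are symmetric in
`p ↔ q` and monotone on [0, 0.5] (property-tested on a grid). The package
ships a published 41-marker cauliflower core panel
(`core_markers()`) as a regression fixture: recomputing PIC and gene
diversity from each tabulated MAF reproduces the printed values. Because
the tabulated MAF is itself rounded to three decimals, the reachable
discrepancy is bounded by error propagation (`|dD/dp| ≤ 2`, so a half-ulp
of 0.0005 in MAF can move D or PIC by up to 0.001, plus the printed
value's own rounding); the regression asserts agreement within 0.0015 and
exact 3-decimal agreement on interior spot checks. The uncorrected
(complete-case) frequency estimate is validated by this same regression.

The summary band for gene diversity, `[0.4, 0.5]`, is **inclusive at both
ends**: a biallelic locus at maximal diversity has `D = 0.500` exactly,
and excluding the right endpoint would misclassify the most informative
markers as out-of-band.

The variant-type spectrum counts the six unordered substitution pairs;
transitions are A/G and C/T, and `Ts/Tv = (A/G + C/T) / (A/T + A/C + G/T +
C/G)`. `variant_spectrum()` also accepts a named vector of published
percentages, so the ratio of a reported spectrum can be recomputed without
the underlying variants. With zero transversions the ratio is reported as
undefined rather than infinite.

## KASP candidacy

For each candidate, the 100 bp flanks are extracted and the assay window
(201 bp: both flanks plus the site) is checked:

* GC fraction of the window strictly below 0.60;
* no other variant inside the window;
* the window occurs exactly once in the genome, by exact forward-strand
  substring search. This is a deterministic uniqueness screen at the
  window level; it does not detect homologous-but-diverged copies the way
  an alignment search would, and users needing homology-aware specificity
  should export the windows and run an aligner. Reverse-complement
  occurrences are not counted.

A candidate is *designable* iff all three hold. Flanks truncated at a
contig edge are flagged, not fatal. Primer-level thermodynamics (melting
temperature, product size, tail design) is out of scope: those properties
belong to the designed oligos, which this package deliberately does not
design.

## Panel selection by discernibility simulation

A sample's genotype string over a panel is one token per marker — hom-ref
`ref·ref`, het the alphabetically sorted allele pair (so `AG` ≡ `GA`),
hom-alt `alt·alt`, missing `NN` — joined in fixed panel order. For a panel
`S` over `n` samples,

```
discernibility(S) = number of distinct genotype strings / n
```

so 1 means every sample is uniquely identified and `1/n` is the floor.
Discernibility is monotone under panel nesting: adding a marker can only
split groups.

`simulate_combinations()` draws, for each panel size `k`, a fixed number
of uniform random `k`-subsets (default 5000; each subset drawn without
replacement of markers; repeats across draws are allowed and not
deduplicated), scores each, and retains every distinct subset achieving
the size's maximum. `minimal_panel_size()` scans sizes upward and reports
the first size whose best score matches the full panel; equality is tested
on the integer count of distinct strings, not on floating-point ratios.
`efficiency_curve()` reports per-size best scores plus their running
maximum — per-size maxima from finite sampling can dip non-monotonically,
and the running maximum is the curve to plot. An exhaustive mode
(`exhaustive_panels()`) enumerates all subsets for instances up to roughly
20 markers; it exists so the randomized search can be validated against
true optima, and it is how the test suite checks simulated per-size best
scores on 12-marker instances.

Determinism: simulations take an explicit seed, restore the caller's RNG
state afterwards, and record the RNG algorithm in the result metadata, so
a published panel selection is reproducible byte for byte. Retained
subsets are reported with marker ids sorted, and ties across subsets are
ordered lexicographically.

**Missing data.** The default (`distinct`) mode treats `NN` as an ordinary
token: two samples missing at the same marker match there. This is the
literal behaviour of joining call strings and comparing them, and it is
the default because it is what the discernibility formula above computes.
A `wildcard` mode instead lets `NN` match any token — conservative
duplicate calling, useful when missingness is platform noise rather than
signal. Wildcard matching is not transitive, so groups are defined as
connected components of the pairwise match relation; its group counts can
only be smaller than distinct-mode counts.

## The fingerprint database

`build_db()` fixes an ordered panel, stores each sample's genotype string
and calls, and partitions samples into identical-genotype groups (under
the same missing-data mode as the panel module; the group count equals the
panel's distinct-string count by construction, and the suite asserts this
cross-module identity). `duplicate_report()` lists groups of two or more,
largest first — in a market cohort these are candidate synonyms or
re-branded lines. Exports are deterministic: the fingerprint matrix TSV
(markers × samples, tokens `0/0`, `0/1`, `1/1`, `./.`) round-trips through
the package's table reader.

Barcode payloads are a documented plain-text scheme,
`sample|panel-hash|RHAN…` (one symbol per marker: `R` hom-ref, `H` het,
`A` hom-alt, `N` missing). The 12-hex-character panel hash is an MD5 over
the canonical panel definition (id, chromosome, position, ref, alt, in
order); decoding verifies it and fails loudly on mismatch, so fingerprints
from different panels can never be compared silently. Rendering the
payload as a QR image is left to any barcode tool.

## The synthetic-data generator

`synth_plan()` describes a cohort; `synth_fixture()` writes a toy genome
(FASTA), annotation (GFF3) and multi-sample VCF, plus a JSON manifest of
every planted property. The generator emulates:

* an **inbred discovery panel** by default — heterozygosity 0.05, missing
  rate 0.02, target allele frequency 0.4, the regime in which markers
  survive the screen (hybrid-like cohorts are a matter of raising
  `het_rate` to 0.3–0.5);
* **marker neutrality** by planting marker sites at the third position of
  glycine (GG·) codons inside small genes, on alternating strands so
  minus-strand codon reconstruction is exercised; any reference base is
  valid there, so the genome always agrees with the declared ref allele.
  A separate chromosome carries two genes tiling all 64 codons, one per
  strand, as the degeneracy test substrate;
* **planted violations**: noncoding sites (`fraction_4d < 1`), triallelic
  records, decoy InDels 50 bp from a marker, and per-marker overrides of
  heterozygosity, MAF and missingness — each deterministically failing one
  known criterion;
* **duplicate cultivars** by cloning sample rows *after* missing-masking,
  so clones are exact string duplicates, as true synonym accessions are
  after joint genotyping.

Genotypes are drawn per sample i.i.d.: het with probability `h`, otherwise
hom-alt with probability `(p − h/2)/(1 − h)`, which makes the expected
allele frequency `p` for any `h`. The manifest records both the planted
intent and the realized per-marker tallies from the generator's own
bookkeeping, so tests can derive expected filter outcomes by direct
threshold comparison without re-running the filter.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: linkage disequilibrium and physical
clustering of variants, population structure and kinship, coalescent
allele-frequency spectra, genotyping-platform error modes (allele-specific
dropout, cluster-calling failures), and reference-genome artifacts such as
collapsed paralogs. Tests built on these fixtures validate the
*machinery*; they say nothing about how many markers a particular real
cohort needs.

## Problem sizes and numerical choices

The shipped test suite runs at deliberately small scale, chosen so that
exhaustive oracles remain feasible: discernibility equivalence is checked
on 25 samples × 12 markers (4095 subsets enumerated, simulated search at
2000 draws per size), monotonicity on 1000 random nested panel pairs,
degeneracy on all 384 tiled codon positions, frequency recovery at 500
samples against a 99% sampling interval, and clone-group recovery (sizes
12 and 11 among 50 samples) exactly. The randomized-simulation default of
5000 draws per size is the conventional operating point for real cohorts;
all defaults can be raised freely, with cost linear in draws × panel size
× samples.

Remaining numerical conventions, collected: all filter thresholds strict;
gene-diversity band inclusive; statistics reported at full precision with
rounding applied only at display; equality of panel scores compared on
integer counts; marker positions 1-based inclusive everywhere in the
public model, with the single 0-based half-open conversion confined to the
BED export and tested; partially missing genotypes (`./1`) and allele
indices above 1 coerced to missing; phase discarded on import; duplicate
sample names rejected rather than renamed.

## Known limitations

* Biallelic SNPs only at the call level; multi-allelic records are carried
  and flagged but never genotyped beyond "missing".
* GFF3 is the only annotation dialect (GTF conversion is the user's job);
  phase semantics in GTF are too inconsistent across producers.
* Window uniqueness is exact-match only (see above).
* The randomized search offers no optimality certificate below the
  exhaustive-mode size limit; greedy or integer-programming selection is
  intentionally absent because the randomized protocol is the method being
  provided.
* No imputation: missing calls stay missing, and the two missing-data
  modes only change how they compare.
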