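---
title: "Methods: composition, codon-usage and skew scans in haloscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition, codon-usage and skew scans in haloscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

haloscan re-implements the composition-level analyses used in genome reports
of multi-replicon prokaryotes — in particular GC-rich haloarchaea such as
*Haloferax volcanii*, whose genome comprises a main chromosome, several
megaplasmid-sized secondary chromosomes and a small plasmid. This vignette is
the package's methodological account: the statistics it computes, the
parameters that matter and their defaults, the choices made where the
published procedures leave the design open, and what the synthetic-data tests
do and do not demonstrate.

## Data model

A `replicon()` is one DNA sequence over {A,C,G,T,N} with a topology flag and
an ordered feature table (CDS, IS, tRNA, rRNA, other). Internal coordinates
are 0-based half-open everywhere; emitted reports use 1-based inclusive
coordinates (and BED/bedGraph outputs follow the 0-based BED standard).
Features wrapping the origin of a circular replicon are stored as two rows
sharing an id, ordered by a `part` column in transcript order. IUPAC
ambiguity codes other than N are collapsed to N with a warning. IS elements
are recognized from annotation labels (default patterns `ISH51`, `IS4`,
`transposase`), not detected de novo: genome reports count IS elements from
curated annotation, and haloscan follows that convention.

GenBank flat files are parsed by a purpose-built reader covering the subset
this package needs (LOCUS topology, join/complement locations, partial
flags, the usual qualifiers); FASTA and GFF3 go through Biostrings and
rtracklayer. CDS translations are taken from the annotation when present —
the annotation is authoritative, and the initial methionine is retained —
otherwise sequences are translated with the bacterial/archaeal genetic code
(table 11). CDSs whose length is not a multiple of three and that are not
flagged partial are kept as features but excluded from all codon statistics
with a warning; annotated-partial CDSs are excluded silently. This
resolves, conservatively, a point the published analyses leave unstated.

## Synonymous codon usage scan

The core statistic asks whether a window of consecutive genes uses synonymous
codons the way its replicon does. A SCU table (`build_scu()`) pools codon
counts over CDSs and converts them to frequencies *conditional on the amino
acid*: for codon $c$ of amino acid $a$, $f_c = n_c / n_a$. Stops, ATG and
TGG are excluded — they carry no synonymous choice. Conditioning on the
amino acid is what makes the scan a test of synonymous usage rather than of
amino-acid composition; it also decouples the statistic from protein
function differences between windows.

`scan_replicon()` slides a window of 30 CDSs (step 1 CDS, wrapping on
circular replicons) in genomic order and `window_chi2()` computes

$$\chi^2 = \sum_{c} \frac{(n_c - n_{a(c)} f^{ref}_c)^2}{n_{a(c)} f^{ref}_c}$$

over codons with positive expectation, with an upper-tail chi-square
p-value. If the reference lacks a codon the window uses, a
pseudo-expectation of 0.5 is substituted with a warning rather than
dropping the evidence of a codon the reference never employs.

**Degrees of freedom.** The published scan used 40 df. The
family-conditional construction over 59 codons in 18 degenerate families
implies $\sum_a (k_a - 1) = 41$ (`scu_df()`). haloscan defaults to the
published 40 so that p-values are comparable with the original analysis,
exposes `df` as a parameter, and uses 41 wherever the package itself
checks calibration: simulated null windows drawn from a reference's
family-conditional frequencies are chi-square distributed with 41 df, and
at 40 df the nominal 5% tail captures ≈6.9% of null windows.

**Island calling.** The published analysis reports genomic islands without
stating a significance threshold or merging rule, so these are package
choices: windows with $p < \alpha$ (default $10^{-4}$) are merged into
maximal runs, and runs shorter than `min_run` (default 3) windows are
discarded. The defaults were chosen so that a homogeneous replicon of
thousands of CDSs yields essentially no false islands
($600 \times 10^{-4} < 1$ stray window expected, and stray windows do not
form runs of 3). The reported CDS range of an island comes from the run
geometry: if significant window starts span $[a, b]$ with window size $w$,
CDSs covered *only* by significant windows are $[a + w - 1,\, b]$ when the
run is at least a window long, and the common intersection $[b,\, a+w-1]$
otherwise; the island span is the genomic extent of those CDSs. On planted
islands this recovers boundaries to within 2 CDSs, whereas the naive union
of member windows overshoots by up to a window on each side. Islands are
labelled `contains_IS`/`no_IS` by annotation overlap, and
`assign_reference()` retests each island's pooled counts against every
replicon's SCU table, reporting the argmin-$\chi^2$ replicon (ties go to
the lexicographically smaller id) and whether even the best reference is
rejected.

**Reference choice.** Scanning a replicon against its own SCU table mirrors
the published procedure, but the reference is then a mixture that includes
any islands. With ~8,000 codons per window the scan is sensitive enough
that an island occupying fraction $q$ of the CDSs shifts *host* windows by
a noncentrality proportional to $q^2$: around 10% divergent content pushes
ordinary windows toward significance, and island boundaries blur. The
package therefore accepts an explicit `ref` argument, and the sharp
recovery tests scan a target replicon against the SCU table of a separate
host-profile replicon — the same logic as asking whether a plasmid's
islands resemble the chromosome. The analysis scripts keep the planted
island at 5% of the chromosome's CDSs so the self-referenced scan remains
clean; the vignette flags this sensitivity because it matters for real
genomes with large mobile regions.

## Composition metrics

`gc_percent()` is $100 (G+C)/(A+C+G+T)$ with N excluded from numerator and
denominator; whole-replicon GC is computed over the full sequence without
feature masking. Coding GC is taken over the union of CDS spans (bases
under overlapping CDSs counted once; IRanges does the arithmetic),
non-coding GC over the complement, and percent coding is the union width
over the length. Codon-position GC pools complete codons across CDSs (and
replicons, if pooled), excluding stop codons by default — the published
value's treatment of stops is unstated, so the flag `exclude_stops` lets
both be computed; for genome-scale codon sets the difference is far below
reporting precision.

The windowed composition track uses
$\chi^2 = \sum_b (o_b - L p_b)^2 / (L p_b)$ against the replicon-wide base
frequencies, with $L$ the window's non-N count; a base absent from the
replicon is skipped with a warning. Window and stride default to 5,000 and
1,000 bp: the published tracks name no window, and 5 kb resolves a
~53 kb anomalous region about ten windows wide while averaging over
gene-scale fluctuation. Reports round percentages to one decimal, matching
genome-report precision.

## Cumulative skew and origin signal

`cumulative_disparity()` computes running sums of ±1 increments for the
five classical Z-curve components (GC: G−C; AT: A−T; RY: purine−pyrimidine;
MK: amino−keto; WS: weak−strong); N contributes 0. Curves are evaluated at
every base and stored at a 100 bp stride (plus the final base), which keeps
a 2.8 Mb chromosome's curve in ~28k points while leaving extremum
localization far finer than the tolerance of any origin inference.
`rotate_to_origin()` recomputes (not merely shifts) the sums from the
rotated sequence, the operation used to overlay curves of different
replicons at their origins; a full-length rotation is accepted as the
identity. `windowed_gc_skew()` emits the per-window (G−C)/(G+C) track.

`locate_skew_extremum()` returns the position of the global minimum (or
maximum) of the raw curve, ties broken toward the smallest coordinate; an
optional moving-average flag exists but the default is no smoothing, since
the published origin placements rested on visual inspection of raw curves
and smoothing can only move a V-shaped vertex. On replicons with one origin
and terminus and a leading-strand G excess the GC-curve minimum marks the
origin. The package reports curve amplitude but deliberately makes no
weak/strong skew call and no multi-origin changepoint inference: genomes
with two origins or recently moved origins (as discussed for *Hfx.
volcanii*) superpose conflicting slopes, and a single extremum is then only
a summary, not an origin prediction.

## Protein isoelectric points

Net charge follows the Henderson–Hasselbalch group model:
$Q(\mathrm{pH}) = \sum_{basic} n_g (1 + 10^{\mathrm{pH} - pK_g})^{-1}
- \sum_{acidic} n_g (1 + 10^{pK_g - \mathrm{pH}})^{-1}$, basic groups being
the N-terminus, H, K, R and acidic the C-terminus, D, E, C, Y; unknown
letters carry no charge. $Q$ is strictly decreasing in pH, so the pI is the
unique root on [0, 14], found by bisection. Convergence is on the interval
width (default $10^{-4}$ pH): a charge-based stop sounds natural but fails
for near-neutral proteins, whose charge curve is flat enough around the
root that $|Q| < 10^{-4}$ can leave the pH tens of millipH units off; the
interval criterion bounds the pH error directly. A charge tolerance remains
available via `tol_q` for callers who want the historical behavior.

Two pKa sets ship as data: `embl` (the EMBL/EMBOSS values used by the
classical BioPerl pI calculator, the set behind published haloarchaeal
proteome means) and `expasy` (Bjellqvist-style) for sensitivity — proteome
means typically differ by a few hundredths of a pH unit between sets, which
is why the set is an explicit parameter of every pI function.
Transmembrane/cytosolic classification is an *input* label joined from a
TSV, never predicted: membrane-topology prediction is out of scope, and
class means are computed only over labelled proteins.

## IS-element GC context

The published "evolving away from IS elements" pattern is graphical; the
permutation test here is this package's formalization and every ingredient
is a parameter. The statistic is the mean GC of fixed-width flanks (default
500 bp each side) at the annotated IS sites. The null redraws the same
number of positions uniformly at random, excluding annotated IS spans so
elements never sample their own AT-rich sequence, and the one-sided
p-value $(1 + \#\{T_{null} \le T_{obs}\})/(1 + n_{perm})$ targets the
"AT-richer-than-random context" alternative. Note what the null is: random
positions fall in coding and non-coding DNA alike, so in a genome whose
coding DNA is GC-richer than its intergenic DNA, *any* intergenically
confined element scores as AT-contextual — that confinement is part of the
biological claim being tested, not a confounder. The package's calibration
check therefore uses a featureless synthetic replicon, where uniform IS
placement provably satisfies the null and the p-value is uniform across
regenerated genomes.

## Genetic-map calibration

Markers carry map positions (kb) and assembly coordinates (bp); each
contributes a start and an end offset, and the calibration offset is the
median of the pooled offsets — pooling start and end offsets into one
median follows the published integration, which reported a single
conversion constant and a mean of all start and end differences alongside
it; haloscan reports both median and mean and adjudicates between neither.
Markers whose mapped gene length differs from the assembly length by more
than a factor (default 2×) are flagged as outliers and the median is
recomputed once without them, mirroring the published exclusion of markers
with marked length discrepancies; named exclusions (operon-scale markers a
coarse map cannot place) are honored via a list. `map_to_genome()` is
$1000x + \text{offset}$ modulo the replicon length, 1-based, with an exact
inverse; `project_intervals()` carries legacy interval tables (with
condition labels) onto the assembly as BED and lists overlapping genes.

In the synthetic marker model the jitter displaces each marker *as a unit*
(both endpoints share one error): a legacy map measures a gene's position
at ~10 kb resolution but knows the gene's extent, so endpoint errors are
almost perfectly correlated. Independent endpoint jitter of ±5 kb would
make the length-ratio outlier rule misfire on every ~1 kb gene, which is a
statement about that error model, not about real maps.

## The synthetic genome generator

`generate_genome()` emulates exactly the structures the detectors assume:
CDSs drawn codon-by-codon from per-family frequency profiles
(`codon_profile(gc3)` grades host-like GC-ending against island-like
AT-ending usage), intergenic bases at a background GC with optional AT
valleys, IS elements of specified GC inserted at intergenic sites weighted
by $e^{-s \cdot \mathrm{GC}_{local}}$, a replication origin that biases
intergenic G vs C by ±g on the leading/lagging halves (producing a V-shaped
cumulative GC curve with vertex at the origin), and a marker map with a
constant offset plus per-marker jitter and an optional gross-length
outlier. Each replicon draws from its own RNG stream derived from the
master seed, so adding a replicon never perturbs another; identical spec
and seed give byte-identical files. `null_window_sampler()` draws 30-CDS
windows directly from a reference's family-conditional frequencies for
chi-square calibration.

What the generator does *not* emulate, and what passing tests therefore do
not show: there is no substitution-over-time model (islands are maximally
"young"), origin skew acts only on intergenic bases (real leading-strand
bias also shapes codon choice), start codons default to ATG only,
amino-acid usage is near-uniform unless the acid-shifted option is chosen,
and there is no gene-expression-linked codon selection, so the
ribosomal-protein-type islands seen in real genomes have no synthetic
counterpart. Recovery results on this generator validate the machinery,
not the biology of any particular genome.

## Problem sizes and numerical conventions

The test suite and the acceptance script run, by choice, on: 2,000 null
windows for type-I calibration (the 2·SE band at nominal 0.05 is ±0.0097);
a 600-CDS target replicon with a 40-CDS planted island scanned against a
300-CDS host reference; a 300 kb replicon with g = 0.02 for origin
recovery; 100 random peptides of 20–200 residues against a 10⁻⁵-resolution
pH-grid oracle; 9 markers with ±5 kb jitter and one planted outlier; and
2,000 permutations for the IS context test with 12 regenerated genomes for
its uniformity check. Degenerate inputs are contracted explicitly: all-N
slices return missing values, constant skew curves raise "no extremum",
empty codon sets and sub-3-marker tables are errors, empty protein classes
are `NA`, and a replicon with fewer CDSs than the window is scanned as a
single whole-replicon window with a warning.

## Known limitations

The GenBank reader covers the flat-file subset above, not the full
standard. Island calling on a self-referenced scan degrades when divergent
content exceeds roughly a tenth of a replicon (see above); scanning against
an external reference is the supported remedy. The permutation test
conflates insertion preference with coding/intergenic composition contrast
by design. The IS family census relies entirely on annotation labels. pI
values are sequence-only (no folded-state pKa shifts, no halophilic
adaptation model), and the published transmembrane-proteome mean is not
reproducible here because it depends on an external topology predictor.
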