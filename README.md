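# haloscan

Composition, codon-usage and replication-skew scans for multi-replicon
prokaryotic genomes, written for the kind of questions a genome report on a
GC-rich haloarchaeon has to answer: Where does the codon usage of a window of
genes stop looking like its replicon — the signature of laterally acquired
genomic islands? How is GC content apportioned between coding and non-coding
DNA and between codon positions? What does the cumulative GC skew say about
replication origins? Do insertion-sequence (IS) elements sit in AT-richer
context than chance, as expected for a genome "evolving away" from its
transposons? And how do coordinates from a legacy genetic map translate onto
the finished assembly?

The package is aimed at microbial genomicists analysing finished or draft
multi-replicon genomes (main chromosome plus secondary chromosomes and
plasmids), and ships a seeded synthetic-genome generator so that every
detector is validated against planted ground truth without downloading
anything.

## The statistics at the core

**Codon-usage islands.** For each replicon a synonymous codon usage (SCU)
table holds family-conditional frequencies `f_c = n_c / n_a(c)` (stops, Met,
Trp excluded). A window of 30 consecutive CDSs (step 1, circular wrap) is
tested against a reference table with

```
chi2 = sum_c (n_c - n_a(c) * f_ref_c)^2 / (n_a(c) * f_ref_c)
```

and an upper-tail chi-square p-value (40 df by default, following the
published convention; the construction itself implies 41, see the methods
vignette). Runs of at least 3 windows with `p < 1e-4` become islands, which
are labelled by IS-element overlap and assigned the replicon whose SCU they
best match.

**Composition.** GC over any slice (N-free), coding vs non-coding GC over
the union of CDS spans, codon-position GC, windowed GC, and a windowed
chi-square deviation of local base composition from the replicon average.

**Skew.** Cumulative Z-curve disparities (GC, AT, RY, MK, WS), windowed
(G−C)/(G+C), rotation of curves to a chosen origin, and extremum
localization of the cumulative GC curve — the origin-side vertex on
replicons with a leading-strand G excess.

**Proteome pI.** Henderson–Hasselbalch net charge with the EMBL/EMBOSS pKa
set (Bjellqvist set included for sensitivity), bisection to 1e-4 pH, and
per-replicon / per-class summaries with histograms.

**IS context.** A one-sided permutation test of "IS flanks are AT-richer
than matched random positions", with the flank width, permutation count and
seed recorded in the output.

**Map integration.** Median-offset calibration between genetic-map kb and
assembly bp with gene-length outlier rejection, plus projection of legacy
intervals onto the assembly.

## Worked example

```r
library(haloscan)

# A synthetic chromosome: GC-ending host codon usage, one planted island of
# AT-ending usage covering CDSs 300-339, scanned against a host reference.
g <- generate_genome(synth_spec(1002, list(
  synth_replicon_spec("target", 6e5, gc = 0.6, n_cds = 600,
                      host_profile = codon_profile(0.9),
                      islands = list(list(at_cds = 300, n_cds = 40,
                                          profile = codon_profile(0.1)))),
  synth_replicon_spec("hostref", 3e5, gc = 0.6, n_cds = 300,
                      host_profile = codon_profile(0.9)))))
ref <- build_scu(extract_cds_codons(g$replicons$hostref))
sc  <- scan_replicon(g$replicons$target, ref = ref)
call_islands(sc, g$replicons$target)
#>   replicon  start    end cds_from cds_to n_windows min_p label ...
#> 1   target 301528 341690      300    339        69     0 no_IS
```

The single called island spans CDSs 300–339 — the planted boundaries
exactly. The same session's origin recovery:

```r
sk <- generate_genome(synth_spec(1003, list(
  synth_replicon_spec("sk", 3e5, gc = 0.6, n_cds = 30,
                      ori = list(pos = 1e5, g = 0.02)))))
locate_skew_extremum(cumulative_disparity(sk$replicons$sk, "GC"))
#> [1] 99700
```

The cumulative-GC minimum lands 300 bp (0.1% of the replicon) from the
planted origin at 100,000.

## Analysis workflow

`analysis/` holds numbered drivers that run the whole study on a generated
genome and write tables and genome-browser tracks under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | builds the synthetic study genome (island, IS elements, origin, AT valleys, marker map) |
| `02_composition.R` | GC / codon-position / coding-density profiles and chi-square tracks |
| `03_scu_islands.R` | SCU tables, 30-CDS scan, island calls and cross-replicon assignment |
| `04_skew.R` | Z-curve disparity tracks and origin-signal localization |
| `05_proteome_pi.R` | proteome pI table, histogram, pKa-set sensitivity |
| `06_is_context.R` | IS/GC overlay track and the insertion-context permutation test |
| `07_map_calibration.R` | marker-offset calibration and legacy-interval projection |
| `08_summary.R` | per-replicon general-features table with totals and start-codon census |
| `09_accession_tier.R` | optional: recompute published values from locally supplied GenBank records |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

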