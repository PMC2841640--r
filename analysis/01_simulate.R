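#!/usr/bin/env Rscript
# Stage 1: build the synthetic study genome used by the downstream stages.
#
# The genome emulates the structures the scans target in a haloarchaeal-style
# multi-replicon genome: a GC-rich main chromosome with a planted island of
# atypical synonymous codon usage, AT-rich IS elements steered into AT
# valleys, a replication origin inducing strand-asymmetric composition, and a
# legacy genetic-marker map with a constant offset plus jitter; plus a
# smaller replicon with a completely different codon-usage profile and a
# linear plasmid. Everything is written as FASTA + GFF3 + TSV under
# results/synthetic/ together with the ground-truth manifest.

suppressPackageStartupMessages(library(haloscan))

out_dir <- "results/synthetic"
seed <- 20101L

spec <- synth_spec(seed, list(
  # 5% of chrM's CDSs form the island, small enough that the island's
  # contribution to the whole-replicon SCU does not push host windows
  # toward significance in the self-referenced scan
  synth_replicon_spec("chrM", 7e5, gc = 0.66, n_cds = 600,
                      host_profile = codon_profile(0.8),
                      islands = list(list(at_cds = 280, n_cds = 30,
                                          profile = codon_profile(0.45))),
                      is_elements = list(
                        list(family = "ISH51", n = 8, gc = 0.42,
                             pref_strength = 25, length = 900),
                        list(family = "IS4", n = 5, gc = 0.45,
                             pref_strength = 25, length = 1100)),
                      ori = list(pos = 2e5, g = 0.02),
                      valleys = list(n = 15, gc = 0.35),
                      aa_freq = acidic_aa_freq(2)),
  synth_replicon_spec("pHA", 1.5e5, gc = 0.58, n_cds = 150,
                      host_profile = codon_profile(0.3),
                      aa_freq = acidic_aa_freq(2)),
  synth_replicon_spec("pHB", 6e4, gc = 0.62, n_cds = 60,
                      topology = "linear",
                      host_profile = codon_profile(0.8))),
  markers = list(replicon = "chrM", n = 12, offset = 90000, jitter_kb = 5,
                 outlier = TRUE))

g <- generate_genome(spec, dir = out_dir)

cat("wrote", length(g$paths), "files under", out_dir, "\n")
for (r in g$replicons) print(r)
cat("\nPlanted truths (manifest):\n")
print(g$manifest[g$manifest$type != "is_site", ])
cat(sprintf("plus %d IS insertion sites; true marker offset %d bp\n",
            sum(g$manifest$type == "is_site"), g$marker_offset))
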