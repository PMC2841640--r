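#!/usr/bin/env Rscript
# Stage 9 (optional, requires local data): recompute the published
# composition values from the five deposited Haloferax volcanii DS2 replicon
# records. Download CP001953-CP001957 as GenBank flat files (with sequence)
# into data/accessions/ (or inst/extdata/accessions/ before installing) and
# run this driver; it prints the recomputed values next to the published
# ones. Nothing is downloaded automatically and no stage depends on this.

suppressPackageStartupMessages(library(haloscan))

dirs <- c("data/accessions",
          system.file("extdata", "accessions", package = "haloscan"))
files <- unlist(lapply(dirs[nzchar(dirs)], list.files,
                       pattern = "\\.(gbk?|genbank)$", full.names = TRUE))
if (length(files) < 5) {
  cat("accession records CP001953-CP001957 not found under data/accessions/;\n")
  cat("skipping the accession tier (see header for how to supply them).\n")
  quit(status = 0)
}

reps <- read_genome(files, format = "genbank")
main <- reps[[which.max(vapply(reps, function(r) r$length, numeric(1)))]]

cat(sprintf("main chromosome GC: %.1f%% (published 66.6)\n",
            gc_percent(main$sequence)))
cat(sprintf("GC of region 2110297..2163576: %.1f%% (published 50.1)\n",
            gc_percent(replicon_subseq(main, 2110296, 2163576))))
codons <- unlist(lapply(reps, extract_cds_codons), recursive = FALSE)
pos <- codon_position_gc(codons)
cat(sprintf("codon-position GC: %.0f / %.0f / %.0f%% (published 68 / 44 / 85)\n",
            pos[1], pos[2], pos[3]))
census <- start_codon_census(reps)
cat(sprintf("start codons: ATG %.1f%%, GTG %.1f%%, TTG %.1f%% (published 82.0 / 17.8 / 0.2)\n",
            census["ATG"], census["GTG"], census["TTG"]))
cat(sprintf("total CDSs: %d (published 4063)\n",
            sum(vapply(reps, function(r) {
              length(unique(r$features$id[r$features$kind == "CDS"]))
            }, numeric(1)))))
cat(sprintf("mean pI, main chromosome, EMBL pKa set: %.2f (published 5.11; +/-0.05 by pKa set)\n",
            mean(replicon_pis(main, pka = pka_set("embl")))))
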