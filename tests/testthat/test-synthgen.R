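test_that("identical spec and seed produce byte-identical output", {
  sp <- synth_spec(901, list(
    synth_replicon_spec("d1", 4e4, gc = 0.6, n_cds = 30,
                        is_elements = list(list(family = "ISH51", n = 2,
                                                gc = 0.4, length = 500)))),
    markers = list(replicon = "d1", n = 4, offset = 8000, jitter_kb = 1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_genome(sp, dir = d1)
  generate_genome(sp, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and adding an unrelated replicon does not perturb the first stream
  sp2 <- synth_spec(901, list(sp$replicons[[1]],
                              synth_replicon_spec("d2", 2e4, n_cds = 10)))
  g1 <- generate_genome(sp)
  g2 <- generate_genome(sp2)
  expect_identical(g2$replicons$d1$sequence, g1$replicons$d1$sequence)
})

test_that("realized composition concentrates on the specified targets", {
  g <- fx_genome()
  r <- g$replicons$hostA  # >= 100 kb
  # global GC within one point of the blend implied by the spec; the
  # intergenic fraction alone is held at its planted value
  cn <- coding_noncoding_gc(g$replicons$plasB)
  expect_lt(abs(cn$noncoding_gc - 55), 1)
  expect_equal(r$length,
               2e5 + 5 * 700)  # backbone plus inserted IS elements
  # island SCU diverges strongly from the host profile when planted so
  fx <- island_fixture()
  host <- build_scu(extract_cds_codons(fx$g$replicons$hostref))
  isl_counts <- island_codon_counts(fx$sc, fx$islands[1, ])
  expect_gt(window_chi2(isl_counts, host)$chi2, 1000)
})

test_that("every generated file parses losslessly through the readers", {
  sp <- synth_spec(905, list(
    synth_replicon_spec("CP000001", 3e4, gc = 0.66, n_cds = 20),
    synth_replicon_spec("CP000002", 2e4, gc = 0.61, n_cds = 12),
    synth_replicon_spec("CP000003", 15e3, gc = 0.65, n_cds = 8),
    synth_replicon_spec("CP000004", 1e4, gc = 0.55, n_cds = 5),
    synth_replicon_spec("CP000005", 6e3, gc = 0.56, n_cds = 3)))
  dir <- withr::local_tempdir()
  g <- generate_genome(sp, dir = dir)
  back <- read_genome(list(fasta = g$paths[["fasta"]], gff = g$paths[["gff"]]),
                      format = "fasta_gff3")
  expect_equal(names(back), paste0("CP00000", 1:5))
  for (id in names(back)) {
    expect_identical(back[[id]]$sequence, g$replicons[[id]]$sequence)
    expect_equal(nrow(back[[id]]$features), nrow(g$replicons[[id]]$features))
  }
  # the manifest parses and its truths match the annotation
  man <- read.delim(g$paths[["manifest"]], comment.char = "#")
  expect_true(all(c("type", "start", "end", "replicon") %in% names(man)))
})

test_that("null windows are calibrated at the implied degrees of freedom", {
  g <- fx_genome()
  ref <- build_scu(extract_cds_codons(g$replicons$hostA))
  w <- null_window_sampler(ref, 400, seed = 17)
  ps <- apply(w, 2, function(cnt) window_chi2(cnt, ref, df = scu_df())$p)
  # loose sanity band here; the tight 2SE check runs in the acceptance tier
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  # seed reproducibility
  expect_identical(null_window_sampler(ref, 5, seed = 3),
                   null_window_sampler(ref, 5, seed = 3))
  # degenerate reference (one codon per family): chi2 identically 0
  info <- Biostrings::getGeneticCode("11")
  one_per_fam <- tapply(names(info), info, `[`, 1)
  one_per_fam <- setdiff(unname(one_per_fam[names(one_per_fam) != "*"]),
                         default_scu_exclusions())
  degen <- build_scu(list(one_per_fam))
  wd <- null_window_sampler(degen, 20, seed = 2)
  chis <- apply(wd, 2, function(cnt) window_chi2(cnt, degen)$chi2)
  expect_true(all(chis == 0))
})

test_that("capacity violations are rejected", {
  expect_error(generate_genome(synth_spec(1, list(
    synth_replicon_spec("tiny", 5e3, n_cds = 50)))), "capacity")
})
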