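test_that("gc_percent matches definition and a counting oracle", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_true(is.na(gc_percent("NNNN")))
  # N excluded from numerator and denominator
  expect_equal(gc_percent("GCNN"), 100)
  s <- random_dna(10000, gc = 0.62, seed = 42)
  expect_equal(gc_percent(s), oracle_gc(s), tolerance = 1e-9)
})

test_that("coding/non-coding GC uses union semantics over CDS spans", {
  mk <- function(starts, ends) {
    replicon("u", "ATGGCCTAAA", topology = "linear",
             features = feature_table(kind = rep("CDS", length(starts)),
                                      start = starts, end = ends,
                                      strand = rep("+", length(starts)),
                                      id = paste0("g", seq_along(starts))))
  }
  expect_equal(coding_noncoding_gc(mk(0L, 6L))$percent_coding, 60)
  # overlapping CDSs: bases counted once
  expect_equal(coding_noncoding_gc(mk(c(0L, 3L), c(6L, 9L)))$percent_coding, 90)
  # weighted recombination of coding + non-coding GC gives whole-sequence GC
  g <- fx_genome()
  r <- g$replicons$hostA
  cn <- coding_noncoding_gc(r)
  w <- cn$percent_coding / 100
  expect_equal(w * cn$coding_gc + (1 - w) * cn$noncoding_gc,
               gc_percent(r$sequence), tolerance = 1e-6)
})

test_that("codon-position GC matches hand values and a positional oracle", {
  expect_equal(unname(codon_position_gc(c("ATG", "GCC"))), c(50, 50, 100))
  expect_equal(unname(codon_position_gc(rep("GAG", 7))), c(100, 0, 100))
  expect_error(codon_position_gc(character()), "empty")
  # stop codons excluded by default, kept on request
  with_stop <- codon_position_gc(c("ATG", "TAA"), exclude_stops = FALSE)
  expect_equal(unname(with_stop), c(0, 0, 50))
  expect_equal(unname(codon_position_gc(c("ATG", "TAA"))), c(0, 0, 100))
  # oracle: count positions by hand over a synthetic CDS set
  codons <- extract_cds_codons(fx_genome()$replicons$plasB)
  flat <- unlist(codons, use.names = FALSE)
  flat <- flat[!flat %in% c("TAA", "TAG", "TGA")]
  ora <- vapply(1:3, function(p) {
    100 * mean(substr(flat, p, p) %in% c("G", "C"))
  }, numeric(1))
  expect_equal(unname(codon_position_gc(codons)), ora, tolerance = 1e-9)
})

test_that("windowed composition chi-square matches direct arithmetic", {
  r <- replicon("ac", paste0(strrep("A", 100), strrep("C", 100)),
                topology = "linear")
  expect_warning(tr <- window_composition_chi2(r, window = 100, stride = 100),
                 "skipped")
  # all-A window in a 50/50 A/C genome: (100-50)^2/50 + (0-50)^2/50 = 100
  expect_equal(tr$chi2, c(100, 100))
  # a window matching the genome composition scores 0
  r2 <- replicon("bal", strrep("ACGT", 100), topology = "linear")
  tr2 <- window_composition_chi2(r2, window = 40, stride = 40)
  expect_true(all(tr2$chi2 == 0))
  # independent recomputation on a synthetic replicon
  g <- fx_genome()
  rr <- g$replicons$plasB
  tr3 <- window_composition_chi2(rr, window = 5000, stride = 5000)
  cnt_all <- table(factor(strsplit(rr$sequence, "")[[1]],
                          levels = c("A", "C", "G", "T")))
  p <- as.numeric(cnt_all) / sum(cnt_all)
  for (i in c(1, nrow(tr3))) {
    w <- substr(rr$sequence, tr3$start[i] + 1, tr3$end[i])
    obs <- table(factor(strsplit(w, "")[[1]], levels = c("A", "C", "G", "T")))
    expd <- sum(obs) * p
    expect_equal(tr3$chi2[i], sum((as.numeric(obs) - expd)^2 / expd),
                 tolerance = 1e-9)
  }
  expect_true(all(tr3$chi2 >= 0))
})

test_that("windowed GC averaged at stride = window recovers global GC", {
  g <- fx_genome()
  r <- g$replicons$plasB  # 60 kb: 1 kb windows tile the replicon exactly
  win <- 1000L
  tr <- windowed_gc(r, window = win, stride = win)
  expect_equal(mean(tr$gc), gc_percent(r$sequence), tolerance = 1e-6)
})

test_that("composition profile recovers planted generator GC within 0.5 points", {
  g <- fx_genome()
  # plasB carries no IS elements, so its non-coding bases are exactly the
  # intergenic background drawn at the spec value of 55%
  cn <- coding_noncoding_gc(g$replicons$plasB)
  expect_lt(abs(cn$noncoding_gc - 55), 0.5)
  r <- g$replicons$hostA
  prof <- composition_profile(r, window = 5000, stride = 5000)
  expect_s3_class(prof, "CompositionProfile")
  expect_true(all(prof$pos_gc >= 0 & prof$pos_gc <= 100))
  # host profile gc3 = 0.7 shows up as third-position GC enrichment
  expect_gt(prof$pos_gc[["pos3"]], prof$pos_gc[["pos2"]])
})
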