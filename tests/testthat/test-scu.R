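test_that("SCU tables are family-conditional frequencies", {
  t1 <- build_scu(list(c("GAA", "GAA", "GAA")))
  expect_equal(unname(t1$codon_freq["GAA"]), 1)
  expect_equal(unname(t1$codon_freq["GAG"]), 0)
  t2 <- build_scu(list(c("GAA", "GAG")))
  expect_equal(unname(t2$codon_freq[c("GAA", "GAG")]), c(0.5, 0.5))
  # excluded codons never appear in the table
  t3 <- build_scu(list(c("ATG", "TGG", "TAA", "GAA")))
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in%
                     names(t3$codon_freq)))
  expect_error(build_scu(list(c("ATG", "TAA"))), "zero usable")
  # oracle: count-and-normalize by hand on a synthetic CDS set
  codons <- extract_cds_codons(fx_genome()$replicons$plasB)
  tab <- build_scu(codons)
  flat <- unlist(codons, use.names = FALSE)
  flat <- flat[!flat %in% default_scu_exclusions()]
  code <- Biostrings::getGeneticCode("11")
  for (cd in c("GCG", "CTT", "AAA", "TAT")) {
    fam <- names(code)[code == code[[cd]] & !names(code) %in%
                         default_scu_exclusions()]
    expect_equal(unname(tab$codon_freq[cd]),
                 sum(flat == cd) / sum(flat %in% fam))
  }
  # family frequencies sum to 1 for families with counts
  info_aa <- code[names(tab$codon_freq)]
  sums <- tapply(tab$codon_freq, info_aa, sum)
  expect_true(all(abs(sums[tab$aa_counts[names(sums)] > 0] - 1) < 1e-9))
})

test_that("window chi-square matches hand evaluation and records df", {
  ref <- build_scu(list(c("GAA", "GAG")))
  obs <- scu_codon_counts(rep("GAA", 10))
  wc <- window_chi2(obs, ref)
  # exp 5/5 against obs 10/0: (10-5)^2/5 + (0-5)^2/5 = 10
  expect_equal(wc$chi2, 10)
  expect_equal(wc$df, 40L)  # published default with the full exclusion set
  expect_equal(wc$p, pchisq(10, 40, lower.tail = FALSE))
  # proportional window scores 0 with p = 1
  obs2 <- scu_codon_counts(c(rep("GAA", 7), rep("GAG", 7)))
  wc2 <- window_chi2(obs2, ref)
  expect_equal(wc2$chi2, 0)
  expect_equal(wc2$p, 1)
  # reference lacking an observed codon: pseudo-expectation 0.5, warning
  expect_warning(wc3 <- window_chi2(scu_codon_counts(c("GAA", "AAA")), ref),
                 "pseudo-expectation")
  expect_gt(wc3$chi2, 0)
  # chi2 is invariant to CDS order inside the window
  g <- fx_genome()
  codons <- extract_cds_codons(g$replicons$hostA)[1:30]
  ref2 <- build_scu(extract_cds_codons(g$replicons$hostA))
  a <- window_chi2(scu_codon_counts(codons), ref2)$chi2
  b <- window_chi2(scu_codon_counts(rev(codons)), ref2)$chi2
  expect_equal(a, b)
  # implied df of the default exclusion set
  expect_equal(scu_df(), 41L)
})

test_that("the scan windows a replicon's CDSs in genomic order", {
  g <- fx_genome()
  r <- g$replicons$hostA
  sc <- scan_replicon(r)
  expect_equal(nrow(sc$stats), 200)  # circular: one window per CDS
  expect_true(all(diff(sc$stats$win) == 1))
  expect_true(all(sc$stats$p >= 0 & sc$stats$p <= 1))
  # linear replicon with exactly `window` CDSs gives a single window
  plas <- g$replicons$plasB
  codons <- extract_cds_codons(plas)
  cds30 <- plas$features[plas$features$kind == "CDS", ][1:30, ]
  r30 <- replicon("r30", plas$sequence, topology = "linear",
                  features = cds30)
  sc30 <- scan_replicon(r30)
  expect_equal(nrow(sc30$stats), 1)
  # fewer CDSs than the window: single whole-replicon window with a warning
  r5 <- replicon("r5", plas$sequence, topology = "linear",
                 features = cds30[1:5, ])
  expect_warning(sc5 <- scan_replicon(r5), "single whole-replicon window")
  expect_equal(nrow(sc5$stats), 1)
})

test_that("no islands are called on a homogeneous replicon", {
  g <- fx_genome()
  r <- g$replicons$hostA  # single host profile, no planted islands
  sc <- scan_replicon(r)
  isl <- call_islands(sc, r)
  expect_equal(nrow(isl), 0)
})

test_that("planted islands are recovered with correct counts and labels", {
  fx <- island_fixture()
  isl <- fx$islands
  truth <- fx$g$manifest[fx$g$manifest$type == "island", ]
  # two planted islands separated by more than a window: two calls
  expect_equal(nrow(isl), 2)
  for (i in 1:2) {
    hit <- which(isl$start < truth$end[i] & isl$end > truth$start[i])
    expect_length(hit, 1)
    expect_lte(abs(isl$cds_from[hit] - truth$cds_from[i]), 2)
    expect_lte(abs(isl$cds_to[hit] - truth$cds_to[i]), 2)
  }
  expect_true(all(isl$label == "no_IS"))  # no IS elements planted
  # reference assignment: both islands match the AT-ending donor replicon
  g <- fx$g
  refs <- list(
    target = fx$sc$ref,
    hostref = build_scu(extract_cds_codons(g$replicons$hostref)),
    donor = build_scu(extract_cds_codons(g$replicons$donor)))
  assigned <- assign_reference(isl, fx$sc, refs)
  expect_true(all(assigned$best_reference == "donor"))
})

test_that("island calls are invariant to rotation of a circular replicon", {
  fx <- island_fixture()
  r <- fx$g$replicons$target
  k <- gap_position(r)
  r_rot <- rotate_replicon(r, k)
  sc_rot <- scan_replicon(r_rot, ref = fx$sc$ref)
  isl_rot <- call_islands(sc_rot, r_rot)
  expect_equal(nrow(isl_rot), nrow(fx$islands))
  # spans map back under the rotation
  back_start <- sort((isl_rot$start + k) %% r$length)
  expect_equal(back_start, sort(fx$islands$start %% r$length))
})

test_that("reference assignment breaks ties toward the smaller replicon id", {
  ref <- build_scu(list(c("GAA", "GAG", "AAA", "AAG")))
  refs <- list(bbb = ref, aaa = ref)
  scan_stub <- list(counts = matrix(scu_codon_counts(c("GAA", "AAA")),
                                    ncol = 1,
                                    dimnames = list(names(ref$codon_freq))),
                    n_cds = 1L)
  island <- data.frame(cds_from = 1L, cds_to = 1L,
                       best_reference = NA_character_, best_p = NA_real_)
  expect_message(out <- assign_reference(island, scan_stub, refs),
                 "tie")
  expect_equal(out$best_reference, "aaa")
})
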