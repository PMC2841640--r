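test_that("net charge obeys its limits and a term-by-term oracle", {
  pka <- pka_set("embl")
  s <- "KDKDHHCY"
  # far below all pKas every basic group is fully protonated
  n_basic <- 1 + 2 + 2  # N-term + 2 K + 2 H
  expect_equal(net_charge(s, -10, pka), n_basic, tolerance = 1e-6)
  # far above all pKas every acidic group is fully deprotonated
  n_acid <- 1 + 2 + 1 + 1  # C-term + 2 D + C + Y
  expect_equal(net_charge(s, 30, pka), -n_acid, tolerance = 1e-6)
  # term-by-term summation oracle at pH 7 on random peptides
  for (i in 1:5) {
    pep <- random_peptide(40, seed = 200 + i)
    ch <- strsplit(pep, "")[[1]]
    q <- 1 / (1 + 10^(7 - pka["Nterm"])) - 1 / (1 + 10^(pka["Cterm"] - 7))
    for (a in ch) {
      if (a %in% c("H", "K", "R")) q <- q + 1 / (1 + 10^(7 - pka[a]))
      if (a %in% c("C", "D", "E", "Y")) q <- q - 1 / (1 + 10^(pka[a] - 7))
    }
    expect_equal(net_charge(pep, 7, pka), unname(q), tolerance = 1e-12)
  }
})

test_that("net charge is strictly decreasing in pH", {
  grid <- seq(0, 14, by = 0.01)
  for (i in 1:10) {
    pep <- random_peptide(sample(5:80, 1), seed = 300 + i)
    q <- net_charge(pep, grid)
    expect_true(all(diff(q) < 0))
  }
})

test_that("the pI solver matches closed-form and grid oracles", {
  # one-acid/one-base system: pI is the pKa midpoint
  custom <- c(Nterm = 9, Cterm = 3)
  expect_equal(isoelectric_point("GGGGG", pka = custom), 6, tolerance = 1e-3)
  # grid-scan oracle at 1e-5 resolution
  pka <- pka_set("embl")
  expect_lt(abs(isoelectric_point("KDKD", pka) - oracle_pi_grid("KDKD", pka)),
            1e-3)
  set.seed(41)
  for (i in 1:20) {
    pep <- random_peptide(sample(10:120, 1), seed = 400 + i)
    expect_lt(abs(isoelectric_point(pep, pka) - oracle_pi_grid(pep, pka)),
              1e-3)
  }
})

test_that("pI responds to composition only, monotonically in acidity", {
  pka <- pka_set("embl")
  for (i in 1:6) {
    pep <- random_peptide(30, seed = 500 + i)
    # appending an acidic residue never raises the pI
    expect_lte(isoelectric_point(paste0(pep, "D"), pka),
               isoelectric_point(pep, pka) + 1e-6)
    # composition-only dependence: a reversed sequence has the same pI
    rev_pep <- paste(rev(strsplit(pep, "")[[1]]), collapse = "")
    expect_equal(isoelectric_point(rev_pep, pka),
                 isoelectric_point(pep, pka), tolerance = 1e-6)
  }
})

test_that("the two shipped pKa sets differ and custom sets are validated", {
  embl <- pka_set("embl")
  expasy <- pka_set("expasy")
  expect_equal(unname(embl["Nterm"]), 8.6)
  expect_false(identical(embl, expasy))
  expect_error(pka_set("nope"), "unknown pKa set")
  # the choice of set shifts a protein's pI only modestly
  pep <- random_peptide(100, seed = 321)
  expect_lt(abs(isoelectric_point(pep, embl) - isoelectric_point(pep, expasy)),
            1)
})

test_that("proteome summaries conserve counts and report class means", {
  pis <- c(a = 4, b = 6)
  sm <- proteome_pi_summary(pis)
  expect_equal(sm$mean_pi, 5)
  expect_equal(sum(sm$histogram$count), 2)
  # labelled class means only over labelled proteins; empty class is NA
  sm2 <- proteome_pi_summary(c(a = 4, b = 6, c = 5),
                             classes = c(a = "cytosolic", b = "cytosolic"))
  expect_equal(unname(sm2$by_class["cytosolic"]), 5)
  # an acid-shifted synthetic proteome averages below 7
  g <- fixture("acidic_genome", function() {
    generate_genome(synth_spec(601, list(
      synth_replicon_spec("ac", 6e4, n_cds = 60,
                          aa_freq = acidic_aa_freq()))))
  })
  pis_ac <- replicon_pis(g$replicons$ac)
  expect_equal(length(pis_ac), 60)
  sm3 <- proteome_pi_summary(pis_ac)
  expect_lt(sm3$mean_pi, 7)
  expect_equal(sum(sm3$histogram$count), 60)
})
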