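# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; nothing is read from disk except what
# the tests themselves write to tempdirs.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A two-replicon genome with contrasting codon profiles, some IS elements
# and a marker map: the workhorse for I/O, summary and SCU tests.
fx_genome <- function() {
  fixture("genome", function() {
    sp <- synth_spec(301, list(
      synth_replicon_spec("hostA", 2e5, gc = 0.62, n_cds = 200,
                          host_profile = codon_profile(0.7),
                          is_elements = list(list(family = "ISH51", n = 5,
                                                  gc = 0.45, length = 700))),
      synth_replicon_spec("plasB", 6e4, gc = 0.55, n_cds = 60,
                          host_profile = codon_profile(0.3),
                          topology = "linear")),
      markers = list(replicon = "hostA", n = 8, offset = 40000,
                     jitter_kb = 3, outlier = FALSE))
    generate_genome(sp)
  })
}

# Tiny hand-built replicon: 10 bp, one CDS over bases 0..6 (ATG GCC TAA
# would need 9; use length 12 for a clean CDS).
fx_tiny <- function() {
  replicon("tiny", "ATGGCCTAATTT", topology = "linear",
           features = feature_table(kind = "CDS", start = 0L, end = 9L,
                                    strand = "+", id = "g1"))
}

# A host-profile target replicon with two planted AT-ending islands, a
# clean host reference replicon, and an AT-ending donor replicon; scanned
# against the host reference. Shared by the SCU and generator tests.
island_fixture <- function() {
  fixture("island_genome", function() {
    sp <- synth_spec(501, list(
      synth_replicon_spec("target", 45e4, gc = 0.6, n_cds = 450,
                          host_profile = codon_profile(0.9),
                          islands = list(
                            list(at_cds = 120, n_cds = 40,
                                 profile = codon_profile(0.1)),
                            list(at_cds = 320, n_cds = 35,
                                 profile = codon_profile(0.1)))),
      synth_replicon_spec("hostref", 25e4, gc = 0.6, n_cds = 250,
                          host_profile = codon_profile(0.9)),
      synth_replicon_spec("donor", 1e5, gc = 0.5, n_cds = 100,
                          host_profile = codon_profile(0.1))))
    g <- generate_genome(sp)
    ref <- build_scu(extract_cds_codons(g$replicons$hostref))
    sc <- scan_replicon(g$replicons$target, ref = ref)
    list(g = g, sc = sc, islands = call_islands(sc, g$replicons$target))
  })
}

# GC-rich replicon with AT valleys whose IS elements were steered into them.
valley_fixture <- function() {
  fixture("valley_genome", function() {
    generate_genome(synth_spec(701, list(
      synth_replicon_spec("v", 2e5, gc = 0.65, n_cds = 100,
                          valleys = list(n = 12, gc = 0.30),
                          is_elements = list(
                            list(family = "ISH51", n = 10, gc = 0.40,
                                 pref_strength = 25, length = 800))))))
  })
}

# Rotate a circular replicon by k bp, where k must fall in an intergenic
# gap (so no feature needs splitting). Used for rotation-invariance checks.
rotate_replicon <- function(r, k) {
  stopifnot(r$topology == "circular", k >= 0, k < r$length)
  f <- r$features
  if (any(f$start < k & f$end > k)) stop("rotation point inside a feature")
  seq_rot <- paste0(substr(r$sequence, k + 1, r$length),
                    substr(r$sequence, 1, k))
  f$start <- (f$start - k) %% r$length
  f$end <- ((f$end - k - 1L) %% r$length) + 1L
  replicon(r$id, seq_rot, topology = "circular", features = f)
}

# A gap position (midpoint of the widest inter-feature gap) usable as a
# rotation point.
gap_position <- function(r) {
  f <- r$features[order(r$features$start), ]
  gaps_start <- c(0L, f$end)
  gaps_end <- c(f$start, r$length)
  w <- gaps_end - gaps_start
  i <- which.max(w)
  as.integer((gaps_start[i] + gaps_end[i]) %/% 2)
}

# Independent per-base reverse complement, used as the oracle against the
# package's Biostrings-backed revcomp().
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Independent GC percent by character counting.
oracle_gc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  ch <- ch[ch != "N"]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

random_dna <- function(n, gc = 0.5, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_peptide <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Two-stage pH-grid scan at 1e-5 resolution: the independent root-finding
# oracle for the pI solver (equivalent to a full 1e-5 grid because net
# charge is strictly decreasing in pH).
oracle_pi_grid <- function(seq, pka) {
  coarse <- seq(0, 14, by = 1e-3)
  q <- net_charge(seq, coarse, pka)
  i <- which.max(q <= 0)
  lo <- max(0, coarse[i] - 2e-3)
  fine <- seq(lo, min(14, coarse[i] + 2e-3), by = 1e-5)
  qf <- net_charge(seq, fine, pka)
  fine[which.min(abs(qf))]
}
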