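test_that("GFF3 1-based coordinates become internal 0-based half-open", {
  dir <- withr::local_tempdir()
  writeLines(c(">chr1", "ATGGCCTAAACGT"), file.path(dir, "g.fna"))
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t1\t6\t.\t+\t0\tID=c1"),
             file.path(dir, "g.gff3"))
  reps <- read_genome(list(fasta = file.path(dir, "g.fna"),
                           gff = file.path(dir, "g.gff3")),
                      format = "fasta_gff3", topology = "linear")
  f <- reps[[1]]$features
  expect_equal(f$start, 0L)
  expect_equal(f$end, 6L)
  expect_equal(f$kind, "CDS")
})

test_that("GenBank origin-spanning join yields one feature id with two spans", {
  dir <- withr::local_tempdir()
  gbk <- c(
    "LOCUS       WRAPREP                 60 bp    DNA     circular BCT 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(55..60,1..6)",
    "                     /locus_tag=\"wrapA\"",
    "     CDS             complement(10..18)",
    "                     /locus_tag=\"revB\"",
    "     mobile_element  20..31",
    "                     /mobile_element_type=\"insertion sequence:ISH51\"",
    "ORIGIN",
    "        1 atggcctaat ttacatttcc cccccccccc cgggggggga aaaaaaaaaa atgaaatatg",
    "//")
  writeLines(gbk, file.path(dir, "t.gbk"))
  r <- read_genome(file.path(dir, "t.gbk"), format = "genbank")[[1]]
  expect_equal(r$topology, "circular")
  wrap <- r$features[r$features$id == "wrapA", ]
  expect_equal(nrow(wrap), 2L)
  expect_setequal(wrap$part, c(1L, 2L))
  # transcript order: the 55..60 piece (part 1) precedes the 1..6 piece
  expect_equal(wrap$start[wrap$part == 1L], 54L)
  expect_equal(r$features$kind[grepl("mobile", r$features$id)], "IS")
  codons <- extract_cds_codons(r)
  expect_equal(codons$wrapA, c("AAT", "ATG", "ATG", "GCC"))
  # minus strand: reverse complement of forward text
  expect_equal(paste(codons$revB, collapse = ""),
               oracle_revcomp(substr(r$sequence, 10, 18)))
})

test_that("write/read round trip reproduces sequences and features exactly", {
  g <- fx_genome()
  dir <- withr::local_tempdir()
  paths <- write_genome(g$replicons, dir, prefix = "rt")
  back <- read_genome(list(fasta = paths[["fasta"]], gff = paths[["gff"]],
                           proteins = paths[["proteins"]]),
                      format = "fasta_gff3")
  expect_setequal(names(back), names(g$replicons))
  for (id in names(g$replicons)) {
    r0 <- g$replicons[[id]]
    r1 <- back[[id]]
    expect_identical(r1$sequence, r0$sequence)
    expect_identical(r1$topology, r0$topology)
    cols <- c("kind", "start", "end", "strand", "id", "part")
    o0 <- r0$features[order(r0$features$id, r0$features$part), cols]
    o1 <- r1$features[order(r1$features$id, r1$features$part), cols]
    rownames(o0) <- rownames(o1) <- NULL
    expect_identical(o1, o0)
  }
  # total genome size is conserved through the round trip
  expect_equal(sum(vapply(back, function(r) r$length, numeric(1))),
               sum(vapply(g$replicons, function(r) r$length, numeric(1))))
})

test_that("codon extraction matches a per-base reverse-complement oracle", {
  set.seed(77)
  for (i in 1:5) {
    n_codons <- sample(20:60, 1)
    body <- random_dna(3 * n_codons, gc = 0.5, seed = 100 + i)
    fwd <- paste0("ATG", body, "TAA")
    L <- nchar(fwd)
    minus_text <- oracle_revcomp(fwd)  # genomic forward-strand text
    r <- replicon("t", paste0(minus_text, "ACGT"), topology = "linear",
                  features = feature_table(kind = "CDS", start = 0L,
                                           end = L, strand = "-", id = "m1"))
    codons <- extract_cds_codons(r)$m1
    expect_equal(paste(codons, collapse = ""), fwd)
    expect_equal(codons[1], "ATG")
    expect_equal(codons[length(codons)], "TAA")
  }
})

test_that("defective CDSs are excluded with the contracted diagnostics", {
  r <- replicon("t", "ATGGCCTAAACGTACGTACG", topology = "linear",
                features = feature_table(
                  kind = c("CDS", "CDS"), start = c(0L, 9L), end = c(9L, 17L),
                  strand = c("+", "+"), id = c("ok", "bad")))
  expect_warning(codons <- extract_cds_codons(r), "not a multiple of 3")
  expect_named(codons, "ok")
  # internal N: that codon dropped from counts
  r2 <- replicon("t2", "ATGGNCTGGTAA", topology = "linear",
                 features = feature_table(kind = "CDS", start = 0L, end = 12L,
                                          strand = "+", id = "g"))
  expect_message(codons2 <- extract_cds_codons(r2), "dropped")
  expect_equal(codons2$g, c("ATG", "TGG", "TAA"))
  # ambiguity codes other than N are mapped to N with a warning
  expect_warning(r3 <- replicon("t3", "ACGTRYK"), "mapped to N")
  expect_equal(r3$sequence, "ACGTNNN")
})

test_that("feature and BED writers use the contracted coordinate systems", {
  r <- fx_tiny()
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "f.tsv")
  write_feature_tsv(r, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$start, 1L)  # reports are 1-based inclusive
  expect_equal(tab$end, 9L)
  bed <- file.path(dir, "f.bed")
  write_bed(data.frame(chrom = "tiny", start = 0L, end = 9L, name = "g1"), bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(0L, 9L))  # BED stays 0-based
})
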