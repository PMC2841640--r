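# Genome-level summary table (per-replicon general features + totals) and
# small helpers for arithmetic over published per-replicon feature tables.

#' Start-codon census over a genome
#'
#' Percentages of annotated CDSs starting with ATG, GTG, TTG or anything
#' else, over all usable CDSs of all replicons.
#'
#' @param replicons list of [replicon()]s.
#' @return named numeric vector (percent): `ATG`, `GTG`, `TTG`, `other`,
#'   plus attribute `n` (CDS count).
#' @export
start_codon_census <- function(replicons) {
  if (is_replicon(replicons)) replicons <- list(replicons)
  firsts <- unlist(lapply(replicons, function(r) {
    if (!any(r$features$kind == "CDS")) return(character())
    vapply(extract_cds_codons(r), `[`, character(1), 1L)
  }), use.names = FALSE)
  if (!length(firsts)) stop("no usable CDSs")
  pct <- function(codon) 100 * sum(firsts == codon) / length(firsts)
  out <- c(ATG = pct("ATG"), GTG = pct("GTG"), TTG = pct("TTG"))
  out <- c(out, other = 100 - sum(out))
  attr(out, "n") <- length(firsts)
  out
}

#' Table-style summary of a multi-replicon genome
#'
#' One row per replicon plus a totals row: replicon size, %GC, rRNA/tRNA and
#' CDS counts, IS element counts by family, percent coding, and mean protein
#' pI. Sizes and counts total by summation; the total %GC and percent coding
#' are length-weighted and the total mean pI is protein-count-weighted.
#' Percentages are reported to one decimal and pI to two.
#'
#' @param replicons list of [replicon()]s.
#' @param pka a [pka_set()] for the pI column.
#' @param is_patterns label patterns identifying IS elements.
#' @param compute_pi set `FALSE` to skip the (relatively slow) pI column.
#' @return list of class `GenomeSummary` with `table` (data.frame, replicons
#'   then a `total` row) and `start_codons` (from [start_codon_census()]).
#' @export
summarize_genome <- function(replicons, pka = pka_set("embl"),
                             is_patterns = default_is_patterns(),
                             compute_pi = TRUE) {
  if (is_replicon(replicons)) replicons <- list(replicons)
  rows <- lapply(replicons, function(r) {
    f <- r$features[r$features$part == 1L, , drop = FALSE]
    is_elts <- is_element_features(r, is_patterns)
    fam <- function(p) sum(grepl(p, is_elts$label))
    n_ish51 <- fam("ISH51")
    n_is4 <- sum(grepl("IS4", is_elts$label) & !grepl("ISH51", is_elts$label))
    cn <- if (any(f$kind == "CDS")) coding_noncoding_gc(r) else
      list(percent_coding = NA_real_)
    pis <- if (compute_pi && any(f$kind == "CDS")) replicon_pis(r, pka) else
      numeric()
    data.frame(
      replicon = r$id,
      size_bp = r$length,
      gc_percent = round(gc_percent(r$sequence), 1),
      rrna = sum(f$kind == "rRNA"),
      trna = sum(f$kind == "tRNA"),
      cds = length(unique(f$id[f$kind == "CDS"])),
      is_ish51 = n_ish51,
      is_is4 = n_is4,
      is_other = nrow(is_elts) - n_ish51 - n_is4,
      is_total = nrow(is_elts),
      percent_coding = round(cn$percent_coding, 1),
      mean_pi = if (length(pis)) round(mean(pis), 2) else NA_real_,
      n_proteins = length(pis),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(
    replicon = "total",
    size_bp = sum(tab$size_bp),
    gc_percent = round(stats::weighted.mean(tab$gc_percent, tab$size_bp), 1),
    rrna = sum(tab$rrna), trna = sum(tab$trna), cds = sum(tab$cds),
    is_ish51 = sum(tab$is_ish51), is_is4 = sum(tab$is_is4),
    is_other = sum(tab$is_other), is_total = sum(tab$is_total),
    percent_coding = round(stats::weighted.mean(tab$percent_coding,
                                                tab$size_bp, na.rm = TRUE), 1),
    mean_pi = if (sum(tab$n_proteins) > 0) {
      round(stats::weighted.mean(tab$mean_pi, tab$n_proteins,
                                 na.rm = TRUE), 2)
    } else NA_real_,
    n_proteins = sum(tab$n_proteins),
    stringsAsFactors = FALSE)
  structure(list(table = rbind(tab, total),
                 start_codons = start_codon_census(replicons)),
            class = "GenomeSummary")
}

#' @export
print.GenomeSummary <- function(x, ...) {
  cat("<GenomeSummary>\n")
  print(x$table, row.names = FALSE)
  sc <- x$start_codons
  cat(sprintf("start codons: ATG %.1f%%, GTG %.1f%%, TTG %.1f%%, other %.1f%% (n = %d)\n",
              sc["ATG"], sc["GTG"], sc["TTG"], sc["other"], attr(sc, "n")))
  invisible(x)
}

#' Totals over a per-replicon feature table
#'
#' Sums the numeric columns of a per-replicon genome-feature table (such as
#' a published "general features" table read from TSV), e.g. to recover the
#' total genome size or total IS count from the per-replicon rows.
#'
#' @param tab data.frame with a `replicon` column and numeric feature
#'   columns; rows named `total` are ignored.
#' @return named numeric vector of column sums.
#' @export
replicon_feature_totals <- function(tab) {
  tab <- tab[tolower(tab$replicon) != "total", , drop = FALSE]
  num <- vapply(tab, is.numeric, logical(1))
  colSums(tab[, num, drop = FALSE], na.rm = TRUE)
}

#' Length of a region given 1-based inclusive coordinates
#' @param start,end 1-based inclusive bp coordinates.
#' @return length in bp.
#' @export
region_length <- function(start, end) {
  stopifnot(end >= start)
  end - start + 1
}

#' Published per-replicon feature table shipped with the package
#'
#' The per-replicon general-features table of the Haloferax volcanii DS2
#' genome (replicon sizes, GC, CDS and IS counts, percent coding, mean pI)
#' as printed in its genome report, for arithmetic cross-checks against
#' computed summaries.
#'
#' @param name `"replicon_features"` or `"regions"` (named printed regions,
#'   e.g. the low-GC island on the main chromosome, with 1-based inclusive
#'   coordinates).
#' @return data.frame.
#' @export
hvolcanii_table <- function(name = c("replicon_features", "regions")) {
  name <- match.arg(name)
  utils::read.delim(system.file("extdata", paste0("hvolcanii_", name, ".tsv"),
                                package = "haloscan"),
                    stringsAsFactors = FALSE)
}
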