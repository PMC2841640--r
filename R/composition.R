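#' GC percentage of a DNA string or slice
#'
#' Computed as 100*(G+C)/(A+C+G+T); N bases are excluded from both numerator
#' and denominator. A slice with no unambiguous base returns `NA`.
#'
#' @param sequence character scalar DNA string (uppercase A/C/G/T/N).
#' @return numeric percent in \[0, 100\], or `NA_real_`.
#' @export
gc_percent <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  cnt <- base_counts(sequence)
  denom <- sum(cnt[c("A", "C", "G", "T")])
  if (denom == 0L) return(NA_real_)
  100 * sum(cnt[c("G", "C")]) / denom
}

#' GC content of coding vs non-coding DNA and the coding fraction
#'
#' Coding bases are the union of all CDS spans (a base under two overlapping
#' CDSs is counted once); non-coding bases are the complement.
#'
#' @param r a [replicon()] with CDS features.
#' @return list with `coding_gc`, `noncoding_gc` and `percent_coding`
#'   (all percents).
#' @export
coding_noncoding_gc <- function(r) {
  stopifnot(is_replicon(r))
  cds <- r$features[r$features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features on replicon ", r$id)
  ir <- IRanges::reduce(IRanges::IRanges(start = cds$start + 1L,
                                         end = cds$end))
  coding_bp <- sum(IRanges::width(ir))
  prefix <- prefix_counts(r$sequence)
  coding <- Reduce(`+`, lapply(seq_along(ir), function(i) {
    span_counts(prefix, IRanges::start(ir)[i] - 1L, IRanges::end(ir)[i],
                r$length)
  }))
  total <- prefix[r$length + 1L, ]
  noncoding <- total - coding
  pct <- function(cnt) {
    denom <- sum(cnt)
    if (denom == 0) NA_real_ else 100 * sum(cnt[c("G", "C")]) / denom
  }
  list(coding_gc = pct(coding), noncoding_gc = pct(noncoding),
       percent_coding = 100 * coding_bp / r$length)
}

#' GC content by codon position
#'
#' Pools all supplied codons and reports the GC percentage at codon positions
#' 1, 2 and 3. Stop codons are excluded by default (the final codon of each
#' CDS as returned by [extract_cds_codons()] is a stop).
#'
#' @param codons a character vector of codons, or a (possibly nested) list of
#'   codon vectors as returned by [extract_cds_codons()] — pooled across
#'   replicons.
#' @param exclude_stops drop stop codons (TAA/TAG/TGA) before counting.
#' @return numeric length-3 vector of percents, names `pos1`..`pos3`.
#' @export
codon_position_gc <- function(codons, exclude_stops = TRUE) {
  codons <- unlist(codons, use.names = FALSE)
  if (!length(codons)) stop("empty codon set")
  if (exclude_stops) codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  if (!length(codons)) stop("no codons left after stop exclusion")
  gc_at <- function(p) {
    b <- substr(codons, p, p)
    100 * sum(b %in% c("G", "C")) / sum(b %in% c("A", "C", "G", "T"))
  }
  c(pos1 = gc_at(1L), pos2 = gc_at(2L), pos3 = gc_at(3L))
}

#' Windowed GC content track
#'
#' @param r a [replicon()].
#' @param window window size in bp.
#' @param stride step between window starts in bp.
#' @return data.frame with `start` (0-based), `end` and `gc` percent columns;
#'   circular replicons wrap, so the last windows cross the origin.
#' @export
windowed_gc <- function(r, window = 5000L, stride = 1000L) {
  idx <- window_starts(r, window, stride)
  prefix <- prefix_counts(r$sequence)
  gc <- vapply(idx, function(s) {
    cnt <- span_counts(prefix, s, s + window, r$length,
                       circular = r$topology == "circular")
    denom <- sum(cnt)
    if (denom == 0) NA_real_ else 100 * sum(cnt[c("G", "C")]) / denom
  }, numeric(1))
  data.frame(start = idx, end = idx + window, gc = gc)
}

#' Windowed chi-square deviation of local base composition
#'
#' For each window, chi2 = sum over bases b of (obs_b - L*p_b)^2 / (L*p_b),
#' where p_b are the replicon-wide base frequencies (over non-N bases) and L
#' is the window's non-N count. A base absent from the whole replicon is
#' skipped with a warning. Circular replicons wrap.
#'
#' @inheritParams windowed_gc
#' @return data.frame with `start`, `end`, `chi2` columns.
#' @export
window_composition_chi2 <- function(r, window = 5000L, stride = 1000L) {
  idx <- window_starts(r, window, stride)
  prefix <- prefix_counts(r$sequence)
  total <- prefix[r$length + 1L, ]
  p <- total / sum(total)
  if (any(p == 0)) {
    warning("base(s) absent from replicon skipped in chi-square: ",
            paste(names(p)[p == 0], collapse = ", "))
  }
  use <- p > 0
  chi2 <- vapply(idx, function(s) {
    obs <- span_counts(prefix, s, s + window, r$length,
                       circular = r$topology == "circular")
    L <- sum(obs)
    if (L == 0) return(NA_real_)
    expd <- L * p[use]
    sum((obs[use] - expd)^2 / expd)
  }, numeric(1))
  data.frame(start = idx, end = idx + window, chi2 = chi2)
}

window_starts <- function(r, window, stride) {
  stopifnot(is_replicon(r), window >= 1L, stride >= 1L)
  if (window > r$length) stop("window exceeds replicon length")
  if (r$topology == "circular") {
    seq.int(0L, r$length - 1L, by = stride)
  } else {
    seq.int(0L, r$length - window, by = stride)
  }
}

#' Full composition profile of a replicon
#'
#' Bundles the global, coding/non-coding and codon-position GC metrics with
#' the windowed GC and composition chi-square tracks.
#'
#' @param r a [replicon()].
#' @param window,stride window geometry in bp for the tracks.
#' @param exclude_stops passed to [codon_position_gc()].
#' @return list of class `CompositionProfile`.
#' @export
composition_profile <- function(r, window = 5000L, stride = 1000L,
                                exclude_stops = TRUE) {
  cn <- coding_noncoding_gc(r)
  codons <- extract_cds_codons(r)
  structure(list(
    replicon = r$id,
    global_gc = gc_percent(r$sequence),
    coding_gc = cn$coding_gc,
    noncoding_gc = cn$noncoding_gc,
    percent_coding = cn$percent_coding,
    pos_gc = codon_position_gc(codons, exclude_stops = exclude_stops),
    window_gc = windowed_gc(r, window, stride),
    window_chi2 = window_composition_chi2(r, window, stride)
  ), class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
  cat(sprintf(paste0(
    "<CompositionProfile> %s\n  GC %.1f%% (coding %.1f%%, non-coding %.1f%%)",
    "\n  codon-position GC %.1f / %.1f / %.1f%%\n  percent coding %.1f%%\n"),
    x$replicon, x$global_gc, x$coding_gc, x$noncoding_gc,
    x$pos_gc[1], x$pos_gc[2], x$pos_gc[3], x$percent_coding))
  invisible(x)
}
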