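# Synonymous codon usage (SCU) tables and the moving-window chi-square scan
# used to call genomic islands of atypical codon usage on a replicon.

#' Default excluded codons for SCU analyses
#'
#' The three stop codons plus ATG (Met) and TGG (Trp): stops are not
#' synonymous choices and Met/Trp are encoded by a single codon, so none of
#' them carries synonymous-usage information.
#' @return character vector of codons.
#' @export
default_scu_exclusions <- function() c("TAA", "TAG", "TGA", "ATG", "TGG")

# Codon universe under genetic code table 11 minus the excluded set, with the
# amino-acid family of each codon.
scu_codon_info <- function(exclude = default_scu_exclusions()) {
  code <- Biostrings::getGeneticCode("11")
  codons <- names(code)[!names(code) %in% exclude & code != "*"]
  list(codons = codons, aa = code[codons], exclude = exclude)
}

#' Count codons over the SCU codon universe
#'
#' @param codons character vector or list of codon vectors.
#' @param exclude codons left out of SCU analyses.
#' @return named integer vector over the non-excluded codon universe.
#' @export
scu_codon_counts <- function(codons, exclude = default_scu_exclusions()) {
  info <- scu_codon_info(exclude)
  codons <- unlist(codons, use.names = FALSE)
  cnt <- table(factor(codons, levels = info$codons))
  stats::setNames(as.integer(cnt), info$codons)
}

#' Build a synonymous codon usage table
#'
#' Pools codon counts over the supplied CDSs and converts them to relative
#' frequencies *within each synonymous family* (frequencies conditional on
#' the amino acid), so the table captures synonymous choice and not
#' amino-acid composition. One SCU table is typically built per replicon and
#' serves as the reference distribution for [window_chi2()].
#'
#' @param cds_codons list of codon vectors (one per CDS), e.g. from
#'   [extract_cds_codons()], or a pre-computed count vector from
#'   [scu_codon_counts()].
#' @param exclude codons excluded from the table (default stops + ATG + TGG).
#' @return object of class `SCUTable`: list with `codon_freq`, `codon_counts`,
#'   `aa_counts`, `excluded`, `n_cds`.
#' @export
build_scu <- function(cds_codons, exclude = default_scu_exclusions()) {
  info <- scu_codon_info(exclude)
  if (is.numeric(cds_codons) && !is.null(names(cds_codons))) {
    counts <- cds_codons[info$codons]
    counts[is.na(counts)] <- 0L
    counts <- stats::setNames(as.integer(counts), info$codons)
    n_cds <- NA_integer_
  } else {
    if (!length(cds_codons)) stop("no CDSs supplied")
    n_cds <- if (is.list(cds_codons)) length(cds_codons) else 1L
    counts <- scu_codon_counts(cds_codons, exclude)
  }
  if (sum(counts) == 0L) stop("zero usable codons")
  fam <- factor(info$aa)
  fam_tot <- tapply(counts, fam, sum)
  freq <- as.numeric(counts) / as.numeric(fam_tot[fam])
  freq[is.na(freq)] <- 0  # empty family: frequencies undefined, stored as 0
  structure(list(codon_freq = stats::setNames(freq, info$codons),
                 codon_counts = counts,
                 aa_counts = stats::setNames(as.integer(fam_tot),
                                             levels(fam)),
                 excluded = exclude, n_cds = n_cds),
            class = "SCUTable")
}

#' @export
print.SCUTable <- function(x, ...) {
  cat(sprintf("<SCUTable> %d codons over %d families (%s CDSs)\n",
              length(x$codon_freq), length(x$aa_counts),
              ifelse(is.na(x$n_cds), "?", x$n_cds)))
  invisible(x)
}

#' Degrees of freedom implied by an SCU table's codon universe
#'
#' Sum over synonymous families of (family size - 1); 41 for the default
#' exclusion set (59 codons in 18 families). The published scan used 40,
#' which remains the package default in [window_chi2()]; this helper gives
#' the value under which simulated family-conditional windows are actually
#' chi-square distributed.
#' @param exclude excluded codon set.
#' @return integer.
#' @export
scu_df <- function(exclude = default_scu_exclusions()) {
  info <- scu_codon_info(exclude)
  length(info$codons) - length(unique(info$aa))
}

#' Chi-square test of one window's codon counts against a reference SCU
#'
#' Expected counts condition on the window's amino-acid composition:
#' `exp_c = (window count of amino acid a) * ref freq(c)` for each codon `c`
#' of family `a`; `chi2 = sum (obs - exp)^2 / exp` over codons with positive
#' expectation. If the reference lacks a codon the window uses (`exp = 0`,
#' `obs > 0`) a pseudo-expectation of 0.5 is substituted with a warning.
#'
#' @param obs_counts named codon count vector ([scu_codon_counts()]).
#' @param ref reference [build_scu()] table.
#' @param df degrees of freedom for the upper-tail p-value (published scans
#'   used 40 with the default exclusion set; see [scu_df()]).
#' @return list with `chi2`, `df`, `p`.
#' @export
window_chi2 <- function(obs_counts, ref, df = 40L) {
  stopifnot(inherits(ref, "SCUTable"))
  info <- scu_codon_info(ref$excluded)
  obs <- obs_counts[info$codons]
  obs[is.na(obs)] <- 0
  fam <- factor(info$aa)
  n_a <- tapply(obs, fam, sum)
  expd <- as.numeric(n_a[fam]) * ref$codon_freq
  zero <- expd == 0 & obs > 0
  if (any(zero)) {
    warning("reference lacks codon(s) used in window: ",
            paste(info$codons[zero], collapse = ", "),
            "; pseudo-expectation 0.5 applied")
    expd[zero] <- 0.5
  }
  use <- expd > 0
  chi2 <- sum((obs[use] - expd[use])^2 / expd[use])
  list(chi2 = chi2, df = as.integer(df),
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Moving-window SCU scan along a replicon
#'
#' Slides a window of `window` consecutive CDSs (ordered by genomic start,
#' step `step` CDSs, wrapping on circular replicons) and tests each window's
#' codon counts against the reference SCU table with [window_chi2()].
#'
#' @param r a [replicon()] with CDS features.
#' @param window window size in CDSs.
#' @param step step in CDSs.
#' @param ref reference `SCUTable`; default is the replicon's own whole-
#'   replicon table.
#' @param df degrees of freedom (see [window_chi2()]).
#' @param exclude excluded codon set.
#' @return object of class `scu_scan`: list with `stats` (data.frame: `win`,
#'   `first_cds`, `last_cds`, `start`, `end`, `chi2`, `df`, `p`), the per-CDS
#'   count matrix, CDS spans, and the scan parameters. If fewer than `window`
#'   CDSs are present a single whole-replicon window is used with a warning.
#' @export
scan_replicon <- function(r, window = 30L, step = 1L, ref = NULL, df = 40L,
                          exclude = default_scu_exclusions()) {
  stopifnot(is_replicon(r), window >= 1L, step >= 1L)
  codons <- extract_cds_codons(r)
  cds <- r$features[r$features$kind == "CDS" & r$features$part == 1L, ,
                    drop = FALSE]
  cds <- cds[cds$id %in% names(codons), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  n <- nrow(cds)
  if (n == 0L) stop("no usable CDSs on replicon ", r$id)
  info <- scu_codon_info(exclude)
  counts <- vapply(cds$id, function(fid) {
    scu_codon_counts(codons[[fid]], exclude)
  }, numeric(length(info$codons)))
  if (is.null(ref)) ref <- build_scu(codons[cds$id], exclude)

  circular <- r$topology == "circular"
  if (n < window) {
    warning("replicon ", r$id, " has ", n, " < ", window,
            " CDSs; using a single whole-replicon window")
    window <- n
  }
  starts <- if (circular && n > window) seq.int(1L, n, by = step) else
    seq.int(1L, n - window + 1L, by = step)
  stats_df <- do.call(rbind, lapply(starts, function(s) {
    idx <- ((s - 1L + seq_len(window) - 1L) %% n) + 1L
    wc <- window_chi2(rowSums(counts[, idx, drop = FALSE]), ref, df)
    last <- idx[length(idx)]
    data.frame(win = s, first_cds = s, last_cds = last,
               start = cds$start[s], end = cds$end[last],
               chi2 = wc$chi2, df = wc$df, p = wc$p)
  }))
  rownames(stats_df) <- NULL
  structure(list(replicon = r$id, stats = stats_df, counts = counts,
                 cds = cds[, c("id", "start", "end", "strand")],
                 window = window, step = step, df = df, exclude = exclude,
                 n_cds = n, circular = circular, ref = ref),
            class = "scu_scan")
}

#' @export
print.scu_scan <- function(x, ...) {
  cat(sprintf("<scu_scan> %s: %d CDSs, %d windows of %d CDSs (df %d)\n",
              x$replicon, x$n_cds, nrow(x$stats), x$window, x$df))
  invisible(x)
}

#' Call genomic islands from a moving-window SCU scan
#'
#' Windows with `p < alpha` are merged into maximal runs (adjacent or
#' overlapping windows join; runs wrap across the origin of circular
#' replicons); runs shorter than `min_run` windows are discarded. The
#' reported CDS range of each island is taken from the run geometry: for
#' runs at least as long as the window, CDSs covered by significant windows
#' only (`[first significant start + window - 1, last significant start]`);
#' for shorter runs, the common intersection of the run's windows. Islands
#' are labelled `contains_IS` when any annotated IS element overlaps the
#' island span.
#'
#' @param scan a `scu_scan` from [scan_replicon()].
#' @param r the scanned [replicon()] (for IS annotation overlap).
#' @param alpha significance threshold on the window p-value.
#' @param min_run minimum number of significant windows in a run.
#' @param is_patterns label patterns identifying IS elements.
#' @return data.frame with one row per island: `replicon`, `start`, `end`
#'   (0-based half-open; `end` may exceed the length for origin-wrapping
#'   islands), `cds_from`, `cds_to`, `n_windows`, `min_p`, `label`,
#'   `best_reference`, `best_p` (the last two filled by
#'   [assign_reference()]).
#' @export
call_islands <- function(scan, r, alpha = 1e-4, min_run = 3L,
                         is_patterns = default_is_patterns()) {
  stopifnot(inherits(scan, "scu_scan"))
  st <- scan$stats
  sig <- st$p < alpha
  if (!any(sig)) return(empty_island_table())
  n_win <- nrow(st)
  runs <- significant_runs(sig, wrap = scan$circular && n_win == scan$n_cds)
  runs <- runs[vapply(runs, function(x) x["len"], numeric(1)) >= min_run]
  if (!length(runs)) return(empty_island_table())

  n <- scan$n_cds
  w <- scan$window
  out <- lapply(runs, function(run) {
    a <- st$win[run[["from"]]]
    b_raw <- st$win[((run[["from"]] - 1L + run[["len"]] - 1L) %% n_win) + 1L]
    b <- if (b_raw < a) b_raw + n else b_raw  # unrolled coordinates
    bounds <- sort(c(a + w - 1L, b))
    cds_from <- ((bounds[1L] - 1L) %% n) + 1L
    cds_to <- ((bounds[2L] - 1L) %% n) + 1L
    start <- scan$cds$start[cds_from]
    end <- scan$cds$end[cds_to]
    if (end <= start) end <- end + r$length  # wrapped island span
    idx <- ((run[["from"]] - 1L + seq_len(run[["len"]]) - 1L) %% n_win) + 1L
    data.frame(replicon = scan$replicon, start = start, end = end,
               cds_from = cds_from, cds_to = cds_to,
               n_windows = run[["len"]], min_p = min(st$p[idx]),
               label = NA_character_, best_reference = NA_character_,
               best_p = NA_real_, stringsAsFactors = FALSE)
  })
  isl <- do.call(rbind, out)
  isl$label <- ifelse(
    vapply(seq_len(nrow(isl)), function(i) {
      island_overlaps_is(r, isl$start[i], isl$end[i], is_patterns)
    }, logical(1)), "contains_IS", "no_IS")
  isl[order(isl$start), , drop = FALSE]
}

empty_island_table <- function() {
  data.frame(replicon = character(), start = integer(), end = integer(),
             cds_from = integer(), cds_to = integer(), n_windows = integer(),
             min_p = numeric(), label = character(),
             best_reference = character(), best_p = numeric(),
             stringsAsFactors = FALSE)
}

# Maximal runs of TRUE, optionally merging a run touching the end with one
# touching the start (circular scans). Returns list of c(from, len) in
# element indices.
significant_runs <- function(sig, wrap = FALSE) {
  r <- rle(sig)
  from <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  runs <- lapply(which(r$values), function(i) {
    c(from = from[i], len = r$lengths[i])
  })
  if (wrap && length(runs) >= 2L && sig[1L] && sig[length(sig)]) {
    first <- runs[[1L]]
    last <- runs[[length(runs)]]
    runs[[1L]] <- c(from = last[["from"]],
                    len = last[["len"]] + first[["len"]])
    runs <- runs[-length(runs)]
  }
  runs
}

island_overlaps_is <- function(r, start, end, is_patterns) {
  f <- r$features
  is_elt <- f$kind == "IS" |
    (!is.na(f$label) & Reduce(`|`, lapply(is_patterns, grepl, x = f$label),
                              FALSE))
  f <- f[is_elt, , drop = FALSE]
  if (!nrow(f)) return(FALSE)
  spans <- if (end > r$length) {
    list(c(start, r$length), c(0L, end - r$length))
  } else list(c(start, end))
  any(vapply(spans, function(sp) {
    any(f$start < sp[2L] & f$end > sp[1L])
  }, logical(1)))
}

#' Pooled codon counts of an island's member CDSs
#' @param scan the `scu_scan` the island was called from.
#' @param island one row of the [call_islands()] table.
#' @return named codon count vector.
#' @export
island_codon_counts <- function(scan, island) {
  n <- scan$n_cds
  from <- island$cds_from
  to <- island$cds_to
  idx <- if (to >= from) from:to else c(from:n, 1:to)
  rowSums(scan$counts[, idx, drop = FALSE])
}

#' Assign each island the reference replicon its SCU best matches
#'
#' Tests the island's pooled codon counts against each candidate replicon's
#' SCU table with [window_chi2()]; the best reference is the argmin chi2,
#' reported as "similar" only when its p-value is at least `alpha`. Ties in
#' chi2 go to the lexicographically smaller replicon id (and are reported
#' via a message).
#'
#' @param islands the [call_islands()] table.
#' @param scan the `scu_scan` the islands came from.
#' @param refs named list of candidate `SCUTable`s (>= 2), e.g. one per
#'   replicon of the genome.
#' @param df degrees of freedom.
#' @param alpha threshold below which even the best reference is not called
#'   similar.
#' @return the island table with `best_reference`, `best_chi2`, `best_p` and
#'   `similar` columns filled.
#' @export
assign_reference <- function(islands, scan, refs, df = 40L, alpha = 1e-4) {
  stopifnot(length(refs) >= 2L, !is.null(names(refs)))
  nm <- sort(names(refs))
  islands$best_chi2 <- NA_real_
  islands$similar <- NA
  for (i in seq_len(nrow(islands))) {
    counts <- island_codon_counts(scan, islands[i, ])
    res <- vapply(nm, function(k) {
      wc <- window_chi2(counts, refs[[k]], df)
      c(chi2 = wc$chi2, p = wc$p)
    }, numeric(2))
    best <- which(res["chi2", ] == min(res["chi2", ]))
    if (length(best) > 1L) message("chi2 tie between references ",
                                   paste(nm[best], collapse = ", "),
                                   "; smaller id wins")
    best <- best[1L]
    islands$best_reference[i] <- nm[best]
    islands$best_chi2[i] <- res["chi2", best]
    islands$best_p[i] <- res["p", best]
    islands$similar[i] <- res["p", best] >= alpha
  }
  islands
}

#' Write called islands as BED
#'
#' BED uses 0-based half-open spans; the name field is `label:best_reference`.
#' Origin-wrapping islands are emitted as two BED records sharing a name.
#'
#' @param islands [call_islands()] table (after [assign_reference()] if
#'   reference labels are wanted).
#' @param r the source [replicon()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, r, path) {
  rows <- list()
  for (i in seq_len(nrow(islands))) {
    name <- paste0(islands$label[i], ":",
                   ifelse(is.na(islands$best_reference[i]), ".",
                          islands$best_reference[i]))
    if (islands$end[i] > r$length) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = r$id, start = c(islands$start[i], 0L),
        end = c(r$length, islands$end[i] - r$length), name = name)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = r$id, start = islands$start[i], end = islands$end[i],
        name = name)
    }
  }
  write_bed(do.call(rbind, rows), path)
}
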