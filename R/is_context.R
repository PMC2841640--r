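# GC context of insertion-sequence (IS) elements: the overlay track behind
# the "genomes evolving away from their IS elements" picture, and a
# permutation test formalizing the insertion-site GC preference.

is_element_features <- function(r, is_patterns = default_is_patterns()) {
  f <- r$features
  hit <- f$kind == "IS" |
    (!is.na(f$label) & Reduce(`|`, lapply(is_patterns, grepl, x = f$label),
                              FALSE))
  f[hit & f$part == 1L, , drop = FALSE]
}

#' Genome GC track with per-IS-element GC marks
#'
#' Produces the windowed GC content of the replicon plus one (position, GC)
#' mark per annotated IS element, where the mark's GC is that of the
#' element's own sequence. In GC-rich genomes whose IS elements are AT-rich
#' the marks sit below the track.
#'
#' @param r a [replicon()].
#' @param window GC track window in bp (stride = window).
#' @param is_patterns label patterns identifying IS elements.
#' @return list with `track` (data.frame start/end/gc) and `marks`
#'   (data.frame id/label/pos/gc, one row per IS element). Empty marks with a
#'   warning when no IS is annotated.
#' @export
is_gc_overlay <- function(r, window = 5000L,
                          is_patterns = default_is_patterns()) {
  track <- windowed_gc(r, window = window, stride = window)
  elts <- is_element_features(r, is_patterns)
  if (!nrow(elts)) {
    warning("no IS elements annotated on replicon ", r$id)
    marks <- data.frame(id = character(), label = character(),
                        pos = integer(), gc = numeric())
  } else {
    marks <- data.frame(
      id = elts$id, label = elts$label,
      pos = as.integer((elts$start + elts$end) %/% 2L),
      gc = vapply(seq_len(nrow(elts)), function(i) {
        gc_percent(replicon_subseq(r, elts$start[i], elts$end[i]))
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }
  list(track = track, marks = marks)
}

# Mean GC over the two fixed-width flanks of each site (0-based element
# spans); computed from prefix counts so the permutation loop is O(1) per
# site.
flank_gc_mean <- function(prefix, starts, ends, flank, L, circular) {
  vals <- vapply(seq_along(starts), function(i) {
    s_left <- ((starts[i] - flank) %% L + L) %% L
    left <- span_counts(prefix, s_left, s_left + flank, L, circular)
    right <- span_counts(prefix, ends[i] %% L, ends[i] %% L + flank, L,
                         circular)
    cnt <- left + right
    denom <- sum(cnt)
    if (denom == 0) NA_real_ else 100 * sum(cnt[c("G", "C")]) / denom
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Permutation test for AT-rich IS insertion contexts
#'
#' Statistic T = mean GC of fixed-width flanking windows at the observed IS
#' sites. The null redraws the same number of positions uniformly at random
#' (avoiding annotated IS spans, so elements never sample their own
#' sequence) `n_perm` times; the one-sided p-value for the "IS sites sit in
#' AT-richer-than-random context" alternative is
#' `(1 + #\{T_null <= T_obs\}) / (1 + n_perm)`.
#'
#' @param r a [replicon()] with IS annotation.
#' @param flank flank width in bp on each side of a site.
#' @param n_perm number of permutations (>= 1000 recommended).
#' @param seed integer seed, recorded in the result.
#' @param is_patterns label patterns identifying IS elements.
#' @return object of class `ISContextResult`: list with `per_is` (data.frame
#'   id/label/element_gc/flank_gc), `t_obs`, `t_null` (vector), `p`,
#'   `n_perm`, `seed`, `flank`.
#' @export
insertion_site_permutation_test <- function(r, flank = 500L, n_perm = 1000L,
                                            seed = 1L,
                                            is_patterns = default_is_patterns()) {
  stopifnot(is_replicon(r), n_perm >= 1L, flank >= 1L)
  elts <- is_element_features(r, is_patterns)
  if (!nrow(elts)) stop("no IS elements annotated on replicon ", r$id)
  circular <- r$topology == "circular"
  if (r$length < 2L * flank + 1L) stop("replicon shorter than flank requirement")
  if (!circular && (any(elts$start < flank) ||
                    any(elts$end + flank > r$length))) {
    stop("IS element too close to the end of a linear replicon for flank ",
         flank)
  }
  prefix <- prefix_counts(r$sequence)

  per_is <- data.frame(
    id = elts$id, label = elts$label,
    element_gc = vapply(seq_len(nrow(elts)), function(i) {
      gc_percent(replicon_subseq(r, elts$start[i], elts$end[i]))
    }, numeric(1)),
    flank_gc = vapply(seq_len(nrow(elts)), function(i) {
      flank_gc_mean(prefix, elts$start[i], elts$end[i], flank, r$length,
                    circular)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  t_obs <- mean(per_is$flank_gc, na.rm = TRUE)

  # candidate positions outside annotated IS spans (and, on linear
  # replicons, far enough from the ends)
  occupied <- rep(FALSE, r$length)
  for (i in seq_len(nrow(elts))) {
    occupied[(elts$start[i] + 1L):elts$end[i]] <- TRUE
  }
  candidates <- which(!occupied)
  if (!circular) {
    candidates <- candidates[candidates > flank &
                               candidates <= r$length - flank]
  }
  if (!length(candidates)) stop("no candidate positions outside IS spans")

  t_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(j) {
      pos <- sample(candidates, nrow(elts), replace = FALSE) - 1L
      flank_gc_mean(prefix, pos, pos, flank, r$length, circular)
    }, numeric(1))
  })
  p <- (1 + sum(t_null <= t_obs)) / (1 + n_perm)
  structure(list(per_is = per_is, t_obs = t_obs, t_null = t_null, p = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 flank = as.integer(flank), replicon = r$id),
            class = "ISContextResult")
}

#' @export
print.ISContextResult <- function(x, ...) {
  cat(sprintf(paste0(
    "<ISContextResult> %s: %d IS elements\n",
    "  mean element GC %.1f%%, mean flank GC %.1f%% (null mean %.1f%%)\n",
    "  one-sided p = %.4g (%d permutations, seed %d, flank %d bp)\n"),
    x$replicon, nrow(x$per_is), mean(x$per_is$element_gc),
    x$t_obs, mean(x$t_null), x$p, x$n_perm, x$seed, x$flank))
  invisible(x)
}

#' Write an IS-context summary TSV
#'
#' The header records seed, permutation count and flank width so runs are
#' reproducible from the output alone.
#' @param result an `ISContextResult`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_is_context_tsv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# replicon=%s t_obs=%.4f p=%.6g n_perm=%d seed=%d flank=%d",
                     result$replicon, result$t_obs, result$p, result$n_perm,
                     result$seed, result$flank), con)
  utils::write.table(result$per_is, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
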