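#' Cumulative nucleotide-disparity (Z-curve) components
#'
#' Each component assigns every base an increment of +1, -1 or 0 and the
#' curve is the running sum along the replicon: GC = G-C, AT = A-T,
#' RY = purines minus pyrimidines (A+G-C-T), MK = amino minus keto
#' (A+C-G-T), WS = weak minus strong (A+T-G-C). Slope changes of the GC
#' curve are the classical replication-origin signal. N contributes 0.
#'
#' @param r a [replicon()].
#' @param component one of `"GC"`, `"AT"`, `"RY"`, `"MK"`, `"WS"`.
#' @param stride storage stride in bp: the curve is evaluated at every base
#'   but stored at positions `stride, 2*stride, ...` (and always the last
#'   base). `stride = 1` stores the full-resolution curve.
#' @return object of class `SkewCurve`: list with `replicon`, `component`,
#'   `pos` (1-based bp), `value`, `stride`, `length`, `offset_origin` and the
#'   sequence (kept so the curve can be recomputed after rotation).
#' @export
cumulative_disparity <- function(r, component = c("GC", "AT", "RY", "MK", "WS"),
                                 stride = 100L) {
  component <- match.arg(component)
  stopifnot(is_replicon(r), stride >= 1L)
  inc <- disparity_increments(r$sequence, component)
  values <- cumsum(inc)
  pos <- unique(c(seq.int(stride, r$length, by = stride), r$length))
  structure(list(replicon = r$id, component = component, pos = pos,
                 value = values[pos], stride = stride, length = r$length,
                 offset_origin = NULL, sequence = r$sequence,
                 topology = r$topology),
            class = "SkewCurve")
}

disparity_increments <- function(sequence, component) {
  raw <- charToRaw(sequence)
  plus <- switch(component,
                 GC = "G", AT = "A", RY = c("A", "G"), MK = c("A", "C"),
                 WS = c("A", "T"))
  minus <- switch(component,
                  GC = "C", AT = "T", RY = c("C", "T"), MK = c("G", "T"),
                  WS = c("G", "C"))
  inc <- integer(length(raw))
  for (b in plus) inc <- inc + (raw == charToRaw(b))
  for (b in minus) inc <- inc - (raw == charToRaw(b))
  inc
}

#' @export
print.SkewCurve <- function(x, ...) {
  cat(sprintf("<SkewCurve> %s %s: %d bp, final value %d, stride %d\n",
              x$replicon, x$component, x$length, x$value[length(x$value)],
              x$stride))
  invisible(x)
}

#' Recompute a skew curve with the origin as x = 0
#'
#' The sequence is rotated so that `origin` becomes the first base and the
#' cumulative sums are recomputed from the rotated sequence (not merely
#' shifted), as when aligning curves of different replicons at their
#' replication origins.
#'
#' @param curve a `SkewCurve` from [cumulative_disparity()].
#' @param origin 0-based bp used as the new x = 0.
#' @return a new `SkewCurve` with `offset_origin` recorded.
#' @export
rotate_to_origin <- function(curve, origin) {
  stopifnot(inherits(curve, "SkewCurve"))
  if (curve$topology != "circular") stop("rotation requires a circular replicon")
  if (origin < 0L || origin > curve$length) {
    stop("origin outside [0, length)")
  }
  if (origin == curve$length) origin <- 0L  # full-turn rotation is identity
  seq_rot <- if (origin == 0L) curve$sequence else
    paste0(substr(curve$sequence, origin + 1L, curve$length),
           substr(curve$sequence, 1L, origin))
  r <- replicon(curve$replicon, seq_rot, topology = "circular")
  out <- cumulative_disparity(r, curve$component, stride = curve$stride)
  out$offset_origin <- origin
  out
}

#' Windowed GC skew track
#'
#' Per-window (G-C)/(G+C); windows with G+C = 0 yield `NA`.
#'
#' @param r a [replicon()].
#' @param window,stride window geometry in bp.
#' @return data.frame with `start` (0-based), `end`, `value` columns.
#' @export
windowed_gc_skew <- function(r, window = 5000L, stride = 1000L) {
  idx <- window_starts(r, window, stride)
  prefix <- prefix_counts(r$sequence)
  value <- vapply(idx, function(s) {
    cnt <- span_counts(prefix, s, s + window, r$length,
                       circular = r$topology == "circular")
    gpc <- cnt[["G"]] + cnt[["C"]]
    if (gpc == 0) NA_real_ else (cnt[["G"]] - cnt[["C"]]) / gpc
  }, numeric(1))
  data.frame(start = idx, end = idx + window, value = value)
}

#' Locate the extremum of a cumulative skew curve
#'
#' Position of the global minimum (default) or maximum of the stored curve;
#' ties are broken by the smallest coordinate. On curves from replicons with
#' a single origin and terminus the GC-curve minimum marks the origin-side
#' slope change. Optional moving-average smoothing is available; the default
#' uses the raw curve.
#'
#' @param curve a `SkewCurve`.
#' @param what `"min"` or `"max"`.
#' @param smooth odd integer window (in stored points) for a moving average;
#'   `0` disables smoothing.
#' @return 1-based bp position of the extremum.
#' @export
locate_skew_extremum <- function(curve, what = c("min", "max"), smooth = 0L) {
  what <- match.arg(what)
  stopifnot(inherits(curve, "SkewCurve"))
  v <- curve$value
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    v <- stats::filter(v, k, sides = 2)
  }
  ok <- !is.na(v)
  if (!any(ok) || diff(range(v[ok])) == 0) stop("no extremum: constant curve")
  i <- if (what == "min") which(v == min(v[ok]))[1L] else
    which(v == max(v[ok]))[1L]
  curve$pos[i]
}

#' Export a skew curve as a bedGraph track
#' @param curve a `SkewCurve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skew_bedgraph <- function(curve, path) {
  starts <- c(0L, curve$pos[-length(curve$pos)])
  write_bedgraph(data.frame(chrom = curve$replicon, start = starts,
                            end = curve$pos, value = curve$value),
                 path, name = paste0(curve$component, "_disparity"))
}
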