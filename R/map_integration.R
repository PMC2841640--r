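# Calibration between legacy genetic-map coordinates (kb) and assembly
# coordinates (bp) by a median marker offset, with outlier rejection, and
# projection of legacy intervals onto the assembly.

#' Calibrate the map-to-assembly offset from a marker table
#'
#' Each marker contributes two offsets, `genome_start - 1000*map_start_kb`
#' and `genome_end - 1000*map_end_kb`; the calibration offset is the median
#' of the pooled start and end offsets over usable markers (a mean is
#' available for sensitivity, and both are reported). Markers whose mapped
#' gene length differs from the assembly gene length by more than
#' `length_ratio`-fold are flagged as outliers and the median recomputed
#' once without them; markers named in `exclude` (e.g. large operons the map
#' could not resolve) are dropped up front.
#'
#' @param markers data.frame with columns `name`, `map_start_kb`,
#'   `map_end_kb`, `genome_start`, `genome_end` (assembly coordinates
#'   1-based bp).
#' @param length_ratio fold-change in marker gene length above which a
#'   marker is flagged as an outlier.
#' @param exclude character vector of marker names excluded from
#'   calibration (kept in the output, flagged).
#' @return list of class `map_calibration`: `offset` (bp, the median),
#'   `offset_mean`, `markers` (input plus `offset_start`, `offset_end`,
#'   `residual_start`, `residual_end`, `outlier`, `excluded` columns),
#'   `n_used`.
#' @export
calibrate_offset <- function(markers, length_ratio = 2, exclude = character()) {
  needed <- c("name", "map_start_kb", "map_end_kb", "genome_start",
              "genome_end")
  stopifnot(all(needed %in% names(markers)))
  m <- markers
  m$offset_start <- m$genome_start - 1000 * m$map_start_kb
  m$offset_end <- m$genome_end - 1000 * m$map_end_kb
  m$excluded <- m$name %in% exclude
  m$outlier <- FALSE

  usable <- !m$excluded
  if (sum(usable) < 3L) stop("fewer than 3 usable markers")
  pooled <- function(sel) c(m$offset_start[sel], m$offset_end[sel])
  med <- stats::median(pooled(usable))

  map_len <- 1000 * (m$map_end_kb - m$map_start_kb)
  gen_len <- m$genome_end - m$genome_start
  ratio <- ifelse(map_len > 0 & gen_len > 0,
                  pmax(map_len / gen_len, gen_len / map_len), NA_real_)
  m$outlier <- usable & !is.na(ratio) & ratio > length_ratio
  if (any(m$outlier)) {
    usable <- usable & !m$outlier
    if (sum(usable) < 3L) stop("fewer than 3 usable markers after outlier rejection")
    med <- stats::median(pooled(usable))
  }
  m$residual_start <- m$offset_start - med
  m$residual_end <- m$offset_end - med
  structure(list(offset = med, offset_mean = mean(pooled(usable)),
                 markers = m, n_used = sum(usable)),
            class = "map_calibration")
}

#' @export
print.map_calibration <- function(x, ...) {
  cat(sprintf(paste0(
    "<map_calibration> offset %.0f bp (median; mean %.1f) from %d markers",
    "; %d outlier(s), %d excluded\n"),
    x$offset, x$offset_mean, x$n_used, sum(x$markers$outlier),
    sum(x$markers$excluded)))
  invisible(x)
}

#' Map a genetic-map position to an assembly coordinate
#'
#' `1000*x + offset`, wrapped modulo the replicon length for circular
#' chromosomes, returned 1-based.
#'
#' @param x_kb position(s) on the genetic map, kb.
#' @param offset calibration offset in bp ([calibrate_offset()]`$offset`).
#' @param length replicon length in bp.
#' @return 1-based assembly bp position(s).
#' @export
map_to_genome <- function(x_kb, offset, length) {
  ((round(1000 * x_kb) + offset - 1) %% length) + 1
}

#' Inverse of [map_to_genome()]
#' @param bp 1-based assembly position(s).
#' @inheritParams map_to_genome
#' @return map position(s) in kb.
#' @export
genome_to_map <- function(bp, offset, length) {
  (((bp - offset - 1) %% length) + 1) / 1000
}

#' Project legacy map intervals onto the assembly
#'
#' Converts a table of genetic-map intervals (with condition labels, e.g.
#' transcription under high/low salt) into assembly-coordinate BED records
#' and lists the annotated genes overlapping each projected interval.
#'
#' @param intervals data.frame with columns `map_start_kb`, `map_end_kb`
#'   and `label`.
#' @param offset calibration offset in bp.
#' @param r the target [replicon()].
#' @return data.frame with `chrom`, `start`, `end` (BED: 0-based half-open;
#'   wrapping intervals are split into two rows sharing a name), `name`
#'   (label) and `genes` (comma-separated overlapping CDS ids, `""` when
#'   none).
#' @export
project_intervals <- function(intervals, offset, r) {
  stopifnot(all(c("map_start_kb", "map_end_kb", "label") %in%
                  names(intervals)), is_replicon(r))
  if (any(1000 * (intervals$map_end_kb - intervals$map_start_kb) > r$length)) {
    stop("interval exceeds map length")
  }
  cds <- r$features[r$features$kind == "CDS", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    g_start <- (round(1000 * intervals$map_start_kb[i]) + offset) %% r$length
    g_end_excl <- g_start + round(1000 * (intervals$map_end_kb[i] -
                                            intervals$map_start_kb[i]))
    spans <- if (g_end_excl > r$length && r$topology == "circular") {
      list(c(g_start, r$length), c(0, g_end_excl - r$length))
    } else {
      list(c(g_start, min(g_end_excl, r$length)))
    }
    for (sp in spans) {
      hit <- cds$start < sp[2] & cds$end > sp[1]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = r$id, start = as.integer(sp[1]), end = as.integer(sp[2]),
        name = intervals$label[i],
        genes = paste(unique(cds$id[hit]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read / write marker tables
#'
#' Plain TSV with the [calibrate_offset()] column contract.
#' @param path file path.
#' @return data.frame.
#' @export
read_marker_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_marker_tsv
#' @param calibration a `map_calibration` object.
#' @export
write_calibration_tsv <- function(calibration, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# offset_median_bp=%.1f offset_mean_bp=%.1f n_used=%d",
                     calibration$offset, calibration$offset_mean,
                     calibration$n_used), con)
  utils::write.table(calibration$markers, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
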