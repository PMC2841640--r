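#' Replicon: a named DNA sequence plus its feature annotations
#'
#' The unit every scan in this package operates on. A replicon holds one
#' uppercase DNA sequence over \{A,C,G,T,N\}, a topology flag, and an ordered
#' feature table. Internal coordinates are 0-based half-open throughout the
#' package; reporting functions convert to 1-based inclusive.
#'
#' @param id character scalar, replicon name (e.g. an accession).
#' @param sequence character scalar DNA string. Lowercase is uppercased;
#'   IUPAC ambiguity codes other than N are mapped to N with a warning.
#' @param topology `"circular"` or `"linear"`.
#' @param features a feature `data.frame` as returned by [feature_table()].
#'
#' @return An object of class `Replicon`: a list with elements `id`,
#'   `sequence`, `topology`, `features` and `length`.
#' @seealso [feature_table()], [read_genome()]
#' @export
replicon <- function(id, sequence, topology = c("circular", "linear"),
                     features = feature_table()) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- normalize_dna(sequence)
  features <- as_feature_table(features)
  if (nrow(features)) {
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
    bad <- features$start < 0L | features$end > nchar(sequence) |
      features$start >= features$end
    if (any(bad)) {
      stop("feature span(s) outside [0, length) or empty: ",
           paste(features$id[bad], collapse = ", "))
    }
  }
  structure(
    list(id = id, sequence = sequence, topology = topology,
         features = features, length = nchar(sequence)),
    class = "Replicon"
  )
}

#' @export
print.Replicon <- function(x, ...) {
  cat(sprintf("<Replicon> %s: %s bp (%s), %d features\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              nrow(x$features)))
  if (nrow(x$features)) {
    print(utils::head(as.data.frame(table(x$features$kind)), 10))
  }
  invisible(x)
}

#' Construct a feature table
#'
#' Features use 0-based half-open spans. A feature wrapping the origin of a
#' circular replicon is represented as two rows sharing one `id`, ordered by
#' the `part` column in 5'-to-3' transcript order.
#'
#' @param kind one of `"CDS"`, `"IS"`, `"tRNA"`, `"rRNA"`, `"other"`.
#' @param start,end integer, 0-based half-open span on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param id feature identifier (shared between parts of a split feature).
#' @param label free-text product / family label (e.g. `"ISH51"`).
#' @param translation optional amino-acid string for CDS features (`NA` to
#'   translate from the sequence).
#' @param partial logical, `TRUE` for annotated partial CDSs (excluded from
#'   codon analyses without a warning).
#' @param part integer part ordinal for origin-split features.
#' @return `data.frame` with one row per feature part.
#' @export
feature_table <- function(kind = character(), start = integer(), end = integer(),
                          strand = character(), id = character(),
                          label = character(), translation = character(),
                          partial = logical(), part = integer()) {
  n <- max(length(kind), length(start))
  if (n > 0L) {
    if (!length(label)) label <- rep(NA_character_, n)
    if (!length(translation)) translation <- rep(NA_character_, n)
    if (!length(partial)) partial <- rep(FALSE, n)
    if (!length(part)) part <- rep(1L, n)
    if (!length(strand)) strand <- rep("+", n)
  }
  data.frame(kind = as.character(kind), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             id = as.character(id), label = as.character(label),
             translation = as.character(translation),
             partial = as.logical(partial), part = as.integer(part),
             stringsAsFactors = FALSE)
}

as_feature_table <- function(x) {
  if (is.null(x) || !nrow(as.data.frame(x))) return(feature_table())
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  needed <- c("kind", "start", "end", "strand", "id")
  missing <- setdiff(needed, names(x))
  if (length(missing)) stop("feature table lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (is.null(x$label)) x$label <- NA_character_
  if (is.null(x$translation)) x$translation <- NA_character_
  if (is.null(x$partial)) x$partial <- FALSE
  if (is.null(x$part)) x$part <- 1L
  feature_table(x$kind, x$start, x$end, x$strand, x$id, x$label,
                x$translation, x$partial, x$part)
}

#' @rdname replicon
#' @param x object to test.
#' @export
is_replicon <- function(x) inherits(x, "Replicon")

# Uppercase and collapse non-ACGTN IUPAC codes to N.
normalize_dna <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    warning("ambiguity codes other than N mapped to N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  sequence
}

#' Extract a (possibly wrapping) subsequence
#'
#' @param r a [replicon()].
#' @param start,end 0-based half-open span; on circular replicons `end` may
#'   exceed the length, in which case the span wraps through the origin.
#' @return character scalar.
#' @export
replicon_subseq <- function(r, start, end) {
  stopifnot(is_replicon(r), start >= 0L, end > start)
  L <- r$length
  if (end <= L) return(substr(r$sequence, start + 1L, end))
  if (r$topology != "circular") stop("span exceeds linear replicon length")
  if (end - start > L) stop("span longer than replicon")
  paste0(substr(r$sequence, start + 1L, L), substr(r$sequence, 1L, end - L))
}

# Base counting on raw bytes: fast and dependency-free.
base_counts <- function(sequence) {
  r <- charToRaw(sequence)
  c(A = sum(r == as.raw(65L)), C = sum(r == as.raw(67L)),
    G = sum(r == as.raw(71L)), T = sum(r == as.raw(84L)),
    N = sum(r == as.raw(78L)))
}

# Cumulative per-base counts; prefix[i + 1, b] = count of base b in seq[1..i].
# Shared backbone for all windowed statistics.
prefix_counts <- function(sequence) {
  r <- charToRaw(sequence)
  m <- cbind(A = cumsum(r == as.raw(65L)), C = cumsum(r == as.raw(67L)),
             G = cumsum(r == as.raw(71L)), T = cumsum(r == as.raw(84L)))
  rbind(c(A = 0, C = 0, G = 0, T = 0), m)
}

# Counts of A,C,G,T in the 0-based half-open span [start, end), wrapping on
# circular sequences when end > L.
span_counts <- function(prefix, start, end, L, circular = FALSE) {
  if (end <= L) return(prefix[end + 1L, ] - prefix[start + 1L, ])
  if (!circular) stop("span exceeds linear replicon length")
  (prefix[L + 1L, ] - prefix[start + 1L, ]) + prefix[end - L + 1L, ]
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] keeping plain character
#' vectors as the package currency.
#' @param sequence character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}
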