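#' Read an annotated genome into Replicon objects
#'
#' Reads either GenBank flat files (one or more records per file) or a
#' FASTA + GFF3 pair, converting the 1-based inclusive coordinates of those
#' formats to the package's internal 0-based half-open convention. CDS
#' translations are taken from the file when present (GenBank `/translation`,
#' or a protein FASTA whose record names are CDS ids); otherwise CDSs are
#' translated on demand with the bacterial/archaeal genetic code (table 11).
#'
#' @param paths for `format = "genbank"`, a character vector of GenBank flat
#'   files; for `format = "fasta_gff3"`, a named character vector or list with
#'   elements `fasta`, `gff` and optionally `proteins`.
#' @param format input format.
#' @param topology topology assigned to records that do not declare one
#'   (GFF3 carries it in a `#!topology <seqid> <circular|linear>` pragma
#'   written by [write_genome()]; GenBank in the LOCUS line).
#' @param is_patterns regular expressions; a non-CDS feature whose label
#'   matches any of them is classified as an IS element. The default reflects
#'   annotation-based IS recognition (ISH51 / IS4 families, transposases).
#' @return list of [replicon()] objects, one per sequence record.
#' @export
read_genome <- function(paths, format = c("genbank", "fasta_gff3"),
                        topology = c("circular", "linear"),
                        is_patterns = default_is_patterns()) {
  format <- match.arg(format)
  topology <- match.arg(topology)
  if (format == "genbank") {
    reps <- unlist(lapply(paths, read_genbank, is_patterns = is_patterns),
                   recursive = FALSE)
  } else {
    reps <- read_fasta_gff3(paths, topology = topology,
                            is_patterns = is_patterns)
  }
  names(reps) <- vapply(reps, function(r) r$id, character(1))
  reps
}

#' @rdname read_genome
#' @export
default_is_patterns <- function() c("ISH51", "IS4", "transposase")

read_fasta_gff3 <- function(paths, topology, is_patterns) {
  paths <- as.list(paths)
  if (is.null(paths$fasta) || is.null(paths$gff)) {
    stop("fasta_gff3 input needs paths$fasta and paths$gff")
  }
  seqs <- Biostrings::readDNAStringSet(paths$fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  topo <- read_topology_pragma(paths$gff)
  gr <- tryCatch(rtracklayer::import(paths$gff, format = "gff3"),
                 error = function(e) stop("GFF3 parse failure in ", paths$gff,
                                          ": ", conditionMessage(e)))
  meta <- S4Vectors::mcols(gr)
  prot <- NULL
  if (!is.null(paths$proteins) && file.exists(paths$proteins)) {
    aa <- Biostrings::readAAStringSet(paths$proteins)
    prot <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }
  lapply(names(seqs), function(sid) {
    sel <- as.character(GenomicRanges::seqnames(gr)) == sid
    feats <- feature_table()
    if (any(sel)) {
      type <- as.character(meta$type[sel])
      keep <- type %in% c("CDS", "tRNA", "rRNA", "mobile_element",
                          "repeat_region", "misc_feature")
      if (any(keep)) {
        idx <- which(sel)[keep]
        type <- type[keep]
        id <- as.character(meta$ID[idx])
        id[is.na(id) | !nzchar(id)] <- paste0(sid, "_f", seq_along(idx))[
          is.na(id) | !nzchar(id)]
        label <- gff_label(meta, idx)
        kind <- classify_feature_kind(type, label, is_patterns)
        part <- if (!is.null(meta$part)) {
          suppressWarnings(as.integer(as.character(meta$part[idx])))
        } else rep(NA_integer_, length(idx))
        part[is.na(part)] <- 1L
        partial <- if (!is.null(meta$partial)) {
          tolower(as.character(meta$partial[idx])) %in% "true"
        } else rep(FALSE, length(idx))
        feats <- feature_table(
          kind = kind,
          start = BiocGenerics::start(gr)[idx] - 1L,  # 1-based -> 0-based
          end = BiocGenerics::end(gr)[idx],
          strand = sub("\\*", "+", as.character(BiocGenerics::strand(gr)[idx])),
          id = id, label = label,
          translation = if (is.null(prot)) rep(NA_character_, length(idx)) else
            unname(prot[id]),
          partial = partial, part = part)
      }
    }
    replicon(sid, as.character(seqs[[sid]]),
             topology = if (!is.null(topo[[sid]])) topo[[sid]] else topology,
             features = feats)
  })
}

gff_label <- function(meta, idx) {
  label <- rep(NA_character_, length(idx))
  for (col in c("product", "Name", "mobile_element_type", "note")) {
    if (!is.null(meta[[col]])) {
      v <- as.character(meta[[col]][idx])
      label[is.na(label) & !is.na(v) & nzchar(v)] <-
        v[is.na(label) & !is.na(v) & nzchar(v)]
    }
  }
  label
}

classify_feature_kind <- function(type, label, is_patterns) {
  kind <- rep("other", length(type))
  kind[type == "CDS"] <- "CDS"
  kind[type == "tRNA"] <- "tRNA"
  kind[type == "rRNA"] <- "rRNA"
  mobile <- type %in% c("mobile_element", "repeat_region", "misc_feature")
  is_hit <- !is.na(label) &
    Reduce(`|`, lapply(is_patterns, grepl, x = label), FALSE)
  kind[mobile & is_hit] <- "IS"
  kind
}

read_topology_pragma <- function(gff_path) {
  head <- readLines(gff_path, warn = FALSE)
  head <- head[startsWith(head, "#!topology")]
  out <- list()
  for (h in head) {
    f <- strsplit(trimws(h), "\\s+")[[1]]
    if (length(f) >= 3L) out[[f[2]]] <- f[3]
  }
  out
}

# ---- GenBank flat-file reader -------------------------------------------
# Minimal parser for the subset this package needs: LOCUS (name, length,
# topology), FEATURES (CDS / tRNA / rRNA / mobile_element / repeat_region
# with join/complement locations and the usual qualifiers), ORIGIN sequence.

read_genbank <- function(path, is_patterns = default_is_patterns()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "LOCUS"))
  if (!length(starts)) stop("GenBank parse failure in ", path,
                            ": no LOCUS line")
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    parse_genbank_record(lines[starts[i]:ends[i]], path, is_patterns)
  })
}

parse_genbank_record <- function(lines, path, is_patterns) {
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  id <- locus[2L]
  topology <- if ("circular" %in% tolower(locus)) "circular" else "linear"

  ori_at <- grep("^ORIGIN", lines)[1L]
  if (is.na(ori_at)) stop("GenBank parse failure in ", path, " (", id,
                          "): no ORIGIN section")
  seq_lines <- lines[(ori_at + 1L):length(lines)]
  seq_lines <- seq_lines[!startsWith(seq_lines, "//")]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)[1L]
  feats <- feature_table()
  if (!is.na(feat_at) && feat_at + 1L < ori_at) {
    block <- lines[(feat_at + 1L):(ori_at - 1L)]
    feats <- parse_genbank_features(block, id, path, is_patterns)
  }
  replicon(id, sequence, topology = topology, features = feats)
}

parse_genbank_features <- function(block, id, path, is_patterns) {
  # A new feature starts with a key in columns 6-20.
  is_key <- grepl("^ {5}\\S", block)
  if (!any(is_key)) return(feature_table())
  key_at <- which(is_key)
  key_end <- c(key_at[-1L] - 1L, length(block))
  rows <- list()
  counter <- 0L
  for (k in seq_along(key_at)) {
    entry <- block[key_at[k]:key_end[k]]
    key <- sub("^ {5}(\\S+).*", "\\1", entry[1L])
    if (!key %in% c("CDS", "tRNA", "rRNA", "mobile_element", "repeat_region",
                    "misc_feature")) next
    counter <- counter + 1L
    body <- c(sub("^ {5}\\S+\\s*", "", entry[1L]), trimws(entry[-1L]))
    qual_start <- which(startsWith(body, "/"))[1L]
    loc_text <- paste(body[seq_len(if (is.na(qual_start)) length(body) else
      qual_start - 1L)], collapse = "")
    loc <- parse_genbank_location(loc_text, path, id)
    quals <- parse_genbank_qualifiers(
      if (is.na(qual_start)) character() else body[qual_start:length(body)])
    fid <- quals[["locus_tag"]] %||% quals[["gene"]] %||%
      sprintf("%s_%s_%d", id, key, counter)
    label <- quals[["product"]] %||% quals[["mobile_element_type"]] %||%
      quals[["note"]] %||% NA_character_
    kind <- if (key %in% c("CDS", "tRNA", "rRNA")) key else
      classify_feature_kind(key, label, is_patterns)
    n_part <- nrow(loc$parts)
    rows[[length(rows) + 1L]] <- feature_table(
      kind = rep(kind, n_part),
      start = loc$parts$start, end = loc$parts$end,
      strand = rep(loc$strand, n_part),
      id = rep(fid, n_part), label = rep(label, n_part),
      translation = rep(quals[["translation"]] %||% NA_character_, n_part),
      partial = rep(loc$partial || !is.null(quals[["pseudo"]]), n_part),
      part = seq_len(n_part))
  }
  if (!length(rows)) return(feature_table())
  do.call(rbind, rows)
}

# "complement(join(100..200,300..400))" etc. -> 0-based half-open parts in
# transcript join order (complementing reverses the read direction but the
# stored spans stay forward-strand).
parse_genbank_location <- function(text, path, id) {
  text <- gsub("\\s", "", text)
  strand <- "+"
  if (grepl("^complement\\(", text)) {
    strand <- "-"
    text <- sub("^complement\\((.*)\\)$", "\\1", text)
  }
  text <- sub("^(join|order)\\((.*)\\)$", "\\2", text)
  partial <- grepl("[<>]", text)
  text <- gsub("[<>]", "", text)
  pieces <- strsplit(text, ",")[[1L]]
  bounds <- lapply(pieces, function(p) {
    m <- regmatches(p, regexec("^(\\d+)(\\.\\.(\\d+))?$", p))[[1L]]
    if (!length(m)) stop("GenBank parse failure in ", path, " (", id,
                         "): bad location '", p, "'")
    a <- as.integer(m[2L])
    b <- if (nzchar(m[4L])) as.integer(m[4L]) else a
    c(a, b)
  })
  parts <- data.frame(start = vapply(bounds, `[`, integer(1), 1L) - 1L,
                      end = vapply(bounds, `[`, integer(1), 2L))
  list(parts = parts, strand = strand, partial = partial)
}

parse_genbank_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  starts <- which(startsWith(lines, "/"))
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    text <- paste(lines[starts[i]:ends[i]], collapse = " ")
    m <- regmatches(text, regexec("^/([A-Za-z_]+)(=(.*))?$", text))[[1L]]
    if (!length(m)) next
    key <- m[2L]
    val <- if (nzchar(m[3L])) gsub("^\"|\"$", "", m[4L]) else TRUE
    if (identical(key, "translation") && is.character(val)) {
      val <- gsub("\\s", "", val)
    }
    out[[key]] <- val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Codon extraction ----------------------------------------------------

#' Extract codons for every usable CDS of a replicon
#'
#' Minus-strand CDSs are reverse-complemented so codons are listed 5' to 3';
#' the stop codon is retained as the final codon. CDSs whose concatenated
#' length is not a multiple of three are excluded from codon analyses (with a
#' warning unless annotated partial), and any codon containing an internal N
#' is dropped from the counts.
#'
#' @param r a [replicon()].
#' @return named list, one character vector of codons per usable CDS id.
#' @export
extract_cds_codons <- function(r) {
  stopifnot(is_replicon(r))
  cds <- r$features[r$features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features on replicon ", r$id)
  out <- list()
  dropped_n <- 0L
  bad_len <- character()
  for (fid in unique(cds$id)) {
    rows <- cds[cds$id == fid, , drop = FALSE]
    rows <- rows[order(rows$part), , drop = FALSE]
    txt <- paste0(substring(r$sequence, rows$start + 1L, rows$end),
                  collapse = "")
    if (rows$strand[1L] == "-") txt <- revcomp(txt)
    n <- nchar(txt)
    if (n %% 3L != 0L) {
      if (!rows$partial[1L]) bad_len <- c(bad_len, fid)
      next
    }
    if (rows$partial[1L]) next  # excluded from codon analyses, no warning
    codons <- substring(txt, seq(1L, n, 3L), seq(3L, n, 3L))
    has_n <- grepl("N", codons, fixed = TRUE)
    dropped_n <- dropped_n + sum(has_n)
    out[[fid]] <- codons[!has_n]
  }
  if (length(bad_len)) {
    warning(length(bad_len), " CDS(s) with length not a multiple of 3 ",
            "excluded from codon analyses: ",
            paste(utils::head(bad_len, 5L), collapse = ", "))
  }
  if (dropped_n > 0L) message(dropped_n, " codon(s) containing N dropped")
  out
}

#' CDS translations for a replicon
#'
#' Uses the annotation's `translation` when present (authoritative),
#' otherwise translates the extracted codons with genetic code table 11,
#' dropping a terminal stop.
#'
#' @param r a [replicon()].
#' @return named character vector of amino-acid strings.
#' @export
cds_translations <- function(r) {
  cds <- r$features[r$features$kind == "CDS" & r$features$part == 1L, ,
                    drop = FALSE]
  if (!nrow(cds)) return(stats::setNames(character(), character()))
  have <- !is.na(cds$translation) & nzchar(cds$translation)
  out <- stats::setNames(cds$translation, cds$id)
  if (any(!have)) {
    codons <- extract_cds_codons(r)
    code <- Biostrings::getGeneticCode("11")
    for (fid in cds$id[!have]) {
      cv <- codons[[fid]]
      if (is.null(cv)) next
      aa <- paste0(code[cv], collapse = "")
      out[fid] <- sub("\\*$", "", aa)
    }
  }
  out[!is.na(out) & nzchar(out)]
}

# ---- Writers -------------------------------------------------------------

#' Write replicons as FASTA + GFF3 (+ protein FASTA)
#'
#' The GFF3 carries 1-based inclusive coordinates per the standard, a
#' `#!topology` pragma per replicon, and `part`/`partial` attributes so that
#' a write/read round trip through [read_genome()] is lossless.
#'
#' @param replicons list of [replicon()] objects.
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @return named character vector of the files written.
#' @export
write_genome <- function(replicons, dir, prefix = "genome") {
  if (is_replicon(replicons)) replicons <- list(replicons)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fna"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  faa <- file.path(dir, paste0(prefix, ".faa"))
  seqs <- Biostrings::DNAStringSet(vapply(replicons, function(r) r$sequence,
                                          character(1)))
  names(seqs) <- vapply(replicons, function(r) r$id, character(1))
  Biostrings::writeXStringSet(seqs, fasta, width = 80L)

  out <- c("##gff-version 3")
  type_of <- c(CDS = "CDS", IS = "mobile_element", tRNA = "tRNA",
               rRNA = "rRNA", other = "misc_feature")
  for (r in replicons) {
    out <- c(out,
             sprintf("##sequence-region %s 1 %d", r$id, r$length),
             sprintf("#!topology %s %s", r$id, r$topology))
    f <- r$features
    if (!nrow(f)) next
    attrs <- sprintf("ID=%s;part=%d", f$id, f$part)
    has_label <- !is.na(f$label)
    attrs[has_label] <- paste0(attrs[has_label], ";product=",
                               gsub("[;=,\t]", "_", f$label[has_label]))
    attrs[f$partial] <- paste0(attrs[f$partial], ";partial=true")
    out <- c(out, sprintf("%s\thaloscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                          r$id, type_of[f$kind], f$start + 1L, f$end,
                          f$strand, ifelse(f$kind == "CDS", "0", "."), attrs))
  }
  writeLines(out, gff)

  prots <- unlist(lapply(replicons, cds_translations))
  if (length(prots)) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(prots), faa, width = 80L)
  } else {
    faa <- NA_character_
  }
  c(fasta = fasta, gff = gff, proteins = faa)
}

#' Write a normalized feature table as TSV (1-based inclusive coordinates)
#' @param replicons list of [replicon()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(replicons, path) {
  if (is_replicon(replicons)) replicons <- list(replicons)
  tabs <- lapply(replicons, function(r) {
    f <- r$features
    if (!nrow(f)) return(NULL)
    data.frame(replicon = r$id, kind = f$kind, start = f$start + 1L,
               end = f$end, strand = f$strand, id = f$id, label = f$label,
               partial = f$partial, part = f$part, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write spans as BED (0-based half-open, per the BED standard)
#' @param spans data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name` and `score`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(spans, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(spans)))
  bed <- data.frame(spans$chrom, spans$start, spans$end,
                    if (!is.null(spans$name)) spans$name else ".",
                    if (!is.null(spans$score)) spans$score else 0)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a windowed track as bedGraph
#' @param track data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param path output file.
#' @param name track name written in the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = "track") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(track[, c("chrom", "start", "end", "value")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
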