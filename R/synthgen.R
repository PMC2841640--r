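# Seeded generator of annotated synthetic multi-replicon genomes. Every
# statistical structure the scans assume can be planted with known ground
# truth: codon-usage profiles (host vs island), IS elements with a GC
# insertion preference, a replication origin inducing strand-asymmetric
# composition, AT valleys, and a jittered genetic-marker map.

#' Build a per-family codon-usage profile at a target third-position GC
#'
#' Within each synonymous family, codons are weighted by `gc3` when their
#' third base is G or C and by `1 - gc3` otherwise, then normalized. `gc3 =
#' 0.5` is (near-)uniform synonymous usage; values near 1 give a strongly
#' GC-ending profile like a haloarchaeal host, values near 0 an AT-ending
#' profile like a laterally acquired island.
#'
#' @param gc3 probability weight on GC-ending codons, in \[0, 1\].
#' @param exclude excluded codon set (kept consistent with the SCU scans).
#' @return named numeric vector of family-conditional codon frequencies.
#' @export
codon_profile <- function(gc3 = 0.5, exclude = default_scu_exclusions()) {
  info <- scu_codon_info(exclude)
  w <- ifelse(substr(info$codons, 3L, 3L) %in% c("G", "C"), gc3, 1 - gc3)
  fam <- factor(info$aa)
  tot <- tapply(w, fam, sum)
  stats::setNames(w / as.numeric(tot[fam]), info$codons)
}

#' Specify one synthetic replicon
#'
#' @param id replicon name.
#' @param length backbone length in bp before IS insertion (inserted IS
#'   elements extend the final sequence).
#' @param topology `"circular"` or `"linear"`.
#' @param gc background (intergenic) GC fraction in \[0, 1\].
#' @param n_cds number of CDSs.
#' @param cds_len_range codon count range (uniform, inclusive, incl. start
#'   and stop codons).
#' @param host_profile [codon_profile()] used for host CDSs.
#' @param islands list of `list(at_cds =, n_cds =, profile =)` entries:
#'   CDSs `at_cds .. at_cds + n_cds - 1` are drawn from `profile` instead.
#' @param is_elements list of `list(family =, n =, gc =, pref_strength =,
#'   length =)` entries; insertion sites are sampled from intergenic
#'   positions with weight `exp(-pref_strength * local GC fraction)`
#'   (1 kb window), so positive strengths prefer AT-rich context.
#' @param ori `list(pos =, g =)`: replication origin position (bp) and
#'   leading-strand G excess `g` (intergenic bases on the leading half get
#'   P(G) = gc/2 + g, P(C) = gc/2 - g; reversed on the lagging half),
#'   producing a V-shaped cumulative GC curve with its vertex at `pos`.
#' @param valleys `list(n =, gc =)`: number of intergenic gaps drawn at the
#'   lower `gc` instead of the background (AT valleys).
#' @param aa_freq optional named amino-acid frequency vector for CDS
#'   interiors (default [default_aa_freq()]; see [acidic_aa_freq()] for an
#'   acid-shifted proteome).
#' @return list of class `synth_replicon_spec`.
#' @export
synth_replicon_spec <- function(id, length, topology = "circular", gc = 0.6,
                                n_cds = 0L, cds_len_range = c(150L, 450L),
                                host_profile = codon_profile(0.8),
                                islands = list(), is_elements = list(),
                                ori = NULL, valleys = NULL, aa_freq = NULL) {
  stopifnot(gc >= 0, gc <= 1, length > 0)
  structure(list(id = id, length = as.integer(length), topology = topology,
                 gc = gc, n_cds = as.integer(n_cds),
                 cds_len_range = as.integer(cds_len_range),
                 host_profile = host_profile, islands = islands,
                 is_elements = is_elements, ori = ori, valleys = valleys,
                 aa_freq = aa_freq),
            class = "synth_replicon_spec")
}

#' Specify a synthetic genome
#'
#' @param seed master integer seed. Each replicon draws from its own
#'   pseudo-random stream derived from it, so adding a replicon does not
#'   perturb the others.
#' @param replicons list of [synth_replicon_spec()]s.
#' @param markers optional `list(replicon =, n =, offset =, jitter_kb =,
#'   outlier =)`: a genetic-marker map over CDSs of one replicon, with map
#'   positions offset by `offset` bp plus uniform jitter of up to
#'   `jitter_kb` kb per endpoint; `outlier = TRUE` corrupts one marker's
#'   mapped gene length fourfold.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(seed, replicons, markers = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(seed = as.integer(seed), replicons = replicons,
                 markers = markers), class = "synth_spec")
}

#' Default amino-acid usage for synthetic CDS interiors
#'
#' Near-uniform over the 18 degenerate amino acids, with Met and Trp kept
#' rare (their codons are excluded from SCU statistics anyway).
#' @return named numeric frequency vector summing to 1.
#' @export
default_aa_freq <- function() {
  info <- scu_codon_info()
  fams <- unique(info$aa)
  f <- stats::setNames(rep(1, length(fams)), fams)
  f <- c(f, M = 0.3, W = 0.2)
  f / sum(f)
}

#' Acid-shifted amino-acid usage
#'
#' Boosts aspartate/glutamate and depletes lysine relative to
#' [default_aa_freq()], emulating the acidic proteomes of halophiles.
#' @param boost multiplicative weight on D and E (K is divided by it).
#' @return named numeric frequency vector summing to 1.
#' @export
acidic_aa_freq <- function(boost = 3) {
  f <- default_aa_freq()
  f[c("D", "E")] <- f[c("D", "E")] * boost
  f["K"] <- f["K"] / boost
  f / sum(f)
}

sample_codons_for_aa <- function(aa, profile, info) {
  codons <- character(length(aa))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    fam_codons <- info$codons[info$aa == a]
    pr <- profile[fam_codons]
    codons[idx] <- sample(fam_codons, length(idx), replace = TRUE, prob = pr)
  }
  codons
}

sample_background <- function(n, p_g, p_c, gc) {
  # p_g / p_c may be per-position vectors (origin skew); A and T symmetric.
  p_a <- (1 - gc) / 2
  u <- stats::runif(n)
  base <- rep("T", n)
  base[u < p_a + p_c + p_g] <- "G"
  base[u < p_a + p_c] <- "C"
  base[u < p_a] <- "A"
  base
}

generate_replicon <- function(rspec, aa_freq, info) {
  if (!is.null(rspec$aa_freq)) aa_freq <- rspec$aa_freq
  L <- rspec$length
  n_cds <- rspec$n_cds
  lens <- if (n_cds > 0L) {
    sample(rspec$cds_len_range[1L]:rspec$cds_len_range[2L], n_cds,
           replace = TRUE)
  } else integer()
  cds_bp <- 3L * sum(lens)
  if (cds_bp >= L) stop("requested CDSs exceed replicon capacity")
  n_gaps <- n_cds + 1L
  gap_len <- as.integer(stats::rmultinom(1L, L - cds_bp,
                                         rep(1, n_gaps))[, 1L])

  # which gaps are AT valleys
  valley_gap <- rep(FALSE, n_gaps)
  if (!is.null(rspec$valleys) && rspec$valleys$n > 0L && n_gaps > 2L) {
    valley_gap[sample(2:(n_gaps - 1L), min(rspec$valleys$n, n_gaps - 2L))] <-
      TRUE
  }

  # which CDS ordinals belong to which island profile
  profile_of <- rep(0L, n_cds)  # 0 = host
  for (k in seq_along(rspec$islands)) {
    isl <- rspec$islands[[k]]
    span <- isl$at_cds + seq_len(isl$n_cds) - 1L
    if (any(span > n_cds)) stop("island exceeds replicon CDS count")
    if (any(profile_of[span] != 0L)) stop("island spans overlap")
    profile_of[span] <- k
  }

  # layout first so origin-skewed background knows its positions
  piece_len <- integer(2L * n_cds + 1L)
  piece_len[seq(1L, length(piece_len), by = 2L)] <- gap_len
  if (n_cds > 0L) piece_len[seq(2L, length(piece_len), by = 2L)] <- 3L * lens
  piece_end <- cumsum(piece_len)
  piece_start <- piece_end - piece_len  # 0-based

  pieces <- character(length(piece_len))
  feats <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_along(piece_len)) {
    if (i %% 2L == 1L) {  # intergenic gap
      n <- piece_len[i]
      if (n == 0L) next
      gap_idx <- (i + 1L) %/% 2L
      gc_here <- if (valley_gap[gap_idx]) rspec$valleys$gc else rspec$gc
      if (is.null(rspec$ori)) {
        p_g <- p_c <- gc_here / 2
      } else {
        pos <- piece_start[i] + seq_len(n) - 1L
        leading <- ((pos - rspec$ori$pos) %% L) < L / 2
        p_g <- ifelse(leading, gc_here / 2 + rspec$ori$g,
                      gc_here / 2 - rspec$ori$g)
        p_c <- gc_here - p_g
      }
      pieces[i] <- paste0(sample_background(n, p_g, p_c, gc_here),
                          collapse = "")
    } else {  # CDS
      ord <- i %/% 2L
      profile <- if (profile_of[ord] == 0L) rspec$host_profile else
        rspec$islands[[profile_of[ord]]]$profile
      aa <- sample(names(aa_freq), lens[ord] - 2L, replace = TRUE,
                   prob = aa_freq)
      body <- character(length(aa))
      is_m <- aa == "M"
      is_w <- aa == "W"
      body[is_m] <- "ATG"
      body[is_w] <- "TGG"
      rest <- !(is_m | is_w)
      body[rest] <- sample_codons_for_aa(aa[rest], profile, info)
      cds_txt <- paste0("ATG", paste0(body, collapse = ""),
                        sample(stops, 1L))
      strand <- sample(c("+", "-"), 1L)
      pieces[i] <- if (strand == "+") cds_txt else revcomp(cds_txt)
      feats[[length(feats) + 1L]] <- feature_table(
        kind = "CDS", start = piece_start[i], end = piece_end[i],
        strand = strand, id = sprintf("%s_cds%04d", rspec$id, ord))
    }
  }
  sequence <- paste0(pieces, collapse = "")
  features <- if (length(feats)) do.call(rbind, feats) else feature_table()

  truth <- list()
  for (k in seq_along(rspec$islands)) {
    isl <- rspec$islands[[k]]
    span <- isl$at_cds + seq_len(isl$n_cds) - 1L
    cds_rows <- 2L * span
    truth[[length(truth) + 1L]] <- data.frame(
      type = "island", name = sprintf("island%d", k),
      start = piece_start[cds_rows[1L]], end = piece_end[cds_rows[length(cds_rows)]],
      value = NA_real_, cds_from = span[1L], cds_to = span[length(span)])
  }

  # IS insertion: pick all sites on the current sequence, then splice from
  # the right so coordinates of remaining sites stay valid.
  is_new <- list()
  if (length(rspec$is_elements)) {
    occupied <- rep(FALSE, nchar(sequence))
    for (j in seq_len(nrow(features))) {
      occupied[(features$start[j] + 1L):features$end[j]] <- TRUE
    }
    prefix <- prefix_counts(sequence)
    Lc <- nchar(sequence)
    local_gc <- function(pos0) {
      s <- max(0L, pos0 - 500L)
      e <- min(Lc, pos0 + 500L)
      cnt <- span_counts(prefix, s, e, Lc)
      sum(cnt[c("G", "C")]) / max(1, sum(cnt))
    }
    counter <- 0L
    for (spec_k in rspec$is_elements) {
      cand <- which(!occupied)
      if (length(cand) < spec_k$n) stop("not enough intergenic space for IS")
      strength <- spec_k$pref_strength %||% 0
      w <- if (strength == 0) rep(1, length(cand)) else
        exp(-strength * vapply(cand - 1L, local_gc, numeric(1)))
      pick <- sample(cand, spec_k$n, prob = w) - 1L
      occupied[pick + 1L] <- TRUE
      elt_len <- spec_k$length %||% 1200L
      for (p in pick) {
        counter <- counter + 1L
        is_new[[length(is_new) + 1L]] <- list(
          pos = p, family = spec_k$family, gc = spec_k$gc,
          len = elt_len,
          id = sprintf("%s_is%03d", rspec$id, counter))
      }
    }
    # splice right-to-left
    ord <- order(vapply(is_new, function(x) x$pos, numeric(1)),
                 decreasing = TRUE)
    for (x in is_new[ord]) {
      elt <- paste0(sample_background(x$len, x$gc / 2, x$gc / 2, x$gc),
                    collapse = "")
      sequence <- paste0(substr(sequence, 1L, x$pos), elt,
                         substr(sequence, x$pos + 1L, nchar(sequence)))
      shift <- features$start >= x$pos
      features$start[shift] <- features$start[shift] + x$len
      features$end[shift] <- features$end[shift] + x$len
      for (ti in seq_along(truth)) {
        if (truth[[ti]]$start >= x$pos) {
          truth[[ti]]$start <- truth[[ti]]$start + x$len
          truth[[ti]]$end <- truth[[ti]]$end + x$len
        }
      }
      if (!is.null(rspec$ori) && rspec$ori$pos >= x$pos) {
        rspec$ori$pos <- rspec$ori$pos + x$len
      }
      # shift the not-yet-spliced sites too (they are all <= x$pos except
      # processed ones, so only equality is possible and harmless)
      features <- rbind(features, feature_table(
        kind = "IS", start = x$pos, end = x$pos + x$len, strand = "+",
        id = x$id, label = x$family))
    }
  }
  features <- features[order(features$start), , drop = FALSE]

  is_rows <- features[features$kind == "IS", , drop = FALSE]
  for (j in seq_len(nrow(is_rows))) {
    truth[[length(truth) + 1L]] <- data.frame(
      type = "is_site", name = is_rows$id[j], start = is_rows$start[j],
      end = is_rows$end[j], value = NA_real_, cds_from = NA_integer_,
      cds_to = NA_integer_)
  }
  if (!is.null(rspec$ori)) {
    truth[[length(truth) + 1L]] <- data.frame(
      type = "ori", name = "ori", start = rspec$ori$pos,
      end = rspec$ori$pos, value = rspec$ori$g, cds_from = NA_integer_,
      cds_to = NA_integer_)
  }
  r <- replicon(rspec$id, sequence, topology = rspec$topology,
                features = features)
  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(truth_df)) truth_df$replicon <- rspec$id
  list(replicon = r, truth = truth_df)
}

#' Generate a synthetic annotated genome
#'
#' Deterministic given the spec (identical spec + seed yields byte-identical
#' output). When `dir` is given, writes FASTA + GFF3 + protein FASTA via
#' [write_genome()], a marker TSV and a ground-truth manifest TSV with a
#' versioned header.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory.
#' @return list with `replicons` (named list of [replicon()]s), `manifest`
#'   (data.frame of planted truths: islands, IS sites, origins),
#'   `markers` (data.frame or NULL), `marker_offset` (true offset, bp) and
#'   `paths` (files written, when `dir` was given).
#' @export
generate_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  info <- scu_codon_info()
  aa_freq <- default_aa_freq()
  out <- list()
  for (i in seq_along(spec$replicons)) {
    stream_seed <- (spec$seed + 7919L * i) %% 2147483647L
    out[[i]] <- with_seed(stream_seed, {
      generate_replicon(spec$replicons[[i]], aa_freq, info)
    })
  }
  replicons <- lapply(out, `[[`, "replicon")
  names(replicons) <- vapply(replicons, function(r) r$id, character(1))
  manifest <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(out, `[[`, "truth")))

  markers <- NULL
  marker_offset <- NULL
  if (!is.null(spec$markers)) {
    ms <- spec$markers
    marker_offset <- ms$offset
    r <- replicons[[ms$replicon]]
    markers <- with_seed((spec$seed + 104729L) %% 2147483647L, {
      synth_marker_table(r, ms)
    })
  }

  paths <- NULL
  if (!is.null(dir)) {
    paths <- write_genome(replicons, dir, prefix = "synthetic")
    if (!is.null(markers)) {
      mp <- file.path(dir, "synthetic_markers.tsv")
      utils::write.table(markers, mp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, markers = mp)
    }
    manifest_path <- file.path(dir, "synthetic_manifest.tsv")
    con <- file(manifest_path, "w")
    writeLines(sprintf("# haloscan synthetic manifest v1 seed=%d", spec$seed),
               con)
    man_out <- if (is.null(manifest)) {
      data.frame(type = character(), name = character(), start = integer(),
                 end = integer(), value = numeric(), cds_from = integer(),
                 cds_to = integer(), replicon = character())
    } else manifest
    utils::write.table(man_out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths <- c(paths, manifest = manifest_path)
  }
  list(replicons = replicons, manifest = manifest, markers = markers,
       marker_offset = marker_offset, paths = paths)
}

synth_marker_table <- function(r, ms) {
  ms$jitter_kb <- ms$jitter_kb %||% 5
  cds <- r$features[r$features$kind == "CDS" & r$features$part == 1L, ,
                    drop = FALSE]
  margin <- 1000 * (ms$jitter_kb + 2)
  eligible <- cds[cds$start + 1L > ms$offset + margin, , drop = FALSE]
  if (nrow(eligible) < ms$n) stop("not enough CDSs beyond the offset for markers")
  pick <- eligible[sort(sample(nrow(eligible), ms$n)), , drop = FALSE]
  g_start <- pick$start + 1L
  g_end <- pick$end
  # Map resolution error displaces a marker as a unit: on the legacy map a
  # gene's start and end derive from one measured position plus its known
  # extent, so both endpoints share the marker's jitter.
  jit <- stats::runif(ms$n, -ms$jitter_kb, ms$jitter_kb)
  map_start <- (g_start - ms$offset) / 1000 + jit
  map_end <- (g_end - ms$offset) / 1000 + jit
  if (isTRUE(ms$outlier)) {
    # one marker with a grossly wrong mapped gene length
    map_end[ms$n] <- map_start[ms$n] + 4 * (g_end[ms$n] - g_start[ms$n]) / 1000
  }
  data.frame(name = sprintf("mk%02d", seq_len(ms$n)),
             map_start_kb = round(map_start, 3),
             map_end_kb = round(map_end, 3),
             genome_start = g_start, genome_end = g_end,
             stringsAsFactors = FALSE)
}

#' Sample null SCU windows from a reference table
#'
#' Draws `n` windows of `window` synthetic CDSs whose amino-acid counts
#' follow the reference's amino-acid usage and whose codons follow its
#' family-conditional frequencies — the null distribution for calibrating
#' the moving-window chi-square scan.
#'
#' @param ref a [build_scu()] table.
#' @param n number of windows.
#' @param window CDSs per window.
#' @param cds_len_range codon count range per CDS.
#' @param seed integer seed.
#' @return numeric matrix, codon universe x `n` windows, of codon counts.
#' @export
null_window_sampler <- function(ref, n, window = 30L,
                                cds_len_range = c(150L, 450L), seed = 1L) {
  stopifnot(inherits(ref, "SCUTable"))
  info <- scu_codon_info(ref$excluded)
  fam <- factor(info$aa)
  aa_tot <- ref$aa_counts[levels(fam)]
  aa_tot[is.na(aa_tot)] <- 0
  aa_freq <- aa_tot / sum(aa_tot)
  with_seed(seed, {
    vapply(seq_len(n), function(j) {
      n_codons <- sum(sample(cds_len_range[1L]:cds_len_range[2L], window,
                             replace = TRUE))
      n_aa <- stats::rmultinom(1L, n_codons, aa_freq)[, 1L]
      counts <- numeric(length(info$codons))
      for (a in levels(fam)) {
        if (n_aa[[a]] == 0L) next
        sel <- which(info$aa == a)
        pr <- ref$codon_freq[sel]
        if (sum(pr) == 0) next
        counts[sel] <- stats::rmultinom(1L, n_aa[[a]], pr)[, 1L]
      }
      stats::setNames(counts, info$codons)
    }, numeric(length(info$codons)))
  })
}
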