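# Protein isoelectric points under the Henderson-Hasselbalch group-charge
# model, and proteome-level pI summaries.

#' Load a named pKa set
#'
#' Side-chain and terminal pKa values are shipped as a plain-text table. Two
#' sets are included: `"embl"`, the EMBL/EMBOSS values used by the classical
#' BioPerl pI calculator (the set haloarchaeal proteome pI figures were
#' computed with), and `"expasy"`, the Bjellqvist-style values, for
#' sensitivity checks (proteome means typically move by ~0.05 pH units
#' between sets).
#'
#' @param name set name, or a named numeric vector with entries `Nterm`,
#'   `Cterm` and side chains among `C`, `D`, `E`, `H`, `K`, `R`, `Y` to use
#'   custom values directly.
#' @return named numeric vector of pKa values.
#' @export
pka_set <- function(name = "embl") {
  if (is.numeric(name)) {
    stopifnot(all(c("Nterm", "Cterm") %in% names(name)),
              all(name > 0 & name < 14))
    return(name)
  }
  tab <- utils::read.delim(system.file("extdata", "pka_sets.tsv",
                                       package = "haloscan"))
  tab <- tab[tab$set == name, , drop = FALSE]
  if (!nrow(tab)) stop("unknown pKa set: ", name)
  stats::setNames(tab$pka, tab$group)
}

basic_groups <- c("Nterm", "H", "K", "R")
acidic_groups <- c("Cterm", "C", "D", "E", "Y")

ionizable_counts <- function(sequence) {
  r <- charToRaw(toupper(sequence))
  cnt <- c(Nterm = 1, Cterm = 1,
           C = sum(r == charToRaw("C")), D = sum(r == charToRaw("D")),
           E = sum(r == charToRaw("E")), H = sum(r == charToRaw("H")),
           K = sum(r == charToRaw("K")), R = sum(r == charToRaw("R")),
           Y = sum(r == charToRaw("Y")))
  cnt
}

#' Net charge of a protein at a given pH
#'
#' Q = sum over basic groups of n/(1 + 10^(pH - pKa)) minus sum over acidic
#' groups of n/(1 + 10^(pKa - pH)); basic groups are the N-terminus, H, K, R
#' and acidic groups the C-terminus, D, E, C, Y. Residues without an entry in
#' the pKa set (and unknown letters) carry no charge. Q is strictly
#' decreasing in pH, which guarantees a unique isoelectric point.
#'
#' @param sequence amino-acid string (one-letter codes).
#' @param pH numeric vector of pH values.
#' @param pka a [pka_set()].
#' @return numeric vector of net charges, same length as `pH`.
#' @export
net_charge <- function(sequence, pH, pka = pka_set("embl")) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  cnt <- ionizable_counts(sequence)
  q <- numeric(length(pH))
  for (g in intersect(basic_groups, names(pka))) {
    q <- q + cnt[[g]] / (1 + 10^(pH - pka[[g]]))
  }
  for (g in intersect(acidic_groups, names(pka))) {
    q <- q - cnt[[g]] / (1 + 10^(pka[[g]] - pH))
  }
  q
}

#' Isoelectric point of a protein
#'
#' The unique root of [net_charge()] on pH 0..14, found by bisection until
#' the bracketing interval is narrower than `tol_ph` (so the returned pH is
#' within `tol_ph` of the root regardless of how shallow the charge curve
#' is); an optional early exit on |Q| < `tol_q` is available but disabled by
#' default, because near-neutral sequences have charge curves flat enough
#' that a charge-based stop leaves the pH displaced by much more than
#' `tol_ph`.
#'
#' @inheritParams net_charge
#' @param tol_q,tol_ph convergence tolerances on |charge| and pH width.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = pka_set("embl"),
                              tol_q = 0, tol_ph = 1e-4) {
  lo <- 0
  hi <- 14
  q_lo <- net_charge(sequence, lo, pka)
  q_hi <- net_charge(sequence, hi, pka)
  if (q_lo < 0 || q_hi > 0) stop("no isoelectric point in pH [0, 14]")
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka)
    if ((tol_q > 0 && abs(q) < tol_q) || (hi - lo) < tol_ph) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Proteome pI summary
#'
#' Computes pI per protein, the mean pI (reported to two decimals) per
#' replicon and per localization class, and a histogram on configurable pH
#' bins for inspecting uni- vs bimodality of the proteome distribution.
#'
#' @param proteins named character vector of amino-acid sequences (or a
#'   named numeric vector of pre-computed pIs).
#' @param replicon optional character vector parallel to `proteins` with the
#'   source replicon of each protein.
#' @param classes optional named character vector (names = protein ids)
#'   of localization labels such as `"cytosolic"` / `"transmembrane"`; class
#'   means are computed only over labelled proteins.
#' @param bin histogram bin width in pH units.
#' @param pka a [pka_set()].
#' @return list with `pi` (data.frame id/replicon/pi/class), `mean_pi`,
#'   `by_replicon`, `by_class` (two-decimal means; `NA` for empty classes)
#'   and `histogram` (data.frame mid/count).
#' @export
proteome_pi_summary <- function(proteins, replicon = NULL, classes = NULL,
                                bin = 0.2, pka = pka_set("embl")) {
  stopifnot(length(proteins) >= 1L)
  pis <- if (is.numeric(proteins)) proteins else
    vapply(proteins, isoelectric_point, numeric(1), pka = pka)
  ids <- names(proteins) %||% paste0("p", seq_along(proteins))
  df <- data.frame(id = ids,
                   replicon = replicon %||% rep(NA_character_, length(pis)),
                   pi = unname(pis),
                   class = if (is.null(classes)) NA_character_ else
                     unname(classes[ids]),
                   stringsAsFactors = FALSE)
  breaks <- seq(0, 14 + bin, by = bin)
  h <- graphics::hist(df$pi, breaks = breaks, plot = FALSE)
  by_class <- if (is.null(classes)) NULL else
    round(tapply(df$pi, df$class, mean), 2)
  list(pi = df,
       mean_pi = round(mean(df$pi), 2),
       by_replicon = if (is.null(replicon)) NULL else
         round(tapply(df$pi, df$replicon, mean), 2),
       by_class = by_class,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' pI of every protein on a replicon
#'
#' Convenience wrapper: translations via [cds_translations()], pI via
#' [isoelectric_point()].
#'
#' @param r a [replicon()].
#' @param pka a [pka_set()].
#' @return named numeric vector of pIs.
#' @export
replicon_pis <- function(r, pka = pka_set("embl")) {
  prots <- cds_translations(r)
  prots <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "", toupper(prots))
  prots <- prots[nzchar(prots)]
  vapply(prots, isoelectric_point, numeric(1), pka = pka)
}
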