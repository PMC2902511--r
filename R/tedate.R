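## Transposable-element structure detection and LTR insertion dating.
## Coordinates are 1-based inclusive throughout; BED import/export converts
## explicitly (BED is 0-based half-open).

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

## mismatch count where N never matches anything (including N)
count_mismatch <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  sum(ca != cb | ca == "N" | cb == "N")
}

#' Find a target-site duplication between the flanks of an insertion
#'
#' Searches for the longest direct repeat formed by a suffix of the left
#' flank and a prefix of the right flank within a mismatch budget; ties are
#' broken by length, then by fewer mismatches (a fixed flank admits one
#' candidate per length, so the longest acceptable repeat wins). `N` bases
#' never match.
#'
#' @param left_flank,right_flank Sequences immediately left/right of the
#'   element (upper-case ACGTN).
#' @param min_len,max_len TSD length bounds searched.
#' @param max_mismatch Mismatch budget.
#' @return List of class `"tsd_report"` (`left_flank_copy`,
#'   `right_flank_copy`, `length`, `mismatches`) or `NULL` when no repeat of
#'   at least `min_len` fits the budget.
#' @export
find_tsd <- function(left_flank, right_flank, min_len = 2L, max_len = 20L,
                     max_mismatch = 0L) {
  left_flank <- toupper(left_flank); right_flank <- toupper(right_flank)
  if (max_len < min_len) stop("max_len must be >= min_len")
  if (nchar(left_flank) < min_len || nchar(right_flank) < min_len)
    stop("flanks shorter than min_len")
  lmax <- min(max_len, nchar(left_flank), nchar(right_flank))
  for (L in seq(lmax, min_len, by = -1L)) {
    suff <- substring(left_flank, nchar(left_flank) - L + 1L, nchar(left_flank))
    pref <- substring(right_flank, 1L, L)
    mm <- count_mismatch(suff, pref)
    if (mm <= max_mismatch)
      return(structure(list(left_flank_copy = suff, right_flank_copy = pref,
                            length = as.integer(L),
                            mismatches = as.integer(mm)),
                       class = "tsd_report"))
  }
  NULL
}

#' @export
print.tsd_report <- function(x, ...) {
  cat(sprintf("TSD: %s / %s (length %d, %d mismatch(es))\n",
              x$left_flank_copy, x$right_flank_copy, x$length, x$mismatches))
  invisible(x)
}

#' Find terminal inverted repeats of an element
#'
#' Searches for the longest prefix of the element matching the
#' reverse-complement of its suffix within a mismatch budget (the hallmark
#' of MITEs and other TIR transposons). `N` bases never match.
#'
#' @param element_seq Element sequence (upper-case ACGTN), length at least
#'   `2 * min_len`.
#' @param min_len Minimum TIR length.
#' @param max_mismatch Mismatch budget.
#' @return List of class `"tir_report"` (`tir5`, `tir3`, `length`,
#'   `mismatches`) or `NULL`.
#' @export
find_tir <- function(element_seq, min_len = 8L, max_mismatch = 0L) {
  element_seq <- toupper(element_seq)
  if (grepl("[^ACGTN]", element_seq))
    stop("element sequence contains non-ACGTN characters")
  n <- nchar(element_seq)
  if (n < 2L * min_len) stop("element shorter than 2 * min_len")
  for (L in seq(n %/% 2L, min_len, by = -1L)) {
    pre <- substring(element_seq, 1L, L)
    suf <- substring(element_seq, n - L + 1L, n)
    mm <- count_mismatch(pre, revcomp(suf))
    if (mm <= max_mismatch)
      return(structure(list(tir5 = pre, tir3 = suf, length = as.integer(L),
                            mismatches = as.integer(mm)),
                       class = "tir_report"))
  }
  NULL
}

#' @export
print.tir_report <- function(x, ...) {
  cat(sprintf("TIR: %s ... %s (length %d, %d mismatch(es))\n",
              x$tir5, x$tir3, x$length, x$mismatches))
  invisible(x)
}

#' Raw divergence between the two LTRs of a retroelement
#'
#' Globally aligns the two LTR copies and returns the mismatch fraction over
#' columns where both are ungapped (indel columns are excluded, the standard
#' practice for LTR dating).
#'
#' @param ltr5_seq,ltr3_seq The two LTR sequences.
#' @param scheme Nucleotide [scoring_scheme()] (default [nuc_scheme()]).
#' @return List: `d_raw` (mismatch fraction), `n_compared`, `n_mismatch`,
#'   plus transition/transversion counts (`n_ts`, `n_tv`) for the
#'   two-parameter correction.
#' @export
ltr_divergence <- function(ltr5_seq, ltr3_seq, scheme = nuc_scheme()) {
  aln <- nw_align(toupper(as.character(ltr5_seq)[[1]]),
                  toupper(as.character(ltr3_seq)[[1]]), scheme)
  a <- strsplit(aln$gapped_a, "")[[1]]
  b <- strsplit(aln$gapped_b, "")[[1]]
  ok <- a != "-" & b != "-" & a != "N" & b != "N"
  if (!any(ok)) stop("no comparable (ungapped) columns between LTRs")
  diff <- ok & a != b
  pur <- c("A", "G"); pyr <- c("C", "T")
  ts <- diff & ((a %in% pur & b %in% pur) | (a %in% pyr & b %in% pyr))
  list(d_raw = sum(diff) / sum(ok), n_compared = sum(ok),
       n_mismatch = sum(diff), n_ts = sum(ts), n_tv = sum(diff & !ts))
}

#' Jukes-Cantor distance correction
#'
#' `K = -(3/4) * log(1 - (4/3) * d_raw)`, converting an observed mismatch
#' fraction into substitutions per site (multiple hits accounted for).
#'
#' @param d_raw Observed mismatch fraction in `[0, 0.75)`.
#' @return `K`, substitutions per site (`K >= d_raw`).
#' @export
jc_correct <- function(d_raw) {
  if (any(d_raw < 0)) stop("d_raw must be non-negative")
  if (any(d_raw >= 0.75)) stop("divergence saturated (d_raw >= 0.75)")
  -0.75 * log(1 - (4 / 3) * d_raw)
}

#' Kimura two-parameter distance correction
#'
#' @param P,Q Observed transition and transversion fractions.
#' @return `K`, substitutions per site.
#' @export
k2p_correct <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0)) stop("divergence saturated under K2P")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Insertion age from corrected LTR divergence
#'
#' At insertion the two LTRs are identical; each accumulates substitutions
#' independently, so the element's age is `T = K / (2 r)` for substitution
#' rate `r` per site per year. Reported in million years.
#'
#' @param K Corrected divergence (substitutions/site).
#' @param r Substitution rate per site per year (default `1.3e-8`, a widely
#'   used rate for rice intergenic DNA; outputs always record the rate used).
#' @return Age in million years.
#' @export
insertion_age <- function(K, r = 1.3e-8) {
  if (any(K < 0)) stop("K must be non-negative")
  if (r <= 0) stop("substitution rate must be positive")
  K / (2 * r) / 1e6
}

#' Full dating chain for one LTR pair
#'
#' @inheritParams ltr_divergence
#' @inheritParams insertion_age
#' @param model Divergence correction: `"jc"` (default) or `"k2p"`.
#' @return List of class `"age_estimate"`: `d_raw`, `K`, `r`, `T_my`,
#'   `model`, `n_compared`.
#' @export
date_ltr_pair <- function(ltr5_seq, ltr3_seq, r = 1.3e-8,
                          model = c("jc", "k2p"), scheme = nuc_scheme()) {
  model <- match.arg(model)
  div <- ltr_divergence(ltr5_seq, ltr3_seq, scheme)
  K <- if (model == "jc") jc_correct(div$d_raw)
       else k2p_correct(div$n_ts / div$n_compared, div$n_tv / div$n_compared)
  structure(list(d_raw = div$d_raw, K = K, r = r, T_my = insertion_age(K, r),
                 model = model, n_compared = div$n_compared),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("LTR dating (%s): d_raw %.5f, K %.5f subs/site, r %.3g /site/yr -> T %.3f MY\n",
              toupper(x$model), x$d_raw, x$K, x$r, x$T_my))
  invisible(x)
}

#' Convert 0-based half-open (BED) intervals to 1-based inclusive
#' @param start0,end0 BED start and end.
#' @return data.frame with `start`, `end`, 1-based inclusive.
#' @export
bed_to_coords <- function(start0, end0) {
  if (any(end0 <= start0)) stop("BED intervals must satisfy end > start")
  data.frame(start = as.integer(start0 + 1L), end = as.integer(end0))
}

#' Convert 1-based inclusive coordinates to 0-based half-open (BED)
#' @param start,end 1-based inclusive coordinates.
#' @return data.frame with `start0`, `end0`.
#' @export
coords_to_bed <- function(start, end) {
  if (any(end < start)) stop("intervals must satisfy end >= start")
  data.frame(start0 = as.integer(start - 1L), end0 = as.integer(end))
}
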