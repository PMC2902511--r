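## Seeded synthetic-data generators with ground-truth annotations.
##
## Substitution sampling uses the conditional channel "change with
## probability p, uniform over the k-1 alternatives", with p given by the
## generalized Jukes-Cantor formula for the requested expected distance.
## That channel IS the JC transition matrix at that distance, so draws
## compose across branches and two independently mutated copies of an
## ancestor have exactly the JC expected divergence at twice the branch
## distance -- the calibration downstream p-distance/JC estimators assume.

AA20 <- setdiff(AA_ALPHABET, "X")
DNA4 <- c("A", "C", "G", "T")

## P(site differs) after expected `d` substitutions/site on a k-letter
## alphabet under the uniform-exchange model
jc_pdiff <- function(d, k) (k - 1) / k * (1 - exp(-k / (k - 1) * d))

## per-copy change probability so that two independently mutated copies have
## expected pairwise identity `ident`:  (1-p)^2 + p^2/(k-1) = ident
pair_identity_to_p <- function(ident, k) {
  disc <- 1 - (k / (k - 1)) * (1 - ident)
  if (disc < 0)
    stop(sprintf("infeasible identity target %.3f for a %d-letter alphabet",
                 ident, k))
  (k - 1) / k * (1 - sqrt(disc))
}

mutate_seq <- function(chars, p, alphabet) {
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch)
      sample(setdiff(alphabet, ch), 1L), "", USE.NAMES = FALSE)
  }
  chars
}

random_chars <- function(n, alphabet) sample(alphabet, n, replace = TRUE)

#' Simulate protein families at controlled identity
#'
#' Draws one random ancestor per family and derives members by independent
#' per-site substitution calibrated (including back-substitutions) so that
#' the expected pairwise identity within a family equals `within_identity`.
#' Between-family ancestors are independent, so between-family identity sits
#' at the ~5% background of a 20-letter alphabet.
#'
#' @param n_families Number of families.
#' @param members_per_family Integer vector (recycled) of members per family.
#' @param seq_length Sequence length (residues).
#' @param within_identity Target expected pairwise identity within a family,
#'   in `(1/20, 1]`.
#' @param between_identity Nominal between-family identity; must be below
#'   `within_identity` (between-family ancestors are independent, so the
#'   realized value is the alphabet background).
#' @param seed Integer seed.
#' @return List: `records` (named character vector) and `truth`
#'   (data.frame `id`, `family`, `member`).
#' @export
simulate_families <- function(n_families = 3L, members_per_family = 4L,
                              seq_length = 300L, within_identity = 0.7,
                              between_identity = 0.05, seed = 1L) {
  if (!(between_identity >= 0 && between_identity < within_identity &&
        within_identity <= 1))
    stop("require 0 <= between_identity < within_identity <= 1")
  if (within_identity <= 1 / length(AA20))
    stop("within_identity at or below alphabet background; infeasible")
  set.seed(seed)
  members <- rep_len(members_per_family, n_families)
  p <- if (within_identity == 1) 0 else pair_identity_to_p(within_identity, length(AA20))
  records <- character(0)
  truth <- list()
  for (f in seq_len(n_families)) {
    anc <- random_chars(seq_length, AA20)
    for (m in seq_len(members[f])) {
      id <- sprintf("F%dM%d", f, m)
      records[id] <- paste(mutate_seq(anc, p, AA20), collapse = "")
      truth[[length(truth) + 1L]] <- data.frame(id = id, family = f,
                                                member = m,
                                                stringsAsFactors = FALSE)
    }
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Plant a motif instance into a sequence
#'
#' @param seq Single sequence (character).
#' @param pattern_instance Literal string to plant.
#' @param pos 1-based position of the instance start.
#' @param anchor_offset 0-based offset of the anchor residue within the
#'   instance (default 0).
#' @return List: `seq` (modified sequence), `truth` (data.frame `start`,
#'   `end`, `anchor_pos`, `instance`).
#' @export
plant_motif <- function(seq, pattern_instance, pos, anchor_offset = 0L) {
  seq <- as.character(seq)[[1]]
  L <- nchar(pattern_instance)
  if (pos < 1L || pos + L - 1L > nchar(seq))
    stop("motif instance does not fit at position ", pos)
  out <- paste0(substring(seq, 1L, pos - 1L), pattern_instance,
                substring(seq, pos + L, nchar(seq)))
  list(seq = out,
       truth = data.frame(start = as.integer(pos),
                          end = as.integer(pos + L - 1L),
                          anchor_pos = as.integer(pos + anchor_offset),
                          instance = pattern_instance,
                          stringsAsFactors = FALSE))
}

#' Evolve a sequence along a tree
#'
#' Independent-site substitution along each branch with expected
#' substitutions per site = branch length x `rate`, under the uniform-
#' exchange model on the sequence's alphabet (protein or DNA).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param root_seq Root sequence (character).
#' @param rate Expected substitutions per site per unit branch length.
#' @param alphabet `"protein"` or `"dna"`.
#' @param seed Integer seed.
#' @return Named character vector of tip sequences (tree tip order).
#' @export
evolve_on_tree <- function(tree, root_seq, rate = 1, alphabet = c("protein", "dna"),
                           seed = 1L) {
  alphabet <- match.arg(alphabet)
  ab <- if (alphabet == "protein") AA20 else DNA4
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  set.seed(seed)
  root_chars <- strsplit(toupper(as.character(root_seq)[[1]]), "")[[1]]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- root_chars
  ## preorder: parents before children
  ord <- stats::reorder(tree, "cladewise")
  edge_order <- ord$edge
  lens <- ord$edge.length
  for (e in seq_len(nrow(edge_order))) {
    parent <- edge_order[e, 1L]; child <- edge_order[e, 2L]
    d <- lens[e] * rate
    p <- jc_pdiff(d, length(ab))
    seqs[[child]] <- mutate_seq(seqs[[parent]], p, ab)
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""), "")
  setNames(out, tree$tip.label)
}

#' Simulate an LTR retroelement of known age
#'
#' Builds `LTR + internal + identical LTR`, mutates each LTR copy
#' independently with expected per-site divergence `rate * age` (years), and
#' flanks the element with a duplicated target site of `tsd_length` inside
#' random flanking DNA. Emulates the situation in which a retroelement's
#' insertion date is read off the divergence between its two LTRs.
#'
#' @param ltr_length,internal_length Element part lengths (bp).
#' @param age_my Insertion age in million years.
#' @param rate Substitution rate per site per year.
#' @param tsd_length Target-site duplication length (bp).
#' @param flank_length Random flanking DNA on each side (bp), beyond the TSD.
#' @param seed Integer seed.
#' @return List: `seq` (full locus), `element` (1-based inclusive coordinate
#'   list: `element_span`, `ltr5`, `ltr3`), `tsd` (planted TSD string),
#'   `truth` (list `age_my`, `rate`, `expected_K = 2 * rate * age`).
#' @export
simulate_ltr_element <- function(ltr_length = 2000L, internal_length = 3000L,
                                 age_my = 0.43, rate = 1.3e-8,
                                 tsd_length = 5L, flank_length = 50L,
                                 seed = 1L) {
  stopifnot(ltr_length > 0, internal_length >= 0, age_my >= 0, rate > 0,
            tsd_length >= 0, flank_length >= 0)
  set.seed(seed)
  lam <- rate * age_my * 1e6
  p <- jc_pdiff(lam, 4L)
  anc <- random_chars(ltr_length, DNA4)
  ltr5 <- mutate_seq(anc, p, DNA4)
  ltr3 <- mutate_seq(anc, p, DNA4)
  internal <- random_chars(internal_length, DNA4)
  tsd <- if (tsd_length > 0) paste(random_chars(tsd_length, DNA4), collapse = "") else ""
  left <- paste(c(random_chars(flank_length, DNA4)), collapse = "")
  right <- paste(c(random_chars(flank_length, DNA4)), collapse = "")
  element <- paste0(paste(ltr5, collapse = ""), paste(internal, collapse = ""),
                    paste(ltr3, collapse = ""))
  full <- paste0(left, tsd, element, tsd, right)
  el_start <- flank_length + tsd_length + 1L
  el_end <- el_start + nchar(element) - 1L
  list(seq = full,
       element = list(
         element_span = c(start = el_start, end = el_end),
         ltr5 = c(start = el_start, end = el_start + ltr_length - 1L),
         ltr3 = c(start = el_end - ltr_length + 1L, end = el_end)),
       tsd = tsd,
       truth = list(age_my = age_my, rate = rate,
                    expected_K = 2 * rate * age_my * 1e6))
}
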