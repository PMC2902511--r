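#' Scoring scheme for global alignment
#'
#' Bundles a substitution matrix with affine gap penalties. Protein schemes
#' use the substitution matrices shipped with Biostrings (default BLOSUM62,
#' with the classic ClustalW-style pairwise penalties of 10/0.1); the
#' `"NUC"` matrix is a +5/-4 nucleotide matrix with `N` scored neutrally.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix Matrix name (`"BLOSUM62"`, `"BLOSUM45"`, `"BLOSUM80"`,
#'   `"PAM250"`, ..., or `"NUC"`) or a symmetric numeric matrix with residue
#'   dimnames.
#' @param gap_open,gap_extend Non-negative penalties, `gap_open >= gap_extend`.
#' @param semi_global If `TRUE`, terminal gaps are free (use for fragment
#'   comparisons).
#' @return An object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.1, semi_global = FALSE) {
  if (is.character(matrix)) {
    name <- matrix
    matrix <- substitution_matrix(name)
  } else {
    name <- "custom"
    matrix <- as.matrix(matrix)
  }
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must have identical row/col residue names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_extend < 0 || gap_open < gap_extend)
    stop("require gap_open >= gap_extend >= 0")
  structure(list(matrix_name = name, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, semi_global = isTRUE(semi_global)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("Scoring scheme: %s, gap open/extend %g/%g%s\n", x$matrix_name,
              x$gap_open, x$gap_extend,
              if (x$semi_global) ", free terminal gaps" else ""))
  invisible(x)
}

#' Default nucleotide scoring scheme (MSA-style 10/0.5 penalties)
#' @export
nuc_scheme <- function(gap_open = 10, gap_extend = 0.5)
  scoring_scheme("NUC", gap_open, gap_extend)

substitution_matrix <- function(name) {
  if (name == "NUC") {
    al <- c("A", "C", "G", "T", "N")
    m <- matrix(-4, 5, 5, dimnames = list(al, al))
    diag(m) <- 5
    m["N", ] <- 0; m[, "N"] <- 0
    return(m)
  }
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || is.null(e[[name]])) stop("unknown substitution matrix: ", name)
  as.matrix(e[[name]])
}

## one-hot profile over the scheme alphabet; gap columns carry zero mass
seqs_to_profile <- function(gapped, alphabet) {
  chars <- do.call(rbind, strsplit(gapped, ""))
  nc <- ncol(chars)
  prof <- matrix(0, nrow = length(alphabet), ncol = nc,
                 dimnames = list(alphabet, NULL))
  w <- 1 / nrow(chars)
  for (a in alphabet) prof[a, ] <- colSums(chars == a) * w
  prof
}

check_alphabet <- function(seq, alphabet, id = "sequence") {
  aa <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(aa, alphabet)
  if (length(bad))
    stop(id, " contains residue(s) absent from the scoring matrix: ",
         paste(bad, collapse = ", "))
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment under a [scoring_scheme()]. Deterministic:
#' on score ties the traceback prefers the diagonal, then a gap in the second
#' sequence, then a gap in the first.
#'
#' @param a,b Single sequences (character scalars, `XString`, or length-1
#'   `XStringSet`), non-empty, gap-free.
#' @param scheme A [scoring_scheme()].
#' @return Object of class `"pairwise_alignment"`: gapped strings `gapped_a`
#'   and `gapped_b`, `score`, `n_identical`, `n_aligned_columns`,
#'   `n_columns`, and the input ids/lengths.
#' @export
nw_align <- function(a, b, scheme = scoring_scheme()) {
  id_a <- names(a) %||% "a"; id_b <- names(b) %||% "b"
  a <- toupper(as.character(a)[[1]]); b <- toupper(as.character(b)[[1]])
  if (is.na(a) || is.na(b) || nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty")
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    stop("input sequences must be ungapped")
  al <- rownames(scheme$matrix)
  check_alphabet(a, al, id_a); check_alphabet(b, al, id_b)
  pa <- seqs_to_profile(a, al); pb <- seqs_to_profile(b, al)
  res <- align_profiles_cpp(pa, pb, scheme$matrix, scheme$gap_open,
                            scheme$gap_extend, scheme$semi_global)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ops <- res$ops
  ga <- gb <- character(length(ops))
  ia <- ib <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != 2L) { ia <- ia + 1L; ga[k] <- ca[ia] } else ga[k] <- "-"
    if (ops[k] != 1L) { ib <- ib + 1L; gb[k] <- cb[ib] } else gb[k] <- "-"
  }
  both <- ops == 0L
  structure(list(
    id_a = id_a, id_b = id_b,
    gapped_a = paste(ga, collapse = ""), gapped_b = paste(gb, collapse = ""),
    score = res$score,
    n_identical = sum(both & ga == gb),
    n_aligned_columns = sum(both),
    n_columns = length(ops),
    len_a = length(ca), len_b = length(cb)),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s: score %.2f, %d/%d identical columns\n",
              x$id_a, x$id_b, x$score, x$n_identical, x$n_aligned_columns))
  cat(x$gapped_a, "\n", x$gapped_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' The identity denominator is not fixed by the AGNC criteria; the default,
#' the shorter input sequence, is the most permissive common convention for
#' family assignment. The choice changes borderline family calls, so it is an
#' explicit argument and is recorded in classification outputs.
#'
#' @param aln A [nw_align()] result.
#' @param denominator `"shorter_seq"` (default), `"aligned_columns"`, or
#'   `"alignment_length"`.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln,
                             denominator = c("shorter_seq", "aligned_columns",
                                             "alignment_length")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator,
                shorter_seq = min(aln$len_a, aln$len_b),
                aligned_columns = aln$n_aligned_columns,
                alignment_length = aln$n_columns)
  if (den == 0) return(0)
  aln$n_identical / den
}

#' Minimal progressive multiple sequence alignment
#'
#' Builds a neighbor-joining guide tree from pairwise percent-identity
#' distances, then merges sub-alignments by profile-profile global alignment
#' in guide-tree join order. Intentionally minimal: no iterative refinement,
#' no position-specific gap penalties. MSA merges default to the classic
#' 10/0.5 multiple-alignment gap penalties.
#'
#' @param seqs Named character vector or `XStringSet` of >= 2 sequences.
#' @param scheme A [scoring_scheme()]; default BLOSUM62 with 10/0.5 penalties.
#' @return Object of class `"msa"`: named character vector `seqs` of gapped
#'   sequences (input order) and `n_columns`.
#' @export
progressive_msa <- function(seqs,
                            scheme = scoring_scheme(gap_open = 10,
                                                    gap_extend = 0.5)) {
  s <- as_char_seqs(seqs)
  ids <- names(s) %||% paste0("seq", seq_along(s))
  if (is.null(names(s))) names(s) <- ids
  n <- length(s)
  if (n < 2L) stop("progressive_msa needs at least 2 sequences")
  al <- rownames(scheme$matrix)
  for (i in seq_len(n)) check_alphabet(s[[i]], al, ids[i])

  if (n == 2L) {
    aln <- nw_align(s[1], s[2], scheme)
    out <- setNames(c(aln$gapped_a, aln$gapped_b), ids)
    return(structure(list(seqs = out, n_columns = aln$n_columns),
                     class = "msa"))
  }

  ## guide: NJ on (1 - identity) distances
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- nw_align(s[i], s[j], scheme)
    d[i, j] <- d[j, i] <- 1 - percent_identity(aln)
  }
  joins <- nj_engine(d)$joins   # sequence of cluster index-set merges

  ## cluster contents live in the slot of their smallest member index
  clusters <- lapply(seq_len(n), function(i) setNames(s[i], ids[i]))
  for (jn in joins) {
    sa <- min(jn$a); sb <- min(jn$b)
    merged <- merge_profiles(clusters[[sa]], clusters[[sb]], scheme)
    slot <- min(sa, sb)
    clusters[[slot]] <- merged
    clusters[setdiff(c(sa, sb), slot)] <- list(NULL)
  }
  final <- Filter(Negate(is.null), clusters)
  stopifnot(length(final) == 1L)
  out <- final[[1]][ids]
  structure(list(seqs = out, n_columns = nchar(out[[1]])), class = "msa")
}

merge_profiles <- function(ga, gb, scheme) {
  al <- rownames(scheme$matrix)
  pa <- seqs_to_profile(unname(ga), al)
  pb <- seqs_to_profile(unname(gb), al)
  res <- align_profiles_cpp(pa, pb, scheme$matrix, scheme$gap_open,
                            scheme$gap_extend, scheme$semi_global)
  ops <- res$ops
  expand <- function(group, consume_op) {
    chars <- do.call(rbind, strsplit(unname(group), ""))
    out <- matrix("-", nrow = nrow(chars), ncol = length(ops))
    idx <- 0L
    for (k in seq_along(ops)) {
      if (ops[k] != consume_op) { idx <- idx + 1L; out[, k] <- chars[, idx] }
    }
    setNames(apply(out, 1, paste, collapse = ""), names(group))
  }
  c(expand(ga, consume_op = 2L), expand(gb, consume_op = 1L))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences, %d columns\n",
              length(x$seqs), x$n_columns))
  invisible(x)
}

#' Convert an MSA to a character matrix (one row per sequence)
#' @param msa An `"msa"` object or named character vector of gapped strings.
#' @return Character matrix with sequence rownames.
#' @export
msa_matrix <- function(msa) {
  s <- if (inherits(msa, "msa")) msa$seqs else as_char_seqs(msa)
  m <- do.call(rbind, strsplit(unname(s), ""))
  rownames(m) <- names(s)
  m
}

#' Write an MSA as aligned FASTA
#' @inheritParams write_fasta
#' @param msa An `"msa"` object.
#' @export
write_msa <- function(msa, path, width = 60L) write_fasta(msa$seqs, path, width)
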