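# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's own code paths.

# -- brute-force global affine-gap alignment score ---------------------------
# Enumerates every monotone gapped pairing recursively. Gap of length L costs
# open + L * ext (first gapped position pays both), matching the package's
# documented convention. Tractable only for short sequences.
bf_align_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  rec <- function(i, j, state) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= na)
      best <- max(best, -(if (state == 1L) ext else open + ext) +
                          rec(i + 1L, j, 1L))
    if (j <= nb)
      best <- max(best, -(if (state == 2L) ext else open + ext) +
                          rec(i, j + 1L, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# -- brute-force PROSITE-style matcher ---------------------------------------
# A pattern is a list of elements; each element is list(allowed = charvec or
# NULL (any), negated = TRUE/FALSE, min, max). Returns every start position
# (1-based) at which the pattern can match.
bf_pattern_starts <- function(seq, elems, anchored_end = FALSE) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  elem_ok <- function(e, pos) {
    if (pos > n) return(FALSE)
    if (is.null(e$allowed)) return(TRUE)
    inset <- ch[pos] %in% e$allowed
    if (isTRUE(e$negated)) !inset else inset
  }
  match_from <- function(pos, k) {
    if (k > length(elems)) return(!anchored_end || pos == n + 1L)
    e <- elems[[k]]
    for (take in e$min:e$max) {
      if (take > 0 && !all(vapply(pos:(pos + take - 1L), elem_ok,
                                  logical(1), e = e))) next
      if (pos + take - 1L > n) next
      if (match_from(pos + take, k + 1L)) return(TRUE)
    }
    FALSE
  }
  which(vapply(seq_len(n), match_from, logical(1), k = 1L))
}

# render an element list into PROSITE syntax
elems_to_prosite <- function(elems) {
  paste(vapply(elems, function(e) {
    core <- if (is.null(e$allowed)) "x"
            else if (isTRUE(e$negated)) paste0("{", paste(e$allowed, collapse = ""), "}")
            else if (length(e$allowed) == 1L) e$allowed
            else paste0("[", paste(e$allowed, collapse = ""), "]")
    if (e$min == 1L && e$max == 1L) core
    else if (e$min == e$max) paste0(core, "(", e$min, ")")
    else paste0(core, "(", e$min, ",", e$max, ")")
  }, ""), collapse = "-")
}

# random element list over a given alphabet
random_elems <- function(n_elem, alphabet, allow_var = TRUE) {
  lapply(seq_len(n_elem), function(i) {
    kind <- sample(c("res", "set", "neg", "any"), 1L)
    e <- switch(kind,
      res = list(allowed = sample(alphabet, 1L), negated = FALSE),
      set = list(allowed = sample(alphabet, sample(2:3, 1L)), negated = FALSE),
      neg = list(allowed = sample(alphabet, 1L), negated = TRUE),
      any = list(allowed = NULL, negated = FALSE))
    if (allow_var && runif(1) < 0.3) {
      e$min <- sample(0:2, 1L); e$max <- e$min + sample(0:2, 1L)
    } else {
      e$min <- e$max <- 1L
    }
    e
  })
}

# -- sequence generators -----------------------------------------------------
AA20_TEST <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n, alphabet = AA20_TEST)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# BLOSUM62-positive partner for each residue (C, G, P excluded: they have no
# positive off-diagonal partner). Used to build sequence pairs whose optimal
# global alignment is gap-free, so pairwise identity is exactly controllable.
B62_PARTNER <- c(A = "S", R = "K", N = "H", D = "E", Q = "E", E = "D",
                 H = "Y", I = "V", L = "M", K = "R", M = "L", F = "Y",
                 S = "T", T = "S", W = "Y", Y = "F", V = "I")

# query sharing exactly `n_match` of the reference's first positions,
# all other positions substituted by a similarity-positive partner
pair_at_identity <- function(len, n_match, seed) {
  set.seed(seed)
  ref <- sample(names(B62_PARTNER), len, replace = TRUE)
  qry <- ref
  swap <- sample(len, len - n_match)
  qry[swap] <- B62_PARTNER[ref[swap]]
  list(ref = paste(ref, collapse = ""), qry = paste(qry, collapse = ""))
}

# independent identity recount from an alignment's gapped strings
recount_identity <- function(aln, denominator = "shorter_seq") {
  a <- strsplit(aln$gapped_a, "")[[1]]
  b <- strsplit(aln$gapped_b, "")[[1]]
  ident <- sum(a == b & a != "-")
  den <- switch(denominator,
                shorter_seq = min(sum(a != "-"), sum(b != "-")),
                aligned_columns = sum(a != "-" & b != "-"),
                alignment_length = length(a))
  ident / den
}

b62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  as.matrix(e$BLOSUM62)
}
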