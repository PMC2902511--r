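#' Uncorrected p-distance matrix from a multiple alignment
#'
#' `d[i, j]` is the fraction of differing residues over the columns compared
#' for that pair: columns where both sequences are ungapped
#' (`"pairwise_delete"`, default) or columns ungapped in every sequence
#' (`"complete_delete"`).
#'
#' @param msa An `"msa"` object, named character vector of equal-length gapped
#'   strings, or character matrix.
#' @param gap_mode `"pairwise_delete"` or `"complete_delete"`.
#' @return Symmetric numeric matrix with zero diagonal and sequence labels.
#' @export
pdistance <- function(msa, gap_mode = c("pairwise_delete", "complete_delete")) {
  gap_mode <- match.arg(gap_mode)
  m <- if (is.matrix(msa)) msa else msa_matrix(msa)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  labels <- rownames(m) %||% paste0("seq", seq_len(n))
  if (gap_mode == "complete_delete") {
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) stop("no columns free of gaps under complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop(sprintf("no comparable columns for pair %s / %s",
                   labels[i], labels[j]))
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

fmt_bl <- function(x) sprintf("%.12g", x)

## Saitou-Nei neighbor joining with a deterministic tie-break and a full
## binary merge schedule (used as the progressive-MSA guide).
## Tie-break: among Q-minimizing pairs, the lexicographically smallest sorted
## pair of cluster representative labels (representative = smallest leaf
## label in the cluster).
## Negative branch-length estimates are clamped to zero with the deficit
## moved to the sister edge, preserving the pair's summed length.
nj_engine <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels)) labels <- rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(!is.finite(d))) stop("distance matrix must be finite")

  frag <- labels
  members <- as.list(seq_len(n))
  rep_lab <- labels                    # representative leaf label per cluster
  active <- seq_len(n)
  D <- d
  joins <- list()

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    c(li, lj)
  }
  pick_pair <- function(score, act) {
    qmin <- min(score)
    cand <- which(score <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij)
      paste(sort(c(rep_lab[act[ij[1]]], rep_lab[act[ij[2]]])), collapse = "\r"))
    cand[order(keys)[1L], ]
  }

  while (length(active) > 3L) {
    m <- length(active)
    Da <- D[active, active]
    r <- rowSums(Da)
    Q <- (m - 2) * Da - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- pick_pair(Q, active)
    i <- active[ij[1]]; j <- active[ij[2]]
    dij <- D[i, j]
    li <- dij / 2 + (r[ij[1]] - r[ij[2]]) / (2 * (m - 2))
    lens <- clamp_pair(li, dij - li)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_bl(lens[1]),
                       frag[j], fmt_bl(lens[2]))
    joins[[length(joins) + 1L]] <- list(a = members[[i]], b = members[[j]])
    for (k in setdiff(active, c(i, j)))
      D[i, k] <- D[k, i] <- (D[i, k] + D[j, k] - dij) / 2
    frag[i] <- newfrag
    members[[i]] <- c(members[[i]], members[[j]])
    rep_lab[i] <- min(c(rep_lab[i], rep_lab[j]))
    active <- setdiff(active, j)
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], fmt_bl(la),
                    frag[b], fmt_bl(lb), frag[c3], fmt_bl(lc))

  ## complete the binary merge schedule over the final three clusters
  Dfin <- D[active, active]
  diag(Dfin) <- Inf
  ij <- pick_pair(Dfin, active)
  i <- active[ij[1]]; j <- active[ij[2]]
  k <- setdiff(active, c(i, j))
  joins[[length(joins) + 1L]] <- list(a = members[[i]], b = members[[j]])
  joins[[length(joins) + 1L]] <- list(a = c(members[[i]], members[[j]]),
                                      b = members[[k]])
  list(newick = newick, joins = joins)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. Deterministic: ties
#' are broken by the lexicographically smallest pair of cluster labels.
#' Negative branch-length estimates are clamped to zero with the deficit
#' moved to the sister edge. Exact on additive matrices.
#'
#' @param d Symmetric non-negative matrix (zero diagonal) with taxon dimnames,
#'   or a `dist` object; at least 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  ape::read.tree(text = nj_engine(d)$newick)
}

## canonical key for the bipartition separating `clade` from the rest;
## NULL for trivial splits
split_key <- function(clade, all_tips) {
  ref <- sort(all_tips)[1L]
  side <- if (ref %in% clade) setdiff(all_tips, clade) else clade
  if (length(side) < 2L || length(side) > length(all_tips) - 2L) return(NULL)
  paste(sort(side), collapse = "|")
}

## non-trivial bipartition keys of an unrooted tree, named by internal node
tree_splits <- function(tree) {
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  out <- character(0)
  nodes <- integer(0)
  for (i in seq_along(pp)) {
    key <- split_key(tips[pp[[i]]], tips)
    if (!is.null(key)) {
      out <- c(out, key)
      nodes <- c(nodes, length(tips) + i)
    }
  }
  setNames(out, nodes)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance + NJ tree per replicate, and scores each internal edge of the
#' full-alignment tree by the percentage of replicates containing its
#' bipartition. Replicates in which some pair shares no comparable columns
#' are dropped (with a warning) and excluded from the denominator.
#'
#' Reproducible: replicate `b` reseeds the generator with `seed + b`, so any
#' subset of replicates can be re-run independently.
#'
#' @param msa An `"msa"` object (or gapped named character vector) with >= 3
#'   sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer base seed.
#' @param gap_mode Passed to [pdistance()].
#' @return The NJ tree of the full alignment with supports (percentages) as
#'   `node.label`; attributes `"supports"` (named by bipartition key) and
#'   `"n_dropped"`.
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L,
                              gap_mode = "pairwise_delete") {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  m <- msa_matrix(msa)
  if (nrow(m) < 3L) stop("bootstrap needs at least 3 sequences")
  main <- nj_tree(pdistance(m, gap_mode))
  main_splits <- tree_splits(main)

  counts <- setNames(numeric(length(main_splits)), main_splits)
  dropped <- 0L
  for (b in seq_len(n_reps)) {
    set.seed(seed + b)
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- tryCatch(nj_tree(pdistance(m[, idx, drop = FALSE], gap_mode)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) { dropped <- dropped + 1L; next }
    seen <- unique(tree_splits(rep_tree))
    hit <- intersect(seen, names(counts))
    counts[hit] <- counts[hit] + 1
  }
  if (dropped > 0L)
    warning(dropped, " replicate(s) dropped (pair with no comparable columns)")
  denom <- n_reps - dropped
  support <- if (denom > 0) 100 * counts / denom else counts * NA_real_

  node_lab <- character(main$Nnode)
  for (k in seq_along(main_splits)) {
    node <- as.integer(names(main_splits)[k])
    node_lab[node - length(main$tip.label)] <-
      fmt_bl(round(support[[main_splits[k]]], 6))
  }
  main$node.label <- node_lab
  attr(main, "supports") <- support
  attr(main, "n_dropped") <- dropped
  main
}

#' Write a tree in Newick format
#'
#' Supports, when present as `node.label`, are written as internal node
#' labels; round-tripping through [read_newick()] recovers topology, branch
#' lengths and supports.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @param with_support Keep internal node labels (default `TRUE`).
#' @export
write_newick <- function(tree, path, with_support = TRUE) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!with_support) tree$node.label <- NULL
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a distance matrix in square PHYLIP format
#' @param d Symmetric labelled matrix.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = "  "), con)
  invisible(path)
}
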