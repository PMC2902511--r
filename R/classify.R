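#' Parse a systematic ALDH name
#'
#' AGNC names read `<species prefix>ALDH<family><subfamily letter><member>`,
#' e.g. `OsALDH2B5` = species Os, family 2, subfamily B, member 5.
#'
#' @param name Character vector of names.
#' @return data.frame with columns `name`, `prefix`, `family`, `subfamily`,
#'   `member`.
#' @export
parse_aldh_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]*?)ALDH([0-9]+)([A-Z])([0-9]+)$", name))
  bad <- lengths(m) == 0L
  if (any(bad))
    stop("name(s) do not parse under the AGNC grammar: ",
         paste(name[bad], collapse = ", "))
  data.frame(name = name,
             prefix = vapply(m, `[`, "", 2L),
             family = as.integer(vapply(m, `[`, "", 3L)),
             subfamily = vapply(m, `[`, "", 4L),
             member = as.integer(vapply(m, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Build a reference panel of named ALDH exemplars
#'
#' @param seqs Named character vector or `XStringSet` whose names are AGNC
#'   names, or unnamed with `names` supplied.
#' @param names Optional character vector of AGNC names (one per sequence).
#' @return data.frame of class `"reference_panel"`: `name`, `family`,
#'   `subfamily`, `member`, `seq`.
#' @export
reference_panel <- function(seqs, names = NULL) {
  s <- as_char_seqs(seqs)
  nm <- names %||% base::names(s)
  if (is.null(nm)) stop("panel sequences must be named with AGNC names")
  if (anyDuplicated(nm))
    stop("duplicate panel names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  parsed <- parse_aldh_name(nm)
  parsed$seq <- unname(s)
  class(parsed) <- c("reference_panel", "data.frame")
  parsed
}

#' Classification thresholds
#'
#' AGNC boundaries: strictly more than 40% identity to a known sequence
#' places a query in that sequence's family; strictly more than 60% places it
#' in the subfamily.
#'
#' @param theta_fam,theta_sub Fractions with `0 < theta_fam < theta_sub < 1`.
#' @return Named list of class `"thresholds"`.
#' @export
thresholds <- function(theta_fam = 0.40, theta_sub = 0.60) {
  if (!(theta_fam > 0 && theta_fam < theta_sub && theta_sub < 1))
    stop("require 0 < theta_fam < theta_sub < 1")
  structure(list(theta_fam = theta_fam, theta_sub = theta_sub),
            class = "thresholds")
}

#' All-against-all percent-identity matrix
#'
#' @param seqs Named character vector or `XStringSet` of >= 2 sequences.
#' @param scheme A [scoring_scheme()].
#' @param denominator Identity denominator (see [percent_identity()]).
#' @return Symmetric matrix of identity fractions with unit diagonal.
#' @export
identity_matrix <- function(seqs, scheme = scoring_scheme(),
                            denominator = "shorter_seq") {
  s <- as_char_seqs(seqs)
  n <- length(s)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- names(s) %||% paste0("seq", seq_len(n))
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- nw_align(s[i], s[j], scheme)
    m[i, j] <- m[j, i] <- percent_identity(aln, denominator)
  }
  m
}

#' Assign a query protein to an ALDH family and subfamily
#'
#' Best-hit assignment against a reference panel: the query joins the family
#' of its highest-identity reference when that identity exceeds
#' `theta_fam` (strictly), otherwise it founds a new family. Within the
#' chosen family, it joins the best reference's subfamily when the identity
#' exceeds `theta_sub`, otherwise it founds a new subfamily. When two
#' references in different families tie exactly, the lower family number wins
#' and a warning is emitted.
#'
#' @param query Single protein sequence (character or `XString`); its name is
#'   used as the query id.
#' @param panel A [reference_panel()].
#' @param th A [thresholds()] object.
#' @param scheme A [scoring_scheme()].
#' @param denominator Identity denominator (see [percent_identity()]).
#' @return List of class `"family_assignment"`.
#' @export
assign_family <- function(query, panel, th = thresholds(),
                          scheme = scoring_scheme(),
                          denominator = "shorter_seq") {
  if (!inherits(panel, "reference_panel")) panel <- reference_panel(panel)
  if (nrow(panel) == 0L) stop("reference panel is empty")
  qid <- names(query) %||% "query"
  qseq <- toupper(as.character(query)[[1]])

  idents <- vapply(panel$seq, function(ref)
    percent_identity(nw_align(qseq, ref, scheme), denominator),
    numeric(1), USE.NAMES = FALSE)
  evidence <- data.frame(name = panel$name, family = panel$family,
                         subfamily = panel$subfamily, identity = idents,
                         stringsAsFactors = FALSE)
  best <- max(idents)
  top <- which(idents >= best - 1e-12)
  if (length(unique(panel$family[top])) > 1L) {
    warning(sprintf("query %s ties at identity %.4f across families %s; using the lowest",
                    qid, best,
                    paste(sort(unique(panel$family[top])), collapse = ",")))
  }
  top <- top[order(panel$family[top], panel$subfamily[top], panel$member[top])][1L]

  new_family <- !(best > th$theta_fam)
  family <- if (new_family) NA_integer_ else panel$family[top]
  if (new_family) {
    subfamily <- NA_character_
    new_subfamily <- TRUE
    best_sub <- best
  } else {
    new_subfamily <- !(best > th$theta_sub)
    subfamily <- if (new_subfamily) NA_character_ else panel$subfamily[top]
    best_sub <- best
  }
  structure(list(query_id = qid, query_seq = qseq,
                 family = family, subfamily = subfamily,
                 new_family = new_family, new_subfamily = new_subfamily,
                 best_family_identity = best, best_subfamily_identity = best_sub,
                 best_reference = panel$name[top],
                 denominator = denominator, matrix_name = scheme$matrix_name,
                 evidence = evidence[order(-evidence$identity), ]),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  fam <- if (x$new_family) "NEW" else x$family
  sub <- if (x$new_subfamily) "NEW" else x$subfamily
  cat(sprintf("%s: family %s, subfamily %s (best identity %.3f to %s; denominator %s)\n",
              x$query_id, fam, sub, x$best_family_identity, x$best_reference,
              x$denominator))
  invisible(x)
}

#' Propose a systematic AGNC name for an assignment
#'
#' Existing family/subfamily: the member ordinal continues from the panel's
#' maximum in that subfamily (a query sequence identical to a panel entry
#' keeps that entry's name). A new subfamily takes the first unused letter in
#' the family; a new family takes the smallest unused family number at or
#' above `family_floor`.
#'
#' @param assignment A [assign_family()] result.
#' @param species_prefix Species prefix for the name (e.g. `"Os"`).
#' @param panel The [reference_panel()] the assignment was made against.
#' @param family_floor Smallest family number a new family may take.
#' @return The proposed name (character scalar), with attributes `family`,
#'   `subfamily`, `member`.
#' @export
propose_name <- function(assignment, species_prefix, panel, family_floor = 1L) {
  if (!inherits(panel, "reference_panel")) panel <- reference_panel(panel)
  identical_hit <- which(panel$seq == assignment$query_seq)
  if (length(identical_hit)) {
    p <- panel[identical_hit[1L], ]
    return(structure(paste0(species_prefix, "ALDH", p$family, p$subfamily, p$member),
                     family = p$family, subfamily = p$subfamily, member = p$member))
  }
  if (assignment$new_family) {
    used <- unique(panel$family)
    family <- setdiff(seq(family_floor, max(c(used, family_floor)) + 1L), used)[1L]
    subfamily <- "A"
    member <- 1L
  } else {
    family <- assignment$family
    in_fam <- panel[panel$family == family, , drop = FALSE]
    if (assignment$new_subfamily) {
      unused <- setdiff(LETTERS, unique(in_fam$subfamily))
      if (!length(unused))
        stop("subfamily letters exhausted beyond Z in family ", family)
      subfamily <- unused[1L]
      member <- 1L
    } else {
      subfamily <- assignment$subfamily
      in_sub <- in_fam[in_fam$subfamily == subfamily, , drop = FALSE]
      member <- max(in_sub$member) + 1L
    }
  }
  structure(paste0(species_prefix, "ALDH", family, subfamily, member),
            family = as.integer(family), subfamily = subfamily,
            member = as.integer(member))
}

#' Classify a set of queries and propose names sequentially
#'
#' Queries are processed in input order; each proposed name is appended to a
#' working copy of the panel, so several queries resolving to the same new
#' family or subfamily receive consecutive member ordinals.
#'
#' @inheritParams assign_family
#' @param queries Named character vector or `XStringSet`.
#' @param species_prefix Species prefix for proposed names.
#' @param family_floor Smallest family number a new family may take.
#' @return data.frame with one row per query: `query_id`, `proposed_name`,
#'   `family`, `subfamily`, `member`, `best_identity`, `best_reference`,
#'   `new_family`, `new_subfamily`, `denominator`, `matrix_name`.
#' @export
classify_queries <- function(queries, panel, species_prefix = "Os",
                             th = thresholds(), scheme = scoring_scheme(),
                             denominator = "shorter_seq", family_floor = 1L) {
  if (!inherits(panel, "reference_panel")) panel <- reference_panel(panel)
  qs <- as_char_seqs(queries)
  qids <- names(qs) %||% paste0("query", seq_along(qs))
  work <- panel
  rows <- vector("list", length(qs))
  for (i in seq_along(qs)) {
    asg <- assign_family(setNames(qs[i], qids[i]), work, th, scheme, denominator)
    nm <- propose_name(asg, species_prefix, work, family_floor)
    rows[[i]] <- data.frame(
      query_id = qids[i], proposed_name = as.character(nm),
      family = attr(nm, "family"), subfamily = attr(nm, "subfamily"),
      member = attr(nm, "member"),
      best_identity = asg$best_family_identity,
      best_reference = asg$best_reference,
      new_family = asg$new_family, new_subfamily = asg$new_subfamily,
      denominator = denominator, matrix_name = scheme$matrix_name,
      stringsAsFactors = FALSE)
    if (!as.character(nm) %in% work$name) {
      add <- data.frame(name = as.character(nm), prefix = species_prefix,
                        family = attr(nm, "family"),
                        subfamily = attr(nm, "subfamily"),
                        member = attr(nm, "member"), seq = qs[i],
                        stringsAsFactors = FALSE)
      work <- rbind(work, add)
      class(work) <- c("reference_panel", "data.frame")
    }
  }
  do.call(rbind, rows)
}

#' Summarize a superfamily from systematic names
#'
#' @param names Character vector of AGNC names (or a data.frame with a `name`
#'   column, e.g. the output of [aldh_table1()]).
#' @return List of class `"superfamily_summary"`: `n_genes`, `n_families`,
#'   `counts` (genes per family), `families_multi`, `families_single`,
#'   `largest_two_total`.
#' @export
summarize_superfamily <- function(names) {
  if (is.data.frame(names)) names <- names$name
  if (!length(names)) stop("no names to summarize")
  parsed <- parse_aldh_name(names)
  counts <- table(parsed$family)
  counts <- setNames(as.integer(counts), base::names(counts))
  multi <- counts[counts > 1L]
  single <- as.integer(base::names(counts[counts == 1L]))
  structure(list(
    n_genes = length(names),
    n_families = length(counts),
    counts = counts,
    families_multi = multi,
    families_single = single,
    largest_two_total = sum(sort(counts, decreasing = TRUE)[seq_len(min(2L, length(counts)))])),
    class = "superfamily_summary")
}

#' @export
print.superfamily_summary <- function(x, ...) {
  cat(sprintf("Superfamily: %d genes in %d families\n", x$n_genes, x$n_families))
  cat("  multi-member:", paste(sprintf("%s:%d", base::names(x$families_multi),
                                       x$families_multi), collapse = ", "), "\n")
  cat("  single-member families:", paste(x$families_single, collapse = ", "), "\n")
  cat("  two largest families together:", x$largest_two_total, "genes\n")
  invisible(x)
}
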