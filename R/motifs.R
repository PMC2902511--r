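#' Compile a PROSITE-syntax pattern
#'
#' Supported syntax: elements separated by `-`; a single residue letter;
#' `x` for any residue; `[ABC]` residue sets; `{ABC}` negated sets; optional
#' repeat counts `(n)` or `(n,m)`; `<` / `>` anchors at the pattern ends; an
#' optional trailing period. The anchor index marks the site-defining element
#' (e.g. the catalytic Cys or Glu); every element before the anchor must have
#' fixed length so the anchor's offset within a match is well defined.
#'
#' @param accession Pattern identifier (e.g. `"PS00070"`).
#' @param pattern PROSITE-syntax string.
#' @param anchor_index 1-based index of the anchor element, or `NA`.
#' @param description Free-text description.
#' @return Object of class `"prosite_pattern"` usable with [scan_motifs()].
#' @export
compile_pattern <- function(accession, pattern, anchor_index = NA_integer_,
                            description = "") {
  raw <- pattern
  p <- sub("\\.$", "", trimws(pattern))
  anchored_start <- startsWith(p, "<")
  if (anchored_start) p <- substring(p, 2L)
  anchored_end <- endsWith(p, ">")
  if (anchored_end) p <- substring(p, 1L, nchar(p) - 1L)
  if (!nzchar(p)) stop("empty pattern: ", raw)

  tokens <- strsplit(p, "-", fixed = TRUE)[[1]]
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!nzchar(tok))
      stop(sprintf("parse error in '%s': empty element at position %d", raw, i))
    rep_min <- rep_max <- 1L
    rm <- regmatches(tok, regexec("\\((\\d+)(,(\\d+))?\\)$", tok))[[1]]
    if (length(rm)) {
      rep_min <- as.integer(rm[2])
      rep_max <- if (nzchar(rm[4])) as.integer(rm[4]) else rep_min
      if (rep_max < rep_min)
        stop(sprintf("parse error in '%s': bad repeat at element %d", raw, i))
      tok <- sub("\\(\\d+(,\\d+)?\\)$", "", tok)
    }
    core <- if (tok == "x") {
      "."
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      tok
    } else if (grepl("^\\{[A-Z]+\\}$", tok)) {
      paste0("[^", substring(tok, 2L, nchar(tok) - 1L), "]")
    } else if (grepl("^[A-Z]$", tok)) {
      tok
    } else {
      stop(sprintf("parse error in '%s': bad token '%s' at element %d",
                   raw, tok, i))
    }
    rx <- if (rep_min == 1L && rep_max == 1L) core
          else if (rep_min == rep_max) paste0(core, "{", rep_min, "}")
          else paste0(core, "{", rep_min, ",", rep_max, "}")
    elements[[i]] <- list(regex = rx, min = rep_min, max = rep_max)
  }

  anchor_offset <- NA_integer_
  if (!is.na(anchor_index)) {
    if (anchor_index < 1L || anchor_index > length(elements))
      stop("anchor_index out of range for pattern ", accession)
    before <- elements[seq_len(anchor_index - 1L)]
    if (any(vapply(before, function(e) e$min != e$max, logical(1))))
      stop("anchor requires fixed-length elements before it: ", accession)
    anchor_offset <- sum(vapply(before, function(e) e$min, integer(1)))
  }

  structure(list(
    accession = accession, pattern = raw, description = description,
    regex = paste(vapply(elements, `[[`, "", "regex"), collapse = ""),
    anchored_start = anchored_start, anchored_end = anchored_end,
    anchor_index = anchor_index, anchor_offset = anchor_offset,
    n_elements = length(elements)), class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$accession, x$pattern,
              if (!is.na(x$anchor_index))
                sprintf(" (anchor element %d)", x$anchor_index) else ""))
  invisible(x)
}

#' Read a pattern configuration table
#'
#' TSV with columns `accession`, `pattern`, `anchor_index`, `description`.
#' The packaged default (`active_site_patterns_synthetic.tsv`) carries
#' synthetic stand-ins for the ALDH cysteine (PS00070-like) and glutamic acid
#' (PS00687-like) active-site patterns; production use should substitute
#' pattern strings from a current PROSITE release.
#'
#' @param path Path to the TSV; default is the packaged file.
#' @return List of compiled [compile_pattern()] objects.
#' @export
read_pattern_config <- function(path = system.file(
    "extdata", "active_site_patterns_synthetic.tsv",
    package = "aldhtools", mustWork = TRUE)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    compile_pattern(df$accession[i], df$pattern[i],
                    as.integer(df$anchor_index[i]), df$description[i]))
}

#' Scan sequences for PROSITE pattern hits
#'
#' @param seqs Named character vector or `XStringSet` of protein sequences.
#' @param patterns A compiled pattern or list of them (see
#'   [compile_pattern()]).
#' @param overlap If `TRUE` (default) report a hit at every matching start
#'   position; otherwise resume scanning after each match end.
#' @return data.frame with columns `seq_id`, `accession`, `start`, `end`,
#'   `matched`, `anchor_pos` (NA when the pattern has no anchor),
#'   `anchor_residue`. Positions are 1-based inclusive.
#' @export
scan_motifs <- function(seqs, patterns, overlap = TRUE) {
  if (inherits(patterns, "prosite_pattern")) patterns <- list(patterns)
  s <- as_char_seqs(seqs)
  ids <- names(s) %||% paste0("seq", seq_along(s))
  rows <- list()
  for (i in seq_along(s)) {
    for (p in patterns) {
      hits <- match_pattern(s[[i]], p, overlap)
      if (nrow(hits)) {
        hits$seq_id <- ids[i]
        hits$accession <- p$accession
        rows[[length(rows) + 1L]] <- hits
      }
    }
  }
  if (!length(rows))
    return(data.frame(seq_id = character(0), accession = character(0),
                      start = integer(0), end = integer(0),
                      matched = character(0), anchor_pos = integer(0),
                      anchor_residue = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[, c("seq_id", "accession", "start", "end", "matched", "anchor_pos",
          "anchor_residue")]
}

match_pattern <- function(seq, p, overlap = TRUE) {
  n <- nchar(seq)
  starts <- if (p$anchored_start) 1L else seq_len(n)
  rx <- paste0("^(", p$regex, ")", if (p$anchored_end) "$" else "")
  res <- list()
  s <- 1L
  while (length(starts)) {
    s <- starts[1L]
    m <- regexpr(rx, substring(seq, s), perl = TRUE)
    if (m[1] == 1L) {
      len <- attr(m, "match.length")
      end <- s + len - 1L
      anchor_pos <- if (is.na(p$anchor_offset)) NA_integer_
                    else s + p$anchor_offset
      res[[length(res) + 1L]] <- data.frame(
        start = s, end = end, matched = substring(seq, s, end),
        anchor_pos = anchor_pos,
        anchor_residue = if (is.na(anchor_pos)) NA_character_
                         else substring(seq, anchor_pos, anchor_pos),
        stringsAsFactors = FALSE)
      starts <- if (overlap) starts[-1L] else starts[starts > end]
    } else {
      starts <- starts[-1L]
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      matched = character(0), anchor_pos = integer(0),
                      anchor_residue = character(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Map a reference residue position onto a query sequence
#'
#' Globally aligns query and reference, then returns the query position
#' aligned to the given reference position, or `NA` when that reference
#' column pairs with a gap in the query (e.g. a deletion spanning the site).
#'
#' @param query,reference Single protein sequences.
#' @param ref_pos 1-based position in the reference.
#' @param scheme A [scoring_scheme()].
#' @return Integer query position or `NA` (unmapped).
#' @export
map_reference_position <- function(query, reference, ref_pos,
                                   scheme = scoring_scheme()) {
  refseq <- toupper(as.character(reference)[[1]])
  if (ref_pos < 1L || ref_pos > nchar(refseq))
    stop("ref_pos out of range: ", ref_pos)
  aln <- nw_align(query, refseq, scheme)
  ga <- strsplit(aln$gapped_a, "")[[1]]
  gb <- strsplit(aln$gapped_b, "")[[1]]
  qi <- cumsum(ga != "-")
  ri <- cumsum(gb != "-")
  col <- which(ri == ref_pos & gb != "-")[1L]
  if (is.na(col) || ga[col] == "-") return(NA_integer_)
  qi[col]
}

#' Call NAD(+)/NADP(+) cofactor preference from the E195-equivalent site
#'
#' Residue-charge rule over the site residue and its flanking window:
#' an arginine at the site switches between cofactors (`dual_switching`);
#' otherwise a `charged` residue (default E and K, following the usual
#' statement of the three-group convention; pass `c("E", "D")` for a strictly
#' acidic set) at or near the site calls `NAD_preferring`; a site and
#' window composed entirely of the `uncharged` set (default A, V, L, I, T, C)
#' calls `NADP_preferring`; anything else is `unresolved`. The site residue
#' dominates the window, so R at the site wins over charged window residues.
#'
#' @param residue Single site residue (character).
#' @param window Residues around the site (the site included), e.g. the
#'   `2k+1`-mer for window half-width `k`.
#' @param uncharged Residue set treated as uncharged.
#' @param charged Residue set triggering the NAD-preferring call.
#' @return One of `"NADP_preferring"`, `"NAD_preferring"`,
#'   `"dual_switching"`, `"unresolved"`.
#' @export
classify_cofactor <- function(residue, window = residue,
                              uncharged = c("A", "V", "L", "I", "T", "C"),
                              charged = c("E", "K")) {
  residue <- toupper(residue)
  chars <- unique(c(residue, strsplit(toupper(window), "")[[1]]))
  if (residue == "R") return("dual_switching")
  if (any(chars %in% charged)) return("NAD_preferring")
  if (all(chars %in% uncharged)) return("NADP_preferring")
  "unresolved"
}

#' Cofactor-preference call for a query against a numbered reference
#'
#' Maps the reference site (default position 195, the residue whose charge
#' state governs NAD(+) vs NADP(+) preference) onto the query, extracts the
#' site residue and its window of `k` flanking residues on each side, and
#' applies [classify_cofactor()].
#'
#' @param query Single protein sequence (named).
#' @param reference Reference sequence carrying the site numbering.
#' @param ref_pos Site position in the reference (default 195).
#' @param k Window half-width in residues (default 2).
#' @param scheme A [scoring_scheme()].
#' @inheritParams classify_cofactor
#' @return data.frame row: `seq_id`, `e195_query_pos`, `e195_residue`,
#'   `adjacent_window`, `call`, `rationale`.
#' @export
cofactor_call <- function(query, reference, ref_pos = 195L, k = 2L,
                          scheme = scoring_scheme(),
                          uncharged = c("A", "V", "L", "I", "T", "C"),
                          charged = c("E", "K")) {
  qid <- names(query) %||% "query"
  qseq <- toupper(as.character(query)[[1]])
  pos <- map_reference_position(qseq, reference, ref_pos, scheme)
  if (is.na(pos)) {
    return(data.frame(seq_id = qid, e195_query_pos = NA_integer_,
                      e195_residue = NA_character_,
                      adjacent_window = NA_character_, call = "unresolved",
                      rationale = "site position unmapped (gap in query)",
                      stringsAsFactors = FALSE))
  }
  win <- substring(qseq, max(1L, pos - k), min(nchar(qseq), pos + k))
  residue <- substring(qseq, pos, pos)
  call <- classify_cofactor(residue, win, uncharged, charged)
  rationale <- switch(call,
    dual_switching = sprintf("R at site position %d", pos),
    NAD_preferring = sprintf("charged-set residue (%s) at or near site %d",
                             paste(intersect(unique(strsplit(win, "")[[1]]), charged),
                                   collapse = ","), pos),
    NADP_preferring = sprintf("site %d and +/-%d window all uncharged {%s}",
                              pos, k, paste(uncharged, collapse = "")),
    unresolved = sprintf("site %d residue %s matches no rule", pos, residue))
  data.frame(seq_id = qid, e195_query_pos = pos, e195_residue = residue,
             adjacent_window = win, call = call, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' Separation of the catalytic Cys/Glu pair in primary sequence
#'
#' Takes motif hits (see [scan_motifs()]) carrying anchor residues and
#' reports the distance between the cysteine and glutamate anchors. Pairs
#' separated by more than `adjacent_max` intervening residues are classed
#' `"separated"`, otherwise `"adjacent"`. With several anchors of a kind the
#' first (leftmost) of each is used.
#'
#' @param hits data.frame of motif hits with `anchor_pos` and
#'   `anchor_residue`.
#' @param adjacent_max Maximum number of intervening residues still counted
#'   as adjacent (default 0: only directly consecutive sites are adjacent).
#' @return List of class `"catalytic_geometry"`: `complete`, `cys_pos`,
#'   `glu_pos`, `separation` (residues between positions, as `|C - E|`),
#'   `classification`.
#' @export
catalytic_pair_geometry <- function(hits, adjacent_max = 0L) {
  cys <- hits$anchor_pos[!is.na(hits$anchor_residue) & hits$anchor_residue == "C"]
  glu <- hits$anchor_pos[!is.na(hits$anchor_residue) & hits$anchor_residue == "E"]
  if (!length(cys) || !length(glu)) {
    return(structure(list(complete = FALSE,
                          cys_pos = if (length(cys)) min(cys) else NA_integer_,
                          glu_pos = if (length(glu)) min(glu) else NA_integer_,
                          separation = NA_integer_,
                          classification = "incomplete"),
                     class = "catalytic_geometry"))
  }
  cp <- min(cys); gp <- min(glu)
  sep <- abs(cp - gp)
  structure(list(complete = TRUE, cys_pos = cp, glu_pos = gp, separation = sep,
                 classification = if (sep - 1L > adjacent_max) "separated"
                                  else "adjacent"),
            class = "catalytic_geometry")
}

#' @export
print.catalytic_geometry <- function(x, ...) {
  if (!x$complete) cat("Catalytic pair: incomplete (missing Cys or Glu anchor)\n")
  else cat(sprintf("Catalytic pair: Cys %d / Glu %d, separation %d (%s)\n",
                   x$cys_pos, x$glu_pos, x$separation, x$classification))
  invisible(x)
}
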