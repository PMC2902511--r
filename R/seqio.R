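#' Read a FASTA file of protein or nucleotide sequences
#'
#' Records are returned as a [Biostrings::AAStringSet] or
#' [Biostrings::DNAStringSet] named by the first whitespace-delimited token of
#' each header; the remainder of the header is kept as the `description`
#' element metadata column. Sequences are uppercased on read.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"`, `"dna"`, or `"auto"` (default), which calls
#'   protein unless every residue is in `ACGTN`.
#' @param on_duplicate What to do with duplicated record IDs: `"error"`
#'   (default) or `"suffix"`, which appends `.2`, `.3`, ... in input order.
#' @return An `XStringSet` named by record ID, in file order.
#' @export
read_fasta <- function(path, type = c("auto", "protein", "dna"),
                       on_duplicate = c("error", "suffix")) {
  type <- match.arg(type)
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    if (on_duplicate == "error")
      stop("duplicate record IDs: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- make.unique(ids, sep = ".")
  }
  seqs <- toupper(as.character(x))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA: ", path)
  if (type == "auto")
    type <- if (all(grepl("^[ACGTN]+$", seqs))) "dna" else "protein"
  out <- switch(type,
    protein = {
      bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
      if (any(bad))
        stop("illegal protein residue characters in record(s): ",
             paste(ids[bad], collapse = ", "))
      Biostrings::AAStringSet(seqs)
    },
    dna = {
      bad <- grepl("[^ACGTN]", seqs)
      if (any(bad))
        stop("illegal nucleotide characters in record(s): ",
             paste(ids[bad], collapse = ", "))
      Biostrings::DNAStringSet(seqs)
    })
  names(out) <- ids
  attr(out, "description") <- setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param records A named character vector or `XStringSet`; names are record
#'   IDs.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  seqs <- as_char_seqs(records)
  if (length(seqs) == 0L) stop("no records to write")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all records must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' The 20-letter amino-acid alphabet plus X
#' @keywords internal
AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Read an ALDH annotation table
#'
#' Reads a TSV with the seven-column layout used for superfamily summary
#' tables: family, revised name, gene locus, molecular function, subcellular
#' localization, CDS length (bp, including the stop codon), protein length
#' (residues, excluding the stop), and molecular weight (kDa). A raw
#' localization column (`localization_raw`), if present, preserves source
#' typography.
#'
#' Row-level invariants are validated: `cds_bp` divisible by 3,
#' `n_aa == cds_bp/3 - 1`, `mw_kda > 0`, unique loci. Violations are reported
#' as a warning and attached as the `"violations"` attribute; rows are never
#' silently dropped.
#'
#' @param path Path to the TSV (header row required).
#' @return A data.frame of typed rows with attribute `"violations"` (character
#'   vector, empty when the table is internally consistent).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("family", "name", "locus", "function", "localization",
            "cds_bp", "n_aa", "mw_kda")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("family", "cds_bp", "n_aa")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) stop("malformed integer cell(s) in column ", col)
    df[[col]] <- v
  }
  mw <- suppressWarnings(as.numeric(df$mw_kda))
  if (anyNA(mw)) stop("malformed numeric cell(s) in column mw_kda")
  df$mw_kda <- mw

  viol <- character(0)
  bad3 <- df$cds_bp %% 3L != 0L
  if (any(bad3))
    viol <- c(viol, sprintf("%s: cds_bp %d not divisible by 3",
                            df$locus[bad3], df$cds_bp[bad3]))
  ok3 <- !bad3
  badlen <- ok3 & (df$n_aa != df$cds_bp %/% 3L - 1L)
  if (any(badlen))
    viol <- c(viol, sprintf("%s: n_aa %d != cds_bp/3 - 1 = %d",
                            df$locus[badlen], df$n_aa[badlen],
                            df$cds_bp[badlen] %/% 3L - 1L))
  if (any(df$mw_kda <= 0))
    viol <- c(viol, sprintf("%s: non-positive mw_kda", df$locus[df$mw_kda <= 0]))
  if (anyDuplicated(df$locus))
    viol <- c(viol, sprintf("duplicated locus: %s",
                            unique(df$locus[duplicated(df$locus)])))
  if (length(viol))
    warning("annotation table invariant violation(s):\n  ",
            paste(viol, collapse = "\n  "))
  attr(df, "violations") <- viol
  df
}

#' The packaged rice ALDH superfamily annotation table
#'
#' Twenty-one genes in ten families with revised AGNC names, loci, functional
#' annotations, CDS and protein lengths and molecular weights.
#'
#' @return A validated annotation data.frame (see [read_annotation_table()]).
#' @export
aldh_table1 <- function() {
  read_annotation_table(system.file("extdata", "rice_aldh_table1.tsv",
                                    package = "aldhtools", mustWork = TRUE))
}

#' Protein length implied by a CDS length
#'
#' The CDS length convention includes the stop codon, so a CDS of `cds_bp`
#' base pairs encodes `cds_bp/3 - 1` residues.
#'
#' @param cds_bp Positive integer vector of CDS lengths, each divisible by 3.
#' @return Integer vector of protein lengths.
#' @export
orf_protein_length <- function(cds_bp) {
  if (any(cds_bp <= 0)) stop("cds_bp must be positive")
  if (any(cds_bp %% 3 != 0)) stop("cds_bp must be divisible by 3")
  as.integer(cds_bp %/% 3 - 1)
}

# Standard average residue masses (Da); residue = amino acid minus water.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Average molecular weight of a protein sequence
#'
#' Sum of standard average residue masses plus one water, in kilodaltons.
#' `X` is scored with a configurable mass (default: mean of the 20 standard
#' residue masses).
#'
#' @param seq Character vector of protein sequences (no gaps).
#' @param x_mass Mass (Da) used for the ambiguity code `X`.
#' @return Numeric vector of masses in kDa.
#' @export
protein_mw <- function(seq, x_mass = mean(RESIDUE_MASS)) {
  masses <- c(RESIDUE_MASS, X = x_mass)
  vapply(as.character(seq), function(s) {
    if (is.na(s) || nchar(s) == 0L) stop("empty protein sequence")
    aa <- strsplit(toupper(s), "")[[1]]
    unknown <- setdiff(aa, names(masses))
    if (length(unknown))
      stop("unknown residue(s): ", paste(unknown, collapse = ", "))
    (sum(masses[aa]) + WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}
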