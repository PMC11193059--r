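#' Read a dataset table
#'
#' The package's tabular interchange format is CSV with a header row and
#' required columns `complex_id`, `protein_seq`, `smiles`, `affinity`
#' (-log molar units) plus the optional column `pocket_positions`
#' (semicolon-separated 1-based residue positions of the binding pocket).
#' Malformed rows (empty sequences, unparseable affinity) are dropped and
#' reported with their line numbers; a missing required column is a hard
#' error. CRLF line endings parse identically to LF.
#'
#' @param path CSV file path.
#' @return Data frame of validated records, with attribute `"rejected"`
#'   holding the 1-based data-row numbers that were dropped (if any).
#' @export
read_dataset_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("complex_id", "protein_seq", "smiles", "affinity")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("dataset table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  aff <- suppressWarnings(as.numeric(df$affinity))
  bad <- !nzchar(df$protein_seq) | !nzchar(df$smiles) | is.na(aff)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped (data rows: ",
            paste(utils::head(which(bad), 20L), collapse = ", "), ")")
  }
  out <- df[!bad, , drop = FALSE]
  out$affinity <- aff[!bad]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(bad)
  out
}

#' Write a dataset table
#'
#' @param records data frame of records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a FASTA file
#'
#' Thin wrapper over `Biostrings` FASTA parsing. Multi-line sequences are
#' joined; the identifier is the header up to the first whitespace, with
#' any remaining description kept in the `"descriptions"` attribute.
#'
#' @param path FASTA file path.
#' @return Named character vector `id -> sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  out <- as.character(set)
  names(out) <- ids
  attr(out, "descriptions") <- stats::setNames(desc, ids)
  out
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a .smi ligand file
#'
#' One SMILES string per line, optionally followed by whitespace and an
#' identifier. Lines without an identifier are numbered.
#'
#' @param path file path.
#' @return Named character vector `id -> SMILES`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  smi <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else as.character(i)
  }, character(1))
  stats::setNames(smi, ids)
}

# 3-letter -> 1-letter residue codes (standard 20; others become X)
AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Extract pocket residues from a PDB file
#'
#' Reads the ATOM records of a (pocket) PDB file with `bio3d`, collapses
#' them to one entry per (chain, residue number), maps 3-letter residue
#' names to 1-letter codes (unknown names map to `X` with a warning), and
#' orders by chain then residue number.
#'
#' @param path PDB file path.
#' @return Data frame with columns `chain`, `position` (author residue
#'   number) and `residue` (1-letter code); zero rows if the file has no
#'   ATOM records.
#' @export
parse_pocket_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    return(data.frame(chain = character(0), position = integer(0),
                      residue = character(0)))
  }
  key <- !duplicated(paste(at$chain, at$resno))
  res <- at[key, c("chain", "resno", "resid")]
  one <- AA_321[res$resid]
  if (anyNA(one)) {
    warning("unknown residue name(s) mapped to X: ",
            paste(unique(res$resid[is.na(one)]), collapse = ", "))
    one[is.na(one)] <- "X"
  }
  out <- data.frame(chain = res$chain, position = res$resno,
                    residue = unname(one), stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a pocket mask from residue positions
#'
#' The pocket mask has the same fixed length as the encoded protein and
#' holds the protein's own token index at each pocket position, zero
#' elsewhere — so the dynamically embedded pocket stream is a masked copy
#' of the protein stream. Residue letters, when supplied, are
#' cross-checked against the protein sequence: mismatches warn but the
#' position is honoured (author numbering wins).
#'
#' @param protein_seq protein amino-acid string.
#' @param pocket_residues integer vector of 1-based positions, or a data
#'   frame with columns `position` and optionally `residue` (as returned
#'   by [parse_pocket_pdb()]).
#' @param dictionary protein `token_dictionary`.
#' @param fixed_length encoded length L_P.
#' @return Integer vector of length `fixed_length` (class
#'   `pocket_mask`).
#' @export
derive_pocket_mask <- function(protein_seq, pocket_residues,
                               dictionary = protein_dictionary(),
                               fixed_length = 1024L) {
  if (is.data.frame(pocket_residues)) {
    posn <- pocket_residues$position
    res <- pocket_residues$residue
  } else {
    posn <- as.integer(pocket_residues)
    res <- NULL
  }
  n <- nchar(protein_seq)
  if (any(posn < 1L | posn > n)) {
    stop("pocket position out of range [1, ", n, "]: ",
         paste(posn[posn < 1L | posn > n], collapse = ", "))
  }
  chars <- strsplit(protein_seq, "", fixed = TRUE)[[1]]
  if (!is.null(res)) {
    mism <- res != chars[posn]
    if (any(mism)) {
      warning(sum(mism), " pocket residue letter(s) disagree with the ",
              "protein sequence at position(s) ",
              paste(posn[mism], collapse = ", "), "; positions honoured")
    }
  }
  enc <- suppressWarnings(
    encode_sequence(protein_seq, dictionary, fixed_length))
  mask <- integer(fixed_length)
  keep <- posn[posn <= fixed_length]
  mask[keep] <- enc$indices[keep]
  structure(mask, class = "pocket_mask")
}

#' Read a PDBbind-style index file
#'
#' Whitespace-delimited lines: PDB code, resolution, year, -log affinity
#' value, then the measurement string; lines starting with `#` are
#' comments. Duplicate codes keep the last occurrence with a warning.
#'
#' @param path index file path.
#' @return Named numeric vector `pdb code -> -log affinity`.
#' @export
read_pdbbind_index <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "\\s+")
  short <- lengths(parts) < 4L
  if (any(short)) {
    stop("malformed index line(s): ", paste(which(short), collapse = ", "))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  val <- as.numeric(vapply(parts, `[[`, character(1), 4L))
  if (anyNA(val)) stop("unparseable affinity value in index file")
  dup <- duplicated(ids, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate id(s), last occurrence kept: ",
            paste(unique(ids[dup]), collapse = ", "))
  }
  stats::setNames(val[!dup], ids[!dup])
}
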