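#' Token dictionaries for label encoding
#'
#' A token dictionary maps single-character tokens to consecutive integer
#' indices `0..V-1`. Index 0 is always the padding token `<MASK>`; padded
#' positions in an encoded sequence carry index 0 and embed to the zero
#' vector downstream. Dictionaries can be frequency-ordered (tokens seen
#' more often in a training corpus receive smaller indices, which keeps
#' gradient updates for common tokens concentrated) or alphabetical
#' (ordered by character code).
#'
#' @param corpus character vector of sequences to count tokens from.
#' @param mode `"frequency"` (descending corpus count, ties broken
#'   lexicographically) or `"alphabetical"`.
#' @return An object of class `token_dictionary`: a list with elements
#'   `tokens` (named integer vector, names are tokens, values indices,
#'   `<MASK>` = 0 first) and `mode`.
#' @examples
#' d <- build_dictionary(c("AAB"), mode = "frequency")
#' d$tokens  # <MASK>=0, A=1, B=2
#' @export
build_dictionary <- function(corpus, mode = c("frequency", "alphabetical")) {
  mode <- match.arg(mode)
  chars <- unlist(strsplit(corpus, "", fixed = TRUE), use.names = FALSE)
  if (length(chars) == 0L) {
    if (mode == "frequency") {
      warning("empty corpus: dictionary contains only the padding token")
    }
    return(new_token_dictionary(character(0), mode))
  }
  counts <- table(chars)
  toks <- names(counts)
  if (mode == "frequency") {
    ord <- order(-as.integer(counts), toks, method = "radix")
  } else {
    ord <- order(toks, method = "radix")
  }
  new_token_dictionary(toks[ord], mode)
}

new_token_dictionary <- function(ordered_tokens, mode) {
  stopifnot(!"<MASK>" %in% ordered_tokens, !anyDuplicated(ordered_tokens))
  tokens <- c(0L, seq_along(ordered_tokens))
  names(tokens) <- c("<MASK>", ordered_tokens)
  structure(list(tokens = tokens, mode = mode), class = "token_dictionary")
}

#' @export
print.token_dictionary <- function(x, ...) {
  cat("<token_dictionary> ", length(x$tokens), " tokens (", x$mode,
      " order), pad '<MASK>' = 0\n", sep = "")
  show <- utils::head(x$tokens[-1], 12L)
  cat(" ", paste0(names(show), "=", show, collapse = " "),
      if (length(x$tokens) > 13L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname build_dictionary
#' @param x a `token_dictionary`.
#' @export
vocab_size <- function(x) length(x$tokens)

#' Canonical dictionaries
#'
#' `protein_dictionary()` returns the 21-entry amino-acid dictionary
#' (padding plus the 20 standard residues in alphabetical order, `A` = 1 ...
#' `Y` = 20). `smiles_dictionary()` returns the 53-entry character-level
#' SMILES dictionary shipped with the package. The SMILES dictionary is a
#' synthetic reconstruction: a frequency-plausible ordering over the SMILES
#' character alphabet of typical ligand libraries, pinned to the published
#' anchor indices `C`=1, `(`=2, `)`=3, `O`=5, `=`=10. Both are stored as
#' plain-text fixtures under `inst/extdata/`.
#'
#' @return A `token_dictionary`.
#' @examples
#' d <- protein_dictionary()
#' d$tokens[c("A", "D", "P", "S", "T")]  # 1 3 13 16 17
#' @export
protein_dictionary <- function() {
  read_dictionary(system.file("extdata", "protein_dict.tsv",
                              package = "seqdta", mustWork = TRUE),
                  mode = "alphabetical")
}

#' @rdname protein_dictionary
#' @export
smiles_dictionary <- function() {
  read_dictionary(system.file("extdata", "smiles_dict_synthetic.tsv",
                              package = "seqdta", mustWork = TRUE),
                  mode = "frequency")
}

#' Read / write a dictionary file
#'
#' The on-disk format is two tab-separated columns, `token<TAB>index`, one
#' row per token with the index-0 padding row first.
#'
#' @param path file path.
#' @param mode ordering mode recorded on the returned object.
#' @return `read_dictionary` returns a `token_dictionary`;
#'   `write_dictionary` returns `path` invisibly.
#' @export
read_dictionary <- function(path, mode = "frequency") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed dictionary rows at line(s): ",
         paste(which(bad), collapse = ", "))
  }
  toks <- vapply(parts, `[[`, character(1), 1L)
  idx <- as.integer(vapply(parts, `[[`, character(1), 2L))
  ord <- order(idx)
  toks <- toks[ord]; idx <- idx[ord]
  if (!identical(idx, seq_along(idx) - 1L) || toks[1] != "<MASK>") {
    stop("dictionary must map '<MASK>' to 0 and use consecutive indices")
  }
  new_token_dictionary(toks[-1], mode)
}

#' @rdname read_dictionary
#' @param dictionary a `token_dictionary` to serialise.
#' @export
write_dictionary <- function(dictionary, path) {
  writeLines(paste(names(dictionary$tokens), dictionary$tokens, sep = "\t"),
             path)
  invisible(path)
}

#' Label-encode a character sequence
#'
#' Looks tokens up character by character against a dictionary and returns a
#' fixed-length integer array: sequences longer than `fixed_length` are
#' truncated at the end (the prefix is kept), shorter ones are right-padded
#' with the padding index 0. Characters absent from the dictionary map to 0
#' with a warning — real protein sequences contain nonstandard residue codes
#' (X, B, Z) that carry no learned embedding.
#'
#' @param sequence a single character string.
#' @param dictionary a `token_dictionary`.
#' @param fixed_length target array length (1024 for proteins/pockets and
#'   256 for SMILES at paper scale).
#' @return An object of class `encoded_sequence`: list with `indices`
#'   (integer vector of length `fixed_length`), `original_length` and
#'   `fixed_length`.
#' @examples
#' enc <- encode_sequence("PTAPSD", protein_dictionary(), 6)
#' enc$indices  # 13 17 1 13 16 3
#' @export
encode_sequence <- function(sequence, dictionary, fixed_length) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            fixed_length >= 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  kept <- utils::head(chars, fixed_length)
  idx <- unname(dictionary$tokens[kept])
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning("mapped ", sum(unknown), " unknown character(s) to index 0: ",
            paste(unique(kept[unknown]), collapse = " "))
    idx[unknown] <- 0L
  }
  indices <- c(as.integer(idx), integer(max(0L, fixed_length - n)))
  structure(list(indices = indices, original_length = n,
                 fixed_length = as.integer(fixed_length)),
            class = "encoded_sequence")
}

#' Invert an encoding
#'
#' Maps indices back to tokens, dropping trailing padding. Only exact for
#' encodings that were neither truncated nor contained unknown characters.
#'
#' @param encoded an `encoded_sequence` (or bare integer vector).
#' @param dictionary the `token_dictionary` used to encode.
#' @return A character string.
#' @export
decode_sequence <- function(encoded, dictionary) {
  idx <- if (inherits(encoded, "encoded_sequence")) encoded$indices else encoded
  n <- if (inherits(encoded, "encoded_sequence")) {
    min(encoded$original_length, encoded$fixed_length)
  } else {
    len <- length(idx)
    while (len > 0L && idx[len] == 0L) len <- len - 1L
    len
  }
  if (n == 0L) return("")
  lut <- names(dictionary$tokens)[order(dictionary$tokens)]
  paste(lut[idx[seq_len(n)] + 1L], collapse = "")
}
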