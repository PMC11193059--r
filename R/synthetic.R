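#' Synthetic dataset specification
#'
#' Describes a downloadless stand-in for a curated binding-affinity
#' corpus. Each record gets a random protein sequence with a contiguous
#' binding pocket, a random character-level SMILES string, and an affinity
#' with a planted multiplicative pocket-by-ligand signal:
#'
#' `affinity = base + w_motif * (#motif copies inside the pocket) *
#'   (#ligand_token occurrences in the SMILES) / normalizer + N(0, noise_sd)`
#'
#' clamped to the plausible -log affinity range `[2, 12]`. Motif copies
#' are planted inside the pocket (signal-bearing) and, as decoys, outside
#' it (signal-free), so a model that cannot see the pocket mask is
#' measurably handicapped; the signal is multiplicative between a protein
#' feature and a ligand feature so a model without a cross-interaction
#' stage is handicapped too.
#'
#' @param n_records number of records.
#' @param protein_length_range,ligand_length_range inclusive length
#'   ranges.
#' @param pocket_fraction fraction of the protein covered by the
#'   contiguous pocket, in `(0, 1]`.
#' @param motif short amino-acid motif whose in-pocket count drives the
#'   signal.
#' @param ligand_token single SMILES character whose count drives the
#'   ligand side of the signal.
#' @param w_motif signal weight.
#' @param base baseline affinity.
#' @param normalizer divisor of the planted product.
#' @param noise_sd Gaussian label noise (>= 0).
#' @param max_motifs_in,max_motifs_out maximum planted in-pocket copies /
#'   out-of-pocket decoys per protein (counts drawn uniformly from 0..max).
#' @param max_ligand_tokens maximum planted ligand-token occurrences.
#' @param seed RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 200L,
                           protein_length_range = c(24L, 40L),
                           pocket_fraction = 0.3,
                           ligand_length_range = c(12L, 20L),
                           motif = "CWM",
                           ligand_token = "O",
                           w_motif = 0.8,
                           base = 5,
                           normalizer = 1,
                           noise_sd = 0.1,
                           max_motifs_in = 3L,
                           max_motifs_out = 2L,
                           max_ligand_tokens = 4L,
                           seed = 1L) {
  if (pocket_fraction <= 0 || pocket_fraction > 1) {
    stop("pocket_fraction must lie in (0, 1]")
  }
  stopifnot(noise_sd >= 0, n_records >= 1L,
            protein_length_range[1] <= protein_length_range[2],
            ligand_length_range[1] <= ligand_length_range[2])
  structure(as.list(environment()), class = "synthetic_spec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# SMILES filler alphabet: common organic-subset characters from the
# shipped dictionary, excluding the default signal token "O"
SMI_FILLER <- c("C", "c", "N", "n", "(", ")", "=", "1", "2", "3", "S", "F")

# sample() without the scalar-x surprise
resample <- function(x, n = length(x), replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

plant_motifs <- function(chars, slots, motif_chars, count) {
  # place `count` non-overlapping motif copies at positions drawn from
  # `slots` (candidate start offsets); returns modified chars + count placed
  k <- length(motif_chars)
  placed <- 0L
  taken <- logical(length(chars))
  slots <- resample(slots)
  for (s in slots) {
    if (placed >= count) break
    span <- s:(s + k - 1L)
    if (any(taken[span])) next
    chars[span] <- motif_chars
    taken[span] <- TRUE
    placed <- placed + 1L
  }
  list(chars = chars, placed = placed, taken = taken)
}

#' Generate a synthetic affinity dataset
#'
#' Deterministic given the spec's seed: the same spec yields byte-identical
#' records.
#'
#' @param spec a [synthetic_spec()].
#' @return Data frame with columns `complex_id`, `protein_seq`,
#'   `pocket_positions` (semicolon-separated), `smiles`, `affinity`, plus
#'   bookkeeping columns `n_motif_pocket`, `n_motif_decoy`,
#'   `n_ligand_token` recording the planted counts.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  motif_chars <- strsplit(spec$motif, "")[[1]]
  k <- length(motif_chars)
  recs <- lapply(seq_len(spec$n_records), function(i) {
    Lp <- resample(spec$protein_length_range[1]:spec$protein_length_range[2], 1L)
    chars <- resample(AA20, Lp, replace = TRUE)
    pocket_len <- max(k, round(spec$pocket_fraction * Lp))
    pocket_start <- sample.int(Lp - pocket_len + 1L, 1L)
    pocket <- pocket_start:(pocket_start + pocket_len - 1L)
    # remove chance motif occurrences so planted counts are exact
    chars <- scrub_motif(chars, motif_chars)

    n_in <- sample.int(spec$max_motifs_in + 1L, 1L) - 1L
    n_out <- sample.int(spec$max_motifs_out + 1L, 1L) - 1L
    in_slots <- pocket[pocket + k - 1L <= max(pocket)]
    out_pos <- setdiff(seq_len(Lp), pocket)
    out_slots <- out_pos[vapply(out_pos, function(s) {
      s + k - 1L <= Lp && all((s:(s + k - 1L)) %in% out_pos)
    }, logical(1))]
    pin <- plant_motifs(chars, in_slots, motif_chars, n_in)
    pout <- plant_motifs(pin$chars, out_slots, motif_chars, n_out)
    chars <- scrub_motif(pout$chars, motif_chars,
                         protect = pin$taken | pout$taken)

    Ls <- resample(spec$ligand_length_range[1]:spec$ligand_length_range[2], 1L)
    filler <- setdiff(SMI_FILLER, spec$ligand_token)
    smi <- resample(filler, Ls, replace = TRUE)
    n_tok <- min(sample.int(spec$max_ligand_tokens + 1L, 1L) - 1L, Ls)
    if (n_tok > 0L) smi[sample.int(Ls, n_tok)] <- spec$ligand_token

    aff <- spec$base +
      spec$w_motif * pin$placed * n_tok / spec$normalizer +
      stats::rnorm(1L, 0, spec$noise_sd)
    data.frame(
      complex_id = sprintf("syn%04d", i),
      protein_seq = paste(chars, collapse = ""),
      pocket_positions = paste(pocket, collapse = ";"),
      smiles = paste(smi, collapse = ""),
      affinity = min(max(aff, 2), 12),
      n_motif_pocket = pin$placed,
      n_motif_decoy = pout$placed,
      n_ligand_token = n_tok,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, recs)
}

# replace chance occurrences of the motif (outside protected spans) so the
# planted copy counts are the true counts
scrub_motif <- function(chars, motif_chars, protect = logical(length(chars))) {
  k <- length(motif_chars)
  n <- length(chars)
  if (n < k) return(chars)
  repeat {
    hit <- FALSE
    for (s in seq_len(n - k + 1L)) {
      span <- s:(s + k - 1L)
      if (all(chars[span] == motif_chars) && !all(protect[span])) {
        repl <- span[!protect[span]][1L]
        chars[repl] <- resample(setdiff(AA20, motif_chars[match(repl, span)]), 1L)
        hit <- TRUE
      }
    }
    if (!hit) break
  }
  chars
}

#' Worked encoding examples
#'
#' Machine-readable fixtures for the two canonical label-encoding worked
#' examples: the protein fragment `PTAPSD` and the ligand `C(=O)CCC`,
#' with their expected index arrays under the shipped dictionaries.
#'
#' @return Data frame with columns `sequence`, `type`, `fixed_length`,
#'   `expected` (space-separated indices).
#' @export
generate_worked_examples <- function() {
  data.frame(
    sequence = c("PTAPSD", "C(=O)CCC"),
    type = c("protein", "smiles"),
    fixed_length = c(6L, 8L),
    expected = c("13 17 1 13 16 3", "1 2 10 5 3 1 1 1"),
    stringsAsFactors = FALSE
  )
}
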