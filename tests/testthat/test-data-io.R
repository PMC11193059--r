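make_table_lines <- function() c(
  "complex_id,protein_seq,smiles,affinity,pocket_positions",
  "c1,PTAPSD,C(=O)CCC,5.32,1;4",
  "c2,ACDEF,CCO,7.1,",
  "c3,MKV,c1ccccc1,4.8,2"
)

test_that("dataset tables read back validated records", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(make_table_lines(), path)
  df <- read_dataset_table(path)
  expect_identical(nrow(df), 3L)
  expect_identical(df$complex_id, c("c1", "c2", "c3"))
  expect_equal(df$affinity, c(5.32, 7.1, 4.8))
})

test_that("malformed rows are dropped with a warning; missing columns are fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(make_table_lines(), "bad,AC, ,oops,"), path)
  expect_warning(df <- read_dataset_table(path), "malformed")
  expect_identical(nrow(df), 3L)
  expect_identical(attr(df, "rejected"), 4L)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("complex_id,protein_seq,affinity", "c1,AC,5"), path2)
  expect_error(read_dataset_table(path2), "smiles")
})

test_that("CRLF and LF dataset files parse identically", {
  lf <- withr::local_tempfile(fileext = ".csv")
  crlf <- withr::local_tempfile(fileext = ".csv")
  writeLines(make_table_lines(), lf)
  con <- file(crlf, "wb")
  writeBin(charToRaw(paste0(paste(make_table_lines(), collapse = "\r\n"),
                            "\r\n")), con)
  close(con)
  a <- read_dataset_table(lf)
  b <- read_dataset_table(crlf)
  attributes(a) <- attributes(a)[c("names", "class", "row.names")]
  attributes(b) <- attributes(b)[c("names", "class", "row.names")]
  expect_identical(a, b)
})

test_that("dataset tables round-trip through write/read", {
  ds <- generate_dataset(synthetic_spec(n_records = 5L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_table(ds, path)
  back <- read_dataset_table(path)
  expect_identical(back$protein_seq, ds$protein_seq)
  expect_identical(back$smiles, ds$smiles)
  expect_equal(back$affinity, ds$affinity, tolerance = 1e-12)
})

test_that("FASTA parsing joins multi-line sequences and keeps descriptions", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some kinase", "PTAP", "SD", ">p2", "ACDEF"), path)
  seqs <- read_fasta(path)
  expect_identical(unname(seqs["p1"]), "PTAPSD")
  expect_identical(unname(seqs["p2"]), "ACDEF")
  expect_identical(unname(attr(seqs, "descriptions")["p1"]), "some kinase")
  # round trip
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(a = "MKVLA", b = "PPP"), out)
  back <- read_fasta(out)
  expect_identical(unname(back[c("a", "b")]), c("MKVLA", "PPP"))
})

test_that(".smi files yield named SMILES vectors", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO lig1", "c1ccccc1   lig2", "C(=O)O"), path)
  smi <- read_smi(path)
  expect_identical(unname(smi["lig1"]), "CCO")
  expect_identical(unname(smi["lig2"]), "c1ccccc1")
  expect_identical(unname(smi["3"]), "C(=O)O")
})

pdb_atom_line <- function(serial, atom, resname, chain, resno, x, y, z,
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, atom, resname, chain, resno, x, y, z, 1, 20)
}

write_pocket_pdb <- function(path, hetatm_only = FALSE) {
  rec <- if (hetatm_only) "HETATM" else "ATOM"
  lines <- c(
    pdb_atom_line(1, "N", "GLY", "A", 10, 1, 1, 1, rec),
    pdb_atom_line(2, "CA", "GLY", "A", 10, 2, 1, 1, rec),
    pdb_atom_line(3, "N", "ALA", "A", 12, 3, 1, 1, rec),
    pdb_atom_line(4, "CA", "ALA", "A", 12, 4, 1, 1, rec),
    pdb_atom_line(5, "CB", "ALA", "A", 12, 5, 1, 1, rec),
    "END")
  writeLines(lines, path)
}

test_that("pocket PDB parsing collapses atoms to ordered one-letter residues", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pocket_pdb(path)
  res <- parse_pocket_pdb(path)
  expect_identical(nrow(res), 2L)  # 5 ATOM lines across 2 residues
  expect_identical(res$residue, c("G", "A"))
  expect_equal(res$position, c(10, 12))
})

test_that("HETATM-only files yield an empty pocket", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pocket_pdb(path, hetatm_only = TRUE)
  res <- parse_pocket_pdb(path)
  expect_identical(nrow(res), 0L)
})

test_that("pocket masks hold the protein's own token indices", {
  # 'PTAPSD': P = 13 under the canonical dictionary
  mask <- derive_pocket_mask("PTAPSD", c(1L, 4L), fixed_length = 6L)
  expect_identical(as.integer(mask), c(13L, 0L, 0L, 13L, 0L, 0L))
  # full coverage equals the encoded protein
  full <- derive_pocket_mask("PTAPSD", 1:6, fixed_length = 6L)
  expect_identical(as.integer(full),
                   encode_sequence("PTAPSD", protein_dictionary(), 6L)$indices)
  # empty pocket is the all-zero mask
  none <- derive_pocket_mask("PTAPSD", integer(0), fixed_length = 6L)
  expect_identical(as.integer(none), rep(0L, 6L))
  expect_error(derive_pocket_mask("PTAPSD", 9L, fixed_length = 6L),
               "out of range")
  expect_warning(
    derive_pocket_mask("PTAPSD",
                       data.frame(position = 1L, residue = "G"),
                       fixed_length = 6L),
    "disagree")
})

test_that("pocket PDB -> mask pipeline marks exactly the pocket residues", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pocket_pdb(path)
  res <- parse_pocket_pdb(path)
  prot <- paste(rep("GAVLK", 4), collapse = "")  # 20 residues, G at 1,6,11,16
  mask <- suppressWarnings(derive_pocket_mask(prot, res, fixed_length = 20L))
  expect_identical(sum(mask != 0L), nrow(res))
})

test_that("PDBbind-style index files parse by documented field positions", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# PDBbind-like index",
               "1abc  2.00  1999  5.32  Kd=4.8uM",
               "2xyz  1.50  2005  7.10  Ki=80nM",
               "1abc  2.00  1999  6.00  Kd=1uM"), path)
  expect_warning(idx <- read_pdbbind_index(path), "duplicate")
  expect_equal(unname(idx["1abc"]), 6.00)  # last occurrence wins
  expect_equal(unname(idx["2xyz"]), 7.10)
  expect_length(idx, 2L)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# only", "# comments"), empty)
  expect_length(read_pdbbind_index(empty), 0L)
})

test_that("synthetic records always encode cleanly under the shipped dictionaries", {
  ds <- generate_dataset(synthetic_spec(n_records = 30L, seed = 9L))
  expect_silent({
    enc <- encode_records(ds, small_config())
  })
  expect_length(enc, 30L)
})
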