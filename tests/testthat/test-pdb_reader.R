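test_that("fixture-written ATOM and HETATM lines round-trip field-for-field", {
  cases <- list(
    list(rec = "ATOM", serial = 1L, name = "CA", alt = "", res = "ALA",
         chain = "A", seq = 1L, icode = "", x = 0, y = 0, z = 0,
         occ = 1, tf = 0, el = "C", chg = ""),
    list(rec = "ATOM", serial = 99999L, name = "OXT", alt = "B", res = "GLY",
         chain = "z", seq = -5L, icode = "A", x = -123.456, y = 9999.999,
         z = 0.001, occ = 0.25, tf = 99.99, el = "O", chg = "1-"),
    list(rec = "HETATM", serial = 7L, name = "O", alt = "", res = "HOH",
         chain = "W", seq = 301L, icode = "", x = 30.5, y = -0.25, z = 12,
         occ = 1, tf = 35.5, el = "O", chg = ""))
  for (cs in cases) {
    line <- format_atom_record(cs$rec, cs$serial, cs$name, cs$alt, cs$res,
                               cs$chain, cs$seq, cs$icode, cs$x, cs$y, cs$z,
                               cs$occ, cs$tf, cs$el, cs$chg)
    row <- parse_section_line(line, cs$rec)
    expect_equal(row$recordName, cs$rec)
    expect_equal(row$serial, cs$serial)
    expect_equal(row$atomName, cs$name)
    expect_equal(row$altLoc, cs$alt)
    expect_equal(row$resName, cs$res)
    expect_equal(row$chainId, cs$chain)
    expect_equal(row$resSeq, cs$seq)
    expect_equal(row$iCode, cs$icode)
    expect_equal(row$x, cs$x)
    expect_equal(row$y, cs$y)
    expect_equal(row$z, cs$z)
    expect_equal(row$occupancy, cs$occ)
    expect_equal(row$tempFactor, cs$tf)
    expect_equal(row$element, cs$el)
    expect_equal(row$charge, cs$chg)
  }
})

test_that("gzip inputs are detected by magic bytes, inflate to identical text,
           and corrupt streams raise a compression error", {
  text <- make_polypeptide(fixture_spec(n_residues = 4, seed = 11), 1)
  plain <- tempfile(fileext = ".ent")
  writeChar(text, plain, eos = NULL)
  # gzip content behind an extension that does not say so
  gz <- tempfile(fileext = ".ent")
  con <- gzfile(gz, "wb"); writeChar(text, con, eos = NULL); close(con)
  expect_identical(read_entry_text(plain), text)
  expect_identical(read_entry_text(gz), text)

  bad <- tempfile(fileext = ".ent.gz")
  raw <- readBin(gz, "raw", file.size(gz))
  writeBin(raw[1:20], bad)  # truncated gzip stream
  expect_error(read_entry_text(bad), class = "pdblake_compression_error")
  expect_error(read_entry_text(tempfile()), class = "pdblake_io_error")
})

test_that("protein id comes from the HEADER idCode, uppercased, else fallback", {
  hdr <- sprintf("HEADER    %-40s%9s   %4s", "PROTEIN", "01-JAN-00", "1abc")
  expect_equal(derive_protein_id(paste(hdr, "END", sep = "\n"), "pdb0001"),
               "1ABC")
  expect_equal(derive_protein_id("ATOM\nEND\n", "pdb0001"), "PDB0001")
  # HEADER wins over the fallback
  expect_equal(derive_protein_id(paste(hdr, "END", sep = "\n"), "zzzz"), "1ABC")
})

test_that("extract_section filters by record name, tracks MODEL context and
           returns the fixed schema when empty", {
  txt <- make_polypeptide(fixture_spec(n_residues = 3, seed = 2), 1)
  atoms <- extract_section(txt, "ATOM")
  het <- extract_section(txt, "HETATM")
  expect_equal(nrow(atoms), 9L)            # N, CA, C per residue
  expect_true(all(atoms$recordName == "ATOM"))
  expect_equal(nrow(het), 1L)              # the water
  expect_equal(het$resName, "HOH")
  expect_true(all(atoms$modelId == 1L))    # no MODEL records -> 1

  multi <- make_polypeptide(fixture_spec(n_residues = 2, n_models = 3,
                                         seed = 2), 1)
  rows <- extract_section(multi, "ATOM")
  expect_equal(unique(rows$modelId), 1:3)
  expect_equal(nrow(rows), 18L)

  empty <- extract_section("HEADER    X\nEND\n", "ATOM")
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), names(section_schema("ATOM")))
  expect_error(extract_section(txt, "CONECT"), class = "pdblake_usage_error")
})

test_that("malformed lines fail fast with a line number in strict mode and
           are skipped and counted in lenient mode", {
  txt <- make_polypeptide(fixture_spec(n_residues = 3, seed = 5), 1)
  lines <- strsplit(txt, "\n")[[1]]
  i <- which(startsWith(lines, "ATOM"))[2]
  lines[i] <- substr(lines[i], 1, 30)      # truncated before the z column
  bad <- paste0(paste(lines, collapse = "\n"), "\n")

  err <- expect_error(extract_section(bad, "ATOM"),
                      class = "pdblake_malformed_line_error")
  expect_equal(err$line, i)

  rows <- extract_section(bad, "ATOM", strict = FALSE)
  expect_equal(nrow(rows), 8L)
  expect_equal(attr(rows, "malformed_skipped"), 1L)
})

test_that("SEQRES rows pad to 13 residue fields and sum to numRes per chain", {
  txt <- make_polypeptide(fixture_spec(n_residues = 18, seed = 9), 1)
  sq <- extract_section(txt, "SEQRES")
  expect_equal(nrow(sq), 2L)               # 13 + 5 residue names
  name_cols <- paste0("resName", 1:13)
  filled <- rowSums(sq[, lapply(.SD, nzchar), .SDcols = name_cols])
  expect_equal(as.vector(filled), c(13L, 5L))
  expect_equal(sum(filled), unique(sq$numRes))
  # padding contract on the short row
  expect_true(all(sq[2, paste0("resName", 6:13), with = FALSE] == ""))
})

test_that("HELIX and SHEET records parse at their fixed columns", {
  txt <- make_polypeptide(fixture_spec(n_residues = 10, seed = 4), 1)
  hx <- extract_section(txt, "HELIX")
  expect_equal(nrow(hx), 1L)
  expect_equal(hx$serNum, 1L)
  expect_equal(hx$helixId, "H1")
  expect_equal(hx$initSeqNum, 1L)
  expect_equal(hx$endSeqNum, 4L)
  expect_equal(hx$helixClass, 1L)
  expect_equal(hx$length, 4L)

  sh <- extract_section(txt, "SHEET")
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$strand, 1L)
  expect_equal(sh$sheetId, "S1")
  expect_equal(sh$numStrands, 1L)
  expect_equal(sh$initSeqNum, 5L)
  expect_equal(sh$endSeqNum, 8L)
  expect_equal(sh$sense, 0L)
})
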