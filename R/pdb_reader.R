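# Fixed-width parsers for the five supported PDB v3.3 sections.
#
# Column positions are the 1-based fixed columns of the wwPDB format v3.3
# dialect used by *.ent files. Fields are sliced, trimmed of flanking
# spaces and converted to their semantic type; optional numeric fields that
# are blank become NA (written as empty in CSV).

SECTION_KINDS <- c("ATOM", "HETATM", "SHEET", "HELIX", "SEQRES")

match_section_kind <- function(kind) {
  k <- toupper(as.character(kind)[1])
  if (!k %in% SECTION_KINDS) {
    stop_usage(sprintf("unsupported section kind '%s' (expected one of %s)",
                       kind, paste(SECTION_KINDS, collapse = ", ")))
  }
  k
}

slice <- function(lines, first, last) trimws(substr(lines, first, last))

as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) suppressWarnings(as.integer(x))

# Optional numeric column: blank -> NA, non-numeric text -> marked bad.
opt_num <- function(raw) {
  v <- rep(NA_real_, length(raw))
  nz <- raw != ""
  v[nz] <- as_num(raw[nz])
  list(value = v, bad = nz & is.na(v))
}

opt_int <- function(raw) {
  v <- rep(NA_integer_, length(raw))
  nz <- raw != ""
  v[nz] <- as_int(raw[nz])
  list(value = v, bad = nz & is.na(v))
}

#' Read the text of one PDB entry, inflating gzip transparently
#'
#' Gzip inputs are detected by their magic bytes (`1f 8b`), never by file
#' extension; plain text passes through unchanged. PDB files are ASCII, so
#' bytes are decoded as Latin-1 (which never fails).
#'
#' @param source Path to a `.ent`/`.pdb` file, plain or gzip-compressed.
#' @return A single string holding the full entry text.
#' @examples
#' p <- tempfile(fileext = ".ent")
#' writeLines(c("HEADER    X", "END"), p)
#' cat(read_entry_text(p))
#' @export
read_entry_text <- function(source) {
  if (!is.character(source) || length(source) != 1L || !file.exists(source)) {
    stop_io(sprintf("cannot read '%s': no such file", source), file = source)
  }
  if (is_gzip_file(source)) {
    con <- gzfile(source, "rb")
    on.exit(close(con), add = TRUE)
    chunks <- list()
    i <- 0L
    res <- tryCatch({
      repeat {
        raw <- readBin(con, "raw", n = 1048576L)
        if (length(raw) == 0L) break
        i <- i + 1L
        chunks[[i]] <- raw
      }
      rawToChar(unlist(chunks, use.names = FALSE))
    }, error = function(e) {
      stop_compression(sprintf("corrupt gzip stream in '%s': %s",
                               source, conditionMessage(e)), file = source)
    })
    Encoding(res) <- "latin1"
    res
  } else {
    n <- file.size(source)
    raw <- readBin(source, "raw", n = n)
    res <- rawToChar(raw)
    Encoding(res) <- "latin1"
    res
  }
}

is_gzip_file <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Derive the protein identifier of an entry
#'
#' Returns the 4-character idCode from the HEADER record (columns 63--66,
#' uppercased) when present, otherwise the caller-supplied fallback (file
#' stem or sequential-record index). PDB idCodes are case-insensitive; the
#' canonical uppercase form is returned.
#'
#' @param entry_text Full text of one PDB entry.
#' @param fallback Identifier to use when no HEADER idCode is present.
#' @return A single string.
#' @export
derive_protein_id <- function(entry_text, fallback) {
  lines <- split_entry_lines(entry_text)
  derive_protein_id_lines(lines, fallback)
}

derive_protein_id_lines <- function(lines, fallback) {
  h <- lines[startsWith(lines, "HEADER")]
  if (length(h) >= 1L) {
    id <- slice(h[1], 63L, 66L)
    if (nzchar(id)) return(toupper(id))
  }
  toupper(as.character(fallback))
}

split_entry_lines <- function(entry_text) {
  lines <- strsplit(entry_text, "\n", fixed = TRUE)[[1]]
  sub("\r$", "", lines)
}

# ---- per-section schemas ----------------------------------------------------

atom_schema <- function() {
  data.table(proteinId = character(), modelId = integer(),
             recordName = character(), serial = integer(),
             atomName = character(), altLoc = character(),
             resName = character(), chainId = character(),
             resSeq = integer(), iCode = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), tempFactor = numeric(),
             element = character(), charge = character())
}

sheet_schema <- function() {
  data.table(proteinId = character(), strand = integer(), sheetId = character(),
             numStrands = integer(),
             initResName = character(), initChainId = character(),
             initSeqNum = integer(), initICode = character(),
             endResName = character(), endChainId = character(),
             endSeqNum = integer(), endICode = character(),
             sense = integer(),
             curAtom = character(), curResName = character(),
             curChainId = character(), curResSeq = integer(),
             curICode = character(),
             prevAtom = character(), prevResName = character(),
             prevChainId = character(), prevResSeq = integer(),
             prevICode = character())
}

helix_schema <- function() {
  data.table(proteinId = character(), serNum = integer(), helixId = character(),
             initResName = character(), initChainId = character(),
             initSeqNum = integer(), initICode = character(),
             endResName = character(), endChainId = character(),
             endSeqNum = integer(), endICode = character(),
             helixClass = integer(), comment = character(), length = integer())
}

seqres_schema <- function() {
  cols <- c(list(proteinId = character(), serNum = integer(),
                 chainId = character(), numRes = integer()),
            stats::setNames(rep(list(character()), 13L),
                            paste0("resName", 1:13)))
  as.data.table(cols)
}

#' Empty rowset with the column schema of a section kind
#'
#' @param kind One of `"ATOM"`, `"HETATM"`, `"SHEET"`, `"HELIX"`, `"SEQRES"`.
#' @return A zero-row `data.table` with the section's fixed columns.
#' @export
section_schema <- function(kind) {
  kind <- match_section_kind(kind)
  switch(kind,
         ATOM = , HETATM = atom_schema(),
         SHEET = sheet_schema(),
         HELIX = helix_schema(),
         SEQRES = seqres_schema())
}

# ---- per-section vectorised line parsers ------------------------------------
# Each returns list(rows = data.table, bad = logical vector over input lines).

parse_atom_lines <- function(lines, protein_id, model_ids) {
  short <- nchar(lines) < 54L
  serial <- as_int(substr(lines, 7L, 11L))
  resSeq <- as_int(substr(lines, 23L, 26L))
  x <- as_num(substr(lines, 31L, 38L))
  y <- as_num(substr(lines, 39L, 46L))
  z <- as_num(substr(lines, 47L, 54L))
  occ <- opt_num(slice(lines, 55L, 60L))
  tf  <- opt_num(slice(lines, 61L, 66L))
  bad <- short | is.na(serial) | is.na(resSeq) |
    is.na(x) | is.na(y) | is.na(z) | occ$bad | tf$bad
  rows <- data.table(
    proteinId = protein_id,
    modelId = model_ids,
    recordName = slice(lines, 1L, 6L),
    serial = serial,
    atomName = slice(lines, 13L, 16L),
    altLoc = slice(lines, 17L, 17L),
    resName = slice(lines, 18L, 20L),
    chainId = slice(lines, 22L, 22L),
    resSeq = resSeq,
    iCode = slice(lines, 27L, 27L),
    x = x, y = y, z = z,
    occupancy = occ$value,
    tempFactor = tf$value,
    element = slice(lines, 77L, 78L),
    charge = slice(lines, 79L, 80L))
  list(rows = rows, bad = bad)
}

parse_sheet_lines <- function(lines, protein_id) {
  short <- nchar(lines) < 40L
  strand <- as_int(substr(lines, 8L, 10L))
  numStrands <- as_int(substr(lines, 15L, 16L))
  initSeqNum <- as_int(substr(lines, 23L, 26L))
  endSeqNum <- as_int(substr(lines, 34L, 37L))
  sense <- as_int(substr(lines, 39L, 40L))
  curResSeq <- opt_int(slice(lines, 51L, 54L))
  prevResSeq <- opt_int(slice(lines, 66L, 69L))
  bad <- short | is.na(strand) | is.na(numStrands) | is.na(initSeqNum) |
    is.na(endSeqNum) | is.na(sense) | !(sense %in% c(-1L, 0L, 1L)) |
    curResSeq$bad | prevResSeq$bad
  rows <- data.table(
    proteinId = protein_id,
    strand = strand,
    sheetId = slice(lines, 12L, 14L),
    numStrands = numStrands,
    initResName = slice(lines, 18L, 20L),
    initChainId = slice(lines, 22L, 22L),
    initSeqNum = initSeqNum,
    initICode = slice(lines, 27L, 27L),
    endResName = slice(lines, 29L, 31L),
    endChainId = slice(lines, 33L, 33L),
    endSeqNum = endSeqNum,
    endICode = slice(lines, 38L, 38L),
    sense = sense,
    curAtom = slice(lines, 42L, 45L),
    curResName = slice(lines, 46L, 48L),
    curChainId = slice(lines, 50L, 50L),
    curResSeq = curResSeq$value,
    curICode = slice(lines, 55L, 55L),
    prevAtom = slice(lines, 57L, 60L),
    prevResName = slice(lines, 61L, 63L),
    prevChainId = slice(lines, 65L, 65L),
    prevResSeq = prevResSeq$value,
    prevICode = slice(lines, 70L, 70L))
  list(rows = rows, bad = bad)
}

parse_helix_lines <- function(lines, protein_id) {
  short <- nchar(lines) < 40L
  serNum <- as_int(substr(lines, 8L, 10L))
  initSeqNum <- as_int(substr(lines, 22L, 25L))
  endSeqNum <- as_int(substr(lines, 34L, 37L))
  helixClass <- as_int(substr(lines, 39L, 40L))
  len <- opt_int(slice(lines, 72L, 76L))
  bad <- short | is.na(serNum) | is.na(initSeqNum) | is.na(endSeqNum) |
    is.na(helixClass) | len$bad |
    (!is.na(len$value) & len$value < 1L)
  rows <- data.table(
    proteinId = protein_id,
    serNum = serNum,
    helixId = slice(lines, 12L, 14L),
    initResName = slice(lines, 16L, 18L),
    initChainId = slice(lines, 20L, 20L),
    initSeqNum = initSeqNum,
    initICode = slice(lines, 26L, 26L),
    endResName = slice(lines, 28L, 30L),
    endChainId = slice(lines, 32L, 32L),
    endSeqNum = endSeqNum,
    endICode = slice(lines, 38L, 38L),
    helixClass = helixClass,
    comment = slice(lines, 41L, 70L),
    length = len$value)
  list(rows = rows, bad = bad)
}

parse_seqres_lines <- function(lines, protein_id) {
  short <- nchar(lines) < 17L
  serNum <- as_int(substr(lines, 8L, 10L))
  numRes <- as_int(substr(lines, 14L, 17L))
  bad <- short | is.na(serNum) | is.na(numRes)
  rows <- data.table(proteinId = protein_id, serNum = serNum,
                     chainId = slice(lines, 12L, 12L), numRes = numRes)
  # 13 residue-name fields of width 3 starting at column 20, stride 4;
  # unused trailing fields stay empty.
  for (i in 1:13) {
    first <- 20L + 4L * (i - 1L)
    rows[, paste0("resName", i) := slice(lines, first, first + 2L)]
  }
  list(rows = rows, bad = bad)
}

#' Parse one PDB record line into a typed row
#'
#' Fields are sliced at the fixed 1-based column positions of wwPDB format
#' v3.3, trimmed and converted. Blank optional numeric fields (occupancy,
#' temperature factor, helix length) become `NA`.
#'
#' @param line One PDB record line whose record name matches `kind`.
#' @param kind Section kind, see [section_schema()].
#' @param protein_id,model_id Context carried into the row.
#' @return A one-row `data.table`.
#' @export
parse_section_line <- function(line, kind, protein_id = "UNK", model_id = 1L) {
  kind <- match_section_kind(kind)
  parsed <- switch(kind,
    ATOM = , HETATM = parse_atom_lines(line, protein_id, as.integer(model_id)),
    SHEET = parse_sheet_lines(line, protein_id),
    HELIX = parse_helix_lines(line, protein_id),
    SEQRES = parse_seqres_lines(line, protein_id))
  if (parsed$bad[1]) {
    stop_malformed_line(sprintf("malformed %s record: '%s'", kind,
                                substr(line, 1L, 40L)), line = NA_integer_)
  }
  parsed$rows
}

record_name_matches <- function(rec6, kind) {
  switch(kind,
         ATOM = trimws(rec6) == "ATOM",
         HETATM = rec6 == "HETATM",
         trimws(rec6) == kind)
}

#' Extract one section of a PDB entry into a rowset
#'
#' Returns one row per matching record line, in file order. `MODEL n`
#' records update the model context of ATOM/HETATM rows (`modelId = 1`
#' when the entry has no MODEL records, as in single-model X-ray entries).
#' Every row carries the entry's protein identifier (HEADER idCode or the
#' fallback). Non-matching lines are skipped.
#'
#' In strict mode a malformed matching line (too short for its mandatory
#' columns, or non-numeric text in a mandatory numeric column) raises a
#' classed error carrying the line number; in lenient mode such lines are
#' skipped and counted in the `malformed_skipped` attribute of the result.
#'
#' @param entry_text Full text of one PDB entry.
#' @param kind Section kind, see [section_schema()].
#' @param fallback_id Protein identifier used when no HEADER idCode exists.
#' @param strict Fail fast on malformed lines (default) or skip and count.
#' @return A `data.table` with the section's fixed column schema and an
#'   integer attribute `malformed_skipped`.
#' @examples
#' txt <- make_polypeptide(fixture_spec(n_residues = 3, noise_sd = 0))
#' extract_section(txt, "ATOM")
#' @export
extract_section <- function(entry_text, kind, fallback_id = "UNK", strict = TRUE) {
  kind <- match_section_kind(kind)
  lines <- split_entry_lines(entry_text)
  rec <- substr(lines, 1L, 6L)
  protein_id <- derive_protein_id_lines(lines, fallback_id)
  hit <- which(record_name_matches(rec, kind))
  if (length(hit) == 0L) {
    out <- section_schema(kind)
    setattr(out, "malformed_skipped", 0L)
    return(out)
  }

  if (kind %in% c("ATOM", "HETATM")) {
    midx <- which(trimws(rec) == "MODEL")
    if (length(midx)) {
      mser <- as_int(substr(lines[midx], 11L, 14L))
      mser[is.na(mser)] <- seq_along(mser)[is.na(mser)]
      pos <- findInterval(hit, midx)
      model_ids <- ifelse(pos == 0L, 1L, mser[pos])
    } else {
      model_ids <- rep(1L, length(hit))
    }
    parsed <- parse_atom_lines(lines[hit], protein_id, as.integer(model_ids))
  } else {
    parsed <- switch(kind,
      SHEET = parse_sheet_lines(lines[hit], protein_id),
      HELIX = parse_helix_lines(lines[hit], protein_id),
      SEQRES = parse_seqres_lines(lines[hit], protein_id))
  }

  bad <- parsed$bad
  if (any(bad)) {
    if (strict) {
      lineno <- hit[which(bad)[1]]
      stop_malformed_line(
        sprintf("malformed %s record at line %d of entry '%s'",
                kind, lineno, protein_id),
        line = lineno)
    }
    out <- parsed$rows[!bad]
  } else {
    out <- parsed$rows
  }
  setattr(out, "malformed_skipped", sum(bad))
  out
}
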