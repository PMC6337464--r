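# Seeded generator of valid toy PDB entries: ideal-geometry polypeptides
# with configurable chains, models, coordinate noise, layout and
# compression. Chemically naive by design — columns are valid per wwPDB
# v3.3 and the C-alpha geometry is exact, which is what the parsing and
# distance machinery needs; stereochemistry is not emulated.

AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Specification of a synthetic fixture corpus
#'
#' An identical spec (including seed) always produces byte-identical
#' output. C-alpha atoms are placed along a seeded random-walk with fixed
#' step length `spacing`; independent isotropic Gaussian noise of sd
#' `noise_sd` is then added to each C-alpha, so a consecutive displacement
#' is `N(mu, 2 * noise_sd^2 * I3)` with `|mu| = spacing` and the
#' consecutive distance follows the corresponding 3-D noncentral chi law
#' (mean ~ spacing for small noise).
#'
#' @param n_entries Number of entries in the corpus.
#' @param n_residues Residues per chain.
#' @param n_chains Chains per entry (ids `A`, `B`, ...).
#' @param n_models Models per entry (`MODEL`/`ENDMDL` blocks are only
#'   written when > 1; models share the walk but get independent noise).
#' @param spacing Ideal consecutive C-alpha distance in Angstroms
#'   (default 3.81).
#' @param noise_sd Isotropic Gaussian coordinate noise sd in Angstroms
#'   (default 0.02).
#' @param seed Integer seed; all randomness derives from it.
#' @param layout `"individual"` (one file per entry) or `"sequential"`
#'   (entries concatenated into END-delimited sequential files).
#' @param compress Gzip the produced files.
#' @param water Emit one HETATM water per entry (exercises the HETATM
#'   path).
#' @param annotate Emit one HELIX and one SHEET annotation record per
#'   entry when the chain is long enough (exercises those parsers; the
#'   annotations are positional placeholders, not geometric truth).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_entries = 10L, n_residues = 50L, n_chains = 1L,
                         n_models = 1L, spacing = 3.81, noise_sd = 0.02,
                         seed = 42L, layout = c("individual", "sequential"),
                         compress = FALSE, water = TRUE, annotate = TRUE) {
  layout <- match.arg(layout)
  stopifnot(n_entries >= 0, n_residues >= 1, n_chains >= 1, n_chains <= 26,
            n_models >= 1, spacing > 0, noise_sd >= 0,
            n_residues <= 9999,           # resSeq/numRes are 4-column fields
            n_chains * n_residues * 3 + 2 <= 99999)  # serial is 5 columns
  structure(list(n_entries = as.integer(n_entries),
                 n_residues = as.integer(n_residues),
                 n_chains = as.integer(n_chains),
                 n_models = as.integer(n_models),
                 spacing = spacing, noise_sd = noise_sd,
                 seed = as.integer(seed), layout = layout,
                 compress = isTRUE(compress), water = isTRUE(water),
                 annotate = isTRUE(annotate)),
            class = "fixture_spec")
}

# Run expr with a private, derived RNG stream; never disturbs the caller's.
with_derived_seed <- function(seed, entry_index, expr) {
  derived <- (abs(as.numeric(seed)) * 1000003 + entry_index * 7919) %% 2147483629
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(derived))
  expr
}

#' Format one fixed-width ATOM/HETATM record line
#'
#' The fixture writer: emits an 80-column line valid per wwPDB v3.3
#' (atom names of up to 3 characters are placed starting at column 14,
#' the convention for single-character element symbols).
#'
#' @param record_name `"ATOM"` or `"HETATM"`.
#' @param serial Atom serial number.
#' @param atom_name Atom name (e.g. `"CA"`).
#' @param alt_loc Alternate-location indicator (0--1 char).
#' @param res_name Residue name (3 chars).
#' @param chain_id Chain identifier (1 char).
#' @param res_seq Residue sequence number.
#' @param i_code Insertion code (0--1 char).
#' @param x,y,z Coordinates in Angstroms.
#' @param occupancy,temp_factor Occupancy and temperature factor.
#' @param element Element symbol, right-justified over 2 columns.
#' @param charge Charge string (0--2 chars).
#' @return A character vector of formatted lines (vectorised).
#' @export
format_atom_record <- function(record_name, serial, atom_name, alt_loc = "",
                               res_name = "ALA", chain_id = "A", res_seq = 1L,
                               i_code = "", x = 0, y = 0, z = 0,
                               occupancy = 1, temp_factor = 0,
                               element = "C", charge = "") {
  name4 <- ifelse(nchar(atom_name) <= 3L,
                  sprintf(" %-3s", atom_name),
                  sprintf("%-4s", atom_name))
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
          record_name, as.integer(serial), name4,
          substr(paste0(alt_loc, " "), 1L, 1L), res_name, chain_id,
          as.integer(res_seq), substr(paste0(i_code, " "), 1L, 1L),
          x, y, z, occupancy, temp_factor,
          formatC(element, width = 2L), formatC(charge, width = 2L))
}

format_seqres_records <- function(chain_id, res_names) {
  n <- length(res_names)
  rows <- split(res_names, ceiling(seq_len(n) / 13))
  vapply(seq_along(rows), function(i) {
    sprintf("SEQRES %3d %1s %4d  %s", i, chain_id, n,
            paste(rows[[i]], collapse = " "))
  }, character(1))
}

entry_id_code <- function(entry_index) sprintf("9%03X", entry_index %% 4096L)

# Random axis-aligned unit steps (+/- x, y or z). Keeping every step on a
# coordinate axis means positions survive the 0.001-A quantisation of the
# %8.3f ATOM columns exactly, so a noise-free walk parses back to
# consecutive distances equal to the step length (for spacings with at
# most 3 decimals).
random_axis_steps <- function(n) {
  steps <- matrix(0, nrow = n, ncol = 3L)
  steps[cbind(seq_len(n), sample.int(3L, n, replace = TRUE))] <-
    sample(c(-1, 1), n, replace = TRUE)
  steps
}

#' Generate one synthetic polypeptide PDB entry
#'
#' Emits a well-formed entry: HEADER with a synthetic idCode, SEQRES
#' records (13 residue names per line, correct `numRes`), optional
#' HELIX/SHEET annotations, optional MODEL/ENDMDL blocks, `N`/`CA`/`C`
#' ATOM records per residue with consecutive C-alpha spacing
#' `spacing` (+noise), a TER per chain, an optional HETATM water, and END.
#'
#' @param spec A [fixture_spec()].
#' @param entry_index 1-based index of the entry within its corpus (part
#'   of the derived seed, so entries differ but reproducibly so).
#' @return The entry text as one string, newline-terminated.
#' @export
make_polypeptide <- function(spec, entry_index = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_derived_seed(spec$seed, entry_index, {
    id <- entry_id_code(entry_index)
    chains <- LETTERS[seq_len(spec$n_chains)]
    res_names <- lapply(seq_len(spec$n_chains), function(ci) {
      AA20[((entry_index + ci + seq_len(spec$n_residues) - 2L) %% 20L) + 1L]
    })

    lines <- c(sprintf("HEADER    %-40s%9s   %4s",
                       "SYNTHETIC POLYPEPTIDE", "18-SEP-26", id))
    for (ci in seq_len(spec$n_chains)) {
      lines <- c(lines, format_seqres_records(chains[ci], res_names[[ci]]))
    }
    if (spec$annotate && spec$n_residues >= 4L) {
      nr <- spec$n_residues
      lines <- c(lines, sprintf(
        "HELIX  %3d %3s %3s %1s %4d%1s %3s %1s %4d%1s%2d%-30s %5d",
        1L, "H1", res_names[[1]][1], chains[1], 1L, " ",
        res_names[[1]][4], chains[1], 4L, " ", 1L, " SYNTHETIC ANNOTATION", 4L))
      if (nr >= 8L) {
        lines <- c(lines, sprintf(
          "SHEET  %3d %3s%2d %3s %1s%4d%1s %3s %1s%4d%1s%2d",
          1L, "S1", 1L, res_names[[1]][5], chains[1], 5L, " ",
          res_names[[1]][8], chains[1], 8L, " ", 0L))
      }
    }

    # one random walk per chain, shared by all models
    walks <- lapply(seq_len(spec$n_chains), function(ci) {
      start <- c(60 * (ci - 1L), 0, 0)
      if (spec$n_residues == 1L) return(matrix(start, nrow = 1L))
      steps <- random_axis_steps(spec$n_residues - 1L) * spec$spacing
      pos <- rbind(rep(0, 3L), apply(steps, 2L, cumsum))
      sweep(pos, 2L, start, `+`)
    })

    for (m in seq_len(spec$n_models)) {
      if (spec$n_models > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
      serial <- 0L
      for (ci in seq_len(spec$n_chains)) {
        ca <- walks[[ci]]
        if (spec$noise_sd > 0) {
          ca <- ca + matrix(rnorm(length(ca), sd = spec$noise_sd),
                            ncol = 3L)
        }
        nres <- spec$n_residues
        serials <- serial + seq_len(3L * nres)
        rn <- rep(res_names[[ci]], each = 3L)
        rs <- rep(seq_len(nres), each = 3L)
        an <- rep(c("N", "CA", "C"), nres)
        el <- rep(c("N", "C", "C"), nres)
        xyz <- matrix(0, nrow = 3L * nres, ncol = 3L)
        xyz[seq(2L, by = 3L, length.out = nres), ] <- ca
        xyz[seq(1L, by = 3L, length.out = nres), ] <-
          sweep(ca, 2L, c(-1.20, 0.80, 0), `+`)
        xyz[seq(3L, by = 3L, length.out = nres), ] <-
          sweep(ca, 2L, c(0.60, 1.40, 0), `+`)
        lines <- c(lines, format_atom_record(
          "ATOM", serials, an, "", rn, chains[ci], rs, "",
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 20, el, ""))
        serial <- serial + 3L * nres
        lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d ",
                                  serial + 1L, res_names[[ci]][nres],
                                  chains[ci], nres))
        serial <- serial + 1L
      }
      if (spec$water) {
        lines <- c(lines, format_atom_record(
          "HETATM", serial + 1L, "O", "", "HOH", "W", 1L, "",
          30 + entry_index, 30, 30, 1, 0, "O", ""))
      }
      if (spec$n_models > 1L) lines <- c(lines, "ENDMDL")
    }
    lines <- c(lines, "END")
    paste0(paste(lines, collapse = "\n"), "\n")
  })
}

#' Materialise a synthetic fixture corpus on disk
#'
#' Writes `n_entries` entries in the requested layout: `"individual"`
#' produces one `.ent` (or `.ent.gz`) file per entry; `"sequential"`
#' routes the entries through [concat_entries()] into END-delimited
#' sequential files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @param config A [store_config()] controlling sequential-file cutting.
#' @return Character vector of produced file paths.
#' @examples
#' dir <- tempfile()
#' make_corpus(fixture_spec(n_entries = 2, n_residues = 5), dir)
#' @export
make_corpus <- function(spec, out_dir, config = store_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (spec$n_entries == 0L) return(character(0))
  texts <- lapply(seq_len(spec$n_entries), function(i) make_polypeptide(spec, i))
  names <- sprintf("pdb%s.ent", tolower(entry_id_code(seq_len(spec$n_entries))))

  write_one <- function(text, path, gz) {
    con <- if (gz) gzfile(path, "wb") else file(path, "wb")
    writeChar(text, con, eos = NULL)
    close(con)
    path
  }

  if (spec$layout == "individual") {
    ext <- if (spec$compress) ".gz" else ""
    vapply(seq_len(spec$n_entries), function(i) {
      write_one(texts[[i]], file.path(out_dir, paste0(names[i], ext)),
                spec$compress)
    }, character(1))
  } else {
    tmp <- tempfile("corpus_members_")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    members <- vapply(seq_len(spec$n_entries), function(i) {
      write_one(texts[[i]], file.path(tmp, names[i]), FALSE)
    }, character(1))
    cfg <- store_config(max_record_size = config$max_record_size,
                       target_file_size = config$target_file_size,
                       compress = spec$compress)
    concat_entries(members, cfg, out_dir)
  }
}
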