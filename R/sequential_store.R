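# Sequential files: many PDB entries concatenated into one file, each entry
# terminated by its END record. A sequential file is bit-exact with `cat` of
# member files that already end with END; the per-record cap mirrors the
# 4 MB row limit of the original extraction platform.

#' Configuration of the sequential-file store
#'
#' @param max_record_size Maximum decompressed size in bytes of one entry
#'   (record). Default 4 MiB (`4 * 2^20`): records are parsed decompressed,
#'   so the cap applies to decompressed text.
#' @param target_file_size Advisory size at which built sequential files are
#'   cut (always at an entry boundary). Default 64 MiB.
#' @param compress Whether built sequential files are gzip-compressed.
#' @return A list of class `store_config`.
#' @export
store_config <- function(max_record_size = 4L * 2L^20L,
                         target_file_size = 64 * 2^20,
                         compress = FALSE) {
  stopifnot(max_record_size > 0, target_file_size > 0)
  structure(list(max_record_size = as.numeric(max_record_size),
                 target_file_size = as.numeric(target_file_size),
                 compress = isTRUE(compress)),
            class = "store_config")
}

# Decompressed byte size of a file (streamed for gzip inputs).
decompressed_size <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot stat '%s'", path), file = path)
  if (!is_gzip_file(path)) return(as.numeric(file.size(path)))
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  total <- 0
  tryCatch({
    repeat {
      raw <- readBin(con, "raw", n = 1048576L)
      if (length(raw) == 0L) break
      total <- total + length(raw)
    }
  }, error = function(e) {
    stop_compression(sprintf("corrupt gzip stream in '%s'", path), file = path)
  })
  total
}

#' Partition input files by the record size cap
#'
#' Splits a collection into files whose decompressed content fits in one
#' sequential-file record (destined for concatenation) and larger files
#' (to be extracted individually). Size is measured on decompressed content.
#'
#' @param paths Character vector of input file paths.
#' @param config A [store_config()].
#' @return `list(small = ..., large = ...)`; the union is the input, disjoint.
#' @export
partition_inputs <- function(paths, config = store_config()) {
  sizes <- vapply(paths, decompressed_size, numeric(1))
  list(small = paths[sizes <= config$max_record_size],
       large = paths[sizes > config$max_record_size])
}

# TRUE for a line whose first non-space token is exactly "END".
# ENDMDL is a distinct record type and never terminates a record.
is_end_line <- function(line) {
  sub("\\s.*$", "", trimws(line)) == "END"
}

ensure_end_terminated <- function(text) {
  if (!endsWith(text, "\n")) text <- paste0(text, "\n")
  lines <- split_entry_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !is_end_line(lines[length(lines)])) {
    text <- paste0(text, "END\n")
  }
  text
}

#' Concatenate PDB entries into sequential files
#'
#' Entries are appended verbatim in input order; an `END` line is appended
#' to any entry lacking one so iteration can recover every record. Output
#' files are cut at entry boundaries once they reach
#' `config$target_file_size`; with `config$compress` the whole sequential
#' file is gzipped.
#'
#' @param paths Input entry files (plain or gzip), each at most
#'   `config$max_record_size` bytes decompressed.
#' @param config A [store_config()].
#' @param out_dir Output directory (created if needed).
#' @param stem File-name stem of the produced sequential files.
#' @return Character vector of produced sequential file paths.
#' @export
concat_entries <- function(paths, config = store_config(), out_dir = ".",
                           stem = "sequential") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_paths <- character(0)
  buf <- character(0)
  buf_size <- 0
  part <- 0L

  flush <- function() {
    if (length(buf) == 0L) return(invisible())
    part <<- part + 1L
    ext <- if (config$compress) ".ent.gz" else ".ent"
    path <- file.path(out_dir, sprintf("%s_%04d%s", stem, part, ext))
    con <- if (config$compress) gzfile(path, "wb") else file(path, "wb")
    writeChar(paste(buf, collapse = ""), con, eos = NULL)
    close(con)
    out_paths <<- c(out_paths, path)
    buf <<- character(0)
    buf_size <<- 0
  }

  for (p in paths) {
    text <- read_entry_text(p)
    size <- nchar(text, type = "bytes")
    if (size > config$max_record_size) {
      stop_oversize_record(
        sprintf("entry '%s' (%d bytes) exceeds the record cap of %.0f bytes",
                p, size, config$max_record_size), file = p)
    }
    text <- ensure_end_terminated(text)
    buf <- c(buf, text)
    buf_size <- buf_size + nchar(text, type = "bytes")
    if (buf_size >= config$target_file_size) flush()
  }
  flush()
  out_paths
}

#' Iterate the entry records of a sequential file
#'
#' Streams a sequential file (plain or gzip) and yields one record per
#' embedded PDB entry, scanning for delimiter lines whose first token is
#' exactly `END` (`ENDMDL` never terminates a record). Memory stays
#' constant beyond one buffered record. Blank lines between entries are
#' tolerated and ignored.
#'
#' @param source Path to a sequential file (a single ordinary entry file is
#'   simply a one-record sequential file).
#' @param config A [store_config()]; a record growing beyond
#'   `max_record_size` before its END raises a classed oversize error
#'   carrying the record index.
#' @param strict With trailing non-blank text after the last END, strict
#'   mode raises a trailing-data error; lenient mode yields it as a final
#'   record.
#' @param callback Optional `function(record)` invoked per record for true
#'   streaming; when `NULL` all records are collected and returned.
#' @return A list of records — each `list(index, text, byteSize)`, indices
#'   starting at 0 — or (invisibly) the record count when `callback` is
#'   given.
#' @export
iter_records <- function(source, config = store_config(), strict = TRUE,
                         callback = NULL) {
  if (!file.exists(source)) {
    stop_io(sprintf("cannot read '%s': no such file", source), file = source)
  }
  con <- if (is_gzip_file(source)) gzfile(source, "r") else file(source, "r")
  on.exit(close(con), add = TRUE)

  collect <- is.null(callback)
  records <- if (collect) vector("list", 16L) else NULL
  n_rec <- 0L
  buf <- vector("list", 1024L)
  n_buf <- 0L
  buf_bytes <- 0

  emit <- function(lines, bytes) {
    rec <- list(index = n_rec, text = paste0(paste(lines, collapse = "\n"), "\n"),
                byteSize = bytes)
    n_rec <<- n_rec + 1L
    if (collect) {
      if (n_rec > length(records)) length(records) <<- 2L * n_rec
      records[[n_rec]] <<- rec
    } else {
      callback(rec)
    }
  }

  repeat {
    lines <- tryCatch(readLines(con, n = 8192L, encoding = "latin1"),
                      error = function(e) {
                        stop_compression(sprintf("corrupt gzip stream in '%s'",
                                                 source), file = source)
                      })
    if (length(lines) == 0L) break
    for (line in lines) {
      if (n_buf == 0L && !nzchar(trimws(line))) next  # inter-record blank
      n_buf <- n_buf + 1L
      if (n_buf > length(buf)) length(buf) <- 2L * n_buf
      buf[[n_buf]] <- line
      buf_bytes <- buf_bytes + nchar(line, type = "bytes") + 1L
      if (buf_bytes > config$max_record_size) {
        stop_oversize_record(
          sprintf("record %d of '%s' exceeds the cap of %.0f bytes before its END",
                  n_rec, source, config$max_record_size),
          file = source, index = n_rec)
      }
      if (is_end_line(line)) {
        emit(unlist(buf[seq_len(n_buf)], use.names = FALSE), buf_bytes)
        n_buf <- 0L
        buf_bytes <- 0
      }
    }
  }

  if (n_buf > 0L) {
    if (strict) {
      stop_trailing_data(
        sprintf("'%s' has trailing data after the last END record", source),
        file = source)
    }
    emit(unlist(buf[seq_len(n_buf)], use.names = FALSE), buf_bytes)
  }

  if (collect) records[seq_len(n_rec)] else invisible(n_rec)
}
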