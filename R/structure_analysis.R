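# Consecutive C-alpha--C-alpha distances per protein chain, selected by a
# Gaussian fuzzy condition "around 3.81 Angstroms" with a minimum degree of
# truth (lambda-cut).

#' Gaussian fuzzy set "around c Angstroms"
#'
#' The membership function is `mu(x) = exp(-(x - center)^2 / (2 sigma^2))`:
#' 1 at the center, symmetric, strictly decreasing in `|x - center|`. A row
#' is selected when its membership reaches the minimum degree of truth
#' `lambda_cut`.
#'
#' Defaults encode the condition *atomic distance around 3.81 A* with
#' lambda = 0.5. The width sigma = 0.04 A is chosen so that a 3.78 A
#' distance satisfies the condition while a 3.87 A distance does not
#' (mu(3.78) > 0.5 > mu(3.87)); any sigma in (0.0255, 0.0510) A — the
#' half-height half-width being sigma * sqrt(2 ln 2) — has that property,
#' and 0.04 sits in the middle of the range.
#'
#' @param center Center of the fuzzy set in Angstroms (default 3.81, the
#'   ideal consecutive C-alpha spacing of a trans peptide).
#' @param sigma Gaussian width in Angstroms, > 0 (default 0.04).
#' @param lambda_cut Minimum degree of truth in `[0, 1]` (default 0.5).
#' @return A list of class `fuzzy_set`.
#' @examples
#' fs <- fuzzy_set()
#' gaussian_membership(c(3.78, 3.81, 3.87), fs)
#' @export
fuzzy_set <- function(center = 3.81, sigma = 0.04, lambda_cut = 0.5) {
  if (!is.finite(sigma) || sigma <= 0) {
    stop_usage("fuzzy set width sigma must be a positive number")
  }
  if (!is.finite(lambda_cut) || lambda_cut < 0 || lambda_cut > 1) {
    stop_usage("lambda_cut must lie in [0, 1]")
  }
  structure(list(center = center, sigma = sigma, lambda_cut = lambda_cut),
            class = "fuzzy_set")
}

#' Gaussian membership degree
#'
#' @param x Numeric vector of distances in Angstroms.
#' @param fs A [fuzzy_set()].
#' @return Membership degrees in `[0, 1]`.
#' @export
gaussian_membership <- function(x, fs = fuzzy_set()) {
  if (any(!is.finite(x))) stop_usage("membership requires finite distances")
  exp(-(x - fs$center)^2 / (2 * fs$sigma^2))
}

#' Euclidean distance between two points
#'
#' The explicit form `sqrt((x2-x1)^2 + (y2-y1)^2 + (z2-z1)^2)`; identical
#' (to floating tolerance) to the norm form `sqrt(t(p-q) %*% (p-q))`.
#'
#' @param p,q Numeric length-3 coordinate vectors (Angstroms).
#' @return The distance in Angstroms.
#' @export
euclidean_distance <- function(p, q) {
  if (any(!is.finite(p)) || any(!is.finite(q))) {
    stop_usage("euclidean_distance requires finite coordinates")
  }
  sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2 + (q[3] - p[3])^2)
}

#' Consecutive C-alpha distances per chain
#'
#' From an ATOM rowset, takes the C-alpha atoms (atom name `CA`; for
#' alternate locations the first occurrence per residue in file order wins)
#' of each `(proteinId, modelId, chainId)` group in file order and emits
#' one row per adjacent pair. No pair crosses a protein, model or chain
#' boundary; a chain with fewer than two C-alpha atoms emits nothing.
#' Calcium HETATM records (also named `CA`) are excluded because only rows
#' with record name `ATOM` are consumed.
#'
#' Adjacency is file order of the extracted C-alpha atoms, not residue-number
#' arithmetic, so insertion codes and numbering gaps are handled by the
#' sliding window; the `seqGap` column (`resSeqTo - resSeqFrom`) annotates
#' each pair so downstream code can drop pairs spanning missing residues.
#'
#' @param rows An ATOM rowset from [extract_section()] / [extract_many()].
#' @return A `data.table` with columns `proteinId`, `modelId`, `chainId`,
#'   `resSeqFrom`, `resNameFrom`, `resSeqTo`, `resNameTo`, `seqGap`,
#'   `distance` (Angstroms) and `membership` (`NA` until [fuzzy_filter()]).
#' @export
consecutive_ca_distances <- function(rows) {
  recordName <- atomName <- proteinId <- modelId <- chainId <- NULL
  resSeq <- iCode <- x <- y <- z <- resName <- distance <- NULL
  ca <- rows[recordName == "ATOM" & atomName == "CA"]
  empty <- data.table(proteinId = character(), modelId = integer(),
                      chainId = character(), resSeqFrom = integer(),
                      resNameFrom = character(), resSeqTo = integer(),
                      resNameTo = character(), seqGap = integer(),
                      distance = numeric(), membership = numeric())
  if (nrow(ca) == 0L) return(empty)
  # first altLoc in file order per residue
  ca <- unique(ca, by = c("proteinId", "modelId", "chainId", "resSeq", "iCode"))
  out <- ca[, {
    n <- .N
    if (n < 2L) {
      NULL
    } else {
      dx <- diff(x); dy <- diff(y); dz <- diff(z)
      list(resSeqFrom = resSeq[-n], resNameFrom = resName[-n],
           resSeqTo = resSeq[-1L], resNameTo = resName[-1L],
           seqGap = diff(resSeq),
           distance = sqrt(dx^2 + dy^2 + dz^2))
    }
  }, by = c("proteinId", "modelId", "chainId")]
  if (nrow(out) == 0L) return(empty)
  out[, membership := NA_real_]
  out[]
}

#' Fuzzy selection of distance rows
#'
#' Fills the `membership` column with the Gaussian membership degree of
#' each distance and keeps the rows whose membership reaches the minimum
#' degree of truth (`membership >= lambda_cut`; `>=` so that `lambda = 1`
#' keeps exactly the center). Row order is preserved, so the result is the
#' selection report: residue pair context, distance and membership degree.
#'
#' @param rows Distance rows from [consecutive_ca_distances()].
#' @param fs A [fuzzy_set()].
#' @return The selected rows with `membership` filled.
#' @export
fuzzy_filter <- function(rows, fs = fuzzy_set()) {
  membership <- distance <- NULL
  if (!inherits(fs, "fuzzy_set")) fs <- do.call(fuzzy_set, as.list(fs))
  out <- copy(rows)
  out[, membership := gaussian_membership(distance, fs)]
  out[membership >= fs$lambda_cut]
}

#' End-to-end C-alpha distance scan
#'
#' Convenience pipeline behind the `cacadist` CLI subcommand: extract the
#' ATOM section from the inputs, compute per-chain consecutive C-alpha
#' distances, apply the fuzzy selection, and optionally write the report
#' as CSV.
#'
#' @inheritParams extract_many
#' @param fs A [fuzzy_set()].
#' @param output Optional CSV path for the report.
#' @return The selected distance rows (invisibly when `output` is given).
#' @export
ca_distance_scan <- function(inputs, fs = fuzzy_set(),
                             workers = max(1L, parallel::detectCores()),
                             mode = "individual", strict = TRUE,
                             config = store_config(), output = NULL) {
  atoms <- extract_many(inputs, "ATOM", workers = workers, mode = mode,
                        strict = strict, config = config)
  kept <- fuzzy_filter(consecutive_ca_distances(atoms), fs)
  if (!is.null(output)) {
    write_rowset_csv(kept, output)
    return(invisible(kept))
  }
  kept
}
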