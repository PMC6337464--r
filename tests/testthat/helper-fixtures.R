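# Shared helpers: corpus builders in session tempdirs, an independent
# PDB-parser oracle (biopython through the system python, tests only), and
# the closed-form distance law implied by the generator's noise model.

corpus_dir <- function() {
  d <- tempfile("corpus_")
  dir.create(d)
  d
}

local_corpus <- function(...) {
  make_corpus(fixture_spec(...), corpus_dir())
}

# Rowset comparison that ignores the job-report attributes.
expect_same_rows <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}

# Independent oracle: parse ATOM-section fields with Bio.PDB. Returns a
# data.table of (serial, name, chain, resseq, x, y, z) for standard
# residues (hetero flag " "), in file order. Used only in tests; never a
# code path of the package.
oracle_atom_table <- function(path) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from Bio.PDB import PDBParser",
    "s = PDBParser(QUIET=True).get_structure('x', sys.argv[1])",
    "rows = []",
    "for model in s:",
    "    for chain in model:",
    "        for res in chain:",
    "            if res.id[0] != ' ':",
    "                continue",
    "            for atom in res:",
    "                rows.append([int(atom.serial_number), atom.get_name(),",
    "                             chain.id, int(res.id[1]),",
    "                             round(atom.coord[0].item(), 3),",
    "                             round(atom.coord[1].item(), 3),",
    "                             round(atom.coord[2].item(), 3)])",
    "rows.sort(key=lambda r: r[0])",
    "print(json.dumps(rows))"), script)
  out <- system2("python", c(script, path), stdout = TRUE, stderr = FALSE)
  m <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyMatrix = TRUE)
  data.table::data.table(
    serial = as.integer(m[, 1]), name = m[, 2], chain = m[, 3],
    resseq = as.integer(m[, 4]), x = as.numeric(m[, 5]),
    y = as.numeric(m[, 6]), z = as.numeric(m[, 7]))
}

# The generator adds iid isotropic N(0, sd^2 I3) noise to each placed
# C-alpha, so a consecutive displacement is N(mu, 2 sd^2 I3), |mu| =
# spacing, and the distance follows the 3-D noncentral chi law:
# d^2 / (2 sd^2) ~ chi'^2(3, ncp = spacing^2 / (2 sd^2)).
analytic_kept_fraction <- function(spacing, noise_sd, fs) {
  tau2 <- 2 * noise_sd^2
  w <- fs$sigma * sqrt(2 * log(1 / fs$lambda_cut))
  lo <- max(0, fs$center - w)
  hi <- fs$center + w
  stats::pchisq(hi^2 / tau2, df = 3, ncp = spacing^2 / tau2) -
    stats::pchisq(lo^2 / tau2, df = 3, ncp = spacing^2 / tau2)
}

analytic_mean_distance <- function(spacing, noise_sd) {
  tau <- sqrt(2) * noise_sd
  dens <- function(d) {
    (d / spacing) * (1 / (tau * sqrt(2 * pi))) *
      (exp(-(d - spacing)^2 / (2 * tau^2)) - exp(-(d + spacing)^2 / (2 * tau^2)))
  }
  stats::integrate(function(d) d * dens(d), 0, spacing + 20 * tau)$value
}

# Corrupt one entry file: truncate its first ATOM line at column `at`.
truncate_first_atom_line <- function(path, at = 30L) {
  lines <- readLines(path)
  i <- which(startsWith(lines, "ATOM"))[1]
  lines[i] <- substr(lines[i], 1L, at)
  writeLines(lines, path)
  path
}
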