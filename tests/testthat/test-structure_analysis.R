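test_that("the explicit Euclidean form agrees with the norm form and behaves
           like a metric", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(3.81, 0, 0)), 3.81)
  expect_equal(euclidean_distance(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(euclidean_distance(c(0, 0, NA), c(0, 0, 0)),
               class = "pdblake_usage_error")

  set.seed(99)
  for (i in 1:500) {
    p <- stats::rnorm(3, sd = 50); q <- stats::rnorm(3, sd = 50)
    r <- stats::rnorm(3, sd = 50)
    d <- euclidean_distance(p, q)
    norm_form <- sqrt(drop(crossprod(p - q)))       # independent oracle
    expect_equal(d, norm_form, tolerance = 1e-12)
    expect_equal(d, euclidean_distance(q, p))       # symmetry
    expect_gte(d, 0)                                # non-negativity
    expect_lte(d, euclidean_distance(p, r) + euclidean_distance(r, q) + 1e-12)
  }
})

test_that("Gaussian membership matches its closed form and the fuzzy-set
           invariants hold", {
  fs <- fuzzy_set()
  expect_equal(fs$center, 3.81)
  expect_equal(gaussian_membership(3.81, fs), 1.0)
  # frozen closed-form values: exp(-0.03^2 / (2 * 0.04^2)), exp(-0.06^2 / ...)
  expect_equal(gaussian_membership(3.78, fs), 0.75483960, tolerance = 1e-7)
  expect_equal(gaussian_membership(3.87, fs), 0.32465247, tolerance = 1e-7)
  # the default width keeps 3.78 and rejects 3.87 at the default cut
  expect_gte(gaussian_membership(3.78, fs), fs$lambda_cut)
  expect_lte(gaussian_membership(3.87, fs), fs$lambda_cut)

  set.seed(7)
  x <- 3.81 + stats::runif(200, -0.5, 0.5)
  mu <- gaussian_membership(x, fs)
  expect_true(all(mu >= 0 & mu <= 1))
  expect_equal(mu, gaussian_membership(2 * fs$center - x, fs))  # symmetry
  off <- abs(x - fs$center)
  ord <- order(off)
  expect_true(all(diff(mu[ord]) <= 1e-15))        # decays with |x - center|

  expect_error(fuzzy_set(sigma = 0), class = "pdblake_usage_error")
  expect_error(fuzzy_set(lambda_cut = 1.5), class = "pdblake_usage_error")
})

test_that("fuzzy_filter applies the lambda-cut, fills membership and is
           monotone in lambda", {
  rows <- data.table::data.table(
    proteinId = "X", modelId = 1L, chainId = "A",
    resSeqFrom = 1:3, resNameFrom = "ALA", resSeqTo = 2:4, resNameTo = "GLY",
    seqGap = 1L, distance = c(3.81, 3.78, 3.87), membership = NA_real_)
  kept <- fuzzy_filter(rows, fuzzy_set())
  expect_equal(kept$distance, c(3.81, 3.78))      # 3.87 rejected, order kept
  expect_equal(kept$membership,
               gaussian_membership(c(3.81, 3.78), fuzzy_set()))
  expect_equal(nrow(fuzzy_filter(rows, fuzzy_set(lambda_cut = 0))), 3L)
  expect_equal(fuzzy_filter(rows, fuzzy_set(lambda_cut = 1))$distance, 3.81)

  set.seed(13)
  rnd <- rows[sample.int(3L, 60, replace = TRUE)]
  rnd[, distance := 3.81 + stats::rnorm(60, sd = 0.05)]
  lambdas <- sort(stats::runif(8))
  kept_sets <- lapply(lambdas, function(l) {
    fuzzy_filter(rnd, fuzzy_set(lambda_cut = l))$distance
  })
  for (i in seq_len(length(lambdas) - 1L)) {
    expect_true(all(kept_sets[[i + 1L]] %in% kept_sets[[i]]))
  }
})

test_that("consecutive C-alpha distances respect chain, model and protein
           boundaries", {
  ca_row <- function(pid, model, chain, seq, x, alt = "", name = "CA",
                     rec = "ATOM") {
    data.table::data.table(
      proteinId = pid, modelId = model, recordName = rec, serial = 1L,
      atomName = name, altLoc = alt, resName = "ALA", chainId = chain,
      resSeq = seq, iCode = "", x = x, y = 0, z = 0, occupancy = 1,
      tempFactor = 0, element = "C", charge = "")
  }
  rows <- data.table::rbindlist(list(
    ca_row("P1", 1L, "A", 1L, 0), ca_row("P1", 1L, "A", 2L, 3.81),
    ca_row("P1", 1L, "A", 3L, 7.62),
    ca_row("P1", 1L, "B", 1L, 100), ca_row("P1", 1L, "B", 2L, 103.81),
    ca_row("P1", 2L, "A", 1L, 50), ca_row("P1", 2L, "A", 2L, 53.81),
    ca_row("P2", 1L, "A", 1L, 0)))       # lone CA: no pair
  d <- consecutive_ca_distances(rows)
  expect_equal(nrow(d), 4L)              # 2 in P1/1/A, 1 in P1/1/B, 1 in P1/2/A
  expect_equal(d$distance, rep(3.81, 4))
  expect_false(any(d$proteinId == "P2"))
  expect_equal(d[chainId == "A" & modelId == 1L, resSeqFrom], 1:2)

  # altLoc duplicates: first occurrence per residue wins
  dup <- data.table::rbindlist(list(
    ca_row("P3", 1L, "A", 1L, 0, alt = "A"),
    ca_row("P3", 1L, "A", 1L, 0.5, alt = "B"),
    ca_row("P3", 1L, "A", 2L, 3.81, alt = "")))
  dd <- consecutive_ca_distances(dup)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$distance, 3.81)

  # calcium HETATM named CA is excluded; non-CA atoms are ignored
  mixed <- data.table::rbindlist(list(
    ca_row("P4", 1L, "A", 1L, 0),
    ca_row("P4", 1L, "A", 1L, 1, name = "N"),
    ca_row("P4", 1L, "A", 2L, 3.81),
    ca_row("P4", 1L, "A", 99L, 50, rec = "HETATM")))
  dm <- consecutive_ca_distances(mixed)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$distance, 3.81)

  # residue-number gaps are annotated, not dropped
  gap <- data.table::rbindlist(list(
    ca_row("P5", 1L, "A", 1L, 0), ca_row("P5", 1L, "A", 2L, 3.81),
    ca_row("P5", 1L, "A", 7L, 7.62)))
  dg <- consecutive_ca_distances(gap)
  expect_equal(dg$seqGap, c(1L, 5L))

  expect_equal(nrow(consecutive_ca_distances(section_schema("ATOM"))), 0L)
})

test_that("a noise-free generated polypeptide yields n-1 distances equal to
           the spacing, end to end", {
  for (spacing in c(3.81, 3.5)) {
    spec <- fixture_spec(n_entries = 1, n_residues = 12, noise_sd = 0,
                         spacing = spacing, seed = 77)
    paths <- make_corpus(spec, corpus_dir())
    atoms <- extract_many(paths, "ATOM", workers = 1)
    d <- consecutive_ca_distances(atoms)
    expect_equal(nrow(d), 11L)
    expect_equal(d$distance, rep(spacing, 11L))
  }
  # degenerate single-residue chain
  one <- make_polypeptide(fixture_spec(n_residues = 1, seed = 3), 1)
  expect_equal(nrow(consecutive_ca_distances(extract_section(one, "ATOM"))), 0L)
})

test_that("ca_distance_scan writes the selection report", {
  paths <- local_corpus(n_entries = 2, n_residues = 10, noise_sd = 0.02,
                        seed = 19)
  f <- tempfile(fileext = ".csv")
  kept <- ca_distance_scan(paths, fuzzy_set(), workers = 1, output = f)
  tab <- utils::read.csv(f)
  expect_equal(nrow(tab), nrow(kept))
  expect_identical(names(tab),
                   c("proteinId", "modelId", "chainId", "resSeqFrom",
                     "resNameFrom", "resSeqTo", "resNameTo", "seqGap",
                     "distance", "membership"))
  expect_true(all(tab$membership >= 0.5))
})
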